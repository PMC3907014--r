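test_that("CPCA maps exact class subspaces with zero reconstruction error", {
  # class I along e1, class W along e2, symmetric so the global mean is ~0
  tI <- c(-2, -1, 1, 2); tW <- c(-2, -1, 1, 2)
  X <- rbind(cbind(tI, 0, 0), cbind(0, tW, 0))
  lab <- rep(c("I", "W"), each = 4)
  cp <- fit_cpca(X, lab, var_retained = 0.99)
  expect_equal(cp$sub$I$m, 1L)
  expect_equal(cp$sub$W$m, 1L)
  pr <- cpca_project(cp, X)
  expect_identical(pr$branch, lab)
  # own-subspace reconstruction error is zero
  for (i in seq_len(nrow(X))) {
    s <- cp$sub[[lab[i]]]
    z <- X[i, ] - cp$mu - s$center
    expect_equal(sum((z - drop(s$U %*% (t(s$U) %*% z)))^2), 0,
                 tolerance = 1e-20)
  }
})

test_that("CPCA: identical classes tie toward idling; full rank is isometric", {
  set.seed(2)
  base <- matrix(rnorm(40 * 3), 40)
  X <- rbind(base, base)                     # identical class distributions
  lab <- rep(c("I", "W"), each = 40)
  cp <- fit_cpca(X, lab, var_retained = 1)
  expect_true(all(cpca_project(cp, X)$branch == "I"))

  # var_retained = 1 on full-rank data: orthonormal basis, norms preserved
  set.seed(3)
  Xi <- matrix(rnorm(100 * 4), 100)
  li <- rep(c("I", "W"), 50)
  cpi <- fit_cpca(Xi, li, var_retained = 1)
  for (cl in c("I", "W")) {
    U <- cpi$sub[[cl]]$U
    expect_equal(ncol(U), 4)
    expect_equal(t(U) %*% U, diag(4), tolerance = 1e-10)
  }
  Z <- sweep(Xi, 2, cpi$mu)
  expect_equal(rowSums((Z %*% cpi$sub$I$U)^2), rowSums(Z^2),
               tolerance = 1e-10)
})

test_that("discriminant recovers the Fisher direction and matches LDA", {
  set.seed(4)
  n <- 2000
  X <- rbind(matrix(rnorm(n / 2 * 3), ncol = 3) +
               matrix(c(-1, 0, 0), n / 2, 3, byrow = TRUE),
             matrix(rnorm(n / 2 * 3), ncol = 3) +
               matrix(c(1, 0, 0), n / 2, 3, byrow = TRUE))
  lab <- rep(c("I", "W"), each = n / 2)
  w <- fit_aida(X, lab)
  ang <- acos(min(1, abs(sum(w * c(1, 0, 0))))) * 180 / pi
  expect_lt(ang, 5)
  # equal-covariance case: AIDA and LDA agree in direction
  wl <- fit_aida(X, lab, method = "lda")
  expect_gt(abs(sum(as.numeric(w) * as.numeric(wl))), 0.99)
  # orientation: walking mean projects higher
  expect_gt(mean(X[lab == "W", ] %*% as.numeric(w)),
            mean(X[lab == "I", ] %*% as.numeric(w)))
})

test_that("shuffled labels give an objective typical of the permutation null", {
  set.seed(5)
  X <- matrix(rnorm(300 * 3), 300)
  lab0 <- rep(c("I", "W"), 150)
  obj <- function(l) attr(fit_aida(X, l), "objective")
  shuffled <- sample(lab0)
  v <- obj(shuffled)
  null <- replicate(200, obj(sample(lab0)))
  p <- mean(null >= v)
  expect_gt(p, 0.05)

  # zero between-class scatter errors out (equal class means)
  Xd <- rbind(diag(2), -diag(2), diag(2), -diag(2))
  expect_error(fit_aida(Xd, rep(c("I", "W"), each = 4)),
               "indistinguishable")
})

test_that("extract_feature is the piecewise linear composition", {
  set.seed(6)
  X <- rbind(matrix(rnorm(50 * 4, sd = 1), 50) - 2,
             matrix(rnorm(50 * 4, sd = 1), 50) + 2)
  lab <- rep(c("I", "W"), each = 50)
  m <- fit_feature_model(X, lab, var_retained = 1, method = "lda")
  # class mean maps to its transformed mean
  muW <- colMeans(X[lab == "W", ])
  pr <- cpca_project(m$cpca, muW)
  f_manual <- sum(pr$coords[[1]] * as.numeric(m$w[[pr$branch[1]]]))
  expect_equal(extract_feature(muW, m), f_manual)
  # linearity within a branch: scaling the centered datum scales f
  z <- X[3, ] - m$cpca$mu
  f1 <- extract_feature(matrix(m$cpca$mu + z, 1), m)
  f2 <- extract_feature(matrix(m$cpca$mu + 2 * z, 1), m)
  expect_equal(f2, 2 * f1, tolerance = 1e-8)
  # the globally centered origin maps to a branch-linear 0
  pr0 <- cpca_project(m$cpca, m$cpca$mu)
  expect_equal(sum(pr0$coords[[1]] * as.numeric(m$w[[pr0$branch[1]]])),
               extract_feature(matrix(m$cpca$mu, 1), m))
  expect_equal(extract_feature(matrix(m$cpca$mu, 1), m), 0,
               tolerance = 1e-10)
})

test_that("Bayes classifier follows the posterior rule with ties to walking", {
  set.seed(7)
  f <- c(rnorm(500, -1), rnorm(500, 1))
  lab <- rep(c("I", "W"), each = 500)
  clf <- fit_bayes(f, lab, priors = c(I = 0.5, W = 0.5))
  # symmetric classes with equal priors: posterior at the midpoint is ~0.5
  mid <- (clf$I$mean + clf$W$mean) / 2
  expect_equal(posterior_walk(clf, mid), 0.5, tolerance = 0.05)
  # monotone in f
  g <- seq(-4, 4, by = 0.25)
  expect_true(all(diff(posterior_walk(clf, g)) > 0))
  # empirical priors
  clf2 <- fit_bayes(c(rnorm(30, -1), rnorm(70, 1)),
                    rep(c("I", "W"), c(30, 70)))
  expect_equal(clf2$I$prior, 0.3)
  expect_equal(clf2$W$prior, 0.7)
  # exact tie classifies as walking (the printed "otherwise" branch)
  clf3 <- structure(list(I = list(mean = -1, sd = 1, prior = 0.5),
                         W = list(mean = 1, sd = 1, prior = 0.5)),
                    class = "bayes_classifier")
  expect_identical(classify(0, clf3), "W")
  expect_identical(classify(c(-3, 3), clf3), c("I", "W"))
})

test_that("cross-validation is stratified and hits the expected accuracies", {
  set.seed(8)
  # perfectly separable
  Xs <- rbind(matrix(rnorm(100 * 2, sd = 0.1), 100) - 3,
              matrix(rnorm(100 * 2, sd = 0.1), 100) + 3)
  ls <- rep(c("I", "W"), each = 100)
  expect_equal(crossvalidate(Xs, ls, seed = 1)$mean, 100)
  # chance level on identical distributions, n = 400
  Xc <- matrix(rnorm(400 * 3), 400)
  lc <- rep(c("I", "W"), 200)
  cv <- crossvalidate(Xc, lc, seed = 2)
  expect_gt(cv$mean, 40); expect_lt(cv$mean, 60)
  expect_equal(sum(cv$confusion), 400)
  # stratification: every fold's class split is balanced within one sample
  folds <- gaitbci:::.stratified_folds(lc, 10, seed = 3)
  tab <- table(folds, lc)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))
})

test_that("CV accuracy is invariant to channel permutation of the features", {
  tr <- fx_training()
  win <- prepare_training_windows(tr$rec, tr$cues)
  pgs <- gaitbci:::.segment_periodograms(win$segments[1:200], win$rate)
  X <- gaitbci:::.band_feature_matrix(pgs, c(8, 12))
  lab <- win$labels[1:200]
  a1 <- crossvalidate(X, lab, k = 5, seed = 4)$mean
  # permute channels = permute the B-sized column blocks
  B <- 2; C <- ncol(X) / B
  set.seed(9); perm <- sample(C)
  cols <- as.numeric(vapply(perm, function(c) (c - 1) * B + seq_len(B),
                            numeric(B)))
  a2 <- crossvalidate(X[, cols], lab, k = 5, seed = 4)$mean
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("band search expands over the informative band and stops on noise", {
  tr <- fx_training()
  win <- prepare_training_windows(tr$rec, tr$cues)
  # subsample windows for speed, keeping both classes
  idx <- seq(1, length(win$segments), by = 2)
  win_s <- list(segments = win$segments[idx], labels = win$labels[idx],
                rate = win$rate, channel_names = win$channel_names)
  opt <- optimize_band(win_s, seed_band = c(8, 10), k = 5, seed = 5)
  expect_lte(opt$band[1], 8)
  expect_gte(opt$band[2], 12)
  expect_gt(opt$report$mean, 85)

  # pure-noise labels: no extension improves by > 0.5 pp
  trn <- fx_training_null()
  winn <- prepare_training_windows(trn$rec, trn$cues)
  idxn <- seq(1, length(winn$segments), by = 4)
  winn_s <- list(segments = winn$segments[idxn], labels = winn$labels[idxn],
                 rate = winn$rate, channel_names = winn$channel_names)
  # on pure noise the plateau is flat up to CV sampling noise: the greedy
  # stays at or near the seed band and never finds real structure
  optn <- optimize_band(winn_s, seed_band = c(8, 10), k = 5, seed = 5)
  expect_lte(optn$band[2] - optn$band[1], 8)
  expect_gt(optn$report$mean, 40); expect_lt(optn$report$mean, 62)
})

test_that("greedy search returns one contiguous band with two disjoint sources", {
  # windows built directly: white background, class W adds band-limited
  # power at 10-12 Hz and 24-26 Hz
  set.seed(10)
  rate <- 128; wlen <- 96
  mk_seg <- function(walk) {
    bg <- matrix(rnorm(4 * wlen), 4)
    if (walk) {
      for (ch in 1:2) {
        add <- gaitbci:::.band_noise(wlen, rate, c(10, 12)) * 0.7 +
          gaitbci:::.band_noise(wlen, rate, c(24, 26)) * 0.7
        bg[ch, ] <- bg[ch, ] + add
      }
    }
    bg
  }
  segments <- lapply(rep(c(FALSE, TRUE), 80), mk_seg)
  labels <- rep(c("I", "W"), 80)
  win <- list(segments = segments, labels = labels, rate = rate,
              channel_names = paste0("ch", 1:4))
  opt <- optimize_band(win, seed_band = c(8, 10), k = 5, seed = 6)
  covers <- function(b, lo, hi) b[1] <= lo && b[2] >= hi
  expect_true(covers(opt$band, 10, 12) || covers(opt$band, 24, 26))
  expect_equal(opt$band[2] - opt$band[1],
               2 * round((opt$band[2] - opt$band[1]) / 2))
})

test_that("salience map peaks on the modulated channels and band", {
  model <- fx_model()
  maps <- salience_map(model$model, n_bins = model$n_bins,
                       channel_names = model$channels)
  mod_names <- gaitbci:::.synth_channel_names(16)[1:4]
  for (cl in c("I", "W")) {
    peak <- which(maps[[cl]] == max(maps[[cl]]), arr.ind = TRUE)
    expect_true(model$channels[peak[1, "col"]] %in% mod_names)
  }
})

test_that("models round-trip through the JSON bundle", {
  model <- fx_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  m2 <- read_model(f)
  expect_equal(m2$band, model$band)
  expect_identical(m2$channels, model$channels)
  set.seed(12)
  d <- matrix(rnorm(5 * length(model$model$cpca$mu)), 5)
  expect_equal(extract_feature(d, m2$model), extract_feature(d, model$model),
               tolerance = 1e-12)
  expect_equal(predict_posterior(d, m2$model),
               predict_posterior(d, model$model), tolerance = 1e-12)
})
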