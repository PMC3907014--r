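#' Classwise principal component analysis
#'
#' Fits one PCA subspace per class on globally centered feature vectors; the
#' resulting piecewise-linear map projects a vector onto the subspace of the
#' class that reconstructs it best (smallest class-centered reconstruction
#' error). Ties are broken toward the idling class.
#'
#' @param X numeric matrix, samples x features (flattened B x C band powers).
#' @param labels factor/character vector of \code{"I"}/\code{"W"} (or
#'   \code{"IDLE"}/\code{"WALK"}) class labels, one per row of \code{X}.
#' @param var_retained fraction of per-class variance to retain, in (0, 1]
#'   (default 0.9).
#' @return An object of class \code{cpca}: global mean \code{mu}, per-class
#'   list \code{sub} with basis \code{U} (features x m_c), class mean
#'   \code{center}, retained dimension \code{m}.
#' @export
fit_cpca <- function(X, labels, var_retained = 0.9) {
  X <- as.matrix(X)
  labels <- .norm_labels(labels)
  if (var_retained <= 0 || var_retained > 1)
    stop("'var_retained' must be in (0, 1]")
  counts <- table(labels)
  if (length(counts) != 2L || any(counts < 2L))
    stop("need at least 2 samples in each of the two classes")
  mu <- colMeans(X)
  Z <- sweep(X, 2, mu)
  sub <- lapply(c(I = "I", W = "W"), function(cl) {
    Zc <- Z[labels == cl, , drop = FALSE]
    ctr <- colMeans(Zc)
    Zcc <- sweep(Zc, 2, ctr)
    sv <- svd(Zcc)
    ev <- sv$d^2
    nz <- ev > max(ev, .Machine$double.eps) * 1e-10
    ev <- ev[nz]
    if (length(ev) == 0L) {
      warning("class ", cl, " has zero variance; retaining one component")
      return(list(U = sv$v[, 1, drop = FALSE], center = ctr, m = 1L))
    }
    cum <- cumsum(ev) / sum(ev)
    m <- which(cum >= var_retained - 1e-12)[1]
    if (is.na(m)) {
      warning("var_retained unreachable for class ", cl,
              "; retaining all nonzero components")
      m <- length(ev)
    }
    list(U = sv$v[, seq_len(m), drop = FALSE], center = ctr, m = m)
  })
  structure(list(mu = mu, sub = sub), class = "cpca")
}

.norm_labels <- function(labels) {
  l <- toupper(as.character(labels))
  l[l %in% c("IDLE", "IDLING")] <- "I"
  l[l %in% c("WALK", "WALKING")] <- "W"
  if (!all(l %in% c("I", "W")))
    stop("labels must be I/IDLE or W/WALK")
  l
}

# class assignment of globally-centered rows Z by minimum class-centered
# reconstruction error; ties toward "I"
.cpca_assign <- function(cpca, Z) {
  err <- vapply(c("I", "W"), function(cl) {
    s <- cpca$sub[[cl]]
    Zc <- sweep(Z, 2, s$center)
    R <- Zc - (Zc %*% s$U) %*% t(s$U)
    rowSums(R^2)
  }, numeric(nrow(Z)))
  err <- matrix(err, nrow = nrow(Z))
  ifelse(err[, 1] <= err[, 2] + 1e-12, "I", "W")
}

#' Apply the piecewise CPCA map
#'
#' Centers rows of \code{X} with the training mean, assigns each to the class
#' subspace with the smallest reconstruction error, and projects it there.
#' The projection itself is linear (no offset): \code{U_c' (x - mu)}.
#'
#' @param cpca a fitted \code{\link{fit_cpca}} object.
#' @param X samples x features matrix (or a single vector).
#' @return List with \code{branch} (assigned class per row) and
#'   \code{coords} (list of projected coordinate vectors, lengths may differ
#'   between branches).
#' @export
cpca_project <- function(cpca, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Z <- sweep(as.matrix(X), 2, cpca$mu)
  branch <- .cpca_assign(cpca, Z)
  coords <- lapply(seq_len(nrow(Z)), function(i) {
    drop(Z[i, , drop = FALSE] %*% cpca$sub[[branch[i]]]$U)
  })
  list(branch = branch, coords = coords)
}

#' One-dimensional information discriminant
#'
#' Learns the unit row vector that maps the m-dimensional subspace features
#' to a single discriminative scalar. The default objective is the Gaussian
#' approximation of the mutual information between the projected feature and
#' the class label,
#' \deqn{J(w) = \tfrac12\log(w' S_T w) - \tfrac12\sum_c p_c \log(w'\Sigma_c w),}
#' with \eqn{S_T} the total scatter and \eqn{\Sigma_c} the class covariances,
#' maximized quasi-Newton from the Fisher direction. \code{method = "lda"}
#' selects the closed-form Fisher discriminant instead; in the
#' equal-covariance two-Gaussian case both coincide.
#'
#' @param X samples x m feature matrix.
#' @param labels class labels (\code{I}/\code{W}).
#' @param method \code{"aida"} (default) or \code{"lda"}.
#' @return Unit-norm numeric vector of length m, oriented so that the
#'   walking-class mean projects higher; attribute \code{"objective"} holds
#'   the attained objective value.
#' @export
fit_aida <- function(X, labels, method = c("aida", "lda")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  labels <- .norm_labels(labels)
  mI <- colMeans(X[labels == "I", , drop = FALSE])
  mW <- colMeans(X[labels == "W", , drop = FALSE])
  dmu <- mW - mI
  p <- c(I = mean(labels == "I"), W = mean(labels == "W"))
  SI <- stats::cov(X[labels == "I", , drop = FALSE])
  SW <- stats::cov(X[labels == "W", , drop = FALSE])
  Sw <- p[["I"]] * SI + p[["W"]] * SW
  if (sqrt(sum(dmu^2)) <= 1e-10 * (1 + sqrt(sum(diag(Sw)))))
    stop("classes indistinguishable: zero between-class scatter")
  ridge <- diag(ncol(X)) * max(diag(Sw), .Machine$double.eps) * 1e-8
  w0 <- drop(solve(Sw + ridge, dmu))
  if (method == "lda") {
    w <- w0
  } else {
    ST <- stats::cov(X)
    obj <- function(w) {
      a <- drop(t(w) %*% ST %*% w)
      bI <- drop(t(w) %*% SI %*% w)
      bW <- drop(t(w) %*% SW %*% w)
      if (a <= 0 || bI <= 0 || bW <= 0) return(1e10)
      -(0.5 * log(a) - 0.5 * (p[["I"]] * log(bI) + p[["W"]] * log(bW)))
    }
    grad <- function(w) {
      STw <- ST %*% w; SIw <- SI %*% w; SWw <- SW %*% w
      a <- drop(t(w) %*% STw); bI <- drop(t(w) %*% SIw)
      bW <- drop(t(w) %*% SWw)
      -drop(STw / a - p[["I"]] * SIw / bI - p[["W"]] * SWw / bW)
    }
    fit <- stats::optim(w0 / sqrt(sum(w0^2)), obj, grad, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-12))
    w <- fit$par
  }
  w <- w / sqrt(sum(w^2))
  if (sum(w * dmu) < 0) w <- -w
  aval <- {
    a <- drop(t(w) %*% stats::cov(X) %*% w)
    bI <- drop(t(w) %*% SI %*% w); bW <- drop(t(w) %*% SW %*% w)
    0.5 * log(a) - 0.5 * (p[["I"]] * log(bI) + p[["W"]] * log(bW))
  }
  structure(w, objective = aval)
}

#' Univariate Gaussian Bayesian classifier
#'
#' Fits per-class Gaussians to the scalar discriminant feature and applies
#' Bayes' rule. Priors default to the empirical class frequencies.
#'
#' @param f numeric vector of scalar features.
#' @param labels class labels.
#' @param priors optional named numeric \code{c(I = , W = )}; normalized to
#'   sum to 1.
#' @return An object of class \code{bayes_classifier} with per-class
#'   \code{mean}, \code{sd} and \code{prior}.
#' @export
fit_bayes <- function(f, labels, priors = NULL) {
  labels <- .norm_labels(labels)
  if (is.null(priors))
    priors <- c(I = mean(labels == "I"), W = mean(labels == "W"))
  priors <- priors[c("I", "W")] / sum(priors)
  par <- lapply(c(I = "I", W = "W"), function(cl) {
    x <- f[labels == cl]
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) s <- .Machine$double.eps^0.25
    list(mean = mean(x), sd = s)
  })
  structure(list(I = c(par$I, prior = unname(priors["I"])),
                 W = c(par$W, prior = unname(priors["W"]))),
            class = "bayes_classifier")
}

#' Posterior probability of the walking class
#' @param clf a \code{bayes_classifier}.
#' @param f scalar feature value(s).
#' @return \code{P(W | f)} in [0, 1].
#' @export
posterior_walk <- function(clf, f) {
  lI <- stats::dnorm(f, clf$I$mean, clf$I$sd, log = TRUE) + log(clf$I$prior)
  lW <- stats::dnorm(f, clf$W$mean, clf$W$sd, log = TRUE) + log(clf$W$prior)
  1 / (1 + exp(pmin(700, pmax(-700, lI - lW))))
}

#' Classify a scalar feature
#'
#' Returns \code{"I"} iff \code{P(I|f) > P(W|f)}, otherwise \code{"W"}
#' (ties go to walking).
#'
#' @param f scalar feature value(s).
#' @param clf a \code{bayes_classifier}.
#' @return Character vector of \code{"I"}/\code{"W"}.
#' @export
classify <- function(f, clf) {
  pw <- posterior_walk(clf, f)
  ifelse(1 - pw > pw, "I", "W")
}

# ---------------------------------------------------------------------------
# Full model
# ---------------------------------------------------------------------------

#' Train the full prediction model on labelled feature windows
#'
#' Pipeline: global mean centering, classwise PCA, one discriminant per class
#' subspace (fit on all training data projected into that subspace, oriented
#' so walking projects higher), then a univariate Gaussian Bayes classifier
#' on the pooled scalar features.
#'
#' @param X samples x (B*C) matrix of (log) band powers.
#' @param labels class labels.
#' @param var_retained CPCA variance fraction (default 0.9).
#' @param method discriminant method, \code{"aida"} or \code{"lda"}.
#' @param priors optional classifier priors.
#' @return An object of class \code{feature_model} with elements
#'   \code{cpca}, \code{w} (per-branch unit discriminants), \code{clf}.
#' @export
fit_feature_model <- function(X, labels, var_retained = 0.9,
                              method = c("aida", "lda"), priors = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  labels <- .norm_labels(labels)
  cp <- fit_cpca(X, labels, var_retained)
  Z <- sweep(X, 2, cp$mu)
  w <- lapply(c(I = "I", W = "W"), function(cl) {
    Y <- Z %*% cp$sub[[cl]]$U
    fit_aida(Y, labels, method = method)
  })
  model <- structure(list(cpca = cp, w = w, clf = NULL, method = method),
                     class = "feature_model")
  f <- extract_feature(X, model)
  model$clf <- fit_bayes(f, labels, priors)
  model
}

#' Extract the scalar discriminant feature (f = T_A Phi_C(d))
#'
#' @param d a single flattened feature vector, or a samples x features
#'   matrix.
#' @param model a \code{feature_model} (or a list with \code{cpca} and
#'   \code{w}).
#' @return Numeric vector of scalar features.
#' @export
extract_feature <- function(d, model) {
  pr <- cpca_project(model$cpca, d)
  vapply(seq_along(pr$coords), function(i) {
    sum(pr$coords[[i]] * as.numeric(model$w[[pr$branch[i]]]))
  }, numeric(1))
}

#' Posterior P(W|d) for raw feature vectors under a feature model
#' @param d feature vector or matrix.
#' @param model a \code{feature_model}.
#' @return numeric vector of posteriors.
#' @export
predict_posterior <- function(d, model) {
  posterior_walk(model$clf, extract_feature(d, model))
}

#' Salient-feature map
#'
#' Renders, per class branch, the absolute weight each channel/bin carries in
#' the composed linear map \code{T_A' U_c'}, normalized to max 1. High values
#' mark the spatio-spectral features that drive the discriminant.
#'
#' @param model a \code{feature_model}.
#' @param n_bins number of frequency bins B (rows of the map).
#' @param channel_names optional channel labels (length C).
#' @return Named list (one B x C matrix per class).
#' @export
salience_map <- function(model, n_bins, channel_names = NULL) {
  out <- list()
  for (cl in c("I", "W")) {
    v <- abs(drop(model$cpca$sub[[cl]]$U %*% as.numeric(model$w[[cl]])))
    m <- matrix(v / max(v, .Machine$double.eps), nrow = n_bins)
    if (!is.null(channel_names)) colnames(m) <- channel_names
    out[[cl]] <- m
  }
  out
}

# ---------------------------------------------------------------------------
# Cross-validation
# ---------------------------------------------------------------------------

# stratified fold assignment: per class, shuffled round-robin
.stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Each fold refits centering, CPCA, the discriminants and the Bayes
#' classifier on the remaining folds and scores the held-out fold.
#'
#' @param X samples x features matrix.
#' @param labels class labels.
#' @param k number of folds (default 10).
#' @param var_retained,method passed to \code{\link{fit_feature_model}}.
#' @param seed RNG seed for the fold assignment (recorded in the report).
#' @return An object of class \code{cv_report}: \code{fold_accuracy} (k
#'   values, percent), \code{mean}, \code{sd}, \code{confusion} (2x2 counts),
#'   \code{seed}, \code{k}.
#' @export
crossvalidate <- function(X, labels, k = 10, var_retained = 0.9,
                          method = c("aida", "lda"), seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  labels <- .norm_labels(labels)
  fold <- .stratified_folds(labels, k, seed)
  acc <- numeric(k)
  conf <- matrix(0L, 2, 2, dimnames = list(truth = c("I", "W"),
                                           pred = c("I", "W")))
  for (j in seq_len(k)) {
    tr <- fold != j; te <- fold == j
    m <- fit_feature_model(X[tr, , drop = FALSE], labels[tr],
                           var_retained = var_retained, method = method)
    pred <- classify(extract_feature(X[te, , drop = FALSE], m), m$clf)
    acc[j] <- 100 * mean(pred == labels[te])
    tb <- table(factor(labels[te], c("I", "W")), factor(pred, c("I", "W")))
    conf <- conf + tb
  }
  structure(list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
                 confusion = conf, seed = seed, k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV accuracy: %.1f%% +/- %.1f%%\n",
              x$k, x$mean, x$sd))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Training from raw epochs and band optimization
# ---------------------------------------------------------------------------

#' Cut cue epochs into fixed-length training windows
#'
#' Slices the recording by cues and cuts each epoch into non-overlapping
#' windows of \code{win} seconds, the same length the online decoder uses.
#'
#' @param rec an \code{eeg_recording} (already channel-screened).
#' @param cues a \code{cue_schedule}.
#' @param win window length in seconds (default 0.75).
#' @return List with \code{segments} (list of channels x samples matrices),
#'   \code{labels}, \code{rate}, \code{channel_names}.
#' @export
prepare_training_windows <- function(rec, cues, win = 0.75) {
  ep <- epoch_by_cues(rec, cues)
  wlen <- round(win * rec$rate)
  segments <- list(); labels <- character(0)
  for (e in ep) {
    n <- ncol(e$rec$samples)
    nw <- n %/% wlen
    for (j in seq_len(nw)) {
      segments[[length(segments) + 1L]] <-
        e$rec$samples[, ((j - 1) * wlen + 1):(j * wlen), drop = FALSE]
      labels <- c(labels, e$label)
    }
  }
  list(segments = segments, labels = .norm_labels(labels), rate = rec$rate,
       channel_names = rec$channel_names)
}

# full-spectrum periodograms for a list of equal-length segments (cached by
# optimize_band); returns list(freq, psd = 3-d array nfreq x C x nseg)
.segment_periodograms <- function(segments, rate) {
  pg1 <- .periodogram(segments[[1]], rate)
  arr <- array(0, c(length(pg1$freq), ncol(pg1$psd), length(segments)))
  arr[, , 1] <- pg1$psd
  for (i in seq_along(segments)[-1])
    arr[, , i] <- .periodogram(segments[[i]], rate)$psd
  list(freq = pg1$freq, psd = arr, rate_over_n = rate / ncol(segments[[1]]))
}

# integrate cached periodograms over a band -> samples x (B*C) matrix of
# log10 band powers (log transform Gaussianizes band power; config flag)
.band_feature_matrix <- function(pgs, band, bin_width = 2, log_power = TRUE,
                                 floor = 1e-12) {
  edges <- seq(band[1], band[2], by = bin_width)
  nseg <- dim(pgs$psd)[3]
  B <- length(edges) - 1L; C <- dim(pgs$psd)[2]
  out <- matrix(0, nseg, B * C)
  sel <- lapply(seq_len(B), function(b)
    which(pgs$freq >= edges[b] - 1e-9 & pgs$freq < edges[b + 1] - 1e-9))
  for (i in seq_len(nseg)) {
    m <- vapply(sel, function(s)
      colSums(pgs$psd[s, , i, drop = FALSE]) * pgs$rate_over_n, numeric(C))
    out[i, ] <- as.numeric(t(m))  # B x C flattened bin-major
  }
  if (log_power) out <- log10(out + floor)
  out
}

#' Greedy optimization of the analysis frequency band
#'
#' Starting from a seed band, repeatedly extends the lower bound (2-Hz steps
#' down to a 0.5-Hz floor) or the upper bound (up to 40 Hz), whichever
#' improves the mean cross-validated accuracy most, stopping when neither
#' improves by more than \code{tol_pp} percentage points. The search is
#' greedy and contiguous by construction.
#'
#' @param windows output of \code{\link{prepare_training_windows}}.
#' @param seed_band starting \code{c(F_L, F_H)} (default \code{c(8, 10)}).
#' @param k,var_retained,method,seed cross-validation settings.
#' @param tol_pp minimum improvement, percentage points (default 0.5).
#' @param f_floor,f_ceiling hard band limits (0.5 and 40 Hz).
#' @param log_power log-transform band powers before modelling.
#' @return List with \code{band}, \code{report} (best \code{cv_report}) and
#'   \code{trace} (data frame of bands tried).
#' @export
optimize_band <- function(windows, seed_band = c(8, 10), k = 10,
                          var_retained = 0.9, method = "aida", seed = 1L,
                          tol_pp = 0.5, f_floor = 0.5, f_ceiling = 40,
                          log_power = TRUE) {
  rate <- windows$rate
  f_ceiling <- min(f_ceiling, rate / 2)
  if (seed_band[2] - seed_band[1] < 2)
    stop("seed band must contain at least one 2-Hz bin")
  pgs <- .segment_periodograms(windows$segments, rate)
  labels <- windows$labels
  cache <- new.env(parent = emptyenv())
  eval_band <- function(band) {
    key <- paste(band, collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    X <- .band_feature_matrix(pgs, band, log_power = log_power)
    r <- crossvalidate(X, labels, k = k, var_retained = var_retained,
                       method = method, seed = seed)
    cache[[key]] <- r
    r
  }
  lower_next <- function(fl) if (fl - 2 >= f_floor + 1.5) fl - 2 else
    if (fl > f_floor) f_floor else NA_real_
  band <- seed_band
  best <- eval_band(band)
  trace <- data.frame(f_lo = band[1], f_hi = band[2], acc = best$mean)
  repeat {
    cand <- list()
    fl2 <- lower_next(band[1])
    if (!is.na(fl2)) cand$lo <- c(fl2, band[2])
    if (band[2] + 2 <= f_ceiling + 1e-9) cand$hi <- c(band[1], band[2] + 2)
    if (length(cand) == 0L) break
    reps <- lapply(cand, eval_band)
    accs <- vapply(reps, function(r) r$mean, numeric(1))
    for (i in seq_along(cand))
      trace <- rbind(trace, data.frame(f_lo = cand[[i]][1],
                                       f_hi = cand[[i]][2], acc = accs[i]))
    j <- which.max(accs)
    if (accs[j] > best$mean + tol_pp) {
      band <- cand[[j]]; best <- reps[[j]]
    } else break
  }
  list(band = band, report = best, trace = trace)
}

#' Train a complete EEG prediction model from a recording and cues
#'
#' End-to-end offline training: artifact-channel screening, windowing,
#' band-power feature extraction (optionally with greedy band optimization),
#' CPCA + discriminant + Bayes classifier fit on all windows, and a final
#' cross-validation report.
#'
#' @param rec an \code{eeg_recording}.
#' @param cues a \code{cue_schedule}.
#' @param band analysis band \code{c(F_L, F_H)}; ignored when
#'   \code{optimize = TRUE}.
#' @param optimize run \code{\link{optimize_band}} (default FALSE).
#' @param z_thresh artifact screen threshold.
#' @param var_retained,method,k,seed,log_power model settings.
#' @param ... passed to \code{\link{optimize_band}}.
#' @return An object of class \code{prediction_model}: \code{band},
#'   \code{channels}, \code{model} (\code{feature_model}), \code{cv}
#'   (\code{cv_report}), \code{rate}, \code{log_power}, \code{n_bins}.
#' @export
train_prediction_model <- function(rec, cues, band = c(8, 12),
                                   optimize = FALSE, z_thresh = 3,
                                   var_retained = 0.9, method = "aida",
                                   k = 10, seed = 1L, log_power = TRUE, ...) {
  keep <- exclude_artifact_channels(rec, z_thresh)
  rec2 <- select_channels(rec, attr(keep, "index"))
  win <- prepare_training_windows(rec2, cues)
  if (optimize) {
    opt <- optimize_band(win, k = k, var_retained = var_retained,
                         method = method, seed = seed,
                         log_power = log_power, ...)
    band <- opt$band; cv <- opt$report
    pgs <- .segment_periodograms(win$segments, win$rate)
    X <- .band_feature_matrix(pgs, band, log_power = log_power)
  } else {
    pgs <- .segment_periodograms(win$segments, win$rate)
    X <- .band_feature_matrix(pgs, band, log_power = log_power)
    cv <- crossvalidate(X, win$labels, k = k, var_retained = var_retained,
                        method = method, seed = seed)
  }
  fm <- fit_feature_model(X, win$labels, var_retained = var_retained,
                          method = method)
  structure(list(band = band, channels = rec2$channel_names, model = fm,
                 cv = cv, rate = rec2$rate, log_power = log_power,
                 n_bins = as.integer((band[2] - band[1]) / 2),
                 var_retained = var_retained, method = method, seed = seed),
            class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf(
    "<prediction_model> band [%g, %g) Hz, %d channel(s), CV %.1f%% +/- %.1f%%\n",
    x$band[1], x$band[2], length(x$channels), x$cv$mean, x$cv$sd))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Model serialization (versioned JSON bundle; matrices as nested arrays)
# ---------------------------------------------------------------------------

#' Save / load a prediction model
#'
#' Serializes the model to a single versioned JSON bundle (all matrices as
#' nested arrays at full precision).
#'
#' @param model a \code{prediction_model}.
#' @param path destination \code{.json} path.
#' @return \code{read_model}: the restored \code{prediction_model}.
#' @export
write_model <- function(model, path) {
  bundle <- list(
    format = "gaitbci-model", version = 1L,
    band = model$band, channels = model$channels, rate = model$rate,
    log_power = model$log_power, n_bins = model$n_bins,
    var_retained = model$var_retained, method = model$method,
    cv = list(fold_accuracy = model$cv$fold_accuracy, mean = model$cv$mean,
              sd = model$cv$sd, seed = model$cv$seed, k = model$cv$k),
    mu = model$model$cpca$mu,
    sub = lapply(model$model$cpca$sub, function(s)
      list(U = s$U, center = s$center, m = s$m)),
    w = lapply(model$model$w, as.numeric),
    clf = unclass(model$model$clf))
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(b$format, "gaitbci-model"))
    stop("not a gaitbci model bundle: ", path)
  asmat <- function(x) if (is.matrix(x)) t(x) else matrix(x, ncol = 1)
  cp <- structure(list(
    mu = as.numeric(b$mu),
    sub = lapply(b$sub, function(s)
      list(U = asmat(s$U), center = as.numeric(s$center),
           m = as.integer(s$m)))), class = "cpca")
  clf <- structure(lapply(b$clf, function(p)
    list(mean = p$mean, sd = p$sd, prior = p$prior)),
    class = "bayes_classifier")
  fm <- structure(list(cpca = cp, w = lapply(b$w, as.numeric), clf = clf,
                       method = b$method), class = "feature_model")
  cv <- structure(list(fold_accuracy = b$cv$fold_accuracy, mean = b$cv$mean,
                       sd = b$cv$sd, confusion = NULL, seed = b$cv$seed,
                       k = b$cv$k), class = "cv_report")
  structure(list(band = b$band, channels = b$channels, model = fm, cv = cv,
                 rate = b$rate, log_power = b$log_power,
                 n_bins = as.integer(b$n_bins),
                 var_retained = b$var_retained, method = b$method,
                 seed = b$cv$seed),
            class = "prediction_model")
}
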