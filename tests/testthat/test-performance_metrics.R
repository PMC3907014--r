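# independent oracle: interval-walking reimplementation of omissions and
# false alarms over explicit time loops
oracle_om_fa <- function(cues, walk01, step = 0.25) {
  t <- attr(walk01, "times")
  om <- 0L; fa_d <- numeric(0)
  for (i in seq_len(nrow(cues))) {
    if (cues$label[i] != "WALK") next
    inside <- which(t >= cues$onset[i] - 1e-9 &
                      t < cues$onset[i] + cues$duration[i] - 1e-9)
    if (!any(walk01[inside] == 1L)) om <- om + 1L
  }
  k <- 1L; n <- length(walk01)
  while (k <= n) {
    if (walk01[k] == 1L && (k == 1L || walk01[k - 1L] == 0L)) {
      j <- k
      while (j < n && walk01[j + 1L] == 1L) j <- j + 1L
      onset <- t[k]
      in_idle <- FALSE
      for (i in seq_len(nrow(cues)))
        if (cues$label[i] == "IDLE" && onset >= cues$onset[i] - 1e-9 &&
            onset < cues$onset[i] + cues$duration[i] - 1e-9)
          in_idle <- TRUE
      if (in_idle) fa_d <- c(fa_d, (j - k + 1L) * step)
      k <- j + 1L
    } else k <- k + 1L
  }
  list(om = om, fa = length(fa_d), durs = fa_d)
}

test_that("binarize produces the shared 4 Hz clock for cues and states", {
  cues <- cue_schedule(rep(c("IDLE", "WALK"), 5), (0:9) * 60, rep(60, 10))
  b <- binarize(cues)
  expect_length(b, 2400)
  alt <- cue_schedule(rep(c("IDLE", "WALK"), 3), (0:5) * 60, rep(60, 6))
  b5 <- binarize(alt, span = 300)
  expect_length(b5, 1200)
  expect_equal(as.numeric(tapply(b5, rep(1:5, each = 240), mean)),
               c(0, 1, 0, 1, 0))
  expect_true(all(binarize(cue_schedule("IDLE", 0, 30)) == 0))
  # state-trace round trip preserves transition times
  walk <- c(rep(0, 10), rep(1, 12), rep(0, 8))
  ses <- mk_session(walk)
  sb <- binarize(ses)
  t <- attr(sb, "times")
  expect_equal(min(t[sb == 1]), ses$states$time[11])
})

test_that("lagged cross-correlation finds identity and pure shifts", {
  x <- binarize(cue_schedule(rep(c("IDLE", "WALK"), 4), (0:7) * 30,
                             rep(30, 8)))
  expect_equal(max_cross_correlation(x, x), list(r = 1, lag = 0))
  shift <- 30                                  # 7.5 s at 4 Hz
  y <- c(rep(0, shift), x[seq_len(length(x) - shift)])
  res <- max_cross_correlation(x, y)
  expect_equal(res$r, 1)
  expect_equal(res$lag, 7.5)
  expect_error(max_cross_correlation(rep(1, 100), x[1:100]), "constant")

  set.seed(20)
  small <- replicate(20, {
    a <- rbinom(1200, 1, 0.5); b <- rbinom(1200, 1, 0.5)
    abs(max_cross_correlation(a, b)$r)
  })
  expect_gte(mean(small < 0.1), 0.9)
})

test_that("omissions and false alarms follow the printed definitions", {
  cues <- cue_schedule(rep(c("IDLE", "WALK"), 3), (0:5) * 20, rep(20, 6))
  span_n <- 120 * 4
  # perfect tracking
  perfect <- binarize(cues, span = 120)
  ses_p <- mk_session(perfect, t0 = 0)
  expect_equal(count_omissions(cues, ses_p), 0)
  expect_equal(detect_false_alarms(cues, ses_p)$count, 0)
  # all-idle decode: every walk cue omitted
  ses_i <- mk_session(rep(0, span_n), t0 = 0)
  expect_equal(count_omissions(cues, ses_i), 3)
  # walk state starting one sample before the cue ends: not an omission
  w <- rep(0, span_n); w[4 * 40] <- 1   # t = 39.75, inside [20, 40)
  expect_equal(count_omissions(cues, mk_session(w, t0 = 0)), 2)

  # single 6-s episode starting mid-idle
  f <- rep(0, span_n); f[4 * 10 + (1:24)] <- 1
  fa <- detect_false_alarms(cues, mk_session(f, t0 = 0))
  expect_equal(fa$count, 1)
  expect_equal(fa$durations, 6)
  # episode spanning a walk-to-idle boundary is attributed to the walk cue
  g <- rep(0, span_n); g[(4 * 35):(4 * 45)] <- 1   # 35 s to 45 s
  fg <- detect_false_alarms(cues, mk_session(g, t0 = 0))
  expect_equal(fg$count, 0)
  # two separate episodes inside one idle cue
  h <- rep(0, span_n); h[4 * 42 + (1:8)] <- 1; h[4 * 50 + (1:4)] <- 1
  fh <- detect_false_alarms(cues, mk_session(h, t0 = 0))
  expect_equal(fh$count, 2)
  expect_equal(sort(fh$durations), c(1, 2))
})

test_that("metrics agree with an exhaustive interval-walk oracle", {
  set.seed(21)
  for (rep_i in 1:400) {
    n_cues <- sample(2:5, 1)
    durs <- sample(3:8, n_cues, replace = TRUE)
    onsets <- cumsum(c(0, durs[-n_cues]))
    lab <- rep(c("IDLE", "WALK"), length.out = n_cues)
    cues <- cue_schedule(lab, onsets, durs)
    n <- ceiling(cue_span(cues) / 0.25)
    walk01 <- rbinom(n, 1, runif(1, 0.1, 0.7))
    ses <- mk_session(walk01, t0 = 0)
    b <- binarize(ses, span = cue_span(cues))
    orc <- oracle_om_fa(cues, b)
    fa <- detect_false_alarms(cues, ses)
    expect_identical(count_omissions(cues, ses), orc$om)
    expect_identical(fa$count, orc$fa)
    expect_equal(fa$durations, orc$durs)
  }
})

test_that("metrics are invariant to synchronized idle padding", {
  on <- fx_online()
  m1 <- on$metrics
  cues_pad <- cue_schedule(c(on$cues$label, "IDLE"),
                           c(on$cues$onset, cue_span(on$cues)),
                           c(on$cues$duration, 30))
  ses_pad <- on$session
  extra <- data.frame(time = max(ses_pad$states$time) + 0.25 * (1:120),
                      state = "IDLE", stringsAsFactors = FALSE)
  ses_pad$states <- rbind(ses_pad$states, extra)
  ses_pad$posterior <- rbind(ses_pad$posterior,
                             data.frame(time = extra$time, P = 0, P_bar = 0))
  m2 <- session_metrics(cues_pad, ses_pad)
  expect_equal(m2$max_xcorr, m1$max_xcorr, tolerance = 0.02)
  expect_equal(m2$lag_at_max, m1$lag_at_max)
  expect_equal(m2$omissions, m1$omissions)
  expect_equal(m2$false_alarms, m1$false_alarms)
})

test_that("aggregation pools sessions and episodes correctly", {
  five <- data.frame(subject = 1, session = 1:5, xcorr = 0.5, lag = 4,
                     omissions = 0, false_alarms = 0, fa_mean = NA_real_,
                     fa_sd = NA_real_)
  agg <- aggregate_sessions(five)
  expect_equal(agg$xcorr_mean, c(0.5, 0.5))
  expect_equal(agg$xcorr_sd, c(0, 0))
  expect_true(all(is.na(agg$fa_dur_mean)))
  # episode reconstruction from (mean, sd, n = 2) is exact
  expect_equal(gaitbci:::.fa_episode_durations(2, 8.4, 4.1),
               8.4 + c(-1, 1) * 4.1 / sqrt(2))
  expect_equal(sd(gaitbci:::.fa_episode_durations(2, 8.4, 4.1)), 4.1)
  # list-column route matches the summary-column route for n <= 2
  s1 <- data.frame(subject = 1, session = 1:2, xcorr = c(0.7, 0.8),
                   lag = c(4, 6), omissions = 0, false_alarms = c(1, 2),
                   fa_mean = c(5, 7), fa_sd = c(NA, 2))
  s2 <- s1; s2$fa_durations <- I(list(5, 7 + c(-1, 1) * 2 / sqrt(2)))
  a1 <- aggregate_sessions(s1); a2 <- aggregate_sessions(s2)
  expect_equal(a1$fa_dur_mean, a2$fa_dur_mean)
  expect_equal(a1$fa_dur_sd, a2$fa_dur_sd)
})
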