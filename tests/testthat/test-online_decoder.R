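test_that("window stream has the exact count, times and contents", {
  # 300-s recording: floor((300 - 0.75)/0.25) + 1 = 1198 windows
  rec <- eeg_recording(matrix(0, 1, 300 * 32), 32)
  ws <- stream_windows(rec)
  expect_equal(ws$n, 1198)
  expect_equal(ws$times[1], 0.75)
  expect_equal(diff(ws$times)[1:5], rep(0.25, 5))

  r1 <- eeg_recording(matrix(seq_len(24), 1), 32)  # exactly 0.75 s
  w1 <- stream_windows(r1)
  expect_equal(w1$n, 1)
  expect_equal(drop(w1[[1]]$samples), 1:24)

  r0 <- eeg_recording(matrix(0, 1, 16), 32)        # 0.5 s
  expect_warning(w0 <- stream_windows(r0), "shorter")
  expect_equal(w0$n, 0)
})

test_that("posterior averaging is a trailing mean with warm-up", {
  expect_equal(average_posterior(rep(0.7, 20)), rep(0.7, 20))
  # unit step: linear ramp over 8 samples after the step
  P <- c(rep(0, 10), rep(1, 12))
  pb <- average_posterior(P)
  expect_equal(pb[10 + (1:8)], (1:8) / 8)
  expect_equal(pb[19:22], rep(1, 4))
  # warm-up averages what exists
  expect_equal(pb[1:7], rep(0, 7))
  expect_equal(average_posterior(c(1, 0))[1], 1)
  # alternation settles at 0.5
  pa <- average_posterior(rep(c(0, 1), 20))
  expect_true(all(abs(pa[-(1:8)] - 0.5) < 1e-12))
  expect_identical(average_posterior(numeric(0)), numeric(0))
})

test_that("state machine follows the printed transition rule", {
  # published thresholds, subject 2: T_I = 0.50, T_W = 0.90
  expect_identical(run_state_machine(c(0.6, 0.95, 0.7, 0.4), 0.50, 0.90),
                   c("IDLE", "WALK", "WALK", "IDLE"))
  # published thresholds, subject 1: T_I = 0.04, T_W = 0.65
  expect_identical(step_state(0.05, "WALK", 0.04, 0.65), "WALK")
  expect_identical(step_state(0.03, "WALK", 0.04, 0.65), "IDLE")
  # strict inequalities: sitting exactly on a threshold never transitions
  expect_true(all(run_state_machine(rep(0.9, 50), 0.5, 0.9) == "IDLE"))
  expect_true(all(run_state_machine(c(0.95, rep(0.5, 50)), 0.5, 0.9)
                  == "WALK"))
  expect_error(step_state(0.5, "IDLE", 0.9, 0.5), "T_I <= T_W")
})

test_that("hysteresis never increases transition count", {
  set.seed(13)
  for (i in 1:50) {
    pb <- runif(200)
    t_i <- runif(1, 0.2, 0.5); t_w <- runif(1, t_i, 0.9)
    n_tr <- function(s) sum(s[-1] != s[-length(s)])
    dual <- run_state_machine(pb, t_i, t_w)
    single <- run_state_machine(pb, (t_i + t_w) / 2, (t_i + t_w) / 2)
    expect_lte(n_tr(dual), n_tr(single))
  }
})

test_that("threshold calibration proposes separating thresholds", {
  set.seed(14)
  pI <- runif(300, 0.00, 0.18); pW <- runif(300, 0.82, 1.00)
  pb <- c(pI, pW); lab <- rep(c("I", "W"), each = 300)
  cal <- calibrate_thresholds(pb, lab)
  expect_false(cal$fallback)
  expect_gt(cal$t_i, 0.2); expect_lt(cal$t_i, 0.8)
  expect_gt(cal$t_w, 0.2); expect_lt(cal$t_w, 0.8)
  expect_lte(cal$t_i, cal$t_w)
  expect_length(cal$histogram$I, 50)
  # replay: idle never triggers walking, walking epochs are reached
  sI <- run_state_machine(pI, cal$t_i, cal$t_w)
  expect_true(all(sI == "IDLE"))
  sW <- run_state_machine(pW, cal$t_i, cal$t_w, init = "IDLE")
  expect_true(any(sW == "WALK"))

  # percentile equivariance under a +0.05 shift
  cal2 <- calibrate_thresholds(pmin(pb + 0.05, 1), lab)
  expect_equal(cal2$t_i, cal$t_i + 0.05, tolerance = 1e-6)
  expect_equal(cal2$t_w, cal$t_w + 0.05, tolerance = 1e-6)

  # identical class distributions trigger the fallback
  set.seed(15)
  same <- runif(400, 0.3, 0.7)
  expect_warning(
    calf <- calibrate_thresholds(c(same, same),
                                 rep(c("I", "W"), each = 400)),
    "crossed")
  expect_true(calf$fallback)
  expect_lte(calf$t_i, calf$t_w)
  expect_error(calibrate_thresholds(runif(50), rep("I", 50)),
               "single class")
})

test_that("online decoding is deterministic, causal, and tracks the cues", {
  on <- fx_online()
  expect_gt(on$metrics$max_xcorr, 0.7)
  expect_equal(on$metrics$omissions, 0)

  model <- fx_model()
  cfg <- synth_config(n_channels = 16, effect_size = 2, seed = 91)
  s <- generate_online_session(cfg, n_epochs = 4, epoch_s = 15)
  a <- run_online_session(s$rec, model, 0.2, 0.8)
  b <- run_online_session(s$rec, model, 0.2, 0.8)
  expect_identical(a, b)                       # bit-identical reruns

  # causality: truncating the future leaves the past unchanged
  n_keep <- 30 * s$rec$rate                    # first 30 s
  rec_tr <- eeg_recording(s$rec$samples[, seq_len(n_keep)], s$rec$rate,
                          s$rec$channel_names)
  tr <- run_online_session(rec_tr, model, 0.2, 0.8)
  n <- nrow(tr$states)
  expect_identical(tr$states$state, a$states$state[seq_len(n)])
  expect_equal(tr$posterior$P, a$posterior$P[seq_len(n)])

  # zero-length recording: empty traces, no error
  e <- suppressWarnings(run_online_session(
    eeg_recording(matrix(0, 16, 0), 256, model$channels), model, 0.2, 0.8))
  expect_equal(nrow(e$states), 0)
  expect_equal(nrow(e$posterior), 0)
})

test_that("decoded walk fraction on pure noise is consistent with the AR null", {
  modeln <- fx("model_null", function() {
    trn <- fx_training_null()
    train_prediction_model(trn$rec, trn$cues, band = c(8, 12), seed = 7)
  })
  cfg <- synth_config(n_channels = 16, effect_size = 0, seed = 92)
  s <- generate_online_session(cfg, n_epochs = 4, epoch_s = 30)
  ses <- run_online_session(s$rec, modeln, 0.3, 0.7)
  obs_frac <- mean(ses$states$state == "WALK")
  null <- suppressWarnings(fit_ar(ses$posterior$P))
  Y <- simulate_null_posteriors(null, nrow(ses$states), n_trials = 200,
                                seed = 17)
  Pb <- gaitbci:::.moving_avg_mat(Y, 8)
  fr <- vapply(seq_len(ncol(Y)), function(j)
    mean(run_state_machine(Pb[, j], 0.3, 0.7) == "WALK"), numeric(1))
  # observed long-run walk fraction lies within the Monte-Carlo spread
  expect_gte(obs_frac, max(0, min(fr) - 0.05))
  expect_lte(obs_frac, min(1, max(fr) + 0.05))
})

test_that("traces round-trip through CSV", {
  on <- fx_online()
  f <- withr::local_tempfile(fileext = ".csv")
  write_traces(on$session, f)
  back <- read_traces(f, t_i = 0.2, t_w = 0.8)
  expect_equal(back$posterior$P_bar, on$session$posterior$P_bar,
               tolerance = 1e-9)
  expect_identical(back$states$state, on$session$states$state)
  expect_equal(back$step, 0.25)
})
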