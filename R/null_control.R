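#' Fit the saturating autoregressive surrogate model to posteriors
#'
#' Models an observed sequence of instantaneous posteriors \code{P_k} as a
#' first-order autoregression driven by uniform white noise and clipped to
#' [0, 1]: \code{X_{k+1} = alpha X_k + beta W_k}, \code{Y_k = h(X_k)}.
#' Assuming wide-sense stationarity, \code{alpha} equals the lag-1
#' autocorrelation of the observed sequence and \code{beta} follows from
#' mean matching (\code{alpha mu + beta/2 = mu} with \code{E[W] = 1/2}),
#' giving \code{beta = 2 mu (1 - alpha)}. The stationary variance is
#' estimated and stored for reporting but not used in fitting.
#'
#' @param p_seq numeric vector of posteriors in [0, 1], length >= 10.
#' @return An object of class \code{ar_null_model}: \code{alpha},
#'   \code{beta}, \code{mu}, \code{sigma2}, \code{rho}.
#' @export
fit_ar <- function(p_seq) {
  p_seq <- as.numeric(p_seq)
  if (length(p_seq) < 10L) stop("need at least 10 posterior values")
  if (any(p_seq < -1e-9 | p_seq > 1 + 1e-9))
    stop("posteriors must lie in [0, 1]")
  if (stats::sd(p_seq) == 0)
    stop("constant posterior sequence: lag-1 autocorrelation undefined")
  n <- length(p_seq)
  rho <- stats::cor(p_seq[-n], p_seq[-1])
  alpha <- rho
  if (alpha < 0 || alpha >= 1) {
    warning(sprintf("fitted alpha = %.3f outside [0, 1); clipping", alpha))
    alpha <- min(max(alpha, 0), 1 - 1e-6)
  }
  mu <- mean(p_seq)
  structure(list(alpha = alpha, beta = 2 * mu * (1 - alpha), mu = mu,
                 sigma2 = stats::var(p_seq), rho = rho),
            class = "ar_null_model")
}

#' @export
print.ar_null_model <- function(x, ...) {
  cat(sprintf(
    "<ar_null_model> alpha=%.3f beta=%.3f mu=%.3f sigma2=%.4f rho=%.3f\n",
    x$alpha, x$beta, x$mu, x$sigma2, x$rho))
  invisible(x)
}

#' Simulate surrogate posterior sequences
#'
#' Runs the fitted recursion with \code{X_0 ~ U(0, 1)} and uniform white
#' noise, applying the hard-clip saturation \code{h(x) = min(max(x, 0), 1)}.
#' Deterministic given \code{seed}. With \code{n_trials > 1} all trials are
#' advanced in lock-step (vectorized over trials).
#'
#' @param model an \code{ar_null_model} (or list with \code{alpha},
#'   \code{beta}).
#' @param n_steps sequence length.
#' @param n_trials number of independent sequences (default 1).
#' @param seed optional RNG seed.
#' @param x0 optional fixed initial state (default drawn U(0,1) per trial).
#' @return Numeric matrix \code{n_steps x n_trials} of simulated posteriors
#'   (a plain vector when \code{n_trials = 1}), with attribute
#'   \code{"clip_rate"}: the fraction of steps where the clip was active.
#' @export
simulate_null_posteriors <- function(model, n_steps, n_trials = 1L,
                                     seed = NULL, x0 = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- model$alpha; b <- model$beta
  X <- if (is.null(x0)) stats::runif(n_trials) else rep_len(x0, n_trials)
  Y <- matrix(0, n_steps, n_trials)
  clipped <- 0
  for (k in seq_len(n_steps)) {
    y <- pmin(pmax(X, 0), 1)
    clipped <- clipped + sum(y != X)
    Y[k, ] <- y
    X <- a * X + b * stats::runif(n_trials)
  }
  out <- if (n_trials == 1L) drop(Y) else Y
  attr(out, "clip_rate") <- clipped / (n_steps * n_trials)
  out
}

# moving average over trailing w values, column-wise on a matrix
.moving_avg_mat <- function(M, w) {
  n <- nrow(M)
  cs <- apply(M, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
  k <- seq_len(n)
  lo <- pmax(0L, k - w)
  top <- cs - rbind(0, cs)[lo + 1L, , drop = FALSE]
  top / (k - lo)
}

# max lagged Pearson correlation of cue_seq vs each column of S (0/1 matrix);
# degenerate lags skipped; fully degenerate columns return -Inf
.max_xcorr_mat <- function(cue_seq, S, max_lag = 30, step = 0.25) {
  n <- length(cue_seq)
  lags <- 0:floor(max_lag / step + 1e-9)
  best <- rep(-Inf, ncol(S))
  for (L in lags) {
    m <- n - L
    if (m < 3L) break
    a <- cue_seq[seq_len(m)]
    sa <- stats::sd(a)
    if (sa == 0) next
    B <- S[(1L + L):n, , drop = FALSE]
    mb <- colMeans(B)
    vb <- colMeans(B^2) - mb^2
    cov_ab <- colMeans(a * B) - mean(a) * mb
    ok <- vb > 0
    r <- rep(-Inf, ncol(S))
    # population-variance normalization cancels in the ratio
    r[ok] <- cov_ab[ok] / sqrt(vb[ok] * (mean(a^2) - mean(a)^2))
    best <- pmax(best, r)
  }
  best
}

#' Monte-Carlo empirical p-value of a session's cue-response correlation
#'
#' Simulates \code{n_trials} surrogate posterior sequences of the session's
#' length from the fitted null model, pushes each through the same posterior
#' averaging and dual-threshold state machine as the real session, computes
#' the maximum lagged cue/state cross-correlation per trial, and reports the
#' fraction of trials exceeding (strictly) the observed value. Surrogate
#' trials whose state sequence never leaves idle have no defined correlation
#' and cannot exceed the observed value.
#'
#' @param observed_r observed maximum cross-correlation.
#' @param cue_seq binary cue sequence on the trace clock (from
#'   \code{\link{binarize}}), or a \code{cue_schedule}.
#' @param model an \code{ar_null_model}.
#' @param t_i,t_w state-machine thresholds of the session.
#' @param n_trials number of Monte-Carlo trials (default 10000).
#' @param span posterior averaging span, seconds.
#' @param step trace step, seconds.
#' @param max_lag correlation search range, seconds.
#' @param seed RNG seed.
#' @return List of class \code{mc_pvalue}: \code{p} (raw fraction),
#'   \code{floor} (\code{1/n_trials}, the reporting resolution),
#'   \code{n_exceed}, \code{n_trials}, \code{null_max} (largest surrogate
#'   correlation), \code{observed}.
#' @export
empirical_pvalue <- function(observed_r, cue_seq, model, t_i, t_w,
                             n_trials = 10000L, span = 2, step = 0.25,
                             max_lag = 30, seed = NULL) {
  if (inherits(cue_seq, "cue_schedule")) cue_seq <- binarize(cue_seq)
  cue_seq <- as.numeric(cue_seq)
  n <- length(cue_seq)
  if (stats::sd(cue_seq) == 0) stop("cue sequence is constant")
  Y <- simulate_null_posteriors(model, n, n_trials, seed = seed)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  Pb <- .moving_avg_mat(Y, max(1L, round(span / step)))
  # vectorized state machine across trials
  S <- matrix(0L, n, ncol(Y))
  s <- rep(0L, ncol(Y))           # 0 = IDLE, 1 = WALK
  for (k in seq_len(n)) {
    s <- ifelse(s == 0L, as.integer(Pb[k, ] > t_w),
                1L - as.integer(Pb[k, ] < t_i))
    S[k, ] <- s
  }
  r_null <- .max_xcorr_mat(cue_seq, S, max_lag = max_lag, step = step)
  n_exceed <- sum(r_null > observed_r)
  structure(list(p = n_exceed / n_trials, floor = 1 / n_trials,
                 n_exceed = n_exceed, n_trials = n_trials,
                 null_max = max(r_null), observed = observed_r),
            class = "mc_pvalue")
}

#' @export
print.mc_pvalue <- function(x, ...) {
  ptxt <- if (x$n_exceed == 0L) sprintf("< %g", x$floor)
          else format(x$p, digits = 3)
  cat(sprintf(
    "<mc_pvalue> p %s (%d/%d trials above r=%.3f; null max %.3f)\n",
    ptxt, x$n_exceed, x$n_trials, x$observed, x$null_max))
  invisible(x)
}
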