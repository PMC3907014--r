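#' Sliding analysis windows over a recording
#'
#' Emits overlapping \code{win}-second windows every \code{step} seconds:
#' window k covers \code{[t_k - win, t_k)} with \code{t_k = win + (k-1) step}
#' on the session clock. A recording shorter than one window yields zero
#' windows (with a warning).
#'
#' @param rec an \code{eeg_recording}.
#' @param win window length, seconds (default 0.75).
#' @param step hop, seconds (default 0.25).
#' @return An object of class \code{window_stream}: \code{times} (window end
#'   times, the 4 Hz trace clock), \code{n}, plus the source recording;
#'   extract window i with \code{x[[i]]}.
#' @export
stream_windows <- function(rec, win = 0.75, step = 0.25) {
  dur <- recording_duration(rec)
  n <- if (dur < win - 1e-9) 0L else floor((dur - win) / step + 1e-9) + 1L
  if (n == 0L) warning("recording shorter than one analysis window")
  times <- if (n > 0L) rec$start_time + win + step * (seq_len(n) - 1L)
           else numeric(0)
  structure(list(rec = rec, win = win, step = step, times = times, n = n),
            class = "window_stream")
}

#' @export
`[[.window_stream` <- function(x, i) {
  i <- as.integer(i)
  if (i < 1L || i > x$n) stop("window index out of range")
  r <- x$rec
  wlen <- round(x$win * r$rate)
  i1 <- round((x$times[i] - r$start_time) * r$rate)
  eeg_recording(r$samples[, (i1 - wlen + 1L):i1, drop = FALSE], r$rate,
                r$channel_names, start_time = x$times[i] - x$win)
}

#' @export
length.window_stream <- function(x) x$n

#' @export
print.window_stream <- function(x, ...) {
  cat(sprintf("<window_stream> %d window(s) of %g s every %g s\n",
              x$n, x$win, x$step))
  invisible(x)
}

#' Running average of posterior probabilities
#'
#' Causal moving average over the trailing \code{span} seconds
#' (\code{span/step} values including the current one). During warm-up,
#' averages whatever is available so the trace stays aligned with the cue
#' clock.
#'
#' @param P numeric vector of instantaneous posteriors at \code{step}-second
#'   spacing.
#' @param span averaging span, seconds (default 2).
#' @param step trace step, seconds (default 0.25).
#' @return Numeric vector of averaged posteriors, same length as \code{P}.
#' @export
average_posterior <- function(P, span = 2, step = 0.25) {
  n <- length(P)
  if (n == 0L) return(numeric(0))
  w <- max(1L, round(span / step))
  cs <- cumsum(P)
  k <- seq_len(n)
  lo <- pmax(0L, k - w)
  (cs - c(0, cs)[lo + 1L]) / (k - lo)
}

#' One step of the dual-threshold state machine
#'
#' From idling, the system switches to walking only when the averaged
#' posterior exceeds \code{T_W}; from walking, it switches back only when it
#' drops below \code{T_I} (strict inequalities). Otherwise the state is
#' unchanged, giving hysteresis against chatter.
#'
#' @param p_bar averaged posterior, in [0, 1].
#' @param state current state, \code{"IDLE"} or \code{"WALK"}.
#' @param t_i,t_w thresholds with \code{t_i <= t_w}.
#' @return Next state.
#' @export
step_state <- function(p_bar, state, t_i, t_w) {
  if (t_i > t_w) stop("need T_I <= T_W")
  if (state == "IDLE") {
    if (p_bar > t_w) "WALK" else "IDLE"
  } else {
    if (p_bar < t_i) "IDLE" else "WALK"
  }
}

#' Run the state machine over an averaged-posterior sequence
#'
#' @param p_bar numeric vector of averaged posteriors.
#' @param t_i,t_w thresholds.
#' @param init initial state (default \code{"IDLE"}: sessions begin at rest).
#' @return Character vector of states, same length as \code{p_bar}.
#' @export
run_state_machine <- function(p_bar, t_i, t_w, init = "IDLE") {
  if (t_i > t_w) stop("need T_I <= T_W")
  n <- length(p_bar)
  out <- character(n)
  s <- init
  for (k in seq_len(n)) {
    s <- step_state(p_bar[k], s, t_i, t_w)
    out[k] <- s
  }
  out
}

#' Calibrate the state-machine thresholds from labelled posteriors
#'
#' Builds per-class histograms of the averaged posterior from a calibration
#' run and proposes thresholds automatically from the class tail quantiles:
#' \code{qI}, the upper quantile of the idle-class values (the lowest safe
#' walk-entry threshold) and \code{qW}, the lower quantile of the walk-class
#' values (the highest safe walk-exit threshold). When the classes separate
#' (\code{qW >= qI}) the thresholds are placed symmetrically inside the gap
#' (\code{T_I,T_W} = gap midpoint -/+ a quarter of the gap). When the tails
#' interleave (\code{qW < qI}: overlapping classes, the typical real
#' calibration) the proposal falls back, with a warning, to the midpoint
#' plus/minus half the (crossed) quantile gap, i.e. \code{T_I = qW},
#' \code{T_W = qI}. The histograms and the proposal are both returned so an
#' operator can override them, mirroring the manual histogram reading plus
#' familiarization fine-tuning done at the rig.
#'
#' @param p_bar averaged posteriors from a calibration run.
#' @param labels cue label per value (\code{I}/\code{W}).
#' @param probs tail quantiles used for the proposal (default \code{c(0.05,
#'   0.95)}: \code{qW} = 5th percentile of walk, \code{qI} = 95th of idle).
#' @param bins number of histogram bins over [0, 1] (default 50).
#' @return List with \code{t_i}, \code{t_w}, \code{histogram} (per-class
#'   counts with \code{breaks}), \code{fallback} (TRUE when the overlap
#'   fallback was used).
#' @export
calibrate_thresholds <- function(p_bar, labels, probs = c(0.05, 0.95),
                                 bins = 50) {
  labels <- .norm_labels(labels)
  if (length(unique(labels)) < 2L)
    stop("calibration data contain a single class; need both I and W")
  pI <- p_bar[labels == "I"]; pW <- p_bar[labels == "W"]
  qI <- unname(stats::quantile(pI, probs[2], type = 7))
  qW <- unname(stats::quantile(pW, probs[1], type = 7))
  mid <- (qI + qW) / 2
  fallback <- FALSE
  if (qW >= qI) {                 # separated classes: sit inside the gap
    t_i <- mid - (qW - qI) / 4
    t_w <- mid + (qW - qI) / 4
  } else {                        # overlapping tails
    warning("threshold proposal crossed (overlapping classes); ",
            "falling back to midpoint +/- half the quantile gap")
    t_i <- max(0, qW)
    t_w <- min(1, qI)
    fallback <- TRUE
  }
  breaks <- seq(0, 1, length.out = bins + 1L)
  clamp <- function(x) pmin(pmax(x, 0), 1)
  hist_counts <- list(
    breaks = breaks,
    I = graphics::hist(clamp(pI), breaks = breaks, plot = FALSE)$counts,
    W = graphics::hist(clamp(pW), breaks = breaks, plot = FALSE)$counts)
  list(t_i = t_i, t_w = t_w, histogram = hist_counts, fallback = fallback)
}

#' Decode a full session online-style
#'
#' Composes the streaming pipeline: sliding windows, band-power features over
#' the model's retained channels and band, piecewise discriminant feature,
#' Bayes posterior, 2-s posterior averaging, and the dual-threshold state
#' machine. Fully causal: the state at time t uses only samples before t.
#'
#' @param rec an \code{eeg_recording} (full montage: the model's channels are
#'   selected by name, or used as-is when names match in count only).
#' @param model a \code{prediction_model}.
#' @param t_i,t_w state-machine thresholds.
#' @param span posterior averaging span, seconds (default 2).
#' @param win,step analysis window and hop, seconds.
#' @return List of class \code{decoded_session}: \code{posterior} (data frame
#'   \code{time}, \code{P}, \code{P_bar}), \code{states} (data frame
#'   \code{time}, \code{state}), \code{thresholds}, \code{step}.
#' @export
run_online_session <- function(rec, model, t_i, t_w, span = 2,
                               win = 0.75, step = 0.25) {
  if (all(model$channels %in% rec$channel_names))
    rec <- select_channels(rec, model$channels)
  else if (nrow(rec$samples) != length(model$channels))
    stop("recording lacks the model's channels")
  ws <- suppressWarnings(stream_windows(rec, win, step))
  if (ws$n == 0L) {
    empty_p <- data.frame(time = numeric(0), P = numeric(0),
                          P_bar = numeric(0))
    empty_s <- data.frame(time = numeric(0), state = character(0))
    return(structure(list(posterior = empty_p, states = empty_s,
                          thresholds = c(t_i = t_i, t_w = t_w), step = step),
                     class = "decoded_session"))
  }
  wlen <- round(win * rec$rate)
  P <- numeric(ws$n)
  for (i in seq_len(ws$n)) {
    i1 <- round((ws$times[i] - rec$start_time) * rec$rate)
    seg <- rec$samples[, (i1 - wlen + 1L):i1, drop = FALSE]
    feats <- compute_psd_features(seg, band = model$band, rate = rec$rate)
    d <- as.numeric(feats$values)   # B x C flattened, bins fastest
    d <- if (model$log_power) log10(d + 1e-12) else d
    P[i] <- predict_posterior(matrix(d, nrow = 1), model$model)
  }
  p_bar <- average_posterior(P, span = span, step = step)
  states <- run_state_machine(p_bar, t_i, t_w)
  structure(list(
    posterior = data.frame(time = ws$times, P = P, P_bar = p_bar),
    states = data.frame(time = ws$times, state = states,
                        stringsAsFactors = FALSE),
    thresholds = c(t_i = t_i, t_w = t_w), step = step),
    class = "decoded_session")
}

#' @export
print.decoded_session <- function(x, ...) {
  n <- nrow(x$states)
  fw <- if (n) mean(x$states$state == "WALK") else NA_real_
  cat(sprintf(
    "<decoded_session> %d step(s) @ 4 Hz, walk fraction %.2f, T_I=%.2f T_W=%.2f\n",
    n, fw, x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

#' Write / read decoded traces as CSV
#'
#' Columns \code{time_s, P, P_bar, state}.
#'
#' @param session a \code{decoded_session}.
#' @param path CSV destination.
#' @export
write_traces <- function(session, path) {
  d <- data.frame(time_s = session$posterior$time, P = session$posterior$P,
                  P_bar = session$posterior$P_bar,
                  state = session$states$state)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @param t_i,t_w thresholds to record on the restored object.
#' @export
read_traces <- function(path, t_i = NA_real_, t_w = NA_real_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  step <- if (nrow(d) > 1L) d$time_s[2] - d$time_s[1] else 0.25
  structure(list(
    posterior = data.frame(time = d$time_s, P = d$P, P_bar = d$P_bar),
    states = data.frame(time = d$time_s, state = d$state,
                        stringsAsFactors = FALSE),
    thresholds = c(t_i = t_i, t_w = t_w), step = step),
    class = "decoded_session")
}
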