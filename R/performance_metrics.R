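#' Sample a cue schedule or state trace on the 4 Hz session clock
#'
#' Produces a 0/1 sequence (\code{WALK} = 1, \code{IDLE} = 0) on the shared
#' trace clock \code{t = 0, step, 2*step, ...} over \code{[0, span)}. For a
#' cue schedule the label at each clock tick is looked up in the half-open
#' cue intervals (ticks outside any cue are idle). For a decoded session the
#' state holding at each tick is used (before the first decoded window the
#' state is idle).
#'
#' @param x a \code{cue_schedule} or \code{decoded_session}.
#' @param span sequence span in seconds; defaults to the cue span / last
#'   trace time.
#' @param step clock step, seconds (default 0.25, i.e. 4 Hz).
#' @return Integer 0/1 vector of length \code{span/step}, with attribute
#'   \code{"times"}.
#' @export
binarize <- function(x, span = NULL, step = 0.25) UseMethod("binarize")

#' @export
binarize.cue_schedule <- function(x, span = NULL, step = 0.25) {
  if (is.null(span)) span <- cue_span(x)
  t <- seq(0, span - step / 2, by = step)
  out <- integer(length(t))
  for (i in seq_len(nrow(x))) {
    if (x$label[i] == "WALK") {
      sel <- t >= x$onset[i] - 1e-9 & t < x$onset[i] + x$duration[i] - 1e-9
      out[sel] <- 1L
    }
  }
  structure(out, times = t)
}

#' @export
binarize.decoded_session <- function(x, span = NULL, step = 0.25) {
  if (is.null(span))
    span <- if (nrow(x$states)) max(x$states$time) + step else 0
  t <- seq(0, span - step / 2, by = step)
  out <- integer(length(t))
  if (nrow(x$states)) {
    walk <- x$states$state == "WALK"
    idx <- findInterval(t + 1e-9, x$states$time)
    has <- idx >= 1L
    out[has] <- as.integer(walk[idx[has]])
  }
  structure(out, times = t)
}

#' @export
binarize.default <- function(x, span = NULL, step = 0.25) {
  structure(as.integer(x != 0), times = (seq_along(x) - 1L) * step)
}

#' Maximum lagged cross-correlation between cue and response sequences
#'
#' Pearson correlation of the cue sequence against the response delayed by
#' each lag in \code{0, step, ..., max_lag} seconds (positive lag = response
#' lags the cue), computed over the overlapping region only. Returns the
#' maximum and its lag; ties resolve to the smallest lag.
#'
#' @param cue_seq,state_seq equal-length numeric (0/1) sequences on the same
#'   clock.
#' @param max_lag largest lag searched, seconds (default 30).
#' @param step clock step, seconds (default 0.25).
#' @return List with \code{r} and \code{lag} (seconds).
#' @export
max_cross_correlation <- function(cue_seq, state_seq, max_lag = 30,
                                  step = 0.25) {
  cue_seq <- as.numeric(cue_seq); state_seq <- as.numeric(state_seq)
  n <- length(cue_seq)
  if (length(state_seq) != n) stop("sequences must have equal length")
  if (stats::sd(cue_seq) == 0)
    stop("cue sequence is constant; cross-correlation undefined")
  if (stats::sd(state_seq) == 0)
    stop("state sequence is constant; cross-correlation undefined")
  lags <- 0:floor(max_lag / step + 1e-9)
  best_r <- -Inf; best_lag <- NA_real_
  for (L in lags) {
    if (n - L < 3L) break
    a <- cue_seq[seq_len(n - L)]
    b <- state_seq[(1L + L):n]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (r > best_r + 1e-12) { best_r <- r; best_lag <- L * step }
  }
  if (!is.finite(best_r))
    stop("no lag with non-degenerate overlap; sequences too short/constant")
  list(r = best_r, lag = best_lag)
}

# contiguous WALK episodes of a binary sequence -> data frame onset/end (s)
.walk_episodes <- function(seq01, step = 0.25, t0 = 0) {
  r <- rle(as.integer(seq01))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  walk <- which(r$values == 1L)
  data.frame(onset = t0 + (starts[walk] - 1L) * step,
             end = t0 + ends[walk] * step)
}

#' Count omissions
#'
#' An omission is a Walk cue interval during which the decoder never entered
#' the walking state.
#'
#' @param cues a \code{cue_schedule}.
#' @param session a \code{decoded_session} (or binary state sequence with a
#'   \code{"times"} attribute from \code{\link{binarize}}).
#' @param step trace step, seconds.
#' @return Integer count.
#' @export
count_omissions <- function(cues, session, step = 0.25) {
  span <- max(cue_span(cues),
              if (inherits(session, "decoded_session") && nrow(session$states))
                max(session$states$time) + step else 0)
  s <- if (inherits(session, "decoded_session"))
    binarize(session, span = span, step = step) else session
  t <- attr(s, "times")
  walks <- cues[cues$label == "WALK", , drop = FALSE]
  n_om <- 0L
  for (i in seq_len(nrow(walks))) {
    inside <- t >= walks$onset[i] - 1e-9 &
      t < walks$onset[i] + walks$duration[i] - 1e-9
    if (!any(s[inside] == 1L)) n_om <- n_om + 1L
  }
  n_om
}

#' Detect false alarms
#'
#' A false alarm is a walking episode whose onset falls inside an Idle cue
#' interval; its duration runs to the end of the episode even when that
#' crosses into a subsequent Walk cue (attribution by onset). Episodes that
#' started during a Walk cue and merely persist into an Idle cue are not
#' counted.
#'
#' @inheritParams count_omissions
#' @return List with \code{count} and \code{durations} (seconds).
#' @export
detect_false_alarms <- function(cues, session, step = 0.25) {
  span <- max(cue_span(cues),
              if (inherits(session, "decoded_session") && nrow(session$states))
                max(session$states$time) + step else 0)
  s <- if (inherits(session, "decoded_session"))
    binarize(session, span = span, step = step) else session
  ep <- .walk_episodes(s, step = step)
  idles <- cues[cues$label == "IDLE", , drop = FALSE]
  is_fa <- vapply(seq_len(nrow(ep)), function(i) {
    any(ep$onset[i] >= idles$onset - 1e-9 &
          ep$onset[i] < idles$onset + idles$duration - 1e-9)
  }, logical(1))
  if (nrow(ep) == 0L) is_fa <- logical(0)
  list(count = sum(is_fa), durations = ep$end[is_fa] - ep$onset[is_fa])
}

#' Score one decoded session against its cues
#'
#' @param cues a \code{cue_schedule}.
#' @param session a \code{decoded_session}.
#' @param max_lag cross-correlation search range, seconds.
#' @param step trace clock step, seconds.
#' @return An object of class \code{session_metrics}: \code{max_xcorr},
#'   \code{lag_at_max} (s), \code{omissions}, \code{false_alarms},
#'   \code{fa_durations} (s).
#' @export
session_metrics <- function(cues, session, max_lag = 30, step = 0.25) {
  span <- max(cue_span(cues),
              if (nrow(session$states)) max(session$states$time) + step else 0)
  cue_seq <- binarize(cues, span = span, step = step)
  st_seq <- binarize(session, span = span, step = step)
  xc <- max_cross_correlation(cue_seq, st_seq, max_lag = max_lag, step = step)
  fa <- detect_false_alarms(cues, session, step = step)
  structure(list(max_xcorr = xc$r, lag_at_max = xc$lag,
                 omissions = count_omissions(cues, session, step = step),
                 false_alarms = fa$count, fa_durations = fa$durations),
            class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf(
    "<session_metrics> r=%.3f @ %.2f s lag, %d omission(s), %d false alarm(s)\n",
    x$max_xcorr, x$lag_at_max, x$omissions, x$false_alarms))
  invisible(x)
}

# reconstruct individual episode durations from a session's (mean, sd, n):
# exact for n <= 2, mean-replicated otherwise
.fa_episode_durations <- function(n, mean_d, sd_d) {
  if (is.na(n) || n == 0) return(numeric(0))
  if (n == 1) return(mean_d)
  if (n == 2) {
    s <- if (is.na(sd_d)) 0 else sd_d
    return(mean_d + c(-1, 1) * s / sqrt(2))
  }
  rep(mean_d, n)
}

#' Aggregate session metrics into a per-subject and overall summary
#'
#' Accepts a data frame with one row per session: columns \code{subject},
#' \code{session}, \code{xcorr}, \code{lag} (s), \code{omissions},
#' \code{false_alarms}, and either a list-column \code{fa_durations} or
#' summary columns \code{fa_mean}/\code{fa_sd} (seconds; \code{fa_sd} may be
#' NA for 0 or 1 episodes). False-alarm durations are pooled over episodes;
#' when only per-session means are available, episode values are
#' reconstructed exactly for sessions with at most two episodes and
#' mean-replicated otherwise.
#'
#' @param sessions data frame as described (e.g. \code{\link{rogo_sessions}}
#'   or rows built from \code{\link{session_metrics}}).
#' @return Data frame with one row per subject plus an \code{"overall"} row:
#'   \code{xcorr_mean}, \code{xcorr_sd}, \code{lag_mean}, \code{lag_sd},
#'   \code{omissions} (total), \code{fa_per_session}, \code{fa_dur_mean},
#'   \code{fa_dur_sd}, \code{n_sessions}.
#' @export
aggregate_sessions <- function(sessions) {
  stopifnot(all(c("subject", "xcorr", "lag", "omissions", "false_alarms")
                %in% names(sessions)))
  episode_durs <- function(rows) {
    if ("fa_durations" %in% names(rows) && is.list(rows$fa_durations)) {
      unlist(rows$fa_durations, use.names = FALSE)
    } else {
      unlist(lapply(seq_len(nrow(rows)), function(i)
        .fa_episode_durations(rows$false_alarms[i], rows$fa_mean[i],
                              if ("fa_sd" %in% names(rows)) rows$fa_sd[i]
                              else NA_real_)), use.names = FALSE)
    }
  }
  summarize <- function(rows, name) {
    durs <- episode_durs(rows)
    data.frame(
      group = name,
      n_sessions = nrow(rows),
      xcorr_mean = mean(rows$xcorr), xcorr_sd = stats::sd(rows$xcorr),
      lag_mean = mean(rows$lag), lag_sd = stats::sd(rows$lag),
      omissions = sum(rows$omissions),
      fa_per_session = mean(rows$false_alarms),
      fa_dur_mean = if (length(durs)) mean(durs) else NA_real_,
      fa_dur_sd = if (length(durs) > 1L) stats::sd(durs) else NA_real_,
      stringsAsFactors = FALSE)
  }
  groups <- unique(sessions$subject)
  out <- do.call(rbind, lapply(groups, function(g)
    summarize(sessions[sessions$subject == g, , drop = FALSE],
              as.character(g))))
  rbind(out, summarize(sessions, "overall"))
}

#' Published online-session performance table
#'
#' The ten online BCI-gait sessions (two subjects, five sessions each) with
#' their cue/response cross-correlation, lag, omission and false-alarm
#' statistics, shipped as package data for aggregation and regression
#' testing.
#'
#' @return Data frame with columns \code{subject}, \code{session},
#'   \code{xcorr}, \code{lag} (s), \code{omissions}, \code{false_alarms},
#'   \code{fa_mean} (s), \code{fa_sd} (s).
#' @export
rogo_sessions <- function() {
  path <- system.file("extdata", "online_sessions.csv", package = "gaitbci",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published offline model accuracies
#'
#' Per-subject cross-validated offline classification accuracy of the EEG
#' prediction model (percent, mean and SD over folds), shipped as package
#' data.
#'
#' @return Data frame with columns \code{subject}, \code{accuracy_mean_pct},
#'   \code{accuracy_sd_pct}.
#' @export
rogo_offline_accuracy <- function() {
  path <- system.file("extdata", "offline_accuracy.csv", package = "gaitbci",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
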