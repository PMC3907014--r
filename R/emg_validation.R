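#' Zero-phase band-pass filter for EMG
#'
#' FFT-domain zero-phase filter with raised-cosine transition edges: unity
#' gain inside \code{band}, zero outside \code{band[1] - transition[1]} /
#' \code{band[2] + transition[2]}. Being a real, symmetric spectral mask the
#' filter introduces no phase distortion and is (approximately) idempotent.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param rate sampling rate, Hz.
#' @param band pass band \code{c(lo, hi)}, Hz (default \code{c(40, 400)}).
#' @param transition transition widths below/above the band, Hz.
#' @return Filtered signal, same shape as \code{x}, with attribute
#'   \code{"filter"} describing the design.
#' @export
emg_bandpass <- function(x, rate, band = c(40, 400),
                         transition = c(10, 40)) {
  mat <- is.matrix(x)
  m <- if (mat) x else matrix(x, nrow = 1)
  n <- ncol(m)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)
  H <- numeric(n)
  lo0 <- band[1] - transition[1]; hi1 <- band[2] + transition[2]
  inside <- f >= band[1] & f <= band[2]
  H[inside] <- 1
  rise <- f > lo0 & f < band[1]
  H[rise] <- 0.5 * (1 - cos(pi * (f[rise] - lo0) / transition[1]))
  fall <- f > band[2] & f < hi1
  H[fall] <- 0.5 * (1 + cos(pi * (f[fall] - band[2]) / transition[2]))
  out <- t(apply(m, 1, function(row)
    Re(stats::fft(stats::fft(row) * H, inverse = TRUE)) / n))
  if (!mat) out <- drop(out)
  attr(out, "filter") <- list(design = "zero-phase FFT raised-cosine",
                              band = band, transition = transition,
                              rate = rate)
  out
}

#' Preprocess raw EMG: band-pass then full-wave rectification
#'
#' Standard surface-EMG conditioning: zero-phase 40-400 Hz band-pass
#' (removing motion artifact and mains-adjacent drift while keeping the
#' muscle-fiber action-potential band) followed by full-wave rectification.
#'
#' @inheritParams emg_bandpass
#' @return Rectified filtered signal with the \code{"filter"} attribute of
#'   \code{\link{emg_bandpass}}.
#' @export
preprocess_emg <- function(x, rate, band = c(40, 400),
                           transition = c(10, 40)) {
  y <- emg_bandpass(x, rate, band, transition)
  meta <- attr(y, "filter")
  out <- abs(y)
  attr(out, "filter") <- c(meta, rectified = TRUE)
  out
}

#' Segment a gyroscope trace into individual steps
#'
#' Smooths the angular-velocity trace with a short moving average and takes
#' its prominent peaks (one per gait cycle) as step boundaries, enforcing a
#' minimum inter-peak distance. A flat trace yields no steps (with a
#' warning).
#'
#' @param gyro numeric angular-velocity trace.
#' @param rate sampling rate, Hz.
#' @param min_period minimum inter-peak distance, seconds (default 0.4).
#' @param smooth smoothing window, seconds (default 0.1).
#' @return An object of class \code{step_segmentation}: \code{boundaries}
#'   (peak times, seconds, strictly increasing), \code{n_steps}
#'   (\code{length(boundaries) - 1}), \code{stride_period} (median
#'   inter-peak interval, seconds; NA with fewer than 2 boundaries).
#' @export
segment_steps <- function(gyro, rate, min_period = 0.4, smooth = 0.1) {
  n <- length(gyro)
  empty <- structure(list(boundaries = numeric(0), n_steps = 0L,
                          stride_period = NA_real_),
                     class = "step_segmentation")
  if (n < 3L) { warning("trace too short to segment"); return(empty) }
  k <- max(1L, round(smooth * rate))
  s <- stats::filter(gyro, rep(1 / k, k), sides = 2)
  s[is.na(s)] <- gyro[is.na(s)]
  s <- as.numeric(s)
  if (stats::sd(s) < 1e-12) {
    warning("flat gyroscope trace: no steps detected")
    return(empty)
  }
  thresh <- mean(s) + 0.5 * stats::sd(s)
  cand <- which(s > thresh &
                  s >= c(-Inf, s[-n]) & s > c(s[-1], -Inf))
  if (length(cand) == 0L) {
    warning("no peaks above threshold: no steps detected")
    return(empty)
  }
  # enforce minimum distance, keeping the larger peak
  min_gap <- round(min_period * rate)
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < min_gap) {
      if (s[i] > s[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  boundaries <- (keep - 1) / rate
  structure(list(boundaries = boundaries,
                 n_steps = max(0L, length(boundaries) - 1L),
                 stride_period = if (length(boundaries) >= 2L)
                   stats::median(diff(boundaries)) else NA_real_),
            class = "step_segmentation")
}

#' @export
print.step_segmentation <- function(x, ...) {
  cat(sprintf("<step_segmentation> %d step(s), stride period %.3f s\n",
              x$n_steps, x$stride_period))
  invisible(x)
}

#' Slice an EMG channel into per-step segments
#'
#' @param emg numeric EMG vector (one channel).
#' @param rate EMG sampling rate, Hz.
#' @param seg a \code{\link{segment_steps}} result (boundary times are
#'   shared across modalities via the session clock).
#' @return List of numeric vectors, one per step.
#' @export
step_segments <- function(emg, rate, seg) {
  b <- seg$boundaries
  if (length(b) < 2L) return(list())
  lapply(seq_len(length(b) - 1L), function(i) {
    i0 <- floor(b[i] * rate) + 1L
    i1 <- min(length(emg), floor(b[i + 1L] * rate))
    emg[i0:i1]
  })
}

# integrated log10 band power of a segment (single channel)
.segment_band_logpower <- function(x, rate, band) {
  pg <- .periodogram(matrix(x, nrow = 1), rate)
  p <- .integrate_bins(pg, band, rate / length(x))
  log10(sum(p) + 1e-300)
}

#' Compare per-step EMG power spectra across walking conditions
#'
#' For every condition, computes each step's integrated log band power
#' (40-400 Hz by default) and the condition's mean PSD curve; condition
#' pairs are then compared with a two-sample rank-sum (Wilcoxon) test on the
#' per-step log powers.
#'
#' @param segments_by_condition named list; each element a list of per-step
#'   EMG vectors (e.g. from \code{\link{step_segments}}).
#' @param rate EMG sampling rate, Hz.
#' @param band integration band, Hz (default \code{c(40, 400)}).
#' @return An object of class \code{emg_comparison}: \code{powers} (named
#'   list of per-step log10 powers), \code{psd} (common frequency grid and
#'   one mean PSD curve per condition), \code{comparisons} (data frame with
#'   \code{a}, \code{b}, \code{direction} in \{-1, 0, 1\} for median a vs b,
#'   \code{statistic}, \code{p_value}).
#' @export
emg_psd_compare <- function(segments_by_condition, rate, band = c(40, 400)) {
  conds <- names(segments_by_condition)
  if (is.null(conds) || any(!nzchar(conds)))
    stop("segments_by_condition must be a named list")
  powers <- lapply(segments_by_condition, function(segs)
    vapply(segs, .segment_band_logpower, numeric(1), rate = rate,
           band = band))
  # mean PSD on a common grid: steps truncated to the shortest step overall
  nmin <- min(unlist(lapply(segments_by_condition, vapply, length,
                            numeric(1))))
  pg_freq <- (seq_len(floor(nmin / 2) + 1L) - 1) * rate / nmin
  curves <- lapply(segments_by_condition, function(segs) {
    acc <- 0
    for (s in segs)
      acc <- acc + .periodogram(matrix(s[seq_len(nmin)], nrow = 1),
                                rate)$psd[, 1]
    acc / length(segs)
  })
  pairs <- utils::combn(conds, 2)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    wt <- stats::wilcox.test(powers[[a]], powers[[b]], exact = FALSE)
    data.frame(a = a, b = b,
               direction = sign(stats::median(powers[[a]]) -
                                  stats::median(powers[[b]])),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  structure(list(powers = powers,
                 psd = list(freq = pg_freq, curves = curves),
                 comparisons = comparisons),
            class = "emg_comparison")
}

#' @export
print.emg_comparison <- function(x, ...) {
  cat("<emg_comparison>\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

# first time the smoothed envelope exceeds baseline mean + 3 SD at/after t0
# and stays above for >= sustain seconds (guards against single noise spikes)
.onset_after <- function(env, rate, t0, base_mean, base_sd, sustain = 0.1) {
  i0 <- max(1L, floor(t0 * rate) + 1L)
  if (i0 > length(env)) return(NA_real_)
  above <- env[i0:length(env)] > base_mean + 3 * base_sd
  need <- max(1L, round(sustain * rate))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0L) return(NA_real_)
  (i0 + starts[ok[1]] - 2L) / rate
}

#' Check that decoded walking onsets precede movement and muscle activity
#'
#' For each decoded idle-to-walk transition, finds the first subsequent EMG
#' burst onset and gyroscope movement onset (threshold: quiescent-baseline
#' mean + 3 SD of the smoothed envelope) and reports the lead of the decoded
#' state over each. An event passes when the state onset does not follow
#' either movement measure; onsets with no threshold crossing are reported
#' as censored.
#'
#' @param session a \code{decoded_session} (or data frame with \code{time}
#'   and \code{state}).
#' @param gyro gyroscope trace; \code{gyro_rate} its rate (Hz).
#' @param emg EMG vector or channels x samples matrix (raw); \code{emg_rate}
#'   its rate (Hz).
#' @param gyro_rate,emg_rate sampling rates, Hz.
#' @param baseline quiescent baseline window \code{c(from, to)} in seconds
#'   used for the thresholds (default the first 5 s).
#' @param smooth envelope smoothing window, seconds (default 0.1).
#' @return An object of class \code{onset_report}: \code{events} data frame
#'   (\code{state_onset}, \code{emg_onset}, \code{gyro_onset},
#'   \code{emg_lead}, \code{gyro_lead}, \code{pass}, \code{censored}) and
#'   \code{pass} (TRUE iff every non-censored event passes).
#' @export
onset_ordering <- function(session, gyro, gyro_rate, emg, emg_rate,
                           baseline = c(0, 5), smooth = 0.1) {
  states <- if (inherits(session, "decoded_session")) session$states
            else session
  walk <- states$state == "WALK"
  onsets <- states$time[walk & !c(FALSE, walk[-length(walk)])]
  env_of <- function(x, rate) {
    k <- max(1L, round(smooth * rate))
    e <- stats::filter(abs(x - stats::median(x)), rep(1 / k, k), sides = 2)
    e[is.na(e)] <- 0
    as.numeric(e)
  }
  emg1 <- if (is.matrix(emg))
    sqrt(colMeans(preprocess_emg(emg, emg_rate)^2))
  else preprocess_emg(emg, emg_rate)
  env_e <- env_of(emg1, emg_rate)
  env_g <- env_of(gyro, gyro_rate)
  base_idx <- function(rate, n) {
    i <- (floor(baseline[1] * rate) + 1L):min(n, floor(baseline[2] * rate))
    i[i >= 1L]
  }
  bi_e <- base_idx(emg_rate, length(env_e))
  bi_g <- base_idx(gyro_rate, length(env_g))
  ev <- do.call(rbind, lapply(onsets, function(t0) {
    te <- .onset_after(env_e, emg_rate, t0 - 0.25,   # allow trace quantization
                       mean(env_e[bi_e]), stats::sd(env_e[bi_e]))
    tg <- .onset_after(env_g, gyro_rate, t0 - 0.25,
                       mean(env_g[bi_g]), stats::sd(env_g[bi_g]))
    data.frame(state_onset = t0, emg_onset = te, gyro_onset = tg,
               emg_lead = te - t0, gyro_lead = tg - t0,
               pass = !isTRUE(te < t0) && !isTRUE(tg < t0),
               censored = is.na(te) || is.na(tg))
  }))
  if (is.null(ev))
    ev <- data.frame(state_onset = numeric(0), emg_onset = numeric(0),
                     gyro_onset = numeric(0), emg_lead = numeric(0),
                     gyro_lead = numeric(0), pass = logical(0),
                     censored = logical(0))
  structure(list(events = ev,
                 pass = nrow(ev) > 0 && all(ev$pass)),
            class = "onset_report")
}

#' @export
print.onset_report <- function(x, ...) {
  cat(sprintf("<onset_report> %d walk onset(s), overall %s\n",
              nrow(x$events), if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
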