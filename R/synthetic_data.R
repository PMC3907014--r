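#' Synthetic-session configuration
#'
#' Describes the stated world the EEG generator emulates: a 1/f ("pink")
#' background with a white floor on every channel, and, on the modulated
#' channels, a band-limited rhythm whose power is multiplied during walking
#' epochs so that the single-window log band-power separation between the
#' classes equals \code{effect_size} (a d-prime; the event-related
#' (de)synchronization analog). Optional artifact channels carry large slow
#' drifts and spikes so the artifact screen has something to find.
#'
#' @param n_channels number of EEG channels (default 16).
#' @param rate sampling rate, Hz (default 256).
#' @param modulated_channels indices of channels carrying the class
#'   modulation (default \code{1:4}).
#' @param band modulated frequency band, Hz (default \code{c(8, 12)}).
#' @param effect_size requested single-window log band-power d-prime
#'   (default 2; 0 = no class information).
#' @param noise_exponent spectral exponent of the 1/f background (default 1).
#' @param white_floor fraction of background variance that is white
#'   (default 0.2).
#' @param background_sd background amplitude, uV (default 10).
#' @param sd_spread log-normal sigma of the per-channel background SD
#'   (default 0.25): real montages have heterogeneous channel variances, and
#'   without this spread any physiological band modulation would itself look
#'   like a variance outlier to the artifact screen.
#' @param band_amp amplitude of the band-limited rhythm relative to the
#'   background SD (default 0.7).
#' @param artifact_channels indices of artifact-contaminated channels
#'   (default none).
#' @param artifact_gain artifact amplitude relative to background SD
#'   (default 10).
#' @param seed RNG seed (mandatory).
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_channels = 16, rate = 256,
                         modulated_channels = 1:4, band = c(8, 12),
                         effect_size = 2, noise_exponent = 1,
                         white_floor = 0.2, background_sd = 10,
                         sd_spread = 0.25, band_amp = 0.7,
                         artifact_channels = integer(0),
                         artifact_gain = 10, seed) {
  if (missing(seed)) stop("'seed' is mandatory for synthetic data")
  stopifnot(effect_size >= 0,
            all(modulated_channels %in% seq_len(n_channels)),
            all(artifact_channels %in% seq_len(n_channels)))
  if (length(intersect(modulated_channels, artifact_channels)))
    stop("a channel cannot be both modulated and artifactual")
  structure(list(n_channels = n_channels, rate = rate,
                 modulated_channels = modulated_channels, band = band,
                 effect_size = effect_size, noise_exponent = noise_exponent,
                 white_floor = white_floor, background_sd = background_sd,
                 sd_spread = sd_spread, band_amp = band_amp,
                 artifact_channels = artifact_channels,
                 artifact_gain = artifact_gain, seed = as.integer(seed)),
            class = "synth_config")
}

.montage_1020 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3",
                   "Cz", "C4", "T8", "P3", "Pz", "P4", "O1", "Oz", "O2",
                   "FC1")

.synth_channel_names <- function(n) {
  if (n <= length(.montage_1020)) .montage_1020[seq_len(n)]
  else sprintf("ch%02d", seq_len(n))
}

# unit-SD 1/f^exponent noise via spectral shaping of white Gaussian noise
.pink_noise <- function(n, exponent) {
  x <- stats::rnorm(n)
  if (exponent == 0) return(x)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))           # avoid DC blow-up
  f <- pmin(f, n - f + 1)             # mirror for negative frequencies
  X <- X * f^(-exponent / 2)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

# unit-SD Gaussian noise band-limited to [lo, hi) Hz (hard spectral mask)
.band_noise <- function(n, rate, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)              # two-sided frequency axis
  X[f < band[1] | f >= band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

# complex band-restricted spectrum of one detrended+Hamming windowed segment
.band_fft <- function(x, rate, band) {
  n <- length(x)
  tt <- seq_len(n); tc <- tt - mean(tt)
  x <- x - mean(x) - sum(x * tc) / sum(tc^2) * tc
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  X <- stats::fft(x * w)
  f <- (seq_len(n) - 1) * rate / n
  X[f >= band[1] - 1e-9 & f < band[2] - 1e-9 & f <= rate / 2]
}

# Core generator: builds the recording for a cue schedule, applying the
# walk-epoch gain over the given modulation regions (data frame start/end in
# seconds). The gain is calibrated so the realized single-window log
# band-power d-prime on the modulated channels equals cfg$effect_size,
# solved exactly on the generated noise via the windows' complex spectra.
.generate_session <- function(cfg, cues, regions, win = 0.75) {
  set.seed(cfg$seed)
  span <- cue_span(cues)
  n <- round(span * cfg$rate)
  nch <- cfg$n_channels
  ch_sd <- cfg$background_sd * exp(stats::rnorm(nch, 0, cfg$sd_spread))
  bg <- matrix(0, nch, n)
  for (i in seq_len(nch)) {
    # slow multiplicative envelope: spontaneous waxing/waning of rhythm
    # amplitude, so every channel shows physiological nonstationarity
    env <- exp(0.2 * .band_noise(n, cfg$rate, c(0.02, 0.1)))
    bg[i, ] <- ch_sd[i] * env *
      (sqrt(1 - cfg$white_floor) * .pink_noise(n, cfg$noise_exponent) +
         sqrt(cfg$white_floor) * stats::rnorm(n))
  }
  a <- cfg$band_amp * cfg$background_sd
  comp <- matrix(0, length(cfg$modulated_channels), n)
  for (j in seq_along(cfg$modulated_channels))
    comp[j, ] <- a * .band_noise(n, cfg$rate, cfg$band)

  # calibration windows: non-overlapping win-second windows inside each
  # constant-gain region
  wlen <- round(win * cfg$rate)
  wins <- list()
  for (r in seq_len(nrow(regions))) {
    i0 <- floor(regions$start[r] * cfg$rate) + 1L
    i1 <- floor(regions$end[r] * cfg$rate)
    nw <- (i1 - i0 + 1L) %/% wlen
    for (j in seq_len(nw))
      wins[[length(wins) + 1L]] <-
        list(idx = (i0 + (j - 1L) * wlen):(i0 + j * wlen - 1L),
             walk = regions$walk[r])
  }
  walk_flag <- vapply(wins, `[[`, logical(1), "walk")
  gain <- 1
  dprime_of <- NULL
  if (cfg$effect_size > 0 && length(cfg$modulated_channels) > 0 &&
      any(walk_flag) && any(!walk_flag)) {
    # per (window, modulated channel): band power of bg + g * comp is
    # B + g^2 C + 2 g X with U, V the band-restricted complex spectra
    nwin <- length(wins); nmod <- length(cfg$modulated_channels)
    B <- C <- X <- matrix(0, nwin, nmod)
    for (k in seq_len(nwin)) {
      for (j in seq_len(nmod)) {
        U <- .band_fft(bg[cfg$modulated_channels[j], wins[[k]]$idx],
                       cfg$rate, cfg$band)
        V <- .band_fft(comp[j, wins[[k]]$idx], cfg$rate, cfg$band)
        B[k, j] <- sum(Mod(U)^2)
        C[k, j] <- sum(Mod(V)^2)
        X[k, j] <- sum(Re(U * Conj(V)))
      }
    }
    dprime_of <- function(g) {
      lw <- log10(pmax(B + g^2 * C + 2 * g * X, 1e-300))[walk_flag, ]
      li <- log10(pmax(B + C + 2 * X, 1e-300))[!walk_flag, ]
      (mean(lw) - mean(li)) /
        sqrt((stats::var(as.numeric(lw)) + stats::var(as.numeric(li))) / 2)
    }
    f <- function(g) dprime_of(g) - cfg$effect_size
    hi <- 10
    while (f(hi) < 0 && hi < 1e6) hi <- hi * 10
    gain <- stats::uniroot(f, c(1, hi), tol = 1e-6)$root
  }

  gvec <- rep(1, n)
  for (r in which(regions$walk)) {
    i0 <- floor(regions$start[r] * cfg$rate) + 1L
    i1 <- min(n, floor(regions$end[r] * cfg$rate))
    if (i1 >= i0) gvec[i0:i1] <- gain
  }
  samples <- bg
  for (j in seq_along(cfg$modulated_channels)) {
    ch <- cfg$modulated_channels[j]
    samples[ch, ] <- samples[ch, ] + comp[j, ] * gvec
  }
  for (ch in cfg$artifact_channels) {
    tt <- (seq_len(n) - 1) / cfg$rate
    drift <- cfg$artifact_gain * cfg$background_sd *
      sin(2 * pi * stats::runif(1, 0.3, 0.7) * tt + stats::runif(1, 0, 2 * pi))
    spikes <- numeric(n)
    n_spk <- stats::rpois(1, span * 0.5)
    if (n_spk > 0) {
      at <- sample.int(n, min(n_spk, n))
      spikes[at] <- stats::rnorm(length(at), 0,
                                 3 * cfg$artifact_gain * cfg$background_sd)
    }
    samples[ch, ] <- samples[ch, ] + drift + spikes
  }
  rec <- eeg_recording(samples, cfg$rate, .synth_channel_names(nch))
  attr(rec, "provenance") <- list(
    config = unclass(cfg), gain = gain,
    achieved_dprime = if (!is.null(dprime_of)) dprime_of(gain) else 0)
  rec
}

#' Generate a synthetic training session
#'
#' A 10-minute recording of 20 alternating 30-second idling/walking cue
#' epochs (idling first), with the class modulation described by the config
#' active throughout each walking epoch.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param n_epochs number of cue epochs (default 20).
#' @param epoch_s epoch duration, seconds (default 30).
#' @return List with \code{rec} (an \code{eeg_recording} carrying a
#'   \code{"provenance"} attribute with config, seed and realized gain) and
#'   \code{cues} (a \code{cue_schedule}).
#' @export
generate_training_session <- function(cfg, n_epochs = 20, epoch_s = 30) {
  labels <- rep(c("IDLE", "WALK"), length.out = n_epochs)
  cues <- cue_schedule(labels, onset = (seq_len(n_epochs) - 1) * epoch_s,
                       duration = rep(epoch_s, n_epochs))
  regions <- data.frame(start = cues$onset,
                        end = cues$onset + cues$duration,
                        walk = cues$label == "WALK")
  list(rec = .generate_session(cfg, cues, regions), cues = cues)
}

#' Generate a synthetic online-evaluation session
#'
#' Ten alternating 1-minute idling/walking cue epochs (idling first; 600 s
#' total). The class modulation follows each cue switch after a configurable
#' reaction delay, standing in for the user's response time.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param n_epochs number of cue epochs (default 10).
#' @param epoch_s epoch duration, seconds (default 60).
#' @param reaction_delay delay between a cue switch and the modulation
#'   change, seconds (default 1).
#' @return List with \code{rec} and \code{cues}, as for
#'   \code{\link{generate_training_session}}.
#' @export
generate_online_session <- function(cfg, n_epochs = 10, epoch_s = 60,
                                    reaction_delay = 1) {
  labels <- rep(c("IDLE", "WALK"), length.out = n_epochs)
  cues <- cue_schedule(labels, onset = (seq_len(n_epochs) - 1) * epoch_s,
                       duration = rep(epoch_s, n_epochs))
  span <- cue_span(cues)
  walk <- cues[cues$label == "WALK", , drop = FALSE]
  regions <- data.frame(
    start = pmin(walk$onset + reaction_delay, span),
    end = pmin(walk$onset + walk$duration + reaction_delay, span),
    walk = TRUE)
  # idle regions = complement (for calibration windows)
  bnd <- sort(unique(c(0, regions$start, regions$end, span)))
  idle <- data.frame(start = bnd[-length(bnd)], end = bnd[-1])
  idle$walk <- FALSE
  keep <- vapply(seq_len(nrow(idle)), function(i)
    !any(idle$start[i] >= regions$start - 1e-9 &
           idle$end[i] <= regions$end + 1e-9), logical(1))
  regions <- rbind(regions, idle[keep & idle$end - idle$start > 1, ])
  list(rec = .generate_session(cfg, cues, regions), cues = cues)
}

#' Generate synthetic gait EMG and gyroscope traces
#'
#' Emulates treadmill walking at a fixed velocity: the single-axis gyroscope
#' sees a periodic angular-velocity pattern (one cycle per stride) and the
#' three EMG channels (quadriceps, tibialis anterior, gastrocnemius) fire
#' broadband bursts phase-locked to the gait cycle. Burst amplitude depends
#' on the walking condition: \emph{active} (voluntary) > \emph{cooperative}
#' >> \emph{passive} (robot-driven, still nonzero) ~ \emph{decoded}
#' (BCI-driven, modelled as passive).
#'
#' @param condition one of \code{"active"}, \code{"cooperative"},
#'   \code{"passive"}, \code{"decoded"}.
#' @param duration trace duration, seconds (0 gives empty traces).
#' @param stride_period gait-cycle period, seconds (default 1.1, the cadence
#'   of slow 2 km/h treadmill walking).
#' @param emg_rate EMG sampling rate, Hz (default 4000).
#' @param gyro_rate gyroscope sampling rate, Hz (default 100).
#' @param amplitude_scale named amplitudes (mV) of the EMG bursts per
#'   condition.
#' @param seed RNG seed (mandatory).
#' @return List with \code{emg} (3 x n matrix, mV), \code{emg_rate},
#'   \code{gyro} (numeric vector, deg/s), \code{gyro_rate},
#'   \code{condition}, \code{stride_period}, \code{provenance}.
#' @export
generate_emg_gyro <- function(condition = c("active", "cooperative",
                                            "passive", "decoded"),
                              duration = 60, stride_period = 1.1,
                              emg_rate = 4000, gyro_rate = 100,
                              amplitude_scale = c(active = 1.0,
                                                  cooperative = 0.55,
                                                  passive = 0.12,
                                                  decoded = 0.13),
                              seed) {
  condition <- match.arg(condition)
  if (missing(seed)) stop("'seed' is mandatory for synthetic data")
  set.seed(seed)
  if (duration <= 0) {
    return(list(emg = matrix(0, 3, 0), emg_rate = emg_rate,
                gyro = numeric(0), gyro_rate = gyro_rate,
                condition = condition, stride_period = stride_period,
                provenance = list(seed = seed, duration = duration)))
  }
  ng <- round(duration * gyro_rate)
  tg <- (seq_len(ng) - 1) / gyro_rate
  phase <- 2 * pi * tg / stride_period
  gyro <- 80 * sin(phase) + 25 * sin(2 * phase + 0.8) +
    6 * stats::rnorm(ng)
  ne <- round(duration * emg_rate)
  te <- (seq_len(ne) - 1) / emg_rate
  ph <- (te / stride_period) %% 1
  burst <- function(center, width) {
    d <- pmin(abs(ph - center), 1 - abs(ph - center))
    ifelse(d < width / 2, 0.5 * (1 + cos(2 * pi * d / width)), 0)
  }
  amp <- amplitude_scale[[condition]]
  centers <- c(quadriceps = 0.05, tibialis = 0.60, gastrocnemius = 0.35)
  emg <- matrix(0, 3, ne, dimnames = list(names(centers), NULL))
  for (i in 1:3) {
    env <- amp * burst(centers[i], 0.30) + 0.02   # quiescent floor
    emg[i, ] <- env * stats::rnorm(ne)
  }
  list(emg = emg, emg_rate = emg_rate, gyro = gyro, gyro_rate = gyro_rate,
       condition = condition, stride_period = stride_period,
       provenance = list(seed = seed, duration = duration,
                         condition = condition, amplitude = amp,
                         stride_period = stride_period))
}

#' Write generator provenance JSON beside a data file
#'
#' @param path the data file the provenance describes; the JSON is written
#'   to \code{<path>.json}.
#' @param provenance named list (config, seed, realized parameters).
#' @param extra optional extra fields (e.g. \code{rate}).
#' @return The sidecar path, invisibly.
#' @export
write_provenance <- function(path, provenance, extra = list()) {
  side <- paste0(path, ".json")
  jsonlite::write_json(c(provenance, extra), side, auto_unbox = TRUE,
                       digits = NA)
  invisible(side)
}
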