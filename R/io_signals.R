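#' Construct an EEG recording
#'
#' Container for a multichannel EEG time series. Samples are stored as a
#' channels-by-time numeric matrix in microvolts; time is measured in seconds
#' on the session clock, with sample \code{i} (zero-based) covering
#' \code{[i/rate, (i+1)/rate)}.
#'
#' @param samples numeric matrix, channels x time (microvolts).
#' @param rate sampling rate in Hz (> 0).
#' @param channel_names character vector, one label per matrix row. Defaults
#'   to \code{"ch1"..."chN"}.
#' @param start_time session-clock time of the first sample, seconds.
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(samples, rate, channel_names = NULL, start_time = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a single positive number (Hz)")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_names) != nrow(samples))
    stop("number of channel names (", length(channel_names),
         ") does not match number of channels (", nrow(samples), ")")
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, rate = as.numeric(rate),
         channel_names = as.character(channel_names),
         start_time = as.numeric(start_time)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  cat(" channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an \code{eeg_recording}.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$rate

#' Construct a cue schedule
#'
#' Ordered, non-overlapping labelled intervals (\code{"IDLE"} / \code{"WALK"})
#' on the session clock. Intervals are half-open \code{[onset, onset+duration)}.
#' Entries are sorted by onset; overlapping entries are an error, and
#' non-alternating labels produce a warning only (generators guarantee
#' alternation, loaders merely check).
#'
#' @param label character vector of \code{"IDLE"}/\code{"WALK"} labels.
#' @param onset numeric vector of onsets, seconds.
#' @param duration numeric vector of durations, seconds (> 0).
#' @return An object of class \code{cue_schedule} (a data frame with columns
#'   \code{label}, \code{onset}, \code{duration}).
#' @export
cue_schedule <- function(label, onset, duration) {
  label <- toupper(as.character(label))
  if (!all(label %in% c("IDLE", "WALK")))
    stop("cue labels must be 'IDLE' or 'WALK'")
  if (length(label) != length(onset) || length(label) != length(duration))
    stop("label, onset and duration must have equal length")
  o <- order(onset)
  label <- label[o]; onset <- as.numeric(onset)[o]
  duration <- as.numeric(duration)[o]
  if (any(duration <= 0)) stop("cue durations must be positive")
  if (length(onset) > 1L &&
      any(onset[-1] < (onset + duration)[-length(onset)] - 1e-9))
    stop("cue intervals overlap")
  if (length(label) > 1L && any(label[-1] == label[-length(label)]))
    warning("cue labels do not alternate")
  structure(data.frame(label = label, onset = onset, duration = duration,
                       stringsAsFactors = FALSE),
            class = c("cue_schedule", "data.frame"))
}

#' Cue label at given session-clock times
#'
#' Looks each time up in the half-open cue intervals; times outside any cue
#' are idling.
#'
#' @param cues a \code{cue_schedule}.
#' @param times numeric vector of times, seconds.
#' @return Character vector of \code{"I"}/\code{"W"}.
#' @export
cue_labels_at <- function(cues, times) {
  out <- rep("I", length(times))
  for (i in seq_len(nrow(cues))) {
    if (cues$label[i] == "WALK") {
      sel <- times >= cues$onset[i] - 1e-9 &
        times < cues$onset[i] + cues$duration[i] - 1e-9
      out[sel] <- "W"
    }
  }
  out
}

#' Total span of a cue schedule
#' @param cues a \code{cue_schedule}.
#' @return end time of the last cue, seconds.
#' @export
cue_span <- function(cues) {
  if (nrow(cues) == 0L) return(0)
  max(cues$onset + cues$duration)
}

#' Read / write a cue schedule
#'
#' CSV dialect: header \code{label,onset_s,duration_s}; JSON dialect: an array
#' of objects with the same fields. Format is chosen by file extension.
#'
#' @param path file path (\code{.csv} or \code{.json}).
#' @return \code{read_cues}: a \code{cue_schedule}.
#' @export
read_cues <- function(path) {
  if (!file.exists(path)) stop("cue file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    d <- jsonlite::fromJSON(path)
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("label", "onset_s", "duration_s")
  if (!all(need %in% names(d)))
    stop("cue file must have fields: ", paste(need, collapse = ", "))
  cue_schedule(d$label, d$onset_s, d$duration_s)
}

#' @rdname read_cues
#' @param cues a \code{cue_schedule}.
#' @export
write_cues <- function(cues, path) {
  d <- data.frame(label = cues$label, onset_s = cues$onset,
                  duration_s = cues$duration)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(d, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Recording file I/O
# ---------------------------------------------------------------------------

#' Read a multichannel recording from disk
#'
#' Two formats are supported. The delimited-matrix dialect (\code{"tsv"}) is a
#' tab-separated text file whose first header row holds the channel names, one
#' column per channel and one row per sample; the sampling rate is not part of
#' the file and must be supplied via \code{rate} or a JSON sidecar
#' (\code{<path>.json} with a \code{rate} field). \code{"edf"} reads European
#' Data Format (EDF) files with a single data-record layout as written by
#' \code{\link{write_recording}}.
#'
#' @param path file to read.
#' @param format \code{"auto"} (by extension), \code{"tsv"} or \code{"edf"}.
#' @param rate sampling rate in Hz; required for \code{"tsv"} unless a sidecar
#'   file provides it.
#' @param na_action \code{"reject"} (default: any NA is a format error) or
#'   \code{"impute"} (NAs replaced by the channel median).
#' @return An \code{eeg_recording}.
#' @export
read_recording <- function(path, format = c("auto", "tsv", "edf"),
                           rate = NULL, na_action = c("reject", "impute")) {
  format <- match.arg(format)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  rec <- if (format == "edf") .read_edf(path) else {
    if (is.null(rate)) {
      sidecar <- paste0(path, ".json")
      if (file.exists(sidecar)) {
        meta <- jsonlite::fromJSON(sidecar)
        if (is.null(meta$rate))
          stop("sidecar ", sidecar, " lacks required field 'rate'")
        rate <- as.numeric(meta$rate)
      } else stop("sampling 'rate' required for delimited-matrix format ",
                  "(argument or <path>.json sidecar)")
    }
    .read_tsv_matrix(path, rate)
  }
  if (anyNA(rec$samples)) {
    if (na_action == "reject")
      stop("recording contains NA samples (field 'samples'); ",
           "use na_action = 'impute' to replace by channel medians")
    for (i in seq_len(nrow(rec$samples))) {
      bad <- is.na(rec$samples[i, ])
      if (any(bad))
        rec$samples[i, bad] <- stats::median(rec$samples[i, ], na.rm = TRUE)
    }
  }
  rec
}

.read_tsv_matrix <- function(path, rate) {
  d <- utils::read.delim(path, check.names = FALSE)
  if (ncol(d) < 1L) stop("delimited recording has no channels (header row)")
  m <- t(as.matrix(d))
  eeg_recording(m, rate = rate, channel_names = colnames(d))
}

#' Write a recording to disk
#'
#' @param rec an \code{eeg_recording}.
#' @param path destination file.
#' @param format \code{"auto"}, \code{"tsv"} or \code{"edf"}.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "tsv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  if (format == "edf") return(.write_edf(rec, path))
  d <- as.data.frame(t(rec$samples))
  names(d) <- rec$channel_names
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Minimal EDF (European Data Format) support: one data record holding the
# whole signal, 16-bit samples, physical range set from the data. Sufficient
# for round-tripping synthetic sessions; no annotations, no EDF+.
.write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  n  <- ncol(rec$samples)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) formatC(substr(x, 1, w), width = -w)
  wr  <- function(x, w) writeChar(pad(x, w), con, nchars = w, eos = NULL)
  phys_min <- apply(rec$samples, 1, min)
  phys_max <- apply(rec$samples, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1   # avoid zero scale
  # fixed header (256 bytes)
  wr("0", 8); wr("synthetic", 80); wr("gaitbci recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(256 + 256 * ns), 8)    # header bytes
  wr("", 44)
  wr("1", 8)                             # number of data records
  wr(format(n / rec$rate, digits = 10), 8)  # record duration (s)
  wr(as.character(ns), 4)
  # per-signal header fields, each field contiguous over signals
  for (nm in rec$channel_names) wr(nm, 16)
  for (i in seq_len(ns)) wr("EEG", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(phys_min[i], digits = 8), 8)
  for (i in seq_len(ns)) wr(format(phys_max[i], digits = 8), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(n), 8)
  for (i in seq_len(ns)) wr("", 32)
  for (i in seq_len(ns)) {
    scale <- (phys_max[i] - phys_min[i]) / 65535
    dig <- as.integer(round((rec$samples[i, ] - phys_min[i]) / scale) - 32768)
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  dur  <- as.numeric(rd(8))
  ns   <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("EDF parse error: signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min  <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max  <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  chunks <- vector("list", ns)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[i], size = 2L, signed = TRUE,
                     endian = "little")
      scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      chunks[[i]] <- c(chunks[[i]], phys_min[i] + (dig - dig_min[i]) * scale)
    }
  }
  m <- do.call(rbind, chunks)
  rate <- nsamp[1] / dur * 1  # samples per record / record duration
  eeg_recording(m, rate = rate, channel_names = labels)
}

# ---------------------------------------------------------------------------
# Artifact channel exclusion
# ---------------------------------------------------------------------------

#' Exclude channels with excessive artifacts
#'
#' Automated screen applied before model training: a channel is retained when
#' the robust z-scores (median/MAD) of both its log-variance and its moment
#' kurtosis fall below \code{z_thresh}. Channels dominated by drift, movement
#' or electrode pops have outlying variance and/or kurtosis and are dropped.
#' Deterministic; permuting channels permutes the retained set identically.
#'
#' @param rec an \code{eeg_recording}.
#' @param z_thresh positive robust z-score threshold (default 3).
#' @return Character vector of retained channel names, with attribute
#'   \code{"index"} giving their row indices.
#' @export
exclude_artifact_channels <- function(rec, z_thresh = 3) {
  stopifnot(z_thresh > 0)
  nch <- nrow(rec$samples)
  if (nch < 2L) {
    warning("single-channel recording: artifact screening skipped")
    return(structure(rec$channel_names, index = seq_len(nch)))
  }
  logvar <- log(apply(rec$samples, 1, stats::var) + .Machine$double.eps)
  kurt <- apply(rec$samples, 1, function(x) {
    m2 <- mean((x - mean(x))^2)
    if (m2 <= 0) return(0)
    mean((x - mean(x))^4) / m2^2
  })
  rz <- function(x) {
    s <- stats::mad(x)
    if (s <= 0) ifelse(abs(x - stats::median(x)) <= .Machine$double.eps^0.5,
                       0, Inf)
    else abs(x - stats::median(x)) / s
  }
  keep <- rz(logvar) < z_thresh & rz(kurt) < z_thresh
  if (!any(keep))
    stop("all channels excluded as artifactual; raise z_thresh")
  structure(rec$channel_names[keep], index = which(keep))
}

#' Subset a recording to a channel set
#' @param rec an \code{eeg_recording}.
#' @param channels channel names or indices to keep, in order.
#' @return An \code{eeg_recording} with the selected channels.
#' @export
select_channels <- function(rec, channels) {
  if (is.character(channels)) {
    idx <- match(channels, rec$channel_names)
    if (anyNA(idx)) stop("unknown channel(s): ",
                         paste(channels[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(channels)
  eeg_recording(rec$samples[idx, , drop = FALSE], rec$rate,
                rec$channel_names[idx], rec$start_time)
}

# ---------------------------------------------------------------------------
# Epoching
# ---------------------------------------------------------------------------

#' Slice a recording by cue intervals
#'
#' Sample-accurate, half-open slicing: cue \code{[onset, onset+duration)}
#' yields the samples whose time stamps fall in the interval. A gap-free
#' alternating schedule reconstructs the recording exactly when its slices
#' are concatenated.
#'
#' @param rec an \code{eeg_recording}.
#' @param cues a \code{cue_schedule}; every interval must lie within the
#'   recording.
#' @return A list with one element per cue entry: \code{list(label, rec)}
#'   where \code{rec} is the sliced \code{eeg_recording} (its
#'   \code{start_time} set to the cue onset).
#' @export
epoch_by_cues <- function(rec, cues) {
  n <- ncol(rec$samples)
  out <- vector("list", nrow(cues))
  for (i in seq_len(nrow(cues))) {
    a <- cues$onset[i] - rec$start_time
    b <- a + cues$duration[i]
    i0 <- floor(a * rec$rate + 1e-9) + 1   # 1-based first sample
    i1 <- floor(b * rec$rate + 1e-9)       # 1-based last sample (half-open)
    if (i0 < 1L || i1 > n)
      stop(sprintf("cue %d [%g, %g) lies outside the recording (%g s)",
                   i, cues$onset[i], cues$onset[i] + cues$duration[i],
                   rec$start_time + n / rec$rate))
    out[[i]] <- list(
      label = cues$label[i],
      rec = eeg_recording(rec$samples[, i0:i1, drop = FALSE], rec$rate,
                          rec$channel_names, start_time = cues$onset[i]))
  }
  out
}

# ---------------------------------------------------------------------------
# Spectral features
# ---------------------------------------------------------------------------

# One-sided periodogram of a channels-x-samples matrix: linear detrend,
# Hamming taper, scaled so that sum(psd) * (rate/N) ~= signal power.
# Returns list(freq, psd) with psd a (nfreq x channels) matrix.
.periodogram <- function(m, rate) {
  n <- ncol(m)
  tt <- seq_len(n)
  # linear detrend (closed form, applied to all channels at once)
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  slope <- (m %*% tc) / denom
  m <- m - rowMeans(m) - slope %*% t(tc)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))  # Hamming
  mw <- sweep(m, 2, w, `*`)
  X <- stats::mvfft(t(mw))
  nf <- floor(n / 2) + 1L
  p <- (Mod(X[seq_len(nf), , drop = FALSE])^2) / (rate * sum(w^2))
  # one-sided: double all but DC (and Nyquist when n even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  p <- p * dbl
  list(freq = (seq_len(nf) - 1) * rate / n, psd = p)
}

# integrate a periodogram over half-open [lo, hi) bins -> B x C matrix
.integrate_bins <- function(pg, edges, rate_over_n) {
  B <- length(edges) - 1L
  out <- matrix(0, B, ncol(pg$psd))
  for (b in seq_len(B)) {
    sel <- pg$freq >= edges[b] - 1e-9 & pg$freq < edges[b + 1] - 1e-9
    if (any(sel))
      out[b, ] <- colSums(pg$psd[sel, , drop = FALSE]) * rate_over_n
  }
  out
}

#' Band-power features of a short EEG segment
#'
#' Computes a single detrended, Hamming-windowed periodogram per channel
#' (segments are too short for Welch averaging) and integrates it over
#' half-open \code{bin_width}-Hz bins covering \code{[F_L, F_H)}. The
#' integrated powers approximately satisfy Parseval's identity: summed over
#' the full band they equal the band-limited signal power.
#'
#' @param segment an \code{eeg_recording} (typically a 0.75-s analysis
#'   window), or a channels-x-samples matrix with \code{rate} supplied.
#' @param band numeric \code{c(F_L, F_H)} in Hz; \code{F_H} must not exceed
#'   the Nyquist frequency.
#' @param bin_width bin width in Hz (default 2).
#' @param rate sampling rate, needed only when \code{segment} is a bare
#'   matrix.
#' @return An object of class \code{spectral_features}: list with
#'   \code{values} (B x C matrix of integrated powers, uV^2),
#'   \code{bin_edges} (length B+1), \code{channel_names},
#'   \code{window_onset} (seconds).
#' @export
compute_psd_features <- function(segment, band = c(8, 12), bin_width = 2,
                                 rate = NULL) {
  if (inherits(segment, "eeg_recording")) {
    m <- segment$samples; rate <- segment$rate
    chn <- segment$channel_names; onset <- segment$start_time
  } else {
    m <- as.matrix(segment)
    if (is.null(rate)) stop("'rate' required for matrix input")
    chn <- rownames(m); onset <- NA_real_
  }
  if (length(band) != 2L || band[1] >= band[2])
    stop("'band' must be c(F_L, F_H) with F_L < F_H")
  if (band[2] > rate / 2 + 1e-9)
    stop(sprintf("upper band edge %g Hz exceeds Nyquist (%g Hz)",
                 band[2], rate / 2))
  edges <- seq(band[1], band[2], by = bin_width)
  if (abs(edges[length(edges)] - band[2]) > 1e-9)
    stop("band width must be a multiple of bin_width")
  if (length(edges) < 2L) stop("band must contain at least one bin")
  pg <- .periodogram(m, rate)
  vals <- .integrate_bins(pg, edges, rate / ncol(m))
  rownames(vals) <- sprintf("%g-%gHz", edges[-length(edges)], edges[-1])
  colnames(vals) <- chn
  structure(list(values = vals, bin_edges = edges, channel_names = chn,
                 window_onset = onset),
            class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf("<spectral_features> %d bin(s) x %d channel(s), [%g, %g) Hz\n",
              nrow(x$values), ncol(x$values),
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Config files
# ---------------------------------------------------------------------------

#' Read a key-value config file
#'
#' Accepts lines of the form \code{key = value} or \code{key: value};
#' \code{#} starts a comment. Values that parse as numbers become numeric.
#'
#' @param path config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
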