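#' Construct a continuous sensor recording
#'
#' @param data channels x samples numeric matrix (no NAs).
#' @param rate sampling rate in Hz.
#' @param channel_ids character channel labels (default `MEG001`...).
#' @param sensors optional [make_sensor_array()] geometry whose sensor count
#'   must match the channel count.
#' @return an object of class `sensor_recording`.
#' @export
sensor_recording <- function(data, rate, channel_ids = NULL, sensors = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("recording contains NAs")
  if (rate <= 0) stop("rate must be positive")
  if (is.null(channel_ids))
    channel_ids <- sprintf("MEG%03d", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data))
    stop("channel_ids length must match channel count")
  if (!is.null(sensors) && nrow(sensors$positions) != nrow(data))
    stop("sensor geometry does not match channel count")
  structure(list(data = data, rate = rate, channel_ids = channel_ids,
                 sensors = sensors),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d channels, %.1f s at %g Hz\n",
              nrow(x$data), ncol(x$data) / x$rate, x$rate))
  invisible(x)
}

# Least-squares removal of stationary sinusoids at the given frequencies
# (the "DFT filter" approach to line noise: fit sine + cosine over the
# whole record and subtract).
.dft_notch <- function(x, rate, freqs) {
  n <- length(x)
  t <- (seq_len(n) - 1) / rate
  for (f in freqs) {
    if (f >= rate / 2) next
    s <- sin(2 * pi * f * t); co <- cos(2 * pi * f * t)
    x <- x - s * (2 * sum(x * s) / n) - co * (2 * sum(x * co) / n)
  }
  x
}

#' Apply the standard preprocessing filters
#'
#' Zero-phase Butterworth high-pass at 1 Hz and low-pass at 170 Hz, plus
#' removal of the 50/100/150 Hz line-noise components by subtracting their
#' least-squares sinusoid fit (DFT filter). Same shape and rate out.
#'
#' @param x a [sensor_recording()].
#' @param hp_hz high-pass corner in Hz.
#' @param lp_hz low-pass corner in Hz.
#' @param notch_hz line frequencies to remove (set `NULL` to skip).
#' @param order Butterworth prototype order.
#' @return a filtered [sensor_recording()].
#' @export
apply_standard_filters <- function(x, hp_hz = 1, lp_hz = 170,
                                   notch_hz = c(50, 100, 150), order = 4) {
  stopifnot(inherits(x, "sensor_recording"))
  if (x$rate <= 2 * lp_hz)
    stop("sampling rate too low for the requested low-pass")
  hp <- butter_sos(order, hp_hz, "high", x$rate)
  lp <- butter_sos(order, lp_hz, "low", x$rate)
  for (ch in seq_len(nrow(x$data))) {
    v <- sos_filtfilt(hp, x$data[ch, ])
    v <- sos_filtfilt(lp, v)
    if (length(notch_hz)) v <- .dft_notch(v, x$rate, notch_hz)
    x$data[ch, ] <- v
  }
  x
}

#' Downsample a recording
#'
#' Anti-alias low-pass at `0.8 * target / 2` followed by spline resampling
#' onto the new grid.
#'
#' @param x a [sensor_recording()].
#' @param target new rate in Hz (must be below the current rate).
#' @return a [sensor_recording()] at `target` Hz.
#' @export
downsample <- function(x, target) {
  stopifnot(inherits(x, "sensor_recording"))
  if (target >= x$rate) stop("target rate must be below the current rate")
  out <- t(apply(x$data, 1, resample_signal, rate = x$rate, target = target))
  if (nrow(x$data) == 1) out <- matrix(out, nrow = 1)
  sensor_recording(out, target, x$channel_ids, x$sensors)
}

#' Epoch a recording into fixed-length segments
#'
#' Cuts the continuous recording (and, when given, the aligned stimulus
#' envelope) into non-overlapping contiguous segments of `len_s` seconds;
#' a trailing partial segment is discarded.
#'
#' @param x a [sensor_recording()].
#' @param len_s epoch length in seconds (default 1).
#' @param envelope optional aligned [envelope_signal()] at the same rate
#'   covering the same time span.
#' @param condition,subject_id,group optional metadata; `condition` is
#'   recycled over trials.
#' @return an object of class `epoch_set` with fields `epochs`
#'   (trials x channels x samples), `envelope_epochs` (trials x samples or
#'   NULL), `rate`, `epoch_len_s`, `condition`, `subject_id`, `group`,
#'   `channel_ids`, `sensors`.
#' @export
epoch_recording <- function(x, len_s = 1, envelope = NULL, condition = NA,
                            subject_id = NA, group = NA) {
  stopifnot(inherits(x, "sensor_recording"))
  ns <- round(len_s * x$rate)
  if (abs(ns - len_s * x$rate) > 1e-9)
    stop("epoch length must be an integer number of samples")
  n_trials <- ncol(x$data) %/% ns
  if (n_trials < 1) stop("recording shorter than one epoch")
  env_ep <- NULL
  if (!is.null(envelope)) {
    stopifnot(inherits(envelope, "envelope_signal"))
    if (abs(envelope$rate - x$rate) > 1e-9)
      stop("envelope rate does not match recording rate")
    if (abs(length(envelope$samples) - ncol(x$data)) > 1)
      stop(sprintf("envelope/recording span mismatch: %d vs %d samples",
                   length(envelope$samples), ncol(x$data)))
    env_ep <- matrix(envelope$samples[seq_len(n_trials * ns)],
                     nrow = n_trials, byrow = TRUE)
  }
  ep <- array(0, c(n_trials, nrow(x$data), ns))
  for (k in seq_len(n_trials))
    ep[k, , ] <- x$data[, ((k - 1) * ns + 1):(k * ns), drop = FALSE]
  structure(list(epochs = ep, envelope_epochs = env_ep, rate = x$rate,
                 epoch_len_s = len_s,
                 condition = rep_len(as.character(condition), n_trials),
                 subject_id = subject_id, group = group,
                 channel_ids = x$channel_ids, sensors = x$sensors),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples at %g Hz\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3], x$rate))
  if (!all(is.na(x$condition)))
    cat("  conditions:", paste(names(table(x$condition)),
                               table(x$condition), sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Subset trials of an epoch set
#'
#' @param e an `epoch_set`.
#' @param trials integer or logical trial index.
#' @return the subsetted `epoch_set`.
#' @export
subset_trials <- function(e, trials) {
  stopifnot(inherits(e, "epoch_set"))
  e$epochs <- e$epochs[trials, , , drop = FALSE]
  if (!is.null(e$envelope_epochs))
    e$envelope_epochs <- e$envelope_epochs[trials, , drop = FALSE]
  e$condition <- e$condition[trials]
  e
}

#' Screen epochs for artifacts
#'
#' Computes per-trial, per-channel variance and range, summarizes them per
#' trial (and per channel), and rejects trials and channels whose robust
#' z-score (median/MAD) of either metric exceeds `z_thresh`. This is the
#' automatic analogue of variance/range pre-screening of outlying
#' trials and channels.
#'
#' @param e an `epoch_set` with at least 5 trials.
#' @param z_thresh robust z-score threshold (default 5).
#' @return a list with `epochs` (the cleaned `epoch_set`) and `report`
#'   (class `rejection_report`: rejected trial indices, rejected channel
#'   labels, and the criteria used).
#' @export
screen_artifacts <- function(e, z_thresh = 5) {
  stopifnot(inherits(e, "epoch_set"))
  n_trials <- dim(e$epochs)[1]
  if (n_trials < 5) stop("need at least 5 trials to screen")
  v <- apply(e$epochs, c(1, 2), var)
  r <- apply(e$epochs, c(1, 2), function(z) diff(range(z)))
  rz <- function(m) {
    med <- median(m); s <- mad(m)
    if (s == 0) s <- .Machine$double.eps
    (m - med) / s
  }
  trial_bad <- rz(rowMeans(v)) > z_thresh | rz(rowMeans(r)) > z_thresh
  chan_bad <- rz(colMeans(v)) > z_thresh | rz(colMeans(r)) > z_thresh
  if (all(trial_bad)) stop("all trials rejected; data degenerate")
  report <- structure(list(rejected_trials = which(trial_bad),
                           rejected_channels = e$channel_ids[chan_bad],
                           criteria = list(z_thresh = z_thresh,
                                           metrics = c("variance", "range"))),
                      class = "rejection_report")
  out <- subset_trials(e, !trial_bad)
  if (any(chan_bad)) {
    out$epochs <- out$epochs[, !chan_bad, , drop = FALSE]
    out$channel_ids <- out$channel_ids[!chan_bad]
    if (!is.null(out$sensors)) {
      out$sensors$positions <- out$sensors$positions[!chan_bad, , drop = FALSE]
      out$sensors$orientations <- out$sensors$orientations[!chan_bad, , drop = FALSE]
    }
  }
  list(epochs = out, report = report)
}
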