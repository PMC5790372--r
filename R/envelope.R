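#' Cochlear filterbank specification
#'
#' Parameters of the envelope-extraction filterbank: `n_bands` contiguous
#' band-pass filters between `lo_hz` and `hi_hz` whose edges are equally
#' spaced along the human basilar membrane, i.e. images of an arithmetic
#' sequence of cochlear positions under the Greenwood frequency-position
#' map `F(p) = A (10^(a p) - k)` with `p` the relative distance from the
#' apex in `[0, 1]`.
#'
#' @param n_bands number of bands (default 9).
#' @param lo_hz,hi_hz frequency range in Hz (defaults 100 and 1000).
#' @param filter_order Butterworth prototype order (default 4).
#' @param greenwood_A,greenwood_a,greenwood_k constants of the human
#'   Greenwood map (defaults 165.4, 2.1, 0.88).
#' @return an object of class `filterbank_spec`.
#' @export
filterbank_spec <- function(n_bands = 9, lo_hz = 100, hi_hz = 1000,
                            filter_order = 4, greenwood_A = 165.4,
                            greenwood_a = 2.1, greenwood_k = 0.88) {
  if (n_bands < 1) stop("n_bands must be >= 1")
  if (lo_hz >= hi_hz) stop("need lo_hz < hi_hz")
  structure(list(n_bands = as.integer(n_bands), lo_hz = lo_hz, hi_hz = hi_hz,
                 filter_order = as.integer(filter_order),
                 greenwood_A = greenwood_A, greenwood_a = greenwood_a,
                 greenwood_k = greenwood_k),
            class = "filterbank_spec")
}

.greenwood <- function(p, spec) {
  spec$greenwood_A * (10^(spec$greenwood_a * p) - spec$greenwood_k)
}

.greenwood_inv <- function(f, spec) {
  log10(f / spec$greenwood_A + spec$greenwood_k) / spec$greenwood_a
}

#' Basilar-membrane-spaced band edges
#'
#' Returns `n_bands + 1` increasing frequencies whose preimages under the
#' Greenwood map are equally spaced cochlear positions, with the first and
#' last edge pinned to `lo_hz` and `hi_hz`.
#'
#' @param spec a [filterbank_spec()].
#' @return numeric vector of band edges in Hz.
#' @export
basilar_edges <- function(spec) {
  stopifnot(inherits(spec, "filterbank_spec"))
  p <- seq(.greenwood_inv(spec$lo_hz, spec), .greenwood_inv(spec$hi_hz, spec),
           length.out = spec$n_bands + 1)
  edges <- .greenwood(p, spec)
  edges[1] <- spec$lo_hz
  edges[spec$n_bands + 1] <- spec$hi_hz
  edges
}

#' Construct an envelope signal
#'
#' @param samples nonnegative numeric vector.
#' @param rate sampling rate in Hz.
#' @param normalized logical; if `TRUE`, `max(samples)` is 1.
#' @return an object of class `envelope_signal`.
#' @export
envelope_signal <- function(samples, rate, normalized = FALSE) {
  samples <- as.numeric(samples)
  if (normalized && length(samples) && max(samples) > 0)
    stopifnot(abs(max(samples) - 1) < 1e-12)
  structure(list(samples = samples, rate = rate, normalized = normalized),
            class = "envelope_signal")
}

#' Extract the broadband speech amplitude envelope
#'
#' Band-pass filters the waveform into the spec's cochlear-spaced bands with
#' a zero-phase (forward-backward) Butterworth filter, takes the modulus of
#' the analytic (Hilbert) signal in each band, sums the band envelopes and
#' scales the sum to a maximum of 1. The result is the slow amplitude
#' modulation that carries the syllabic rhythm of speech.
#'
#' @param x an [audio_signal()] with `rate > 2 * hi_hz`.
#' @param spec a [filterbank_spec()].
#' @return an [envelope_signal()] at the audio rate, normalized to max 1.
#' @export
extract_speech_envelope <- function(x, spec = filterbank_spec()) {
  stopifnot(inherits(x, "audio_signal"), inherits(spec, "filterbank_spec"))
  if (x$rate <= 2 * spec$hi_hz)
    stop("audio rate must exceed twice the filterbank's upper edge")
  if (x$duration_s < 0.5) stop("signal too short for stable band filtering")
  edges <- basilar_edges(spec)
  env <- numeric(length(x$samples))
  for (b in seq_len(spec$n_bands)) {
    sos <- butter_sos(spec$filter_order, c(edges[b], edges[b + 1]),
                      "pass", x$rate)
    xb <- sos_filtfilt(sos, x$samples)
    env <- env + Mod(analytic_signal(xb))
  }
  m <- max(env)
  if (m > 0) env <- env / m
  envelope_signal(env, x$rate, normalized = m > 0)
}

#' Align a stimulus envelope with preprocessed sensor data
#'
#' Passes the envelope through the same chain as the sensor recordings --
#' the standard filters (high-pass, low-pass, line-noise removal) followed
#' by anti-aliased downsampling -- so that envelope and MEG samples stay on
#' one grid and can be epoched together.
#'
#' @param e an [envelope_signal()].
#' @param target_rate output rate in Hz (the preprocessed sensor rate).
#' @param hp_hz,lp_hz,notch_hz filter-chain parameters, matching
#'   [apply_standard_filters()] defaults.
#' @param expected_duration_s optional recording duration; a mismatch of
#'   more than one output sample raises an alignment error reporting the
#'   offset.
#' @return an [envelope_signal()] at `target_rate` (not re-normalized; the
#'   high-pass removes the mean, so values may be negative).
#' @export
align_envelope_to_recording <- function(e, target_rate, hp_hz = 1,
                                        lp_hz = 170, notch_hz = c(50, 100, 150),
                                        expected_duration_s = NULL) {
  stopifnot(inherits(e, "envelope_signal"))
  if (e$rate < target_rate) stop("envelope rate must be >= target_rate")
  if (!is.null(expected_duration_s)) {
    offset <- length(e$samples) / e$rate - expected_duration_s
    if (abs(offset) > 1 / target_rate)
      stop(sprintf("stimulus/recording duration mismatch: offset %.4f s", offset))
  }
  rec <- sensor_recording(matrix(e$samples, nrow = 1), e$rate,
                          channel_ids = "envelope")
  rec <- apply_standard_filters(rec, hp_hz = hp_hz, lp_hz = lp_hz,
                                notch_hz = notch_hz)
  rec <- downsample(rec, target_rate)
  envelope_signal(rec$data[1, ], target_rate, normalized = FALSE)
}
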