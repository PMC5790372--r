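#' Cross-spectral density of epoched data and envelope
#'
#' Applies a Hanning taper to every 1 s segment, Fourier transforms each
#' channel together with the aligned stimulus envelope, and averages the
#' cross-terms over trials on an integer frequency grid. The envelope enters
#' as an extra channel labelled `"envelope"`.
#'
#' @param e an `epoch_set` (with `envelope_epochs` unless `with_envelope`
#'   is `FALSE`).
#' @param fmin,fmax,step frequency grid in Hz (defaults 1, 30, 1). `step`
#'   must be a multiple of the epoch's spectral resolution
#'   `1 / epoch_len_s`; there is no implicit padding.
#' @param with_envelope include the envelope channel (default if present).
#' @return an object of class `csd` with fields `freqs`, `S` (complex array
#'   `n_channels x n_channels x n_freqs`, Hermitian per frequency),
#'   `n_trials`, `taper`, `channel_ids`.
#' @export
compute_csd <- function(e, fmin = 1, fmax = 30, step = 1,
                        with_envelope = !is.null(e$envelope_epochs)) {
  stopifnot(inherits(e, "epoch_set"))
  ns <- dim(e$epochs)[3]
  res <- 1 / e$epoch_len_s
  if (step < res - 1e-9 || abs(step / res - round(step / res)) > 1e-9)
    stop("step must be a multiple of the spectral resolution 1/epoch_len_s")
  freqs <- seq(fmin, fmax, by = step)
  bins <- round(freqs * e$epoch_len_s) + 1L
  if (any(bins > ns)) stop("requested frequencies above Nyquist")
  n_trials <- dim(e$epochs)[1]
  nch <- dim(e$epochs)[2]
  ids <- e$channel_ids
  if (with_envelope) {
    if (is.null(e$envelope_epochs)) stop("epoch_set has no envelope")
    ids <- c(ids, "envelope")
  }
  nc <- nch + as.integer(with_envelope)
  w <- .hanning(ns)
  norm <- sqrt(2 / (sum(w^2) * e$rate))
  S <- array(0 + 0i, c(nc, nc, length(freqs)))
  for (tr in seq_len(n_trials)) {
    x <- e$epochs[tr, , , drop = TRUE]
    if (nch == 1) x <- matrix(x, nrow = 1)
    if (with_envelope) x <- rbind(x, e$envelope_epochs[tr, ])
    X <- t(mvfft(t(x * rep(w, each = nc)))) * norm
    Xf <- X[, bins, drop = FALSE]
    for (fi in seq_along(freqs))
      S[, , fi] <- S[, , fi] + tcrossprod(Xf[, fi], Conj(Xf[, fi]))
  }
  structure(list(freqs = freqs, S = S / n_trials, n_trials = n_trials,
                 taper = "hanning", channel_ids = ids),
            class = "csd")
}

#' Coherence spectrum between two channels
#'
#' Magnitude coherence `|S_xy| / sqrt(S_xx S_yy)` from a trial-averaged
#' cross-spectral density, with the Fisher z-transform `atanh(coh)` for
#' variance stabilization. A coherence of exactly 1 maps to `Inf` and is
#' flagged with a warning; zero power in either channel yields `NaN` with
#' a warning rather than a silent 0.
#'
#' @param csd a [compute_csd()] result.
#' @param x,y channel labels or indices.
#' @return an object of class `coherence_spectrum` with `freqs`, `coh`,
#'   `z`, `n_trials`, `pair`.
#' @export
coherence <- function(csd, x, y) {
  stopifnot(inherits(csd, "csd"))
  ix <- if (is.character(x)) match(x, csd$channel_ids) else as.integer(x)
  iy <- if (is.character(y)) match(y, csd$channel_ids) else as.integer(y)
  if (is.na(ix) || is.na(iy)) stop("unknown channel")
  sxx <- Re(csd$S[ix, ix, ]); syy <- Re(csd$S[iy, iy, ])
  sxy <- csd$S[ix, iy, ]
  den <- sqrt(sxx * syy)
  coh <- Mod(sxy) / den
  if (any(!is.finite(coh))) warning("zero power at some frequencies; coherence undefined there")
  if (any(coh >= 1 - 1e-12, na.rm = TRUE) && csd$n_trials > 1)
    warning("coherence of 1 encountered; Fisher z is infinite there")
  structure(list(freqs = csd$freqs, coh = coh, z = atanh(pmin(coh, 1)),
                 n_trials = csd$n_trials,
                 pair = c(csd$channel_ids[ix], csd$channel_ids[iy])),
            class = "coherence_spectrum")
}

#' Cerebro-acoustic coherence of every channel with the envelope
#'
#' @param csd a [compute_csd()] result that includes the envelope channel.
#' @return a `coherence_spectrum` whose `coh`/`z` are
#'   `n_channels x n_freqs` matrices (envelope channel excluded).
#' @export
envelope_coherence <- function(csd) {
  stopifnot(inherits(csd, "csd"))
  ie <- match("envelope", csd$channel_ids)
  if (is.na(ie)) stop("csd has no envelope channel")
  nch <- length(csd$channel_ids) - 1L
  coh <- matrix(0, nch, length(csd$freqs),
                dimnames = list(csd$channel_ids[-ie], NULL))
  see <- Re(csd$S[ie, ie, ])
  for (ch in seq_len(nch)) {
    sxx <- Re(csd$S[ch, ch, ])
    coh[ch, ] <- Mod(csd$S[ch, ie, ]) / sqrt(sxx * see)
  }
  structure(list(freqs = csd$freqs, coh = coh, z = atanh(pmin(coh, 1)),
                 n_trials = csd$n_trials, pair = c("sensors", "envelope")),
            class = "coherence_spectrum")
}

#' Mean sensor coherence spectrum over a region of interest
#'
#' Averages the Fisher-z cerebro-acoustic coherence across the given
#' channels per frequency, e.g. over bilateral temporal sensors, and
#' locates the spectral peak.
#'
#' @param e an `epoch_set` with envelope epochs.
#' @param roi channel labels or indices (non-empty).
#' @param fmin,fmax,step frequency grid, as in [compute_csd()].
#' @return a list with `freqs`, `z` (mean z-coherence per frequency) and
#'   `peak_hz` (frequency of the maximum).
#' @export
sensor_coherence_spectrum <- function(e, roi, fmin = 1, fmax = 30, step = 1) {
  if (length(roi) == 0) stop("roi must be non-empty")
  csd <- compute_csd(e, fmin, fmax, step)
  ec <- envelope_coherence(csd)
  idx <- if (is.character(roi)) match(roi, rownames(ec$z)) else as.integer(roi)
  if (anyNA(idx)) stop("unknown roi channel")
  z <- colMeans(ec$z[idx, , drop = FALSE])
  list(freqs = ec$freqs, z = z, peak_hz = ec$freqs[which.max(z)])
}
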