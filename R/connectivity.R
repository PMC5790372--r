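# Per-trial Hanning-tapered spectra of two virtual sensors, zero-padded to
# pad_s seconds. Returns trials x nbins complex matrices and the frequency
# grid (0..fmax).
.pair_spectra <- function(x1, x2, pad_s = 2, fmax = 50) {
  stopifnot(inherits(x1, "virtual_sensor"), inherits(x2, "virtual_sensor"))
  if (nrow(x1$epochs) != nrow(x2$epochs)) stop("trial counts differ")
  if (abs(x1$rate - x2$rate) > 1e-9) stop("rates differ")
  ns <- ncol(x1$epochs)
  npad <- round(pad_s * x1$rate)
  if (npad < ns) stop("padding shorter than the epoch")
  w <- .hanning(ns)
  n_trials <- nrow(x1$epochs)
  pad <- function(m) cbind(m * rep(w, each = n_trials),
                           matrix(0, n_trials, npad - ns))
  X1 <- t(mvfft(t(pad(x1$epochs))))
  X2 <- t(mvfft(t(pad(x2$epochs))))
  freqs <- (seq_len(npad) - 1) / pad_s
  keep <- freqs <= fmax + 1e-9
  list(X1 = X1[, keep, drop = FALSE], X2 = X2[, keep, drop = FALSE],
       freqs = freqs[keep], n_trials = n_trials)
}

#' Phase-locking value spectrum between two virtual sensors
#'
#' Per trial, both series are Hanning-tapered, zero-padded to 2 s and
#' Fourier transformed; per frequency the cross-spectrum is normalized to
#' unit amplitude and averaged over trials:
#' `plv(f) = |mean_t S12 / |S12||`. Amplitude fluctuations therefore do not
#' contribute -- only phase consistency does. The Fisher z-transform
#' `atanh` is applied for variance stabilization.
#'
#' @param x1,x2 `virtual_sensor` objects with equal trial counts and rates.
#' @param pad_s padded length in seconds (default 2, giving 0.5 Hz bins).
#' @param fmax upper frequency in Hz (default 50).
#' @return an object of class `connectivity_spectrum` with `freqs`, `plv`,
#'   `z`, `n_trials`, `pair_labels`, `n_excluded` (trial/bin phases
#'   excluded for zero amplitude).
#' @export
plv_spectrum <- function(x1, x2, pad_s = 2, fmax = 50) {
  sp <- .pair_spectra(x1, x2, pad_s, fmax)
  S12 <- sp$X1 * Conj(sp$X2)
  amp <- Mod(S12)
  bad <- amp == 0
  n_excluded <- sum(bad)
  if (n_excluded > 0) {
    warning(n_excluded, " trial/bin phases excluded (zero amplitude)")
    S12[bad] <- NA
    amp[bad] <- 1
  }
  U <- S12 / amp
  plv <- Mod(colMeans(U, na.rm = TRUE))
  structure(list(freqs = sp$freqs, plv = plv,
                 z = atanh(pmin(plv, 1 - 1e-15)), n_trials = sp$n_trials,
                 pair_labels = c(x1$location_label, x2$location_label),
                 n_excluded = n_excluded),
            class = "connectivity_spectrum")
}

#' Mean connectivity over a frequency band
#'
#' Arithmetic mean of the Fisher-z values over all bins inside
#' `[lo, hi]` (inclusive), e.g. the theta band 4-8 Hz.
#'
#' @param c a [plv_spectrum()] result.
#' @param lo,hi band edges in Hz.
#' @return scalar mean z value.
#' @export
band_mean <- function(c, lo, hi) {
  stopifnot(inherits(c, "connectivity_spectrum"))
  sel <- c$freqs >= lo - 1e-9 & c$freqs <= hi + 1e-9
  if (!any(sel)) stop("empty frequency band")
  mean(c$z[sel])
}

#' Phase slope index between two virtual sensors
#'
#' Estimates the direction of information flow from the slope of the
#' cross-phase spectrum: with complex coherency `C(f)` (from the same
#' Hanning/zero-padding pipeline as the PLV),
#' `psi = Im( sum_f Conj(C(f)) C(f + df) )` over the band
#' `[center - halfwidth, center + halfwidth]` (clipped to `[1, Nyquist]`),
#' with `df` one 0.5 Hz bin. A positive value means `x1` temporally
#' precedes (drives) `x2`. The estimate is normalized by its jackknife
#' standard error (leave-one-trial-out).
#'
#' @param x1,x2 `virtual_sensor` objects (>= 3 trials).
#' @param band_center band center in Hz (default 6, the syllabic-rate
#'   frequency of interest).
#' @param halfwidth half bandwidth in Hz (default 5).
#' @param pad_s padded length in seconds (default 2).
#' @return an object of class `psi_estimate` with `psi_raw`,
#'   `se_jackknife`, `psi_norm`, `band_center`, `bandwidth`,
#'   `direction_convention`.
#' @export
phase_slope_index <- function(x1, x2, band_center = 6, halfwidth = 5,
                              pad_s = 2) {
  nyq <- x1$rate / 2
  lo <- max(1, band_center - halfwidth)
  hi <- min(nyq, band_center + halfwidth)
  sp <- .pair_spectra(x1, x2, pad_s, fmax = min(hi + 1, nyq))
  n <- sp$n_trials
  if (n < 3) stop("need at least 3 trials for the jackknife")
  df <- sp$freqs[2] - sp$freqs[1]
  sel <- which(sp$freqs >= lo - 1e-9 & sp$freqs <= hi + 1e-9)
  sel <- sel[sel + 1 <= length(sp$freqs)]   # need f + df in range
  if (length(sel) < 2) stop("fewer than 2 frequency bins in the PSI band")
  selp <- c(sel, max(sel) + 1)

  S12 <- sp$X1[, selp, drop = FALSE] * Conj(sp$X2[, selp, drop = FALSE])
  S11 <- Mod(sp$X1[, selp, drop = FALSE])^2
  S22 <- Mod(sp$X2[, selp, drop = FALSE])^2

  psi_of <- function(s12, s11, s22) {
    C <- s12 / sqrt(s11 * s22)
    k <- seq_len(length(C) - 1)
    sum(Im(Conj(C[k]) * C[k + 1]))
  }
  tot12 <- colSums(S12); tot11 <- colSums(S11); tot22 <- colSums(S22)
  psi_raw <- psi_of(tot12 / n, tot11 / n, tot22 / n)
  psi_loo <- vapply(seq_len(n), function(i)
    psi_of((tot12 - S12[i, ]) / (n - 1), (tot11 - S11[i, ]) / (n - 1),
           (tot22 - S22[i, ]) / (n - 1)), 0)
  se <- sqrt((n - 1) / n * sum((psi_loo - mean(psi_loo))^2))
  if (se <= 0) se <- .Machine$double.eps
  structure(list(psi_raw = psi_raw, se_jackknife = se,
                 psi_norm = psi_raw / se, band_center = band_center,
                 bandwidth = halfwidth,
                 direction_convention = "positive => x1 leads x2"),
            class = "psi_estimate")
}

#' @export
print.psi_estimate <- function(x, ...) {
  cat(sprintf("<psi_estimate> raw %.4g, se %.4g, normalized %.3f (%s)\n",
              x$psi_raw, x$se_jackknife, x$psi_norm, x$direction_convention))
  invisible(x)
}
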