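#' @useDynLib speechtrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft spline rnorm runif var sd median mad pt qnorm
NULL

#' Design a Butterworth filter in second-order sections
#'
#' Designs a digital Butterworth filter from the analog prototype via the
#' bilinear transform and returns it as a cascade of biquads (second-order
#' sections). The SOS form stays numerically stable at the extreme normalized
#' cutoffs this pipeline needs (e.g. a 1 Hz high-pass on 1 kHz data), where
#' the expanded transfer-function polynomial would not.
#'
#' @param order prototype filter order (a band-pass of order `n` has `2n`
#'   poles, following the usual convention).
#' @param w corner frequency in Hz (one value for `"low"`/`"high"`, two for
#'   `"pass"`).
#' @param type filter type: `"low"`, `"high"` or `"pass"`.
#' @param rate sampling rate in Hz.
#' @return a `k x 6` matrix of SOS rows `(b0, b1, b2, 1, a1, a2)` with the
#'   overall gain folded into the first section.
#' @examples
#' sos <- butter_sos(4, c(4, 9), "pass", rate = 256)
#' @export
butter_sos <- function(order, w, type = c("low", "high", "pass"), rate) {
  type <- match.arg(type)
  if (order < 1) stop("filter order must be >= 1")
  wn <- w / (rate / 2)
  if (any(wn <= 0) || any(wn >= 1))
    stop("corner frequencies must lie strictly between 0 and Nyquist")
  n <- as.integer(order)
  k <- seq_len(n)
  pa <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # LHP prototype poles

  if (type == "low") {
    W <- tan(pi * wn / 2)
    p <- W * pa
    nz <- 0L
  } else if (type == "high") {
    W <- tan(pi * wn / 2)
    p <- W / pa
    nz <- n
  } else {
    if (length(wn) != 2 || wn[1] >= wn[2])
      stop("band-pass needs two increasing corner frequencies")
    W1 <- tan(pi * wn[1] / 2); W2 <- tan(pi * wn[2] / 2)
    Bw <- W2 - W1; W0 <- sqrt(W1 * W2)
    t1 <- 0.5 * Bw * pa
    rt <- sqrt(t1^2 - W0^2)
    p <- c(t1 + rt, t1 - rt)
    nz <- n  # n analog zeros at s = 0
  }

  # bilinear transform s = (z - 1)/(z + 1); analog corners prewarped above
  pd <- (1 + p) / (1 - p)
  np <- length(pd)

  # digital zeros: analog zeros at s = 0 map to z = +1; the remaining
  # (np - nz) zeros sit at z = -1
  # group poles into conjugate pairs (any strictly real poles are paired up)
  cplx <- pd[Im(pd) > 1e-10]
  real_p <- Re(pd[abs(Im(pd)) <= 1e-10])
  sections <- list()
  for (pp in cplx)
    sections[[length(sections) + 1]] <-
      c(1, -2 * Re(pp), Mod(pp)^2)  # (z - p)(z - conj(p))
  while (length(real_p) >= 2) {
    sections[[length(sections) + 1]] <-
      c(1, -(real_p[1] + real_p[2]), real_p[1] * real_p[2])
    real_p <- real_p[-(1:2)]
  }
  if (length(real_p) == 1)
    sections[[length(sections) + 1]] <- c(1, -real_p[1], 0)

  ksec <- length(sections)
  sos <- matrix(0, ksec, 6)
  zplus <- nz        # zeros at z = +1 to distribute
  zminus <- np - nz  # zeros at z = -1
  for (s in seq_len(ksec)) {
    a <- sections[[s]]
    nslots <- if (a[3] == 0 && s == ksec && np %% 2 == 1) 1L else 2L
    zr <- numeric(0)
    # interleave so a band-pass section gets one zero of each kind
    for (j in seq_len(nslots)) {
      if (zplus > 0 && (j %% 2 == 1 || zminus == 0)) {
        zr <- c(zr, 1); zplus <- zplus - 1
      } else if (zminus > 0) {
        zr <- c(zr, -1); zminus <- zminus - 1
      }
    }
    b <- switch(as.character(length(zr)),
                "0" = c(1, 0, 0),
                "1" = c(1, -zr, 0),
                "2" = c(1, -(zr[1] + zr[2]), zr[1] * zr[2]))
    sos[s, ] <- c(b, a)
  }

  # normalize overall gain at a reference frequency
  fref <- switch(type,
                 low = 0,
                 high = rate / 2,
                 pass = sqrt(w[1] * w[2]))
  z0 <- exp(2i * pi * fref / rate)
  H <- 1 + 0i
  for (s in seq_len(ksec)) {
    H <- H * (sos[s, 1] + sos[s, 2] / z0 + sos[s, 3] / z0^2) /
             (sos[s, 4] + sos[s, 5] / z0 + sos[s, 6] / z0^2)
  }
  sos[1, 1:3] <- sos[1, 1:3] / Mod(H)
  attr(sos, "rate") <- rate
  attr(sos, "corner") <- min(w)
  sos
}

# steady-state internal states of the cascade for a unit-step input
# (per-section, with the DC gain of earlier sections propagated)
.sos_step_zi <- function(sos) {
  ksec <- nrow(sos)
  zi <- matrix(0, ksec, 2)
  scale <- 1
  for (s in seq_len(ksec)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    H0 <- sum(b) / sum(a)
    z2 <- b[3] - a[3] * H0
    z1 <- b[2] - a[2] * H0 + z2
    zi[s, ] <- scale * c(z1, z2)
    scale <- scale * H0
  }
  zi
}

#' Zero-phase forward-backward filtering
#'
#' Applies a second-order-section filter forward and backward so the net
#' result has exactly zero phase (the magnitude response is applied twice).
#' Edges are handled as in the classic filtfilt recipe: the signal is
#' extended by odd reflection and the filter is started in its step
#' steady-state, so constant inputs pass through a high-pass as exact zeros
#' and transients stay confined to the (discarded) pads.
#'
#' @param sos SOS matrix from [butter_sos()].
#' @param x numeric vector or a channels-in-columns matrix.
#' @param padlen reflection pad length in samples; defaults to three time
#'   constants of the lowest corner frequency (capped at `length(x) - 1`).
#' @return filtered data, same shape as `x`.
#' @export
sos_filtfilt <- function(sos, x, padlen = NULL) {
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x))) x[, j] <- sos_filtfilt(sos, x[, j], padlen)
    return(x)
  }
  n <- length(x)
  if (n < 4) stop("signal too short to filter")
  if (is.null(padlen)) {
    rate <- attr(sos, "rate"); corner <- attr(sos, "corner")
    padlen <- if (!is.null(rate) && !is.null(corner))
      ceiling(3 * rate / corner) else 3L * nrow(sos) * 2L + 1L
  }
  padlen <- max(3L, min(n - 1L, as.integer(padlen)))
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  xx <- c(pre, x, post)
  zi <- .sos_step_zi(sos)
  y <- sosfilt_cpp(sos, xx, zi * xx[1])
  y <- rev(y)
  y <- sosfilt_cpp(sos, y, zi * y[1])
  rev(y)[(padlen + 1):(padlen + n)]
}

#' Analytic signal via the Hilbert transform
#'
#' Returns the complex analytic signal whose modulus is the instantaneous
#' amplitude envelope, constructed in the frequency domain by zeroing
#' negative frequencies.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Hanning window (raised cosine), symmetric
.hanning <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Resample a signal to a new rate
#'
#' Applies a zero-phase Butterworth anti-alias low-pass at `0.8 * target / 2`
#' (when downsampling) and interpolates with a cubic spline onto the new
#' sampling grid. Output length is `round(length(x) * target / rate)`.
#'
#' @param x numeric vector.
#' @param rate current sampling rate in Hz.
#' @param target desired sampling rate in Hz.
#' @param antialias logical; apply the anti-alias filter before decimating.
#' @return numeric vector at the target rate.
#' @export
resample_signal <- function(x, rate, target, antialias = TRUE) {
  if (target == rate) return(x)
  if (target > rate) stop("upsampling is not supported; target must be <= rate")
  if (antialias) {
    sos <- butter_sos(4, 0.8 * target / 2, "low", rate)
    x <- sos_filtfilt(sos, x)
  }
  n_out <- round(length(x) * target / rate)
  t_out <- (seq_len(n_out) - 1) / target
  spline(x = (seq_along(x) - 1) / rate, y = x, xout = t_out, method = "fmm")$y
}

# 1/f ("pink") noise, generated by shaping white noise in the FFT domain.
# Unit variance. Flat below f_lo to keep finite power at DC.
.pink_noise <- function(n, rate, f_lo = 0.5) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f)  # two-sided
  g <- 1 / sqrt(pmax(f, f_lo))
  g[1] <- g[2]
  p <- Re(fft(W * g, inverse = TRUE)) / n
  as.numeric(scale(p))
}

# Evaluate an expression with a local RNG seed, restoring global RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a stream of child seeds from a master seed (kept below 2^31).
.child_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
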