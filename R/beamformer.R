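# Band-averaged sensor blocks of a CSD: sensor x sensor matrix, the
# sensor-envelope cross vector, and the envelope autospectrum, averaged
# over the bins inside [center - halfwidth, center + halfwidth].
.band_csd <- function(csd, center, halfwidth) {
  sel <- which(csd$freqs >= center - halfwidth - 1e-9 &
               csd$freqs <= center + halfwidth + 1e-9)
  if (!length(sel)) stop("frequency window outside the computed CSD range")
  ie <- match("envelope", csd$channel_ids)
  ich <- setdiff(seq_along(csd$channel_ids), ie)
  Sb <- apply(csd$S[, , sel, drop = FALSE], c(1, 2), mean)
  list(Sss = Sb[ich, ich, drop = FALSE],
       Sse = if (!is.na(ie)) Sb[ich, ie] else NULL,
       See = if (!is.na(ie)) Re(Sb[ie, ie]) else NULL)
}

# Regularized inverse of the real part of a sensor CSD / covariance.
.reg_inverse <- function(S, lambda) {
  Sr <- Re(S)
  Sr <- Sr + lambda * mean(diag(Sr)) * diag(nrow(Sr))
  solve(Sr)
}

#' DICS spatial filter at one grid point
#'
#' Computes the frequency-domain beamformer weights
#' `W = (L' (S + lambda I)^-1 L)^-1 L' (S + lambda I)^-1` for a grid point,
#' using the real part of the band-averaged sensor CSD, plus the
#' dominant-orientation scalar filter (the orientation maximizing
#' minimum-variance output power). Because the radial orientation of a
#' spherical conductor is magnetically silent, the leadfield is first
#' reduced to its rank-2 tangential subspace; the vector filter is
#' 2 x sensors in that basis. Both filters satisfy the unit-gain
#' constraint `W L = I` (or `w l = 1`).
#'
#' @param csd a [compute_csd()] result.
#' @param lf a [sphere_leadfield()].
#' @param point grid point index.
#' @param lambda regularization as a fraction of mean sensor power
#'   (default 0.05).
#' @param center,halfwidth frequency window in Hz to average the CSD over
#'   (defaults: the full computed range).
#' @return an object of class `spatial_filter` with `weights`
#'   (2 x sensors, tangential basis in `basis`), `scalar_weights`
#'   (1 x sensors), `orientation` (unit 3-vector), `point`, `lambda`,
#'   `degenerate` flag.
#' @export
dics_filter <- function(csd, lf, point, lambda = 0.05,
                        center = mean(range(csd$freqs)),
                        halfwidth = diff(range(csd$freqs)) / 2) {
  stopifnot(inherits(csd, "csd"), inherits(lf, "leadfield"))
  bb <- .band_csd(csd, center, halfwidth)
  Sinv <- .reg_inverse(bb$Sss, lambda)
  .dics_filter_point(Sinv, lf$L[, , point],
                     degenerate = lf$degenerate[point], point = point,
                     lambda = lambda)
}

# Tangential (rank-2) orientation basis of a spherical-conductor leadfield:
# the radial orientation is magnetically silent, so beamforming is done in
# the 2-D subspace spanned by the two non-null leadfield orientations.
.tangential_basis <- function(Lp) {
  ev <- eigen(crossprod(Lp), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], .Machine$double.eps))
    return(NULL)
  ev$vectors[, 1:2, drop = FALSE]
}

.dics_filter_point <- function(Sinv, Lp, degenerate = FALSE, point = NA,
                               lambda = NA) {
  V2 <- .tangential_basis(Lp)
  if (degenerate || is.null(V2)) {
    return(structure(list(weights = matrix(0, 2, nrow(Lp)),
                          scalar_weights = rep(0, nrow(Lp)),
                          orientation = c(0, 0, 1),
                          basis = diag(3)[, 1:2], point = point,
                          lambda = lambda, degenerate = TRUE),
                     class = "spatial_filter"))
  }
  L2 <- Lp %*% V2                   # sensors x 2
  SL <- Sinv %*% L2
  G <- crossprod(L2, SL)            # 2 x 2
  W <- solve(G, t(SL))              # 2 x sensors, unit gain W L2 = I
  u2 <- eigen(G, symmetric = TRUE)$vectors[, 2]  # max output power
  l <- drop(L2 %*% u2)
  w <- drop(Sinv %*% l) / drop(crossprod(l, Sinv %*% l))
  structure(list(weights = W, scalar_weights = w,
                 orientation = drop(V2 %*% u2), basis = V2, point = point,
                 lambda = lambda, degenerate = FALSE),
            class = "spatial_filter")
}

#' Source-level cerebro-acoustic coherence map (DICS)
#'
#' For each frequency window, band-averages the CSD, derives a
#' dominant-orientation scalar DICS filter per grid point and computes the
#' coherence between the beamformed source signal and the stimulus
#' envelope; the per-window maps are Fisher z-transformed and arithmetically
#' averaged into a single map (e.g. windows 6 +/- 2 and 7 +/- 2 Hz give one
#' image for 4-9 Hz).
#'
#' @param e an `epoch_set` with envelope epochs, or a precomputed
#'   [compute_csd()] result including the envelope channel.
#' @param lf a [sphere_leadfield()] for the same sensors.
#' @param windows list of `c(center, halfwidth)` pairs in Hz
#'   (default `list(c(6, 2), c(7, 2))`).
#' @param lambda regularization fraction (default 0.05).
#' @return an object of class `source_map` with `values` (z-coherence per
#'   grid point), `grid`, `band_label`.
#' @export
source_coherence_map <- function(e, lf, windows = list(c(6, 2), c(7, 2)),
                                 lambda = 0.05) {
  stopifnot(inherits(lf, "leadfield"))
  csd <- if (inherits(e, "csd")) e else compute_csd(e)
  if (!"envelope" %in% csd$channel_ids) stop("csd has no envelope channel")
  lo <- min(vapply(windows, function(w) w[1] - w[2], 0))
  hi <- max(vapply(windows, function(w) w[1] + w[2], 0))
  if (lo < min(csd$freqs) - 1e-9 || hi > max(csd$freqs) + 1e-9)
    stop("frequency window outside the computed CSD range")
  npts <- dim(lf$L)[3]
  nch <- dim(lf$L)[1]
  zmaps <- matrix(0, npts, length(windows))
  for (wi in seq_along(windows)) {
    bb <- .band_csd(csd, windows[[wi]][1], windows[[wi]][2])
    Sinv <- .reg_inverse(bb$Sss, lambda)
    Ssr <- Re(bb$Sss)
    Lmat <- matrix(lf$L, nch)          # sensors x (3 npts)
    SL <- Sinv %*% Lmat                # sensors x (3 npts)
    MS <- Ssr %*% SL                   # for w' Re(S) w
    ce <- bb$Sse                       # complex sensor-envelope cross
    for (p in seq_len(npts)) {
      cols <- (3 * p - 2):(3 * p)
      Lp <- lf$L[, , p]
      V2 <- .tangential_basis(Lp)
      if (lf$degenerate[p] || is.null(V2)) { zmaps[p, wi] <- NA; next }
      SLp <- SL[, cols] %*% V2                # Sinv L2, sensors x 2
      G <- crossprod(Lp %*% V2, SLp)          # 2 x 2
      u <- eigen(G, symmetric = TRUE)$vectors[, 2]
      gu <- drop(crossprod(u, G %*% u))       # l' Sinv l
      wv <- drop(SLp %*% u) / gu              # scalar sensor weights
      num <- Mod(sum(wv * ce))
      P3 <- crossprod(SL[, cols], MS[, cols]) # (Sinv L)' Ssr (Sinv L)
      pow <- drop(crossprod(V2 %*% u, P3 %*% (V2 %*% u))) / gu^2
      coh <- num / sqrt(pow * bb$See)
      zmaps[p, wi] <- atanh(min(coh, 1 - 1e-12))
    }
  }
  lab <- sprintf("%g-%g Hz", lo, hi)
  structure(list(values = rowMeans(zmaps), grid = lf$grid, band_label = lab),
            class = "source_map")
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("<source_map> %d points, band %s, max %.4f at point %d\n",
              length(x$values), x$band_label,
              max(x$values, na.rm = TRUE), which.max(x$values)))
  invisible(x)
}

#' LCMV virtual sensor at a grid point
#'
#' Computes a common spatial filter from the trial-averaged sensor
#' covariance, `W = (L' C^-1 L)^-1 L' C^-1` (in the rank-2 tangential
#' basis, since the radial orientation is silent in a spherical conductor),
#' applies it to every trial, and reduces the orientation components to a
#' single time series by SVD of the concatenated component-by-time matrix
#' (dominant left singular vector).
#' The sign is fixed so that the retained component correlates positively
#' with its largest-weight sensor.
#'
#' @param e an `epoch_set`.
#' @param lf a [sphere_leadfield()].
#' @param point grid point index.
#' @param lambda regularization fraction of mean sensor power (default
#'   0.05); rank-deficient covariances raise an error advising `lambda > 0`.
#' @param location_label optional label (e.g. `"STG"`, `"CS"`).
#' @return an object of class `virtual_sensor` with `epochs`
#'   (trials x samples), `rate`, `location_label`, `svd_gain` (fraction of
#'   variance in the retained component), `condition`.
#' @export
lcmv_virtual_sensor <- function(e, lf, point, lambda = 0.05,
                                location_label = NA) {
  stopifnot(inherits(e, "epoch_set"), inherits(lf, "leadfield"))
  n_trials <- dim(e$epochs)[1]; nch <- dim(e$epochs)[2]; ns <- dim(e$epochs)[3]
  C <- matrix(0, nch, nch)
  for (tr in seq_len(n_trials)) {
    x <- matrix(e$epochs[tr, , ], nch)
    x <- x - rowMeans(x)
    C <- C + tcrossprod(x) / (ns - 1)
  }
  C <- C / n_trials
  if (lambda == 0 && rcond(C) < 1e-12)
    stop("sensor covariance is rank-deficient; use lambda > 0")
  Cinv <- .reg_inverse(C, lambda)
  Lp <- lf$L[, , point]
  V2 <- .tangential_basis(Lp)
  if (is.null(V2)) stop("leadfield is silent at this point (radial/center)")
  L2 <- Lp %*% V2
  G <- crossprod(L2, Cinv %*% L2)
  W <- solve(G, crossprod(L2, Cinv))  # 2 x sensors (tangential coords)
  src <- array(0, c(n_trials, 2, ns))
  for (tr in seq_len(n_trials))
    src[tr, , ] <- W %*% matrix(e$epochs[tr, , ], nch)
  concat <- matrix(aperm(src, c(2, 3, 1)), nrow = 2)  # 2 x (ns * trials)
  sv <- svd(concat, nu = 2, nv = 0)
  u1 <- sv$u[, 1]
  wscal <- drop(crossprod(u1, W))
  if (wscal[which.max(abs(wscal))] < 0) u1 <- -u1
  series <- matrix(0, n_trials, ns)
  for (tr in seq_len(n_trials)) series[tr, ] <- crossprod(u1, src[tr, , ])
  structure(list(epochs = series, rate = e$rate,
                 location_label = location_label,
                 svd_gain = sv$d[1]^2 / sum(sv$d^2),
                 condition = e$condition),
            class = "virtual_sensor")
}
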