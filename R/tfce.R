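# Gaussian smoothing operator over the masked grid points: row-normalized
# kernel exp(-d^2 / (2 sigma^2)) with sigma = fwhm / 2.3548. fwhm = 0 gives
# the identity.
.smoothing_matrix <- function(grid, fwhm_mm) {
  npts <- nrow(grid$points)
  if (fwhm_mm <= 0) return(diag(npts))
  sigma <- (fwhm_mm / 1000) / (2 * sqrt(2 * log(2)))
  d2 <- as.matrix(stats::dist(grid$points))^2
  W <- exp(-d2 / (2 * sigma^2))
  W / rowSums(W)
}

.maps_matrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  if (inherits(maps, "source_map")) return(matrix(maps$values, 1))
  do.call(rbind, lapply(maps, function(m)
    if (inherits(m, "source_map")) m$values else as.numeric(m)))
}

#' Pseudo-t statistic map with variance smoothing
#'
#' Voxelwise two-sample (independent) or paired (dependent) t statistic in
#' which the variance map is Gaussian-smoothed at the stated FWHM before
#' forming the ratio (a pseudo-t). Smoothing the variance, not the effect,
#' suppresses high-spatial-frequency noise in the statistic while leaving
#' the contrast untouched; `fwhm_mm = 0` recovers the ordinary t statistic.
#'
#' @param maps_a,maps_b per-subject maps: `subjects x voxels` matrices or
#'   lists of `source_map`s on one grid. For the dependent design the rows
#'   must be paired.
#' @param grid the [make_grid()] the maps live on.
#' @param design `"independent"` or `"dependent"`.
#' @param fwhm_mm variance smoothing FWHM in mm (default 15).
#' @param smooth_op optional precomputed smoothing operator (internal use).
#' @return an object of class `stat_map` with `t_values`, `df`, `design`,
#'   `smoothing_fwhm_mm`, `grid`.
#' @export
pseudo_t_map <- function(maps_a, maps_b, grid,
                         design = c("independent", "dependent"),
                         fwhm_mm = 15, smooth_op = NULL) {
  design <- match.arg(design)
  A <- .maps_matrix(maps_a); B <- .maps_matrix(maps_b)
  if (ncol(A) != ncol(B)) stop("maps have different voxel counts")
  # degenerate (beamformer-silent) voxels carry NA; they contribute zero
  A[!is.finite(A)] <- 0; B[!is.finite(B)] <- 0
  if (is.null(smooth_op)) smooth_op <- .smoothing_matrix(grid, fwhm_mm)
  colvar <- function(X) {
    n <- nrow(X)
    (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
  }
  if (design == "independent") {
    na <- nrow(A); nb <- nrow(B)
    if (na < 2 || nb < 2) stop("need >= 2 subjects per group")
    va <- colvar(A); vb <- colvar(B)
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    s2s <- drop(smooth_op %*% s2)
    if (any(s2s <= 0)) warning("zero smoothed variance at some voxels")
    tv <- (colMeans(A) - colMeans(B)) / sqrt(s2s * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    if (nrow(A) != nrow(B)) stop("dependent design requires paired maps")
    n <- nrow(A)
    if (n < 2) stop("need >= 2 subjects")
    D <- A - B
    vs <- drop(smooth_op %*% colvar(D))
    if (any(vs <= 0)) warning("zero smoothed variance at some voxels")
    tv <- colMeans(D) / sqrt(vs / n)
    df <- n - 1
  }
  tv[!is.finite(tv)] <- 0
  tv[abs(tv) < 1e-12] <- 0
  structure(list(t_values = tv, df = df, design = design,
                 smoothing_fwhm_mm = fwhm_mm, grid = grid),
            class = "stat_map")
}

#' TFCE parameters
#'
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh integration step in statistic units; `NULL` (default) uses
#'   `max(|t|) / n_steps` per map.
#' @param n_steps number of integration steps when `dh` is `NULL`
#'   (default 100).
#' @param connectivity neighborhood: 6 (faces), 18 (+edges) or 26
#'   (+corners; default).
#' @return an object of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, n_steps = 100,
                        connectivity = 26) {
  if (E <= 0 || H <= 0 || (!is.null(dh) && dh <= 0))
    stop("E, H and dh must be positive")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  structure(list(E = E, H = H, dh = dh, n_steps = n_steps,
                 connectivity = connectivity),
            class = "tfce_params")
}

# CSR adjacency of the masked lattice points under the given neighborhood.
.grid_adjacency <- function(grid, connectivity = 26) {
  ijk <- grid$ijk
  npts <- nrow(ijk)
  span <- max(ijk) - min(ijk) + 3L
  shift <- -min(ijk) + 1L
  key <- function(m) ((m[, 1] + shift) * span + (m[, 2] + shift)) * span +
    (m[, 3] + shift)
  lookup <- integer(0)
  lookup[key(ijk) + 1L] <- seq_len(npts)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  man <- rowSums(abs(offs))
  offs <- offs[man > 0 & man <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  nbr <- vector("list", nrow(offs))
  src <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    shifted <- ijk + matrix(offs[o, ], npts, 3, byrow = TRUE)
    idx <- lookup[key(shifted) + 1L]
    ok <- !is.na(idx)
    src[[o]] <- which(ok); nbr[[o]] <- idx[ok]
  }
  src <- unlist(src); nbr <- unlist(nbr)
  ord <- order(src)
  src <- src[ord]; nbr <- nbr[ord]
  ptr <- cumsum(c(0L, tabulate(src, npts)))
  list(nbr = as.integer(nbr - 1L), ptr = as.integer(ptr))
}

#' Threshold-free cluster enhancement
#'
#' Replaces each voxel's statistic by the integral over thresholds `h` of
#' `e_v(h)^E * h^H * dh`, where `e_v(h)` is the number of voxels in the
#' suprathreshold connected component containing `v`. Peaks supported by a
#' spatial cluster are enhanced relative to isolated peaks, without an
#' arbitrary cluster-forming threshold. Negative values are enhanced on the
#' negated map and re-negated.
#'
#' @param map a `stat_map`, `source_map`, or numeric vector of voxel values.
#' @param grid the [make_grid()] the map lives on (taken from the map
#'   object when present).
#' @param params a [tfce_params()].
#' @param adjacency optional precomputed [.grid_adjacency()] result
#'   (internal use, for permutation loops).
#' @return a `source_map` of enhanced values.
#' @export
tfce <- function(map, grid = NULL, params = tfce_params(), adjacency = NULL) {
  vals <- if (inherits(map, "stat_map")) map$t_values
          else if (inherits(map, "source_map")) map$values
          else as.numeric(map)
  if (is.null(grid))
    grid <- if (inherits(map, "stat_map") || inherits(map, "source_map"))
      map$grid else stop("grid required for a bare numeric map")
  vals[!is.finite(vals)] <- 0
  if (is.null(adjacency)) adjacency <- .grid_adjacency(grid, params$connectivity)
  enh <- .tfce_signed(vals, adjacency, params)
  structure(list(values = enh, grid = grid, band_label = "tfce"),
            class = "source_map")
}

.tfce_signed <- function(vals, adjacency, params) {
  out <- numeric(length(vals))
  for (sgn in c(1, -1)) {
    v <- pmax(sgn * vals, 0)
    if (max(v) <= 0) next
    dh <- if (is.null(params$dh)) max(v) / params$n_steps else params$dh
    out <- out + sgn * tfce_cpp(v, adjacency$nbr, adjacency$ptr,
                                params$E, params$H, dh)
  }
  out
}

#' Max-statistic permutation test with TFCE
#'
#' Group-level family-wise-error-corrected inference: for every permutation
#' (random relabelling of group membership for the independent design;
#' random within-subject condition sign flip for the dependent design) the
#' pseudo-t map is recomputed, TFCE-enhanced, and its maximum absolute
#' value over the mask recorded. Voxelwise
#' `fwe_p = (1 + #[perm max >= |observed|]) / (1 + n_perms)`.
#'
#' @param maps_a,maps_b per-subject maps (as in [pseudo_t_map()]).
#' @param grid the source grid.
#' @param design `"independent"` or `"dependent"`.
#' @param n_perms number of permutations (default 1000). If the design
#'   admits fewer distinct relabellings, all are enumerated with a warning.
#' @param seed integer seed; the permutation sequence is deterministic
#'   given the seed.
#' @param fwhm_mm variance smoothing FWHM in mm (default 15).
#' @param params a [tfce_params()].
#' @param mask optional logical/integer voxel subset entering the max
#'   statistic (a small-volume restriction); per-voxel t values are
#'   unaffected.
#' @return an object of class `permutation_result` with `fwe_p`,
#'   `max_stat_null`, `observed_tfce`, `stat_map`, `n_perms`, `scheme`,
#'   `seed`.
#' @export
permutation_fwe <- function(maps_a, maps_b, grid,
                            design = c("independent", "dependent"),
                            n_perms = 1000, seed = 1, fwhm_mm = 15,
                            params = tfce_params(), mask = NULL) {
  design <- match.arg(design)
  if (n_perms < 100) stop("n_perms must be >= 100")
  A <- .maps_matrix(maps_a); B <- .maps_matrix(maps_b)
  npts <- ncol(A)
  if (is.null(mask)) mask <- rep(TRUE, npts)
  if (!is.logical(mask)) mask <- seq_len(npts) %in% mask
  smooth_op <- .smoothing_matrix(grid, fwhm_mm)
  adjacency <- .grid_adjacency(grid, params$connectivity)

  observed <- pseudo_t_map(A, B, grid, design, fwhm_mm, smooth_op = smooth_op)
  obs_enh <- .tfce_signed(observed$t_values, adjacency, params)

  na <- nrow(A); nb <- nrow(B)
  n_distinct <- if (design == "independent")
    choose(na + nb, na) else 2^nrow(A)
  enumerate <- n_distinct < n_perms
  if (enumerate)
    warning("fewer distinct permutations (", n_distinct,
            ") than requested; enumerating all")
  scheme <- if (design == "independent") "group-shuffle" else "within-subject-swap"
  perms <- .with_seed(seed, {
    if (design == "independent") {
      if (enumerate) {
        asplit(utils::combn(na + nb, na), 2)
      } else {
        lapply(seq_len(n_perms), function(p) sample.int(na + nb, na))
      }
    } else {
      if (enumerate) {
        asplit(as.matrix(expand.grid(rep(list(c(1, -1)), na))), 1)
      } else {
        lapply(seq_len(n_perms), function(p) sample(c(1, -1), na, TRUE))
      }
    }
  })
  n_eff <- length(perms)
  max_null <- vapply(perms, function(pp) {
    if (design == "independent") {
      X <- rbind(A, B)
      tp <- pseudo_t_map(X[pp, , drop = FALSE],
                         X[-pp, , drop = FALSE],
                         grid, design, fwhm_mm, smooth_op = smooth_op)
    } else {
      D <- (A - B) * as.numeric(pp)
      tp <- pseudo_t_map(B + D, B, grid, design, fwhm_mm,
                         smooth_op = smooth_op)
    }
    enh <- .tfce_signed(tp$t_values, adjacency, params)
    max(abs(enh[mask]))
  }, 0)
  fwe_p <- vapply(abs(obs_enh), function(v)
    (1 + sum(max_null >= v)) / (1 + n_eff), 0)
  structure(list(fwe_p = fwe_p, max_stat_null = max_null,
                 observed_tfce = obs_enh, stat_map = observed,
                 n_perms = n_eff, scheme = scheme, seed = seed,
                 mask = mask),
            class = "permutation_result")
}

#' Interaction contrast between two groups' condition differences
#'
#' Forms per-subject difference maps `nat - ctrl` in each group; the
#' group-by-condition interaction (e.g.
#' `(nat_EB - 1channel_EB) - (nat_SI - 1channel_SI)`) is then an
#' independent-design comparison of the difference maps, run through
#' [permutation_fwe()].
#'
#' @param nat_a,ctrl_a paired condition maps for group A (subjects x voxels).
#' @param nat_b,ctrl_b paired condition maps for group B.
#' @param grid the source grid.
#' @param ... passed on to [permutation_fwe()].
#' @return a `permutation_result` for the interaction, with the difference
#'   maps attached as `diff_a` / `diff_b`.
#' @export
interaction_contrast <- function(nat_a, ctrl_a, nat_b, ctrl_b, grid, ...) {
  Na <- .maps_matrix(nat_a); Ca <- .maps_matrix(ctrl_a)
  Nb <- .maps_matrix(nat_b); Cb <- .maps_matrix(ctrl_b)
  drop_incomplete <- function(N, C, label) {
    # a subject is incomplete when one of its condition maps is absent
    # (all-NA row); isolated NA voxels (degenerate grid points) are fine
    ok <- rowSums(is.finite(N)) > 0 & rowSums(is.finite(C)) > 0
    if (!all(ok))
      warning(sum(!ok), " subject(s) in group ", label,
              " missing a condition; excluded")
    list(N = N[ok, , drop = FALSE], C = C[ok, , drop = FALSE])
  }
  ga <- drop_incomplete(Na, Ca, "A"); gb <- drop_incomplete(Nb, Cb, "B")
  diff_a <- ga$N - ga$C; diff_b <- gb$N - gb$C
  res <- permutation_fwe(diff_a, diff_b, grid, design = "independent", ...)
  res$diff_a <- diff_a; res$diff_b <- diff_b
  res
}
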