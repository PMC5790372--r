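#' Construct a sensor array on the upper hemisphere
#'
#' Places `n` approximately uniformly distributed point magnetometers on the
#' upper hemisphere of the given radius (Fibonacci spiral), oriented
#' radially. Coordinates are meters in the head frame (origin at the
#' conductor center).
#'
#' @param n number of sensors (>= 3; the study abstraction uses 102).
#' @param radius sensor shell radius in meters (default 0.12).
#' @param conductor_radius conductor sphere radius the sensors must clear
#'   (default 0.09).
#' @return an object of class `sensor_array` with `positions` (n x 3),
#'   `orientations` (n x 3, unit norm) and `kind = "magnetometer"`.
#' @export
make_sensor_array <- function(n = 102, radius = 0.12, conductor_radius = 0.09) {
  if (n < 3) stop("need at least 3 sensors")
  if (radius <= conductor_radius)
    stop("sensor radius must exceed the conductor radius")
  i <- seq_len(n)
  # Fibonacci lattice on the upper hemisphere: z from ~0 to 1
  z <- (i - 0.5) / n
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2))
  s <- sqrt(1 - z^2)
  dirs <- cbind(s * cos(phi), s * sin(phi), z)
  pos <- radius * dirs
  structure(list(positions = pos, orientations = dirs,
                 kind = "magnetometer", radius = radius),
            class = "sensor_array")
}

#' Construct a regular source grid inside a spherical conductor
#'
#' Axis-aligned lattice with the given spacing covering the conductor
#' sphere; points with `||p|| < 0.9 * conductor_radius` are flagged as
#' inside (the outer shell is excluded, as beamformer grids exclude the
#' skull vicinity). Only the masked points are retained.
#'
#' @param spacing lattice spacing in meters (default 0.008, i.e. the
#'   8 x 8 x 8 mm imaging grid).
#' @param conductor_radius sphere radius in meters (default 0.09).
#' @return an object of class `source_grid` with `points` (m x 3 meters,
#'   masked points only), `ijk` (integer lattice coordinates), `spacing`,
#'   `conductor_radius`.
#' @export
make_grid <- function(spacing = 0.008, conductor_radius = 0.09) {
  if (spacing <= 0) stop("spacing must be positive")
  kmax <- floor(conductor_radius / spacing)
  ax <- (-kmax):kmax
  ijk <- as.matrix(expand.grid(i = ax, j = ax, k = ax))
  pts <- ijk * spacing
  inside <- sqrt(rowSums(pts^2)) < 0.9 * conductor_radius
  structure(list(points = pts[inside, , drop = FALSE],
                 ijk = ijk[inside, , drop = FALSE],
                 spacing = spacing, conductor_radius = conductor_radius),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d points, %.0f mm spacing, conductor R = %.0f mm\n",
              nrow(x$points), x$spacing * 1000, x$conductor_radius * 1000))
  invisible(x)
}

# Magnetic field of a current dipole in a homogeneous conducting sphere
# centered at the origin (Sarvas closed form). rq: dipole position (m),
# q: dipole moment (A m), pos: n x 3 field points outside the sphere.
# Returns n x 3 field in tesla. Radial dipoles and dipoles at the center
# produce an exactly zero field (q x rq = 0 term).
.sarvas_field <- function(rq, q, pos) {
  mu0 <- 4e-7 * pi
  n <- nrow(pos)
  qxrq <- c(q[2] * rq[3] - q[3] * rq[2],
            q[3] * rq[1] - q[1] * rq[3],
            q[1] * rq[2] - q[2] * rq[1])
  if (sum(qxrq^2) == 0) return(matrix(0, n, 3))
  rn <- sqrt(rowSums(pos^2))
  a <- pos - matrix(rq, n, 3, byrow = TRUE)
  an <- sqrt(rowSums(a^2))
  ar <- rowSums(a * pos)
  f <- an * (rn * an + rn^2 - drop(pos %*% rq))
  c1 <- an^2 / rn + ar / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + ar / an
  gf <- c1 * pos - outer(c2, rq)
  coef <- mu0 / (4 * pi * f^2)
  outer(coef * f, qxrq) - (coef * drop(pos %*% qxrq)) * gf
}

# Leadfield columns (x/y/z unit dipoles) at one source point, projected on
# sensor orientations. Returns n_sensors x 3.
.leadfield_point <- function(rq, sensors) {
  L <- matrix(0, nrow(sensors$positions), 3)
  for (d in 1:3) {
    q <- c(0, 0, 0); q[d] <- 1
    B <- .sarvas_field(rq, q, sensors$positions)
    L[, d] <- rowSums(B * sensors$orientations)
  }
  L
}

#' Spherical-conductor MEG leadfield
#'
#' Computes, for every grid point, the measured field of unit dipoles along
#' x/y/z using the closed-form solution for a current dipole in a
#' homogeneous conducting sphere, projected onto each sensor's orientation
#' (ideal point magnetometers). Radial dipoles and dipoles at the sphere
#' center are magnetically silent and yield exact zeros; near-silent points
#' are flagged in `degenerate`.
#'
#' @param grid a [make_grid()] (points strictly inside the conductor).
#' @param sensors a [make_sensor_array()] (positions outside the conductor).
#' @return an object of class `leadfield` with `L` (array
#'   `n_sensors x 3 x n_points`, tesla per A m), `grid`, `sensors`,
#'   `conductor_radius`, `degenerate` (logical per point).
#' @export
sphere_leadfield <- function(grid, sensors) {
  stopifnot(inherits(grid, "source_grid"), inherits(sensors, "sensor_array"))
  if (any(sqrt(rowSums(sensors$positions^2)) <= grid$conductor_radius))
    stop("sensors must lie outside the conductor sphere")
  npts <- nrow(grid$points)
  L <- array(0, c(nrow(sensors$positions), 3, npts))
  for (p in seq_len(npts)) L[, , p] <- .leadfield_point(grid$points[p, ], sensors)
  scale <- apply(L, 3, function(m) sqrt(mean(m^2)))
  degenerate <- scale < 1e-6 * stats::median(scale)
  structure(list(L = L, grid = grid, sensors = sensors,
                 conductor_center = c(0, 0, 0),
                 conductor_radius = grid$conductor_radius,
                 degenerate = degenerate),
            class = "leadfield")
}
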