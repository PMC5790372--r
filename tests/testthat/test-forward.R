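# Sensor geometry, source grid, spherical-conductor forward solution.

test_that("sensor arrays sit on the upper hemisphere without duplicates", {
  s <- make_sensor_array(102, 0.12)
  expect_equal(nrow(s$positions), 102)
  expect_lt(max(abs(sqrt(rowSums(s$positions^2)) - 0.12)), 1e-12)
  expect_true(all(s$positions[, 3] >= 0))
  expect_lt(max(abs(sqrt(rowSums(s$orientations^2)) - 1)), 1e-9)
  dmin <- min(stats::dist(s$positions))
  expect_gt(dmin, 0)
  expect_error(make_sensor_array(102, 0.05), "exceed")
  expect_error(make_sensor_array(2), "at least 3")
})

test_that("the source grid is a masked lattice with the stated spacing", {
  g <- make_grid(0.008, 0.09)
  expect_equal(g$spacing, 0.008)
  nn <- min(stats::dist(g$points[1:200, ]))
  expect_equal(nn, 0.008, tolerance = 1e-12)
  expect_true(all(sqrt(rowSums(g$points^2)) < 0.09))

  # brute-force lattice enumeration gives the same point count
  count <- 0
  for (i in -11:11) for (j in -11:11) for (k in -11:11)
    if (sqrt(sum((c(i, j, k) * 0.008)^2)) < 0.9 * 0.09) count <- count + 1
  expect_equal(nrow(g$points), count)
})

test_that("radial and central dipoles are magnetically silent", {
  sens <- make_sensor_array(64, 0.12)
  tang_scale <- max(abs(speechtrack:::.sarvas_field(c(0.05, 0, 0), c(0, 1, 0),
                                                    sens$positions)))
  radial <- speechtrack:::.sarvas_field(c(0.05, 0, 0), c(1, 0, 0),
                                        sens$positions)
  expect_lt(max(abs(radial)) / tang_scale, 1e-18)
  center <- speechtrack:::.sarvas_field(c(0, 0, 0), c(0, 1, 0),
                                        sens$positions)
  expect_equal(max(abs(center)), 0)
})

test_that("the field is linear in the dipole moment", {
  sens <- make_sensor_array(32, 0.12)
  rq <- c(0.03, 0.02, 0.04)
  q1 <- c(0.2, -1, 0.4); q2 <- c(-0.7, 0.1, 1.2)
  B12 <- speechtrack:::.sarvas_field(rq, q1 + q2, sens$positions)
  B1 <- speechtrack:::.sarvas_field(rq, q1, sens$positions)
  B2 <- speechtrack:::.sarvas_field(rq, q2, sens$positions)
  expect_lt(max(abs(B12 - (B1 + B2))), 1e-12 * max(abs(B12)))
})

test_that("rotating source and sensors together leaves measurements unchanged", {
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sens <- make_sensor_array(32, 0.12)
  rq <- c(0.03, 0.01, 0.05); q <- c(0.1, 0.9, -0.3)
  B <- speechtrack:::.sarvas_field(rq, q, sens$positions)
  meas <- rowSums(B * sens$orientations)
  rsens <- sens
  rsens$positions <- sens$positions %*% t(R)
  rsens$orientations <- sens$orientations %*% t(R)
  Br <- speechtrack:::.sarvas_field(drop(R %*% rq), drop(R %*% q),
                                    rsens$positions)
  measr <- rowSums(Br * rsens$orientations)
  expect_lt(max(abs(meas - measr)), 1e-12 * max(abs(meas)))
})

test_that("tangential-dipole field decays monotonically along a radial ray", {
  rq <- c(0.05, 0, 0); q <- c(0, 1, 0)
  dists <- seq(0.1, 0.6, by = 0.025)
  dir <- c(0.3, 0.5, 0.81); dir <- dir / sqrt(sum(dir^2))
  mags <- vapply(dists, function(d)
    sqrt(sum(speechtrack:::.sarvas_field(rq, q, matrix(dir * d, 1))^2)), 0)
  expect_true(all(diff(mags) < 0))
})

test_that("the far field approaches the free-space magnetic dipole form", {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 1) / sqrt(3), c(-0.5, 0.8, 0.33) / sqrt(0.9989))
  dev_at <- function(rq, q, rmult) {
    pos <- dirs * (0.09 * rmult)
    Bs <- speechtrack:::.sarvas_field(rq, q, pos)
    m <- 0.5 * c(rq[2] * q[3] - rq[3] * q[2], rq[3] * q[1] - rq[1] * q[3],
                 rq[1] * q[2] - rq[2] * q[1])
    mu0 <- 4e-7 * pi
    max(vapply(seq_len(nrow(pos)), function(i) {
      r <- pos[i, ]; rn <- sqrt(sum(r^2)); rh <- r / rn
      Bd <- mu0 / (4 * pi) * (3 * sum(m * rh) * rh - m) / rn^3
      sqrt(sum((Bs[i, ] - Bd)^2)) / sqrt(sum(Bd^2))
    }, 0))
  }
  # convergence: the deviation shrinks with distance for a cortical-depth
  # source, and a deep (near-center) source is within 1% at 10x radius
  # (the point-dipole error itself scales as source offset / distance)
  devs <- vapply(c(10, 30, 100), function(rm)
    dev_at(c(0.05, 0, 0), c(0, 1, 0), rm), 0)
  expect_true(all(diff(devs) < 0))
  expect_lt(dev_at(c(0.004, 0, 0), c(0, 1, 0), 10), 0.01)
})

test_that("leadfields are finite, silent only at the center, degenerate flagged", {
  g <- make_grid(0.02, 0.09)
  sens <- make_sensor_array(32, 0.12)
  lf <- sphere_leadfield(g, sens)
  expect_true(all(is.finite(lf$L)))
  center <- which(rowSums(g$points^2) == 0)
  expect_true(lf$degenerate[center])
  expect_equal(max(abs(lf$L[, , center])), 0)
  expect_false(any(lf$degenerate[-center]))
  expect_error(sphere_leadfield(make_grid(0.02, 0.2), sens), "outside")
})
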