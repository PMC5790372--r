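# Pseudo-t maps, TFCE and max-statistic permutation inference.

grid_s <- make_grid(0.014, 0.06)   # compact lattice for statistics tests
npts_s <- nrow(grid_s$points)

test_that("pseudo-t reduces to the ordinary t and vanishes for equal groups", {
  set.seed(41)
  A <- matrix(rnorm(8 * npts_s), 8); B <- matrix(rnorm(10 * npts_s) + 0.3, 10)

  tm <- pseudo_t_map(A, B, grid_s, "independent", fwhm_mm = 0)
  tt <- vapply(seq_len(npts_s), function(v)
    unname(stats::t.test(A[, v], B[, v], var.equal = TRUE)$statistic), 0)
  expect_lt(max(abs(tm$t_values - tt)), 1e-10)
  expect_equal(tm$df, 16)

  paired <- suppressWarnings(pseudo_t_map(A, A, grid_s, "dependent"))
  expect_true(all(paired$t_values == 0))

  expect_equal(pseudo_t_map(A, B, grid_s)$smoothing_fwhm_mm, 15)
  expect_error(pseudo_t_map(A[1, , drop = FALSE], B, grid_s, "independent"),
               ">= 2 subjects")
})

test_that("TFCE matches its closed form, the R oracle, and favors clusters", {
  # all-zero map stays zero
  expect_true(all(tfce(numeric(npts_s), grid_s)$values == 0))

  # single voxel of height t: integral of h^H dh -> t^(H+1)/(H+1)
  v <- numeric(npts_s); v[14] <- 3
  enh <- tfce(v, grid_s, tfce_params(n_steps = 1000))
  expect_lt(abs(enh$values[14] - 3^3 / 3) / (3^3 / 3), 0.01)

  # equal-height voxel inside a plateau beats an isolated one
  v2 <- numeric(npts_s)
  seedpt <- which.max(grid_s$points[, 3])
  plateau <- order(colSums((t(grid_s$points) - grid_s$points[seedpt, ])^2))[1:10]
  iso <- which.min(grid_s$points[, 3])
  v2[plateau] <- 2; v2[iso] <- 2
  e2 <- tfce(v2, grid_s)$values
  expect_gt(e2[seedpt], e2[iso])

  # compiled implementation vs the pure-R threshold-sweep oracle
  set.seed(42)
  v3 <- pmax(rnorm(npts_s), 0)
  mine <- tfce(v3, grid_s, tfce_params(n_steps = 25))$values
  oracle <- brute_tfce(v3, grid_s, n_steps = 25)
  expect_lt(max(abs(mine - oracle)), 1e-10)

  # negative lobes are enhanced on the negated map
  e_neg <- tfce(-v3, grid_s, tfce_params(n_steps = 25))$values
  expect_equal(e_neg, -mine)
})

test_that("TFCE is monotone and strictly increasing under map scaling", {
  set.seed(43)
  m2 <- pmax(rnorm(npts_s), 0)
  m1 <- m2 + stats::runif(npts_s, 0, 0.5)   # m1 >= m2 voxelwise
  p <- tfce_params(dh = 0.02)
  e1 <- tfce(m1, grid_s, p)$values
  e2 <- tfce(m2, grid_s, p)$values
  expect_true(all(e1 - e2 > -1e-12))

  ec <- tfce(1.5 * m2, grid_s, p)$values
  nz <- e2 > 0
  expect_true(all(ec[nz] > e2[nz]))
})

test_that("permutation p-values are exact for a permutation-invariant map", {
  A <- matrix(0.7, 6, npts_s)
  B <- matrix(0.7, 6, npts_s)
  res <- suppressWarnings(
    permutation_fwe(A, B, grid_s, "independent", n_perms = 100, seed = 9))
  expect_true(all(res$fwe_p > 0.95))
})

test_that("a planted group effect is localized by the permutation test", {
  set.seed(45)
  bump_pt <- which.min(colSums((t(grid_s$points) - c(0.02, 0.02, 0.02))^2))
  d2 <- colSums((t(grid_s$points) - grid_s$points[bump_pt, ])^2)
  bump <- 2.5 * exp(-d2 / (2 * 0.012^2))
  A <- matrix(rnorm(8 * npts_s), 8) + matrix(bump, 8, npts_s, byrow = TRUE)
  B <- matrix(rnorm(8 * npts_s), 8)
  res <- permutation_fwe(A, B, grid_s, "independent", n_perms = 200, seed = 10)
  best <- which.min(res$fwe_p)
  err <- sqrt(sum((grid_s$points[best, ] - grid_s$points[bump_pt, ])^2))
  expect_lte(err, 2 * grid_s$spacing + 1e-12)
  expect_lt(min(res$fwe_p), 0.05)

  # determinism given the seed
  res2 <- permutation_fwe(A, B, grid_s, "independent", n_perms = 200, seed = 10)
  expect_identical(res$fwe_p, res2$fwe_p)
  expect_identical(res$max_stat_null, res2$max_stat_null)
})

test_that("a small-volume mask changes the max statistic but not the t map", {
  set.seed(46)
  A <- matrix(rnorm(6 * npts_s), 6); B <- matrix(rnorm(6 * npts_s), 6)
  mask <- colSums((t(grid_s$points) - c(0.02, 0, 0.02))^2) < 0.02^2
  full <- permutation_fwe(A, B, grid_s, "independent", n_perms = 100,
                          seed = 11)
  svc <- permutation_fwe(A, B, grid_s, "independent", n_perms = 100,
                         seed = 11, mask = mask)
  expect_identical(full$stat_map$t_values, svc$stat_map$t_values)
  expect_identical(full$observed_tfce, svc$observed_tfce)
  expect_true(all(svc$max_stat_null <= full$max_stat_null + 1e-12))
})

test_that("interaction contrasts are linear and handle missing subjects", {
  set.seed(47)
  base <- matrix(rnorm(6 * npts_s), 6)
  # ctrl equal to nat for every subject: difference maps all zero
  res0 <- suppressWarnings(
    interaction_contrast(base, base, base + 1, base + 1, grid_s,
                         n_perms = 100, seed = 12))
  expect_true(all(res0$stat_map$t_values == 0))
  expect_true(all(res0$diff_a == 0))

  # scaling all maps scales the difference maps
  natA <- matrix(rnorm(6 * npts_s), 6); ctlA <- matrix(rnorm(6 * npts_s), 6)
  natB <- matrix(rnorm(6 * npts_s), 6); ctlB <- matrix(rnorm(6 * npts_s), 6)
  r1 <- suppressWarnings(interaction_contrast(natA, ctlA, natB, ctlB, grid_s,
                                              n_perms = 100, seed = 13))
  r3 <- suppressWarnings(interaction_contrast(3 * natA, 3 * ctlA, 3 * natB,
                                              3 * ctlB, grid_s,
                                              n_perms = 100, seed = 13))
  expect_equal(r3$diff_a, 3 * r1$diff_a)
  expect_equal(r3$diff_b, 3 * r1$diff_b)

  # a subject with an absent condition map is dropped with a warning
  natA_m <- natA; natA_m[2, ] <- NA
  expect_warning(
    rm2 <- interaction_contrast(natA_m, ctlA, natB, ctlB, grid_s,
                                n_perms = 100, seed = 14),
    "excluded")
  expect_equal(nrow(rm2$diff_a), 5)
})
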