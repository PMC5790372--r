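# The synthetic study generator.

test_that("synthetic stimuli are speech-like and reproducible", {
  s <- synth_stimulus(7, 10, seed = 61, audio_rate = 8000)
  expect_equal(s$rate, 8000)
  expect_equal(s$duration_s, 10)
  expect_equal(max(abs(s$samples)), 1)

  # modulator spectrum peaks at the syllabic rate
  m <- attr(s, "modulator")
  m <- m - mean(m)
  sp <- Mod(stats::fft(m))[2:151]
  fgrid <- (1:150) / 10
  pk <- fgrid[which.max(sp)]
  expect_true(pk >= 6 && pk <= 8)

  s2 <- synth_stimulus(7, 10, seed = 61, audio_rate = 8000)
  expect_identical(s$samples, s2$samples)

  expect_error(synth_stimulus(25, 10), "below 20")
  expect_error(synth_stimulus(7, 1), "at least 2")
})

test_that("configuration validation catches bad coupling and positions", {
  expect_error(simulation_config(
    coupling_alpha = list(STG = list(EB = c(nat = 1.4)))), "\\[0, 1\\]")
  expect_error(simulation_config(
    source_positions = rbind(STG = c(0.1, 0, 0))), "inside")
  expect_error(synth_subject(simulation_config(), "XX", 1), "unknown group")
  cfg <- simulation_config(
    coupling_alpha = list(NOWHERE = list(EB = c(nat = 0.5))))
  expect_error(synth_subject(cfg, "EB", 1), "without a position")
})

test_that("the default cohort has the study's group sizes and conditions", {
  cfg <- simulation_config(n_trials_per_condition = 6, n_sensors = 12,
                           audio_rate_hz = 4096, seed = 3)
  cfg$source_positions <- cfg$source_positions  # defaults kept
  expect_equal(unname(cfg$n_subjects), c(17, 16))
  ds <- synth_cohort(cfg)
  expect_length(ds$subjects, 33)
  expect_equal(unname(table(ds$groups)), c(17, 16), ignore_attr = TRUE)
  e1 <- ds$subjects[[1]]
  expect_equal(sort(unique(e1$condition)),
               sort(c("nat", "8-channel", "1-channel")))
  expect_equal(dim(e1$epochs), c(18, 12, 256))
  expect_equal(dim(e1$envelope_epochs), c(18, 256))
  expect_s3_class(ds$ground_truth, "simulation_config")
})

test_that("cohorts regenerate bit-identically from the master seed", {
  cfg <- simulation_config(n_trials_per_condition = 5, n_sensors = 8,
                           n_subjects = c(EB = 2, SI = 1),
                           conditions = "nat", audio_rate_hz = 4096, seed = 77)
  d1 <- synth_cohort(cfg)
  d2 <- synth_cohort(cfg)
  expect_identical(d1$subjects[[1]]$epochs, d2$subjects[[1]]$epochs)
  expect_identical(d1$subjects[[3]]$envelope_epochs,
                   d2$subjects[[3]]$envelope_epochs)
  # different subjects are different data
  expect_false(identical(d1$subjects[[1]]$epochs, d1$subjects[[2]]$epochs))
})

test_that("sensor-level coupling grows monotonically with alpha", {
  cfg0 <- simulation_config(
    n_trials_per_condition = 30, conditions = "nat",
    n_subjects = c(A = 1, B = 1),
    coupling_alpha = list(SRC = list(A = c(nat = 0.5), B = c(nat = 0.5))),
    source_positions = rbind(SRC = c(0.056, -0.008, 0.016)),
    n_sensors = 16, snr_db = 0, seed = 62)
  mats <- speechtrack:::.synth_materials(cfg0)
  zmax_of <- function(alpha, seed) {
    cfg <- cfg0
    cfg$coupling_alpha$SRC$A["nat"] <- alpha
    e <- synth_subject(cfg, "A", seed, stimuli = mats$stimuli,
                       envelopes = mats$envelopes,
                       envelopes_aligned = mats$aligned)
    z <- envelope_coherence(compute_csd(e))$z
    max(rowMeans(z[, 4:9]))
  }
  zs <- vapply(c(0.2, 0.4, 0.6, 0.8), function(a)
    mean(c(zmax_of(a, 63), zmax_of(a, 64), zmax_of(a, 65))), 0)
  expect_true(all(diff(zs) > 0))
})

test_that("without coupling the coherence map sits at the permutation null", {
  sim <- small_coupled_subject(alpha = 0, n_trials = 30, n_sensors = 16,
                               seed = 65, subject_seed = 66)
  csd <- compute_csd(sim$epochs)
  obs <- max(rowMeans(envelope_coherence(csd)$z[, 4:9]))
  # trial-shuffled envelope null
  nulls <- vapply(1:20, function(s) {
    ep <- sim$epochs
    set.seed(s)
    ep$envelope_epochs <- ep$envelope_epochs[sample(nrow(ep$envelope_epochs)), ]
    max(rowMeans(envelope_coherence(compute_csd(ep))$z[, 4:9]))
  }, 0)
  expect_lt(obs, max(nulls))   # not above the null distribution's range
})

test_that("directed pairs validate PSI and flip with role reversal", {
  dp <- directed_pair(40, 20, seed = 67)
  expect_equal(dim(dp$x1$epochs), c(40, 256))
  p12 <- phase_slope_index(dp$x1, dp$x2)
  p21 <- phase_slope_index(dp$x2, dp$x1)
  expect_gt(p12$psi_norm, 0)
  expect_lt(p21$psi_norm, 0)
  expect_error(directed_pair(10, 1500), "smaller than")
})
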