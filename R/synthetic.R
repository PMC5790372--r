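#' Default coupling structure of the synthetic study
#'
#' Mirrors the qualitative effect structure of the emulated experiment:
#' superior temporal gyrus (STG) tracks the envelope in everyone;
#' parieto-occipital cortex (POC) tracks it only in the early-blind (EB)
#' group, in every condition; calcarine sulcus (CS) tracks it only in EB
#' and only for intelligible (natural) speech, producing a
#' group-by-intelligibility interaction.
#'
#' @param alpha_stg,alpha_poc,alpha_cs coupling strengths in `[0, 1]`.
#' @return nested list `alpha[[source]][[group]][[condition]]`.
#' @export
default_coupling <- function(alpha_stg = 0.5, alpha_poc = 0.4,
                             alpha_cs = 0.4) {
  conds <- c("nat", "8-channel", "1-channel")
  all_on <- function(a) stats::setNames(rep(a, 3), conds)
  list(
    STG = list(EB = all_on(alpha_stg), SI = all_on(alpha_stg)),
    POC = list(EB = all_on(alpha_poc), SI = all_on(0)),
    CS  = list(EB = stats::setNames(c(alpha_cs, 0, 0), conds),
               SI = all_on(0)))
}

#' Configuration of the synthetic cerebro-acoustic study
#'
#' Defines the full generative model: speech-like stimuli with
#' syllabic-rate amplitude modulation, cortical dipole sources whose
#' activity is partially coupled (strength `alpha`, lag `tau`) to the
#' theta-band stimulus envelope on a background of pink noise, projection
#' through the spherical-conductor leadfield onto the sensor array, sensor
#' noise at a given SNR, and a two-group cohort over three conditions.
#'
#' @param syllable_rate_hz mean syllable rate of the stimuli (default 7,
#'   the Italian syllabic rate).
#' @param n_trials_per_condition 1 s epochs per condition (default 60,
#'   i.e. one ~1 min story).
#' @param conditions condition labels (subset of
#'   `c("nat", "8-channel", "1-channel")`).
#' @param n_subjects named vector of group sizes (default
#'   `c(EB = 17, SI = 16)`).
#' @param coupling_alpha nested list `[[source]][[group]][[condition]]` in
#'   `[0, 1]` (default [default_coupling()]).
#' @param lag_tau_ms named lag per source in ms (default 20 for each).
#' @param snr_db sensor-level SNR in dB (default 0).
#' @param source_positions named matrix of source coordinates in meters
#'   (defaults: STG, CS, POC inside the conductor).
#' @param n_sensors,sensor_radius_m,conductor_radius_m,grid_spacing_m
#'   geometry (defaults 102, 0.12, 0.09, 0.008).
#' @param sim_rate_hz rate of the simulated continuous recording
#'   (default 512; preprocessing filters and downsamples it to 256).
#' @param audio_rate_hz stimulus audio rate (default 22050).
#' @param epoch_len_s epoch length in seconds (default 1).
#' @param seed master seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(syllable_rate_hz = 7,
                              n_trials_per_condition = 60,
                              conditions = c("nat", "8-channel", "1-channel"),
                              n_subjects = c(EB = 17, SI = 16),
                              coupling_alpha = default_coupling(),
                              lag_tau_ms = c(STG = 20, CS = 20, POC = 20),
                              snr_db = 0,
                              source_positions = NULL,
                              n_sensors = 102, sensor_radius_m = 0.12,
                              conductor_radius_m = 0.09,
                              grid_spacing_m = 0.008,
                              sim_rate_hz = 512, audio_rate_hz = 22050,
                              epoch_len_s = 1, seed = 1) {
  if (is.null(source_positions)) {
    source_positions <- rbind(STG = c(0.056, -0.008, 0.016),
                              CS  = c(0.008, -0.056, 0.016),
                              POC = c(0.000, -0.048, 0.048))
  }
  a <- unlist(coupling_alpha)
  if (any(a < 0 | a > 1)) stop("coupling alpha values must lie in [0, 1]")
  if (syllable_rate_hz <= 0 || sim_rate_hz <= 0) stop("rates must be positive")
  if (any(sqrt(rowSums(source_positions^2)) >= conductor_radius_m))
    stop("source positions must lie inside the conductor")
  structure(list(syllable_rate_hz = syllable_rate_hz,
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 conditions = conditions, n_subjects = n_subjects,
                 coupling_alpha = coupling_alpha, lag_tau_ms = lag_tau_ms,
                 snr_db = snr_db, source_positions = source_positions,
                 n_sensors = as.integer(n_sensors),
                 sensor_radius_m = sensor_radius_m,
                 conductor_radius_m = conductor_radius_m,
                 grid_spacing_m = grid_spacing_m,
                 sim_rate_hz = sim_rate_hz, audio_rate_hz = audio_rate_hz,
                 epoch_len_s = epoch_len_s, seed = as.integer(seed)),
            class = "simulation_config")
}

.alpha_of <- function(config, src, group, cond) {
  a <- config$coupling_alpha[[src]][[group]][[cond]]
  if (is.null(a) || is.na(a)) 0 else a
}

#' Synthesize a speech-like stimulus
#'
#' Band-limited noise carrier multiplied by a jittered syllable-train
#' modulator: gamma-shaped amplitude bursts at the given mean rate with
#' 15% coefficient-of-variation jitter on the inter-burst intervals. The
#' result reproduces the amplitude statistics of connected speech (a
#' dominant envelope modulation at the syllabic rate) without phonetic
#' content. Normalized to peak 1; deterministic given the seed.
#'
#' @param rate_hz mean syllable rate in Hz (< 20).
#' @param duration_s duration in seconds (>= 2).
#' @param seed integer seed.
#' @param audio_rate audio sampling rate in Hz (default 22050).
#' @return an [audio_signal()]; the modulator is attached as
#'   `attr(, "modulator")`.
#' @export
synth_stimulus <- function(rate_hz = 7, duration_s = 60, seed = 1,
                           audio_rate = 22050) {
  if (rate_hz >= 20) stop("syllable rate must be below 20 Hz (speech-like)")
  if (duration_s < 2) stop("duration must be at least 2 s")
  n <- round(duration_s * audio_rate)
  .with_seed(seed, {
    # jittered syllable onsets
    mean_gap <- 1 / rate_hz
    gaps <- rnorm(ceiling(duration_s * rate_hz * 1.5), mean_gap,
                  0.15 * mean_gap)
    gaps <- pmax(gaps, 0.3 * mean_gap)
    onsets <- cumsum(c(0.05, gaps))
    onsets <- onsets[onsets < duration_s]
    train <- numeric(n)
    train[pmin(n, round(onsets * audio_rate) + 1)] <- 1
    # gamma-shaped burst kernel, peak 1 at t = s
    s <- 0.25 / rate_hz
    tk <- seq(0, 8 * s, by = 1 / audio_rate)
    kern <- (tk / s) * exp(1 - tk / s)
    m <- ceiling(log2(n + length(kern)))
    Ft <- fft(c(train, numeric(2^m - n)))
    Fk <- fft(c(kern, numeric(2^m - length(kern))))
    mod <- Re(fft(Ft * Fk, inverse = TRUE))[seq_len(n)] / 2^m
    mod <- pmax(mod, 0)
    carrier_sos <- butter_sos(4, c(100, min(9000, 0.45 * audio_rate)),
                              "pass", audio_rate)
    carrier <- sos_filtfilt(carrier_sos, rnorm(n))
    x <- carrier * mod
    x <- x / max(abs(x))
    out <- audio_signal(x, audio_rate)
    attr(out, "modulator") <- mod
    out
  })
}

# Leadfield of one source position projected on the sensors, times a fixed
# tangential unit orientation. Returns a sensor-gain vector.
.source_gain <- function(pos, sensors) {
  u <- c(-pos[2], pos[1], 0)               # z x p: tangential
  if (sqrt(sum(u^2)) < 1e-9) u <- c(0, -pos[3], pos[2])
  u <- u / sqrt(sum(u^2))
  drop(.leadfield_point(pos, sensors) %*% u) * 1e-8  # 10 nA m dipole
}

# Theta-band (4-9 Hz), unit-variance version of a stimulus envelope at the
# simulation rate.
.theta_envelope <- function(env, sim_rate) {
  e <- resample_signal(env$samples, env$rate, sim_rate)
  sos <- butter_sos(4, c(4, 9), "pass", sim_rate)
  drop(scale(sos_filtfilt(sos, e)))
}

.delay <- function(x, k) {
  if (k <= 0) return(x)
  c(rep(x[1], k), x[seq_len(length(x) - k)])
}

#' Simulate one subject's epoched recording
#'
#' For each condition, builds per-source activity
#' `s(t) = alpha * env_theta(t - tau) + sqrt(1 - alpha^2) * pink(t)`
#' (theta-band stimulus envelope plus pink noise, unit variance), projects
#' all sources through the spherical leadfield onto the sensor array, adds
#' white sensor noise at the configured SNR, runs the standard
#' preprocessing chain (filters, downsampling to 256 Hz), and epochs the
#' result together with the identically processed stimulus envelope.
#'
#' @param config a [simulation_config()].
#' @param group group label (must appear in `config$n_subjects`).
#' @param subject_seed integer seed for this subject.
#' @param subject_id subject identifier.
#' @param stimuli optional named list of per-condition [audio_signal()]s
#'   (generated from the config when omitted).
#' @param envelopes optional named list of per-condition
#'   [extract_speech_envelope()] results.
#' @param envelopes_aligned optional named list of envelopes already passed
#'   through [align_envelope_to_recording()] at 256 Hz.
#' @param sensors optional [make_sensor_array()] (built from the config
#'   when omitted).
#' @return an `epoch_set` with all conditions' trials and the aligned
#'   envelope.
#' @export
synth_subject <- function(config, group, subject_seed,
                          subject_id = paste0(group, "_", subject_seed),
                          stimuli = NULL, envelopes = NULL,
                          envelopes_aligned = NULL, sensors = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!group %in% names(config$n_subjects)) stop("unknown group: ", group)
  missing_src <- setdiff(names(config$coupling_alpha),
                         rownames(config$source_positions))
  if (length(missing_src))
    stop("source label(s) without a position: ",
         paste(missing_src, collapse = ", "))
  mats <- .synth_materials(config, stimuli, envelopes, envelopes_aligned)
  if (is.null(sensors))
    sensors <- make_sensor_array(config$n_sensors, config$sensor_radius_m,
                                 config$conductor_radius_m)
  gains <- lapply(rownames(config$source_positions), function(s)
    .source_gain(config$source_positions[s, ], sensors))
  names(gains) <- rownames(config$source_positions)

  rate <- config$sim_rate_hz
  dur <- config$n_trials_per_condition * config$epoch_len_s
  nsamp <- round(dur * rate)
  per_cond <- .with_seed(subject_seed, lapply(config$conditions, function(cond) {
    envth <- mats$theta[[cond]][seq_len(nsamp)]
    sig <- matrix(0, length(sensors$positions[, 1]), nsamp)
    for (src in rownames(config$source_positions)) {
      a <- .alpha_of(config, src, group, cond)
      tau_ms <- config$lag_tau_ms[src]
      if (is.na(tau_ms)) tau_ms <- 20
      tau <- round(tau_ms / 1000 * rate)
      series <- a * .delay(envth, tau) +
        sqrt(1 - a^2) * .pink_noise(nsamp, rate)
      sig <- sig + outer(gains[[src]], series)
    }
    p_sig <- mean(sig^2)
    noise_sd <- sqrt(p_sig / 10^(config$snr_db / 10))
    sig <- sig + matrix(rnorm(length(sig), sd = noise_sd), nrow(sig))
    rec <- sensor_recording(sig, rate, sensors = sensors)
    rec <- apply_standard_filters(rec)
    rec <- downsample(rec, 256)
    env_al <- mats$aligned[[cond]]
    env_al$samples <- env_al$samples[seq_len(ncol(rec$data))]
    epoch_recording(rec, config$epoch_len_s, env_al, condition = cond,
                    subject_id = subject_id, group = group)
  }))
  .concat_epochs(per_cond)
}

# Stimuli, envelopes and aligned envelopes for the configured conditions;
# anything already supplied is reused.
.synth_materials <- function(config, stimuli = NULL, envelopes = NULL,
                             aligned = NULL) {
  dur <- config$n_trials_per_condition * config$epoch_len_s
  if (is.null(stimuli)) {
    nat <- synth_stimulus(config$syllable_rate_hz, dur,
                          seed = config$seed + 101L,
                          audio_rate = config$audio_rate_hz)
    # vocoder analysis range capped below the stimulus Nyquist
    hi <- min(9000, floor(0.45 * config$audio_rate_hz))
    vspec <- function(nch, seed) vocoder_spec(nch, band_hi_hz = hi,
                                              noise_seed = seed)
    stimuli <- list()
    for (cond in config$conditions) {
      stimuli[[cond]] <- switch(cond,
        "nat" = nat,
        "8-channel" = vocode(nat, vspec(8, config$seed + 8L)),
        "1-channel" = vocode(nat, vspec(1, config$seed + 1L)),
        stop("unknown condition: ", cond))
    }
  }
  if (is.null(envelopes))
    envelopes <- lapply(stimuli, extract_speech_envelope)
  if (is.null(aligned))
    aligned <- lapply(envelopes, align_envelope_to_recording,
                      target_rate = 256)
  theta <- lapply(envelopes, .theta_envelope, sim_rate = config$sim_rate_hz)
  list(stimuli = stimuli, envelopes = envelopes, aligned = aligned,
       theta = theta)
}

.concat_epochs <- function(sets) {
  out <- sets[[1]]
  if (length(sets) == 1) return(out)
  out$epochs <- do.call(abind_trials, lapply(sets, `[[`, "epochs"))
  env <- lapply(sets, `[[`, "envelope_epochs")
  if (!any(vapply(env, is.null, TRUE)))
    out$envelope_epochs <- do.call(rbind, env)
  out$condition <- unlist(lapply(sets, `[[`, "condition"))
  out
}

# rbind for trials x channels x samples arrays
abind_trials <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], 0L))
  out <- array(0, c(total, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1]
    out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}

#' Simulate the full synthetic cohort
#'
#' Generates the stimuli once (natural plus its 8-channel and 1-channel
#' vocoded versions, as configured), then simulates every subject of every
#' group with independent seeds derived from the master seed. Ground truth
#' (the configuration) is embedded in the result.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_dataset` with `subjects` (list of
#'   `epoch_set`s), `groups` (group label per subject), `stimuli`,
#'   `envelopes`, `sensors` and `ground_truth`.
#' @export
synth_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  mats <- .synth_materials(config)
  sensors <- make_sensor_array(config$n_sensors, config$sensor_radius_m,
                               config$conductor_radius_m)
  n_total <- sum(config$n_subjects)
  seeds <- .child_seeds(config$seed, n_total)
  subjects <- list(); groups <- character(0)
  i <- 0L
  for (g in names(config$n_subjects)) {
    for (k in seq_len(config$n_subjects[[g]])) {
      i <- i + 1L
      id <- sprintf("%s%02d", g, k)
      subjects[[id]] <- synth_subject(config, g, seeds[i], subject_id = id,
                                      stimuli = mats$stimuli,
                                      envelopes = mats$envelopes,
                                      envelopes_aligned = mats$aligned,
                                      sensors = sensors)
      groups <- c(groups, g)
    }
  }
  structure(list(subjects = subjects, groups = groups,
                 stimuli = mats$stimuli, envelopes = mats$envelopes,
                 sensors = sensors, ground_truth = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d subjects (%s), conditions: %s\n",
              length(x$subjects),
              paste(names(table(x$groups)), table(x$groups), sep = ":",
                    collapse = " "),
              paste(x$ground_truth$conditions, collapse = ", ")))
  invisible(x)
}

#' Generate a directed virtual-sensor pair with known lead/lag
#'
#' `x2` is a delayed, noise-mixed copy of `x1`, so `x1` temporally precedes
#' `x2` by `lag_ms`; used to validate the sign and magnitude of the phase
#' slope index.
#'
#' @param n_trials number of 1 s epochs (default 60).
#' @param lag_ms delay of `x2` relative to `x1` in ms (may be 0 for a
#'   null pair; must be smaller than the epoch length).
#' @param noise_sd standard deviation of the independent noise added to
#'   `x2` (relative to the unit-variance shared signal; default 1).
#' @param rate sampling rate in Hz (default 256).
#' @param seed integer seed.
#' @return a list with `x1`, `x2` (`virtual_sensor` objects) and `lag_ms`.
#' @export
directed_pair <- function(n_trials = 60, lag_ms = 20, noise_sd = 1,
                          rate = 256, seed = 1) {
  if (lag_ms / 1000 >= 1) stop("lag must be smaller than the 1 s epoch")
  k <- round(lag_ms / 1000 * rate)
  n <- n_trials * rate
  .with_seed(seed, {
    s <- .pink_noise(n + k, rate)
    x1 <- s[(k + 1):(n + k)]
    x2 <- s[seq_len(n)] + noise_sd * .pink_noise(n, rate)
    as_vs <- function(v, lab) structure(
      list(epochs = matrix(v, n_trials, rate, byrow = TRUE), rate = rate,
           location_label = lab, svd_gain = 1, condition = NA),
      class = "virtual_sensor")
    list(x1 = as_vs(x1, "x1"), x2 = as_vs(x2, "x2"), lag_ms = lag_ms)
  })
}
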