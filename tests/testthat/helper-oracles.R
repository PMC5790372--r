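# Independent oracles and small shared fixtures.

# Brute-force magnitude coherence with the envelope via explicit DFT sums
# (no FFT, no shared code path with compute_csd/coherence).
brute_coherence <- function(epochs, envelope, fmin = 1, fmax = 30, step = 1,
                            rate = 256, epoch_len_s = 1) {
  n_trials <- dim(epochs)[1]; nch <- dim(epochs)[2]; ns <- dim(epochs)[3]
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(ns - 1)) / (ns - 1))
  freqs <- seq(fmin, fmax, by = step)
  coh <- matrix(0, nch, length(freqs))
  for (fi in seq_along(freqs)) {
    k <- freqs[fi] * epoch_len_s          # DFT bin index
    basis <- exp(-2i * pi * k * (0:(ns - 1)) / ns)
    Xe <- complex(length.out = n_trials)
    for (tr in seq_len(n_trials))
      Xe[tr] <- sum(envelope[tr, ] * w * basis)
    for (ch in seq_len(nch)) {
      Sxy <- 0 + 0i; Sxx <- 0; Syy <- 0
      for (tr in seq_len(n_trials)) {
        Xc <- sum(epochs[tr, ch, ] * w * basis)
        Sxy <- Sxy + Xc * Conj(Xe[tr])
        Sxx <- Sxx + Mod(Xc)^2
        Syy <- Syy + Mod(Xe[tr])^2
      }
      coh[ch, fi] <- Mod(Sxy) / sqrt(Sxx * Syy)
    }
  }
  list(freqs = freqs, coh = coh)
}

# Pure-R TFCE by explicit threshold sweep and breadth-first component
# labelling (independent of the compiled union-find implementation).
brute_tfce <- function(values, grid, E = 0.5, H = 2, n_steps = 100,
                       connectivity = 26) {
  stopifnot(all(values >= 0))
  npts <- length(values)
  vmax <- max(values)
  if (vmax <= 0) return(numeric(npts))
  dh <- vmax / n_steps
  ijk <- grid$ijk
  is_nbr <- function(a, b) {
    d <- abs(ijk[a, ] - ijk[b, ])
    max(d) == 1 && sum(d) <= switch(as.character(connectivity),
                                    "6" = 1, "18" = 2, "26" = 3)
  }
  enh <- numeric(npts)
  for (s in seq_len(n_steps)) {
    h <- s * dh
    act <- which(values >= h)
    if (!length(act)) next
    lab <- rep(0L, length(act)); cur <- 0L
    for (i in seq_along(act)) {
      if (lab[i] > 0) next
      cur <- cur + 1L
      queue <- i; lab[i] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (j in seq_along(act)) {
          if (lab[j] == 0 && is_nbr(act[v], act[j])) {
            lab[j] <- cur; queue <- c(queue, j)
          }
        }
      }
    }
    sizes <- tabulate(lab)
    enh[act] <- enh[act] + sizes[lab]^E * h^H * dh
  }
  enh
}

# Epoch set of white-noise channels plus an independent white-noise
# envelope channel.
white_epochs <- function(n_trials, nch = 1, ns = 256, rate = 256, seed = 1) {
  set.seed(seed)
  structure(list(epochs = array(rnorm(n_trials * nch * ns),
                                c(n_trials, nch, ns)),
                 envelope_epochs = matrix(rnorm(n_trials * ns), n_trials),
                 rate = rate, epoch_len_s = ns / rate,
                 condition = rep("x", n_trials),
                 subject_id = NA, group = NA,
                 channel_ids = sprintf("MEG%03d", seq_len(nch)),
                 sensors = NULL),
            class = "epoch_set")
}

# Wrap a continuous series into a virtual_sensor with 1 s epochs.
as_virtual_sensor <- function(x, n_trials, rate = 256, label = "vs") {
  structure(list(epochs = matrix(x[seq_len(n_trials * rate)], n_trials,
                                 rate, byrow = TRUE),
                 rate = rate, location_label = label, svd_gain = 1,
                 condition = NA),
            class = "virtual_sensor")
}

# A small simulation: one envelope-coupled source, reduced sensor count.
# Used by beamformer and coherence tests.
small_coupled_subject <- function(alpha = 0.8, n_trials = 40, n_sensors = 32,
                                  pos = c(0.056, -0.008, 0.016), seed = 7,
                                  subject_seed = 11, snr_db = 0) {
  cfg <- simulation_config(
    n_trials_per_condition = n_trials, conditions = "nat",
    n_subjects = c(A = 1, B = 1),
    coupling_alpha = list(SRC = list(A = c(nat = alpha), B = c(nat = alpha))),
    source_positions = rbind(SRC = pos),
    n_sensors = n_sensors, snr_db = snr_db, seed = seed)
  list(cfg = cfg, epochs = synth_subject(cfg, "A", subject_seed))
}
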