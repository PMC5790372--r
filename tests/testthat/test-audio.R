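# WAV input/output and the noise vocoder.

test_that("WAV files round-trip", {
  path <- withr::local_tempfile(fileext = ".wav")

  x <- audio_signal(numeric(44100), 44100)
  write_wav(x, path, "float32")
  y <- read_wav(path)
  expect_equal(y$rate, 44100)
  expect_identical(y$samples, numeric(44100))

  # full-scale 16-bit sine: peak within 1 LSB of 1.0
  s <- audio_signal(sin(2 * pi * 440 * (0:4409) / 44100), 44100)
  write_wav(s, path, "pcm16")
  z <- read_wav(path)
  expect_lt(abs(max(abs(z$samples)) - max(abs(s$samples))), 1 / 32768)
  expect_lt(max(abs(z$samples - s$samples)), 2 / 32768)

  # float32 round-trip at float precision
  write_wav(s, path, "float32")
  expect_lt(max(abs(read_wav(path)$samples - s$samples)), 1e-7)
})

test_that("stereo files with identical channels read as that channel", {
  path <- withr::local_tempfile(fileext = ".wav")
  n <- 1000
  mono <- sin(2 * pi * 100 * (0:(n - 1)) / 8000) * 0.5
  v <- as.integer(round(rep(mono, each = 2) * 32767))  # interleaved L = R
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 4 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(2L, con, size = 2, endian = "little")          # stereo
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(4 * n), con, size = 4, endian = "little")
  writeBin(v, con, size = 2, endian = "little")
  close(con)
  y <- read_wav(path)
  expect_equal(y$rate, 8000)
  expect_equal(length(y$samples), n)
  expect_lt(max(abs(y$samples - round(mono * 32767) / 32768)), 1e-12)
})

test_that("read_wav rejects missing or malformed files", {
  expect_error(read_wav(file.path(tempdir(), "no-such-file.wav")), "not found")
  bad <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:32), bad)
  expect_error(read_wav(bad))
})

test_that("log band edges are geometric and contiguous", {
  s1 <- vocoder_spec(1, 70, 9000)
  expect_equal(unname(log_band_edges(s1)), matrix(c(70, 9000), 1))

  s8 <- vocoder_spec(8, 70, 9000)
  b <- log_band_edges(s8)
  expect_equal(nrow(b), 8)
  expect_equal(b[-1, "lo"], b[-8, "hi"])          # contiguous
  ratios <- b[, "hi"] / b[, "lo"]
  expect_equal(ratios, rep((9000 / 70)^(1 / 8), 8), tolerance = 1e-12)
  expect_error(vocoder_spec(0), "n_channels")
})

test_that("vocoding preserves the slow envelope and destroys fine structure", {
  stim <- synth_stimulus(7, 8, seed = 41)
  broadband_env <- function(a) {
    e <- Mod(analytic_signal(a$samples))
    sos_filtfilt(butter_sos(4, 30, "low", a$rate), e)
  }
  e0 <- broadband_env(stim)
  for (nch in c(1, 8)) {
    v <- vocode(stim, vocoder_spec(nch, noise_seed = 5))
    expect_equal(length(v$samples), length(stim$samples))
    expect_gt(stats::cor(e0, broadband_env(v)), 0.8)
  }

  # all-zero input stays zero
  z <- vocode(audio_signal(numeric(22050), 22050), vocoder_spec(8))
  expect_identical(z$samples, numeric(22050))

  # determinism: same signal, same seed, bit-identical
  v1 <- vocode(stim, vocoder_spec(1, noise_seed = 9))
  v2 <- vocode(stim, vocoder_spec(1, noise_seed = 9))
  expect_identical(v1$samples, v2$samples)

  # band edges above Nyquist rejected
  expect_error(vocode(audio_signal(rnorm(8000), 8000), vocoder_spec(1)),
               "Nyquist")
})

test_that("per-band RMS of the vocoded output matches the input within 1%", {
  stim <- synth_stimulus(7, 6, seed = 42)
  spec <- vocoder_spec(8)
  v <- vocode(stim, spec)
  bands <- log_band_edges(spec)
  for (b in seq_len(8)) {
    sos <- butter_sos(4, bands[b, ], "pass", stim$rate)
    r_in <- sqrt(mean(sos_filtfilt(sos, stim$samples)^2))
    r_out <- sqrt(mean(sos_filtfilt(sos, v$samples)^2))
    expect_lt(abs(r_out / r_in - 1), 0.01)
  }
})

test_that("waveform fine structure decorrelates over seeds; 7 Hz AM envelope survives", {
  # 1-channel vocode of 7 Hz AM noise: output envelope tracks the input
  set.seed(8)
  fs <- 22050; t <- (0:(6 * fs - 1)) / fs
  carrier <- sos_filtfilt(butter_sos(4, c(100, 9000), "pass", fs),
                          rnorm(length(t)))
  am <- audio_signal((1 + 0.9 * sin(2 * pi * 7 * t)) * carrier /
                       max(abs(carrier)) / 2, fs)
  env_of <- function(a) sos_filtfilt(butter_sos(4, c(1, 30), "pass", a$rate),
                                     Mod(analytic_signal(a$samples)))
  v <- vocode(am, vocoder_spec(1, noise_seed = 3))
  expect_gt(stats::cor(env_of(am), env_of(v)), 0.9)

  # sample-wise correlation with the input is negligible across >= 10 seeds
  stim <- synth_stimulus(7, 4, seed = 43)
  rs <- vapply(1:10, function(s)
    stats::cor(stim$samples,
               vocode(stim, vocoder_spec(1, noise_seed = s))$samples), 0)
  expect_true(all(abs(rs) < 0.1))
})

test_that("spectrogram similarity to the original increases with channel count", {
  # needs a signal with independent per-band dynamics (formant-like
  # movement): only then can more channels track structure that a single
  # broadband envelope cannot
  set.seed(44)
  fs <- 22050
  n <- 6 * fs
  x <- numeric(n)
  for (b in list(c(150, 400), c(400, 1200), c(1200, 3500), c(3500, 9000))) {
    carrier <- sos_filtfilt(butter_sos(4, b, "pass", fs), rnorm(n))
    modu <- pmax(sos_filtfilt(butter_sos(4, stats::runif(1, 3, 8), "low", fs),
                              rnorm(n)), 0)
    x <- x + carrier * modu / stats::sd(carrier * modu)
  }
  stim <- audio_signal(x / max(abs(x)), fs)
  log_spectrogram <- function(a, nwin = 512) {
    n <- length(a$samples)
    nseg <- n %/% nwin
    m <- matrix(a$samples[seq_len(nseg * nwin)], nwin)
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))
    sp <- abs(stats::mvfft(m * w))[1:(nwin / 2), ]
    log10(sp + 1e-8)
  }
  s0 <- log_spectrogram(stim)
  sims <- vapply(c(1, 4, 8), function(nch) {
    v <- vocode(stim, vocoder_spec(nch, noise_seed = 6))
    stats::cor(as.numeric(s0), as.numeric(log_spectrogram(v)))
  }, 0)
  expect_true(all(diff(sims) > 0))
})
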