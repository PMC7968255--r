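fs <- 10000

test_that("high-pass filter has the specified stopband and passband", {
  tv <- (0:(3 * fs - 1)) / fs
  low <- sin(2 * pi * 100 * tv)
  hi <- sin(2 * pi * 1500 * tv)
  rms <- function(x) sqrt(mean(x^2))
  y_low <- highpass_oae(low, fs)
  y_hi <- highpass_oae(hi, fs)
  expect_lt(rms(y_low) / rms(low), 0.01)
  expect_lt(abs(rms(y_hi) / rms(hi) - 1), 0.02)
  expect_error(highpass_oae(low, fs, cutoff = 6000), "Nyquist")
})

test_that("filtered white-noise spectrum matches the analytic response", {
  set.seed(42)
  nseg <- 300
  nfft <- 1024
  flt <- cochleamod:::.highpass_filter(fs, 500, 6)
  acc <- numeric(nfft)
  for (i in seq_len(nseg)) {
    x <- rnorm(nfft + 400)
    y <- signal::filtfilt(flt, x)[201:(200 + nfft)]
    acc <- acc + Mod(stats::fft(y))^2
  }
  psd <- acc / nseg
  f <- (0:(nfft - 1)) / nfft * fs
  h2 <- cochleamod:::.iir_mag2(flt, f, fs)  # single-pass |H|^2 = filtfilt gain
  sel <- f > 600 & f < 4500
  ratio_db <- 10 * log10(psd[sel] / (h2[sel]^2 * nfft))
  # compare shape after removing the overall level
  expect_lt(max(abs(ratio_db - mean(ratio_db))), 1)
})

test_that("epoch extraction drops only out-of-bounds trials", {
  rec <- rnorm(fs * 20)
  attr(rec, "sampling_rate") <- fs
  tt <- data.frame(trial = 1:4, condition = c("auditory", "visual",
                                              "auditory", "visual"),
                   interval_onset = c(1, 5, 9, 18.5))
  ep <- extract_epochs(rec, tt, duration = 3)
  expect_equal(nrow(ep$data), 3)
  expect_equal(ep$rejected$trial, 4L)
  expect_equal(ep$rejected$reason, "onset_out_of_bounds")
  expect_equal(ep$trial_info$trial, 1:3)

  ep0 <- extract_epochs(rec, tt[0, ], duration = 3)
  expect_equal(nrow(ep0$data), 0)
})

test_that("a full synthetic session yields 40 trials per condition and ear", {
  cfg <- generator_config(n_trials_per_condition = 40, artifact_rate = 0,
                          seed = 6)
  s <- simulate_subject(cfg, 1, assemble_recording = TRUE, ears = "left")
  ep <- extract_epochs(s$recordings$left, s$trial_table, duration = 3)
  expect_equal(nrow(ep$data), 80)
  expect_equal(sum(ep$trial_info$condition == "auditory"), 40)
  expect_equal(sum(ep$trial_info$condition == "visual"), 40)
})

test_that("saturation rejection follows the run-length definition exactly", {
  set.seed(3)
  n <- 3 * fs
  clean <- matrix(rnorm(3 * n), 3, n)
  full_scale <- 8
  min_run <- round(2 / 1000 * fs)  # 20 samples
  # trial 1: 50 ms run; trial 2: run of exactly min_run - 1; trial 3 clean
  clean[1, ] <- inject_saturation(clean[1, ], 50, full_scale, fs, start = 500)
  idx <- 1000:(1000 + min_run - 2)
  clean[2, idx] <- full_scale
  ep <- epoch_set(clean, fs, full_scale = full_scale)
  out <- reject_saturation(ep)
  expect_equal(nrow(out$data), 2)
  expect_equal(out$rejected$reason, "saturation")
  expect_equal(out$rejected$trial, 1L)

  # run placed flush at the epoch edge is still caught
  edge <- matrix(rnorm(n), 1, n)
  edge[1, (n - 499):n] <- full_scale
  out2 <- reject_saturation(epoch_set(edge, fs, full_scale = full_scale))
  expect_equal(nrow(out2$data), 0)
})

test_that("bandpass bank recovers analytic envelopes of known signals", {
  tv <- (0:(3 * fs - 1)) / fs
  amp <- 0.7
  tone <- amp * sin(2 * pi * 1500 * tv)
  ep <- epoch_set(matrix(tone, 1), fs)
  bk <- bandpass_bank(ep, n_windows = 3)  # centers 1000, 1500, 2000
  expect_equal(bk$band_centers, c(1000, 1500, 2000))
  m <- dim(bk$envelopes)[3]
  inner <- round(0.2 * m):round(0.8 * m)
  expect_true(all(abs(bk$envelopes[1, 2, inner] - amp) < 0.02 * amp))
  expect_true(all(bk$envelopes[1, 1, inner] < 0.01 * amp))

  # amplitude-modulated carrier: envelope tracks e(t)
  e_t <- 1 + 0.3 * sin(2 * pi * 6 * tv)
  am <- sin(2 * pi * 1500 * tv) * e_t
  bk2 <- bandpass_bank(epoch_set(matrix(am, 1), fs), n_windows = 3)
  e_dec <- e_t[(seq_len(m) - 1) * (length(e_t) / m) + 1]  # envelope sample times
  expect_gt(cor(bk2$envelopes[1, 2, inner], e_dec[inner]), 0.99)

  # 201 windows step exactly 5 Hz from 1000 to 2000
  bk3 <- bandpass_bank(epoch_set(matrix(tone[1:fs], 1), fs), n_windows = 201)
  expect_equal(bk3$band_centers[1], 1000)
  expect_equal(bk3$band_centers[201], 2000)
  expect_true(all(abs(diff(bk3$band_centers) - 5) < 1e-12))
  expect_error(bandpass_bank(ep, n_windows = 1), "n_windows")
})

test_that("induced spectra behave as power spectra must", {
  # constant envelopes: demeaning leaves numerical zero power
  bands <- structure(list(
    envelopes = array(2, dim = c(3, 2, 300)),
    band_centers = c(1200, 1500), envelope_sr = 100, epoch_duration = 3,
    epoch_start = 1, trial_info = data.frame(trial = 1:3)),
    class = "band_envelope_set")
  sp <- induced_mod_spectrum(bands)
  expect_lt(max(sp$power), 1e-20)

  # modulated envelope: argmax in 1-11 Hz at f_m; power scales quadratically
  cfg <- generator_config(seed = 9, noise_sd = 0.05, aperiodic_sd = 0.1)
  set.seed(91)
  env <- simulate_envelope_trials(cfg, 40)
  sp1 <- induced_mod_spectrum(env)
  ba <- band_average(sp1)
  sel <- ba$freqs <= 11
  expect_lt(abs(ba$freqs[sel][which.max(ba$power[sel])] - 6), 0.59 + 1e-9)

  env2 <- env
  env2$envelopes <- env$envelopes * 2
  sp2 <- induced_mod_spectrum(env2)
  expect_equal(sp2$power, sp1$power * 4, tolerance = 1e-10)

  expect_error(induced_mod_spectrum(env, window = c(0.25, 3.5)), "window")
})

test_that("evoked spectra isolate phase-locked modulation", {
  cfg_l <- generator_config(phase_mode = "locked", locked_phase = 1,
                            mod_freq = 4, seed = 10, noise_sd = 0.05)
  set.seed(101)
  env_l <- simulate_envelope_trials(cfg_l, 40)
  ev <- evoked_mod_spectrum(env_l)
  ba <- band_average(ev)
  sel <- ba$freqs <= 11
  expect_lt(abs(ba$freqs[sel][which.max(ba$power[sel])] - 4), 0.59 + 1e-9)

  cfg_r <- generator_config(phase_mode = "random", seed = 11, noise_sd = 0.05)
  set.seed(102)
  env_r <- simulate_envelope_trials(cfg_r, 40)
  ind <- induced_mod_spectrum(env_r)
  evr <- evoked_mod_spectrum(env_r)
  k <- which.min(abs(ind$mod_freqs - 6))
  expect_lt(mean(evr$power[, k]), mean(ind$power[, k]) / 4)

  # single trial: evoked and induced are the same transform
  env1 <- simulate_envelope_trials(cfg_r, 1)
  expect_equal(evoked_mod_spectrum(env1)$power,
               induced_mod_spectrum(env1)$power, tolerance = 1e-12)
})

test_that("one-sided spectra conserve tapered signal energy (Parseval)", {
  set.seed(12)
  env <- simulate_envelope_trials(generator_config(seed = 12), 5)
  sp <- induced_mod_spectrum(env)
  # recompute the windowed, demeaned, tapered variance for each trial
  m <- dim(env$envelopes)[3]
  tt <- (seq_len(m) - 1) / env$envelope_sr
  j <- which(tt >= 0.25 & tt < 1.95)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_along(j) - 1) / (length(j) - 1))
  target <- mean(sapply(seq_len(5), function(i) {
    x <- env$envelopes[i, 1, j]
    sum((w * (x - mean(x)))^2) / sum(w^2)
  }))
  got <- sum(colMeans(sp$full_power) * sp$df)
  expect_lt(abs(got / target - 1), 0.01)
})

test_that("spectra are invariant to trial order", {
  set.seed(13)
  cfg <- generator_config(seed = 13)
  s <- simulate_subject(cfg, 1, assemble_recording = FALSE, ears = "left")
  ep <- subset_epochs(s$epochs$left, 1:12)
  bk <- bandpass_bank(ep, n_windows = 5)
  perm <- sample(12)
  bkp <- subset_bands(bk, perm)
  expect_equal(induced_mod_spectrum(bkp)$power,
               induced_mod_spectrum(bk)$power, tolerance = 1e-12)
  expect_equal(evoked_mod_spectrum(bkp)$power,
               evoked_mod_spectrum(bk)$power, tolerance = 1e-12)
})

test_that("the full pipeline recovers planted modulation frequencies", {
  for (fm in c(4, 6, 8)) {
    cfg <- generator_config(mod_freq = fm, subject_peak_jitter_sd = 0,
                            seed = 60 + fm)
    s <- simulate_subject(cfg, 1, assemble_recording = FALSE)
    for (ear in c("left", "right")) {
      a <- analyze_subject(s, fast_study_config(cfg), ears = ear,
                           evoked = FALSE)
      ba <- band_average(a$ears[[ear]]$induced$spectrum_a)
      sel <- ba$freqs <= 11
      fhat <- ba$freqs[sel][which.max(ba$power[sel])]
      expect_lt(abs(fhat - fm), 0.75)
    }
  }
})
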