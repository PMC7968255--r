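# Shared fixtures, memoized so expensive cohorts are built once per run.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small, fast analysis configuration used where band density is irrelevant.
fast_study_config <- function(gen, ...) {
  study_config(gen, n_windows = 21, ...)
}

# Band-averaged induced spectrum of one simulated subject ear.
subject_induced_spectrum <- function(cfg, subject_id = 1, ear = "right",
                                     n_windows = 21) {
  s <- simulate_subject(cfg, subject_id, assemble_recording = FALSE,
                        ears = ear)
  a <- analyze_subject(s, study_config(cfg, n_windows = n_windows),
                       ears = ear, evoked = FALSE, rt_split = FALSE)
  list(subject = s, analysis = a, ear = a$ears[[ear]])
}

# Hilbert + FFT oracle: trial-averaged envelope power spectrum of waveform
# trials (columns), computed independently of the package's bank/PSD path.
envelope_psd_oracle <- function(waves, fs, band = c(1000, 2000)) {
  n <- nrow(waves)
  spec <- stats::mvfft(waves)
  f <- (seq_len(n) - 1) / n * fs
  keep <- f >= band[1] & f <= band[2] & seq_len(n) <= n / 2
  spec[!keep, ] <- 0
  analytic <- stats::mvfft(spec, inverse = TRUE) / n * 2
  env <- Mod(analytic)
  env <- sweep(env, 2, colMeans(env))
  E <- stats::mvfft(env)
  pw <- rowMeans(Mod(E)^2)
  list(freqs = f, power = pw)
}
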