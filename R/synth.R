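# ---- internal FFT helpers -------------------------------------------------

# Squared magnitude response (= zero-phase forward-backward response) of a
# 4th-order Butterworth bandpass at the FFT frequencies of an N-sample epoch.
.carrier_response <- function(fs, n, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  h <- signal::freqz(bf$b, bf$a, region = "whole", n = n, Fs = fs)
  Mod(h$h)^2
}

# Real bandlimited noise trials synthesized directly in the frequency domain:
# complex white Gaussian coefficients shaped by `mag` (response at positive
# FFT bins), returned as an N x n real matrix with unit expected RMS. Pairs
# of trials share one inverse transform (Hermitian spectra packed into the
# real and imaginary parts).
.freq_domain_noise <- function(n_samples, n_trials, mag_pos, bins_pos) {
  nb <- length(bins_pos)
  spec <- matrix(0 + 0i, n_samples, n_trials)
  z <- matrix(complex(real = stats::rnorm(nb * n_trials),
                      imaginary = stats::rnorm(nb * n_trials)), nb, n_trials)
  spec[bins_pos, ] <- z * mag_pos
  spec[n_samples + 2L - bins_pos, ] <- Conj(spec[bins_pos, , drop = FALSE])
  odd <- seq(1L, n_trials, by = 2L)
  even <- if (n_trials >= 2L) seq(2L, n_trials, by = 2L) else integer(0)
  packed <- spec[, odd, drop = FALSE]
  if (length(even)) {
    packed[, seq_along(even)] <- packed[, seq_along(even)] +
      1i * spec[, even, drop = FALSE]
  }
  y <- stats::mvfft(packed, inverse = TRUE) / n_samples
  x <- matrix(0, n_samples, n_trials)
  x[, odd] <- Re(y)
  if (length(even)) x[, even] <- Im(y[, seq_along(even), drop = FALSE])
  # Var(x_j) = 4/N^2 * sum(mag^2) per the CN(0,1) coefficient model
  x / sqrt(4 * sum(mag_pos^2) / n_samples^2)
}

# Columnwise linear upsampling of a coarse matrix to n_out rows (used for
# low-frequency envelope noise, whose content is far below the coarse rate).
.upsample_linear <- function(x, n_out) {
  m <- nrow(x)
  pos <- (seq_len(n_out) - 1) * (m / n_out) + 1
  i0 <- pmin(floor(pos), m)
  fr <- pos - i0
  i1 <- pmin(i0 + 1, m)
  x[i0, , drop = FALSE] * (1 - fr) + x[i1, , drop = FALSE] * fr
}

# ---- single-trial generator -----------------------------------------------

#' Simulate one ear-canal epoch
#'
#' Generates a 3 s broadband carrier (white noise bandpassed to
#' `carrier_band` with a 4th-order zero-phase Butterworth response) whose
#' amplitude envelope is `e(t) = max(0.05, 1 + d * sin(2*pi*f_m*t + phi) +
#' a(t))`, with `a(t)` a 1/f^chi low-frequency fluctuation, plus white
#' measurement noise. This is the phenomenological model of ongoing
#' otoacoustic activity whose theta-band envelope modulation the pipeline is
#' designed to recover.
#'
#' @param config A [generator_config()].
#' @param condition `"auditory"` or `"visual"`; selects the modulation depth.
#' @param seed Optional integer seed for this trial.
#' @param mod_freq Override of the modulation frequency (used to apply
#'   per-subject frequency jitter); defaults to `config$mod_freq`.
#' @param keep_envelope If `TRUE`, the true envelope is attached as attribute
#'   `"envelope"`.
#' @return Numeric waveform of length `epoch_duration * sampling_rate`, with
#'   the modulator phase in attribute `"phase"`.
#' @export
simulate_ear_trial <- function(config, condition = c("auditory", "visual"),
                               seed = NULL, mod_freq = NULL,
                               keep_envelope = FALSE) {
  condition <- match.arg(condition)
  validate_generator_config(config)
  if (!is.null(seed)) set.seed(seed)
  depth <- if (condition == "auditory") config$depth_auditory else config$depth_visual
  block <- .simulate_epoch_block(config, depths = depth, mod_freq = mod_freq,
                                 keep_envelope = keep_envelope)
  w <- block$wave[, 1]
  attr(w, "phase") <- block$phases[1]
  if (keep_envelope) attr(w, "envelope") <- block$env[, 1]
  w
}

# Vectorized epoch generator: one column per trial. `depths` is recycled to
# the number of trials. Consumes RNG in a fixed order (carrier, phases,
# aperiodic, noise) so seeded callers are reproducible.
.simulate_epoch_block <- function(config, depths, n_trials = length(depths),
                                  mod_freq = NULL, keep_envelope = FALSE,
                                  resp = NULL) {
  fs <- config$sampling_rate
  n <- round(config$epoch_duration * fs)
  depths <- rep_len(depths, n_trials)
  fm <- if (is.null(mod_freq)) config$mod_freq else mod_freq
  if (is.null(resp)) resp <- .carrier_response(fs, n, config$carrier_band)
  pos <- 2:floor(n / 2)
  keep <- pos[resp[pos] > 1e-6]
  carrier <- .freq_domain_noise(n, n_trials, resp[keep], keep)

  phases <- if (config$phase_mode == "locked") {
    rep(config$locked_phase, n_trials)
  } else {
    stats::runif(n_trials, 0, 2 * pi)
  }
  tv <- (seq_len(n) - 1) / fs
  # sin(2 pi f t + phi) expanded as two rank-1 terms (cheap per trial)
  st <- sin(2 * pi * fm * tv)
  ct <- cos(2 * pi * fm * tv)
  env <- 1 + outer(st, depths * cos(phases)) + outer(ct, depths * sin(phases))

  if (config$aperiodic_sd > 0) {
    # 1/f^chi fluctuation built on a 200 Hz grid (content stops at 30 Hz)
    # and linearly upsampled to the carrier rate
    m <- round(200 * config$epoch_duration)
    kmax <- floor(30 * config$epoch_duration)
    ka <- seq_len(kmax) + 1L
    fa <- (ka - 1) / config$epoch_duration
    amp <- fa^(-config$aperiodic_exponent / 2)
    a <- .freq_domain_noise(m, n_trials, amp, ka) * config$aperiodic_sd
    env <- env + .upsample_linear(a, n)
  }
  env <- pmax(env, 0.05)
  wave <- carrier * env
  if (config$noise_sd > 0) {
    wave <- wave + config$noise_sd * matrix(stats::rnorm(n * n_trials), n, n_trials)
  }
  out <- list(wave = wave, phases = phases)
  if (keep_envelope) out$env <- env
  out
}

#' Inject a saturation artifact into a waveform
#'
#' Replaces a contiguous run of samples by values clipped exactly at
#' +/- `full_scale` (the sign of each original sample is kept), emulating
#' microphone overload periods that the saturation detector must reject.
#'
#' @param waveform Numeric vector.
#' @param run_length_ms Artifact duration in ms; `0` returns the input
#'   unchanged.
#' @param full_scale Clip level (positive).
#' @param sampling_rate Sampling rate in Hz.
#' @param start First sample of the run (1-based); random if `NULL`.
#' @return The waveform with the clipped run.
#' @export
inject_saturation <- function(waveform, run_length_ms, full_scale,
                              sampling_rate = 10000, start = NULL) {
  run <- round(run_length_ms / 1000 * sampling_rate)
  if (run < 1) return(waveform)
  if (run > length(waveform)) stop("saturation run longer than the epoch")
  if (is.null(start)) {
    start <- sample.int(length(waveform) - run + 1L, 1L)
  }
  idx <- start:(start + run - 1L)
  if (any(idx < 1L | idx > length(waveform))) stop("saturation run out of bounds")
  waveform[idx] <- full_scale * ifelse(waveform[idx] >= 0, 1, -1)
  waveform
}

#' Simulate envelope-process trials directly
#'
#' Returns the generator's envelope process `e(t) = max(0.05, 1 + d *
#' sin(2*pi*f_m*t + phi) + a(t))` sampled at the envelope rate, bypassing the
#' carrier. This exposes the modulation process with exactly known spectral
#' content (sinusoid of depth `d` plus 1/f^chi fluctuation), the reference
#' input for validating the spectral parameterizer's exponent and peak
#' recovery on stochastic spectra.
#'
#' @param config A [generator_config()]; `depth_auditory` is used as the
#'   depth unless `condition = "visual"`.
#' @param n_trials Number of trials.
#' @param envelope_sr Sample rate of the envelope process (Hz).
#' @param condition Which condition's depth to use.
#' @return A `"band_envelope_set"` with a single nominal band, suitable for
#'   [induced_mod_spectrum()] / [evoked_mod_spectrum()].
#' @export
simulate_envelope_trials <- function(config, n_trials = 40,
                                     envelope_sr = 200,
                                     condition = c("auditory", "visual")) {
  condition <- match.arg(condition)
  validate_generator_config(config)
  depth <- if (condition == "auditory") config$depth_auditory else config$depth_visual
  m <- round(config$epoch_duration * envelope_sr)
  tv <- (seq_len(m) - 1) / envelope_sr
  phases <- if (config$phase_mode == "locked") {
    rep(config$locked_phase, n_trials)
  } else {
    stats::runif(n_trials, 0, 2 * pi)
  }
  env <- 1 + depth * sin(outer(2 * pi * config$mod_freq * tv, phases, "+"))
  if (config$aperiodic_sd > 0) {
    kmax <- floor(min(30, envelope_sr / 2 - 1) * config$epoch_duration)
    ka <- seq_len(kmax) + 1L
    fa <- (ka - 1) / config$epoch_duration
    a <- .freq_domain_noise(m, n_trials, fa^(-config$aperiodic_exponent / 2), ka)
    env <- env + a * config$aperiodic_sd
  }
  if (config$noise_sd > 0) {
    env <- env + config$noise_sd * matrix(stats::rnorm(m * n_trials), m, n_trials)
  }
  env <- pmax(env, 0.05)
  arr <- array(0, dim = c(n_trials, 1L, m))
  arr[, 1, ] <- t(env)
  structure(list(envelopes = arr, band_centers = mean(config$carrier_band),
                 envelope_sr = envelope_sr,
                 epoch_duration = config$epoch_duration,
                 epoch_start = 1,
                 trial_info = data.frame(trial = seq_len(n_trials))),
            class = "band_envelope_set")
}

# ---- subject-level generator ----------------------------------------------

#' Simulate one subject
#'
#' Generates the full per-subject dataset: a behavioral trial table with
#' interleaved attention conditions, lognormal reaction times (auditory trials
#' shifted by `rt_shift_ms`), near-ceiling accuracy, and artifact flags; and
#' two-ear waveform data. The subject's individual modulation frequency is
#' jittered around `config$mod_freq`.
#'
#' Trial timing follows the cueing paradigm the pipeline targets: a 1 s cue,
#' then the silent cue-target interval from which the 3 s analysis epoch
#' starts, then a uniformly jittered 1-2 s inter-trial gap.
#'
#' @param config A [generator_config()].
#' @param subject_id Integer subject index (also seeds the subject's RNG
#'   stream together with `config$seed`).
#' @param assemble_recording If `TRUE`, continuous two-ear recordings are
#'   assembled (epochs embedded in measurement noise) so the epoch-extraction
#'   path can be exercised; if `FALSE`, raw epoch sets are returned directly,
#'   which is faster and bypasses only the trivially invertible assembly step.
#' @param ears Ears to generate (both by default).
#' @return A list of class `"synthetic_subject"` with elements
#'   `trial_table`, `subject_id`, `mod_freq`, and either `recordings`
#'   (list `left`/`right` waveforms with sampling metadata) or `epochs`
#'   (list `left`/`right` of [epoch_set] objects).
#' @export
simulate_subject <- function(config, subject_id = 1L,
                             assemble_recording = TRUE,
                             ears = c("left", "right")) {
  validate_generator_config(config)
  set.seed(derive_seed(config$seed, subject_id))
  fs <- config$sampling_rate
  ntr <- 2L * config$n_trials_per_condition
  epoch_n <- round(config$epoch_duration * fs)

  condition <- sample(rep(c("auditory", "visual"), config$n_trials_per_condition))
  iti <- stats::runif(ntr, config$iti_range[1], config$iti_range[2])
  cue_onset <- numeric(ntr)
  cue_onset[1] <- 1
  interval_onset <- numeric(ntr)
  for (i in seq_len(ntr)) {
    interval_onset[i] <- cue_onset[i] + 1
    if (i < ntr) cue_onset[i + 1] <- interval_onset[i] + config$epoch_duration + iti[i]
  }
  rt <- stats::rlnorm(ntr, config$rt_meanlog, config$rt_sdlog) +
    ifelse(condition == "auditory", config$rt_shift_ms, 0)
  accuracy <- stats::rbinom(ntr, 1, config$accuracy_p)
  artifact_flag <- stats::runif(ntr) < config$artifact_rate
  trial_table <- data.frame(
    trial = seq_len(ntr), condition = condition,
    cue_onset = cue_onset, interval_onset = interval_onset,
    reaction_time = rt, accuracy = accuracy, artifact_flag = artifact_flag,
    stringsAsFactors = FALSE
  )

  mod_freq <- config$mod_freq +
    stats::rnorm(1, 0, config$subject_peak_jitter_sd)
  mod_freq <- min(max(mod_freq, 1.5), 10.5)

  depths <- ifelse(condition == "auditory",
                   config$depth_auditory, config$depth_visual)
  resp <- .carrier_response(fs, epoch_n, config$carrier_band)
  ear_names <- ears
  ears <- list()
  for (ear in ear_names) {
    block <- .simulate_epoch_block(config, depths, mod_freq = mod_freq,
                                   resp = resp)
    wave <- block$wave
    for (i in which(artifact_flag)) {
      wave[, i] <- inject_saturation(wave[, i], run_length_ms = 50,
                                     full_scale = config$full_scale,
                                     sampling_rate = fs)
    }
    ears[[ear]] <- list(wave = wave, phases = block$phases)
  }

  subj <- list(trial_table = trial_table, subject_id = subject_id,
               mod_freq = mod_freq, sampling_rate = fs,
               full_scale = config$full_scale,
               epoch_duration = config$epoch_duration)
  if (assemble_recording) {
    total_n <- ceiling((interval_onset[ntr] + config$epoch_duration + 1) * fs)
    recs <- list()
    for (ear in ear_names) {
      rec <- config$noise_sd * stats::rnorm(total_n)
      for (i in seq_len(ntr)) {
        j0 <- round(interval_onset[i] * fs)
        rec[(j0 + 1):(j0 + epoch_n)] <- ears[[ear]]$wave[, i]
      }
      attr(rec, "sampling_rate") <- fs
      attr(rec, "full_scale") <- config$full_scale
      recs[[ear]] <- rec
    }
    subj$recordings <- recs
  } else {
    subj$epochs <- lapply(ears, function(e) {
      epoch_set(data = t(e$wave), sampling_rate = fs,
                epoch_start = 1, trial_info = trial_table,
                full_scale = config$full_scale)
    })
    names(subj$epochs) <- ear_names
  }
  subj$modulator_phases <- lapply(ears, `[[`, "phases")
  class(subj) <- "synthetic_subject"
  subj
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat("<synthetic_subject> id", x$subject_id,
      "|", nrow(x$trial_table), "trials |",
      if (!is.null(x$recordings)) "continuous recordings" else "epoch sets",
      "| f_m =", round(x$mod_freq, 2), "Hz\n")
  invisible(x)
}

# ---- source-space power grids ---------------------------------------------

# Corner sub-blocks of the voxel lattice used to plant effects.
.voxel_blocks <- function(grid_shape) {
  b <- max(1L, round(min(grid_shape) / 3))
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                                  y = seq_len(grid_shape[2]),
                                  z = seq_len(grid_shape[3])))
  posterior <- which(coords[, 1] <= b & coords[, 2] <= b & coords[, 3] <= b)
  temporal <- which(coords[, 1] > grid_shape[1] - b &
                    coords[, 2] > grid_shape[2] - b &
                    coords[, 3] > grid_shape[3] - b)
  list(coords = coords, posterior = posterior, temporal = temporal)
}

#' Simulate a source-space power grid
#'
#' Generates per-subject voxel x frequency (1-30 Hz, 1 Hz steps) x condition
#' oscillatory power on a cubic lattice with 1 cm spacing. Power is lognormal
#' around a 1/f frequency profile. Two effects are planted: a multiplicative
#' condition effect (auditory > visual) at 8-25 Hz in a "posterior" voxel
#' block, and a per-subject condition modulation in a "temporal" voxel block
#' scaled so that the across-subject correlation between that block's AMI and
#' `per_subject_ooa_ami` approaches `config$planted_correlation`.
#'
#' @param config A [generator_config()].
#' @param per_subject_ooa_ami Numeric vector (one cochlear AMI per subject)
#'   that the temporal-block effect is correlated with.
#' @param seed Optional seed (defaults to a stream derived from
#'   `config$seed`).
#' @return A list of class `"brain_power_grid"`: `power` (subjects x voxels x
#'   30 frequencies x 2 conditions), `voxel_positions` (cm), `freqs`,
#'   `conditions`, `grid_shape`, and the planted `blocks`.
#' @export
simulate_brain_power <- function(config, per_subject_ooa_ami, seed = NULL) {
  validate_generator_config(config)
  n_sub <- length(per_subject_ooa_ami)
  if (n_sub < 2) stop("need at least two subjects")
  set.seed(if (is.null(seed)) derive_seed(config$seed, 9001L) else seed)
  rho <- config$planted_correlation
  blocks <- .voxel_blocks(config$grid_shape)
  n_vox <- nrow(blocks$coords)
  freqs <- 1:30
  n_f <- length(freqs)

  base <- -log(freqs)  # 1/f profile in log power
  logp <- array(stats::rnorm(n_sub * n_vox * n_f * 2, sd = config$brain_noise_sd),
                dim = c(n_sub, n_vox, n_f, 2))
  subj_off <- stats::rnorm(n_sub, sd = 0.2)
  logp <- logp + rep(subj_off, times = n_vox * n_f * 2)
  logp <- sweep(logp, 3, base, "+")

  # posterior block: fixed auditory > visual effect at 8-25 Hz
  f_eff <- which(freqs >= 8 & freqs <= 25)
  if (config$planted_brain_effect != 0) {
    logp[, blocks$posterior, f_eff, 1] <-
      logp[, blocks$posterior, f_eff, 1] + log1p(config$planted_brain_effect)
  }

  # temporal block: per-subject effect correlated with the cochlear AMI
  if (config$brain_effect_scale != 0) {
    if (stats::sd(per_subject_ooa_ami) == 0 && rho != 0) {
      stop("zero-variance OOA AMI vector: planted correlation undefined")
    }
    z <- if (stats::sd(per_subject_ooa_ami) > 0) {
      as.numeric(scale(per_subject_ooa_ami))
    } else {
      rep(0, n_sub)
    }
    g <- config$brain_effect_scale *
      (rho * z + sqrt(1 - rho^2) * stats::rnorm(n_sub))
    logp[, blocks$temporal, , 1] <- logp[, blocks$temporal, , 1] +
      rep(g, times = length(blocks$temporal) * n_f)
  }

  out <- list(power = exp(logp),
              voxel_positions = blocks$coords,
              freqs = freqs,
              conditions = c("auditory", "visual"),
              grid_shape = config$grid_shape,
              blocks = blocks[c("posterior", "temporal")])
  class(out) <- "brain_power_grid"
  out
}

# ---- circular sampler (used for phase statistics) --------------------------

# von Mises sampler, Best & Fisher (1979) rejection scheme.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}
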