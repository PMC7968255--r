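#' Generator configuration for synthetic OOA cohorts
#'
#' Collects every parameter of the synthetic-data module: ear-canal recording
#' synthesis, behavioral tables, and source-space power grids. The seed fully
#' determines all generated outputs.
#'
#' @param sampling_rate Microphone sampling rate in Hz.
#' @param epoch_duration Epoch length in seconds.
#' @param n_trials_per_condition Trials per attention condition (per subject).
#' @param carrier_band Two-element numeric, carrier passband in Hz.
#' @param mod_freq Envelope modulation frequency f_m in Hz (the cochlear
#'   rhythm the generator plants; ~6 Hz theta by default).
#' @param depth_auditory,depth_visual Modulation depth in [0, 1) for the
#'   Attend Auditory / Attend Visual condition.
#' @param phase_mode `"random"` (per-trial uniform modulator phase; induced
#'   rhythm) or `"locked"` (fixed phase; evoked rhythm).
#' @param locked_phase Modulator phase in radians used when
#'   `phase_mode = "locked"`.
#' @param aperiodic_exponent Exponent chi of the 1/f^chi envelope background.
#' @param aperiodic_sd Standard deviation of the aperiodic envelope
#'   fluctuation a(t) (relative to the unit envelope mean).
#' @param noise_sd Measurement white-noise SD relative to unit carrier RMS.
#' @param artifact_rate Probability that a trial carries an injected
#'   saturation artifact.
#' @param full_scale Recording full-scale value (arbitrary units); saturation
#'   artifacts clip exactly at +/- this value.
#' @param n_subjects Number of subjects in a simulated cohort.
#' @param subject_peak_jitter_sd Across-subject SD (Hz) of the individual
#'   modulation frequency around `mod_freq`.
#' @param grid_shape Integer vector of 3 lattice dimensions for the
#'   source-power grid (1 cm spacing).
#' @param planted_brain_effect Multiplicative condition effect (auditory >
#'   visual) planted in the posterior voxel block at 8-25 Hz.
#' @param planted_correlation Target across-subject correlation rho in
#'   (-1, 1) between the temporal-block brain AMI and the cochlear AMI.
#' @param brain_effect_scale Scale of the per-subject temporal-block
#'   modulation used to plant the correlation.
#' @param brain_noise_sd SD of the per-cell log-power noise in the grid.
#' @param rt_meanlog,rt_sdlog Lognormal reaction-time parameters (RT in ms).
#' @param rt_shift_ms Additive RT shift (ms) for the auditory condition.
#' @param accuracy_p Bernoulli probability of a correct response.
#' @param iti_range Inter-trial interval jitter range in seconds.
#' @param seed Integer seed; identical config + seed gives identical cohorts.
#'
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(sampling_rate = 10000,
                             epoch_duration = 3,
                             n_trials_per_condition = 40,
                             carrier_band = c(1000, 2000),
                             mod_freq = 6,
                             depth_auditory = 0.25,
                             depth_visual = 0.15,
                             phase_mode = c("random", "locked"),
                             locked_phase = pi / 2,
                             aperiodic_exponent = 0.4,
                             aperiodic_sd = 0.35,
                             noise_sd = 0.1,
                             artifact_rate = 0.05,
                             full_scale = 8,
                             n_subjects = 12,
                             subject_peak_jitter_sd = 0.5,
                             grid_shape = c(8, 8, 8),
                             planted_brain_effect = 0.3,
                             planted_correlation = -0.8,
                             brain_effect_scale = 0.2,
                             brain_noise_sd = 0.05,
                             rt_meanlog = log(450),
                             rt_sdlog = 0.25,
                             rt_shift_ms = 60,
                             accuracy_p = 0.93,
                             iti_range = c(1, 2),
                             seed = 1L) {
  phase_mode <- match.arg(phase_mode)
  cfg <- list(
    sampling_rate = sampling_rate, epoch_duration = epoch_duration,
    n_trials_per_condition = as.integer(n_trials_per_condition),
    carrier_band = carrier_band, mod_freq = mod_freq,
    depth_auditory = depth_auditory, depth_visual = depth_visual,
    phase_mode = phase_mode, locked_phase = locked_phase,
    aperiodic_exponent = aperiodic_exponent, aperiodic_sd = aperiodic_sd,
    noise_sd = noise_sd, artifact_rate = artifact_rate,
    full_scale = full_scale, n_subjects = as.integer(n_subjects),
    subject_peak_jitter_sd = subject_peak_jitter_sd,
    grid_shape = as.integer(grid_shape),
    planted_brain_effect = planted_brain_effect,
    planted_correlation = planted_correlation,
    brain_effect_scale = brain_effect_scale,
    brain_noise_sd = brain_noise_sd,
    rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
    rt_shift_ms = rt_shift_ms, accuracy_p = accuracy_p,
    iti_range = iti_range, seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the invariants the generator relies on: modulation depths below 1
#' (so the envelope stays positive before clipping), the Nyquist condition for
#' the carrier band, and basic range constraints.
#'
#' @param cfg A `generator_config`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$depth_auditory < 0 || cfg$depth_auditory >= 1 ||
      cfg$depth_visual < 0 || cfg$depth_visual >= 1) {
    stop("invalid config: modulation depths must lie in [0, 1)")
  }
  if (cfg$sampling_rate <= 2 * max(cfg$carrier_band)) {
    stop("invalid config: sampling_rate must exceed twice the carrier band upper edge")
  }
  if (length(cfg$carrier_band) != 2 || diff(cfg$carrier_band) <= 0) {
    stop("invalid config: carrier_band must be an increasing [low, high] pair")
  }
  if (abs(cfg$planted_correlation) >= 1) {
    stop("invalid config: |planted_correlation| must be < 1")
  }
  if (cfg$epoch_duration <= 0 || cfg$n_trials_per_condition < 1 ||
      cfg$n_subjects < 1) {
    stop("invalid config: sizes must be positive")
  }
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1) {
    stop("invalid config: artifact_rate must lie in [0, 1]")
  }
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 1)) {
    stop("invalid config: grid_shape must be 3 positive lattice dimensions")
  }
  invisible(cfg)
}

#' Full study configuration
#'
#' Bundles the generator section with the parameters of every analysis stage
#' so that a complete run is reproducible from one object. All defaults follow
#' the analysis conventions of the pipeline: a [0.25, 1.95] s analysis window
#' within the 3 s epoch (1.7 s of the cue-target interval), 201 bandpass
#' windows between 1000 and 2000 Hz, spectral fits over 1-30 Hz, AMI pooling
#' over 3-10 Hz (left ear) and 1-10 Hz (right ear), and cluster permutation
#' over 3-25 Hz.
#'
#' @param generator A `generator_config` (or arguments passed to
#'   [generator_config()] as a list).
#' @param window Analysis sub-window in seconds, relative to epoch start.
#' @param n_windows Number of bandpass windows spanning the carrier band.
#' @param half_width Bandpass half-width in Hz.
#' @param envelope_sr Envelope sample rate in Hz after demodulation.
#' @param pad_freq_step Modulation-frequency grid step after zero padding (Hz).
#' @param mod_range Modulation-frequency range retained, in Hz.
#' @param clip_fraction,min_run_ms Saturation-detector parameters.
#' @param fit_range Frequency range for spectral parameterization (Hz).
#' @param max_peaks,peak_threshold,min_peak_height Peak-search parameters.
#' @param peak_limit Upper frequency bound (Hz) for the primary low-frequency
#'   peak.
#' @param pool_left,pool_right AMI pooling ranges (Hz) per ear.
#' @param fdr_q FDR level.
#' @param cluster_freq_range Frequency range for cluster permutation (Hz).
#' @param n_perm Number of permutations.
#' @param forming_alpha Cluster-forming alpha (two-sided, parametric).
#' @param seed Study-level seed used for all stochastic stages.
#'
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(generator = generator_config(),
                         window = c(0.25, 1.95),
                         n_windows = 201,
                         half_width = 30,
                         envelope_sr = 100,
                         pad_freq_step = 0.25,
                         mod_range = c(1, 30),
                         clip_fraction = 0.999,
                         min_run_ms = 2,
                         fit_range = c(1, 30),
                         max_peaks = 6,
                         peak_threshold = 2,
                         min_peak_height = 0.05,
                         peak_limit = 11,
                         pool_left = c(3, 10),
                         pool_right = c(1, 10),
                         fdr_q = 0.05,
                         cluster_freq_range = c(3, 25),
                         n_perm = 1000,
                         forming_alpha = 0.05,
                         seed = NULL) {
  if (!inherits(generator, "generator_config")) {
    generator <- do.call(generator_config, as.list(generator))
  }
  if (is.null(seed)) seed <- generator$seed
  cfg <- list(
    generator = generator, window = window, n_windows = as.integer(n_windows),
    half_width = half_width, envelope_sr = envelope_sr,
    pad_freq_step = pad_freq_step, mod_range = mod_range,
    clip_fraction = clip_fraction, min_run_ms = min_run_ms,
    fit_range = fit_range, max_peaks = as.integer(max_peaks),
    peak_threshold = peak_threshold, min_peak_height = min_peak_height,
    peak_limit = peak_limit, pool_left = pool_left, pool_right = pool_right,
    fdr_q = fdr_q, cluster_freq_range = cluster_freq_range,
    n_perm = as.integer(n_perm), forming_alpha = forming_alpha,
    seed = as.integer(seed)
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

#' @rdname study_config
#' @param cfg A `study_config` to validate.
#' @export
validate_study_config <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  validate_generator_config(cfg$generator)
  bad <- character(0)
  if (!(length(cfg$window) == 2 && cfg$window[1] >= 0 &&
        cfg$window[2] > cfg$window[1] &&
        cfg$window[2] <= cfg$generator$epoch_duration)) bad <- c(bad, "window")
  if (cfg$n_windows < 2) bad <- c(bad, "n_windows")
  nyq <- cfg$generator$sampling_rate / 2
  if (max(cfg$generator$carrier_band) > nyq - cfg$half_width) {
    bad <- c(bad, "half_width")
  }
  if (cfg$envelope_sr < 2 * max(cfg$mod_range)) bad <- c(bad, "envelope_sr")
  if (cfg$fdr_q <= 0 || cfg$fdr_q >= 1) bad <- c(bad, "fdr_q")
  if (cfg$n_perm < 1) bad <- c(bad, "n_perm")
  if (length(bad)) {
    stop("invalid study config, offending keys: ", paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

#' Serialize / read configurations as YAML
#'
#' Round-trip safe: `read_study_config(write_study_config(cfg, f))` restores
#' an identical configuration.
#'
#' @param cfg A `study_config`.
#' @param path File path.
#' @return `write_study_config` returns `path` invisibly;
#'   `read_study_config` returns a `study_config`.
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  x <- unclass(cfg)
  x$generator <- unclass(x$generator)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  gen <- do.call(generator_config, x$generator)
  x$generator <- NULL
  do.call(study_config, c(list(generator = gen), x))
}

# Derive a deterministic per-stream seed below 2^31 from a base seed.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647
}
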