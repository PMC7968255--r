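# ---- epoch container ------------------------------------------------------

#' Epoch container
#'
#' Holds a trials x samples waveform block together with sampling metadata,
#' per-trial information, and a log of rejected trials.
#'
#' @param data Numeric matrix, trials in rows.
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_start Epoch start in seconds relative to cue onset.
#' @param trial_info Data frame with one row per retained trial (must include
#'   a `condition` column for condition-wise analyses).
#' @param rejected Data frame of rejected trials (`trial`, `reason`).
#' @param full_scale Full-scale value of the recording chain, if known.
#' @return A list of class `"epoch_set"`.
#' @export
epoch_set <- function(data, sampling_rate, epoch_start = 0,
                      trial_info = NULL, rejected = NULL, full_scale = NA) {
  data <- as.matrix(data)
  if (is.null(trial_info)) {
    trial_info <- data.frame(trial = seq_len(nrow(data)))
  }
  stopifnot(nrow(trial_info) == nrow(data))
  if (is.null(rejected)) {
    rejected <- data.frame(trial = integer(0), reason = character(0),
                           stringsAsFactors = FALSE)
  }
  structure(list(data = data, sampling_rate = sampling_rate,
                 epoch_start = epoch_start, trial_info = trial_info,
                 rejected = rejected, full_scale = full_scale),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", nrow(x$data), "trials x", ncol(x$data), "samples @",
      x$sampling_rate, "Hz |", nrow(x$rejected), "rejected\n")
  invisible(x)
}

#' Subset an epoch set by trial index
#' @param ep An [epoch_set].
#' @param idx Trial indices (into the retained trials) to keep.
#' @return An [epoch_set] with the selected trials.
#' @export
subset_epochs <- function(ep, idx) {
  stopifnot(inherits(ep, "epoch_set"))
  ep$data <- ep$data[idx, , drop = FALSE]
  ep$trial_info <- ep$trial_info[idx, , drop = FALSE]
  ep
}

# ---- filtering ------------------------------------------------------------

#' High-pass filter for otoacoustic recordings
#'
#' 6th-order Butterworth high-pass applied forward-backward (zero phase), the
#' standard first step that removes body noise and ear-canal pressure drift
#' below the otoacoustic band. Works on a numeric vector or on every trial of
#' an [epoch_set].
#'
#' @param x Numeric vector or [epoch_set].
#' @param sampling_rate Sampling rate in Hz (taken from the epoch set or the
#'   `sampling_rate` attribute when present).
#' @param cutoff Cutoff frequency in Hz.
#' @param order Filter order (single pass; the effective zero-phase response
#'   is the squared magnitude).
#' @return Filtered object of the same shape.
#' @export
highpass_oae <- function(x, sampling_rate = NULL, cutoff = 500, order = 6) {
  if (inherits(x, "epoch_set")) {
    fs <- x$sampling_rate
    flt <- .highpass_filter(fs, cutoff, order)
    x$data <- t(apply(x$data, 1, function(row) signal::filtfilt(flt, row)))
    return(x)
  }
  if (is.null(sampling_rate)) sampling_rate <- attr(x, "sampling_rate")
  if (is.null(sampling_rate)) stop("sampling_rate required")
  flt <- .highpass_filter(sampling_rate, cutoff, order)
  y <- signal::filtfilt(flt, as.numeric(x))
  attributes(y) <- attributes(x)
  y
}

.highpass_filter <- function(fs, cutoff, order) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  signal::butter(order, cutoff / (fs / 2), type = "high")
}

# Squared magnitude (zero-phase forward-backward) response of a digital IIR
# filter at frequencies `f` (Hz).
.iir_mag2 <- function(flt, f, fs) {
  ew <- exp(-2i * pi * f / fs)
  num <- outer(ew, seq_along(flt$b) - 1, "^") %*% flt$b
  den <- outer(ew, seq_along(flt$a) - 1, "^") %*% flt$a
  Mod(num / den)^2
}

# ---- epoch extraction and artifact rejection ------------------------------

#' Extract analysis epochs from a continuous recording
#'
#' Cuts one fixed-duration epoch per trial, starting at the cue-target
#' interval onset. Trials whose epoch would run past the end of the recording
#' (or start before its beginning) are dropped individually and logged with a
#' reason code; the remaining trials are unaffected.
#'
#' @param recording Numeric vector with a `sampling_rate` attribute (or pass
#'   `sampling_rate`).
#' @param trial_table Data frame with at least `interval_onset` (s); other
#'   columns are carried into `trial_info`.
#' @param duration Epoch duration in seconds.
#' @param sampling_rate Sampling rate in Hz if not attached to `recording`.
#' @return An [epoch_set]; empty (0 trials) for an empty table.
#' @export
extract_epochs <- function(recording, trial_table, duration = 3,
                           sampling_rate = NULL) {
  fs <- if (!is.null(sampling_rate)) sampling_rate else attr(recording, "sampling_rate")
  if (is.null(fs)) stop("sampling_rate required")
  n_ep <- round(duration * fs)
  n_rec <- length(recording)
  keep <- logical(nrow(trial_table))
  data <- matrix(0, 0, n_ep)
  rows <- list()
  for (i in seq_len(nrow(trial_table))) {
    j0 <- round(trial_table$interval_onset[i] * fs)
    ok <- j0 >= 0 && (j0 + n_ep) <= n_rec
    keep[i] <- ok
    if (ok) rows[[length(rows) + 1L]] <- recording[(j0 + 1):(j0 + n_ep)]
  }
  if (length(rows)) data <- do.call(rbind, rows)
  rejected <- data.frame(trial = which(!keep),
                         reason = rep("onset_out_of_bounds", sum(!keep)),
                         stringsAsFactors = FALSE)
  epoch_set(data = data, sampling_rate = fs,
            epoch_start = 1,  # interval onset follows the 1 s cue
            trial_info = trial_table[keep, , drop = FALSE],
            rejected = rejected,
            full_scale = attr(recording, "full_scale") %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reject trials containing signal saturation
#'
#' Automated replacement for manual saturation screening: a trial is rejected
#' when it contains a run of at least `min_run_ms` consecutive samples with
#' `|x| >= clip_fraction * full_scale`. Runs touching the epoch edges count.
#'
#' @param ep An [epoch_set].
#' @param clip_fraction Fraction of full scale treated as clipped.
#' @param min_run_ms Minimum run duration in ms.
#' @param full_scale Full-scale value; defaults to the epoch set's metadata,
#'   falling back to the maximum absolute sample.
#' @return The [epoch_set] with saturated trials moved to `rejected`.
#' @export
reject_saturation <- function(ep, clip_fraction = 0.999, min_run_ms = 2,
                              full_scale = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  if (nrow(ep$data) == 0) return(ep)
  fsv <- full_scale %||% ep$full_scale
  if (is.null(fsv) || is.na(fsv)) fsv <- max(abs(ep$data))
  min_run <- max(1L, round(min_run_ms / 1000 * ep$sampling_rate))
  thr <- clip_fraction * fsv
  bad <- vapply(seq_len(nrow(ep$data)), function(i) {
    r <- rle(abs(ep$data[i, ]) >= thr)
    any(r$lengths[r$values] >= min_run)
  }, logical(1))
  if (any(bad)) {
    rej <- data.frame(trial = ep$trial_info$trial[bad] %||% which(bad),
                      reason = rep("saturation", sum(bad)),
                      stringsAsFactors = FALSE)
    ep$rejected <- rbind(ep$rejected, rej)
    ep <- subset_epochs(ep, which(!bad))
  }
  ep
}

# ---- bandpass bank + Hilbert envelopes ------------------------------------

#' Bandpass filter bank with Hilbert envelopes
#'
#' Decomposes each epoch into `n_windows` overlapping carrier bands spanning
#' `low`-`high` Hz (each band center +/- `half_width`), and extracts the
#' amplitude envelope of every band via the analytic signal. The band
#' filtering and Hilbert transform are computed jointly in the frequency
#' domain on the full epoch (zero-phase by construction), and the envelope is
#' returned at the reduced rate `envelope_sr` by complex demodulation, which
#' leaves the analytic-signal magnitude unchanged.
#'
#' @param ep An [epoch_set] (high-pass filtered recording epochs).
#' @param low,high Band-center range in Hz.
#' @param half_width Band half-width in Hz.
#' @param n_windows Number of band centers (equally spaced, so 201 windows
#'   over 1000-2000 Hz step by 5 Hz).
#' @param envelope_sr Envelope sampling rate in Hz.
#' @param highpass Optional list `(cutoff, order)`: the zero-phase
#'   (magnitude-squared) Butterworth high-pass response is applied to the
#'   band slices. Because the bank is linear and diagonal in frequency this
#'   is identical to high-pass filtering the epochs first, at no extra cost.
#' @return A list of class `"band_envelope_set"`: `envelopes` (trials x bands
#'   x envelope samples, nonnegative), `band_centers`, `envelope_sr`,
#'   `epoch_duration`, `trial_info`.
#' @export
bandpass_bank <- function(ep, low = 1000, high = 2000, half_width = 30,
                          n_windows = 201, envelope_sr = 100,
                          highpass = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  if (n_windows < 2) stop("n_windows must be at least 2")
  fs <- ep$sampling_rate
  if (high > fs / 2 - half_width) stop("band edge too close to Nyquist")
  n <- ncol(ep$data)
  n_tr <- nrow(ep$data)
  if (n_tr == 0) stop("no trials to filter")
  dur <- n / fs
  m <- round(dur * envelope_sr)
  centers <- seq(low, high, length.out = n_windows)
  x <- t(ep$data)                      # samples x trials
  X <- stats::mvfft(x)
  f_bin <- (seq_len(n) - 1) / dur      # Hz at FFT bins (positive half used)
  half <- floor(n / 2)
  hp_mag2 <- NULL
  if (!is.null(highpass)) {
    flt <- .highpass_filter(fs, highpass$cutoff %||% 500,
                            highpass$order %||% 6)
    hp_mag2 <- .iir_mag2(flt, f_bin, fs)
  }
  env <- array(0, dim = c(n_tr, n_windows, m))
  for (b in seq_len(n_windows)) {
    k <- which(f_bin >= centers[b] - half_width &
               f_bin <= centers[b] + half_width)
    k <- k[k <= half + 1L & k >= 2L]
    slice <- matrix(0 + 0i, m, n_tr)
    slice[seq_along(k), ] <- X[k, , drop = FALSE]
    if (!is.null(hp_mag2)) {
      slice[seq_along(k), ] <- slice[seq_along(k), , drop = FALSE] * hp_mag2[k]
    }
    z <- stats::mvfft(slice, inverse = TRUE)   # complex demodulated analytic
    env[, b, ] <- t(Mod(z)) * (2 / n)
  }
  structure(list(envelopes = env, band_centers = centers,
                 envelope_sr = envelope_sr, epoch_duration = dur,
                 epoch_start = ep$epoch_start,
                 trial_info = ep$trial_info),
            class = "band_envelope_set")
}

#' Subset a band-envelope set by trial index
#'
#' Selecting trials after the filter bank lets one bank decomposition serve
#' several trial groupings (conditions, reaction-time splits) without
#' refiltering.
#'
#' @param bands A [bandpass_bank()] result.
#' @param idx Trial indices to keep.
#' @return A `"band_envelope_set"` with the selected trials.
#' @export
subset_bands <- function(bands, idx) {
  stopifnot(inherits(bands, "band_envelope_set"))
  bands$envelopes <- bands$envelopes[idx, , , drop = FALSE]
  bands$trial_info <- bands$trial_info[idx, , drop = FALSE]
  bands
}

#' @export
print.band_envelope_set <- function(x, ...) {
  d <- dim(x$envelopes)
  cat("<band_envelope_set>", d[1], "trials x", d[2], "bands x", d[3],
      "samples @", x$envelope_sr, "Hz\n")
  invisible(x)
}

# ---- modulation spectra ---------------------------------------------------

# One-sided Hann-tapered power spectra of envelope segments.
# seg: samples x series matrix (already windowed in time). Returns list with
# freqs, power (freq x series), complex coefficients, and the scale used.
.hann_psd <- function(seg, fs, pad_step) {
  n <- nrow(seg)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  seg <- sweep(seg, 2, colMeans(seg))
  seg <- seg * w
  nfft <- round(fs / pad_step)
  if (nfft < n) nfft <- n
  pad <- rbind(seg, matrix(0, nfft - n, ncol(seg)))
  Y <- stats::mvfft(pad)
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  half <- 1:(floor(nfft / 2) + 1)
  # one-sided PSD normalized so that sum(psd * df) over the one-sided
  # spectrum equals the taper-weighted signal variance (Parseval)
  scale <- 2 / (fs * sum(w^2))
  list(freqs = freqs[half],
       power = Mod(Y[half, , drop = FALSE])^2 * scale,
       coef = Y[half, , drop = FALSE],
       df = fs / nfft)
}

.window_index <- function(m, fs, window) {
  tt <- (seq_len(m) - 1) / fs
  which(tt >= window[1] & tt < window[2])
}

#' Induced envelope modulation spectrum
#'
#' Computes the trial-wise power spectral density of the band envelopes
#' within the analysis window (demeaned, Hann-tapered, zero-padded to a
#' regular frequency grid) and averages power across trials. Averaging power
#' rather than signals retains rhythms that are not phase-locked to the cue
#' ("induced" power).
#'
#' @param bands A [bandpass_bank()] result.
#' @param window Analysis window in seconds relative to epoch start.
#' @param mod_range Modulation-frequency range retained (Hz).
#' @param pad_step Frequency-grid step after zero padding (Hz).
#' @return A list of class `"modulation_spectrum"` with `mode = "induced"`,
#'   `power` (bands x modulation frequencies), `band_centers`, `mod_freqs`,
#'   `n_trials_used`, and the full one-sided spectrum in `full_power` /
#'   `full_freqs` for energy bookkeeping.
#' @export
induced_mod_spectrum <- function(bands, window = c(0.25, 1.95),
                                 mod_range = c(1, 30), pad_step = 0.25) {
  .mod_spectrum(bands, window, mod_range, pad_step, mode = "induced")
}

#' Evoked envelope modulation spectrum
#'
#' Averages the band envelopes across trials first and transforms the
#' average; only phase-locked ("evoked") modulation survives the averaging.
#' Complex Fourier coefficients are retained so the evoked phase is defined.
#'
#' @inheritParams induced_mod_spectrum
#' @return A `"modulation_spectrum"` with `mode = "evoked"` and
#'   `evoked_coef` (complex, bands x modulation frequencies).
#' @export
evoked_mod_spectrum <- function(bands, window = c(0.25, 1.95),
                                mod_range = c(1, 30), pad_step = 0.25) {
  .mod_spectrum(bands, window, mod_range, pad_step, mode = "evoked")
}

.mod_spectrum <- function(bands, window, mod_range, pad_step, mode) {
  stopifnot(inherits(bands, "band_envelope_set"))
  d <- dim(bands$envelopes)
  if (d[1] == 0) stop("no retained trials")
  if (window[1] < 0 || window[2] > bands$epoch_duration) {
    stop("analysis window outside the epoch")
  }
  fs <- bands$envelope_sr
  j <- .window_index(d[3], fs, window)
  n_b <- d[2]
  power <- NULL
  coef <- NULL
  for (b in seq_len(n_b)) {
    seg <- t(bands$envelopes[, b, j, drop = FALSE][, 1, ])  # samples x trials
    if (d[1] == 1) seg <- matrix(bands$envelopes[1, b, j], ncol = 1)
    if (mode == "evoked") seg <- matrix(rowMeans(seg), ncol = 1)
    ps <- .hann_psd(seg, fs, pad_step)
    if (is.null(power)) {
      power <- matrix(0, n_b, length(ps$freqs))
      coef <- matrix(0 + 0i, n_b, length(ps$freqs))
    }
    power[b, ] <- rowMeans(ps$power)
    if (mode == "evoked") coef[b, ] <- ps$coef[, 1]
  }
  freqs <- ps$freqs
  sel <- freqs >= mod_range[1] & freqs <= mod_range[2]
  out <- list(mode = mode, band_centers = bands$band_centers,
              mod_freqs = freqs[sel], power = power[, sel, drop = FALSE],
              full_freqs = freqs, full_power = power,
              df = ps$df, n_trials_used = d[1],
              window = window, epoch_start = bands$epoch_start,
              envelope_sr = fs, n_window_samples = length(j))
  if (mode == "evoked") out$evoked_coef <- coef[, sel, drop = FALSE]
  class(out) <- "modulation_spectrum"
  out
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  cat("<modulation_spectrum>", x$mode, "|", length(x$band_centers),
      "bands x", length(x$mod_freqs), "modulation freqs (",
      min(x$mod_freqs), "-", max(x$mod_freqs), "Hz ) |",
      x$n_trials_used, "trials\n")
  invisible(x)
}

#' Band-averaged modulation spectrum
#'
#' Collapses a modulation spectrum across carrier bands (mean power per
#' modulation frequency), the representation used for spectral
#' parameterization.
#'
#' @param spec A `"modulation_spectrum"`.
#' @return List with `freqs` and `power` vectors.
#' @export
band_average <- function(spec) {
  stopifnot(inherits(spec, "modulation_spectrum"))
  list(freqs = spec$mod_freqs, power = colMeans(spec$power))
}
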