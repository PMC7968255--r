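# ---- periodic / aperiodic spectral parameterization -----------------------

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Fits the model
#' `log10 P(f) = b - chi * log10(f) + sum_k A_k * exp(-(f - CF_k)^2 / (2 sigma_k^2))`
#' to a modulation-power spectrum: a 1/f-like aperiodic component (offset `b`,
#' exponent `chi`; fixed mode, no knee) plus up to `max_peaks` Gaussian peaks.
#' The procedure mirrors the now-standard iterative scheme: (1) robust
#' log-log line fit that down-weights points sticking up above the trend,
#' (2) iterative residual-maximum peak seeding, (3) joint least-squares refit
#' of all Gaussians on the flattened spectrum, (4) aperiodic refit on the
#' peak-removed spectrum.
#'
#' @param power Positive power values.
#' @param freqs Frequency axis (Hz), same length.
#' @param freq_range Fit range in Hz.
#' @param max_peaks Maximum number of Gaussian peaks.
#' @param peak_threshold Peak seeding threshold in SDs of the flattened
#'   spectrum.
#' @param min_peak_height Minimum peak height in log10-power units.
#' @param sigma_limits Allowed Gaussian SD range in Hz (guards against
#'   spike/plateau fits).
#' @return A list of class `"spectral_fit"`: `offset`, `exponent`, `peaks`
#'   (data frame `cf`, `amp`, `bw` = 2 * sigma, sorted by `cf`), `fit_error`
#'   (RMS in log10 space), `freq_range`, `freqs`, `log_power`, `model`.
#' @export
fit_spectral_model <- function(power, freqs, freq_range = c(1, 30),
                               max_peaks = 6, peak_threshold = 2,
                               min_peak_height = 0.05,
                               sigma_limits = c(0.25, 6)) {
  sel <- freqs >= freq_range[1] & freqs <= freq_range[2]
  f <- freqs[sel]
  p <- power[sel]
  if (length(f) < 10) stop("need at least 10 frequency bins in range")
  if (any(!is.finite(p)) || any(p <= 0)) stop("power must be positive and finite")
  lp <- log10(p)
  lf <- log10(f)

  ap <- .robust_aperiodic_fit(lf, lp)
  flat <- lp - (ap[1] + ap[2] * lf)

  guesses <- list()
  resid <- flat
  for (k in seq_len(max_peaks)) {
    i <- which.max(resid)
    h <- resid[i]
    thr <- max(peak_threshold * stats::sd(resid), min_peak_height)
    if (h <= thr) break
    half <- h / 2
    li <- i
    while (li > 1 && resid[li] > half) li <- li - 1
    ri <- i
    while (ri < length(f) && resid[ri] > half) ri <- ri + 1
    fwhm <- f[ri] - f[li]
    sg <- min(max(fwhm / 2.355, sigma_limits[1]), sigma_limits[2])
    guesses[[k]] <- c(cf = f[i], amp = h, sigma = sg)
    resid <- resid - h * exp(-(f - f[i])^2 / (2 * sg^2))
  }

  peaks <- data.frame(cf = numeric(0), amp = numeric(0), bw = numeric(0))
  if (length(guesses)) {
    th0 <- unlist(guesses)
    npk <- length(guesses)
    lower <- rep(c(freq_range[1], 0, sigma_limits[1]), npk)
    upper <- rep(c(freq_range[2], Inf, sigma_limits[2]), npk)
    obj <- function(th) {
      m <- .gaussian_sum(f, th)
      sum((flat - m)^2)
    }
    opt <- stats::optim(th0, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
    th <- matrix(opt$par, nrow = 3)
    peaks <- data.frame(cf = th[1, ], amp = th[2, ], bw = 2 * th[3, ])
    peaks <- peaks[peaks$amp > min_peak_height / 2, , drop = FALSE]
    peaks <- peaks[order(peaks$cf), , drop = FALSE]
    rownames(peaks) <- NULL
  }

  peak_model <- .gaussian_sum(f, rbind(peaks$cf, peaks$amp, peaks$bw / 2))
  ap_final <- .robust_aperiodic_fit(lf, lp - peak_model, robust = FALSE)
  model <- ap_final[1] + ap_final[2] * lf + peak_model
  structure(list(offset = unname(ap_final[1]),
                 exponent = unname(-ap_final[2]),
                 peaks = peaks,
                 fit_error = sqrt(mean((lp - model)^2)),
                 freq_range = freq_range,
                 freqs = f, log_power = lp, model = model),
            class = "spectral_fit")
}

.gaussian_sum <- function(f, th) {
  if (is.null(th) || length(th) == 0) return(numeric(length(f)))
  th <- matrix(th, nrow = 3)
  m <- numeric(length(f))
  for (k in seq_len(ncol(th))) {
    m <- m + th[2, k] * exp(-(f - th[1, k])^2 / (2 * th[3, k]^2))
  }
  m
}

# Robust line fit of log power on log frequency: an initial OLS fit, then a
# refit on the points that do not protrude above the trend (the lowest 2.5%
# of the positive part of the flattened spectrum, which keeps everything at
# or below the line and discards peak bins).
.robust_aperiodic_fit <- function(lf, lp, robust = TRUE) {
  co <- stats::lm.fit(cbind(1, lf), lp)$coefficients
  if (!robust) return(co)
  flat <- lp - (co[1] + co[2] * lf)
  flat[flat < 0] <- 0
  thr <- stats::quantile(flat, 0.025)
  keep <- flat <= thr
  if (sum(keep) >= 2) {
    co <- stats::lm.fit(cbind(1, lf[keep]), lp[keep])$coefficients
  }
  co
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat("<spectral_fit> offset", round(x$offset, 3),
      "| exponent", round(x$exponent, 3),
      "|", nrow(x$peaks), "peaks | RMS error", signif(x$fit_error, 3), "\n")
  if (nrow(x$peaks)) print(round(x$peaks, 3))
  invisible(x)
}

#' Evaluate a spectral fit on its frequency axis
#' @param fit A `"spectral_fit"`.
#' @param freqs Frequencies (defaults to the fit's axis).
#' @return Linear power values of the fitted model.
#' @export
synthesize_spectrum <- function(fit, freqs = fit$freqs) {
  lm0 <- fit$offset - fit$exponent * log10(freqs) +
    .gaussian_sum(freqs, rbind(fit$peaks$cf, fit$peaks$amp, fit$peaks$bw / 2))
  10^lm0
}

#' Primary low-frequency peak
#'
#' Among fitted peaks with center frequency below `limit`, returns the one
#' with the largest amplitude (the selection rule is explicit because
#' spectra can carry several sub-11 Hz peaks). Returns a no-peak status
#' rather than dropping the spectrum silently.
#'
#' @param fit A `"spectral_fit"`.
#' @param limit Upper frequency bound in Hz.
#' @param rule `"largest_amplitude"` (default) or `"lowest_cf"`.
#' @return List with `found` (logical) and, when found, `cf`, `amp`, `bw`.
#' @export
primary_low_freq_peak <- function(fit, limit = 11,
                                  rule = c("largest_amplitude", "lowest_cf")) {
  rule <- match.arg(rule)
  stopifnot(inherits(fit, "spectral_fit"))
  cand <- fit$peaks[fit$peaks$cf < limit, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(found = FALSE, cf = NA_real_, amp = NA_real_, bw = NA_real_))
  }
  i <- if (rule == "largest_amplitude") which.max(cand$amp) else which.min(cand$cf)
  list(found = TRUE, cf = cand$cf[i], amp = cand$amp[i], bw = cand$bw[i])
}

# ---- Dixon's Q peak-significance test -------------------------------------

# Two-sided critical values of Dixon's r10 ("Q") ratio at alpha = 0.05,
# n = 3..30 (Rorabacher 1991, 95% confidence, two-tailed).
.dixon_q_crit <- c(
  0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466, 0.444, 0.426,
  0.410, 0.396, 0.384, 0.374, 0.365, 0.356, 0.349, 0.342, 0.337, 0.331,
  0.326, 0.321, 0.317, 0.312, 0.308, 0.305, 0.301, 0.298
)

#' Dixon's Q outlier test for a spectral peak
#'
#' Tests whether the power at a peak frequency is an outlier of the power
#' distribution at non-peak frequencies: the candidate is pooled with the
#' non-peak powers and the classic gap/range ratio
#' `Q = |candidate - nearest neighbor| / range` is compared against the
#' two-sided critical value at `alpha = 0.05`. The test is applicable only
#' for pooled sample sizes 3-30 with a nonzero range; inapplicability is
#' reported as a status, not an error, matching how spectra that do not meet
#' the requirements are excluded rather than failed.
#'
#' @param peak_power Power at the peak frequency.
#' @param nonpeak_powers Powers at non-peak frequencies.
#' @param alpha Significance level (only 0.05 is tabulated).
#' @return A list of class `"peak_validation"`: `q_statistic`,
#'   `q_applicable`, `q_significant`, `n_nonpeak_bins`, `n_pooled`.
#' @export
dixon_q_test <- function(peak_power, nonpeak_powers, alpha = 0.05) {
  stopifnot(is.finite(peak_power), all(is.finite(nonpeak_powers)))
  if (alpha != 0.05) stop("critical values are tabulated for alpha = 0.05 only")
  pooled <- c(nonpeak_powers, peak_power)
  n <- length(pooled)
  rng <- max(pooled) - min(pooled)
  out <- list(q_statistic = NA_real_, q_applicable = FALSE,
              q_significant = FALSE, n_nonpeak_bins = length(nonpeak_powers),
              n_pooled = n)
  class(out) <- "peak_validation"
  if (n < 3 || n > 30 || rng <= 0) return(out)
  gap <- min(abs(peak_power - nonpeak_powers))
  q <- gap / rng
  out$q_statistic <- q
  out$q_applicable <- TRUE
  out$q_significant <- q > .dixon_q_crit[n - 2]
  out
}

#' Exact two-sided binomial proportion test
#'
#' Exact binomial test of `k` successes in `n` trials against probability
#' `p0`, with the two-sided p-value computed by summing the probabilities of
#' all outcomes no more likely than the observed one (the "minimum
#' likelihood" convention).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return List with `k`, `n`, `p0`, `proportion`, `p_value`.
#' @export
binomial_proportion_test <- function(k, n, p0 = 0.5) {
  if (n < 1) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  d <- stats::dbinom(0:n, n, p0)
  obs <- d[k + 1]
  p <- sum(d[d <= obs * (1 + 1e-7)])
  list(k = k, n = n, p0 = p0, proportion = k / n, p_value = min(1, p))
}

# ---- evoked phase ----------------------------------------------------------

#' Extract the evoked modulation phase
#'
#' Returns the circular mean, across carrier bands in `band_range`, of the
#' Fourier phase at the modulation-frequency bin nearest `peak_freq`, mapped
#' back to the phase convention of the modulator
#' `sin(2*pi*f*t + phi)` at epoch time zero. Because the taper is symmetric,
#' the coefficient phase is referenced to the analysis-window center and then
#' rewound to the epoch origin using `peak_freq`.
#'
#' @param evoked A `"modulation_spectrum"` with `mode = "evoked"`.
#' @param band_range Carrier-band range in Hz (two values).
#' @param peak_freq Modulation frequency of interest in Hz.
#' @return Angle in radians in (-pi, pi].
#' @export
extract_evoked_phase <- function(evoked, band_range = c(1000, 2000),
                                 peak_freq) {
  stopifnot(inherits(evoked, "modulation_spectrum"))
  if (evoked$mode != "evoked") stop("evoked-mode spectrum required")
  bsel <- evoked$band_centers >= band_range[1] &
    evoked$band_centers <= band_range[2]
  if (!any(bsel)) stop("band_range selects no bands")
  k <- which.min(abs(evoked$mod_freqs - peak_freq))
  fk <- evoked$mod_freqs[k]
  co <- evoked$evoked_coef[bsel, k]
  # FFT phase is referenced to window start; move to the (symmetric-window)
  # center at f_k, then rewind to epoch time zero at the true frequency.
  t_c <- (evoked$n_window_samples - 1) / (2 * evoked$envelope_sr)
  ph <- Arg(co) + 2 * pi * fk * t_c
  z <- mean(exp(1i * ph))
  phi <- Arg(z) + pi / 2 - 2 * pi * peak_freq * (evoked$window[1] + t_c)
  atan2(sin(phi), cos(phi))
}
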