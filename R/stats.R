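# ---- attention modulation index -------------------------------------------

#' Attention modulation index (AMI)
#'
#' Cellwise bounded percent contrast of power between attention conditions:
#' `(auditory - visual) / (auditory + visual) * 100`. Cells where both
#' condition powers are zero are recorded as `NaN` and excluded from pooling.
#'
#' @param power_a,power_v `"modulation_spectrum"` objects for the Attend
#'   Auditory and Attend Visual conditions (matching axes and mode).
#' @return A list of class `"ami_map"`: `values` (bands x modulation
#'   frequencies, percent), `band_centers`, `mod_freqs`.
#' @export
compute_ami <- function(power_a, power_v) {
  stopifnot(inherits(power_a, "modulation_spectrum"),
            inherits(power_v, "modulation_spectrum"))
  if (power_a$mode != power_v$mode ||
      !isTRUE(all.equal(power_a$band_centers, power_v$band_centers)) ||
      !isTRUE(all.equal(power_a$mod_freqs, power_v$mod_freqs))) {
    stop("condition spectra have mismatching axes or mode")
  }
  a <- power_a$power
  v <- power_v$power
  values <- (a - v) / (a + v) * 100
  values[a == 0 & v == 0] <- NaN
  structure(list(values = values, band_centers = power_a$band_centers,
                 mod_freqs = power_a$mod_freqs, mode = power_a$mode),
            class = "ami_map")
}

#' Pool an AMI map to a scalar
#'
#' Arithmetic mean of the non-NaN AMI cells within a carrier-band range and a
#' modulation-frequency range (the index is averaged, not recomputed from
#' pooled power; see the methods vignette for the alternative).
#'
#' @param ami An [compute_ami()] result.
#' @param band_range Carrier-band range in Hz.
#' @param mod_range Modulation-frequency range in Hz (e.g. 3-10 Hz for the
#'   left ear, 1-10 Hz for the right).
#' @param method `"mean_ami"` (default) or `"pooled_power"` (AMI of the mean
#'   powers is not available from the map alone, so this recomputes the index
#'   from the stored condition powers when attached).
#' @return Scalar percent.
#' @export
pool_ami <- function(ami, band_range = c(1000, 2000), mod_range,
                     method = c("mean_ami")) {
  method <- match.arg(method)
  stopifnot(inherits(ami, "ami_map"))
  bs <- ami$band_centers >= band_range[1] & ami$band_centers <= band_range[2]
  ms <- ami$mod_freqs >= mod_range[1] & ami$mod_freqs <= mod_range[2]
  if (!any(bs) || !any(ms)) stop("pooling ranges intersect no cells")
  cells <- ami$values[bs, ms]
  mean(cells[!is.nan(cells)])
}

# ---- t tests ---------------------------------------------------------------

#' One-sample / paired t test with explicit degenerate handling
#'
#' Standard one-sample (or paired-difference) t test. One-tailed p-values
#' halve the two-tailed p when the observed effect sign matches the
#' alternative and are `1 - p/2` otherwise. Zero-variance input yields an
#' error status rather than a spurious statistic.
#'
#' @param values Numeric vector.
#' @param paired_with Optional second vector for a paired comparison.
#' @param mu Null value.
#' @param tail `"two"`, `"greater"`, or `"less"`.
#' @return A list of class `"group_test"`: `statistic`, `df`, `p_value`,
#'   `tail`, `n`, `mean`, `se`, `status` (`"ok"` or `"zero_variance"`).
#' @export
group_t_test <- function(values, paired_with = NULL, mu = 0,
                         tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  if (!is.null(paired_with)) {
    stopifnot(length(values) == length(paired_with))
    values <- values - paired_with
  }
  n <- length(values)
  if (n < 2) stop("need at least two observations")
  s <- stats::sd(values)
  out <- list(statistic = NA_real_, df = n - 1, p_value = NA_real_,
              tail = tail, n = n, mean = mean(values),
              se = s / sqrt(n), status = "ok")
  class(out) <- "group_test"
  if (s == 0) {
    out$status <- "zero_variance"
    return(out)
  }
  t <- (mean(values) - mu) / (s / sqrt(n))
  p2 <- 2 * stats::pt(-abs(t), n - 1)
  out$statistic <- t
  out$p_value <- switch(tail,
    two = p2,
    greater = stats::pt(t, n - 1, lower.tail = FALSE),
    less = stats::pt(t, n - 1)
  )
  out
}

#' @export
print.group_test <- function(x, ...) {
  cat("<group_test>", x$status, "| t(", x$df, ") =",
      round(x$statistic, 4), ", p =", signif(x$p_value, 4),
      paste0("(", x$tail, "-tailed)"), "\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values with a rejection mask at level `q`.
#'
#' @param p_values Vector of p-values in [0, 1].
#' @param q FDR level.
#' @return List with `p_adjusted` and logical `rejected`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) {
    return(list(p_adjusted = numeric(0), rejected = logical(0)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}

# ---- uniformity test -------------------------------------------------------

#' Kolmogorov-Smirnov test for uniformity
#'
#' One-sample KS test of peak frequencies against a uniform distribution on
#' `support`. Reports the classical `D` in [0, 1], the sqrt(n)-scaled
#' statistic (conventions differ between packages; both are reported), and
#' the asymptotic p-value.
#'
#' @param x Values within the support.
#' @param support Two-element interval.
#' @return A `"group_test"` list with `statistic` = D, `statistic_scaled` =
#'   sqrt(n) * D, and asymptotic `p_value`.
#' @export
ks_uniformity_test <- function(x, support) {
  n <- length(x)
  if (n < 3) stop("need at least three values")
  if (any(x < support[1] | x > support[2])) stop("values outside support")
  u <- sort((x - support[1]) / diff(support))
  ecdf_hi <- seq_len(n) / n
  ecdf_lo <- (seq_len(n) - 1) / n
  d <- max(ecdf_hi - u, u - ecdf_lo)
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  p <- min(1, max(0, p))
  out <- list(statistic = d, statistic_scaled = sqrt(n) * d,
              df = n, p_value = p, tail = "two", n = n, status = "ok")
  class(out) <- "group_test"
  out
}

# ---- circular statistics ---------------------------------------------------

# Circular median: data-point candidate minimizing the mean circular absolute
# deviation pi - |pi - |theta - phi||.
circ_median <- function(theta) {
  dev <- vapply(theta, function(ph) {
    d <- abs(theta - ph)
    mean(pi - abs(pi - d))
  }, numeric(1))
  theta[which.min(dev)]
}

#' Common circular median test
#'
#' Nonparametric test (Fisher's P statistic) that two groups of angles share
#' a common circular median: the pooled circular median splits the circle
#' into the semicircle centered on it and the opposite semicircle, and the
#' per-group membership counts form a 2 x r proportion-homogeneity statistic
#' referred to chi-square with r - 1 df. Under a common median the expected
#' membership proportion is the same in every group regardless of dispersion,
#' so the statistic is calibrated; any shift of one group's median (sideways
#' or antipodal) changes its proportion. Observations exactly on the
#' semicircle boundary are excluded from the counts.
#'
#' @param angles_g1,angles_g2 Angles in radians.
#' @return A `"group_test"` list with `statistic` (P), `df`, `p_value`,
#'   `status` (`"ok"` or `"degenerate"`).
#' @export
circ_common_median_test <- function(angles_g1, angles_g2) {
  if (length(angles_g1) < 5 || length(angles_g2) < 5) {
    stop("each group needs at least five angles")
  }
  groups <- list(angles_g1, angles_g2)
  pooled <- unlist(groups)
  med <- circ_median(pooled)
  # membership in the semicircle centered on the pooled median
  side <- function(a) {
    d <- abs(atan2(sin(a - med), cos(a - med)))
    ifelse(abs(d - pi / 2) < 1e-12, NA, d < pi / 2)
  }
  m <- vapply(groups, function(g) sum(side(g), na.rm = TRUE), numeric(1))
  n <- vapply(groups, function(g) sum(!is.na(side(g))), numeric(1))
  nn <- sum(n)
  mm <- sum(m)
  out <- list(statistic = NA_real_, df = 1, p_value = NA_real_,
              tail = "two", n = nn, status = "ok")
  class(out) <- "group_test"
  if (any(n == 0)) {
    out$status <- "degenerate"
    return(out)
  }
  if (mm == 0 || mm == nn) {
    # every observation on one side in every group: proportions trivially
    # homogeneous
    out$statistic <- 0
    out$p_value <- 1
    return(out)
  }
  p_stat <- nn^2 / (mm * (nn - mm)) * sum(m^2 / n) - nn * mm / (nn - mm)
  out$statistic <- p_stat
  out$p_value <- stats::pchisq(p_stat, df = 1, lower.tail = FALSE)
  out
}

# ---- repeated-measures ANOVA ----------------------------------------------

#' Repeated-measures ANOVA (main effects, 2-level within factors)
#'
#' Main-effect F tests for a fully crossed within-subject design with
#' two-level factors. For a 2-level within factor the classical univariate
#' RM-ANOVA main effect (error term = factor x subject interaction) equals
#' the squared paired t on the subject-level means collapsed over the other
#' factors, with df (1, n - 1); interactions are not reported.
#'
#' @param values Numeric matrix, subjects x cells.
#' @param factors Named list of factor level assignments, one character/
#'   factor vector of length `ncol(values)` per factor, each with exactly two
#'   levels.
#' @return A data frame with one row per factor: `factor`, `F`, `df1`, `df2`,
#'   `p_value`, `status`.
#' @export
rm_anova <- function(values, factors) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 2) stop("need at least two subjects")
  if (any(!is.finite(values))) stop("missing cells are not supported")
  lv <- lapply(factors, function(f) {
    u <- unique(as.character(f))
    if (length(u) != 2) stop("each factor must have exactly two levels")
    u
  })
  cells <- expand.grid(lapply(factors, function(f) unique(as.character(f))))
  if (nrow(unique(as.data.frame(factors))) != 2^length(factors)) {
    stop("design must be fully crossed with no missing cells")
  }
  res <- lapply(names(factors), function(nm) {
    f <- as.character(factors[[nm]])
    m1 <- rowMeans(values[, f == lv[[nm]][1], drop = FALSE])
    m2 <- rowMeans(values[, f == lv[[nm]][2], drop = FALSE])
    d <- m1 - m2
    sdd <- stats::sd(d)
    if (sdd == 0) {
      fstat <- if (mean(d) == 0) 0 else Inf
      status <- if (mean(d) == 0) "ok" else "zero_error_variance"
      p <- if (is.infinite(fstat)) 0 else 1
    } else {
      tstat <- mean(d) / (sdd / sqrt(n))
      fstat <- tstat^2
      p <- stats::pf(fstat, 1, n - 1, lower.tail = FALSE)
      status <- "ok"
    }
    data.frame(factor = nm, F = fstat, df1 = 1, df2 = n - 1,
               p_value = p, status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# ---- reaction-time median split -------------------------------------------

#' Median split of trials by reaction time
#'
#' Labels each trial "fast" or "slow" relative to the median computed
#' separately per subject and condition. Trials exactly at the median go to
#' the fast group (explicit tie rule), so group sizes differ by at most one.
#'
#' @param trial_table Data frame with `condition` and the split key; may
#'   carry a `subject` column (otherwise all rows are one subject).
#' @param key Column name to split on.
#' @param ties `"fast"` (default) or `"slow"`.
#' @return The trial table with an added `rt_group` column and a `status`
#'   attribute marking degenerate (all-identical) splits per
#'   subject x condition.
#' @export
median_split <- function(trial_table, key = "reaction_time",
                         ties = c("fast", "slow")) {
  ties <- match.arg(ties)
  tt <- trial_table
  if (is.null(tt$subject)) tt$subject <- 1L
  tt$rt_group <- NA_character_
  status <- character(0)
  for (s in unique(tt$subject)) {
    for (cond in unique(tt$condition)) {
      i <- which(tt$subject == s & tt$condition == cond)
      if (length(i) < 2) stop("need at least two trials per subject x condition")
      x <- tt[[key]][i]
      med <- stats::median(x)
      if (max(x) == min(x)) {
        status <- c(status, sprintf("degenerate:%s:%s", s, cond))
        tt$rt_group[i] <- "fast"
        next
      }
      if (ties == "fast") {
        tt$rt_group[i] <- ifelse(x <= med, "fast", "slow")
      } else {
        tt$rt_group[i] <- ifelse(x < med, "fast", "slow")
      }
    }
  }
  attr(tt, "status") <- if (length(status)) status else "ok"
  tt
}
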