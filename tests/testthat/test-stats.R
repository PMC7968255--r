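make_spec <- function(power, mode = "induced") {
  structure(list(mode = mode, band_centers = c(1200, 1600),
                 mod_freqs = c(2, 6, 10), power = power),
            class = "modulation_spectrum")
}

test_that("the AMI follows its defining formula and symmetry", {
  a <- make_spec(matrix(2, 2, 3))
  v <- make_spec(matrix(1, 2, 3))
  ami <- compute_ami(a, v)
  expect_equal(ami$values, matrix(100 / 3, 2, 3), tolerance = 1e-12)
  expect_equal(compute_ami(v, a)$values, -ami$values)

  same <- compute_ami(a, a)
  expect_true(all(same$values == 0))

  z <- make_spec(matrix(0, 2, 3))
  both0 <- compute_ami(z, z)
  expect_true(all(is.nan(both0$values)))

  # antisymmetry and bounds on random maps
  set.seed(1)
  for (i in 1:20) {
    pa <- make_spec(matrix(rexp(6), 2, 3))
    pv <- make_spec(matrix(rexp(6), 2, 3))
    m1 <- compute_ami(pa, pv)$values
    expect_equal(m1, -compute_ami(pv, pa)$values, tolerance = 1e-12)
    expect_true(all(abs(m1) <= 100))
  }

  bad <- make_spec(matrix(1, 2, 3), mode = "evoked")
  expect_error(compute_ami(a, bad), "mismatch")
})

test_that("AMI pooling averages the index over in-range cells", {
  vals <- matrix(5, 2, 3)
  ami <- structure(list(values = vals, band_centers = c(1200, 1600),
                        mod_freqs = c(2, 6, 10)), class = "ami_map")
  expect_equal(pool_ami(ami, mod_range = c(1, 10)), 5)

  vals2 <- matrix(c(10, 10, 10, 0, 0, 0), 2, 3)
  ami2 <- ami; ami2$values <- vals2
  expect_equal(pool_ami(ami2, mod_range = c(1, 10)), 5)

  # wider modulation range can only add cells
  amir <- ami
  amir$mod_freqs <- c(2, 6, 10)
  n_cells <- function(range) {
    sum(amir$mod_freqs >= range[1] & amir$mod_freqs <= range[2]) *
      length(amir$band_centers)
  }
  expect_gt(n_cells(c(1, 10)), n_cells(c(3, 10)) - 1)
  expect_error(pool_ami(ami, mod_range = c(20, 25)), "no cells")

  # NaN cells are excluded, not propagated
  ami3 <- ami; ami3$values[1, 1] <- NaN
  expect_equal(pool_ami(ami3, mod_range = c(1, 10)), 5)
})

test_that("t tests match hand computation and flag degenerate input", {
  x <- c(0.5, 1.5, 1.0, 2.0, 1.0)
  r <- group_t_test(x, tail = "greater")
  # hand computation: mean 1.2, sd sqrt(1.3/4), t = 1.2/(0.5701/sqrt(5))
  expect_equal(r$statistic, 1.2 / (sqrt(1.3 / 4) / sqrt(5)), tolerance = 1e-6)
  expect_equal(r$statistic, 4.7068, tolerance = 1e-4)
  expect_equal(r$p_value,
               stats::t.test(x, alternative = "greater")$p.value,
               tolerance = 1e-12)

  z <- group_t_test(c(1, 1, 1))
  expect_equal(z$status, "zero_variance")
  expect_true(is.na(z$p_value))

  zp <- group_t_test(c(1, 2, 3), paired_with = c(1, 2, 3))
  expect_equal(zp$status, "zero_variance")
})

test_that("BH correction equals brute-force step-up on an exhaustive grid", {
  r <- fdr_correct(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$p_adjusted, rep(0.04, 4))
  expect_true(all(r$rejected))
  expect_equal(fdr_correct(0.2)$p_adjusted, 0.2)
  expect_false(any(fdr_correct(rep(1, 5))$rejected))
  expect_length(fdr_correct(numeric(0))$p_adjusted, 0)

  step_up <- function(p) {       # literal BH step-up, written independently
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    prev <- Inf
    for (i in n:1) {
      prev <- min(prev, p[o[i]] * n / i)
      adj[o[i]] <- min(1, prev)
    }
    adj
  }
  grid <- c(0.01, 0.05, 0.3, 1)
  for (len in 1:8) {
    combos <- as.matrix(expand.grid(rep(list(grid), len)))
    # sorted combos suffice: BH is permutation-equivariant (checked below)
    combos <- unique(t(apply(combos, 1, sort)))
    for (i in seq_len(nrow(combos))) {
      p <- combos[i, ]
      expect_equal(fdr_correct(p)$p_adjusted, step_up(p), tolerance = 1e-12)
    }
  }
  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1))
    expect_equal(fdr_correct(p)$p_adjusted, step_up(p), tolerance = 1e-12)
  }
})

test_that("KS uniformity statistic and p behave as specified", {
  x <- rep(6, 27)
  r <- ks_uniformity_test(x, c(1, 11))
  expect_equal(r$statistic, 0.5, tolerance = 1e-12)
  expect_lt(r$p_value, 0.001)
  expect_equal(r$statistic_scaled, sqrt(27) * 0.5)

  set.seed(3)
  y <- runif(40, 1, 11)
  ref <- suppressWarnings(stats::ks.test(y, "punif", 1, 11))
  mine <- ks_uniformity_test(y, c(1, 11))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)

  # calibration: under uniformity the p-values are themselves uniform
  set.seed(4)
  ps <- replicate(200, ks_uniformity_test(runif(50, 0, 1), c(0, 1))$p_value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  expect_error(ks_uniformity_test(c(1, 2), c(0, 3)), "three")
  expect_error(ks_uniformity_test(c(1, 2, 12), c(1, 11)), "support")
})

test_that("the circular common median test is calibrated and powered", {
  set.seed(5)
  null_p <- replicate(100, {
    g1 <- cochleamod:::rvonmises(27, 0, 2)
    g2 <- cochleamod:::rvonmises(27, 0, 2)
    circ_common_median_test(g1, g2)$p_value
  })
  expect_gte(mean(null_p > 0.05, na.rm = TRUE), 0.9)

  alt_p <- replicate(100, {
    g1 <- cochleamod:::rvonmises(27, 0, 4)
    g2 <- cochleamod:::rvonmises(27, pi, 4)
    circ_common_median_test(g1, g2)$p_value
  })
  expect_gte(mean(alt_p < 0.05, na.rm = TRUE), 0.9)

  g <- cochleamod:::rvonmises(27, 1, 2)
  same <- circ_common_median_test(g, g)
  expect_true(same$status == "ok")
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  expect_error(circ_common_median_test(g[1:3], g), "five")
})

test_that("repeated-measures main effects match hand sums of squares", {
  # 4-subject 2x2 toy with known cell values
  vals <- rbind(c(10, 12, 20, 23),
                c(11, 13, 19, 24),
                c( 9, 11, 21, 22),
                c(10, 14, 20, 25))
  f <- list(ear = c("L", "L", "R", "R"), rt = c("fast", "slow", "fast", "slow"))
  res <- rm_anova(vals, f)

  # oracle: classical within-subject sums of squares per factor
  ss_f <- function(level_vec) {
    m <- t(apply(vals, 1, function(r) tapply(r, level_vec, mean)))
    grand <- mean(m)
    k <- ncol(vals) / 2       # cells aggregated per factor level
    ss_a <- k * nrow(m) * sum((colMeans(m) - grand)^2)
    resid <- m - outer(rowMeans(m), rep(1, 2)) -
      outer(rep(1, nrow(m)), colMeans(m)) + grand
    ss_as <- k * sum(resid^2)
    (ss_a / 1) / (ss_as / (nrow(m) - 1))
  }
  expect_equal(res$F[res$factor == "ear"], ss_f(f$ear), tolerance = 1e-10)
  expect_equal(res$F[res$factor == "rt"], ss_f(f$rt), tolerance = 1e-10)

  # identical cell means per subject: F = 0
  same <- matrix(rep(c(3, 3, 3, 3), each = 4), 4, 4) + rnorm(16) * 0
  same <- same + matrix(rnorm(4), 4, 4)  # subject offsets only
  r0 <- rm_anova(same, f)
  expect_true(all(r0$F == 0))

  # fixed shift with zero noise: infinite F flagged
  shift <- matrix(0, 4, 4)
  shift[, f$ear == "R"] <- 1
  shift <- shift + matrix(rnorm(4), 4, 4)
  rs <- rm_anova(shift, f)
  expect_true(is.infinite(rs$F[rs$factor == "ear"]))
  expect_equal(rs$status[rs$factor == "ear"], "zero_error_variance")

  expect_error(rm_anova(vals, list(ear = c("L", "L", "L", "R"),
                                   rt = c("f", "s", "f", "s"))),
               "crossed|levels")
})

test_that("2x2x2 main-effect p-values are uniform under the null", {
  set.seed(6)
  cells <- expand.grid(ear = c("L", "R"), rt = c("f", "s"), cond = c("a", "v"))
  f <- list(ear = as.character(cells$ear), rt = as.character(cells$rt),
            cond = as.character(cells$cond))
  rej <- matrix(0, 500, 3)
  for (r in 1:500) {
    vals <- matrix(rnorm(27 * 8), 27, 8)
    res <- rm_anova(vals, f)
    rej[r, ] <- res$p_value < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates > 0.03 & rates < 0.07))
})

test_that("median splits are per subject and condition with explicit ties", {
  tt <- data.frame(condition = rep("auditory", 4),
                   reaction_time = c(400, 500, 600, 700))
  out <- median_split(tt)
  expect_equal(out$rt_group, c("fast", "fast", "slow", "slow"))

  tt3 <- data.frame(condition = rep("auditory", 3),
                    reaction_time = c(400, 500, 600))
  out3 <- median_split(tt3)
  expect_equal(out3$rt_group, c("fast", "fast", "slow"))

  # per-condition split stays balanced under a condition RT shift
  set.seed(7)
  ttc <- data.frame(condition = rep(c("auditory", "visual"), each = 20),
                    reaction_time = c(rnorm(20, 600, 30), rnorm(20, 500, 30)))
  outc <- median_split(ttc)
  for (cond in c("auditory", "visual")) {
    grp <- outc$rt_group[outc$condition == cond]
    expect_lte(abs(sum(grp == "fast") - sum(grp == "slow")), 1)
  }
  # a pooled split would be grossly unbalanced within conditions
  pooled_med <- stats::median(ttc$reaction_time)
  aud_fast_pooled <- sum(ttc$reaction_time[ttc$condition == "auditory"] <= pooled_med)
  expect_gt(abs(aud_fast_pooled - 10), 3)

  degen <- data.frame(condition = rep("auditory", 4),
                      reaction_time = rep(500, 4))
  dd <- median_split(degen)
  expect_match(attr(dd, "status"), "degenerate")
})
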