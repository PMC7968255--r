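null_grid <- function(n_sub, shape = c(4, 4, 4), seed = 1) {
  cfg <- generator_config(grid_shape = shape, planted_brain_effect = 0,
                          brain_effect_scale = 0, seed = seed)
  simulate_brain_power(cfg, rnorm(n_sub), seed = seed)
}

test_that("lattice adjacency is symmetric with no self edges", {
  adj <- lattice_adjacency(c(3, 3, 3), 4)
  expect_length(adj$neighbors, 27 * 4)
  for (cell in seq_along(adj$neighbors)) {
    nb <- adj$neighbors[[cell]]
    expect_false(cell %in% nb)
    for (v in nb) expect_true(cell %in% adj$neighbors[[v]])
  }
  # corner voxel at same frequency: 7 spatial neighbors (queen) + 1 freq edge
  expect_length(adj$neighbors[[1]], 8)
  # rook connectivity: 3 spatial + 1 frequency at the corner
  adjr <- lattice_adjacency(c(3, 3, 3), 4, spatial = "rook")
  expect_length(adjr$neighbors[[1]], 4)
})

test_that("R and C++ cluster-mass kernels agree", {
  set.seed(10)
  adj <- lattice_adjacency(c(4, 4, 4), 10)
  for (i in 1:25) {
    tmap <- rnorm(640, sd = 1.5)
    thr <- runif(1, 1, 2.5)
    expect_equal(cochleamod:::.max_cluster_mass(tmap, thr, adj$neighbors),
                 cochleamod:::.max_cluster_mass_cpp(tmap, thr, adj$neighbors),
                 tolerance = 1e-12)
  }
})

test_that("condition clusters recover a planted posterior effect", {
  set.seed(20)
  adj <- lattice_adjacency(c(8, 8, 8), 23)
  hits <- 0
  for (r in 1:5) {
    cfg <- generator_config(grid_shape = c(8, 8, 8), brain_effect_scale = 0,
                            seed = 400 + r)
    g <- simulate_brain_power(cfg, rnorm(12), seed = 400 + r)
    res <- condition_cluster_test(g$power[, , 3:25, ], adj, n_perm = 300,
                                  seed = r, freqs = 3:25)
    pos <- Filter(function(cl) cl$sign > 0 && cl$p_mc < 0.05, res$clusters)
    if (length(pos)) {
      planted <- as.vector(outer(g$blocks$posterior,
                                 (which(3:25 %in% 8:25) - 1) * 512, "+"))
      overlap <- max(vapply(pos, function(cl) {
        mean(planted %in% cl$cells)
      }, numeric(1)))
      if (overlap >= 0.5) hits <- hits + 1
    }
  }
  expect_gte(hits, 4)
})

test_that("null data produce no spuriously confident clusters", {
  set.seed(30)
  adj <- lattice_adjacency(c(4, 4, 4), 23)
  minp <- replicate(10, {
    g <- null_grid(10, seed = sample.int(1e6, 1))
    res <- condition_cluster_test(g$power[, , 3:25, ], adj, n_perm = 200,
                                  seed = sample.int(1e6, 1))
    if (length(res$clusters)) min(vapply(res$clusters, `[[`, 0, "p_mc")) else 1
  })
  expect_lte(sum(minp < 0.05), 2)
})

test_that("correlation clusters track a planted negative association", {
  set.seed(40)
  adj <- lattice_adjacency(c(8, 8, 8), 23)
  cfg <- generator_config(grid_shape = c(8, 8, 8), planted_brain_effect = 0,
                          planted_correlation = -0.8, seed = 41)
  ooa <- rnorm(24, 1.5, 1)
  g <- simulate_brain_power(cfg, ooa, seed = 42)
  bam <- (g$power[, , 3:25, 1] - g$power[, , 3:25, 2]) /
    (g$power[, , 3:25, 1] + g$power[, , 3:25, 2]) * 100
  res <- correlation_cluster_test(bam, ooa, adj, n_perm = 300, seed = 43)
  expect_gt(length(res$clusters), 0)
  top <- res$clusters[[1]]
  expect_equal(top$sign, -1)
  expect_lt(top$p_mc, 0.05)

  # self-null: shuffling the cochlear vector destroys the association
  set.seed(44)
  ps <- replicate(10, {
    r <- correlation_cluster_test(bam, sample(ooa), adj, n_perm = 200,
                                  seed = sample.int(1e6, 1))
    if (length(r$clusters)) min(vapply(r$clusters, `[[`, 0, "p_mc")) else 1
  })
  expect_lte(sum(ps < 0.05), 2)

  expect_error(correlation_cluster_test(bam, rep(1, 24), adj), "variance")
})

test_that("Monte-Carlo p agrees with exhaustive enumeration", {
  set.seed(50)
  adj <- lattice_adjacency(c(3, 3, 3), 10)
  # sign flips at n = 8
  cfg <- generator_config(grid_shape = c(3, 3, 3),
                          planted_brain_effect = 0.08,
                          brain_effect_scale = 0, seed = 51)
  g <- simulate_brain_power(cfg, rnorm(8), seed = 51)
  pw <- g$power[, , 11:20, ]
  ex <- condition_cluster_test(pw, adj, exact = TRUE)
  mc <- condition_cluster_test(pw, adj, n_perm = 10000, seed = 52)
  expect_equal(ex$n_permutations, 256)
  expect_lt(abs(ex$clusters[[1]]$p_mc - mc$clusters[[1]]$p_mc), 0.02)

  # subject orderings at n = 7
  ooa <- rnorm(7)
  g2 <- simulate_brain_power(generator_config(grid_shape = c(3, 3, 3),
                                              planted_brain_effect = 0,
                                              planted_correlation = -0.6,
                                              seed = 53), ooa, seed = 53)
  bam <- (g2$power[, , 11:20, 1] - g2$power[, , 11:20, 2]) /
    (g2$power[, , 11:20, 1] + g2$power[, , 11:20, 2]) * 100
  ex2 <- correlation_cluster_test(bam, ooa, adj, exact = TRUE)
  mc2 <- correlation_cluster_test(bam, ooa, adj, n_perm = 10000, seed = 54)
  expect_equal(ex2$n_permutations, factorial(7))
  if (length(ex2$clusters)) {
    expect_lt(abs(ex2$clusters[[1]]$p_mc - mc2$clusters[[1]]$p_mc), 0.02)
  }
})

test_that("results are deterministic and invariant to voxel relabeling", {
  set.seed(60)
  g <- null_grid(8, seed = 61)
  adj <- lattice_adjacency(c(4, 4, 4), 23)
  pw <- g$power[, , 3:25, ]
  r1 <- condition_cluster_test(pw, adj, n_perm = 200, seed = 7)
  r2 <- condition_cluster_test(pw, adj, n_perm = 200, seed = 7)
  expect_identical(r1$null_max_mass, r2$null_max_mass)
  expect_identical(lapply(r1$clusters, `[[`, "mass"),
                   lapply(r2$clusters, `[[`, "mass"))

  # permute voxel labels consistently in the data and the graph
  perm <- sample(64)
  inv <- integer(64); inv[perm] <- seq_len(64)
  pw_p <- pw[, perm, , ]
  adj_p <- adj
  adj_p$neighbors <- lapply(seq_along(adj$neighbors), function(cell) {
    v <- (cell - 1) %% 64 + 1
    fq <- (cell - 1) %/% 64
    orig <- adj$neighbors[[perm[v] + fq * 64]]
    ov <- (orig - 1) %% 64 + 1
    of <- (orig - 1) %/% 64
    sort(inv[ov] + of * 64)
  })
  r3 <- condition_cluster_test(pw_p, adj_p, n_perm = 200, seed = 7)
  expect_equal(sort(vapply(r3$clusters, `[[`, 0, "mass")),
               sort(vapply(r1$clusters, `[[`, 0, "mass")), tolerance = 1e-10)
  expect_identical(vapply(r3$clusters, `[[`, 0, "p_mc")[order(vapply(r3$clusters, `[[`, 0, "mass"))],
                   vapply(r1$clusters, `[[`, 0, "p_mc")[order(vapply(r1$clusters, `[[`, 0, "mass"))])
})

test_that("larger planted effects never shrink the detected cluster mass", {
  set.seed(70)
  adj <- lattice_adjacency(c(6, 6, 6), 23)
  med_mass <- sapply(c(0.1, 0.25, 0.5), function(eff) {
    masses <- replicate(5, {
      cfg <- generator_config(grid_shape = c(6, 6, 6),
                              planted_brain_effect = eff,
                              brain_effect_scale = 0,
                              seed = sample.int(1e6, 1))
      g <- simulate_brain_power(cfg, rnorm(10), seed = sample.int(1e6, 1))
      r <- condition_cluster_test(g$power[, , 3:25, ], adj, n_perm = 50,
                                  seed = sample.int(1e6, 1))
      pos <- vapply(Filter(function(cl) cl$sign > 0, r$clusters), `[[`, 0, "mass")
      if (length(pos)) max(pos) else 0
    })
    stats::median(masses)
  })
  expect_true(all(diff(med_mass) >= 0))
})

test_that("cluster profiles count member voxels per frequency", {
  set.seed(80)
  adj <- lattice_adjacency(c(8, 8, 8), 23)
  cfg <- generator_config(grid_shape = c(8, 8, 8), brain_effect_scale = 0,
                          seed = 81)
  g <- simulate_brain_power(cfg, rnorm(12), seed = 81)
  res <- condition_cluster_test(g$power[, , 3:25, ], adj, n_perm = 100,
                                seed = 82, freqs = 3:25)
  prof <- cluster_profile(res)
  expect_equal(sum(prof$n_voxels), length(res$clusters[[1]]$cells))
  # planted effect spans 8-25 Hz: the bulk of the cluster lies there
  in_band <- prof$freq >= 8
  expect_gt(sum(prof$n_voxels[in_band]), 0.9 * sum(prof$n_voxels))

  # single-cell cluster
  one <- res
  one$clusters <- list(list(cells = 3L + 512L * 4L, mass = 3, sign = 1,
                            p_mc = 0.5))
  p1 <- cluster_profile(one)
  expect_equal(sum(p1$n_voxels), 1)
  expect_equal(p1$n_voxels[5], 1)

  empty <- res
  empty$clusters <- list()
  expect_equal(nrow(cluster_profile(empty)), 0)
})
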