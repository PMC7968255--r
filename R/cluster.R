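# ---- spatio-spectral adjacency --------------------------------------------

#' Lattice adjacency for voxel x frequency maps
#'
#' Builds the neighbor structure used for cluster formation: voxels are
#' spatial neighbors when each lattice coordinate differs by at most one
#' step, and cells are connected either spatially at the same frequency or
#' across adjacent frequency bins at the same voxel (no diagonal
#' space-frequency edges).
#'
#' @param grid_shape Integer vector of 3 lattice dimensions.
#' @param n_freqs Number of frequency bins.
#' @param spatial `"queen"` (default: all coordinates within one step,
#'   26-neighborhood) or `"rook"` (orthogonal steps only).
#' @return A list of class `"adjacency_graph"`: `neighbors` (list of integer
#'   vectors over cells, cell index = voxel + (freq - 1) * n_voxels),
#'   `n_voxels`, `n_freqs`, `grid_shape`.
#' @export
lattice_adjacency <- function(grid_shape, n_freqs,
                              spatial = c("queen", "rook")) {
  spatial <- match.arg(spatial)
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                                  y = seq_len(grid_shape[2]),
                                  z = seq_len(grid_shape[3])))
  nv <- nrow(coords)
  # voxel neighbor lists
  steps <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  steps <- steps[rowSums(abs(steps)) > 0, , drop = FALSE]
  if (spatial == "rook") steps <- steps[rowSums(abs(steps)) == 1, , drop = FALSE]
  key <- function(cc) {
    ok <- cc[, 1] >= 1 & cc[, 1] <= grid_shape[1] &
      cc[, 2] >= 1 & cc[, 2] <= grid_shape[2] &
      cc[, 3] >= 1 & cc[, 3] <= grid_shape[3]
    ifelse(ok, cc[, 1] + (cc[, 2] - 1) * grid_shape[1] +
             (cc[, 3] - 1) * grid_shape[1] * grid_shape[2], NA)
  }
  vox_nb <- vector("list", nv)
  for (s in seq_len(nrow(steps))) {
    nb <- key(sweep(coords, 2, as.numeric(steps[s, ]), "+"))
    ok <- !is.na(nb)
    idx <- which(ok)
    for (v in idx) vox_nb[[v]] <- c(vox_nb[[v]], nb[v])
  }
  n_cells <- nv * n_freqs
  neighbors <- vector("list", n_cells)
  for (fq in seq_len(n_freqs)) {
    off <- (fq - 1L) * nv
    for (v in seq_len(nv)) {
      nb <- vox_nb[[v]] + off
      if (fq > 1) nb <- c(nb, v + off - nv)
      if (fq < n_freqs) nb <- c(nb, v + off + nv)
      neighbors[[v + off]] <- nb
    }
  }
  structure(list(neighbors = neighbors, n_voxels = nv, n_freqs = n_freqs,
                 grid_shape = grid_shape, coords = coords),
            class = "adjacency_graph")
}

# Connected components of suprathreshold cells; returns a list of integer
# vectors. `active` is a logical vector over cells.
.find_clusters <- function(active, neighbors) {
  idx <- which(active)
  if (!length(idx)) return(list())
  visited <- logical(length(active))
  stack <- integer(length(idx))
  members <- integer(length(idx))
  out <- list()
  for (seed in idx) {
    if (visited[seed]) next
    sp <- 1L
    mp <- 0L
    stack[1L] <- seed
    visited[seed] <- TRUE
    while (sp > 0L) {
      cell <- stack[sp]
      sp <- sp - 1L
      mp <- mp + 1L
      members[mp] <- cell
      nb <- neighbors[[cell]]
      nb <- nb[active[nb] & !visited[nb]]
      ln <- length(nb)
      if (ln) {
        visited[nb] <- TRUE
        stack[(sp + 1L):(sp + ln)] <- nb
        sp <- sp + ln
      }
    }
    out[[length(out) + 1L]] <- members[seq_len(mp)]
  }
  out
}

# Max |cluster mass| over both signs for a t map (internal, used in the
# permutation loop). Suprathreshold detection happens in one pass over the
# map; positive and negative cells are clustered separately.
.max_cluster_mass <- function(tmap, thr, neighbors) {
  idx <- which(abs(tmap) > thr)
  if (!length(idx)) return(0)
  mx <- 0
  n <- length(tmap)
  for (sgn in c(1, -1)) {
    sidx <- idx[sign(tmap[idx]) == sgn]
    if (!length(sidx)) next
    act <- logical(n)
    act[sidx] <- TRUE
    for (m in .find_clusters(act, neighbors)) {
      mx <- max(mx, abs(sum(tmap[m])))
    }
  }
  mx
}

.observed_clusters <- function(tmap, thr, neighbors) {
  out <- list()
  idx <- which(abs(tmap) > thr)
  for (sgn in c(1, -1)) {
    sidx <- idx[sign(tmap[idx]) == sgn]
    if (!length(sidx)) next
    act <- logical(length(tmap))
    act[sidx] <- TRUE
    for (m in .find_clusters(act, neighbors)) {
      out[[length(out) + 1L]] <- list(cells = sort(m), mass = sum(tmap[m]),
                                      sign = sgn)
    }
  }
  if (length(out)) out <- out[order(-vapply(out, function(c) abs(c$mass), 0))]
  out
}

.cluster_result <- function(clusters, null_max, n_perm, tmap, thr,
                            adjacency, forming_alpha, freqs) {
  for (i in seq_along(clusters)) {
    # tolerance so the identity permutation's own mass counts as >= observed
    clusters[[i]]$p_mc <-
      (1 + sum(null_max >= abs(clusters[[i]]$mass) * (1 - 1e-9))) /
      (1 + n_perm)
  }
  structure(list(clusters = clusters, n_permutations = n_perm,
                 cluster_forming_alpha = forming_alpha,
                 forming_threshold = thr,
                 observed_stat_map = tmap,
                 null_max_mass = null_max,
                 n_voxels = adjacency$n_voxels,
                 freqs = freqs),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", length(x$clusters), "clusters |",
      x$n_permutations, "permutations | forming alpha",
      x$cluster_forming_alpha, "\n")
  for (i in seq_len(min(5L, length(x$clusters)))) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d: %d cells, mass %.1f (%s), p = %.4g\n", i,
                length(cl$cells), cl$mass,
                if (cl$sign > 0) "positive" else "negative", cl$p_mc))
  }
  if (length(x$clusters) > 5) {
    cat("  ...", length(x$clusters) - 5L, "more\n")
  }
  invisible(x)
}

# ---- condition contrast ----------------------------------------------------

#' Cluster-based permutation test of a condition contrast
#'
#' Paired t statistics per (voxel, frequency) cell for condition 1 minus
#' condition 2, thresholded at a parametric two-sided cluster-forming alpha;
#' connected suprathreshold cells (per sign) form clusters scored by their t
#' mass. The null distribution of the maximal |mass| is built by random
#' per-subject sign flips of the condition differences, and each observed
#' cluster gets the Monte-Carlo p-value `(1 + #(null >= |mass|)) / (1 +
#' n_perm)`.
#'
#' @param power Array subjects x voxels x frequencies x 2 conditions,
#'   already restricted to the analysis frequency range.
#' @param adjacency A [lattice_adjacency()] matching voxels and frequencies.
#' @param n_perm Number of permutations.
#' @param forming_alpha Two-sided cluster-forming alpha.
#' @param seed Optional seed for the permutation draws.
#' @param exact If `TRUE`, enumerate all `2^n` sign-flip patterns instead of
#'   sampling (feasible for small n; `n_perm` is ignored).
#' @param freqs Optional frequency labels stored in the result.
#' @return A `"cluster_result"`; empty `clusters` when no cell crosses the
#'   forming threshold.
#' @export
condition_cluster_test <- function(power, adjacency, n_perm = 1000,
                                   forming_alpha = 0.05, seed = NULL,
                                   exact = FALSE, freqs = NULL) {
  d <- dim(power)
  stopifnot(length(d) == 4, d[4] == 2)
  n <- d[1]
  if (n < 6 && !exact) stop("need at least six subjects")
  n_cells <- d[2] * d[3]
  stopifnot(length(adjacency$neighbors) == n_cells)
  if (!is.null(seed)) set.seed(seed)
  D <- matrix(power[, , , 1] - power[, , , 2], n, n_cells)
  ss <- colSums(D^2)
  thr <- stats::qt(1 - forming_alpha / 2, n - 1)
  t_of <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  tmap <- t_of(colMeans(D))
  clusters <- .observed_clusters(tmap, thr, adjacency$neighbors)

  signs <- if (exact) {
    s <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_perm <- nrow(s)
    s
  } else {
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  # all permutation means in one BLAS product, then cluster row-wise
  M <- signs %*% D / n
  Vp <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  Vp[Vp < .Machine$double.eps] <- .Machine$double.eps
  Tm <- M / sqrt(Vp / n)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    null_max[p] <- .max_cluster_mass_cpp(Tm[p, ], thr, adjacency$neighbors)
  }
  .cluster_result(clusters, null_max, n_perm, tmap, thr, adjacency,
                  forming_alpha, freqs)
}

# ---- brain-cochlea correlation ---------------------------------------------

#' Cluster-based permutation test of an across-subject correlation
#'
#' Pearson correlation, per (voxel, frequency) cell, between a brain AMI map
#' and a per-subject cochlear AMI vector; cell statistics are
#' `t = r * sqrt((n - 2) / (1 - r^2))`, clustered as in
#' [condition_cluster_test()]. The null permutes the subject order of the
#' cochlear vector (preserving the spatial covariance of the brain maps).
#'
#' @param brain_ami Array subjects x voxels x frequencies.
#' @param ooa_ami Numeric vector, one cochlear AMI per subject.
#' @param adjacency A [lattice_adjacency()].
#' @param n_perm,forming_alpha,seed,freqs As in [condition_cluster_test()].
#' @param exact If `TRUE`, enumerate all `n!` subject orderings (feasible
#'   for n <= 7).
#' @return A `"cluster_result"`.
#' @export
correlation_cluster_test <- function(brain_ami, ooa_ami, adjacency,
                                     n_perm = 1000, forming_alpha = 0.05,
                                     seed = NULL, exact = FALSE,
                                     freqs = NULL) {
  d <- dim(brain_ami)
  stopifnot(length(d) == 3)
  n <- d[1]
  if (length(ooa_ami) != n) stop("ooa_ami length must match subjects")
  if (n < 6 && !exact) stop("need at least six subjects")
  if (stats::sd(ooa_ami) == 0) stop("zero-variance cochlear AMI vector")
  n_cells <- d[2] * d[3]
  stopifnot(length(adjacency$neighbors) == n_cells)
  if (!is.null(seed)) set.seed(seed)
  B <- matrix(brain_ami, n, n_cells)
  Bc <- scale(B)            # columns standardized
  Bc[is.nan(Bc)] <- 0       # zero-variance cells carry no signal
  thr <- stats::qt(1 - forming_alpha / 2, n - 2)
  t_of_x <- function(x) {
    r <- as.numeric(crossprod(x, Bc)) / (n - 1)
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    r * sqrt((n - 2) / (1 - r^2))
  }
  x0 <- as.numeric(scale(ooa_ami))
  tmap <- t_of_x(x0)
  clusters <- .observed_clusters(tmap, thr, adjacency$neighbors)

  orders <- if (exact) {
    po <- .all_permutations(n)
    n_perm <- nrow(po)
    po
  } else {
    t(replicate(n_perm, sample.int(n)))
  }
  Xp <- matrix(x0[orders], n_perm, n)
  Rp <- Xp %*% Bc / (n - 1)
  Rp <- pmin(pmax(Rp, -1 + 1e-12), 1 - 1e-12)
  Tp <- Rp * sqrt((n - 2) / (1 - Rp^2))
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    null_max[p] <- .max_cluster_mass_cpp(Tp[p, ], thr, adjacency$neighbors)
  }
  .cluster_result(clusters, null_max, n_perm, tmap, thr, adjacency,
                  forming_alpha, freqs)
}

# All permutations of 1..n (lexicographic), rows of a matrix. n! rows.
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Per-frequency profile of a cluster
#'
#' Counts the member voxels of one cluster at each frequency bin (the
#' standard way to display the spectral extent of a spatio-spectral
#' cluster).
#'
#' @param result A `"cluster_result"`.
#' @param which_cluster Cluster index (default 1 = largest |mass|).
#' @return Data frame `freq_index`, `freq` (if labels stored), `n_voxels`;
#'   zero rows when the result has no clusters.
#' @export
cluster_profile <- function(result, which_cluster = 1) {
  stopifnot(inherits(result, "cluster_result"))
  if (length(result$clusters) == 0) {
    return(data.frame(freq_index = integer(0), n_voxels = integer(0)))
  }
  cl <- result$clusters[[which_cluster]]
  fq <- (cl$cells - 1L) %/% result$n_voxels + 1L
  n_f <- length(result$observed_stat_map) / result$n_voxels
  counts <- tabulate(fq, nbins = n_f)
  out <- data.frame(freq_index = seq_len(n_f), n_voxels = counts)
  if (!is.null(result$freqs)) out$freq <- result$freqs
  out
}
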