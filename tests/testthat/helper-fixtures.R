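# Shared fixture builders. Everything is generated in code at test time.

# Small maps-only cohort with one planted cluster (shift in map units).
tiny_map_cohort <- function(n_per_group = 10, shift = 0.2, cluster_size = 20,
                            grid = c(12, 14, 12), map_noise_sd = 0.1,
                            seed = 1) {
  bm <- make_brain_mask(grid)
  vox <- pick_cluster_voxels(bm, cluster_size)
  cfg <- cohort_config(
    n_group_a = n_per_group, n_group_b = n_per_group, grid_shape = grid,
    planted_clusters = if (shift != 0)
      list(list(voxels = vox, shift = shift)) else list(),
    map_noise_sd = map_noise_sd, include_timeseries = FALSE, seed = seed)
  co <- generate_cohort(cfg)
  list(cohort = co, voxels = vox,
       cluster_idx = vox[, 1] + grid[1] * (vox[, 2] - 1 + grid[2] * (vox[, 3] - 1)),
       maps = lapply(co$subjects, `[[`, "map"),
       ids = vapply(co$subjects, `[[`, "", "id"),
       groups = vapply(co$subjects, `[[`, "", "group"))
}

# Per-subject 90-region time series with group-specific planted correlations,
# built directly at region level (cheap stand-in for full 4-D cohorts when
# only connectivity matters). Returns a list of connectivity_matrix.
region_level_cohort <- function(n_per_group = 15, t_len = 135,
                                edges = list(list(i = 1, j = 2,
                                                  r_a = 0.8, r_b = 0.1)),
                                seed = 1) {
  set.seed(seed)
  groups <- rep(c("A", "B"), each = n_per_group)
  cms <- lapply(seq_along(groups), function(s) {
    x <- matrix(stats::rnorm(90 * t_len), nrow = 90)
    for (e in edges) {
      r <- if (groups[s] == "A") e$r_a else e$r_b
      f <- stats::rnorm(t_len)
      w <- sqrt(abs(r))
      x[e$i, ] <- w * f + sqrt(1 - abs(r)) * stats::rnorm(t_len)
      x[e$j, ] <- sign(r) * w * f + sqrt(1 - abs(r)) * stats::rnorm(t_len)
    }
    rts <- structure(list(matrix = x, region_labels = 1:90, tr_seconds = 3),
                     class = "region_timeseries")
    compute_connectivity(rts, subject_id = sprintf("sub-%03d", s))
  })
  list(cms = cms, groups = groups,
       ids = sprintf("sub-%03d", seq_along(groups)))
}

# Random symmetric nonnegative weight matrix (zero diagonal, no isolated node).
random_weight_matrix <- function(n) {
  w <- matrix(stats::runif(n * n), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# Brute-force flood fill (set-based, independent of label_components).
brute_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0) return(list())
  adj <- function(a, b) {
    dd <- abs(coords[a, ] - coords[b, ])
    if (connectivity == 6) sum(dd) == 1 else max(dd) == 1 && sum(dd) > 0
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      a <- stack[1]; stack <- stack[-1]
      for (b in seq_len(n)) {
        if (comp[b] == 0 && adj(a, b)) { comp[b] <- cur; stack <- c(stack, b) }
      }
    }
  }
  lapply(seq_len(cur), function(k) {
    v <- coords[comp == k, , drop = FALSE]
    sort(as.vector(v[, 1] + d[1] * (v[, 2] - 1 + d[2] * (v[, 3] - 1))))
  })
}
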