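#' Configuration for a synthetic two-group rs-fMRI cohort
#'
#' Describes a cohort of "preprocessed" 4-D volumes for two groups (A = aMCI,
#' B = HC) with known, planted ground-truth effects: cluster-level group mean
#' shifts in per-subject scalar maps, and group-specific correlation strengths
#' between pairs of the 90 atlas regions.
#'
#' @param n_group_a,n_group_b Number of subjects per group (each >= 2).
#'   Defaults follow the study design this package emulates (33 aMCI, 34 HC).
#' @param grid_shape Integer vector of 3 voxel dimensions, each >= 3.
#' @param n_timepoints Number of time points T acquired (default 140).
#' @param tr_seconds Repetition time in seconds (default 3).
#' @param planted_clusters List of planted map effects. Each element is a list
#'   with `voxels` (n x 3 integer matrix of voxel coordinates inside the brain
#'   mask), `shift` (group A minus group B mean difference, in map units) and
#'   optionally `cv` (target within-group coefficient of variation of the map
#'   values at those voxels, as a fraction of the group mean).
#' @param planted_edges List of planted connectivity effects. Each element is a
#'   list with `i`, `j` (region labels in 1..90) and `r_a`, `r_b` (target
#'   Pearson correlation of the two region time series in each group, each in
#'   (-1, 1)).
#' @param noise_sd Marginal standard deviation of the spatially smoothed
#'   time-series noise field.
#' @param map_baseline,map_noise_sd Mean and between-subject standard deviation
#'   of the per-subject scalar maps outside planted clusters. Map noise is
#'   voxelwise independent, so voxelwise null tests are exactly calibrated.
#' @param smooth_fwhm Full width at half maximum, in voxels, of the Gaussian
#'   spatial smoothing applied to the time-series noise field (default 2,
#'   mimicking smoothed rs-fMRI).
#' @param include_timeseries,include_maps Whether to generate 4-D volumes and
#'   per-subject scalar maps. Map-only cohorts are much cheaper and are enough
#'   for the voxel-space masking stages.
#' @param seed Integer seed; cohorts are bit-reproducible given the config.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_group_a = 33L, n_group_b = 34L,
                          grid_shape = c(24L, 28L, 24L),
                          n_timepoints = 140L, tr_seconds = 3,
                          planted_clusters = list(),
                          planted_edges = list(),
                          noise_sd = 1, map_baseline = 1, map_noise_sd = 0.1,
                          smooth_fwhm = 2,
                          include_timeseries = TRUE, include_maps = TRUE,
                          seed = 1L) {
  if (n_group_a < 2 || n_group_b < 2)
    stop("each group needs at least 2 subjects")
  if (length(grid_shape) != 3 || any(grid_shape < 3))
    stop("grid_shape must have 3 dimensions, each >= 3")
  if (n_timepoints < 3) stop("n_timepoints must be >= 3")
  if (tr_seconds <= 0 || noise_sd <= 0) stop("tr_seconds and noise_sd must be positive")
  for (pc in planted_clusters) {
    if (is.null(pc$voxels) || ncol(as.matrix(pc$voxels)) != 3)
      stop("each planted cluster needs an n x 3 `voxels` matrix")
    if (is.null(pc$shift)) stop("each planted cluster needs a `shift`")
  }
  if (length(planted_clusters) > 1) {
    keys <- unlist(lapply(planted_clusters, function(pc) {
      v <- as.matrix(pc$voxels)
      v[, 1] + grid_shape[1] * (v[, 2] - 1 + grid_shape[2] * (v[, 3] - 1))
    }))
    if (anyDuplicated(keys)) stop("planted cluster voxel sets must be disjoint")
  }
  for (pe in planted_edges) {
    if (is.null(pe$i) || is.null(pe$j) || pe$i == pe$j ||
        !all(c(pe$i, pe$j) %in% 1:90))
      stop("planted edges need distinct region labels i, j in 1..90")
    if (any(abs(c(pe$r_a, pe$r_b)) >= 1))
      stop("infeasible correlation target: |r| must be < 1 (got ",
           paste(c(pe$r_a, pe$r_b), collapse = ", "), ")")
  }
  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    grid_shape = as.integer(grid_shape), n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, planted_clusters = planted_clusters,
    planted_edges = planted_edges, noise_sd = noise_sd,
    map_baseline = map_baseline, map_noise_sd = map_noise_sd,
    smooth_fwhm = smooth_fwhm,
    include_timeseries = isTRUE(include_timeseries),
    include_maps = isTRUE(include_maps),
    seed = as.integer(seed)), class = "cohort_config")
}

#' Ellipsoidal brain mask centred in the grid
#'
#' The same mask [generate_cohort()] uses; exposed so that planted-cluster
#' voxel sets can be chosen inside the mask before building a config.
#'
#' @param grid_shape Integer vector of 3 voxel dimensions.
#' @return 3-D logical array.
#' @export
make_brain_mask <- function(grid_shape) {
  d <- grid_shape
  ctr <- (d + 1) / 2
  rad <- pmax(d / 2 - 0.5, 1)
  x <- (seq_len(d[1]) - ctr[1]) / rad[1]
  y <- (seq_len(d[2]) - ctr[2]) / rad[2]
  z <- (seq_len(d[3]) - ctr[3]) / rad[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(r2 <= 1, dim = d)
}

# Voronoi partition of the in-mask voxels around 90 seed voxels.
make_atlas <- function(brain_mask, n_regions = 90L) {
  idx <- which(brain_mask)
  if (length(idx) < n_regions)
    stop("brain mask too small for ", n_regions, " regions")
  coords <- arrayInd(idx, dim(brain_mask))
  seeds <- coords[sample.int(length(idx), n_regions), , drop = FALSE]
  # squared distance from every mask voxel to every seed
  d2 <- outer(coords[, 1], seeds[, 1], `-`)^2 +
        outer(coords[, 2], seeds[, 2], `-`)^2 +
        outer(coords[, 3], seeds[, 3], `-`)^2
  lab <- max.col(-d2, ties.method = "first")
  atlas <- array(0L, dim = dim(brain_mask))
  atlas[idx] <- lab
  atlas
}

# Separable Gaussian blur of a 3-D or 4-D array (4th axis untouched).
gaussian_smooth <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmin(pmax(i + seq(-half, half), 1L), n)
      for (q in seq_along(j)) S[i, j[q]] <- S[i, j[q]] + k[q]
    }
    S <- S / rowSums(S)
    perm <- c(axis, setdiff(seq_along(dim(a)), axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- S %*% matrix(ap, nrow = dp[1])
    ap <- array(m, dim = dp)
    aperm(ap, order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

#' Generate a synthetic two-group cohort with planted effects
#'
#' Subject time series are spatially smoothed Gaussian noise; planted
#' connectivity is injected by mixing a shared latent time series into the two
#' regions of each planted edge, with the mixing weights solved per subject
#' from the target correlation and the measured region-averaged noise
#' variance, so the population correlation of the two region means equals the
#' target. Per-subject scalar maps carry the planted cluster shifts exactly in
#' map units, with independent between-subject noise per voxel.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `subjects` (each
#'   with `id`, `group`, and optionally `volume` (4-D array) and `map` (3-D
#'   array)), `atlas`, `brain_mask`, `tr_seconds`, and `truth` echoing the
#'   planted effects.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  d <- config$grid_shape
  Tn <- config$n_timepoints
  brain_mask <- make_brain_mask(d)
  atlas <- make_atlas(brain_mask)
  n <- config$n_group_a + config$n_group_b
  groups <- rep(c("A", "B"), c(config$n_group_a, config$n_group_b))
  ids <- sprintf("sub-%03d", seq_len(n))

  cl_idx <- lapply(config$planted_clusters, function(pc) {
    v <- as.matrix(pc$voxels)
    i <- v[, 1] + d[1] * (v[, 2] - 1 + d[2] * (v[, 3] - 1))
    if (!all(brain_mask[i])) stop("planted cluster voxels must lie in the brain mask")
    i
  })
  region_idx <- lapply(1:90, function(g) which(atlas == g))

  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    sub <- list(id = ids[s], group = groups[s])
    if (config$include_maps) {
      m <- array(config$map_baseline +
                   config$map_noise_sd * stats::rnorm(prod(d)), dim = d)
      for (ci in seq_along(cl_idx)) {
        pc <- config$planted_clusters[[ci]]
        mu <- config$map_baseline + if (groups[s] == "A") pc$shift else 0
        if (!is.null(pc$cv)) {
          m[cl_idx[[ci]]] <- mu * (1 + pc$cv * stats::rnorm(length(cl_idx[[ci]])))
        } else {
          m[cl_idx[[ci]]] <- mu + config$map_noise_sd * stats::rnorm(length(cl_idx[[ci]]))
        }
      }
      m[!brain_mask] <- 0
      sub$map <- m
    }
    if (config$include_timeseries) {
      vol <- array(stats::rnorm(prod(d) * Tn), dim = c(d, Tn))
      vol <- gaussian_smooth(vol, config$smooth_fwhm)
      vol <- vol * (config$noise_sd / stats::sd(vol))
      flat <- matrix(vol, nrow = prod(d))  # voxels x T view
      # planted edges: latent-factor construction on region-averaged noise
      for (pe in config$planted_edges) {
        r <- if (groups[s] == "A") pe$r_a else pe$r_b
        if (r == 0) next
        vi <- region_idx[[pe$i]]; vj <- region_idx[[pe$j]]
        ni <- colMeans(flat[vi, , drop = FALSE])
        nj <- colMeans(flat[vj, , drop = FALSE])
        s2 <- max(stats::var(ni), stats::var(nj))
        # signal variance a2 and factor loading rho solving
        # a2 * rho = |r| * (s2 + a2) with rho = (1 + |r|) / 2
        a2 <- 2 * abs(r) * s2 / (1 - abs(r))
        a2 <- max(a2, s2)  # keep the signal from degenerating when r is tiny
        rho <- abs(r) * sqrt((stats::var(ni) + a2) * (stats::var(nj) + a2)) / a2
        rho <- min(rho, 1 - 1e-9)
        f  <- stats::rnorm(Tn); ui <- stats::rnorm(Tn); uj <- stats::rnorm(Tn)
        w <- sqrt(rho)
        ai <- sqrt(a2) * (w * f + sqrt(1 - rho) * ui)
        aj <- sign(r) * sqrt(a2) * (w * f) + sqrt(a2 * (1 - rho)) * uj
        flat[vi, ] <- flat[vi, ] + rep(ai, each = length(vi))
        flat[vj, ] <- flat[vj, ] + rep(aj, each = length(vj))
      }
      # planted clusters leave a coherent low-frequency trace in group A
      for (ci in seq_along(cl_idx)) {
        pc <- config$planted_clusters[[ci]]
        if (groups[s] != "A" || pc$shift == 0) next
        tt <- seq_len(Tn) * config$tr_seconds
        sig <- abs(pc$shift) * config$noise_sd *
          sin(2 * pi * 0.03 * tt + stats::runif(1, 0, 2 * pi))
        flat[cl_idx[[ci]], ] <- flat[cl_idx[[ci]], ] +
          rep(sig, each = length(cl_idx[[ci]]))
      }
      flat[!brain_mask, ] <- 0
      sub$volume <- array(flat, dim = c(d, Tn))
    }
    subjects[[s]] <- sub
  }
  structure(list(subjects = subjects, atlas = atlas, brain_mask = brain_mask,
                 tr_seconds = config$tr_seconds,
                 truth = list(planted_clusters = config$planted_clusters,
                              planted_edges = config$planted_edges),
                 config = config),
            class = "synthetic_cohort")
}

#' Discard the first k time points of a 4-D volume
#'
#' Scanner signal at the start of an acquisition is unstable, so the standard
#' practice is to drop the leading volumes (5 of 140 in the emulated design).
#'
#' @param volume 4-D array (X, Y, Z, T).
#' @param k Number of leading time points to discard; must be < T.
#' @return The trailing T - k volumes, order preserved.
#' @export
drop_initial_timepoints <- function(volume, k) {
  stopifnot(length(dim(volume)) == 4)
  Tn <- dim(volume)[4]
  if (k < 0) stop("k must be nonnegative")
  if (k >= Tn) stop("cannot drop ", k, " of ", Tn, " time points")
  if (k == 0) return(volume)
  volume[, , , (k + 1):Tn, drop = FALSE]
}

#' Pick a contiguous in-mask voxel block for planting a cluster
#'
#' Convenience for building `planted_clusters`: grows a connected set of
#' `size` voxels around an in-mask anchor by breadth-first search over
#' 6-neighbours.
#'
#' @param brain_mask 3-D logical array.
#' @param size Number of voxels wanted.
#' @param anchor Optional voxel coordinate to grow from (defaults to the mask
#'   centroid voxel).
#' @return A `size` x 3 integer matrix of voxel coordinates.
#' @export
pick_cluster_voxels <- function(brain_mask, size, anchor = NULL) {
  d <- dim(brain_mask)
  idx <- which(brain_mask)
  if (length(idx) < size) stop("mask smaller than requested cluster")
  if (is.null(anchor)) {
    coords <- arrayInd(idx, d)
    ctr <- round(colMeans(coords))
    anchor_i <- idx[which.min(colSums((t(coords) - ctr)^2))]
  } else {
    anchor_i <- anchor[1] + d[1] * (anchor[2] - 1 + d[2] * (anchor[3] - 1))
    if (!brain_mask[anchor_i]) stop("anchor outside brain mask")
  }
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  chosen <- anchor_i
  frontier <- anchor_i
  while (length(chosen) < size && length(frontier) > 0) {
    fc <- arrayInd(frontier, d)
    cand <- unique(unlist(lapply(seq_len(nrow(offs)), function(o) {
      v <- sweep(fc, 2, offs[o, ], `+`)
      ok <- v[, 1] >= 1 & v[, 1] <= d[1] & v[, 2] >= 1 & v[, 2] <= d[2] &
            v[, 3] >= 1 & v[, 3] <= d[3]
      v <- v[ok, , drop = FALSE]
      v[, 1] + d[1] * (v[, 2] - 1 + d[2] * (v[, 3] - 1))
    })))
    cand <- setdiff(cand[brain_mask[cand]], chosen)
    take <- utils::head(cand, size - length(chosen))
    chosen <- c(chosen, take)
    frontier <- take
  }
  if (length(chosen) < size) stop("could not grow a connected cluster of that size")
  arrayInd(chosen, d)
}
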