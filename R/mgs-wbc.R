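# MGS-WBC: within-class volatility detection (coefficient of variation) plus
# dual significance-band masks (0.001 < p < 0.05 intersected with low
# volatility, and p < 0.001), over voxel maps or connectivity edges.

EPS_MEAN <- 1e-8

#' Variable coefficient (within-group coefficient of variation, percent)
#'
#' VC = sqrt(sum_i (x_i - xbar)^2 / n) / xbar * 100, with the population
#' divisor n. Undefined (NA) when |xbar| < 1e-8; since ReHo/ALFF values are
#' positive this guard rarely triggers in practice.
#'
#' @param values Numeric vector of one group's values at a single feature
#'   location (n >= 2).
#' @return VC in percent, or NA if the mean is numerically zero.
#' @export
variable_coefficient <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  if (abs(m) < EPS_MEAN) return(NA_real_)
  sqrt(sum((values - m)^2) / n) / m * 100
}

#' Per-feature VC maps for the two groups
#'
#' @param values Numeric matrix, subjects x features.
#' @param groups Factor or character vector of "A"/"B" per subject.
#' @return List with `vc_a` and `vc_b`, each a numeric vector over features
#'   (NA where the group mean is numerically zero).
#' @export
vc_map <- function(values, groups) {
  stopifnot(nrow(values) == length(groups))
  one <- function(x) {
    m <- colMeans(x)
    vc <- sqrt(colMeans(sweep(x, 2, m)^2)) / m * 100
    vc[abs(m) < EPS_MEAN] <- NA_real_
    vc
  }
  list(vc_a = one(values[groups == "A", , drop = FALSE]),
       vc_b = one(values[groups == "B", , drop = FALSE]))
}

#' Volatility mask: lowest-VC fraction within each group
#'
#' Ranks the defined VC values of each group ascending and keeps the lowest
#' floor(fraction * N_defined); the returned mask combines the two groups'
#' keep-sets (intersection by default, union behind the flag).
#'
#' @param vc_a,vc_b VC vectors over the same feature space.
#' @param fraction Fraction of features to keep per group (default 0.05).
#' @param combine `"intersection"` (default) or `"union"`.
#' @return Logical vector over the feature space.
#' @export
volatility_mask <- function(vc_a, vc_b, fraction = 0.05,
                            combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  stopifnot(length(vc_a) == length(vc_b), fraction > 0, fraction < 1)
  keep_set <- function(vc) {
    def <- which(!is.na(vc))
    if (length(def) == 0) stop("all VC values are undefined")
    k <- floor(fraction * length(def))
    out <- logical(length(vc))
    if (k > 0) out[def[order(vc[def])][seq_len(k)]] <- TRUE
    out
  }
  ka <- keep_set(vc_a)
  kb <- keep_set(vc_b)
  if (combine == "intersection") ka & kb else ka | kb
}

#' Two-sample Student t-test (pooled variance, two-sided)
#'
#' Sign convention: t > 0 when mean(A) > mean(B), i.e. aMCI minus HC.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `p` and `df`.
#' @export
two_sample_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("need at least 2 values per group")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / df
  dm <- mean(group_a) - mean(group_b)
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, p = 1, df = df))
    stop("zero pooled variance with unequal means")
  }
  t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Vectorized pooled two-sample t over feature columns
#'
#' @param values Numeric matrix, subjects x features.
#' @param groups "A"/"B" per subject.
#' @return List with numeric vectors `t` and `p` over features.
#' @export
group_t_test <- function(values, groups) {
  a <- values[groups == "A", , drop = FALSE]
  b <- values[groups == "B", , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) stop("need at least 2 subjects per group")
  df <- na + nb - 2
  va <- colSums(sweep(a, 2, colMeans(a))^2)
  vb <- colSums(sweep(b, 2, colMeans(b))^2)
  sp2 <- (va + vb) / df
  dm <- colMeans(a) - colMeans(b)
  t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  t[sp2 == 0 & dm == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df)
}

#' Assemble the dual significance masks
#'
#' `strict` is the traditional single-threshold mask {p < 0.001}; `band` is
#' {0.001 < p < 0.05} intersected with the volatility mask. The two are
#' disjoint by construction and are used together for feature extraction.
#'
#' @param t_map,p_map Numeric vectors/arrays over the feature space.
#' @param volatility Logical array from [volatility_mask()].
#' @param strict_p,band_p The two significance thresholds (0.001 and 0.05).
#' @return A `mask_set`: list with `volatility`, `band`, `strict`, `t_map`,
#'   `p_map`.
#' @export
build_masks <- function(t_map, p_map, volatility,
                        strict_p = 0.001, band_p = 0.05) {
  stopifnot(length(t_map) == length(p_map),
            length(p_map) == length(volatility),
            strict_p < band_p)
  strict <- p_map < strict_p
  band <- (p_map > strict_p & p_map < band_p) & volatility
  structure(list(volatility = volatility, band = band, strict = strict,
                 t_map = t_map, p_map = p_map),
            class = "mask_set")
}

# Connected-component labelling of a 3-D logical array (6- or 26-connectivity).
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  labels <- array(0L, dim = d)
  todo <- which(mask)
  cur <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0) {
      co <- arrayInd(queue, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
        sweep(co, 2, offs[o, ], `+`)))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      li <- unique(nb[, 1] + d[1] * (nb[, 2] - 1 + d[2] * (nb[, 3] - 1)))
      li <- li[mask[li] & labels[li] == 0L]
      labels[li] <- cur
      queue <- li
    }
  }
  labels
}

#' Extract suprathreshold clusters from a voxel mask
#'
#' Connected components under 26-connectivity (6 behind the flag); components
#' smaller than `min_cluster` voxels are dropped. Each surviving cluster is
#' reported with its peak (the in-cluster voxel of maximum |t|), the atlas
#' region at the peak, the peak t-score and the cluster size.
#'
#' @param mask 3-D logical array (voxel space only; edge masks are never
#'   clustered).
#' @param t_map 3-D numeric array of t-scores.
#' @param atlas 3-D integer label array.
#' @param min_cluster Minimum cluster extent in voxels (default 5).
#' @param connectivity 26 (default) or 6.
#' @param region_names Optional character vector mapping atlas label g to a
#'   region name; defaults to "region_g".
#' @return List with `table` (data.frame: Cluster, Region, Peak_x, Peak_y,
#'   Peak_z, t_score, Cluster_size) and `voxels` (list of linear voxel indices
#'   per cluster, same order as the table).
#' @export
extract_clusters <- function(mask, t_map, atlas, min_cluster = 5,
                             connectivity = 26, region_names = NULL) {
  stopifnot(length(dim(mask)) == 3, all(dim(t_map) == dim(mask)))
  labels <- label_components(mask, connectivity)
  ncomp <- max(labels)
  rows <- list()
  voxels <- list()
  for (cid in seq_len(ncomp)) {
    vi <- which(labels == cid)
    if (length(vi) < min_cluster) next
    peak <- vi[which.max(abs(t_map[vi]))]
    pc <- arrayInd(peak, dim(mask))
    g <- atlas[peak]
    nm <- if (!is.null(region_names) && g >= 1 && g <= length(region_names))
      region_names[g] else sprintf("region_%02d", g)
    rows[[length(rows) + 1]] <- data.frame(
      Cluster = length(rows) + 1L, Region = nm,
      Peak_x = pc[1], Peak_y = pc[2], Peak_z = pc[3],
      t_score = t_map[peak], Cluster_size = length(vi),
      stringsAsFactors = FALSE)
    voxels[[length(voxels) + 1]] <- vi
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(Cluster = integer(), Region = character(),
               Peak_x = integer(), Peak_y = integer(), Peak_z = integer(),
               t_score = numeric(), Cluster_size = integer(),
               stringsAsFactors = FALSE)
  list(table = table, voxels = voxels)
}

# Build a feature table skeleton (subject_id + group) and attach provenance.
new_feature_table <- function(subject_ids, groups, features, provenance) {
  stopifnot(is.null(features) || nrow(features) == length(subject_ids))
  df <- data.frame(subject_id = subject_ids, group = groups,
                   stringsAsFactors = FALSE)
  if (!is.null(features) && ncol(features) > 0) {
    if (anyDuplicated(colnames(features))) stop("duplicate feature names")
    if (anyNA(features)) stop("feature table contains missing values")
    df <- cbind(df, as.data.frame(features))
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Run MGS-WBC on per-subject scalar maps
#'
#' Computes per-group VC maps over in-mask voxels, the volatility mask, the
#' voxelwise pooled t-test, the dual significance masks, cluster extraction in
#' each mask, and the per-subject cluster-mean features.
#'
#' @param maps List of 3-D arrays (or `feature_map`s), one per subject.
#' @param subject_ids,groups Per-subject identifier and "A"/"B" label.
#' @param brain_mask 3-D logical array.
#' @param atlas 3-D integer label array.
#' @param kind Short tag ("reho"/"alff") used in feature names.
#' @param fraction Volatility keep fraction (default 0.05).
#' @param min_cluster Minimum cluster size (default 5).
#' @param combine Volatility combination across groups (see
#'   [volatility_mask()]).
#' @param region_names Optional atlas region names.
#' @return List with `mask_set` (arrays in voxel space), `clusters_band`,
#'   `clusters_strict` (see [extract_clusters()]), and `features` (a
#'   `feature_table`: band clusters then strict clusters, cluster means).
#' @export
mgswbc_maps <- function(maps, subject_ids, groups, brain_mask, atlas,
                        kind = "map", fraction = 0.05, min_cluster = 5,
                        combine = "intersection", region_names = NULL) {
  midx <- which(brain_mask)
  vals <- do.call(rbind, lapply(maps, function(m) {
    if (inherits(m, "feature_map")) m <- m$values
    m[midx]
  }))
  vc <- vc_map(vals, groups)
  vol <- volatility_mask(vc$vc_a, vc$vc_b, fraction, combine)
  tt <- group_t_test(vals, groups)
  ms <- build_masks(tt$t, tt$p, vol)
  to3 <- function(v, fill = 0) {
    a <- array(fill, dim = dim(brain_mask)); a[midx] <- v; a
  }
  t3 <- to3(tt$t); p3 <- to3(tt$p, fill = 1)
  band3 <- to3(ms$band, fill = FALSE); strict3 <- to3(ms$strict, fill = FALSE)
  cb <- extract_clusters(band3, t3, atlas, min_cluster, region_names = region_names)
  cs <- extract_clusters(strict3, t3, atlas, min_cluster, region_names = region_names)
  feat <- NULL
  prov <- character()
  cols <- list()
  add_clusters <- function(cl, tag) {
    for (k in seq_along(cl$voxels)) {
      nm <- sprintf("%s_%s_c%d", kind, tag, k)
      cols[[nm]] <<- vapply(maps, function(m) {
        if (inherits(m, "feature_map")) m <- m$values
        mean(m[cl$voxels[[k]]])
      }, numeric(1))
      prov[nm] <<- sprintf("%s cluster mean | mask=%s | region=%s | size=%d",
                           kind, tag, cl$table$Region[k], cl$table$Cluster_size[k])
    }
  }
  add_clusters(cb, "band")
  add_clusters(cs, "strict")
  feat <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = length(maps), ncol = 0)
  masks3 <- structure(list(volatility = to3(ms$volatility, fill = FALSE),
                           band = band3, strict = strict3,
                           t_map = t3, p_map = p3), class = "mask_set")
  list(mask_set = masks3, clusters_band = cb, clusters_strict = cs,
       features = new_feature_table(subject_ids, groups, feat, prov))
}

# Upper-triangle index pairs of an n x n matrix, row-major over i < j.
upper_triangle_pairs <- function(n = 90) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

#' Run MGS-WBC on connectivity edges
#'
#' Flattens each subject's 90 x 90 matrix to its 4,005 upper-triangle edges,
#' then applies the same volatility + dual-threshold selection as for voxel
#' maps. No cluster thresholding is applied to edges; each selected edge
#' contributes the subject's signed correlation as one feature.
#'
#' @param cms List of `connectivity_matrix` (or plain 90 x 90 matrices).
#' @param subject_ids,groups Per-subject identifier and "A"/"B" label.
#' @param fraction,combine Volatility parameters (see [volatility_mask()]).
#' @return List with `mask_set` (vectors over the 4,005 edges), `edges`
#'   (data.frame region_i, region_j, mask, vc_a, vc_b, t, p, one row per
#'   selected edge: band rows first), and `features` (a `feature_table`).
#' @export
mgswbc_edges <- function(cms, subject_ids, groups, fraction = 0.05,
                         combine = "intersection") {
  pairs <- upper_triangle_pairs(90)
  vals <- do.call(rbind, lapply(cms, function(cm) {
    r <- if (inherits(cm, "connectivity_matrix")) cm$r else cm
    r[pairs]
  }))
  vc <- vc_map(vals, groups)
  vol <- volatility_mask(vc$vc_a, vc$vc_b, fraction, combine)
  tt <- group_t_test(vals, groups)
  ms <- build_masks(tt$t, tt$p, vol)
  sel <- c(which(ms$band), which(ms$strict))
  mask_tag <- rep(c("band", "strict"), c(sum(ms$band), sum(ms$strict)))
  edges <- data.frame(region_i = pairs[sel, 1], region_j = pairs[sel, 2],
                      mask = mask_tag, vc_a = vc$vc_a[sel], vc_b = vc$vc_b[sel],
                      t = tt$t[sel], p = tt$p[sel], stringsAsFactors = FALSE)
  feat <- vals[, sel, drop = FALSE]
  nms <- sprintf("edge_%d_%d_%s", pairs[sel, 1], pairs[sel, 2], mask_tag)
  colnames(feat) <- nms
  prov <- stats::setNames(
    sprintf("edge r | mask=%s | regions=(%d,%d)", mask_tag,
            pairs[sel, 1], pairs[sel, 2]), nms)
  list(mask_set = ms, edges = edges,
       features = new_feature_table(subject_ids, groups, feat, prov))
}
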