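test_that("variable coefficient matches its definition and guards", {
  expect_equal(variable_coefficient(c(2, 2, 2, 2)), 0)
  expect_equal(variable_coefficient(1:4), sqrt(5 / 4) / 2.5 * 100,
               tolerance = 1e-12)
  expect_equal(round(variable_coefficient(1:4), 2), 44.72)
  expect_true(is.na(variable_coefficient(c(-1, 1, -1, 1))))
  expect_error(variable_coefficient(3), "at least 2")
})

test_that("VC implementation matches brute-force arithmetic to 1e-12", {
  set.seed(10)
  brute <- function(x) {
    n <- length(x); xb <- sum(x) / n
    s <- 0
    for (xi in x) s <- s + (xi - xb)^2
    sqrt(s / n) / xb * 100
  }
  for (rep in 1:200) {
    x <- stats::runif(sample(2:20, 1), 0.5, 10)
    expect_equal(variable_coefficient(x), brute(x), tolerance = 1e-12)
  }
  # matrix form agrees with the scalar form per column and group
  vals <- matrix(stats::runif(8 * 6, 0.5, 2), nrow = 8)
  groups <- rep(c("A", "B"), each = 4)
  vm <- vc_map(vals, groups)
  expect_equal(vm$vc_a[3], variable_coefficient(vals[1:4, 3]))
  expect_equal(vm$vc_b[6], variable_coefficient(vals[5:8, 6]))
})

test_that("volatility mask keeps the lowest fraction and combines groups", {
  vc <- as.numeric(1:100)
  expect_equal(sum(volatility_mask(vc, vc, 0.05)), 5)
  expect_true(all(which(volatility_mask(vc, vc, 0.05)) == 1:5))
  # disjoint lowest-5% sets: intersection empty, union has both
  vc2 <- rev(vc)
  expect_equal(sum(volatility_mask(vc, vc2, 0.05)), 0)
  expect_equal(sum(volatility_mask(vc, vc2, 0.05, combine = "union")), 10)
  set.seed(4)
  va <- stats::runif(4005); vb <- stats::runif(4005)
  expect_lte(sum(volatility_mask(va, vb, 0.05)), floor(0.05 * 4005))
  # NA (undefined) entries never enter the keep-set
  va[1:100] <- NA
  m <- volatility_mask(va, vb, 0.05)
  expect_true(all(!m[1:100]))
  expect_error(volatility_mask(rep(NA_real_, 5), vb[1:5]), "undefined")
})

test_that("pooled two-sample t matches the reference implementation", {
  out <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(out$p, ref$p.value, tolerance = 1e-10)
  expect_equal(out$df, 4)
  expect_equal(out$t, -3.674, tolerance = 1e-3)
  swapped <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -out$t)
  expect_equal(swapped$p, out$p)
  same <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(two_sample_t(c(2, 2), c(3, 3)), "unequal means")
  # vectorized form agrees with t.test column by column
  set.seed(5)
  vals <- matrix(stats::rnorm(12 * 7), nrow = 12)
  groups <- rep(c("A", "B"), c(5, 7))
  tt <- group_t_test(vals, groups)
  for (j in c(1, 4, 7)) {
    ref <- stats::t.test(vals[groups == "A", j], vals[groups == "B", j],
                         var.equal = TRUE)
    expect_equal(tt$t[j], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tt$p[j], ref$p.value, tolerance = 1e-10)
  }
})

test_that("dual masks partition the significance scale and need volatility", {
  p <- c(0.5, 0.0005, 0.01, 0.01, 0.04, 1e-6)
  vol <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  ms <- build_masks(t_map = seq_along(p), p_map = p, volatility = vol)
  expect_false(any(ms$band & ms$strict))
  expect_equal(which(ms$strict), c(2, 6))
  expect_equal(which(ms$band), c(4, 5))
  all_ns <- build_masks(rep(0, 4), rep(0.5, 4), rep(TRUE, 4))
  expect_false(any(all_ns$band | all_ns$strict))
})

test_that("cluster extraction matches brute-force flood fill", {
  set.seed(6)
  for (rep in 1:5) {
    mask <- array(stats::runif(5 * 5 * 5) < 0.25, dim = c(5, 5, 5))
    tmap <- array(stats::rnorm(125), dim = c(5, 5, 5))
    atlas <- array(sample(1:90, 125, replace = TRUE), dim = c(5, 5, 5))
    got <- extract_clusters(mask, tmap, atlas, min_cluster = 1)
    want <- brute_components(mask)
    expect_equal(length(got$voxels), length(want))
    expect_setequal(lapply(got$voxels, function(v) as.numeric(sort(v))),
                    lapply(want, as.numeric))
  }
})

test_that("clusters below the size threshold are dropped, peak is max |t|", {
  mask <- array(FALSE, c(8, 8, 8))
  mask[1:2, 1:3, 1] <- TRUE           # 2 x 3 x 1 block: size 6
  mask[7, 7, 6:8] <- TRUE             # isolated 3-voxel line: dropped
  tmap <- array(0, c(8, 8, 8))
  tmap[1:2, 1:3, 1] <- c(1, -5, 2, 3, 0.5, 1)
  tmap[7, 7, 6:8] <- 9
  atlas <- array(1L, c(8, 8, 8))
  out <- extract_clusters(mask, tmap, atlas, min_cluster = 5)
  expect_equal(nrow(out$table), 1)
  expect_equal(out$table$Cluster_size, 6)
  expect_equal(out$table$t_score, -5)
  expect_equal(unlist(out$table[1, c("Peak_x", "Peak_y", "Peak_z")],
                      use.names = FALSE), c(2, 1, 1))
  # report schema mirrors the published cluster-table layout
  expect_named(out$table, c("Cluster", "Region", "Peak_x", "Peak_y", "Peak_z",
                            "t_score", "Cluster_size"))
})

test_that("map feature extraction yields one column per surviving cluster", {
  fx <- tiny_map_cohort(n_per_group = 10, shift = 0.3, cluster_size = 24,
                        seed = 8)
  mg <- mgswbc_maps(fx$maps, fx$ids, fx$groups, fx$cohort$brain_mask,
                    fx$cohort$atlas, kind = "reho")
  n_band <- length(mg$clusters_band$voxels)
  n_strict <- length(mg$clusters_strict$voxels)
  expect_equal(ncol(mg$features) - 2, n_band + n_strict)
  expect_gte(n_strict, 1)
  # feature values are the cluster means of each subject's map
  v1 <- mg$clusters_strict$voxels[[1]]
  nm <- sprintf("reho_strict_c%d", 1)
  expect_equal(mg$features[[nm]][3], mean(fx$maps[[3]][v1]))
  expect_false(any(mg$mask_set$band & mg$mask_set$strict))
  prov <- attr(mg$features, "provenance")
  expect_equal(length(prov), n_band + n_strict)
})

test_that("edge-level selection finds planted edges and tags provenance", {
  fx <- region_level_cohort(n_per_group = 15,
                            edges = list(list(i = 7, j = 30,
                                              r_a = 0.8, r_b = 0.1)),
                            seed = 9)
  eg <- mgswbc_edges(fx$cms, fx$ids, fx$groups)
  expect_true(any(eg$edges$region_i == 7 & eg$edges$region_j == 30))
  hit <- which(eg$edges$region_i == 7 & eg$edges$region_j == 30)
  expect_equal(eg$edges$mask[hit], "strict")
  expect_equal(ncol(eg$features) - 2, nrow(eg$edges))
  # edge feature is the subject's signed r at that edge
  nm <- sprintf("edge_7_30_%s", eg$edges$mask[hit])
  expect_equal(eg$features[[nm]][2], fx$cms[[2]]$r[7, 30])
})

test_that("empty masks give a valid zero-column feature table", {
  fx <- tiny_map_cohort(n_per_group = 5, shift = 0, grid = c(8, 8, 8),
                        seed = 12)
  mg <- mgswbc_maps(fx$maps, fx$ids, fx$groups, fx$cohort$brain_mask,
                    fx$cohort$atlas, kind = "alff", min_cluster = 50)
  expect_equal(ncol(mg$features), 2)
  expect_s3_class(mg$features, "feature_table")
})
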