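# Formats, configuration and the umbrella pipeline: simulate-or-load ->
# feature maps -> MGS-WBC -> VGBN-LM -> fuse -> LOOCV classification.

GROUP_LABELS <- c(A = "aMCI", B = "HC")

#' Write a synthetic cohort to disk
#'
#' One 4-D NIfTI per subject (when time series are present), per-subject map
#' NIfTIs (when maps are present), atlas and brain mask NIfTIs, a
#' `labels.csv` (subject_id, group) and the planted truth as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wn <- function(x, name) {
    p <- file.path(dir, name)
    RNifti::writeNifti(RNifti::asNifti(x), p)
    files <<- c(files, p)
  }
  wn(cohort$atlas, "atlas.nii.gz")
  wn(cohort$brain_mask + 0L, "brain_mask.nii.gz")
  for (s in cohort$subjects) {
    if (!is.null(s$volume)) wn(s$volume, sprintf("%s_bold.nii.gz", s$id))
    if (!is.null(s$map)) wn(s$map, sprintf("%s_map.nii.gz", s$id))
  }
  lab <- data.frame(subject_id = vapply(cohort$subjects, `[[`, "", "id"),
                    group = vapply(cohort$subjects, `[[`, "", "group"))
  p <- file.path(dir, "labels.csv")
  utils::write.csv(lab, p, row.names = FALSE)
  files <- c(files, p)
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(rapply(cohort$truth, unclass, how = "replace"), p,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- c(files, p)
  invisible(files)
}

#' Load a cohort from a directory written by [write_cohort()]
#'
#' @param dir Directory with `labels.csv`, `atlas.nii.gz`, `brain_mask.nii.gz`
#'   and per-subject `<id>_bold.nii.gz` and/or `<id>_map.nii.gz`.
#' @param tr_seconds Repetition time of the stored volumes.
#' @return A `synthetic_cohort`-shaped list (without `truth` unless stored).
#' @export
load_cohort <- function(dir, tr_seconds = 3) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         colClasses = "character")
  atlas <- array(as.integer(RNifti::readNifti(file.path(dir, "atlas.nii.gz"))),
                 dim = dim(RNifti::readNifti(file.path(dir, "atlas.nii.gz"))))
  mask <- RNifti::readNifti(file.path(dir, "brain_mask.nii.gz"))
  brain_mask <- array(as.numeric(mask) > 0, dim = dim(mask))
  subjects <- lapply(seq_len(nrow(lab)), function(i) {
    s <- list(id = lab$subject_id[i], group = lab$group[i])
    bp <- file.path(dir, sprintf("%s_bold.nii.gz", s$id))
    mp <- file.path(dir, sprintf("%s_map.nii.gz", s$id))
    if (file.exists(bp)) {
      v <- RNifti::readNifti(bp)
      s$volume <- array(as.numeric(v), dim = dim(v))
    }
    if (file.exists(mp)) {
      m <- RNifti::readNifti(mp)
      s$map <- array(as.numeric(m), dim = dim(m))
    }
    s
  })
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  structure(list(subjects = subjects, atlas = atlas, brain_mask = brain_mask,
                 tr_seconds = tr_seconds, truth = truth),
            class = "synthetic_cohort")
}

#' Write a connectivity matrix as CSV (90 x 90 with region-label header)
#' @param cm A `connectivity_matrix` or plain matrix.
#' @param path Output CSV path.
#' @export
write_connectivity_csv <- function(cm, path) {
  r <- if (inherits(cm, "connectivity_matrix")) cm$r else cm
  df <- as.data.frame(r)
  colnames(df) <- sprintf("region_%02d", seq_len(ncol(r)))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read a connectivity matrix written by [write_connectivity_csv()]
#' @param path CSV path.
#' @return A `connectivity_matrix`.
#' @export
read_connectivity_csv <- function(path) {
  r <- as.matrix(utils::read.csv(path))
  dimnames(r) <- NULL
  structure(list(r = r, subject_id = NULL), class = "connectivity_matrix")
}

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] used when no `input_dir` is given.
#' @param input_dir Optional directory of an existing cohort
#'   ([load_cohort()] format); overrides `cohort`.
#' @param drop_timepoints Leading time points to discard (default 5).
#' @param band Bandpass in Hz (default 0.01-0.08).
#' @param fraction Volatility keep fraction (default 0.05).
#' @param strict_p,band_p Significance thresholds (defaults 0.001 and 0.05).
#' @param min_cluster Minimum cluster size in voxels (default 5).
#' @param alpha Global-feature selection threshold (default 0.05).
#' @param classifiers Which classifiers to evaluate.
#' @param methods Which method variants to evaluate (subset of "SSW",
#'   "MGS-WBC", "FUSE").
#' @param combine Volatility combination ("intersection" or "union").
#' @param use_cohort_maps Use per-subject maps stored in the cohort as the
#'   scalar-map channel when present (default TRUE); otherwise ReHo and ALFF
#'   are computed from the 4-D data.
#' @param seed Seed for the generation stage.
#' @param out Optional output directory for artifacts and the manifest.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), input_dir = NULL,
                            drop_timepoints = 5, band = c(0.01, 0.08),
                            fraction = 0.05, strict_p = 0.001, band_p = 0.05,
                            min_cluster = 5, alpha = 0.05,
                            classifiers = c("nb", "lda", "lr", "svm"),
                            methods = c("SSW", "MGS-WBC", "FUSE"),
                            combine = "intersection",
                            use_cohort_maps = TRUE, seed = 1L, out = NULL) {
  if (!(strict_p > 0 && strict_p < band_p && band_p < 1))
    stop("thresholds must satisfy 0 < strict_p < band_p < 1")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  stopifnot(all(classifiers %in% c("nb", "lda", "lr", "svm")),
            all(methods %in% c("SSW", "MGS-WBC", "FUSE")))
  structure(list(cohort = cohort, input_dir = input_dir,
                 drop_timepoints = drop_timepoints, band = band,
                 fraction = fraction, strict_p = strict_p, band_p = band_p,
                 min_cluster = min_cluster, alpha = alpha,
                 classifiers = classifiers, methods = methods,
                 combine = combine,
                 use_cohort_maps = isTRUE(use_cohort_maps),
                 seed = as.integer(seed), out = out),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [pipeline_config()];
#' a `cohort:` block holds [cohort_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, if (is.null(y$cohort)) list() else y$cohort)
  y$cohort <- NULL
  do.call(pipeline_config, c(list(cohort = cohort), y))
}

# strict-only (traditional single-threshold) columns of a feature table
strict_columns <- function(tb) {
  keep <- c("subject_id", "group",
            grep("_strict", colnames(tb), value = TRUE))
  out <- tb[, keep, drop = FALSE]
  attr(out, "provenance") <- attr(tb, "provenance")[grep("_strict",
                                                         names(attr(tb, "provenance")))]
  class(out) <- class(tb)
  out
}

has_features <- function(tb) ncol(tb) > 2

#' Run the full diagnosis pipeline
#'
#' Generates (or loads) the cohort, computes the per-subject representations,
#' applies MGS-WBC to every scalar-map channel and to the connectivity edges,
#' extracts the global network vectors with VGBN-LM, fuses the feature sets
#' and evaluates each requested classifier under LOOCV for three method
#' variants: `SSW` (single strict threshold p < 0.001 only), `MGS-WBC` (dual
#' masks) and `FUSE` (dual masks plus the selected global-vector entries).
#'
#' @param config A [pipeline_config()].
#' @return List with `report` (data.frame Classifier, Method, ACC, F1_Score,
#'   AUC), `details` (per-stage objects) and, when `config$out` is set,
#'   `manifest` (also written to disk with every artifact).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  cohort <- if (!is.null(config$input_dir)) load_cohort(config$input_dir)
            else {
              cc <- config$cohort; cc$seed <- config$seed
              generate_cohort(cc)
            }
  ids <- vapply(cohort$subjects, `[[`, "", "id")
  groups <- vapply(cohort$subjects, `[[`, "", "group")
  tr <- cohort$tr_seconds
  have_vol <- !is.null(cohort$subjects[[1]]$volume)
  have_map <- !is.null(cohort$subjects[[1]]$map) && config$use_cohort_maps

  channels <- list()
  cms <- NULL
  if (have_vol) {
    reho <- vector("list", length(ids)); alff <- vector("list", length(ids))
    cms <- vector("list", length(ids))
    for (i in seq_along(cohort$subjects)) {
      vol <- drop_initial_timepoints(cohort$subjects[[i]]$volume,
                                     config$drop_timepoints)
      bp <- bandpass_filter(vol, config$band[1], config$band[2], tr)
      reho[[i]] <- compute_reho(bp, cohort$brain_mask, subject_id = ids[i])
      alff[[i]] <- compute_alff(vol, cohort$brain_mask, config$band, tr,
                                subject_id = ids[i])
      rts <- extract_region_timeseries(bp, cohort$atlas, tr)
      cms[[i]] <- compute_connectivity(rts, subject_id = ids[i])
    }
    channels$reho <- reho
    channels$alff <- alff
  }
  if (have_map) channels$map <- lapply(cohort$subjects, `[[`, "map")
  if (length(channels) == 0) stop("cohort provides neither volumes nor maps")

  mg <- lapply(names(channels), function(kind)
    mgswbc_maps(channels[[kind]], ids, groups, cohort$brain_mask,
                cohort$atlas, kind = kind, fraction = config$fraction,
                min_cluster = config$min_cluster, combine = config$combine))
  names(mg) <- names(channels)

  edge <- NULL; vg <- NULL
  if (!is.null(cms)) {
    edge <- mgswbc_edges(cms, ids, groups, fraction = config$fraction,
                         combine = config$combine)
    ymat <- do.call(rbind, lapply(cms, function(cm) vgbn_vector(cm)$y_opt))
    vg <- ttest_select_regions(ymat, ids, groups, alpha = config$alpha)
    vg$y_mat <- align_global_vectors(ymat)
  }

  map_tables <- lapply(mg, `[[`, "features")
  strict_tables <- lapply(map_tables, strict_columns)
  variant <- list(
    SSW = c(strict_tables,
            if (!is.null(edge)) list(strict_columns(edge$features))),
    `MGS-WBC` = c(map_tables, if (!is.null(edge)) list(edge$features)),
    FUSE = c(map_tables, if (!is.null(edge)) list(edge$features),
             if (!is.null(vg)) list(vg$features)))

  rows <- list()
  reports <- list()
  for (mv in intersect(names(variant), config$methods)) {
    tabs <- Filter(has_features, variant[[mv]])
    if (length(tabs) == 0) next
    fused <- fuse_features(tabs)
    for (cl in config$classifiers) {
      rep <- loocv_evaluate(fused, spec = classifier_spec(cl))
      reports[[paste(cl, mv, sep = ".")]] <- rep
      rows[[length(rows) + 1]] <- data.frame(
        Classifier = toupper(cl), Method = mv, ACC = rep$acc, F1_Score = rep$f1,
        AUC = rep$auc, stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)

  result <- list(report = report,
                 details = list(cohort = cohort, channels = names(channels),
                                mgswbc = mg, edges = edge, vgbn = vg,
                                evaluations = reports),
                 config = config)
  if (!is.null(config$out)) result$manifest <- write_artifacts(result, config)
  result
}

# Write pipeline artifacts plus a manifest referencing every file.
write_artifacts <- function(result, config) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  add <- function(path, stage) {
    entries[[length(entries) + 1]] <<- list(
      file = basename(path), stage = stage,
      md5 = unname(tools::md5sum(path)))
  }
  wcsv <- function(df, name, stage) {
    p <- file.path(config$out, name)
    utils::write.csv(df, p, row.names = FALSE)
    add(p, stage)
  }
  for (kind in names(result$details$mgswbc)) {
    m <- result$details$mgswbc[[kind]]
    p <- file.path(config$out, sprintf("%s_tmap.nii.gz", kind))
    RNifti::writeNifti(RNifti::asNifti(m$mask_set$t_map), p); add(p, "mgswbc")
    p <- file.path(config$out, sprintf("%s_pmap.nii.gz", kind))
    RNifti::writeNifti(RNifti::asNifti(m$mask_set$p_map), p); add(p, "mgswbc")
    cl <- rbind(
      cbind(m$clusters_band$table,
            Mask = rep("band", nrow(m$clusters_band$table))),
      cbind(m$clusters_strict$table,
            Mask = rep("strict", nrow(m$clusters_strict$table))))
    wcsv(cl, sprintf("%s_clusters.csv", kind), "mgswbc")
  }
  if (!is.null(result$details$edges))
    wcsv(result$details$edges$edges, "edge_selection.csv", "mgswbc")
  if (!is.null(result$details$vgbn)) {
    ym <- as.data.frame(result$details$vgbn$y_mat)
    colnames(ym) <- sprintf("region_%02d", seq_len(ncol(ym)))
    wcsv(cbind(subject_id = result$details$vgbn$features$subject_id, ym),
         "global_vectors.csv", "vgbnlm")
    wcsv(result$details$vgbn$table, "global_regions.csv", "vgbnlm")
  }
  rep <- result$report
  rep$Method_label <- rep$Method
  wcsv(rep, "classification_report.csv", "classify")
  manifest <- list(
    seed = config$seed,
    parameters = list(drop_timepoints = config$drop_timepoints,
                      band = config$band, fraction = config$fraction,
                      strict_p = config$strict_p, band_p = config$band_p,
                      min_cluster = config$min_cluster, alpha = config$alpha,
                      combine = config$combine),
    group_labels = as.list(GROUP_LABELS),
    artifacts = entries)
  mp <- file.path(config$out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest
}
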