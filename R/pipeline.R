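#' Slow-band ALFF map for one subject
#'
#' Applies the functional preprocessing chain in order: discard the first
#' \code{band$n_discard} volumes, build the Friston-24 confound matrix from
#' the (trimmed) motion trace, voxelwise OLS regression of linear trend +
#' confounds (+ optional tissue signals) within the mask, then the spectral
#' ALFF computation on the residuals.
#'
#' @param functional 4D array.
#' @param motion n_volumes x 6 motion trace.
#' @param mask binary 3D analysis mask.
#' @param band a \code{\link{band_spec}}.
#' @param tr repetition time (s).
#' @param tissue_signals optional matrix of mean WM/CSF series (full length;
#'   trimmed along with the data).
#' @return an \code{alff_map} (see \code{\link{compute_alff}}).
#' @export
subject_alff <- function(functional, motion, mask, band = band_spec(), tr,
                         tissue_signals = NULL) {
  nt <- dim(functional)[4]
  if (band$n_discard >= nt) stop_data("n_discard leaves no volumes")
  keep <- (band$n_discard + 1):nt
  ts <- functional[, , , keep, drop = FALSE]
  mo <- motion[keep, , drop = FALSE]
  tis <- if (!is.null(tissue_signals))
    as.matrix(tissue_signals)[keep, , drop = FALSE]
  res <- regress_confounds(ts, mask, confounds = friston24(mo),
                           include_linear_trend = TRUE,
                           tissue_signals = tis)
  compute_alff(res, mask,
               band = band_spec(band$low_hz, band$high_hz, n_discard = 0L),
               tr = tr)
}

#' Extract the multimodal feature tables for a cohort
#'
#' For every subject passing motion QC, computes the slow-band ALFF map and
#' extracts the 101-feature vector per ROI from both the structural volume
#' (modality \code{"T1-w"}) and the ALFF map (modality \code{"ALFF"}).
#'
#' @param cohort a \code{synthetic_cohort} (or a list with \code{subjects}
#'   and \code{table} of the same shape).
#' @param rois subset of \code{c("left", "right", "bilateral")};
#'   \code{"bilateral"} uses the union mask.
#' @param band a \code{\link{band_spec}}.
#' @param n_bins gray levels for discretization.
#' @param thresholds \code{\link{qc_thresholds}}; set to NULL to skip QC.
#' @param modalities subset of \code{c("T1-w", "ALFF")}.
#' @return list with \code{tables} (\code{tables[[roi]][[modality]]} data
#'   frames over kept subjects), \code{labels}, \code{scores},
#'   \code{subject_ids} and \code{qc} (the QC report for all subjects).
#' @export
extract_cohort_features <- function(cohort, rois = c("left", "right"),
                                    band = band_spec(), n_bins = 32L,
                                    thresholds = qc_thresholds(),
                                    modalities = c("T1-w", "ALFF")) {
  subjects <- cohort$subjects
  qc <- NULL
  keep <- seq_along(subjects)
  if (!is.null(thresholds)) {
    qc <- qc_exclude(subjects, thresholds)
    keep <- which(qc$kept)
  }
  if (!length(keep)) stop_data("no subject passed motion QC")
  subjects <- subjects[keep]
  ids <- vapply(subjects, `[[`, "", "subject_id")
  roi_mask <- function(s, roi) switch(roi,
    left = s$masks$left, right = s$masks$right,
    bilateral = combine_bilateral(s$masks$left, s$masks$right),
    stop_data(sprintf("unknown ROI '%s'", roi)))
  tables <- setNames(vector("list", length(rois)), rois)
  rows <- lapply(rois, function(roi) NULL)
  need_alff <- "ALFF" %in% modalities
  feat <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    alff <- NULL
    if (need_alff) {
      analysis_mask <- combine_bilateral(s$masks$left, s$masks$right)
      alff <- subject_alff(s$functional, s$motion, analysis_mask, band, s$tr)
    }
    for (roi in rois) {
      mk <- roi_mask(s, roi)
      if ("T1-w" %in% modalities)
        feat[[roi]][["T1-w"]][[i]] <-
          extract_feature_vector(s$structural, mk, n_bins, "T1-w")
      if (need_alff)
        feat[[roi]][["ALFF"]][[i]] <-
          extract_feature_vector(alff$map, mk, n_bins, "ALFF")
    }
  }
  for (roi in rois)
    for (m in modalities) {
      tab <- as.data.frame(do.call(rbind, feat[[roi]][[m]]),
                           check.names = FALSE)
      rownames(tab) <- ids
      tables[[roi]][[m]] <- tab
    }
  list(tables = tables,
       labels = vapply(subjects, `[[`, "", "group"),
       scores = vapply(subjects, `[[`, 0, "score"),
       subject_ids = ids, qc = qc)
}

#' Read and validate a pipeline configuration
#'
#' A single declarative YAML file; every omitted field falls back to the
#' pipeline defaults (slow-5 band 0.01-0.027 Hz, 10 discarded volumes, QC at
#' 3 mm / 3 degrees / mean FD 0.5, 32 gray levels, mRMR 20, 10 CV folds,
#' 70/30 split repeated 10 times).
#'
#' @param path YAML file path.
#' @return a validated \code{pipeline_config} list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw)
}

#' @rdname read_pipeline_config
#' @param config a named list with the same structure as the YAML file.
#' @export
as_pipeline_config <- function(config) {
  defaults <- list(
    output_dir = "radalff-output",
    seed = 1L,
    band = list(low_hz = 0.01, high_hz = 0.027, n_discard = 10L),
    qc = list(max_translation_mm = 3, max_rotation_deg = 3,
              max_mean_fd_mm = 0.5),
    features = list(n_bins = 32L),
    model = list(mrmr_k = 20L, folds = 10L, smote_k = 5L),
    split = list(train_fraction = 0.7, n_repetitions = 10L),
    rois = c("left", "right"),
    modalities = c("T1-w", "ALFF", "combined"),
    contrasts = list(c("AD", "NC"), c("aMCI", "NC")),
    simulate = NULL, cohort_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  # modifyList would deep-merge these unnamed/atomic fields; take the user's
  # value verbatim instead
  for (k in c("contrasts", "rois", "modalities"))
    if (!is.null(config[[k]])) cfg[[k]] <- config[[k]]
  if (is.null(cfg$simulate) && is.null(cfg$cohort_dir))
    stop_data("config must provide either 'simulate' or 'cohort_dir'")
  cfg$contrasts <- lapply(cfg$contrasts, unlist)
  cfg$rois <- unlist(cfg$rois)
  cfg$modalities <- unlist(cfg$modalities)
  if (!(cfg$band$low_hz > 0 && cfg$band$high_hz > cfg$band$low_hz))
    stop_data("invalid band: need 0 < low_hz < high_hz")
  structure(cfg, class = "pipeline_config")
}

#' @keywords internal
load_cohort_dir <- function(dir) {
  csv <- file.path(dir, "subjects.csv")
  if (!file.exists(csv)) stop_data(sprintf("missing subject table: %s", csv))
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$subject_id[i]
    base <- file.path(dir, id)
    need <- paste0(base, c("_T1w.nii.gz", "_bold.nii.gz",
                           "_mask-left.nii.gz", "_mask-right.nii.gz"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop_data(sprintf("missing image file(s) for %s: %s", id,
                        paste(basename(miss), collapse = ", ")))
    bold <- read_volume(need[2])
    tr <- RNifti::pixdim(RNifti::readNifti(need[2]))[4]
    list(subject_id = id, group = tab$group[i],
         structural = read_volume(need[1])$data,
         functional = bold$data,
         masks = list(left = read_volume(need[3])$data,
                      right = read_volume(need[4])$data),
         motion = read_motion(tab$motion_path[i]),
         score = tab$score[i], geom = bold$geom, tr = tr)
  })
  list(subjects = subjects, table = tab)
}

#' Run the pipeline end-to-end from a configuration
#'
#' Stages in order: simulate (or load) the cohort, motion QC, ALFF map
#' computation and feature extraction, signature training and repeated-split
#' evaluation, report writing. Every JSON artifact carries a provenance block
#' (configuration hash, seed, package version); re-running with an identical
#' configuration reproduces identical numeric outputs.
#'
#' @param config a \code{pipeline_config} (or path to a YAML file).
#' @param verbose log stage timings to stderr.
#' @return the \code{evaluation_report}, invisibly; outputs are written under
#'   \code{config$output_dir}.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- as_pipeline_config(config)
  t0 <- proc.time()[3]
  log_stage <- function(...) if (verbose)
    message(sprintf("[radalff +%6.1fs] ", proc.time()[3] - t0), ...)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = config_hash(unclass(config)),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("radalff")))

  log_stage("stage 1/4: cohort")
  cohort <- if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$n_per_group <- unlist(sim$n_per_group)
    spec <- do.call(cohort_spec, c(sim, list(seed = config$seed)))
    generate_cohort(spec)
  } else load_cohort_dir(config$cohort_dir)

  log_stage("stage 2/4: motion QC")
  thr <- do.call(qc_thresholds, config$qc)
  qc <- qc_exclude(cohort$subjects, thr)
  write.csv(qc, file.path(out, "qc_report.csv"), row.names = FALSE)

  log_stage("stage 3/4: ALFF + feature extraction")
  band <- do.call(band_spec, config$band)
  feats <- extract_cohort_features(
    cohort, rois = config$rois, band = band,
    n_bins = config$features$n_bins, thresholds = thr,
    modalities = intersect(c("T1-w", "ALFF"),
                           unique(c(config$modalities, "T1-w", "ALFF"))))
  for (roi in config$rois)
    for (m in names(feats$tables[[roi]])) {
      tab <- cbind(subject_id = feats$subject_ids, group = feats$labels,
                   score = feats$scores, feats$tables[[roi]][[m]])
      write.csv(tab, file.path(out, sprintf("features_%s_%s.csv", roi, m)),
                row.names = FALSE)
    }

  log_stage("stage 4/4: signatures + evaluation")
  scheme <- split_scheme(config$split$train_fraction,
                         config$split$n_repetitions, seed = config$seed)
  report <- run_experiment(
    feats$tables, feats$labels,
    contrasts = config$contrasts, rois = config$rois,
    modalities = config$modalities, scheme = scheme,
    clinical_scores = feats$scores,
    mrmr_k = config$model$mrmr_k, folds = config$model$folds,
    smote_k = config$model$smote_k)
  write_report(report, out)

  # one frozen model per cell, fitted on the full cohort, for external use
  models_dir <- file.path(out, "models")
  dir.create(models_dir, showWarnings = FALSE)
  for (ct in config$contrasts) {
    sub <- which(feats$labels %in% ct)
    y <- factor(feats$labels[sub], levels = c(ct[2], ct[1]))
    for (roi in config$rois)
      for (m in config$modalities) {
        tab <- if (m == "combined")
          cbind(feats$tables[[roi]][["T1-w"]], feats$tables[[roi]][["ALFF"]])
        else feats$tables[[roi]][[m]]
        model <- tryCatch(
          fit_signature(tab[sub, , drop = FALSE], y,
                        mrmr_k = config$model$mrmr_k,
                        folds = config$model$folds,
                        smote_k = config$model$smote_k,
                        seed = config$seed),
          error = function(e) NULL)
        if (!is.null(model))
          write_signature_model(
            model, file.path(models_dir,
                             sprintf("model_%svs%s_%s_%s.json",
                                     ct[1], ct[2], roi, m)))
      }
  }
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("done; outputs in ", normalizePath(out))
  invisible(report)
}
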