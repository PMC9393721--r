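#' Mean test AUC of signature models on one simulated cohort
#'
#' Convenience driver for calibration and effect-recovery studies: generates
#' a two-group cohort (cases vs controls) with the requested planted effects,
#' extracts left-hippocampus features, runs the repeated-split signature
#' pipeline for the requested modalities and returns each modality's mean
#' test AUC.
#'
#' @param n subjects per group.
#' @param texture_effect,alff_effect planted group effects (see
#'   \code{\link{cohort_spec}}).
#' @param modalities subset of \code{c("T1-w", "ALFF", "combined")}.
#' @param n_repetitions repeated splits per cohort.
#' @param seed integer seed for the cohort and the splits.
#' @param mrmr_k,folds model hyperparameters.
#' @return named numeric vector: mean test AUC per modality.
#' @export
simulate_cohort_auc <- function(n = 20L, texture_effect = 0, alff_effect = 0,
                                modalities = "ALFF", n_repetitions = 2L,
                                seed = 1L, mrmr_k = 20L, folds = 10L) {
  spec <- cohort_spec(n_per_group = c(case = as.integer(n),
                                      NC = as.integer(n)),
                      texture_effect = texture_effect,
                      alff_effect = alff_effect, seed = seed)
  cohort <- generate_cohort(spec)
  extract <- unique(c(if (any(modalities %in% c("T1-w", "combined"))) "T1-w",
                      if (any(modalities %in% c("ALFF", "combined"))) "ALFF"))
  feats <- extract_cohort_features(cohort, rois = "left",
                                   modalities = extract)
  rep <- suppressWarnings(run_experiment(
    feats$tables, feats$labels, contrasts = list(c("case", "NC")),
    rois = "left", modalities = modalities,
    scheme = split_scheme(n_repetitions = n_repetitions,
                          seed = derive_seed(seed, 777L)),
    mrmr_k = mrmr_k, folds = folds))
  if (length(rep$failed))
    stop_data(paste("simulation cell failed:",
                    paste(unlist(rep$failed), collapse = "; ")))
  out <- rep$summary$mean_test_auc
  names(out) <- rep$summary$modality
  out[modalities]
}
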