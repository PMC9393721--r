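#' Run the full repeated-split signature experiment
#'
#' For every cell of (contrast x ROI x modality) this runs, per repetition:
#' stratified 70/30 split, z-normalization fitted on the training rows, SMOTE
#' balancing, greedy mRMR filtering, LASSO logistic selection, radscore
#' computation and ROC analysis of train and test scores (test accuracy uses
#' the training Youden threshold, frozen). Splits are shared across ROIs and
#' modalities within a contrast and repetition, so that DeLong comparisons
#' between modality models are paired on identical subjects. The reported
#' mean AUC of a cell is the exact arithmetic mean of its per-repetition
#' AUCs.
#'
#' DeLong comparisons (combined vs structural, structural vs ALFF) are
#' computed per repetition on the training scores by default
#' (\code{delong_on = "test"} switches to test scores). Wilcoxon rank-sum
#' tests compare case vs control radscores in train and test sets. If
#' \code{clinical_scores} is given, the features retained in each combined
#' model are Spearman-correlated with the clinical score over the contrast's
#' subjects.
#'
#' @param tables named list: \code{tables[[roi]][[modality]]} is a subjects x
#'   features data frame; every ROI needs the \code{"T1-w"} and \code{"ALFF"}
#'   tables (the \code{"combined"} modality is their column-wise
#'   concatenation, built internally).
#' @param labels group label per subject (rows of every table).
#' @param contrasts list of length-2 character vectors \code{c(case,
#'   control)}.
#' @param rois ROIs to analyse (default: all in \code{tables}).
#' @param modalities subset of \code{c("T1-w", "ALFF", "combined")}.
#' @param scheme a \code{\link{split_scheme}}.
#' @param clinical_scores optional numeric vector (one per subject).
#' @param mrmr_k,folds,smote_k passed to \code{\link{fit_signature}}.
#' @param delong_on \code{"train"} (default) or \code{"test"}.
#' @return an object of class \code{evaluation_report}: list with
#'   \code{cells} (per-cell list: per-repetition data frame, mean AUCs,
#'   selected features, test-set ROC curve points),
#'   \code{summary} (flat data frame, one row per cell),
#'   \code{repetitions} (flat data frame, one row per cell x repetition),
#'   \code{delong}, \code{wilcoxon}, \code{spearman} data frames, and
#'   \code{failed} (named reasons for any failed cell).
#' @export
run_experiment <- function(tables, labels,
                           contrasts = list(c("AD", "NC"), c("aMCI", "NC")),
                           rois = names(tables),
                           modalities = c("T1-w", "ALFF", "combined"),
                           scheme = split_scheme(),
                           clinical_scores = NULL,
                           mrmr_k = 20L, folds = 10L, smote_k = 5L,
                           delong_on = c("train", "test")) {
  delong_on <- match.arg(delong_on)
  labels <- as.character(labels)
  get_table <- function(roi, modality) {
    if (modality == "combined")
      cbind(tables[[roi]][["T1-w"]], tables[[roi]][["ALFF"]])
    else tables[[roi]][[modality]]
  }
  cells <- list()
  failed <- list()
  delong_rows <- list(); wilcox_rows <- list(); spearman_rows <- list()
  for (ci in seq_along(contrasts)) {
    case <- contrasts[[ci]][1]; control <- contrasts[[ci]][2]
    sub <- which(labels %in% c(case, control))
    y <- factor(labels[sub], levels = c(control, case)) # case = positive
    splits <- lapply(seq_len(scheme$n_repetitions), function(r)
      split_cohort(as.character(y), scheme, r))
    for (roi in rois) {
      scores_store <- list() # scores_store[[modality]][[rep]] = list(train=,test=,...)
      for (modality in modalities) {
        cell_id <- paste(paste(case, "vs", control), roi, modality,
                         sep = "|")
        res <- tryCatch({
          tab <- get_table(roi, modality)[sub, , drop = FALSE]
          reps <- vector("list", scheme$n_repetitions)
          sel_feats <- list(); curves <- list()
          for (r in seq_len(scheme$n_repetitions)) {
            sp <- splits[[r]]
            model <- fit_signature(tab[sp$train, , drop = FALSE],
                                   y[sp$train], mrmr_k = mrmr_k,
                                   folds = folds, smote_k = smote_k,
                                   seed = derive_seed(scheme$seed,
                                                      1000 * ci + r))
            s_tr <- radscore(model, tab[sp$train, , drop = FALSE])
            s_te <- radscore(model, tab[sp$test, , drop = FALSE])
            roc_tr <- roc_auc(s_tr, y[sp$train], positive = case)
            roc_te <- roc_auc(s_te, y[sp$test], positive = case,
                              threshold = roc_tr$threshold)
            reps[[r]] <- data.frame(
              repetition = r,
              train_auc = roc_tr$auc, test_auc = roc_te$auc,
              train_ci_lo = roc_tr$ci[1], train_ci_hi = roc_tr$ci[2],
              test_ci_lo = roc_te$ci[1], test_ci_hi = roc_te$ci[2],
              train_accuracy = roc_tr$accuracy,
              test_accuracy = roc_te$accuracy,
              n_selected = length(model$features))
            sel_feats[[r]] <- model$features
            curves[[r]] <- cbind(repetition = r, set = "test", roc_te$curve)
            scores_store[[modality]][[r]] <-
              list(train = s_tr, test = s_te, split = sp)
            w_tr <- wilcoxon_ranksum(s_tr[y[sp$train] == case],
                                     s_tr[y[sp$train] == control])
            w_te <- wilcoxon_ranksum(s_te[y[sp$test] == case],
                                     s_te[y[sp$test] == control])
            wilcox_rows[[length(wilcox_rows) + 1L]] <- data.frame(
              contrast = paste(case, "vs", control), roi = roi,
              modality = modality, repetition = r,
              p_train = w_tr$p, p_test = w_te$p)
          }
          repdf <- do.call(rbind, reps)
          list(repetitions = repdf,
               mean_train_auc = mean(repdf$train_auc),
               mean_test_auc = mean(repdf$test_auc),
               mean_train_accuracy = mean(repdf$train_accuracy),
               mean_test_accuracy = mean(repdf$test_accuracy),
               selected_features = sel_feats,
               roc_curves = do.call(rbind, curves),
               contrast = paste(case, "vs", control),
               roi = roi, modality = modality)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failed[[cell_id]] <- conditionMessage(res)
        } else {
          cells[[cell_id]] <- res
        }
      }
      # DeLong comparisons between modality models, paired per repetition
      pairs <- list(c("combined", "T1-w"), c("T1-w", "ALFF"))
      for (pr in pairs) {
        if (!all(pr %in% modalities)) next
        if (is.null(scores_store[[pr[1]]]) || is.null(scores_store[[pr[2]]]))
          next
        for (r in seq_len(scheme$n_repetitions)) {
          sa <- scores_store[[pr[1]]][[r]]; sb <- scores_store[[pr[2]]][[r]]
          idx <- if (delong_on == "train") "train" else "test"
          yy <- if (delong_on == "train") y[sa$split$train] else y[sa$split$test]
          dl <- tryCatch(delong_test(sa[[idx]], sb[[idx]], yy,
                                     positive = case),
                         error = function(e) NULL)
          if (is.null(dl)) next
          delong_rows[[length(delong_rows) + 1L]] <- data.frame(
            contrast = paste(case, "vs", control), roi = roi,
            comparison = paste(pr[1], "vs", pr[2]), repetition = r,
            auc_a = dl$auc_a, auc_b = dl$auc_b, auc_diff = dl$auc_diff,
            z = dl$z, p = dl$p)
        }
      }
      # Spearman of combined-model features vs clinical score
      if (!is.null(clinical_scores) && "combined" %in% modalities) {
        cell_id <- paste(paste(case, "vs", control), roi, "combined",
                         sep = "|")
        if (!is.null(cells[[cell_id]])) {
          feats <- unique(unlist(cells[[cell_id]]$selected_features))
          tab <- get_table(roi, "combined")[sub, , drop = FALSE]
          for (f in feats) {
            cr <- tryCatch(spearman_cor(tab[[f]], clinical_scores[sub],
                                        feature = f),
                           error = function(e) NULL)
            if (is.null(cr)) next
            spearman_rows[[length(spearman_rows) + 1L]] <- data.frame(
              contrast = paste(case, "vs", control), roi = roi,
              feature = f, rho = cr$rho, p = cr$p, n = cr$n)
          }
        }
      }
    }
  }
  bindrows <- function(x) if (length(x)) do.call(rbind, x) else NULL
  summary_df <- bindrows(lapply(cells, function(cl) data.frame(
    contrast = cl$contrast, roi = cl$roi, modality = cl$modality,
    mean_train_auc = cl$mean_train_auc, mean_test_auc = cl$mean_test_auc,
    mean_train_accuracy = cl$mean_train_accuracy,
    mean_test_accuracy = cl$mean_test_accuracy)))
  if (!is.null(summary_df)) rownames(summary_df) <- NULL
  reps_df <- bindrows(lapply(cells, function(cl) {
    df <- cl$repetitions
    cbind(data.frame(contrast = cl$contrast, roi = cl$roi,
                     modality = cl$modality), df)
  }))
  if (!is.null(reps_df)) rownames(reps_df) <- NULL
  structure(list(cells = cells, summary = summary_df,
                 repetitions = reps_df,
                 delong = bindrows(delong_rows),
                 wilcoxon = bindrows(wilcox_rows),
                 spearman = bindrows(spearman_rows),
                 scheme = scheme, failed = failed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", length(x$cells), "signature cell(s)\n")
  if (!is.null(x$summary)) print(x$summary, digits = 3)
  if (length(x$failed))
    cat("failed cells:", paste(names(x$failed), collapse = ", "), "\n")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON summary plus flat CSVs (one row per cell x repetition, DeLong,
#' Wilcoxon and Spearman tables).
#'
#' @param report an \code{evaluation_report}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            failed = report$failed),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in c("repetitions", "delong", "wilcoxon", "spearman"))
    if (!is.null(report[[nm]]))
      write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
  curves <- do.call(rbind, lapply(names(report$cells), function(id) {
    cc <- report$cells[[id]]$roc_curves
    if (is.null(cc)) return(NULL)
    cbind(cell = id, cc)
  }))
  if (!is.null(curves))
    write.csv(curves, file.path(dir, "roc_curves.csv"), row.names = FALSE)
  invisible(dir)
}
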