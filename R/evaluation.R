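#' Repeated stratified split scheme
#'
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.7; per-class train count is \code{round(fraction * n)}).
#' @param n_repetitions number of repeated splits (default 10).
#' @param stratified keep class ratios equal across train/test (default TRUE).
#' @param seed master seed; repetition r uses \code{derive_seed(seed, r)}.
#' @return an object of class \code{split_scheme}.
#' @export
split_scheme <- function(train_fraction = 0.7, n_repetitions = 10L,
                         stratified = TRUE, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repetitions >= 1)
  structure(list(train_fraction = train_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_scheme")
}

#' Stratified train/test split
#'
#' Per class, \code{round(fraction * n_class)} subjects go to training; the
#' remainder is the test set. Reproducible for a given scheme and repetition
#' index.
#'
#' @param labels class labels (one per subject).
#' @param scheme a \code{\link{split_scheme}}.
#' @param repetition repetition index (1-based).
#' @return list with integer vectors \code{train} and \code{test}
#'   partitioning \code{seq_along(labels)}.
#' @export
split_cohort <- function(labels, scheme = split_scheme(), repetition = 1L) {
  labels <- as.character(labels)
  cls <- table(labels)
  if (any(cls < 2L)) stop_data("every class needs at least 2 subjects")
  with_seed(derive_seed(scheme$seed, repetition), {
    train <- integer(0)
    if (scheme$stratified) {
      for (lv in names(cls)) {
        i <- which(labels == lv)
        n_tr <- round(scheme$train_fraction * length(i))
        n_tr <- min(max(n_tr, 1L), length(i) - 1L)
        train <- c(train, sample(i, n_tr))
      }
    } else {
      n_tr <- round(scheme$train_fraction * length(labels))
      train <- sample(seq_along(labels), n_tr)
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' @keywords internal
auc_mw <- function(scores, positive) {
  # Mann-Whitney AUC with 1/2 tie weighting via midranks
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @keywords internal
delong_placements <- function(scores, positive) {
  # V10 (per positive) and V01 (per negative) structural components
  xs <- scores[positive]; ys <- scores[!positive]
  v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), 0)
  v01 <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC analysis of a score vector
#'
#' AUC by the trapezoidal rule over all thresholds (equivalently the
#' Mann-Whitney statistic with 1/2 weighting of ties), a 95% confidence
#' interval from the DeLong variance (normal interval truncated to [0, 1]),
#' the full ROC curve, and the accuracy at the Youden-optimal threshold
#' (highest sensitivity + specificity - 1; the threshold is also returned so
#' it can be frozen on a training set and applied to a test set).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels.
#' @param positive label of the positive class (default: the second factor
#'   level).
#' @param threshold optional fixed threshold at which accuracy is computed
#'   (default: the Youden-optimal threshold of this data).
#' @return an object of class \code{roc_result}: \code{auc}, \code{ci}
#'   (length 2), \code{accuracy}, \code{threshold}, \code{curve} (data frame
#'   fpr/tpr), \code{n_pos}, \code{n_neg}.
#' @export
roc_auc <- function(scores, labels, positive = NULL, threshold = NULL) {
  stopifnot(length(scores) == length(labels))
  y <- factor(labels)
  if (nlevels(y) != 2L) stop_data("both classes must be present")
  if (is.null(positive)) positive <- levels(y)[2]
  pos <- y == positive
  pl <- delong_placements(scores, pos)
  auc <- pl$auc
  n1 <- sum(pos); n0 <- sum(!pos)
  v <- var(pl$v10) / n1 + var(pl$v01) / n0
  se <- sqrt(max(v, 0))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * qnorm(0.975) * se))
  # ROC curve over all distinct thresholds
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  if (is.null(threshold)) {
    youden <- tpr - fpr
    threshold <- thr[which.max(youden)]
  }
  acc <- mean((scores >= threshold) == pos)
  structure(list(auc = auc, ci = ci, accuracy = acc, threshold = threshold,
                 curve = curve, n_pos = n1, n_neg = n0,
                 positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), accuracy %.3f\n",
              x$auc, x$ci[1], x$ci[2], x$accuracy))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors on the same subjects,
#' using the structural-components (placement-value) estimate of the variance
#' of the AUC difference; \code{z = dAUC / SE} with a two-sided normal
#' p-value. If the difference has zero variance, p = 1 when the AUCs are
#' equal and an error otherwise.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary labels (shared).
#' @param positive positive class label (default: second factor level).
#' @return an object of class \code{delong_result}: \code{auc_a},
#'   \code{auc_b}, \code{auc_diff}, \code{z}, \code{p}, \code{se}.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = NULL) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  y <- factor(labels)
  if (nlevels(y) != 2L) stop_data("both classes must be present")
  if (is.null(positive)) positive <- levels(y)[2]
  pos <- y == positive
  pa <- delong_placements(scores_a, pos)
  pb <- delong_placements(scores_b, pos)
  n1 <- sum(pos); n0 <- sum(!pos)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  S <- s10 / n1 + s01 / n0
  dauc <- pa$auc - pb$auc
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (v <= .Machine$double.eps) {
    if (abs(dauc) < 1e-12)
      return(structure(list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = 0,
                            z = 0, p = 1, se = 0), class = "delong_result"))
    stop_data("zero variance with nonzero AUC difference")
  }
  z <- dauc / sqrt(v)
  structure(list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = dauc,
                 z = z, p = 2 * pnorm(-abs(z)), se = sqrt(v)),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("<delong_result> dAUC %.3f, z = %.3f, p = %.4g\n",
              x$auc_diff, x$z, x$p))
  invisible(x)
}

#' Wilcoxon rank-sum test (two independent groups)
#'
#' Exact null distribution (via \code{stats::pwilcox}) when both groups have
#' at most 10 observations and there are no ties; otherwise the tie-corrected
#' normal approximation without continuity correction. When all pooled values
#' are identical, p = 1.
#'
#' @param a,b numeric score vectors for the two groups.
#' @return list with \code{statistic} (Mann-Whitney U of group a), \code{p},
#'   \code{method}.
#' @export
wilcoxon_ranksum <- function(a, b) {
  if (!length(a) || !length(b)) stop_data("both groups must be non-empty")
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1L)
    return(list(statistic = U, p = 1, method = "degenerate"))
  if (m <= 10L && n <= 10L && !ties) {
    p <- 2 * min(stats::pwilcox(U, m, n),
                 1 - stats::pwilcox(U - 1, m, n))
    return(list(statistic = U, p = min(1, p), method = "exact"))
  }
  N <- m + n
  tie_tab <- table(pooled)
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = U, p = 1, method = "degenerate"))
  z <- (U - m * n / 2) / sqrt(sigma2)
  list(statistic = U, p = 2 * pnorm(-abs(z)), method = "normal")
}

#' Spearman rank correlation with the rank-Pearson formula
#'
#' rho is the Pearson correlation of the midranks of x and y (ties receive
#' average ranks); the p-value uses the t approximation with n - 2 degrees of
#' freedom. Invariant under strictly monotone transforms of either argument.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param feature optional feature name carried into the result.
#' @return an object of class \code{correlation_result}: \code{rho},
#'   \code{p}, \code{n}, \code{feature}.
#' @export
spearman_cor <- function(x, y, feature = NA_character_) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop_data("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    stop_data("zero rank variance: correlation undefined")
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p = p, n = n, feature = feature),
            class = "correlation_result")
}

#' Apply a frozen signature model to an external cohort
#'
#' No parameter is re-estimated: the stored normalization and coefficients
#' are applied as-is and the resulting radscores are evaluated by ROC
#' analysis.
#'
#' @param model a \code{signature_model}.
#' @param table external feature table (raw scale) containing all model
#'   features.
#' @param labels external labels.
#' @param threshold optional frozen accuracy threshold (e.g. the training
#'   Youden threshold).
#' @return a \code{roc_result}.
#' @export
apply_frozen_model <- function(model, table, labels, threshold = NULL) {
  scores <- radscore(model, table)
  roc_auc(scores, labels, positive = model$positive_class,
          threshold = threshold)
}
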