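#' Z-normalization fitted on training rows
#'
#' Means and sample (n-1) standard deviations per feature column, estimated
#' on the training table only and applied unchanged to any other table
#' (test or external validation). Zero-variance features are flagged and
#' transformed to all-zeros with a warning, keeping column indices stable.
#'
#' @param train data frame or matrix of training features.
#' @return an object of class \code{znorm_params} with \code{mean},
#'   \code{sd}, \code{zero_sd} (logical), \code{features}.
#' @export
zscore_fit <- function(train) {
  train <- as.matrix(train)
  if (!nrow(train)) stop_data("training table is empty")
  mu <- colMeans(train)
  sdev <- apply(train, 2, sd)
  zero <- sdev == 0 | !is.finite(sdev)
  structure(list(mean = mu, sd = sdev, zero_sd = zero,
                 features = colnames(train)), class = "znorm_params")
}

#' @rdname zscore_fit
#' @param params a \code{znorm_params}.
#' @param table table to transform (must contain the fitted features).
#' @return data frame of transformed features (same row order).
#' @export
zscore_apply <- function(params, table) {
  tab <- as.matrix(table)[, params$features, drop = FALSE]
  if (any(params$zero_sd))
    warning(sprintf("%d zero-variance feature(s) transformed to zeros",
                    sum(params$zero_sd)))
  sdev <- ifelse(params$zero_sd, 1, params$sd)
  out <- sweep(sweep(tab, 2, params$mean), 2, sdev, `/`)
  out[, params$zero_sd] <- 0
  as.data.frame(out, check.names = FALSE)
}

#' SMOTE minority over-sampling
#'
#' Synthetic minority rows are drawn on the segment between a minority row
#' and one of its k nearest minority neighbours (Euclidean metric,
#' interpolation factor uniform in [0,1]) until the minority count equals the
#' majority count. Original rows are preserved; an already balanced table is
#' returned unchanged. With fewer than k+1 minority rows, k is reduced with a
#' warning; a single minority row is an error.
#'
#' @param table feature data frame / matrix.
#' @param labels factor or vector with exactly two classes, one per row.
#' @param k neighbour count (default 5).
#' @param seed integer RNG seed.
#' @return list with \code{table} (balanced), \code{labels}, and
#'   \code{synthetic} (logical marker per row).
#' @export
smote <- function(table, labels, k = 5L, seed = 1L) {
  X <- as.matrix(table)
  labels <- if (is.factor(labels)) labels else factor(labels)
  stopifnot(nrow(X) == length(labels))
  cls <- table(labels)
  if (length(cls) != 2L) stop_data("smote needs exactly two classes")
  if (cls[1] == cls[2])
    return(list(table = as.data.frame(X, check.names = FALSE),
                labels = labels, synthetic = rep(FALSE, nrow(X))))
  minority <- names(cls)[which.min(cls)]
  min_idx <- which(labels == minority)
  n_min <- length(min_idx); n_need <- max(cls) - n_min
  if (n_min < 2L) stop_data("smote needs at least 2 minority rows")
  if (k > n_min - 1L) {
    warning(sprintf("k reduced from %d to %d (minority size)", k, n_min - 1L))
    k <- n_min - 1L
  }
  Xm <- X[min_idx, , drop = FALSE]
  D <- as.matrix(dist(Xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
  synth <- with_seed(seed, {
    base <- rep(seq_len(n_min), length.out = n_need)
    pick <- nn[cbind(base, sample.int(k, n_need, replace = TRUE))]
    u <- runif(n_need)
    Xm[base, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  })
  out <- rbind(X, synth)
  rownames(out) <- c(rownames(X) %||% as.character(seq_len(nrow(X))),
                     sprintf("synthetic-%03d", seq_len(n_need)))
  list(table = as.data.frame(out, check.names = FALSE),
       labels = factor(c(as.character(labels), rep(minority, n_need)),
                       levels = levels(labels)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_need)))
}

#' @keywords internal
discretize3 <- function(x) {
  # three states at mean +/- sd, the binning used for all mutual information
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(1L, length(x)))
  findInterval(x, c(m - s, m + s)) + 1L
}

#' @keywords internal
mutual_information <- function(x, y) {
  # x, y: integer state vectors; MI in bits
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

#' Greedy mRMR feature selection (MID criterion)
#'
#' Features are discretized into 3 states at mean +/- sd; the first selected
#' feature maximizes mutual information with the label, and each subsequent
#' feature maximizes relevance minus mean redundancy,
#' \code{MI(f; y) - mean over selected MI(f; s)} (the mutual-information
#' difference criterion). Ties are broken by column name. The \code{"MIQ"}
#' variant (relevance / redundancy quotient) and a pure-relevance ranking
#' are available via \code{criterion}.
#'
#' @param table feature data frame / matrix (candidate features in columns).
#' @param labels class labels (one per row, >= 2 classes).
#' @param k number of features to select (default 20).
#' @param criterion \code{"MID"} (default), \code{"MIQ"} or
#'   \code{"relevance"}.
#' @return character vector of k selected names, in selection order.
#' @export
mrmr_select <- function(table, labels, k = 20L,
                        criterion = c("MID", "MIQ", "relevance")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(table)
  if (length(unique(labels)) < 2L) stop_data("need at least two classes")
  feats <- colnames(X)
  if (is.null(feats)) stop_data("feature columns must be named")
  if (ncol(X) < k) {
    warning(sprintf("only %d candidate features; returning all", ncol(X)))
    k <- ncol(X)
  }
  Xd <- apply(X, 2, discretize3)
  y <- as.integer(factor(labels))
  rel <- apply(Xd, 2, mutual_information, y = y)
  # deterministic tie-break: highest relevance, then alphabetical name
  ord <- order(-rel, feats)
  selected <- feats[ord[1]]
  if (criterion == "relevance") return(feats[ord[seq_len(k)]])
  remaining <- setdiff(feats, selected)
  red_sum <- setNames(rep(0, length(feats)), feats)
  while (length(selected) < k) {
    last <- selected[length(selected)]
    red_sum[remaining] <- red_sum[remaining] +
      vapply(remaining, function(f)
        mutual_information(Xd[, f], Xd[, last]), 0)
    red_mean <- red_sum[remaining] / length(selected)
    score <- if (criterion == "MID") rel[remaining] - red_mean
             else rel[remaining] / pmax(red_mean, .Machine$double.eps)
    pick <- remaining[order(-score, remaining)[1]]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' LASSO logistic signature fit with cross-validated lambda
#'
#' L1-penalized logistic regression (\pkg{glmnet}) over a descending lambda
#' grid; lambda is chosen at the minimum mean cross-validated binomial
#' deviance (\code{lambda.min}). Features with zero coefficient at the chosen
#' lambda are dropped. Fold assignment is drawn once from \code{seed}, making
#' the fit fully reproducible. If no lambda retains any feature, an
#' intercept-only model is returned with a warning.
#'
#' @param table normalized (and balanced) training features, mRMR-selected.
#' @param labels binary labels; the second factor level is the positive
#'   class.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param norm_params optional \code{\link{zscore_fit}} parameters to store
#'   so that \code{\link{radscore}} can consume raw feature tables.
#' @return an object of class \code{signature_model}: normalization
#'   parameters, selected names, coefficients, intercept, lambda, seed.
#' @export
lasso_cv_fit <- function(table, labels, folds = 10L, seed = 1L,
                         norm_params = NULL) {
  X <- as.matrix(table)
  y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(y) != 2L) stop_data("labels must have exactly two classes")
  if (min(table(y)) < folds)
    stop_data("need at least `folds` rows per class")
  foldid <- with_seed(seed, {
    # stratified fold assignment keeps both classes in every fold
    f <- integer(length(y))
    for (lv in levels(y)) {
      i <- which(y == lv)
      f[i] <- sample(rep(seq_len(folds), length.out = length(i)))
    }
    f
  })
  cv <- glmnet::cv.glmnet(X, y, family = "binomial",
                          type.measure = "deviance", foldid = foldid,
                          standardize = FALSE)
  beta <- as.matrix(coef(cv, s = "lambda.min"))
  keep <- which(beta[-1, 1] != 0)
  if (!length(keep))
    warning("no feature retained at lambda.min; intercept-only model")
  structure(list(
    normalization = norm_params,
    features = colnames(X)[keep],
    coefficients = beta[-1, 1][keep],
    intercept = beta[1, 1],
    lambda = cv$lambda.min,
    positive_class = levels(y)[2],
    levels = levels(y),
    folds = folds, foldid = foldid, seed = seed),
    class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d feature(s), lambda = %.4g, positive = %s\n",
              length(x$features), x$lambda, x$positive_class))
  invisible(x)
}

#' Radiomics score
#'
#' \code{radscore = intercept + sum(coef * normalized feature value)}; the
#' linear predictor of the fitted LASSO logistic model. If the model stores
#' normalization parameters they are applied first, so the table may be raw;
#' otherwise the table must already be normalized.
#'
#' @param model a \code{signature_model}.
#' @param table feature table containing all selected features.
#' @return numeric vector of scores, one per row.
#' @export
radscore <- function(model, table) {
  missing <- setdiff(model$features, colnames(table))
  if (length(missing))
    stop_data(sprintf("missing feature column(s): %s",
                      paste(missing, collapse = ", ")))
  X <- as.matrix(table[, model$features, drop = FALSE])
  np <- model$normalization
  if (!is.null(np) && length(model$features)) {
    i <- match(model$features, np$features)
    sdev <- ifelse(np$zero_sd[i], 1, np$sd[i])
    X <- sweep(sweep(X, 2, np$mean[i]), 2, sdev, `/`)
    X[, np$zero_sd[i]] <- 0
  }
  drop(model$intercept + X %*% model$coefficients)
}

#' Fit a full radiomic signature on a training table
#'
#' The training chain of the pipeline: z-normalization fitted on the training
#' rows, SMOTE balancing of the minority class, greedy mRMR filtering to
#' \code{mrmr_k} features and LASSO logistic selection with \code{folds}-fold
#' cross-validation. All parameters are estimated on training rows only.
#'
#' @param train raw training feature table.
#' @param labels training labels (two classes).
#' @param mrmr_k mRMR feature count (default 20).
#' @param folds LASSO CV folds (default 10).
#' @param smote_k SMOTE neighbour count (default 5).
#' @param seed integer seed (SMOTE draws and fold assignment).
#' @return a \code{signature_model} storing the normalization, so
#'   \code{\link{radscore}} accepts raw tables.
#' @export
fit_signature <- function(train, labels, mrmr_k = 20L, folds = 10L,
                          smote_k = 5L, seed = 1L) {
  np <- zscore_fit(train)
  z <- suppressWarnings(zscore_apply(np, train))
  bal <- smote(z, labels, k = smote_k, seed = derive_seed(seed, 1L))
  sel <- mrmr_select(bal$table, bal$labels, k = mrmr_k)
  lasso_cv_fit(bal$table[, sel, drop = FALSE], bal$labels, folds = folds,
               seed = derive_seed(seed, 2L), norm_params = np)
}

#' Serialize / deserialize a signature model as JSON
#' @param model a \code{signature_model}.
#' @param path output file.
#' @export
write_signature_model <- function(model, path) {
  obj <- list(features = model$features,
              coefficients = as.list(model$coefficients),
              intercept = model$intercept,
              lambda = model$lambda,
              positive_class = model$positive_class,
              levels = model$levels,
              folds = model$folds, seed = model$seed,
              normalization = if (!is.null(model$normalization)) list(
                features = model$normalization$features,
                mean = as.list(model$normalization$mean),
                sd = as.list(model$normalization$sd)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  np <- NULL
  if (!is.null(obj$normalization)) {
    mu <- unlist(obj$normalization$mean)
    sdev <- unlist(obj$normalization$sd)
    np <- structure(list(mean = mu, sd = sdev,
                         zero_sd = sdev == 0,
                         features = obj$normalization$features),
                    class = "znorm_params")
  }
  structure(list(normalization = np,
                 features = obj$features,
                 coefficients = setNames(unlist(obj$coefficients),
                                         obj$features),
                 intercept = obj$intercept, lambda = obj$lambda,
                 positive_class = obj$positive_class, levels = obj$levels,
                 folds = obj$folds, seed = obj$seed),
            class = "signature_model")
}
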