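# Splits, ROC/AUC, DeLong, Wilcoxon, Spearman; pROC is the independent
# cross-check for AUC variance computations.

test_that("stratified splits follow the 70/30 rounding rule and partition", {
  labels <- rep(c("AD", "NC"), c(84, 44))
  sp <- split_cohort(labels, split_scheme(seed = 3), 1)
  expect_equal(sum(labels[sp$train] == "AD"), 59)   # round(0.7 * 84)
  expect_equal(sum(labels[sp$train] == "NC"), 31)   # round(0.7 * 44)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_identical(sp, split_cohort(labels, split_scheme(seed = 3), 1))
  sp2 <- split_cohort(labels, split_scheme(seed = 3), 2)
  expect_false(identical(sp, sp2))
  expect_error(split_cohort(c("a", "b", "b"), split_scheme(), 1), "at least 2")
})

test_that("AUC equals the exhaustive pairwise Mann-Whitney oracle", {
  set.seed(17)
  for (i in 1:100) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    scores <- c(rnorm(n1, 0.4), rnorm(n0))
    if (i %% 3 == 0) scores <- round(scores)  # force ties regularly
    pos <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc_auc(scores, factor(pos, levels = c(FALSE, TRUE)),
                 positive = "TRUE")
    expect_equal(r$auc, oracle_auc(scores, pos), tolerance = 1e-12)
    expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  }
})

test_that("ROC degenerate and complementation properties", {
  y <- rep(c("n", "p"), each = 10)
  r <- roc_auc(c(rep(0, 10), rep(1, 10)), y, positive = "p")
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 1)
  r2 <- roc_auc(rep(3, 20), y, positive = "p")
  expect_equal(r2$auc, 0.5)
  set.seed(2)
  s <- rnorm(20)
  expect_equal(roc_auc(-s, y, positive = "p")$auc,
               1 - roc_auc(s, y, positive = "p")$auc)
  expect_error(roc_auc(s, rep("p", 20)), "both classes")
})

test_that("AUC confidence interval agrees with pROC's DeLong interval", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:10) {
    y <- rep(c(0, 1), c(25, 25))
    s <- rnorm(50) + 0.8 * y
    r <- roc_auc(s, factor(y), positive = "1")
    ci <- suppressMessages(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE),
                                        method = "delong"))
    expect_equal(r$auc, as.numeric(ci[2]), tolerance = 1e-10)
    expect_equal(r$ci[1], max(0, as.numeric(ci[1])), tolerance = 1e-8)
    expect_equal(r$ci[2], min(1, as.numeric(ci[3])), tolerance = 1e-8)
  }
})

test_that("DeLong test matches pROC and is antisymmetric", {
  skip_if_not_installed("pROC")
  set.seed(29)
  y <- rep(c(0, 1), c(30, 30))
  a <- rnorm(60) + 0.9 * y
  b <- 0.5 * a + rnorm(60) + 0.4 * y
  d <- delong_test(a, b, factor(y), positive = "1")
  ref <- suppressMessages(pROC::roc.test(
    pROC::roc(y, a, quiet = TRUE), pROC::roc(y, b, quiet = TRUE),
    method = "delong", paired = TRUE))
  expect_equal(abs(d$z), abs(as.numeric(ref$statistic)), tolerance = 1e-10)
  expect_equal(d$p, as.numeric(ref$p.value), tolerance = 1e-10)
  dr <- delong_test(b, a, factor(y), positive = "1")
  expect_equal(dr$z, -d$z)
  expect_equal(dr$p, d$p)
  expect_equal(sign(d$z), sign(d$auc_diff))
  # identical scores: exact null
  d0 <- delong_test(a, a, factor(y), positive = "1")
  expect_equal(d0$z, 0); expect_equal(d0$p, 1)
})

test_that("Wilcoxon rank-sum: exact small-sample p, symmetry, degeneracy", {
  w <- wilcoxon_ranksum(1:10, 11:20)
  expect_equal(w$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(w$method, "exact")
  a <- c(1.2, 3.4, 5.1, 0.3); b <- c(2.2, 4.4, 1.1, 6.3, 0.9)
  expect_equal(wilcoxon_ranksum(a, b)$p, wilcoxon_ranksum(b, a)$p)
  expect_equal(wilcoxon_ranksum(a, b)$p,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(wilcoxon_ranksum(rep(2, 5), rep(2, 7))$p, 1)
  # identical multisets give p = 1 up to tie handling
  x <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_ranksum(x, x)$p, 1)
  # tie-corrected normal approximation against wilcox.test
  set.seed(3)
  big_a <- round(rnorm(30), 1); big_b <- round(rnorm(35), 1)
  expect_equal(wilcoxon_ranksum(big_a, big_b)$p,
               suppressWarnings(wilcox.test(big_a, big_b, exact = FALSE,
                                            correct = FALSE)$p.value),
               tolerance = 1e-10)
})

test_that("Spearman correlation implements the rank-Pearson formula", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10)^3)$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  set.seed(5)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  r <- spearman_cor(x, y)
  expect_equal(r$rho, unname(ref$estimate), tolerance = 1e-12)
  # ties: midranks against cor() on ranks
  xt <- round(x); yt <- round(y)
  expect_equal(spearman_cor(xt, yt)$rho,
               cor(rank(xt), rank(yt)), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(spearman_cor(exp(x), y)$rho, r$rho)
  expect_error(spearman_cor(rep(1, 5), 1:5), "rank variance")
})

test_that("DeLong variance is close to a paired bootstrap variance", {
  set.seed(37)
  y <- rep(c(0, 1), c(25, 25))
  a <- rnorm(50) + 0.7 * y
  b <- 0.6 * a + rnorm(50, sd = 0.8) + 0.3 * y
  d <- delong_test(a, b, factor(y), positive = "1")
  B <- 2000
  pos <- which(y == 1); neg <- which(y == 0)
  boot <- replicate(B, {
    i <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    yy <- factor(y[i]); ppos <- yy == "1"
    (radalff:::delong_placements(a[i], ppos)$auc -
       radalff:::delong_placements(b[i], ppos)$auc)
  })
  expect_lt(abs(var(boot) - d$se^2) / d$se^2, 0.15)
})

test_that("apply_frozen_model reproduces the training ROC and demands all
           features", {
  set.seed(43)
  X <- as.data.frame(matrix(rnorm(60 * 22), 60))
  colnames(X) <- sprintf("f%02d", 1:22)
  y <- factor(rep(c("n", "p"), each = 30), levels = c("n", "p"))
  X$f01 <- X$f01 + 2 * (y == "p")
  m <- fit_signature(X, y, mrmr_k = 8, folds = 5, seed = 9)
  r1 <- roc_auc(radscore(m, X), y, positive = "p")
  r2 <- apply_frozen_model(m, X, y)
  expect_equal(r2$auc, r1$auc, tolerance = 1e-12)
  if (length(m$features))
    expect_error(apply_frozen_model(m, X[, setdiff(names(X), m$features[1])],
                                    y), "missing feature")
})
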