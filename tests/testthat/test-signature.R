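# Normalization, SMOTE, mRMR, LASSO radscore signature.

test_that("z-normalization uses training parameters only (sample sd)", {
  np <- zscore_fit(data.frame(a = c(1, 2, 3)))
  expect_equal(unname(unlist(zscore_apply(np, data.frame(a = c(1, 2, 3))))),
               c(-1, 0, 1))
  set.seed(1)
  train <- as.data.frame(matrix(rnorm(50 * 4, mean = 3, sd = 2), 50))
  colnames(train) <- paste0("f", 1:4)
  np <- zscore_fit(train)
  z <- zscore_apply(np, train)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
  # test rows are transformed with the training parameters, not their own
  test <- train[1:5, ] + 10
  zt <- zscore_apply(np, test)
  expect_equal(as.matrix(zt),
               sweep(as.matrix(z[1:5, ]), 2, 10 / np$sd, `+`),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("constant features are flagged and zeroed with a warning", {
  train <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5))
  np <- zscore_fit(train)
  expect_true(np$zero_sd[["b"]])
  expect_warning(z <- zscore_apply(np, train), "zero-variance")
  expect_equal(z$b, c(0, 0, 0))
})

test_that("SMOTE balances the minority class with convex synthetic rows", {
  set.seed(4)
  X <- as.data.frame(matrix(rnorm(40 * 3), 40))
  colnames(X) <- c("x", "y", "z")
  lab <- rep(c("case", "ctrl"), c(10, 30))
  out <- smote(X, lab, k = 5, seed = 11)
  expect_equal(as.integer(table(out$labels)), c(30L, 30L))
  expect_equal(as.matrix(out$table[1:40, ]), as.matrix(X),
               ignore_attr = TRUE)  # originals preserved
  # every synthetic row solves a 1-D interpolation between two minority rows
  minority <- as.matrix(X[1:10, ])
  synth <- as.matrix(out$table[out$synthetic, ])
  for (i in seq_len(nrow(synth))) {
    s <- synth[i, ]
    ok <- FALSE
    for (a in 1:10) for (b in 1:10) {
      if (a == b) next
      dir <- minority[b, ] - minority[a, ]
      u <- sum((s - minority[a, ]) * dir) / sum(dir^2)
      resid <- s - minority[a, ] - u * dir
      if (u >= -1e-9 && u <= 1 + 1e-9 && max(abs(resid)) < 1e-9) ok <- TRUE
    }
    expect_true(ok)
  }
})

test_that("SMOTE edge cases: balanced input, tiny minority, single row", {
  X <- as.data.frame(matrix(rnorm(20 * 2), 20))
  lab <- rep(c("a", "b"), each = 10)
  out <- smote(X, lab, seed = 2)
  expect_equal(as.matrix(out$table), as.matrix(X), ignore_attr = TRUE)
  lab2 <- rep(c("a", "b"), c(3, 17))
  expect_warning(out2 <- smote(X, lab2, k = 5, seed = 2), "k reduced")
  expect_equal(as.integer(table(out2$labels)), c(17L, 17L))
  lab3 <- rep(c("a", "b"), c(1, 19))
  expect_error(smote(X, lab3, seed = 2), "minority")
})

test_that("mRMR picks the most label-informative feature first and avoids
           duplicate redundancy", {
  set.seed(6)
  n <- 150
  y <- rep(c("p", "n"), each = n / 2)
  X <- as.data.frame(matrix(rnorm(n * 25), n))
  colnames(X) <- sprintf("f%02d", 1:25)
  X$f03 <- X$f03 + 2 * (y == "p")          # strongly informative
  X$f07 <- X$f07 + 0.8 * (y == "p")        # weakly informative
  sel <- mrmr_select(X, y, k = 10)
  expect_length(sel, 10)
  expect_equal(sel[1], "f03")
  # exhaustive MI scan oracle for the first pick
  mi <- vapply(colnames(X), function(f) {
    xd <- radalff:::discretize3(X[[f]])
    radalff:::mutual_information(xd, as.integer(factor(y)))
  }, 0)
  expect_equal(sel[1], names(which.max(mi)))
  # an exact duplicate of the winner is not picked second
  X$f25 <- X$f03
  sel2 <- mrmr_select(X, y, k = 3)
  expect_equal(sel2[1], "f03")
  expect_false(sel2[2] == "f25")
  # brute-force the step-2 MID score
  selected <- sel2[1]
  xd_sel <- radalff:::discretize3(X[[selected]])
  yi <- as.integer(factor(y))
  scores <- vapply(setdiff(colnames(X), selected), function(f) {
    xd <- radalff:::discretize3(X[[f]])
    radalff:::mutual_information(xd, yi) -
      radalff:::mutual_information(xd, xd_sel)
  }, 0)
  expect_equal(sel2[2], names(which.max(scores)))
})

test_that("mRMR count contract and column-order invariance", {
  set.seed(13)
  n <- 60
  y <- rep(c("p", "n"), each = 30)
  X <- as.data.frame(matrix(rnorm(n * 30), n))
  colnames(X) <- sprintf("g%02d", 1:30)
  sel <- mrmr_select(X, y, k = 20)
  expect_length(sel, 20)
  expect_equal(anyDuplicated(sel), 0L)
  perm <- sample(ncol(X))
  expect_equal(mrmr_select(X[, perm], y, k = 20), sel)
  expect_warning(sel_all <- mrmr_select(X[, 1:5], y, k = 20), "candidate")
  expect_length(sel_all, 5)
})

test_that("LASSO recovers a single informative feature across seeds", {
  hits <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n <- 200
    y <- rep(c("ctrl", "case"), each = n / 2)
    X <- matrix(rnorm(n * 15), n)
    colnames(X) <- sprintf("f%02d", 1:15)
    X[, "f05"] <- X[, "f05"] + 2 * (y == "case")   # effect size d = 2
    m <- lasso_cv_fit(as.data.frame(X),
                      factor(y, levels = c("ctrl", "case")),
                      folds = 10, seed = s)
    if ("f05" %in% m$features) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("radscore is the stored linear functional of normalized features", {
  set.seed(21)
  n <- 80
  y <- factor(rep(c("n", "p"), each = 40), levels = c("n", "p"))
  X <- as.data.frame(matrix(rnorm(n * 25), n))
  colnames(X) <- sprintf("f%02d", 1:25)
  X$f01 <- X$f01 + 1.5 * (y == "p")
  model <- fit_signature(X, y, mrmr_k = 10, folds = 5, seed = 3)
  expect_true(all(model$features %in% mrmr_select(
    suppressWarnings(zscore_apply(zscore_fit(X), X)), y, k = 10)) ||
    length(model$features) == 0)
  s <- radscore(model, X)
  # direct dot-product oracle on 5 random subjects
  z <- suppressWarnings(zscore_apply(model$normalization, X))
  for (i in sample(n, 5)) {
    expect_equal(s[i], model$intercept +
      sum(unlist(z[i, model$features]) * model$coefficients),
      tolerance = 1e-12)
  }
  # linearity in a single feature
  if (length(model$features)) {
    f <- model$features[1]
    X2 <- X; X2[[f]] <- X2[[f]] + 1
    delta <- unname(radscore(model, X2) - s)
    expect_equal(delta,
                 rep(unname(model$coefficients[f] / model$normalization$sd[f]), n),
                 tolerance = 1e-10)
  }
  # intercept-only model scores a constant
  m0 <- model; m0$features <- character(0)
  m0$coefficients <- numeric(0)
  expect_equal(radscore(m0, X), rep(m0$intercept, n), ignore_attr = TRUE)
  expect_error(radscore(model, X[, -match(model$features[1], names(X))]),
               model$features[1], fixed = TRUE)
})

test_that("the fitted model is independent of test-set perturbations
           (leakage sentinel)", {
  set.seed(31)
  X <- as.data.frame(matrix(rnorm(60 * 25), 60))
  colnames(X) <- sprintf("f%02d", 1:25)
  y <- factor(rep(c("n", "p"), each = 30), levels = c("n", "p"))
  X$f02 <- X$f02 + 1.2 * (y == "p")
  train_idx <- c(1:20, 31:50)
  m1 <- fit_signature(X[train_idx, ], y[train_idx], mrmr_k = 8, folds = 5,
                      seed = 7)
  Xp <- X
  Xp[-train_idx, ] <- Xp[-train_idx, ] * 100 + 5   # perturb test rows only
  m2 <- fit_signature(Xp[train_idx, ], y[train_idx], mrmr_k = 8, folds = 5,
                      seed = 7)
  expect_identical(m1$features, m2$features)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$intercept, m2$intercept)
})

test_that("signature models survive a JSON round trip", {
  set.seed(41)
  X <- as.data.frame(matrix(rnorm(60 * 22), 60))
  colnames(X) <- sprintf("f%02d", 1:22)
  y <- factor(rep(c("n", "p"), each = 30), levels = c("n", "p"))
  X$f04 <- X$f04 + 2 * (y == "p")
  m <- fit_signature(X, y, mrmr_k = 8, folds = 5, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_model(m, path)
  m2 <- read_signature_model(path)
  expect_equal(radscore(m2, X), radscore(m, X), tolerance = 1e-12)
  expect_equal(m2$features, m$features)
  expect_equal(m2$positive_class, m$positive_class)
})
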