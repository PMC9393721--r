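# Motion QC, Friston-24 expansion, nuisance regression and ALFF.

test_that("framewise displacement follows the 50 mm Power convention", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))
  m[5:10, 1] <- 0.2                       # 0.2 mm step in tx at volume 5
  fd <- framewise_displacement(m)
  expect_equal(fd[5], 0.2)
  expect_equal(fd[-5], rep(0, 9))
  m2 <- matrix(0, 10, 6); m2[5:10, 4] <- 0.01   # 0.01 rad step in rx
  expect_equal(framewise_displacement(m2)[5], 0.5)
  expect_error(framewise_displacement(matrix(NA_real_, 5, 6)), "finite")
})

test_that("FD is invariant to constant offsets of the parameters", {
  set.seed(1)
  m <- matrix(rnorm(60), 10, 6)
  shift <- sweep(m, 2, c(5, -3, 2, 0.1, -0.2, 0.05), `+`)
  expect_equal(framewise_displacement(m), framewise_displacement(shift))
})

test_that("friston24 builds [R, R(t-1), R^2, R(t-1)^2]", {
  set.seed(2)
  m <- matrix(rnorm(48), 8, 6)
  f <- friston24(m)
  expect_equal(dim(f), c(8L, 24L))
  expect_equal(unname(f[, 13:18]), unname(m^2))
  expect_equal(unname(f[, 7:12]), unname(rbind(0, m[-8, ])))
  expect_equal(friston24(matrix(0, 8, 6)), matrix(0, 8, 24),
               ignore_attr = TRUE)
})

test_that("qc_exclude applies the 3 mm / 3 deg / mean-FD 0.5 rules with reasons", {
  clean <- matrix(0, 50, 6)
  trans <- clean; trans[30:50, 2] <- 3.5
  rot <- clean; rot[10:50, 5] <- 3.5 * pi / 180
  fd <- clean; fd[seq(2, 50, 2), 1] <- 0.8   # alternating steps: mean FD ~ 0.78
  subj <- list(ok = clean, bad_trans = trans, bad_rot = rot, bad_fd = fd)
  qc <- qc_exclude(subj)
  expect_equal(qc$kept, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(qc$reason, c("", "translation", "rotation", "FD"))
  expect_gt(qc$mean_fd[4], 0.5)
})

test_that("nuisance regression projects out design components exactly", {
  nt <- 60
  conf <- matrix(rnorm(nt * 2), nt, 2)
  # signal equal to a confound column -> residual ~ 0
  ts <- array(rep(conf[, 1], each = 8), c(2, 2, 2, nt))
  res <- regress_confounds(ts, confounds = conf,
                           include_linear_trend = FALSE)
  expect_lt(max(abs(res)), 1e-10)
  # pure linear ramp with trend regression on -> residual ~ 0
  ts2 <- array(rep(3 * seq_len(nt) + 2, each = 8), c(2, 2, 2, nt))
  res2 <- regress_confounds(ts2)
  expect_lt(max(abs(res2)), 1e-8)
})

test_that("a series orthogonal to the design is returned unchanged", {
  nt <- 64
  # cosine centered on the scan midpoint: zero mean over full cycles (so
  # orthogonal to the intercept) and even about the centre (so orthogonal to
  # the centered linear trend)
  x <- cos(2 * pi * 8 * (seq_len(nt) - (nt + 1) / 2) / nt)
  ts <- array(rep(x, each = 8), c(2, 2, 2, nt))
  res <- regress_confounds(ts)
  # explicit normal-equations oracle
  X <- cbind(1, seq_len(nt) - (nt + 1) / 2)
  beta <- solve(t(X) %*% X, t(X) %*% x)
  oracle <- x - X %*% beta
  expect_equal(res[1, 1, 1, ], as.vector(oracle), tolerance = 1e-10)
  expect_lt(max(abs(res[1, 1, 1, ] - x)), 1e-8)
})

test_that("residuals are orthogonal to all design columns", {
  set.seed(5)
  nt <- 50
  conf <- friston24(matrix(rnorm(nt * 6, sd = 0.1), nt, 6))
  ts <- array(rnorm(8 * nt), c(2, 2, 2, nt))
  res <- regress_confounds(ts, confounds = conf)
  X <- cbind(1, seq_len(nt) - (nt + 1) / 2, conf)
  r <- matrix(res, nrow = 8)
  ip <- t(X) %*% t(r)
  expect_lt(max(abs(ip)) / max(abs(r)), 1e-8)
})

test_that("collinear design columns are dropped with a warning", {
  nt <- 40
  conf <- cbind(a = rnorm(nt))
  conf <- cbind(conf, b = 2 * conf[, 1])
  ts <- array(rnorm(8 * nt), c(2, 2, 2, nt))
  expect_warning(regress_confounds(ts, confounds = conf), "collinear")
})

test_that("ALFF of a bin-aligned sinusoid equals amplitude / bin count", {
  tt <- (0:199) * 2
  ts <- array(rep(sin(2 * pi * 0.02 * tt), each = 8), c(2, 2, 2, 200))
  a <- compute_alff(ts, band = band_spec(n_discard = 0), tr = 2)
  expect_length(a$freq_bins, 7)          # 0.0025 Hz spacing, 0.01..0.025
  expect_lt(abs(a$map[1, 1, 1] - 1 / 7), 1e-10)
  # constant series -> 0 (DC excluded)
  z <- compute_alff(array(5, c(2, 2, 2, 200)),
                    band = band_spec(n_discard = 0), tr = 2)
  expect_lt(max(abs(z$map)), 1e-10)
  # homogeneity
  a3 <- compute_alff(3 * ts, band = band_spec(n_discard = 0), tr = 2)
  expect_equal(a3$map, 3 * a$map, tolerance = 1e-12)
})

test_that("multi-sinusoid ALFF equals the mean of in-band component amplitudes", {
  tt <- (0:199) * 2
  amp <- c(0.8, 1.3, 2.1)
  fr <- c(0.0125, 0.02, 0.025)            # all bin-aligned, in-band
  x <- amp[1] * sin(2 * pi * fr[1] * tt + 0.3) +
       amp[2] * sin(2 * pi * fr[2] * tt + 1.1) +
       amp[3] * sin(2 * pi * fr[3] * tt + 2.0)
  ts <- array(rep(x, each = 8), c(2, 2, 2, 200))
  a <- compute_alff(ts, band = band_spec(n_discard = 0), tr = 2)
  expect_lt(abs(a$map[1, 1, 1] - sum(amp) / 7) / (sum(amp) / 7), 1e-10)
})

test_that("ALFF is nonnegative, zero outside the mask, and scales with noise sd", {
  set.seed(9)
  msk <- array(0, c(4, 4, 4)); msk[2:3, 2:3, 2:3] <- 1
  means <- sapply(c(0.5, 1, 2), function(s) {
    ts <- array(rnorm(64 * 128, sd = s), c(4, 4, 4, 128))
    a <- compute_alff(ts, msk, band = band_spec(n_discard = 0), tr = 2)
    expect_true(all(a$map >= 0))
    expect_equal(sum(a$map[msk == 0]), 0)
    mean(a$map[msk == 1])
  })
  slope <- coef(lm(means ~ c(0.5, 1, 2)))[2]
  expect_gt(slope, 0)
})

test_that("ALFF configuration errors are raised", {
  ts <- array(rnorm(8 * 40), c(2, 2, 2, 40))
  expect_error(compute_alff(ts, band = band_spec(n_discard = 39), tr = 2),
               "volumes")
  expect_error(compute_alff(ts, band = band_spec(0.2, 0.3, 0), tr = 2),
               "Nyquist")
  ts2 <- array(rnorm(8 * 40), c(2, 2, 2, 40))
  expect_error(compute_alff(ts2, band = band_spec(0.001, 0.002, 0), tr = 2),
               "no frequency bins")
})

test_that("the subject-level chain discards volumes then regresses then
           transforms", {
  spec <- tiny_spec(seed = 4)
  s <- generate_subject(spec, "case", 77)
  mask <- combine_bilateral(s$masks$left, s$masks$right)
  a <- subject_alff(s$functional, s$motion, mask, band_spec(), tr = s$tr)
  expect_equal(a$n_used, spec$n_volumes - 10L)
  expect_true(all(a$map >= 0))
  expect_equal(sum(a$map[mask == 0]), 0)
})
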