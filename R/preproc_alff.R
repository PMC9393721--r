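#' Framewise displacement (Power convention)
#'
#' FD at volume t is the sum of absolute backward differences of the three
#' translations (mm) plus 50 mm times the sum of absolute differences of the
#' three rotations (rad), i.e. arc length on a 50 mm sphere. FD of the first
#' volume is 0 by definition. FD depends only on parameter differences, so it
#' is invariant to adding a constant to every column.
#'
#' @param motion numeric matrix n_volumes x 6 (tx,ty,tz mm; rx,ry,rz rad).
#' @param head_radius_mm rotation-to-arc conversion radius (default 50).
#' @return numeric vector of length n_volumes, nonnegative, first element 0.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L || ncol(motion) != 6L)
    stop_data("motion trace must be an n x 6 matrix with n >= 2")
  if (!all(is.finite(motion)))
    stop_data("motion trace contains non-finite values")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Motion quality-control thresholds
#'
#' Defaults follow the usual resting-state exclusion rules: maximum absolute
#' translation 3 mm, maximum absolute rotation 3 degrees, mean framewise
#' displacement 0.5 mm.
#'
#' @param max_translation_mm,max_rotation_deg,max_mean_fd_mm positive limits.
#' @param fd_summary \code{"mean"} (default) or \code{"max"}: which FD
#'   summary is compared against \code{max_mean_fd_mm}.
#' @return an object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(max_translation_mm = 3, max_rotation_deg = 3,
                          max_mean_fd_mm = 0.5, fd_summary = c("mean", "max")) {
  stopifnot(max_translation_mm > 0, max_rotation_deg > 0, max_mean_fd_mm > 0)
  structure(list(max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 max_mean_fd_mm = max_mean_fd_mm,
                 fd_summary = match.arg(fd_summary)),
            class = "qc_thresholds")
}

#' Motion-based subject exclusion
#'
#' A subject is excluded iff any |translation| exceeds the translation limit,
#' any |rotation| exceeds the rotation limit (input rotations are radians,
#' the limit is degrees), or the FD summary (mean by default) exceeds the FD
#' limit. Reasons are recorded per subject; a subject can fail several rules.
#'
#' @param subjects either a list of \code{synthetic_subject}s or a named list
#'   of motion matrices (n_volumes x 6).
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return data frame with one row per subject: \code{subject_id},
#'   \code{max_trans}, \code{max_rot_deg}, \code{mean_fd}, \code{kept},
#'   \code{reason} (comma-separated, \code{""} if kept).
#' @export
qc_exclude <- function(subjects, thresholds = qc_thresholds()) {
  get_motion <- function(s) {
    if (is.list(s) && !is.null(s$motion)) s$motion
    else if (is.matrix(s)) s
    else stop_data("subject without a motion trace")
  }
  ids <- names(subjects)
  if (is.null(ids))
    ids <- vapply(seq_along(subjects), function(i) {
      s <- subjects[[i]]
      if (is.list(s) && !is.null(s$subject_id)) s$subject_id
      else sprintf("subject-%03d", i)
    }, "")
  rows <- lapply(seq_along(subjects), function(i) {
    m <- get_motion(subjects[[i]])
    fd <- framewise_displacement(m)
    fd_stat <- if (thresholds$fd_summary == "mean") mean(fd) else max(fd)
    max_trans <- max(abs(m[, 1:3]))
    max_rot_deg <- max(abs(m[, 4:6])) * 180 / pi
    reasons <- c(
      if (max_trans > thresholds$max_translation_mm) "translation",
      if (max_rot_deg > thresholds$max_rotation_deg) "rotation",
      if (fd_stat > thresholds$max_mean_fd_mm) "FD")
    data.frame(subject_id = ids[i], max_trans = max_trans,
               max_rot_deg = max_rot_deg, mean_fd = mean(fd),
               kept = length(reasons) == 0L,
               reason = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Friston 24-parameter motion confound expansion
#'
#' Columns 1-6 are the realignment parameters R(t), 7-12 the one-volume lag
#' R(t-1) (first row zero), 13-18 the squares R(t)^2 and 19-24 the lagged
#' squares R(t-1)^2.
#'
#' @param motion numeric matrix n_volumes x 6.
#' @return numeric matrix n_volumes x 24.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L || ncol(motion) != 6L)
    stop_data("motion trace must be an n x 6 matrix with n >= 2")
  lag <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag, motion^2, lag^2)
  colnames(out) <- c(paste0(colnames(motion) %||% paste0("p", 1:6)),
                     paste0("lag_", 1:6), paste0("sq_", 1:6),
                     paste0("lagsq_", 1:6))
  out
}

#' Voxelwise nuisance regression
#'
#' Ordinary least squares of every voxel time series inside the mask on an
#' intercept, an optional linear trend, the supplied confound matrix (e.g.
#' \code{\link{friston24}} output) and optional tissue mean series (white
#' matter / CSF). Residuals are returned; collinear design columns are
#' dropped with a warning.
#'
#' @param ts 4D array (x, y, z, time).
#' @param mask binary 3D array; voxels outside keep their original series.
#' @param confounds numeric matrix with one row per volume, or NULL.
#' @param include_linear_trend add a linear trend regressor (default TRUE).
#' @param tissue_signals optional matrix of extra mean series (rows = volumes).
#' @return 4D array of residuals (zero mean inside the mask).
#' @export
regress_confounds <- function(ts, mask = NULL, confounds = NULL,
                              include_linear_trend = TRUE,
                              tissue_signals = NULL) {
  d <- dim(ts)
  stopifnot(length(d) == 4L)
  nt <- d[4]
  if (is.null(mask)) mask <- array(1, d[1:3])
  check_same_shape(array(0, d[1:3]), mask, "time series and mask")
  X <- cbind(intercept = rep(1, nt))
  if (include_linear_trend) X <- cbind(X, trend = seq_len(nt) - (nt + 1) / 2)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nt)
      stop_data("confound rows must equal the number of volumes")
    X <- cbind(X, confounds)
  }
  if (!is.null(tissue_signals)) {
    tissue_signals <- as.matrix(tissue_signals)
    if (nrow(tissue_signals) != nt)
      stop_data("tissue signal rows must equal the number of volumes")
    X <- cbind(X, tissue_signals)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning(sprintf("dropping %d collinear design column(s)",
                    ncol(X) - qrX$rank))
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  idx <- which(mask > 0)
  Y <- t(matrix(ts, nrow = prod(d[1:3]))[idx, , drop = FALSE]) # nt x V
  res <- qr.resid(qrX, Y)
  out <- matrix(ts, nrow = prod(d[1:3]))
  out[idx, ] <- t(res)
  array(out, d)
}

#' Frequency-band specification for ALFF
#'
#' @param low_hz,high_hz band edges in Hz (closed interval; a discrete
#'   frequency bin is in-band iff \code{low_hz <= f <= high_hz}).
#' @param n_discard initial volumes discarded before analysis (default 10).
#' @return an object of class \code{band_spec}.
#' @export
band_spec <- function(low_hz = 0.01, high_hz = 0.027, n_discard = 10L) {
  stopifnot(low_hz > 0, high_hz > low_hz, n_discard >= 0)
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 n_discard = as.integer(n_discard)), class = "band_spec")
}

#' Slow-band amplitude of low-frequency fluctuation (ALFF)
#'
#' After discarding the first \code{band$n_discard} volumes, each voxel series
#' inside the mask is Fourier transformed and ALFF is the mean, over the
#' discrete frequency bins falling inside the closed band, of the
#' single-sided spectral amplitude \code{2|X(f)|/N}. The DC bin is always
#' excluded. No global-mean standardization is applied unless
#' \code{standardize = TRUE} (division by the within-mask mean ALFF).
#'
#' The series is expected to be detrended / confound-regressed beforehand
#' (see \code{\link{regress_confounds}}); \code{compute_alff} itself only
#' removes the series mean (via DC exclusion).
#'
#' @param ts 4D array (x, y, z, time).
#' @param mask binary 3D array of voxels to analyse (NULL = whole volume).
#' @param band a \code{\link{band_spec}}.
#' @param tr repetition time in seconds.
#' @param standardize divide by the mean within-mask ALFF (off by default).
#' @return list with \code{map} (3D array, zero outside mask), \code{band},
#'   \code{n_used} (volumes used), \code{freq_bins} (Hz of the in-band bins).
#' @export
compute_alff <- function(ts, mask = NULL, band = band_spec(), tr,
                         standardize = FALSE) {
  d <- dim(ts)
  stopifnot(length(d) == 4L, tr > 0)
  if (is.null(mask)) mask <- array(1, d[1:3])
  check_same_shape(array(0, d[1:3]), mask, "time series and mask")
  if (band$n_discard >= d[4])
    stop_data("n_discard leaves no volumes")
  nt <- d[4] - band$n_discard
  if (nt < 32L)
    stop_data("fewer than 32 volumes remain after discarding")
  nyq <- 1 / (2 * tr)
  if (band$high_hz > nyq)
    stop_data("band exceeds the Nyquist frequency for this TR")
  freqs <- (seq_len(nt) - 1) / (nt * tr)        # bin k -> (k-1)/(N*TR)
  inband <- which(freqs >= band$low_hz & freqs <= band$high_hz &
                    seq_len(nt) > 1L & freqs <= nyq + 1e-12)
  if (!length(inband))
    stop_data("no frequency bins fall inside the band; increase scan length")
  idx <- which(mask > 0)
  Y <- matrix(ts, nrow = prod(d[1:3]))[idx, , drop = FALSE]
  Y <- Y[, (band$n_discard + 1):d[4], drop = FALSE]       # V x nt
  sp <- stats::mvfft(t(Y))                                 # nt x V
  amp <- 2 * Mod(sp[inband, , drop = FALSE]) / nt
  alff <- colMeans(amp)
  if (standardize && mean(alff) > 0) alff <- alff / mean(alff)
  map <- array(0, d[1:3])
  map[idx] <- alff
  structure(list(map = map, band = band, n_used = nt,
                 freq_bins = freqs[inband]), class = "alff_map")
}
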