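#' Specify a synthetic multimodal cohort
#'
#' Defines the generative model for a cohort of paired structural volumes and
#' resting-state functional time series with hippocampus-like ellipsoidal
#' ROIs, rigid-body motion traces and a clinical score. Group effects are
#' planted through two orthogonal mechanisms: \code{texture_effect} widens
#' the Gaussian smoothing kernel of the structural texture field inside the
#' ROI for patient groups (changing spatial correlation without changing
#' first-order intensity statistics), and \code{alff_effect} scales the
#' amplitude of low-frequency (0.01-0.027 Hz) oscillations in the functional
#' channel of patient groups by \code{1 + alff_effect}.
#'
#' Defaults mirror a three-group dementia cohort: 84 AD, 50 aMCI and 44
#' normal controls, TR = 2 s, 210 functional volumes, and an MMSE-like
#' clinical score (AD 17.512 +/- 5.084, aMCI 26.200 +/- 0.881,
#' NC 29.023 +/- 0.902). The default grid emulates the functional (EPI)
#' resolution, where a human hippocampus spans roughly 100 voxels; each
#' hemisphere ROI is an ellipsoid of about 110 voxels.
#'
#' @param n_per_group named integer vector: subjects per group label.
#' @param image_shape voxel dimensions of both channels (length 3).
#' @param roi_spec list with elements \code{left} and \code{right}, each a
#'   list with \code{center} and \code{radii} in voxels (1-based center).
#' @param tr_seconds repetition time of the functional channel.
#' @param n_volumes number of functional volumes (before any discarding).
#' @param texture_effect nonnegative scalar: added smoothing width (voxels)
#'   in patient groups.
#' @param alff_effect nonnegative scalar: relative in-band amplitude increase
#'   in patient groups.
#' @param noise_sd standard deviation of the white observation noise (> 0).
#' @param drift_slope linear drift per volume added to every functional voxel.
#' @param osc_freqs oscillation frequencies in Hz; the defaults are aligned
#'   with the discrete frequency grid of the default TR and length.
#' @param osc_amplitude baseline amplitude of each oscillatory component.
#' @param motion_profile list with \code{walk_sd_mm}, \code{walk_sd_rad}
#'   (random-walk step SDs) and optionally \code{jumps}, a data frame with
#'   columns \code{subject} (index), \code{volume}, \code{trans_mm},
#'   \code{rot_rad} planting a step displacement for chosen subjects.
#' @param clinical_score_model list with named vectors \code{means} and
#'   \code{sds} (per group); groups absent from \code{means} fall back to a
#'   linear map of the group index.
#' @param patient_groups labels receiving the planted effects; default all
#'   groups except \code{"NC"} and \code{"control"}.
#' @param seed master integer seed; per-subject seeds are derived by
#'   \code{\link{derive_seed}}.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = c(AD = 84L, aMCI = 50L, NC = 44L),
                        image_shape = c(20L, 16L, 12L),
                        roi_spec = list(
                          left  = list(center = c(6, 8, 6),  radii = c(3, 3, 3)),
                          right = list(center = c(15, 8, 6), radii = c(3, 3, 3))),
                        tr_seconds = 2,
                        n_volumes = 210L,
                        texture_effect = 0.5,
                        alff_effect = 0.5,
                        noise_sd = 1,
                        drift_slope = 0.01,
                        osc_freqs = c(0.0125, 0.02, 0.025),
                        osc_amplitude = 1,
                        motion_profile = list(walk_sd_mm = 0.02,
                                              walk_sd_rad = 2e-4,
                                              jumps = NULL),
                        clinical_score_model = list(
                          means = c(AD = 17.512, aMCI = 26.200, NC = 29.023),
                          sds   = c(AD = 5.084,  aMCI = 0.881,  NC = 0.902)),
                        patient_groups = NULL,
                        seed = 1L) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == ""))
    stop_data("n_per_group must be a named vector of group sizes")
  if (any(n_per_group < 2L))
    stop_data("n_per_group: every group needs at least 2 subjects")
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 3L, all(image_shape >= 4L))
  for (side in c("left", "right")) {
    r <- roi_spec[[side]]
    if (is.null(r)) stop_data("roi_spec needs 'left' and 'right' ellipsoids")
    lo <- r$center - r$radii; hi <- r$center + r$radii
    if (any(lo < 1) || any(hi > image_shape))
      stop_data(sprintf("roi_spec$%s extends outside image_shape", side))
  }
  if (texture_effect < 0 || alff_effect < 0)
    stop_data("texture_effect and alff_effect must be >= 0")
  if (noise_sd <= 0) stop_data("noise_sd must be > 0")
  if (n_volumes * tr_seconds < 1 / 0.01)
    stop_data(paste0("n_volumes too small: the scan must span at least ",
                     "1/0.01 = 100 s to resolve the slow-5 band"))
  if (is.null(patient_groups))
    patient_groups <- setdiff(names(n_per_group), c("NC", "control"))
  structure(list(
    n_per_group = n_per_group, image_shape = image_shape,
    roi_spec = roi_spec, tr_seconds = tr_seconds,
    n_volumes = as.integer(n_volumes),
    texture_effect = texture_effect, alff_effect = alff_effect,
    noise_sd = noise_sd, drift_slope = drift_slope,
    osc_freqs = osc_freqs, osc_amplitude = osc_amplitude,
    motion_profile = motion_profile,
    clinical_score_model = clinical_score_model,
    patient_groups = patient_groups, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", paste(sprintf("%s=%d", names(x$n_per_group),
                                     x$n_per_group), collapse = ", "),
      sprintf("| %s voxels | %d vols @ TR %gs | texture %.2f alff %.2f\n",
              paste(x$image_shape, collapse = "x"), x$n_volumes,
              x$tr_seconds, x$texture_effect, x$alff_effect))
  invisible(x)
}

#' Ellipsoidal binary mask
#' @param shape image dimensions (length 3).
#' @param center ellipsoid center in voxels (1-based).
#' @param radii semi-axes in voxels.
#' @return binary 3D array.
#' @export
ellipsoid_mask <- function(shape, center, radii) {
  ix <- (seq_len(shape[1]) - center[1]) / radii[1]
  iy <- (seq_len(shape[2]) - center[2]) / radii[2]
  iz <- (seq_len(shape[3]) - center[3]) / radii[3]
  d2 <- outer(outer(ix^2, iy^2, `+`), iz^2, `+`)
  array(as.numeric(d2 <= 1), dim = shape)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Truncated (3 sigma) kernel, renormalized at the edges.
#' @param arr 3D array.
#' @param sigma kernel SD in voxels; \code{sigma <= 0} returns \code{arr}.
#' @return smoothed array of the same shape.
#' @export
smooth_gaussian <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  smooth_axis <- function(m, n) {
    # m: n x q matrix, smooth down columns with edge renormalization
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - half):min(n, i + half)
      w <- k[j - i + half + 1L]
      K[i, j] <- w / sum(w)
    }
    K %*% m
  }
  a <- smooth_axis(matrix(arr, d[1]), d[1])                      # x
  a <- array(a, d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(smooth_axis(matrix(a, d[2]), d[2]), d[c(2, 1, 3)])  # y
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 1, 2))
  a <- array(smooth_axis(matrix(a, d[3]), d[3]), d[c(3, 1, 2)])  # z
  aperm(a, c(2, 3, 1))
}

#' @keywords internal
group_score <- function(spec, group) {
  m <- spec$clinical_score_model
  if (!is.null(m$means) && group %in% names(m$means)) {
    c(mean = unname(m$means[group]), sd = unname(m$sds[group] %||% 1))
  } else {
    i <- match(group, names(spec$n_per_group))
    c(mean = 29 - 6 * (i - 1), sd = 2)
  }
}

#' Generate one synthetic subject
#'
#' Fully deterministic given \code{(spec, group, subject_seed)}. The
#' structural channel is a baseline plus, inside each ROI, a Gaussian random
#' field smoothed with kernel width \code{0.6 + texture_effect} voxels for
#' patient groups (0.6 otherwise) and re-standardized within the ROI so that
#' first-order statistics carry no group information. The functional channel
#' is baseline + linear drift + in-band sinusoids whose amplitude is spatially
#' modulated by a smooth positive field and scaled by
#' \code{1 + alff_effect} in patient groups, plus white Gaussian noise.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param group group label (must appear in \code{spec$n_per_group}).
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier string.
#' @param jump optional planted motion jump: list/vector with
#'   \code{volume}, \code{trans_mm}, \code{rot_rad}.
#' @return a \code{synthetic_subject}: list with \code{subject_id},
#'   \code{group}, \code{structural} (3D), \code{functional} (4D),
#'   \code{masks} (left/right binary arrays), \code{motion}
#'   (n_volumes x 6: tx,ty,tz mm, rx,ry,rz rad), \code{score}, \code{geom},
#'   \code{tr}.
#' @export
generate_subject <- function(spec, group, subject_seed,
                             subject_id = sprintf("sub-%05d", subject_seed %% 1e5),
                             jump = NULL) {
  if (!group %in% names(spec$n_per_group))
    stop_data(sprintf("unknown group '%s'", group))
  is_patient <- group %in% spec$patient_groups
  shp <- spec$image_shape
  masks <- lapply(spec$roi_spec, function(r)
    ellipsoid_mask(shp, r$center, r$radii))
  roi_any <- (masks$left + masks$right) > 0

  with_seed(subject_seed, {
    ## --- structural channel -------------------------------------------
    sigma <- 0.6 + if (is_patient) spec$texture_effect else 0
    field <- smooth_gaussian(array(rnorm(prod(shp)), dim = shp), sigma)
    structural <- 100 + array(rnorm(prod(shp), sd = spec$noise_sd), dim = shp)
    for (mk in masks) {
      idx <- which(mk > 0)
      v <- field[idx]
      # standardize the smoothed field within the ROI so its first-order
      # statistics carry no group information; white observation noise stays
      v <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
      structural[idx] <- structural[idx] + 10 + 10 * v
    }

    ## --- functional channel -------------------------------------------
    nt <- spec$n_volumes
    tt <- (seq_len(nt) - 1) * spec$tr_seconds
    phases <- runif(length(spec$osc_freqs), 0, 2 * pi)
    sinmat <- sapply(seq_along(spec$osc_freqs), function(k)
      sin(2 * pi * spec$osc_freqs[k] * tt + phases[k]))   # nt x K
    osc <- rowSums(sinmat) * spec$osc_amplitude
    ampfield <- exp(0.4 * smooth_gaussian(array(rnorm(prod(shp)), dim = shp), 1.5))
    scale_grp <- 1 + if (is_patient) spec$alff_effect else 0
    nv <- prod(shp)
    fmat <- matrix(rnorm(nv * nt, sd = spec$noise_sd), nv, nt)
    drift <- spec$drift_slope * (seq_len(nt) - 1)
    fmat <- fmat + rep(100 + drift, each = nv)            # baseline + drift
    idx <- which(roi_any)
    fmat[idx, ] <- fmat[idx, ] +
      outer(ampfield[idx] * scale_grp, osc)               # V x nt signal
    functional <- array(fmat, dim = c(shp, nt))

    ## --- motion trace --------------------------------------------------
    mp <- spec$motion_profile
    steps <- cbind(matrix(rnorm(3 * nt, sd = mp$walk_sd_mm), nt, 3),
                   matrix(rnorm(3 * nt, sd = mp$walk_sd_rad), nt, 3))
    steps[1, ] <- 0
    motion <- apply(steps, 2, cumsum)
    if (!is.null(jump)) {
      v0 <- max(2L, as.integer(jump$volume %||% 2L))
      period <- jump$period %||% NA
      if (!is.na(period) && !is.null(period)) {
        # sustained square-wave movement: raises FD without large absolute
        # displacement (amplitude trans_mm/2, step size trans_mm)
        tog <- ((seq(v0, nt) - v0) %/% period) %% 2
        motion[v0:nt, 1] <- motion[v0:nt, 1] +
          (tog - 0.5) * (jump$trans_mm %||% 0)
        motion[v0:nt, 4] <- motion[v0:nt, 4] +
          (tog - 0.5) * (jump$rot_rad %||% 0)
      } else {
        motion[v0:nt, 1] <- motion[v0:nt, 1] + (jump$trans_mm %||% 0)
        motion[v0:nt, 4] <- motion[v0:nt, 4] + (jump$rot_rad %||% 0)
      }
    }
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

    sc <- group_score(spec, group)
    score <- rnorm(1, sc["mean"], sc["sd"])

    structure(list(subject_id = subject_id, group = group,
                   structural = structural, functional = functional,
                   masks = masks, motion = motion, score = score,
                   geom = vox_geometry(shp), tr = spec$tr_seconds),
              class = "synthetic_subject")
  })
}

#' Generate a full synthetic cohort
#'
#' Subjects are generated group by group in the order of
#' \code{spec$n_per_group}; subject \code{i} uses seed
#' \code{derive_seed(spec$seed, i)}, so any subject can be regenerated in
#' isolation and two cohorts from the same spec are bit-identical.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list with \code{subjects} (list of \code{synthetic_subject}) and
#'   \code{table} (data frame: subject_id, group, score, motion_path).
#' @export
generate_cohort <- function(spec) {
  groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
  n <- length(groups)
  jumps <- spec$motion_profile$jumps
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    jump <- NULL
    if (!is.null(jumps)) {
      row <- jumps[jumps$subject == i, , drop = FALSE]
      if (nrow(row)) jump <- as.list(row[1, ])
    }
    subjects[[i]] <- generate_subject(
      spec, groups[i], derive_seed(spec$seed, i),
      subject_id = sprintf("sub-%03d", i), jump = jump)
  }
  tab <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    group = groups,
    score = vapply(subjects, `[[`, 0, "score"),
    motion_path = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects, table = tab, spec = spec),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' NIfTI-1 images and masks, 6-column whitespace-delimited motion traces
#' (translations mm, rotations rad), a subject table CSV and a JSON sidecar
#' recording the generating parameters and seed.
#'
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param dir output directory (created if needed).
#' @return the subject-table path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort$table
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    base <- file.path(dir, s$subject_id)
    write_volume(s$structural, paste0(base, "_T1w.nii.gz"), s$geom)
    write_volume(s$functional, paste0(base, "_bold.nii.gz"), s$geom, tr = s$tr)
    write_volume(s$masks$left,  paste0(base, "_mask-left.nii.gz"), s$geom)
    write_volume(s$masks$right, paste0(base, "_mask-right.nii.gz"), s$geom)
    mp <- paste0(base, "_motion.txt")
    write.table(format(s$motion, digits = 17), mp, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    tab$motion_path[i] <- mp
  }
  csv <- file.path(dir, "subjects.csv")
  write.csv(tab, csv, row.names = FALSE)
  spec <- cohort$spec
  side <- spec[c("n_per_group", "image_shape", "tr_seconds", "n_volumes",
                 "texture_effect", "alff_effect", "noise_sd", "drift_slope",
                 "osc_freqs", "osc_amplitude", "patient_groups", "seed")]
  jsonlite::write_json(side, file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read a motion trace file
#' @param path whitespace-delimited 6-column text file.
#' @return numeric matrix n_volumes x 6.
#' @export
read_motion <- function(path) {
  m <- as.matrix(read.table(path))
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}
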