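#' Fixed-bin-number gray-level discretization within an ROI
#'
#' Levels are \code{1 + floor(n_bins * (x - min) / (max - min))} with the
#' maximum mapped to \code{n_bins}; a constant ROI maps every voxel to level
#' 1. The fixed-bin-number scheme is invariant under monotone affine
#' transforms of the intensities, which makes texture features scale-free
#' (structural and ALFF intensities live on incomparable scales).
#'
#' The returned level array is cropped to the ROI bounding box with
#' \code{NA} outside the ROI, so all texture computations are translation
#' invariant by construction.
#'
#' @param image 3D numeric array.
#' @param mask binary 3D array, same shape, non-empty.
#' @param n_bins number of gray levels (>= 2).
#' @return an object of class \code{discretized_roi}: list with
#'   \code{levels} (integer 3D array, NA outside ROI), \code{n_g},
#'   \code{range} (original intensity min/max), \code{n_voxels},
#'   \code{values} (raw ROI intensities, for first-order features).
#' @export
discretize <- function(image, mask, n_bins = 32L) {
  check_same_shape(image, mask, "image and mask")
  if (!is_binary_mask(mask)) stop_data("mask must be a binary 3D array")
  if (n_bins < 2L) stop_data("n_bins must be >= 2")
  idx <- which(mask > 0)
  if (!length(idx)) stop_data("ROI is empty")
  vals <- image[idx]
  if (any(!is.finite(vals))) stop_data("non-finite intensities inside ROI")
  rng <- range(vals)
  lev <- if (rng[1] == rng[2]) rep(1L, length(vals)) else {
    l <- 1L + as.integer(floor(n_bins * (vals - rng[1]) / (rng[2] - rng[1])))
    l[l > n_bins] <- as.integer(n_bins)
    l
  }
  full <- array(NA_integer_, dim = dim(mask))
  full[idx] <- lev
  # crop to bounding box
  pos <- which(mask > 0, arr.ind = TRUE)
  rr <- apply(pos, 2, range)
  cropped <- full[rr[1, 1]:rr[2, 1], rr[1, 2]:rr[2, 2], rr[1, 3]:rr[2, 3],
                  drop = FALSE]
  structure(list(levels = cropped, n_g = as.integer(n_bins), range = rng,
                 n_voxels = length(idx), values = vals),
            class = "discretized_roi")
}

#' The 13 unique distance-1 direction offsets of the 26-neighbourhood
#' @return 13 x 3 integer matrix (one row per direction, up to sign).
#' @export
texture_directions <- function() {
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
             c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(m) <- "integer"
  m
}
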