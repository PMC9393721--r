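#' Dice overlap coefficient between two binary masks
#'
#' \code{2 |A intersect B| / (|A| + |B|)}; symmetric, 1 for identical
#' non-empty masks, 0 for disjoint masks. Undefined (error) when both masks
#' are empty.
#'
#' @param a,b binary 3D arrays with identical dimensions.
#' @return a number in [0, 1].
#' @export
dice <- function(a, b) {
  check_same_shape(a, b, "masks")
  if (!is_binary_mask(a) || !is_binary_mask(b))
    stop_data("masks must be binary 3D arrays")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop_data("dice is undefined for two empty masks")
  2 * sum(a * b) / (na + nb)
}

#' Nearest-neighbour mask resampling between voxel grids
#'
#' Each target voxel centre is mapped to world coordinates through the target
#' affine, optionally through a world-to-world rigid/affine transform, and
#' back into source voxel space, where the nearest source voxel is sampled.
#' Nearest-neighbour interpolation keeps labels binary. With an identity
#' transform and equal geometries the input is returned unchanged.
#'
#' @param mask binary 3D array in the source grid.
#' @param source_geom,target_geom \code{\link{vox_geometry}} objects.
#' @param transform optional 4x4 world-to-world affine (source to target
#'   world); must be invertible.
#' @return binary 3D array on the target grid.
#' @export
resample_mask <- function(mask, source_geom, target_geom, transform = NULL) {
  if (!is_binary_mask(mask)) stop_data("mask must be a binary 3D array")
  if (!identical(dim(mask), as.integer(source_geom$dim)) &&
      !identical(dim(mask), source_geom$dim))
    stop_data("mask does not match source geometry")
  if (is.null(transform)) transform <- diag(4)
  if (abs(det(transform)) < .Machine$double.eps)
    stop_data("transform must be invertible")
  if (identical(source_geom$dim, target_geom$dim) &&
      isTRUE(all.equal(source_geom$affine, target_geom$affine)) &&
      isTRUE(all.equal(transform, diag(4))))
    return(mask)
  td <- target_geom$dim
  ijk <- as.matrix(expand.grid(i = seq_len(td[1]) - 1L,
                               j = seq_len(td[2]) - 1L,
                               k = seq_len(td[3]) - 1L))
  world <- voxel_to_world(target_geom, ijk)
  world <- t(solve(transform) %*% rbind(t(world), 1))[, 1:3, drop = FALSE]
  src <- round(world_to_voxel(source_geom, world))  # 0-based
  sd3 <- dim(mask)
  inside <- src[, 1] >= 0 & src[, 1] < sd3[1] &
            src[, 2] >= 0 & src[, 2] < sd3[2] &
            src[, 3] >= 0 & src[, 3] < sd3[3]
  out <- numeric(nrow(src))
  lin <- src[inside, 1] + sd3[1] * (src[inside, 2] + sd3[2] * src[inside, 3]) + 1
  out[inside] <- mask[lin]
  array(out, td)
}

#' Combine left and right masks into a bilateral mask
#'
#' Voxelwise union. The two masks are expected to be disjoint; overlapping
#' masks produce a warning but the union is still returned.
#'
#' @param left,right binary 3D arrays with identical dimensions.
#' @return binary 3D array.
#' @export
combine_bilateral <- function(left, right) {
  check_same_shape(left, right, "masks")
  if (!is_binary_mask(left) || !is_binary_mask(right))
    stop_data("masks must be binary 3D arrays")
  if (sum(left * right) > 0)
    warning("left and right masks overlap; returning their union")
  array(as.numeric((left + right) > 0), dim = dim(left))
}
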