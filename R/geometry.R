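#' Voxel grid geometry
#'
#' Lightweight description of a 3D voxel grid: array dimensions plus the
#' 4x4 voxel-to-world affine (NIfTI sform convention, 0-based voxel indices).
#'
#' @param dim integer vector of length 3 (voxels per axis).
#' @param affine 4x4 numeric voxel-to-world matrix; default is an isotropic
#'   1 mm grid anchored at the origin.
#' @return an object of class \code{vox_geometry}.
#' @export
vox_geometry <- function(dim, affine = diag(4)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L),
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop_data("affine must be invertible")
  structure(list(dim = dim, affine = affine), class = "vox_geometry")
}

#' @export
print.vox_geometry <- function(x, ...) {
  cat("<vox_geometry>", paste(x$dim, collapse = " x "), "voxels\n")
  invisible(x)
}

#' Map 0-based voxel indices to world coordinates
#' @param geom a \code{vox_geometry}.
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates.
#' @keywords internal
voxel_to_world <- function(geom, ijk) {
  ijk <- rbind(t(ijk), 1)
  t(geom$affine %*% ijk)[, 1:3, drop = FALSE]
}

#' @keywords internal
world_to_voxel <- function(geom, xyz) {
  xyz <- rbind(t(xyz), 1)
  t(solve(geom$affine) %*% xyz)[, 1:3, drop = FALSE]
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around \pkg{RNifti} returning plain arrays plus a
#' \code{vox_geometry}.
#'
#' @param path file path (.nii or .nii.gz).
#' @return \code{read_volume}: list with \code{data} (array) and \code{geom}.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d3 <- dim(arr)[1:3]
  list(data = arr, geom = vox_geometry(d3, unclass(RNifti::xform(img))))
}

#' @rdname read_volume
#' @param data 3D or 4D array.
#' @param geom a \code{vox_geometry} for the spatial axes.
#' @param tr repetition time in seconds (4D only).
#' @export
write_volume <- function(data, path, geom = vox_geometry(dim(data)[1:3]),
                         tr = NULL) {
  img <- RNifti::asNifti(data)
  RNifti::qform(img) <- structure(geom$affine, code = 2L)
  RNifti::sform(img) <- structure(geom$affine, code = 2L)
  if (!is.null(tr) && length(dim(data)) == 4L) {
    pd <- RNifti::pixdim(img)
    pd[4] <- tr
    RNifti::pixdim(img) <- pd
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
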