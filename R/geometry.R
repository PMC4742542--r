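#' Grid geometry of a phantom volume
#'
#' Describes the voxel lattice a phantom lives on: grid shape, voxel size and
#' the voxel-to-world affine. World coordinates are RAS+ millimetres and voxel
#' indices are 0-based (the NIfTI convention), so world = affine %*% c(i,j,k,1)
#' for 0-based (i,j,k). Direction vectors throughout the package are stored in
#' this world frame.
#'
#' @param shape Integer vector of length 3, voxels per axis (all positive).
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm.
#' @param affine Optional 4x4 voxel-to-world matrix. Defaults to an axis-aligned
#'   RAS+ affine with the grid centre at the world origin. Its 3x3 block must
#'   have column norms equal to `voxel_size` (within 1e-6).
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(shape, voxel_size = c(2, 2, 2), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    abort_dwiph("`shape` must be 3 positive integers", "dwiph_structural_error")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort_dwiph("`voxel_size` must be 3 positive lengths (mm)", "dwiph_structural_error")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    # centre of the grid at the world origin
    affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine))) {
    abort_dwiph("`affine` must be a finite 4x4 matrix", "dwiph_structural_error")
  }
  if (abs(det(affine)) < .Machine$double.eps * 100) {
    abort_dwiph("`affine` must be invertible", "dwiph_structural_error")
  }
  col_norms <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(col_norms - voxel_size) > 1e-6)) {
    abort_dwiph(
      sprintf(
        "voxel_size (%s) does not match affine column norms (%s)",
        paste(signif(voxel_size, 6), collapse = ", "),
        paste(signif(col_norms, 6), collapse = ", ")
      ),
      "dwiph_structural_error"
    )
  }
  structure(
    list(shape = shape, voxel_size = voxel_size, affine = affine),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(
    "<grid_geometry> ", paste(x$shape, collapse = " x "), " voxels, ",
    paste(signif(x$voxel_size, 4), collapse = " x "), " mm\n",
    sep = ""
  )
  invisible(x)
}

n_voxels <- function(geometry) prod(geometry$shape)

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$affine - b$affine) < tol)
}

#' World coordinates of all voxel centres
#'
#' @param geometry A [grid_geometry()].
#' @return An n-voxel x 3 matrix of RAS+ mm coordinates, voxel index varying
#'   fastest along the first grid axis (column-major order).
#' @keywords internal
voxel_centers <- function(geometry) {
  s <- geometry$shape
  idx <- cbind(
    rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
    rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  )
  t(geometry$affine[1:3, 1:3] %*% t(idx) + geometry$affine[1:3, 4])
}
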