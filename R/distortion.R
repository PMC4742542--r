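# Susceptibility-distortion emulation: a smooth displacement field along the
# phase-encode axis, applied to a simulated volume with Jacobian intensity
# modulation (signal pile-up and stretching, the first-order physics of EPI
# geometric distortion).

#' Displacement field along a phase-encode axis
#'
#' @param values 3D array on the grid: per-voxel displacement in mm along
#'   `pe_axis` (positive = towards increasing voxel index).
#' @param geometry A [grid_geometry()].
#' @param pe_axis Phase-encode axis, 1, 2 or 3.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(values, geometry, pe_axis = 2L) {
  values <- check_array(values, geometry$shape, "values")
  if (any(!is.finite(values))) {
    abort_dwiph("displacement field must be finite", "dwiph_validation_error")
  }
  pe_axis <- as.integer(pe_axis)
  if (!pe_axis %in% 1:3) {
    abort_dwiph("pe_axis must be 1, 2 or 3", "dwiph_validation_error")
  }
  structure(
    list(values = values, geometry = geometry, pe_axis = pe_axis),
    class = "displacement_field"
  )
}

#' Synthetic susceptibility fieldmap (Gaussian bump)
#'
#' A smooth, localized displacement focus: a compactly supported Gaussian
#' bump of peak `magnitude_mm` centred at `focus_center`, decaying to zero at
#' `extent_mm` from the centre (the raw Gaussian is shifted and rescaled so
#' the field is exactly zero beyond the extent, keeping the warp strictly
#' local), emulating the focal distortions near air-tissue interfaces. Zero
#' everywhere when `magnitude_mm = 0`.
#'
#' @param geometry A [grid_geometry()].
#' @param focus_center World-frame mm coordinates of the focus (default: grid
#'   centre).
#' @param magnitude_mm Peak displacement (mm, `>= 0`).
#' @param extent_mm Radius at which the bump has decayed below 1% of peak.
#' @param pe_axis Phase-encode axis, 1, 2 or 3.
#' @param seed Accepted for API uniformity; the analytic bump uses no
#'   randomness.
#' @return A [displacement_field()].
#' @export
make_synthetic_fieldmap <- function(geometry, focus_center = NULL,
                                    magnitude_mm = 6, extent_mm = 20,
                                    pe_axis = 2L, seed = NULL) {
  if (magnitude_mm < 0) {
    abort_dwiph("magnitude_mm must be non-negative", "dwiph_validation_error")
  }
  if (is.null(focus_center)) {
    centre_vox <- (geometry$shape - 1) / 2
    focus_center <- as.numeric(geometry$affine[1:3, 1:3] %*% centre_vox +
      geometry$affine[1:3, 4])
  }
  pos <- voxel_centers(geometry)
  r2 <- rowSums((pos - matrix(focus_center, nrow(pos), 3, byrow = TRUE))^2)
  # sigma such that the raw Gaussian is 1% of peak at extent_mm; subtracting
  # that floor and rescaling makes the support exactly [0, extent_mm]
  floor_frac <- 0.01
  sig2 <- extent_mm^2 / (-2 * log(floor_frac))
  raw <- exp(-r2 / (2 * sig2))
  vals <- magnitude_mm * pmax(raw - floor_frac, 0) / (1 - floor_frac)
  displacement_field(array(vals, dim = geometry$shape), geometry, pe_axis)
}

# move `axis` to the first dimension of a 3D/4D array
axis_first <- function(arr, axis) {
  perm <- c(axis, setdiff(seq_along(dim(arr)), axis))
  aperm(arr, perm)
}

axis_back <- function(arr, axis, ndim) {
  perm <- c(axis, setdiff(seq_len(ndim), axis))
  aperm(arr, order(perm))
}

# 1D pull-back resample with Jacobian modulation, vectorized over columns.
# A: n x m matrix (lines along the warp axis in columns' rows), phi: n x m
# sampling positions (1-based), jac: n x m modulation.
resample_lines <- function(A, phi, jac) {
  n <- nrow(A)
  i0 <- clamp(floor(phi), 1, n - 1)
  w <- clamp(phi - i0, 0, 1)
  col_off <- rep((seq_len(ncol(A)) - 1L) * n, each = n)
  lin0 <- as.integer(i0) + col_off
  out <- (A[lin0] * (1 - w) + A[lin0 + 1L] * w) * jac
  dim(out) <- dim(A)
  out
}

#' Warp a diffusion volume with a displacement field
#'
#' Pull-back resampling along the phase-encode axis: the output voxel at
#' position x takes the input value at `x + d(x)` (linear interpolation, edge
#' clamping), modulated by the 1D Jacobian `1 + dd/dx` (central differences,
#' clipped at 0). Because the modulation is the exact change of variables of
#' the warp, total image intensity is conserved up to discretization error.
#' A zero field returns the input unchanged (within round-off).
#'
#' @param volume A [diffusion_volume()].
#' @param field A [displacement_field()] on the same grid.
#' @return The warped [diffusion_volume()].
#' @export
apply_distortion <- function(volume, field) {
  if (!same_grid(volume$geometry, field$geometry)) {
    abort_dwiph("volume and field are on different grids", "dwiph_structural_error")
  }
  ax <- field$pe_axis
  vox <- volume$geometry$voxel_size[ax]
  d_vox <- axis_first(field$values / vox, ax) # displacement in voxel units
  n <- dim(d_vox)[1]
  d_mat <- matrix(d_vox, nrow = n)

  # Jacobian of phi(x) = x + d(x): 1 + d'(x), central differences, clip at 0
  dd <- d_mat
  dd[2:(n - 1), ] <- (d_mat[3:n, , drop = FALSE] - d_mat[1:(n - 2), , drop = FALSE]) / 2
  dd[1, ] <- d_mat[2, ] - d_mat[1, ]
  dd[n, ] <- d_mat[n, ] - d_mat[n - 1, ]
  jac <- pmax(1 + dd, 0)

  nvol <- dim(volume$data)[4]
  A <- matrix(axis_first(volume$data, ax), nrow = n)
  m0 <- ncol(d_mat)
  phi <- matrix(seq_len(n), n, m0) + d_mat
  phi_all <- matrix(rep(as.numeric(phi), nvol), nrow = n)
  jac_all <- matrix(rep(as.numeric(jac), nvol), nrow = n)
  out <- resample_lines(A, phi_all, jac_all)

  s <- volume$geometry$shape
  perm_shape <- c(s[ax], s[-ax], nvol)
  out <- axis_back(array(out, dim = perm_shape), ax, 4L)
  diffusion_volume(out, volume$geometry, volume$scheme, volume$s0)
}

#' Write / read a displacement field as a NIfTI scalar volume (mm)
#'
#' @param field A [displacement_field()].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `write_fieldmap`: invisibly, the path.
#' @export
write_fieldmap <- function(field, path) {
  write_nifti_map(field$values, field$geometry, path)
  invisible(path)
}

#' @rdname write_fieldmap
#' @param pe_axis Phase-encode axis the displacements apply to.
#' @return `read_fieldmap`: a [displacement_field()].
#' @export
read_fieldmap <- function(path, pe_axis = 2L) {
  img <- RNifti::readNifti(path)
  displacement_field(as.array(img), geometry_from_nifti(img), pe_axis)
}
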