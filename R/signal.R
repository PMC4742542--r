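# Core simulator: per-voxel multi-compartment diffusion signal.
#
# Restricted compartments follow an axially symmetric Gaussian (zeppelin)
# kernel; hindered and free compartments decay mono-exponentially with
# isotropic diffusivities. The voxel signal is the fraction-weighted convex
# combination of compartment attenuations, scaled by s0.

#' Single-fiber response kernel
#'
#' Axially symmetric Gaussian diffusion tensor with eigenvalues
#' `lambda_par >= lambda_perp > 0`. Defaults: axial 2.2e-3 mm^2/s, radial
#' 0.2e-3 mm^2/s.
#'
#' @param lambda_par Axial diffusivity (mm^2/s).
#' @param lambda_perp Radial diffusivity (mm^2/s).
#' @return An object of class `fiber_kernel`.
#' @export
fiber_kernel <- function(lambda_par = 2.2e-3, lambda_perp = 0.2e-3) {
  if (!is_scalar_number(lambda_par) || !is_scalar_number(lambda_perp) ||
    lambda_perp <= 0 || lambda_par < lambda_perp) {
    abort_dwiph(
      "fiber kernel requires lambda_par >= lambda_perp > 0",
      "dwiph_validation_error"
    )
  }
  structure(
    list(lambda_par = lambda_par, lambda_perp = lambda_perp),
    class = "fiber_kernel"
  )
}

#' Isotropic diffusivities of the hindered and free compartments
#'
#' Defaults (mm^2/s): hindered WM 2.0e-4, cortical GM 7.0e-4, deep GM
#' 9.0e-4; free CSF 3.0e-3. The abnormal-tissue compartment has no default
#' and must be set explicitly before simulating a model that uses it.
#'
#' @param WM,cGM,dGM,CSF,abnormal Diffusivities in mm^2/s.
#' @return An object of class `diffusivity_set` (named vector ordered as
#'   [TISSUE_NAMES]).
#' @export
diffusivity_set <- function(WM = 2.0e-4, cGM = 7.0e-4, dGM = 9.0e-4,
                            CSF = 3.0e-3, abnormal = NA_real_) {
  d <- c(cGM = cGM, dGM = dGM, WM = WM, CSF = CSF, abnormal = abnormal)
  if (any(!is.na(d) & d <= 0)) {
    abort_dwiph("diffusivities must be positive", "dwiph_validation_error")
  }
  structure(d, class = "diffusivity_set")
}

#' Rician noise specification
#'
#' `snr` is the mean in-brain b = 0 intensity divided by the Gaussian noise
#' sigma; `Inf` means noise-free. Default 30.
#'
#' @param snr Signal-to-noise ratio (> 0, possibly `Inf`).
#' @param seed Integer seed for reproducible noise.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr = 30, seed = NULL) {
  if (!(is.numeric(snr) && length(snr) == 1 && (is.infinite(snr) || snr > 0))) {
    abort_dwiph("snr must be positive (or Inf for noise-free)", "dwiph_validation_error")
  }
  structure(list(snr = snr, seed = seed), class = "noise_spec")
}

#' Attenuation of a single fiber compartment
#'
#' `exp(-b (lambda_perp + (lambda_par - lambda_perp) (g . v)^2))`: the
#' signal attenuation of an axially symmetric Gaussian tensor along `v`
#' probed by gradient `g` at b-value `b`. Symmetric under `v -> -v` and
#' `g -> -g`; equals 1 at b = 0.
#'
#' @param kernel A [fiber_kernel()].
#' @param v Unit fiber direction (3-vector).
#' @param g Unit gradient direction (3-vector).
#' @param b b-value (s/mm^2, `>= 0`).
#' @return Attenuation in (0, 1].
#' @export
fiber_attenuation <- function(kernel, v, g, b) {
  if (any(b < 0)) {
    abort_dwiph("b-values must be non-negative", "dwiph_validation_error")
  }
  if (abs(sum(v^2) - 1) > 1e-6 || abs(sum(g^2) - 1) > 1e-6) {
    abort_dwiph("v and g must be unit vectors", "dwiph_validation_error")
  }
  ct2 <- sum(v * g)^2
  exp(-b * (kernel$lambda_perp + (kernel$lambda_par - kernel$lambda_perp) * ct2))
}

#' Attenuation of an isotropic compartment
#'
#' Mono-exponential decay `exp(-b D)`.
#'
#' @param D Diffusivity (mm^2/s, > 0).
#' @param b b-value (s/mm^2, `>= 0`).
#' @return Attenuation in (0, 1].
#' @export
isotropic_attenuation <- function(D, b) {
  if (any(b < 0)) {
    abort_dwiph("b-values must be non-negative", "dwiph_validation_error")
  }
  if (any(D <= 0)) {
    abort_dwiph("diffusivity must be positive", "dwiph_validation_error")
  }
  exp(-b * D)
}

check_diffusivities <- function(tissue_active, diffusivities) {
  missing <- tissue_active & is.na(unclass(diffusivities))
  if (any(missing)) {
    abort_dwiph(
      sprintf(
        "compartment(s) present with no configured diffusivity: %s",
        paste(TISSUE_NAMES[missing], collapse = ", ")
      ),
      "dwiph_configuration_error"
    )
  }
}

#' Noise-free signal of a single voxel composition
#'
#' `S(g, b) = s0 (sum_i F_i A_fiber(V_i; g, b) + sum_j T_j exp(-b D_j))`:
#' the convex mixture of compartment attenuations. At b = 0 this equals
#' `s0 * (sum F + sum T)`.
#'
#' @param tissue_fractions Length-5 vector ordered as [TISSUE_NAMES].
#' @param fiber_fractions Vector of up to 3 fiber fractions.
#' @param fiber_dirs Matrix, one unit row vector per fiber.
#' @param scheme A [gradient_scheme()].
#' @param kernel A [fiber_kernel()].
#' @param diffusivities A [diffusivity_set()].
#' @param s0 Non-weighted reference intensity (arbitrary units).
#' @return Numeric vector, one signal value per scheme volume.
#' @export
voxel_signal <- function(tissue_fractions, fiber_fractions = numeric(0),
                         fiber_dirs = NULL, scheme,
                         kernel = fiber_kernel(),
                         diffusivities = diffusivity_set(), s0 = 1) {
  tissue_fractions <- as.numeric(tissue_fractions)
  stopifnot(length(tissue_fractions) == 5L)
  check_diffusivities(tissue_fractions > 0, diffusivities)
  b <- scheme$bvals
  s <- numeric(length(b))
  for (j in which(tissue_fractions > 0)) {
    s <- s + tissue_fractions[j] * isotropic_attenuation(unclass(diffusivities)[j], b)
  }
  if (length(fiber_fractions) > 0) {
    fiber_dirs <- matrix(fiber_dirs, ncol = 3)
    for (i in which(fiber_fractions > 0)) {
      v <- fiber_dirs[i, ]
      ct2 <- as.numeric(scheme$bvecs %*% v)^2
      att <- exp(-b * (kernel$lambda_perp +
        (kernel$lambda_par - kernel$lambda_perp) * ct2))
      att[b == 0] <- 1
      s <- s + fiber_fractions[i] * att
    }
  }
  s0 * s
}

#' A simulated diffusion-weighted volume
#'
#' @param data 4D array, grid shape x number of volumes, non-negative.
#' @param geometry A [grid_geometry()].
#' @param scheme The [gradient_scheme()] the data was sampled on.
#' @param s0 Reference non-weighted intensity.
#' @return An object of class `diffusion_volume`.
#' @export
diffusion_volume <- function(data, geometry, scheme, s0) {
  data <- as.array(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 4L || !all(dim(data)[1:3] == geometry$shape) ||
    dim(data)[4] != length(scheme$bvals)) {
    abort_dwiph("data dimensions do not match geometry and scheme", "dwiph_structural_error")
  }
  structure(
    list(data = data, geometry = geometry, scheme = scheme, s0 = s0),
    class = "diffusion_volume"
  )
}

#' @export
print.diffusion_volume <- function(x, ...) {
  cat(
    sprintf(
      "<diffusion_volume> %s voxels x %d volumes, s0 = %g\n",
      paste(x$geometry$shape, collapse = " x "), dim(x$data)[4], x$s0
    )
  )
  invisible(x)
}

#' Simulate the noise-free diffusion signal of a whole model
#'
#' Vectorized voxel-wise application of [voxel_signal()]: every voxel's
#' signal is the fraction-weighted mixture of its compartment attenuations.
#' Deterministic; add noise separately with [add_rician_noise()].
#'
#' @param model A valid [microstructural_model()].
#' @param scheme A [gradient_scheme()].
#' @param kernel A [fiber_kernel()].
#' @param diffusivities A [diffusivity_set()].
#' @param s0 Reference intensity (default 1000, flat across tissues so the
#'   phantom's contrast is purely diffusion-driven).
#' @return A [diffusion_volume()].
#' @export
simulate_volume <- function(model, scheme, kernel = fiber_kernel(),
                            diffusivities = diffusivity_set(), s0 = 1000) {
  g <- model$geometry
  nv <- n_voxels(g)
  b <- scheme$bvals
  nvol <- length(b)
  tm <- tissue_matrix(model)
  fm <- fiber_matrix(model)
  check_diffusivities(colSums(tm) > 0, diffusivities)

  S <- matrix(0, nv, nvol)
  for (j in which(colSums(tm) > 0)) {
    S <- S + outer(tm[, j], isotropic_attenuation(unclass(diffusivities)[j], b))
  }
  dl <- kernel$lambda_par - kernel$lambda_perp
  bmat <- matrix(b, nv, nvol, byrow = TRUE)
  for (i in which(colSums(fm) > 0)) {
    vi <- fiber_dir_matrix(model, i)
    ct <- vi %*% t(scheme$bvecs) # nv x nvol dot products
    att <- exp(-bmat * (kernel$lambda_perp + dl * ct^2))
    att[, b == 0] <- 1
    S <- S + fm[, i] * att
  }
  diffusion_volume(array(s0 * S, dim = c(g$shape, nvol)), g, scheme, s0)
}

#' Add Rician noise to a simulated volume
#'
#' Each sample becomes `sqrt((S + n1)^2 + n2^2)` with `n1, n2` independent
#' zero-mean Gaussians of standard deviation `sigma = mean in-brain b0 /
#' snr`, where "in-brain" means voxels whose mean b0 intensity exceeds half
#' of s0 (i.e. compartment fraction sum > 0.5). Background magnitudes are
#' then Rayleigh-distributed with mean `sigma sqrt(pi/2)`. Deterministic
#' given `noise$seed`; `snr = Inf` returns the input unchanged.
#'
#' @param volume A [diffusion_volume()].
#' @param noise A [noise_spec()].
#' @return A [diffusion_volume()] with noisy non-negative data and attribute
#'   `"sigma"` recording the noise level used.
#' @export
add_rician_noise <- function(volume, noise = noise_spec()) {
  if (is.infinite(noise$snr)) {
    return(volume)
  }
  b0_idx <- which(volume$scheme$bvals == 0)
  nv <- n_voxels(volume$geometry)
  dat <- matrix(volume$data, nrow = nv)
  b0_mean <- rowMeans(dat[, b0_idx, drop = FALSE])
  inbrain <- b0_mean > 0.5 * volume$s0
  if (!any(inbrain)) {
    abort_dwiph(
      "no in-brain b=0 voxels; cannot define the noise sigma",
      "dwiph_configuration_error"
    )
  }
  sigma <- mean(b0_mean[inbrain]) / noise$snr
  noisy <- with_seed(noise$seed, {
    n1 <- array(stats::rnorm(length(volume$data), sd = sigma), dim = dim(volume$data))
    n2 <- array(stats::rnorm(length(volume$data), sd = sigma), dim = dim(volume$data))
    sqrt((volume$data + n1)^2 + n2^2)
  })
  out <- diffusion_volume(noisy, volume$geometry, volume$scheme, volume$s0)
  attr(out, "sigma") <- sigma
  out
}

#' NIfTI + gradient-table output for a diffusion volume
#'
#' Writes the 4D data as NIfTI-1, the scheme as FSL bval/bvec, and a JSON
#' sidecar with simulation provenance.
#'
#' @param volume A [diffusion_volume()].
#' @param prefix Output path prefix (files `<prefix>.nii.gz`, `.bval`,
#'   `.bvec`, `.json`).
#' @param sidecar Named list of extra provenance fields for the sidecar.
#' @return Invisibly, the vector of paths written.
#' @export
write_diffusion_volume <- function(volume, prefix, sidecar = list()) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(nifti_from_array(volume$data, volume$geometry), nii)
  write_fsl_scheme(volume$scheme, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  side <- c(list(s0 = volume$s0), sidecar)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paste0(prefix, c(".nii.gz", ".bval", ".bvec", ".json")))
}

#' Read a diffusion volume written by [write_diffusion_volume()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [diffusion_volume()].
#' @export
read_diffusion_volume <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  geom <- geometry_from_nifti(img)
  scheme <- read_fsl_scheme(paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  s0 <- if (!is.null(side$s0)) side$s0 else 1
  diffusion_volume(as.array(img), geom, scheme, s0)
}
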