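# Self-validation estimators: log-linear tensor fit, FA/MD, ADC, and SNR
# estimation from background Rayleigh statistics.

#' Log-linear diffusion tensor fit
#'
#' Ordinary least squares on `-ln(S/s0) = b g' D g` over the diffusion
#' weighted volumes. Exact (to numerical precision) whenever the signal was
#' generated by a single Gaussian tensor without noise. Unweighted by design:
#' simplicity and exactness on noise-free data.
#'
#' @param signal Per-volume signal vector (all values > 0).
#' @param scheme A [gradient_scheme()]; needs >= 6 non-collinear directions
#'   with b > 0.
#' @param s0 Reference non-weighted intensity; if `NULL`, the mean of the
#'   b = 0 volumes of `signal`.
#' @return An object of class `tensor_fit`: `tensor` (3x3, mm^2/s),
#'   `eigenvalues` (descending), `principal_direction` (unit vector),
#'   `negative_eigenvalues` flag.
#' @export
fit_tensor_loglinear <- function(signal, scheme, s0 = NULL) {
  dw <- which(scheme$bvals > 0)
  if (length(dw) < 6) {
    abort_dwiph("need at least 6 diffusion-weighted volumes", "dwiph_estimation_error")
  }
  if (any(signal <= 0)) {
    abort_dwiph("all signals must be positive for the log-linear fit", "dwiph_estimation_error")
  }
  if (is.null(s0)) {
    b0 <- which(scheme$bvals == 0)
    s0 <- mean(signal[b0])
  }
  g <- scheme$bvecs[dw, , drop = FALSE]
  b <- scheme$bvals[dw]
  X <- b * cbind(
    g[, 1]^2, g[, 2]^2, g[, 3]^2,
    2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3]
  )
  qrX <- qr(X)
  if (qrX$rank < 6) {
    abort_dwiph(
      sprintf("rank-deficient design (rank %d < 6): directions are collinear or too few", qrX$rank),
      "dwiph_estimation_error"
    )
  }
  y <- -log(signal[dw] / s0)
  beta <- qr.coef(qrX, y)
  D <- matrix(c(
    beta[1], beta[4], beta[5],
    beta[4], beta[2], beta[6],
    beta[5], beta[6], beta[3]
  ), 3, 3)
  e <- eigen(D, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  structure(
    list(
      tensor = D,
      eigenvalues = e$values[ord],
      eigenvectors = e$vectors[, ord, drop = FALSE],
      principal_direction = e$vectors[, ord[1]],
      negative_eigenvalues = any(e$values < 0)
    ),
    class = "tensor_fit"
  )
}

#' Fractional anisotropy of a set of eigenvalues
#'
#' Standard FA: `sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`.
#' Negative eigenvalues (possible on noisy fits) are clamped to zero with a
#' warning; all-zero input is an error.
#'
#' @param eigenvalues Numeric vector of 3 eigenvalues (mm^2/s).
#' @return FA in `[0, 1]`.
#' @export
fa <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  stopifnot(length(ev) == 3L)
  if (any(ev < 0)) {
    warning("negative eigenvalues clamped to 0 for FA")
    ev <- pmax(ev, 0)
  }
  if (all(ev == 0)) {
    abort_dwiph("FA undefined for all-zero eigenvalues", "dwiph_estimation_error")
  }
  mn <- mean(ev)
  sqrt(1.5 * sum((ev - mn)^2) / sum(ev^2))
}

#' Mean diffusivity of a set of eigenvalues
#' @param eigenvalues Numeric vector of 3 eigenvalues (mm^2/s).
#' @return MD in mm^2/s.
#' @export
md <- function(eigenvalues) mean(as.numeric(eigenvalues))

#' Apparent diffusion coefficient by mono-exponential fit
#'
#' Least-squares slope through the origin of `-ln(S / S_b0)` against b,
#' pooled over all diffusion-weighted volumes. Exact for isotropic
#' mono-exponential voxels.
#'
#' @param signal Per-volume signal vector.
#' @param scheme A [gradient_scheme()] with at least 2 distinct b-values
#'   (including b = 0).
#' @return Estimated diffusivity (mm^2/s).
#' @export
estimate_adc <- function(signal, scheme) {
  if (length(unique(scheme$bvals)) < 2) {
    abort_dwiph("need at least 2 distinct b-values", "dwiph_estimation_error")
  }
  b0 <- mean(signal[scheme$bvals == 0])
  dw <- which(scheme$bvals > 0)
  if (any(signal[dw] <= 0) || b0 <= 0) {
    abort_dwiph("signals must be positive for the log fit", "dwiph_estimation_error")
  }
  y <- -log(signal[dw] / b0)
  b <- scheme$bvals[dw]
  sum(b * y) / sum(b * b)
}

#' Estimate SNR from background Rayleigh statistics
#'
#' On magnitude images, pure-noise background voxels follow a Rayleigh
#' distribution with mean `sigma * sqrt(pi/2)`; hence `sigma_hat = mean
#' background b0 / sqrt(pi/2)` and `SNR_hat = mean foreground b0 /
#' sigma_hat`.
#'
#' @param volume A [diffusion_volume()].
#' @param foreground_mask,background_mask Logical 3D arrays on the grid;
#'   the background must contain no signal.
#' @return List with `snr`, `sigma`, and the voxel counts used. When the
#'   background carries no measurable noise, `snr` is `Inf` and a message
#'   notes it.
#' @export
estimate_snr <- function(volume, foreground_mask, background_mask) {
  fg <- as.logical(foreground_mask)
  bg <- as.logical(background_mask)
  if (!any(fg) || !any(bg)) {
    abort_dwiph("foreground and background masks must be non-empty", "dwiph_validation_error")
  }
  b0_idx <- which(volume$scheme$bvals == 0)
  nv <- n_voxels(volume$geometry)
  dat <- matrix(volume$data, nrow = nv)
  b0 <- rowMeans(dat[, b0_idx, drop = FALSE])
  bg_vals <- as.numeric(dat[bg, b0_idx])
  sigma <- mean(bg_vals) / sqrt(pi / 2)
  fg_mean <- mean(b0[fg])
  if (sigma <= .Machine$double.eps * fg_mean) {
    message("no measurable noise in the background; SNR is infinite")
    return(list(snr = Inf, sigma = 0, n_foreground = sum(fg), n_background = sum(bg)))
  }
  list(
    snr = fg_mean / sigma, sigma = sigma,
    n_foreground = sum(fg), n_background = sum(bg)
  )
}

#' Parameter-recovery evaluation report
#'
#' Runs the self-validation estimators on a simulated volume against the
#' configured ground truth: tensor eigenvalue recovery on a single-fiber
#' voxel composition is reported elsewhere; this report covers whole-volume
#' quantities — SNR recovery (if noise was added) and ADC in pure-tissue
#' voxels (noise-free volumes only).
#'
#' @param volume A [diffusion_volume()].
#' @param model The generating [microstructural_model()].
#' @param truth Named list of generating parameters (`snr`, `diffusivities`).
#' @param tolerances Named list of relative tolerances (defaults: snr 0.05,
#'   adc 1e-6).
#' @return A list (class `evaluation_report`) with one entry per check:
#'   estimate, truth, relative error, pass flag.
#' @export
evaluate_volume <- function(volume, model, truth = list(),
                            tolerances = list(snr = 0.05, adc = 1e-6)) {
  checks <- list()
  fs <- fraction_sums(model)
  if (!is.null(truth$snr) && is.finite(truth$snr)) {
    est <- estimate_snr(volume, foreground_mask = fs > 0.5, background_mask = fs == 0)
    rel <- abs(est$snr - truth$snr) / truth$snr
    checks$snr <- list(
      estimate = est$snr, truth = truth$snr, relative_error = rel,
      pass = rel <= tolerances$snr
    )
  }
  if (is.null(truth$snr) || !is.finite(truth$snr)) {
    # noise-free: ADC recovery in pure-CSF voxels, if any
    tm <- tissue_matrix(model)
    csf_idx <- which(tm[, match("CSF", TISSUE_NAMES)] > 0.999)
    if (length(csf_idx) > 0) {
      diffusivities <- if (!is.null(truth$diffusivities)) truth$diffusivities else diffusivity_set()
      nv <- n_voxels(volume$geometry)
      dat <- matrix(volume$data, nrow = nv)
      adc <- estimate_adc(dat[csf_idx[1], ], volume$scheme)
      d_true <- unclass(diffusivities)[["CSF"]]
      rel <- abs(adc - d_true) / d_true
      checks$adc_csf <- list(
        estimate = adc, truth = d_true, relative_error = rel,
        pass = rel <= tolerances$adc
      )
    }
  }
  structure(checks, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  for (nm in names(x)) {
    c_ <- x[[nm]]
    cat(sprintf(
      "  %s: estimate %.6g vs truth %.6g (rel err %.3g) %s\n",
      nm, c_$estimate, c_$truth, c_$relative_error,
      if (c_$pass) "PASS" else "FAIL"
    ))
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
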