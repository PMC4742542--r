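# Microstructural model: per-voxel compartment fractions and fiber directions.

#' Tissue compartment names, in canonical order
#'
#' Hindered compartments are cortical gray matter (cGM), deep gray matter
#' (dGM) and white matter (WM); the free compartment is CSF; an optional
#' "abnormal" compartment supports pathology simulation and has no default
#' diffusivity.
#' @export
TISSUE_NAMES <- c("cGM", "dGM", "WM", "CSF", "abnormal")

MAX_FIBERS <- 3L

#' Construct a microstructural model
#'
#' The voxel-wise ground truth a phantom is simulated from: up to five
#' isotropic tissue fraction maps (see [TISSUE_NAMES]), up to three restricted
#' fiber compartments with volume fractions `F_i` and unit direction fields
#' `V_i`. Per voxel the fractions form a convex-combination weight vector
#' (non-negative, summing to 1 inside the head and 0 outside).
#'
#' @param geometry A [grid_geometry()].
#' @param tissues 4D array `c(shape, 5)` of tissue fractions in `[0,1]`,
#'   ordered as [TISSUE_NAMES]. Missing maps may be passed as zeros.
#' @param fiber_fractions 4D array `c(shape, 3)` of restricted fractions.
#' @param fiber_dirs 5D array `c(shape, 3, 3)`: dimension 4 is the xyz
#'   component (world frame), dimension 5 the fiber population. Wherever
#'   `F_i > 0` the corresponding vector must be unit length; elsewhere it may
#'   be zero.
#' @return An object of class `microstructural_model`.
#' @seealso [validate_model()], [assemble_model()], [normalize_fractions()]
#' @export
microstructural_model <- function(geometry, tissues, fiber_fractions, fiber_dirs) {
  stopifnot(inherits(geometry, "grid_geometry"))
  s <- geometry$shape
  tissues <- check_array(tissues, c(s, 5L), "tissues")
  fiber_fractions <- check_array(fiber_fractions, c(s, MAX_FIBERS), "fiber_fractions")
  fiber_dirs <- check_array(fiber_dirs, c(s, 3L, MAX_FIBERS), "fiber_dirs")
  structure(
    list(
      geometry = geometry,
      tissues = tissues,
      fiber_fractions = fiber_fractions,
      fiber_dirs = fiber_dirs
    ),
    class = "microstructural_model"
  )
}

check_array <- function(x, dims, name) {
  x <- as.array(x)
  if (length(dim(x)) != length(dims) || !all(dim(x) == dims)) {
    abort_dwiph(
      sprintf(
        "`%s` must have dimensions (%s), got (%s)",
        name, paste(dims, collapse = ", "), paste(dim(x), collapse = ", ")
      ),
      "dwiph_structural_error"
    )
  }
  storage.mode(x) <- "double"
  attributes(x) <- list(dim = dim(x)) # drop foreign attributes (NIfTI pointers etc.)
  x
}

#' @export
print.microstructural_model <- function(x, ...) {
  fs <- fraction_sums(x)
  cat("<microstructural_model>\n")
  print(x$geometry)
  cat(
    sprintf(
      "  %d/%d voxels in head (fraction sum > 0); tissue maps present: %s; fibers present: %s\n",
      sum(fs > 0), length(fs),
      paste(TISSUE_NAMES[tissue_present(x)], collapse = ", "),
      paste(which(fiber_present(x)), collapse = ", ")
    )
  )
  invisible(x)
}

tissue_matrix <- function(model) matrix(model$tissues, ncol = 5L)
fiber_matrix <- function(model) matrix(model$fiber_fractions, ncol = MAX_FIBERS)

# n_voxels x 3 matrix of the i-th fiber direction field
fiber_dir_matrix <- function(model, i) {
  nv <- n_voxels(model$geometry)
  matrix(model$fiber_dirs[(1 + (i - 1) * nv * 3):(i * nv * 3)], ncol = 3L)
}

tissue_present <- function(model) colSums(tissue_matrix(model)) > 0
fiber_present <- function(model) colSums(fiber_matrix(model)) > 0

#' Per-voxel sum of all compartment fractions
#'
#' @param model A [microstructural_model()].
#' @return 3D array on the model grid.
#' @export
fraction_sums <- function(model) {
  array(
    rowSums(tissue_matrix(model)) + rowSums(fiber_matrix(model)),
    dim = model$geometry$shape
  )
}

#' Validate a microstructural model
#'
#' Checks every structural invariant and reports violations with voxel
#' counts rather than stopping: fractions within `[0,1]`, per-voxel sums
#' within `[0, 1 + tol]` and either ~0 or ~1, and unit-norm direction vectors
#' wherever the matching fiber fraction is positive.
#'
#' @param model A [microstructural_model()].
#' @param tol Numeric tolerance on sums and unit norms.
#' @return An object of class `validation_report`: a list of violations, each
#'   with a `check` id, affected voxel `count` and a `message`. Empty if and
#'   only if the model is valid (see [is_valid()]).
#' @export
validate_model <- function(model, tol = 1e-6) {
  violations <- list()
  add <- function(check, count, message) {
    if (count > 0) {
      violations[[length(violations) + 1L]] <<- list(
        check = check, count = as.integer(count), message = message
      )
    }
  }

  tm <- tissue_matrix(model)
  fm <- fiber_matrix(model)

  n_bad <- sum(rowSums(tm < -tol | tm > 1 + tol) > 0)
  add("tissue_fraction_range", n_bad, sprintf("%d voxels with a tissue fraction outside [0,1]", n_bad))

  n_bad <- sum(rowSums(fm < -tol | fm > 1 + tol) > 0)
  add("fiber_fraction_range", n_bad, sprintf("%d voxels with a fiber fraction outside [0,1]", n_bad))

  sums <- rowSums(tm) + rowSums(fm)
  n_bad <- sum(sums > 1 + tol)
  add("fraction_sum_exceeds_one", n_bad, sprintf("%d voxels with fraction sum > 1", n_bad))
  n_bad <- sum(sums > tol & abs(sums - 1) > tol)
  add(
    "fraction_sum_not_normalized", n_bad,
    sprintf("%d in-head voxels whose fractions do not sum to 1 (unnormalized model?)", n_bad)
  )

  for (i in seq_len(MAX_FIBERS)) {
    vi <- fiber_dir_matrix(model, i)
    norms <- row_norms(vi)
    n_bad <- sum(fm[, i] > 0 & abs(norms - 1) > tol)
    add(
      sprintf("fiber_%d_direction_not_unit", i), n_bad,
      sprintf("%d voxels with F_%d > 0 but |V_%d| != 1", n_bad, i, i)
    )
  }

  structure(violations, class = "validation_report")
}

#' @rdname validate_model
#' @param report A `validation_report`.
#' @export
is_valid <- function(report) length(report) == 0L

#' @export
print.validation_report <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<validation_report> no violations\n")
  } else {
    cat("<validation_report>", length(x), "violation type(s):\n")
    for (v in x) cat("  -", v$message, "\n")
  }
  invisible(x)
}

#' Normalize per-voxel compartment fractions to sum to one
#'
#' Rescales tissue and fiber fractions voxel-wise so the mixture is a convex
#' combination. Voxels whose fraction sum is zero (background) pass through
#' untouched; relative proportions are preserved everywhere.
#'
#' @param model A [microstructural_model()].
#' @return The normalized model.
#' @export
normalize_fractions <- function(model) {
  tm <- tissue_matrix(model)
  fm <- fiber_matrix(model)
  sums <- rowSums(tm) + rowSums(fm)
  scale <- ifelse(sums > 0, 1 / sums, 1)
  s <- model$geometry$shape
  model$tissues <- array(tm * scale, dim = c(s, 5L))
  model$fiber_fractions <- array(fm * scale, dim = c(s, MAX_FIBERS))
  model
}

#' Raw ingredients of a microstructural model
#'
#' Bundles the estimates an assembled model is derived from: raw fiber
#' fraction maps `F'_i` (as a crossing-fiber model would estimate them), a
#' fractional anisotropy map, raw tissue fractions `T'_j` (as segmentation of
#' an anatomical image would produce), and fiber direction fields.
#'
#' @param geometry A [grid_geometry()].
#' @param raw_fiber_fractions 4D array `c(shape, 3)` in `[0,1]`.
#' @param fa_map 3D array on the grid, values in `[0,1]`.
#' @param raw_tissue_fractions 4D array `c(shape, 5)` in `[0,1]`,
#'   ordered as [TISSUE_NAMES].
#' @param directions 5D array `c(shape, 3, 3)` of unit direction fields.
#' @return An object of class `raw_model_inputs`.
#' @export
raw_model_inputs <- function(geometry, raw_fiber_fractions, fa_map,
                             raw_tissue_fractions, directions) {
  stopifnot(inherits(geometry, "grid_geometry"))
  s <- geometry$shape
  out <- structure(
    list(
      geometry = geometry,
      raw_fiber_fractions = check_array(raw_fiber_fractions, c(s, MAX_FIBERS), "raw_fiber_fractions"),
      fa_map = check_array(fa_map, s, "fa_map"),
      raw_tissue_fractions = check_array(raw_tissue_fractions, c(s, 5L), "raw_tissue_fractions"),
      directions = check_array(directions, c(s, 3L, MAX_FIBERS), "directions")
    ),
    class = "raw_model_inputs"
  )
  n_bad <- sum(out$fa_map < 0 | out$fa_map > 1)
  if (n_bad > 0) {
    abort_dwiph(
      sprintf("FA map outside [0,1] in %d voxels", n_bad),
      "dwiph_validation_error"
    )
  }
  out
}

#' Assemble the final microstructural model from raw ingredients
#'
#' Combination rule (the package's documented convention, see the methods
#' vignette): the dominant fiber fraction is inferred from anisotropy,
#' `F_1 = FA * T'_WM` (clipped to `[0,1]`), rather than taken from the noisy
#' raw estimate; secondary fibers keep their raw ordering and ratio,
#' `F_i = F'_i * T'_WM` for i in 2,3; the total restricted fraction is capped
#' at `T'_WM` by proportional rescaling; the hindered WM fraction is the
#' remainder `T_WM = T'_WM - sum(F)`; other tissue maps pass through; finally
#' fractions are normalized per voxel. Restricted compartments are thereby
#' confined to voxels with nonzero WM fraction, and direction fields pass
#' through unchanged.
#'
#' @param raw A [raw_model_inputs()].
#' @return A normalized [microstructural_model()].
#' @export
assemble_model <- function(raw) {
  stopifnot(inherits(raw, "raw_model_inputs"))
  s <- raw$geometry$shape
  nv <- prod(s)
  t_raw <- matrix(raw$raw_tissue_fractions, ncol = 5L)
  f_raw <- matrix(raw$raw_fiber_fractions, ncol = MAX_FIBERS)
  wm <- t_raw[, match("WM", TISSUE_NAMES)]
  fa <- as.numeric(raw$fa_map)

  f <- matrix(0, nv, MAX_FIBERS)
  f[, 1] <- clamp(fa * wm, 0, 1)
  f[, 2] <- f_raw[, 2] * wm
  f[, 3] <- f_raw[, 3] * wm

  # restricted total cannot exceed the available WM fraction
  ftot <- rowSums(f)
  over <- ftot > wm & ftot > 0
  if (any(over)) {
    f[over, ] <- f[over, , drop = FALSE] * (wm[over] / ftot[over])
  }

  tissues <- t_raw
  tissues[, match("WM", TISSUE_NAMES)] <- wm - rowSums(f)

  model <- microstructural_model(
    raw$geometry,
    tissues = array(tissues, dim = c(s, 5L)),
    fiber_fractions = array(f, dim = c(s, MAX_FIBERS)),
    fiber_dirs = raw$directions
  )
  normalize_fractions(model)
}
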