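# Microstructural model serialization: one NIfTI per map plus a YAML manifest.

nifti_from_array <- function(arr, geometry) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geometry$voxel_size
  RNifti::`sform<-`(img, structure(geometry$affine, code = 2L))
}

write_nifti_map <- function(arr, geometry, path) {
  RNifti::writeNifti(nifti_from_array(arr, geometry), path)
  path
}

geometry_from_nifti <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  shape <- dim(img)[1:3]
  affine <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(affine) <- list(dim = c(4L, 4L))
  grid_geometry(shape, voxel_size = sqrt(colSums(affine[1:3, 1:3]^2)), affine = affine)
}

#' Write a microstructural model to a directory
#'
#' Writes one NIfTI file per scalar map (five tissue fractions, three fiber
#' fractions), one 4D (3-component, world-frame) NIfTI per direction field,
#' and a `model.yml` manifest naming each file's role. All-zero maps are
#' written too so the layout is self-describing.
#'
#' @param model A [microstructural_model()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- model$geometry
  s <- g$shape
  manifest <- list(
    format = "dwiphantom-model",
    version = 1L,
    shape = as.integer(s),
    voxel_size = as.numeric(g$voxel_size),
    tissues = list(),
    fibers = list()
  )
  for (j in seq_along(TISSUE_NAMES)) {
    fname <- sprintf("tissue_%s.nii.gz", TISSUE_NAMES[j])
    write_nifti_map(array(model$tissues[, , , j], dim = s), g, file.path(dir, fname))
    manifest$tissues[[TISSUE_NAMES[j]]] <- fname
  }
  nv <- n_voxels(g)
  for (i in seq_len(MAX_FIBERS)) {
    ff <- sprintf("fiber_fraction_%d.nii.gz", i)
    fd <- sprintf("fiber_dirs_%d.nii.gz", i)
    write_nifti_map(array(model$fiber_fractions[, , , i], dim = s), g, file.path(dir, ff))
    di <- array(model$fiber_dirs[(1 + (i - 1) * nv * 3):(i * nv * 3)], dim = c(s, 3L))
    write_nifti_map(di, g, file.path(dir, fd))
    manifest$fibers[[i]] <- list(fraction = ff, directions = fd)
  }
  path <- file.path(dir, "model.yml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a microstructural model written by [write_model()]
#'
#' @param dir Directory containing `model.yml`, or the manifest path itself.
#' @return A [microstructural_model()].
#' @export
read_model <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "model.yml") else dir
  if (!file.exists(path)) {
    abort_dwiph(sprintf("model manifest not found at '%s'", path), "dwiph_structural_error")
  }
  manifest <- yaml::read_yaml(path)
  base <- dirname(path)
  first <- RNifti::readNifti(file.path(base, manifest$tissues[[1]]))
  g <- geometry_from_nifti(first)
  s <- g$shape

  tissues <- array(0, dim = c(s, 5L))
  for (j in seq_along(TISSUE_NAMES)) {
    fname <- manifest$tissues[[TISSUE_NAMES[j]]]
    if (!is.null(fname)) {
      tissues[, , , j] <- as.array(RNifti::readNifti(file.path(base, fname)))
    }
  }
  fiber_fractions <- array(0, dim = c(s, MAX_FIBERS))
  fiber_dirs <- array(0, dim = c(s, 3L, MAX_FIBERS))
  for (i in seq_len(MAX_FIBERS)) {
    entry <- manifest$fibers[[i]]
    if (!is.null(entry)) {
      fiber_fractions[, , , i] <- as.array(RNifti::readNifti(file.path(base, entry$fraction)))
      fiber_dirs[, , , , i] <- as.array(RNifti::readNifti(file.path(base, entry$directions)))
    }
  }
  microstructural_model(g, tissues, fiber_fractions, fiber_dirs)
}
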