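# Synthetic microstructure fixtures: stand-ins for a real-data-derived model
# with the same statistical structure (crossing fibers, partial voluming,
# concentric tissue layout), so every downstream stage is testable offline.

#' Specification of a synthetic microstructure fixture
#'
#' @param kind One of `"single_voxel"`, `"crossing_slab"`, `"mini_brain"`.
#' @param shape Grid shape (ignored for `single_voxel`).
#' @param crossing_angle Crossing angle in degrees, in `(0, 90]`
#'   (`crossing_slab` only).
#' @param fiber_fraction Peak volume fraction of each bundle.
#' @param seed Integer seed. Fixture generation is a pure function of
#'   `(spec, seed)`.
#' @param voxel_size Voxel size in mm (isotropic default 2 mm, of the order of
#'   typical dMRI acquisitions).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("mini_brain", "crossing_slab", "single_voxel"),
                         shape = NULL, crossing_angle = 60,
                         fiber_fraction = NULL, seed = 1L,
                         voxel_size = c(2, 2, 2)) {
  kind <- match.arg(kind)
  if (is.null(shape)) {
    shape <- switch(kind,
      single_voxel = c(1L, 1L, 1L),
      crossing_slab = c(16L, 16L, 4L),
      mini_brain = c(32L, 32L, 32L)
    )
  }
  if (is.null(fiber_fraction)) {
    fiber_fraction <- switch(kind, crossing_slab = 0.45, 0.6)
  }
  structure(
    list(
      kind = kind, shape = as.integer(shape), crossing_angle = crossing_angle,
      fiber_fraction = fiber_fraction, seed = as.integer(seed),
      voxel_size = voxel_size
    ),
    class = "fixture_spec"
  )
}

#' Build the fixture a spec describes
#'
#' @param spec A [fixture_spec()].
#' @param ... Passed to [make_single_voxel()] for `kind = "single_voxel"`.
#' @return A [microstructural_model()].
#' @export
make_fixture <- function(spec, ...) {
  switch(spec$kind,
    single_voxel = make_single_voxel(...),
    crossing_slab = make_crossing_slab(spec),
    mini_brain = make_mini_brain(spec)
  )
}

#' Single-voxel model with a requested composition
#'
#' The smallest useful fixture: one voxel whose compartment mixture is given
#' exactly, used for closed-form signal checks.
#'
#' @param tissues Named numeric vector of tissue fractions; names from
#'   [TISSUE_NAMES].
#' @param fibers Numeric vector (length up to 3) of fiber fractions.
#' @param directions Matrix with one row per fiber, each a unit 3-vector
#'   (world frame).
#' @param voxel_size Voxel size in mm.
#' @return A normalized 1x1x1 [microstructural_model()].
#' @export
make_single_voxel <- function(tissues = c(), fibers = c(), directions = NULL,
                              voxel_size = c(2, 2, 2)) {
  g <- grid_geometry(c(1L, 1L, 1L), voxel_size = voxel_size)
  tis <- array(0, dim = c(1, 1, 1, 5))
  if (length(tissues) > 0) {
    idx <- match(names(tissues), TISSUE_NAMES)
    if (anyNA(idx)) {
      abort_dwiph(
        sprintf("unknown tissue name(s): %s",
                paste(setdiff(names(tissues), TISSUE_NAMES), collapse = ", ")),
        "dwiph_validation_error"
      )
    }
    tis[1, 1, 1, idx] <- tissues
  }
  ff <- array(0, dim = c(1, 1, 1, MAX_FIBERS))
  fd <- array(0, dim = c(1, 1, 1, 3, MAX_FIBERS))
  if (length(fibers) > 0) {
    if (is.null(directions)) {
      abort_dwiph("fiber fractions given without directions", "dwiph_validation_error")
    }
    directions <- matrix(directions, ncol = 3)
    for (i in seq_along(fibers)) {
      ff[1, 1, 1, i] <- fibers[i]
      if (fibers[i] > 0) {
        v <- directions[i, ]
        fd[1, 1, 1, , i] <- v / sqrt(sum(v^2))
      }
    }
  }
  total <- sum(tis) + sum(ff)
  if (total > 1 + 1e-6) {
    abort_dwiph(
      sprintf("requested fractions sum to %.4f > 1", total),
      "dwiph_validation_error"
    )
  }
  normalize_fractions(microstructural_model(g, tis, ff, fd))
}

# cosine-taper profile: 1 inside the core, smooth rolloff to 0 at the edge
taper_profile <- function(d, core, edge) {
  out <- numeric(length(d))
  out[d <= core] <- 1
  roll <- d > core & d < edge
  out[roll] <- 0.5 * (1 + cos(pi * (d[roll] - core) / (edge - core)))
  out
}

#' Two straight fiber bundles crossing at a prescribed angle
#'
#' A slab in which two bundles cross at `crossing_angle` degrees in a central
#' region, flanked by single-fiber regions, with hindered WM filling the
#' remainder of every voxel. Bundle cross-sections use a cosine-taper fraction
#' falloff, mimicking the partial voluming of smoothed real fraction maps.
#' In crossing voxels `V_1 . V_2 = cos(crossing_angle)` by construction.
#'
#' @param spec A [fixture_spec()] with `kind = "crossing_slab"`; `shape` must
#'   be at least 8 along each axis and `crossing_angle` in `(0, 90]`.
#' @return A normalized [microstructural_model()].
#' @export
make_crossing_slab <- function(spec) {
  s <- spec$shape
  if (any(s[1:2] < 8L) || s[3] < 1L) {
    abort_dwiph("crossing_slab requires shape >= 8 along the in-plane axes", "dwiph_validation_error")
  }
  ang <- spec$crossing_angle
  if (!is_scalar_number(ang) || ang <= 0 || ang > 90) {
    abort_dwiph("crossing_angle must be in (0, 90] degrees", "dwiph_validation_error")
  }
  g <- grid_geometry(s, voxel_size = spec$voxel_size)
  half <- ang * pi / 360 # half-angle in radians
  u1 <- c(cos(half), sin(half), 0)
  u2 <- c(cos(half), -sin(half), 0)

  # in-plane distance of each voxel centre to the bundle axis through centre
  cx <- (s[1] - 1) / 2
  cy <- (s[2] - 1) / 2
  px <- rep.int(seq_len(s[1]) - 1, s[2]) - cx
  py <- rep(seq_len(s[2]) - 1, each = s[1]) - cy
  dist_to <- function(u) abs(px * (-u[2]) + py * u[1])
  width <- max(2, min(s[1], s[2]) / 5)
  core <- width / 2

  f1_plane <- spec$fiber_fraction * taper_profile(dist_to(u1), core, width)
  f2_plane <- spec$fiber_fraction * taper_profile(dist_to(u2), core, width)

  nv <- prod(s)
  nz <- s[3]
  f1 <- rep(f1_plane, nz)
  f2 <- rep(f2_plane, nz)

  ff <- array(0, dim = c(s, MAX_FIBERS))
  ff[, , , 1] <- f1
  ff[, , , 2] <- f2
  fd <- array(0, dim = c(s, 3, MAX_FIBERS))
  for (k in 1:3) {
    fd[, , , k, 1] <- array(ifelse(f1 > 0, u1[k], 0), dim = s)
    fd[, , , k, 2] <- array(ifelse(f2 > 0, u2[k], 0), dim = s)
  }
  tis <- array(0, dim = c(s, 5))
  tis[, , , match("WM", TISSUE_NAMES)] <- array(1 - f1 - f2, dim = s)

  normalize_fractions(microstructural_model(g, tis, ff, fd))
}

#' Concentric whole-head-style fixture
#'
#' A small "brain": an outer cortical gray-matter shell, white-matter
#' interior, a central CSF ventricle, two deep-gray nuclei, and two fiber
#' bundles inside the white matter — one straight (population 2) and one arc
#' with a smoothly varying tangent direction field (population 1). Fractions
#' sum to 1 inside the head and 0 outside, and the result passes
#' [validate_model()] with an empty report.
#'
#' @param spec A [fixture_spec()] with `kind = "mini_brain"`; `shape` must be
#'   at least 24 along each axis.
#' @return A normalized [microstructural_model()].
#' @export
make_mini_brain <- function(spec) {
  s <- spec$shape
  if (any(s < 24L)) {
    abort_dwiph("mini_brain requires shape >= 24 along each axis", "dwiph_validation_error")
  }
  g <- grid_geometry(s, voxel_size = spec$voxel_size)
  nv <- prod(s)
  c0 <- (s - 1) / 2
  px <- rep.int(seq_len(s[1]) - 1, s[2] * s[3]) - c0[1]
  py <- rep.int(rep(seq_len(s[2]) - 1, each = s[1]), s[3]) - c0[2]
  pz <- rep(seq_len(s[3]) - 1, each = s[1] * s[2]) - c0[3]
  r <- sqrt(px^2 + py^2 + pz^2)

  R <- 0.45 * min(s) # head radius in voxels
  head <- r <= R
  shell <- head & r > 0.82 * R # cortical GM
  ventricle <- r <= 0.18 * R # central CSF
  nuc_off <- 0.4 * R
  nuc_r <- 0.12 * R
  nucleus <- (sqrt((px - nuc_off)^2 + py^2 + pz^2) <= nuc_r) |
    (sqrt((px + nuc_off)^2 + py^2 + pz^2) <= nuc_r)
  wm <- head & !shell & !ventricle & !nucleus

  f <- matrix(0, nv, MAX_FIBERS)
  v <- array(0, dim = c(nv, 3, MAX_FIBERS))

  tube_r <- max(1.5, 0.08 * min(s))
  core <- tube_r / 2

  # straight bundle along x, below the central plane
  z_off <- -0.3 * R
  d_straight <- sqrt((py - 0)^2 + (pz - z_off)^2)
  in_straight <- wm & d_straight < tube_r
  f[in_straight, 2] <- spec$fiber_fraction *
    taper_profile(d_straight[in_straight], core, tube_r)
  v[in_straight, 1, 2] <- 1

  # arc bundle: circle of radius 0.5 R in the plane z = +0.25 R,
  # centred below the grid centre so the arc sweeps through the WM
  arc_r <- 0.5 * R
  arc_cy <- -0.15 * R
  rho <- sqrt(px^2 + (py - arc_cy)^2)
  d_arc <- sqrt((rho - arc_r)^2 + (pz - 0.25 * R)^2)
  in_arc <- wm & d_arc < tube_r & rho > 1e-6
  w_arc <- spec$fiber_fraction * taper_profile(d_arc[in_arc], core, tube_r)
  f[in_arc, 1] <- w_arc
  # unit tangent to the circle through the voxel's nearest arc point
  tx <- -(py[in_arc] - arc_cy) / rho[in_arc]
  ty <- px[in_arc] / rho[in_arc]
  v[in_arc, 1, 1] <- tx
  v[in_arc, 2, 1] <- ty

  # voxels where both bundles would overlap: keep the stronger, drop the other
  both <- f[, 1] > 0 & f[, 2] > 0
  if (any(both)) {
    keep1 <- both & f[, 1] >= f[, 2]
    f[keep1, 2] <- 0
    v[keep1, , 2] <- 0
    keep2 <- both & !keep1
    f[keep2, 1] <- 0
    v[keep2, , 1] <- 0
  }

  tis <- matrix(0, nv, 5)
  tis[shell, match("cGM", TISSUE_NAMES)] <- 1
  tis[ventricle, match("CSF", TISSUE_NAMES)] <- 1
  tis[nucleus & !ventricle & head, match("dGM", TISSUE_NAMES)] <- 1
  tis[wm, match("WM", TISSUE_NAMES)] <- 1 - f[wm, 1] - f[wm, 2]

  model <- microstructural_model(
    g,
    tissues = array(tis, dim = c(s, 5)),
    fiber_fractions = array(f, dim = c(s, MAX_FIBERS)),
    fiber_dirs = array(aperm(v, c(1, 2, 3)), dim = c(s, 3, MAX_FIBERS))
  )
  normalize_fractions(model)
}
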