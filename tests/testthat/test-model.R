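# Microstructural model assembly, normalization and validation.

make_raw <- function(shape = c(2, 2, 2), fa = 0, wm = 0, cgm = 0, csf = 0,
                     f2 = 0, f3 = 0) {
  g <- grid_geometry(shape)
  s <- g$shape
  tis <- array(0, dim = c(s, 5))
  tis[, , , match("cGM", TISSUE_NAMES)] <- cgm
  tis[, , , match("WM", TISSUE_NAMES)] <- wm
  tis[, , , match("CSF", TISSUE_NAMES)] <- csf
  ff <- array(0, dim = c(s, 3))
  ff[, , , 2] <- f2
  ff[, , , 3] <- f3
  fd <- array(0, dim = c(s, 3, 3))
  fd[, , , 1, ] <- 1 # all direction fields along +x
  raw_model_inputs(g, ff, array(fa, dim = s), tis, fd)
}

test_that("assembly confines restricted compartments to white matter", {
  # no WM: everything stays in the hindered cGM compartment
  m <- assemble_model(make_raw(fa = 0, wm = 0, cgm = 1))
  expect_equal(max(abs(matrix(m$fiber_fractions, ncol = 3))), 0)
  expect_equal(unique(as.numeric(m$tissues[, , , match("cGM", TISSUE_NAMES)])), 1)

  # all-zero input voxels stay zero (background preserved)
  m0 <- assemble_model(make_raw())
  expect_equal(max(fraction_sums(m0)), 0)
})

test_that("assembly derives F1 from FA and renormalizes to a convex mixture", {
  m <- assemble_model(make_raw(fa = 0.8, wm = 1, f2 = 0.2, f3 = 0.1))
  f <- matrix(m$fiber_fractions, ncol = 3)[1, ]
  # oracle: F' = (0.8, 0.2, 0.1) capped at WM = 1 by proportional rescale
  expect_equal(f, c(0.8, 0.2, 0.1) / 1.1, tolerance = 1e-12)
  expect_true(f[1] > f[2] && f[2] > f[3] && f[3] > 0)
  expect_equal(as.numeric(fraction_sums(m)[1, 1, 1]), 1, tolerance = 1e-12)
})

test_that("assembly is permutation-covariant in the secondary fibers", {
  a <- assemble_model(make_raw(fa = 0.5, wm = 0.8, cgm = 0.2, f2 = 0.3, f3 = 0.1))
  b <- assemble_model(make_raw(fa = 0.5, wm = 0.8, cgm = 0.2, f2 = 0.1, f3 = 0.3))
  fa_ <- matrix(a$fiber_fractions, ncol = 3)
  fb <- matrix(b$fiber_fractions, ncol = 3)
  expect_equal(fa_[, 2], fb[, 3], tolerance = 1e-12)
  expect_equal(fa_[, 3], fb[, 2], tolerance = 1e-12)
  expect_equal(fa_[, 1], fb[, 1], tolerance = 1e-12)
})

test_that("FA outside [0,1] is rejected with the offending voxel count", {
  g <- grid_geometry(c(2, 2, 2))
  fa_bad <- array(0, dim = g$shape)
  fa_bad[1, 1, 1] <- 1.5
  fa_bad[2, 1, 1] <- -0.1
  expect_error(
    raw_model_inputs(
      g,
      array(0, dim = c(g$shape, 3)), fa_bad,
      array(0, dim = c(g$shape, 5)), array(0, dim = c(g$shape, 3, 3))
    ),
    "2 voxels", class = "dwiph_validation_error"
  )
})

test_that("normalize_fractions rescales to unit sum and preserves proportions", {
  m <- make_single_voxel(tissues = c(WM = 0.5), fibers = 0.5, directions = c(0, 0, 1))
  expect_equal(normalize_fractions(m)$tissues, m$tissues) # already normalized

  g <- grid_geometry(c(1, 1, 1))
  tis <- array(0, dim = c(1, 1, 1, 5))
  tis[1, 1, 1, match("cGM", TISSUE_NAMES)] <- 0.3
  tis[1, 1, 1, match("CSF", TISSUE_NAMES)] <- 0.1
  ff <- array(0, dim = c(1, 1, 1, 3))
  ff[1, 1, 1, 1] <- 0.2
  fd <- array(0, dim = c(1, 1, 1, 3, 3))
  fd[1, 1, 1, 3, 1] <- 1
  m2 <- normalize_fractions(microstructural_model(g, tis, ff, fd))
  expect_equal(m2$tissues[1, 1, 1, match("cGM", TISSUE_NAMES)], 0.5)
  expect_equal(m2$tissues[1, 1, 1, match("CSF", TISSUE_NAMES)], 1 / 6)
  expect_equal(m2$fiber_fractions[1, 1, 1, 1], 1 / 3)
  # idempotent on its own output; background voxels untouched
  expect_equal(normalize_fractions(m2), m2)
})

test_that("validate_model reports each invariant violation with voxel counts", {
  m <- make_single_voxel(tissues = c(WM = 1))
  expect_true(is_valid(validate_model(m)))

  bad <- m
  bad$fiber_fractions[1, 1, 1, 1] <- 1.3
  rep <- validate_model(bad)
  expect_false(is_valid(rep))
  checks <- vapply(rep, `[[`, "", "check")
  expect_true("fiber_fraction_range" %in% checks)
  expect_equal(rep[[which(checks == "fiber_fraction_range")]]$count, 1L)

  # nonzero fraction with a zero direction vector is named specifically
  bad2 <- m
  bad2$fiber_fractions[1, 1, 1, 1] <- 0.1
  rep2 <- validate_model(bad2)
  expect_true(any(grepl("direction_not_unit", vapply(rep2, `[[`, "", "check"))))
})

test_that("valid models carry convex-combination weights per voxel", {
  for (mk in list(
    make_mini_brain(fixture_spec("mini_brain", shape = c(24, 24, 24))),
    make_crossing_slab(fixture_spec("crossing_slab", crossing_angle = 45))
  )) {
    tm <- cbind(matrix(mk$tissues, ncol = 5), matrix(mk$fiber_fractions, ncol = 3))
    expect_true(all(tm >= 0))
    sums <- rowSums(tm)
    expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
  }
})

test_that("models round-trip through NIfTI + YAML manifest", {
  m <- make_crossing_slab(fixture_spec("crossing_slab", crossing_angle = 60))
  dir <- tempfile("model")
  write_model(m, dir)
  m2 <- read_model(dir)
  expect_equal(m2$tissues, m$tissues, tolerance = 1e-6)
  expect_equal(m2$fiber_fractions, m$fiber_fractions, tolerance = 1e-6)
  expect_equal(m2$fiber_dirs, m$fiber_dirs, tolerance = 1e-6)
  expect_equal(m2$geometry$affine, m$geometry$affine, tolerance = 1e-5)
  unlink(dir, recursive = TRUE)
})
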