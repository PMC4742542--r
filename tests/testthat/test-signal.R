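# Multi-compartment signal synthesis: closed-form attenuations, mixtures,
# whole-volume simulation, Rician noise.

test_that("fiber attenuation matches the axially symmetric closed form", {
  k <- fiber_kernel()
  z <- c(0, 0, 1)
  x <- c(1, 0, 0)
  expect_equal(fiber_attenuation(k, z, z, 1000), exp(-2.2), tolerance = 1e-12)
  expect_equal(fiber_attenuation(k, z, x, 1000), exp(-0.2), tolerance = 1e-12)
  expect_identical(fiber_attenuation(k, z, x, 0), 1)
  # symmetric under sign flips of either vector
  g <- c(0.6, 0.8, 0) / 1
  expect_equal(fiber_attenuation(k, z, g, 700), fiber_attenuation(k, -z, g, 700))
  expect_equal(fiber_attenuation(k, z, g, 700), fiber_attenuation(k, z, -g, 700))
  expect_error(fiber_attenuation(k, c(0, 0, 2), z, 1000), class = "dwiph_validation_error")
})

test_that("isotropic attenuation is mono-exponential in b", {
  expect_equal(isotropic_attenuation(3.0e-3, 1000), exp(-3), tolerance = 1e-12)
  expect_equal(isotropic_attenuation(2.0e-4, 1000), exp(-0.2), tolerance = 1e-12)
  expect_identical(isotropic_attenuation(3.0e-3, 0), 1)
  expect_error(isotropic_attenuation(3.0e-3, -1), class = "dwiph_validation_error")
})

test_that("voxel signal is the fraction-weighted compartment mixture", {
  sch <- gradient_scheme(c(0, 1000, 2000), rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 1)))
  mixed <- make_single_voxel(
    tissues = c(WM = 0.2, CSF = 0.1), fibers = 0.7, directions = c(0, 0, 1)
  )
  s <- signal_of_voxel(mixed, sch)
  expect_equal(s[1], 1) # b0 = s0 * (sum of fractions)
  expect_equal(s[2], 0.7 * exp(-2.2) + 0.2 * exp(-0.2) + 0.1 * exp(-3), tolerance = 1e-12)

  csf <- make_single_voxel(tissues = c(CSF = 1))
  expect_equal(signal_of_voxel(csf, sch)[3], exp(-6), tolerance = 1e-12)

  empty <- voxel_signal(rep(0, 5), scheme = sch)
  expect_equal(empty, c(0, 0, 0))

  # abnormal tissue without a configured diffusivity is a configuration error
  expect_error(
    voxel_signal(c(0, 0, 0, 0, 1), scheme = sch),
    class = "dwiph_configuration_error"
  )
})

test_that("volume simulation reduces to the voxel closed form", {
  sch <- cached_scheme(15L, 1000, 1L, seed = 7L, n_restarts = 3L)
  csf <- make_single_voxel(tissues = c(CSF = 1))
  vol <- simulate_volume(csf, sch, s0 = 500)
  expect_equal(
    as.numeric(vol$data[1, 1, 1, ]),
    500 * isotropic_attenuation(3.0e-3, sch$bvals),
    tolerance = 1e-12
  )

  mb <- make_mini_brain(fixture_spec("mini_brain", shape = c(24, 24, 24)))
  volb <- simulate_volume(mb, sch, s0 = 1000)
  fs <- fraction_sums(mb)
  b0 <- volb$data[, , , which(sch$bvals == 0)[1]]
  expect_true(all(abs(b0[fs > 0] - 1000) < 1e-9)) # b0 conservation
  expect_true(all(b0[fs == 0] == 0))
})

test_that("signals are convex mixtures and antipodally symmetric", {
  sch <- cached_scheme(30L, 1000, 1L, seed = 7L, n_restarts = 3L)
  cs <- make_crossing_slab(fixture_spec("crossing_slab", crossing_angle = 90))
  vol <- simulate_volume(cs, sch, s0 = 1)

  fm <- matrix(cs$fiber_fractions, ncol = 3)
  tmx <- matrix(cs$tissues, ncol = 5)
  nv <- prod(cs$geometry$shape)
  dat <- matrix(vol$data, nrow = nv)
  k <- fiber_kernel()
  # bounded per volume by min/max compartment attenuation
  for (vi in which(sch$bvals > 0)[1:5]) {
    g <- sch$bvecs[vi, ]
    atts <- cbind(
      exp(-1000 * (k$lambda_perp + (k$lambda_par - k$lambda_perp) *
        (matrix(cs$fiber_dirs[, , , , 1], ncol = 3) %*% g)^2)),
      exp(-1000 * (k$lambda_perp + (k$lambda_par - k$lambda_perp) *
        (matrix(cs$fiber_dirs[, , , , 2], ncol = 3) %*% g)^2)),
      matrix(exp(-1000 * 2e-4), nv, 1)
    )
    present <- cbind(fm[, 1] > 0, fm[, 2] > 0, tmx[, 3] > 0)
    lo <- apply(ifelse(present, atts, Inf), 1, min)
    hi <- apply(ifelse(present, atts, -Inf), 1, max)
    expect_true(all(dat[, vi] >= lo - 1e-9 & dat[, vi] <= hi + 1e-9))
  }

  # a 90-degree crossing voxel, probed along bundle 1, lies between the two
  # single-fiber compositions with the same fiber/WM split (convex mixture)
  both <- which(fm[, 1] > 0.4 & fm[, 2] > 0.4)[1]
  v1 <- matrix(cs$fiber_dirs[, , , , 1], ncol = 3)[both, ]
  v2 <- matrix(cs$fiber_dirs[, , , , 2], ncol = 3)[both, ]
  f_tot <- fm[both, 1] + fm[both, 2]
  wm_frac <- tmx[both, 3]
  tis <- c(0, 0, wm_frac, 0, 0)
  s_cross <- voxel_signal(tis, fm[both, 1:2], rbind(v1, v2), sch)
  s_one <- voxel_signal(tis, f_tot, rbind(v1), sch)
  s_two <- voxel_signal(tis, f_tot, rbind(v2), sch)
  gi <- which.max(abs(sch$bvecs %*% v1))
  expect_gte(s_cross[gi], min(s_one[gi], s_two[gi]) - 1e-12)
  expect_lte(s_cross[gi], max(s_one[gi], s_two[gi]) + 1e-12)

  # negating every gradient direction leaves the signal bit-identical
  neg <- gradient_scheme(sch$bvals, -sch$bvecs)
  vol_neg <- simulate_volume(cs, neg, s0 = 1)
  expect_identical(vol$data, vol_neg$data)
})

test_that("Rician noise follows its defining construction", {
  mb <- make_mini_brain(fixture_spec("mini_brain", shape = c(24, 24, 24)))
  sch <- cached_scheme(15L, 1000, 1L, seed = 7L, n_restarts = 3L)
  vol <- simulate_volume(mb, sch)

  expect_identical(add_rician_noise(vol, noise_spec(Inf)), vol)

  n1 <- add_rician_noise(vol, noise_spec(30, seed = 21L))
  n2 <- add_rician_noise(vol, noise_spec(30, seed = 21L))
  expect_identical(n1$data, n2$data)
  expect_true(all(n1$data >= 0))
  expect_equal(attr(n1, "sigma"), 1000 / 30, tolerance = 1e-12)

  # background magnitudes are Rayleigh: mean sigma * sqrt(pi/2)
  zeros <- diffusion_volume(
    array(0, dim = c(40, 50, 50, 1)), grid_geometry(c(40, 50, 50)),
    gradient_scheme(0, rbind(c(0, 0, 0))), s0 = 1
  )
  zeros$data[1, 1, 1, 1] <- 1 # one in-brain voxel to define sigma = 1/snr
  noisy <- add_rician_noise(zeros, noise_spec(10, seed = 3L))
  bg <- as.numeric(noisy$data[-1])
  sigma <- 1 / 10
  expect_length(bg, 40 * 50 * 50 - 1)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.02)

  # a volume with no in-brain b0 voxels cannot define sigma
  expect_error(
    add_rician_noise(
      diffusion_volume(array(0, dim = c(2, 2, 2, 1)), grid_geometry(c(2, 2, 2)),
        gradient_scheme(0, rbind(c(0, 0, 0))),
        s0 = 1
      ),
      noise_spec(30, seed = 1L)
    ),
    class = "dwiph_configuration_error"
  )
})
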