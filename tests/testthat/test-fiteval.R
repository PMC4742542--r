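# Self-validation estimators: tensor fit, FA, ADC, SNR.

test_that("log-linear tensor fit exactly recovers generating tensors", {
  sch <- cached_scheme(30L, 1000, 1L, seed = 7L, n_restarts = 3L)

  fib <- make_single_voxel(fibers = 1, directions = c(0, 0, 1))
  s <- signal_of_voxel(fib, sch)
  tf <- fit_tensor_loglinear(s, sch, s0 = 1)
  expect_equal(tf$eigenvalues[1], 2.2e-3, tolerance = 1e-9)
  expect_equal(tf$eigenvalues[2], 0.2e-3, tolerance = 1e-9)
  expect_equal(tf$eigenvalues[3], 0.2e-3, tolerance = 1e-9)
  expect_equal(abs(tf$principal_direction[3]), 1, tolerance = 1e-6)

  csf <- make_single_voxel(tissues = c(CSF = 1))
  tf2 <- fit_tensor_loglinear(signal_of_voxel(csf, sch), sch, s0 = 1)
  expect_equal(tf2$eigenvalues, rep(3.0e-3, 3), tolerance = 1e-9)

  # constant signal fits a zero tensor
  tf3 <- fit_tensor_loglinear(rep(5, length(sch$bvals)), sch, s0 = 5)
  expect_equal(tf3$eigenvalues, rep(0, 3), tolerance = 1e-12)

  # collinear directions are a rank-deficient design
  bad <- gradient_scheme(
    c(0, rep(1000, 6)),
    rbind(c(0, 0, 0), matrix(rep(c(0, 0, 1), 6), ncol = 3, byrow = TRUE))
  )
  expect_error(
    fit_tensor_loglinear(rep(1, 7), bad, s0 = 1),
    "rank", class = "dwiph_estimation_error"
  )
})

test_that("FA follows the standard eigenvalue formula", {
  expect_equal(fa(c(3e-3, 3e-3, 3e-3)), 0)
  expect_equal(fa(c(2.2e-3, 0.2e-3, 0.2e-3)), 0.9016696, tolerance = 1e-6)
  expect_equal(fa(c(1, 0, 0)), 1)
  expect_error(fa(c(0, 0, 0)), class = "dwiph_estimation_error")
  expect_warning(v <- fa(c(1e-3, -1e-5, 1e-5)), "clamped")

  # monotone in lambda1 for fixed lambda2 = lambda3
  l1 <- seq(0.3e-3, 3e-3, length.out = 20)
  fas <- vapply(l1, function(l) fa(c(l, 0.2e-3, 0.2e-3)), numeric(1))
  expect_true(all(diff(fas) > 0))
})

test_that("ADC fit recovers isotropic diffusivities exactly", {
  sch <- cached_scheme(15L, 1000, 1L, seed = 7L, n_restarts = 3L)
  csf <- make_single_voxel(tissues = c(CSF = 1))
  expect_equal(estimate_adc(signal_of_voxel(csf, sch), sch), 3.0e-3, tolerance = 1e-9)

  dgm <- make_single_voxel(tissues = c(dGM = 1))
  expect_equal(estimate_adc(signal_of_voxel(dgm, sch), sch), 9.0e-4, tolerance = 1e-9)

  expect_equal(estimate_adc(rep(2, length(sch$bvals)), sch), 0, tolerance = 1e-12)

  single_b <- gradient_scheme(c(0, 0), matrix(0, 2, 3))
  expect_error(estimate_adc(c(1, 1), single_b), class = "dwiph_estimation_error")
})

test_that("background-Rayleigh SNR estimation is unbiased across levels", {
  mb <- make_mini_brain(fixture_spec("mini_brain", shape = c(32, 32, 32)))
  sch <- cached_scheme(15L, 1000, 1L, seed = 7L, n_restarts = 3L)
  vol <- simulate_volume(mb, sch)
  fs <- fraction_sums(mb)
  expect_gt(sum(fs == 0), 1e4)

  for (snr in c(30, 10)) {
    noisy <- add_rician_noise(vol, noise_spec(snr, seed = 17L))
    est <- estimate_snr(noisy, fs > 0.5, fs == 0)
    expect_equal(est$snr, snr, tolerance = 0.05)
    expect_equal(est$sigma, 1000 / snr, tolerance = 0.05)
  }

  expect_message(
    est0 <- estimate_snr(vol, fs > 0.5, fs == 0),
    "no measurable noise"
  )
  expect_identical(est0$snr, Inf)
  expect_error(
    estimate_snr(vol, fs > 2, fs == 0),
    class = "dwiph_validation_error"
  )
})

test_that("evaluation reports round-trip simulated volumes against truth", {
  mb <- make_mini_brain(fixture_spec("mini_brain", shape = c(24, 24, 24)))
  sch <- cached_scheme(15L, 1000, 1L, seed = 7L, n_restarts = 3L)
  vol <- simulate_volume(mb, sch)
  noisy <- add_rician_noise(vol, noise_spec(30, seed = 2L))

  rep_noisy <- evaluate_volume(noisy, mb, truth = list(snr = 30))
  expect_true(rep_noisy$snr$pass)

  rep_clean <- evaluate_volume(vol, mb, truth = list(snr = Inf))
  expect_true(rep_clean$adc_csf$pass)

  path <- tempfile(fileext = ".json")
  write_evaluation_report(rep_noisy, path)
  expect_equal(jsonlite::read_json(path)$snr$truth, 30)
})
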