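# Configuration, BIDS layout and the end-to-end workflow.

small_config <- function(out_dir = tempfile("run"), ...) {
  run_config(
    fixture = fixture_spec("mini_brain", shape = c(24, 24, 24)),
    scheme = list(n_per_shell = 12L, bvals = 1000, n_b0 = 1L),
    out_dir = out_dir, seed = 3L, ...
  )
}

test_that("BIDS writer lays out the dataset and refuses silent overwrites", {
  sch <- cached_scheme(6L, 1000, 1L, seed = 42L, n_restarts = 5L)
  vol <- simulate_volume(make_single_voxel(tissues = c(WM = 1)), sch)
  root <- tempfile("bids")
  write_bids_dataset(vol, root, "01", provenance = list(seed = 1))
  expect_true(file.exists(file.path(root, "dataset_description.json")))
  dwi <- file.path(root, "sub-01", "dwi")
  expect_setequal(
    list.files(dwi),
    paste0("sub-01_dwi", c(".nii.gz", ".bval", ".bvec", ".json"))
  )
  # sidecar carries provenance
  side <- jsonlite::read_json(file.path(dwi, "sub-01_dwi.json"))
  expect_equal(side$DwiphantomProvenance$seed, 1)
  # rereading the gradient tables reproduces the scheme
  rt <- read_fsl_scheme(
    file.path(dwi, "sub-01_dwi.bval"),
    file.path(dwi, "sub-01_dwi.bvec")
  )
  expect_equal(rt$bvecs, sch$bvecs, tolerance = 1e-6)

  expect_error(write_bids_dataset(vol, root, "01"), class = "dwiph_validation_error")
  expect_silent(write_bids_dataset(vol, root, "01", overwrite = TRUE))
  expect_error(write_bids_dataset(vol, root, "bad label"), class = "dwiph_validation_error")
  unlink(root, recursive = TRUE)
})

test_that("run configurations round-trip through YAML", {
  cfg <- small_config(
    snr = Inf,
    distortion = list(magnitude_mm = 4, extent_mm = 15, pe_axis = 2L)
  )
  path <- tempfile(fileext = ".yml")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$fixture$shape, cfg$fixture$shape)
  expect_equal(cfg2$kernel, cfg$kernel)
  expect_equal(unclass(cfg2$diffusivities), unclass(cfg$diffusivities))
  expect_identical(cfg2$snr, Inf)
  expect_equal(cfg2$distortion$magnitude_mm, 4)
  expect_equal(cfg2$seed, cfg$seed)
})

test_that("the end-to-end run is deterministic under a fixed seed", {
  m1 <- run_diffantomize(small_config())
  m2 <- run_diffantomize(small_config())
  expect_identical(m1$volume$data, m2$volume$data)
  expect_identical(m1$scheme$bvecs, m2$scheme$bvecs)
  # written gradient tables are byte-identical too
  b1 <- readBin(m1$reference[2], "raw", 1e6)
  b2 <- readBin(m2$reference[2], "raw", 1e6)
  expect_identical(b1, b2)
})

test_that("a distortion-enabled run writes a reference and distorted pair", {
  cfg <- small_config(distortion = list(magnitude_mm = 6, extent_mm = 20, pe_axis = 2L))
  m <- run_diffantomize(cfg)
  expect_true(file.exists(m$reference[1]))
  expect_true(file.exists(m$distorted[1]))
  expect_true(file.exists(m$fieldmap))

  ref <- read_diffusion_volume(sub("\\.nii\\.gz$", "", m$reference[1]))
  dst <- read_diffusion_volume(sub("\\.nii\\.gz$", "", m$distorted[1]))
  # the difference is confined to the distorted focus region
  diff_map <- apply(abs(ref$data - dst$data), 1:3, max)
  ctr_mm <- dwiphantom:::voxel_centers(ref$geometry)
  far <- array(sqrt(rowSums(ctr_mm^2)) > 22, dim = ref$geometry$shape)
  expect_lt(max(diff_map[far]) / max(ref$data), 1e-5)
  expect_gt(max(diff_map[!far]), 0)
  unlink(cfg$out_dir, recursive = TRUE)
})

test_that("noise-free runs satisfy the closed-form checks end to end", {
  cfg <- small_config(snr = Inf)
  m <- run_diffantomize(cfg)
  fs <- fraction_sums(m$model)
  b0 <- m$volume$data[, , , which(m$scheme$bvals == 0)[1]]
  expect_true(all(abs(b0[fs > 0] - cfg$s0) < 1e-9))
  expect_true(m$report$adc_csf$pass)
  unlink(cfg$out_dir, recursive = TRUE)
})
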