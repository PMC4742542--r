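# Pipeline interface: run configuration, BIDS dataset layout, and the
# end-to-end phantom generation workflow
# (fixture -> scheme -> simulate -> noise -> distort -> write -> evaluate).

#' Full configuration of a phantom-generation run
#'
#' Collects every tunable of the pipeline in one serializable object; a run's
#' config is persisted beside its outputs so any dataset can be regenerated.
#'
#' @param fixture A [fixture_spec()], or `NULL` when `model_path` is given.
#' @param model_path Path to a model manifest written by [write_model()]
#'   (alternative to `fixture`).
#' @param scheme List with `n_per_shell`, `bvals`, `n_b0` (defaults: 100
#'   directions on one b = 1000 shell, one b = 0).
#' @param kernel A [fiber_kernel()].
#' @param diffusivities A [diffusivity_set()].
#' @param snr Signal-to-noise ratio (default 30; `Inf` for noise-free).
#' @param s0 Reference intensity.
#' @param distortion `NULL` for none, or a list with `magnitude_mm`,
#'   `extent_mm`, `pe_axis`; when set, the run writes a reference and a
#'   distorted dataset pair.
#' @param label BIDS subject label (alphanumeric).
#' @param out_dir Output dataset root.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param fod_path If `TRUE`, synthesize the restricted-compartment signal
#'   through the FOD/spherical-harmonic convolution (order `fod_order`)
#'   instead of the exact discrete tensor sum.
#' @param fod_order Even SH order for the FOD path.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fixture = fixture_spec("mini_brain"),
                       model_path = NULL,
                       scheme = list(n_per_shell = 100L, bvals = 1000, n_b0 = 1L),
                       kernel = fiber_kernel(),
                       diffusivities = diffusivity_set(),
                       snr = 30, s0 = 1000,
                       distortion = NULL,
                       label = "01", out_dir = tempfile("diffphantom"),
                       seed = 1L,
                       fod_path = FALSE, fod_order = 8L) {
  if (is.null(fixture) && is.null(model_path)) {
    abort_dwiph("either a fixture spec or a model path is required", "dwiph_validation_error")
  }
  if (!grepl("^[A-Za-z0-9]+$", label)) {
    abort_dwiph("BIDS label must be alphanumeric and non-empty", "dwiph_validation_error")
  }
  structure(
    list(
      fixture = fixture, model_path = model_path, scheme = scheme,
      kernel = kernel, diffusivities = diffusivities, snr = snr, s0 = s0,
      distortion = distortion, label = label, out_dir = out_dir,
      seed = as.integer(seed), fod_path = fod_path, fod_order = fod_order
    ),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config`: invisibly, the path.
#' @export
write_run_config <- function(config, path) {
  lst <- list(
    fixture = if (is.null(config$fixture)) NULL else unclass(config$fixture),
    model_path = config$model_path,
    scheme = config$scheme,
    kernel = unclass(config$kernel),
    diffusivities = as.list(unclass(config$diffusivities)),
    snr = if (is.infinite(config$snr)) ".inf" else config$snr,
    s0 = config$s0,
    distortion = config$distortion,
    label = config$label,
    out_dir = config$out_dir,
    seed = config$seed,
    fod_path = config$fod_path,
    fod_order = config$fod_order
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @return `read_run_config`: a [run_config()].
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  snr <- lst$snr
  if (is.character(snr)) snr <- Inf
  d <- lst$diffusivities
  run_config(
    fixture = if (is.null(lst$fixture)) NULL else do.call(fixture_spec, lst$fixture),
    model_path = lst$model_path,
    scheme = lst$scheme,
    kernel = do.call(fiber_kernel, lst$kernel),
    diffusivities = diffusivity_set(
      WM = d$WM, cGM = d$cGM, dGM = d$dGM, CSF = d$CSF,
      abnormal = if (is.null(d$abnormal)) NA_real_ else d$abnormal
    ),
    snr = snr, s0 = lst$s0,
    distortion = lst$distortion,
    label = lst$label, out_dir = lst$out_dir, seed = lst$seed,
    fod_path = isTRUE(lst$fod_path),
    fod_order = if (is.null(lst$fod_order)) 8L else lst$fod_order
  )
}

#' Write a diffusion volume as a BIDS dataset
#'
#' Layout: `sub-<label>/dwi/sub-<label>_dwi.{nii.gz,bval,bvec,json}` plus a
#' `dataset_description.json` at the root. The JSON sidecar carries the full
#' simulation provenance (seed, SNR, kernel, diffusivities) under a
#' vendor-prefixed block so any dataset is regenerable without a separate
#' manifest.
#'
#' @param volume A [diffusion_volume()].
#' @param out_dir Dataset root directory.
#' @param label Subject label (alphanumeric).
#' @param provenance Named list stored under the `DwiphantomProvenance`
#'   sidecar key.
#' @param overwrite Overwrite an existing subject directory.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_bids_dataset <- function(volume, out_dir, label, provenance = list(),
                               overwrite = FALSE) {
  if (missing(label) || length(label) != 1 || !grepl("^[A-Za-z0-9]+$", label)) {
    abort_dwiph("BIDS label must be a non-empty alphanumeric string", "dwiph_validation_error")
  }
  sub_dir <- file.path(out_dir, paste0("sub-", label), "dwi")
  if (dir.exists(sub_dir) && length(list.files(sub_dir)) > 0 && !overwrite) {
    abort_dwiph(
      sprintf("target '%s' exists and is non-empty; pass overwrite = TRUE", sub_dir),
      "dwiph_validation_error"
    )
  }
  dir.create(sub_dir, showWarnings = FALSE, recursive = TRUE)
  desc_path <- file.path(out_dir, "dataset_description.json")
  if (!file.exists(desc_path)) {
    jsonlite::write_json(
      list(
        Name = "dwiphantom simulated dMRI dataset",
        BIDSVersion = "1.8.0",
        DatasetType = "raw",
        GeneratedBy = list(list(Name = "dwiphantom",
                                Version = as.character(utils::packageVersion("dwiphantom"))))
      ),
      desc_path, auto_unbox = TRUE, pretty = TRUE
    )
  }
  prefix <- file.path(sub_dir, sprintf("sub-%s_dwi", label))
  paths <- write_diffusion_volume(
    volume, prefix,
    sidecar = list(DwiphantomProvenance = provenance)
  )
  invisible(c(paths, dataset_description = desc_path))
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[dwiphantom] %s %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Run the full phantom-generation workflow
#'
#' Executes fixture build (or model load), scheme generation, noise-free
#' simulation, Rician noise, optional susceptibility distortion, and BIDS
#' output. Fully deterministic given `config$seed` (stage seeds are derived
#' from it: scheme = seed, noise = seed + 1). When distortion is configured,
#' a reference (`sub-<label>`) and distorted (`sub-<label>dist`) pair is
#' written.
#'
#' @param config A [run_config()].
#' @param verbose Log each stage with its parameters to stderr.
#' @return Invisibly, a manifest list: paths of the files written, the model,
#'   scheme, volumes and the evaluation report.
#' @export
run_diffantomize <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stage <- "model"
  manifest <- list()
  result <- tryCatch(
    {
      model <- if (!is.null(config$model_path)) {
        log_stage(verbose, "loading model from %s", config$model_path)
        read_model(config$model_path)
      } else {
        log_stage(verbose, "building '%s' fixture (%s voxels, seed %d)",
                  config$fixture$kind, paste(config$fixture$shape, collapse = "x"),
                  config$fixture$seed)
        make_fixture(config$fixture)
      }
      report <- validate_model(model)
      if (!is_valid(report)) {
        abort_dwiph(
          paste("model invalid:", paste(vapply(report, `[[`, "", "message"), collapse = "; ")),
          "dwiph_validation_error"
        )
      }

      stage <- "scheme"
      log_stage(verbose, "generating scheme: %s directions at b = %s + %d b0 (seed %d)",
                paste(config$scheme$n_per_shell, collapse = ","),
                paste(config$scheme$bvals, collapse = ","), config$scheme$n_b0, config$seed)
      scheme <- generate_uniform_scheme(
        n_per_shell = config$scheme$n_per_shell, bvals = config$scheme$bvals,
        n_b0 = config$scheme$n_b0, seed = config$seed
      )

      stage <- "simulate"
      log_stage(verbose, "simulating %d volumes (s0 = %g, %s path)",
                length(scheme$bvals), config$s0,
                if (config$fod_path) "FOD" else "discrete")
      clean <- if (config$fod_path) {
        simulate_volume_fod(model, scheme, config$kernel, config$diffusivities,
                            config$s0, L = config$fod_order)
      } else {
        simulate_volume(model, scheme, config$kernel, config$diffusivities, config$s0)
      }

      stage <- "noise"
      noisy <- if (is.infinite(config$snr)) {
        log_stage(verbose, "noise-free run (snr = Inf)")
        clean
      } else {
        log_stage(verbose, "adding Rician noise at SNR = %g (seed %d)", config$snr, config$seed + 1L)
        add_rician_noise(clean, noise_spec(snr = config$snr, seed = config$seed + 1L))
      }

      provenance <- list(
        seed = config$seed, snr = config$snr, s0 = config$s0,
        kernel = unclass(config$kernel),
        diffusivities = as.list(unclass(config$diffusivities)),
        scheme = config$scheme
      )

      stage <- "write"
      files <- write_bids_dataset(noisy, config$out_dir, config$label,
                                  provenance = provenance, overwrite = TRUE)
      manifest$reference <- files

      if (!is.null(config$distortion)) {
        stage <- "distort"
        d <- config$distortion
        log_stage(verbose, "distorting: peak %g mm, extent %g mm, axis %d",
                  d$magnitude_mm, d$extent_mm, d$pe_axis)
        field <- make_synthetic_fieldmap(
          noisy$geometry,
          magnitude_mm = d$magnitude_mm, extent_mm = d$extent_mm,
          pe_axis = d$pe_axis
        )
        warped <- apply_distortion(noisy, field)
        dist_label <- paste0(config$label, "dist")
        provenance$distortion <- d
        manifest$distorted <- write_bids_dataset(
          warped, config$out_dir, dist_label,
          provenance = provenance, overwrite = TRUE
        )
        fmap_path <- file.path(config$out_dir, paste0("sub-", dist_label), "dwi",
                               sprintf("sub-%s_fieldmap.nii.gz", dist_label))
        write_fieldmap(field, fmap_path)
        manifest$fieldmap <- fmap_path
      }

      stage <- "evaluate"
      report <- evaluate_volume(noisy, model, truth = list(
        snr = config$snr, diffusivities = config$diffusivities
      ))
      eval_path <- file.path(config$out_dir, "evaluation.json")
      write_evaluation_report(report, eval_path)
      manifest$evaluation <- eval_path

      config_path <- file.path(config$out_dir, "run_config.yml")
      write_run_config(config, config_path)
      manifest$config <- config_path

      manifest$model <- model
      manifest$scheme <- scheme
      manifest$volume <- noisy
      manifest$report <- report
      manifest
    },
    dwiphantom_error = function(e) {
      abort_dwiph(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                  class(e)[1])
    }
  )
  invisible(result)
}
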