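# Shared objects built once per test run. Scheme optimization is the only
# costly step, so schemes are cached by their parameters.

.scheme_cache <- new.env(parent = emptyenv())

cached_scheme <- function(n = 30L, b = 1000, n_b0 = 1L, seed = 7L, n_restarts = 3L) {
  key <- paste(n, b, n_b0, seed, n_restarts, sep = "_")
  if (is.null(.scheme_cache[[key]])) {
    .scheme_cache[[key]] <- generate_uniform_scheme(
      n_per_shell = n, bvals = b, n_b0 = n_b0, seed = seed, n_restarts = n_restarts
    )
  }
  .scheme_cache[[key]]
}

# default acquisition protocol (100 directions, one shell, one b0)
default_scheme <- function(seed = 11L) cached_scheme(100L, 1000, 1L, seed, 20L)

# fraction/direction accessors for single-voxel models
voxel_fractions <- function(model) {
  list(
    tissues = model$tissues[1, 1, 1, ],
    fibers = model$fiber_fractions[1, 1, 1, ],
    dirs = t(model$fiber_dirs[1, 1, 1, , ]) # one row per fiber
  )
}

signal_of_voxel <- function(model, scheme, ..., s0 = 1) {
  vf <- voxel_fractions(model)
  voxel_signal(vf$tissues, vf$fibers, vf$dirs, scheme, ..., s0 = s0)
}
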