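# Gradient sampling schemes: uniform-coverage direction sets and gradient
# table I/O in the two dialects in common use (FSL bval/bvec, MRtrix table).

#' Construct a gradient scheme
#'
#' @param bvals Numeric vector of per-volume b-values (s/mm^2), `>= 0`; at
#'   least one must be 0.
#' @param bvecs n x 3 matrix of per-volume gradient directions in the world
#'   frame (the same frame as the model's fiber direction fields — no
#'   image-axis flip is ever applied). Rows must be unit length where
#'   `b > 0`; zero vectors are allowed only on `b = 0` volumes.
#' @return An object of class `gradient_scheme` with fields `bvals`, `bvecs`
#'   and `shells` (indices grouped by distinct positive b-value).
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- matrix(as.numeric(bvecs), ncol = 3)
  if (nrow(bvecs) != length(bvals)) {
    abort_dwiph(
      sprintf("%d b-values but %d direction rows", length(bvals), nrow(bvecs)),
      "dwiph_format_error"
    )
  }
  if (any(bvals < 0)) {
    abort_dwiph("b-values must be non-negative", "dwiph_validation_error")
  }
  if (!any(bvals == 0)) {
    abort_dwiph("scheme must contain at least one b=0 volume", "dwiph_validation_error")
  }
  norms <- row_norms(bvecs)
  bad <- bvals > 0 & abs(norms - 1) > 1e-6
  if (any(bad)) {
    abort_dwiph(
      sprintf("%d diffusion-weighted directions are not unit length", sum(bad)),
      "dwiph_validation_error"
    )
  }
  shell_b <- sort(unique(bvals[bvals > 0]))
  shells <- lapply(shell_b, function(b) which(bvals == b))
  names(shells) <- format(shell_b, trim = TRUE)
  structure(
    list(bvals = bvals, bvecs = bvecs, shells = shells),
    class = "gradient_scheme"
  )
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(
    sprintf(
      "<gradient_scheme> %d volumes: %d b=0, shells at b = %s (n = %s)\n",
      length(x$bvals), sum(x$bvals == 0),
      paste(names(x$shells), collapse = ", "),
      paste(vapply(x$shells, length, 1L), collapse = ", ")
    )
  )
  invisible(x)
}

#' @export
length.gradient_scheme <- function(x) length(x$bvals)

#' Antipodally symmetric electrostatic energy of a direction set
#'
#' Sum over pairs of `1/|v_i - v_j| + 1/|v_i + v_j|`, the standard
#' uniformity criterion for diffusion direction sets (each direction and its
#' negation repel all others).
#'
#' @param v n x 3 matrix of unit vectors.
#' @return Scalar energy.
#' @export
antipodal_energy <- function(v) {
  v <- matrix(v, ncol = 3)
  n <- nrow(v)
  if (n < 2) return(0)
  gram <- tcrossprod(v) # v_i . v_j
  d2m <- 2 - 2 * gram # |v_i - v_j|^2
  d2p <- 2 + 2 * gram # |v_i + v_j|^2
  ut <- upper.tri(d2m)
  sum(1 / sqrt(pmax(d2m[ut], .Machine$double.eps))) +
    sum(1 / sqrt(pmax(d2p[ut], .Machine$double.eps)))
}

# gradient of antipodal_energy wrt each row of v (n x 3)
antipodal_energy_grad <- function(v) {
  n <- nrow(v)
  gram <- tcrossprod(v)
  d3m <- (pmax(2 - 2 * gram, .Machine$double.eps))^(-1.5)
  d3p <- (pmax(2 + 2 * gram, .Machine$double.eps))^(-1.5)
  diag(d3m) <- 0
  diag(d3p) <- 0
  # dE/dv_i = -sum_j (v_i - v_j) / |v_i - v_j|^3 - sum_j (v_i + v_j) / |v_i + v_j|^3
  -(v * (rowSums(d3m) + rowSums(d3p)) - d3m %*% v + d3p %*% v)
}

normalize_rows <- function(v) v / row_norms(v)

random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(n * 3), ncol = 3)
  normalize_rows(v)
}

# projected gradient descent on the sphere with backtracking line search
minimize_antipodal_energy <- function(v, max_iter = 1000L, tol = 1e-8) {
  e <- antipodal_energy(v)
  step <- 0.1 / nrow(v)
  for (iter in seq_len(max_iter)) {
    gr <- antipodal_energy_grad(v)
    # tangential component only: motion along v is lost to renormalization
    gr <- gr - v * rowSums(gr * v)
    gnorm <- max(row_norms(gr))
    if (gnorm < 1e-12) break
    repeat {
      v_new <- normalize_rows(v - step * gr)
      e_new <- antipodal_energy(v_new)
      if (e_new < e || step < 1e-14) break
      step <- step / 2
    }
    if (e_new >= e) break
    improved <- (e - e_new) / e
    v <- v_new
    e <- e_new
    step <- step * 1.5
    if (improved < tol) break
  }
  list(v = v, energy = e)
}

#' Generate a uniform-coverage gradient scheme
#'
#' Places `n_per_shell` directions per shell by minimizing the antipodally
#' symmetric electrostatic energy ([antipodal_energy()]) with projected
#' gradient descent from seeded random starts, keeping the best of
#' `n_restarts` runs per shell. The default protocol is 100 directions on a
#' single b = 1000 shell plus one b = 0 volume. Deterministic given `seed`.
#'
#' @param n_per_shell Integer vector, directions per shell (each `>= 1`).
#' @param bvals Numeric vector of distinct positive shell b-values (s/mm^2).
#' @param n_b0 Number of b = 0 volumes, placed first.
#' @param seed Integer seed for the random starts.
#' @param n_restarts Random restarts per shell.
#' @param max_iter Iteration cap per descent.
#' @param tol Relative energy-change stopping tolerance.
#' @return A [gradient_scheme()].
#' @export
generate_uniform_scheme <- function(n_per_shell = 100L, bvals = 1000,
                                    n_b0 = 1L, seed = NULL,
                                    n_restarts = 20L, max_iter = 1000L,
                                    tol = 1e-8) {
  n_per_shell <- as.integer(n_per_shell)
  if (length(n_per_shell) != length(bvals)) {
    abort_dwiph("n_per_shell and bvals must have equal length", "dwiph_validation_error")
  }
  if (any(n_per_shell < 1L)) {
    abort_dwiph("each shell needs at least one direction", "dwiph_validation_error")
  }
  if (any(bvals <= 0) || anyDuplicated(bvals)) {
    abort_dwiph("shell b-values must be positive and distinct", "dwiph_validation_error")
  }
  if (n_b0 < 1L) {
    abort_dwiph("at least one b=0 volume is required", "dwiph_validation_error")
  }
  dirs <- with_seed(seed, {
    lapply(n_per_shell, function(n) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- minimize_antipodal_energy(random_unit_vectors(n), max_iter, tol)
        if (is.null(best) || fit$energy < best$energy) best <- fit
      }
      best$v
    })
  })
  all_b <- c(rep(0, n_b0), rep(bvals, n_per_shell))
  all_v <- rbind(matrix(0, n_b0, 3), do.call(rbind, dirs))
  gradient_scheme(all_b, all_v)
}

#' Minimal angle between any two directions of a set (antipodal metric)
#'
#' @param v n x 3 matrix of unit vectors.
#' @return Smallest pairwise angle in degrees, treating `v` and `-v` as the
#'   same direction.
#' @export
min_antipodal_angle <- function(v) {
  v <- matrix(v, ncol = 3)
  gram <- abs(tcrossprod(v))
  diag(gram) <- 0
  acos(clamp(max(gram), -1, 1)) * 180 / pi
}

# ---- FSL dialect (bval + bvec) ----

#' Read / write FSL-style bval and bvec gradient tables
#'
#' The FSL dialect stores one whitespace-separated line of b-values and three
#' lines (x, y, z) of direction components. A transposed (n x 3) bvec layout
#' is auto-detected. `write_fsl_scheme`/`read_fsl_scheme` round-trip within
#' 1e-6.
#'
#' @param bval_path,bvec_path Paths of the two text files.
#' @return `read_fsl_scheme`: a [gradient_scheme()].
#' @export
read_fsl_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) {
    l <- trimws(l)
    if (nchar(l) == 0) numeric(0) else as.numeric(strsplit(l, "[ \t]+")[[1]])
  })
  rows <- rows[lengths(rows) > 0]
  mat <- do.call(rbind, rows)
  if (nrow(mat) == 3L && ncol(mat) != 3L) {
    mat <- t(mat)
  } else if (ncol(mat) != 3L) {
    abort_dwiph("bvec file must have 3 rows or 3 columns", "dwiph_format_error")
  }
  if (nrow(mat) != length(bvals)) {
    abort_dwiph(
      sprintf("bvec has %d directions but bval has %d entries", nrow(mat), length(bvals)),
      "dwiph_format_error"
    )
  }
  gradient_scheme(bvals, mat)
}

#' @rdname read_fsl_scheme
#' @param scheme A [gradient_scheme()].
#' @return `write_fsl_scheme`: invisibly, the two paths.
#' @export
write_fsl_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, digits = 15), collapse = " "), bval_path)
  lines <- apply(t(scheme$bvecs), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")
  })
  writeLines(lines, bvec_path)
  invisible(c(bval_path, bvec_path))
}

# ---- MRtrix dialect (single 4-column table) ----

#' Read / write an MRtrix-style gradient table
#'
#' One row per volume, four columns (x, y, z, b); lines starting with `#` are
#' comments. Round-trips within 1e-6.
#'
#' @param path Path of the gradient table.
#' @return `read_mrtrix_scheme`: a [gradient_scheme()].
#' @export
read_mrtrix_scheme <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nchar(lines) > 0 & !startsWith(lines, "#")]
  rows <- lapply(lines, function(l) as.numeric(strsplit(l, "[ \t,]+")[[1]]))
  if (any(lengths(rows) != 4L)) {
    abort_dwiph(
      sprintf(
        "gradient table must have 4 columns (x, y, z, b); got %s",
        paste(unique(lengths(rows)), collapse = "/")
      ),
      "dwiph_format_error"
    )
  }
  mat <- do.call(rbind, rows)
  gradient_scheme(mat[, 4], mat[, 1:3])
}

#' @rdname read_mrtrix_scheme
#' @param scheme A [gradient_scheme()].
#' @return `write_mrtrix_scheme`: invisibly, the path.
#' @export
write_mrtrix_scheme <- function(scheme, path) {
  tab <- cbind(scheme$bvecs, scheme$bvals)
  lines <- c(
    "# gradient table: x y z b (world frame, b in s/mm^2)",
    apply(tab, 1, function(r) paste(format(r, trim = TRUE, digits = 15), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}
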