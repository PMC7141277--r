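#' Gradient tables for multi-shell q-space sampling
#'
#' A gradient table pairs one b-value (s/mm^2) with one unit gradient
#' direction per acquisition volume. The default layout mirrors a typical
#' three-shell clinical protocol: one null (b = 0) image followed by
#' `n_per_shell` diffusion-weighted directions on each shell.
#'
#' Directions on each shell are laid out by a deterministic spherical
#' Fibonacci spiral (near-uniform coverage without iterative optimisation);
#' shells are rotated against each other by a fixed golden-angle offset so
#' the combined scheme is non-collinear across shells. The seed only
#' permutes the acquisition order of the weighted rows, never the geometry.
#'
#' @param n_per_shell number of weighted directions per shell (>= 0).
#' @param shell_bvalues positive b-values, one per shell, in s/mm^2.
#' @param seed integer seed controlling the row permutation.
#' @return an object of class `gradient_table`: a list with `bvals`
#'   (numeric vector) and `bvecs` (n x 3 matrix of unit rows; the zero
#'   vector on b = 0 rows).
#' @examples
#' gtab <- make_gradient_table(64, c(1000, 1500, 2000))
#' table(gtab$bvals)
#' @export
make_gradient_table <- function(n_per_shell = 64,
                                shell_bvalues = c(1000, 1500, 2000),
                                seed = 0L) {
  if (length(n_per_shell) != 1 || is.na(n_per_shell) || n_per_shell < 0)
    stop_invalid("n_per_shell must be a single non-negative integer")
  if (any(!is.finite(shell_bvalues)) || any(shell_bvalues <= 0))
    stop_invalid("shell b-values must be positive and finite")
  n_per_shell <- as.integer(n_per_shell)

  bvals <- 0
  bvecs <- matrix(0, 1, 3)
  if (n_per_shell > 0) {
    golden <- pi * (3 - sqrt(5))
    for (s in seq_along(shell_bvalues)) {
      dirs <- fibonacci_sphere(n_per_shell, phase = (s - 1) * golden / 3)
      bvals <- c(bvals, rep(shell_bvalues[s], n_per_shell))
      bvecs <- rbind(bvecs, dirs)
    }
    perm <- with_seed(seed, sample(seq_len(length(bvals) - 1)))
    bvals <- c(0, bvals[-1][perm])
    bvecs <- rbind(bvecs[1, , drop = FALSE], bvecs[-1, , drop = FALSE][perm, , drop = FALSE])
  }
  gtab <- structure(list(bvals = as.numeric(bvals), bvecs = unname(bvecs)),
                    class = "gradient_table")
  validate_gradient_table(gtab)
  gtab
}

# Deterministic near-uniform points on the unit sphere.
fibonacci_sphere <- function(n, phase = 0) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden + phase
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Validate a gradient table
#'
#' Checks the structural invariants: non-negative b-values, at least one
#' b = 0 row, and unit-norm directions (to 1e-8) wherever b > 0.
#'
#' @param gtab a `gradient_table`.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_gradient_table <- function(gtab) {
  if (!inherits(gtab, "gradient_table"))
    stop_invalid("not a gradient_table")
  b <- gtab$bvals
  v <- gtab$bvecs
  if (!is.matrix(v) || ncol(v) != 3 || nrow(v) != length(b))
    stop_invalid("bvecs must be an n x 3 matrix matching bvals")
  if (any(!is.finite(b)) || any(b < 0))
    stop_invalid("b-values must be finite and non-negative")
  if (!any(b == 0))
    stop_invalid("gradient table must contain at least one b = 0 row")
  norms <- sqrt(rowSums(v^2))
  if (any(abs(norms[b > 0] - 1) > 1e-8))
    stop_invalid("directions with b > 0 must have unit norm")
  invisible(gtab)
}

#' @exportS3Method base::print
print.gradient_table <- function(x, ...) {
  shells <- sort(unique(x$bvals[x$bvals > 0]))
  cat("Gradient table:", length(x$bvals), "rows;",
      sum(x$bvals == 0), "b=0;",
      "shells:", paste(shells, collapse = ", "), "s/mm^2\n")
  invisible(x)
}

#' Write / read FSL-style bval and bvec files
#'
#' `write_bval_bvec` writes the b-values as a single space-separated row
#' and the directions as three rows (x, y, z components). `read_bval_bvec`
#' reads that format back into a `gradient_table`.
#'
#' @param gtab a `gradient_table`.
#' @param bval_path,bvec_path file paths.
#' @return `write_bval_bvec` returns the paths invisibly;
#'   `read_bval_bvec` returns a `gradient_table`.
#' @export
write_bval_bvec <- function(gtab, bval_path, bvec_path) {
  validate_gradient_table(gtab)
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  rows <- apply(t(gtab$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " "))
  writeLines(rows, bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_bval_bvec
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  comp <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  if (length(comp) != 3)
    stop_invalid("bvec file must have exactly three rows")
  bvecs <- cbind(comp[[1]], comp[[2]], comp[[3]])
  structure(list(bvals = bvals, bvecs = unname(bvecs)),
            class = "gradient_table")
}
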