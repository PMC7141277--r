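#' Generalized q-sampling reconstruction settings
#'
#' The GQI kernel relates the measured q-space signals to the spin
#' distribution function through a sinc transform. Its two constants are
#' the sampling length ratio (diffusion sampling length relative to the
#' mean diffusion displacement) and the free-water diffusion constant used
#' to scale b-values; neither is part of the acquisition, both are
#' reconstruction choices.
#'
#' @param sampling_length_ratio unitless sampling length ratio (> 0);
#'   1.25 is the common default of the method.
#' @param free_diffusion free diffusion constant D in mm^2/s (> 0).
#' @param order tessellation order of the ODF direction set (k >= 0;
#'   default 3, i.e. 321 hemisphere directions).
#' @return an object of class `gqi_config`.
#' @export
gqi_config <- function(sampling_length_ratio = 1.25,
                       free_diffusion = 2.5e-3,
                       order = 3) {
  if (sampling_length_ratio <= 0) stop_invalid("sampling_length_ratio must be > 0")
  if (free_diffusion <= 0) stop_invalid("free_diffusion must be > 0")
  if (order < 0) stop_invalid("order must be >= 0")
  structure(list(sampling_length_ratio = sampling_length_ratio,
                 free_diffusion = free_diffusion,
                 order = as.integer(order)),
            class = "gqi_config")
}

# Kernel matrix K[i, j] = sinc(sigma * sqrt(6 D b_i) * (g_i . u_j)) with the
# unnormalized sinc(x) = sin(x)/x, sinc(0) = 1. The ODF of a signal vector
# S is S %*% K — linear in the signal.
gqi_kernel <- function(gtab, dirs, cfg) {
  scale <- cfg$sampling_length_ratio * sqrt(6 * cfg$free_diffusion * gtab$bvals)
  x <- (gtab$bvecs * scale) %*% t(dirs)
  k <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  k
}

#' Reconstruct orientation distribution functions by generalized q-sampling
#'
#' Evaluates, for every ODF direction u_j, the sinc-kernel sum
#' \deqn{\psi(u_j) = \sum_i S_i \,
#'   \mathrm{sinc}(\sigma \sqrt{6 D b_i}\; g_i \cdot u_j)}
#' over all acquisition rows i. Negative values (possible because the sinc
#' kernel oscillates) are truncated to zero: the spin distribution function
#' is a density.
#'
#' @param signal numeric vector (one voxel) or matrix (voxels x rows).
#' @param gtab a `gradient_table`.
#' @param dirs a [make_direction_set()] direction set.
#' @param cfg a [gqi_config()].
#' @return ODF values: a vector of `nrow(dirs)` values, or a matrix
#'   (voxels x directions) when `signal` is a matrix.
#' @export
reconstruct_odf <- function(signal, gtab, dirs, cfg = gqi_config()) {
  validate_gradient_table(gtab)
  one <- is.null(dim(signal))
  s <- if (one) matrix(signal, 1) else as.matrix(signal)
  if (ncol(s) != length(gtab$bvals))
    stop_invalid("signal length (%d) must equal gradient-table rows (%d)",
                 ncol(s), length(gtab$bvals))
  if (any(!is.finite(s))) stop_invalid("signals must be finite")
  odf <- pmax(s %*% gqi_kernel(gtab, dirs, cfg), 0)
  if (one) as.vector(odf) else odf
}

#' Generalized fractional anisotropy of an ODF
#'
#' GFA is the (population) standard deviation of the ODF values divided by
#' their root mean square. It is scale-invariant, 0 for a constant ODF,
#' and at most sqrt((N-1)/N) (attained by a one-hot ODF of length N). An
#' all-zero ODF is assigned GFA 0 by convention.
#'
#' @param odf non-negative numeric vector.
#' @return scalar in [0, 1).
#' @examples
#' compute_gfa(c(1, 0, 0, 0))  # sqrt(3)/2
#' @export
compute_gfa <- function(odf) {
  if (length(odf) == 0) stop_invalid("odf must be non-empty")
  rms <- sqrt(mean(odf^2))
  if (rms == 0) return(0)
  sqrt(max(0, mean(odf^2) - mean(odf)^2)) / rms
}

#' Isotropic value of an ODF
#'
#' The minimum of the ODF values, representing the orientation-independent
#' background diffusion component.
#'
#' @param odf numeric vector.
#' @return scalar minimum.
#' @export
compute_iso <- function(odf) {
  if (length(odf) == 0) stop_invalid("odf must be non-empty")
  min(odf)
}

#' ODF fields and index maps
#'
#' `odf_field` bundles per-voxel ODF values (4D: x, y, z, direction) with
#' their direction set; `index_map` is a labelled 3D scalar volume.
#'
#' @param values 4D array of non-negative ODF values.
#' @param dirs the `direction_set` the 4th axis indexes.
#' @return an `odf_field` object.
#' @export
odf_field <- function(values, dirs) {
  d <- dim(values)
  if (length(d) != 4) stop_invalid("odf_field values must be 4D")
  if (d[4] != nrow(dirs))
    stop_invalid("4th dimension must equal the direction count")
  if (any(values < 0)) stop_invalid("ODF values must be >= 0")
  structure(list(values = values, dirs = dirs), class = "odf_field")
}

#' @param data 3D numeric array.
#' @param map_type one of "GFA", "ISO", "QA", "NQA".
#' @param voxel_size voxel size in mm (optional metadata).
#' @rdname odf_field
#' @export
index_map <- function(data, map_type = c("GFA", "ISO", "QA", "NQA"),
                      voxel_size = NULL) {
  map_type <- match.arg(map_type)
  if (length(dim(data)) != 3) stop_invalid("index map data must be 3D")
  structure(list(data = data, map_type = map_type, voxel_size = voxel_size),
            class = "index_map")
}

#' @exportS3Method base::print
print.index_map <- function(x, ...) {
  cat(sprintf("IndexMap %s: %s; range [%.4g, %.4g]\n", x$map_type,
              paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

# Row-wise max and min without large intermediates.
row_range <- function(m) {
  mx <- m[, 1]; mn <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) {
    mx <- pmax(mx, m[, j])
    mn <- pmin(mn, m[, j])
  }
  list(max = mx, min = mn)
}

row_gfa <- function(m) {
  msq <- rowMeans(m^2)
  v <- pmax(0, msq - rowMeans(m)^2)
  ifelse(msq > 0, sqrt(v) / sqrt(msq), 0)
}

#' Quantitative anisotropy and its per-field normalization
#'
#' Per voxel, QA is the ODF value at that voxel's global peak direction
#' minus the voxel's isotropic floor (the ODF minimum), floored at zero.
#' NQA divides QA by the maximum QA over the whole field, so NQA is in
#' [0, 1] per subject; a degenerate field (all-constant ODFs) yields
#' all-zero maps.
#'
#' @param field an [odf_field()].
#' @param voxel_size optional voxel size metadata.
#' @return list with `QA` and `NQA` index maps.
#' @export
compute_qa_nqa <- function(field, voxel_size = NULL) {
  stopifnot(inherits(field, "odf_field"))
  d <- dim(field$values)
  m <- matrix(field$values, prod(d[1:3]), d[4])
  rr <- row_range(m)
  qa <- pmax(0, rr$max - rr$min)
  qmax <- max(qa)
  nqa <- if (qmax > 0) qa / qmax else qa
  list(QA = index_map(array(qa, d[1:3]), "QA", voxel_size),
       NQA = index_map(array(nqa, d[1:3]), "NQA", voxel_size))
}

#' Reconstruct GFA, ISO and NQA index maps from a diffusion volume
#'
#' Runs the GQI reconstruction voxel-wise inside a mask (default: voxels
#' whose mean b = 0 signal is positive) and derives the three scalar maps.
#' Outside the mask all maps are zero. NQA is normalized per subject by
#' the maximum QA over the masked field.
#'
#' @param dwi a `dwi_volume`.
#' @param cfg a [gqi_config()].
#' @param mask optional 3D logical array; `NULL` for the b0 > 0 default.
#' @param dirs optional precomputed `direction_set` (must match
#'   `cfg$order`); avoids re-tessellating in per-subject loops.
#' @return named list of `index_map`s: GFA, ISO, NQA.
#' @export
build_index_maps <- function(dwi, cfg = gqi_config(), mask = NULL,
                             dirs = NULL) {
  validate_dwi_volume(dwi)
  d <- dim(dwi$data)
  grid <- d[1:3]
  if (is.null(dirs)) dirs <- make_direction_set(cfg$order)
  b0 <- dwi$gtab$bvals == 0
  sig <- matrix(dwi$data, prod(grid), d[4])
  b0map <- rowMeans(sig[, b0, drop = FALSE])
  if (is.null(mask)) {
    mvec <- b0map > 0
  } else {
    if (!identical(as.integer(dim(mask)), as.integer(grid)))
      stop_invalid("mask shape must match the volume grid")
    mvec <- as.vector(mask)
  }
  gfa <- iso <- qa <- numeric(prod(grid))
  if (any(mvec)) {
    odf <- reconstruct_odf(sig[mvec, , drop = FALSE], dwi$gtab, dirs, cfg)
    rr <- row_range(odf)
    gfa[mvec] <- row_gfa(odf)
    iso[mvec] <- rr$min
    qa[mvec] <- pmax(0, rr$max - rr$min)
  }
  qmax <- max(qa)
  nqa <- if (qmax > 0) qa / qmax else qa
  list(GFA = index_map(array(gfa, grid), "GFA", dwi$voxel_size),
       ISO = index_map(array(iso, grid), "ISO", dwi$voxel_size),
       NQA = index_map(array(nqa, grid), "NQA", dwi$voxel_size))
}
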