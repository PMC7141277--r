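#' Specify a synthetic diffusion-MRI cohort
#'
#' Defines a four-group cohort (healthy controls HC, depressed non-ideation
#' NS, depressed with suicidal ideation SI, and suicide attempters SA) of
#' multi-shell diffusion volumes on a shared grid, with a group-dependent
#' reduction of the anisotropic volume fraction inside a configurable
#' region of interest. Subjects in `effect_groups` have their white-matter
#' volume fraction multiplied by `(1 - effect_delta)` inside `effect_roi`;
#' all other variability comes from per-subject fiber-orientation jitter
#' and acquisition noise, so with `effect_delta = 0` the groups are
#' exchangeable by construction.
#'
#' @param group_sizes named integer vector with entries HC, NS, SI, SA.
#' @param grid_shape 3 integers, the voxel grid.
#' @param effect_roi integer matrix (n x 3) of 1-based voxel coordinates,
#'   or `NULL` for the default central cube of side `round(dim/3)`.
#' @param effect_delta fractional reduction of the anisotropic volume
#'   fraction inside the ROI for affected groups, in [0, 1].
#' @param effect_groups groups receiving the effect (default SI and SA).
#' @param noise_sigma Rician noise standard deviation in signal units.
#' @param seed master seed; all per-subject seeds derive from it.
#' @param s0 baseline (b = 0) signal.
#' @param f_aniso anisotropic volume fraction of unaffected white matter.
#' @param ad,rd axial/radial diffusivity of the fiber compartment (mm^2/s).
#' @param d_iso free-water diffusivity (mm^2/s).
#' @param jitter_sd_deg per-subject fiber-orientation jitter (degrees).
#' @param voxel_size isotropic voxel size in mm.
#' @param n_per_shell,shell_bvalues acquisition scheme passed to
#'   [make_gradient_table()].
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(HC = 58, NS = 54, SI = 41, SA = 33),
                        grid_shape = c(24, 24, 24),
                        effect_roi = NULL,
                        effect_delta = 0.4,
                        effect_groups = c("SI", "SA"),
                        noise_sigma = 2,
                        seed = 1L,
                        s0 = 100,
                        f_aniso = 0.62,
                        ad = 1.7e-3, rd = 0.3e-3, d_iso = 3.0e-3,
                        jitter_sd_deg = 10,
                        voxel_size = 2,
                        n_per_shell = 64,
                        shell_bvalues = c(1000, 1500, 2000)) {
  if (is.null(names(group_sizes)) ||
      !all(c("HC", "NS", "SI", "SA") %in% names(group_sizes)))
    stop_invalid("group_sizes must be named with HC, NS, SI, SA")
  if (any(group_sizes < 0)) stop_invalid("group counts must be >= 0")
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    stop_invalid("grid_shape must be 3 positive integers")
  if (effect_delta < 0 || effect_delta > 1)
    stop_invalid("effect_delta must lie in [0, 1]")
  if (is.null(effect_roi)) effect_roi <- default_effect_roi(grid_shape)
  effect_roi <- as.matrix(effect_roi)
  if (ncol(effect_roi) != 3)
    stop_invalid("effect_roi must be an n x 3 coordinate matrix")
  for (a in 1:3)
    if (any(effect_roi[, a] < 1) || any(effect_roi[, a] > grid_shape[a]))
      stop_invalid("grid too small for effect_roi: axis %d exceeds [1, %d]",
                   a, grid_shape[a])
  if (noise_sigma < 0) stop_invalid("noise_sigma must be >= 0")
  structure(list(group_sizes = group_sizes[c("HC", "NS", "SI", "SA")],
                 grid_shape = as.integer(grid_shape),
                 effect_roi = effect_roi,
                 effect_delta = effect_delta,
                 effect_groups = effect_groups,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed),
                 s0 = s0, f_aniso = f_aniso,
                 ad = ad, rd = rd, d_iso = d_iso,
                 jitter_sd_deg = jitter_sd_deg,
                 voxel_size = voxel_size,
                 n_per_shell = as.integer(n_per_shell),
                 shell_bvalues = shell_bvalues),
            class = "cohort_spec")
}

# Central cube of side round(dim/3) per axis.
default_effect_roi <- function(grid_shape) {
  rng <- lapply(grid_shape, function(d) {
    side <- max(1, round(d / 3))
    lo <- floor((d - side) / 2) + 1
    seq(lo, lo + side - 1)
  })
  as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
}

# Ellipsoidal "brain" support inscribed in the grid; outside it the signal
# is exactly zero (and is excluded from the default reconstruction mask).
default_brain_mask <- function(grid_shape) {
  cc <- (grid_shape + 1) / 2
  rr <- 0.45 * grid_shape
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  d2 <- ((g$x - cc[1]) / rr[1])^2 + ((g$y - cc[2]) / rr[2])^2 +
    ((g$z - cc[3]) / rr[3])^2
  array(d2 <= 1, dim = grid_shape)
}

#' Cohort manifest: subject ids, groups, seeds and ground truth
#'
#' Enumerates the subjects a spec defines without simulating any data.
#' The manifest records, per subject, the derived simulation seed and the
#' true anisotropic volume fractions inside and outside the effect ROI.
#'
#' @param spec a [cohort_spec()].
#' @return a data.frame with columns subject_id, group, seed, affected,
#'   f_background, f_roi.
#' @export
cohort_manifest <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$group_sizes), times = spec$group_sizes)
  n <- length(groups)
  affected <- groups %in% spec$effect_groups
  data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = groups,
    seed = vapply(seq_len(n), function(i) derive_seed(spec$seed, 1000 + i),
                  integer(1)),
    affected = affected,
    f_background = rep(spec$f_aniso, n),
    f_roi = ifelse(affected, spec$f_aniso * (1 - spec$effect_delta),
                   spec$f_aniso),
    stringsAsFactors = FALSE
  )
}

#' Simulate one subject's diffusion-weighted volume
#'
#' Deterministic given the manifest row's seed: the subject's fiber
#' orientation is the z-axis plus a small random tangential jitter, the
#' anisotropic fraction is `f_roi` inside the effect ROI and `f_background`
#' elsewhere inside the brain support, and Rician noise of the spec's
#' `noise_sigma` is applied to in-brain voxels.
#'
#' @param spec a [cohort_spec()].
#' @param gtab gradient table shared by the cohort (built from the spec if
#'   `NULL`).
#' @param manifest_row one row of [cohort_manifest()].
#' @return an object of class `dwi_volume`: list with `data` (4D array),
#'   `gtab` and `voxel_size`.
#' @export
simulate_subject <- function(spec, gtab = NULL, manifest_row) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(gtab)) gtab <- cohort_gradient_table(spec)
  grid <- spec$grid_shape
  nvox <- prod(grid)
  nrows <- length(gtab$bvals)

  with_seed(manifest_row$seed, {
    jit <- rnorm(2, 0, spec$jitter_sd_deg * pi / 180)
    fdir <- c(jit[1], jit[2], 1)
    fdir <- fdir / sqrt(sum(fdir^2))

    att_for <- function(f) {
      fc <- fiber_config(list(list(f = f, dir = fdir, ad = spec$ad,
                                   rd = spec$rd)),
                         f_iso = 1 - f, d_iso = spec$d_iso)
      signal_attenuation(fc, gtab$bvals, gtab$bvecs)
    }
    sig_bg <- spec$s0 * att_for(manifest_row$f_background)
    sig_roi <- spec$s0 * att_for(manifest_row$f_roi)

    brain <- as.vector(default_brain_mask(grid))
    roi_idx <- spec$effect_roi[, 1] +
      (spec$effect_roi[, 2] - 1) * grid[1] +
      (spec$effect_roi[, 3] - 1) * grid[1] * grid[2]
    in_roi <- rep(FALSE, nvox)
    in_roi[roi_idx] <- TRUE

    data <- matrix(0, nvox, nrows)
    data[brain & !in_roi, ] <- rep(sig_bg, each = sum(brain & !in_roi))
    data[brain & in_roi, ] <- rep(sig_roi, each = sum(brain & in_roi))
    if (spec$noise_sigma > 0) {
      nb <- sum(brain)
      re <- data[brain, ] + matrix(rnorm(nb * nrows, 0, spec$noise_sigma),
                                   nb, nrows)
      im <- matrix(rnorm(nb * nrows, 0, spec$noise_sigma), nb, nrows)
      data[brain, ] <- sqrt(re^2 + im^2)
    }
    structure(list(data = array(data, dim = c(grid, nrows)),
                   gtab = gtab, voxel_size = spec$voxel_size),
              class = "dwi_volume")
  })
}

#' Gradient table implied by a cohort spec
#' @param spec a [cohort_spec()].
#' @return a `gradient_table` shared by every subject of the cohort.
#' @export
cohort_gradient_table <- function(spec) {
  make_gradient_table(spec$n_per_shell, spec$shell_bvalues,
                      seed = derive_seed(spec$seed, 17L))
}

#' Generate a full synthetic cohort in memory
#'
#' Materialises every subject of the spec. Deterministic: calling twice
#' with the same spec yields bit-identical cohorts. For large cohorts
#' prefer iterating over [cohort_manifest()] with [simulate_subject()] so
#' only one 4D volume is held in memory at a time.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `dmri_cohort`: list with `spec`, `gtab`,
#'   `manifest` and `subjects` (named list of `dwi_volume`).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  man <- cohort_manifest(spec)
  gtab <- cohort_gradient_table(spec)
  subjects <- lapply(seq_len(nrow(man)), function(i)
    simulate_subject(spec, gtab, man[i, ]))
  names(subjects) <- man$subject_id
  structure(list(spec = spec, gtab = gtab, manifest = man,
                 subjects = subjects),
            class = "dmri_cohort")
}

#' @exportS3Method base::print
print.dmri_cohort <- function(x, ...) {
  cat("Synthetic dMRI cohort:", nrow(x$manifest), "subjects (",
      paste(sprintf("%s=%d", names(x$spec$group_sizes), x$spec$group_sizes),
            collapse = ", "),
      "); grid", paste(x$spec$grid_shape, collapse = "x"),
      "; effect_delta", x$spec$effect_delta, "\n")
  invisible(x)
}

#' Validate a diffusion-weighted volume
#' @param dwi a `dwi_volume`.
#' @return the volume, invisibly, if valid.
#' @export
validate_dwi_volume <- function(dwi) {
  if (!inherits(dwi, "dwi_volume")) stop_invalid("not a dwi_volume")
  d <- dim(dwi$data)
  if (length(d) != 4) stop_invalid("dwi data must be 4D")
  if (d[4] != length(dwi$gtab$bvals))
    stop_invalid("4th dimension (%d) must equal gradient-table rows (%d)",
                 d[4], length(dwi$gtab$bvals))
  if (any(dwi$data < 0)) stop_invalid("signals must be >= 0")
  invisible(dwi)
}
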