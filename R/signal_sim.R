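#' Multi-tensor voxel configurations
#'
#' Describes the microstructural content of one voxel as a mixture of
#' anisotropic Gaussian tensor compartments plus one free-water (isotropic)
#' compartment. Volume fractions must sum to one.
#'
#' @param compartments list of compartments, each a list with `f` (volume
#'   fraction), `dir` (principal direction, unit 3-vector), `ad` (axial
#'   diffusivity, mm^2/s) and `rd` (radial diffusivity, mm^2/s).
#' @param f_iso isotropic volume fraction.
#' @param d_iso isotropic diffusivity in mm^2/s (default 3.0e-3, free water
#'   at body temperature).
#' @return an object of class `fiber_config`.
#' @examples
#' fc <- fiber_config(list(list(f = 0.7, dir = c(0, 0, 1),
#'                              ad = 1.7e-3, rd = 0.3e-3)), f_iso = 0.3)
#' @export
fiber_config <- function(compartments = list(), f_iso = 0, d_iso = 3.0e-3) {
  fc <- structure(list(compartments = compartments, f_iso = f_iso,
                       d_iso = d_iso), class = "fiber_config")
  validate_fiber_config(fc)
  fc
}

validate_fiber_config <- function(fc) {
  if (!inherits(fc, "fiber_config")) stop_invalid("not a fiber_config")
  fr <- fc$f_iso
  for (cp in fc$compartments) {
    if (!all(c("f", "dir", "ad", "rd") %in% names(cp)))
      stop_invalid("each compartment needs f, dir, ad, rd")
    if (cp$f < 0) stop_invalid("volume fractions must be >= 0")
    if (abs(sqrt(sum(cp$dir^2)) - 1) > 1e-8)
      stop_invalid("compartment direction must be a unit vector")
    if (!(cp$ad >= cp$rd && cp$rd >= 0))
      stop_invalid("diffusivities must satisfy ad >= rd >= 0")
    fr <- fr + cp$f
  }
  if (fc$f_iso < 0 || fc$d_iso < 0)
    stop_invalid("isotropic fraction and diffusivity must be >= 0")
  if (abs(fr - 1) > 1e-8)
    stop_invalid("volume fractions must sum to 1 (got %.10f)", fr)
  invisible(fc)
}

#' Simulate the diffusion-weighted signal of one voxel
#'
#' Multi-tensor forward model: for acquisition row i with b-value b_i and
#' unit direction g_i,
#' \deqn{S_i = s_0 [\sum_k f_k \exp(-b_i g_i' D_k g_i)
#'       + f_{iso} \exp(-b_i d_{iso})]}
#' with axially symmetric tensors D_k. When `noise_sigma > 0`, Rician noise
#' is applied as the magnitude of the signal plus complex Gaussian noise;
#' `noise_model = "gaussian"` adds real Gaussian noise instead (debugging).
#'
#' @param fibers a [fiber_config()].
#' @param gtab a [make_gradient_table()] gradient table.
#' @param s0 non-diffusion-weighted signal level (> 0).
#' @param noise_sigma noise standard deviation in signal units (>= 0).
#' @param seed integer seed for the noise draw.
#' @param noise_model `"rician"` (default) or `"gaussian"`.
#' @return numeric vector of signals, one per gradient-table row.
#' @export
simulate_voxel_signal <- function(fibers, gtab, s0 = 100, noise_sigma = 0,
                                  seed = 0L, noise_model = c("rician", "gaussian")) {
  validate_fiber_config(fibers)
  validate_gradient_table(gtab)
  noise_model <- match.arg(noise_model)
  if (length(s0) != 1 || !is.finite(s0) || s0 <= 0)
    stop_invalid("s0 must be a single positive number")
  if (noise_sigma < 0) stop_invalid("noise_sigma must be >= 0")
  att <- signal_attenuation(fibers, gtab$bvals, gtab$bvecs)
  sig <- s0 * att
  if (noise_sigma > 0)
    sig <- with_seed(seed, add_noise(sig, noise_sigma, noise_model))
  sig
}

# Noise-free attenuation A(b, g) in (0, 1]; vectorized over rows.
signal_attenuation <- function(fibers, bvals, bvecs) {
  att <- fibers$f_iso * exp(-bvals * fibers$d_iso)
  for (cp in fibers$compartments) {
    # g' D g = rd |g|^2 + (ad - rd) (g . v)^2 ; |g| = 1 on weighted rows,
    # 0 on null rows, so the exponent vanishes at b = 0 either way.
    proj2 <- as.vector(bvecs %*% cp$dir)^2
    gDg <- cp$rd * rowSums(bvecs^2) + (cp$ad - cp$rd) * proj2
    att <- att + cp$f * exp(-bvals * gDg)
  }
  att
}

add_noise <- function(signal, sigma, model) {
  n <- length(signal)
  if (model == "rician") {
    re <- signal + rnorm(n, 0, sigma)
    im <- rnorm(n, 0, sigma)
    sqrt(re^2 + im^2)
  } else {
    signal + rnorm(n, 0, sigma)
  }
}
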