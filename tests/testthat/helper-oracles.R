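# Independent oracles, deliberately naive: these re-derive expected values
# by brute force and must not share code with the implementation paths
# they check.

# GQI sinc-kernel sum as an explicit double loop over acquisitions i and
# directions j.
odf_brute_force <- function(signal, gtab, dirs, cfg) {
  out <- numeric(nrow(dirs))
  for (j in seq_len(nrow(dirs))) {
    acc <- 0
    for (i in seq_along(gtab$bvals)) {
      x <- cfg$sampling_length_ratio *
        sqrt(6 * cfg$free_diffusion * gtab$bvals[i]) *
        sum(gtab$bvecs[i, ] * dirs[j, ])
      acc <- acc + signal[i] * (if (abs(x) < 1e-12) 1 else sin(x) / x)
    }
    out[j] <- max(acc, 0)
  }
  out
}

# Pairwise-concordance AUC: (concordant + 0.5 * tied) / (P * N).
auc_pairwise <- function(truth, scores) {
  pos <- which(truth == 1)
  neg <- which(truth == 0)
  total <- 0
  for (p in pos) for (n in neg) {
    if (scores[p] > scores[n]) total <- total + 1
    else if (scores[p] == scores[n]) total <- total + 0.5
  }
  total / (length(pos) * length(neg))
}

# Small deterministic structured volumes for autoencoder tests.
make_blob_volumes <- function(n, dims, seed = 7) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- array(0, dim = dims)
    lo <- pmax(1, round(dims / 4))
    hi <- pmin(dims, round(3 * dims / 4))
    a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- runif(1, 0.4, 1)
    a + array(runif(prod(dims), 0, 0.05), dim = dims)
  })
}

tiny_gtab <- function(n = 12, shells = c(1000, 2000), seed = 3) {
  make_gradient_table(n, shells, seed = seed)
}
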