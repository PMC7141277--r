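fiber_signal <- function(dir, gtab, f = 0.7, noise = 0, seed = 0) {
  fc <- fiber_config(list(list(f = f, dir = dir, ad = 1.7e-3, rd = 0.3e-3)),
                     f_iso = 1 - f)
  simulate_voxel_signal(fc, gtab, s0 = 100, noise_sigma = noise, seed = seed)
}

test_that("reconstruction matches the brute-force kernel oracle on random signals", {
  gtab <- tiny_gtab(8, c(1000, 2000))
  dirs <- make_direction_set(1)
  cfg <- gqi_config()
  set.seed(31)
  for (rep in 1:5) {
    sig <- runif(length(gtab$bvals), 0, 100)
    fast <- reconstruct_odf(sig, gtab, dirs, cfg)
    slow <- odf_brute_force(sig, gtab, dirs, cfg)
    expect_equal(fast, slow, tolerance = 1e-10)
  }
})

test_that("reconstruction is linear in the signal and zero maps to zero", {
  gtab <- tiny_gtab()
  dirs <- make_direction_set(1)
  expect_equal(reconstruct_odf(numeric(length(gtab$bvals)), gtab, dirs),
               numeric(nrow(dirs)))
  sig <- fiber_signal(c(0, 0, 1), gtab)
  expect_equal(reconstruct_odf(3 * sig, gtab, dirs),
               3 * reconstruct_odf(sig, gtab, dirs), tolerance = 1e-12)
  expect_error(reconstruct_odf(sig[-1], gtab, dirs), "length")
})

test_that("an isotropic voxel yields a nearly flat ODF", {
  gtab <- make_gradient_table(64, c(1000, 1500, 2000), seed = 0)
  iso <- fiber_config(list(), f_iso = 1)
  sig <- simulate_voxel_signal(iso, gtab, s0 = 100, noise_sigma = 0)
  odf <- reconstruct_odf(sig, gtab, make_direction_set(3))
  expect_lte(max(odf) / min(odf), 1.05)
})

test_that("single-fiber peaks are recovered within the angular sampling limit", {
  gtab <- make_gradient_table(64, c(1000, 1500, 2000), seed = 0)
  dirs <- make_direction_set(3)
  spacing <- nn_angular_spacing(dirs)
  set.seed(77)
  n_ok <- 0
  for (rep in 1:20) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    odf <- reconstruct_odf(fiber_signal(v, gtab), gtab, dirs)
    err <- axis_angle(dirs[which.max(odf), ], v)
    if (err <= spacing) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 20)
})

test_that("two orthogonal fibers produce two well-separated ODF maxima", {
  gtab <- make_gradient_table(64, c(1000, 1500, 2000), seed = 0)
  dirs <- make_direction_set(3)
  fc <- fiber_config(list(
    list(f = 0.45, dir = c(0, 0, 1), ad = 1.7e-3, rd = 0.3e-3),
    list(f = 0.45, dir = c(1, 0, 0), ad = 1.7e-3, rd = 0.3e-3)),
    f_iso = 0.1)
  sig <- simulate_voxel_signal(fc, gtab, 100, 0)
  odf <- reconstruct_odf(sig, gtab, dirs)
  ord <- order(odf, decreasing = TRUE)
  top <- dirs[ord[1], ]
  # best direction at least 60 degrees (axially) from the global peak
  far <- which(apply(dirs, 1, function(u) axis_angle(u, top)) >= pi / 3)
  second <- far[which.max(odf[far])]
  # both maxima must be genuine local peaks close to the true fibers
  expect_lt(min(axis_angle(top, c(0, 0, 1)), axis_angle(top, c(1, 0, 0))),
            nn_angular_spacing(dirs))
  expect_gt(odf[second], 0.8 * max(odf))
  expect_gte(axis_angle(dirs[second, ], top), pi / 3)
})

test_that("GFA closed forms, bounds and scale invariance hold", {
  expect_equal(compute_gfa(c(0.5, 0.5, 0.5, 0.5)), 0)
  expect_equal(compute_gfa(c(1, 0, 0, 0)), sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(compute_gfa(rep(0, 10)), 0)  # all-zero convention
  expect_error(compute_gfa(numeric(0)), "non-empty")
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:50, 1)
    odf <- runif(n)
    g <- compute_gfa(odf)
    expect_gte(g, 0)
    expect_lte(g, sqrt((n - 1) / n) + 1e-12)
    expect_equal(compute_gfa(odf * runif(1, 0.1, 10)), g, tolerance = 1e-12)
  }
})

test_that("ISO is the permutation-invariant minimum", {
  expect_equal(compute_iso(c(0.2, 0.5, 0.3)), 0.2)
  expect_equal(compute_iso(rep(0.7, 9)), 0.7)
  expect_equal(compute_iso(c(0.5, 0.3, 0.2)), compute_iso(c(0.2, 0.5, 0.3)))
  expect_error(compute_iso(numeric(0)), "non-empty")
})

test_that("QA/NQA follow the peak-minus-floor and max-normalization rules", {
  dirs <- make_direction_set(0)
  nd <- nrow(dirs)
  # constant field: QA and NQA identically zero
  flat <- odf_field(array(0.4, dim = c(2, 2, 1, nd)), dirs)
  qn <- compute_qa_nqa(flat)
  expect_true(all(qn$QA$data == 0))
  expect_true(all(qn$NQA$data == 0))
  # forced arithmetic: QA 0.4 and 0.2 -> NQA 1.0 and 0.5
  vals <- array(0.1, dim = c(2, 1, 1, nd))
  vals[1, 1, 1, 1] <- 0.5   # QA = 0.4
  vals[2, 1, 1, 2] <- 0.3   # QA = 0.2
  qn2 <- compute_qa_nqa(odf_field(vals, dirs))
  expect_equal(as.vector(qn2$QA$data), c(0.4, 0.2))
  expect_equal(as.vector(qn2$NQA$data), c(1.0, 0.5))
  expect_equal(max(qn2$NQA$data), 1)
})

test_that("GFA of a single-tensor voxel grows with anisotropy", {
  gtab <- make_gradient_table(32, c(1000, 1500, 2000), seed = 1)
  dirs <- make_direction_set(2)
  deltas <- seq(0, 1.4e-3, length.out = 5)
  gfas <- vapply(deltas, function(dl) {
    md <- 0.9e-3
    fc <- fiber_config(list(list(f = 1, dir = c(0, 0, 1),
                                 ad = md + 2 * dl / 3, rd = md - dl / 3)),
                       f_iso = 0)
    sig <- simulate_voxel_signal(fc, gtab, 100, 0)
    compute_gfa(reconstruct_odf(sig, gtab, dirs))
  }, numeric(1))
  expect_true(all(diff(gfas) >= -1e-12))
  expect_gt(gfas[5], gfas[1])
})

test_that("index maps: isotropic volumes give near-zero GFA, fiber ROIs exceed isotropic ROIs", {
  gtab <- tiny_gtab(24, c(1000, 1500, 2000))
  grid <- c(6, 6, 6)
  nvox <- prod(grid)
  iso <- fiber_config(list(), f_iso = 1)
  sig_iso <- simulate_voxel_signal(iso, gtab, 100, 0)
  data <- array(rep(sig_iso, each = nvox), dim = c(grid, length(gtab$bvals)))
  dwi <- structure(list(data = data, gtab = gtab, voxel_size = 2),
                   class = "dwi_volume")
  maps <- build_index_maps(dwi, gqi_config(order = 2))
  expect_equal(dim(maps$GFA$data), grid)
  expect_true(all(maps$GFA$data <= 0.05))
  expect_equal(dim(maps$ISO$data), grid)
  expect_equal(dim(maps$NQA$data), grid)

  # half the volume single-fiber, half isotropic
  sig_fib <- fiber_signal(c(0, 0, 1), gtab)
  data2 <- data
  data2[1:3, , , ] <- array(rep(sig_fib, each = 3 * 36),
                            dim = c(3, 6, 6, length(gtab$bvals)))
  dwi2 <- structure(list(data = data2, gtab = gtab, voxel_size = 2),
                    class = "dwi_volume")
  maps2 <- build_index_maps(dwi2, gqi_config(order = 2))
  expect_gt(mean(maps2$GFA$data[1:3, , ]), mean(maps2$GFA$data[4:6, , ]))
  expect_equal(max(maps2$NQA$data), 1)
})

test_that("masking: outside-mask voxels are zero; zero-signal voxels are excluded by default", {
  gtab <- tiny_gtab(12, c(1000))
  grid <- c(4, 4, 4)
  sig <- fiber_signal(c(0, 0, 1), gtab)
  data <- array(rep(sig, each = prod(grid)), dim = c(grid, length(gtab$bvals)))
  data[1, 1, 1, ] <- 0  # dead voxel
  dwi <- structure(list(data = data, gtab = gtab, voxel_size = 2),
                   class = "dwi_volume")
  maps <- build_index_maps(dwi, gqi_config(order = 1))
  expect_equal(maps$GFA$data[1, 1, 1], 0)
  mask <- array(FALSE, grid)
  mask[2, 2, 2] <- TRUE
  maps2 <- build_index_maps(dwi, gqi_config(order = 1), mask = mask)
  expect_true(all(maps2$GFA$data[!mask] == 0))
  expect_gt(maps2$GFA$data[2, 2, 2], 0)
})
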