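test_that("objective evaluates exactly on hand-computable inputs", {
  m <- stripe_model()
  u0 <- matrix(runif(64), 8, 8)
  # lam = 0 -> TV(u0)
  expect_equal(destripe_objective(u0, matrix(0, 8, 8), m),
               spimpipe:::tv_norm(u0))
  # constant image -> 0
  expect_equal(destripe_objective(matrix(3.7, 8, 8), matrix(0, 8, 8), m), 0)
  # one vertical edge of step h -> 8 h
  h <- 0.43
  edge <- cbind(matrix(0, 8, 4), matrix(h, 8, 4))
  expect_equal(destripe_objective(edge, matrix(0, 8, 8), m), 8 * h,
               tolerance = 1e-12)
  expect_error(destripe_objective(u0, matrix(0, 4, 4), m), "shapes differ")
})

test_that("default_psi is unit-normalized, symmetric and correctly anisotropic", {
  psi <- default_psi(15, 0.8)
  expect_equal(sum(psi$matrix^2), 1, tolerance = 1e-12)
  iso <- default_psi(2, 2, voxel_size_um = c(0.5, 0.5, 1))
  expect_equal(iso$matrix, t(iso$matrix), tolerance = 1e-12)
  # second moments on a fine grid reproduce (sigma_along/sigma_across)^2
  fine <- default_psi(6, 2, voxel_size_um = c(0.1, 0.1, 1))
  k2 <- fine$matrix^2                      # intensity-squared weights of the L2-normalized kernel
  xs <- (seq_len(ncol(k2)) - (ncol(k2) + 1) / 2) * 0.1
  ys <- (seq_len(nrow(k2)) - (nrow(k2) + 1) / 2) * 0.1
  mx <- sum(t(k2) * xs^2) / sum(k2)
  my <- sum(k2 * ys^2) / sum(k2)
  expect_equal(mx / my, (6 / 2)^2, tolerance = 0.02)
  expect_error(default_psi(-1, 1), "positive")
})

test_that("decomposition identity holds exactly and the trace is monotone", {
  sim <- tiny_sim()
  u0 <- unclass(sim$corrupted)[, , 20]
  r <- estimate_stripes(u0, stripe_model())
  expect_lt(max(abs((r$clean + r$noise) - u0)), 1e-12 * max(abs(u0)))
  expect_true(all(diff(r$objective_trace) <= 0))
  expect_true(r$converged)
})

test_that("a stripe-free piecewise-constant image yields a near-zero stripe estimate", {
  u0 <- matrix(0, 64, 64)
  u0[20:40, 12:50] <- 0.8
  u0[5:12, 30:60] <- 0.4
  r <- estimate_stripes(u0, stripe_model())
  expect_lt(sqrt(sum(r$noise^2)) / sqrt(sum(u0^2)), 1e-2)
})

test_that("with psi = delta and l2 prior the solver matches the ROF oracle", {
  set.seed(31)
  truth <- matrix(0, 32, 32)
  truth[8:20, 10:25] <- 1
  f <- truth + matrix(rnorm(32 * 32, 0, 0.1), 32, 32)
  alpha <- 8
  m <- stripe_model(psi = psi_delta(), alpha = alpha, prior = "l2",
                    max_iter = 4000, tol = 1e-9)
  r <- suppressWarnings(estimate_stripes(f, m, step_ratio = 1))
  u_hat <- r$clean
  u_ref <- chambolle_rof(f, alpha)
  expect_lt(sqrt(sum((u_hat - u_ref)^2)) / sqrt(sum(u_ref^2)), 1e-3)
})

test_that("destriping is scale covariant when alpha is scaled with the data", {
  sim <- tiny_sim()
  u0 <- unclass(sim$corrupted)[, , 26]
  c0 <- 2.5
  # l1 objective is 1-homogeneous: same alpha, solution scales with the data
  r1 <- estimate_stripes(u0, stripe_model(alpha = 1))
  r2 <- estimate_stripes(c0 * u0, stripe_model(alpha = 1))
  expect_lt(max(abs(c0 * r1$clean - r2$clean)) / max(abs(r2$clean)), 1e-9)
})

test_that("per-slice volume processing composes estimate_stripes", {
  sim <- tiny_sim()
  vol <- image_volume(unclass(sim$corrupted)[, , 20:21],
                      voxel_size(sim$corrupted))
  rv <- destripe_volume(vol, stripe_model())
  r1 <- estimate_stripes(unclass(vol)[, , 1], stripe_model())
  r2 <- estimate_stripes(unclass(vol)[, , 2], stripe_model())
  expect_equal(unclass(rv$clean)[, , 1], r1$clean, tolerance = 1e-12)
  expect_equal(unclass(rv$clean)[, , 2], r2$clean, tolerance = 1e-12)
  expect_lt(max(abs((as.numeric(rv$clean) + as.numeric(rv$noise)) -
                    as.numeric(vol))), 1e-12)
  expect_equal(voxel_size(rv$clean), voxel_size(vol))
})

test_that("the volumetric 3D-TV solve removes z-coherent stripes and decomposes", {
  # the volumetric formulation suits stripes coherent along z; build such a
  # stack by tiling one corrupted slice
  sim <- tiny_sim()
  u0 <- unclass(sim$corrupted)[, , 20]
  cl2 <- unclass(sim$clean)[, , 20]
  vol <- image_volume(array(u0, c(dim(u0), 5)), voxel_size(sim$corrupted))
  cl <- array(cl2, c(dim(u0), 5))
  r <- destripe_volume(vol, stripe_model(per_slice = FALSE))
  expect_lt(max(abs((as.numeric(r$clean) + as.numeric(r$noise)) -
                    as.numeric(vol))), 1e-12)
  expect_gt(psnr(unclass(r$clean), cl), psnr(unclass(vol), cl) + 3)
  expect_true(all(diff(r$objective_trace) <= 0))
})

test_that("a high alpha on stripe-free input gives the fixed point lambda = 0", {
  u0 <- matrix(0, 48, 48); u0[15:30, 10:35] <- 1
  r <- estimate_stripes(u0, stripe_model(alpha = 50))
  expect_lt(max(abs(r$lambda_hat)), 1e-8)
  expect_equal(r$clean, u0, tolerance = 1e-8)
})

test_that("non-finite input is rejected", {
  u0 <- matrix(1, 8, 8); u0[3, 3] <- NA
  expect_error(estimate_stripes(u0), "non-finite")
})
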