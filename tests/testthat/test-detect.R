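blob_volume <- function(centers_um, sigma_um = 2.5, dims = c(64, 64, 48),
                        vs = c(0.645, 0.645, 1), amp = 0.5) {
  arr <- array(0, dims)
  co <- spimpipe:::axis_coords(dims, stats::setNames(vs, c("x", "y", "z")))
  for (i in seq_len(nrow(centers_um))) {
    dx2 <- outer(outer((co$y - centers_um[i, 2])^2,
                       (co$x - centers_um[i, 1])^2, "+"),
                 (co$z - centers_um[i, 3])^2, "+")
    arr <- arr + amp * exp(-dx2 / (2 * sigma_um^2))
  }
  image_volume(arr, vs)
}

test_that("an all-zero volume yields no detections", {
  v <- image_volume(array(0, c(32, 32, 16)))
  expect_equal(nrow(detect_nuclei(v)), 0)
})

test_that("detection honours physical units and finds isolated blobs", {
  v <- blob_volume(rbind(c(12, 20, 14), c(28, 20, 30)))
  d <- detect_nuclei(v)
  expect_equal(nrow(d), 2)
  err <- min(sqrt((d$x_um - 12)^2 + (d$y_um - 20)^2 + (d$z_um - 14)^2))
  expect_lt(err, 1.5)
})

test_that("two blobs closer than half the minimum separation merge to one", {
  p <- detect_params(min_separation_um = 6)
  ctr <- c(20, 20, 24)
  off <- c(0.5 * 6, 0, 0)
  v <- blob_volume(rbind(ctr - off / 2, ctr + off / 2))
  d <- detect_nuclei(v, p)
  expect_equal(nrow(d), 1)
})

test_that("detection count is invariant under global intensity scaling", {
  v <- tiny_sim()$clean
  n0 <- nrow(detect_nuclei(v))
  for (c0 in c(0.5, 2)) {
    vc <- vol_scaled <- image_volume(unclass(v) * c0, voxel_size(v))
    expect_equal(nrow(detect_nuclei(vc)), n0)
  }
})

test_that("an isolated isotropic blob measures round and moderately spherical", {
  v <- blob_volume(matrix(c(20, 20, 24), 1))
  d <- segment_and_measure(v, detect_nuclei(v))
  expect_equal(nrow(d), 1)
  expect_lt(d$elongation, 1.3)
  expect_gt(d$sphericity_proxy, 0.7)
})

test_that("watershed labels are disjoint, contain their seeds, and measure volume", {
  # voxelized hard sphere of radius r: volume within 15% of (4/3) pi r^3
  r <- 6
  dims <- c(48, 48, 40); vs <- c(0.645, 0.645, 1)
  co <- spimpipe:::axis_coords(dims, stats::setNames(vs, c("x", "y", "z")))
  ctr <- c(15, 15, 20)
  D2 <- outer(outer((co$y - ctr[2])^2, (co$x - ctr[1])^2, "+"),
              (co$z - ctr[3])^2, "+")
  arr <- ifelse(D2 <= r^2, 1, 0)
  v <- image_volume(arr, vs)
  d <- detect_nuclei(v, detect_params(min_radius_um = 4, max_radius_um = 8))
  expect_gte(nrow(d), 1)
  d <- segment_and_measure(v, d, smooth_um = 0.3, floor_frac = 0.5)
  expect_equal(d$volume_um3[1], 4 / 3 * pi * r^3, tolerance = 0.15)
  labels <- attr(d, "labels")
  expect_true(all(sort(unique(as.integer(labels[labels > 0]))) %in% d$id))
  # two-blob case: disjoint labels each containing its seed
  v2 <- blob_volume(rbind(c(12, 20, 14), c(28, 20, 30)))
  d2 <- segment_and_measure(v2, detect_nuclei(v2))
  l2 <- attr(d2, "labels")
  for (i in seq_len(nrow(d2))) {
    iy <- round(d2$y_um[i] / 0.645) + 1; ix <- round(d2$x_um[i] / 0.645) + 1
    iz <- round(d2$z_um[i]) + 1
    expect_equal(as.integer(l2[iy, ix, iz]), d2$id[i])
  }
})

test_that("classification applies the two-feature rule and its trivial cases", {
  d <- data.frame(id = 1:3,
                  background_ratio = c(1.0, 2.5, 2.5),
                  elongation = c(1.0, 2.2, 1.1),
                  volume_um3 = c(400, 380, 420))
  class(d) <- c("detections", "data.frame")
  d <- classify_mitotic(d)
  expect_equal(d$klass, c("interphase", "mitotic", "interphase"))
  expect_match(attr(d, "classification_rule"), "background_ratio")
  expect_error(classify_mitotic(data.frame(id = 1)), "unfilled")
})

test_that("an all-interphase scene draws zero mitotic calls", {
  sim <- fixture("tiny_allinter", simulate_scene(
    scene_preset("tiny", seed = 13, mitotic_fraction = 0)))
  d <- analyze_frame(destripe_volume(sim$corrupted)$clean)
  expect_equal(sum(d$klass == "mitotic"), 0)
})

test_that("fit_spheroid recovers an exact sphere sample within 1%", {
  set.seed(5)
  n <- 60
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  P <- sweep(u * 50, 2, c(60, 55, 70), "+")
  d <- data.frame(x_um = P[, 1], y_um = P[, 2], z_um = P[, 3])
  f <- fit_spheroid(d)
  expect_equal(f$radius_um, 50, tolerance = 0.01)
  expect_equal(unname(f$center_um), c(60, 55, 70), tolerance = 0.5)
  expect_lt(f$rms_residual_um, 0.5)
})

test_that("fit_spheroid is translation equivariant", {
  tr <- place_nuclei(scene_preset("tiny", seed = 3))
  d0 <- data.frame(x_um = tr$nuclei$x_um, y_um = tr$nuclei$y_um,
                   z_um = tr$nuclei$z_um)
  v <- c(7, -13, 21)
  d1 <- data.frame(x_um = d0$x_um + v[1], y_um = d0$y_um + v[2],
                   z_um = d0$z_um + v[3])
  f0 <- fit_spheroid(d0); f1 <- fit_spheroid(d1)
  expect_equal(unname(f1$center_um - f0$center_um), v, tolerance = 1e-6)
  expect_equal(f1$radius_um, f0$radius_um, tolerance = 1e-6)
})

test_that("degenerate coplanar configurations are rejected", {
  set.seed(4)
  d <- data.frame(x_um = runif(20, 0, 50), y_um = runif(20, 0, 50), z_um = 10)
  expect_error(fit_spheroid(d), "coplanar")
  expect_error(fit_spheroid(d[1:5, ]), "at least 10")
})

test_that("depth from surface matches the center and surface limit cases", {
  f <- structure(list(center_um = c(x = 10, y = 20, z = 30), radius_um = 40,
                      rms_residual_um = 0.1),
                 class = "spheroid_fit")
  d <- data.frame(x_um = c(10, 50), y_um = c(20, 20), z_um = c(30, 30))
  d <- depth_from_surface(d, f)
  expect_equal(d$depth_from_surface_um, c(40, 0))
})
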