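# nuclei placed exactly on voxel centers so peak readout is not biased by
# sub-voxel sampling of narrow blobs
on_grid <- function(spec, pos_um) {
  vs <- spec$voxel_size_um
  c(round(pos_um[1] / vs[["x"]]) * vs[["x"]],
    round(pos_um[2] / vs[["y"]]) * vs[["y"]],
    round(pos_um[3] / vs[["z"]]) * vs[["z"]])
}
two_nucleus_truth <- function(spec, dx_um) {
  ctr <- spimpipe:::scene_center_um(spec)
  p1 <- on_grid(spec, c(ctr[["x"]] - dx_um / 2, ctr[["y"]], ctr[["z"]]))
  p2 <- on_grid(spec, c(ctr[["x"]] + dx_um / 2, ctr[["y"]], ctr[["z"]]))
  scene_truth(data.frame(x_um = c(p1[1], p2[1]), y_um = c(p1[2], p2[2]),
                         z_um = c(p1[3], p2[3])), spec)
}

test_that("without attenuation, equal nuclei at different x have equal peaks", {
  spec <- scene_spec(spheroid_radius_um = 20, volume_shape_vox = c(80, 80, 52),
                     n_nuclei = 2, margin_um = 4, seed = 1)
  tr <- two_nucleus_truth(spec, 20)
  v <- render_volume(tr, spec, optics_quiet(), noise = FALSE)
  half <- as_array <- unclass(v)
  p1 <- max(half[, 1:40, ]); p2 <- max(half[, 41:80, ])
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("attenuation follows the closed-form exponential chord decay", {
  spec <- scene_spec(spheroid_radius_um = 20, volume_shape_vox = c(80, 80, 52),
                     n_nuclei = 2, margin_um = 4, seed = 1)
  dx <- 20
  tr <- two_nucleus_truth(spec, dx)
  ell <- 60
  opt <- optics_quiet(attenuation_length_um = ell)
  v <- unclass(render_volume(tr, spec, opt, noise = FALSE))
  p_near <- max(v[, 1:40, ]); p_far <- max(v[, 41:80, ])
  expect_equal(p_far / p_near, exp(-dx / ell), tolerance = 0.05)
})

test_that("mitotic peak is mitotic_gain times the interphase peak", {
  spec <- scene_spec(spheroid_radius_um = 20, volume_shape_vox = c(80, 80, 52),
                     n_nuclei = 2, margin_um = 4, seed = 1)
  ctr <- spimpipe:::scene_center_um(spec)
  p1 <- on_grid(spec, c(ctr[["x"]] - 10, ctr[["y"]], ctr[["z"]]))
  p2 <- on_grid(spec, c(ctr[["x"]] + 10, ctr[["y"]], ctr[["z"]]))
  tr <- scene_truth(data.frame(
    x_um = c(p1[1], p2[1]), y_um = c(p1[2], p2[2]), z_um = c(p1[3], p2[3]),
    class = c("interphase", "mitotic")), spec)
  v <- unclass(render_volume(tr, spec, optics_quiet(mitotic_gain = 2),
                             noise = FALSE))
  p_int <- max(v[, 1:40, ]); p_mit <- max(v[, 41:80, ])
  expect_equal(p_mit / p_int, 2, tolerance = 0.02)
})

test_that("unlabeled nuclei contribute nothing", {
  spec <- scene_preset("tiny", seed = 3)
  tr <- place_nuclei(spec)
  tr$nuclei$labeled <- FALSE
  v <- render_volume(tr, spec, optics_quiet(), noise = FALSE)
  expect_true(all(v == 0))
})

test_that("all rendered mass stays near the spheroid", {
  sim_spec <- scene_preset("tiny", seed = 3)
  tr <- place_nuclei(sim_spec)
  opt <- optics_quiet(blur_sigma0_um = 0.8)
  v <- unclass(render_volume(tr, sim_spec, opt, noise = FALSE))
  vs <- sim_spec$voxel_size_um
  cx <- spimpipe:::scene_center_um(sim_spec)
  co <- spimpipe:::axis_coords(dim(v), vs)
  R2 <- outer(outer((co$y - cx["y"])^2, (co$x - cx["x"])^2, "+"),
              (co$z - cx["z"])^2, "+")
  lim <- sim_spec$spheroid_radius_um +
    3 * (opt$blur_sigma0_um + sim_spec$nucleus_radius_um)
  outside <- v[R2 > lim^2]
  expect_lt(sum(outside), 1e-9 * sum(v))
})

test_that("nucleus peak intensity is non-increasing in illumination path length", {
  spec <- scene_preset("tiny", seed = 6, mitotic_fraction = 0)
  tr <- place_nuclei(spec)
  opt <- optics_quiet(attenuation_length_um = 100, blur_sigma0_um = 0.5)
  v <- unclass(render_volume(tr, spec, opt, noise = FALSE))
  vs <- spec$voxel_size_um
  n <- tr$nuclei
  # chord path length to each nucleus center
  rho2 <- (n$y_um - tr$center_um["y"])^2 + (n$z_um - tr$center_um["z"])^2
  hx <- sqrt(pmax(tr$spheroid_radius_um^2 - rho2, 0))
  d <- pmin(pmax((n$x_um - tr$center_um["x"]) + hx, 0), 2 * hx)
  peak <- vapply(seq_len(nrow(n)), function(i) {
    iy <- round(n$y_um[i] / vs["y"]) + 1
    ix <- round(n$x_um[i] / vs["x"]) + 1
    iz <- round(n$z_um[i] / vs["z"]) + 1
    max(v[max(1, iy - 2):min(dim(v)[1], iy + 2),
          max(1, ix - 2):min(dim(v)[2], ix + 2),
          max(1, iz - 2):min(dim(v)[3], iz + 2)])
  }, numeric(1))
  ord <- order(d)
  # binned means along path length are non-increasing (small slack for
  # blob overlap)
  bins <- split(peak[ord], cut(seq_along(ord), 3))
  m <- vapply(bins, mean, numeric(1))
  expect_true(all(diff(m) <= 0.02))
  expect_lt(cor(d, peak), -0.8)
})

test_that("rendering is deterministic given the seed", {
  spec <- scene_preset("tiny", seed = 3)
  tr <- place_nuclei(spec)
  v1 <- render_volume(tr, spec, optics_spec(), seed = 11)
  v2 <- render_volume(tr, spec, optics_spec(), seed = 11)
  expect_identical(as.numeric(v1), as.numeric(v2))
})
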