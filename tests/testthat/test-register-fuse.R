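test_that("an exactly flipped copy registers to zero translation with score 1", {
  v <- tiny_sim()$clean
  flipped_back <- vol_like(spimpipe:::flip_xz(unclass(v)), v)
  rs <- register_opposing(v, flipped_back)
  expect_equal(unname(rs$translation_vox), c(0, 0, 0), tolerance = 1e-6)
  expect_equal(rs$score, 1, tolerance = 1e-4)
  expect_setequal(rs$flip_axes, c("x", "z"))
})

test_that("a known flip+shift is recovered within 0.25 voxel per axis", {
  s <- c(2, -3, 1)
  v0 <- tiny_sim()$clean
  v180 <- image_volume(spimpipe:::flip_xz(
    spimpipe:::shift_integer(unclass(v0), s)), voxel_size(v0))
  rs <- register_opposing(v0, v180)
  expect_lt(max(abs(unname(rs$translation_vox) + s)), 0.25)
})

test_that("independently rendered opposing views register within half a voxel", {
  # opposite illumination gives the two views asymmetric attenuation
  # envelopes, the hard case for correlation-based registration
  s <- c(2, -3, 1)
  p <- reg_pair(shift_vox = s)
  rs <- register_opposing(p$views$view0, p$views$view180)
  # shifting the stored (flipped) stack by s moves the re-flipped image by
  # the x/z-mirrored vector, so the aligning translation is its negation
  expected <- c(-s[1], s[2], s[3])
  expect_lt(max(abs(unname(rs$translation_vox) - expected)), 0.5)
  expect_gt(rs$score, 0.8)
})

test_that("pure-noise pairs are rejected as unreliable", {
  set.seed(2)
  a <- image_volume(array(rnorm(32^3), c(32, 32, 32)))
  b <- image_volume(array(rnorm(32^3), c(32, 32, 32)))
  expect_error(register_opposing(a, b), "unreliable")
})

test_that("registration is equivariant under a common shift of both views", {
  p <- reg_pair(shift_vox = c(2, -3, 1))
  rs0 <- register_opposing(p$views$view0, p$views$view180)
  common <- c(0, 2, -1)
  v0s <- vol_like(spimpipe:::shift_integer(unclass(p$views$view0), common),
                  p$views$view0)
  # shifting view180's array by s shifts its flipped image by the mirrored
  # vector, so shift the flipped-and-registered frame consistently instead:
  v1f <- spimpipe:::flip_xz(unclass(p$views$view180))
  v1s <- vol_like(spimpipe:::flip_xz(spimpipe:::shift_integer(v1f, common)),
                  p$views$view180)
  rs1 <- register_opposing(v0s, v1s)
  expect_lt(max(abs(unname(rs1$translation_vox - rs0$translation_vox))), 0.25)
})

test_that("rigid shift round-trips within interpolation error", {
  # smooth noise-free scene: interpolation error, not noise, is measured
  sc <- scene_preset("tiny", seed = 3)
  v <- unclass(render_volume(place_nuclei(sc), sc,
                             optics_quiet(blur_sigma0_um = 1.5),
                             noise = FALSE))
  t_vox <- c(1.4, -2.3, 0.6)
  fwd <- spimpipe:::translate_trilinear(v, t_vox)
  back <- spimpipe:::translate_trilinear(fwd$data, -t_vox)
  core <- back$inside & fwd$inside
  # RMS error relative to the scene's dynamic range
  rel <- sqrt(mean((back$data[core] - v[core])^2)) / diff(range(v))
  expect_lt(rel, 0.02)
})

test_that("fusing two identical aligned views reproduces the input", {
  v <- tiny_sim()$clean
  for (mode in c("ramp", "local_contrast")) {
    f <- fuse_views(list(v, v), list(rigid_identity(), rigid_identity()),
                    fusion_weights(mode))
    expect_equal(as.numeric(f), as.numeric(v), tolerance = 1e-6)
  }
})

test_that("fusion weights sum to one at every voxel", {
  p <- reg_pair()
  rs <- register_opposing(p$views$view0, p$views$view180)
  for (mode in c("ramp", "local_contrast")) {
    w <- spimpipe:::fusion_weight_maps(list(p$views$view0, p$views$view180),
                                       list(rigid_identity(), rs),
                                       fusion_weights(mode))
    expect_lt(max(abs(w[[1]] + w[[2]] - 1)), 1e-6)
  }
})

test_that("fusing opposing attenuated views beats each single view", {
  p <- reg_pair()
  ref <- render_volume(p$truth, p$scene, optics_quiet(), noise = FALSE)
  rs <- register_opposing(p$views$view0, p$views$view180)
  fused <- fuse_views(list(p$views$view0, p$views$view180),
                      list(rigid_identity(), rs))
  v180_aligned <- apply_rigid_shift(p$views$view180, rs)$data
  p_fused <- psnr(unclass(fused), unclass(ref))
  p_v0 <- psnr(unclass(p$views$view0), unclass(ref))
  p_v180 <- psnr(unclass(v180_aligned), unclass(ref))
  expect_gt(p_fused, p_v0)
  expect_gt(p_fused, p_v180)
})

test_that("identical frames need no drift correction", {
  v <- tiny_sim()$clean
  dc <- correct_drift(list(v, v, v))
  expect_equal(max(abs(as.matrix(dc$shifts[, c("dx_um", "dy_um", "dz_um")]))), 0,
               tolerance = 1e-6)
  expect_identical(as.numeric(dc$frames[[2]]), as.numeric(v))
})

test_that("injected linear drift is recovered within half a voxel", {
  sc <- scene_preset("tiny", seed = 9, mitotic_fraction = 0)
  drift <- c(1.2, -0.8, 0.5)
  tl <- timelapse_spec(n_frames = 4, drift_per_frame_um = drift, seed = 9)
  mv <- render_timelapse(sc, optics_spec(), stripes = NULL, tl)
  vs <- voxel_size(mv$frames[[1]])
  for (ref in c("first", "previous")) {
    dc <- correct_drift(mv$frames, reference = ref)
    for (t in 2:4) {
      est <- -c(dc$shifts$dx_um[t], dc$shifts$dy_um[t], dc$shifts$dz_um[t])
      err_vox <- abs(est - (t - 1) * drift) / vs[c("x", "y", "z")]
      expect_lt(max(err_vox), 0.5)
    }
  }
})
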