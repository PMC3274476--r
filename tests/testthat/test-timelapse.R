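test_that("a 1-frame movie reproduces render_volume plus stripes, no drift", {
  sc <- scene_preset("tiny", seed = 3)
  tl <- timelapse_spec(n_frames = 1, drift_per_frame_um = c(2, 0, 0), seed = 17)
  mv <- render_timelapse(sc, optics_spec(), stripe_spec(), tl)
  truth <- place_nuclei(sc)
  ref <- render_volume(truth, sc, optics_spec(), seed = 17)
  sf <- make_stripe_field(sc$volume_shape_vox, stripe_spec(),
                          sc$voxel_size_um, seed = 17 + 500L)
  expect_identical(as.numeric(mv$frames[[1]]),
                   as.numeric(corrupt_volume(ref, sf)))
})

test_that("injected drift shows up at the cross-correlation peak", {
  sc <- scene_preset("tiny", seed = 4, mitotic_fraction = 0)
  tl <- timelapse_spec(n_frames = 5, drift_per_frame_um = c(1, 0, 0), seed = 4)
  mv <- render_timelapse(sc, optics_quiet(), stripes = NULL, tl, noise = FALSE)
  a <- unclass(mv$frames[[1]]); b <- unclass(mv$frames[[5]])
  # plain cross-correlation oracle via FFT
  r <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  pk <- arrayInd(which.max(r), dim(r))[1, ] - 1
  pk <- ifelse(pk > dim(r) / 2, pk - dim(r), pk)
  # frame 4 = frame 0 shifted by +4 um along x => peak at -shift on x axis
  expect_equal(pk[1], 0)
  expect_equal(pk[3], 0)
  expect_equal(abs(pk[2]), round(4 / 0.645), tolerance = 1)
})

test_that("daughters first appear ceiling(duration/interval) frames after entry", {
  sc <- scene_preset("tiny", seed = 6)
  tl <- timelapse_spec(n_frames = 20, mitosis_duration_min = 45,
                       frame_interval_min = 3,
                       division_events = data.frame(id = 1, entry_frame = 2),
                       seed = 6)
  mv <- render_timelapse(sc, optics_spec(), stripes = NULL, tl, noise = FALSE)
  dd <- mv$per_frame[mv$per_frame$state == "daughter", ]
  expect_equal(min(dd$frame), 2 + ceiling(45 / 3))
  # the state machine passes through every phase in order
  st <- mv$per_frame$state[mv$per_frame$id == 1]
  expect_equal(rle(st)$values,
               c("interphase", "condensed", "metaphase", "anaphase"))
})

test_that("paclitaxel mode never leaves the condensed unaligned state", {
  sc <- scene_preset("tiny", seed = 6)
  tl <- timelapse_spec(n_frames = 12,
                       division_events = data.frame(id = 1, entry_frame = 0),
                       paclitaxel_mode = TRUE, seed = 6)
  mv <- render_timelapse(sc, optics_spec(), stripes = NULL, tl, noise = FALSE)
  st <- mv$per_frame[mv$per_frame$id == 1, ]
  expect_true(all(st$state == "condensed"))
  expect_false(any(mv$per_frame$state %in% c("metaphase", "anaphase", "daughter")))
  # chromosome centroid jitters frame to frame
  expect_gt(sd(st$x_um), 0.1)
})

test_that("division events on unlabeled or too-deep nuclei are skipped with a warning", {
  sc <- scene_preset("tiny", seed = 8)
  ctr <- spimpipe:::scene_center_um(sc)
  tr <- scene_truth(data.frame(
    x_um = ctr[["x"]] + c(-12, 0, 12), y_um = ctr[["y"]], z_um = ctr[["z"]],
    labeled = c(FALSE, TRUE, TRUE)), sc)   # nucleus 2 sits at the center (deep)
  tl <- timelapse_spec(n_frames = 3,
                       division_events = data.frame(id = c(1, 2),
                                                    entry_frame = c(0, 0)),
                       seed = 8)
  expect_warning(expect_warning(
    mv <- render_timelapse(sc, optics_spec(), stripes = NULL, tl,
                           noise = FALSE, truth = tr),
    "unlabeled"), "too-deep")
  expect_true(all(mv$events$skipped))
})

test_that("time-lapse output is deterministic given the specs", {
  sc <- scene_preset("tiny", seed = 5)
  tl <- timelapse_spec(n_frames = 2, seed = 5)
  m1 <- render_timelapse(sc, optics_spec(), stripe_spec(), tl)
  m2 <- render_timelapse(sc, optics_spec(), stripe_spec(), tl)
  expect_identical(lapply(m1$frames, as.numeric), lapply(m2$frames, as.numeric))
  expect_identical(m1$per_frame, m2$per_frame)
})
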