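det_frame <- function(ids, x, y = 0, z = 0, klass = "interphase") {
  d <- data.frame(id = ids, x_um = x, y_um = rep_len(y, length(ids)),
                  z_um = rep_len(z, length(ids)),
                  klass = rep_len(klass, length(ids)))
  class(d) <- c("detections", "data.frame")
  d
}

test_that("a static scene links one track per initial detection", {
  f <- det_frame(1:4, c(0, 20, 40, 60))
  trs <- link_tracks(list(f, f, f))
  expect_equal(length(trs$tracks), 4)
  expect_true(all(vapply(trs$tracks, nrow, integer(1)) == 3))
  expect_true(all(is.na(trs$parent)))
})

test_that("duplicate detection ids within a frame are rejected", {
  f <- det_frame(c(1, 1), c(0, 20))
  expect_error(link_tracks(list(f)), "duplicate")
})

test_that("two approaching bodies keep their identities", {
  # approach to half the gate, then separate; per-frame step stays below
  # half their separation
  xs_a <- c(0, 2, 4, 5, 4, 2, 0)
  xs_b <- c(10, 8, 6, 5 + 5, 6 + 4, 8 + 2, 10)  # b stays >= 5 um away
  xs_b <- c(10, 8, 6.5, 6, 6.5, 8, 10)
  frames <- lapply(seq_along(xs_a), function(t)
    det_frame(1:2, c(xs_a[t], xs_b[t]), y = c(0, 0)))
  trs <- link_tracks(frames, gate_um = 10)
  expect_equal(length(trs$tracks), 2)
  for (k in 1:2) {
    ids <- trs$tracks[[k]]$det_id
    expect_equal(length(unique(ids)), 1)   # no identity swap
  }
})

test_that("gaps up to max_gap are bridged", {
  f1 <- det_frame(1, 0); f2 <- det_frame(integer(0), numeric(0))
  f3 <- det_frame(1, 1)
  trs <- link_tracks(list(f1, f2, f3), max_gap = 1)
  expect_equal(length(trs$tracks), 1)
  expect_equal(trs$tracks[[1]]$frame, c(0, 2))
  trs2 <- link_tracks(list(f1, f2, f2, f3), max_gap = 1)
  expect_equal(length(trs2$tracks), 2)
})

test_that("a division yields exactly one parent with two daughters", {
  # one cell: interphase 2 frames, mitotic 3 frames, then two daughters
  frames <- list(
    det_frame(1, 50), det_frame(1, 50),
    det_frame(1, 50, klass = "mitotic"),
    det_frame(1, 50, klass = "mitotic"),
    det_frame(1, 50, klass = "mitotic"),
    det_frame(c(2, 3), c(46, 54)),
    det_frame(c(2, 3), c(45, 55)))
  trs <- link_tracks(frames)
  expect_equal(sum(!is.na(trs$parent)), 2)
  pk <- unique(trs$parent[!is.na(trs$parent)])
  expect_equal(length(pk), 1)
  # parent track ends mitotic
  pr <- trs$tracks[[pk]]
  expect_equal(pr$klass[nrow(pr)], "mitotic")
  ev <- extract_mitotic_events(trs, 3, n_frames = 7)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$outcome, "completed")
  expect_equal(ev$entry_frame, 2)
  expect_equal(ev$exit_frame, 5)
  expect_equal(ev$duration_min, 9)
})

test_that("single-frame mitotic flicker emits no event and gaps are bridged", {
  mk <- function(states) {
    frames <- lapply(seq_along(states), function(t)
      det_frame(1, 0, klass = states[t]))
    link_tracks(frames)
  }
  ev <- extract_mitotic_events(mk(c("interphase", "mitotic", "interphase",
                                    "interphase")), 3, n_frames = 4)
  expect_equal(nrow(ev), 0)
  # one interphase flicker inside a long mitotic run is bridged
  ev2 <- extract_mitotic_events(
    mk(c("interphase", "mitotic", "mitotic", "interphase", "mitotic",
         "mitotic", "interphase", "interphase")), 3, n_frames = 8)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$entry_frame, 1)
  expect_equal(ev2$exit_frame, 6)
})

test_that("a run reaching movie end 70 min after entry is arrested at the 60-min horizon", {
  states <- c("interphase", rep("mitotic", 24))  # entry at frame 1, 72 min observed
  frames <- lapply(seq_along(states), function(t)
    det_frame(1, 0, klass = states[t]))
  trs <- link_tracks(frames)
  ev <- extract_mitotic_events(trs, 3, arrest_threshold_min = 60,
                               n_frames = length(states))
  expect_equal(ev$outcome, "arrested")
  expect_gte(ev$duration_min, 60)
  expect_true(is.na(ev$exit_frame))
  # shorter run -> censored, never completed
  states2 <- c(rep("interphase", 20), rep("mitotic", 5))
  frames2 <- lapply(seq_along(states2), function(t)
    det_frame(1, 0, klass = states2[t]))
  ev2 <- extract_mitotic_events(link_tracks(frames2), 3, n_frames = 25)
  expect_equal(ev2$outcome, "censored")
  expect_equal(ev2$duration_min, 15)
})

test_that("frame interval is required for event extraction", {
  trs <- link_tracks(list(det_frame(1, 0)))
  expect_error(extract_mitotic_events(trs), "frame_interval_min")
})

test_that("alignment scoring separates plates from spheres and condensed masses", {
  # moment analysis of rendered masses via segment_and_measure
  sc <- scene_spec(spheroid_radius_um = 16, volume_shape_vox = c(64, 64, 44),
                   n_nuclei = 1, margin_um = 4, seed = 1)
  ctr <- spimpipe:::scene_center_um(sc)
  shapes <- list(metaphase = "metaphase", condensed = "condensed",
                 interphase = "interphase")
  ratio_of <- function(shape) {
    tbl <- data.frame(id = 1, x_um = ctr["x"], y_um = ctr["y"], z_um = ctr["z"],
                      shape = shape, amp = 1, axis_x = 0, axis_y = 0,
                      axis_z = 1, sep_um = 0)
    arr <- spimpipe:::render_core(tbl, sc$volume_shape_vox, sc$voxel_size_um,
                                  ctr, sc$spheroid_radius_um,
                                  sc$nucleus_radius_um, optics_quiet(),
                                  seed = 1, noise = FALSE)
    v <- image_volume(arr, sc$voxel_size_um)
    d <- segment_and_measure(v, detect_nuclei(v, detect_params(
      min_radius_um = 2, max_radius_um = 6)))
    d$eig3[1] / d$eig2[1]
  }
  expect_lt(ratio_of("metaphase"), 0.35)     # flat plate: collapsed axis
  expect_gt(ratio_of("interphase"), 0.7)     # sphere: isotropic
  expect_gt(ratio_of("condensed"), 0.7)      # prolate: two equal small axes
})

test_that("comparing an arm with itself gives zero arrest difference", {
  ev <- data.frame(track_id = 1:3, entry_frame = 0, exit_frame = c(5, 6, NA),
                   duration_min = c(15, 18, 60),
                   outcome = c("completed", "completed", "arrested"),
                   aligned = c(TRUE, TRUE, FALSE), daughter_track_ids = "")
  cmp <- compare_conditions(ev, ev)
  expect_equal(cmp$arrested_fraction_difference, 0)
  expect_equal(cmp$control$median_duration_completed_min, 16.5)
  expect_error(compare_conditions(ev[0, ], ev), "at least one event")
})

test_that("an all-censored arm reports medians as flagged lower bounds", {
  ev_c <- data.frame(track_id = 1, entry_frame = 0, exit_frame = 5,
                     duration_min = 15, outcome = "completed", aligned = TRUE,
                     daughter_track_ids = "")
  ev_t <- data.frame(track_id = 1:2, entry_frame = 0, exit_frame = NA,
                     duration_min = c(30, 36), outcome = "censored",
                     aligned = NA, daughter_track_ids = "")
  cmp <- compare_conditions(ev_c, ev_t)
  expect_true(cmp$treated$duration_is_lower_bound)
  expect_true(is.na(cmp$treated$median_duration_completed_min))
  expect_equal(cmp$treated$median_duration_observed_min, 33)
})
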