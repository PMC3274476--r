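# Time-lapse rendering: global drift, a per-division mitosis state machine
# (interphase -> condensed -> metaphase -> anaphase -> two daughters), a
# paclitaxel mode that never leaves the condensed unaligned state, fresh
# stripe fields per frame.

# frame counts of each mitotic phase for an n_mit-frame division
phase_plan <- function(n_mit) {
  if (n_mit <= 1) return(c(condensed = n_mit, metaphase = 0, anaphase = 0))
  if (n_mit == 2) return(c(condensed = 1, metaphase = 0, anaphase = 1))
  nc <- max(1, round(0.3 * n_mit))
  na <- max(1, round(0.3 * n_mit))
  nm <- n_mit - nc - na
  if (nm < 1) { nm <- 1; nc <- n_mit - na - nm }
  c(condensed = nc, metaphase = nm, anaphase = na)
}

#' Render a synthetic SPIM time-lapse
#'
#' Frame `t` (0-based) is shifted by `t * drift_per_frame_um` before
#' rendering.  Each division event walks interphase -> condensed ->
#' metaphase -> anaphase (two masses separating along the spindle axis at
#' constant speed) -> two daughter interphase nuclei over
#' `mitosis_duration_min`; daughters first appear
#' `ceiling(duration / interval)` frames after entry.  In
#' `paclitaxel_mode` the machine never leaves the condensed, unaligned
#' state: the chromosome mass jitters every frame, no metaphase plate forms
#' and no anaphase occurs through movie end.  A fresh stripe field is drawn
#' per frame.  Frame `t` uses render seed `tl$seed + 1000 t` and stripe seed
#' `tl$seed + 1000 t + 500`, so frame 0 of a 1-frame movie reproduces
#' [render_volume()] plus [make_stripe_field()] exactly.
#'
#' @param scene a [scene_spec()].
#' @param optics an [optics_spec()].
#' @param stripes a [stripe_spec()], or `NULL` for stripe-free frames.
#' @param tl a [timelapse_spec()].
#' @param noise apply sensor noise.
#' @param truth optional pre-built `scene_truth` (defaults to
#'   `place_nuclei(scene)`).
#' @return a `timelapse_truth` list: `frames` (corrupted volumes),
#'   `clean_frames`, `stripe_fields`, `truth` (base `scene_truth`),
#'   `per_frame` state table, `drift_um` per frame, `events`
#'   (with `skipped` flag), and the specs.
#' @export
render_timelapse <- function(scene, optics = optics_spec(),
                             stripes = stripe_spec(), tl = timelapse_spec(),
                             noise = TRUE, truth = NULL) {
  stopifnot(inherits(scene, "scene_spec"), inherits(tl, "timelapse_spec"))
  if (is.null(truth)) truth <- place_nuclei(scene)
  stopifnot(inherits(truth, "scene_truth"))
  nuc <- truth$nuclei
  dims <- scene$volume_shape_vox; vs <- scene$voxel_size_um

  ev <- tl$division_events
  if (is.null(ev)) ev <- data.frame(id = integer(0), entry_frame = integer(0))
  ev$skipped <- logical(nrow(ev))
  for (k in seq_len(nrow(ev))) {
    i <- match(ev$id[k], nuc$id)
    if (is.na(i)) stopf("render_timelapse: unknown nucleus id %s", ev$id[k])
    if (!nuc$labeled[i] || nuc$depth_um[i] > scene$rim_thickness_um) {
      warnf("render_timelapse: division event on %s nucleus %d skipped",
            if (!nuc$labeled[i]) "an unlabeled" else "a too-deep", ev$id[k])
      ev$skipped[k] <- TRUE
    }
  }
  act <- ev[!ev$skipped, , drop = FALSE]
  n_mit <- ceiling(tl$mitosis_duration_min / tl$frame_interval_min)
  # stable daughter ids
  act$d1 <- max(nuc$id) + 2 * seq_len(nrow(act)) - 1
  act$d2 <- act$d1 + 1
  # spindle orientation: cells divide into available space, so pick the
  # candidate axis whose daughter positions clear the neighbours best
  act$ax <- act$ay <- act$az <- rep(NA_real_, nrow(act))
  for (k in seq_len(nrow(act))) {
    i <- match(act$id[k], nuc$id)
    cand <- with_seed(tl$seed + 811L * k, {
      m <- matrix(rnorm(3 * 24), 24, 3)
      m / sqrt(rowSums(m^2))
    })
    cand <- rbind(c(nuc$axis_x[i], nuc$axis_y[i], nuc$axis_z[i]), cand)
    oth <- nuc[nuc$id != act$id[k], c("x_um", "y_um", "z_um")]
    p0 <- c(nuc$x_um[i], nuc$y_um[i], nuc$z_um[i])
    score <- apply(cand, 1, function(a) {
      d1 <- p0 + 5.5 * a; d2 <- p0 - 5.5 * a
      min(sqrt((oth$x_um - d1[1])^2 + (oth$y_um - d1[2])^2 + (oth$z_um - d1[3])^2),
          sqrt((oth$x_um - d2[1])^2 + (oth$y_um - d2[2])^2 + (oth$z_um - d2[3])^2))
    })
    best <- cand[which.max(score), ]
    act$ax[k] <- best[1]; act$ay[k] <- best[2]; act$az[k] <- best[3]
  }

  frames <- clean_frames <- stripe_fields <- vector("list", tl$n_frames)
  per_frame <- vector("list", tl$n_frames)
  drift_um <- matrix(0, tl$n_frames, 3, dimnames = list(NULL, c("x", "y", "z")))

  for (t in seq_len(tl$n_frames) - 1L) {
    dr <- t * tl$drift_per_frame_um
    drift_um[t + 1, ] <- dr
    tbl <- data.frame(id = nuc$id, x_um = nuc$x_um + dr["x"],
                      y_um = nuc$y_um + dr["y"], z_um = nuc$z_um + dr["z"],
                      shape = "interphase", amp = 0.5,
                      axis_x = nuc$axis_x, axis_y = nuc$axis_y,
                      axis_z = nuc$axis_z, sep_um = 0,
                      labeled = nuc$labeled, state = "interphase",
                      stringsAsFactors = FALSE)
    # static mitotic figures stay condensed throughout
    stat_mit <- nuc$class == "mitotic" & !(nuc$id %in% act$id)
    tbl$shape[stat_mit] <- "condensed"
    tbl$state[stat_mit] <- "condensed"
    tbl$amp[stat_mit] <- 0.5 * optics$mitotic_gain

    drop_rows <- integer(0); add_rows <- NULL
    for (k in seq_len(nrow(act))) {
      i <- match(act$id[k], tbl$id)
      rel <- t - act$entry_frame[k]
      if (rel < 0) next
      if (tl$paclitaxel_mode) {
        jit <- with_seed(tl$seed + 13L * t + 7919L * k, rnorm(6, 0, 1))
        tbl$shape[i] <- "condensed"; tbl$state[i] <- "condensed"
        tbl$amp[i] <- 0.5 * optics$mitotic_gain
        tbl$x_um[i] <- tbl$x_um[i] + 0.8 * jit[1]
        tbl$y_um[i] <- tbl$y_um[i] + 0.8 * jit[2]
        tbl$z_um[i] <- tbl$z_um[i] + 0.8 * jit[3]
        a <- jit[4:6]; a <- a / sqrt(sum(a^2))
        tbl$axis_x[i] <- a[1]; tbl$axis_y[i] <- a[2]; tbl$axis_z[i] <- a[3]
        next
      }
      if (rel >= 0 && !tl$paclitaxel_mode) {
        tbl$axis_x[i] <- act$ax[k]; tbl$axis_y[i] <- act$ay[k]
        tbl$axis_z[i] <- act$az[k]
      }
      if (rel >= n_mit) {
        # daughters only after anaphase
        drop_rows <- c(drop_rows, i)
        off <- 5.5 * c(tbl$axis_x[i], tbl$axis_y[i], tbl$axis_z[i])
        for (s in c(1, -1)) {
          add_rows <- rbind(add_rows, data.frame(
            id = if (s > 0) act$d1[k] else act$d2[k],
            x_um = tbl$x_um[i] + s * off[1], y_um = tbl$y_um[i] + s * off[2],
            z_um = tbl$z_um[i] + s * off[3],
            shape = "interphase", amp = 0.5,
            axis_x = tbl$axis_x[i], axis_y = tbl$axis_y[i],
            axis_z = tbl$axis_z[i], sep_um = 0, labeled = TRUE,
            state = "daughter", stringsAsFactors = FALSE))
        }
        next
      }
      pp <- phase_plan(n_mit)
      tbl$amp[i] <- 0.5 * optics$mitotic_gain
      if (rel < pp["condensed"]) {
        tbl$shape[i] <- "condensed"; tbl$state[i] <- "condensed"
      } else if (rel < pp["condensed"] + pp["metaphase"]) {
        tbl$shape[i] <- "metaphase"; tbl$state[i] <- "metaphase"
      } else {
        prog <- (rel - pp["condensed"] - pp["metaphase"] + 1) / pp["anaphase"]
        tbl$shape[i] <- "anaphase"; tbl$state[i] <- "anaphase"
        tbl$sep_um[i] <- 1 + 5 * prog
      }
    }
    if (length(drop_rows)) tbl <- tbl[-drop_rows, , drop = FALSE]
    if (!is.null(add_rows)) tbl <- rbind(tbl, add_rows)

    rtbl <- tbl[tbl$labeled, , drop = FALSE]
    arr <- render_core(rtbl, dims, vs, truth$center_um,
                       truth$spheroid_radius_um, scene$nucleus_radius_um,
                       optics, seed = tl$seed + 1000L * t, noise = noise)
    clean <- image_volume(arr, vs)
    if (!is.null(stripes)) {
      sf <- make_stripe_field(dims, stripes, vs, seed = tl$seed + 1000L * t + 500L)
      frames[[t + 1]] <- corrupt_volume(clean, sf)
      stripe_fields[[t + 1]] <- sf$b
    } else {
      frames[[t + 1]] <- clean
    }
    clean_frames[[t + 1]] <- clean
    per_frame[[t + 1]] <- data.frame(frame = t, id = tbl$id, x_um = tbl$x_um,
                                     y_um = tbl$y_um, z_um = tbl$z_um,
                                     state = tbl$state, labeled = tbl$labeled,
                                     stringsAsFactors = FALSE)
  }

  structure(list(frames = frames, clean_frames = clean_frames,
                 stripe_fields = stripe_fields,
                 truth = truth,
                 per_frame = do.call(rbind, per_frame),
                 drift_um = drift_um,
                 events = ev, n_mitotic_frames = n_mit,
                 scene = scene, optics = optics, stripes = stripes, tl = tl),
            class = "timelapse_truth")
}
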