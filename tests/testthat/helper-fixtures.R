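# shared fixtures, built once per test run

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, force(expr), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# fast small spheroid scene shared by several files
tiny_sim <- function() fixture("tiny_sim", {
  simulate_scene(scene_preset("tiny", seed = 3))
})

# quiet optics: no attenuation, no depth blur growth, no noise
optics_quiet <- function(...) {
  args <- list(attenuation_length_um = Inf, blur_sigma0_um = 0,
               blur_growth_per_um = 0, photon_scale = Inf, read_noise_sd = 0)
  do.call(optics_spec, utils::modifyList(args, list(...)))
}

# moderate-density dynamics scene (divisions resolvable by the tracker)
dyn_scene <- function(seed, ...) {
  scene_spec(spheroid_radius_um = 20, volume_shape_vox = c(88, 88, 56),
             n_nuclei = 20, min_separation_um = 11, rim_thickness_um = 12,
             labeled_fraction = 1, mitotic_fraction = 0, margin_um = 4,
             seed = seed, ...)
}

# detect -> measure -> classify one frame
analyze_frame <- function(vol) {
  classify_mitotic(segment_and_measure(vol, detect_nuclei(vol)))
}

# independent ROF oracle: Chambolle's projection algorithm (dual fixed
# point) for min_u TV(u) + (alpha/2) ||u - f||^2, same forward-difference
# Neumann discretization as the solver under test
chambolle_rof <- function(f, alpha, n_iter = 3000, tau = 0.24) {
  lam <- 1 / alpha
  ny <- nrow(f); nx <- ncol(f)
  p1 <- matrix(0, ny, nx); p2 <- matrix(0, ny, nx)
  divp <- matrix(0, ny, nx)
  for (it in seq_len(n_iter)) {
    w <- divp - f / lam
    gx <- cbind(w[, -1] - w[, -nx], rep(0, ny))
    gy <- rbind(w[-1, ] - w[-ny, ], rep(0, nx))
    den <- 1 + tau * sqrt(gx^2 + gy^2)
    p1 <- (p1 + tau * gx) / den
    p2 <- (p2 + tau * gy) / den
    # divergence consistent with the forward-difference gradient
    d1 <- p1; d1[, 2:nx] <- p1[, 2:nx] - p1[, 1:(nx - 1)]; d1[, nx] <- -p1[, nx - 1]
    d2 <- p2; d2[2:ny, ] <- p2[2:ny, ] - p2[1:(ny - 1), ]; d2[ny, ] <- -p2[ny - 1, ]
    divp <- d1 + d2
  }
  f - lam * divp
}


# full desk-scale evaluation shared by several acceptance checks; only
# summary quantities and the detection table are retained (the raw volumes
# are hundreds of MB over three seeds)
desk_eval <- function(seed) fixture(paste0("desk_", seed), {
  sim <- simulate_scene(scene_spec(seed = seed))
  dv <- destripe_volume(sim$corrupted)
  det <- classify_mitotic(segment_and_measure(dv$clean, detect_nuclei(dv$clean)))
  attr(det, "labels") <- NULL
  out <- list(
    psnr_gain = psnr(unclass(dv$clean), unclass(sim$clean)) -
                psnr(unclass(sim$corrupted), unclass(sim$clean)),
    stripe_corr = cor(as.numeric(dv$noise), as.numeric(sim$stripe_field$b)),
    decomp_rel = max(abs((as.numeric(dv$clean) + as.numeric(dv$noise)) -
                         as.numeric(sim$corrupted))) /
                 max(abs(as.numeric(sim$corrupted))),
    traces = dv$objective_trace[c(1, 64, 128)],
    det = det,
    truth = sim$truth)
  rm(sim, dv); gc(FALSE)
  out
})

# one dynamics arm: movie -> destripe -> detect -> track -> events
run_dynamics_arm <- function(seed, paclitaxel, n_frames = 20) {
  sc <- dyn_scene(seed)
  tr <- place_nuclei(sc)
  ids <- suggest_division_ids(tr, sc, n = 3)
  ev <- if (paclitaxel) data.frame(id = ids, entry_frame = c(0, 0, 0))
        else data.frame(id = ids, entry_frame = c(1, 2, 4))
  tl <- timelapse_spec(n_frames = n_frames, division_events = ev,
                       paclitaxel_mode = paclitaxel, seed = seed)
  mv <- render_timelapse(sc, optics_spec(), stripe_spec(), tl, truth = tr)
  mv$clean_frames <- NULL; mv$stripe_fields <- NULL
  # 35 iterations suppress the stripes well below the detection threshold;
  # full convergence buys nothing downstream at several times the cost
  m35 <- stripe_model(max_iter = 35L, tol = 1e-9)
  dets <- lapply(seq_along(mv$frames), function(t) {
    d <- analyze_frame(suppressWarnings(destripe_volume(mv$frames[[t]], m35))$clean)
    attr(d, "labels") <- NULL
    mv$frames[t] <<- list(NULL)
    d
  })
  trs <- link_tracks(dets)
  events <- extract_mitotic_events(trs, tl$frame_interval_min,
                                   n_frames = n_frames)
  for (i in seq_len(nrow(events)))
    events$aligned[i] <- alignment_score(events[i, ], trs, dets)$aligned
  out <- list(tracks = trs, events = events, ids = ids,
              nuclei = mv$truth$nuclei,
              true_duration_min = mv$n_mitotic_frames * tl$frame_interval_min)
  rm(mv, dets); gc(FALSE)
  out
}

# match measured events to the movie's true division events by entry
# position; returns measured duration per true event (NA when unmatched)
match_event_durations <- function(arm) {
  nuc <- arm$nuclei
  out <- data.frame(id = arm$ids,
                    true_duration = arm$true_duration_min,
                    measured = NA_real_)
  for (j in seq_along(arm$ids)) {
    p <- nuc[nuc$id == arm$ids[j], ]
    best <- Inf; bestdur <- NA
    for (i in seq_len(nrow(arm$events))) {
      e <- arm$events[i, ]
      r <- arm$tracks$tracks[[e$track_id]]
      row <- which(r$frame == e$entry_frame)
      if (!length(row)) next
      d2 <- (r$x_um[row] - p$x_um)^2 + (r$y_um[row] - p$y_um)^2 +
            (r$z_um[row] - p$z_um)^2
      if (d2 < best && d2 <= 8^2) { best <- d2; bestdur <- e$duration_min }
    }
    out$measured[j] <- bestdur
  }
  out
}

reg_pair <- function(shift_vox = c(0, 0, 0), seed = 12) {
  fixture(paste0("reg_pair_", paste(shift_vox, collapse = "_"), "_", seed), {
    sc <- scene_spec(spheroid_radius_um = 16, volume_shape_vox = c(72, 72, 48),
                     n_nuclei = 20, margin_um = 4, rim_thickness_um = 10,
                     labeled_fraction = 1, seed = seed)
    truth <- place_nuclei(sc)
    opt <- optics_spec(attenuation_length_um = 60, read_noise_sd = 0.005)
    list(scene = sc, truth = truth, optics = opt,
         views = render_opposing_views(truth, sc, opt, shift_vox = shift_vox))
  })
}

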