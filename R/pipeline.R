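# Reproducible pipeline driver: one flat config (YAML or list) validated
# up front, fixed stage order simulate -> destripe -> driftcorrect ->
# detect -> track -> report, a JSON manifest linking every artifact.

config_schema <- function() list(
  seed = NULL, out_dir = NULL, frame_interval_min = NULL,
  voxel_size_um = NULL,
  stages = list(simulate = NULL, destripe = NULL, driftcorrect = NULL,
                detect = NULL, track = NULL, report = NULL),
  simulate = list(preset = NULL, scene = NA, optics = NA, stripes = NA,
                  timelapse = NA, arms = NA),
  destripe = list(sigma_along_um = NULL, sigma_across_um = NULL, alpha = NULL,
                  prior = NULL, max_iter = NULL, tol = NULL),
  driftcorrect = list(reference = NULL),
  detect = list(min_radius_um = NULL, max_radius_um = NULL, n_scales = NULL,
                response_threshold = NULL, min_separation_um = NULL,
                intensity_threshold = NULL, elong_threshold = NULL,
                volume_fraction = NULL),
  track = list(gate_um = NULL, max_gap = NULL, arrest_threshold_min = NULL))

check_keys <- function(cfg, schema, path = "") {
  for (nm in names(cfg)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(schema))
      stopf("pipeline config: unknown key `%s`", here)
    sub <- schema[[nm]]
    if (is.list(sub) && !identical(sub, NA) && is.list(cfg[[nm]]))
      check_keys(cfg[[nm]], sub, here)
  }
  invisible(TRUE)
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and materializes every stage's parameter object so
#' contract violations surface before any computation starts.
#'
#' @param config a named list or a YAML file path.
#' @return the normalized config (invisibly usable by [run_pipeline()]).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("pipeline config must be a list or YAML file")
  schema <- config_schema()
  # `simulate.scene` etc. hold free-form constructor arguments; only check
  # them by constructing the spec objects below
  check_keys(config[setdiff(names(config), character(0))], schema)

  defaults <- list(seed = 1L, out_dir = "spimpipe_out", frame_interval_min = 3,
                   stages = list(simulate = TRUE, destripe = TRUE,
                                 driftcorrect = FALSE, detect = TRUE,
                                 track = TRUE, report = TRUE))
  config <- utils::modifyList(defaults, config)

  sim <- config$simulate
  scene_args <- if (!is.null(sim$scene)) sim$scene else list()
  config$.scene <- do.call(scene_spec, c(scene_args, list(seed = config$seed)))
  config$.optics <- do.call(optics_spec, if (!is.null(sim$optics)) sim$optics else list())
  config$.stripes <- do.call(stripe_spec, if (!is.null(sim$stripes)) sim$stripes else list())

  arms <- sim$arms
  if (is.null(arms)) arms <- list(main = if (!is.null(sim$timelapse)) sim$timelapse else list())
  config$.arms <- lapply(seq_along(arms), function(i) {
    a <- arms[[i]]
    if (!is.null(a$division_events)) a$division_events <- as.data.frame(a$division_events)
    do.call(timelapse_spec,
            utils::modifyList(list(frame_interval_min = config$frame_interval_min,
                                   seed = config$seed + 17L * i), a))
  })
  names(config$.arms) <- names(arms)

  dz <- config$destripe
  psi <- default_psi(
    sigma_along_um = if (!is.null(dz$sigma_along_um)) dz$sigma_along_um else 15,
    sigma_across_um = if (!is.null(dz$sigma_across_um)) dz$sigma_across_um else 0.8,
    voxel_size_um = config$.scene$voxel_size_um)
  config$.model <- stripe_model(
    psi = psi,
    alpha = if (!is.null(dz$alpha)) dz$alpha else 1,
    prior = if (!is.null(dz$prior)) dz$prior else "l1",
    max_iter = if (!is.null(dz$max_iter)) dz$max_iter else 500L,
    tol = if (!is.null(dz$tol)) dz$tol else 3e-4)

  de <- config$detect
  if (!is.list(de)) de <- list()
  config$detect <- de
  config$.params <- do.call(detect_params,
    de[intersect(names(de), c("min_radius_um", "max_radius_um", "n_scales",
                              "response_threshold", "min_separation_um"))])
  config
}

#' Run the pipeline
#'
#' Executes the enabled stages in fixed order on each simulated arm:
#' simulate -> destripe -> driftcorrect -> detect -> track; a final report
#' stage compares the first two arms.  Every stage writes its outputs under
#' `out_dir` plus a log with parameters, seed and wall time; a JSON manifest
#' links all artifacts.  Fully deterministic given (config, seed).
#'
#' @param config a config list or YAML path (see [validate_config()]).
#' @param out_dir output directory (overrides the config entry).
#' @return the manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]
  logf <- file.path(cfg$out_dir, "log.txt")
  cat(sprintf("spimpipe run, seed %d\n", cfg$seed), file = logf)
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("spimpipe")),
                   stages = cfg$stages, artifacts = list())

  arm_events <- list()
  for (an in names(cfg$.arms)) {
    tl <- cfg$.arms[[an]]
    log_line("arm %s: simulate (%d frames, paclitaxel=%s)", an, tl$n_frames,
             tl$paclitaxel_mode)
    movie <- render_timelapse(cfg$.scene, cfg$.optics, cfg$.stripes, tl)
    frames <- movie$frames

    if (isTRUE(cfg$stages$destripe)) {
      log_line("arm %s: destripe (alpha=%g, prior=%s)", an, cfg$.model$alpha,
               cfg$.model$prior)
      frames <- lapply(frames, function(f) destripe_volume(f, cfg$.model)$clean)
    }
    if (isTRUE(cfg$stages$driftcorrect) && length(frames) >= 2) {
      ref <- if (!is.null(cfg$driftcorrect$reference)) cfg$driftcorrect$reference else "first"
      log_line("arm %s: driftcorrect (reference=%s)", an, ref)
      dc <- correct_drift(frames, reference = ref)
      frames <- dc$frames
      utils::write.csv(dc$shifts,
                       file.path(cfg$out_dir, sprintf("shifts_%s.csv", an)),
                       row.names = FALSE)
      manifest$artifacts[[sprintf("shifts_%s", an)]] <- sprintf("shifts_%s.csv", an)
    }

    dets <- NULL
    if (isTRUE(cfg$stages$detect)) {
      log_line("arm %s: detect", an)
      de <- cfg$detect
      dets <- lapply(frames, function(f) {
        d <- detect_nuclei(f, cfg$.params)
        d <- segment_and_measure(f, d)
        classify_mitotic(d,
          intensity_threshold = if (!is.null(de$intensity_threshold)) de$intensity_threshold else 1.6,
          elong_threshold = if (!is.null(de$elong_threshold)) de$elong_threshold else 1.8,
          volume_fraction = if (!is.null(de$volume_fraction)) de$volume_fraction else 0.6)
      })
      all_det <- do.call(rbind, lapply(seq_along(dets), function(t) {
        d <- as.data.frame(dets[[t]])
        if (nrow(d)) cbind(frame = t - 1L, d) else NULL
      }))
      cols <- c("frame", "id", "x_um", "y_um", "z_um", "volume_um3",
                "mean_intensity", "background_ratio", "elongation", "klass")
      det_file <- sprintf("detections_%s.csv", an)
      utils::write.csv(all_det[, intersect(cols, names(all_det)), drop = FALSE],
                       file.path(cfg$out_dir, det_file), row.names = FALSE)
      manifest$artifacts[[sprintf("detections_%s", an)]] <- det_file
    }

    if (isTRUE(cfg$stages$track) && !is.null(dets)) {
      tk <- cfg$track
      log_line("arm %s: track", an)
      trs <- link_tracks(dets,
        gate_um = if (!is.null(tk$gate_um)) tk$gate_um else 10,
        max_gap = if (!is.null(tk$max_gap)) tk$max_gap else 1L)
      ev <- extract_mitotic_events(trs, cfg$frame_interval_min,
        arrest_threshold_min = if (!is.null(tk$arrest_threshold_min)) tk$arrest_threshold_min else 60,
        n_frames = tl$n_frames)
      for (i in seq_len(nrow(ev))) {
        al <- alignment_score(ev[i, ], trs, dets)
        ev$aligned[i] <- al$aligned
      }
      ev_file <- sprintf("events_%s.csv", an)
      utils::write.csv(as.data.frame(ev), file.path(cfg$out_dir, ev_file),
                       row.names = FALSE)
      manifest$artifacts[[sprintf("events_%s", an)]] <- ev_file
      arm_events[[an]] <- ev
    }
  }

  if (isTRUE(cfg$stages$report) && length(arm_events) >= 2) {
    log_line("report: comparing %s vs %s", names(arm_events)[1], names(arm_events)[2])
    cmp <- compare_conditions(arm_events[[1]], arm_events[[2]])
    jsonlite::write_json(unclass(cmp), file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest$artifacts$report <- "report.json"
  }

  manifest$wall_time_s <- unname(proc.time()[3] - t0)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_line("done in %.1f s", manifest$wall_time_s)
  invisible(manifest)
}
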