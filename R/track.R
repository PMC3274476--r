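# Linking detections over time, delimiting mitotic events, measuring
# mitotic duration, scoring drug-induced arrest.

#' Link detections across frames into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment under a distance gate,
#' ties broken by smallest distance then smallest detection id; unmatched
#' detections start new tracks; gaps up to `max_gap` frames are bridged.
#' When a mitotic track ends and two new tracks begin within the gate, they
#' are linked as daughters (geometric division detection).
#'
#' @param per_frame_detections list of detection frames (classified), in
#'   frame order (frame 0 first); each needs `id`, `x_um`, `y_um`, `z_um`
#'   and (for event extraction) `klass`.
#' @param gate_um assignment gate (default 10 um).
#' @param max_gap maximum bridged gap in frames (default 1).
#' @return a `tracks` object: list of per-track data frames (`frame`,
#'   `det_id`, `x_um`, `y_um`, `z_um`, `klass`) plus a `parent` vector.
#' @export
link_tracks <- function(per_frame_detections, gate_um = 10, max_gap = 1L) {
  nf <- length(per_frame_detections)
  if (nf < 1) stopf("link_tracks: no frames")
  for (t in seq_len(nf)) {
    ids <- per_frame_detections[[t]]$id
    if (anyDuplicated(ids))
      stopf("link_tracks: duplicate detection ids within frame %d", t - 1L)
  }

  tracks <- list()     # each: data.frame rows
  open <- integer(0)   # indices of open tracks
  last_frame <- numeric(0)

  row_of <- function(det, i, t, klass) {
    data.frame(frame = t, det_id = det$id[i], x_um = det$x_um[i],
               y_um = det$y_um[i], z_um = det$z_um[i],
               klass = klass, stringsAsFactors = FALSE)
  }

  for (t in seq_len(nf) - 1L) {
    det <- per_frame_detections[[t + 1]]
    kl <- if ("klass" %in% names(det)) det$klass else rep(NA_character_, nrow(det))
    nd <- nrow(det)
    cand_tracks <- open[last_frame[open] >= t - 1L - max_gap]
    assigned_det <- logical(nd)
    assigned_trk <- setdiff(open, open)  # empty int

    if (length(cand_tracks) && nd) {
      lp <- t(vapply(cand_tracks, function(k) {
        r <- tracks[[k]]
        c(r$x_um[nrow(r)], r$y_um[nrow(r)], r$z_um[nrow(r)])
      }, numeric(3)))
      D2 <- outer(lp[, 1], det$x_um, "-")^2 + outer(lp[, 2], det$y_um, "-")^2 +
            outer(lp[, 3], det$z_um, "-")^2
      ok <- which(D2 <= gate_um^2, arr.ind = TRUE)
      if (nrow(ok)) {
        ord <- order(D2[ok], det$id[ok[, 2]])
        ok <- ok[ord, , drop = FALSE]
        used_k <- logical(length(cand_tracks))
        for (r in seq_len(nrow(ok))) {
          ki <- ok[r, 1]; di <- ok[r, 2]
          if (used_k[ki] || assigned_det[di]) next
          used_k[ki] <- TRUE; assigned_det[di] <- TRUE
          k <- cand_tracks[ki]
          tracks[[k]] <- rbind(tracks[[k]], row_of(det, di, t, kl[di]))
          last_frame[k] <- t
        }
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <- row_of(det, di, t, kl[di])
      last_frame[length(tracks)] <- t
      open <- c(open, length(tracks))
    }
    if (nd == 0 && !length(tracks)) next
    open <- which(last_frame >= t - max_gap)
  }

  # Division detection.  Greedy linking continues a dividing cell into its
  # nearest daughter, so a division shows up as (a) a mitotic->interphase
  # transition inside one track and (b) one new interphase track starting
  # alongside it within the gate.  Split the parent at the transition: the
  # interphase tail and the new track become the two daughters.
  parent <- rep(NA_integer_, length(tracks))
  n_orig <- length(tracks)
  starts <- vapply(tracks, function(r) r$frame[1], numeric(1))
  for (k in seq_len(n_orig)) {
    r <- tracks[[k]]
    if (nrow(r) < 3) next
    mit <- !is.na(r$klass) & r$klass == "mitotic"
    trans <- which(mit[-nrow(r)] & !is.na(r$klass[-1]) & r$klass[-1] == "interphase")
    for (i in trans) {
      # require a genuine mitotic run (>= 2 frames) ending at row i
      run <- i
      while (run > 1 && mit[run - 1]) run <- run - 1
      if (i - run + 1 < 2) next
      f <- r$frame[i]
      lp <- c(r$x_um[i], r$y_um[i], r$z_um[i])
      cand <- which(starts > f & starts <= r$frame[i + 1] + max_gap &
                    seq_along(tracks) != k & is.na(parent))
      if (!length(cand)) next
      d2 <- vapply(cand, function(j) {
        s <- tracks[[j]]
        (s$x_um[1] - lp[1])^2 + (s$y_um[1] - lp[2])^2 + (s$z_um[1] - lp[3])^2
      }, numeric(1))
      okc <- vapply(cand, function(j) {
        kk <- tracks[[j]]$klass[1]
        !is.na(kk) && kk == "interphase"
      }, logical(1))
      keep2 <- okc & d2 <= gate_um^2
      cand <- cand[keep2]; d2 <- d2[keep2]
      if (!length(cand)) next
      sib <- cand[which.min(d2)]
      # split: interphase tail becomes one daughter, the new track the other
      tail_rows <- r[(i + 1):nrow(r), , drop = FALSE]
      tracks[[k]] <- r[1:i, , drop = FALSE]
      tracks[[length(tracks) + 1]] <- tail_rows
      parent <- c(parent, k)
      starts <- c(starts, tail_rows$frame[1])
      parent[sib] <- k
      break   # one division per track
    }
  }

  structure(list(tracks = tracks, parent = parent),
            class = "tracks")
}

#' @export
print.tracks <- function(x, ...) {
  cat(sprintf("<tracks> %d tracks, %d daughter links\n",
              length(x$tracks), sum(!is.na(x$parent))))
  invisible(x)
}

#' Extract mitotic events from tracks
#'
#' An event is a maximal run of mitotic classification in a track (runs
#' shorter than 2 frames are discarded as flicker).  Exit is the first
#' subsequent frame with daughters, or the reversion to interphase
#' (`completed`); a run reaching movie end is `censored` unless its observed
#' duration reaches `arrest_threshold_min`, then `arrested`.  Completed
#' durations are `(exit - entry) * interval`; censored/arrested durations
#' are the observed mitotic occupancy `(last - entry + 1) * interval`.
#'
#' @param tracks a [link_tracks()] result.
#' @param frame_interval_min frame interval, minutes (required).
#' @param arrest_threshold_min arrest horizon (default 60 min).
#' @param n_frames movie length in frames; defaults to the last observed
#'   frame + 1.
#' @return a `mitotic_events` data frame: `track_id`, `entry_frame`,
#'   `exit_frame`, `duration_min`, `outcome`, `aligned`,
#'   `daughter_track_ids`.
#' @export
extract_mitotic_events <- function(tracks, frame_interval_min,
                                   arrest_threshold_min = 60,
                                   n_frames = NULL) {
  if (missing(frame_interval_min) || is.null(frame_interval_min) ||
      !is_scalar_num(frame_interval_min) || frame_interval_min <= 0)
    stopf("extract_mitotic_events: frame_interval_min is required and must be > 0")
  stopifnot(inherits(tracks, "tracks"))
  trs <- tracks$tracks
  if (is.null(n_frames))
    n_frames <- if (length(trs))
      max(vapply(trs, function(r) r$frame[nrow(r)], numeric(1))) + 1 else 0

  out <- NULL
  for (k in seq_along(trs)) {
    r <- trs[[k]]
    mit <- !is.na(r$klass) & r$klass == "mitotic"
    if (!any(mit)) next
    # single-frame interphase interruptions inside a mitotic run are
    # classification flicker too: bridge them before run extraction
    if (nrow(r) >= 3) {
      mid <- 2:(nrow(r) - 1)
      bridge <- mid[!mit[mid] & mit[mid - 1] & mit[mid + 1]]
      mit[bridge] <- TRUE
    }
    rl <- rle(mit)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    kids <- which(!is.na(tracks$parent) & tracks$parent == k)
    kid_birth <- if (length(kids))
      min(vapply(kids, function(j) trs[[j]]$frame[1], numeric(1))) else NA

    for (seg in which(rl$values)) {
      if (rl$lengths[seg] < 2) next   # flicker
      i0 <- starts[seg]; i1 <- ends[seg]
      entry <- r$frame[i0]; last <- r$frame[i1]
      is_tail <- i1 == nrow(r)
      if (is_tail && length(kids) && !is.na(kid_birth)) {
        exit <- kid_birth
        outcome <- "completed"
        dur <- (exit - entry) * frame_interval_min
      } else if (!is_tail) {
        exit <- r$frame[i1 + 1]
        outcome <- "completed"
        dur <- (exit - entry) * frame_interval_min
      } else {
        exit <- NA
        dur <- (last - entry + 1) * frame_interval_min
        outcome <- if (dur >= arrest_threshold_min) "arrested" else "censored"
      }
      out <- rbind(out, data.frame(
        track_id = k, entry_frame = entry, exit_frame = exit,
        duration_min = dur, outcome = outcome, aligned = NA,
        daughter_track_ids = if (length(kids)) paste(kids, collapse = ";") else "",
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(track_id = integer(0), entry_frame = numeric(0),
                      exit_frame = numeric(0), duration_min = numeric(0),
                      outcome = character(0), aligned = logical(0),
                      daughter_track_ids = character(0))
  attr(out, "frame_interval_min") <- frame_interval_min
  attr(out, "arrest_threshold_min") <- arrest_threshold_min
  attr(out, "n_frames") <- n_frames
  class(out) <- c("mitotic_events", "data.frame")
  out
}

#' Metaphase-plate alignment of one event
#'
#' For each mitotic frame of the event the planarity of the chromosome mass
#' is the smallest-to-middle eigenvalue ratio of its second-moment tensor
#' (a flat plate has one collapsed axis, ratio << 1; spheres and prolate
#' condensed masses have ratio near 1).  The event is `aligned` when the
#' ratio drops below `plate_threshold` for at least 2 consecutive frames;
#' the score is the minimum ratio observed.
#'
#' @param event one row of a `mitotic_events` frame.
#' @param tracks the [link_tracks()] result the event came from.
#' @param per_frame_detections measured detection frames (with `eig2`,
#'   `eig3` moment columns).
#' @param plate_threshold ratio threshold (default 0.35).
#' @return list: `aligned`, `score`, `censored` (TRUE when too few frames
#'   carry usable moments).
#' @export
alignment_score <- function(event, tracks, per_frame_detections,
                            plate_threshold = 0.35) {
  r <- tracks$tracks[[event$track_id]]
  lastf <- if (is.na(event$exit_frame)) r$frame[nrow(r)] else event$exit_frame - 1
  sel <- r$frame >= event$entry_frame & r$frame <= lastf
  ratios <- rep(NA_real_, sum(sel))
  rows <- which(sel)
  for (j in seq_along(rows)) {
    fr <- r$frame[rows[j]]; did <- r$det_id[rows[j]]
    det <- per_frame_detections[[fr + 1]]
    i <- match(did, det$id)
    if (!is.na(i) && !is.null(det$eig2) && !is.na(det$eig2[i]) && det$eig2[i] > 0)
      ratios[j] <- det$eig3[i] / det$eig2[i]
  }
  usable <- !is.na(ratios)
  if (sum(usable) < 2)
    return(list(aligned = NA, score = NA_real_, censored = TRUE))
  below <- !is.na(ratios) & ratios < plate_threshold
  rl <- rle(below)
  aligned <- any(rl$values & rl$lengths >= 2)
  list(aligned = aligned, score = min(ratios, na.rm = TRUE), censored = FALSE)
}

#' Compare mitotic dynamics between two conditions
#'
#' Reports per-arm event counts, median completed duration (censored events
#' reported separately, as observed lower bounds), arrested and aligned
#' fractions, and a rank-based two-sample (Wilcoxon) statistic on observed
#' durations.
#'
#' @param events_control,events_treated `mitotic_events` frames (>= 1 event
#'   each).
#' @return a `condition_comparison` list, JSON-serializable.
#' @export
compare_conditions <- function(events_control, events_treated) {
  if (nrow(events_control) == 0 || nrow(events_treated) == 0)
    stopf("compare_conditions: both arms need at least one event")
  arm <- function(e) {
    comp <- e$outcome == "completed"
    cens <- e$outcome == "censored"
    arr <- e$outcome == "arrested"
    list(n_events = nrow(e),
         n_completed = sum(comp), n_arrested = sum(arr), n_censored = sum(cens),
         median_duration_completed_min =
           if (any(comp)) stats::median(e$duration_min[comp]) else NA,
         median_duration_observed_min = stats::median(e$duration_min),
         duration_is_lower_bound = !any(comp) && any(cens | arr),
         arrested_fraction = mean(arr),
         aligned_fraction = if (any(!is.na(e$aligned))) mean(e$aligned, na.rm = TRUE) else NA)
  }
  wt <- suppressWarnings(stats::wilcox.test(events_control$duration_min,
                                            events_treated$duration_min))
  structure(list(control = arm(events_control), treated = arm(events_treated),
                 arrested_fraction_difference =
                   mean(events_treated$outcome == "arrested") -
                   mean(events_control$outcome == "arrested"),
                 rank_test = list(statistic = unname(wt$statistic),
                                  p_value = wt$p.value)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  f <- function(a, nm) sprintf(
    "  %-8s n=%d completed=%d arrested=%d censored=%d median(completed)=%s min arrested_frac=%.2f",
    nm, a$n_events, a$n_completed, a$n_arrested, a$n_censored,
    ifelse(is.na(a$median_duration_completed_min), "NA",
           format(a$median_duration_completed_min)), a$arrested_fraction)
  cat("<condition_comparison>\n", f(x$control, "control"), "\n",
      f(x$treated, "treated"), "\n",
      sprintf("  rank test p = %.4g\n", x$rank_test$p_value), sep = "")
  invisible(x)
}
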