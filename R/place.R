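#' Place nuclei inside a synthetic spheroid
#'
#' Dart-throwing (rejection) placement of nucleus centers uniformly inside
#' the spheroid with a hard minimum separation.  Each nucleus is
#' independently labelled with probability `labeled_fraction`; nuclei whose
#' depth from the surface is at most `rim_thickness_um` are mitotic with
#' probability `mitotic_fraction` (the proliferative outer shell), deeper
#' nuclei never are.  Deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @param max_attempts_per_nucleus rejection budget per nucleus before the
#'   target density is declared infeasible.
#' @return a `scene_truth` object: `$nuclei` data frame (`id`, `x_um`,
#'   `y_um`, `z_um`, `depth_um`, `class`, `labeled`, spindle axis), spheroid
#'   `$center_um` and `$spheroid_radius_um`, and the generating `$spec`.
#' @export
place_nuclei <- function(spec, max_attempts_per_nucleus = 200L) {
  stopifnot(inherits(spec, "scene_spec"))
  R <- spec$spheroid_radius_um
  n <- spec$n_nuclei
  sep2 <- spec$min_separation_um^2
  ctr <- scene_center_um(spec)

  with_seed(spec$seed, {
    pts <- matrix(NA_real_, n, 3)
    placed <- 0L
    attempts <- 0L
    budget <- max_attempts_per_nucleus * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > budget)
        stopf(paste("place_nuclei: placed only %d of %d nuclei after %d attempts;",
                    "the requested density (radius %g um, separation %g um) is infeasible"),
              placed, n, attempts - 1L, R, spec$min_separation_um)
      # uniform point in the ball
      u <- runif(3, -1, 1)
      r2 <- sum(u^2)
      if (r2 > 1 || r2 == 0) next
      p <- ctr + u * R * stats::runif(1)^(1/3) / sqrt(r2)
      # recompute as uniform-in-ball: direction u/|u|, radius R*U^(1/3)
      if (placed > 0L) {
        d2 <- (pts[seq_len(placed), 1] - p[1])^2 +
              (pts[seq_len(placed), 2] - p[2])^2 +
              (pts[seq_len(placed), 3] - p[3])^2
        if (any(d2 < sep2)) next
      }
      placed <- placed + 1L
      pts[placed, ] <- p
    }

    depth <- R - sqrt((pts[, 1] - ctr["x"])^2 + (pts[, 2] - ctr["y"])^2 +
                      (pts[, 3] - ctr["z"])^2)
    labeled <- runif(n) < spec$labeled_fraction
    in_rim <- depth <= spec$rim_thickness_um
    mitotic <- in_rim & (runif(n) < spec$mitotic_fraction)
    # spindle orientation, fixed per nucleus (used when rendered mitotic)
    ax <- matrix(rnorm(3 * n), n, 3)
    ax <- ax / sqrt(rowSums(ax^2))

    nuclei <- data.frame(
      id = seq_len(n),
      x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
      depth_um = depth,
      class = ifelse(mitotic, "mitotic", "interphase"),
      labeled = labeled,
      axis_x = ax[, 1], axis_y = ax[, 2], axis_z = ax[, 3],
      stringsAsFactors = FALSE)

    structure(list(nuclei = nuclei,
                   center_um = ctr,
                   spheroid_radius_um = R,
                   spec = spec),
              class = "scene_truth")
  })
}

#' Construct a scene truth by hand
#'
#' Builds a `scene_truth` from an explicit nucleus table, for controlled
#' experiments (two-nucleus attenuation probes and the like).
#'
#' @param nuclei data frame with `x_um`, `y_um`, `z_um` and optionally
#'   `class`, `labeled` and spindle axis columns (defaults: interphase,
#'   labelled, axis +x).
#' @param spec the [scene_spec()] providing geometry defaults.
#' @param center_um spheroid center (defaults to the volume center).
#' @param spheroid_radius_um spheroid radius (defaults to the spec's).
#' @return a `scene_truth`.
#' @export
scene_truth <- function(nuclei, spec, center_um = scene_center_um(spec),
                        spheroid_radius_um = spec$spheroid_radius_um) {
  nuclei <- as.data.frame(nuclei)
  n <- nrow(nuclei)
  if (is.null(nuclei$id)) nuclei$id <- seq_len(n)
  if (is.null(nuclei$class)) nuclei$class <- "interphase"
  if (is.null(nuclei$labeled)) nuclei$labeled <- TRUE
  if (is.null(nuclei$axis_x)) { nuclei$axis_x <- 1; nuclei$axis_y <- 0; nuclei$axis_z <- 0 }
  nuclei$depth_um <- spheroid_radius_um -
    sqrt((nuclei$x_um - center_um[["x"]])^2 + (nuclei$y_um - center_um[["y"]])^2 +
         (nuclei$z_um - center_um[["z"]])^2)
  structure(list(nuclei = nuclei, center_um = center_um,
                 spheroid_radius_um = spheroid_radius_um, spec = spec),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  n <- x$nuclei
  cat(sprintf("<scene_truth> %d nuclei (%d labeled, %d mitotic), spheroid radius %g um\n",
              nrow(n), sum(n$labeled), sum(n$class == "mitotic"),
              x$spheroid_radius_um))
  invisible(x)
}

#' Suggest well-separated division candidates
#'
#' Picks up to `n` labelled nuclei in the proliferative rim whose pairwise
#' distances are at least `min_spacing_um` (greedily, deterministic), so
#' that simulated divisions do not run into one another.
#'
#' @param truth a `scene_truth`.
#' @param spec the generating [scene_spec()].
#' @param n number of candidates wanted.
#' @param min_spacing_um minimum pairwise spacing (um); relaxed stepwise if
#'   too few nuclei qualify.
#' @return integer vector of nucleus ids (length <= n).
#' @export
suggest_division_ids <- function(truth, spec, n = 3, min_spacing_um = 25) {
  cand <- truth$nuclei[truth$nuclei$labeled &
                       truth$nuclei$depth_um <= spec$rim_thickness_um, ]
  if (!nrow(cand)) return(integer(0))
  spacing <- min_spacing_um
  repeat {
    chosen <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (!length(chosen)) { chosen <- i; next }
      d2 <- (cand$x_um[chosen] - cand$x_um[i])^2 +
            (cand$y_um[chosen] - cand$y_um[i])^2 +
            (cand$z_um[chosen] - cand$z_um[i])^2
      if (all(d2 >= spacing^2)) chosen <- c(chosen, i)
      if (length(chosen) >= n) break
    }
    if (length(chosen) >= min(n, nrow(cand)) || spacing <= 5) break
    spacing <- spacing - 2.5
  }
  cand$id[chosen]
}
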