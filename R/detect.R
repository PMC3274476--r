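# 3D nucleus detection (multiscale Laplacian-of-Gaussian), marker-based
# watershed feature measurement, mitotic/interphase classification, spheroid
# surface geometry.

#' Detection parameters
#'
#' @param min_radius_um,max_radius_um expected nucleus radius bracket (um).
#' @param n_scales number of LoG scales spanning the bracket.
#' @param response_threshold minimum scale-normalized LoG response, on the
#'   robustly normalized (0.999-quantile-scaled) volume; normalization makes
#'   detection counts invariant under global intensity scaling.
#' @param min_separation_um duplicate-suppression distance (um).
#' @param pre_smooth_um Gaussian pre-smoothing before detection (um).
#' @return a `detect_params` list.
#' @export
detect_params <- function(min_radius_um = 3, max_radius_um = 7, n_scales = 3L,
                          response_threshold = 0.2, min_separation_um = 6,
                          pre_smooth_um = 0.5) {
  check_positive(min_radius_um, "min_radius_um")
  check_positive(max_radius_um, "max_radius_um")
  if (max_radius_um < min_radius_um)
    stopf("max_radius_um must be >= min_radius_um")
  structure(list(min_radius_um = min_radius_um, max_radius_um = max_radius_um,
                 n_scales = as.integer(n_scales),
                 response_threshold = response_threshold,
                 min_separation_um = min_separation_um,
                 pre_smooth_um = pre_smooth_um),
            class = "detect_params")
}

# 3D Laplacian with physical spacing, replicated (Neumann) boundaries
laplacian3 <- function(a, vs) {
  d <- dim(a)
  iy <- c(2:d[1], d[1]); iy0 <- c(1, 1:(d[1] - 1))
  ix <- c(2:d[2], d[2]); ix0 <- c(1, 1:(d[2] - 1))
  iz <- c(2:d[3], d[3]); iz0 <- c(1, 1:(d[3] - 1))
  (a[iy, , ] - 2 * a + a[iy0, , ]) / vs["y"]^2 +
  (a[, ix, ] - 2 * a + a[, ix0, ]) / vs["x"]^2 +
  (a[, , iz] - 2 * a + a[, , iz0]) / vs["z"]^2
}

#' Detect nuclei in a 3D stack
#'
#' Gaussian pre-smoothing, multiscale scale-normalized Laplacian-of-Gaussian
#' blob detection at scales bracketing the expected nucleus radius (blob
#' radius r corresponds to sigma = r/sqrt(3)), 26-neighbourhood local-maxima
#' extraction above a normalized response threshold, and greedy duplicate
#' suppression at the minimum separation.  Anisotropic voxel size is
#' honoured in physical units.
#'
#' @param vol an `image_volume` (voxel-size metadata required).
#' @param params a [detect_params()].
#' @return a `detections` data frame: `id`, `x_um`, `y_um`, `z_um`,
#'   `response`, `radius_um` (feature columns are filled by
#'   [segment_and_measure()]).
#' @export
detect_nuclei <- function(vol, params = detect_params()) {
  if (!inherits(vol, "image_volume"))
    stopf("detect_nuclei: need an image_volume with voxel-size metadata")
  vs <- voxel_size(vol)
  arr <- as_plain_array(vol)
  d <- dim(arr)

  pos <- arr[arr > 0]
  if (!length(pos)) return(empty_detections(vs))
  q <- quantile(pos, 0.999, names = FALSE)
  if (q <= 0) return(empty_detections(vs))
  v <- arr / q
  if (params$pre_smooth_um > 0)
    v <- smooth_gauss3(v, params$pre_smooth_um / vs[c("y", "x", "z")])

  radii <- exp(seq(log(params$min_radius_um), log(params$max_radius_um),
                   length.out = params$n_scales))
  best <- array(-Inf, d); best_r <- array(radii[1], d)
  for (r in radii) {
    s <- r / sqrt(3)
    sm <- smooth_gauss3(v, s / vs[c("y", "x", "z")])
    resp <- -s^2 * laplacian3(sm, vs)
    upd <- resp > best
    best[upd] <- resp[upd]
    best_r[upd] <- r
  }

  idx <- local_maxima3(as.numeric(best), as.integer(d), params$response_threshold)
  if (!length(idx)) return(empty_detections(vs))
  sub <- arrayInd(idx, d)
  det <- data.frame(
    y_um = (sub[, 1] - 1) * vs["y"],
    x_um = (sub[, 2] - 1) * vs["x"],
    z_um = (sub[, 3] - 1) * vs["z"],
    response = best[idx],
    radius_um = best_r[idx])
  det <- det[order(-det$response), , drop = FALSE]

  # greedy duplicate suppression at the minimum separation
  keep <- logical(nrow(det))
  kx <- ky <- kz <- numeric(0)
  sep2 <- params$min_separation_um^2
  for (i in seq_len(nrow(det))) {
    if (length(kx)) {
      d2 <- (kx - det$x_um[i])^2 + (ky - det$y_um[i])^2 + (kz - det$z_um[i])^2
      if (any(d2 < sep2)) next
    }
    keep[i] <- TRUE
    kx <- c(kx, det$x_um[i]); ky <- c(ky, det$y_um[i]); kz <- c(kz, det$z_um[i])
  }
  det <- det[keep, , drop = FALSE]
  det <- det[order(det$z_um, det$x_um, det$y_um), , drop = FALSE]
  det$id <- seq_len(nrow(det))
  rownames(det) <- NULL
  det <- det[, c("id", "x_um", "y_um", "z_um", "response", "radius_um")]
  attr(det, "voxel_size_um") <- vs
  class(det) <- c("detections", "data.frame")
  det
}

empty_detections <- function(vs) {
  det <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                    z_um = numeric(0), response = numeric(0),
                    radius_um = numeric(0))
  attr(det, "voxel_size_um") <- vs
  class(det) <- c("detections", "data.frame")
  det
}

#' Segment detections and measure features
#'
#' Marker-based watershed (priority flood, 6-connectivity) on the smoothed
#' volume seeded at the detections; each region floods down to a fraction of
#' its own seed intensity, which keeps segmentation robust to the
#' illumination-attenuation gradient.  Per label: volume, mean intensity,
#' local background (median in a concentric shell 2-4 detection radii out,
#' outside any label), `background_ratio`, principal-axis `elongation` and
#' `sphericity_proxy` from the background-subtracted second-moment tensor.
#'
#' @param vol the `image_volume` the detections came from.
#' @param detections output of [detect_nuclei()].
#' @param smooth_um smoothing before watershed (um).
#' @param floor_frac per-region flood floor as a fraction of seed intensity.
#' @param shell_radii background shell, in units of the detection radius.
#' @return the detections with feature columns filled (`volume_um3`,
#'   `mean_intensity`, `background`, `background_ratio`, `elongation`,
#'   `sphericity_proxy`, `eig1..3`), with the label volume as attribute
#'   `labels`.
#' @export
segment_and_measure <- function(vol, detections, smooth_um = 1,
                                floor_frac = 0.3, shell_radii = c(2, 4)) {
  if (!inherits(detections, "detections"))
    stopf("segment_and_measure: `detections` must come from detect_nuclei()")
  if (nrow(detections) == 0) return(detections)
  vs <- voxel_size(vol)
  arr <- as_plain_array(vol)
  d <- dim(arr)
  sm <- smooth_gauss3(arr, smooth_um / vs[c("y", "x", "z")])

  iy <- pmin(pmax(round(detections$y_um / vs["y"]) + 1, 1), d[1])
  ix <- pmin(pmax(round(detections$x_um / vs["x"]) + 1, 1), d[2])
  iz <- pmin(pmax(round(detections$z_um / vs["z"]) + 1, 1), d[3])
  seed_idx <- as.integer(iy + (ix - 1) * d[1] + (iz - 1) * d[1] * d[2])
  floors <- floor_frac * sm[seed_idx]
  labels <- seeded_watershed3(as.numeric(sm), as.integer(d), seed_idx,
                              as.integer(detections$id), floors)

  voxvol <- prod(vs)
  n <- nrow(detections)
  volume <- mean_int <- bg <- elong <- spher <- numeric(n)
  eig <- matrix(NA_real_, n, 3)
  in_label <- labels > 0
  lab_idx <- split(which(in_label), labels[in_label])

  for (i in seq_len(n)) {
    id <- as.character(detections$id[i])
    idx <- lab_idx[[id]]
    if (is.null(idx)) { volume[i] <- 0; next }
    volume[i] <- length(idx) * voxvol
    mean_int[i] <- mean(arr[idx])

    r <- detections$radius_um[i]
    bg[i] <- shell_background(arr, labels, d, vs,
                              c(detections$y_um[i], detections$x_um[i],
                                detections$z_um[i]), r * shell_radii)

    sub <- arrayInd(idx, d)
    py <- (sub[, 1] - 1) * vs["y"]; px <- (sub[, 2] - 1) * vs["x"]
    pz <- (sub[, 3] - 1) * vs["z"]
    # moments from the smoothed, floor-subtracted signal, restricted to the
    # detection's own neighbourhood: occasional label bleed into a missed
    # neighbour otherwise corrupts the shape features
    r_mom <- 2.5 * r
    near <- (px - detections$x_um[i])^2 + (py - detections$y_um[i])^2 +
            (pz - detections$z_um[i])^2 <= r_mom^2
    if (sum(near) >= 4) {
      idx <- idx[near]; px <- px[near]; py <- py[near]; pz <- pz[near]
    }
    w <- pmax(sm[idx] - floors[i], 0) + 1e-12
    w <- w / sum(w)
    cy <- sum(w * py); cx <- sum(w * px); cz <- sum(w * pz)
    dxyz <- cbind(px - cx, py - cy, pz - cz)
    cv <- crossprod(dxyz * sqrt(w))
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 1e-12)
    eig[i, ] <- ev
    elong[i] <- sqrt(ev[1] / ev[3])
    spher[i] <- sqrt(ev[3] / ev[1])
  }

  detections$volume_um3 <- volume
  detections$mean_intensity <- mean_int
  detections$background <- bg
  detections$background_ratio <- ifelse(bg > 0, mean_int / bg, Inf)
  detections$elongation <- elong
  detections$sphericity_proxy <- spher
  detections$eig1 <- eig[, 1]; detections$eig2 <- eig[, 2]; detections$eig3 <- eig[, 3]
  attr(detections, "labels") <- labels
  detections
}

# median intensity in a concentric shell, excluding labelled voxels
shell_background <- function(arr, labels, d, vs, pos_yxz, shell_um) {
  r_out <- shell_um[2]
  iy <- which(abs((seq_len(d[1]) - 1) * vs["y"] - pos_yxz[1]) <= r_out)
  ix <- which(abs((seq_len(d[2]) - 1) * vs["x"] - pos_yxz[2]) <= r_out)
  iz <- which(abs((seq_len(d[3]) - 1) * vs["z"] - pos_yxz[3]) <= r_out)
  dy <- (iy - 1) * vs["y"] - pos_yxz[1]
  dx <- (ix - 1) * vs["x"] - pos_yxz[2]
  dz <- (iz - 1) * vs["z"] - pos_yxz[3]
  ny <- length(iy); nx <- length(ix); nz <- length(iz)
  D2 <- array(rep(dx^2, each = ny), c(ny, nx, nz)) +
        array(dy^2, c(ny, nx, nz)) +
        array(rep(dz^2, each = ny * nx), c(ny, nx, nz))
  box_a <- arr[iy, ix, iz]
  box_l <- labels[iy, ix, iz]
  sel <- D2 >= shell_um[1]^2 & D2 <= r_out^2 & box_l == 0
  if (!any(sel)) sel <- D2 >= shell_um[1]^2 & D2 <= r_out^2
  if (!any(sel)) return(stats::median(box_a))
  stats::median(box_a[sel])
}

#' Classify detections as mitotic or interphase
#'
#' A detection is mitotic iff its intensity over local background reaches
#' `intensity_threshold` AND it is either elongated (condensed-chromosome
#' shape, `elongation >= elong_threshold`) or small (volume below
#' `volume_fraction` of the interphase median volume); otherwise interphase.
#' This operationalizes the visual criteria of high fluorescence intensity
#' plus the condensed-chromosome shape.
#'
#' @param detections measured detections (from [segment_and_measure()]).
#' @param intensity_threshold background-ratio threshold (default 1.6).
#' @param elong_threshold elongation threshold (default 1.8).
#' @param volume_fraction condensed-volume fraction of the interphase median
#'   (default 0.6).
#' @return detections with a `klass` column; the applied rule is recorded in
#'   attribute `classification_rule`.
#' @export
classify_mitotic <- function(detections, intensity_threshold = 1.6,
                             elong_threshold = 1.8, volume_fraction = 0.6) {
  need <- c("background_ratio", "elongation", "volume_um3")
  if (!all(need %in% names(detections)))
    stopf("classify_mitotic: features unfilled; run segment_and_measure() first")
  if (nrow(detections) == 0) { detections$klass <- character(0); return(detections) }
  base <- detections$background_ratio < intensity_threshold
  med_vol <- if (any(base)) stats::median(detections$volume_um3[base])
             else stats::median(detections$volume_um3)
  mit <- detections$background_ratio >= intensity_threshold &
    (detections$elongation >= elong_threshold |
     detections$volume_um3 < volume_fraction * med_vol)
  detections$klass <- ifelse(mit, "mitotic", "interphase")
  attr(detections, "classification_rule") <- sprintf(
    paste("mitotic iff background_ratio >= %.3g AND (elongation >= %.3g OR",
          "volume_um3 < %.3g * interphase median volume [%.4g um^3])"),
    intensity_threshold, elong_threshold, volume_fraction, med_vol)
  detections
}

# quasi-uniform directions (Fibonacci sphere)
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# support-point sphere fit: algebraic (Coope) LS on the directional support
# points, refined by geometric Gauss-Newton
sphere_fit_support <- function(P, dirs) {
  ctr0 <- colMeans(P)
  sup <- unique(apply(dirs %*% t(sweep(P, 2, ctr0)), 1, which.max))
  S <- P[sup, , drop = FALSE]
  A <- cbind(2 * S, 1)                 # ||p||^2 = 2 c.p + (r^2 - ||c||^2)
  sol <- qr.solve(A, rowSums(S^2))
  ctr <- sol[1:3]
  r <- sqrt(max(sol[4] + sum(ctr^2), 0))
  for (it in 1:10) {                   # Gauss-Newton on ||p - c|| - r
    dv <- sweep(S, 2, ctr)
    dist <- sqrt(rowSums(dv^2))
    step <- tryCatch(qr.solve(cbind(-dv / dist, -1), -(dist - r)),
                     error = function(e) rep(0, 4))
    ctr <- ctr + step[1:3]; r <- r + step[4]
    if (sqrt(sum(step^2)) < 1e-10) break
  }
  dv <- sweep(S, 2, ctr)
  res <- sqrt(rowSums(dv^2)) - r
  list(ctr = ctr, r = r, rms = sqrt(mean(res^2)), n_surface = nrow(S))
}

#' Fit the spheroid surface
#'
#' Algebraic least-squares sphere fit to the outer-hull detections (the
#' directional support points of the centroid cloud, a subset of its convex
#' hull vertices), refined by a geometric least-squares pass.  Because
#' nuclei sample the spheroid volume at finite density, the raw support fit
#' underestimates the radius by roughly one inter-nuclear spacing; a
#' Monte-Carlo correction (synthetic clouds with the empirical radial
#' distribution and fresh uniform directions, fixed internal seed) removes
#' this bias.  For points sampled on the surface itself the correction
#' vanishes.  Stray detections far outside the cloud (beyond 1.3x its 90%
#' radial quantile) are excluded before fitting.
#'
#' @param detections at least 10 detections.
#' @param n_directions number of support directions probed.
#' @param bias_correction apply the sampling-bias correction (default TRUE).
#' @return a `spheroid_fit`: `center_um` (x, y, z), `radius_um`,
#'   `rms_residual_um`, `n_surface`.
#' @export
fit_spheroid <- function(detections, n_directions = 300L,
                         bias_correction = TRUE) {
  if (nrow(detections) < 10)
    stopf("fit_spheroid: need at least 10 detections, got %d", nrow(detections))
  P <- cbind(detections$x_um, detections$y_um, detections$z_um)
  # gate stray detections far outside the cloud: a single spurious point
  # outside the spheroid would dominate the support fit and its correction
  r0 <- sqrt(rowSums(sweep(P, 2, colMeans(P))^2))
  keep <- r0 <= 1.3 * stats::quantile(r0, 0.9)
  if (sum(keep) >= 10) P <- P[keep, , drop = FALSE]
  sv <- svd(sweep(P, 2, colMeans(P)), nu = 0, nv = 0)$d
  if (min(sv) < 1e-6 * max(sv))
    stopf("fit_spheroid: degenerate (coplanar) detection configuration")
  dirs <- fib_sphere(n_directions)
  f0 <- sphere_fit_support(P, dirs)
  r <- f0$r
  if (bias_correction) {
    ri <- sqrt(rowSums(sweep(P, 2, f0$ctr)^2))
    n <- nrow(P); B <- 30L
    rb <- with_seed(777L, vapply(seq_len(B), function(b) {
      u <- matrix(rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      sphere_fit_support(u * sample(ri, n, replace = TRUE), dirs)$r
    }, numeric(1)))
    r <- f0$r + (max(ri) - mean(rb))
  }
  structure(list(center_um = stats::setNames(f0$ctr, c("x", "y", "z")),
                 radius_um = r,
                 rms_residual_um = f0$rms,
                 n_surface = f0$n_surface),
            class = "spheroid_fit")
}

#' @export
print.spheroid_fit <- function(x, ...) {
  cat(sprintf("<spheroid_fit> center (%.1f, %.1f, %.1f) um, radius %.2f um, RMS residual %.2f um (%d surface points)\n",
              x$center_um["x"], x$center_um["y"], x$center_um["z"],
              x$radius_um, x$rms_residual_um, x$n_surface))
  invisible(x)
}

#' Depth of each detection from the spheroid surface
#'
#' `depth = radius - ||centroid - center||`; positive inside.  Together with
#' the carried-through z position this situates every mitotic cell by (depth
#' from surface, z).
#'
#' @param detections a detections frame.
#' @param fit a [fit_spheroid()] result.
#' @return detections with `depth_from_surface_um` filled.
#' @export
depth_from_surface <- function(detections, fit) {
  stopifnot(inherits(fit, "spheroid_fit"))
  dd <- sqrt((detections$x_um - fit$center_um["x"])^2 +
             (detections$y_um - fit$center_um["y"])^2 +
             (detections$z_um - fit$center_um["z"])^2)
  detections$depth_from_surface_um <- fit$radius_um - dd
  detections
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching by distance (closest pairs first) within
#' `tol_um`; only labelled truth nuclei are considered visible.
#'
#' @param detections a detections frame.
#' @param truth a `scene_truth` (or a data frame with `x_um`, `y_um`,
#'   `z_um` and optionally `class`, `labeled`).
#' @param tol_um matching tolerance, typically one nucleus radius.
#' @return list: `precision`, `recall`, `f1`, `n_matched`, and the matched
#'   index pairs.
#' @export
score_detections <- function(detections, truth, tol_um) {
  tn <- if (inherits(truth, "scene_truth")) truth$nuclei else as.data.frame(truth)
  if ("labeled" %in% names(tn)) tn <- tn[tn$labeled, , drop = FALSE]
  nd <- nrow(detections); nt <- nrow(tn)
  if (nd == 0 || nt == 0)
    return(list(precision = as.numeric(nd == 0 && nt == 0), recall = as.numeric(nt == 0),
                f1 = 0, n_matched = 0L,
                matches = data.frame(det = integer(0), truth = integer(0))))
  D <- outer(detections$x_um, tn$x_um, "-")^2 +
       outer(detections$y_um, tn$y_um, "-")^2 +
       outer(detections$z_um, tn$z_um, "-")^2
  ok <- which(D <= tol_um^2, arr.ind = TRUE)
  ord <- order(D[ok])
  ok <- ok[ord, , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  md <- mt <- integer(0)
  for (k in seq_len(nrow(ok))) {
    i <- ok[k, 1]; j <- ok[k, 2]
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    md <- c(md, i); mt <- c(mt, j)
  }
  m <- length(md)
  list(precision = m / nd, recall = m / nt,
       f1 = if (m == 0) 0 else 2 * m / (nd + nt), n_matched = m,
       matches = data.frame(det = md, truth = mt))
}

#' Balanced classification accuracy against truth
#'
#' Matches detections to labelled truth nuclei and averages the per-class
#' (mitotic / interphase) recall of the predicted `klass`.
#'
#' @inheritParams score_detections
#' @return list: `balanced_accuracy`, `confusion` table.
#' @export
classification_accuracy <- function(detections, truth, tol_um) {
  sc <- score_detections(detections, truth, tol_um)
  tn <- if (inherits(truth, "scene_truth")) truth$nuclei else as.data.frame(truth)
  if ("labeled" %in% names(tn)) tn <- tn[tn$labeled, , drop = FALSE]
  if (sc$n_matched == 0) return(list(balanced_accuracy = 0, confusion = table(NULL)))
  pred <- detections$klass[sc$matches$det]
  ref <- tn$class[sc$matches$truth]
  conf <- table(truth = ref, predicted = pred)
  classes <- unique(ref)
  recalls <- vapply(classes, function(cl) mean(pred[ref == cl] == cl), numeric(1))
  list(balanced_accuracy = mean(recalls), confusion = conf)
}
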