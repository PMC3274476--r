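# Geometric stages: opposing-view registration, weighted fusion, drift
# compensation.  Translation estimation: whitened, Hann-windowed phase
# correlation locates the integer peak robustly; the subvoxel position is
# then refined by evaluating the raw (unwhitened, unwindowed) correlation
# surface at fractional lags around the peak with a local upsampled DFT.
# Whitening and windowing sharpen localization but bias fractional shifts
# on compact scenes, hence the split.

hann_window3 <- function(d) {
  h <- function(n) if (n == 1) 1 else 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  wy <- h(d[1]); wx <- h(d[2]); wz <- h(d[3])
  array(outer(outer(wy, wx), wz), d)
}

fft_freqs <- function(N) c(0:floor((N - 1) / 2), -(ceiling((N - 1) / 2)):-1)[1:N]

# evaluate Re(IDFT of X) on a fractional-lag grid around integer peak `pk`
# (1-based); returns the refined lag (y, x, z)
refine_peak_updft <- function(X, pk, up = 20L, half = 1) {
  d <- dim(X)
  mats <- lapply(1:3, function(ax) {
    N <- d[ax]
    tau <- (pk[ax] - 1) + seq(-half, half, by = 1 / up)
    list(W = exp(2i * pi * outer(tau, fft_freqs(N)) / N), tau = tau)
  })
  G <- length(mats[[1]]$tau)
  A <- mats[[1]]$W %*% matrix(X, d[1], d[2] * d[3])
  A <- aperm(array(A, c(G, d[2], d[3])), c(2, 1, 3))
  A <- mats[[2]]$W %*% matrix(A, d[2], G * d[3])
  A <- aperm(array(A, c(G, G, d[3])), c(3, 1, 2))
  A <- mats[[3]]$W %*% matrix(A, d[3], G * G)
  r <- Re(array(A, c(G, G, G)))          # [g_z, g_x, g_y]
  ix <- arrayInd(which.max(r), c(G, G, G))[1, ]
  c(mats[[1]]$tau[ix[3]], mats[[2]]$tau[ix[2]], mats[[3]]$tau[ix[1]])
}

# translation (y, x, z; subvoxel) that aligns `b` onto `a`, plus the
# normalized phase-correlation peak value.  The integer peak and its
# fractional refinement use the raw cross-correlation: on compact scenes
# (content clear of the borders) whitening and windowing measurably bias
# the estimate, so they only feed the reported peak score.
phase_correlation <- function(a, b, eps = 1e-6, window = TRUE) {
  a <- as_plain_array(a); b <- as_plain_array(b)
  if (!all(dim(a) == dim(b))) stopf("phase_correlation: shapes differ")
  d <- dim(a)
  FA0 <- stats::fft(a); FB0 <- stats::fft(b)
  X0 <- FA0 * Conj(FB0)
  r0 <- Re(stats::fft(X0, inverse = TRUE)) / length(X0)
  pk <- arrayInd(which.max(r0), d)[1, ]

  # whitened, windowed phase-correlation peak as a sharpness score
  if (window) {
    w <- hann_window3(d)
    FA <- stats::fft(a * w); FB <- stats::fft(b * w)
  } else {
    FA <- FA0; FB <- FB0
  }
  Xw <- FA * Conj(FB)
  Xw <- Xw / (Mod(Xw) + eps)
  rw <- Re(stats::fft(Xw, inverse = TRUE)) / length(Xw)
  score <- max(min(max(rw), 1), 0)

  # peak at index n means b = a shifted by s with n-1 = -s (mod N)
  tau <- refine_peak_updft(X0, pk)
  tau <- ifelse(tau > d / 2, tau - d, tau)
  list(translation_vox = stats::setNames(tau, c("y", "x", "z")),
       score = score)
}

as_plain_array <- function(v) {
  a <- unclass(v)
  attributes(a) <- list(dim = dim(a))
  a
}

# Pearson correlation of the overlap after applying the estimated aligning
# translation: an interpretable [0, 1] reliability score (the whitened
# phase-correlation peak itself is tiny even for perfect alignments)
alignment_quality <- function(ref, moving, t_vox) {
  tr <- translate_trilinear(moving, t_vox)
  m <- tr$inside
  if (sum(m) < 32) return(0)
  a <- ref[m]; b <- tr$data[m]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  max(min(stats::cor(a, b), 1), 0)
}

#' Register opposing 0/180-degree views
#'
#' Applies the fixed 180-degrees-about-the-vertical-axis model (flip x and
#' z), then estimates the residual translation by 3D phase correlation with
#' subvoxel parabolic peak refinement.  The reliability score is the
#' Pearson correlation of the two views over their aligned overlap.
#'
#' @param view0,view180 `image_volume`s with the same voxel size.
#' @param score_floor registrations whose score falls below this floor are
#'   rejected as unreliable (default 0.05).
#' @return a `rigid_shift`: `flip_axes`, `translation_vox` (y, x, z) and
#'   `score`.
#' @export
register_opposing <- function(view0, view180, score_floor = 0.05) {
  if (!all(dim(view0) == dim(view180)))
    stopf("register_opposing: views differ in shape")
  if (inherits(view0, "image_volume") && inherits(view180, "image_volume") &&
      any(abs(voxel_size(view0) - voxel_size(view180)) > 1e-9))
    stopf("register_opposing: views differ in voxel size")
  flipped <- flip_xz(as_plain_array(view180))
  ref <- as_plain_array(view0)
  pc <- phase_correlation(ref, flipped)
  score <- alignment_quality(ref, flipped, pc$translation_vox)
  if (score < score_floor)
    stopf("registration unreliable: alignment score %.4f below floor %.3f",
          score, score_floor)
  structure(list(flip_axes = c("x", "z"),
                 translation_vox = pc$translation_vox,
                 score = score),
            class = "rigid_shift")
}

#' Identity transform (reference view)
#' @return a `rigid_shift` with no flips and zero translation.
#' @export
rigid_identity <- function() {
  structure(list(flip_axes = character(0),
                 translation_vox = c(y = 0, x = 0, z = 0), score = 1),
            class = "rigid_shift")
}

# subvoxel translation by trilinear interpolation, zero fill outside;
# returns the shifted array and an inside-support mask
translate_trilinear <- function(arr, t_vox) {
  k <- floor(t_vox); f <- t_vox - k
  out <- array(0, dim(arr)); msk <- array(0, dim(arr))
  ones <- array(1, dim(arr))
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
         (if (c) f[3] else 1 - f[3])
    if (w == 0) next
    s <- c(k[1] + a, k[2] + b, k[3] + c)
    out <- out + w * shift_integer(arr, s)
    msk <- msk + w * shift_integer(ones, s)
  }
  list(data = out, inside = msk > 1 - 1e-9)
}

#' Apply a rigid shift
#'
#' Flips the listed axes, then translates by the transform's (subvoxel)
#' translation with trilinear interpolation; voxels mapped from outside the
#' source get zero.
#'
#' @param vol `image_volume` or 3D array.
#' @param shift a `rigid_shift`.
#' @return list `data` (same class as input) and logical `inside` mask.
#' @export
apply_rigid_shift <- function(vol, shift) {
  arr <- as_plain_array(vol)
  if (all(c("x", "z") %in% shift$flip_axes)) arr <- flip_xz(arr)
  else if (length(shift$flip_axes))
    stopf("apply_rigid_shift: only the x+z opposing-view flip is supported")
  tr <- translate_trilinear(arr, shift$translation_vox)
  if (inherits(vol, "image_volume")) tr$data <- vol_like(tr$data, vol)
  tr
}

#' Fusion weighting rule
#'
#' @param mode `"ramp"` (linear down-weighting along each view's own
#'   illumination direction; needs no tuning) or `"local_contrast"`
#'   (Gaussian-windowed gradient energy).
#' @param ramp_length_um length over which a ramp weight decays to its floor.
#' @param window_um Gaussian window of the contrast measure.
#' @return a `fusion_weights` spec.
#' @export
fusion_weights <- function(mode = c("ramp", "local_contrast"),
                           ramp_length_um = 120, window_um = 5) {
  mode <- match.arg(mode)
  check_positive(ramp_length_um, "ramp_length_um")
  check_positive(window_um, "window_um")
  structure(list(mode = mode, ramp_length_um = ramp_length_um,
                 window_um = window_um), class = "fusion_weights")
}

grad_energy <- function(arr, vs, window_um) {
  d <- dim(arr)
  gx <- arr; gx[, -d[2], ] <- arr[, -1, ] - arr[, -d[2], ]; gx[, d[2], ] <- 0
  gy <- arr; gy[-d[1], , ] <- arr[-1, , ] - arr[-d[1], , ]; gy[d[1], , ] <- 0
  e <- gx^2 + gy^2
  smooth_gauss3(e, c(window_um / vs["y"], window_um / vs["x"], window_um / vs["z"]))
}

#' Fuse registered views
#'
#' Resamples every view into the reference frame (trilinear interpolation)
#' and combines them by a normalized weighted average; weights of all views
#' sum to 1 at every voxel (voxels outside a view's support get zero weight
#' for that view; voxels outside every view fall back to equal weights).
#'
#' @param views list of >= 2 `image_volume`s.
#' @param transforms list of `rigid_shift`s, one per view
#'   ([rigid_identity()] for the reference).
#' @param weights a [fusion_weights()].
#' @param illumination_dirs optional +1/-1 per view in the reference frame;
#'   by default +1, flipped to -1 for x-flipped views.
#' @return the fused `image_volume` (metadata of the first view).
#' @export
fuse_views <- function(views, transforms, weights = fusion_weights(),
                       illumination_dirs = NULL) {
  nv <- length(views)
  if (nv < 2) stopf("fuse_views: need at least 2 views")
  if (length(transforms) != nv) stopf("fuse_views: one transform per view required")
  ref <- views[[1]]
  d <- dim(ref); vs <- voxel_size(ref)
  if (is.null(illumination_dirs))
    illumination_dirs <- vapply(transforms, function(tr)
      if ("x" %in% tr$flip_axes) -1 else 1, numeric(1))

  res <- lapply(seq_len(nv), function(i) apply_rigid_shift(views[[i]], transforms[[i]]))
  if (!any(Reduce(`|`, lapply(res, `[[`, "inside"))))
    stopf("fuse_views: resampled views do not overlap the reference frame")

  xv <- (seq_len(d[2]) - 1) * vs["x"]
  Xmax <- xv[d[2]]
  wmaps <- vector("list", nv)
  for (i in seq_len(nv)) {
    if (weights$mode == "ramp") {
      depth <- if (illumination_dirs[i] > 0) xv else Xmax - xv
      w1 <- pmax(1 - depth / weights$ramp_length_um, 0.02)
      w <- array(rep(w1, each = d[1]), d)
    } else {
      w <- grad_energy(as_plain_array(res[[i]]$data), vs, weights$window_um) + 1e-9
    }
    w[!res[[i]]$inside] <- 0
    wmaps[[i]] <- w
  }
  W <- Reduce(`+`, wmaps)
  dead <- W <= 0
  for (i in seq_len(nv)) {
    wmaps[[i]][dead] <- 1 / nv
  }
  W[dead] <- 1
  acc <- array(0, d)
  for (i in seq_len(nv)) acc <- acc + (wmaps[[i]] / W) * as_plain_array(res[[i]]$data)
  vol_like(acc, ref)
}

# normalized weight maps (exposed for the weight-sum contract)
fusion_weight_maps <- function(views, transforms, weights = fusion_weights(),
                               illumination_dirs = NULL) {
  nv <- length(views)
  ref <- views[[1]]; d <- dim(ref); vs <- voxel_size(ref)
  if (is.null(illumination_dirs))
    illumination_dirs <- vapply(transforms, function(tr)
      if ("x" %in% tr$flip_axes) -1 else 1, numeric(1))
  res <- lapply(seq_len(nv), function(i) apply_rigid_shift(views[[i]], transforms[[i]]))
  xv <- (seq_len(d[2]) - 1) * vs["x"]; Xmax <- xv[d[2]]
  wmaps <- vector("list", nv)
  for (i in seq_len(nv)) {
    if (weights$mode == "ramp") {
      depth <- if (illumination_dirs[i] > 0) xv else Xmax - xv
      w1 <- pmax(1 - depth / weights$ramp_length_um, 0.02)
      w <- array(rep(w1, each = d[1]), d)
    } else {
      w <- grad_energy(as_plain_array(res[[i]]$data), vs, weights$window_um) + 1e-9
    }
    w[!res[[i]]$inside] <- 0
    wmaps[[i]] <- w
  }
  W <- Reduce(`+`, wmaps)
  dead <- W <= 0
  for (i in seq_len(nv)) wmaps[[i]][dead] <- 1 / nv
  W[dead] <- 1
  lapply(wmaps, function(w) w / W)
}

#' Compensate time-lapse drift
#'
#' Estimates a per-frame 3D translation by phase correlation against the
#' first frame (default) or the previous frame (chained cumulative shifts),
#' and applies the aligning subvoxel shift by trilinear interpolation.
#' Frames whose correlation peak falls below `score_floor` fall back to zero
#' incremental shift with a warning.
#'
#' @param frames list of >= 2 `image_volume`s of identical shape.
#' @param reference `"first"` (avoids error accumulation) or `"previous"`
#'   (for large drifts).
#' @param score_floor reliability floor on the correlation peak.
#' @return list: `shifts` data frame (`frame`, `dx_um`, `dy_um`, `dz_um`,
#'   `score`; the aligning translation in micrometres) and `frames`
#'   (corrected volumes).
#' @export
correct_drift <- function(frames, reference = c("first", "previous"),
                          score_floor = 0.05) {
  reference <- match.arg(reference)
  n <- length(frames)
  if (n < 2) stopf("correct_drift: need at least 2 frames")
  d <- dim(frames[[1]])
  for (f in frames) if (!all(dim(f) == d)) stopf("correct_drift: frames differ in shape")
  vs <- voxel_size(frames[[1]])

  shifts <- matrix(0, n, 3, dimnames = list(NULL, c("y", "x", "z")))
  scores <- numeric(n); scores[1] <- 1
  cum <- c(y = 0, x = 0, z = 0)
  for (t in 2:n) {
    ref <- if (reference == "first") as_plain_array(frames[[1]])
           else as_plain_array(frames[[t - 1]])
    mov <- as_plain_array(frames[[t]])
    pc <- phase_correlation(ref, mov)
    scores[t] <- alignment_quality(ref, mov, pc$translation_vox)
    if (scores[t] < score_floor) {
      warnf("correct_drift: frame %d alignment score %.4f below floor; using zero shift",
            t - 1L, scores[t])
      inc <- c(y = 0, x = 0, z = 0)
    } else inc <- pc$translation_vox
    shifts[t, ] <- if (reference == "first") inc else (cum <- cum + inc)
  }
  corrected <- vector("list", n)
  corrected[[1]] <- frames[[1]]
  for (t in 2:n) {
    tr <- translate_trilinear(as_plain_array(frames[[t]]), shifts[t, ])
    corrected[[t]] <- vol_like(tr$data, frames[[t]])
  }
  list(shifts = data.frame(frame = 0:(n - 1),
                           dx_um = shifts[, "x"] * vs["x"],
                           dy_um = shifts[, "y"] * vs["y"],
                           dz_um = shifts[, "z"] * vs["z"],
                           score = scores),
       frames = corrected)
}
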