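# Synthetic SPIM forward model: Gaussian-blob nuclei, chord-geometry
# illumination attenuation, depth-dependent detection blur, sensor noise.

# blob geometry derived from the nucleus radius r (um):
#   interphase: isotropic Gaussian, sigma = r/2
#   condensed:  prolate Gaussian along the spindle axis, axis ratio 2.2
#   metaphase:  oblate Gaussian (plate) with the spindle axis as its normal
#   anaphase:   two small masses separating along the spindle axis
blob_sigmas <- function(r) {
  iso <- r / 2
  sc <- 0.45 * iso
  list(iso = iso, cond_short = sc, cond_long = 2.2 * sc,
       plate_normal = 0.5 * sc, plate_radius = 2.2 * sc,
       ana_mass = 0.8 * sc)
}

# add one (possibly anisotropic) Gaussian blob to `arr` in place-ish
add_blob <- function(arr, dims, vs, pos, amp, sigma_par, sigma_perp, axis,
                     trunc = 4) {
  hw <- trunc * max(sigma_par, sigma_perp)
  ix <- which(abs((seq_len(dims[2]) - 1) * vs["x"] - pos[1]) <= hw)
  iy <- which(abs((seq_len(dims[1]) - 1) * vs["y"] - pos[2]) <= hw)
  iz <- which(abs((seq_len(dims[3]) - 1) * vs["z"] - pos[3]) <= hw)
  if (!length(ix) || !length(iy) || !length(iz)) return(arr)
  dx <- (ix - 1) * vs["x"] - pos[1]
  dy <- (iy - 1) * vs["y"] - pos[2]
  dz <- (iz - 1) * vs["z"] - pos[3]
  ny <- length(iy); nx <- length(ix); nz <- length(iz)
  DX <- array(rep(dx, each = ny), c(ny, nx, nz))
  DY <- array(dy, c(ny, nx, nz))
  DZ <- array(rep(dz, each = ny * nx), c(ny, nx, nz))
  if (sigma_par == sigma_perp) {
    val <- exp(-(DX^2 + DY^2 + DZ^2) / (2 * sigma_par^2))
  } else {
    t <- DX * axis[1] + DY * axis[2] + DZ * axis[3]
    p2 <- pmax(DX^2 + DY^2 + DZ^2 - t^2, 0)
    val <- exp(-t^2 / (2 * sigma_par^2) - p2 / (2 * sigma_perp^2))
  }
  arr[iy, ix, iz] <- arr[iy, ix, iz] + amp * val
  arr
}

# chord-geometry attenuation field exp(-d/l): d is the path length from the
# sheet's entry point into the ideal truth sphere to the voxel, along x
attenuation_field <- function(dims, vs, center, R, ell, dir) {
  arr <- array(1, dims)
  if (!is.finite(ell)) return(arr)
  yv <- (seq_len(dims[1]) - 1) * vs["y"] - center["y"]
  zv <- (seq_len(dims[3]) - 1) * vs["z"] - center["z"]
  rho2 <- outer(yv^2, zv^2, "+")
  hx <- sqrt(pmax(R^2 - rho2, 0))
  xv <- (seq_len(dims[2]) - 1) * vs["x"] - center["x"]
  for (i in seq_len(dims[2])) {
    d <- pmin(pmax(dir * xv[i] + hx, 0), 2 * hx)
    arr[, i, ] <- exp(-d / ell)
  }
  arr
}

# depth-dependent detection blur: slice at tissue depth dz (along z) blurred
# with sigma0 + k*dz (um), separable in-plane Gaussian
depth_blur <- function(arr, dims, vs, center, R, sigma0, k) {
  if (sigma0 <= 0 && k <= 0) return(arr)
  zv <- (seq_len(dims[3]) - 1) * vs["z"]
  z_top <- center["z"] - R
  for (iz in seq_len(dims[3])) {
    dz <- min(max(zv[iz] - z_top, 0), 2 * R)
    s <- sigma0 + k * dz
    if (s <= 0) next
    sl <- array(arr[, , iz], c(dims[1], dims[2], 1))
    sl <- smooth_gauss3(sl, c(s / vs["y"], s / vs["x"], 0))
    arr[, , iz] <- sl[, , 1]
  }
  arr
}

apply_sensor_noise <- function(arr, optics, seed) {
  with_seed(seed, {
    out <- arr
    if (is.finite(optics$photon_scale)) {
      out <- rpois(length(out), optics$photon_scale * pmax(as.numeric(out), 0)) /
        optics$photon_scale
    }
    if (optics$read_noise_sd > 0)
      out <- out + rnorm(length(out), 0, optics$read_noise_sd)
    array(out, dim(arr))
  })
}

# shared renderer over a per-frame nucleus table with columns
# x_um, y_um, z_um, shape, amp, axis_x/y/z, sep_um
render_core <- function(tbl, dims, vs, center, R, r_nuc, optics, seed,
                        noise = TRUE) {
  sg <- blob_sigmas(r_nuc)
  arr <- array(0, dims)
  for (i in seq_len(nrow(tbl))) {
    p <- c(tbl$x_um[i], tbl$y_um[i], tbl$z_um[i])
    a <- c(tbl$axis_x[i], tbl$axis_y[i], tbl$axis_z[i])
    amp <- tbl$amp[i]
    arr <- switch(tbl$shape[i],
      interphase = add_blob(arr, dims, vs, p, amp, sg$iso, sg$iso, a),
      condensed  = add_blob(arr, dims, vs, p, amp, sg$cond_long, sg$cond_short, a),
      metaphase  = add_blob(arr, dims, vs, p, amp, sg$plate_normal, sg$plate_radius, a),
      anaphase   = {
        off <- a * tbl$sep_um[i] / 2
        arr <- add_blob(arr, dims, vs, p + off, amp, sg$ana_mass, sg$ana_mass, a)
        add_blob(arr, dims, vs, p - off, amp, sg$ana_mass, sg$ana_mass, a)
      },
      stopf("render: unknown shape '%s'", tbl$shape[i]))
  }
  arr <- arr * attenuation_field(dims, vs, center, R,
                                 optics$attenuation_length_um,
                                 optics$illumination_dir)
  arr <- depth_blur(arr, dims, vs, center, R, optics$blur_sigma0_um,
                    optics$blur_growth_per_um)
  if (noise) arr <- apply_sensor_noise(arr, optics, seed)
  arr
}

# static-scene nucleus table from truth (labelled nuclei only contribute)
truth_to_table <- function(truth, optics) {
  n <- truth$nuclei[truth$nuclei$labeled, , drop = FALSE]
  data.frame(x_um = n$x_um, y_um = n$y_um, z_um = n$z_um,
             shape = ifelse(n$class == "mitotic", "condensed", "interphase"),
             amp = ifelse(n$class == "mitotic", 0.5 * optics$mitotic_gain, 0.5),
             axis_x = n$axis_x, axis_y = n$axis_y, axis_z = n$axis_z,
             sep_um = rep(0, nrow(n)), stringsAsFactors = FALSE)
}

#' Render a synthetic spheroid volume
#'
#' Labelled interphase nuclei are rendered as isotropic Gaussian blobs,
#' mitotic nuclei as brighter prolate condensed-chromatin shapes
#' (peak x `mitotic_gain`); the signal is attenuated as `exp(-d/l)` along
#' the illumination chord through the truth sphere, each z-slice is blurred
#' with a detection-depth-dependent sigma, and shot plus read noise is
#' applied.  Unlabelled nuclei contribute nothing.
#'
#' @param truth a `scene_truth` from [place_nuclei()].
#' @param scene the [scene_spec()] the truth was generated from.
#' @param optics an [optics_spec()].
#' @param seed noise seed (defaults to `scene$seed`).
#' @param noise apply sensor noise (default `TRUE`).
#' @return an `image_volume`.
#' @export
render_volume <- function(truth, scene, optics = optics_spec(),
                          seed = scene$seed, noise = TRUE) {
  stopifnot(inherits(truth, "scene_truth"), inherits(scene, "scene_spec"))
  dims <- scene$volume_shape_vox
  vs <- scene$voxel_size_um
  ext <- scene_extent_um(scene)
  need <- 2 * (truth$spheroid_radius_um + scene$margin_um)
  if (any(ext < need))
    stopf("render_volume: volume extent (%s um) violates the %g um margin around the %g um spheroid",
          paste(round(ext, 1), collapse = " x "), scene$margin_um,
          truth$spheroid_radius_um)
  arr <- render_core(truth_to_table(truth, optics), dims, vs, truth$center_um,
                     truth$spheroid_radius_um, scene$nucleus_radius_um,
                     optics, seed, noise)
  image_volume(arr, vs)
}

flip_xz <- function(arr) {
  d <- dim(arr)
  arr[, rev(seq_len(d[2])), rev(seq_len(d[3])), drop = FALSE]
}

#' Render an opposing 0/180-degree view pair
#'
#' The 0-degree view is illuminated from the low-x side; the 180-degree view
#' is rendered with opposite illumination and then flipped along x and z,
#' emulating the acquisition geometry after rotating the sample by 180
#' degrees about the vertical axis.
#'
#' @inheritParams render_volume
#' @param shift_vox integer `(y, x, z)` voxel shift applied to the 180-degree
#'   stack after flipping (mounting offset between the two acquisitions).
#' @return list with `view0`, `view180` (both `image_volume`) and the
#'   applied `shift_vox`.
#' @export
render_opposing_views <- function(truth, scene, optics = optics_spec(),
                                  seed = scene$seed, noise = TRUE,
                                  shift_vox = c(0, 0, 0)) {
  o0 <- optics; o0$illumination_dir <- 1L
  o1 <- optics; o1$illumination_dir <- -1L
  v0 <- render_volume(truth, scene, o0, seed = seed, noise = noise)
  v1 <- render_volume(truth, scene, o1, seed = seed + 1L, noise = noise)
  a1 <- flip_xz(as_array3(v1))
  if (any(shift_vox != 0)) a1 <- shift_integer(a1, shift_vox)
  list(view0 = v0, view180 = vol_like(a1, v1), shift_vox = shift_vox)
}

# integer-voxel shift with zero fill (used to inject known offsets)
shift_integer <- function(arr, s) {
  d <- dim(arr)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    k <- s[ax]
    if (abs(k) >= d[ax]) return(out)
    if (k >= 0) { dst[[ax]] <- (1 + k):d[ax]; src[[ax]] <- 1:(d[ax] - k) }
    else        { dst[[ax]] <- 1:(d[ax] + k); src[[ax]] <- (1 - k):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Simulate a complete static scene
#'
#' Convenience wrapper: places nuclei, renders the stripe-free volume,
#' draws a stripe field and returns the additive composition
#' `corrupted = clean + b` together with all ground truth.
#'
#' @param scene a [scene_spec()].
#' @param optics an [optics_spec()].
#' @param stripes a [stripe_spec()].
#' @param seed master seed (defaults to `scene$seed`); the stripe field uses
#'   `seed + 500`.
#' @return list: `truth`, `clean` (stripe-free `image_volume`), `corrupted`,
#'   `stripe_field` (list `b`, `lambda`, `psi`).
#' @export
simulate_scene <- function(scene = scene_spec(), optics = optics_spec(),
                           stripes = stripe_spec(), seed = scene$seed) {
  truth <- place_nuclei(scene)
  clean <- render_volume(truth, scene, optics, seed = seed)
  sf <- make_stripe_field(scene$volume_shape_vox, stripes,
                          scene$voxel_size_um, seed = seed + 500L)
  list(truth = truth, clean = clean,
       corrupted = corrupt_volume(clean, sf), stripe_field = sf)
}
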