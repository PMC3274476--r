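#' Synthetic spheroid scene specification
#'
#' Describes the geometry and labelling of a synthetic H2B-labelled tumor
#' spheroid.  Defaults give a desk-scale scene (radius 50 um, ~150 labelled
#' nuclei in a 192 x 192 x 128 volume); real acquisitions of up to ~400 um
#' spheroids are reached with `scene_preset("large")`.
#'
#' @param spheroid_radius_um spheroid radius (um).
#' @param nucleus_radius_um nucleus radius (um); HCT116-like nuclei ~5 um.
#' @param min_separation_um minimum distance between nucleus centers (um);
#'   must be at least `nucleus_radius_um`.
#' @param labeled_fraction fraction of nuclei expressing the fluorescent
#'   reporter (the imaged clone expresses it in a subpopulation only).
#' @param mitotic_fraction probability that a nucleus in the proliferative
#'   outer rim is mitotic; deeper nuclei are never mitotic.
#' @param rim_thickness_um thickness of the outer proliferative shell (um)
#'   to which mitoses are restricted.
#' @param voxel_size_um voxel size `(x, y, z)` in um.
#' @param volume_shape_vox array shape `(ny, nx, nz)`.
#' @param n_nuclei number of nuclei to place.
#' @param margin_um clearance required between the spheroid and the volume
#'   boundary (um).
#' @param seed integer seed; the scene is a pure function of the spec.
#' @return a validated `scene_spec` object.
#' @export
scene_spec <- function(spheroid_radius_um = 50,
                       nucleus_radius_um = 5,
                       min_separation_um = 9,
                       labeled_fraction = 0.7,
                       mitotic_fraction = 0.25,
                       rim_thickness_um = 15,
                       voxel_size_um = c(0.645, 0.645, 1),
                       volume_shape_vox = c(192, 192, 128),
                       n_nuclei = 220,
                       margin_um = 5,
                       seed = 1L) {
  check_positive(spheroid_radius_um, "spheroid_radius_um")
  check_positive(nucleus_radius_um, "nucleus_radius_um")
  check_positive(min_separation_um, "min_separation_um")
  check_fraction(labeled_fraction, "labeled_fraction")
  check_fraction(mitotic_fraction, "mitotic_fraction")
  check_positive(rim_thickness_um, "rim_thickness_um")
  check_positive(margin_um, "margin_um", strict = FALSE)
  if (rim_thickness_um > spheroid_radius_um)
    stopf("rim_thickness_um (%g) must not exceed spheroid_radius_um (%g)",
          rim_thickness_um, spheroid_radius_um)
  if (min_separation_um < nucleus_radius_um)
    stopf("min_separation_um (%g) must be >= nucleus_radius_um (%g)",
          min_separation_um, nucleus_radius_um)
  if (length(volume_shape_vox) != 3L || any(volume_shape_vox < 1))
    stopf("volume_shape_vox must be 3 positive integers (ny, nx, nz)")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 3L ||
      any(voxel_size_um <= 0))
    stopf("voxel_size_um must be 3 positive numbers (x, y, z)")
  n_nuclei <- as.integer(n_nuclei)
  if (n_nuclei < 1L) stopf("n_nuclei must be >= 1")

  spec <- structure(list(
    spheroid_radius_um = spheroid_radius_um,
    nucleus_radius_um = nucleus_radius_um,
    min_separation_um = min_separation_um,
    labeled_fraction = labeled_fraction,
    mitotic_fraction = mitotic_fraction,
    rim_thickness_um = rim_thickness_um,
    voxel_size_um = stats::setNames(as.numeric(voxel_size_um), c("x", "y", "z")),
    volume_shape_vox = as.integer(volume_shape_vox),
    n_nuclei = n_nuclei,
    margin_um = margin_um,
    seed = as.integer(seed)), class = "scene_spec")

  ext <- scene_extent_um(spec)
  need <- 2 * (spheroid_radius_um + margin_um)
  if (any(ext < need))
    stopf("spheroid of radius %g um with margin %g um does not fit the %s um volume (needs %g um per axis)",
          spheroid_radius_um, margin_um, paste(round(ext, 1), collapse = " x "), need)
  spec
}

scene_extent_um <- function(spec) {
  d <- spec$volume_shape_vox; vs <- spec$voxel_size_um
  c(y = d[1] * vs["y"], x = d[2] * vs["x"], z = d[3] * vs["z"])
}

scene_center_um <- function(spec) {
  d <- spec$volume_shape_vox; vs <- spec$voxel_size_um
  c(x = (d[2] - 1) / 2 * vs[["x"]],
    y = (d[1] - 1) / 2 * vs[["y"]],
    z = (d[3] - 1) / 2 * vs[["z"]])
}

#' Scene presets
#'
#' `"desk"` is the test-scale default (radius 50 um); `"tiny"` is a fast
#' small scene for unit work (radius 18 um); `"large"` approximates a full
#' 400-um-diameter spheroid acquisition and is documentation-scale, not a
#' test default.
#'
#' @param name one of `"desk"`, `"tiny"`, `"large"`.
#' @param seed integer seed.
#' @param ... overrides passed to [scene_spec()].
#' @return a `scene_spec`.
#' @export
scene_preset <- function(name = c("desk", "tiny", "large"), seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    desk = list(),
    tiny = list(spheroid_radius_um = 18, volume_shape_vox = c(80, 80, 52),
                n_nuclei = 30, rim_thickness_um = 10, margin_um = 4,
                labeled_fraction = 1),
    large = list(spheroid_radius_um = 200, volume_shape_vox = c(672, 672, 420),
                 n_nuclei = 8000, rim_thickness_um = 30))
  args <- utils::modifyList(args, list(...))
  do.call(scene_spec, c(args, list(seed = seed)))
}

#' Optical forward-model specification
#'
#' Parameters of the synthetic SPIM optics: exponential light-sheet
#' attenuation along the illumination (x) axis, detection blur growing with
#' tissue depth along z, brightness gain of condensed mitotic chromatin, and
#' sensor noise.
#'
#' @param attenuation_length_um decay length (um) of the illumination along
#'   its chord through the spheroid; `Inf` disables attenuation.  The default
#'   200 um makes nuclei identifiable through a desk-scale spheroid while
#'   giving a clearly visible depth gradient.
#' @param blur_sigma0_um detection blur sigma at the spheroid surface (um).
#' @param blur_growth_per_um additional blur sigma per um of detection-axis
#'   tissue depth (dimensionless).
#' @param mitotic_gain peak-intensity multiplier of condensed mitotic
#'   chromatin relative to interphase nuclei (>= 1).
#' @param photon_scale photons per unit intensity for shot noise; `Inf`
#'   disables shot noise.
#' @param read_noise_sd additive Gaussian read noise (intensity units).
#' @param illumination_dir +1 if the sheet enters from the low-x side, -1
#'   from the high-x side (used for opposing-view simulation).
#' @return an `optics_spec`.
#' @export
optics_spec <- function(attenuation_length_um = 200,
                        blur_sigma0_um = 0.8,
                        blur_growth_per_um = 0.01,
                        mitotic_gain = 2,
                        photon_scale = 200,
                        read_noise_sd = 0.01,
                        illumination_dir = 1L) {
  if (!is_scalar_num(attenuation_length_um) && !identical(attenuation_length_um, Inf))
    stopf("attenuation_length_um must be a positive number or Inf")
  if (attenuation_length_um <= 0) stopf("attenuation_length_um must be > 0")
  check_positive(blur_sigma0_um, "blur_sigma0_um", strict = FALSE)
  check_positive(blur_growth_per_um, "blur_growth_per_um", strict = FALSE)
  if (!is_scalar_num(mitotic_gain) || mitotic_gain < 1)
    stopf("mitotic_gain must be >= 1")
  if (!(is_scalar_num(photon_scale) || identical(photon_scale, Inf)) ||
      photon_scale <= 0)
    stopf("photon_scale must be > 0 (Inf disables shot noise)")
  check_positive(read_noise_sd, "read_noise_sd", strict = FALSE)
  if (!illumination_dir %in% c(-1L, 1L, -1, 1))
    stopf("illumination_dir must be +1 or -1")
  structure(list(attenuation_length_um = attenuation_length_um,
                 blur_sigma0_um = blur_sigma0_um,
                 blur_growth_per_um = blur_growth_per_um,
                 mitotic_gain = mitotic_gain,
                 photon_scale = photon_scale,
                 read_noise_sd = read_noise_sd,
                 illumination_dir = as.integer(illumination_dir)),
            class = "optics_spec")
}

#' Stripe-artifact specification
#'
#' Stripes are modelled as white noise convolved with an elementary
#' stripe-like pattern: a sparse Bernoulli-Gaussian coefficient field
#' convolved with an anisotropic Gaussian elongated along the illumination
#' (x) axis.
#'
#' @param psi_sigma_along_um pattern sigma along x (um); must exceed
#'   `psi_sigma_across_um`.
#' @param psi_sigma_across_um pattern sigma across the stripe (um).
#' @param noise_density Bernoulli activation probability of the coefficient
#'   field, in [0, 1]; density 1 recovers dense white noise, density 0 a
#'   stripe-free field.
#' @param noise_sd standard deviation of active Gaussian coefficients.
#' @param per_slice if `TRUE` (default) the stripe field is drawn
#'   independently per z-slice, matching stripes that live in the light-sheet
#'   plane.
#' @return a `stripe_spec`.
#' @export
stripe_spec <- function(psi_sigma_along_um = 15,
                        psi_sigma_across_um = 0.8,
                        noise_density = 0.05,
                        noise_sd = 0.5,
                        per_slice = TRUE) {
  check_positive(psi_sigma_along_um, "psi_sigma_along_um")
  check_positive(psi_sigma_across_um, "psi_sigma_across_um")
  if (psi_sigma_along_um <= psi_sigma_across_um)
    stopf("stripes must be elongated along x: psi_sigma_along_um (%g) must exceed psi_sigma_across_um (%g)",
          psi_sigma_along_um, psi_sigma_across_um)
  check_fraction(noise_density, "noise_density")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  structure(list(psi_sigma_along_um = psi_sigma_along_um,
                 psi_sigma_across_um = psi_sigma_across_um,
                 noise_density = noise_density,
                 noise_sd = noise_sd,
                 per_slice = isTRUE(per_slice)),
            class = "stripe_spec")
}

#' Time-lapse specification
#'
#' @param n_frames number of frames (>= 1).
#' @param frame_interval_min time between frames in minutes (default 3, the
#'   live-acquisition cadence).
#' @param drift_per_frame_um global sample drift per frame, `(x, y, z)` um.
#' @param mitosis_duration_min total duration of an unperturbed division
#'   (condensation through anaphase), minutes.
#' @param division_events data frame with columns `id` (nucleus id) and
#'   `entry_frame` (0-based frame at which condensation starts), or `NULL`.
#' @param paclitaxel_mode if `TRUE`, divisions never progress past the
#'   condensed, unaligned state: chromosomes jitter frame to frame, no
#'   metaphase plate forms and no anaphase occurs through movie end
#'   (spindle-poison phenotype; cells are already blocked at movie start
#'   after drug pre-incubation).
#' @param seed integer seed for per-frame stripe fields, sensor noise and
#'   jitter.
#' @return a `timelapse_spec`.
#' @export
timelapse_spec <- function(n_frames = 20,
                           frame_interval_min = 3,
                           drift_per_frame_um = c(0, 0, 0),
                           mitosis_duration_min = 21,
                           division_events = NULL,
                           paclitaxel_mode = FALSE,
                           seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stopf("n_frames must be >= 1")
  check_positive(frame_interval_min, "frame_interval_min")
  check_positive(mitosis_duration_min, "mitosis_duration_min")
  if (length(drift_per_frame_um) != 3L || any(!is.finite(drift_per_frame_um)))
    stopf("drift_per_frame_um must be 3 finite numbers (x, y, z)")
  if (!is.null(division_events)) {
    division_events <- as.data.frame(division_events)
    if (!all(c("id", "entry_frame") %in% names(division_events)))
      stopf("division_events needs columns `id` and `entry_frame`")
    if (any(division_events$entry_frame < 0 |
            division_events$entry_frame >= n_frames))
      stopf("division entry frames must lie within the movie (0..%d)", n_frames - 1L)
  }
  structure(list(n_frames = n_frames,
                 frame_interval_min = frame_interval_min,
                 drift_per_frame_um = stats::setNames(as.numeric(drift_per_frame_um),
                                                      c("x", "y", "z")),
                 mitosis_duration_min = mitosis_duration_min,
                 division_events = division_events,
                 paclitaxel_mode = isTRUE(paclitaxel_mode),
                 seed = as.integer(seed)),
            class = "timelapse_spec")
}
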