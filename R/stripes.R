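#' Generate a stationary stripe field
#'
#' Draws a sparse Bernoulli-Gaussian white-noise coefficient field
#' `lambda` and convolves it with the elementary stripe pattern `psi`
#' (an anisotropic Gaussian elongated along the illumination x-axis, unit
#' L2 norm) to produce the additive stripe field `b = lambda (*) psi`.
#' Convolution uses zero-padded boundaries; with `per_slice = TRUE`
#' (the default) both `lambda` and the convolution are independent per
#' z-slice, else the same 2D pattern is applied to a single 3D coefficient
#' field slice by slice.
#'
#' @param shape_vox array shape `(ny, nx, nz)`.
#' @param stripes a [stripe_spec()].
#' @param voxel_size_um voxel size `(x, y, z)` um.
#' @param seed integer seed.
#' @return list with 3D arrays `b` (stripe field) and `lambda`
#'   (coefficients), plus the sampled `psi` kernel.
#' @export
make_stripe_field <- function(shape_vox, stripes, voxel_size_um = c(0.645, 0.645, 1),
                              seed = 1L) {
  stopifnot(inherits(stripes, "stripe_spec"))
  shape_vox <- as.integer(shape_vox)
  if (length(shape_vox) != 3L || any(shape_vox < 1))
    stopf("make_stripe_field: shape_vox must be 3 positive integers (ny, nx, nz)")
  psi <- default_psi(stripes$psi_sigma_along_um, stripes$psi_sigma_across_um,
                     voxel_size_um)
  n <- prod(shape_vox)
  with_seed(seed, {
    lam <- rbinom(n, 1L, stripes$noise_density) * rnorm(n, 0, stripes$noise_sd)
    lam <- array(lam, shape_vox)
  })
  b <- conv_axis3(as.numeric(lam), shape_vox, psi$kx, 2L, FALSE)
  b <- conv_axis3(b, shape_vox, psi$ky, 1L, FALSE)
  list(b = array(b, shape_vox), lambda = lam, psi = psi)
}

#' Add a stripe field to a clean volume
#'
#' The corruption is exactly additive, `corrupted = clean + b`, so the
#' destriping decomposition identity can be tested against ground truth.
#'
#' @param vol an `image_volume` (or 3D array).
#' @param stripe_field output of [make_stripe_field()] (or a matching array).
#' @return corrupted volume of the same class as `vol`.
#' @export
corrupt_volume <- function(vol, stripe_field) {
  b <- if (is.list(stripe_field)) stripe_field$b else stripe_field
  if (!all(dim(vol) == dim(b)))
    stopf("corrupt_volume: stripe field shape %s does not match volume %s",
          paste(dim(b), collapse = "x"), paste(dim(vol), collapse = "x"))
  out <- unclass(vol) + as.numeric(b)
  if (inherits(vol, "image_volume")) vol_like(out, vol) else array(out, dim(vol))
}
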