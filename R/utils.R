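# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched, so every generator is a pure function of its seed.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# 1D Gaussian kernel sampled on the voxel grid, truncated at `trunc` sigmas.
# sigma in voxels; returns an odd-length kernel.  L2 or L1 normalization.
gauss_kernel <- function(sigma_vox, trunc = 4, norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  if (sigma_vox <= 0) return(1)
  h <- max(1L, ceiling(trunc * sigma_vox))
  x <- seq(-h, h)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  if (norm == "l1") k / sum(k) else k / sqrt(sum(k^2))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_fraction <- function(x, name) {
  if (!is_scalar_num(x) || x < 0 || x > 1)
    stopf("`%s` must be a single number in [0, 1], got %s", name,
          paste(format(x), collapse = ", "))
  x
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is_scalar_num(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) stopf("`%s` must be a %s number", name,
                 if (strict) "positive" else "non-negative")
  x
}

# separable anisotropic Gaussian smoothing of a 3D array, sigma given in
# voxels per axis (y, x, z); zero-padded boundaries, L1-normalized kernels.
smooth_gauss3 <- function(arr, sigma_vox, trunc = 4) {
  d <- dim(arr)
  out <- as.numeric(arr)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      k <- gauss_kernel(sigma_vox[ax], trunc, "l1")
      if (length(k) > 1L)
        out <- conv_axis3(out, as.integer(d), k, ax, FALSE)
    }
  }
  array(out, d)
}

# peak-signal-to-noise ratio in dB; peak defaults to the dynamic range of ref
#' Peak signal-to-noise ratio
#'
#' @param x,ref numeric arrays of identical shape.
#' @param peak signal peak used in the ratio; defaults to `diff(range(ref))`.
#' @return PSNR in dB (`Inf` for identical inputs).
#' @export
psnr <- function(x, ref, peak = NULL) {
  x <- as.numeric(x); ref <- as.numeric(ref)
  if (length(x) != length(ref)) stopf("psnr: inputs differ in length")
  if (is.null(peak)) peak <- diff(range(ref))
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}
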