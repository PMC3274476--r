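# Stationary-stripe removal by MAP estimation.
#
# Observed slice u0 = u + b with b = lambda (*) psi: white-noise coefficients
# convolved with an elementary stripe-like pattern.  The MAP estimate under a
# total-variation image prior and an l1 (or Gaussian) coefficient prior is
#
#   lambda_hat = argmin_lambda  TV(u0 - lambda (*) psi) + alpha * Phi(lambda)
#
# solved by a Chambolle-Pock primal-dual scheme; u_hat = u0 - lambda_hat (*) psi.

#' Elementary stripe pattern
#'
#' Anisotropic Gaussian sampled on the voxel grid, elongated along the
#' illumination (x) axis, support truncated at 4 sigma, unit L2 norm.
#'
#' @param sigma_along_um sigma along x (um); must exceed `sigma_across_um`.
#' @param sigma_across_um sigma across the stripe (um).
#' @param voxel_size_um voxel size `(x, y, z)` um.
#' @return a `psi_kernel`: separable factors `kx`, `ky` (unit L2 each, so
#'   the outer product has unit L2 norm) plus the dense matrix.
#' @export
default_psi <- function(sigma_along_um = 15, sigma_across_um = 0.8,
                        voxel_size_um = c(0.645, 0.645, 1)) {
  if (!is_scalar_num(sigma_along_um) || sigma_along_um <= 0 ||
      !is_scalar_num(sigma_across_um) || sigma_across_um <= 0)
    stopf("default_psi: sigmas must be positive")
  if (sigma_along_um < sigma_across_um)
    stopf("default_psi: sigma_along_um must be >= sigma_across_um (long axis along x)")
  kx <- gauss_kernel(sigma_along_um / voxel_size_um[1], 4, "l2")
  ky <- gauss_kernel(sigma_across_um / voxel_size_um[2], 4, "l2")
  psi_kernel(kx = kx, ky = ky,
             sigma_along_um = sigma_along_um, sigma_across_um = sigma_across_um)
}

#' Construct a stripe pattern kernel
#'
#' Either from separable factors `kx` (along x) and `ky` (across), or from a
#' dense matrix `ker` (rows = y, cols = x).  The kernel is L2-normalized.
#'
#' @param kx,ky separable 1D factors, or `NULL`.
#' @param ker dense 2D kernel, or `NULL`.
#' @param sigma_along_um,sigma_across_um optional provenance metadata.
#' @return a `psi_kernel`.
#' @export
psi_kernel <- function(kx = NULL, ky = NULL, ker = NULL,
                       sigma_along_um = NA_real_, sigma_across_um = NA_real_) {
  if (!is.null(kx)) {
    kx <- as.numeric(kx); ky <- as.numeric(ky)
    if (any(!is.finite(kx)) || any(!is.finite(ky)))
      stopf("psi_kernel: factors must be finite")
    kx <- kx / sqrt(sum(kx^2)); ky <- ky / sqrt(sum(ky^2))
    structure(list(kx = kx, ky = ky, matrix = outer(ky, kx), separable = TRUE,
                   sigma_along_um = sigma_along_um,
                   sigma_across_um = sigma_across_um),
              class = "psi_kernel")
  } else {
    ker <- as.matrix(ker)
    if (any(!is.finite(ker))) stopf("psi_kernel: kernel must be finite")
    n2 <- sqrt(sum(ker^2))
    if (n2 == 0) stopf("psi_kernel: kernel must be nonzero")
    structure(list(matrix = ker / n2, separable = FALSE,
                   sigma_along_um = sigma_along_um,
                   sigma_across_um = sigma_across_um),
              class = "psi_kernel")
  }
}

#' Dirac stripe pattern
#'
#' With `psi = delta` and the l2 prior the MAP problem reduces to classical
#' TV (ROF) denoising, which provides an independent oracle for the solver.
#' @return a `psi_kernel`.
#' @export
psi_delta <- function() psi_kernel(kx = 1, ky = 1)

# convolve a 2D slice with psi (or its adjoint), zero-padded boundaries
psi_conv <- function(img, psi, adjoint = FALSE) {
  if (psi$separable) {
    d <- c(nrow(img), ncol(img), 1L)
    v <- conv_axis3(as.numeric(img), d, psi$kx, 2L, adjoint)
    v <- conv_axis3(v, d, psi$ky, 1L, adjoint)
    matrix(v, nrow(img), ncol(img))
  } else {
    conv2_full(img, psi$matrix, adjoint)
  }
}

#' Stripe removal model
#'
#' @param psi a [psi_kernel()] (default [default_psi()]).
#' @param alpha regularization weight on the coefficient prior (> 0).
#'   Slices are normalized internally by their maximum absolute intensity
#'   before solving, so `alpha` always refers to unit-scaled data and the
#'   l1 solution is exactly scale covariant.
#' @param prior `"l1"` (sparse streaks, default) or `"l2"` on the
#'   coefficients.
#' @param max_iter iteration cap of the primal-dual solver.
#' @param tol stopping threshold: iteration ends when the per-iteration
#'   relative decrease of the (best-so-far) objective, averaged over a
#'   10-iteration window, falls below `tol`.
#' @param per_slice process volumes slice by slice (default `TRUE`; stripes
#'   live in the light-sheet plane).
#' @return a `stripe_model`.
#' @export
stripe_model <- function(psi = default_psi(), alpha = 1, prior = c("l1", "l2"),
                         max_iter = 500L, tol = 3e-4, per_slice = TRUE) {
  prior <- match.arg(prior)
  stopifnot(inherits(psi, "psi_kernel"))
  check_positive(alpha, "alpha")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stopf("max_iter must be >= 1")
  check_positive(tol, "tol")
  structure(list(psi = psi, alpha = alpha, prior = prior,
                 max_iter = max_iter, tol = tol, per_slice = isTRUE(per_slice)),
            class = "stripe_model")
}

# isotropic discrete TV, forward differences, Neumann boundary
tv_norm <- function(u) {
  nx <- ncol(u); ny <- nrow(u)
  dx <- cbind(u[, -1, drop = FALSE] - u[, -nx, drop = FALSE], rep(0, ny))
  dy <- rbind(u[-1, , drop = FALSE] - u[-ny, , drop = FALSE], rep(0, nx))
  sum(sqrt(dx^2 + dy^2))
}

#' MAP destriping objective
#'
#' `TV(u0 - lam (*) psi) + alpha * Phi(lam)` with isotropic forward-difference
#' TV and `Phi` the l1 norm or half squared l2 norm.
#'
#' @param u0 observed 2D slice (matrix).
#' @param lam coefficient field, same shape as `u0`.
#' @param model a [stripe_model()].
#' @return scalar energy.
#' @export
destripe_objective <- function(u0, lam, model) {
  u0 <- as.matrix(u0); lam <- as.matrix(lam)
  if (!all(dim(u0) == dim(lam)))
    stopf("destripe_objective: shapes differ (%s vs %s)",
          paste(dim(u0), collapse = "x"), paste(dim(lam), collapse = "x"))
  phi <- if (model$prior == "l1") sum(abs(lam)) else 0.5 * sum(lam^2)
  tv_norm(u0 - psi_conv(lam, model$psi)) + model$alpha * phi
}

cp_args <- function(psi) {
  if (psi$separable) list(kx = psi$kx, ky = psi$ky, ker = NULL)
  else list(kx = NULL, ky = NULL, ker = psi$matrix)
}

#' Estimate and remove stripes from one slice
#'
#' Minimizes the MAP objective over the coefficient field by a primal-dual
#' (Chambolle-Pock) scheme with deterministic zero initialization; step
#' sizes come from a power-iteration bound on the composite operator norm.
#' The reported objective trace is the best value seen so far (monotone
#' non-increasing); the returned iterate is the best one.
#'
#' @param u0 observed 2D slice (matrix), finite.
#' @param model a [stripe_model()].
#' @param L optional precomputed operator norm (reused across slices).
#' @param step_ratio primal/dual step-size ratio (`tau/sigma = step_ratio^2`);
#'   the dual-heavy default converges fastest on stripe problems.
#' @return a `destripe_result`: `clean` (`u0 - noise`), `noise`
#'   (`lambda_hat (*) psi`), `lambda_hat`, `objective_trace`, `iterations`,
#'   `converged`.
#' @export
estimate_stripes <- function(u0, model = stripe_model(), L = NULL,
                             step_ratio = 0.1) {
  u0 <- as.matrix(u0)
  if (any(!is.finite(u0))) stopf("estimate_stripes: input contains non-finite values")
  stopifnot(inherits(model, "stripe_model"))
  # normalize by the maximum absolute intensity: with the 1-homogeneous l1
  # objective this makes destripe(c * u0) == c * destripe(u0) exactly (for
  # the l2 prior, scale alpha by 1/c to keep covariance)
  s <- max(abs(u0))
  if (s == 0) {
    z <- u0 * 0
    return(structure(list(clean = u0, noise = z, lambda_hat = z,
                          objective_trace = 0, iterations = 0L,
                          converged = TRUE, model = model),
                     class = "destripe_result"))
  }
  alpha_eff <- if (model$prior == "l1") model$alpha else model$alpha * s
  ka <- cp_args(model$psi)
  if (is.null(L))
    L <- cp_operator_norm(nrow(u0), ncol(u0), ka$kx, ka$ky, ka$ker, 30L)
  res <- cp_destripe_slice(u0 / s, ka$kx, ka$ky, ka$ker, alpha_eff,
                           if (model$prior == "l1") 1L else 2L,
                           model$max_iter, model$tol, L, step_ratio)
  if (!res$converged)
    warnf("estimate_stripes: no convergence within %d iterations", model$max_iter)
  noise <- s * res$noise
  structure(list(clean = u0 - noise, noise = noise,
                 lambda_hat = s * res$lambda,
                 objective_trace = s * res$objective_trace,
                 iterations = res$iterations, converged = res$converged,
                 model = model),
            class = "destripe_result")
}

#' @export
print.destripe_result <- function(x, ...) {
  tr <- x$objective_trace
  if (is.list(tr)) tr <- tr[[1]]
  cat(sprintf("<destripe_result> %s iterations, converged: %s, objective %.6g -> %.6g\n",
              paste(x$iterations, collapse = "/"), all(x$converged),
              tr[1], tr[length(tr)]))
  invisible(x)
}

#' Remove stripes from a 3D stack
#'
#' With `per_slice = TRUE` (default) each z-slice is destriped independently
#' (stripes lie in the light-sheet plane); the operator norm is computed once
#' and shared.  With `per_slice = FALSE` a single volumetric solve couples
#' the slices through 3D total variation (psi still acts within each plane;
#' requires a separable psi).  Voxel metadata is preserved.
#'
#' @param vol an `image_volume` or 3D array.
#' @param model a [stripe_model()].
#' @return a `destripe_result` with 3D `clean`, `noise` and `lambda_hat`,
#'   per-slice `objective_trace` list, `iterations` vector and `converged`
#'   vector.
#' @export
destripe_volume <- function(vol, model = stripe_model()) {
  arr <- if (inherits(vol, "image_volume")) as_array3(vol) else vol
  if (length(dim(arr)) != 3L) stopf("destripe_volume: need a 3D volume")
  d <- dim(arr)
  ka <- cp_args(model$psi)
  L <- cp_operator_norm(d[1], d[2], ka$kx, ka$ky, ka$ker, 30L)
  if (!model$per_slice) {
    if (!model$psi$separable)
      stopf("destripe_volume: the volumetric solve needs a separable psi")
    s <- max(abs(arr))
    if (s == 0) s <- 1
    alpha_eff <- if (model$prior == "l1") model$alpha else model$alpha * s
    res <- cp_destripe_vol3(as.numeric(arr) / s, as.integer(d), ka$kx, ka$ky,
                            alpha_eff, if (model$prior == "l1") 1L else 2L,
                            model$max_iter, model$tol, L, 0.1)
    noise <- array(s * res$noise, d)
    clean <- arr - noise
    out_clean <- if (inherits(vol, "image_volume")) vol_like(clean, vol) else clean
    out_noise <- if (inherits(vol, "image_volume")) vol_like(noise, vol) else noise
    return(structure(list(clean = out_clean, noise = out_noise,
                          lambda_hat = array(s * res$lambda, d),
                          objective_trace = s * res$objective_trace,
                          iterations = res$iterations,
                          converged = res$converged, model = model),
                     class = "destripe_result"))
  }
  clean <- array(0, d); noise <- array(0, d); lam <- array(0, d)
  traces <- vector("list", d[3])
  iters <- integer(d[3]); conv <- logical(d[3])
  for (iz in seq_len(d[3])) {
    r <- tryCatch(
      suppressWarnings(estimate_stripes(arr[, , iz], model, L = L)),
      error = function(e) stopf("destripe_volume: slice %d failed: %s",
                                iz, conditionMessage(e)))
    clean[, , iz] <- r$clean; noise[, , iz] <- r$noise
    lam[, , iz] <- r$lambda_hat
    traces[[iz]] <- r$objective_trace
    iters[iz] <- r$iterations; conv[iz] <- r$converged
  }
  out_clean <- if (inherits(vol, "image_volume")) vol_like(clean, vol) else clean
  out_noise <- if (inherits(vol, "image_volume")) vol_like(noise, vol) else noise
  structure(list(clean = out_clean, noise = out_noise, lambda_hat = lam,
                 objective_trace = traces, iterations = iters,
                 converged = conv, model = model),
            class = "destripe_result")
}
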