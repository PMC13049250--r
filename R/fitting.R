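#' Actual flip angle from a B1+ ratio
#'
#' The measured transmit-field map gives the ratio of actual to nominal flip
#' angle; the voxel's actual excitation angle is `b1_ratio * alpha_nominal`
#' (the standard actual-flip-angle-imaging convention).
#'
#' @param alpha_nominal Nominal (set) flip angle, degrees; may be a vector.
#' @param b1_ratio Actual-to-nominal ratio, dimensionless, > 0; may be a
#'   vector (recycled against `alpha_nominal`).
#' @return Actual flip angle(s), degrees.
#' @examples
#' actual_flip_angle(10, 0.9)
#' @export
actual_flip_angle <- function(alpha_nominal, b1_ratio) {
  if (any(!is.finite(b1_ratio)) || any(b1_ratio <= 0))
    stop("b1_ratio must be positive")
  b1_ratio * alpha_nominal
}

#' 3-D Gaussian smoothing of a B1+ ratio map
#'
#' Separable Gaussian filter applied along each array dimension. The kernel is
#' truncated at 3 standard deviations and renormalized at the array borders,
#' so constant maps are preserved exactly. `sigma = 0` returns the input
#' unchanged.
#'
#' @param b1_map Numeric array (1-D, 2-D, or 3-D).
#' @param sigma Gaussian standard deviation in voxels, >= 0. A single value
#'   (isotropic) or one value per dimension.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_b1_map <- function(b1_map, sigma = 1) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  dims <- dim(b1_map)
  if (is.null(dims)) dims <- length(b1_map)
  sigma <- rep_len(sigma, length(dims))
  out <- array(as.numeric(b1_map), dim = dims)
  for (d in seq_along(dims)) {
    if (sigma[d] == 0 || dims[d] == 1) next
    rad <- ceiling(3 * sigma[d])
    kern <- exp(-(seq(-rad, rad))^2 / (2 * sigma[d]^2))
    out <- .convolve_along(out, kern, d)
  }
  out
}

# separable 1-D convolution along dimension d with border renormalization
.convolve_along <- function(x, kern, d) {
  dims <- dim(x)
  perm <- c(d, seq_along(dims)[-d])
  xp <- aperm(x, perm)
  n <- dims[d]
  m <- matrix(xp, nrow = n)
  rad <- (length(kern) - 1) / 2
  num <- matrix(0, n, ncol(m))
  den <- numeric(n)
  for (j in seq_along(kern)) {
    off <- j - rad - 1
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    num[ok, ] <- num[ok, ] + kern[j] * m[src[ok], , drop = FALSE]
    den[ok] <- den[ok] + kern[j]
  }
  res <- num / den
  aperm(array(res, dims[perm]), order(perm))
}

.nonconverged_fit <- function(model) {
  structure(list(T1 = NA_real_, T2 = NA_real_, M0 = NA_real_,
                 residual_norm = NA_real_, converged = FALSE,
                 at_bound = FALSE, model = model),
            class = "tissue_fit")
}

#' Joint T1/T2/M0 fit of one voxel's measurement vector
#'
#' Bounded least-squares estimation of T1, T2, and M0 from the per-measurement
#' magnitude signals of one voxel, using the semi-steady-state I-SPGR forward
#' model (or the steady-state SPGR/Ernst model, in which case only T1 and M0
#' are estimated and `T2` is returned as `NA`). Residuals are ordinary
#' (Gaussian) differences between the measured and predicted magnitudes.
#'
#' The model is linear in M0, so the fit uses variable projection: M0 is
#' solved by linear least squares at every candidate (T1, T2), and bounded
#' Levenberg-Marquardt runs on the profiled residuals over (T1, T2) only
#' (T1 only for the SPGR model). The joint objective still has local minima at
#' short T2, so the profiled fit starts from a coarse T1 x T2 grid and refines
#' the best starts. The procedure is deterministic.
#'
#' @param signals Numeric vector, one magnitude value per protocol
#'   measurement.
#' @param protocol An [ispgr_protocol()] object.
#' @param alpha_scale Voxel B1+ ratio scaling the nominal flip angles.
#' @param model `"ispgr"` (3-parameter joint fit) or `"spgr"` (2-parameter
#'   Ernst fit, e.g. to quantify the bias of ignoring the preparation).
#' @param n Readout index of the forward model (default 1: the readout that
#'   samples central k-space and so determines image contrast).
#' @param t1_bounds,t2_bounds Fitting bounds in ms. Defaults are the in-vivo
#'   bounds T1 in \[100, 3000\], T2 in \[20, 300\].
#' @param m0_upper Upper bound for M0; default `1000 * max(abs(signals))`.
#'   Deliberately loose: with strong blood and fat suppression the unit-M0
#'   signal is only a few percent of M0, so a tight signal-based M0 bound can
#'   exclude the true value.
#' @param n_refine Number of best grid starts refined by Levenberg-Marquardt.
#' @return An object of class `tissue_fit`: a list with `T1`, `T2`, `M0`,
#'   `residual_norm`, `converged`, `at_bound` (TRUE if T1 or T2 ended on a
#'   bound), and `model`. Degenerate input (non-finite or all-zero signals)
#'   yields `converged = FALSE` with `NA` parameters.
#' @examples
#' p <- protocol_preset("invivo_ispgr")
#' y <- model_vector(tissue_params(800, 50), p)
#' fit_voxel(y, p)
#' @export
fit_voxel <- function(signals, protocol, alpha_scale = 1,
                      model = c("ispgr", "spgr"), n = 1,
                      t1_bounds = c(100, 3000), t2_bounds = c(20, 300),
                      m0_upper = NULL, n_refine = 3) {
  model <- match.arg(model)
  meas <- protocol$measurements
  if (length(signals) != nrow(meas))
    stop("length(signals) must equal the number of protocol measurements")
  if (length(signals) < 3) stop("at least 3 measurements are required")
  if (!all(is.finite(signals)) || all(signals == 0))
    return(.nonconverged_fit(model))
  if (is.null(m0_upper)) m0_upper <- 1000 * max(abs(signals))
  alpha <- meas$alpha * alpha_scale

  unit_fwd <- if (model == "ispgr") {
    function(T1, T2) .ispgr_forward(T1, T2, 1, alpha, protocol$TR,
                                    protocol$k, protocol$T_FS, meas$T_BS,
                                    meas$T_Sp, n)
  } else {
    function(T1, T2) .ernst(T1, 1, protocol$TR, alpha)
  }
  # M0 profiled out by linear least squares (variable projection)
  prof_m0 <- function(f) min(max(sum(signals * f) / sum(f * f), 0), m0_upper)
  resid_fn <- function(p) {
    f <- unit_fwd(p[1], if (length(p) > 1) p[2] else NA_real_)
    signals - prof_m0(f) * f
  }

  # coarse grid multi-start on the profiled surface
  t1s <- unique(pmin(pmax(c(300, 800, 1500, 2500), t1_bounds[1]), t1_bounds[2]))
  if (model == "ispgr") {
    t2s <- unique(pmin(pmax(c(30, 60, 150), t2_bounds[1]), t2_bounds[2]))
    starts <- as.matrix(expand.grid(T1 = t1s, T2 = t2s))
    lower <- c(t1_bounds[1], t2_bounds[1])
    upper <- c(t1_bounds[2], t2_bounds[2])
  } else {
    starts <- matrix(t1s, ncol = 1, dimnames = list(NULL, "T1"))
    lower <- t1_bounds[1]
    upper <- t1_bounds[2]
  }
  sse0 <- apply(starts, 1, function(s) sum(resid_fn(s)^2))
  keep <- order(sse0)[seq_len(min(n_refine, nrow(starts)))]

  best <- NULL
  for (i in keep) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn)
      best <- list(par = fit$par, rn = rn, info = fit$info)
  }
  if (is.null(best)) {
    # LM failed everywhere: fall back to the best grid start
    best <- list(par = starts[keep[1], ], rn = sqrt(sse0[keep[1]]), info = 0L)
  }

  p <- unname(best$par)
  f <- unit_fwd(p[1], if (model == "ispgr") p[2] else NA_real_)
  m0 <- prof_m0(f)
  tol <- 1e-6
  at_bound <- any(abs(p[1] - t1_bounds) < tol * diff(t1_bounds))
  if (model == "ispgr")
    at_bound <- at_bound || any(abs(p[2] - t2_bounds) < tol * diff(t2_bounds))
  structure(list(T1 = p[1],
                 T2 = if (model == "ispgr") p[2] else NA_real_,
                 M0 = m0,
                 residual_norm = best$rn,
                 converged = best$info %in% 1:4,
                 at_bound = at_bound, model = model),
            class = "tissue_fit")
}

#' Voxel-wise parameter mapping of an image stack
#'
#' Applies [fit_voxel()] to every voxel inside the mask, with per-voxel flip
#' angle scaling taken from the Gaussian-smoothed B1+ ratio map. Produces
#' volumetric T1, T2, and M0 maps plus residual-norm and convergence-flag
#' maps. The fit is deterministic (fixed multi-start grid).
#'
#' @param stack An [image_stack()] object.
#' @param protocol An [ispgr_protocol()] object matching the stack.
#' @param model `"ispgr"` or `"spgr"`.
#' @param b1_sigma Standard deviation (voxels) of the 3-D Gaussian smoothing
#'   applied to the B1+ map before fitting; 0 disables smoothing.
#' @param ... Further arguments passed to [fit_voxel()] (bounds, `n`, ...).
#' @return An object of class `parameter_maps`: a list of arrays `T1`, `T2`,
#'   `M0`, `residual_norm` (all `NA` outside the mask), logical arrays
#'   `converged` and `at_bound`, the `mask`, and a `metadata` list.
#' @export
fit_volume <- function(stack, protocol, model = c("ispgr", "spgr"),
                       b1_sigma = 1, ...) {
  model <- match.arg(model)
  mask <- stack$mask
  idx <- which(mask > 0)
  if (!length(idx)) stop("mask is empty")
  b1 <- smooth_b1_map(stack$b1_ratio, b1_sigma)
  dims <- dim(mask)
  nm <- array(NA_real_, dims)
  maps <- list(T1 = nm, T2 = nm, M0 = nm, residual_norm = nm,
               converged = array(FALSE, dims), at_bound = array(FALSE, dims))
  nvol <- length(idx) # voxel count; volumes is [x, y, z, measurement]
  vols <- matrix(stack$volumes, nrow = prod(dims))
  for (v in idx) {
    fit <- fit_voxel(vols[v, ], protocol, alpha_scale = b1[v], model = model,
                     ...)
    maps$T1[v] <- fit$T1
    maps$T2[v] <- fit$T2
    maps$M0[v] <- fit$M0
    maps$residual_norm[v] <- fit$residual_norm
    maps$converged[v] <- fit$converged
    maps$at_bound[v] <- fit$at_bound
  }
  structure(c(maps, list(mask = mask,
                         metadata = list(model = model, b1_sigma = b1_sigma,
                                         protocol = protocol,
                                         n_voxels = nvol))),
            class = "parameter_maps")
}

#' Region-averaged fits (one fit per labeled region)
#'
#' Averages the measurement signals over each labeled region of the mask and
#' fits the averaged signal vector once per region — the alternative to
#' voxel-wise fitting followed by region averaging. The region's B1+ scaling
#' is the mean smoothed ratio over the region.
#'
#' @inheritParams fit_volume
#' @return A `data.frame` with one row per region label: `label`, `n_voxels`,
#'   `T1`, `T2`, `M0`, `residual_norm`, `converged`.
#' @export
fit_regions <- function(stack, protocol, model = c("ispgr", "spgr"),
                        b1_sigma = 1, ...) {
  model <- match.arg(model)
  labels <- sort(unique(stack$mask[stack$mask > 0]))
  if (!length(labels)) stop("mask is empty")
  b1 <- smooth_b1_map(stack$b1_ratio, b1_sigma)
  vols <- matrix(stack$volumes, nrow = prod(dim(stack$mask)))
  out <- lapply(labels, function(lb) {
    vox <- which(stack$mask == lb)
    fit <- fit_voxel(colMeans(vols[vox, , drop = FALSE]), protocol,
                     alpha_scale = mean(b1[vox]), model = model, ...)
    data.frame(label = lb, n_voxels = length(vox), T1 = fit$T1, T2 = fit$T2,
               M0 = fit$M0, residual_norm = fit$residual_norm,
               converged = fit$converged)
  })
  do.call(rbind, out)
}
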