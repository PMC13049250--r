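#' Image stack: multi-measurement volumes, B1+ map, and mask
#'
#' Container for the inputs of [fit_volume()]: one magnitude volume per
#' protocol measurement (4-D array, measurement last), a B1+
#' actual-to-nominal flip-angle ratio map, and an integer ROI label mask.
#'
#' @param volumes 4-D numeric array `[x, y, z, measurement]`.
#' @param b1_ratio 3-D array matching the spatial grid; default all 1.
#' @param mask 3-D integer (or logical) array of region labels; default all 1.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(volumes, b1_ratio = NULL, mask = NULL) {
  if (length(dim(volumes)) != 4)
    stop("volumes must be a 4-D array [x, y, z, measurement]")
  sp <- dim(volumes)[1:3]
  if (is.null(b1_ratio)) b1_ratio <- array(1, sp)
  if (is.null(mask)) mask <- array(1L, sp)
  mask <- array(as.integer(mask), dim(mask))
  if (!identical(dim(b1_ratio), sp) || !identical(dim(mask), sp))
    stop("volumes, b1_ratio, and mask must share the spatial grid")
  if (any(b1_ratio[mask > 0] <= 0))
    stop("b1_ratio must be positive inside the mask")
  structure(list(volumes = volumes, b1_ratio = b1_ratio, mask = mask),
            class = "image_stack")
}

#' Digital multi-vial relaxometry phantom
#'
#' Builds a voxelized phantom of cylindrical vials (constant T1/T2/M0 inside
#' each vial, zero-M0 background). The `standard_8vial` preset emulates an
#' 8-vial MnCl2 calibration phantom whose reference T1 values span 236-2013 ms
#' and T2 values span 15-328 ms; the intermediate per-vial values are
#' log-spaced between those printed endpoints (the manufacturer's per-vial
#' values are not public), so they are synthetic by construction and returned
#' as the ground truth table.
#'
#' @param preset `"standard_8vial"` or `"custom"` (supply `vials`).
#' @param grid_dim Spatial grid `(nx, ny, nz)`. The default 40 x 40 x 3 is a
#'   desk-scale matrix.
#' @param voxel_size Voxel size in mm, default `c(0.98, 0.98, 4)` (the
#'   reconstructed resolution of the emulated acquisition).
#' @param vials For `preset = "custom"`: `data.frame` with columns `cx`, `cy`
#'   (vial center, 1-based voxel coordinates), `radius` (voxels), `T1`, `T2`,
#'   `M0`. Vials must not overlap.
#' @return An object of class `digital_phantom`: arrays `label`, `T1`, `T2`,
#'   `M0`; the `vials` table; `grid_dim`; `voxel_size`.
#' @examples
#' ph <- make_phantom()
#' ph$vials
#' @export
make_phantom <- function(preset = c("standard_8vial", "custom"),
                         grid_dim = c(40, 40, 3),
                         voxel_size = c(0.98, 0.98, 4), vials = NULL) {
  preset <- match.arg(preset)
  grid_dim <- as.integer(grid_dim)
  if (preset == "standard_8vial") {
    if (!is.null(vials)) stop("supply vials only with preset = 'custom'")
    nv <- 8
    ring <- 0.325 * min(grid_dim[1:2])
    rad <- 0.10 * min(grid_dim[1:2])
    ang <- 2 * pi * (seq_len(nv) - 1) / nv
    cx0 <- (grid_dim[1] + 1) / 2
    cy0 <- (grid_dim[2] + 1) / 2
    vials <- data.frame(
      label = seq_len(nv),
      cx = cx0 + ring * cos(ang),
      cy = cy0 + ring * sin(ang),
      radius = rad,
      T1 = exp(seq(log(236), log(2013), length.out = nv)),
      T2 = exp(seq(log(15), log(328), length.out = nv)),
      M0 = 1)
  } else {
    if (is.null(vials)) stop("preset = 'custom' requires a vials table")
    req <- c("cx", "cy", "radius", "T1", "T2", "M0")
    if (!all(req %in% names(vials)))
      stop("custom vials need columns: ", paste(req, collapse = ", "))
    vials$label <- seq_len(nrow(vials))
  }
  # non-overlap check
  if (nrow(vials) > 1) {
    for (i in seq_len(nrow(vials) - 1)) for (j in (i + 1):nrow(vials)) {
      d <- sqrt((vials$cx[i] - vials$cx[j])^2 + (vials$cy[i] - vials$cy[j])^2)
      if (d < vials$radius[i] + vials$radius[j])
        stop("vials ", i, " and ", j, " overlap")
    }
  }
  label <- array(0L, grid_dim)
  xy <- expand.grid(x = seq_len(grid_dim[1]), y = seq_len(grid_dim[2]))
  sl <- matrix(0L, grid_dim[1], grid_dim[2])
  for (i in seq_len(nrow(vials))) {
    inside <- (xy$x - vials$cx[i])^2 + (xy$y - vials$cy[i])^2 <=
      vials$radius[i]^2
    sl[cbind(xy$x[inside], xy$y[inside])] <- vials$label[i]
  }
  for (z in seq_len(grid_dim[3])) label[, , z] <- sl
  lut <- function(col, bg) {
    v <- c(bg, vials[[col]])[label + 1L]
    array(v, grid_dim)
  }
  structure(list(label = label,
                 T1 = lut("T1", 0), T2 = lut("T2", 0), M0 = lut("M0", 0),
                 vials = vials, grid_dim = grid_dim,
                 voxel_size = voxel_size),
            class = "digital_phantom")
}

#' Noise model for simulated acquisitions
#'
#' The noise level is set through a signal-to-noise ratio: the noise standard
#' deviation is the mean noiseless signal of the reference measurement over
#' all nonzero-M0 voxels divided by `snr`. By default the reference
#' measurement is the one closest to flip angle 10 degrees at T_BS 13 ms (the
#' measurement nearest the Ernst angle for mid-range T1).
#'
#' @param kind `"gaussian_magnitude"` (additive Gaussian on the magnitude
#'   images) or `"rician"` (magnitude of a complex signal with independent
#'   Gaussian noise on both channels).
#' @param snr Signal-to-noise ratio, > 0.
#' @param reference Index of the reference measurement, or `NULL` to select
#'   the measurement closest to (alpha 10, T_BS 13).
#' @param seed Integer seed for reproducible noise.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("gaussian_magnitude", "rician"), snr = 30,
                        reference = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (!is.finite(snr) || snr <= 0) stop("snr must be positive")
  structure(list(kind = kind, snr = snr, reference = reference,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# index of the reference measurement used to define the SNR
.reference_index <- function(protocol, reference = NULL) {
  if (!is.null(reference)) return(as.integer(reference))
  m <- protocol$measurements
  which.min(abs(m$alpha - 10) + abs(m$T_BS - 13))
}

#' Forward-simulate a multi-measurement image stack from a phantom
#'
#' Evaluates the I-SPGR forward model (readout index `n`) per voxel and
#' measurement, with nominal flip angles scaled by the local B1+ ratio, and
#' optionally adds noise. The mask of the returned stack is the phantom's
#' vial label map; the ground truth and noise level are attached as
#' attributes.
#'
#' @param phantom A [make_phantom()] object.
#' @param protocol An [ispgr_protocol()] object.
#' @param b1_field Scalar or 3-D array of B1+ ratios (default 1 everywhere).
#' @param noise A [noise_model()] or `NULL` for a noiseless stack.
#' @param n Readout index of the forward model (default 1).
#' @return An [image_stack()] with attributes `truth` (the phantom), `sigma`
#'   (noise SD actually used, or 0), and `protocol`.
#' @examples
#' st <- simulate_stack(make_phantom(), protocol_preset("invivo_ispgr"))
#' @export
simulate_stack <- function(phantom, protocol, b1_field = 1, noise = NULL,
                           n = 1) {
  gd <- phantom$grid_dim
  m <- protocol$measurements
  if (length(b1_field) == 1) b1_field <- array(b1_field, gd)
  if (length(dim(b1_field)) != 3 || !all(dim(b1_field) == gd))
    stop("b1_field must be scalar or match the phantom grid")
  vols <- array(0, c(gd, nrow(m)))
  # zero-M0 background voxels give zero signal for any relaxation times;
  # substitute T1 = T2 = 1 there to avoid 0/0 in the exponentials
  bg <- phantom$M0 == 0
  T1s <- ifelse(bg, 1, phantom$T1)
  T2s <- ifelse(bg, 1, phantom$T2)
  for (j in seq_len(nrow(m))) {
    vols[, , , j] <- .ispgr_forward(T1s, T2s, phantom$M0,
                                    m$alpha[j] * b1_field, protocol$TR,
                                    protocol$k, protocol$T_FS, m$T_BS[j],
                                    m$T_Sp[j], n)
  }
  sigma <- 0
  if (!is.null(noise)) {
    ref <- .reference_index(protocol, noise$reference)
    refvol <- vols[, , , ref]
    sigma <- mean(refvol[phantom$M0 > 0]) / noise$snr
    set.seed(noise$seed)
    if (noise$kind == "gaussian_magnitude") {
      vols <- vols + array(rnorm(length(vols), sd = sigma), dim(vols))
    } else {
      n1 <- array(rnorm(length(vols), sd = sigma), dim(vols))
      n2 <- array(rnorm(length(vols), sd = sigma), dim(vols))
      vols <- sqrt((vols + n1)^2 + n2^2)
    }
  }
  st <- image_stack(vols, b1_ratio = b1_field, mask = phantom$label)
  attr(st, "truth") <- phantom
  attr(st, "sigma") <- sigma
  attr(st, "protocol") <- protocol
  st
}

#' Paired replicate acquisitions for repeatability analysis
#'
#' Simulates `n_pairs` pairs of stacks sharing the phantom and protocol but
#' with independent noise draws (seeds `seed`, `seed + 1`, `seed + 2`, ...),
#' the synthetic analogue of repeated same-day scans.
#'
#' @inheritParams simulate_stack
#' @param noise A [noise_model()]; its `seed` seeds the first replicate.
#' @param n_pairs Number of replicate pairs, >= 1.
#' @return A list of `n_pairs` lists, each with elements `a` and `b`.
#' @export
paired_replicates <- function(phantom, protocol, noise, n_pairs = 1,
                              b1_field = 1) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  lapply(seq_len(n_pairs), function(i) {
    sa <- noise; sa$seed <- noise$seed + 2L * (i - 1L)
    sb <- noise; sb$seed <- noise$seed + 2L * (i - 1L) + 1L
    list(a = simulate_stack(phantom, protocol, b1_field, sa),
         b = simulate_stack(phantom, protocol, b1_field, sb))
  })
}
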