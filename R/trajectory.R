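#' One pseudo-spiral arm on the Cartesian phase-encode grid
#'
#' The arm is defined parametrically by `r = -x^2 + 2x` and `phi = 2*pi*x +
#' rotation` for `x` sampled uniformly on \[0, 1\] (`points_per_arm` points,
#' endpoints included). The polar point `(r, phi)` is mapped onto the
#' rectangular `(ky, kz)` grid anisotropically, so that `r = 1` reaches both
#' grid extents, then rounded to the nearest integer index and clipped to the
#' grid. Indices are 0-based with the DC point at `floor(n/2)` along each
#' axis. Because `r` is monotone increasing in `x`, every arm runs
#' center-outward: the first sample of each arm is the grid center.
#'
#' Duplicate indices after rounding (frequent near the center) are retained:
#' the acquisition plays all `k` readouts regardless of gridding collisions.
#'
#' @param rotation Arm rotation (degrees).
#' @param grid `(n_ky, n_kz)` matrix size.
#' @param points_per_arm Number of sampled points along the arm.
#' @return A `data.frame` with columns `order` (1-based sample order), `ky`,
#'   `kz` (0-based grid indices).
#' @examples
#' spiral_arm(0)
#' @export
spiral_arm <- function(rotation = 0, grid = c(178, 30), points_per_arm = 30) {
  if (any(grid < 1)) stop("grid dimensions must be >= 1")
  if (points_per_arm < 1) stop("points_per_arm must be >= 1")
  x <- if (points_per_arm == 1) 0 else seq(0, 1, length.out = points_per_arm)
  r <- -x^2 + 2 * x
  phi <- 2 * pi * x + rotation * pi / 180
  cy <- floor(grid[1] / 2)
  cz <- floor(grid[2] / 2)
  ky <- pmin(pmax(round(r * cos(phi) * grid[1] / 2) + cy, 0), grid[1] - 1)
  kz <- pmin(pmax(round(r * sin(phi) * grid[2] / 2) + cz, 0), grid[2] - 1)
  data.frame(order = seq_len(points_per_arm), ky = ky, kz = kz)
}

#' Golden-angle pseudo-spiral Cartesian trajectory plan
#'
#' Generates `n_shots` spiral arms, arm `i` rotated by `(i - 1) *
#' golden_angle` degrees, each gridded with [spiral_arm()]. One arm is played
#' per shot, so the first readout of every shot (immediately after the
#' preparation block) samples the center of k-space, and later readouts move
#' outward. Successive golden-angle rotations give dense central coverage
#' while the periphery stays undersampled. The plan is fully deterministic.
#'
#' @param n_shots Number of shots (arms), >= 1.
#' @param grid `(n_ky, n_kz)` matrix size.
#' @param points_per_arm Sampled points per arm.
#' @param golden_angle Rotation between successive arms (degrees).
#' @return A `data.frame` of class `trajectory_plan` with columns `shot`,
#'   `order`, `ky`, `kz`, and the generation parameters as attributes.
#' @examples
#' plan <- generate_trajectory(n_shots = 3)
#' @export
generate_trajectory <- function(n_shots, grid = c(178, 30),
                                points_per_arm = 30, golden_angle = 137) {
  if (n_shots < 1) stop("n_shots must be >= 1")
  arms <- lapply(seq_len(n_shots), function(i) {
    arm <- spiral_arm((i - 1) * golden_angle, grid, points_per_arm)
    cbind(shot = i, arm)
  })
  plan <- do.call(rbind, arms)
  rownames(plan) <- NULL
  structure(plan, class = c("trajectory_plan", "data.frame"),
            grid = grid, points_per_arm = points_per_arm,
            golden_angle = golden_angle, n_shots = n_shots)
}

# normalized elliptical radius of 0-based grid indices (1 = grid edge)
.norm_radius <- function(ky, kz, grid) {
  cy <- floor(grid[1] / 2)
  cz <- floor(grid[2] / 2)
  sqrt(((ky - cy) / (grid[1] / 2))^2 + ((kz - cz) / (grid[2] / 2))^2)
}

#' Radial sampling-density report for a trajectory plan
#'
#' Bins all grid points by normalized elliptical radius and reports, per bin,
#' the fraction of grid points sampled at least once and the mean number of
#' visits per grid point.
#'
#' @param plan A `trajectory_plan` from [generate_trajectory()].
#' @param n_bins Number of radius bins.
#' @return A `data.frame` with columns `r_lo`, `r_hi`, `n_grid`,
#'   `fraction_sampled`, `mean_visits`.
#' @export
sampling_report <- function(plan, n_bins = 10) {
  grid <- attr(plan, "grid")
  gk <- expand.grid(ky = 0:(grid[1] - 1), kz = 0:(grid[2] - 1))
  gk$r <- .norm_radius(gk$ky, gk$kz, grid)
  key_all <- gk$ky * grid[2] + gk$kz
  key_smp <- plan$ky * grid[2] + plan$kz
  visits <- tabulate(match(key_smp, key_all), nbins = length(key_all))
  breaks <- seq(0, max(gk$r), length.out = n_bins + 1)
  bin <- cut(gk$r, breaks, include.lowest = TRUE, labels = FALSE)
  out <- lapply(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    data.frame(r_lo = breaks[b], r_hi = breaks[b + 1], n_grid = length(idx),
               fraction_sampled = if (length(idx)) mean(visits[idx] > 0) else NA_real_,
               mean_visits = if (length(idx)) mean(visits[idx]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Unique-sample density of the central disc versus the outer annulus
#'
#' Fraction of grid points sampled at least once inside the central disc of
#' normalized radius `r_disc`, and in the outer radial band `r > r_outer` of
#' the grid. The outer band includes the rectangle's corners (normalized
#' radius above 1), which the spiral — confined to the inscribed ellipse —
#' can never reach: the genuinely undersampled periphery. Within the
#' inscribed ellipse the arm endpoints pile up at `r = 1`, so unique coverage
#' there is not representative of peripheral undersampling; visit density
#' (see [sampling_report()]) falls off from the center regardless.
#'
#' @param plan A `trajectory_plan`.
#' @param r_disc Normalized radius of the central disc (default 0.1).
#' @param r_outer Inner edge of the outer band (default 0.9).
#' @return A list with elements `disc` and `annulus` (sampled fractions).
#' @export
center_density <- function(plan, r_disc = 0.1, r_outer = 0.9) {
  grid <- attr(plan, "grid")
  gk <- expand.grid(ky = 0:(grid[1] - 1), kz = 0:(grid[2] - 1))
  gk$r <- .norm_radius(gk$ky, gk$kz, grid)
  key_all <- gk$ky * grid[2] + gk$kz
  sampled <- key_all %in% (plan$ky * grid[2] + plan$kz)
  list(disc = mean(sampled[gk$r <= r_disc]),
       annulus = mean(sampled[gk$r > r_outer]))
}

#' Write a trajectory plan to CSV
#'
#' @param plan A `trajectory_plan`.
#' @param path Output CSV path (columns `shot`, `order`, `ky`, `kz`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(plan, path) {
  write.csv(as.data.frame(plan), path, row.names = FALSE)
  invisible(path)
}

#' Boolean sampling mask of a trajectory plan
#'
#' @param plan A `trajectory_plan`.
#' @return A logical `n_ky x n_kz` matrix, TRUE where sampled at least once.
#' @export
sampling_mask <- function(plan) {
  grid <- attr(plan, "grid")
  m <- matrix(FALSE, grid[1], grid[2])
  m[cbind(plan$ky + 1, plan$kz + 1)] <- TRUE
  m
}
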