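#' Tissue relaxation parameters
#'
#' Bundles the longitudinal relaxation time T1, the transverse relaxation
#' time T2, and the equilibrium magnetization M0 of one voxel or isochromat.
#' All times are in milliseconds; M0 is in arbitrary units.
#'
#' T2 > T1 is physically implausible for most tissues but is permitted with a
#' warning, because least-squares fitting bounds allow such combinations to be
#' visited during optimization.
#'
#' @param T1 Longitudinal relaxation time (ms), > 0.
#' @param T2 Transverse relaxation time (ms), > 0.
#' @param M0 Equilibrium magnetization (a.u.), >= 0. Default 1.
#' @return An object of class `tissue_params`.
#' @examples
#' tissue_params(T1 = 800, T2 = 50)
#' @export
tissue_params <- function(T1, T2, M0 = 1) {
  if (!is.finite(T1) || T1 <= 0) stop("T1 must be a positive number (ms)")
  if (!is.finite(T2) || T2 <= 0) stop("T2 must be a positive number (ms)")
  if (!is.finite(M0) || M0 < 0) stop("M0 must be a nonnegative number")
  if (T2 > T1) warning("T2 > T1 is physically implausible (allowed for fitting)")
  structure(list(T1 = T1, T2 = T2, M0 = M0), class = "tissue_params")
}

#' Sequence timing and flip-angle parameters of one I-SPGR shot
#'
#' One shot consists of a readout block of `k` RF excitations spaced `TR`
#' apart, followed by a preparation block: a fat-suppression-plus-gap period
#' `T_FS` (pure T1 relaxation for on-resonance spins), a blood-suppression
#' period `T_BS` during which the magnetization is stored transverse and
#' decays with T2, and a spoiling period `T_Sp` (T1 relaxation).
#'
#' @param TR Repetition time between RF pulses within the readout block (ms).
#' @param alpha Excitation flip angle (degrees), in \[0, 90\].
#' @param k Number of readouts (RF pulses) per shot, >= 1.
#' @param T_FS Fat-suppression plus temporal-gap duration (ms), >= 0.
#' @param T_BS Blood-suppression transverse duration (ms), >= 0.
#' @param T_Sp Spoiling duration (ms), >= 0.
#' @return An object of class `seq_params`.
#' @examples
#' seq_params(TR = 5, alpha = 15, k = 20, T_FS = 50, T_BS = 12, T_Sp = 6)
#' @export
seq_params <- function(TR, alpha, k = 1, T_FS = 0, T_BS = 0, T_Sp = 0) {
  if (!is.finite(TR) || TR <= 0) stop("TR must be positive (ms)")
  if (!is.finite(alpha) || alpha < 0 || alpha > 90)
    stop("alpha must lie in [0, 90] degrees")
  if (!is.finite(k) || k < 1 || k != round(k)) stop("k must be an integer >= 1")
  for (d in c(T_FS = T_FS, T_BS = T_BS, T_Sp = T_Sp))
    if (!is.finite(d) || d < 0) stop("preparation durations must be >= 0 (ms)")
  structure(list(TR = TR, alpha = alpha, k = as.integer(k),
                 T_FS = T_FS, T_BS = T_BS, T_Sp = T_Sp),
            class = "seq_params")
}

#' Relaxation attenuation factors of one shot
#'
#' The four exponential factors that drive the semi-steady-state signal:
#' `E1 = exp(-TR/T1)`, `E_FS = exp(-T_FS/T1)`, `E_BS = exp(-T_BS/T2)`, and
#' `E_Sp = exp(-T_Sp/T1)`. Each lies in (0, 1].
#'
#' @param tissue A [tissue_params()] object.
#' @param seq A [seq_params()] object.
#' @return A list with elements `E1`, `E_FS`, `E_BS`, `E_Sp`.
#' @export
relaxation_factors <- function(tissue, seq) {
  list(E1 = exp(-seq$TR / tissue$T1),
       E_FS = exp(-seq$T_FS / tissue$T1),
       E_BS = exp(-seq$T_BS / tissue$T2),
       E_Sp = exp(-seq$T_Sp / tissue$T1))
}

# (1 - r^m) / (1 - r) with the r -> 1 limit m; vectorized with recycling.
.geom_series <- function(r, m) {
  out <- suppressWarnings((1 - r^m) / (1 - r))
  near1 <- rep_len(abs(1 - r) < 1e-12, length(out)) | !is.finite(out)
  if (any(near1)) out[near1] <- rep_len(m, length(out))[near1]
  out
}

# Vectorized forward model: semi-steady-state I-SPGR signal after RF pulse n.
# All arguments recycle elementwise. Times in ms, flip angle in degrees.
# A tissue with M0 = 0 (and T1 = T2 = 0 allowed as background convention)
# returns exactly 0.
.ispgr_forward <- function(T1, T2, M0, alpha_deg, TR, k, T_FS, T_BS, T_Sp,
                           n = 1) {
  a <- alpha_deg * (pi / 180)
  E1 <- exp(-TR / T1)
  E_FS <- exp(-T_FS / T1)
  E_BS <- exp(-T_BS / T2)
  E_Sp <- exp(-T_Sp / T1)
  C <- E1 * cos(a)
  Q <- E_Sp * E_BS * E_FS
  M1 <- M0 * ((1 - E_Sp) + (1 - E_FS) * E_Sp * E_BS +
                Q * (1 - E1) * .geom_series(C, k)) / (1 - Q * C^k)
  sin(a) * (M0 * (1 - E1) * .geom_series(C, n - 1) + M1 * C^(n - 1))
}

# Vectorized Ernst (steady-state SPGR) signal.
.ernst <- function(T1, M0, TR, alpha_deg) {
  a <- alpha_deg * (pi / 180)
  E1 <- exp(-TR / T1)
  denom <- 1 - cos(a) * E1
  small <- abs(denom) < 1e-14
  out <- M0 * sin(a) * (1 - E1) / denom
  # analytic limit: as E1 -> 1 with alpha -> 0 the signal tends to 0
  if (any(small)) out[rep_len(small, length(out))] <- 0
  out
}

#' Steady-state SPGR signal (Ernst equation)
#'
#' `S = M0 sin(alpha) (1 - E1) / (1 - cos(alpha) E1)` with
#' `E1 = exp(-TR/T1)`: the steady-state signal of a perfectly spoiled
#' gradient-echo sequence.
#'
#' @param tissue A [tissue_params()] object (T2 is not used).
#' @param TR Repetition time (ms), > 0.
#' @param alpha Flip angle (degrees); may be a vector.
#' @return Signal in the same arbitrary units as `M0`.
#' @examples
#' ernst_signal(tissue_params(500, 50), TR = 5, alpha = 15)
#' @export
ernst_signal <- function(tissue, TR, alpha) {
  if (!is.finite(TR) || TR <= 0) stop("TR must be positive (ms)")
  .ernst(tissue$T1, tissue$M0, TR, alpha)
}

#' Semi-steady-state I-SPGR signal at readout index n
#'
#' Closed-form signal after the n-th RF pulse of a shot, once the sequence has
#' reached its semi steady state (the same within-shot evolution repeating
#' shot after shot). With all preparation durations zero the expression
#' collapses algebraically to the Ernst equation for every `n`.
#'
#' @param tissue A [tissue_params()] object.
#' @param seq A [seq_params()] object.
#' @param n Readout index (1-based position within the shot); may be a vector
#'   with all entries in `[1, seq$k]`.
#' @return Signal value(s), arbitrary units.
#' @examples
#' s <- seq_params(TR = 5, alpha = 15, k = 20, T_FS = 50, T_BS = 12, T_Sp = 6)
#' ispgr_signal(tissue_params(500, 25), s, n = 1:20)
#' @export
ispgr_signal <- function(tissue, seq, n = 1) {
  if (any(n < 1 | n > seq$k)) stop("readout index n must lie in [1, k]")
  .ispgr_forward(tissue$T1, tissue$T2, tissue$M0, seq$alpha, seq$TR, seq$k,
                 seq$T_FS, seq$T_BS, seq$T_Sp, n)
}

#' Longitudinal magnetization at the end of the preparation block
#'
#' The semi-steady-state longitudinal magnetization just before the first RF
#' pulse of a shot (equal to `M_{n=1}`), so that
#' `ispgr_signal(tissue, seq, n = 1) == sin(alpha) * end_prep_magnetization(...)`.
#'
#' @inheritParams ispgr_signal
#' @return Longitudinal magnetization, same units as `M0`.
#' @export
end_prep_magnetization <- function(tissue, seq) {
  a <- seq$alpha * pi / 180
  if (abs(sin(a)) < 1e-12) {
    f <- relaxation_factors(tissue, seq)
    C <- f$E1 * cos(a)
    Q <- f$E_Sp * f$E_BS * f$E_FS
    return(tissue$M0 * ((1 - f$E_Sp) + (1 - f$E_FS) * f$E_Sp * f$E_BS +
                          Q * (1 - f$E1) * .geom_series(C, seq$k)) /
             (1 - Q * C^seq$k))
  }
  ispgr_signal(tissue, seq, n = 1) / sin(a)
}

#' Forward model vector for a measurement protocol
#'
#' Evaluates the I-SPGR signal at readout index `n` for every measurement of a
#' protocol (each measurement being an `(alpha, T_BS, T_Sp)` triple sharing the
#' protocol's TR, k, and T_FS). This is the forward model used by the joint
#' T1/T2/M0 fit; `n = 1` is the default because central k-space is sampled by
#' the first readout of each shot.
#'
#' @param tissue A [tissue_params()] object.
#' @param protocol An [ispgr_protocol()] object.
#' @param n Readout index used for all measurements (default 1).
#' @param alpha_scale Dimensionless B1+ scaling applied to all nominal flip
#'   angles (default 1).
#' @return Numeric vector with one signal per measurement, in protocol order.
#' @examples
#' p <- protocol_preset("invivo_ispgr")
#' model_vector(tissue_params(800, 50), p)
#' @export
model_vector <- function(tissue, protocol, n = 1, alpha_scale = 1) {
  m <- protocol$measurements
  if (nrow(m) == 0) stop("protocol has no measurements")
  .ispgr_forward(tissue$T1, tissue$T2, tissue$M0,
                 m$alpha * alpha_scale, protocol$TR, protocol$k,
                 protocol$T_FS, m$T_BS, m$T_Sp, n)
}
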