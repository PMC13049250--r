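#' Per-region accuracy (bias) table
#'
#' Compares region-mean fitted T1/T2 against reference values, for one or more
#' fitted models (e.g. the I-SPGR fit and the naive SPGR fit of the same
#' data). Error is defined as `fitted - reference` (ms). Only converged voxels
#' enter the region means; empty regions are dropped with a warning.
#'
#' @param maps_by_model Named list of [fit_volume()] results (names are model
#'   labels), or a single `parameter_maps` object.
#' @param label_map Integer array of region labels (e.g. the phantom's vial
#'   label map).
#' @param reference `data.frame` with columns `label`, `T1`, `T2` (reference
#'   values in ms; `T2` may be `NA` for T1-only models).
#' @return A `data.frame` of class `bias_table` with columns `model`, `label`,
#'   `parameter`, `reference`, `fitted`, `error`. The grand mean error per
#'   model and parameter is available via [bias_summary()].
#' @export
bias_table <- function(maps_by_model, label_map, reference) {
  if (inherits(maps_by_model, "parameter_maps"))
    maps_by_model <- list(fit = maps_by_model)
  stopifnot(all(c("label", "T1", "T2") %in% names(reference)))
  rows <- list()
  for (mod in names(maps_by_model)) {
    maps <- maps_by_model[[mod]]
    for (i in seq_len(nrow(reference))) {
      lb <- reference$label[i]
      vox <- which(label_map == lb & maps$converged)
      if (!length(vox)) {
        warning("region ", lb, " has no converged voxels in model '", mod,
                "'; excluded")
        next
      }
      for (par in c("T1", "T2")) {
        ref <- reference[[par]][i]
        if (is.na(ref)) next
        fitted <- mean(maps[[par]][vox], na.rm = TRUE)
        if (is.nan(fitted)) fitted <- NA_real_
        rows[[length(rows) + 1]] <-
          data.frame(model = mod, label = lb, parameter = par,
                     reference = ref, fitted = fitted,
                     error = fitted - ref)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("bias_table", "data.frame"))
}

#' Grand mean bias per model and parameter
#'
#' @param tab A [bias_table()].
#' @return `data.frame` with columns `model`, `parameter`, `mean_error`.
#' @export
bias_summary <- function(tab) {
  ag <- aggregate(error ~ model + parameter, data = as.data.frame(tab),
                  FUN = mean)
  names(ag)[names(ag) == "error"] <- "mean_error"
  ag
}

#' Monte-Carlo noise sensitivity of the joint fit
#'
#' For every (T1, T2) cell of a ground-truth grid, generates the noiseless
#' signal vector under the protocol, adds Gaussian noise at the requested SNR,
#' fits T1/T2/M0 with [fit_voxel()], and summarizes the absolute relative
#' estimation errors over `n_reps` repetitions. Fits that end on a bound are
#' kept as boundary-value estimates rather than dropped, so boundary pile-up
#' degrades (rather than flatters) the reported precision.
#'
#' Noise is an acquisition property, not a tissue property, so by default one
#' noise standard deviation is used for the whole map
#' (`snr_scope = "grid"`): the reference-measurement signal averaged over all
#' grid cells, divided by `snr` — the grid analogue of defining a stack's SNR
#' from the object-averaged reference signal. Tissues with weaker signals
#' (short T2, strong suppression decay) therefore see a lower effective SNR,
#' as they would on a scanner. `snr_scope = "cell"` instead scales the noise
#' to each cell's own reference signal.
#'
#' @param protocol An [ispgr_protocol()] object.
#' @param t1_grid,t2_grid Ground-truth grids (ms).
#' @param snr Signal-to-noise ratio of the added Gaussian noise.
#' @param n_reps Noise realizations per cell.
#' @param seed Integer seed; the map is reproducible from it.
#' @param summary `"median"` (default; robust to boundary pile-up) or
#'   `"mean"` over repetitions.
#' @param reference Reference measurement index for the SNR definition
#'   (`NULL`: closest to alpha 10, T_BS 13; see [noise_model()]).
#' @param snr_scope `"grid"` (one noise SD for the whole map, default) or
#'   `"cell"` (noise SD per cell).
#' @param ... Further arguments passed to [fit_voxel()].
#' @return A `data.frame` of class `sensitivity_map` with columns `T1_true`,
#'   `T2_true`, `t1_err_pct`, `t2_err_pct`, `m0_err_pct` (summarized absolute
#'   relative errors, percent of ground truth), plus `snr`, `n_reps`, `seed`
#'   attributes.
#' @export
sensitivity_analysis <- function(protocol, t1_grid = c(300, 700, 1100, 1500,
                                                       2000, 2500),
                                 t2_grid = c(20, 30, 40, 60, 100, 150, 200),
                                 snr = 30, n_reps = 100, seed = 1,
                                 summary = c("median", "mean"),
                                 reference = NULL,
                                 snr_scope = c("grid", "cell"), ...) {
  summary <- match.arg(summary)
  snr_scope <- match.arg(snr_scope)
  if (!length(t1_grid) || !length(t2_grid)) stop("grids must be non-empty")
  if (snr <= 0) stop("snr must be positive")
  sfun <- if (summary == "median") stats::median else mean
  ref <- .reference_index(protocol, reference)
  cells <- expand.grid(T1_true = t1_grid, T2_true = t2_grid)
  nm <- nrow(protocol$measurements)
  s0_all <- lapply(seq_len(nrow(cells)), function(i)
    model_vector(tissue_params(cells$T1_true[i], cells$T2_true[i], 1),
                 protocol))
  sigma_grid <- mean(vapply(s0_all, `[`, numeric(1), ref)) / snr
  set.seed(seed)
  res <- matrix(NA_real_, nrow(cells), 3)
  for (i in seq_len(nrow(cells))) {
    s0 <- s0_all[[i]]
    sigma <- if (snr_scope == "grid") sigma_grid else s0[ref] / snr
    err <- matrix(NA_real_, n_reps, 3)
    for (r in seq_len(n_reps)) {
      y <- s0 + rnorm(nm, sd = sigma)
      fit <- fit_voxel(y, protocol, ...)
      err[r, ] <- 100 * abs(c(fit$T1 - cells$T1_true[i],
                              fit$T2 - cells$T2_true[i], fit$M0 - 1) /
                              c(cells$T1_true[i], cells$T2_true[i], 1))
    }
    res[i, ] <- apply(err, 2, sfun, na.rm = TRUE)
  }
  out <- cbind(cells, t1_err_pct = res[, 1], t2_err_pct = res[, 2],
               m0_err_pct = res[, 3])
  structure(out, class = c("sensitivity_map", "data.frame"),
            snr = snr, n_reps = n_reps, seed = seed, summary = summary,
            snr_scope = snr_scope)
}

#' Repeatability statistics from paired measurements
#'
#' Bland-Altman mean difference and 95% limits of agreement, and the
#' within-subject coefficient of variation
#' `wCV = sqrt(mean(d^2) / 2) / grand mean`, where `d` are the paired
#' differences (the within-subject SD of paired replicates is
#' `sqrt(mean(d^2)/2)`).
#'
#' @param x1,x2 Paired measurement vectors (e.g. region medians from two
#'   replicate scans), length >= 2.
#' @return An object of class `repeatability_result`: `mean_difference`,
#'   `loa_lower`, `loa_upper` (mean difference -/+ 1.96 SD of differences),
#'   `wcv`, `n_pairs`.
#' @examples
#' repeatability(c(100, 200), c(102, 196))
#' @export
repeatability <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  if (length(x1) < 2) stop("at least 2 pairs are required")
  d <- x1 - x2
  gm <- mean(c(x1, x2))
  if (gm == 0) stop("grand mean is zero: wCV undefined")
  md <- mean(d)
  s <- sd(d)
  structure(list(mean_difference = md,
                 loa_lower = md - 1.96 * s, loa_upper = md + 1.96 * s,
                 wcv = sqrt(mean(d^2) / 2) / gm,
                 n_pairs = length(x1)),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf(
    "Repeatability over %d pairs: mean diff %.4g, 95%% LoA [%.4g, %.4g], wCV %.4g\n",
    x$n_pairs, x$mean_difference, x$loa_lower, x$loa_upper, x$wcv))
  invisible(x)
}

#' ROI summary: median and interquartile range per parameter
#'
#' Summarizes T1, T2, and M0 over the masked, converged voxels of a parameter
#' map set. Quantiles use the linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param maps A [fit_volume()] result.
#' @param mask Optional logical/integer array restricting the summary (voxels
#'   with `mask > 0`); default: the maps' own mask.
#' @return `data.frame` with columns `parameter`, `median`, `q25`, `q75`, `n`.
#' @export
roi_summary <- function(maps, mask = NULL) {
  if (is.null(mask)) mask <- maps$mask
  sel <- mask > 0 & maps$converged
  if (!any(sel)) stop("no converged voxels in the mask")
  out <- lapply(c("T1", "T2", "M0"), function(par) {
    v <- maps[[par]][sel]
    v <- v[is.finite(v)]
    if (!length(v))
      return(data.frame(parameter = par, median = NA_real_, q25 = NA_real_,
                        q75 = NA_real_, n = 0L))
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(parameter = par, median = median(v), q25 = q[1], q75 = q[2],
               n = length(v))
  })
  do.call(rbind, out)
}

#' Normality-gated correlation of ROI medians with a covariate
#'
#' Applies the Shapiro-Wilk test to both variables; if both are compatible
#' with normality (p >= 0.05) Pearson's correlation is used, otherwise
#' Spearman's rank correlation. This is the gate used when correlating fitted
#' median relaxation times against aneurysm diameter.
#'
#' @param medians Numeric vector (e.g. per-subject median T1), length >= 3.
#' @param diameters Numeric vector of the same length (e.g. maximum aneurysm
#'   diameter, mm).
#' @return A list: `method` ("pearson" or "spearman"), `estimate`, `p_value`,
#'   `shapiro_p` (both variables' Shapiro-Wilk p-values).
#' @export
correlate_with_diameter <- function(medians, diameters) {
  if (length(medians) != length(diameters))
    stop("medians and diameters must have equal length")
  if (length(medians) < 3) stop("at least 3 paired values are required")
  if (sd(medians) == 0 || sd(diameters) == 0)
    stop("correlation undefined for a constant input vector")
  sw1 <- shapiro.test(medians)$p.value
  sw2 <- shapiro.test(diameters)$p.value
  method <- if (sw1 >= 0.05 && sw2 >= 0.05) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(medians, diameters, method = method,
                                  exact = FALSE))
  list(method = method, estimate = unname(ct$estimate),
       p_value = ct$p.value, shapiro_p = c(medians = sw1, diameters = sw2))
}
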