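# Phenotype layer: marker readouts, the immunoblot heterogeneity correction,
# Hill and monoexponential compression of dose-response / time-series data,
# mutant-over-WT ratios and panel scoring.

marker_patterns <- list(
  cAMP = "^cAMP$",
  D32p34 = "D32p@34",
  D32p75 = "D32p@75",
  STEPp = "STEP2?p@S",
  ERKpp = "ERKp@Tp@Y",
  GluR1p845 = "GluR1p@845",
  RASRAF = "RASgtp\\.RAF"
)

#' Marker value of a state or trajectory
#'
#' Markers sum all species carrying the phospho-form (free and in complexes),
#' as an immunoblot would.  `STEPact` is the non-phosphorylated fraction of
#' total STEP; `RASRAF_fraction` is the RAS-RAF complex over total RAS;
#' `NMDAR_current_scale` is the Ca2+ scaling factor of the trajectory.
#'
#' @param x an `msn_traj` or a named state vector.
#' @param marker marker name.
#' @param t readout time (s), for trajectories; defaults to the protocol
#'   readout stored in the trajectory.
#' @param network network (needed for totals-based markers when `x` is a
#'   state vector).
#' @return Marker value (uM, fraction, or scale).
#' @export
readout <- function(x, marker, t = NULL, network = NULL) {
  if (inherits(x, "msn_traj")) {
    tt <- if (is.null(t)) max(x$times) else t
    if (tt < min(x$times) || tt > max(x$times)) stop("t outside trajectory span")
    if (marker == "NMDAR_current_scale")
      return(stats::approx(x$times, x$scale, tt)$y)
    y <- traj_state(x, tt)
    return(state_marker(y, marker))
  }
  if (marker == "NMDAR_current_scale")
    stop("NMDAR_current_scale needs a trajectory")
  state_marker(x, marker)
}

#' Marker value of a named state vector
#'
#' Lower-level companion of [readout()]: sums the species carrying a marker
#' in a named concentration vector (e.g. an equilibrated state or one row of
#' a trajectory).
#'
#' @param y named state vector (uM).
#' @param marker marker name (see [readout()]).
#' @return Marker value.
#' @export
state_marker <- function(y, marker) {
  nm <- names(y)
  msum <- function(pat) sum(y[grepl(pat, nm)])
  switch(marker,
         STEPact = {
           tot <- msum("STEP")
           1 - msum(marker_patterns$STEPp) / tot
         },
         RASRAF_fraction = msum(marker_patterns$RASRAF) / msum("RAS"),
         {
           pat <- marker_patterns[[marker]]
           if (is.null(pat)) stop("unknown marker: ", marker)
           msum(pat)
         })
}

#' Immunoblot heterogeneity correction
#'
#' Inverts the two-population mixture behind a Western-blot fold change
#' measured in a cellularly heterogeneous sample.  Forward model: a fraction
#' `f_t` of cells in the treated sample (and `f_c` in the control) carry the
#' cell-specific fold change `FC` over basal while the rest sit at basal, so
#' the blot reports `W = (1 + f_t (FC - 1)) / (1 + f_c (FC - 1))`.  Solving
#' for the cell-specific fold change gives
#' `FC = 1 + (W - 1) / (f_t - W f_c)`.  With no positive cells in the
#' control and a fully responding sample (`f_c = 0`, `f_t = 1`) the
#' correction vanishes and `FC = W`; `W = 1` always maps to `FC = 1`.
#'
#' @param W measured fold change over basal.
#' @param f_c,f_t fraction of marker-positive cells (immunohistochemistry)
#'   in control and treatment; must lie in `[0, 1]` with `f_t > 0`.
#' @return Cell-specific fold change `FC`.
#' @export
ib_correction <- function(W, f_c, f_t) {
  if (any(W <= 0)) stop("W must be positive")
  if (any(f_c < 0 | f_c > 1) || any(f_t <= 0 | f_t > 1))
    stop("fractions must lie in (0, 1]")
  out <- numeric(length(W))
  one <- abs(W - 1) < 1e-12
  out[one] <- 1
  den <- f_t - W * f_c
  if (any(!one & den <= 0))
    stop("mixture not invertible: need f_t > W * f_c")
  out[!one] <- 1 + (W[!one] - 1) / den[!one]
  out
}

#' Forward immunoblot mixture
#'
#' The Western-blot fold change a heterogeneous sample would report for a
#' cell-specific fold change `FC` (see [ib_correction()]).
#' @inheritParams ib_correction
#' @param FC cell-specific fold change.
#' @export
ib_mixture <- function(FC, f_c, f_t) {
  (1 + f_t * (FC - 1)) / (1 + f_c * (FC - 1))
}

#' Fit the Hill equation to a dose response
#'
#' `y = Cmin + (Cmax - Cmin) x^h / (K^h + x^h)` by least squares.
#'
#' @param doses,responses numeric vectors (>= 5 points spanning K).
#' @return List with `Cmin`, `Cmax`, `K`, `h`, `r2` and the `fit` object.
#' @export
fit_hill <- function(doses, responses) {
  stopifnot(length(doses) == length(responses), length(doses) >= 5)
  rng <- diff(range(responses))
  if (rng < 0.02 * max(abs(responses), 1e-12))
    stop("flat response: K and h unidentifiable")
  d <- data.frame(x = doses, y = responses)
  half <- min(responses) + rng / 2
  K0 <- stats::approx(responses, doses, half, ties = "ordered")$y
  if (is.na(K0) || K0 <= 0) K0 <- stats::median(doses)
  fit <- minpack.lm::nlsLM(
    y ~ Cmin + (Cmax - Cmin) * x^h / (K^h + x^h), data = d,
    start = list(Cmin = min(responses), Cmax = max(responses), K = K0, h = 2),
    lower = c(-Inf, -Inf, 1e-9, 0.1), upper = c(Inf, Inf, Inf, 30),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((responses - mean(responses))^2)
  list(Cmin = unname(co["Cmin"]), Cmax = unname(co["Cmax"]),
       K = unname(co["K"]), h = unname(co["h"]), r2 = r2, fit = fit)
}

#' Fit a monoexponential rise
#'
#' `y = A (1 - exp(-k t))`; values should be baseline-subtracted so the
#' curve starts at 0.
#'
#' @param times,values numeric vectors.
#' @return List with `A`, `k`, `r2` and the `fit` object.
#' @export
fit_monoexp <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (diff(range(values)) < 1e-9 * max(abs(values), 1e-12)) {
    warning("constant data: rate unidentifiable, returning k = 0")
    return(list(A = mean(values), k = 0, r2 = NA_real_, fit = NULL))
  }
  if (any(diff(stats::smooth(values)) < -0.2 * diff(range(values))))
    warning("markedly non-monotone data for a monoexponential fit")
  d <- data.frame(t = times, y = values)
  A0 <- max(values)
  k0 <- 1 / max(times[which(values >= 0.63 * A0)][1], times[2])
  fit <- minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = d,
                           start = list(A = A0, k = k0),
                           lower = c(0, 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((values - mean(values))^2)
  list(A = unname(co["A"]), k = unname(co["k"]), r2 = r2, fit = fit)
}

#' Mutant-over-WT ratio of fold changes
#'
#' `(mutant marker fold over its saline arm) / (WT fold over its saline arm)`
#' at matched readout time.
#'
#' @param mutant_traj,mutant_saline,wt_traj,wt_saline trajectories sharing
#'   protocol timing.
#' @param marker marker name.
#' @param t readout time (s).
#' @return The ratio.
#' @export
wt_ratio <- function(mutant_traj, mutant_saline, wt_traj, wt_saline, marker, t) {
  fc_mut <- readout(mutant_traj, marker, t) / readout(mutant_saline, marker, t)
  fc_wt <- readout(wt_traj, marker, t) / readout(wt_saline, marker, t)
  if (!is.finite(fc_wt) || fc_wt == 0) stop("zero WT fold change")
  fc_mut / fc_wt
}

#' The 17-variable phenotype panel
#'
#' The default panel of phenotypic variables with experimental targets and
#' comparison modes: basal markers (absolute), slice treatments
#' (fold-over-basal), fitted dose-response / time-course parameters, and the
#' mutant APA ratios (ratio-to-WT).  `basal-D32p34` is a range target.
#'
#' @return Tibble with columns `variable`, `phenotype`, `marker`,
#'   `comparison`, `target`, `lo`, `hi`, `units`.
#' @export
phenotype_panel <- function() {
  file <- system.file("extdata", "phenotype_panel.csv", package = "msnsig",
                      mustWork = FALSE)
  if (nzchar(file)) return(tibble::as_tibble(utils::read.csv(file)))
  panel_builtin()
}

panel_builtin <- function() {
  tibble::tribble(
    ~variable, ~phenotype, ~marker, ~comparison, ~target, ~lo, ~hi, ~units,
    "basal-cAMP", "basal", "cAMP", "absolute", 0.06, NA, NA, "uM",
    "basal-STEPact", "basal", "STEPact", "absolute", 0.80, NA, NA, "fraction",
    "basal-D32p34", "basal", "D32p34", "absolute", 0.35, 0.2, 0.5, "uM",
    "basal-D32p75", "basal", "D32p75", "absolute", 13, NA, NA, "uM",
    "DAslice-D32p34", "DAslice", "D32p34", "fold-over-basal", 12, NA, NA, "fold",
    "DAslice-D32p75", "DAslice", "D32p75", "fold-over-basal", 0.5, NA, NA, "fold",
    "NMDAslice-D32p34", "NMDAslice", "D32p34", "fold-over-basal", 0.5, NA, NA, "fold",
    "NMDAslice-D32p75", "NMDAslice", "D32p75", "fold-over-basal", 0.5, NA, NA, "fold",
    "activateRAS-h", "activateRAS", "RASRAF_fraction", "fitted-parameter", 4.1, NA, NA, "",
    "activateRAS-K", "activateRAS", "RASRAF_fraction", "fitted-parameter", 0.8, NA, NA, "uM",
    "trafficNMDAR-k", "trafficNMDAR", "NMDAR_current_scale", "fitted-parameter", 0.15, NA, NA, "min^-1",
    "haploD1R-ERKpp", "haploD1R", "ERKpp", "ratio-to-WT", 0.5, NA, NA, "x WT",
    "haploD1R-GluR1p", "haploD1R", "GluR1p845", "ratio-to-WT", 1.0, NA, NA, "x WT",
    "haploGolf-ERKpp", "haploGolf", "ERKpp", "ratio-to-WT", 0.9, NA, NA, "x WT",
    "haploGolf-GluR1p", "haploGolf", "GluR1p845", "ratio-to-WT", 0.6, NA, NA, "x WT",
    "D32KO-ERKpp", "D32KO", "ERKpp", "ratio-to-WT", 0.4, NA, NA, "x WT",
    "D32KO-GluR1p", "D32KO", "GluR1p845", "ratio-to-WT", 0.35, NA, NA, "x WT"
  )
}

#' Score simulated values against the panel
#'
#' Relative divergence per variable (zero anywhere inside a range target,
#' linear outside) and the coefficient of determination
#' `r2 = 1 - SS_res / SS_tot` over the panel values.
#'
#' @param simulated named numeric vector (names = panel variables).
#' @param panel panel tibble, default [phenotype_panel()].
#' @param subset optional character vector restricting scoring (e.g. the
#'   mutant panel for crosstalk-scheme ranking).
#' @return Tibble of per-variable target, value and divergence; the r2 is
#'   attached as attribute `r2` and via [glance()].
#' @export
evaluate_panel <- function(simulated, panel = phenotype_panel(), subset = NULL) {
  if (!is.null(subset)) panel <- panel[panel$variable %in% subset, ]
  missing <- setdiff(panel$variable, names(simulated))
  if (length(missing)) stop("missing simulated values: ",
                            paste(missing, collapse = ", "))
  sim <- simulated[panel$variable]
  div <- purrr::map2_dbl(seq_len(nrow(panel)), sim, function(i, v) {
    lo <- panel$lo[i]; hi <- panel$hi[i]
    if (!is.na(lo) && !is.na(hi)) {
      if (v >= lo && v <= hi) 0
      else if (v < lo) (lo - v) / lo
      else (v - hi) / hi
    } else abs(v - panel$target[i]) / panel$target[i]
  })
  ref <- ifelse(!is.na(panel$lo) & !is.na(panel$hi),
                pmin(pmax(sim, panel$lo), panel$hi), panel$target)
  r2 <- 1 - sum((sim - ref)^2) / sum((ref - mean(ref))^2)
  out <- tibble::tibble(variable = panel$variable, target = panel$target,
                        simulated = unname(sim), divergence = div)
  attr(out, "r2") <- r2
  class(out) <- c("msn_panel_eval", class(out))
  out
}

#' @export
glance.msn_panel_eval <- function(x, ...) {
  tibble::tibble(r2 = attr(x, "r2"), n = nrow(x),
                 frac_within_20 = mean(x$divergence <= 0.2))
}

#' Inferred immunohistochemistry fractions behind the fold-change corrections
#'
#' The positive-cell fractions are not printed in the source data; these
#' values are inferred (synthetic) so that [ib_correction()] maps the
#' reported Western-blot folds onto the corrected cell-specific folds, and
#' are shipped for regression tests only.
#'
#' @return Tibble with `marker`, `W`, `f_c`, `f_t`, `FC_corrected`.
#' @export
ib_correction_examples <- function() {
  tibble::tribble(
    ~marker, ~W, ~f_c, ~f_t, ~FC_corrected,
    "D32p34", 6, 0, 0.5, 11,
    "STEPp", 2.6, 0, 0.5, 4.2,
    "ERKpp", 2.2, 0, 1.2 / 29, 30,
    "GluR1p845", 6, 0, 0.5, 11
  )
}
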