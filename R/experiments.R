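# In-silico experiments: the psychostimulant (APA) grid over genotypes x
# crosstalk schemes x mechanisms, compartment-distribution sweeps, the
# culture sensitisation assay, Poisson-vs-regular convergence, and the PP2B
# inhibition scenario.

#' Run one genotype under APA and its saline control
#'
#' Re-equilibrates the genotype (totals rescaled, then equilibrated), then
#' simulates the psychostimulant protocol and its saline arm (DA held at
#' baseline, same spike train) with the given mechanism.
#'
#' @param scheme crosstalk code.
#' @param genotype genotype name.
#' @param mechanism NMDAR-enhancement mechanism (default the traffic-based
#'   one, the best-fitting mechanism).
#' @param F fold-increase constant; if `NULL`, calibrated on this model.
#' @param duration protocol duration (s).
#' @param spike_kind,seed spike train options.
#' @param ... passed to [standard_model()].
#' @return List with `apa`, `saline` trajectories, `basal` state and `F`.
#' @export
run_apa_pair <- function(scheme = "010", genotype = "WT", mechanism = "yTrf",
                         F = NULL, duration = 1200, spike_kind = "regular",
                         seed = NULL, R0 = NULL, ...) {
  m <- standard_model(scheme = scheme, genotype = genotype, ...)
  eq <- equilibrate(m, horizon = 3e5)
  if (is.null(F)) F <- calibrate_mechanism(m, eq$state, mechanism)$F
  # the normalisation constant is part of the (WT-calibrated) model: mutants
  # inherit it, so a mutant's resting NMDAR function may sit slightly off 1
  if (is.null(R0)) R0 <- scaling_ratio(m, eq$state, mechanism)
  apa <- simulate_protocol(m, eq$state,
                           protocol("APA", duration = duration,
                                    spike_kind = spike_kind, seed = seed),
                           mechanism = mechanism, F = F, R0 = R0)
  sal <- simulate_protocol(m, eq$state,
                           protocol("saline", duration = duration,
                                    spike_kind = spike_kind, seed = seed),
                           mechanism = mechanism, F = F, R0 = R0)
  list(model = m, basal = eq$state, apa = apa, saline = sal, F = F,
       scheme = scheme, genotype = genotype, mechanism = mechanism)
}

#' APA grid over genotypes and crosstalk schemes
#'
#' Runs the psychostimulant paradigm for every (scheme, genotype) cell,
#' computes ERK and GluR1 phosphorylation ratios to wild type at the readout
#' time (fold change over saline, relative to the WT fold change), and scores
#' each scheme's mutant panel.
#'
#' @param schemes character vector of crosstalk codes.
#' @param genotypes character vector (must include `"WT"`).
#' @param mechanism NMDAR-enhancement mechanism.
#' @param t_read readout time (s), default 15 min.
#' @param duration simulation horizon (s).
#' @param ... passed to [standard_model()].
#' @return Tibble with one row per (scheme, genotype, marker) ratio plus a
#'   per-scheme `r2` against the experimental mutant panel; failed cells are
#'   reported with `NA` and a message.
#' @export
run_apa_grid <- function(schemes = all_schemes(),
                         genotypes = c("WT", "Drd1a_het", "Gnal_het", "D32KO"),
                         mechanism = "yTrf", t_read = 900, duration = 1200,
                         ...) {
  stopifnot("WT" %in% genotypes)
  panel <- phenotype_panel()
  geno_pheno <- c(Drd1a_het = "haploD1R", Gnal_het = "haploGolf",
                  D32KO = "D32KO")
  out <- list()
  for (sc in schemes) {
    runs <- list()
    failed <- FALSE
    Fwt <- NULL  # calibrated on WT, reused for mutants: the fold-increase
                 # constant is a biophysical property, not genotype-specific
    for (g in genotypes) {
      r <- tryCatch(run_apa_pair(scheme = sc, genotype = g,
                                 mechanism = mechanism, duration = duration,
                                 F = if (g == "WT") NULL else Fwt,
                                 ...),
                    error = function(e) {
                      message("cell (", sc, ", ", g, ") failed: ",
                              conditionMessage(e))
                      NULL
                    })
      runs[[g]] <- r
      if (g == "WT") { if (is.null(r)) failed <- TRUE else Fwt <- r$F }
    }
    if (failed) next
    wt <- runs[["WT"]]
    sim <- c()
    for (g in setdiff(genotypes, "WT")) {
      for (mk in c("ERKpp", "GluR1p845")) {
        val <- if (is.null(runs[[g]])) NA_real_ else
          wt_ratio(runs[[g]]$apa, runs[[g]]$saline, wt$apa, wt$saline, mk, t_read)
        nm <- paste0(geno_pheno[[g]], "-", if (mk == "ERKpp") "ERKpp" else "GluR1p")
        sim[nm] <- val
        out[[length(out) + 1]] <- tibble::tibble(
          scheme = sc, genotype = g, marker = mk, ratio_to_wt = val)
      }
    }
    mut_vars <- intersect(names(sim), panel$variable)
    r2 <- if (anyNA(sim[mut_vars])) NA_real_ else
      attr(evaluate_panel(sim[mut_vars], panel, subset = mut_vars), "r2")
    out[[length(out)]]$scheme_r2 <- r2
    ix <- vapply(out, function(x) identical(x$scheme[1], sc), logical(1))
    for (j in which(ix)) out[[j]]$scheme_r2 <- r2
  }
  dplyr::bind_rows(out)
}

#' Equilibrium D1R/Golf compartment occupancy versus total dosage
#'
#' Sweeps the total amount of D1R or Golf from 0 to wild type and reports the
#' equilibrated content of the AC5-linked and NMDAR-linked compartments.
#'
#' @param ligand `"D1R"` or `"Golf"`.
#' @param fractions dosage grid as fractions of the WT total.
#' @param ... passed to [standard_model()].
#' @return Tibble with `fraction`, `ac5`, `nmdar`, `reservoir` (uM).
#' @export
compartment_sweep <- function(ligand = c("D1R", "Golf"),
                              fractions = seq(0, 1, by = 0.1), ...) {
  ligand <- match.arg(ligand)
  m0 <- standard_model(...)
  wt <- stats::setNames(m0$totals$total, m0$totals$moiety)
  purrr::map_dfr(fractions, function(f) {
    tot <- if (ligand == "D1R") c(D1R = unname(wt["D1R"]) * f) else
      c(Gaolf = unname(wt["Gaolf"]) * f, Gbg = unname(wt["Gbg"]) * f)
    m <- standard_model(totals = tot, ...)
    y <- equilibrate(m, horizon = 3e5)$state
    nm <- names(y)
    if (ligand == "D1R") {
      tibble::tibble(ligand = ligand, fraction = f,
                     ac5 = sum(y[grepl("D1R(da)?\\.AncRA", nm)]),
                     nmdar = sum(y[grepl("D1R(da)?\\.AncRN", nm)]),
                     reservoir = unname(y["D1R"]))
    } else {
      tibble::tibble(ligand = ligand, fraction = f,
                     ac5 = sum(y[grepl("Golf\\.AncGA|Gaolf_A|GaolfGDP_A|Gbg\\.AncGA", nm)]),
                     nmdar = sum(y[grepl("Golf\\.AncGN|Gaolf_N|GaolfGDP_N|Gbg\\.AncGN", nm)]),
                     reservoir = unname(y["Golf"]))
    }
  })
}

#' Dopamine sensitisation of Ca2+-triggered ERK activation in culture
#'
#' Dose-response of ERK activation to a single scaled Ca2+ transient, with
#' and without dopamine (3 uM step at time zero), read at 8 min; both curves
#' are fitted with the Hill equation and the ratio of half-activating Ca2+
#' amplitudes (without / with dopamine) is returned.
#'
#' @param mechanism NMDAR-enhancement mechanism.
#' @param amps Ca2+ transient amplitude grid (uM above baseline).
#' @param F fold-increase constant (calibrated if `NULL`).
#' @param da_level dopamine concentration (uM); 0 makes both arms identical.
#' @param ... passed to [standard_model()].
#' @return List with `ratio` (`K_noDA / K_DA`), both fits and the raw curves.
#' @export
sensitization_assay <- function(mechanism, amps = c(0.3, 0.5, 0.7, 1, 1.4, 2, 3),
                                F = NULL, da_level = 3, ...) {
  m <- standard_model(...)
  eq <- equilibrate(m, horizon = 3e5)
  if (is.null(F)) F <- calibrate_mechanism(m, eq$state, mechanism)$F
  R0 <- scaling_ratio(m, eq$state, mechanism)
  amps <- sort(unique(c(amps, 1)))  # curves are normalised at 1 uM amplitude
  run_curve <- function(da) {
    raw <- vapply(amps, function(a) {
      pr <- protocol("culture_sensitization", ca_pulse_amp = a,
                     da_level = max(da, 0.01))
      tr <- simulate_protocol(m, eq$state, pr, mechanism = mechanism, F = F,
                              R0 = R0, dt_out = 10)
      readout(tr, "ERKpp", pr$readout)
    }, numeric(1))
    raw / raw[amps == 1]
  }
  with_da <- run_curve(da_level)
  no_da <- run_curve(0)
  fit_w <- fit_hill(amps, with_da)
  fit_n <- fit_hill(amps, no_da)
  list(ratio = fit_n$K / fit_w$K, K_with = fit_w$K, K_without = fit_n$K,
       fit_with = fit_w, fit_without = fit_n,
       curves = tibble::tibble(amp = rep(amps, 2),
                               da = rep(c(da_level, 0), each = length(amps)),
                               ERKpp = c(with_da, no_da)))
}

#' Poisson-train convergence of the ERK time course
#'
#' Mean of `n_replicates` ERKpp time courses under random Poisson Ca2+ spike
#' trains, compared (R^2) with the regular-train time course of the same
#' rate.
#'
#' @param n_replicates number of Poisson replicates.
#' @param seed master seed; replicate seeds derive from it.
#' @param duration protocol duration (s).
#' @param mechanism NMDAR-enhancement mechanism.
#' @param F fold-increase constant (calibrated if `NULL`).
#' @param ... passed to [standard_model()].
#' @return List with `r2`, the mean stochastic and the regular time courses.
#' @export
poisson_convergence <- function(n_replicates = 20, seed = 1, duration = 1200,
                                mechanism = "yTrf", F = NULL, ...) {
  stopifnot(n_replicates >= 1)
  m <- standard_model(...)
  eq <- equilibrate(m, horizon = 3e5)
  if (is.null(F)) F <- calibrate_mechanism(m, eq$state, mechanism,
                                           apa = protocol("APA", duration = 1200))$F
  R0 <- scaling_ratio(m, eq$state, mechanism)
  grid <- seq(0, duration, by = 10)
  reg <- simulate_protocol(m, eq$state, protocol("APA", duration = duration),
                           mechanism = mechanism, F = F, R0 = R0)
  erk_reg <- vapply(grid, function(t) readout(reg, "ERKpp", t), numeric(1))
  acc <- matrix(0, n_replicates, length(grid))
  for (i in seq_len(n_replicates)) {
    tr <- simulate_protocol(
      m, eq$state,
      protocol("APA", duration = duration, spike_kind = "poisson",
               seed = seed * 1000L + i),
      mechanism = mechanism, F = F, R0 = R0)
    acc[i, ] <- vapply(grid, function(t) readout(tr, "ERKpp", t), numeric(1))
  }
  mean_sto <- colMeans(acc)
  r2 <- 1 - sum((mean_sto - erk_reg)^2) / sum((erk_reg - mean(erk_reg))^2)
  list(r2 = r2, time = grid, regular = erk_reg, mean_stochastic = mean_sto,
       replicates = acc)
}

#' PP2B-inhibition scenario
#'
#' Paired trajectories under sustained high Ca2+ (glutamate surrogate) with
#' PP2B catalytic activity intact or zeroed (cyclosporin arm); returns the
#' STEPp and ERKpp time courses of both arms.
#'
#' @param duration protocol duration (s).
#' @param nmda_ca tonic Ca2+ level (uM).
#' @param ... passed to [standard_model()].
#' @return Tibble with `time`, `arm`, `STEPp`, `ERKpp`.
#' @export
pp2b_inhibition <- function(duration = 600, nmda_ca = 10, ...) {
  m <- standard_model(...)
  eq <- equilibrate(m, horizon = 3e5)
  run <- function(inhibited) {
    pr <- protocol("PP2B_inhibition", duration = duration, nmda_ca = nmda_ca)
    pr$pp2b_inhibited <- inhibited
    tr <- simulate_protocol(m, eq$state, pr, dt_out = 10)
    tibble::tibble(time = tr$times,
                   arm = if (inhibited) "PP2B_inhibited" else "control",
                   STEPp = vapply(seq_along(tr$times), function(i)
                     state_marker(tr$conc[i, ], "STEPp"), numeric(1)),
                   ERKpp = vapply(seq_along(tr$times), function(i)
                     state_marker(tr$conc[i, ], "ERKpp"), numeric(1)))
  }
  dplyr::bind_rows(run(FALSE), run(TRUE))
}
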