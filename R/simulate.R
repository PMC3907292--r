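# Stiff ODE integration of the assembled network under a protocol:
# equilibration to the basal steady state, event-driven Ca2+ spike handling,
# and the NMDAR-enhancement scaling factors that close the loop from
# signalling state to Ca2+ input amplitude.

forcing_default <- function(base) list(type = 0L, base = base)

model_pointer <- function(network, ca = forcing_default(0.06),
                          da = forcing_default(0.01), params = NULL) {
  p <- if (is.null(params)) network$params else params
  st <- network$steps
  k <- unname(p[st$par])
  model_build(nrow(network$species), k, st$subptr, st$subidx,
              st$stptr, st$stspec, st$stdelta, ca, da)
}

ode_func <- function(ptr) {
  function(t, y, parms) list(rhs_eval(ptr, t, y))
}

jac_func <- function(ptr) {
  function(t, y, parms) jac_eval(ptr, t, y)
}

ode_run <- function(ptr, y, times, rtol, atol) {
  deSolve::ode(y, times, ode_func(ptr), parms = NULL, method = "lsoda",
               jacfunc = jac_func(ptr), jactype = "fullusr",
               rtol = rtol, atol = atol, maxsteps = 1e5)
}

#' Equilibrate the model to its basal steady state
#'
#' Runs the basal protocol (tonic 10 nM DA, 60 nM Ca2+) over a long horizon
#' (default 1e6 s; the slow compartment exchange of D1R and Golf requires
#' long equilibration) and verifies a plateau: `max |dC/dt| / max(C, floor)`
#' below `tol` for every species.
#'
#' @param network an assembled `msn_network` / `msn_model`.
#' @param protocol basal protocol (tonic forcings only).
#' @param tol relative plateau tolerance (s^-1).
#' @param horizon integration horizon (s).
#' @param rtol,atol solver tolerances.
#' @return List with `state` (named vector), `ok`, and `worst` (diagnostic
#'   tibble of the least-converged species).
#' @export
equilibrate <- function(network, protocol = msnsig::protocol("basal"),
                        tol = 1e-8, horizon = 1e6, rtol = 1e-7, atol = 1e-10) {
  if (!is.null(protocol$train) || protocol$da$type != 0L || protocol$ca$type != 0L)
    stop("equilibration requires tonic forcings")
  params <- protocol_params(network, protocol)
  ptr <- model_pointer(network, ca = protocol$ca, da = protocol$da,
                       params = params)
  y0 <- initial_state(network)
  times <- unique(c(0, 10^seq(-2, log10(horizon), length.out = 40)))
  sol <- ode_run(ptr, y0, times, rtol, atol)
  yend <- sol[nrow(sol), -1]
  names(yend) <- network$species$id
  dy <- rhs_eval(ptr, horizon, yend)
  rel <- abs(dy) / pmax(abs(yend), 1e-4)  # 0.1 nM floor: empty pools are noise
  ok <- max(rel) < tol
  ord <- order(rel, decreasing = TRUE)[1:5]
  worst <- tibble::tibble(species = network$species$id[ord], rate = dy[ord],
                          relative = rel[ord])
  if (!ok)
    warning("equilibration plateau not reached; worst species: ",
            paste(worst$species, signif(worst$relative, 3), collapse = ", "))
  list(state = yend, ok = ok, worst = worst)
}

# species index sets used by the scaling-factor ratios
nmdar_groups <- function(network) {
  ids <- network$species$id
  has_nmdar_m <- grepl("NMDARm", ids)
  has_nmdar_i <- grepl("NMDARi", ids)
  list(
    membrane = which(has_nmdar_m),
    total = which(has_nmdar_m | has_nmdar_i),
    membrane_pS = which(has_nmdar_m & grepl("NMDARm[^.]*p@S", ids)),
    membrane_pY = which(has_nmdar_m & grepl("NMDARm[^.]*p@Y", ids))
  )
}

#' NMDAR-enhancement state ratio for a mechanism
#'
#' `sSCh`: PKA-phosphorylated membrane NMDAR over total membrane NMDAR.
#' `yTrf`: membrane NMDAR over total NMDAR.
#' `ySCh`: tyrosine-phosphorylated membrane NMDAR over total membrane NMDAR.
#'
#' @param network the network (for species indexing).
#' @param state named state vector or matrix (rows = states).
#' @param mechanism `"sSCh"`, `"yTrf"` or `"ySCh"`.
#' @return Ratio(s) in `[0, 1]`.
#' @export
scaling_ratio <- function(network, state, mechanism) {
  g <- nmdar_groups(network)
  ssum <- function(ix) {
    if (is.matrix(state)) rowSums(state[, ix, drop = FALSE]) else sum(state[ix])
  }
  memb <- ssum(g$membrane)
  if (any(memb <= 0)) stop("no membrane NMDAR: scaling ratio undefined")
  switch(mechanism,
         sSCh = ssum(g$membrane_pS) / memb,
         yTrf = memb / ssum(g$total),
         ySCh = ssum(g$membrane_pY) / memb,
         stop("unknown mechanism: ", mechanism))
}

#' Ca2+ amplitude scaling factor
#'
#' `factor = 1 + (max - 1) * min(1, F * (R - R0))`: proportional to the
#' increase of the mechanism's state ratio over its basal value, normalised
#' to exactly 1 at the equilibrated basal state (`R0`) and saturating at the
#' common maximum amplitude (2.5).  `F` is the mechanism's fold-increase
#' constant, calibrated so the maximum factor under the psychostimulant
#' protocol reaches the cap (see [calibrate_mechanism()]).
#'
#' @inheritParams scaling_ratio
#' @param F fold-increase constant (`F = 0` gives a factor of 1).
#' @param R0 basal ratio (normalisation constant).
#' @param amax maximum amplitude of the scaling factor.
#' @return Scaling factor(s).
#' @export
scaling_factor <- function(network, state, mechanism, F, R0, amax = 2.5) {
  R <- scaling_ratio(network, state, mechanism)
  pmax(0, 1 + (amax - 1) * pmin(1, F * (R - R0)))
}

protocol_params <- function(network, protocol) {
  p <- network$params
  if (isTRUE(protocol$pp2b_inhibited)) p["pp2b3.kcat"] <- 0
  p
}

#' Simulate the model under a protocol
#'
#' Integrates the stiff ODE system from `init` (normally the equilibrated
#' basal state).  For spiking protocols the integration restarts at every
#' spike onset; the spike's amplitude term is multiplied by the current
#' scaling factor evaluated at onset time, closing the loop from signalling
#' state to Ca2+ input.
#'
#' @param network assembled network.
#' @param init named initial state (consistent with the moiety totals).
#' @param protocol an [protocol()] object.
#' @param mechanism NMDAR-enhancement mechanism, or `NULL` for none.
#' @param F fold-increase constant for the mechanism.
#' @param R0 basal ratio; defaults to the ratio at `init`.
#' @param dt_out output grid spacing (s).
#' @param rtol,atol solver tolerances.
#' @return An `msn_traj`: output times, concentration matrix, the scaling
#'   factor series and run metadata.
#' @export
simulate_protocol <- function(network, init, protocol, mechanism = NULL,
                              F = 0, R0 = NULL, dt_out = 5,
                              rtol = 1e-7, atol = 1e-10) {
  params <- protocol_params(network, protocol)
  dur <- protocol$duration
  onsets <- if (!is.null(protocol$train)) protocol$train$times else numeric(0)
  onsets <- onsets[onsets < dur]
  cap <- protocol$ca_params
  base_amp <- if (!is.null(protocol$ca_pulse_amp)) protocol$ca_pulse_amp else
    cap$Cmax - cap$Cb
  if (is.null(R0) && !is.null(mechanism))
    R0 <- scaling_ratio(network, init, mechanism)

  ca0 <- protocol$ca
  ptr <- model_pointer(network, ca = ca0, da = protocol$da, params = params)
  out_times <- unique(sort(c(seq(0, dur, by = dt_out), protocol$readout, dur,
                             onsets)))
  bounds <- unique(c(0, onsets, dur))
  y <- init
  rows <- list(); tacc <- numeric(0)
  amps <- numeric(0); scales <- numeric(0)
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    if (t0 %in% onsets) {
      sc <- if (is.null(mechanism)) 1 else
        scaling_factor(network, y, mechanism, F, R0)
      amps <- c(amps, sc * base_amp)
      scales <- c(scales, sc)
      model_set_forcing(ptr, "ca", list(type = 1L, base = ca0$base,
                                        k1 = cap$k1, k2 = cap$k2,
                                        onsets = onsets[seq_along(amps)],
                                        amps = amps))
    }
    tt <- unique(c(t0, out_times[out_times > t0 & out_times <= t1], t1))
    sol <- ode_run(ptr, y, tt, rtol, atol)
    if (attr(sol, "istate")[1] < 0)
      stop("solver failure in [", t0, ",", t1, "] s; last good time ",
           max(sol[, 1]))
    y <- sol[nrow(sol), -1]
    names(y) <- network$species$id
    keep <- sol[, 1] %in% out_times & (sol[, 1] > (if (i == 1) -1 else t0))
    if (any(keep)) {
      rows[[length(rows) + 1]] <- sol[keep, -1, drop = FALSE]
      tacc <- c(tacc, sol[keep, 1])
    }
  }
  conc <- do.call(rbind, rows)
  colnames(conc) <- network$species$id
  scale_series <- if (is.null(mechanism)) rep(1, length(tacc)) else
    scaling_factor(network, conc, mechanism, F, R0)
  structure(list(
    times = tacc, conc = conc, scale = scale_series,
    spike_onsets = onsets[seq_along(amps)], spike_scales = scales,
    protocol = protocol$name, mechanism = mechanism, F = F, R0 = R0,
    genotype = network$options$genotype %||% "WT",
    scheme = network$options$scheme %||% NA_character_,
    final_state = y
  ), class = "msn_traj")
}

#' @export
print.msn_traj <- function(x, ...) {
  cat("<msn_traj> protocol=", x$protocol, " genotype=", x$genotype,
      " scheme=", x$scheme,
      if (!is.null(x$mechanism)) paste0(" mechanism=", x$mechanism) else "",
      "; ", length(x$times), " time points over ", max(x$times), " s\n",
      sep = "")
  invisible(x)
}

#' State of a trajectory at a given time (linear interpolation)
#' @param traj an `msn_traj`.
#' @param t time (s).
#' @return Named state vector.
#' @export
traj_state <- function(traj, t) {
  stopifnot(t >= min(traj$times), t <= max(traj$times))
  apply(traj$conc, 2, function(col) stats::approx(traj$times, col, t)$y)
}

#' Moiety conservation drift along a trajectory
#'
#' @param network the network the trajectory came from.
#' @param traj an `msn_traj`.
#' @return Tibble of per-moiety maximum relative drift.
#' @export
moiety_drift <- function(network, traj) {
  cm <- conserved_moieties(network)
  purrr::map_dfr(seq_len(nrow(cm)), function(i) {
    ix <- match(cm$species[[i]], colnames(traj$conc))
    tot <- as.vector(traj$conc[, ix, drop = FALSE] %*% cm$mult[[i]])
    ref <- tot[1]
    drift <- if (ref > 1e-12) max(abs(tot - ref)) / ref else max(abs(tot - ref))
    tibble::tibble(moiety = cm$moiety[i], total = ref, max_rel_drift = drift)
  })
}

#' Calibrate a mechanism's fold-increase constant
#'
#' Finds `F` such that the maximum scaling factor over the psychostimulant
#' protocol equals `target` (2.5).  The factor
#' `(1 + F R)/(1 + F R0)` is increasing in `F` for `R > R0`, so `F` is
#' solved by fixed-point iteration on the simulated maximum ratio; failure
#' to bracket (the ratio never exceeds `target * R0`) is reported.
#'
#' @param network assembled network.
#' @param basal equilibrated basal state.
#' @param mechanism `"sSCh"`, `"yTrf"` or `"ySCh"`.
#' @param target maximum scaling factor (default 2.5).
#' @param tol relative tolerance on the achieved maximum.
#' @param apa the protocol to calibrate against.
#' @return List with `F`, `achieved` maximum factor, and the trajectory.
#' @export
calibrate_mechanism <- function(network, basal, mechanism, target = 2.5,
                                tol = 0.01, apa = protocol("APA")) {
  R0 <- scaling_ratio(network, basal, mechanism)
  tr <- simulate_protocol(network, basal, apa, mechanism = mechanism, F = 0,
                          R0 = R0)
  dR <- max(scaling_ratio(network, tr$conc, mechanism)) - R0
  if (dR <= 0)
    stop("cannot calibrate ", mechanism,
         ": the state ratio never rises above its basal value")
  Fcur <- 1 / dR
  for (it in 1:8) {
    tr <- simulate_protocol(network, basal, apa, mechanism = mechanism,
                            F = Fcur, R0 = R0)
    achieved <- max(tr$scale)
    if (abs(achieved - target) < tol * target) break
    dR <- max(scaling_ratio(network, tr$conc, mechanism)) - R0
    if (dR <= 0) stop("calibration bracket failure for ", mechanism)
    Fcur <- 1 / dR
  }
  list(F = Fcur, achieved = max(tr$scale), R0 = R0, traj = tr)
}
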