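# Forcing functions and stimulation protocols: Ca2+ spike transients,
# psychostimulant dopamine overflow, slice/culture treatments, and synthetic
# dose-response / time-series fixtures for the fitting layer.

#' Double-exponential transient parameters
#'
#' @param Cb basal concentration (uM).
#' @param Cmax maximum amplitude of the transient (uM).
#' @param k1,k2 rise and decay rate constants (s^-1); `k1 > k2` for a
#'   well-formed transient.  The degenerate case `k1 == k2` is served by the
#'   alpha-function limit of the difference of exponentials.
#' @return A `transient_params` list.
#' @export
transient_params <- function(Cb, Cmax, k1, k2) {
  stopifnot(Cb >= 0, Cmax > Cb, k1 > 0, k2 > 0)
  if (k1 < k2) stop("k1 (rise) must be >= k2 (decay)")
  structure(list(Cb = Cb, Cmax = Cmax, k1 = k1, k2 = k2),
            class = "transient_params")
}

#' Standard Ca2+ spike: 60 nM baseline, 500 nM peak, k1 = 17.2 s^-1,
#' k2 = 15.7 s^-1.
#' @rdname transient_params
#' @export
ca_transient_params <- function() transient_params(0.06, 0.5, 17.2, 15.7)

#' Consensus psychostimulant dopamine overflow: 10 nM baseline, 300 nM peak,
#' k1 = 0.15 min^-1, k2 = 0.055 min^-1 (converted to s^-1 internally).
#' @rdname transient_params
#' @export
da_transient_params <- function() transient_params(0.01, 0.3, 0.15 / 60, 0.055 / 60)

transient_shape <- function(dt, k1, k2) {
  out <- numeric(length(dt))
  pos <- dt >= 0
  if (abs(k1 - k2) < 1e-12 * k1) {
    out[pos] <- k1 * dt[pos] * exp(1 - k1 * dt[pos])
  } else {
    tp <- log(k1 / k2) / (k1 - k2)
    gmax <- exp(-k2 * tp) - exp(-k1 * tp)
    out[pos] <- (exp(-k2 * dt[pos]) - exp(-k1 * dt[pos])) / gmax
  }
  out
}

#' Evaluate transient waveforms
#'
#' `ca_spike_waveform()` and `da_transient()` return the concentration at
#' times `t` (s) after onset: baseline plus the amplitude-normalised
#' double-exponential, so the curve peaks exactly at `Cmax` and returns to
#' `Cb`.
#'
#' @param t times since onset (s); values before onset return the baseline.
#' @param params a [transient_params()] object.
#' @return Concentrations (uM).
#' @export
ca_spike_waveform <- function(t, params = ca_transient_params()) {
  params$Cb + (params$Cmax - params$Cb) * transient_shape(t, params$k1, params$k2)
}

#' @rdname ca_spike_waveform
#' @export
da_transient <- function(t, params = da_transient_params()) {
  params$Cb + (params$Cmax - params$Cb) * transient_shape(t, params$k1, params$k2)
}

#' Generate a Ca2+ spike train
#'
#' @param rate spike rate (s^-1), `>= 0`.
#' @param duration train duration (s).
#' @param kind `"poisson"` or `"regular"` (constant inter-spike interval
#'   `1/rate`, first spike at `1/rate`).
#' @param seed RNG seed for Poisson trains (reproducible).
#' @return A `spike_train` object with strictly increasing onset times.
#' @export
spike_train <- function(rate, duration, kind = c("regular", "poisson"),
                        seed = NULL) {
  kind <- match.arg(kind)
  if (rate < 0 || duration < 0) stop("rate and duration must be non-negative")
  times <- if (rate == 0) {
    numeric(0)
  } else if (kind == "regular") {
    seq(1 / rate, duration, by = 1 / rate)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    # draw inter-spike intervals until the horizon is passed
    n_guess <- max(10, ceiling(rate * duration + 6 * sqrt(rate * duration)))
    gaps <- stats::rexp(n_guess, rate)
    while (sum(gaps) < duration) gaps <- c(gaps, stats::rexp(n_guess, rate))
    tt <- cumsum(gaps)
    tt[tt <= duration]
  }
  structure(list(times = times, rate = rate, duration = duration,
                 kind = kind, seed = seed), class = "spike_train")
}

#' Superposed waveform of a spike train
#'
#' Baseline plus the sum of double-exponential transients triggered at the
#' spike onsets; `amps` optionally rescales each spike's amplitude term
#' (`Cmax - Cb`), as done by the NMDAR-enhancement scaling factor.
#'
#' @param train a [spike_train()].
#' @param t evaluation times (s).
#' @param params transient shape, default the standard Ca2+ spike.
#' @param amps per-spike amplitude scale factors (default 1).
#' @return Concentrations (uM).
#' @export
spike_train_waveform <- function(train, t, params = ca_transient_params(),
                                 amps = NULL) {
  if (is.null(amps)) amps <- rep(1, length(train$times))
  base_amp <- params$Cmax - params$Cb
  out <- rep(params$Cb, length(t))
  for (j in seq_along(train$times)) {
    out <- out + amps[j] * base_amp * transient_shape(t - train$times[j],
                                                      params$k1, params$k2)
  }
  out
}

#' Stimulation protocols
#'
#' Returns a fully specified protocol: dopamine and Ca2+ forcing, spike
#' train (if any), total duration, readout time and special flags.
#' Available protocols:
#' \describe{
#'   \item{basal}{DA 10 nM, Ca 60 nM tonic; the equilibration condition.}
#'   \item{DAslice}{tonic 10 uM DA, read at 5 min.}
#'   \item{NMDAslice}{NMDA 100 uM represented as sustained Ca2+ elevation
#'     (default 10 uM), read at 10 min.}
#'   \item{APA}{psychostimulant DA transient plus a 0.1 s^-1 Ca2+ spike
#'     train, read at 15 min.}
#'   \item{DA_only}{the APA DA transient without Ca2+ spikes.}
#'   \item{Ca_only}{the APA spike train with DA held at baseline.}
#'   \item{saline}{spike train with DA at baseline; the APA control arm.}
#'   \item{culture_sensitization}{DA 3 uM step plus a single scaled Ca2+
#'     transient, ERK read at 8 min.}
#'   \item{PP2B_inhibition}{tonic 10 uM Ca2+; the inhibited arm zeroes PP2B
#'     catalytic activity.}
#' }
#'
#' @param name protocol name.
#' @param duration override total duration (s).
#' @param spike_kind `"regular"` or `"poisson"` for spiking protocols.
#' @param seed RNG seed for Poisson trains.
#' @param nmda_ca tonic Ca2+ level standing for NMDA 100 uM (uM).
#' @param ca_pulse_amp amplitude of the single culture Ca2+ transient (uM
#'   above baseline), varied in dose-response assays.
#' @param da_level tonic DA level for culture protocols (uM).
#' @return An `msn_protocol` list.
#' @export
protocol <- function(name, duration = NULL, spike_kind = "regular",
                     seed = NULL, nmda_ca = 10, ca_pulse_amp = 1,
                     da_level = 3) {
  ca0 <- 0.06; da0 <- 0.01
  cap <- ca_transient_params(); dap <- da_transient_params()
  mk <- function(dur, readout, da, ca, train = NULL, pp2b_inhibited = FALSE) {
    structure(list(name = name, duration = dur, readout = readout, da = da,
                   ca = ca, train = train, pp2b_inhibited = pp2b_inhibited,
                   ca_params = cap),
              class = "msn_protocol")
  }
  tonic <- function(x) list(type = 0L, base = x)
  apa_da <- list(type = 2L, base = da0, amp = dap$Cmax - dap$Cb,
                 k1 = dap$k1, k2 = dap$k2, t0 = 0)
  switch(
    name,
    basal = mk(duration %||% 3600, 3600, tonic(da0), tonic(ca0)),
    DAslice = mk(duration %||% 300, 300, tonic(10), tonic(ca0)),
    NMDAslice = mk(duration %||% 600, 600, tonic(da0), tonic(nmda_ca)),
    APA = {
      dur <- duration %||% 2700
      mk(dur, 900, apa_da, tonic(ca0),
         spike_train(0.1, dur, spike_kind, seed))
    },
    DA_only = mk(duration %||% 2700, 900, apa_da, tonic(ca0)),
    Ca_only = ,
    saline = {
      dur <- duration %||% 2700
      mk(dur, 900, tonic(da0), tonic(ca0),
         spike_train(0.1, dur, spike_kind, seed))
    },
    culture_sensitization = {
      dur <- duration %||% 600
      tr <- structure(list(times = 30, rate = NA, duration = dur,
                           kind = "single", seed = NULL), class = "spike_train")
      p <- mk(dur, 480, tonic(da_level), tonic(ca0), tr)
      p$ca_pulse_amp <- ca_pulse_amp
      # unitary culture transient: slower than the spine spike
      p$ca_params <- transient_params(ca0, ca0 + ca_pulse_amp, 0.5, 0.05)
      p
    },
    PP2B_inhibition = mk(duration %||% 600, 600, tonic(da0), tonic(nmda_ca),
                         pp2b_inhibited = TRUE),
    stop("unknown protocol name: ", name)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise / restore a protocol
#'
#' @param p an `msn_protocol`.
#' @param file JSON path.
#' @export
write_protocol_json <- function(p, file) {
  x <- unclass(p)
  if (!is.null(x$train)) x$train <- unclass(x$train)
  if (!is.null(x$ca_params)) x$ca_params <- unclass(x$ca_params)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!is.null(x$train)) class(x$train) <- "spike_train"
  if (!is.null(x$ca_params)) class(x$ca_params) <- "transient_params"
  structure(x, class = "msn_protocol")
}

#' Export a spike train as a two-column CSV (time, amplitude scale)
#' @param train a [spike_train()].
#' @param file output path.
#' @param amps per-spike amplitude scales (default 1).
#' @export
write_spike_train_csv <- function(train, file, amps = NULL) {
  if (is.null(amps)) amps <- rep(1, length(train$times))
  utils::write.csv(data.frame(time = train$times, amp_scale = amps), file,
                   row.names = FALSE)
  invisible(file)
}

#' Synthetic dose-response / time-series fixtures
#'
#' Generates data from a known Hill or monoexponential model with optional
#' Gaussian noise, for exercising the fitting layer.
#'
#' @param model `"hill"` or `"monoexp"`.
#' @param true_params named list: Hill needs `Cmin, Cmax, K, h`; monoexp
#'   needs `A, k`.
#' @param n_points number of points.
#' @param noise_sd Gaussian noise standard deviation (response units).
#' @param seed RNG seed.
#' @param x predictor grid; defaults to a log grid spanning `K` for Hill and
#'   `0..5/k` for monoexp.
#' @return Tibble with columns `x`, `y`, and the noiseless `y_true`.
#' @export
synthetic_fit_fixtures <- function(model = c("hill", "monoexp"), true_params,
                                   n_points = 12, noise_sd = 0, seed = 1,
                                   x = NULL) {
  model <- match.arg(model)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  npar <- if (model == "hill") 4 else 2
  if (n_points < npar) stop("need at least ", npar, " points")
  if (model == "hill") {
    p <- true_params
    if (is.null(x)) x <- p$K * 10^seq(-1.2, 1.2, length.out = n_points)
    y_true <- p$Cmin + (p$Cmax - p$Cmin) * x^p$h / (p$K^p$h + x^p$h)
  } else {
    p <- true_params
    if (is.null(x)) x <- seq(0, 5 / p$k, length.out = n_points)
    y_true <- p$A * (1 - exp(-p$k * x))
  }
  set.seed(seed)
  tibble::tibble(x = x, y = y_true + stats::rnorm(length(x), 0, noise_sd),
                 y_true = y_true)
}
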