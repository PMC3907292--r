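# broom-style tidiers and ggplot2 methods for the package's result objects.

#' Tidy a trajectory into long format
#'
#' @param x an `msn_traj`.
#' @param markers optional marker names to summarise instead of raw species.
#' @param ... unused.
#' @return Tibble `time`, `species`/`marker`, `value` (uM).
#' @export
tidy.msn_traj <- function(x, markers = NULL, ...) {
  if (is.null(markers)) {
    tibble::tibble(
      time = rep(x$times, times = ncol(x$conc)),
      species = rep(colnames(x$conc), each = length(x$times)),
      value = as.vector(x$conc)
    )
  } else {
    purrr::map_dfr(markers, function(mk) {
      v <- if (mk == "NMDAR_current_scale") x$scale else
        apply(x$conc, 1, state_marker, marker = mk)
      tibble::tibble(time = x$times, marker = mk, value = v)
    })
  }
}

#' @export
glance.msn_traj <- function(x, ...) {
  tibble::tibble(protocol = x$protocol, genotype = x$genotype,
                 scheme = x$scheme,
                 mechanism = x$mechanism %||% NA_character_,
                 duration = max(x$times), n_spikes = length(x$spike_onsets),
                 max_scale = max(x$scale))
}

#' Write a trajectory as tidy CSV
#' @param x an `msn_traj`.
#' @param file output path.
#' @export
write_trajectory_csv <- function(x, file) {
  utils::write.csv(tidy.msn_traj(x), file, row.names = FALSE)
  invisible(file)
}

#' Log run metadata as JSON
#' @param x an `msn_traj`.
#' @param file output path.
#' @export
write_run_metadata <- function(x, file) {
  jsonlite::write_json(as.list(glance.msn_traj(x)), file, auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @export
tidy.msn_sensitivity <- function(x, ...) {
  A <- unclass(x)
  tibble::tibble(
    target = rep(rownames(A), times = ncol(A)),
    output = rep(colnames(A), each = nrow(A)),
    S = as.vector(A)
  )
}

#' Marker time-course plot of a trajectory
#'
#' @param object an `msn_traj`.
#' @param markers marker names.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.msn_traj <- function(object, markers = c("ERKpp", "GluR1p845",
                                                  "D32p34", "cAMP"), ...) {
  d <- tidy.msn_traj(object, markers = markers)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time / 60, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (uM)",
                  title = paste("protocol:", object$protocol)) +
    ggplot2::theme_minimal()
}

#' Sensitivity heat map
#' @param object an `msn_sensitivity`.
#' @param top show only the `top` parameters by summed sensitivity.
#' @param ... unused.
#' @export
autoplot.msn_sensitivity <- function(object, top = 40, ...) {
  keep <- rank_parameters(object)$target[seq_len(min(top, nrow(object)))]
  d <- tidy.msn_sensitivity(object)
  d <- d[d$target %in% keep, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$output, y = .data$target,
                                  fill = abs(.data$S))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "|S|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Compartment-distribution sweep plot
#' @param sweep output of [compartment_sweep()].
#' @export
plot_compartment_sweep <- function(sweep) {
  d <- tidyr::pivot_longer(sweep, c("ac5", "nmdar", "reservoir"),
                           names_to = "compartment", values_to = "amount")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction, y = .data$amount,
                                  colour = .data$compartment)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "dosage (fraction of WT total)", y = "amount (uM)",
                  title = unique(d$ligand)) +
    ggplot2::theme_minimal()
}

#' Dose-response plot with Hill fit
#' @param doses,responses data.
#' @param fit optional [fit_hill()] result.
#' @export
plot_dose_response <- function(doses, responses, fit = NULL) {
  d <- tibble::tibble(dose = doses, response = responses)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$dose, .data$response)) +
    ggplot2::geom_point() + ggplot2::scale_x_log10() +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xx <- exp(seq(log(min(doses)), log(max(doses)), length.out = 100))
    yy <- fit$Cmin + (fit$Cmax - fit$Cmin) * xx^fit$h / (fit$K^fit$h + xx^fit$h)
    p <- p + ggplot2::geom_line(data = tibble::tibble(dose = xx, response = yy))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
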