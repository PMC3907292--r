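# Local one-at-a-time parameter sensitivity: perturbation conventions
# (K_M through k_f; k_cat with a balancing change in k_f and k_r so K_M is
# held constant; totals directly), normalized sensitivities, sensitive-set
# extraction, overlap measure and ranking.

#' Enumerate perturbable parameters
#'
#' Enzymatic reactions contribute their `K_M` and `k_cat`; reversible
#' reactions `k_f` and `k_r`; irreversible reactions their single constant;
#' plus the conserved totals.
#'
#' @param network an `msn_network`.
#' @return Tibble with `target` (id), `type` and `reaction`/`moiety`.
#' @export
perturbable_parameters <- function(network) {
  rx <- network$reactions
  rows <- list()
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    if (r$class == "enzymatic") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        target = c(paste0(r$id, ".KM"), paste0(r$id, ".kcat")),
        type = c("KM", "kcat"), reaction = r$id, moiety = NA_character_)
    } else if (r$class == "reversible") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        target = c(paste0(r$id, ".kf"), paste0(r$id, ".kr")),
        type = "rate", reaction = r$id, moiety = NA_character_)
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        target = paste0(r$id, ".kf"), type = "rate", reaction = r$id,
        moiety = NA_character_)
    }
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    target = paste0("total.", network$totals$moiety), type = "total",
    reaction = NA_character_, moiety = network$totals$moiety)
  dplyr::bind_rows(rows)
}

#' Perturb one parameter
#'
#' `k_cat` targets multiply `k_cat`, `k_f` and `k_r` of the reaction by the
#' same factor, leaving `K_M = (k_cat + k_r)/k_f` unchanged; `K_M` targets
#' multiply `k_f` by the inverse factor (scaling `K_M` by the factor while
#' `k_cat` is untouched); plain rate constants and totals are multiplied
#' directly.
#'
#' @param network an `msn_network` (or `msn_model`).
#' @param target a target id from [perturbable_parameters()].
#' @param direction `+1` or `-1`.
#' @param rel half relative perturbation size (default 0.005, i.e. a total
#'   two-sided perturbation of 1%).
#' @return The perturbed network.
#' @export
perturb <- function(network, target, direction = +1, rel = 0.005) {
  fac <- 1 + direction * rel
  if (startsWith(target, "total.")) {
    m <- sub("^total\\.", "", target)
    i <- match(m, network$totals$moiety)
    if (is.na(i)) stop("unknown target: ", target)
    network$totals$total[i] <- network$totals$total[i] * fac
    return(network)
  }
  parts <- strsplit(target, ".", fixed = TRUE)[[1]]
  rid <- paste(parts[-length(parts)], collapse = ".")
  kind <- parts[length(parts)]
  r <- network$reactions[network$reactions$id == rid, ]
  if (nrow(r) != 1) stop("unknown target: ", target)
  p <- network$params
  if (kind == "kcat") {
    stopifnot(r$class == "enzymatic")
    for (k in c("kf", "kr", "kcat")) p[paste0(rid, ".", k)] <- p[paste0(rid, ".", k)] * fac
  } else if (kind == "KM") {
    stopifnot(r$class == "enzymatic")
    p[paste0(rid, ".kf")] <- p[paste0(rid, ".kf")] / fac
  } else if (kind %in% c("kf", "kr")) {
    nm <- paste0(rid, ".", kind)
    if (!nm %in% names(p)) stop("unknown target: ", target)
    p[nm] <- p[nm] * fac
  } else stop("unknown target: ", target)
  network$params <- p
  network
}

#' Derived constants of a parameter set
#'
#' `K_d = k_r/k_f` for reversible reactions and
#' `K_M = (k_cat + k_r)/k_f` for enzymatic reactions.
#'
#' @param network an `msn_network`.
#' @return Tibble with `id`, `class`, `Kd`, `KM`.
#' @export
derived_constants <- function(network) {
  rx <- network$reactions
  p <- network$params
  g <- function(id, k) unname(p[paste0(id, ".", k)])
  tibble::tibble(
    id = rx$id, class = rx$class,
    Kd = ifelse(rx$class == "reversible",
                vapply(rx$id, function(i) g(i, "kr") / g(i, "kf"), 1), NA),
    KM = ifelse(rx$class == "enzymatic",
                vapply(rx$id, function(i) {
                  if (is.na(g(i, "kcat"))) return(NA_real_)
                  (g(i, "kcat") + g(i, "kr")) / g(i, "kf")
                }, 1), NA))
}

#' Normalized local sensitivity matrix
#'
#' Central-difference normalized sensitivities
#' `S_ij = (o_i(p_j+) - o_i(p_j-)) / o_i(p_j) / (2 * rel)` for each target
#' parameter (rows) and each output (columns), using a total relative
#' perturbation of 1% (`rel = 0.005` per side).  The output function maps a
#' (possibly perturbed) network to a named numeric vector; failed runs are
#' flagged as missing and reported.
#'
#' @param network an `msn_network`.
#' @param outputs function `network -> named numeric vector`.
#' @param targets character vector of target ids (default: all 316).
#' @param rel half relative perturbation.
#' @param cache optional environment used to memoise perturbed runs so a
#'   long computation is resumable within a session.
#' @param verbose print progress.
#' @return An `msn_sensitivity`: matrix `S` (targets x outputs) with
#'   attributes `rel` and `failed`.
#' @export
sensitivity_matrix <- function(network, outputs,
                               targets = perturbable_parameters(network)$target,
                               rel = 0.005, cache = NULL, verbose = FALSE) {
  base <- outputs(network)
  out_names <- names(base)
  S <- matrix(NA_real_, length(targets), length(base),
              dimnames = list(targets, out_names))
  failed <- character(0)
  eval_pert <- function(target, dir) {
    key <- paste0(target, ":", dir)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(outputs(perturb(network, target, dir, rel)),
                    error = function(e) NULL)
    if (!is.null(cache)) cache[[key]] <- val
    val
  }
  for (i in seq_along(targets)) {
    if (verbose) message("perturbing ", targets[i])
    up <- eval_pert(targets[i], +1)
    dn <- eval_pert(targets[i], -1)
    if (is.null(up) || is.null(dn)) {
      failed <- c(failed, targets[i])
      next
    }
    S[i, ] <- (up[out_names] - dn[out_names]) / base / (2 * rel)
  }
  if (length(failed))
    warning("failed perturbed runs (entries left missing): ",
            paste(failed, collapse = ", "))
  structure(S, rel = rel, failed = failed, class = c("msn_sensitivity", "matrix"))
}

#' Sensitive parameter sets per output
#'
#' The demarcation between insensitive and sensitive parameters defaults to
#' the median of the distribution of each parameter's maximum absolute
#' sensitivity across outputs.  Also reports the fraction of sensitive
#' (parameter, output) pairs and the fraction of parameters whose mean
#' absolute sensitivity exceeds the threshold.
#'
#' @param S an `msn_sensitivity` matrix.
#' @param threshold demarcation; default the median of per-parameter maxima.
#' @return List with `threshold`, `sets` (named list of parameter ids per
#'   output), `per_parameter_max`, `n_sensitive` per output,
#'   `frac_pairs_sensitive` and `frac_mean_sensitive`.
#' @export
sensitive_sets <- function(S, threshold = NULL) {
  A <- abs(unclass(S))
  ok <- stats::complete.cases(A)
  if (any(!ok)) message(sum(!ok), " parameters with missing entries excluded")
  A <- A[ok, , drop = FALSE]
  pmax_ <- apply(A, 1, max)
  if (is.null(threshold)) threshold <- stats::median(pmax_)
  sets <- lapply(colnames(A), function(j) rownames(A)[A[, j] > threshold])
  names(sets) <- colnames(A)
  list(threshold = threshold,
       sets = sets,
       per_parameter_max = pmax_,
       n_sensitive = vapply(sets, length, 1L),
       frac_pairs_sensitive = mean(A > threshold),
       frac_mean_sensitive = mean(rowMeans(A) > threshold))
}

#' Overlap of two sensitive sets
#'
#' Number of common members divided by the size of the larger set; zero by
#' convention when both sets are empty.
#'
#' @param set_a,set_b character vectors.
#' @return Fraction in `[0, 1]`.
#' @export
overlap <- function(set_a, set_b) {
  if (!length(set_a) && !length(set_b)) return(0)
  length(intersect(set_a, set_b)) / max(length(set_a), length(set_b))
}

#' Rank parameters by summed sensitivity
#'
#' @param S an `msn_sensitivity` matrix.
#' @return Tibble sorted by decreasing `sum_abs_S`.
#' @export
rank_parameters <- function(S) {
  A <- abs(unclass(S))
  tibble::tibble(target = rownames(A),
                 sum_abs_S = rowSums(A),
                 is_total = startsWith(rownames(A), "total.")) |>
    dplyr::arrange(dplyr::desc(.data$sum_abs_S))
}

#' Non-APA phenotype outputs for sensitivity analysis
#'
#' A fast output vector (basal markers plus the slice fold changes) used to
#' exercise the sensitivity machinery at desk scale; the full 17-variable
#' panel (including APA mutant ratios and fitted parameters) is available
#' through the experiments layer as a long-running batch.
#'
#' @param network an `msn_network`.
#' @return Named numeric vector.
#' @export
phenotypes_nonapa <- function(network) {
  eq <- suppressWarnings(equilibrate(network, horizon = 3e5))
  y <- eq$state
  b34 <- state_marker(y, "D32p34"); b75 <- state_marker(y, "D32p75")
  da <- simulate_protocol(network, y, protocol("DAslice"), dt_out = 30)
  nm <- simulate_protocol(network, y, protocol("NMDAslice"), dt_out = 30)
  c(`basal-cAMP` = state_marker(y, "cAMP"),
    `basal-STEPact` = state_marker(y, "STEPact"),
    `basal-D32p34` = b34,
    `basal-D32p75` = b75,
    `DAslice-D32p34` = readout(da, "D32p34", 300) / b34,
    `DAslice-D32p75` = readout(da, "D32p75", 300) / b75,
    `NMDAslice-D32p34` = readout(nm, "D32p34", 600) / b34,
    `NMDAslice-D32p75` = readout(nm, "D32p75", 600) / b75)
}
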