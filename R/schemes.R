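# Crosstalk schemes: 3-bit codes, edge sets and their application to the
# network as forward-rate-constant switches on STEP(-p)-substrate association.

#' Map a crosstalk code to its active edge set
#'
#' Schemes are encoded by a 3-character binary string:
#' bit 1 - PKA-sensitive crosstalk via STEP at Fyn & NMDAR (1 = only
#' non-phosphorylated STEP acts there), bit 2 - PKA-sensitive crosstalk at
#' ERK, bit 3 - two STEP pools (pool 2 then serves the ERK node).  Edges
#' number the (STEP form, substrate) interactions: 1/2 = STEP/STEPp on ERK
#' (pool 1), 3/4 = the same for the second pool, 5/6 = STEP/STEPp on Fyn,
#' 7/8 = STEP/STEPp on NMDAR.
#'
#' @param code 3-character string over `{0,1}`, e.g. `"010"`.
#' @return Sorted integer vector of active edges.
#' @examples
#' scheme_to_edges("010")  # 1 5 6 7 8
#' @export
scheme_to_edges <- function(code) {
  if (!is.character(code) || length(code) != 1 || !grepl("^[01]{3}$", code))
    stop("crosstalk code must be a 3-character binary string, got ", deparse(code))
  bits <- as.integer(strsplit(code, "")[[1]])
  erk <- if (bits[3] == 1) {
    if (bits[2] == 1) 3L else c(3L, 4L)
  } else {
    if (bits[2] == 1) 1L else c(1L, 2L)
  }
  fyn_nmdar <- if (bits[1] == 1) c(5L, 7L) else c(5L, 6L, 7L, 8L)
  sort(c(erk, fyn_nmdar))
}

#' All eight crosstalk schemes
#' @return Character vector of the 8 codes.
#' @export
all_schemes <- function() {
  c("000", "001", "010", "011", "100", "101", "110", "111")
}

#' Apply a crosstalk scheme to a network
#'
#' Turns each inactive edge off by zeroing the forward association rate
#' constant of its STEP(-p)-substrate reactions, and splits the STEP total
#' between the two pools for two-pool schemes.
#'
#' @param network an `msn_network` built from the standard reaction table.
#' @param code 3-character binary crosstalk code.
#' @param step_split fraction of total STEP given to the second pool under
#'   two-pool schemes.
#' @return The modified network.
#' @export
apply_scheme <- function(network, code, step_split = 0.5) {
  edges <- scheme_to_edges(code)
  ed <- edge_reactions()
  for (e in names(ed)) {
    pars <- paste0(ed[[e]], ".kf")
    if (!as.integer(e) %in% edges) network$params[pars] <- 0
  }
  two_pools <- substr(code, 3, 3) == "1"
  i1 <- match("STEP", network$totals$moiety)
  i2 <- match("STEP2", network$totals$moiety)
  total <- network$totals$total[i1] + network$totals$total[i2]
  if (two_pools) {
    network$totals$total[i1] <- total * (1 - step_split)
    network$totals$total[i2] <- total * step_split
  } else {
    network$totals$total[i1] <- total
    network$totals$total[i2] <- 0
  }
  network$options$scheme <- code
  network
}
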