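# Shared fixtures: toy networks built in code and memoised expensive runs.

# several acceptance checks are documented-red at the shipped fit; keep the
# runner from aborting before the later test files execute
options(testthat.progress.max_fails = 100)

toy_enzyme_network <- function() {
  # textbook Michaelis scheme E + S <-> ES -> E + P
  rx <- rxn_enz("r1", "E + S", "E + P", 1, 0.5, 0.2)
  totals <- tibble::tibble(moiety = c("E", "S"), total = c(0.5, 2),
                           seed = c("E", "S"))
  build_network(rx, totals, registry = moiety_registry(list(P = c(S = 1))))
}

toy_three_reaction_network <- function() {
  # A + B <-> C ; C -> D ; E + S <-> ES -> E + P
  rx <- dplyr::bind_rows(
    rxn_rev("b1", "A + B", "C", 2, 1),
    rxn_irr("c1", "C", "D", 0.3),
    rxn_enz("e1", "E + S", "E + P", 1, 0.5, 0.2))
  totals <- tibble::tibble(moiety = c("A", "B", "E", "S"),
                           total = c(1, 2, 0.5, 2),
                           seed = c("A", "B", "E", "S"))
  reg <- moiety_registry(list(C = c(A = 1, B = 1), D = c(A = 1, B = 1),
                              P = c(S = 1)))
  build_network(rx, totals, registry = reg)
}

toy_two_state_network <- function(kf = 0.2, kr = 0.2, total = 1) {
  rx <- rxn_rev("ab", "A", "B", kf, kr)
  totals <- tibble::tibble(moiety = "A", total = total, seed = "A")
  build_network(rx, totals, registry = moiety_registry(list(B = c(A = 1))))
}

# memoised expensive objects (computed once per test session)
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

wt_model <- function() memo("wt_model", standard_model())

wt_basal <- function() {
  memo("wt_basal",
       suppressWarnings(equilibrate(wt_model(), horizon = 3e5))$state)
}

wt_calibration <- function() {
  memo("wt_cal", calibrate_mechanism(wt_model(), wt_basal(), "yTrf",
                                     apa = protocol("APA", duration = 1200)))
}

apa_pair_cached <- function(scheme, genotype, F, duration = 1200) {
  key <- paste("pair", scheme, genotype, round(F, 4), duration, sep = "_")
  memo(key, suppressWarnings(
    run_apa_pair(scheme = scheme, genotype = genotype, F = F,
                 duration = duration)))
}

# 4-scheme reduced grid shared between the crosstalk-scheme tests
grid4_cached <- function() {
  memo("grid4", suppressWarnings(
    run_apa_grid(schemes = c("000", "010", "011", "110"), duration = 960)))
}
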