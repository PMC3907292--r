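# Mutant genotypes: moiety-total scaling.

#' Genotype definitions
#'
#' `Drd1a_het` scales total D1R to 20% of wild type, `Gnal_het` scales total
#' G-alpha-olf (and with it the Golf heterotrimer, i.e. the G-beta-gamma
#' pool) to 40%, and `D32KO` removes DARPP-32.  Rate constants are never
#' touched.
#'
#' @return Named list of scaling maps (moiety -> fraction of WT total).
#' @export
genotype_scalings <- function() {
  list(
    WT = c(),
    Drd1a_het = c(D1R = 0.2),
    Gnal_het = c(Gaolf = 0.4, Gbg = 0.4),
    D32KO = c(D32 = 0)
  )
}

#' Apply a genotype to a network
#'
#' @param network an `msn_network`.
#' @param genotype one of `names(genotype_scalings())`.
#' @return The network with scaled conserved totals.
#' @export
apply_genotype <- function(network, genotype) {
  sc <- genotype_scalings()
  if (!genotype %in% names(sc)) stop("unknown genotype: ", genotype)
  s <- sc[[genotype]]
  for (m in names(s)) {
    i <- match(m, network$totals$moiety)
    if (is.na(i)) stop("genotype targets unknown moiety: ", m)
    network$totals$total[i] <- network$totals$total[i] * s[[m]]
  }
  network$options$genotype <- genotype
  network
}
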