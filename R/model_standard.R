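# The standard D1R+MSN signalling network: reaction table, conserved totals
# and assembly options (crosstalk scheme, genotype, compartment variants).
#
# Rate constants and totals are a manual fit of the network to the phenotype
# panel (basal markers, slice treatments, RAS ultrasensitivity, NMDAR traffic
# kinetics and the mutant APA ratios); literature-typical magnitudes were used
# as starting points wherever they exist.  Units: uM and s throughout.

#' Conserved totals of the standard model
#'
#' The 40 conserved pools of the network with their wild-type total
#' concentrations (uM) and the species each pool is seeded into before
#' equilibration.
#'
#' @return Tibble with columns `moiety`, `total`, `seed`.
#' @export
standard_totals <- function() {
  tibble::tribble(
    ~moiety,  ~total, ~seed,
    "CaM",      10,   "CaM",
    "Ng",       20,   "Ng",
    "AKAPc",     0.02, "AKAPc",
    "PP2B",      4,   "PP2B",
    "AKAP",      6,   "AKAP",
    "PP2A72",    1,   "PP2A72",
    "PP2A56",    2,   "PP2A56",
    "CDK5",      2,   "CDK5",
    "p35",       2,   "p35",
    "PKAr",      1.2, "PKA",
    "PKAc",      2.4, "PKAc",
    "PP1",       2,   "PP1",
    "D32",      50,   "D32",
    "AC5",       2.5, "AC5",
    "PDE1",      4,   "PDE1",
    "PDE4",      2,   "PDE4",
    "PDE10",     1,   "PDE10",
    "D1R",       1,   "D1R",
    "Gbg",       1,   "Golf",
    "Gaolf",     1,   "GaolfGDP_A",
    "AncRA",     0.2, "AncRA",
    "AncRN",     1,   "AncRN",
    "AncGA",     1,   "AncGA",
    "AncGN",     0.18, "AncGN",
    "Fyn",       2,   "Fyn",
    "Csk",       0.5, "Csk",
    "PAG",       0.6, "PAG",
    "PTPa",      0.5, "PTPa",
    "STEP",      0.3, "STEP",
    "STEP2",     0,   "STEP2",
    "NMDAR",     0.3, "NMDARi",
    "AP2",       1,   "AP2",
    "GRF",       0.5, "GRF",
    "RAS",       0.5, "RASgdp",
    "GAP",       0.1, "GAP",
    "RAF",       0.5, "RAF",
    "MEK",       1.2, "MEK",
    "ERK",       2,   "ERK",
    "DUSP",      1,   "DUSPi",
    "GluR1",     2,   "GluR1"
  )
}

#' Reaction table of the standard model
#'
#' The full reaction network: Ca2+ buffers and calmodulin, the phosphatases
#' PP2B (calcineurin) and the two PP2A pools (Ca2+-stimulated B72 and
#' PKA-sensitive B56), CDK5/p35, the PKA holoenzyme cycle, PP1 and its
#' inhibition by DARPP-32 phospho-Thr34, the AC5/cAMP machinery with three
#' phosphodiesterases (CaM-activated PDE1, PKA-modulated PDE4, cAMP-activated
#' PDE10a), the two D1R/Golf signalling compartments exchanging through a
#' non-signalling reservoir, the Fyn activation cycle (Csk, PTPa, STEP,
#' G-beta-gamma), NMDAR tyrosine/serine phosphorylation and AP2-dependent
#' traffic, the RAS-GRF1/RAS/RAF/MEK/ERK cascade with GAP, STEP and PP2A-B56
#' shutdown and the inducible-DUSP negative feedback, and GluR1 Ser845
#' phosphorylation.
#'
#' @return Reaction tibble in the frozen table dialect (see [rxn_enz()]).
#' @export
standard_reactions <- function() {
  dplyr::bind_rows(
    ## Ca2+ buffering and calmodulin
    rxn_rev("cam1", "CaM + 2 Ca", "CaMCa2", 5, 10, "two-site lobe binding"),
    rxn_rev("cam2", "CaMCa2 + 2 Ca", "CaMCa4", 5, 5),
    rxn_rev("ng1", "Ng + CaM", "Ng.CaM", 0.5, 1, "neurogranin CaM buffer"),

    ## PP2B (calcineurin)
    rxn_rev("pp2b1", "AKAP + PP2B", "AKAP.PP2B", 0.03, 0.1, "anchored, inactive pool"),
    rxn_rev("pp2b2", "PP2B + CaMCa4", "PP2B.CaMCa4", 2, 20,
            "low-affinity, fast: follows tonic Ca2+ but not brief spikes"),
    rxn_enz("pp2b3", "PP2B.CaMCa4 + D32p@34", "PP2B.CaMCa4 + D32", 15, 1.2, 0.3,
            "PP1-bound Thr34 is protected"),
    rxn_enz("pp2b4", "PP2B + D32p@34", "PP2B + D32", 0.75, 4, 1,
            "CaM-independent residual calcineurin activity"),

    ## PP2A pools
    rxn_rev("p72a", "PP2A72 + Ca", "PP2A72ca", 1, 1, "single-site Ca activation"),
    rxn_enz("p72b", "PP2A72 + D32p@75", "PP2A72 + D32", 0.175, 5.6, 1.4),
    rxn_enz("p72c", "PP2A72ca + D32p@75", "PP2A72ca + D32", 0.875, 28, 7),
    rxn_enz("p56a", "PP2A56 + D32p@75", "PP2A56 + D32", 0.133, 16, 4),
    rxn_enz("p56b", "PP2A56p@S + D32p@75", "PP2A56p@S + D32", 0.6, 72, 18),
    rxn_enz("p56c", "PP2A56 + ERKp@Tp@Y", "PP2A56 + ERKp@Y", 0.15, 0.12, 0.03),
    rxn_enz("p56d", "PP2A56p@S + ERKp@Tp@Y", "PP2A56p@S + ERKp@Y", 0.15, 0.12, 0.03),
    rxn_enz("p56e", "PP2A56 + ERKp@T", "PP2A56 + ERK", 0.15, 0.12, 0.03),
    rxn_enz("p56f", "PP2A56p@S + ERKp@T", "PP2A56p@S + ERK", 0.15, 0.12, 0.03),
    rxn_enz("p56g", "PP2A56 + MEKp@1", "PP2A56 + MEK", 0.15, 0.12, 0.03),
    rxn_enz("p56h", "PP2A56 + MEKp@1p@2", "PP2A56 + MEKp@1", 0.15, 0.12, 0.03),

    ## CDK5/p35 -> DARPP-32 Thr75
    rxn_rev("cdk1", "CDK5 + p35", "CDK5.p35", 1, 0.2),
    rxn_enz("cdk2", "CDK5.p35 + D32", "CDK5.p35 + D32p@75", 0.375, 3, 0.75),

    ## PKA holoenzyme cycle and catalytic-subunit targets
    rxn_rev("pka0", "AKAPc + 2 PKAc", "AKAPc.PKAc2", 100, 0.03,
            "anchored PKA subpool (cooperative) serving STEP and Thr34"),
    rxn_rev("pka1", "PKA + 2 cAMP", "PKAcamp2", 5, 8),
    rxn_rev("pka2", "PKAcamp2 + 2 cAMP", "PKAcamp4", 5, 8),
    rxn_rev("pka3", "PKAcamp4", "PKAcamp4c1 + PKAc", 1, 10),
    rxn_rev("pka4", "PKAcamp4c1", "PKAr + PKAc", 1, 10),
    rxn_rev("pka5", "PKAc + D32p@75", "PKAc.D32p@75", 1, 200,
            "Thr75 pseudosubstrate inhibition of PKA"),
    rxn_enz("pka6", "AKAPc.PKAc2 + D32", "AKAPc.PKAc2 + D32p@34", 5, 240, 60),
    rxn_enz("pka6b", "PKAc + D32", "PKAc + D32p@34", 0.0188, 14.4, 3.6,
            "cytosolic PKA component of Thr34 phosphorylation"),
    rxn_enz("pka7", "AKAPc.PKAc2 + STEP", "AKAPc.PKAc2 + STEPp@S", 30, 1.6, 0.4,
            "near-saturated in STEP: anchored-pool capacity limits flux"),
    rxn_enz("pka8", "AKAPc.PKAc2 + STEP2", "AKAPc.PKAc2 + STEP2p@S", 30, 1.6, 0.4),
    rxn_enz("pka9", "AKAPc.PKAc2 + GluR1", "AKAPc.PKAc2 + GluR1p@845", 40, 160, 40,
            "AKAP-anchored PKA is the Ser845 kinase"),
    rxn_enz("pka10", "PKAc + NMDARm", "PKAc + NMDARmp@S", 4, 16, 4),
    rxn_enz("pka11", "PKAc + NMDARmp@Y", "PKAc + NMDARmp@Yp@S", 4, 16, 4),
    rxn_enz("pka12", "PKAc + NMDARi", "PKAc + NMDARip@S", 4, 16, 4),
    rxn_enz("pka13", "PKAc + NMDARip@Y", "PKAc + NMDARip@Yp@S", 4, 16, 4),
    rxn_enz("pka14", "PKAc + PP2A56", "PKAc + PP2A56p@S", 1, 4, 1),
    rxn_enz("pka15", "PKAc + PDE4", "PKAc + PDE4p@S", 2, 8, 2),
    rxn_enz("pka16", "PKAc + PDE10", "PKAc + PDE10p@S", 2, 8, 2),

    ## PP1 and its DARPP-32 brake
    rxn_irr("stk1", "STEP", "STEPp@S", 0.022,
            "constitutive KIM-kinase tone on STEP"),
    rxn_irr("stk2", "STEP2", "STEP2p@S", 0.022),
    rxn_rev("pp1a", "PP1 + D32p@34", "PP1.D32p@34", 0.005, 0.0015,
            "slow, tight inhibitory binding"),
    rxn_enz("pp1b", "PP1 + GluR1p@845", "PP1 + GluR1", 2.4, 4.8, 1.2),
    rxn_irr("gk1", "GluR1", "GluR1p@845", 0.02,
            "constitutive Ser845 kinase tone"),
    rxn_enz("p72g", "PP2A72 + GluR1p@845", "PP2A72 + GluR1", 0.8, 1.6, 0.4),
    rxn_enz("pp1c", "PP1 + STEPp@S", "PP1 + STEP", 0.5, 4.8, 1.2),
    rxn_enz("pp1d", "PP1 + STEP2p@S", "PP1 + STEP2", 0.5, 4.8, 1.2),
    rxn_enz("pp1e", "PP1 + NMDARmp@S", "PP1 + NMDARm", 1, 2, 0.5),
    rxn_enz("pp1f", "PP1 + NMDARmp@Yp@S", "PP1 + NMDARmp@Y", 1, 2, 0.5),
    rxn_enz("pp1g", "PP1 + NMDARip@S", "PP1 + NMDARi", 1, 2, 0.5),
    rxn_enz("pp1h", "PP1 + NMDARip@Yp@S", "PP1 + NMDARip@Y", 1, 2, 0.5),
    rxn_enz("pp1i", "PP1 + PDE4p@S", "PP1 + PDE4", 0.4, 0.8, 0.2),
    rxn_enz("pp1j", "PP1 + PDE10p@S", "PP1 + PDE10", 0.4, 0.8, 0.2),
    rxn_enz("pp1k", "PP1 + PP2A56p@S", "PP1 + PP2A56", 0.4, 0.8, 0.2),

    ## AC5 and cAMP turnover
    rxn_rev("ac1", "AC5 + Ca", "AC5ca", 2, 1, "Ca inhibits AC5 to ~half"),
    rxn_rev("ac2", "AC5 + Gaolf_A", "AC5.Gaolf_A", 10, 0.01),
    rxn_rev("ac3", "AC5ca + Gaolf_A", "AC5ca.Gaolf_A", 10, 0.01),
    rxn_rev("ac4", "AC5.Gaolf_A + Ca", "AC5ca.Gaolf_A", 2, 1),
    rxn_irr("ac5", "AC5", "AC5 + cAMP", 0.004, "basal cyclase activity"),
    rxn_irr("ac6", "AC5ca", "AC5ca + cAMP", 0.022),
    rxn_irr("ac7", "AC5.Gaolf_A", "AC5.Gaolf_A + cAMP", 30),
    rxn_irr("ac8", "AC5ca.Gaolf_A", "AC5ca.Gaolf_A + cAMP", 15),
    rxn_irr("ac9", "AC5.Gaolf_A", "AC5 + GaolfGDP_A", 2,
            "GTP hydrolysis on the effector"),
    rxn_irr("ac10", "AC5ca.Gaolf_A", "AC5ca + GaolfGDP_A", 2),
    rxn_irr("amp1", "AMP", "", 1, "5'-AMP clearance sink"),
    rxn_rev("pde1a", "PDE1 + CaMCa4", "PDE1.CaMCa4", 5, 1),
    rxn_enz("pde1b", "PDE1 + cAMP", "PDE1 + AMP", 0.6, 2.4, 0.6),
    rxn_enz("pde1c", "PDE1.CaMCa4 + cAMP", "PDE1.CaMCa4 + AMP", 3, 12, 3),
    rxn_enz("pde4a", "PDE4 + cAMP", "PDE4 + AMP", 3, 4.8, 1.2),
    rxn_enz("pde4b", "PDE4p@S + cAMP", "PDE4p@S + AMP", 6, 9.6, 2.4),
    rxn_rev("pde10a", "PDE10 + cAMP", "PDE10a", 2, 0.1,
            "allosteric activation by cAMP"),
    rxn_enz("pde10b", "PDE10a + cAMP", "PDE10a + AMP", 4.5, 3.6, 0.9),

    ## D1R/Golf compartments and the G-protein cycle
    rxn_rev("r1", "D1R + AncRA", "D1R.AncRA", 0.03, 0.000006,
            "high-affinity AC5-compartment D1R anchor"),
    rxn_rev("r2", "D1R + AncRN", "D1R.AncRN", 0.03, 0.009),
    rxn_rev("r3", "D1R.AncRA + DA", "D1Rda.AncRA", 1, 0.5),
    rxn_rev("r4", "D1R.AncRN + DA", "D1Rda.AncRN", 1, 0.5),
    rxn_rev("r5", "Golf + AncGA", "Golf.AncGA", 0.03, 0.009),
    rxn_rev("r6", "Golf + AncGN", "Golf.AncGN", 0.03, 0.00003,
            "high-affinity NMDAR-compartment Golf anchor"),
    rxn_irr("g1", "D1Rda.AncRA + Golf.AncGA",
            "D1Rda.AncRA + Gaolf_A + Gbg.AncGA", 5, "receptor GEF activity"),
    rxn_irr("g2", "D1Rda.AncRN + Golf.AncGN",
            "D1Rda.AncRN + Gaolf_N + Gbg.AncGN", 12),
    rxn_irr("g3", "Gaolf_A", "GaolfGDP_A", 2),
    rxn_irr("g4", "Gaolf_N", "GaolfGDP_N", 2),
    rxn_irr("g5", "GaolfGDP_A + Gbg.AncGA", "Golf.AncGA", 20),
    rxn_irr("g6", "GaolfGDP_N + Gbg.AncGN", "Golf.AncGN", 20),

    ## Fyn activation cycle
    rxn_rev("fy1", "Gbg.AncGN + Fynp@527", "Gbg.AncGN.Fynp@527", 5, 0.5),
    rxn_rev("fy2", "Gbg.AncGN + Fynp@420p@527", "Gbg.AncGN.Fynp@420p@527", 5, 1),
    rxn_irr("fy3", "2 Fyn", "Fyn + Fynp@420", 0.001,
            "second-order autophosphorylation"),
    rxn_irr("fy4", "Fynp@420 + Fyn", "2 Fynp@420", 0.05),
    rxn_irr("fy5", "Fynp@420p@527 + Fyn", "Fynp@420p@527 + Fynp@420", 0.05),
    rxn_irr("fy6", "Fyn + Gbg.AncGN.Fynp@527",
            "Fyn + Gbg.AncGN.Fynp@420p@527", 0.005,
            "G-beta-gamma binding permits autophosphorylation of p@527 Fyn"),
    rxn_irr("fy7", "Fynp@420 + Gbg.AncGN.Fynp@527",
            "Fynp@420 + Gbg.AncGN.Fynp@420p@527", 0.67),
    rxn_irr("fy8", "Fynp@420p@527 + Gbg.AncGN.Fynp@527",
            "Fynp@420p@527 + Gbg.AncGN.Fynp@420p@527", 0.67),
    rxn_rev("csk1", "PAG + Csk", "PAG.Csk", 1, 0.1),
    rxn_enz("csk2", "PAG.Csk + Fyn", "PAG.Csk + Fynp@527", 4, 16, 4),
    rxn_enz("csk3", "PAG.Csk + Fynp@420", "PAG.Csk + Fynp@420p@527", 4, 16, 4),
    rxn_enz("ptp1", "PTPa + Fynp@527", "PTPa + Fyn", 2, 4, 1),
    rxn_enz("ptp2", "PTPa + Fynp@420p@527", "PTPa + Fynp@420", 2, 4, 1),
    rxn_enz("st5a", "STEP + Fynp@420", "STEP + Fyn", 2, 8, 2),
    rxn_enz("st5b", "STEP + Fynp@420p@527", "STEP + Fynp@527", 2, 8, 2),
    rxn_enz("st6a", "STEPp@S + Fynp@420", "STEPp@S + Fyn", 2, 8, 2),
    rxn_enz("st6b", "STEPp@S + Fynp@420p@527", "STEPp@S + Fynp@527", 2, 8, 2),

    ## NMDAR phosphorylation and traffic
    rxn_enz("fn1", "Fynp@420 + NMDARm", "Fynp@420 + NMDARmp@Y", 4, 8, 2),
    rxn_enz("fn2", "Fynp@420 + NMDARmp@S", "Fynp@420 + NMDARmp@Yp@S", 4, 8, 2),
    rxn_enz("fn3", "Fynp@420 + NMDARi", "Fynp@420 + NMDARip@Y", 4, 8, 2),
    rxn_enz("fn4", "Fynp@420 + NMDARip@S", "Fynp@420 + NMDARip@Yp@S", 4, 8, 2),
    rxn_enz("fn5", "Fynp@420p@527 + NMDARm", "Fynp@420p@527 + NMDARmp@Y", 4, 8, 2),
    rxn_enz("fn6", "Fynp@420p@527 + NMDARmp@S",
            "Fynp@420p@527 + NMDARmp@Yp@S", 4, 8, 2),
    rxn_enz("fn7", "Fynp@420p@527 + NMDARi", "Fynp@420p@527 + NMDARip@Y", 4, 8, 2),
    rxn_enz("fn8", "Fynp@420p@527 + NMDARip@S",
            "Fynp@420p@527 + NMDARip@Yp@S", 4, 8, 2),
    rxn_enz("st7a", "STEP + NMDARmp@Y", "STEP + NMDARm", 1.34, 2.68, 0.67),
    rxn_enz("st7b", "STEP + NMDARmp@Yp@S", "STEP + NMDARmp@S", 1.34, 2.68, 0.67),
    rxn_enz("st7c", "STEP + NMDARip@Y", "STEP + NMDARi", 1.34, 2.68, 0.67),
    rxn_enz("st7d", "STEP + NMDARip@Yp@S", "STEP + NMDARip@S", 1.34, 2.68, 0.67),
    rxn_enz("st8a", "STEPp@S + NMDARmp@Y", "STEPp@S + NMDARm", 1.34, 2.68, 0.67),
    rxn_enz("st8b", "STEPp@S + NMDARmp@Yp@S", "STEPp@S + NMDARmp@S", 1.34, 2.68, 0.67),
    rxn_enz("st8c", "STEPp@S + NMDARip@Y", "STEPp@S + NMDARi", 1.34, 2.68, 0.67),
    rxn_enz("st8d", "STEPp@S + NMDARip@Yp@S", "STEPp@S + NMDARip@S", 1.34, 2.68, 0.67),
    rxn_irr("tr1", "NMDARi", "NMDARm", 0.0007, "basal exocytosis"),
    rxn_irr("tr2", "NMDARip@S", "NMDARmp@S", 0.0007),
    rxn_irr("tr3", "NMDARip@Y", "NMDARmp@Y", 0.0019,
            "faster exocytosis of Y1472-phosphorylated receptor"),
    rxn_irr("tr4", "NMDARip@Yp@S", "NMDARmp@Yp@S", 0.0019),
    rxn_rev("ap1", "AP2 + NMDARm", "AP2.NMDARm", 1, 1,
            "Y1472 phosphorylation blocks AP2 binding"),
    rxn_rev("ap2r", "AP2 + NMDARmp@S", "AP2.NMDARmp@S", 1, 1),
    rxn_irr("ap3", "AP2.NMDARm", "AP2 + NMDARi", 0.022),
    rxn_irr("ap4", "AP2.NMDARmp@S", "AP2 + NMDARip@S", 0.022),

    ## RAS-GRF1 / RAS / RAF / MEK / ERK
    rxn_irr("ras0", "RASgdp", "RASgtp", 0.0001, "intrinsic exchange"),
    rxn_rev("grf1", "GRF + CaMCa4", "GRF.CaMCa4", 10, 3),
    rxn_enz("grf2", "GRF.CaMCa4 + RASgdp", "GRF.CaMCa4 + RASgtp", 40, 20, 5,
            "GEF-catalysed nucleotide exchange; GTP excess"),
    rxn_enz("gap1", "GAP + RASgtp", "GAP + RASgdp", 80, 40, 10),
    rxn_rev("raf1", "RASgtp + RAF", "RASgtp.RAF", 10, 1),
    rxn_enz("raf2", "RASgtp.RAF + MEK", "RASgtp.RAF + MEKp@1", 2.2, 2.2, 0.55),
    rxn_enz("raf3", "RASgtp.RAF + MEKp@1", "RASgtp.RAF + MEKp@1p@2", 2.2, 2.2, 0.55),
    rxn_enz("mek1", "MEKp@1p@2 + ERK", "MEKp@1p@2 + ERKp@Y", 9.6, 9.6, 2.4),
    rxn_enz("mek2", "MEKp@1p@2 + ERKp@Y", "MEKp@1p@2 + ERKp@Tp@Y", 9.6, 9.6, 2.4),
    rxn_enz("st1", "STEP + ERKp@Tp@Y", "STEP + ERKp@T", 64, 6.4, 1.6,
            "crosstalk edge 1; low Km drives sequestration"),
    rxn_enz("st2", "STEPp@S + ERKp@Tp@Y", "STEPp@S + ERKp@T", 64, 6.4, 1.6,
            "crosstalk edge 2"),
    rxn_enz("st3", "STEP2 + ERKp@Tp@Y", "STEP2 + ERKp@T", 64, 6.4, 1.6,
            "crosstalk edge 3 (second STEP pool)"),
    rxn_enz("st4", "STEP2p@S + ERKp@Tp@Y", "STEP2p@S + ERKp@T", 64, 6.4, 1.6,
            "crosstalk edge 4 (second STEP pool)"),
    rxn_enz("du1", "ERKp@Tp@Y + DUSPi", "ERKp@Tp@Y + DUSP", 0.012, 0.024, 0.006,
            "lumped transcription/translation of inducible DUSP"),
    rxn_irr("du2", "DUSP", "DUSPi", 0.001),
    rxn_enz("du3", "DUSP + ERKp@Tp@Y", "DUSP + ERKp@T", 4, 4, 1),
    rxn_enz("du4", "DUSP + ERKp@Y", "DUSP + ERK", 4, 4, 1)
  )
}

# reaction ids toggled by each crosstalk edge (forward association constants)
edge_reactions <- function() {
  list(
    `1` = "st1", `2` = "st2", `3` = "st3", `4` = "st4",
    `5` = c("st5a", "st5b"), `6` = c("st6a", "st6b"),
    `7` = c("st7a", "st7b", "st7c", "st7d"),
    `8` = c("st8a", "st8b", "st8c", "st8d")
  )
}

#' Assemble the standard model
#'
#' Builds the standard network and applies a crosstalk scheme, genotype and
#' compartment option.
#'
#' @param scheme 3-character binary crosstalk code (see [scheme_to_edges()]).
#' @param genotype one of `"WT"`, `"Drd1a_het"`, `"Gnal_het"`, `"D32KO"`.
#' @param two_compartments if `FALSE`, a single-compartment variant is built
#'   in which both signalling compartments share one D1R anchor pool and one
#'   Golf anchor pool of intermediate affinity (the failure-demonstration
#'   variant).
#' @param step_split fraction of total STEP assigned to the second pool under
#'   two-pool schemes (third code bit set); ignored otherwise.
#' @param param_overrides named numeric vector of rate-constant overrides.
#' @param totals optional named numeric overrides of conserved totals.
#' @return An `msn_model`: the assembled `msn_network` plus option metadata.
#' @export
standard_model <- function(scheme = "010", genotype = "WT",
                           two_compartments = TRUE, step_split = 0.5,
                           param_overrides = NULL, totals = NULL) {
  tot <- standard_totals()
  if (!is.null(totals)) tot$total[match(names(totals), tot$moiety)] <- totals
  net <- build_network(standard_reactions(), tot, param_overrides = param_overrides)
  net <- apply_scheme(net, scheme, step_split = step_split)
  net <- apply_genotype(net, genotype)
  if (!two_compartments) {
    # collapse the compartment asymmetry: both anchors get equal intermediate
    # affinity and capacity, so D1R and Golf see a single effective pool
    p <- net$params
    p["r1.kr"] <- 0.009; p["r2.kr"] <- 0.009
    p["r5.kr"] <- 0.009; p["r6.kr"] <- 0.009
    net$params <- p
    i <- match(c("AncRA", "AncRN", "AncGA", "AncGN"), net$totals$moiety)
    net$totals$total[i] <- c(0.6, 0.6, 0.7, 0.7)
  }
  net$options <- list(scheme = scheme, genotype = genotype,
                      two_compartments = two_compartments,
                      step_split = step_split)
  class(net) <- c("msn_model", class(net))
  net
}
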