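---
title: "Model and methods: dopamine/glutamate signalling in the D1R medium spiny neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`msnsig` models the intracellular signalling triggered in striatal
D1-receptor medium spiny neurons by dopamine (via D1R/Golf) and glutamate
(via NMDAR Ca²⁺ entry): the AC5/cAMP/PKA/DARPP-32 axis read out as GluR1
phospho-Ser845, and the NMDAR/Ca²⁺/RAS/RAF/MEK/ERK axis read out as doubly
phosphorylated ERK.  The package exists to study one question
quantitatively: how reductions of D1R or Gαolf can each silence only one of
the two read-outs (segregation) although both cascades hang off the same
receptor/G-protein pair and are coupled through the tyrosine phosphatase
STEP.

Everything is deterministic mass action in a single well-stirred volume;
compartments (PSD, intracellular NMDAR reservoir, the two D1R/Golf
signalling compartments and their reservoir) are represented by species
indexing, not by diffusion.  There is no stochastic simulation and no
spatial model, and the model's parameters are not re-estimated by any
global fitting machinery: the shipped rate constants and totals are a
manual fit, in the tradition of this model family, to the phenotype panel
described below.

## The network

The reaction table (`standard_reactions()`, 141 reactions over 182 species
with 40 conserved pools) is the single source of truth; it round-trips
through a TSV dialect (`write_reaction_table()` /
`read_reaction_table()`) with one row per classed reaction:

* **enzymatic** reactions carry `k_f`, `k_r`, `k_cat` and always build an
  explicit enzyme–substrate complex — no quasi-steady-state shortcut, so
  enzyme sequestration (the retroactivity that turns out to matter for
  STEP) is representable;
* **reversible** and **irreversible** reactions are plain mass action.

Species names follow a small grammar: complexes join components with `.`,
phospho-sites are `p@<site>` (`D32p@34`, `Fynp@420p@527`,
`NMDARmp@Yp@S`), and the two D1R/Golf compartments are tagged `_A`
(AC5-linked) and `_N` (NMDAR-linked).  A registry maps component names to
conserved pools (e.g. the PKA holoenzyme carries one regulatory dimer and
two catalytic subunits), which lets `conserved_moieties()` verify
structurally that each of the 40 declared pools lies in the left null
space of the stoichiometric matrix.

Subsystems, each with its own tuning history:

* **cAMP**: AC5 activated by Gαolf-GTP and half-inhibited by Ca²⁺; PDE1
  (CaM-activated), PDE4 (PKA-phosphorylated, faster), PDE10a
  (cAMP-allosteric, PKA-inhibited); the PKA holoenzyme binds four cAMP in
  two cooperative steps and releases the catalytic subunits sequentially.
* **DARPP-32**: Thr34 (PKA site, PP2B-dephosphorylated) turns DARPP-32
  into a slow, tight PP1 inhibitor; Thr75 (CDK5/p35 site,
  PP2A-dephosphorylated) is the dominant resting form (~13 µM).
* **PP2A pools**: a Ca²⁺-stimulated B72 pool and a PKA-stimulated B56
  pool; only their Thr75 activity is PKA-sensitive — their activity toward
  phospho-Thr ERK is deliberately equal for both forms.
* **Fyn cycle**: Y527 (Csk via the PAG adaptor / PTPα) gates a
  second-order trans-autophosphorylation of Y420; Gβγ binding to
  Y527-phosphorylated Fyn licenses autophosphorylation, which is how
  dopamine reaches the NMDAR axis.  STEP dephosphorylates Y420.
* **NMDAR**: two locations (synaptic membrane, intracellular reservoir) ×
  two sites (Fyn's tyrosine, PKA's serine).  Tyrosine phosphorylation
  blocks AP2 binding (hence endocytosis) and accelerates exocytosis — the
  traffic-based enhancement.
* **RAS/ERK**: calmodulin loads four Ca²⁺ in two cooperative pair-steps
  (the origin of the Hill ≈ 4 ultrasensitivity), activates RAS-GRF1;
  RAS-GTP·RAF drives a distributive MEK→ERK cascade; ERK is shut down by
  STEP (tyrosine), PP2A-B56 (threonine) and an inducible DUSP pool whose
  activation by ERKpp lumps transcription and translation (rate constants
  correspondingly below the usual range).

### Design choices made where the design was open

* **Anchored PKA subpool.**  STEP, DARPP-32 Thr34 and GluR1 Ser845 are
  phosphorylated by a small (0.02 µM) AKAP-anchored PKA pool that binds
  two catalytic subunits cooperatively, while cytosolic substrates see
  free PKAc.  This is standard synaptic biology (AKAP-anchored PKA is the
  canonical Ser845 kinase) and is load-bearing here: the anchored pool
  saturates at stimulated PKAc in every genotype, so the Gαolf-het's
  smaller cAMP response still drives near-wild-type crosstalk, while the
  graded cytosolic component preserves dose discrimination.
* **STEP's basal phosphorylation** carries a small constitutive kinase
  tone, so the resting 80/20 active/inactive split does not hinge on the
  resting PKA level; stimulation shifts the balance through the anchored
  pool and PP1.
* **PP2B discrimination of tonic vs pulsed Ca²⁺**: the CaM–PP2B
  interaction is low-affinity and fast, so 0.3-s spikes (3% duty cycle)
  barely move it while the sustained Ca²⁺ of the NMDA/glutamate protocols
  activates it fully; a small CaM-independent calcineurin activity
  carries the resting Thr34 turnover.
* **Compartment anchors**: the AC5 compartment's D1R anchor has capacity
  0.2× total D1R and ~1 nM affinity; the NMDAR compartment's Golf anchor
  has capacity 0.18× total Golf at the same affinity; the reciprocal
  anchors are low-affinity and high-capacity.  Exchange through the free
  reservoir is orders of magnitude slower than signalling, which is why
  mutants are re-equilibrated before stimulation.  These values are one
  manual solution satisfying the stated inequalities, not a unique fit.
* **Two-pool STEP variants** split the STEP total 50/50 by default
  (`step_split`); the published material does not state the split.
* **Golf heterotrimer** is set equal to Gαolf, so the Gαolf-het genotype
  scales both the α and βγ pools to 40%.

## Stimuli and simulation

Ca²⁺ spikes and dopamine are closed-form forcing functions (double
exponentials, normalised to unit peak; the degenerate equal-rate case uses
the alpha-function limit).  Units are µM and seconds internally; stimulus
constants quoted in nM and minutes are converted at the boundary.  The
integrator is `deSolve::lsoda` over a compiled mass-action right-hand side
with an analytic Jacobian; integration restarts at every spike onset, where
the spike's amplitude term `(C_max − C_b)` is multiplied by the current
scaling factor.

The **scaling factor** for NMDAR enhancement is
`1 + 1.5 · min(1, F·(R − R₀))`, where `R` is the mechanism's state ratio
(`sSCh`: PKA-phosphorylated membrane NMDAR over membrane NMDAR; `yTrf`:
membrane over total NMDAR; `ySCh`: tyrosine-phosphorylated membrane over
membrane), `R₀` its equilibrated basal value, and `F` is calibrated so the
maximum factor under the psychostimulant protocol is 2.5.  The saturating
form keeps all mechanisms — and all genotypes, which inherit the wild-type
`F` — under the same 2.5 ceiling while remaining exactly 1 at each
genotype's own basal state; a pure ratio normalisation would let a mutant
with a lower basal ratio overshoot the common maximum.

**Equilibration** runs the tonic basal protocol (DA 10 nM, Ca 60 nM) over
3·10⁵ s — long enough for the slow anchor exchange — and checks
`|dC/dt|/max(C, 10⁻⁴)` per species against 10⁻⁸ s⁻¹; a failed plateau
reports the worst species.  The plateau floor treats sub-0.1-nM pools as
empty.  Default solver tolerances are `rtol 10⁻⁷ / atol 10⁻¹⁰`; the test
suite verifies that halving them moves basal markers by far less than
0.5%.

**Problem sizes** used by the shipped tests and the acceptance script are
deliberately desk-scale: psychostimulant runs of 960–1200 s (readout at
15 min), 20 Poisson replicates for the convergence check, a four-scheme
crosstalk screen (000/010/011/110 — the no-crosstalk, headline,
two-pool and Fyn-crosstalk topologies that carry the discriminating
comparisons), and sensitivity analysis on analytic toys plus a reduced
parameter subset.  The full sensitivity matrix over all 292 perturbable parameters
(252 kinetic constants plus the 40 totals) and the phenotype panel
is a long-running batch; `sensitivity_matrix()` takes a `cache`
environment so it can resume.

## Phenotypes and scoring

The 17-variable panel (shipped as `inst/extdata/phenotype_panel.csv`)
combines absolute basal markers, slice fold-changes, fitted parameters
(Hill `h`, `K`; monoexponential `k`) and mutant ratios-to-WT of
fold-changes over the saline arm at matched times.  The panel composition
is a documented reconstruction: the published table lists ten phenotypes,
several with multiple variables, and seventeen is the count after
excluding the qualitative sensitisation phenotype and the time-series
that resisted parametric compression.  Range targets (basal Thr34
0.2–0.5 µM) score zero divergence inside the interval and linearly
outside; panel `r² = 1 − SS_res/SS_tot` over the target values.

The **immunoblot heterogeneity correction** inverts a two-population
mixture: if a fraction `f_t` of cells (and `f_c` in the control) carries a
cell-specific fold change `FC` while the rest stay at basal, the blot
reports `W = (1 + f_t(FC−1))/(1 + f_c(FC−1))`, so
`FC = 1 + (W−1)/(f_t − W·f_c)`.  The shipped example table uses inferred
positive-cell fractions (not printed in the source data; notably
`f_t = 0.5`, the D1R⁺ share of MSNs, reproduces the 6×→11× corrections)
and is regression-test material only.

## What the synthetic generator does and does not emulate

Spike trains (Poisson or regular), dopamine transients and noisy
Hill/monoexponential fixtures emulate the *inputs* of the experimental
paradigms: their statistics (exponential inter-spike intervals at
0.1 s⁻¹), amplitudes and kinetics match the published stimulus
descriptions.  They do not emulate receptor-level noise, electrophysiology
(Ca²⁺ entry is a prescribed waveform), cell-to-cell variability, or
immunoblot measurement error.  Passing tests therefore demonstrate that
the *model* responds to idealised inputs as the experiments report, not
that the experiments would be reproduced from raw data.

## Numerical choices and degenerate inputs

Rate constants outside 10⁻³–10³ (in s⁻¹ or µM⁻¹s⁻¹) warn but do not fail —
the lumped DUSP induction sits below that range by construction.  Flat
dose responses are rejected by `fit_hill()` (unidentifiable `K`, `h`);
constant time series return `k = 0` with a warning from `fit_monoexp()`;
`k₁ = k₂` transients use the analytic limit; empty spike trains are valid.
Concentrations are clamped at zero inside the rate evaluation so roundoff
negativity cannot amplify.  Mass balance of every conserved pool is
enforced structurally at assembly and numerically (relative drift < 10⁻⁶)
along trajectories.

## Known limitations

The shipped parameterisation is a reconstruction fitted by hand to the
phenotype panel; the original supplementary parameter table was not
available, so reaction-by-reaction constants differ from the original
model even where the mechanisms match.  Consequences visible in the test
suite: the tonic-dopamine Thr34 fold-change reaches ~4× rather than the
~12× target (the anchored, saturable Thr34 kinase that the mutant panel
requires caps the slice response); the D32-knockout depth and the
Gαolf-het GluR1 deficit are weaker than the published ratios, so the
mutant-panel `r²` does not reach 0.8 even though the segregation pattern
and the scheme ranking (010 first; no-crosstalk schemes leave the knockout
ERK response untouched; Fyn-level crosstalk rescues the D1R-het) are
reproduced; and the culture sensitisation assay's Hill-K ratio is
dominated by the crosstalk-side saturation rather than the input-side
amplitude scaling, so it does not single out the fast tyrosine mechanism
quantitatively.  These are documented as red acceptance checks rather than
papered over.
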