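# msnsig

Kinetic modelling of convergent dopamine and glutamate signalling in the
striatal D1-receptor medium spiny neuron (D1R+MSN).

## The problem

Acute psychostimulants flood the striatum with dopamine while cortical
glutamate keeps driving NMDA-receptor Ca²⁺ spikes in MSN spines.  Both
inputs act through one receptor/G-protein pair — D1R coupled to Golf — yet
their two read-outs segregate in mutant mice: phosphorylation of the AMPA
receptor subunit GluR1 (Ser845, via AC5/cAMP/PKA) is lost when Gαolf is
halved but not when D1R is reduced to 20%, while activation of ERK (via
NMDAR/Ca²⁺/RAS) shows exactly the opposite pattern.  This is puzzling twice
over: receptor and G-protein sit on the same linear step, and the two
cascades are coupled by the tyrosine phosphatase STEP, whose PKA-dependent
inhibition broadcasts AC5-axis activity into the NMDAR axis.

`msnsig` implements a mass-action ODE model of this system and the
machinery around it:

* the full reaction network (≈180 species) — AC5/cAMP/PKA with three
  phosphodiesterases and DARPP-32 control of PP1; the NMDAR axis with
  RAS-GRF1, the RAF/MEK/ERK cascade, inducible-DUSP feedback; the Fyn
  activation cycle and NMDAR tyrosine-phosphorylation-dependent traffic;
  STEP with one or two pools acting on Fyn, NMDAR and ERK;
* two D1R/Golf signalling compartments (AC5-linked and NMDAR-linked) whose
  anchors differ in capacity and affinity, exchanging through a
  non-signalling reservoir — the mechanism that produces the segregation;
* the eight PKA-sensitive STEP crosstalk topologies, encoded as 3-bit
  schemes mapped to edge sets (e.g. `"010"` → edges {1,5,6,7,8});
* stiff ODE simulation (compiled mass-action right-hand side, `deSolve`)
  under pulsed Ca²⁺ spike trains and double-exponential dopamine
  transients, with the three NMDAR-enhancement scaling mechanisms
  (`sSCh`, `ySCh`, `yTrf`) closing the loop from signalling state to Ca²⁺
  input amplitude;
* phenotype scoring against a 17-variable experimental panel (basal
  markers, slice treatments, Hill and monoexponential compression of
  dose-response/time-series data, mutant-over-WT ratios), the immunoblot
  heterogeneity correction, and local one-at-a-time sensitivity analysis
  of all rate constants and conserved totals.

Inputs and outputs are tabular (tibbles in, tibbles out); fitted objects
carry `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## The model in brief

Species concentrations `C` (µM) evolve by mass action over three reaction
classes — enzymatic (explicit Michaelis complex, constants `k_f`, `k_r`,
`k_cat`), reversible (`k_f`, `k_r`) and irreversible (`k`) — with 40
conserved pools.  Ca²⁺ spikes and dopamine transients are forcing
functions of the form

    C(t) = C_b + (C_max − C_b) · (e^(−k₂t) − e^(−k₁t)) / norm

with Ca_b = 60 nM, Ca_max = 500 nM, k₁ = 17.2 s⁻¹, k₂ = 15.7 s⁻¹ for a
spike and DA_b = 10 nM, DA_max = 300 nM, k₁ = 0.15 min⁻¹,
k₂ = 0.055 min⁻¹ for the psychostimulant dopamine overflow.  Each spike's
amplitude is multiplied by a scaling factor computed from the NMDAR state
(PKA-phosphorylated fraction, membrane fraction, or tyrosine-phosphorylated
membrane fraction, depending on mechanism), normalised to 1 at basal and
calibrated to a maximum of 2.5 under the psychostimulant protocol.
Dose-response data are compressed with the Hill equation
`y = C_min + (C_max−C_min)·x^h/(K^h+x^h)` and time courses with
`y = A(1 − e^(−kt))`.

## Worked example

```r
library(msnsig)

model <- standard_model(scheme = "010")          # single STEP pool, ERK edge
basal <- equilibrate(model, horizon = 3e5)$state
state_marker(basal, "cAMP")        # 0.0663  (µM; resting cAMP ~60 nM)
state_marker(basal, "D32p75")      # 12.7    (µM DARPP-32 phospho-Thr75)
state_marker(basal, "STEPact")     # 0.84    (active STEP fraction)

# tonic dopamine on a slice: the DARPP-32 Thr34 switch
da <- simulate_protocol(model, basal, protocol("DAslice"))
readout(da, "D32p34", 300) / state_marker(basal, "D32p34")   # ~4.0-fold

# acute psychostimulant paradigm with the traffic-based NMDAR enhancement
cal <- calibrate_mechanism(model, basal, "yTrf")
cal$achieved                       # 2.5  (maximum Ca2+ scaling factor)
apa <- cal$traj
readout(apa, "ERKpp", 900)         # ~0.05 µM doubly phosphorylated ERK at 15'
autoplot(apa)                      # marker time courses
```

The numbers printed above are what the model computes at its fitted
parameter set: a resting state with cAMP near 60 nM, most DARPP-32 held as
phospho-Thr75, ~84% of STEP active; tonic dopamine flips the Thr34/PP1
switch; under the psychostimulant protocol ERK activates only when the
dopamine transient and the Ca²⁺ spike train coincide (AND gate), and the
mutant genotypes (`apply_genotype`, or `run_apa_grid` across crosstalk
schemes) reproduce the segregated ERK/GluR1 sensitivity pattern.

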