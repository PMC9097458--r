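---
title: "Structure-based kinetics of PLC-gamma1: model, protocols, and spatial coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based kinetics of PLC-gamma1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plcgkin)
```

## The model

Phospholipase C-γ1 (PLC-γ1) hydrolyzes PIP~2~ into DAG and IP~3~ downstream
of receptor tyrosine kinases (RTKs). The enzyme is basally autoinhibited:
regulatory domains in its X–Y linker, chiefly the C-terminal SH2 (cSH2)
domain, occlude the catalytic core and keep it off the membrane. Activation
is a multistep process — recruitment to a receptor phosphotyrosine by the
N-terminal SH2 (nSH2) domain, phosphorylation of Tyr783, intramolecular
capture of the cSH2 domain by pTyr783 (relieving autoinhibition), and
insertion of the freed core into the membrane — and inactivation is a
random two-step walk back (receptor release and membrane release in either
order), with rebinding at each step.

`plcgkin` encodes this as a rule-based model over a four-site molecular
state:

* `nsh2`: free or receptor-bound,
* `y783`: unphosphorylated or phosphorylated,
* `csh2`: free, bound to the core, or bound to pTyr783,
* `core`: inactive (cytosolic/occluded) or active (membrane-inserted).

Two structural constraints prune the 24 raw combinations to 16 valid
states: the cSH2 domain can sit on the core only while the core is
inactive, and it can engage Tyr783 only once that residue is
phosphorylated. Twelve reaction rules, each reading only the sites it
constrains and flipping exactly one site, expand over these states into a
network of 17 species (8 free PLC states, 8 PLC·RTK complexes, free RTK)
and 53 unidirectional mass-action reactions:

```{r network}
net <- generate_network()
net
```

### Parameters and thermodynamic consistency

The base rate constants (`plcg_parameters()`) put the system in a
physically motivated regime: nSH2–phosphotyrosine exchange with K~D~ =
1 µM (`k_on_nSH2` = 1 µM⁻¹s⁻¹, `k_off_nSH2` = 1 s⁻¹); fast intramolecular
cSH2 transitions favoring autoinhibition (K~c~ = `k_bind_c`/`k_unbind_c` =
100) and, symmetrically, pTyr783 capture (K~p~ = 100); slow membrane
insertion from the cytosol (`k_act` = 0.01 s⁻¹) against `k_inact` =
0.1 s⁻¹ (K~a~ = 0.1); and Tyr783 (de)phosphorylation at 1 s⁻¹. Total
PLC-γ1 is 0.02 µM and the receptor input spans 0.005–0.05 µM.

Induced proximity at the membrane is carried by a single enhancement
factor χ = 1000 applied to exactly two rules: receptor capture of the
membrane-inserted enzyme (`k_on_nSH2_2` = χ·`k_on_nSH2`) and membrane
insertion of the receptor-anchored enzyme (`k_act_2` = χ·`k_act` =
10 s⁻¹). Because one shared factor enhances both edges, the four-state
binding/insertion cycle satisfies detailed balance by construction
(`check_detailed_balance()` verifies the cycle product is one), and the
12 rule rate constants carry 11 independent values. The
phosphorylation/dephosphorylation cycle is deliberately not balanced — it
is chemically driven by ATP turnover.

## Simulation protocols

The network integrates as a stiff mass-action ODE system (deSolve::lsoda,
relative tolerance 10⁻⁸, absolute tolerance 10⁻¹² µM, maximum step 1 s)
over a 5000 s horizon; steady state additionally requires
max|dc/dt|/PLC~tot~ < 10⁻⁸ s⁻¹, with the horizon doubled automatically for
slow variants. The default initial condition places all PLC-γ1 in the
cytosolic autoinhibited unphosphorylated state; steady-state readouts are
verified (property test) to be independent of the initial distribution.

* **Dose–response** (`dose_response()`): steady-state active fraction —
  the summed six active species over total PLC — versus receptor
  concentration. The nonphosphorylatable limit (`k_phos = 0`, standing in
  for Y783F) still activates weakly through spontaneous cSH2 release; at
  zero receptor the curve collapses onto the analytic three-state
  equilibrium K~a~/(1 + K~c~ + K~a~). The phosphomimetic limit starts
  phosphorylated with `k_dephos = 0`. Both are constitutive limiting
  cases, which is why they bracket the wildtype curves.
* **Lifetime decay** (`decay_protocol()`): run to steady state, then zero
  exactly the two rules whose reactants are cytosolic — nSH2 capture of
  the inactive enzyme (`k_on_nSH2`) and direct membrane insertion
  (`k_act`) — while freezing the χ-enhanced rebinding rules at their
  pre-switch absolute values, so the receptor-proximal rebinding narrative
  stays intact. The half-life is the time for the active fraction to fall
  to half its value at the switch. This readout is sensitive to `k_act`
  (rebinding while receptor-anchored) and conspicuously insensitive to
  `k_phos`, because pTyr783 is shielded by the cSH2 domain exactly while
  the enzyme is active.
* **Variant scans** (`standard_variants()`, `variant_scan()`): six
  hypothetical activating variants at ten-fold edits — autoinhibition
  (K~c~) weakened via `k_bind_c`×0.1, `k_unbind_c`×10, or both; membrane
  affinity (K~a~) strengthened via `k_act`×10, `k_inact`×0.1, or both —
  plus the two phospho-limits. Edits to `k_act` propagate to `k_act_2`
  through χ, preserving detailed balance. The scan dose defaults to
  0.05 µM (top of the receptor range) so every variant is well activated;
  ten-fold is also the documented fold for the lifetime scans, and both
  choices are plain function arguments.
* **Two-state reduction** (`fit_two_state()`): a time course is summarized
  by dA/dt = k~f~(1−A) − k~r~A, identified from the steady-state active
  fraction and activation half-time: k~f~ = a~ss~·ln2/t~1/2~, k~r~ =
  (1−a~ss~)·ln2/t~1/2~. The reduction is exact on literal two-state
  kinetics (recovered to ≤1% over a log-grid in the tests) and cleanly
  separates the variant classes: K~c~ edits move the apparent forward
  rate, K~a~ edits the apparent reverse rate, and ln2/k~r,app~ predicts
  the measured decay half-life within a factor of two across all variants.

Half-times are located by linear interpolation of the first crossing on
the stored output grid (1 s at the default horizon), which keeps them
stable under grid refinement.

## Spatial polarization model

`build_spatial_model()` embeds the 16-state network in a 1D
reaction–diffusion description of PLC/PKC gradient sensing: a 30 µm
domain (a typical fibroblast scale; configurable) with no-flux ends,
cell-centered finite differences, and method-of-lines integration
(deSolve::ode.1D/lsodes, relative tolerance 10⁻⁶). Cytosolic PLC states
diffuse at 19 µm²/s, receptor/membrane-bound states and membrane species
at 0.01 µm²/s. The receptor input is a linear profile r(x) =
rfrac·(1 + steepness·(x/L − ½)) with 10% steepness by default. For these
runs the nSH2 binding constants are overridden to 0.1 µM⁻¹s⁻¹ on and
0.1 s⁻¹ off (the slower receptor-exchange regime appropriate to the
spatial model; the printed off-rate value is read as such despite a
likely typo labeling both as on-rates in the source description), with
all other rule constants at base values.

Three couplings tie the network to the lipid circuit:

1. receptor availability in the binding rate laws is the local active
   receptor density minus the sum of the eight receptor-bound PLC species;
2. PIP~2~ hydrolysis is proportional to the sum of the six active PLC
   species times available PIP~2~;
3. PA multiplies both membrane-insertion constants by (1 + K~PA~·d~p~)
   with K~PA~ = 10 µm² — the PFL 1\* positive feedback. An optional second
   loop (PFL 2) adds PKC-driven PA production as a Hill term with n = 2,
   K~PLD~ = 0.1, and maximal rate 10.

### The stand-in downstream circuit, and why it is shaped this way

The downstream PIP~2~/DAG/PA/MARCKS/PKC equations here are a deliberately
simple stand-in: PIP~2~ resynthesizes toward a resting level and is
sequestered by membrane MARCKS; hydrolysis produces DAG; DAG is consumed
basally and phosphorylated by DAG kinase (`k_DAGK`) into PA; PA turns over
at 1 s⁻¹; DAG activates PKC cooperatively (Hill n = 2 — PKC recruitment by
DAG-containing membranes is a multivalent, effectively cooperative event);
active PKC releases MARCKS. Every rate is a named `circuit_params()`
entry, so a different circuit can be substituted without code changes.

The default scales were chosen so that the narrated feedback mechanisms
actually operate rather than idling:

* With the base rule constants, the receptor-anchored insertion step
  (`k_act_2` = 10 s⁻¹ against 0.1 s⁻¹ off-rates) is already saturated, so
  PA's leverage is through the *direct cytosolic* insertion path; that
  requires K~PA~·d~p~ of order 1–10 at the front of a responding cell,
  i.e. PA densities of order 0.1–1 µm⁻². The hydrolysis throughput and PA
  turnover defaults put the front there in the responsive occupancy range
  (rfrac ≈ 0.02–0.04).
* Back-of-cell PKC stays below the PLD threshold K~PLD~ = 0.1, which makes
  PFL 2 front-selective instead of igniting the whole domain.
* Basal DAG consumption (2 s⁻¹) dominates DAG removal, so `k_DAGK` mainly
  routes hydrolysis flux into PA: raising it strengthens the feedback
  without collapsing the PKC readout.

With these defaults the model reproduces the expected qualitative
directions: the 10% input gradient is amplified in the front/back active
PKC ratio; scaling `k_DAGK` by 0.3× weakens and by 3× strengthens the
maximal polarization; enabling PFL 2 raises it further while narrowing and
shifting the responsive occupancy range downward; and constitutively
activating K~c~ or K~a~ variants flatten polarization (K~a~ at least as
strongly), because a pre-activated enzyme no longer discriminates front
from back.

What the stand-in does *not* emulate: the quantitative input–output curves
of a full lipid-circuit model (absolute concentrations, oscillation
boundaries, exact peak positions). Passing spatial tests therefore
demonstrate the coupling mechanics and response directions, not numeric
field values in real cells.

### Classifier and numerical choices

A run is called steady when the envelope of active PKC at each domain end
varies by <1% (relative) over the last 10% of the run, and oscillating
otherwise, in which case min/max envelopes are reported; the window and
threshold are operational choices needed to classify sustained
oscillations. Front/back ratios change by <2% when the grid is doubled
from 24 to 48 cells, so scans use 24–30 cells and 2500 s horizons;
single-run examples use 60 cells. Negative receptor availability is
clipped at zero (it can only arise transiently at solver tolerance);
state concentrations below −10⁻⁹ µM abort a run.

## Degenerate inputs and edge cases

All-zero rate constants yield a constant trajectory; a zero receptor pool
reduces the system to the analytic three-state cytosolic chain; a
one-point grid with feedbacks off reproduces the compartmental model
exactly; `fit_two_state()` rejects a~ss~ outside (0, 1) and nonpositive
half-times; config files with unknown parameter or protocol names are
rejected rather than silently ignored.

## Problem sizes used in the tests

The bundled tests run the compartmental protocols at their production
settings (17 ODEs, 5000 s) and the spatial checks on 24–30 cell grids
with six-point occupancy sweeps — the response surfaces are smooth enough
that these settings resolve every direction tested, while keeping the
whole suite under a minute of integration time.

## Known limitations

Single phosphorylation site (Tyr783) only; PH and SH3 domain interactions
are not modeled; no stochastic simulation; clinical variants (P867R,
D1165H, R48W, R687W, R753H) are represented only by mechanism class
(K~c~/K~a~), not by fitted parameter values; the spatial geometry is 1D
with no-flux ends; and calcium/IP~3~ signaling is outside the model
boundary.
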