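---
title: "Deciding metabolite compartmentation from 13C isotopologue dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding metabolite compartmentation from 13C isotopologue dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labelflux)
```

## The question the package answers

Hepatocytes incubated with ¹³C-labeled glucose or lactate redistribute the
label through glycolysis, gluconeogenesis, the pentose phosphate pathway,
the TCA cycle and glycogen turnover. Mass spectrometry reports, per
metabolite and per fragment, the fractions of molecules carrying 0, 1, 2, …
¹³C atoms. Whether those measurements are consistent with a *single
well-mixed* hexose phosphate pool, or instead require a *channeled* pool
reserved for glycogen synthesis, is a question about network topology — and
it can be answered without any extra experiment, by fitting both topologies
to the same data and applying a goodness-of-fit test to each.

`labelflux` implements the full chain: network schemes with explicit carbon
atom-transition maps, a two-stage ODE simulation of total concentrations and
positional isotopomers, a χ² objective against measured isotopologue
tables, simulated-annealing parameter estimation, and the
incomplete-gamma/Hessian-SVD discrimination statistics.

## The model

### Pools, reactions, atom maps

A scheme is a list of pools (with carbon counts) and reactions. Every
reaction carries an atom map: which substrate carbon becomes which product
carbon, which carbons are released to CO₂, and — for reactions passing
through symmetric intermediates (fumarate/succinate) — a set of map variants
with probabilities. Carbon indexing is 1-based biochemical numbering
(glucose C1 = the aldehyde carbon); isotopomers of an *n*-carbon pool are
indexed 0…2ⁿ−1 with bit *i*−1 encoding carbon *i*.

Fast-equilibrating metabolites are lumped: glucose-6-P with fructose-6-P as
`hexP`, the pentose phosphates as `p5p`, 2-oxoglutarate with glutamate as
`glu`. Dihydroxyacetone phosphate and glyceraldehyde-3-P stay distinct,
connected by a triose-isomerase pair (`aldex_f`/`aldex_r`) whose map
reverses the carbon order. The shipped atom maps cover hexokinase /
glucose-6-phosphatase / phosphofructokinase / fructose-bisphosphatase and
glycogen turnover (identity), aldolase (fbp C1–C3 → dhap, C4–C6 → g3p),
lower glycolysis and lactate exchange (identity on the trioses, so
[1,2-¹³C₂]glucose yields [2,3-¹³C₂]lactate), pyruvate dehydrogenase
(C1 → CO₂), pyruvate carboxylase (CO₂ → oxaloacetate C4), PEP carboxykinase,
citrate synthase lumped with aconitase/isocitrate dehydrogenase to
2-oxoglutarate, the 2-oxoglutarate → malate stretch with a 0.5/0.5
orientation scramble, malate ↔ oxaloacetate with the same scramble, the
oxidative pentose phosphate branch (hexP C1 → CO₂), and the full
transketolase/transaldolase set with both net reactions and half-reaction
isotope-exchange fluxes (`p5p_g3p`, `f6p_g3p`, `s7p_e4p`, `f6p_s7p`,
`p5p_s7p`, `s7p_f6p`).

`validate_atom_maps()` enforces, for every reaction and variant, that each
substrate carbon has exactly one fate, each product carbon exactly one
source, carbon counts balance, and exchange-only reactions leave all totals
unchanged. The two topologies differ only in the channel: `build_scheme("B")`
adds `hexP_chan` with its own `hk2`, `g6pase2`, `pfk2`, `fbpase2` and reroutes
glycogen synthase and phosphorylase to it. (The named set of channel
reactions includes `pfk2` so the channel pool can balance; the published
flux table for the channeled model lists all four.)

### CO₂

Released carbons leave to an untracked sink by default, and carboxylation
introduces unlabeled carbon: the bicarbonate buffer dominates any
respiratory CO₂, so treating the pool as unlabeled is the physiologically
sensible default. A `track_co2 = TRUE` flag switches to an explicitly
tracked 1-carbon pool (label inflow only; the buffer concentration itself is
held constant), preserving both readings of how the original analysis
handled bicarbonate.

### Glycogen

Glycogen is an accumulating pool in glucosyl-unit mM: synthase deposits
units carrying the instantaneous composition of its hexose phosphate
source, phosphorylase removes units proportional to the current
composition. Because removal is proportional to composition, this
bookkeeping is exactly a well-mixed pool ODE with a near-zero unlabeled
initial amount (starved cells), and the endpoint composition is the
time-integrated record of what synthase saw — no 2⁶-state polymer model is
needed. Reported glycogen concentration converts at 162 mg per mmol
glucosyl units.

### Kinetic layer

Because the contribution under test is the topology and the label routing —
not any particular rate algebra — each reaction gets a deliberately simple,
configurable rate law: irreversible mass action by default (one constant),
Michaelis–Menten optionally. The aldolase trio is the exception: its three
fluxes are derived jointly from one six-constant elementary-step cycle
(see below). Units are minutes and mM per volume of cell suspension; medium
and intracellular pools share that volume base, so no medium/cell scaling
factor enters the equations. This is a convention, not a measurement — the
published work does not state its normalization — and it only rescales rate
constants, not the isotopologue fractions the fit actually uses.

### Aldolase exchange fluxes

With elementary rates v₁ (fbp binding, ∝ [fbp]), v₂ (cleavage), v₃ (dhap
release), v₋₁, v₋₂ (g3p binding, ∝ [g3p]), v₋₃ (dhap binding, ∝ [dhap]),
the steady-state fraction of enzyme-bound dhap originating from fbp is
P = v₁v₂/D with D = v₂v₁ + v₋₃v₁ + v₋₃v₋₂, giving

* forward whole-cycle flux v_f = v₁v₂v₃/D (reaction `aldf`),
* reverse whole-cycle flux v_r = v₋₁v₋₂v₋₃/D (`aldr`),
* half-molecule exchanges v_fg = v₁v₂/(v₁+v₋₂) and v_gf = v₋₃v₋₂/(v₋₂+v₂)
  (`aldhex`), which swap fbp's lower half with the free g3p pool without
  releasing dhap.

v_f − v_r is identically the net chemical flux, so the label layer and the
kinetic layer cannot disagree about aldolase. The reverse half-exchange
formula mirrors the forward one under the forward↔reverse relabeling of the
cycle; the construction is validated against a single-molecule Monte-Carlo
oracle that resolves molecule origins by stochastic recursion on the input
branches. The same donor-half treatment realizes the
transketolase/transaldolase exchange fluxes, with the donor ketose playing
fbp's role.

## Simulation

Stage one integrates the ~18 totals ODEs with an implicit BDF scheme
(`deSolve`, rtol 1e-8, atol 1e-10). Stage two integrates the isotopomer
system (~600 states). Product isotopomer distributions are OR-convolutions
of independent parts — exact because every product carbon has exactly one
source — executed by a compiled kernel over a flattened program; the default
solver is `lsodes`, BDF with an internally detected sparse Jacobian, which
suits the block-sparse coupling between pools.

By default the label stage re-evaluates the rate laws at its own current
pool totals rather than interpolating stage-one fluxes; per-pool isotopomer
sums then satisfy the totals ODE *exactly*, and agreement with the
separately integrated totals trajectory (better than 1e-6 relative; ~1e-8 at
test tolerances) is a genuine cross-check of both stages rather than an
artifact of construction. An `interpolate` mode (linear in time on the
output grid) exists for driving the label system with externally supplied
flux series.

Reporting runs use a 1-min grid at rtol 1e-7; fitting runs use a 10-min
output grid at rtol 1e-6 (the solvers' internal steps adapt independently of
the output grid). These sizes keep a full two-stage simulation near 0.4 s,
so annealing budgets of tens of moves complete in minutes on one CPU.

## Default parameters and what the generator emulates

`default_params()` encodes rate constants via documented target fluxes at
the canonical initial concentrations (k = flux / ∏ conc₀). Glycolytic,
glycogen and pentose phosphate magnitudes follow the published best-fit
values for hepatocytes on glucose alone (hk1 ≈ 2.7e-3, gs ≈ 2.2e-3 mM/min,
aldolase v_f ≈ 1.9e-2, the large f6p↔g3p exchange 7.5e-3); the channel split
(hk2 ≈ 2.1e-3 vs fbpase2 ≈ 5.5e-4) matches the same source. TCA-cycle
fluxes are set to ~2–5e-4 mM/min — between the two published incubation
conditions — because at the glucose-only condition's vanishing TCA
estimates glutamate would stay unlabeled and its measured rows would carry
no information; this is a one-time generator design choice, stated here
rather than tuned. The non-oxidative pentose set keeps the classical 3:2:1
stoichiometry, and outflow constants are balanced so every intracellular
pool starts near metabolic (not isotopic) steady state — the experiment is
a labeling transient, not a concentration transient. Initial pool sizes are
plausible hepatocyte values expressed per suspension volume; glycogen
starts near zero (24-h starved animals).

The synthetic generator reproduces the *structure* of the study's data:
2-h incubations; 50% [1,2-¹³C₂]glucose (20 mM) or 50% [U-¹³C₃]lactate
(9 mM + 1 mM pyruvate); the exact metabolite/fragment/quantity panel of the
printed tables (29 rows for the glucose-only design); independent Gaussian
noise with standard deviations in the printed magnitude range (fractions:
5% of the mean, floored at 0.005, capped at 0.05; concentrations: 10%);
clipping to [0, 1] with renormalization per fragment. It does not emulate
correlated channel errors, derivatization artifacts, or natural-abundance
residuals (packaged data are natural-abundance corrected; the measurement
module provides the binomial convolution and its inverse for raw data).
Passing recovery tests therefore demonstrates that the inference machinery
is sound under the stated noise model — not that real GC/MS data satisfy
that model.

## Fitting and discrimination

The annealer proposes multiplicative log-normal steps on one randomly
chosen free parameter at a time (fluxes span six orders of magnitude, so
moves must be scale-free), accepts by the Metropolis rule under geometric
cooling T_k = T₀·0.95ᵏ, and finishes with a coordinate-descent polish whose
step factor halves on sweeps without improvement. The published work states
no schedule or budget; ours is documented in `anneal()`'s defaults and every
result records its seed.

Effective parameters: the residual Jacobian is computed by central finite
differences (relative step 1e-4), the Gauss–Newton matrix
α = 2 Jᵀ diag(σ⁻²) J is decomposed by SVD, and greedy forward selection
(ranked by diagonal sensitivity, ties broken lexicographically) grows the
largest subset whose reciprocal condition number stays above 1e-10 — far
from machine epsilon, so the count is stable across platforms. The curvature
matrix at a χ² minimum must be positive-semidefinite, so the Gauss–Newton
form carries a positive sign. F = N − P_eff, and Q(F/2, χ²/2) — computed by
the classical series/continued-fraction split and cross-checked against the
χ² survival function to 1e-10 — yields accept (> 0.05), marginal, or reject
(≤ 0.001).

Confidence intervals follow the χ²-threshold convention: all parameter sets
visited by an ensemble of annealing runs whose χ² lies within
qchisq(level, 1) of the minimum (6.63 at 99%) define the envelope of each
time-averaged flux. Reported fluxes are time averages over the incubation —
the reporting convention for a non-steady-state model must be chosen, and
the flux integral over [0, T]/T is the one used throughout.

## Numerical choices and degenerate inputs

* Empty pools: fractional abundances fall back to a delta at the unlabeled
  isotopomer when a pool's total drops below 1e-12 mM, preserving mass.
* Negative concentrations proposed by the stiff solver are clamped to zero
  inside the rate laws; clamps are counted and surfaced as a warning.
* Simulation failures inside the objective yield +∞, which the annealer
  treats as a rejected move.
* All scramble variants are deterministic weighted maps, so repeated runs
  are bit-identical and results are invariant to pool ordering.
* The natural-abundance correction inverts the binomial skeleton-carbon
  convolution M[j,k] = C(n−k, j−k)p^{j−k}(1−p)^{n−j} (p = 0.0107 by
  default), clipping inversion artifacts below 1e-9 and renormalizing.

## Reduced-scale studies

The packaged tests and `scripts/acceptance.R` run desk-scale versions of
the study's logic: topology recovery uses 3–5 seeds with a 50–60-move
annealing budget on the 29-row glucose-only design (each trial fits both
topologies and applies the discrimination test), and envelope coverage is
measured on a closed-form wash-in surrogate (30 replicates, 4-run
ensembles) plus a spot check on the full scheme. These problem sizes are
the package's chosen defaults for reproducible single-CPU runs; the
machinery accepts larger budgets unchanged.

## Known limitations

* The rate-law layer is intentionally generic; fitted rate constants are
  effective parameters and only the flux space they span is comparable
  across studies.
* The medium/cell volume normalization is a convention (per suspension
  volume); absolute glycogen mass per mL therefore differs from pellet-based
  reporting by a fixed factor.
* Natural abundance is corrected, not simulated; raw (uncorrected) spectra
  must be passed through `correct_natural_abundance()` first.
* The tracked-CO₂ option follows label inflow only; it does not model
  bicarbonate exchange kinetics.
* No EMU-style state reduction: full isotopomer vectors are tractable here
  (largest pool 2⁷ states) but the engine is not meant for pools beyond
  ~10 carbons.

## Session

```{r}
sessionInfo()
```
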