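# labelflux

Non-stationary ¹³C isotopologue dynamics and metabolite-compartmentation
analysis for central carbon metabolism.

## The problem

Stable-isotope tracing experiments incubate cells with a ¹³C-labeled
substrate — for example 50% [1,2-¹³C₂]glucose, or 50% [U-¹³C₃]lactate — and
measure, by GC/MS, the mass-isotopologue distributions (m0, m1, m2, …) of
downstream metabolites: medium glucose and lactate, glutamate fragments
(C2–C4, C2–C5), and glucose units hydrolyzed from glycogen together with
their C1–C4 and C3–C6 fragments. Metabolic fluxes are inferred by fitting a
kinetic model of the network to these distributions. But the measurements
average over subcellular compartments: if an intermediate such as
glucose-6-phosphate is channeled — handed preferentially to the next enzyme
of one pathway rather than mixing freely in the cytosol — a model with a
single well-mixed pool can be inconsistent with the data even when every
reaction is included. `labelflux` simulates the full non-steady-state
positional-isotopomer dynamics of a hepatocyte central-metabolism network
under two topologies:

* **Scheme A** — one well-mixed hexose phosphate pool shared by glycolysis,
  gluconeogenesis and glycogen turnover;
* **Scheme B** — an additional channeled hexose phosphate pool with its own
  hexokinase, glucose-6-phosphatase, phosphofructokinase and
  fructose-bisphosphatase, feeding glycogen synthesis exclusively;

fits each to measured isotopologue tables, and decides between them with a
formal model-discrimination test.

## The machinery

* **Two-stage simulation.** Total concentrations obey mass-action /
  Michaelis–Menten ODEs integrated with an implicit stiff (BDF) scheme; the
  positional-isotopomer system (up to 2⁷ = 128 states per pool, ~600 states
  overall) is then integrated on top, with product isotopomer distributions
  assembled exactly from the carbon atom-transition maps of every reaction —
  including aldolase cleavage/condensation, transketolase/transaldolase
  half-reactions, the symmetric succinate/fumarate scramble, and the
  oxidative pentose phosphate shunt.
* **Aldolase isotope-exchange calculus.** The three-step catalytic cycle
  E → E-fbp → E-dhap → E with elementary rates v₁, v₂, v₃, v₋₁, v₋₂, v₋₃ is
  resolved into a forward whole-cycle flux v_f = v₁v₂v₃/D, a reverse flux
  v_r = v₋₁v₋₂v₋₃/D (D = v₂v₁ + v₋₃v₁ + v₋₃v₋₂), and half-molecule exchange
  fluxes v_fg = v₁v₂/(v₁+v₋₂), v_gf = v₋₃v₋₂/(v₋₂+v₂) that swap the lower
  half of fructose-1,6-bisphosphate with the triose pool without net
  chemistry. A single-molecule Monte-Carlo oracle validates the algebra.
* **χ² fitting.** χ² = Σᵢ[(yᵢ − y(xᵢ; a))/σᵢ]², minimized by simulated
  annealing (multiplicative log-normal proposals, geometric cooling) with a
  coordinate-descent polish; several experiments can be fitted jointly with
  one shared parameter set.
* **Model discrimination.** The effective (identifiable) parameter count
  P_eff is the size of the maximal parameter subset whose Gauss–Newton
  Hessian α_kl = 2Σᵢ σᵢ⁻²(∂yᵢ/∂a_k)(∂yᵢ/∂a_l) stays numerically non-singular
  under SVD; F = N − P_eff degrees of freedom and the regularized upper
  incomplete gamma Q(F/2, χ²/2) give the verdict: accept (Q > 0.05),
  marginal (0.001 < Q ≤ 0.05), reject (Q ≤ 0.001).
* **Confidence intervals.** Envelopes of each flux over all ensemble points
  within qchisq(0.99, 1) = 6.63 of the χ² minimum.
* **Synthetic studies.** A generator reproduces the study design (tracer
  enrichments, 2-h incubations, fragment panels, Gaussian noise with
  Table-like standard deviations) from known ground truth, enabling
  topology- and parameter-recovery experiments without any external data.

## Worked example

```r
library(labelflux)

# the channeled topology with its documented default rate constants
sch <- build_scheme("B")
p   <- default_params(sch)

# 2 h with 20 mM glucose, 50% [1,2-13C2]
sim <- simulate_labeling(sch, p, experiment_glucose_only())
obs <- observables(sim)
dplyr::filter(obs, metabolite == "lactate")
#>   experiment   metabolite fragment quantity   value units
#> 1 glucose_only lactate    C1-C3    m0       0.763   fraction
#> 2 glucose_only lactate    C1-C3    m1       0.0319  fraction
#> 3 glucose_only lactate    C1-C3    m2       0.197   fraction
#> 4 glucose_only lactate    C1-C3    m3       0.00870 fraction
#> 5 glucose_only lactate    C1-C3    conc     0.480   mM
```

Lactate label appears almost entirely as m2: [1,2-¹³C₂]glucose carbons C1–C2
travel through the aldolase/triose-isomerase split into [2,3-¹³C₂]lactate —
the canonical glycolytic signature.

The discrimination arithmetic of the printed study tables:

```r
# one-pool model on 22 whole-molecule points with 16 effective parameters
discrimination_report(22, 16, 38.28, model = "well-mixed")
#> Model discrimination report [well-mixed]
#>   N = 22 data points, P_eff = 16 effective parameters, F = 6
#>   chi2 = 38.28, Q = 9.9e-07  ->  reject

# channeled model, same data, 18 effective parameters
discrimination_report(22, 18, 3.13, model = "channeled")
#>   N = 22 data points, P_eff = 18 effective parameters, F = 4
#>   chi2 = 3.13, Q = 0.536  ->  accept
```

A full synthetic topology-recovery trial (generate from B, fit both):

```r
tr <- topology_recovery_trial("B", c("A", "B"), seed = 1,
                              schedule = list(steps = 50, polish_sweeps = 1))
tr$reports
#>   model  n p_eff  f  chi2        q verdict
#> 1 A     29     6 23  86.0  3.3e-09 reject
#> 2 B     29     7 22  15.1  0.86    accept
```

## Command line

A thin wrapper ships in `inst/cli/` (after installation:
`system.file("cli", "labelflux", package = "labelflux")`; link it onto your
PATH to use it as below):

```sh
labelflux simulate --scheme B --experiment glucose_only --out runs/sim1
labelflux synth --scheme B --seed 7 --out runs/synth7
labelflux fit --scheme B --measurements runs/synth7/synthetic_measurements.csv
labelflux discriminate --measurements runs/synth7/synthetic_measurements.csv
```
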