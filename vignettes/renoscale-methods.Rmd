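---
title: "Methods: single-species extrapolation and PBPK simulation of tofacitinib in renal failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-species extrapolation and PBPK simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renoscale)
```

## The problem

Tofacitinib is cleared about 70% by hepatic metabolism (CYP3A4/2C19) and
about 30% renally, so renal failure raises its exposure both directly
(reduced renal excretion) and indirectly (renal disease also depresses
hepatic enzyme activity). `renoscale` predicts human plasma
concentration–time profiles and PK parameters for healthy subjects and
patients with moderate or severe renal failure using nothing but rat data:
a Dedrick-plot projection of rat profiles, and a whole-body PBPK model
whose hepatic and renal clearances are extrapolated from a single species.
Rats with gentamicin-induced (moderate) and cisplatin-induced (severe)
kidney injury serve as the disease models.

## Non-compartmental analysis

`run_nca()` computes AUC to the last sample by the linear trapezoid
(default) or linear-up/log-down rule, extrapolates to infinity with
$C_\mathrm{last}/\lambda_z$, and derives $\lambda_z$ as the negative
least-squares slope of $\ln C$ vs $t$ over the last three samples after the
peak. Conventions, chosen once and documented here because different NCA
software differs:

* **Tmax ties** break to the earliest time.
* **λz window**: last 3 points, excluding Cmax; a fitted slope below
  1e-12 h⁻¹ is reported "not estimable" (`NA`) rather than a spurious
  positive half-life.
* **IV C0**: when an IV-bolus profile starts after time zero, C0 is
  back-extrapolated log-linearly from the first two samples and the initial
  segment enters the AUC. On the sparse 8-point rat grid this matters: the
  plain linear trapezoid without C0 handling biases the IV AUC by several
  percent (chords lie above an exponential decay), while log-down plus C0
  recovers a mono-exponential's generating clearance essentially exactly —
  the property the test suite asserts at 2%.
* **Units**: internally ng/mL, hours, mg, kg; constructors convert minutes
  at the boundary.

## Dedrick projection

The simple species-invariant transform divides concentration by dose per
body weight and time by $BW^{0.25}$:
$C^* = C/(\mathrm{Dose}/BW)$, $t^* = t/BW^{0.25}$ (time in minutes). Rat
profiles are transformed, and the invariant curve is re-dimensionalised at
the human dose (10 mg) and body weight. The human body weight for
projection defaults to the healthy-stage representative subject (76 kg, the
midpoint of the demographic weight range), since the projection target
weight is otherwise unspecified. The exponent is fixed at 0.25; complex
Dedrick variants needing three or more species are out of scope by design.
Under this transform the projected AUC obeys the closed-form identity
$\mathrm{AUC}_h = \mathrm{AUC}_r \cdot
\frac{\mathrm{Dose}_h/BW_h}{\mathrm{Dose}_r/BW_r}\cdot(BW_h/BW_r)^{0.25}$,
which the tests use as an independent oracle for the profile-level
pipeline.

## Single-species clearance scaling

Total human clearance uses the fixed empirical coefficient
$CL_h = 0.152\,CL_r$ (mL/min/kg); the coefficient is exposed as
`single_species_coefficient` for other compounds. Renal clearance is
corrected for protein binding and renal blood flow,
$CL_{R,h} = CL_{R,r}\,(f_{u,h}/f_{u,r})(RBF_h/RBF_r)$, with
$f_u$ 0.61 (human) and 0.793 (rat) and stage-specific RBF of
(18.0, 5.24, 3.83) mL/min/kg in humans and (33.3, 28.0, 18.0) in rats for
(normal, moderate, severe). Hepatic clearance is the remainder, the drug
being treated as metabolised exclusively in the liver.

One discrepancy is carried openly: the published severe-stage human renal
clearance (0.0164 mL/min/kg) does not follow from the correction equation
with the published inputs, which give ≈0.0111. `human_clearance_table()`
reports both; the equation value feeds the PBPK model. The difference is
immaterial downstream (renal clearance is ~0.5% of total clearance at that
stage).

## Virtual physiology

Constants ship as a versioned JSON file (`inst/extdata/physiology.json`).
Subjects are built from a reference-adult table of organ volume fractions
(of body weight) and blood-flow fractions (of cardiac output) — standard
reference-man values embedded in `reference_organs()` — with cardiac output
scaled allometrically, $336\,(BW/73)^{0.75}$ L/h. Kidney perfusion is
overridden by the stage RBF, and the lung (cardiac output) is recomputed as
the sum of systemic flows, so flow conservation holds by construction; the
rest-of-body compartment closes the volume balance.

Population sampling is uniform over the published demographic ranges per
stage (only ranges are given, no distributions), with height and weight
jointly rejection-sampled until the implied BMI also lies in its printed
range; sex is 50/50 in expectation. eGFR is uniform in the stage window;
the healthy window is not stated alongside the disease stages, so 90–120
mL/min/1.73 m² (the conventional normal range) is used. eGFR and absolute
GFR interconvert via DuBois body surface area. Deterministic
"representative" subjects sit at the midpoint of every range (76, 90.5 and
91.5 kg for normal, moderate, severe).

## Synthetic rat profiles

The generator reproduces the published rat group means: body weight
(280/251/188 g), AUC (264/433/693 µg·min/mL), CL (39.0/24.3/14.7) and
CL_R (4.75/1.45/0.0679 mL/min/kg) after 10 mg/kg IV. Each animal draws a
lognormal body weight and clearance (CVs default to the published SD/mean
ratios), and its noise-free curve is a one-compartment IV bolus with rat
$V_{ss}$ = 1.7 L/kg, so the true AUC equals Dose/CL by construction —
AUC-anchored results are independent of the shape assumption.
Multiplicative lognormal residual error is applied per sample. The default
grid (2, 5, 15, 30, 60, 120, 240, 480 min) covers more than five terminal
half-lives at every stage.

What the generator deliberately does **not** emulate: multi-compartment
distribution kinetics, absorption-phase shapes (the anchored study is IV),
below-quantification censoring, and correlated residuals. Tests passing on
these profiles therefore demonstrate correctness of the analysis chain
under the stated disposition model, not robustness to real-data artefacts.
The IV 10 mg/kg anchor is taken from the tabulated record (the narrative
elsewhere mentions 20 mg/kg oral); route and dose are exposed in
`rat_study_design()` so the alternative reading can be regenerated.

## Whole-body PBPK model

Fourteen compartments, all perfusion-limited: lungs, liver (hepatic artery
plus portal inflow from gut and spleen), kidney, gut, muscle, adipose,
skin, brain, heart, bone, spleen, rest-of-body, and arterial/venous plasma
pools. Oral drug enters the gut lumen, is absorbed first-order (rate
$k_a$, fraction $f_a f_g$) into gut tissue and traverses the liver before
the systemic circulation, so first pass is mechanistic.

**Partitioning.** Tissue:plasma coefficients use the Rodgers–Rowland
scheme for a weak monoprotic base with pKa < 7 (tofacitinib: pKa 5.07,
logP 1.15, $f_u$ 0.61): extracellular water, pH-partitioned intracellular
water (pH 7.0 vs plasma 7.4), neutral-lipid/phospholipid solubilisation of
the neutral species, and residual extracellular protein binding scaled by
tissue:plasma albumin ratios, with $K_p = f_u \cdot K_{pu}$. The residual
binding term is clamped at zero for hypothetical unbound drugs
($f_u = 1$), where the plasma lipid correction would otherwise drive it
slightly negative. The composition and albumin-ratio tables are standard
published values embedded in `tissue_composition()`. The blood:plasma
ratio defaults to 1.0 — the footnoted source table names B/P but prints no
value, and all clearances here are plasma-referenced.

**Elimination.** The scaled per-kg clearances are converted to absolute
L/h and applied to the emergent organ outflow concentration with a
well-stirred back-correction $CL' = CL\,Q/(Q - CL)$ for liver and kidney.
This makes the model's systemic plasma clearance equal $CL_H + CL_R$
exactly, so the closed-form identity AUC = Dose/CL holds to solver
tolerance (asserted at 0.5%), and the hepatic extraction seen by portal
inflow is exactly $CL_H/Q_\mathrm{liver}$.

**Absorption and bioavailability.** The printed permeabilities (Caco-2
22.1e-6 cm/s; MDCK 6.3e-6 cm/min, retained for provenance) imply an
implausibly slow uptake relative to the observed Tmax of ~0.75 h, so
absorption is a first-order $k_a$ calibrated once against that observed
Tmax: $k_a$ = 1.2 h⁻¹ puts the healthy representative subject's simulated
Tmax at 0.70 h, inside the observed 0.5–1.5 h range; it is then frozen for
all stages. $f_a f_g$ is derived in code, not hand-set: from the
literature absolute oral bioavailability of 74% in healthy volunteers,
$f_a f_g = F/(1 - CL_H/Q_\mathrm{liver})$ evaluated for the healthy
representative subject (≈0.93), then held constant across stages so renal
failure alters exposure only through clearances and physiology.

**Numerics.** `deSolve::lsoda` with rtol 1e-8, atol 1e-10 by default; a
10-fold tolerance change moves the AUC by far less than 0.1% (tested).
Mass balance — body + eliminated + unabsorbed + gut-unavailable = dose —
is exposed via `mass_balance_error()` and asserted to solver tolerance.
One numerical caveat the tests encode: after an IV bolus the venous pool
mixes with a ~90 h⁻¹ rate constant, so IV output grids must be dense over
the first ~0.2 h or the trapezoidal AUC inflates by several percent; oral
profiles have no such spike and a 0.05-h grid suffices.

**Population simulation.** Lognormal inter-individual variability on
$CL_H$, $CL_R$ and $k_a$ (default CV 0.3 each — the variability settings of
the commercial simulators are unpublished, so these are this package's own
defaults and population spread is not a validation target), on top of the
sampled physiology; arithmetic mean ± SD profiles are reported, matching
how simulated populations are usually summarised.

## Validation statistics

`r_ratio()` is simulated/observed; `within_fold()` applies the 0.5–2.0
band with **inclusive** boundaries (the convention "between 0.5 and 2.0"
leaves inclusivity unstated; inclusive is chosen and documented).
`f1_difference()` is $100\sum_i |R_i - T_i| / \sum_i R_i$ over time-aligned
curves; when grids differ the predicted curve is linearly interpolated in
time to the observed points. The packaged observed fixture
(`observed_human_pk()`) carries parameter-level clinical values only
(AUC, Cmax, median Tmax per stage, 10 mg oral). Observed clinical
concentration–time curves were digitized from a figure in the original
clinical report and are not redistributable here, so curve-level f1
against clinical data is a user-supplied-CSV feature and published f1
values are not test targets. Student's t-tests between cohort means are
deliberately omitted; the report carries means ± SD and fold-flags.

## Problem sizes

The test suite and acceptance script run: 6–8 animals per rat group on an
8-point grid; populations of 3–6 virtual subjects; single-subject PBPK
integrations over 0–48 h (oral, 0.05–0.1 h output steps) and 0–96 h (IV,
dense early grid). These match the anchored study design (six subjects per
simulated trial) and keep the whole suite in seconds on one CPU.

## Known limitations

* Perfusion-limited tissues only; no permeability-limited kidney model and
  no filtration/secretion/reabsorption split — renal elimination is a
  lumped plasma clearance.
* Metabolism is a lumped hepatic clearance; no enzyme-level CYP kinetics,
  no gut-wall metabolism beyond the constant $f_a f_g$, no transporters,
  food effects or drug–drug interactions.
* The Dedrick pathway's moderate/severe projections are sensitive to which
  rat dataset (IV vs oral) is taken as the source; only the healthy-stage
  projection is treated as quantitatively anchored.
* Immediate-release dissolution is assumed; formulation effects are not
  modelled.
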