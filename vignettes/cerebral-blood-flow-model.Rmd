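---
title: "A hematocrit-aware hierarchical model of neonatal cerebral blood flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hematocrit-aware hierarchical model of neonatal cerebral blood flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerebroflow)
```

## The model

Cerebral blood flow (CBF) in the preterm brain is represented by an
electrical-analogue circuit: the cerebral vasculature is divided into 19
levels connected in series, each level consisting of $m_j$ identical
vessels in parallel, so that

$$CBF = \frac{MAP - P_{ic}}{RES}, \qquad
  RES = \sum_{j=1}^{19} RES_j^{level}, \qquad
  RES_j^{level} = \frac{RES_j}{m_j},$$

with $MAP$ the mean arterial pressure, $P_{ic}$ the intracranial pressure
(fixed at 5 mmHg, since it cannot be measured in preterm infants), and
$RES_j$ the hydraulic resistance of a single vessel on level $j$. Flow in
an individual vessel is $CBF_j = CBF/m_j$. The flow is normalized per
100 g of brain tissue; brain weight is estimated from gestational age (or
birth weight) and scales the vessel counts linearly (exponents are
configurable; lengths and diameters are held fixed by default).

Level 10, the capillary bed, is split into two parallel compartments: the
germinal matrix (GM) — the transient, densely vascularized periventricular
region whose fragile capillaries are the typical origin of
intraventricular hemorrhage (IVH) — and the rest of the brain (non-GM).
The GM capillary count declines linearly from its full size at 25 weeks of
gestation to zero at 32 weeks, the clinically accepted involution window.

### Viscosity in arteries, arterioles and veins

The resistance of a non-capillary vessel is Poiseuille's law with the
*in-vivo apparent viscosity*, a phenomenological function of tube diameter
$d$ (µm) and discharge hematocrit $H_D$:

$$\mu_a = \mu_{PL}\!\left[1 + (\mu_{0.45} - 1)\,
   \frac{(1-H_D)^C - 1}{(1-0.45)^C - 1}\, W\right] W, \qquad
   W = \left(\frac{d}{d-1.1}\right)^{2},$$

$$\mu_{0.45}(d) = 6e^{-0.085 d} + 3.2 - 2.44 e^{-0.06 d^{0.645}},$$

$$C(d) = (0.8 + e^{-0.075 d})\left(-1 + \frac{1}{1+10^{-11}d^{12}}\right)
   + \frac{1}{1+10^{-11}d^{12}},$$

with plasma viscosity $\mu_{PL} = 0.001$ Pa·s. The discharge hematocrit is
equated with the clinically measured systemic hematocrit $H_{SYS}$. Two
numerical points deserve note:

* **Wall offset.** The wall factor uses an offset of 1.1 µm. The law is
  singular at $d = 1.1$ µm and the implementation rejects any diameter at
  or below the offset; in practice the smallest non-capillary level is
  ~13 µm. The offset is configurable and overrides are recorded in the
  constants object.
* **Overflow.** $d^{12}$ overflows double precision for very large $d$;
  the $1/(1+10^{-11}d^{12})$ terms are evaluated in log space with a
  guarded branch, so the exponent is exact (`-0.8`) at any diameter.

At $H_D = 0.45$ the hematocrit correction factor is identically 1
independent of $C$ — a property the test suite checks by perturbing the
$C$ coefficients. The law's diameter profile is the classic
Fåhraeus–Lindqvist shape: a steep rise below ~30 µm, a minimum near
40–50 µm, and a slow approach to the wide-tube plateau of 3.2 relative
units. (The minimum's location matters below for calibration.)

### Capillaries: two-phase single-file flow

In capillaries (< 10 µm) red cells travel in single file along the
centerline, surrounded by a plasma sleeve. A single capillary of radius
$r$ and length $l$ has resistance

$$RES = \rho + (\hat\rho - \rho) H_T,$$

interpolating with the *tube hematocrit* $H_T$ between the all-plasma
Poiseuille resistance $\rho = 8 l \mu_{PL}(H_T)/(\pi r^4)$ and the
continuous-core resistance

$$\hat\rho = \frac{8l}{\pi}\left[\frac{r^4 - r_0^4}{\mu_{PL}(H_T)} +
  \frac{r_0^4}{\mu_{RBC}}\right]^{-1},
  \qquad r_0 = 0.3\,\mu m + 0.8\,r,$$

with $\mu_{RBC} = 0.1$ Pa·s and the hematocrit-dependent plasma law
$\mu_{PL}(H_T) = 0.001\,(16 + 5H_T)/15$ Pa·s. The plasma law enters
*both* endpoints: with a constant plasma viscosity the resistance would be
exactly linear in $H_T$, while the reference values it is calibrated to
are visibly convex; the $H_T$-dependent law reproduces that curvature.
The tube hematocrit itself comes from the Fåhraeus relation

$$H_T/H_D = H_D + (1-H_D)\left(1 + 1.7e^{-0.35 d} - 0.6e^{-0.01 d}\right),$$

evaluated at each compartment's own diameter (a configuration switch,
`gm$shared_tube_hematocrit`, restores a shared value). The geometry
requires $r \ge 1.5$ µm so the cell core stays strictly inside the lumen.

## Calibration of the shipped morphometry

The model's source morphometry is not publicly available, so the shipped
configuration (`inst/extdata/morphometry_default.json`) is *calibrated*,
not transcribed, by `scripts/calibrate_morphometry.R` against the
25-week-gestation reference quantities:

* non-GM capillaries are fixed at d = 5.6 µm, l = 600 µm — the unique
  diameter reproducing the reference tube-hematocrit triple (10.8 / 36.9 /
  52.1 % at $H_{SYS}$ = 15 / 45 / 60 %) — and GM geometry (d = 6.58 µm,
  l = 369 µm) is a least-squares fit to the GM capillary resistance
  triple; capillary counts ($m_{GM} = 6.3\times10^5$,
  $m_{nGM} = 2.06\times10^7$) anchor the per-level capillary resistances;
* the precapillary level's diameter (13.3 µm) and length are fitted to the
  reference single-vessel resistance triple;
* the remaining 17 levels receive per-level resistance shares by a
  floor-constrained quadratic program that matches the total resistance at
  15% and 45% hematocrit **exactly** (74.6 and 142 ×10⁸ Pa·s/m³) while
  staying close to a physiologically shaped profile.

Two calibration trade-offs are worth stating openly. First, the three
total-resistance targets cannot all be met exactly: the hematocrit
sensitivity of the total is a conductance-weighted mixture of the level
sensitivities, and the attainable mixture range caps the 60% total at
~208.6×10⁸ (0.2% below its 209×10⁸ target) once the other two are exact.
Exactness was given to the 15/45% pair because their ratio carries the
model's headline result, the 1.90-fold CBF increase on hemodilution.
Second, the per-level split between the precapillary and capillary layers
cannot simultaneously honor the reference per-level values and the totals
under this assembly; the calibration keeps the *single-vessel*
precapillary resistances and all capillary-level quantities at their
reference values, lets the precapillary count float, and the precapillary
layer remains the largest per-level resistance, as expected
physiologically. The feasibility of the totals hinges on the viscosity
law's sensitivity minimum near d ≈ 40–50 µm — levels in that range are
what allow the tree's aggregate hematocrit response to be as shallow as
the reference values demand.

The brain-weight model (the published source formula is likewise
unavailable) is a gestational-age table anchored at 130 g (25 wk) with a
30/25-week ratio of 2.18, back-solved so the 30-week total resistance at
45% hematocrit comes out at its reference value (65.9×10⁸); an allometric
relation $W_b = 0.468\,BW^{0.85}$ maps birth weight to brain weight when
gestational age is unavailable. With the clinical rule of thumb
MAP ≈ gestational age (mmHg), the model then reproduces the reference
absolute CBF values (8.67 vs 8.64 ml/min/100 g at 25 wk, 10.7 vs 10.5 at
30 wk) without further tuning. Note that at *strictly constant* MAP the
mass-normalized CBF is nearly flat in gestational age (resistance scales
as ~1/brain weight under the count-scaling rule); the familiar rise of CBF
with age appears as soon as MAP follows its clinical increase
(~1 mmHg/week), which is how the sweep examples are run.

```{r reference}
cfg <- default_morphometry()
sapply(c(0.15, 0.45, 0.60), function(h)
  assemble_resistances(cfg, run_conditions(25, 25, h))$total / 1e8)
compute_cbf(run_conditions(25, 25, 0.15), cfg)$cbf_global /
  compute_cbf(run_conditions(25, 25, 0.45), cfg)$cbf_global
```

A legacy mode (`viscosity_mode = "constant_003"`) replaces every
viscosity by the constant 0.003 Pa·s. It is a plain constant-viscosity
Poiseuille assembly — deliberately *not* a re-implementation of the older
micropolar-fluid vessel model, whose closed-form expressions are not
available — and serves as the hematocrit-invariant reference curve.
Vasoreactivity to MAP and pCO₂ is accepted in the data schema but not
modelled: the diameter-modifier hook defaults to the identity, because no
functional form is published for this model; pCO₂ is carried through the
pipeline untouched.

## The cohort pipeline

`read_records()` ingests routine monitoring data (MAP, pCO₂ and systemic
hematocrit time series per infant, plus demographics and IVH grade).
Hematocrit is sampled less often than blood gases, so
`align_hematocrit()` attaches to every gas time point the last available
laboratory value (LOCF), flagging each point as measured, carried, or
missing (gas before any laboratory record; excluded from analysis).
`compute_patient_cbf()` then runs the full model per time point — within
the first 10 days of life for infants without IVH, and from 7 days before
to 3 days after the hemorrhage otherwise — under either the measured
hematocrit or a fixed 45%, and averages over all valid points in the
window (the per-patient mean over points, not over daily aggregates, is
the default; the choice is benign because the schedule is near-uniform).
`summarize_cohort()` assembles the comparison tables: demographics
(Fisher's exact test for categorical, two-sided Wilcoxon rank-sum for
continuous variables), hematocrit by factor and by IVH status, and global
plus single-capillary CBF under both hematocrit modes. The measured-vs-45%
comparison uses the two-sided rank-sum test on per-patient means — a
paired test would be more powerful, but the unpaired rank-sum mirrors the
study design this pipeline reproduces. Because CBF is strictly decreasing
in hematocrit at fixed pressure, a patient's measured-mode mean exceeds
the fixed-mode mean exactly when the mean measured hematocrit is below
45% — the mechanism behind the affected group's higher measured-mode CBF.

## The synthetic cohort generator

No clinical records ship with the package; `generate_cohort()` draws
cohorts with the published summary structure: 254 infants (118 controls,
IVH grades I/II/III/IV = 38/42/48/8), gestational age from per-group
truncated normals on [23, 30] weeks (26.68 ± 2.17 control, 26.26 ± 2.04
affected), birth weight conditional on gestational age (+100 g/week,
residual SD 150 g, truncated to [335, 1580] g — the published cohort's
range), and per-patient hematocrit means from group-specific truncated
normals (45.14 ± 7.92 vs 41.41 ± 7.48 %, truncated to [15, 65] %). Daily
laboratory hematocrit follows an AR(1) around the patient mean (ρ = 0.8,
within-SD 2 %) so the LOCF alignment is non-trivially exercised; blood
gases are drawn 3 per day (the frequency is not documented for the
original data; it is configurable). MAP rises with gestational age
(baseline GA − 1 mmHg with AR(1) noise, SD 3), consistent with the
clinical rule of thumb. Group labels are assigned *first* and hematocrit
drawn per group: the generator mirrors an observational design and
encodes no causal hematocrit→IVH mechanism.

What passing tests on synthetic cohorts do and do not show: they verify
the pipeline's statistical machinery and the direction and detectability
of the hematocrit effect under the published group distributions; they
cannot certify the published absolute CBF group means, which depend on the
joint MAP/hematocrit distribution of the real records. Real data also
contain features the generator omits: irregular sampling, transfusions
(step changes in hematocrit), autoregulation, and grade-specific
hematocrit differences.

```{r cohort, eval = FALSE}
g <- generate_cohort(cohort_params(), seed = 42)
tables <- summarize_cohort(g$records)
tables$cbf_global
```

## Numerical conventions and limitations

All internal arithmetic is SI (m, Pa, Pa·s, Pa·s/m³, hematocrit as a
fraction); µm, mmHg (1 mmHg = 133.322 Pa) and percent exist only at user
and file boundaries, converted in one helper module. Circuit identities
(series sums, parallel harmonic means, per-vessel flow conservation) hold
to floating-point tolerance by construction and are tested to 1e-10 on
random trees. Scaled vessel counts are floored at 1. Degenerate inputs
fail fast: MAP ≤ P<sub>ic</sub>, hematocrit outside [0, 1), diameters at
or below the wall offset, capillary radii below 1.5 µm.

Known limitations: no pulsatility or vascular compliance, no venous
collapse, no oxygen transport, no red-cell aggregation or plasma-viscosity
regulation, no MAP/pCO₂ vasoreactivity, and a calibrated (not measured)
morphometry whose per-level split away from the capillary and precapillary
anchors is under-determined by the available reference values. Problem
sizes used in the shipped tests — 50 random trees for circuit identities,
100 random capillaries against the brute-force oracle, 100 synthetic
cohorts of 254 infants for the direction-of-effect check — were chosen as
the smallest giving stable verdicts for these properties.
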