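---
title: "Methods: a flow-limited PBPK model for oral 3-chloroallyl alcohol in the rat"
author: "caaPBPK"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a flow-limited PBPK model for oral 3-chloroallyl alcohol in the rat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caaPBPK)
```

## Purpose

3-chloroallyl alcohol (3-CAA) is a primary alcohol encountered as a
metabolite of the herbicide clethodim and of the soil fumigant
1,3-dichloropropene.  Repeat-dose and genotoxicity studies of 3-CAA have
used both oral gavage and drinking-water administration, and the choice of
route turns out to matter: a bolus by gavage produces a transient blood
peak several-fold higher than the same daily dose sipped from drinking
water, while the daily area under the curve is nearly identical.  Because
severe toxicity of 3-CAA (via its reactive metabolite 3-chloroacrolein)
tracks the peak concentration rather than the integrated exposure, the
route determines how much sustained internal exposure can be achieved
below a maximum tolerated dose.  `caaPBPK` implements the
physiologically based pharmacokinetic (PBPK) model that quantifies this
trade-off, and the dose metrics (venous Cmax, AUC, systemic
bioavailability, bone-marrow exposure) used to reason about study design.

## Model structure

The model is a conventional minimal PBPK structure for an orally dosed,
moderately volatile chemical in the rat:

* an oral dosing (gut) compartment holding unabsorbed chemical,
* five perfused, flow-limited tissue compartments — liver, fat, bone
  marrow, richly perfused and slowly perfused — exchanging with blood,
* algebraic venous and arterial blood (no blood compartment volume), and
* steady-state gas exchange at the lung against chemical-free inhaled air.

Amounts are mg, volumes L, times h, concentrations mg/L.  With $A_i$ the
amount in tissue $i$, $V_i$ its volume, $P_i$ its tissue:blood partition
coefficient and $Q_i$ its blood flow, each non-liver tissue obeys

$$\frac{dA_i}{dt} = Q_i \left( C_{art} - \frac{C_i}{P_i} \right), \qquad
  C_i = A_i / V_i .$$

The gut loses mass by first-order absorption into the liver at rate
$k_a A_{gut}$ ($k_a = 1.0\,\mathrm{h^{-1}}$), so the liver balance gains
the absorbed flux and loses saturable (Michaelis–Menten) metabolism at the
liver venous concentration $C_{VL} = C_{liver}/P_{liver}$:

$$\frac{dA_{liver}}{dt} = k_a A_{gut}
  + Q_{liver}\left( C_{art} - C_{VL} \right)
  - \frac{V_{max}\, C_{VL}}{K_m + C_{VL}} .$$

Mixed venous blood is the flow-weighted mixture of tissue effluents,
$C_{ven} = \sum_i Q_i (C_i/P_i) / Q_{tot}$, and arterial blood follows
from a steady-state lung with alveolar ventilation $Q_{alv}$ and blood:air
partition coefficient $P_{ba}$:

$$C_{art} = \frac{Q_{tot}\, C_{ven}}{Q_{tot} + Q_{alv}/P_{ba}}, \qquad
  \text{exhalation rate} = Q_{alv}\, C_{art} / P_{ba}.$$

With $P_{ba} = 1492$ (3-CAA is highly blood-soluble) the arterial:venous
ratio exceeds 0.99 and exhalation removes well under 2 % of the absorbed
dose; the model asserts both properties in its tests.  Metabolism is
restricted to the liver: the parameterization is carried over from
hepatic alcohol-dehydrogenase kinetics, and no comparable basis exists
for extrahepatic tissues.  The model deliberately does not track the
metabolite (3-chloroacrolein / 3-chloroacrylic acid): only the parent
chemical and the cumulative amount metabolized are simulated.

## Parameters

**Physiology** (editable defaults, standard adult-rat compendium values):
body weight 0.225 kg; cardiac output $14\,BW^{0.74}$ L/h with alveolar
ventilation set equal to cardiac output; flow fractions liver 0.183, fat
0.07, bone marrow 0.03, richly perfused 0.47, slowly perfused 0.247 (sum
exactly 1); volume fractions liver 0.034, fat 0.07, bone marrow 0.03,
richly 0.05, slowly 0.727 (sum 0.911; the remainder is unperfused mass).
These give $Q_{liver} \approx 0.85$ L/h at 0.225 kg, which was verified
against the closed-form bioavailability oracle below before the defaults
were locked.  All values ship in the JSON profile
`inst/extdata/rat_3caa_default.json` and can be overridden per run.

**Chemistry**: molecular weight 92.52 g/mol; blood:air partition
coefficient 1492; tissue:blood partition coefficients liver 0.95, fat
1.47, richly 0.95, slowly 0.64, bone marrow 1.06; absorption rate
constant $k_a = 1.0$ /h.

**Metabolism by read-across.**  Measured Michaelis–Menten parameters for
3-CAA are unavailable, so the model carries over published rat
alcohol-dehydrogenase parameters for ethanol — $V_{max} = 110.64$ mg/h,
$K_m = 23$ mg/L — scaled by the molecular-weight ratio 92.52/46.07 to
keep them molar-equivalent: $V_{max} = 222.16$ mg/h, $K_m = 46.1$ mg/L
(`mw_read_across()`).  $V_{max}$ is body-weight specific and is converted
to the scalable form $V_{maxC} = V_{max}/BW^{0.75}$
(`vmaxc_from_vmax()`), giving 680 mg/h/kg^0.75 at 0.225 kg.  Note that
this relationship is sometimes typeset as a multiplication by
$BW^{0.75}$; the published numeric values (222.16 mg/h at 0.225 kg
giving 680) are only consistent with division, which is what the package
implements, with the inverse `vmax_from_vmaxc()` round-tripping exactly.
Because the read-across values are starting points rather than
measurements, the package scans a 4 × 4 uncertainty grid
(`scan_grid()`): $V_{maxC} \in \{226, 452, 904, 1808\}$ and
$K_m \in \{15.3, 30.6, 61.2, 122\}$ — one third of the read-across
values, then doubled progressively.  The metabolism-maximizing corner,
$V_{maxC} = 1808$, $K_m = 15.0$ mg/L, is the default parameterization
and the one used for the 28-day predictive scenarios.  (The scan grid's
smallest $K_m$ is 15.3 while the predictive scenarios use the rounder
15.0; both values are kept as stated rather than reconciled.)

## Dosing as exact square pulses

Both routes infuse into the gut compartment as square pulses of 15 s
(`gavage_schedule()`, `drinking_schedule()`).  Gavage is one pulse at the
start of each simulated day; drinking water is 48 pulses, one per
half-hour slot, with per-slot amounts proportional to a drinking
pattern.  The integrator is restarted at every pulse edge, so scheduled
mass enters the system exactly (to 1e-12 relative) and no event smoothing
can blur the peak.  A sensitivity test confirms that describing the
gavage bolus as a 10 s rather than 15 s infusion changes Cmax by less
than 0.5 %, so the exact pulse length is immaterial.  Gavage is placed at
the start of the simulated day; at periodic steady state the time of day
does not affect Cmax or AUC.

**The diurnal drinking pattern.**  Rats drink predominantly in the dark
phase, in discrete bouts, with a pronounced bout just after lights-off
and a smaller anticipatory rise before lights-on.  The measured
half-hourly consumption weights behind the original analysis are not
published, so the package encodes this behavior parametrically
(`diurnal_drinking_pattern()`): a fraction (default 0.85) of daily intake
in the 12-h dark phase starting at $t = 0$, an exponential onset bout
(default 25 % of daily intake, 1.5 h decay), an anticipatory end-of-dark
bout (default 10 %, 2 h rise), uniform intake otherwise.  The bout
magnitudes were fixed once so that the drinking-water dose metrics and
the gavage:drinking-water Cmax ratio reproduce the reported
drinking-water dosimetry (≈ 6-fold peak ratio), and are not tuned per
analysis; they are plausible for measured rat drinking rhythms.  Because
this shape is a modelling choice, drinking-water Cmax carries a wider
reproduction tolerance than the gavage metrics, and the tests bound its
sensitivity: the diurnal default concentrates intake less than 3-fold
relative to uniform sipping, and steady-state daily AUC is insensitive
to any permutation of the weights (AUC depends on the daily dose, not its
within-day distribution, in the linear regime).

What the dosing generator emulates — and what it does not.  It reproduces
fixed daily doses partitioned within the day; it does not model variable
daily water intake, feed consumption, body-weight growth over a 28-day
study, or adjustment of achieved dose to measured consumption (achieved
doses such as 61.9 or 83.9 mg/kg/day are taken as given inputs).  Passing
tests therefore demonstrate correctness of the dosimetry model under
idealized intake, not agreement with individual-animal kinetics.

## Bioavailability

Systemic bioavailability $F$ is the fraction of the *absorbed* dose that
escapes hepatic first-pass metabolism (chemical that is exhaled after
reaching blood counts as systemically available).  Because the same liver
also clears recirculating chemical, cumulative metabolized mass over a
long simulation approaches the entire absorbed dose and cannot be used to
measure first-pass escape.  The model therefore integrates the escape
flux explicitly as an additional state: newly absorbed chemical passes
the liver with instantaneous escape probability

$$\phi(t) = \frac{Q_{liver}}{Q_{liver} + V_{max}/(K_m + C_{VL}(t))},$$

the well-stirred-liver escape fraction at the prevailing liver venous
concentration, and $F$ is cumulative escaped over cumulative absorbed
mass after a terminal washout (the simulation continues drug-free until
gut plus tissue amounts fall below 1e-6 of the infused mass).  Three
limits anchor the definition and are asserted in tests: $V_{max} = 0$
gives $F = 1$ exactly; in the linear regime ($C_{VL} \ll K_m$) $F$
equals the closed form $Q_{liver}/(Q_{liver} + V_{max}/K_m)$, the
independent oracle used in the tests; and saturation raises $F$ toward
1, which is why $F$ is non-decreasing in dose.  At the defaults
($V_{maxC} = 1808$, $K_m = 15$) the closed form gives 2.1 %: nearly all
of an oral dose of 3-CAA is destroyed on first pass, and the grid corner
with the weakest metabolism ($V_{maxC} = 226$, $K_m = 122$) gives about
60 %.

## Dose metrics

`compute_cmax()` reports the maximum venous concentration over the
returned grid (earliest time on ties).  `compute_auc()` integrates the
venous curve trapezoidally over the full dosing horizon — cumulative over
all simulated days, not per-day — and is cross-checked against an
auxiliary ODE state that integrates the venous concentration exactly
(agreement to 0.1 % is asserted).  `compute_tissue_exposure()` reports
the time-average of a tissue concentration over the horizon and its
ratio to venous Cmax; for bone marrow this ratio quantifies how sustained
marrow exposure is relative to the blood peak (near the partition
coefficient 1.06 for a constant profile, far below it for spiky gavage
profiles).  `compare_routes()` and `run_scan()` assemble the
gavage:drinking-water Cmax and AUC ratios across the metabolic grid;
`run_reference_scenarios()` runs the five 28-day study regimens (gavage
25 and 75, drinking water 61.9, 75 and 83.9 mg/kg/day).

## Numerical choices

* Integrator: `deSolve::lsoda` with a compiled C right-hand side;
  relative tolerance 1e-8, absolute 1e-10.  The 15-s pulses against
  multi-hour dynamics make the system stiff at pulse edges; restarting
  the integrator at every edge keeps pulse mass exact and peaks sharp.
* Output grid: 0.01 h plus every pulse edge.  The venous response time
  constant is about 0.2 h, so the grid resolves the peak: refining the
  grid 10-fold, or halving the grid and tightening tolerances, changes
  Cmax and AUC by less than 0.1 % (asserted in tests).
* Mass bookkeeping: at every output time the gut, tissue, metabolized
  and exhaled amounts must sum to the mass infused so far; the worst
  relative error is stored on every time course (typically ~1e-10, with
  0.1 % the acceptance bound).
* Degenerate inputs: a zero-dose run returns an identically zero course;
  bioavailability is then undefined and signalled as an error rather
  than returned as NaN.  Pattern files must have exactly 48 non-negative
  weights summing to 1.  Negative states beyond integrator tolerance
  abort with a diagnostic carrying the time.
* Problem sizes: the metabolic scan runs each cell for 7 days, which the
  steady-state check (`check_steady_state()`: final two daily peaks and
  troughs within 1 %) shows is ample — the elimination half-life is far
  below a day, so daily profiles converge by day 3.  The predictive
  scenarios run 28 days to match the repeat-dose study designs; a
  28-day scenario takes well under a second, and the full 128-simulation
  scan under half a minute, on one CPU.

## Known limitations

* Metabolite kinetics are out of scope; the model reports cumulative
  metabolism of the parent only, so toxicity reasoning based on local
  metabolite concentration is outside what it can support.
* Metabolism is hepatic only, and the read-across carries the usual
  uncertainty of parameter transfer between chemicals; the scan grid is
  the uncertainty analysis, not a substitute for measured kinetics.
* The diurnal drinking pattern is a calibrated behavioral model, not a
  measurement; drinking-water Cmax (but not AUC) depends on it, which is
  why it carries the widest tolerance in the reproduction tests.
* Physiological parameters are point values for a 0.225-kg adult rat; no
  growth, variability or uncertainty propagation is modelled.
* Inhalation dosing and human physiology are out of scope.
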