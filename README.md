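# caaPBPK

A physiologically based pharmacokinetic (PBPK) model for oral dosing of
**3-chloroallyl alcohol (3-CAA)** in the rat.

3-CAA — a metabolite of the herbicide clethodim and of the soil fumigant
1,3-dichloropropene — has been tested in repeat-dose and genotoxicity
studies by both oral gavage and drinking-water administration.  The two
routes deliver the same daily dose very differently: a gavage bolus
produces a blood peak (Cmax) roughly six times higher than the same dose
sipped from drinking water, while the area under the concentration-time
curve (AUC) is nearly identical.  Since severe 3-CAA toxicity tracks
Cmax (consistent with a reactive metabolite, 3-chloroacrolein), the
route determines how much sustained internal exposure a study can reach
without exceeding a maximum tolerated dose.  `caaPBPK` is aimed at
toxicokinetic modellers and study designers who need those dose metrics —
venous Cmax, AUC, systemic bioavailability and bone-marrow exposure —
for candidate dosing regimens.

## The model

Flow-limited, five-compartment PBPK structure (liver, fat, bone marrow,
richly and slowly perfused) with an oral dosing compartment, algebraic
venous/arterial blood, and steady-state gas exchange.  For tissue *i*
with flow *Q<sub>i</sub>* and tissue:blood partition coefficient
*P<sub>i</sub>*:

```
dA_i/dt      = Q_i (C_art − C_i/P_i)
dA_liver/dt  = ka·A_gut + Q_L (C_art − CVL) − Vmax·CVL/(Km + CVL),   CVL = C_liver/P_liver
C_ven        = Σ Q_i (C_i/P_i) / Q_tot
C_art        = Q_tot·C_ven / (Q_tot + Q_alv/P_ba)
```

Hepatic Michaelis–Menten metabolism is parameterized by read-across from
the rat ethanol/alcohol-dehydrogenase model, scaled by molecular weight
(Vmax 222.16 mg/h, Km 46.1 mg/L; VmaxC = Vmax/BW^0.75 = 680 mg/h/kg^0.75
at 0.225 kg), and an uncertainty grid VmaxC ∈ {226, 452, 904, 1808} ×
Km ∈ {15.3, 30.6, 61.2, 122} is scanned.  Dosing enters the gut as exact
15-s square pulses — once daily for gavage, 48 half-hourly pulses
weighted by a diurnal drinking pattern for drinking water — with the
integrator restarted at every pulse edge.  Bioavailability is the
fraction of absorbed dose escaping first-pass metabolism, integrated
explicitly as a well-stirred-liver escape flux.  See the methods
vignette (`vignettes/caa-pbpk-methods.Rmd`) for assumptions, parameter
provenance and numerical choices.

## Worked example

```r
library(caaPBPK)

# 28 days of daily oral gavage at 25 mg/kg/day, default rat parameters
tc <- run_simulation("gavage", 25, 28)
tc
#> PBPK time course: gavage, 25 mg/kg/day, 28 day(s), 67229 time points
#>   venous Cmax 0.09158 mg/L; mass-balance error 4.1e-11 (relative)

dose_metrics(tc)
#>  route dose_mgkgday n_days vmaxc km cmax_mgL t_cmax_h auc_mghrL
#> gavage           25     28  1808 15   0.0916      240      4.01
#>  bioavailability_pct bm_avg_mgL bm_to_cmax
#>                 2.12    0.00632      0.069
```

The daily bolus peaks at 0.092 mg/L in venous blood and accumulates a
28-day AUC of 4.0 mg·h/L; only 2.1 % of the absorbed dose survives
hepatic first-pass metabolism.  Comparing routes at 75 mg/kg/day:

```r
compare_routes(75, 28)
#> Route comparison (gavage vs drinking water)
#>           route dose_mgkgday n_days vmaxc km cmax_mgL t_cmax_h auc_mghrL
#>          gavage           75     28  1808 15  0.27884     0.36     12.13
#>  drinking_water           75     28  1808 15  0.04791   649.13     11.98
#>  bioavailability_pct bm_avg_mgL bm_to_cmax
#>                2.142    0.01913     0.0686
#>                2.116    0.01888     0.3941
#>   Cmax ratio: 5.82   AUC ratio: 1.01
```

Gavage reaches a 5.8-fold higher peak for essentially the same AUC, and
the bone-marrow average sits at only 7 % of Cmax under gavage versus
39 % under drinking water — the drinking-water profile sustains tissue
exposure near its peak.  `run_scan()` repeats this comparison across the
full metabolic uncertainty grid, and `run_reference_scenarios()` runs
the five 28-day study regimens (gavage 25/75; drinking water
61.9/75/83.9 mg/kg/day).

A command-line front end wrapping the same functions is provided in
`inst/scripts/caa-pbpk.R`:

```sh
Rscript inst/scripts/caa-pbpk.R simulate --route gavage --dose 25 --days 28 --out tc.csv
Rscript inst/scripts/caa-pbpk.R scenarios --out scenarios.csv
Rscript inst/scripts/caa-pbpk.R scan --out scan.csv
```

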