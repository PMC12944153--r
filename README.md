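# fluvopbpk

A minimal population physiologically-based pharmacokinetic (PBPK) simulator
for **fluvoxamine**, built to quantify how **CYP2D6 metabolizer phenotype**
(PM / IM / EM / UM) and **age** shape drug exposure, and what that implies
for dosing elderly patients against the 60–230 ng/mL therapeutic trough
range. It is aimed at pharmacometricians and clinical-pharmacology
researchers who want a transparent, fully scriptable alternative to
proprietary simulators for this class of question.

## The model in brief

Per virtual subject, oral dosing is integrated through a three-state minimal
PBPK system — gut depot (first-order `ka`), central volume `(Vss − Vsac)·W`,
peripheral volume `Vsac·W` exchanging at `Q` — with elimination by hepatic
clearance from the well-stirred liver model:

    CLh,b = Qh·fub·CLint,u / (Qh + fub·CLint,u),   Fh = Qh / (Qh + fub·CLint,u)

Whole-liver intrinsic clearance comes from IVIVE:

    CLint,u = (Vmax/Km)·s2D6·[CYP2D6 abundance] · MPPGL · liver mass  +  CLint,add

with the published fluvoxamine parameters (MW 318.3, fup 0.14, B/P 1.5,
Vss 21 L/kg, Q 0.5 L/h, Vsac 6 L/kg, Vmax 70 pmol/min/pmol, Km 38.6 µM).
Two unknowns are calibrated from clinical anchors by `fit_fluvoxamine()`:
the CYP2D6 fraction metabolized, `fm = 1 − 1/2.1 ≈ 0.524` from the observed
single-dose PM/EM AUC fold, and the absolute clearance scale from the
observed mean single-dose 100 mg AUC(0–∞) of 1308 ng·h/mL. A third
calibrated constant — a geriatric hepatic activity scalar — reproduces the
~50% lower oral clearance reported in the elderly. Virtual populations
(10 trials × 10 subjects) carry log-normal between-subject variability in
MPPGL, liver mass, flow and a shared hepatic activity deviate, with
phenotype-specific CYP2D6 abundance (UM = 2×EM, IM = 0.364×EM, PM = 0).
See the methods vignette (`vignettes/fluvoxamine-cyp2d6-geriatric.Rmd`)
for every assumption and its rationale.

## Worked example

```r
library(fluvopbpk)

fit <- fit_fluvoxamine(seed = 1)
print(fit)
#> Fluvoxamine population PBPK model (calibrated)
#>   fm,CYP2D6 = 0.5238 (from PM/EM fold 2.10)
#>   CYP2D6 pathway scalar = 6.468; non-CYP2D6 CLint = 85.31 uL/min/mg
#>   AUC anchor: simulated 1308 vs observed 1308 ng.h/mL (0.0%)
#>   Geriatric activity scalar = 0.609 (CL ratio 0.500, target 0.50)

st <- run_phenotype_study(fit, doses = 100, seed = 2)
st$folds
#>        daily_dose phenotype fold_auc_vs_em fold_cmin_vs_em
#> 100_IM        100        IM      1.4664145       1.5558046
#> 100_PM        100        PM      1.9834013       2.1902587
#> 100_UM        100        UM      0.6634332       0.6165001
st$window_classification
#>        daily_dose phenotype mean_cmin frac_below frac_within frac_above
#> 100_EM        100        EM  93.15183       0.40        0.54       0.06
#> 100_IM        100        IM 144.92604       0.15        0.70       0.15
#> 100_PM        100        PM 204.02661       0.06        0.63       0.31
#> 100_UM        100        UM  57.42812       0.65        0.35       0.00
```

Reading this: in uniform-phenotype geriatric populations at 100 mg/day,
steady-state exposure in PMs is ~2× that of EMs and UMs sit at ~0.66×; mean
troughs put PMs (204 ng/mL) near the 230 ng/mL ceiling — with 31% of PM
subjects above it — while EMs (93 ng/mL) sit comfortably inside the window
and UMs (57 ng/mL) mostly below it. That is the quantitative case for
phenotype-stratified dosing (lower doses for PMs, higher for UMs) in the
elderly. `run_age_comparison()` likewise gives the elderly/younger
steady-state AUC fold (~1.95 under the 50% clearance anchor), and
`run_verification_suite()` checks predictions against six published clinical
studies under the a priori two-fold criterion. `predict()`, `simulate()` and
`plot()` methods give typical-subject values, per-subject Monte-Carlo
metrics, and interval concentration profiles with the therapeutic band.

A thin command-line runner is included:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "fvpbpk.R", package = "fluvopbpk"))')" \
    run --study phenotype --doses 50,100 --seed 3 --out out/
```

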