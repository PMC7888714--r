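# wbpleth

Breath-by-breath analysis of whole-body barometric plethysmography in
rodents, with rule-based apnea/sigh scoring, craniofacial landmark
morphometrics and a cohort statistics layer — plus seeded synthetic-data
generators that emulate the traces and cohorts such pipelines are run on, so
the whole stack is testable without animal data.

## Who it is for

Respiratory physiologists analysing open-flow (barometric) plethysmography
recordings of mice across gas-challenge protocols (normoxia → hypoxia →
recovery → hyperoxia), and anyone needing a reproducible implementation of
the standard scoring rules for spontaneous apneas (SA), sighs and post-sigh
apneas (PSA).

## The core computations

**Breath segmentation.** Breaths are delimited by hysteresis-gated upward
threshold crossings of the chamber-pressure signal, with all thresholds
relative to the local signal range (detection is invariant to amplitude
scaling and offset). Per breath: onset, peak (end of inspiration), offset,
T_i, T_e, T_TOT, and peak deflection P_T.

**Tidal volume** via the barometric (Drorbaugh–Fenn) correction,

    V_T = V_K (P_T / P_K) · Tb (P_B − P_C) / [ Tb (P_B − P_C) − T_A (P_B − P_R) ]

with Tb, T_A in Kelvin, P_B barometric pressure, P_C chamber and P_R
body-temperature water vapor pressure (Arden Buck equation). Minute
ventilation is V̇_E = fR × V_T; V̇_O2 comes from pull-mode indirect
calorimetry (Lighton),

    V̇_O2 = FR_e [ (FiO2 − FeO2) − FiO2 (FeCO2 − FiCO2) ] / (1 − FiO2)

with mass (per kg) and STPD normalization, ΔO2 and RER = V̇_CO2/V̇_O2.

**Event scoring.** An apnea is ≥ 2 missing breath cycles *and* a pause ≥ 1 s
(pause = inter-onset interval minus the rolling-median cycle duration); a
sigh is a breath ≥ 2× the local normal breath volume (rolling median,
sigh-excluding); a PSA is an apnea within 20 s after a sigh, linked to its
nearest preceding sigh; sighs are categorized by whether they are followed
by < 2 or ≥ 2 linked apneas.

**Morphometrics.** Config-driven inter-landmark distances, vertex and
line-pair angles (optionally projected onto the axial/sagittal/coronal
plane), bilateral averages, and triplicate-rater reliability via ICC(3,1).

**Statistics.** Student's t, one-way ANOVA, split-plot two-way
repeated-measures ANOVA with Holm–Sidak-adjusted pairwise post tests,
per-metabolite screening, and breath-pattern variability metrics.

## Worked example

Simulate one apneic-mutant animal through the scaled gas protocol and run
the full pipeline:

```r
library(wbpleth)
sim <- simulate_protocol_trace("ncko_a", seed = 1)
res <- analyze_protocol_trace(sim$trace)

res$rates[, c("label", "n_sa", "n_psa", "n_sighs", "apneas_per_h", "sighs_per_h")]
#>      label n_sa n_psa n_sighs apneas_per_h sighs_per_h
#>   normoxia    4     3       3           84          36
#>    hypoxia    2     0       0           60           0
#>   recovery   20     0       0          400           0
#>  hyperoxia    0     0       0            0           0

res$summary[, c("condition", "fr", "vt_ml", "ve", "tb_c", "sa_per_h")]
#>      condition    fr vt_ml      ve  tb_c sa_per_h
#>       normoxia 145.8  0.15  867.06 37.29       48
#>  hypoxia_early 180.0  0.18 1278.51 37.06      120
#>   hypoxia_late 160.0  0.16 1046.86 37.02        0
#>       recovery 150.0  0.15  893.96 37.32        0
#>      hyperoxia 144.0  0.15  856.14 37.37        0

res$recovery_minute_sa
#> [1] 20
```

Reading the output: this animal breathes at ~146/min in normoxia with
V_T ≈ 0.15 ml (V̇_E ≈ 867 ml/min/kg); hypoxia drives the biphasic response
(fR 180/min early, attenuating to 160/min by late hypoxia); events cluster
as expected for the apneic preset, including a burst of 20 spontaneous
apneas in the first minute of recovery (this animal drew a high count from
the preset distribution, mean 8.2). Detected events equal the generator's
inserted ground truth exactly on noiseless traces and remain exact under
the default sensor noise.

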