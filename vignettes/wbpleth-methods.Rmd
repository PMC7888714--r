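---
title: "Methods: breath analysis, event scoring and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath analysis, event scoring and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbpleth)
```

This vignette is the package's account of its models and the choices behind
them: what each computation assumes, which parameters matter and why their
defaults are what they are, what the synthetic generators do and do not
emulate, and where the design was genuinely open.

## The measurement model

Open-flow whole-body plethysmography measures breathing indirectly: the
warming and humidification of inspired air produces pressure oscillations in
the chamber, recorded (here at 200 Hz) in arbitrary transducer units. Two
conversions give those units physiological meaning.

**Calibration and the barometric correction.** A known volume `V_K`
(typically 0.25 ml) injected into the chamber produces a deflection `P_K`.
A breath with peak deflection `P_T` then has tidal volume

$$V_T = V_K \frac{P_T}{P_K}\cdot
\frac{T_b (P_B - P_C)}{T_b (P_B - P_C) - T_A (P_B - P_R)}$$

with body and chamber temperature in Kelvin and the vapor pressures at
chamber humidity ($P_C$) and body saturation ($P_R$). The correction factor
exceeds 1 whenever the animal is warmer and wetter than the chamber and
diverges as the chamber approaches body conditions — the package raises an
explicit singularity error there rather than returning a sign-flipped
volume. Vapor pressures use the Arden Buck equation (within 0.1% of steam
tables over 0–45 °C); the tables-based originals are not uniquely specified,
and any formula at this accuracy changes $V_T$ by far less than calibration
error. The printed linear form of the equation is ambiguous about
bracketing; the adopted form is the classical one, which has the correct
singular limit.

Body temperature is measured sparsely (four protocol timepoints); `tb_at()`
interpolates linearly and holds ends constant. Units are fixed at module
boundaries — seconds, ml, ml/min, °C externally, Kelvin only inside the
equations — to prevent silent K/°C bugs.

**Calorimetry.** Pull-mode V̇O2 uses the excurrent flow and the four gas
fractions; the divisor is $(1-FiO_2)$ and the flow multiplies the full
bracket, the dimensionally consistent reading of the pull-mode equation.
Negative V̇O2 beyond tolerance is flagged as sensor inconsistency but still
returned, so users see the data problem instead of a masked zero. STPD
rescaling $(273.15/T_A)\cdot(P_B-P_C)/760$ is applied to V̇O2 by default;
whether to also apply it to V̇E is exposed as an option (`normalize_and_stpd`)
because conventions differ — mass normalization (per kg) is the default for
both.

## Breath segmentation

The published analysis relied on interactive software; the detector here is
a from-scratch design validated against the package's own generators:

- all thresholds are *relative*: the local signal floor and ceiling are the
  5th/98th percentiles in 1 s blocks, spread over ±3 neighbouring blocks so
  thresholds stay meaningful inside apneic gaps. Detection is therefore
  invariant to amplitude scaling and offset (a property test).
- a breath candidate is an upward crossing of floor + 20% of local range,
  armed only after the signal has returned below a quarter of that level
  (hysteresis); candidates closer than 60 ms — above the physiological
  maximum mouse fR of ~1000/min — are rejected as noise.
- the onset is then refined to the preceding local minimum of the raw
  signal, and the peak is the raw maximum of the cycle. On noiseless
  generated traces this recovers onsets exactly to the sample, which is what
  makes the generator–analyzer closure tests exact rather than approximate.
- `T_i` = onset→peak, `T_e` = peak→next onset: the standard barometric
  convention; only the symbols, not the waveform landmarks, are fixed by the
  source conventions.

A flat trace yields an empty table (not an error); fewer than 10 samples per
cycle sets a `low_rate_warning` flag.

## Event scoring

The scoring rules are definitional thresholds, implemented literally:

- **apnea**: for each consecutive breath pair, pause = inter-onset interval
  − T̄, where T̄ is the rolling median cycle duration of up to 15 preceding
  non-sigh breaths (at least 5 required; the breath immediately before the
  gap is excluded since its own T_TOT spans the gap). An event requires
  *both* ≥ 2 missing cycles (rounded pause/T̄) *and* pause ≥ 1 s. The two
  gates are conjunctive because the 1 s figure is stated as the
  fR-dependent correspondence of two missing cycles: at 120/min they
  coincide; at higher fR the absolute gate dominates.
- **sigh**: breath volume ≥ 2× the rolling median volume of preceding
  non-sigh breaths in a 60 s window. The median is outlier-robust and
  excludes previously flagged sighs, so a sigh does not inflate the
  baseline for a nearby later one. "Normal breath volume" is not formally
  defined anywhere authoritative; the sigh-excluding rolling median is this
  package's definition.
- **post-sigh apnea**: an apnea whose time lies within (sigh, sigh + 20 s],
  linked to the *nearest preceding* sigh. Whether the 1 s pause is measured
  onset-to-onset or as flat-signal time is not specified by the source
  conventions; the onset-to-onset minus T̄ convention is used and the gates
  are configurable (`event_params`).
- apneas are assigned to the epoch containing their onset; the
  first-recovery-minute SA count is taken over [recovery_start,
  recovery_start + 60 s).

Invariants enforced by tests: every apnea is scored exactly once (SA + PSA
= total), every PSA carries one sigh reference preceding it by ≤ 20 s, and
sigh-category percentages sum to 100 whenever sighs exist.

## The synthetic study design

The generators define the study conditions; they are fixed, not tuned.

**Waveform.** Each breath is a quarter-period sine rise over `T_i` (peaking
exactly at onset + T_i, consistent with the segmentation convention)
followed by an exponential expiratory decay with time constant `T_e/3`,
normalised to reach baseline exactly at the breath end. No waveform is
prescribed by the source conventions; any shape with unambiguous onsets
works, and this one resembles published mouse plethysmograms. Apnea
insertion deletes whole cycles and holds the signal at end-expiratory
baseline (the "missing breath cycles" semantics); an explicit-pause variant
splices in a flat pause of arbitrary duration for threshold scans. Peak
deflections are computed by *inverting* the tidal-volume equation, so the
forward equation recovers the programmed V_T exactly — the basis of the
forward–inverse closure tests.

**Protocol.** Eupneic baseline fR 150/min, V_T 0.15 ml, T_i/T_TOT 0.35, 4%
amplitude jitter, sensor noise 3% of the eupneic deflection — typical
adult-mouse values. The full protocol is 150/20/60/20 min
(normoxia/hypoxia/recovery/hyperoxia at FiO2 0.21/0.10/0.21/0.40); the
desk-scale default is 5/2/3/2 min, chosen as the analysis problem size for
tests and the reproduction script (the averaging windows rescale
proportionally, with a warning). Hypoxia drives the biphasic ventilatory
response: fR × 1.35 and V_T × 1.20 early, attenuating exponentially (time
constant a quarter of the epoch) toward × 1.05 plateaus; hyperoxia mildly
depresses fR (× 0.95).

**Events.** Sighs arrive at 25/h with folds uniform in 2.3–3.0; a
preset-specific fraction of sighs is followed by 1–2 apneas (post-sigh
clusters); spontaneous apneas arrive at preset per-epoch rates. Inserted
apneas use the smallest cycle count that clears both detection gates with
margin, so ground truth and detection agree exactly — by design the
generator only plants events the stated rules define as events. Spontaneous
insertions are kept out of the 20 s post-sigh window so their planned label
matches their scored label. The per-epoch rates other than the
recovery-minute distribution are not documented quantities; they are
package choices, configurable per preset.

**The one documented group statistic.** The first-recovery-minute SA count
distributions are the documented group summaries: ctrl 0.3 ± 0.5, ncko_r
3.0 ± 4.7, ncko_a 8.2 ± 5.5 (mean ± SD). Counts are drawn from a negative
binomial matched to mean and variance where overdispersed. The ctrl group
is *not* (variance 0.25 < mean 0.3), so no negative binomial exists for it
and the draw falls back to Poisson — overdispersion holds for the mutant
groups but not, contrary to a naive SD-vs-mean reading, for the control.

**Landmarks.** The skull template is a synthetic midline-plus-bilateral
configuration with plausible adult-mouse proportions (~22 mm); it is a
geometric stand-in, not a digitised specimen, and the shipped measurement
definitions (`inst/extdata/measurements.yaml`) are an editable template —
the geometry engine is exact, anatomical placement is user data.
Between-animal variation for reliability studies is realised as
*per-landmark* Gaussian displacement (10% of configuration scale), not a
global affine: near-straight anatomical angles are first-order invariant
under any linear map (a line and its reverse rotate identically), so an
affine "10% spread" would leave angle measurements with essentially no
between-animal variance and make reliability undefined rather than high.
Per-landmark displacement gives every measurement the intended 10:1
between:within spread against 1% rater jitter. Reliability study angles
should use long-rayed, mid-range angles: with 10% anatomical spread, short
(~3 mm) segments can collapse and near-180° angles fold at the boundary,
both of which distort error propagation (this is a property of the
geometry, not of the estimator).

**What the generators do not emulate**: sleep/wake state and behaviour,
movement artifacts, thermoregulatory dynamics, airway mechanics, drift or
sensor nonlinearity beyond additive Gaussian noise. Passing closure tests
therefore demonstrates correctness of the *rules and equations*, not
robustness to every artifact of real recordings; the segmentation defaults
are validated only against these generators and are fully exposed as
configuration.

## Statistics layer

Standard fits go through base R (`t.test`, `lm`/`aov`, `p.adjust`); the
package authors only what base R lacks:

- **Holm–Šidák step-down**: sort m raw p ascending; adjusted
  $p_{(i)} = \max_{j\le i}\,1-(1-p_{(j)})^{\,m-j+1}$, clipped at 1.
  Hand-oracle: {0.01, 0.03, 0.04} → {0.0297, 0.0591, 0.0591}.
- **Two-way RM-ANOVA** as a split-plot `aov` with the animal as the
  whole-plot error stratum; no sphericity correction is applied (none is
  part of the reproduced convention); post tests are pairwise between-group
  t-tests within each gas condition, Holm–Šidák adjusted over the family.
  Animals with incomplete condition sets are dropped with a message.
- **ICC(3,1)** (two-way mixed, single rater, consistency) from the
  subject/replicate mean squares, with the > 0.9 "excellent reliability"
  flag. This form matches a single fixed rater measuring in triplicate.
- **Metabolite screen**: per-column Student's t at uncorrected p < 0.05 (the
  convention of the screen reproduced); a BH-FDR column is emitted for
  reference but not used for the primary call.
- **Variability metrics** (CV and lag-1 difference SD of cycle duration and
  V_T) are explicitly stand-ins — the original variability statistic is not
  publicly specified.
- **Outlier handling** is config-gated and logged (Tukey fence, default
  Q3 + 3·IQR), never silent, mirroring the reproduced study's ad hoc
  exclusion of one hyperoxia animal as an explicit, auditable rule.

Degenerate inputs are handled explicitly throughout: zero pooled variance
gives t = 0/p = 1 (equal means) or a flagged p → 0 (unequal); empty windows
return flagged NAs, never silent zeros; undefined ratios (V̇E/V̇O2 at
V̇O2 ≤ 0) are NA with a warning.

## Numerical choices

Time is 0-based seconds; epochs and analysis windows are half-open
`[start, end)`. Event-gate comparisons carry a 1e-9 absolute guard so that
sample-grid arithmetic (onsets are integer multiples of 1/200 s) cannot flip
a boundary case by floating-point rounding: a pause of exactly 1 s is an
apnea, a lag of exactly 20 s is a PSA. Text round-trips write 15–17
significant digits, lossless well below the 1e-9 test tolerance. All
generators are bit-deterministic under their seed; derived sub-seeds stay
below 2^31 − 1.

## Problem sizes

Tests and the reproduction script use the desk-scale protocol (12 min of
simulated recording per animal at 200 Hz), 200-animal replicate sets for
distributional recovery, 10,000 null simulations for t-test calibration,
and 6-animal × 3-replicate landmark studies — the sizes at which the checked
quantities (counts, rates, means within 3 SE, ICC) are already stable. The
full 250 min protocol is available via `protocol_epochs("full")`.

## Known limitations

- Central versus obstructive apneas cannot be distinguished from the
  chamber signal alone; no arousal or behavioural-state scoring.
- The segmentation defaults have not been exercised against real
  plethysmograms within this package; treat them as starting points.
- The RM-ANOVA assumes sphericity as implemented (correction available as
  an explicit option through the design, not applied by default).
- The shipped landmark template and measurement definitions are synthetic
  placeholders pending real digitised anatomy.
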