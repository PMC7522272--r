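---
title: "Methods: ocular pulse-waveform analysis and its synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ocular pulse-waveform analysis and its synthetic test world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsfgpwf)
```

## The measurement model

Laser speckle flowgraphy reports relative blood flow as a mean blur rate
(MBR, arbitrary units) map of the optic nerve head, sampled at the device
frame rate over a ~4 s acquisition. Flow at the ONH pulses with the
cardiac cycle, so the analysable object is the beat-averaged waveform of
the region-mean MBR over one cycle. Three regions are analysed: the whole
rectangular ROI (MA), the bright vessel compartment (MV), and the darker
tissue compartment (MT). By construction the MA series is the
pixel-count-weighted mean of MV and MT at every frame — the package treats
this as a testable identity, not an approximation.

## Cardiac-cycle synchronization

`synchronize_cycles()` works in three steps:

1. **Period.** The dominant cardiac period is the smallest autocorrelation
   peak comparable (≥ 80%) to the strongest peak, refined to sub-frame
   precision by parabolic interpolation. A constant or aperiodic series is
   a synchronization error, not a silent zero.
2. **Beat fiducials.** One fiducial per beat is placed where the lightly
   smoothed series crosses the mid-level of its range on the systolic
   upstroke, located by linear interpolation between frames. The upstroke
   is the steepest part of the pulse, so this landmark has the smallest
   timing jitter; minima, by contrast, sit in a flat diastolic trough
   (especially for exponential-fall pulses), where the argmin moves by
   whole frames under small perturbations.
3. **Average and rotate.** Each complete fiducial-to-fiducial segment is
   linearly resampled to `n_out` samples (default N = 30), segments are
   averaged pointwise, and the averaged cycle is rotated to start at its
   minimum — the cycle-onset convention every downstream parameter
   assumes. `F` is the mean beat duration.

The default N = 30 reflects the frames-per-beat scale of LSFG at high
heart rates; all parameters that depend on the grid (t_peak, hence ATI,
RR, FR) are quantized at 1/N of the cycle, which matters when choosing
test tolerances (below).

## Parameter definitions and numerical choices

* **Integration baseline.** All limb areas integrate the waveform against
  y = 0, not against the diastolic minimum, because the S1 definition
  integrates y(t) itself with no offset subtraction.
* **Limb aggregates.** The waveform subdivision names twelve sub-areas but
  only four aggregates enter any formula. The package adopts the only
  identification under which the four formulas are mutually consistent:
  the rising-limb under-curve area and its complement inside the
  `t_peak × MBRmax` rectangle, and the same pair for the falling limb.
  With this choice `RR = 25 × rise_under / rise_above`,
  `FR = 25 × fall_above / fall_under`, and the S2 area
  (`fit integral × FR/25`) returns exactly the falling complement when the
  quadratic fit is exact. The individual sub-areas and the grid lines of
  the original figure are not derivable from any published text and are
  not implemented.
* **S1/S2 via trend line.** Each limb is fitted with a second-order
  polynomial by least squares and the *fitted* polynomial is integrated in
  closed form. On an exactly quadratic limb this reproduces the analytic
  integral to machine precision; the trapezoid rule on the raw samples —
  the independent oracle used in the tests — agrees within its O(h²) bias
  (exactly so on linear limbs). On the gamma-like template the two
  disagree by well under 5% at N ≥ 100 because one parabola cannot follow
  an exponential tail perfectly; that residual is a property of the
  published procedure, not a bug.
* **ATI.** No formula for the acceleration time index is published
  anywhere we could find. The package defines
  `ATI = 100 × t_peak / F` — the conventional acceleration-time
  construction — and documents it as a package definition.
* **BOT conventions.** Samples exactly at the half level count as above
  it; crossings are located by linear interpolation on the closed cycle
  (the onset value is repeated at t = F). A flat cycle (AC = 0) sits at
  its own half level throughout, so `W = F`, `BOT = 100` by documented
  convention. Plateau maxima use the first peak sample for `t_peak`.
* **BOS range.** As printed, the blowout score of a flat wave is 200;
  values above 100 are normal, and the formula is implemented literally.
* **FAI** is the maximum consecutive-frame increment on the normalized
  cycle, in AU/frame; it therefore scales with amplitude and is invariant
  to level shifts — a property the suite tests.

## Segmentation

The device's vessel-segmentation algorithm is proprietary and unpublished;
equivalence with it is neither tested nor claimed. The package thresholds
the time-mean map — Otsu's criterion by default, a top-quantile rule
(default vessel fraction 0.2) as fallback for non-bimodal maps — so masks
are constant across the acquisition, mirroring the single composite-map
segmentation of the device software. Coordinates are 0-based, half-open,
row-major; no physical pixel calibration is assumed because none is
published.

## The synthetic world

The generator's defaults are the modelled study's stated conditions:
10 rabbits, 8 pre-surgery baseline sessions, daily follow-up days 1–28,
4-s acquisitions, heart rate 240 bpm (rabbits beat at 3–5 Hz), frame rate
30 Hz, regime change at day 19. Two waveform families are provided:
*triangular* (every parameter has a closed form — the workhorse of the
tests) and *gamma-like* (power-law rise, exponential fall — a smooth,
physiologically shaped pulse). Both are normalized to minimum
`dc − ac/2` and maximum `dc + ac/2`; for the triangular family the cycle
mean is exactly `dc` in the continuous limit. Pixel noise is additive
i.i.d. Gaussian (default 0.5 AU) — the simplest model that exercises the
averaging chain. The vessel mask is a seeded, procedurally drawn branching
pattern tuned to 10–30% coverage; only the partition matters downstream.

**Longitudinal drift is generated in parameter space.** This is the one
place the package deliberately departs from simulating waveforms all the
way down, for a geometric reason: the six phase-defining parameters are
coupled through any fixed waveform family. For a triangular template, BOT
is identically 50 and FR is proportional to AC/(MBRmax + MBRmin), so an
amplitude decline that raises BOS necessarily drags FR down — yet the VRP
pattern requires FR flat. Likewise BOS falling together with RI (the VEP
pattern) requires growing peak overshoot, outside what a three-number
(min, mean, max) summary can express. Real waveforms achieve these
patterns through higher-order shape changes that no published description
parameterizes. The default generator therefore drifts the parameters
directly — log-linear daily rates per regime, multiplicative session noise
(CV 3%), with the internal identities `BOS = (2 − AC/DC)×100`,
`RI = AC/MBRmax`, `MBRmax = AC/RI`, `W = BOT·F/100` enforced exactly —
and a `level = "timeseries"` mode emits template-generated per-session
MBR series (DC and AC drifting) to drive the synchronize→analyze pipeline
end to end. The time-series mode reproduces the amplitude-driven sign
pattern (BOS up, RI/FAI/AC down, and the published correlation signs) but
not the "FR flat during VRP" clause; a green phase-recovery test therefore
certifies the statistical layer on the parameter-level world, not
waveform-level realism.

Drift magnitudes are not published (only directions and significance), so
the defaults — VRP: AC −2.5%/day at constant DC, RI −2%/day, FAI
−2.5%/day, BOT/FR flat; VEP: DC −3%/day, AC −1%/day, RI −1.5%/day, FAI
−2%/day, BOT/FR −1.5%/day — were chosen once as rates a per-day
significant decline over a 9–19 day window plausibly implies, and are not
tuned thereafter. NBA totals are an affine function of day (default slope
0.5 points/day) plus discrete noise, clamped to 0–19; this reproduces the
reported correlation sign structure without modelling neurology.

## What the tests do and do not establish

* The closed-form suite certifies the PWF formulas exactly; the
  homogeneity and monotonicity properties certify their scaling behaviour.
* The parameter-recovery suite runs the whole chain
  (simulate frames → segment → extract → synchronize → compute) noise-free
  and with 0.5 AU pixel noise. It uses the **gamma-like** template at
  **120 Hz** (30 samples/beat) and compares against the template sampled
  on the same N = 30 normalized grid. Three deliberate choices: a
  triangular corner peak loses up to ~15% of its amplitude to linear
  resampling at coarse rates (a sampling artefact, not an implementation
  error); at the default 30 Hz there are only 7.5 samples per beat, below
  what any beat-averaging method can resolve against a 2/N tolerance; and
  peak-time grid quantization is definitional for t_peak-derived
  parameters, so it must affect reference and measurement equally.
* Phase and sign recovery (200 seeds) and the Monte-Carlo calibration of
  the repeated-measures test and the regression F test (500 replicates,
  null rejection within [0.03, 0.07]) certify the statistical layer at the
  generator's default effect sizes.
* Nothing here validates against real LSFG hardware, real rabbit data, or
  the device's proprietary segmentation — no such data are public.

## Statistical conventions

The published analysis names its tests but not its gates. Package
defaults, documented rather than discovered: Shapiro–Wilk at α = 0.05
decides RM-ANOVA vs Friedman (on the additive-model residuals) and
Pearson vs Spearman (on each margin); Mauchly's test at α = 0.05 triggers
Greenhouse–Geisser correction of the RM-ANOVA degrees of freedom; outliers
are removed by Tukey fences (1.5 IQR, type-7 quartiles) with the rule
skipped below n = 4; no multiple-testing correction is applied, matching
the published α = 0.05 convention. `classify_phase()` operates on
baseline-normalized series over user-chosen windows — the day-19
changeover is an empirical observation of the modelled study, not an
algorithmic constant — and "BOT/FR not down" during VRP encodes the
published wording "no changes", since strict flatness is untestable.

## Known limitations

* The synchronizer assumes a steady rhythm; ectopic beats are averaged in,
  not rejected.
* MBR is generated directly; no speckle statistics are simulated.
* The item-level NBA decomposition used by the pipeline distributes totals
  across rubric items arbitrarily (any decomposition re-scores to the same
  total); it exercises the scoring plumbing, not behaviour.
* Published group-level tables cannot be reproduced numerically because
  the underlying per-animal data are not public; the package substitutes
  sign-pattern and calibration criteria on the synthetic world, as stated
  above.
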