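---
title: "Measuring time to occlude on a thrombosis chip: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring time to occlude on a thrombosis chip: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thromboFlow)
```

## The assay

Occlusive thrombosis-on-a-chip assays perfuse recalcified whole blood over a
collagen/tissue-factor patch inside a PDMS microchannel at arteriolar wall
shear (1000 s⁻¹) and ask one primary question: how long until the growing
platelet–fibrin thrombus stops bulk flow? In a single straight channel fed by
a syringe pump the question has no answer — the pump forces flow through, the
pressure across the clot rises, and the clot embolizes. A bifurcated
"pressure-relief" design lets the parallel arm accept the diverted flow, so
the patch arm can occlude stably. Two complications make the raw endpoint
unreliable: microscopy-based calls of "flow stopped" are subjective (cells
keep permeating the clot after bulk flow ceases), and coagulation can spread
downstream of the patch ("off-site") and block the channel for reasons
unrelated to platelet activation. The assay therefore (i) measures flow
gravimetrically — the waste tubing drips into a vessel on a balance — and
(ii) quenches downstream coagulation with an EDTA co-flow where the chamber
width doubles.

thromboFlow implements the complete quantitative machinery of this assay:
the shear/flow design arithmetic, the balance-log → flow → occlusion-call
chain, confocal-stack quantification, the repeated-measures group
statistics, and a hydraulic simulator that generates synthetic experiments
with known ground truth so that every stage is testable without blood.

## Flow design

For a wide rectangular slot (height H ≤ width W, both mm) carrying Q mL/min,
the wall shear rate is

$$\dot\gamma = \frac{100\,Q}{H^2 W}\ \mathrm{s}^{-1},$$

the parallel-plate result $\dot\gamma = 6Q/(wh^2)$ after converting mL/min to
mm³/s (100 = 6·1000/60). The formula is applied as a design rule, without
aspect-ratio correction — the correction belongs to the simulator's
resistance model, not to the pump setting. Three consequences used
throughout:

* the reference device (H = 70 µm, W = 500 µm) needs `r
  pumpFlowForShear(channelGeometry(), 1000)` mL/min for 1000 s⁻¹;
* with two parallel arms the programmed pump flow doubles;
* where the chamber width doubles at the quench inlet, adding a quench flow
  equal to the per-arm blood flow keeps the shear uniform
  (`quenchFlowForUniformShear()` handles partial widenings too).

Device fabrication targets a 65–70 µm depth; the package default is 70 µm,
the value consistent with the 0.0245 mL/min design flow, and a 65 µm
geometry is accepted anywhere a `ChannelGeometry` is. The recalcification
buffer joins at 1:9 buffer:blood (`coagBufferFlow()`); it is a design
quantity only — the simulator's inlet flow is the programmed pump flow.

## Gravimetric flow and the occlusion call

The balance records cumulative mass every 5 s from the moment blood enters
the device; the first reading (tubing weight) is subtracted (`tare()`), mass
becomes volume at 1 g = 1/1.06 mL, and flow is the time derivative.
`estimateFlow()` smooths the volume series with a centered moving average
(default 30 s ≈ 7 samples; rounded to an odd sample count; one sample
disables smoothing) and differentiates with central differences, one-sided
at the edges. Negative estimates are kept: they mean "no forward flow", and
clipping them would bias the detector.

`detectOcclusion()` applies the occlusion definition — flow strictly below
0.001 mL/min maintained for at least 3 min — as a run-length scan over
consecutive below-threshold samples, a run qualifying when its last-minus-
first timestamp reaches the dwell (robust to slightly irregular sampling). A
run truncated by the end of the trace counts only if it already spans the
dwell. Two conventions are deliberate and recorded in the output:

* **Occlusion time is the start of the first qualifying run**, not the
  instant the 3-min dwell completes: "time to occlude" means when flow
  ceased; the dwell only confirms that it stayed ceased.
* **Channels that never qualify are censored at 40 min**
  (`censoredTime()`), a fixed-value substitution (not survival analysis)
  that feeds the rank-based group comparison. The 40-min value exceeds the
  30-min run length by design; the package requires only censor ≥ duration.

### Detection limits

Differentiation amplifies balance noise. With iid reading noise of standard
deviation σ grams, the default pipeline (7-sample moving average, central
differences at 5-s spacing) yields a flow-estimate noise of about
$\sigma_f \approx 12\,\sigma/(1.06\,n_w)$ mL/min for an $n_w$-sample window
— ≈ 0.0003 mL/min at σ = 0.2 mg (analytical-balance repeatability, the
package's default read noise) but ≈ 0.0032 mL/min at σ = 2 mg. Since the
occlusion threshold is 0.001 mL/min, a 2 mg balance cannot support the
per-sample dwell criterion at all: each post-occlusion sample is below
threshold with probability ≈ 0.62, and an unbroken 37-sample run essentially
never occurs, so occlusion goes undetected regardless of how long the trace
is. This is a genuine detection limit of the published criterion, not an
implementation artifact; the acceptance suite demonstrates it at σ = 2 mg.
Practical use of the method needs a balance resolving ≲ 0.5 mg, which the
assay implicitly assumes anyway (its per-sample mass increments are ~2 mg).
At the 0.2 mg default, detection is reliable but the detected time still
scatters by a minute or two around the truth, because near the crossing the
true flow sits within a few noise standard deviations of the threshold.

## Image quantification

Stacks are 19 slices at 5 µm covering the 70 µm channel depth, one stack per
channel (platelet: DiOC₆-type label; fibrin: labelled fibrinogen) every
2 min. `maxIntensityProjection()` takes the per-pixel maximum across slices;
`integratedDensity()` is the raw pixel sum of the projection — no background
subtraction and no mean-times-area, matching how the original measurement is
made in Fiji; `accumulationCurves()` applies both per frame and channel, and
`endpointValue()` takes the value at the latest timepoint at or before
30 min. Channels are processed independently (acquisition alternates lasers
slice by slice, but analysis never mixes them). Input may be 8- or 16-bit
integer or floating point; sums accumulate in double precision, so a
16-bit 4096×4096 frame is still exact. Bit depth and background handling
are stated choices — the source assay specifies neither.

## Group statistics

Endpoints arrive as complete blocks: every donor contributes every
condition exactly once, with run order balanced across experimental days
(recorded as a covariate column, never modelled). Two comparisons:

* `rmAnova2x2()` — two-way fully within-subject ANOVA on the 30-min
  integrated densities over quench × treatment, each effect tested against
  its effect-by-donor stratum. With 2-level factors every effect has 1 df,
  so no sphericity correction exists to apply; that is exact, not an
  approximation. Tukey-adjusted pairwise contrasts among the four cells come
  from the estimated marginal means (via emmeans). An effect whose sum of
  squares is exactly zero (all values identical; perfectly additive data for
  the interaction) is reported as F = 0, p = 1 rather than the indeterminate
  0/0 of the classical formula.
* `friedmanDunn()` — Friedman's test on within-donor ranks of the censored
  occlusion times (average ranks for ties, which the 40-min censor
  guarantees; fully tied tables report χ² = 0, p = 1), followed by Dunn's
  z-comparisons of mean ranks, $z = (\bar R_i - \bar R_j)/\sqrt{k(k+1)/(6n)}$.
  The multiplicity adjustment inside Dunn's test is not specified by the
  assay's description; the package defaults to Holm — uniformly more
  powerful than Bonferroni at the same familywise error — and any
  `p.adjust` method is selectable.

Fixed-value censoring is used exactly as the assay defines it; survival
estimators (Kaplan–Meier, log-rank) are out of scope by design.

## The simulator

No hydraulic or growth equations are published for this assay, so the
generator is the minimal lumped-parameter model consistent with the
described mechanics; every constant lives in `SimConfig` and the important
ones are listed here.

**Network.** A constant-flow inlet (syringe pump) feeds one or two parallel
paths, each an arm plus its waste tubing, all outlets at atmospheric
pressure. Baseline arm resistance follows the rectangular-slot law
$R \propto \mu L / (W H^3 (1 - 0.63 H/W))$ (≈ 45 kPa·min/mL for the
reference arm at µ = 3.5 mPa·s, a plausible whole-blood value at arteriolar
shear). Tubing resistance defaults to one baseline arm. Flows split by
conductance (`flowSplit()`), conserving the inlet flow exactly.

**Thrombus as a resistance.** The patch occupies 20% of the arm length; a
thrombus occluding fraction f of the gap multiplies that segment's
resistance by $(1-f)^{-3}$ (the cubic slot law, with the aspect correction
held at baseline), capped at 10⁶× so the network stays finite
(`armResistance()`).

**Growth.** f follows logistic growth, $df = r(1-\text{drug})f(1-f)\,dt$,
seeded at f₀ = 0.01, active while local flow is positive; `drugEffect` is a
fractional inhibition of this platelet-driven rate, emulating graded
integrin-αIIbβ3 blockade. Off-site coagulation g grows logistically on the
monitored arm's tubing with a feed-forward acceleration
$(1 + \kappa(1 - Q/Q_0))$, κ = 2 — falling flow promotes coagulation —
and is active only in the unquenched pressure-relief scenario. (A literal
reading would also activate it in the single channel, but that regime is
defined by embolism with flow never ceasing, so off-site blockage is gated
off there.) The platelet fluorescence signal tracks f; the fibrin signal
relaxes to min(1, f+g) with a 0.3 min⁻¹ first-order lag.

**Rates.** The defaults r = 0.5 min⁻¹ and r_off = 0.35 min⁻¹ were
calibrated once so that the control pressure-relief device occludes in
10–20 min (the published regime: all control devices within 20 min) and the
unquenched drug-treated device occludes with only a minor delay relative to
its control, driven off-site. A per-run lognormal jitter (sd 0.1) on both
rates plays the role of donor-to-donor variability; it is drawn first from
the run's seed, so the same seed at different drug doses represents the same
donor — exactly the pairing structure of the real repeated-measures design.

**Embolism.** Single-channel runs carry a lumped compliance (0.005 mL/kPa)
between pump and chip, so measured outlet flow can dip below the pump rate
while pressure builds and spike after the clot detaches. Detachment is a
deterministic threshold on the excess patch pressure drop Q·(R(f)−R(0))
(default 5 kPa, ≈ 4.5× the baseline drop, with seeded 10% jitter per run),
after which f resets to f₀. The result is the published single-channel
phenotype: unstable flow with large swings, at least one embolism in 30 min,
and never a qualifying occlusion.

**Measurement synthesis.** The monitored-outlet flow is integrated
(trapezoid, fine grid) to volume, converted at 1.06 g/mL, offset by the
tubing weight (2.5 g), sampled every 5 s and given iid Gaussian reading
noise (default σ = 0.2 mg, analytical-balance repeatability; the 2 mg
stress case is discussed above). Image stacks are generated every 2 min:
the thrombus is an ellipsoidal cap on the channel floor whose volume scales
with the channel signal, filled at constant voxel intensity
`round(intensityScale × signal)` plus Gaussian read noise (sd 20 counts),
clipped to 16 bits. The analytic integrated density of the projection —
voxel intensity × footprint pixel count — is stored alongside as ground
truth, and with zero noise the measured curve equals it exactly. The default
frame is 36 × 46 px at 20 µm/px (a downsampled 10× field of view), which
keeps a 30-min two-channel series around 8 MB.

**Numerics.** Fixed-step explicit integration at dt = 0.5 s. The only stiff
region is the final approach to occlusion, which the resistance cap bounds;
the test suite verifies first-order convergence of the growth update by step
halving, with the Richardson-extrapolated value matching the closed-form
logistic to 10⁻⁶. The true occlusion time of a run is defined as the
detector's verdict on the noise-free 5-s flow samples, so detector-recovery
comparisons are free of convention mismatches.

## What the simulator does and does not establish

The generator reproduces the *regimes* of the real assay: pressure-relief
occlusion in 10–20 min, embolism without occlusion in single channels,
off-site occlusion masking drug effect in unquenched devices, no occlusion
under quench + full platelet inhibition, dose-monotone delay of occlusion.
Passing tests therefore show the analysis chain is correct and the detector
recovers known truths under realistic noise. They do not validate the
biology: real thrombi are heterogeneous, non-ellipsoidal and porous; blood
is non-Newtonian; balances drift and evaporate; fibrin spreads spatially
rather than as a lumped fraction; donor variability is richer than a
lognormal rate multiplier. Conclusions about real devices still require
real blood.

## Problem sizes used by the checks

The packaged checks use 200 seeded runs for detector recovery, 6 donors per
cell for the 2×2 quench-by-drug comparison, 20 seeds per level for the
four-dose monotonicity property, and hundreds of randomized cases for the
projection/scan oracle equivalences — sizes chosen to make the stochastic
properties stable (binomial error well inside the asserted margins) while a
full suite run stays in the tens of seconds.

## Known limitations

* The 0.001 mL/min × 3 min criterion is unusable at balance noise ≳ 1 mg
  (see *Detection limits*); the package reports the criterion faithfully
  rather than silently rescuing it.
* The occlusion-time convention (start versus completion of the dwell) and
  the smoothing window are not specified by the assay description; both are
  configurable, defaulted as above, and echoed in every output summary.
* The hydraulic model is quasi-static for bifurcated devices; compliance is
  modelled only where it is load-bearing (single-channel embolism).
* `rmAnova2x2()` is exact only for the 2×2 within-subject design; larger
  factorial designs would need sphericity handling that the package does
  not implement.
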