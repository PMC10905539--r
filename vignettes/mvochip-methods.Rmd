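---
title: "Quantifying drug delivery around microthrombi in a chip model of microvascular obstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug delivery around microthrombi in a chip model of microvascular obstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvochip)
```

## The problem

Microvascular obstruction (MVO) is the blockage of the coronary
microcirculation by microthrombi (MT, clot fragments of roughly 200 µm)
after a myocardial infarction has been treated by catheter intervention.
Because the affected vessels are 50–500 µm wide, drugs infused into the
coronary artery may never reach the thrombi: open neighbouring branches
carry the infusate away. A proposed remedy is *balloon occlusion-infusion* —
inflating a balloon proximal to the microvascular bed during the infusion so
the drug is neither diluted nor washed out.

`mvochip` implements, end to end, the image-analysis pipeline used to
quantify this effect on a backlit microfluidic chip that models four
generations of the arteriolar tree, together with a synthetic-experiment
generator (network flow, dye transport, camera model, ground truth) against
which every stage of the pipeline is validated. The bench videos themselves
are not publicly deposited, so all quantitative validation in this package
is against the generator.

## The measurement pipeline

For every recorded experiment (180 s at 10 Hz, starting 10 s before the
infusion) the pipeline:

1. **extracts the channel area** — from the known chip layout, or by
   thresholding the mean pre-infusion frame;
2. **inverts per-pixel calibration curves** — piecewise-linear monotone maps
   from log-intensity (optical density) to dye concentration, fitted per
   pixel from frames of the clean chip filled with known uniform dye levels
   (0, 0.25, 0.5, 0.75, 1). Interpolating in the OD domain, as in any
   absorbance calibration, is exact for exponential attenuation; an
   intensity-domain chord would read systematically high between knots (up
   to +1.5%), enough to push borderline no-contact thrombi across the 20%
   threshold. Concentrations are clamped to [0, 1]. Pixels with a
   non-monotone response, or with a full-scale response span below 8% of
   their clean intensity (the extreme channel edge, where the optical path
   vanishes), are excluded as uncalibratable — and the generator's
   effective-truth classification restricts itself to the same measurable
   pixel domain;
3. **detects microthrombi** — channel pixels whose mean pre-infusion
   intensity deviates from the clean-chip reference by more than 30%,
   grouped by 8-connectivity, components of at least 4 px kept;
4. **builds an annulus ROI per thrombus** — Euclidean dilation of the
   footprint by 16 px (ca. 240 µm) minus dilation by 5 px (ca. 75 µm),
   intersected with the channel mask; the 16 px radius corresponds to the
   diffusion length over which a one-minute balloon hold reduces a 20%
   boundary concentration by a factor of 4 (`diffusion_penetration()`), and
   the 5 px gap guards against small thrombus movements. Dilation uses the
   Euclidean metric ("enlarged in all directions"); a Chebyshev square
   would inflate diagonals by 41%;
5. **computes dose metrics** — the ROI concentration `c(t)` is the mean over
   annulus pixels, low-pass filtered with a moving average one heartbeat
   wide (`round(10 Hz × 60 / 69 bpm) = 9` frames) to remove pulsatility;
   the cumulated dose is `D(t) = ∫ c dt′` (trapezoidal), and the headline
   metrics are `c_max = max_t c(t)` and `D_final = D(180 s)`;
6. **classifies each thrombus** — a thrombus *segment* is *occlusive* if
   every pixel of every distal segment stays strictly below 20%
   concentration at all times (for a leaf, the leaf's own pixels distal to
   the footprint decide). A thrombus is *nonocclusive* / *fully occlusive* /
   *semiocclusive* if none / all / some of its segments are occlusive.
   *Contact* is reached when any pixel of the 1-px edge band touches 20%
   (non-strict ≥); *diffusion range* when only the annulus does; otherwise
   *no contact*.

Smoothing acts on the ROI-mean series for dose metrics, and on each pixel's
series (same window) for the threshold classifications, so that "ever
≥ 20%" is evaluated on pulsatility-free signals in both places.

## The synthetic experiment generator

### Chip geometry

`build_symmetric_tree()` embeds two mirror-symmetric strict binary trees —
one per inlet — of Strahler-type orders 8 → 5 in a 256 × 512 raster at
15 µm/px. Only the diameter range (555 µm inlet down to 50–100 µm leaves)
is fixed by the chip design; per-generation lengths are not printed
anywhere, so the defaults (1500/1200/750/525 µm for orders 8/7/6/5, with
diameters 555/300/180/80 µm) were chosen once to respect those bounds and
the raster, and are configurable. Junction pixels belong to the
higher-order (wider) channel, which makes label maps deterministic; the
right tree is rasterized by mirroring the left tree's pixel sets, so the
raster is exactly symmetric.

### Perfusion

Lumped Poiseuille flow: each segment is a hydraulic resistor
`R = 128 µ L / (π d⁴)` (viscosity default 3.4 mPa·s, a 40% glycerol
blood-mimicking fluid), each leaf is terminated by a distal resistor, and
the nodal pressures solve the linear conductance system with the inlet at
the mean driving pressure of a 52/82 mmHg, 69 bpm pulse. The distal
resistors are tuned — as on the bench, where a static resistor was closed
until the chip carried 2% of the 30 mL/min infusion — by root finding until
the unobstructed chip flow is 0.6 mL/min. Occluded segments have zero
conductance (their subtree relaxes to a zero-flow state); channels narrowed
by a permeable thrombus carry a ×100 residual-lumen resistance multiplier.

Pulsatility enters as a multiplicative factor `p(t)/p̄` on all flows (the
network is linear), and the distal RC compliance elements are represented
by a zero-mean oscillatory leaf flow at the heart rate with amplitude 0.8 ×
the leaf's mean flow. A fully occluded subtree carries no base flow and
therefore no compliance flow — the same "compliance vanishes if a channel
is blocked" behaviour as the rigid bench chip. Oscillatory outflow that
re-enters at a leaf returns at the leaf's own concentration (a Stokes-flow
reversibility argument: pure oscillation transports no net mass).

### Dye transport

1-D finite-volume advection–diffusion along the centerlines (control
volumes of 75 µm, explicit upwind stepping at 0.9 of the CFL bound,
implemented in C++), with flow-weighted mixing at junctions by upwind
donors. The dye diffusivity is not stated for the bench dye; the default
5×10⁻¹⁰ m²/s is the small-molecule-in-water order of magnitude and is a
configurable, surfaced parameter. Occlusive thrombus faces carry no flux at
all; permeable thrombus segments keep their (reduced) advective flow and a
0.3 diffusive permeability. First-order upwinding adds numerical diffusion
proportional to the local velocity; in stagnant dead-end branches — exactly
where diffusive penetration matters for classification — the advective flux
is zero and only molecular diffusion acts, so the 20%-threshold physics is
not polluted by scheme diffusion.

Mass is accounted exactly: inflow minus outflow matches the dye resident in
the network to well below 1%.

### Protocol timeline

The balloon case switches the inlet to the controlled infusion (steady
0.6 mL/min, inlet concentration 1) for 30 s, holds the balloon for another
60 s (stagnant flow; dye diffuses), then resumes pulsatile washout.
The no-balloon case keeps pulsatile coronary flow throughout; during the
infusion the inlet concentration is the infusion diluted by coronary flow,
`Q_Inf/(Q_Inf + Q_cor) = 0.5` (the coronary model flow implied by the chip
carrying 2% = 0.6 mL/min is 30 mL/min), and the chip flow rises
proportionally. This dilution rule is a modeling choice (the bench protocol
does not state one) and is surfaced in the flow-boundary configuration.

### Microthrombus placement and ground truth

Lodging sites are sampled with weight `diameter^-2` (debris lodges in small
distal channels) and a thrombus straddles a bifurcation with probability
0.76. A junction thrombus is anchored a little inside a daughter channel so
its 200 µm disk footprint covers parent- and daughter-labelled pixels — a
200 µm thrombus cannot straddle the 555 µm inlet mouth, and the chip offers
only 12 junctions it can straddle, so at the default load of 14 MT per chip
junction sites can saturate and the realized bifurcation fraction falls
slightly below the target (sparse cohorts recover it exactly).

Occlusivity ground truth is drawn class-first: each thrombus is
nonocclusive / semiocclusive / fully occlusive with probabilities
0.27/0.28/0.45 (the observed cohort composition), with per-segment flags
assigned consistently — any occluded channel must be no wider than the
thrombus itself, and a semiocclusive thrombus blocks exactly one daughter
channel of the junction it straddles, keeping the parent and at least one
daughter open. The last constraint makes the flag set semantically
consistent with the concentration rule: blocking every daughter would
darken the open parent's whole distal subtree, and the thrombus would
measure fully occlusive despite its mixed flags. Semiocclusive thrombi therefore
sit at bifurcations, and the junction probability of the other classes is
adjusted so the overall bifurcation fraction still meets the target. A
geometric alternative (`occlusivity = "geometry"`: occlusive iff the
thrombus covers the channel width) is available.

The default load of ~14 MT per experiment reproduces the observed mean
(282 MT over 20 experiments).

**Two truth layers.** The generator records the *mechanical* truth (which
segments each thrombus physically blocks) and the *effective* truth — the
occlusivity/contact classification computed from the true, noise-free
concentration field by the same classifiers the pipeline uses. The two
differ systematically at realistic thrombus densities: an occlusive
thrombus upstream of another thrombus shadows it (no dye arrives at all,
so everything there measures fully occlusive and no-contact). That is a
property of perfusion physics, not of the measurement, and a
concentration-based classification — the bench one included — cannot see
past it. Pipeline validation therefore scores the frames → calibration →
classification route against the effective truth (a genuine dual route:
camera model and calibration inversion on one side, direct field access on
the other), while parameter-recovery checks use sparsely seeded chips
(4 MT), and estimate the class mix only over thrombi whose feed path is not
blocked by another thrombus (`shadowed_thrombi()`): the occlusivity class
of a thrombus that no dye can reach is unobservable to any
concentration-based measurement, so shadowed thrombi — about one in ten
even at sparse seeding — are excluded from the rate estimate (the drawn
class composition itself is checked unconditionally).

### Camera model

Beer–Lambert attenuation through the circular channel:
`I = I₀·10^(−OD)`, `OD = OD_full · c · ℓ/ℓ_ref` with `ℓ` the chord of the
lumen at the pixel's radial offset and `OD_full = 1.2` at full dye through
the 555 µm reference chord. Thrombus pixels transmit 3% of the backlight.
Additive Gaussian noise (σ = 0.5% of `I₀`) and 16-bit quantization complete
the model. No motion, drift, or flat-field error is simulated — the bench
camera is rigidly mounted — so registration is identity and passing tests
say nothing about motion robustness on real videos.

## Numerical choices

* Quartiles: linear interpolation between order statistics
  (`quantile(type = 7)`); no convention is stated for the published table.
* Percent changes are reported raw and half-away-from-zero rounded (57.5
  prints as 58).
* Moving-average edges use shrinking windows so `c_max` near the end of the
  recording remains defined; the integral of a smoothed series then matches
  the raw integral to within `w·max|c|/frame_rate`.
* Trapezoidal dose integration starts at the first frame (−10 s) and ends
  at the last (169.9 s); a constant c = 0.5 gives `D_final = 89.95 s`.
* The inlet-occluded degenerate case returns a zero-flow state rather than
  an error; fully isolated nodes are dropped from the nodal solve, keeping
  the conductance matrix well conditioned without a regularization leak.
* Thresholds are applied with the stated strictness: occlusivity uses
  `< 20%` (a pixel exactly at 0.20 makes a segment nonocclusive), contact
  uses `≥ 20%`.
* Determinism: one master seed per experiment splits into independent
  substreams for placement, occlusivity and camera noise, so paired
  balloon/no-balloon runs share their MVO configuration bit for bit.

## Problem sizes used in validation

The validation suite runs the full protocol geometry (256 × 512 raster,
1800 frames): classification and parameter recovery on 25 sparsely seeded
chips (100 MT), and the paired balloon/no-balloon comparison on 10
cohorts of 14 MT with camera noise. These sizes give binomial confidence
intervals of roughly ±10 percentage points on recovered fractions; they
were chosen as the smallest cohorts that make the 95%-recovery and
CI-coverage statements meaningful.

## Known limitations

* The chip geometry is a parameterized stand-in for the fabricated layout,
  not a digitization of it; per-generation lengths are assumptions.
* Pharmacokinetics are deliberately absent: higher `c_max` and `D_final`
  are taken as better delivery, exactly as in the bench analysis.
* The transport model is 1-D per channel; radial concentration gradients
  within a lumen are not represented (the camera model re-introduces the
  chord-length weighting optically).
* The residual-lumen parameters of permeable thrombi (×100 hydraulic,
  0.3 diffusive) are plausible but unmeasured.
* At default density the generator slightly under-realizes the 0.76
  bifurcation fraction because junction sites saturate (see above).
* Thrombus washout/movement during a run is not simulated; the 5-px ROI
  gap exists for the bench case, not the synthetic one.
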