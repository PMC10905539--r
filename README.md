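# mvochip

Quantifies catheter-based drug delivery around microthrombi in a
microfluidic model of cardiac **microvascular obstruction (MVO)** — the
blockage of 50–500 µm coronary vessels by clot fragments (microthrombi,
MT, ~200 µm) after myocardial infarction. The package is written for
researchers studying occlusion-infusion catheter therapy on backlit
microfluidic chips: it turns grayscale video of dye infusions into
per-thrombus dose metrics and classifications, and ships a full synthetic
experiment generator (network flow + dye transport + camera model with
ground truth) against which every pipeline stage is validated.

## The measurement

For each microthrombus detected in the pre-infusion frames, the pipeline
builds an annulus region of interest — the footprint dilated by 16 px
(ca. 240 µm, the one-minute diffusion length) minus a 5 px (ca. 75 µm)
guard gap, an annulus ca. 165 µm wide — and computes, from per-pixel
calibrated dye concentrations smoothed over one heartbeat,

* `c(t)` — mean ROI concentration per frame,
* `D(t) = ∫₀ᵗ c dt′` — cumulated dose (seconds of full-strength exposure),
* `c_max = max_t c(t)` and `D_final = D(180 s)`,

plus two classifications with a 20% concentration threshold:

* **occlusivity** — a thrombus segment is *occlusive* if all pixels distal
  to it stay `< 20%` at all times; a thrombus is *nonocclusive* /
  *semiocclusive* / *fully occlusive* if none / some / all of its segments
  are occlusive;
* **contact** — *contact* if the thrombus edge reaches `≥ 20%`,
  *diffusion range* if only the annulus does, *no contact* otherwise.

Balloon vs. no-balloon infusion protocols are compared as paired cohorts
(same thrombus configuration, different inlet boundary).

## Worked example

```r
library(mvochip)

layout  <- build_symmetric_tree()          # 2 mirror trees, orders 8..5
maps    <- rasterize_layout(layout)        # 256 x 512 raster at 15 um/px
thrombi <- place_microthrombi(layout, maps, n = 14, rng_seed = 7)

sim <- run_protocol(layout, maps, thrombi,
                    protocol_config("balloon", seed = 7))   # 1800 frames
an  <- analyze_experiment(sim$frames, sim$calibration, layout, maps)
head(an$table[, c("id", "n_segments", "occlusivity", "contact", "c_max", "D_final_s")])
```

```
  id n_segments     occlusivity         contact      c_max D_final_s
1  1          3    nonocclusive         contact 0.96805478 87.579973
2  2          3    nonocclusive         contact 0.99165496 89.876906
3  3          3 fully_occlusive      no_contact 0.09894350  6.892751
4  4          3   semiocclusive         contact 0.76678861 69.503934
5  5          1 fully_occlusive      no_contact 0.01798116  1.953641
6  6          1 fully_occlusive diffusion_range 0.74246548 67.971412
```

Rows 1–2 are thrombi beside open channels: the balloon holds full-strength
dye at them for ~90 s of cumulated dose (`D_final` near its ceiling).
Row 3 blocks all three of its channels — dye never reaches 20% anywhere in
its annulus, the no-contact situation a balloon cannot fix. Row 4 is
semiocclusive: its open branch carries dye to the thrombus edge (contact,
`c_max` 0.77) while the blocked branch keeps the distal bed dark. Scoring
these labels against the generator's field-oracle ground truth:

```r
score <- score_classification(an, sim$truth)
mean(score$occlusivity_match); mean(score$contact_match)
#> [1] 1
#> [1] 1
```

The numbered drivers under `analysis/` run the same machinery as a
workflow: `01_simulate.R` (paired recordings + ground truth),
`02_analyze.R` (per-thrombus CSV + recovery report), `03_cohort_report.R`
(cohort quartile table, fraction tables, balloon-vs-no-balloon comparison,
occurrence heatmap), writing their tables under `results/`.

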