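# necroscope

Label-free discrimination of apoptosis from oncosis by quantitative phase
imaging (QPI), with a flow-cytometry arm for cross-validation.

## The problem

The annexin V / propidium iodide (PI) assay is the workhorse of cell-death
typing, but it cannot tell early apoptosis from oncosis: oncotic cells —
swollen, blebbing, ATP-depleted, and potentially still rescuable — can
externalise phosphatidylserine with an intact membrane and therefore land
in the same annexin V+/PI− quadrant as apoptotic cells. Morphology
disambiguates: apoptotic cells shrink and fragment into apoptotic bodies;
oncotic cells swell and bleb. Off-axis holographic microscopy measures
per-pixel optical path delay φ (radians), which is directly proportional
to dry-mass surface density, so a time-lapse of phase images yields each
cell's footprint area and dry mass

    m = κ · Σ φ(x, y),   κ = 0.05 / 0.21 pg/(rad·px)

(the calibration pinned by the segmentation threshold pair: τ = 0.21 rad ≡
0.05 pg/pixel). Cells are classified by the median relative area A_t/A_0
over the final quarter of the monitoring window: **increase** (≥ 1.20,
oncotic track), **decrease** (≤ 0.80, apoptotic track), or **no change**.
The cohort split is then compared against annexin V/PI quadrant counts
with a Pearson χ² on the 2×3 contingency table, with an optional
"adjusted-for-oncosis" mapping that uses FSC back-gating to split the
annexin+/PI− population into small (apoptotic) and large (oncotic) cells.

The package implements the full chain, plus a first-class synthetic-data
generator (phase phantoms with known dry mass and fate, rendered to
off-axis holograms; class-conditional cytometry events) that stands in
for the unavailable microscope and cytometer raw data:

| module | exported entry points |
|---|---|
| phantoms | `phantom_spec()`, `make_cell_phantom()`, `simulate_timelapse_cohort()`, `render_hologram()`, `simulate_fcm_events()` |
| recon | `estimate_carrier()`, `demodulate()`, `unwrap_phase()`, `flatten_background()`, `simulated_dic()`, `reconstruct_phase()` |
| quant | `calibration()`, `phase_to_mass_density()`, `segment_cells()`, `split_touching()`, `measure_cells()` |
| track | `link_tracks()`, `classify_trajectory()`, `cohort_summary()` |
| cyto | `fit_quadrant_gates()`, `quadrant_counts()`, `backgate_fsc_split()`, `map_to_size_classes()`, `chi2_compare()` |
| staging | `oncosis_features()`, `stage_oncosis()`, `stage_cohort()` |
| cli | `run_pipeline()`, `analyze_cohort()`, `inst/cli/necroscope` |

## Worked example

```r
library(necroscope)

# a 9-cell synthetic time-lapse (44/32/24% unchanged/swelling/shrinking),
# rendered to off-axis holograms and pushed through the full chain
spec   <- phantom_spec(cell_count = 9, n_frames = 20, seed = 7)
cohort <- simulate_timelapse_cohort(spec)
res    <- analyze_cohort(cohort)

round(res$summary$fractions, 1)
#> no_change  increase  decrease
#>      44.4      33.3      22.2
res$summary$mass_stable_fraction        # % of cells with < 7% mass drift
#> [1] 100
round(res$summary$mass_ratio_decrease_vs_rest, 2)
#> [1] 1.17

# morphology vs flow cytometry, 2x3 contingency
cmp <- chi2_compare(c(44, 32, 24), c(61, 8, 31))
round(cmp$chi2, 3); cmp$df; signif(cmp$p, 2)
#> [1] 18.043
#> [1] 2
#> [1] 0.00012
```

The 9-cell cohort (4/3/2 cells by largest-remainder apportionment) is
classified perfectly — 44.4/33.3/22.2% — every cell's measured dry mass
stays within 7% of its start (the generator conserves mass by
construction, so this measures pipeline accuracy), and the shrinking
cells are measured ~1.2-fold heavier, recovering the generator's 1.3×
draw within small-sample noise. The χ² of 18.04 (p ≈ 1e-4) quantifies
how strongly plain quadrant counts disagree with morphology.

The same workflow runs file-to-file from one YAML config
(`run_pipeline()`: holograms as multi-page float32 TIFF, measurements as
CSV, summaries as YAML) or from the command line via
`inst/cli/necroscope` (subcommands `simulate`, `reconstruct`, `quantify`,
`classify`, `fcm-gate`, `compare`, `stage`, `run`).

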