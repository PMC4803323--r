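# neuroquant

Quantitative multimodal MRI for the preclinical mouse brain, as one tested
R pipeline. The package is written for imaging scientists who acquire
arterial spin labeling (ASL), multi-echo gradient-echo and diffusion-weighted
series in rodent models of neurodegeneration — for example dopamine-deficient
MitoPark mice versus wild-type littermates — and need the chain from raw 4-D
series to an FDR-corrected group table to be reproducible and testable.

## What it computes

**Cerebral blood flow.** An interleaved control/label ASL series is split,
frame-averaged, and quantified voxelwise with the single-compartment model

    CBF = 60 · (λ / T1) · (S_c − S_L) / (S_c + (2α − 1) · S_L)   [mL/g/min]

with λ = 0.9 mL/g (water tissue–blood partition coefficient), T1 = 1.8 s and
labeling efficiency α = 0.75 by default.

**T2\* relaxometry.** Voxelwise ordinary least squares on
`ln S_i = ln S_0 − TE_i / T2*` over the echo train (default five echoes,
2.4 ms first TE, 3.3 ms spacing); `T2* = −1/slope`.

**Diffusion tensor, ADC and FA.** Log-linear least squares for the six
tensor elements from one b = 0 plus n ≥ 6 diffusion-weighted volumes
(default b = 1200 s/mm², 30 directions), then from the sorted eigenvalues
λ₁ ≥ λ₂ ≥ λ₃:

    ADC = (λ₁ + λ₂ + λ₃) / 3
    FA  = sqrt( 3 Σ(λᵢ − ADC)² / (2 Σ λᵢ²) )

**Ventricle volumetry.** Ventricles are segmented as in-brain voxels with
ADC strictly above `mean + 3·SD` of the in-brain ADC distribution (single
pass), and ventricular / brain-tissue volumes are tabulated in mm³.

**Group statistics.** Per-region means per animal feed a tidy cohort table;
each (region, parameter) cell is compared between groups with a
Shapiro-Wilk-gated choice of Student's t-test or Mann-Whitney test, and
p-values are corrected per parameter family with the Benjamini–Hochberg
step-up rule at q = 0.05.

**Digital phantom.** `build_phantom()` generates a labeled digital
mouse-brain phantom (10 disjoint regions, 64×64×16 voxels at
0.2×0.2×1.0 mm) with known CBF/T2*/tensor ground truth, and
`simulate_asl()`, `simulate_multiecho()`, `simulate_dwi()` and
`simulate_cohort()` emulate the three acquisitions and the two-group cohort
structure, so every downstream stage is verifiable without animal data.

## Worked example

```r
library(neuroquant)

ph <- build_phantom(phantom_spec())          # digital subject, known truth
te <- echo_schedule()                        # 2.4 5.7 9.0 12.3 15.6 ms

# simulate and quantify the three acquisitions (noise-free here)
cbf <- quantify_cbf(simulate_asl(ph$cbf, ph$s0, n_reps = 200),
                    mask = ph$brain_mask)
t2  <- fit_t2star(simulate_multiecho(ph$t2star, ph$s0, te), te, ph$brain_mask)
g   <- make_gradient_scheme(30)
tf  <- fit_tensor(simulate_dwi(ph$tensor, ph$s0, 1200, g), 1200, g,
                  ph$brain_mask)

roi_summary(t2$t2star, ph$label_map) |> head(3)
#> # A tibble: 3 × 5
#>   region           label  mean n_valid n_voxels
#>   <chr>            <int> <dbl>   <int>    <int>
#> 1 substantia nigra     1  39.0     336      336
#> 2 striatum             2  43.0     480      480
#> 3 thalamus             3  38.6     480      480
```

The fitted substantia-nigra T2* of 39.0 ms is exactly the phantom's planted
wild-type value — the noise-free simulate→fit round trip is the package's
core correctness guarantee. Volumetry and group statistics chain on top:

```r
seg <- segment_ventricles(adc_map(tf), ph$brain_mask)
volume_report(ph$brain_mask, seg, ph$spec$voxel_dims)
#> # A tibble: 1 × 6
#>   ventricular_volume_mm3 brain_tissue_volume_mm3 brain_volume_mm3 ...
#> 1                      8                    911.             919.

cohort <- simulate_cohort(group_effect_spec(), seed = 1)
res <- cohort_compare(cohort, stats_config(q = 0.05))
glance(res)
#> # A tibble: 1 × 5
#>   n_tests n_discoveries n_nonparametric     q family
#>     <int>         <int>           <int> <dbl> <chr>
#> 1      22             9               2  0.05 per-parameter
```

`percent_difference(38.5, 33.4)` returns `15.27`: a 38.5 mm³ ventricular
volume is ~15 % larger than a 33.4 mm³ reference — the arithmetic used to
report group volumetry. `autoplot(res)` draws the adjusted p-values per
region and parameter; `tidy(res)` returns the full result table.

A command-line front end with `simulate`, `quantify-cbf`, `quantify-t2star`,
`quantify-dti`, `segment-ventricles`, `roi-summary`, `group-stats` and
`run-all` subcommands is installed at
`system.file("cli", "neuroquant.R", package = "neuroquant")`.

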