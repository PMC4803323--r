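---
title: "Models and design of the neuroquant pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the neuroquant pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroquant)
```

neuroquant turns three raw preclinical MRI acquisitions — interleaved
control/label arterial spin labeling (ASL), a multi-echo gradient-echo
train, and a single-shell diffusion-weighted series — into quantitative
maps, regional summaries, ventricle volumetry and an FDR-corrected
two-group comparison. This vignette records the models, the tunable
parameters and the design choices, and states what the synthetic phantom
does and does not establish about real data.

## Quantification models

### Cerebral blood flow

The ASL series alternates control and label frames (first frame control,
by convention; the simulator honours the same convention). All control
frames and all label frames are averaged first and the single-compartment
model is applied once to the mean images — the mean-then-ratio order, which
gives the ratio a higher SNR than averaging per-pair ratios:

$$\mathrm{CBF} \;=\; 60\,\frac{\lambda}{T_1}\,
  \frac{S_c - S_L}{S_c + (2\alpha - 1)\,S_L} \quad [\mathrm{mL/g/min}],$$

with defaults $\lambda = 0.9$ mL/g (water tissue–blood partition
coefficient), $T_1 = 1.8$ s (whole-brain spin–lattice relaxation at 7 T)
and labeling efficiency $\alpha = 0.75$. $T_1$ is in seconds, so the
factor 60 converts the per-second rate to the conventional per-minute
units. Printed forms of this equation are typographically ambiguous about
which signal the $(2\alpha-1)$ factor multiplies; we default to the
control-weighted-label grouping above and expose the algebraic variant
$S_L + (2\alpha-1)S_c$ behind `denominator = "label_weighted_control"`.
The two coincide at $\alpha = 1$ and differ by under 2 % at typical mouse
label differences; the choice is recorded here rather than hidden. Voxels
with a non-positive denominator are flagged `NaN` and excluded from ROI
summaries. No dummy frames are discarded and no outlier rejection is
applied across repetitions.

### T2* relaxometry

Per voxel, ordinary least squares on the log-signal,
$\ln S_i = \ln S_0 - TE_i / T_2^*$, across the echo train (default: five
echoes, first TE 2.4 ms, spacing 3.3 ms). $T_2^* = -1/\mathrm{slope}$. The
fit is unweighted: log-transforming makes late (noisier) echoes relatively
more influential, but a weighted variant is a different estimator and is
deliberately out of scope. A voxel with any non-positive echo signal is
invalidated outright rather than echo-dropped, which keeps the per-voxel
design matrix fixed and avoids variable-echo bias. A non-negative fitted
slope (no decay) also invalidates the voxel. Fits above 200 ms are flagged
as non-physiological for QC — healthy mouse brain tissue sits at 32–47 ms
at 7 T — but stored unclipped.

### Diffusion tensor, ADC and FA

With one $b=0$ volume and $n \ge 6$ directions at a single shell (default
$b = 1200$ s/mm², 30 directions), the log-linear system
$\ln(S_0/S_i) = b\,g_i^\top D\, g_i$ is solved per voxel by unweighted
least squares for the six tensor elements, followed by a symmetric
eigen-decomposition with eigenvalues sorted descending. Then

$$\mathrm{ADC} = \tfrac{1}{3}(\lambda_1+\lambda_2+\lambda_3), \qquad
  \mathrm{FA} = \sqrt{\frac{3\sum_i (\lambda_i - \mathrm{ADC})^2}
                           {2\sum_i \lambda_i^2}}.$$

The square-root form of FA is the only one bounded by 1 and is consistent
with white-matter values around 0.35–0.5. Noise can drive a fitted
eigenvalue negative; such values are kept for ADC (which remains unbiased)
but clamped at zero inside the FA formula so FA stays in $[0,1]$, and the
voxel is flagged. Gradient timing metadata ($\Delta$, $\delta$) is carried
but not used: a single-shell design without imaging-gradient cross-terms
cannot resolve it.

### Ventricle segmentation and volumetry

Cerebrospinal fluid diffuses roughly three times faster than tissue water,
so ventricles are segmented as in-brain voxels with ADC **strictly above**
`mean + 3·SD`, where the mean and SD are computed over the full brain mask
— ventricles included — in a single pass. One pass is a deliberate choice:
iterating (re-estimating the statistics after removing detected
ventricles) would lower the threshold and is an undeclared extension of
the rule. With ventricles at roughly 1–2 % of brain volume the
contamination raises the threshold but leaves CSF far above it. A
connected-component minimum-size filter exists (`min_cluster`) but is off
by default. Volumes are voxel counts times the voxel volume from the NIfTI
header, the single source of truth for mm³; the report enforces
`brain = tissue + ventricles` exactly. Constant ADC (SD = 0) yields an
empty ventricle mask with a warning, not an error.

### Group statistics

Each (region, parameter) cell is a per-animal sample. Normality is tested
per group by Shapiro–Wilk; by default the nonparametric branch is taken
when **either** group deviates at $\alpha = 0.05$ — the conservative
reading of a "not normally distributed" gate, chosen because single-group
deviations are the common case at n = 6–9 — with the strict both-fail
reading available via `stats_config(gate = "both")`. The parametric branch
is Student's (equal-variance) two-sample t-test; the nonparametric branch
is the two-sided Mann–Whitney test, exact when the combined sample size is
at most 20 and tie-free (the n = 6 + 9 regime), otherwise the normal
approximation with tie and continuity correction. All tests are two-sided.

The Benjamini–Hochberg step-up rule is implemented directly: with sorted
p-values, adjusted $p_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$ capped at 1,
and discoveries are all ranks up to the largest $i$ with
$p_{(i)} \le i\,q/m$. Correction families default to one parameter across
regions — matching how results tables are organized — with an
all-tests-together option; the family definition is a genuine judgment
call and is therefore a visible configuration field, not a constant.
Bilateral structures contribute one value per animal (a single ROI mean),
not two observations.

The behavioral discrimination index,
$100\,t_{novel}/(t_{novel}+t_{familiar})$, is included because cognition
scores are analyzed with the same two-group machinery; 50 is chance.

## The digital phantom

`build_phantom()` places ten disjoint regions — substantia nigra,
striatum, thalamus, motor / somatosensory / visual cortex, hippocampus,
corpus callosum, bilateral ventricles, and remaining brain tissue — as
boxes intersected with an ellipsoidal brain on a 64×64×16 grid at
0.2×0.2×1.0 mm (a 12.8 mm field of view on a 64 matrix, 1 mm slices).
Geometry is deterministic; seeds only drive noise and cohort draws.
Per-region defaults are representative wild-type mouse values at 7 T:
T2* 36–47 ms in tissue, ADC 0.70–0.82 ×10⁻³ mm²/s, CBF 0.6–1.16 mL/g/min,
FA 0.45 in the corpus callosum and 0.35 in the substantia nigra, and
free-water ventricles (ADC 2.2 ×10⁻³ mm²/s, no perfusion, long T2*).
Tensors are prolate with mean diffusivity and FA matched per region: for
target FA $f$, $\delta = f/\sqrt{3-2f^2}$ gives
$\lambda_1 = m(1+2\delta)$, $\lambda_{2,3} = m(1-\delta)$.

Each simulator inverts exactly the model its fitter assumes — the ASL
label signal is $S_L = S_c(1-c)/(1+(2\alpha-1)c)$ with
$c = \mathrm{CBF}\cdot T_1/(60\lambda)$, echo decay is mono-exponential,
and DWI attenuation is $\exp(-b\,g^\top D g)$ — so noise-free
simulate→fit round trips recover ground truth to machine precision, and
the test suite asserts ≤ 10⁻⁶ relative error for every estimator over the
whole brain. Noise is additive zero-mean Gaussian by default; Rician
magnitude noise is available (`rician = TRUE`) but Gaussian is the default
because at the simulated SNR (S0 ≈ 100, noise SD ≲ 1) the two are nearly
indistinguishable and Gaussian keeps the estimator oracles analytic.

Diffusion directions come from a golden-angle (Fibonacci) spherical
spiral with a slightly asymmetric latitude ladder — the symmetric ladder
degenerates to a rank-5 design at exactly n = 6 — giving a reproducible,
well-conditioned design for any $n \ge 6$ without a published direction
table.

Cohorts are drawn per cell as $\mathcal{N}(\mu_g, \sigma_g)$ with default
group sizes 9 wild-type and 6 affected; means and SDs per region and
parameter encode the emulated disease contrast (reduced nigral and
striatal T2*, broadly reduced ADC, non-significantly reduced CBF, enlarged
ventricles, reduced brain volume). A normal per-cell model is the minimal
assumption consistent with mean ± SD summaries.

**What the phantom does not establish.** It is piecewise-constant with
sharp borders and no partial-volume mixing, no motion, no $B_0$/$B_1$
field structure, no transit-time or dispersion effects in ASL, and no
imaging-gradient cross-terms in diffusion. Passing tests therefore verify
the estimators and the statistical machinery, not robustness to
acquisition artifacts; on real data those upstream effects are the
dominant error source.

## Numerical choices and degenerate inputs

* All lengths are mm, relaxometry times ms, ASL $T_1$ seconds,
  diffusivities mm²/s; volumes are written as 64-bit float NIfTI-1 so
  write→read round-trips are exact (header `pixdim` is float32, so voxel
  dimensions round-trip to single precision).
* T2* and tensor fits are closed-form/vectorized least squares; the
  3×3 eigen-decompositions use the symmetric solver per voxel, which is
  numerically safer near degenerate (isotropic) tensors than the analytic
  trigonometric formulas.
* Strict inequality at the segmentation threshold ("above" read
  literally); ties therefore stay tissue.
* Empty masks, odd ASL frame counts, non-unit gradient directions,
  rank-deficient designs, negative voxel dimensions, unnamed labels and
  out-of-range p-values are hard errors; constant-ADC masks and
  essentially-constant cohort cells degrade softly (warning + skipped
  cell) because they arise legitimately in noise-free simulations.
* `run_full_pipeline()` derives every per-animal seed from the single run
  seed, writes an MD5 manifest, and is byte-reproducible; stage failures
  are re-raised with the failing stage named.

## Problem sizes in the test suite

Module tests run on a 32×32×8 phantom; the end-to-end exactness checks use
the full 64×64×16 grid. Calibration checks use 10⁴ replicates for the
t-test branch's type-I error (n = 9 vs 6), 10⁴ random p-vectors for the
step-up cross-check against an independent brute-force implementation, 10³
replicates for effect-direction consistency, and 300 null-cohort
replicates (7 regions × 4 parameters) for family-wise FDR behaviour —
sizes at which the binomial uncertainty of each estimated rate is several
times smaller than the tolerance it is compared against.

## Known limitations

Single-compartment ASL without transit-time modeling; unweighted log-space
fits (no WLS/NLS variants); no motion correction, registration or
resampling (deliberately — the upstream acquisitions this emulates need
none); no voxel-wise statistics; no DICOM/vendor-format ingestion. The
per-parameter FDR family and the either-group normality gate are
documented defaults, not the only defensible readings; both alternatives
are one configuration flag away.
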