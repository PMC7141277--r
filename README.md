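# gqidl

Classifying suicidal ideation from diffusion MRI: generalized q-sampling
index maps, 3D convolutional autoencoder features, and an
imbalance-aware iterated classification protocol — with a synthetic
multi-shell cohort simulator so the whole analysis is verifiable end to
end without any clinical data.

## The problem

Structural differences in white matter between depressed patients with
suicidal ideation (SI) and non-ideation subjects (healthy controls HC
and depressed patients NS) are subtle, high-dimensional and
class-imbalanced: typical cohorts have far more non-ideation subjects
(e.g. 112 vs 41). `gqidl` is aimed at researchers who want to study
whether — and under what conditions — a machine-learning pipeline can
detect such an effect from multi-shell diffusion-weighted MRI, and to
validate every stage of that pipeline against ground truth.

## The method

**Reconstruction.** Generalized q-sampling imaging (GQI) maps the
diffusion signals $S_i$ (b-value $b_i$, gradient direction $\hat g_i$)
to a spin distribution function evaluated on unit directions $\hat u$:

$$\psi(\hat u) = \sum_i S_i\,\mathrm{sinc}\big(\sigma\sqrt{6 D b_i}\;
  \hat g_i\cdot\hat u\big), \qquad \mathrm{sinc}(x)=\sin(x)/x,$$

with sampling length ratio $\sigma = 1.25$ and free diffusion constant
$D = 2.5\times10^{-3}\ \mathrm{mm^2/s}$. From the per-voxel ODF the
package derives **GFA** (sd/rms of the ODF), **ISO** (the ODF minimum),
**QA** (peak value minus ISO) and **NQA** (QA normalized by the
subject-wise maximum).

**Features.** Each index map is compressed by a 3D convolutional
autoencoder (six convolutions, three 2×2×2 max-pools, three 2×
upsamplings; binary cross-entropy loss under Adadelta). On the
(91, 109, 91) template grid, maps are pruned to (88, 104, 88) and the
encoder bottleneck is (11, 13, 11, 16), flattened to 25,168 features per
subject. The network is implemented inside the package (C++ im2col
primitives + BLAS); no deep-learning framework is required.

**Classification.** The non-ideation subjects are split into two
stratified halves (29 HC + 27 NS each at full scale) to soften the
112:41 imbalance; each half plus all SI subjects is analysed separately
with a stratified 4:1 train/test hold-out, 5-fold cross-validation on
the training portion (the 4:1:1 design), iterated over random states
0–9. Models: gradient-boosted trees (`max_depth = 5`,
`n_estimators = 1000`, optional `scale_pos_weight`) and ridge-penalized
logistic regression. Metrics: ACC/SEN/SPE at threshold 0.5 and
concordance AUC, reported as the 10-iteration average and the best
iteration by test AUC.

**Simulation.** A multi-tensor forward model with Rician noise generates
four-group cohorts (HC/NS/SI/SA, default 58/54/41/33) on a shared grid,
three b-shells (1000/1500/2000 s/mm²) with 64 directions each plus one
b = 0 image, and a configurable reduction of the anisotropic volume
fraction inside a region of interest for the affected groups.

See `vignette("gqidl-methods")` for assumptions, parameter rationale and
limitations.

## Worked example

```r
library(gqidl)

## one white-matter voxel: simulate, reconstruct, measure
gtab <- make_gradient_table(64, c(1000, 1500, 2000))
print(gtab)
#> Gradient table: 193 rows; 1 b=0; shells: 1000, 1500, 2000 s/mm^2

fib <- fiber_config(list(list(f = 0.7, dir = c(0, 0, 1),
                              ad = 1.7e-3, rd = 0.3e-3)), f_iso = 0.3)
sig  <- simulate_voxel_signal(fib, gtab, s0 = 100, noise_sigma = 2, seed = 1)
dirs <- make_direction_set(3)                    # 321 hemisphere directions
odf  <- reconstruct_odf(sig, gtab, dirs)
round(compute_gfa(odf), 3)                       # anisotropy of this voxel
#> 0.237
round(dirs[which.max(odf), ], 3)                 # recovered fiber axis
#> 0 0 1

## a small end-to-end study: inject a 40% regional effect and ask the
## pipeline to find it
spec <- cohort_spec(group_sizes = c(HC = 10, NS = 10, SI = 8, SA = 4),
                    grid_shape = c(16, 16, 16), effect_delta = 0.4, seed = 7)
res <- signal_recovery_study(spec,
                             ae = ae_config(c(16, 16, 16), epochs = 10, seed = 1),
                             random_states = 0:4)
res$averaged
#> metrics_report [xgb-GFA-1, random_state NA]
#>   CV:   ACC 0.900 SEN 0.960 SPE 0.840 AUC 0.900
#>   Test: ACC 0.900 SEN 1.000 SPE 0.800 AUC 0.900
```

The voxel-level numbers say the reconstruction recovered the simulated
fiber axis exactly and assigned it a plausible white-matter GFA; the
study-level report says that, averaged over five train/test iterations,
the classifier separated the synthetic ideation group from the
non-ideation half with mean test AUC 0.90 — the injected effect is
detectable through the full map → autoencoder → classifier chain.

A four-stage file-based pipeline (NIfTI maps, feature CSVs, metric
tables, ROC points, run manifest) is available through
`run_pipeline(pipeline_config("config.yaml"))` or the wrapper
`inst/scripts/run_pipeline.R`.

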