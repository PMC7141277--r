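---
title: "Methods: generalized q-sampling maps, volumetric autoencoder features, and imbalance-aware classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalized q-sampling maps, volumetric autoencoder features, and imbalance-aware classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`gqidl` implements a four-stage analysis for asking whether a regional
white-matter difference, measurable with multi-shell diffusion MRI, can
discriminate depressed patients with suicidal ideation (SI) from
non-ideation subjects (healthy controls, HC, plus depressed non-ideation
patients, NS):

1. **Synthetic cohort simulation** — multi-tensor diffusion signals with
   Rician noise and a controllable group effect;
2. **Generalized q-sampling (GQI) reconstruction** — per-voxel orientation
   distribution functions (ODFs) and the scalar maps GFA, ISO, QA, NQA;
3. **Unsupervised feature extraction** — a 3D convolutional autoencoder
   compresses each subject's index map into a flattened bottleneck vector;
4. **Imbalance-aware classification** — stratified half-splits of the
   non-ideation subjects, a 4:1:1 train/validation/test design realized as a
   stratified 4:1 hold-out with 5-fold cross-validation on the training
   portion, iterated over ten split seeds, with gradient-boosted trees and
   logistic regression.

No clinical imaging data ship with the package; the simulator exists so
that every stage is verifiable end to end, with known ground truth, on any
machine. The whole deep-learning stack (3D convolution, pooling,
upsampling, Adadelta, binary cross-entropy) is implemented inside the
package — im2col/col2im primitives in C++, matrix products through R's
BLAS — so the pipeline has no framework dependency.

# The simulator

Each voxel follows a multi-tensor forward model. For acquisition row $i$
with b-value $b_i$ (s/mm²) and unit gradient direction $\hat g_i$:

$$S_i = s_0\Big[\sum_k f_k \exp(-b_i\,\hat g_i^{\top} D_k \hat g_i)
      + f_{\mathrm{iso}}\exp(-b_i d_{\mathrm{iso}})\Big],$$

with axially symmetric tensors $D_k$ parameterized by an axial and a
radial diffusivity. Rician noise is applied as
$|S + \varepsilon_1 + i\,\varepsilon_2|$, $\varepsilon\sim N(0,\sigma^2)$,
the correct magnitude-MRI noise model; a plain Gaussian option exists for
debugging.

Defaults, chosen once as typical literature values (the source study
reports none of them, only the acquisition scheme):

| parameter | default | meaning |
|---|---|---|
| shells | 1000 / 1500 / 2000 s/mm² | three b-shells plus one b = 0 row |
| directions per shell | 64 | 192 weighted directions total |
| axial / radial diffusivity | 1.7e-3 / 0.3e-3 mm²/s | white-matter-like tensor |
| free-water diffusivity | 3.0e-3 mm²/s | CSF compartment |
| $s_0$ | 100 | baseline signal |
| `noise_sigma` | 2 | SNR 50 at b = 0 — a low-noise regime |
| `f_aniso` | 0.62 | anisotropic volume fraction of background white matter |
| `jitter_sd_deg` | 10° | per-subject fiber-orientation variability |

Shell directions are deterministic spherical Fibonacci spirals (near
uniform without iterative electrostatic optimization); the seed only
permutes acquisition order. The per-shell split of the 192 directions
(64/64/64) is a convention — the acquisition description does not state
it.

The cohort has the four groups HC/NS/SI/SA with default sizes
58/54/41/33. The group effect multiplies the anisotropic volume fraction
by $(1-\delta)$ (`effect_delta`) inside a region of interest (default: the
central cube of side one third of the grid) for the affected groups
(default SI and SA — attempters plausibly share the ideation biology, and
they never enter classification, which uses only HC + NS + SI = 153
subjects). A multiplicative rather than subtractive reduction keeps the
volume fractions valid for any $\delta \in [0,1]$. With $\delta = 0$ all
groups are generated from exactly the same distribution, so the pipeline
can be calibrated against a true null. Within-group variability comes from
orientation jitter and noise, not from varying $f$: this makes the
$\delta = 0$ exchangeability exact by construction.

What the simulator deliberately does **not** emulate: eddy-current/motion/
susceptibility artifacts, registration (volumes are born aligned on a
shared grid), spatially heterogeneous fiber architecture (one fiber
population per subject plus an isotropic compartment), partial-volume
cortex, or scanner reconstruction physics. Passing tests therefore show
that the analysis machinery recovers a known regional effect under clean
conditions; they do not certify performance on real, artifact-laden data.

# Generalized q-sampling reconstruction

GQI relates q-space signals to the spin distribution function through a
sinc-kernel sum. For ODF direction $\hat u_j$:

$$\psi(\hat u_j) = \sum_i S_i\,
  \mathrm{sinc}\big(\sigma\sqrt{6 D b_i}\;\hat g_i\cdot\hat u_j\big),$$

with the unnormalized $\mathrm{sinc}(x) = \sin(x)/x$. The sampling length
ratio $\sigma$ defaults to 1.25 and the free diffusion constant $D$ to
2.5e-3 mm²/s — the method's common usage; both are exposed in
`gqi_config()`. Negative kernel-sum values are truncated to zero before
any index computation, since the SDF is a density. The reconstruction is
linear in the signal, which the tests exploit by checking against an
independent brute-force double-loop evaluation to 1e-10.

ODFs are evaluated on one hemisphere of a subdivided icosahedron
(antipodal duplicates removed), $(10\cdot4^k+2)/2$ directions at order
$k$; the default $k = 3$ gives 321 directions with a worst-case
nearest-neighbour spacing near 9°, which bounds the angular error of peak
recovery.

Scalar maps, per voxel:

- **GFA** = population standard deviation of $\psi$ / root mean square of
  $\psi$. Scale-invariant, zero for a constant ODF, bounded by
  $\sqrt{(N-1)/N}$ (one-hot case). The population (divide by $N$)
  convention is used so the one-hot closed form is exact and the bound
  approaches 1 as $N \to \infty$. An all-zero ODF maps to 0.
- **ISO** = the ODF minimum — the orientation-independent background.
- **QA** = ODF value at the voxel's global peak direction minus ISO,
  floored at zero. The global maximum over the direction set is used (no
  local-peak search): the scalar indices only need the dominant
  orientation.
- **NQA** = QA divided by the maximum QA over that subject's masked
  field, so NQA ∈ [0, 1] per subject; a degenerate all-constant field
  yields all-zero QA and NQA.

The default reconstruction mask keeps voxels whose mean b = 0 signal is
positive; outside the mask all maps are zero. Eddy correction and template
registration are out of scope — synthetic volumes are already aligned.

# The autoencoder

Architecture (six 3D convolutions, three 2× max-pools, three 2×
upsamplings):

```
conv(3³, 32) → pool → conv(3³, 16) → pool → conv(3³, 16) → pool   encoder
up → conv(3³, 16) → up → conv(3³, 16) → up → conv(3³, 1, sigmoid) decoder
```

All convolutions preserve spatial size (zero padding), hidden activations
are rectified-linear, and the output is a sigmoid so the binary
cross-entropy reconstruction loss is defined on [0, 1] intensities. Only
the bottleneck width (16) is fixed by the design; the (32, 16, 16) encoder
taper and kernel size 3 are conventional choices. On the (91, 109, 91)
template grid, volumes are center-cropped to (88, 104, 88) — every
dimension divisible by 8 — removing (1, 2, 1) voxels from the low sides
and (2, 3, 2) from the high sides (the asymmetry is a convention; only the
before/after shapes are fixed). The encoder output is then
(11, 13, 11, 16), flattened to 25,168 features in column-major order
(voxels x-fastest within channel, channels slowest).

Intensities are min-max normalized **per volume** before training (a
constant volume maps to zeros); whether normalization should be per-volume
or global is genuinely open, and per-volume is the choice here because it
makes every input occupy the full [0, 1] range regardless of subject-level
scale.

Training is mini-batch (default batch 8) gradient descent under Adadelta
(decay 0.95, stabiliser 1e-6) with learning-rate multiplier 0.01 over 50
epochs, the recipe of the source analysis. One autoencoder is trained per
index type, on **all** subjects' maps (the four groups, 186 at default
scale), unsupervised; classification later uses only the 153 HC/NS/SI
subjects.

A property of Adadelta worth stating: with a learning-rate multiplier
well below 1, its steady-state step size is approximately
$lr\sqrt{\epsilon}$ per update, so at $lr = 0.01$ weights stay close to
their (Glorot) initialization over a 50-epoch run and the loss decreases
only slightly; the bottleneck then behaves like a structured random
projection — which is still an effective feature extractor, as the
signal-recovery results below show. At the optimizer's classic
parameterization ($lr = 1$) the same machinery drives the reconstruction
loss down rapidly; the test suite verifies convergence in that regime and
verifies the backward pass against finite differences, so the slow
movement at $lr = 0.01$ is a property of the recipe, not a defect of the
gradients.

# Classification protocol

Positive class: SI. Negative: the HC + NS subjects of one half. The
negative:positive ratio at full scale is 112/41 = 2.73; to soften this
imbalance the non-ideation subjects are split into two stratified halves
(29 HC + 27 NS each; an odd group count puts the surplus subject in half
1), and each half plus all SI subjects is analysed separately.

Per iteration (`random_state` 0..9 — ten distinct seeds): a stratified
4:1 train/test hold-out (per class, one fifth rounded, at least one
subject), then stratified 5-fold cross-validation inside the training
portion — each fold serving once as validation, which realizes the 4:1:1
arithmetic without a third fixed partition. Metrics: ACC/SEN/SPE at
probability threshold 0.5 (no threshold is stated in the source design;
0.5 is the neutral choice) and threshold-free AUC computed as pairwise
concordance with 0.5 credit for ties. Reported tables are the arithmetic
mean over the ten iterations and the single best iteration by test AUC
(ties resolved toward the lowest random state). Fold means are averaged
before iteration means; pooling predictions instead is a defensible
alternative the package does not take. The half-split itself is fixed per
cohort (seeded once), not refreshed per iteration.

Models: gradient-boosted trees (`xgboost`, max_depth 5, n_estimators
1000, other settings at library defaults, optional `scale_pos_weight`)
and logistic regression. Because the feature dimension far exceeds the
sample count, plain maximum-likelihood logistic regression is degenerate
(complete separation); the package fits ridge-penalized logistic
regression — the summed log-loss plus $\tfrac{1}{2}\lVert w\rVert^2$ with
an unpenalized intercept, the objective behind the common library default
of an L2 penalty at C = 1 — by Newton/IRLS in the kernel representation
of the data (exact for an L2 penalty, since the optimum lies in the row
span of the design), so the cost scales with the sample count rather
than the 25,168-dimensional feature space, and the fit is well-posed for
any fold composition.

The cross-validation fold count is exposed (default 5, with the error
that a class must have at least as many training members as folds) so
that very small plumbing-test cohorts can run the full pipeline with 2
folds; scientific runs keep 5.

# Numerical and degenerate-input choices

- $\mathrm{sinc}(0) = 1$ exactly (threshold $|x| < 10^{-12}$).
- All-zero ODF: GFA defined as 0; empty ODFs are errors.
- Degenerate ODF field: QA = NQA = 0 everywhere rather than an error.
- Constant volume under min-max normalization: all zeros.
- Rician noise at $\sigma = 0$ is bypassed exactly (no degenerate draw).
- BCE probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ inside the loss;
  gradients ignore the clip (standard practice).
- Seeds: every stochastic step (weight init, batch order, noise, splits)
  derives deterministically from user-visible seeds; reruns are
  bit-identical, including across the pipeline's stage-isolation path.

# Problem sizes used by the tests and the acceptance script

Unit tests run at desk scale: 8³–16³ grids, tessellation orders 0–2 where
the full order-3 set is not the point, cohorts of a dozen subjects for
pipeline plumbing. The full-geometry facts (crop shapes, bottleneck
25,168) are checked by exact shape arithmetic plus one real encoder pass.

The end-to-end signal-recovery evaluation (`signal_recovery_study()`)
uses a 16³ grid and a half-scale cohort (HC/NS/SI/SA = 29/27/21/17,
sizes halved and rounded up), keeping the full acquisition scheme (193
rows), the full autoencoder recipe (50 epochs), and the full iterated
protocol (10 random states, 5 folds, half 1, gradient-boosted trees).
These sizes are the package's evaluation choice: they preserve every
structural property of the full-scale design — class imbalance, stratified
halving, per-class fold feasibility — while keeping a complete
simulate-to-classify run at a few minutes on one CPU core. With
`effect_delta = 0.4` the injected effect is strong and the mean test AUC
over ten iterations is expected above 0.85; with `effect_delta = 0` the
same pipeline calibrates to chance (mean test AUC within [0.35, 0.65]).

# Known limitations

- Single fiber population per subject: crossing-fiber geometry is tested
  at voxel level but not simulated at cohort level.
- The autoencoder is CPU-bound and double-precision; at the full
  (91, 109, 91) geometry a training run over a 186-subject cohort is
  possible but slow — the package targets reduced geometry for routine
  use.
- `scale_pos_weight` is supported and tested, but the headline protocol
  follows the halving design rather than reweighting.
- The seven alternative classifiers sometimes discussed alongside this
  design (CART, LDA, naive Bayes, KNN, SVM, MLP, random forests) are out
  of scope, as are tractography, registration, and artifact correction.
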