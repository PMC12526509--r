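---
title: "Depth-resolved soil moisture estimation from canopy texture: methods"
author: "texSMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved soil moisture estimation from canopy texture: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texSMC)
```

## The problem

Volumetric soil moisture content (SMC) in cropland varies with depth, and
canopy-level remote sensing observes it only indirectly: water status shapes
canopy density, leaf angle and leaf water content, which in turn shape the
*spatial texture* of high-resolution multispectral imagery. `texSMC`
implements a complete pipeline that turns six-band UAV reflectance mosaics
of field plots into depth-resolved SMC estimates (0–20, 20–40 and 40–60 cm)
through four stages:

1. **Vegetation masking** — NDVI thresholding with morphological refinement,
   so texture statistics describe canopy, not soil background.
2. **GLCM texture extraction** — the eight second-order texture metrics per
   band, the 48 metric x band "positions".
3. **Texture indices and correlation-matrix screening** — six 2-D and four
   3-D index families over position tuples, exhaustively screened for
   correlation with SMC, then filtered for significance, redundancy and
   multicollinearity.
4. **Regression** — random forest (RF), partial least squares (PLSR) and a
   single-hidden-layer tanh network (BPNN) over seven input combinations
   (raw textures, 2-D indices, 3-D indices and their unions).

Because no field dataset ships with the package, a synthetic generator
emulates the study conditions end to end, with a *known* texture–moisture
coupling so every stage is testable.

## GLCM texture features

Each band is quantized to $G = 64$ gray levels. The default scaling
stretches the 1st–99th percentile of the masked pixels of that band and
plot; the percentile clip guards against hot pixels. An optional `"global"`
mode accepts fixed per-band ranges when textures must be comparable across
flights. Whether plot-wise or global scaling is the better emulation of
ENVI-style workflows is not decidable from typical method descriptions; the
per-image default is the self-contained choice and the global mode is one
configuration key away.

For every interior $5 \times 5$ window with at least 60% valid (vegetation)
pixels, the co-occurrence matrix $P(i,j)$ is accumulated symmetrically at a
one-pixel offset along $0°, 45°, 90°, 135°$, normalized, and summarized by

$$\mathrm{MEA} = \sum_{i,j} i\,P(i,j), \quad
  \mathrm{VAR} = \sum_{i,j} (i-u)^2 P(i,j), \quad
  \mathrm{HOM} = \sum_{i,j} \frac{P(i,j)}{1+(i-j)^2},$$
$$\mathrm{CON} = \sum_{i,j} (i-j)^2 P(i,j), \quad
  \mathrm{DIS} = \sum_{i,j} P(i,j)\,|i-j|, \quad
  \mathrm{ENT} = -\sum_{i,j} P(i,j)\log P(i,j),$$
$$\mathrm{SEC} = \sum_{i,j} P(i,j)^2, \quad
  \mathrm{COR} = \frac{\sum_{i,j}(i-\mathrm{MEA}_j)(j-\mathrm{MEA}_i)P(i,j)}
                      {\sqrt{\mathrm{VAR}_i\,\mathrm{VAR}_j}}.$$

Numerical conventions worth stating explicitly:

* **Entropy sign.** GLCM entropy is sometimes printed without the minus
  sign, which would make it nonpositive. We use the standard Shannon form
  $-\sum P \log P$ in natural log, so $\mathrm{ENT} \ge 0$. Base-$e$ rather
  than base-2 only rescales every ENT column by a constant and therefore
  cannot change any correlation, screening decision or model fit.
* **Correlation marginals.** Because the matrix is accumulated
  symmetrically, $\mathrm{MEA}_i = \mathrm{MEA}_j$ and
  $\mathrm{VAR}_i = \mathrm{VAR}_j$; the cross-indexed form above then
  coincides with the standard GLCM correlation. Windows whose GLCM variance
  is zero in any direction have undefined COR and are excluded from COR's
  plot mean only — reporting 0 instead would bias COR toward zero on
  near-uniform canopies.
* **Aggregation.** The four directions are averaged per window (reducing
  rotational effects), and the plot value is the arithmetic mean over
  admissible windows; windows are interior-only (no padding). The mean is
  the convention for plot-scale GLCM statistics.

The windowed kernel is implemented in C++ (`src/glcm.cpp`); a naive
triple-loop R implementation lives in the test suite and the two are held
to $10^{-10}$ relative agreement on random masked images.

## Texture indices

A *position* is one (metric, band) pair, e.g. `HOM6` = homogeneity of the
NIR band. Indices combine position values $T_i, T_j(, T_k)$:

| family | formula | family | formula |
|---|---|---|---|
| ATI | $T_i + T_j$ | BDSI | $(T_i - T_j)/(T_k - T_j)$ |
| DTI | $T_i - T_j$ | DTTI | $T_i - T_j - T_k$ |
| NDTI | $(T_i - T_j)/(T_i + T_j)$ | MSI | $T_i \, T_j \, T_k$ |
| RTI | $T_i / T_j$ | NDTTI | $(T_i - T_j - T_k)/(T_i + T_j + T_k)$ |
| RDTI | $1/T_i - 1/T_j$ | | |
| RATI | $1/T_i + 1/T_j$ | | |

The search space is **ordered tuples with repetition** ($48^2$ pairs,
$48^3$ triples per family): published best-combination reports include
repeated positions (e.g. a RATI pair using the same position twice and a
DTTI triple repeating `HOM4`), and several families are asymmetric in their
arguments, so unordered tuples would silently discard attainable optima.

Degenerate denominators yield an *undefined marker* (`NA`) rather than an
epsilon-stabilized value: an epsilon choice would silently distort the
correlation ranking on which the whole screening stage rests. Columns with
more than 10% undefined rows are excluded from screening.

## Correlation-matrix screening

Per depth layer, every position and every tuple of every family is
correlated with SMC (Pearson $r$; two-sided $p$ from the $t$ transform).
The screening protocol is two-stage: (i) keep features with $p < 0.05$
(unadjusted — a Bonferroni option exists but defaults off to match the
protocol the pipeline mirrors); (ii) remove redundancy by greedy
elimination of inter-feature $|r| \ge 0.90$ — walking features in
decreasing $|r|$-with-SMC, so the more informative member of a correlated
pair survives — followed by iterative removal of the largest variance
inflation factor until all $\mathrm{VIF}_j = 1/(1-R_j^2) \le 10$.

Two design points were genuinely open:

* **How many index combinations enter the models.** Only best combinations
  are reported in the source tables, but the fused input combinations need
  a finite feature set per family. We carry forward the best combination
  plus any combination within 95% of the best $|r|$, capped at 20 per
  family, then pool per group (2-D / 3-D) before the redundancy and VIF
  filters. The cap is configurable (`capFrac`, `capN`).
* **Tie-breaking.** Exact $|r|$ ties (symmetric families produce them
  structurally) resolve lexicographically by column label, with a
  $10^{-12}$ tolerance so that algebraically identical tuples evaluated in
  different operand order tie as intended. This makes every "best
  combination" report reproducible.

The exhaustive grids are evaluated blockwise (default 20,000 tuples per
block) so the $4 \times 48^3$ 3-D searches run in bounded memory; the full
DTTI search at $n = 96$ takes a few seconds on one CPU.

## Modeling

The split is depth-stratified 2:1 — plots sorted by SMC, consecutive strata
of three, one plot per stratum drawn into validation — with 10-fold CV
inside the training set for hyperparameter selection. All predictors are
z-standardized with statistics computed on training rows only.

* **RF**: 200 trees, variance-reduction (squared-error) splits, all
  features eligible per split, OOB error recorded. (A "Gini criterion" is
  a classification notion; regression forests use variance reduction —
  with "max features = auto" read as the historical all-features
  regression default.)
* **PLSR**: the latent-variable count is grown while each additional LV
  adds at least 5% to the cumulative explained variance of $Y$, estimated
  from 10-fold CV *predictions* (not calibration fit, which would always
  grow). The PLS decomposition itself comes from `mixOmics`.
* **BPNN**: one hidden layer, tanh activation, trained in-package by batch
  BFGS (quasi-Newton) with L2 weight decay ($10^{-3}$) and 5 random
  restarts; hidden size selected over $\{10, 15, \dots, 100\}$ by
  fold-averaged CV RMSE. A Levenberg–Marquardt optimizer is the classical
  choice here; a damped/quasi-Newton batch method is the contract this
  implementation honors, and the optimizer is recorded in the fitted
  model. Weight decay plays the regularization role of early stopping.
  Hidden-size selection is re-run per dataset rather than pinned to any
  previously reported optimum, which is data-dependent.

**Leakage.** In the default `"strict"` mode, screening statistics are
computed on training rows only, so validation rows never influence feature
selection, standardization or hyperparameters. A `"paper"` mode screens on
all samples before splitting — the order many field studies report — and is
exposed for comparability; the two modes bracket the optimism attributable
to screening leakage.

Validation metrics: $R^2 = 1 - SSE/SST$, RMSE in SMC units (percent
volumetric), and MRE $= \mathrm{mean}(|\hat y - y|/y) \times 100\%$ (the
relative-error denominator is the observed value, consistent with
percent-scale MREs of a few percent).

## The seven input combinations

Combinations 1–7 are the non-empty subsets of {raw textures, 2-D indices,
3-D indices}: 1–3 the single groups, 4–6 the pairwise unions, 7 the union
of all three. `runGrid()` fits every requested depth x combination x model
cell; a failing cell (e.g. a BPNN non-convergence) is flagged and never
aborts the remaining cells. `relativeImprovement()` reports
$100 (R^2_{c7} - R^2_{c1}) / R^2_{c1}$ per depth, the fusion-gain summary.

## The synthetic study conditions

The generator emulates a 96-plot field campaign with three sampled depth
layers; its defaults are the package's fixed study conditions, not tuning
knobs:

* **SMC**: shallow-layer SMC uniform on 10–30% volumetric; deeper layers
  follow an AR(1) chain over depth with coefficient $\rho = 0.6$, clipped
  to the range. Percent units put RMSE/MRE on the magnitudes familiar from
  field studies.
* **Canopy**: a Gaussian random field synthesized spectrally (FFT) with
  power-law spectrum $|f|^{-\beta/2}$. Shallow SMC modulates the spectral
  slope $\beta$ linearly over $[1.2, 3.2]$: wetter plots get smoother,
  less contrasted canopies — the monotone texture–moisture coupling that
  denser, more uniform well-watered canopies exhibit. Slope (not
  amplitude) is modulated because per-plot percentile quantization is
  invariant to pure amplitude changes.
* **Bands**: canopy-spectrum baselines with band gains rising toward
  red-edge/NIR (structure-sensitive bands respond most), independent
  Gaussian sensor noise (sd 0.01 reflectance), soil gaps as Bernoulli
  seeds (rate 0.015) dilated 3 x 3, carrying soil reflectance — so the
  masking stage has real work.
* **Depth coupling**: the image depends *only* on shallow SMC; deeper
  layers couple to texture solely through the AR(1) SMC chain, so the
  effective coupling is $\kappa_d = \kappa_1 \rho^{\,d-1}$ — strictly
  decreasing with depth. This reproduces, by construction, the expectation
  that canopy texture tracks shallow moisture best. The `depthCoupling`
  vector stores these effective strengths; element 1 is the generator's
  gain and setting it to zero switches the coupling off entirely.

What the generator does *not* emulate: radiative transfer, row structure,
irrigation/fertilization treatment factors, view/illumination geometry, or
any quantitative field-calibrated SMC-texture law (none is available).
Passing tests therefore demonstrate that the pipeline recovers structure
*when the assumed monotone coupling holds*, not that the coupling form is
agronomically accurate.

## Verification strategy and problem sizes

The test suite checks every stage against an independent oracle: a naive
triple-loop GLCM, literal nested-loop tuple searches, closed-form VIFs and
least-squares fits, and hand-computed index values. The end-to-end
property checks run the default 96-plot conditions over five seeds and
assert, by majority: (a) the best screened $|r|$ is higher for the shallow
than the deep layer; (b) each model family's validation $R^2$ is higher
for the shallow than the deep layer at the fused input (Combination 7, the
headline input); and (c) RF's Combination 7 validation $R^2$ is within
0.02 of or above Combination 1's, shallow layer. Those checks use the
targeted cells rather than the full 63-cell grid; the grid machinery
itself is exercised separately on a smaller planted-structure fixture.
Image size is 64 x 64 px per plot — large enough for ~3,600 texture
windows per band, small enough that a full multi-seed study runs on one
CPU in minutes.

## Known limitations

* The synthetic coupling is a stand-in; absolute performance numbers on
  synthetic data say nothing about field accuracy.
* `tiff`-based I/O reads/writes plain multipage TIFF; georeferencing tags
  are ignored, and polygon geometries are interpreted in pixel
  coordinates.
* PLSR inherits `mixOmics`' internal column scaling; since the pipeline
  standardizes upstream, this is a no-op in practice.
* The BPNN is a batch optimizer on small data; at hundreds of plots per
  fit it is fast, but it is not a minibatch deep-learning engine.
* p-values in screening are unadjusted by design; with $48^3$ candidate
  tuples they are selection statistics, not inferential ones.
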