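---
title: "Connectome topology from ROI time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome topology from ROI time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectopo)
```

# The analysis in one paragraph

`connectopo` implements a resting-state functional-connectome workflow on
regional (ROI-level) BOLD time series. Each subject's T × N matrix is
preprocessed (initial-volume discard, linear detrend, nuisance regression
with optional global-signal removal, ideal band-pass), correlated into an
N × N Pearson functional-connectivity (FC) matrix, and binarized at every
sparsity threshold on a grid (default 10%–34% in steps of 1%). At each
threshold the package computes the clustering coefficient Cp,
characteristic path length Lp, global efficiency Eglob, local efficiency
Eloc and per-node nodal efficiency Enod, and normalizes Cp and Lp against
degree-preserving random networks to obtain γ = Cp/Cp~rand~,
λ = Lp/Lp~rand~ and the small-worldness σ = γ/λ. Every metric curve is
summarized by its trapezoidal area under the curve (AUC) over the grid, a
threshold-independent statistic. Group inference uses Wilcoxon rank-sum
tests with Benjamini–Hochberg FDR over the nodal family, and a
LASSO-logistic classifier on Enod AUC features is selected by 10-fold
cross-validation, evaluated with a ROC/Youden analysis and a
repeated-subsampling internal validation.

# Preprocessing

The chain is fixed in this order: discard → detrend → nuisance regression →
band-pass.

* **Volume discard** (`n_discard`, default 10 volumes): removes
  magnetization-equilibration transients; with the default 200 acquired
  volumes this leaves T = 190 points at TR = 2 s.
* **Detrending** is linear only: an intercept-plus-slope least-squares fit
  per column. Higher-order drift removal is left to the band-pass.
* **Nuisance regression** projects each column on an intercept, any
  user-supplied confounds, and optionally the *global signal*. Because the
  package starts from ROI series, the global signal is defined as the
  unweighted per-timepoint mean over the N ROI columns; voxelwise
  whole-brain means are not available at this stage. Motion, white-matter
  and CSF regressors can be passed through `extra_confounds` but cannot be
  derived here.
* **Band-pass** (default 0.01–0.08 Hz) is an ideal rectangular filter in
  the discrete Fourier domain: bins strictly outside the band are zeroed,
  bins exactly at the edges are kept. This matches the convention of the
  common fMRI toolchains, is idempotent, and avoids the edge effects that
  IIR filters produce on series this short. The cost is spectral leakage
  for components that do not fall exactly on DFT bins; with T = 190 and
  TR = 2 s the bin spacing is 1/380 Hz, narrow relative to the band.

Whether nuisance regression should precede or follow band-pass is not
uniquely defined across toolchains; the fixed order above is a deliberate
choice, and `bandpass()` being linear and idempotent keeps the alternative
order close in practice.

# Network construction

Edges are Pearson correlations between ROI columns. The FC matrix is
binarized by **rank**: at sparsity s, exactly `round(s·N(N−1)/2)` node
pairs with the largest edge values become edges (round half away from
zero, for platform independence). Two details are configurable because the
field uses both conventions:

* `edge_rank = "signed"` (default) ranks by the signed correlation, the
  usual choice for positive-connectivity networks; `"absolute"` ranks by
  magnitude.
* Ties are broken by upper-triangle (row, column) order, making stacks
  bit-reproducible.

Because one global edge ranking serves all thresholds, stacks are *nested*:
an edge present at sparsity s is present at every larger s. No Fisher
z-transform is applied before thresholding — rank-based selection is
invariant to monotone transforms.

# Graph metrics and the null model

All metrics operate on binary, undirected, zero-diagonal graphs and are
implemented in compiled code with bitset adjacency rows (verified in the
test suite against brute-force triangle enumeration, Floyd–Warshall
distances, and explicit induced-subgraph reconstruction, exactly, on
dozens of random graphs).

* **Cp**: mean over nodes of 2·(edges among neighbours)/(k(k−1)), 0 for
  degree < 2.
* **Lp**: mean BFS hop distance over *connected* ordered pairs.
  Disconnected pairs are excluded with a warning; an edgeless graph has
  undefined Lp (`NA`). The harmonic alternative is already captured by
  Eglob, which treats 1/∞ as 0.
* **Eglob / Enod**: mean inverse distance over ordered pairs, globally and
  per source node.
* **Eloc**: mean over nodes of the global efficiency of the subgraph
  induced by the node's neighbours (node removed); 0 for degree < 2.
* **Null model**: Maslov–Sneppen pairwise edge swaps, rejecting self-loops
  and duplicate edges, with 10 attempted swaps per edge by default —
  enough to decorrelate clustering on lattices while preserving every
  degree exactly. γ, λ and σ use means over `n_random` (default 100)
  rewired graphs, regenerated per threshold, each ensemble consuming an
  independent substream seeded by (seed, subject, threshold) so that
  subject-level results do not depend on cohort ordering.

γ, λ and σ are computed per threshold and AUC-summarized like every other
metric. If a null ensemble has zero mean clustering (possible on very
sparse graphs), γ is reported `NA` with a warning rather than infinite.

# Group statistics

Per-subject AUC values are compared with the two-sided Wilcoxon rank-sum
test: the exact rank-sum distribution when both groups have ≤ 10 subjects
and no ties, otherwise the normal approximation with tie and continuity
correction (at the default 20 + 20 design the approximation applies).
Benjamini–Hochberg FDR is applied within the nodal family only; global
metrics (Cp, Lp, Eglob, Eloc, γ, λ, σ) are reported with raw p-values, as
is conventional when only a handful of global curves are tested. Whether
the FDR family should be all 160 nodes or a pre-selected subset is exposed
simply by what is passed to `compare_groups()`.

# Classification

`fit_lasso_cv()` fits an L1-penalized logistic regression of group on the
160 Enod AUC features via glmnet, with internal standardization and
coefficients reported on the original feature scale (Enod AUC values are
≈ 0.14, so meaningful coefficients have magnitudes of order 10). The
penalty is the **strict minimizer** of the 10-fold cross-validated
binomial deviance (not the one-standard-error rule), with folds stratified
by class and seeded. Evaluation:

* ROC AUC by the trapezoidal rule (equal to the tie-corrected rank-sum
  statistic; the suite checks this identity to 1e−12),
* decision cutoff at the maximum of Youden's index (lowest threshold on
  ties), reported on the probability scale — the packaged reference model
  validates under both the probability and linear-predictor reading of its
  printed cutoff,
* a stratified-bootstrap percentile CI for the AUC (2,000 resamples by
  default),
* internal validation by 19 subsamples of sizes 21, 22, …, 39 drawn
  without replacement from the *whole cohort* (redrawn if single-class,
  unstratified). Because training subjects are included, these AUCs are
  optimistic by construction; they measure stability, not out-of-sample
  accuracy.

The package ships a published nine-node reference model
(`load_reference_model()`) with its coefficients, intercept, group-mean
feature values and decision cutoff, which serves as a self-contained
worked example for `predict_probability()`.

# The synthetic cohort generator

No public recordings accompany the clinical study design this package
targets, so `simulate_cohort()` provides a generative stand-in with the
statistical structure the analysis assumes:

* **Topology.** A Watts–Strogatz small-world base graph by default
  (N = 160, lattice degree 12, rewiring 0.1) — chosen because networks
  built from it reproduce σ > 1, as healthy-control connectomes do.
  Modular and Erdős–Rényi bases are available.
* **Covariance.** The control correlation matrix is
  `C = w·C0 + b·J + (1−w−b)·I`, with `C0` the row-normalized
  neighbourhood-overlap matrix `(A+I)(A+I)'` of the base graph. As a sum
  of PSD terms it is positive definite by construction; direct neighbours
  correlate at ≈ w·0.85 + b (≈ 0.44 with the defaults w = 0.5, b = 0.05,
  a realistic magnitude for band-passed ROI data), and correlation decays
  with lattice distance, which is what gives thresholded graphs their
  small-world character.
* **Group effects.** Patients' within-neighbourhood correlations are
  multiplied by `patient_local_attenuation` (default 0.8), emulating
  reduced local interconnectivity; *discriminative nodes* receive a signed
  uniform shift of their off-diagonal row/column (default magnitude 0.04,
  calibrated once so the per-node Enod-AUC group shift is about one SD
  under the default design without GSR). If a modification costs positive
  definiteness, diagonal loading `(|min eigenvalue|+0.01)·I` plus
  renormalization to correlation form repairs it.
* **Dynamics.** Innovations are multivariate normal with the group
  covariance, AR(1)-filtered (coefficient 0.4, giving BOLD-like temporal
  smoothness at TR = 2 s) and overlaid with white noise (SD 0.2 per unit
  signal). A shared AR coefficient leaves the stationary cross-correlation
  equal to the innovation correlation, so long simulations converge to the
  ground truth (checked in the suite at T = 20,000).
* **Seeding.** One master seed fans out into per-subject substreams, so a
  subject's data do not depend on cohort size or order.

The number of acquired volumes is not part of the emulated design
specification; the default T~raw~ = 200 (190 retained) is a choice exposed
in `cohort_spec()`.

**What the generator does not emulate:** volumetric acquisition, head
motion, physiological noise, hemodynamic convolution, spatial smoothing,
inter-subject anatomical variability, or negatively-correlated anticorrelation
structure. Passing recovery tests on this generator therefore demonstrates
that the pipeline detects the *kind* of effects it models — multiplicative
local-coupling deficits and nodal connectivity shifts under Gaussian,
stationary dynamics — not that it would have equal power on real fMRI.

## A note on GSR and nodal effects

Global-signal regression removes each series' projection on the cohort
mean signal. A *uniform* elevation of one node's row of the correlation
matrix loads almost entirely on that global component, so GSR absorbs much
of it: the measured Enod effect of a 0.04 row shift is ≈ 0.35 SD with GSR
versus ≈ 1 SD without. The recovery analyses in the test suite therefore
run the without-GSR variant — which is why the pipeline treats with- and
without-GSR as first-class dual variants rather than a single setting.

# Numerical choices and degenerate inputs

* Edge counts use round-half-away-from-zero; tie-breaks are documented and
  deterministic everywhere (edge ranking, Youden cutoff).
* Constant (zero-variance) ROI columns are an input error naming the node;
  rank-deficient confound designs are an error naming the collinear
  columns.
* Graphs with no valid degree-preserving swap (e.g. a triangle) are
  returned unchanged with a message.
* `swaps_per_edge = 0` is allowed as a degenerate identity null
  (γ = λ = σ = 1), useful for testing.
* All randomization (simulation, folds, bootstrap, subsampling, rewiring)
  derives from explicit integer seeds through one substream function; the
  compiled rewiring uses its own Mersenne Twister stream so results are
  platform-independent.

# Problem sizes in the shipped tests

The test suite exercises the full 160-node, 25-threshold design where the
science requires it (small-worldness, Eloc recovery over 20 replicate
cohorts of 20 + 20 subjects with 190 retained volumes, feature-selection
recovery with held-out cohorts) and miniature designs (6–40 nodes, a few
subjects, reduced null ensembles) where only mechanics are under test.
Null-model ensembles are reduced from 100 to 20 networks in the
small-world acceptance check; 100 are used by `scripts/acceptance.R`.

# Known limitations

* Lp on fragmented graphs averages connected pairs only; comparisons
  between graphs with very different fragmentation should rely on Eglob.
* The internal validation reuses training subjects by design and must not
  be read as generalization accuracy.
* The LASSO support at n = 40, p = 160 is unstable for effects near one
  SD per node: joint recovery of five such features by cross-validated
  LASSO is not reliable at this sample size (the suite documents this
  honestly; recovery becomes reliable by ≈ 1.5 SD).
* Weighted, signed, and directed network variants are out of scope, as are
  betweenness/degree centralities, modularity and rich-club statistics.
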