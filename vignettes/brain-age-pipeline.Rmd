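---
title: "Characterizing healthy aging from functional connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing healthy aging from functional connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state fMRI measures spontaneous BOLD fluctuations; averaging the
signal within the parcels of an atlas (e.g. a 100-region, 17-network
cortical parcellation, or a 64-region multiscale one) gives each subject a
`T x p` matrix of regional time courses.  The static functional
connectivity (sFC) matrix is the `p x p` Pearson correlation of those
columns.  sFC reorganizes through adulthood — connectivity within some
networks declines roughly linearly with age, while other circuits rise
into middle age before declining — so the sFC carries enough signal to
predict a healthy adult's chronological age, and the *way* a predictive
model uses the matrix points at the circuits that age.

The package implements that programme end to end: sFC extraction,
four-bin age-group classification (young 20–40, adult 41–55, middle-old
56–69, old 70–88 years; ages outside 20–88 are excluded) and continuous
age regression with small attention-augmented convolutional networks, and
integrated-gradient attribution of the trained models back to connectome
edges and regions.

## Feature extraction

`compute_sfc()` is a plain Pearson correlation with hard validation:
zero-variance parcels are an error (in parcellated data they indicate a
parcellation fault, and the synthetic generator never produces them), as
are missing values and series shorter than 3 timepoints.  Classical
(vector-input) learners consume the strictly lower triangle, linearized in
a frozen row-major order — row 2 first, then row 3, and so on
(`vectorize_lower_triangle()`); `p(p-1)/2` gives 4950 features for
`p = 100` and 2016 for `p = 64`.  Any consistent order would do; freezing
one makes feature indices reproducible across runs and languages.

Inputs to the networks are standardized per edge: each matrix entry is
z-scored across the *training* subjects (population-SD convention), and
test data reuse the training moments (`standardize_features()`, or
`ayu_net(scale = "edge")`).  Whether the network should see raw
correlations or per-edge z-scores is not obvious a priori; the package
defaults to z-scores (which equalize edge scales and speed up
optimization) and keeps raw input behind `scale = "none"`.  Zero-variance
features — the diagonal, after z-scoring — pass through unscaled and are
reported, not errored.

## Architectures

Both trunks take the `p x p` matrix as a single-channel image, use 3x3
kernels, ReLU activations, 2x2 max-pooling, and end in one
fully-connected layer (64 units) plus an output layer — softmax over the
four groups for classification, one linear unit for regression.

* **VGG5**: convolutions at 32–64–128–128 channels with pooling after
  layers 1, 2 and 4.
* **ResNet5**: a stem convolution (32 channels) followed by four residual
  blocks at 32–64–128–128 channels, each two 3x3 convolutions with an
  identity shortcut (1x1 projection where the channel count changes);
  pooling follows the stem and the first two blocks, and once more after
  the fourth, so the last two blocks (the attention taps) share a
  resolution and the flattened trunk keeps several positions per channel.
  Residual sums are divided by sqrt(2): without normalization layers the
  activation variance would otherwise grow block by block, which in
  practice destabilized optimization.

The channel schedule and pooling placement are package choices (the layer
counts — five weight layers, four residual blocks — are the fixed part);
they are frozen in `build_model()` for reproducibility.  Pooling floors
odd dimensions and becomes a no-op once a map reaches a single position,
so the same code handles `p` of 32, 64, or 100.

Weights follow Kaiming initialization: each weight tensor is drawn from a
zero-mean normal with variance `2 / fan_in` (fan-in `9 * c_in` for a 3x3
convolution), biases start at zero, and the draw is fully determined by
the seed.

### The attention block

Attention attaches to layers 3 and 4 (the third and fourth
convolution/block outputs), before their pooling, with channel-reduction
ratios 1/2 and 1/4 respectively.  At a tapped layer with feature map
`x_i` (position `i`, `c` channels), two projections `M(x) = W_m x` and
`N(x) = W_n x` map each position to `ratio * c` dimensions.  Pairwise
compatibilities `M(x_i) N(x_j)^T` are averaged over `j`, a projection of
the global feature `g` (the flattened trunk output, through a learned
`W_g`) is added, and a softmax over positions yields the attention
weights `lambda` — nonnegative, summing to one.  The attended descriptor
is the lambda-weighted sum of the original local features; the
descriptors from both layers are concatenated with the flattened trunk
output before the fully-connected head.  (Whether the two descriptors
should be concatenated, summed, or used to re-weight the trunk is an open
design point; concatenation keeps all three information paths intact and
makes the ablation exact.)

Two numerical points matter:

* **Score standardization.**  Raw compatibility scores inherit the
  trunk's activation scale; on an untrained network they reach hundreds,
  the softmax saturates to a one-hot vector, and the gradients of `W_m`
  and `W_n` are exactly zero — the attention would stay frozen at its
  initialization.  The score vector is therefore standardized (mean 0,
  unit scale, a parameter-free layer norm) before the softmax.  This
  keeps the attention responsive at any activation scale and leaves the
  ordering of scores untouched.
* **Ablation.**  `attention = FALSE` creates no `W_m`/`W_n`/`W_g`
  parameters and forces `lambda` uniform, so the descriptor degenerates
  to average pooling.  Head dimensions are unchanged, which makes the
  with/without parameter-count difference exactly the size of the
  attention projections, and the comparison architecturally clean.

## Training and evaluation protocols

Loss functions are the standard pairings — cross-entropy behind the
softmax head, mean squared error behind the linear head.  The optimizer
is Adam (`lr = 1e-3` by default, no weight decay), batch size 16.
Initialization, batch shuffling, and therefore the final weights are
reproducible functions of the seed.  Training aborts with a diagnostic on
a non-finite loss; `epochs = 0` returns the untouched initialization.

Evaluation follows two protocols: a stratified 80:20 split
(`stratified_split()`, per-group test counts within one subject of 20%,
with sex as a secondary stratification key when present) and stratified
k-fold cross-validation (`cross_validate()`, per-fold class counts within
one of a perfect partition, fresh initialization per fold, mean row =
arithmetic mean of folds).  Regression is scored by MAE, RMSE, and the
coefficient of determination `r2 = 1 - SS_res/SS_tot` — which can be
negative and is *not* the squared correlation; the squared Pearson
correlation is reported alongside (`r2_pearson`) because the two are
often conflated.

## Integrated gradients and downstream summaries

For a scalar model output `F` (the softmax probability of the attributed
class by default — the predicted class unless one is named — or the
pre-softmax logit behind `output = "logit"`, or the regression output),
the attribution of input feature `i` is the Riemann approximation of the
path integral from an all-zero baseline matrix `x'`:

```
attr_i = (x_i - x'_i) * (1/m) * sum_{k=1..m} dF(x' + (k/m)(x - x'))/dx_i
```

The path runs in the network's input space.  With the default per-edge
z-scoring this gives the zero baseline a useful meaning: it is the
training-mean connectome, so the interpolated inputs stay inside the
distribution the network was trained on, and an edge earns attribution
only insofar as it deviates from the average subject.  (Attributing in
raw correlation units instead would divide every gradient by that edge's
training SD, systematically inflating low-variance edges, and would drag
the path through inputs many SDs outside the data.)  A user-supplied
baseline is given in correlation units and standardized like the input,
so a zero matrix reproduces the literal all-zero-correlation baseline;
under `scale = "none"` the two readings coincide.  Completeness is with
respect to `F(x) - F(baseline)`.  The default `m = 50` steps are checked
against completeness; if the relative gap exceeds 5% the step count
doubles, up to 800.  For a linear model the quadrature is exact at any
`m` (`integrated_gradients_path()` exposes the bare quadrature for such
checks).  Because the input is symmetric, the raw attribution of each
undirected edge is split between its two triangles; the result is folded
(upper + lower, mirrored) so each edge carries one number.

Group-level analysis (`group_attribution_analysis()`) attributes the
model's prediction on each age group's mean connectivity matrix, then
derives:

* **Node strengths** (`node_strength()`): per ROI, the sum of positive
  and of negative incident edge values, and their net.  Net strengths
  summed over nodes equal twice the summed edge values — each edge has
  two endpoints — which is the conservation check in the tests.
* **Edge tables** (`edge_contribution_table()`): one row per edge, one
  strength column per group, rows omitted when below 0.2 in every group.
* **Trajectory labels** (`trajectory_classification()`): per ROI, from
  the four ordered group values — `decreasing` when every step decreases
  or rises by at most `tau` and the young-to-old drop exceeds `tau`;
  `inverted_U` when the peak sits at adult/middle-old, both ends are
  below it, and the range exceeds `tau`; otherwise `flat`.  The default
  `tau = 0.01` is below the smallest group difference the analysis is
  meant to flag (about 0.02 on the correlation scale) and configurable.

Two notions of "strength" are supported, because attribution magnitudes
and correlation values live on different scales.  The default,
`mode = "masked_fc"`, reports the group-mean *correlation* of every edge
whose attribution magnitude reaches 20% of the maximum in any group —
attribution-selected connectivity.  Printed strength tables in this
literature carry values of 0.2–0.65 with a 0.2 omission rule, i.e. the
correlation scale, which is what this mode reproduces; it is also the
scale on which age trajectories of connectivity are interpretable.
`mode = "attribution"` reports the raw integrated-gradient values
instead.

## The synthetic cohort

`generate_cohort()` draws `n` subjects with ages uniform over 20–88 (a
preset reproduces the reference cohort's group sizes 172/152/154/160 for
split-arithmetic checks) and, for each subject, `T` multivariate-normal
timepoints whose correlation matrix carries the planted structure:

* `E_dec` edges fall linearly from 0.75 at age 20 to 0.05 at 88;
* `E_invU` edges follow a piecewise-quadratic inverted-U peaking at 0.75
  at age 60 (inside the middle-old bin) and falling to 0.15 at both ends;
* `E_null` edges sit at 0.45 at every age — informative about nothing.

Signal is planted in the correlation structure rather than mean
amplitude, because every downstream feature is a correlation.  The
default sets include shared-node triangles, so the planted matrix can
leave the PSD cone; it is repaired by eigenvalue clipping at `1e-6` and
rescaling to unit diagonal (`nearest_psd_corr()`), deterministically.
Independent Gaussian observation noise (SD 0.2) attenuates all
correlations by a common factor, as measurement noise does.

Defaults are `n = 600`, `p = 32`, `T = 200`.  The subject count and the
age range mirror a realistic single-site aging cohort; `p = 32` rather
than 100 keeps a full training run at desk scale (the architectures
handle `p = 100` unchanged, and shape-fidelity tests use it), and
`T = 200` gives per-edge sampling noise of about 0.07 — large enough
that the tasks are not trivial, small enough that they are solvable.
The trajectory endpoints were chosen once so that group-mean differences
(~0.1–0.3 in correlation) dominate that sampling noise.

What the generator does *not* emulate: temporal autocorrelation and
hemodynamics, scanner drift, motion artifacts, site effects, realistic
network topology (planted edges are a handful among `p(p-1)/2`), and
inter-subject variability beyond the age trend.  Tests passing on this
cohort therefore demonstrate that the pipeline's machinery — extraction,
optimization, attribution, aggregation — recovers planted structure;
they say nothing about accuracy attainable on real imaging data.

## Desk-scale study protocol

The reference protocol used by the package's end-to-end checks and by
`scripts/acceptance.R`: default cohort, stratified 80:20 split, ResNet5
with attention, Adam at `lr = 1e-3` (batch 16) for 25 epochs
(classification) or 15 (regression, whose loss plateaus earlier), three
seeds,
median-reported.  The epoch budgets came from watching the training loss
plateau on the default cohort; at this budget a full
classification + regression + attribution cycle runs in a few minutes on
one CPU core.  Under this protocol the held-out four-group accuracy sits
far above the 25% chance level, regression MAE is a few years, planted
edges dominate the attribution ranking, and the planted
decreasing/inverted-U labels are recovered for most incident ROIs (the
exact figures are computed, not quoted — run the acceptance script).

## Known limitations

* The networks are trained with a fixed protocol — no early stopping,
  no learning-rate schedule, no augmentation, no hyperparameter search.
* Attention at a tapped layer whose feature map has collapsed to a
  single position is degenerate (`lambda = 1`); with the default pooling
  schedule this happens for `p < 16`.
* Integrated gradients on the probability of a near-saturated class can
  have a tiny `F(x) - F(0)` denominator; the logit mode is the stabler
  choice there.
* Attribution credits what the *model* uses, not everything informative
  in the data: when several edges carry redundant age signal, a trained
  network may rely on a subset and leave the rest with near-zero
  attribution, so their ROIs classify as `flat` even though their
  connectivity does follow an age trajectory.  On the synthetic cohort
  this is visible as planted edges that never enter the attribution
  mask.
* The min-max rescaling flag on `compute_sfc()` exists for pipeline
  fidelity only; Pearson correlation is invariant to it by construction.
* Dynamic (time-resolved) functional connectivity is out of scope; the
  pipeline is static by design.
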