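---
title: "Sample expansion for small-sample expression classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample expansion for small-sample expression classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seclass)
```

## The problem and the model

Microarray-era tumor studies routinely produce expression matrices with
thousands of genes and twenty to sixty labelled samples. Neural classifiers
are data-hungry; at these sample sizes they either cannot be trained or
memorize immediately. `seclass` implements a corruption-based augmentation —
*sample expansion* (SE) — that manufactures labelled training rows from the
labelled rows one already has, plus two classifiers designed around it.

Sample expansion borrows the masking noise of denoising autoencoders but
moves it from the training objective to the dataset. For one training
profile `x` of length `m` and a corruption parameter `a`, one uniformly
random permutation of the `m` gene positions is cut into consecutive groups
of `a`; the first `floor(m/a)` groups each yield a copy of `x` with that
group's values set to 0. Reading the corruption groups off a single
permutation enforces the method's defining constraint — the groups of one
sample are pairwise disjoint ("non-repeated" corruption locations) — and
when `a` does not divide `m` the `m mod a` leftover positions are simply
never corrupted for that sample. Merged with the raw samples this produces
`n_train (floor(m/a) + 1)` rows, each carrying its source's label. The
manufactured rows are not new biological information; they are a structured
regularizer: the classifier is forced to tolerate any small group of genes
being silenced, so no single gene can carry the decision.

The augmentation sits inside a fixed pipeline: unsupervised gene ranking
(Infinite Feature Selection) keeps `k` genes; the reduced matrix is
standardized per gene; the data are split by class-stratified sampling;
only the training part is expanded; a classifier is trained and scored on
the raw held-out samples.

## Design choices, and why

**Corruption after standardization.** Expansion operates on standardized
rows, so a zeroed entry equals the gene's training mean — the analogue of
masking noise on standardized inputs. Zeroing *before* standardization would
instead inject a value whose meaning varies per gene. (A flag order could be
added without touching the count law, which is scale-free.)

**Corruption groups fixed once.** Each processed sample is generated once
and reused across training epochs, rather than redrawn per epoch. This keeps
the expanded set a dataset (writable, round-trippable, with provenance
columns recording source sample and corrupted indices) rather than a
stochastic layer.

**Normalization statistics from training samples only.** Per-gene means and
SDs are estimated on the training columns and applied to held-out columns,
so no test information leaks into the transform; `normalize_all = TRUE`
restores the simpler whole-matrix reading. The population SD (divide by
`n`) is used; with `n` around 5-13 the distinction from the sample SD is
visible but immaterial downstream, and constant rows map to zero rather
than dividing by zero.

**Stratified splits with the ceiling rule.** Training takes
`ceil(f · n_c)` samples of each class (default `f = 0.2`). The ceiling is
forced by the arithmetic of the published training-set sizes: classes
{8, 12} must give 2 + 3 = 5 training samples so that `5 × 501 = 2505` rows
at `a = 1`, and {12, 20, 10, 18} must give 13 so that `13 × 501 = 6513`.
Evaluation repeats the split (default 10 times) and pools accuracy as
total correct over total predictions; with 15 held-out samples per repeat
this reports in steps of 1/150, matching the two-decimal percent
convention the accuracy tables use.

**Inf-FS as a reconstruction.** The source describing this pipeline names
Infinite Feature Selection and its ingredients — a fully connected gene
graph, edge costs mixing standard deviation and Spearman correlation, and
a convergent matrix power series — but not the exact coefficients. The
implementation therefore follows the published Inf-FS formulation:
`A_ij = α max(σ̂_i, σ̂_j) + (1−α)(1 − |ρ_ij|)` with per-gene SDs rescaled
by their maximum so the two terms are commensurate, `α = 0.5` by default,
and scores from the closed form `S = (I − rA)^{-1} − I` with
`r = 0.9/ρ(A)`. This is flagged as a reconstruction, not a transcription;
a `selector = "variance"` fallback (top-k by SD) is provided for users who
prefer not to depend on it. The closed form is preferred over explicit
series summation for accuracy and cost; tests verify the two agree to
1e-8 once the geometric tail (ratio 0.9) is below that tolerance, which
takes a few hundred terms, not the few dozen one might guess.

**Tied-weight autoencoder with decode-from-code.** The autoencoder encodes
`y = σ(W x + b_y)` and decodes `z = σ(Wᵀ y + b_z)`. A literal reading of
the source's decoder formula would decode from `x` rather than `y`, which
contradicts both the autoencoder idea and the tied-weight dimension
arithmetic; it is treated as a typo and the decoder consumes the code. The
reconstruction cost is mean squared error — inputs are standardized
real-valued expression, for which cross-entropy is not defined — and the
classifier head is softmax with cross-entropy, the standard pairing that
keeps fine-tuning gradients well scaled (`head = "squared"` gives the
squared-error head for strict symmetry with the CNN).

**CNN conventions.** Convolutions use the cross-correlation convention
(no kernel flip — learned kernels absorb the difference), valid borders,
and full connectivity from all `k1` first-layer maps into each second-layer
map. Pooling windows are non-overlapping, the pool width must divide the
map length (checked at configuration time, where the whole chain
`m2 = m1−w1+1, m3 = m2/p1, m4 = m3−w2+1, m5 = m4/p2` is validated), and
pooling backprop routes each delta to its window's argmax, first position
on ties. The output layer is sigmoid with squared-error loss, so the
output delta is `(y − t)·y·(1−y)`; the loss is averaged over the batch.
The fully connected width `m6` is not fixed by the published architectures
and defaults to 100.

**Optimization.** Both models use plain gradient descent (the delta rule),
full batch by default, with uniform `±sqrt(6/(fan_in+fan_out))`
initialization (scaled by 4 for sigmoid layers) and biases 0. No momentum,
no adaptive optimizers — deliberately, to keep the update rule exactly the
stated one. Learning rates and epoch counts are not given by the source;
the defaults (`η = 0.1` for the SAE, `0.05` for the CNN, 100/200 epochs)
are conventional, and every experiment in the tests states its own,
chosen by pilot runs for convergence at the problem sizes used. All
randomness — initialization, permutations, splits, batch order — flows
from explicit seeds, and fits are bit-reproducible under them.

## What the synthetic generator emulates — and what it does not

`synth_spec()`/`generate_dataset()` produce the shape the method targets:
thousands of genes, tens of samples, 2-4 classes. Gene `g` has baseline
`μ_g ~ N(0, baseline_sd²)`; values add `N(0, noise_sd²)` noise; each of the
`n_informative` genes shifts exactly one class (assigned round-robin) by
`effect_size · noise_sd`. Defaults mirror the published dataset shapes
(e.g. 2000 × 62 with classes 22/40) with 100 informative genes and effect
size 2 — a clearly learnable but not trivial signal, in line with what a
two-group microarray comparison with moderate effect sizes would show
after gene selection.

The generator is Gaussian, independent across genes, and batch-free. Real
microarray data have heavy tails, gene-gene correlation blocks,
batch effects and intensity-dependent noise; a `lognormal` option restores
positivity but nothing else. Consequently, passing tests demonstrate that
the algorithms are implemented correctly and that expansion helps on clean
separable signal — they do not certify accuracy on real tumor data, whose
headline numbers additionally depend on the original microarray matrices
and unstated training hyperparameters and are explicitly out of scope here.

## Numerical checks the package holds itself to

* Every analytic gradient (autoencoder, fine-tuning stack, all eight CNN
  tensors) agrees with central finite differences to relative error below
  1e-5 on toy configurations — the single most load-bearing test of the
  backpropagation formulas.
* The expansion count law `n(floor(m/a)+1)`, exact-`a` zeros per row,
  per-sample disjointness and label inheritance hold over randomized
  `m, a, n` property tests.
* Standardized rows have mean 0 and SD 1 to 1e-10; the transform is
  idempotent; constant rows map to zero.
* Pooling backprop conserves delta mass into each window.
* Experiments are deterministic under their master seed.

Problem sizes in the test-suite experiments (500 genes, classes {8, 12},
expansion to 2505 rows, compact CNNs with `k1 = 6, k2 = 4`, tens of
epochs) are chosen so the whole suite runs in minutes on one CPU while
still exercising the full-size count laws and the 500 → 480 → 120 → 100 →
25 geometry.

## Known limitations

* Inf-FS edge weights are a reconstruction (see above); rankings may
  differ in detail from other implementations of the method.
* With `a` near `m`, expanded rows are mostly zeros and carry little
  signal; the method's own small-`a` regime (`a ≤ 5`) is the tested one.
* The CNN treats gene order as spatial structure. Expression vectors have
  no natural gene adjacency, so convolution acts as a random local mixing;
  this mirrors the published design rather than a modelling conviction.
* Plain gradient descent needs per-problem learning rates; the defaults
  are starting points, not guarantees.
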