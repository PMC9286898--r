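---
title: "Predicting compound-disease relationships from fused descriptor images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting compound-disease relationships from fused descriptor images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrscreen)
```

## The method

A compound-disease relationship (CDR) asserts that a compound treats, marks
or is mechanistically related to a disease.  `cdrscreen` predicts CDRs from
two per-entity feature vectors:

* a **molecular descriptor vector** $V_C = (b_1, \dots, b_{D_c})$ per
  compound (the reference pipeline uses $D_c = 5270$ Dragon descriptors:
  atom types, functional groups, topological and geometric indices, ...);
* a **symptom descriptor vector** $V_D = (a_1, \dots, a_{D_d})$ per disease
  ($D_d = 322$ literature co-occurrence weights from the human
  symptom-disease network).

Each candidate pair is *fused* into a two-dimensional matrix $M$ whose entry
for compound feature $r$ and disease feature $c$ is

$$ M_{rc} = \frac{b_r + a_c}{2}, $$

rendered as an 8-bit grayscale image (pixel $= \mathrm{round}(255\,M_{rc})$),
and classified by a softmax convolutional network that outputs the
probability that the pair is a true relationship.  Both descriptor tables are
min-max normalized per feature beforehand, so $M \in [0,1]$ and the image
uses the full dynamic range.

Downstream, the trained classifier screens a compound library: compounds
passing annotation filters (quality-control marker, detected in blood, or
oral bioavailability $> 30\%$) are paired with the disease panel, ranked by
predicted probability, and pairs above 0.9 are flagged as high-confidence
candidates.  Finally, SVM-RFE ranks which structural/ADME descriptors
separate candidate compounds from the rest: a linear SVM is fitted
repeatedly, each round scoring feature $i$ by $F_i = w_i^2$ and discarding
the single lowest-scoring feature.

## Design choices

Several points are genuinely open in this kind of pipeline; the package
settles them as follows.

**Normalization granularity.**  "Normalized separately" can mean per feature
or per entity vector.  The default is per-feature min-max to $[0,1]$,
computed over the compound table and the disease table independently,
because the fusion rule averages raw feature values and the grayscale
rendering requires a bounded range; z-scoring is rejected as unbounded.
Per-vector scaling is available via `normalize_descriptors(method =
"vector")` but is not the tested configuration.  Constant features map to 0
and are kept, so the feature count — and hence the image geometry — never
changes.  Missing values are an error by default (`na_action = "median"`
opts into column-median fill); silent imputation would alter images
invisibly.  Normalization parameters are fitted on the benchmark tables and
frozen; screened libraries are transformed with `apply_normalization()`,
which also clips to $[0,1]$ so out-of-range library compounds cannot break
the pixel contract.

**Matrix orientation.**  The fused matrix is stated both as "disease feature
as the row" and as having size $5270 \times 322$ (compound-feature rows).
The more specific statement wins: rows are compound features.
`build_cdr_matrix(..., transpose = TRUE)` exposes the other reading; the
two orientations carry identical information.

**Quantization.** Pixels are `round(255 * value)` with halves away from zero
(a fused value of exactly 0.5 becomes pixel 128); quantization error is at
most $1/510$.  Resizing for network input, when wanted, is corner-aligned
bilinear interpolation (`resize_image()`); the desk-scale network consumes
unresized images, and no claim is made about the rendering bytes of any
other implementation.

**Architectures and optimiser.**  `build_network()` provides three
architectures: `tiny` (two 3x3-conv/ReLU/2x2-maxpool blocks and a dense head
with 32 hidden units — the head is a hidden layer plus the 2-class output
because the planted benchmark label is bilinear in the two descriptor
vectors while every pixel is additive, so at least one nonlinear
combination stage after the convolutional features is needed to form
products), `alexnet_like` (five convolutions then three dense layers, ReLU
throughout, reduced channel widths) and `inception_like` (a stem convolution
and two inception blocks — parallel 1x1 / 3x3 / 5x5 / pooled-projection
branches concatenated along channels — with global average pooling).  All
end in a 2-class softmax trained by mini-batch SGD with momentum on
cross-entropy.  The full-scale reference settings (learning rate $10^{-4}$,
momentum 0.9, 20 epochs, batch 20) are the defaults for the two large
architectures; `tiny` defaults to learning rate 0.01, which matches its much
smaller parameter count and input size.  No weight decay and no learning-rate
schedule are applied, so runs are exactly reproducible from the seed; models
are trained from scratch (no pretrained weights).  Iterations per epoch
follow from the actual training-set size rather than any fixed count.
The hard label uses a strict rule: positive iff probability $> 0.5$, so a
probability of exactly 0.5 is negative.  Single-channel images are the
native input; channel replication is only a concern for externally shaped
networks.

**Held-out splits.**  The disease-held-out construction repeatedly picks a
random unassigned disease and moves *all* of its positive pairs into
training until the training target is reached, then samples the test
positives from the untouched diseases; the same grouped procedure is applied
independently to the negatives, and compound-held-out swaps the grouping
key.  Two details are settled here: (i) the first whole group that crosses
the target is kept — truncating mid-group would break the held-out
guarantee — and realized counts are recorded in the split provenance;
(ii) disjointness is enforced within each label class, mirroring the
stepwise construction, and any cross-class group overlap is reported rather
than forbidden.  A master seed derives per-repeat seeds as `seed + repeat`;
negatives are drawn once per experiment, not per epoch.

**Screening rules.**  The three admission clauses (QC, blood, OB $> 30\%$)
are a union — the reference text reads as a list of admissible classes — and
OB comparison is strict, so exactly 30 is excluded and a missing OB value
never passes.  An `"all"` mode exists for sensitivity analysis.  Pairs
already labeled in the benchmark are excluded from screening enumeration
(they are not unknown), and the number removed is reported.  "Predicted
positive" (probability $> 0.5$) and "candidate" (probability $> 0.9$) are
deliberately distinct counts.

**SVM-RFE.**  The SVM inside the loop is a linear-kernel `e1071::svm` with
cost 1 on z-scored features — a linear kernel is required for the weight
vector to exist, and squared weights are only comparable across features on
a common scale.  Elimination is strictly one feature per iteration (ties by
column order, first wins); a `step` option permits chunked removal for very
wide matrices but warns that it deviates from one-at-a-time elimination.
The importance reported for a feature is its squared weight at elimination
time, since a removed feature has no later weight.  No class reweighting is
applied by default.  How many features to keep is not fixed by the method;
`select_top_k()` takes an explicit `k` or a score threshold, and rankings
over structural and ADME descriptors can be run jointly or separately.
The candidate-vs-background labeling is an explicit input.

**MCC.**  The standard Matthews coefficient (with the square root and all
four marginal factors) is implemented; `classification_metrics(legacy_mcc =
TRUE)` additionally exposes a non-standard unnormalized variant occasionally
seen in print, for audit only.  Metrics with zero denominators are `NA`,
never 0.  AUC is the Mann-Whitney statistic with rank-averaged ties, which
equals the trapezoidal area under the full-sweep ROC curve.

## The synthetic benchmark

Real inputs (curated CDR databases, commercial descriptor software, the
symptom-disease network) cannot ship with a package, so
`simulate_cdr_world()` generates all three tables with a planted rule:

* compound latents $u_c \sim N(0, I_k)$ and disease latents
  $v_d \sim |N(0, I_k)|$ in a shared space ($k = 4$ by default);
* compound descriptors: dense Gaussian mixing of $u_c$ plus noise
  (`noise_sd`, default 0.5) — mimicking continuous molecular descriptors;
* disease symptom vectors: each symptom loads positively on one latent,
  plus noise, clipped at zero — sparse and non-negative like co-occurrence
  weights.  Disease latents are half-normal *by design*: with signed
  latents, clipping would erase the sign information that the label rule
  depends on, making the world unlearnable from the rendered image through
  no fault of the classifier;
* labels: $P(\text{positive}) = \mathrm{logit}^{-1}(s\,\langle u_c, v_d
  \rangle + \beta_0)$ with `signal_strength` $s$ (default 5) and $\beta_0$
  calibrated by root-finding so the expected positive rate equals
  `positive_rate` (default 0.5, matching a balanced benchmark); labels are
  then Bernoulli draws.

The default desk scale is 64 compounds x 32 diseases with 64/32 descriptor
dimensions, i.e. 2048 pairs and 64 x 32 images; QC/blood flags and OB
percentages are drawn at configurable rates so the screening filter is
exercisable.  Everything is bit-reproducible from the seed.

What the generator does *not* emulate: real descriptor correlation
structure, molecular graphs or SMILES, disease ontology structure, and the
extreme class imbalance and label noise of curated databases.  Passing tests
therefore demonstrate that the pipeline's machinery is correct and that the
classifier can extract a planted cross-table signal from the fused images —
not that any particular accuracy will be achieved on real curated data.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at sizes chosen to exercise the
claimed behaviour in minutes on one CPU:

* end-to-end learnability: 2000 pairs sampled 1:1 from the default world,
  75/25 split, `tiny` at its defaults (20 epochs); held-out AUC is required
  to exceed 0.9 at `signal_strength = 5` and to sit within $0.5 \pm 0.07$
  at zero signal;
* imbalance series: ratios 1:1 through 1:5, 2000 pairs each, three repeats
  averaged (the benchmark procedure), 10 epochs — scaled down alongside the
  10x smaller sample; sensitivity and MCC must decline monotonically up to
  one small inversion while accuracy stays roughly flat;
* split guarantees: 100 seeded held-out splits at 750/250 per class;
* SVM-RFE: two features planted at a two-standard-deviation shift among
  three noise features, $n = 200$, 100 seeds; both planted features must
  occupy the top two ranks in at least 95 runs;
* metric identities: the exhaustive grid of confusion matrices with entries
  0..20 against per-sample tallies, and AUC against brute-force concordant
  pair counting on small tied score sets.

## Known limitations

* The convolutional engine is plain vectorised R: ideal for desk-scale
  images and exact reproducibility, but training the full-scale
  architectures on 224 x 224 inputs is computationally out of reach here;
  the two large architectures are provided for completeness and forward
  passes, with `tiny` as the tested surface.
* The additive fusion destroys within-cell multiplicative interactions (a
  pixel sees only $b_r + a_c$); classifiers must reconstruct interactions
  from the global image, which is exactly what the planted benchmark
  stresses.
* One-at-a-time RFE on thousands of features is $O(p^2)$ SVM fits; use
  `step` for exploratory runs on very wide matrices.
* Published absolute benchmark values depend on external curated databases
  and commercial descriptors and are not reproducible from this package;
  only the printed comparison arithmetic and the qualitative behaviours are.

## A worked desk-scale example

```{r example, eval = FALSE}
w <- simulate_cdr_world(sim_config(seed = 7))
enc <- encode_world(w)
pos <- w$pairs[w$pairs$label == "positive", ]
pool <- w$pairs[w$pairs$label == "negative", ]
pool$label <- "unknown"
sp <- make_ratio_datasets(pos, pool,
                          split_spec(sample_size = 2000, repeats = 1,
                                     seed = 42))[["1"]][[1]]
comp <- normalize_descriptors(w$compounds)
dis <- normalize_descriptors(w$diseases)
model <- cdr_cnn(encode_images(comp, dis, sp$train),
                 as.integer(sp$train$label == "positive"),
                 cdr_train_config("tiny", seed = 1))
metric_report(predict(model, encode_images(comp, dis, sp$test),
                      type = "prob"),
              sp$test$label)
```

See the README for the output this produces and for how to regenerate the
package's headline numbers with `scripts/acceptance.R`.
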