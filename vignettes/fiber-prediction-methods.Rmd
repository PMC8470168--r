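---
title: "Methods: category-partitioned weighted KNN for fiber imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: category-partitioned weighted KNN for fiber imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberknn)
```

This vignette is the package's own account of its method: the model and
its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical conventions, and the
design choices that were genuinely open. It states no empirical result
that the test suite does not itself compute.

## The model

A packaged product is represented by six nutrient features per 100 g or
100 mL: total sugar, starch, protein, saturated fat, unsaturated fat,
and sodium. Two are derived from panel arithmetic — starch =
carbohydrate − total sugar, unsaturated fat = total fat − saturated fat
— so the six are mutually exclusive mass fractions, which keeps
collinearity low. The prediction target, fiber, is voluntary on labels
and therefore missing for a large share of products.

Features are min–max normalized with *training-set* extrema. The
distance between two normalized products is the Manhattan distance
(sum of absolute coordinate differences), and a query's fiber is the
inverse-distance weighted average of its k = 8 nearest same-category
neighbors' labeled fiber values, Q = Σ w_j q_j / Σ w_j with w_j = 1/d_j.

The core assumption is local smoothness: products close in panel space
have similar ingredient profiles and hence similar fiber. The method
cannot extrapolate — predictions are convex combinations of neighbor
fibers, so they never leave the range of observed fiber values in the
query's category — and its error grows where the training data are
sparse, which is why the first-neighbor distance d1 is reported with
every prediction as a confidence proxy.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 8 | neighbors | performance plateaus around 8 in cross-validation; fewer is noisy, more blurs category sub-structure |
| `metric` | manhattan | — | Manhattan and Euclidean perform almost identically here; Manhattan is cheaper and is the reference semantics |
| `weighting` | inverse | — | 1/d weighting emphasizes close (more similar) products and consistently beats uniform averaging |
| `caution_threshold` | 0.08 | d1, normalized 6-feature scale | beyond this first-neighbor distance, predictions rest on weak evidence and should be interpreted with caution |
| `min_reporting_rate` | 0.25 | fraction | categories where fewer than a quarter of products report fiber provide too thin a neighbor pool |
| `train_fraction` | 0.75 | fraction of brands | conventional 75/25 split, applied to brands, not products |

All thresholds are inclusive at the boundary (a category at exactly 25%
reporting is retained; fiber exactly at a density cut-off takes the
upper class) — a single convention applied everywhere for determinism.

## Why a hard category partition, not dummy features

Restricting neighbors to the query's category can be attempted by
appending 0/1 category indicator features. With Manhattan distance on
[0,1]-normalized features this does *not* guarantee same-category
neighbors: two dummy coordinates differ by at most 2.0 in total, while
the six nutrient coordinates can differ by up to 6.0, so a nutrient-close
product from another category could still win. The package therefore
implements the same-category guarantee directly as a hard per-category
partition of the training store, which makes the property structural
rather than metric-dependent (and is cheaper).

## Numerical conventions and degenerate inputs

* **Zero distance.** The weight 1/d is undefined at d = 0. A query with
  exact matches in the store is predicted as the unweighted mean of all
  zero-distance neighbors among the selected k — the limit behavior of
  inverse weighting and the dominant convention for weighted KNN.
* **Ties at the k-th neighbor** are broken by ascending neighbor
  product id, so predictions are deterministic and independent of store
  order.
* **Leave-self-out** is by product id, not by feature equality: a query
  present in the store never uses itself, but true duplicate
  formulations under different ids still count as neighbors.
* **Small stores.** If a category store holds fewer than k products,
  all of them are used (`k_effective`).
* **No clipping** of query features outside the training range:
  normalized values may leave [0,1]. Clipping would discard signal and
  would break the invariance of predictions under positive rescaling of
  any raw feature (tested as a property).
* **Constant features** (min = max in training) normalize to 0; any
  constant contributes nothing to any pairwise difference.
* **Negative derived features** (starch or unsaturated fat slightly
  below 0 from independently rounded label values) are clamped to 0
  with a warning.
* **Percentiles** (medians, IQRs, d1 quartile edges) use linear
  interpolation between order statistics (R type 7) throughout; d1
  quartile groups are lower-inclusive on their edges.
* **Exclusion rules** are applied in a fixed order (missing panel,
  missing ingredients, unbalanced ingredients, missing brand, duplicate
  id) and each product is logged under the *first* rule it violates,
  mirroring a sequential exclusion flow chart. The parenthesis check is
  count-based, not nesting-based: `")("` passes, a truncated list does
  not.
* **Group comparison.** The reported-vs-unreported fiber comparison is
  a two-sided Mann–Whitney rank-sum test: the two groups are
  independent samples of unequal size, for which a signed-rank (paired)
  test is not applicable. Exact p-values (full enumeration) are used
  for min(n1, n2) ≤ 8 without ties; otherwise the normal approximation
  with tie correction.
* **Cross-validation** deals products (not brands) into five folds and
  refits normalization parameters inside every fold to avoid leakage of
  test extrema. Tie-breaks in hyperparameter selection prefer smaller
  k, then Manhattan, then inverse weighting — simpler computation at
  equal accuracy.

## The synthetic generator: what it emulates, what it does not

`generate_supply()` draws, per category: a mass composition over
(sugar, starch, protein, saturated fat, unsaturated fat, other) from a
brand-tilted Dirichlet scaled to 100 g; log-normal sodium; a true fiber
value `clamp(β0 + β1·starch + β2·sugar + ε, 0, other)` carved out of
the "other" mass so that all seven masses sum to exactly 100 g; and a
reporting flag with probability `plogis(γ0 + γ1·fiber)`.

Choices worth recording:

* **Concentration scale.** Archetype Dirichlet concentrations are the
  category's mean composition scaled to a total concentration of 60,
  giving unimodal component marginals with standard deviations of a few
  grams — the within-category spread of real panels. (Concentrations
  summing to ~10 were tried first and rejected: Beta(<1,·) marginals
  put mass at the extremes and produce physically absurd tail products
  such as juices with 10 g fiber per 100 mL.)
* **Fiber depends on starch and sugar only** — deliberately simple so
  that recoverability can be reasoned about analytically; σ controls
  the irreducible error.
* **Carbohydrate excludes fiber by default** (the Australian
  "available carbohydrate" labeling convention);
  `carbohydrate_convention = "total"` switches to US-style labels to
  allow experiments on cross-convention transfer.
* **Reporting masking defaults** γ0 = −1, γ1 = 0.35 give roughly half
  of products reporting, with the reporting group visibly richer in
  fiber — the direction and rough magnitude of real-world reporting
  bias.
* **Brand effects** tilt a brand's concentrations by a log-normal
  factor (sd 0.15), clustering same-brand products in feature space;
  this is what makes product-level splits leak and motivates the
  brand-grouped split.
* **Determinism.** One RNG stream per `generate_supply()` call, seeded
  once, with a documented draw order (per category: brand tilts, brand
  assignments, compositions, sodium, fiber noise, reporting uniforms).

What the generator does **not** emulate: ingredient lists with real
structure (a fixed balanced template is used), label rounding, serving
sizes, pack-size variants, category hierarchies, or fiber that depends
on non-carbohydrate features. A green test on synthetic data therefore
establishes that the pipeline is implemented correctly and behaves as
the theory predicts — not that any particular accuracy will be achieved
on a real national food supply, where the fiber relation is rougher and
categories are less cleanly separated.

## Open design decisions taken

* **Density class boundaries are lower-inclusive** ([0.9, 3.7) is
  "low", etc.), consistent with "negligible < 0.9".
* **The "pack size variant" deduplication** seen in real pipelines is
  replaced by a generic duplicate-id rule: identity criteria for pack
  variants are data-source specific.
* **Category intake-share filtering** (dropping categories that
  contribute little to population fiber intake) requires external
  dietary survey data; it is exposed as a user-supplied category
  allow-list instead.
* **Brand quota rounding** in the split is `ceiling` on the training
  side.
* **Products on a per-100 mL basis are pooled** with per-100 g
  products, as label-data pipelines conventionally do; the `basis`
  field is carried through for users who want to stratify.
* **Config files are JSON** rather than YAML (no extra dependency;
  semantics identical, flag > file > default).

## Known limitations

* Exhaustive-scan neighbor search is O(store size) per query — the
  intended reference semantics; category stores in label datasets are
  small (10²–10⁴), so no approximate index is provided.
* Cross-validation folds are product-level, not brand-level; CV scores
  may be slightly optimistic relative to the brand-grouped test split.
  The final evaluation is always brand-grouped.
* A query in a category absent from the training data cannot be
  predicted; such products are flagged and excluded from predicted
  summaries with a warning rather than silently dropped.
* Predictions cannot exceed the fiber range seen in the query's
  category store (convexity) — a feature for robustness, a limitation
  for genuinely novel high-fiber products.
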