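---
title: "Probabilistic pathway scores: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic pathway scores: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`propscore` scores one sample against one pathway by asking: *how probable is
this sample's expression under the pathway's reference behaviour?* The
reference behaviour is a linear-Gaussian Bayesian network on the pathway's
directed acyclic graph: each gene node is normal with mean linear in its
parents,

$$X_i \mid \mathrm{pa}(X_i) \sim \mathcal{N}\!\left(\beta_0 + \textstyle\sum_k \beta_k\, y_k,\ \sigma^2\right),$$

fitted by maximum likelihood on reference samples (healthy and non-lesional
tissue in the disease application). The per-node MLE is the ordinary
least-squares fit, with the residual variance divided by $n$, not $n-p-1$ —
the MLE, not the unbiased estimator. The sample's pathway score is the joint
log-likelihood, a sum of per-node conditional log-densities in natural-log
units (nats). No per-node normalization is applied: pathways of different
sizes live on different scales, which is deliberate — downstream random
forests are scale-tolerant, and absolute scores are only ever compared
within a pathway.

Key assumptions: expression is continuous, approximately Gaussian on the log
scale, and already normalized and batch-corrected *before* it reaches this
package (the annotation records batch labels but nothing here transforms
intensities); pathway topology is taken as given and assumed relevant at the
mRNA level; reference samples characterize the unperturbed state.

## DAG construction from cyclic pathway graphs

Curated pathways contain feedback loops, but a Bayesian network needs a DAG.
We start from the node set with no edges and insert the deduplicated edges in
a uniformly random permutation determined by an integer seed, skipping any
edge whose insertion would create a cycle. Consequences:

* acyclic inputs keep 100% of their edges, for every seed;
* a simple $k$-cycle loses exactly one edge — which one depends on the seed;
* self-loops (length-1 cycles) are always dropped;
* parallel duplicate edges are deduplicated first, since a duplicate edge
  cannot change a Gaussian parent set and would only inflate dropped-edge
  counts.

KGML relations whose subtype is an undirected interaction
(binding/association) are emitted as two opposed directed candidate edges;
both enter the insertion pool, so either direction may survive, and a cycle
formed by the pair resolves to whichever direction comes first. KGML group
entries expand to their component genes with relations duplicated to each
member; entries naming several genes expand over all gene pairs. These are
documented reader choices — pathway databases do not prescribe them.

The insertion order is a potential source of variance, so
`edge_order_dispersion()` refits and rescores a pathway over many orderings
(seeds `seed + 1 … seed + n_orderings`) and reports each sample's index of
dispersion — variance over $|\text{mean}|$; the absolute value matters
because log-likelihoods are typically negative. It is exactly zero for
acyclic pathways (identical DAGs, identical fits), zero by definition when
all values are identical, and flagged `Inf` rather than erroring in the
degenerate zero-mean case. A run fixes one shared seed for all pathways
(default 0), and the dispersion analysis bounds the consequences of that
choice.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `seed` (DAG-ification) | 0 | — | one integer fully determines all edge permutations; shared across pathways per run |
| variance floor $\varepsilon$ | 1e-8 | (log-expression)² | a perfect linear fit would give an unusable zero-variance Gaussian; engaging the floor warns |
| ridge $\lambda$ | 1e-6 | — | only for underdetermined or rank-deficient node regressions, applied to parent coefficients, never the intercept; flagged on the fit |
| GED `alpha` | 0.05 | — | conventional KS significance level for gene inclusion |
| `n_models` | 100 | — | ensemble size over which the median AUC is taken |
| `ntree` | 500 | — | the randomForest classification default; hyperparameters are recorded verbatim in reports, not tuned |
| `n_orderings` | 1000 | — | resolution of the dispersion analysis |

# Competitor feature methods

The four set-based pathway scores treat a pathway as a bag of genes. Where
the original descriptions leave formulas open, the choices here are:

* **LLR** — per gene, class-conditional Gaussians (MLE mean and variance) are
  fitted on the two case classes' *training* samples; the raw per-sample LLR
  is z-normalized per gene and summed over the pathway. The normalization is
  frozen on training statistics by default (`pool_normalization = TRUE`
  pools all scored samples instead — the original description is ambiguous
  between the two). A gene whose two class fits coincide has zero LLR
  variance; its normalized value is defined as 0.
* **CORG** — pathway genes are z-scored across all samples, ranked by
  absolute Welch $t$ between the case classes, and added greedily to the
  responsive subset while the averaged-activity $t$ ($\sum_S z / \sqrt{|S|}$)
  strictly improves. The strict-improvement stop and $\sqrt{|S|}$ scaling
  follow the original method; the selected genes are recorded as metadata.
* **NTC** — Euclidean distance to the per-gene reference centroid in the
  pathway's gene subspace.
* **GED** — two features per pathway (over- and under-expressed). A gene
  participates when a two-sample KS test between either case class's
  training values and the reference values is significant at `alpha`; its
  per-sample score — by default the absolute reference-standardized deviation
  $|x - \mu_{\mathrm{ref}}| / \mathrm{sd}_{\mathrm{ref}}$, an injectable
  function since the original work does not print a formula — accumulates
  into the over or under feature according to the sign of the training-mean
  deviation. No promiscuous-gene or silhouette pruning is applied, keeping
  all methods comparable.

Gene inclusion, class fits and normalization constants always come from
training samples only; a test sample can never flip a decision. Welch
(unequal-variance) $t$ is used wherever a "t-test score" is needed, as the
robust default; the one deliberate asymmetry is the misclassification
report, which uses the classic pooled-variance Student $t$-test, matching
how that analysis is conventionally named.

# Evaluation harness

Ensembles are `n_models` random forests differing only in seed
(`seed + 0 …`; bootstrap resampling of training samples is available behind a
flag but off by default, since the protocol inside a seed-varied ensemble is
otherwise unspecified). AUC uses the Mann-Whitney convention (tied pairs
count ½) with class A — the Crohn's-disease analogue — positive; AUPRC uses
step-wise interpolation over distinct thresholds, so constant scores give
the positive prevalence. DeLong's paired test uses the structural-component
covariance estimate with a two-sided normal approximation; identical score
vectors have a zero-variance difference, mapped explicitly to $z = 0$,
$p = 1$. Aggregate validation metrics pool per-sample *median*
class-probabilities across validation sets. MDS uses classical scaling of
cosine distances — an eigendecomposition, hence deterministic with no
stochastic layout stage.

# The synthetic generator

`make_scenario()` emulates the structure of a multi-study two-disease
comparison: disjoint random pathway DAGs (lower-triangular sampling under a
random node order, acyclic by construction), plausible log-intensity
parameters (intercepts uniform on 6–10, coefficient magnitudes 0.3–0.9 with
random sign, residual variances 0.25–1 — typical ranges for log2 microarray
data), ancestral sampling for reference and case samples, and optional
constant per-study offsets recorded as batches. Perturbations act on the
*generative* model — rescaling a pathway's coefficients or shifting every
intercept by a multiple of its residual SD — so "dysregulation = low
likelihood under the reference model" is literally true in the ground truth.

The default scale (20 pathways × 15 genes, 80 reference, 25 + 60 cases)
loosely mirrors the motivating study's training cohort while keeping runs
fast. What the generator does **not** emulate: probe-level artifacts,
heavy-tailed or non-Gaussian expression, correlated pathways sharing genes,
model misspecification of the topology, or realistic disease biology.
Passing the synthetic benchmarks therefore shows the machinery is correct
and powerful under its own assumptions — not that comparable AUCs will be
attained on real cohorts.

Problem sizes in the verification suite are chosen for statistical
adequacy: the null-calibration scenario uses 150 + 150 cases so the
chance-level band (AUC 0.5 ± 0.1) is several standard errors wide, the
parameter-recovery chain gives the root node variance 1 so downstream
coefficient standard errors at n = 1000 sit well inside the ±0.05 band, and
the power scenario uses the default sizes with a 5-SD mean shift.

# Numerical and degenerate-input choices

* Natural logarithm throughout.
* Zero-residual fits floor $\sigma^2$ at $\varepsilon$ with a warning rather
  than erroring; all-constant genes likewise.
* Underdetermined node regressions (samples ≤ parents) never crash: ridge on
  the coefficients, flagged on the returned fit.
* Duplicate gene or sample identifiers are hard errors on input, never
  silently merged; probes without a gene mapping are dropped with a count,
  never imputed.
* Pathways that lose every edge after restriction to measured genes are
  excluded (a topology score needs topology); an edgeless *input* set is an
  error only when nothing scorable remains.
* Cosine distance is undefined for all-zero feature vectors; the offending
  sample is named in the error.

# Known limitations

* Gene identifiers are opaque strings; expression and pathway files must
  already agree on the naming system.
* Forest probability cutoffs only transfer between datasets on a shared
  scale; cross-study harmonization (e.g. empirical-Bayes batch correction)
  is deliberately upstream of this package.
* The linear-Gaussian assumption ignores saturation and switch-like
  regulation; the score is a goodness-of-fit measure, not a mechanistic
  estimate.
* Structure is taken from the database; no structure learning is attempted,
  although any directed graph source can be supplied via the edge-list
  dialect.
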