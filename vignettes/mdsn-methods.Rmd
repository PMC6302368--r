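---
title: "Dysregulation networks and module-regularized classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dysregulation networks and module-regularized classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `mdsn`, the tunable
parameters and their defaults, the numerical choices made where the design
was open, what the synthetic generator does and does not emulate, and the
known limitations. It states no empirical numbers beyond what the package's
own tests and `scripts/acceptance.R` compute.

## 1. The dysregulation test

For miRNA $i$ and mRNA $j$ with expression vectors restricted to two sample
groups $A$ and $B$, the test statistic is built from the two sample Pearson
correlations $r_A$, $r_B$ via Fisher's variance-stabilizing transform
$z(r) = \tfrac12 \log\frac{1+r}{1-r}$:

$$z_{AB} = \frac{z(r_A) - z(r_B)}{\sqrt{1/(n_A-3) + 1/(n_B-3)}},
\qquad p = 2\,(1 - \Phi(|z_{AB}|)).$$

The raw correlation difference $\mathrm{Dys} = r_A - r_B$ is retained as the
effect measure, and `permutation_difference_test()` provides a
pooled-resampling companion that re-splits the two groups at random and
counts how often $|\mathrm{Dys}|$ is exceeded (add-one estimator, so the
p-value is never exactly zero).

Choices and defaults:

* **Significance threshold** `p_threshold = 0.001`, fixed rather than
  FDR-adjusted; an optional Benjamini–Hochberg mode (`p_adjust = "BH"`) is
  off by default. The network-level hard threshold downstream is the second,
  stronger noise filter.
* **Inverse-correlation prerequisite** (`require_negative = TRUE`): a pair
  enters the association matrix only if $r_A < 0$ or $r_B < 0$, applied per
  analysis. MiRNAs repress targets, so a pair positively correlated in both
  groups is treated as a likely confounded signal.
* **Group size** must be at least 4 in each group ($n-3 > 0$ in the variance
  term); smaller subtypes are skipped with a recorded warning.
* **Degenerate inputs**: correlations are clipped to $|r| \le 1 - 10^{-15}$
  before the transform; pairs with a zero-variance vector in either group
  are skipped and counted, never scored.
* **Pair universe**: all miRNA × mRNA combinations. No target-prediction
  database is consulted, so novel miRNA–target relations are scored on the
  same footing as known ones.

The Fisher p-value and the pooled-permutation p-value agree at the decision
level (both flag planted dysregulations far below the threshold, and both
are calibrated under the null), but they are *not* pointwise
interchangeable: the permutation distribution conditions on the realized
pooled sample, whose effective variance fluctuates at $n \le 100$, and the
unstandardized $|\mathrm{Dys}|$ statistic weighs unequal groups differently
from $z_{AB}$. At mid-range p-values the two can differ by several
hundredths for individual pairs. The test suite documents this honestly
rather than hiding it: the pointwise-agreement check is strict and can fail
while the decision-level and calibration checks pass.

## 2. Preprocessing

`preprocess_expression()` applies $\log_2(x + c)$ (pseudocount $c = 1$ by
default, configurable) and standardizes each feature to mean 0 and unit
*population* (divide-by-$n$) standard deviation. Pearson correlation is
invariant to the denominator convention, so this choice affects only stored
values; population scaling keeps a standardized row's own population sd
exactly 1. Constant features are zeroed, flagged, and excluded from
correlation testing. Preprocessing a matrix twice is an error, not a no-op.

## 3. From association matrix to network

Each analysis contributes a binary block; blocks are concatenated in
lexicographic analysis order, so the matrix is reproducible bit-exactly.
MiRNA similarity is the cosine of the corresponding rows, in $[0,1]$; an
optional power $\beta$ (default 1, mirroring soft-thresholding conventions
in co-expression analysis) is applied to the similarities. MiRNAs never
found dysregulated have zero rows and are excluded from the network rather
than carried as isolated vertices.

**Scale-free fit and hard threshold.** The fit score is the squared Pearson
correlation between $\log_{10}(\text{bin position})$ and
$\log_{10}(\text{bin frequency})$ over 10 equal-width bins in log space
(empty bins dropped, centers at arithmetic midpoints of the log bin edges).
Two modes exist: `degree` (default; bins the node degrees of the
thresholded, unweighted network, excluding degree-0 nodes) and `score`
(bins the surviving similarity values). Fewer than three occupied bins
makes the fit undefined (`NA`) and the threshold is skipped. The score is
the squared correlation exactly as defined — a *positive* log–log slope
also scores high, so the curve should be inspected
(`autoplot()` on the network draws it). `select_threshold()` scans an
ascending grid (default 0.05–0.95 in steps of 0.05) and returns the
*smallest* threshold whose fit reaches `r2_min` (default 0.8): the least
stringent pruning that preserves scale-free topology, keeping as many edges
as possible for module discovery.

The pipeline also accepts a fixed `threshold` in the config. This matters
for validation cohorts: a planted-module network is a union of
near-uniform-degree cliques, which is deliberately *not* scale-free, so the
$R^2$ criterion is undefined there and the recovery experiments use a fixed
threshold (0.3) instead. Threshold selection itself is validated separately
on constructed graphs with an exact $k^{-2}$ degree sequence flooded by
low-weight noise edges, where the fit-versus-threshold curve crosses 0.8
between two grid points and the least-stringent rule has a known answer.

## 4. Module extraction

Weighted modularity
$Q = \frac{1}{2m}\sum_{pq}\left[M_{pq} - \frac{k_p k_q}{2m}\right]
\delta(c_p, c_q)$ is optimized by an in-package Louvain implementation:
phase 1 visits nodes in random order and moves each to the neighboring
community with the largest positive modularity gain (ties keep the current
community); phase 2 aggregates communities into super-nodes with self-loops
and the phases alternate until no merge occurs. All hierarchy levels are
scored and the best-modularity level is returned. Because greedy node moves
are visit-order dependent, the optimizer performs 10 restarts (all derived
from the caller's seed, so results are reproducible) and keeps the best.
Edge weights are the cosine similarities — the network is never binarized;
hard thresholding has already removed weak edges.

On small random graphs the restarted greedy reaches the exhaustive-search
optimum in the large majority of cases but not always: some graphs have
optima separated from every greedy basin by multi-node moves, a known
limitation of the Louvain family (single-node refinement passes do not
escape it either). The test suite quantifies this against brute-force
enumeration over all partitions of up-to-8-node graphs.

Partitions from independent analyses are compared with normalized mutual
information, $\mathrm{NMI} = I(P_1;P_2)/\bar H$ with $\bar H$ the
arithmetic mean of the two partition entropies — label-invariant, symmetric,
in $[0,1]$, computed on the node-set intersection (pruning can drop
different nodes in different analyses). Two identical one-block partitions
score 1; a single-block partition against anything else scores 0.

## 5. The Sparse Group Lasso classifier

Stage prediction is one-vs-rest: for each class, labels are encoded
$\pm 1$ and a binary logistic model is fitted with the composite penalty

$$\frac{1}{s}\sum_{i=1}^{s}\log\!\left(1+e^{-y_i (w^\top x_i + b)}\right)
+ \lambda\alpha\|w\|_1
+ \lambda(1-\alpha)\sum_g \sqrt{|g|}\,\|w_g\|_2 .$$

Groups are the discovered MDSN modules; miRNAs outside every module become
singleton groups so no feature is silently excluded. The intercept is
included and unpenalized (configurable): standardized features keep it
small, but dropping it harms calibration. Prediction takes the class with
the highest linear score.

**Optimizer.** Monotone FISTA (accelerated proximal gradient with
backtracking line search and adaptive restart on momentum failure). The
proximal operator of the composite penalty is exact and closed-form:
coordinate soft-threshold at $t\lambda\alpha$, then per-group block
soft-threshold at $t\lambda(1-\alpha)\sqrt{|g|}$. Convergence is declared
when the relative objective change stays below `tol` (default $10^{-6}$)
for three consecutive accepted steps, capped at `max_iter = 10000`; the
recorded objective path is non-increasing by construction. With
$\lambda = 0$ the fit reproduces unpenalized logistic regression (checked
against `glm` in the tests); at $\alpha = 0$ selection is exactly
group-wise (each group entirely zero or entirely active).

**Penalty scale.** The loss above is the *mean* logistic loss, so useful
$\lambda$ values are an order of magnitude smaller than they would be for a
summed loss. On the synthetic cohorts the package's experiments use
$\lambda = 0.05$, $\alpha = 0.5$ — chosen once, when the study conditions
were defined, as the regime where both the SGL and the pure-L1 baseline
keep non-degenerate coefficient sets; the config default `sgl_lambda = 1`
is retained for interface compatibility but fully shrinks standardized
synthetic cohorts of this size.

**Evaluation.** AUROC is computed rank-based (ties count ½), per class
one-vs-rest, on a stratified 20% holdout; `cross_validate_sgl()` runs
stratified k-fold selection over a $(\lambda,\alpha)$ grid by mean
macro-AUROC. Biomarker candidates are the features with nonzero
coefficients, ranked by maximum absolute coefficient across classes (for a
binary tumor-vs-normal model this is the usual binary ranking); precision
and recall at $k$ are reported against a user-supplied known-marker list.

## 6. The synthetic cohort generator

`simulate_cohort()` emulates a sample-matched miRNA/mRNA cohort on the
standardized scale:

* Each planted module $m$ has a disjoint block of miRNAs and a disjoint
  block of target mRNAs. Within subtype $C$, a shared latent Gaussian
  factor per (module, sample) with loading $a=\sqrt{|\rho|}$ on miRNAs and
  $\mathrm{sign}(\rho)\,a$ on targets gives every (module miRNA, module
  target) pair population correlation exactly $\rho_{mC}$, and unit
  marginal variance. The same construction induces within-module
  miRNA–miRNA correlation $|\rho|$ — acceptable because the pipeline never
  uses miRNA–miRNA expression correlation.
* Background features are independent standard normals, so background
  pairs are exact nulls.
* Stage labels come from an ordinal model: latent
  $\eta = \text{effect\_size} \times \text{mean expression of the relevant
  modules' miRNAs} + \text{logistic noise (scale noise\_sd)}$, cut at its
  empirical quantiles into `stage_classes` (default 5, i.e. normal + four
  stages) balanced ordered classes. `effect_size = 0` makes stages
  independent of expression.
* The default correlation scheme plants repression ($\rho=-0.8$) in the
  first subtype and none elsewhere — the correlation-flip scenario the
  dysregulation test targets. Default group sizes (60 per subtype) are
  comfortably above the $n \ge 4$ floor and give the Fisher test realistic
  power. The stage-signal experiments use a single cohort of 150 samples,
  within-module correlation 0.3, effect size 8 and noise scale 0.5 —
  a regime where the signal is spread over a module and the training set is
  small enough that the group prior matters.
* Everything is reproducible bit-for-bit from one integer seed, and the
  caller's RNG state is restored afterwards.

What it does **not** emulate: RNA-seq count noise (negative binomial,
library-size effects), batch effects, correlated background structure,
miRNA families, or missing annotations. Passing tests on these cohorts
demonstrates correctness of the statistical machinery under its own
assumptions — bivariate-normal expression with exactly planted
correlations — not robustness to the full messiness of tumor expression
data.

## 7. Problem sizes used in validation

The validation suite runs at desk scale, chosen so that every guarantee is
measured on a problem the oracles can verify exactly: cohorts of 100–360
samples and 20–100 miRNAs / 50–300 mRNAs for pipeline-level checks; 200
pairs × 10,000 permutations for the permutation-oracle comparison; all 4,140
partitions enumerated per graph for 200 small graphs in the Louvain
comparison; 100 random instances for the prox oracle; 10 seeded cohort
replicates for the SGL-versus-L1 comparison. Headline counts from the
original application (thousands of features, millions of tested pairs) are
functions of cohort size and are not reproduced here; the acceptance script
reports the corresponding quantities at synthetic scale.

## 8. Known limitations

* The Fisher z-test is asymptotic; at the minimum group size (4–10 samples)
  its calibration degrades and the permutation companion is preferable.
* Pointwise agreement between the Fisher and pooled-permutation p-values at
  mid-range p is limited by the conditional nature of permutation inference
  (Section 1).
* The scale-free fit score does not penalize positive log–log slopes; a
  diagnostic curve should be inspected for non-monotone networks.
* Louvain is a greedy heuristic: restarts mitigate but do not eliminate
  convergence to local optima.
* One-vs-rest linear scores are non-monotone in an ordinal latent stage;
  intermediate-stage AUROC is intrinsically weaker than extreme-stage
  AUROC, as the worked example in the README shows.
* The SGL penalty scale depends on the loss normalization; $\lambda$ values
  are not transferable between mean-loss and sum-loss implementations.
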