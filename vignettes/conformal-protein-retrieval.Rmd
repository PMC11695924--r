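---
title: "Risk-controlled protein retrieval: models, thresholds and calibrated probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-controlled protein retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformalpr)
```

## The problem

Fast homology and function-prediction models score every query protein
against a lookup database, but the scores themselves are arbitrary: modern
embedding models can emit nearly all of their similarity values inside a
sliver such as \[0.9995, 1\], and a raw cutoff carries no statement about
how many of the returned proteins are actually functional matches. This
package treats threshold selection as a statistical calibration problem.
Given a calibration set of annotated queries, it picks a threshold
$\hat\lambda$ such that retrieval sets built for *future, exchangeable*
queries have expected loss at most a user-chosen $\alpha$, and separately
converts individual scores into calibrated probabilities of a true match.

Everything is model-agnostic: the only inputs are a query-by-lookup score
matrix $S_{ij}$ with a declared kind (similarity or distance) and an
annotation table (Pfam accession sets, or 4-level EC/SCOPe hierarchy
labels).

## Losses

A retrieval set for query $x$ at threshold $\lambda$ is
$C_\lambda(x) = \{y : S_{xy} \ge \lambda\}$ (similarity; $\le$ for
distances). Three set losses are built in:

* **FDR** — fraction of retrieved proteins that are not matches,
  $FP/(FP+TP)$. Empty set: 0 (no discoveries, no false discoveries).
* **FNR** — fraction of the query's true matches in the lookup that were
  missed, $FN/(FN+TP)$. A query with no true matches scores 0 and is
  flagged so it can be excluded from calibration.
* **Hierarchical mismatch** — for 4-level labels, each retrieved item is
  charged $c_d$ where $d \in \{0,\dots,4\}$ is the depth of the first
  level at which its label disagrees with the query's ($d=0$: exact match;
  $d=4$: wrong class). The set loss is the maximum item charge (the mean
  is available behind a flag); the empty set scores 0, so abstention — the
  correct answer for a query without homologs — is never penalized. With
  costs $(0,1,2,3,4)$ the loss of a singleton set reduces to the mismatch
  depth itself.

Two conventions deserve a note. Wildcard levels (`2.3.1.*`, common in
preliminary enzyme annotations) count as *agreement* by default, since
penalizing an un-asserted level would discourage exactly the partial
matches such annotations exist to permit; the strict reading is a flag.
When a query carries several valid labels, the minimum loss over its labels
is used, so the model is not penalized for agreeing with one admissible
assignment. Unannotated retrieved proteins count as non-matches rather than
being dropped — dropping them would bias the FDR downward.

## Threshold calibration

All calibration code sees one *permissiveness* parameter under which sets
are nested nondecreasing: similarity thresholds are negated internally,
distance thresholds pass through. This single convention prevents sign
errors when the same machinery serves similarity search and
Euclidean-distance classification.

**Conformal risk control (CRC).** For a loss monotone in permissiveness
and bounded by $B$, the calibrated threshold is the boundary of the grid
region where the empirical risk satisfies
$\hat R(\lambda) \le \alpha - (B-\alpha)/n$. The $(B-\alpha)/n$ term is
the finite-sample correction; with $B = 1$ it is the familiar
$(1-\alpha)/n$, and the $B$-general form follows from requiring
$(n\hat R + B)/(n+1)\le\alpha$. For FNR-type losses (nonincreasing in
permissiveness) the *least* permissive qualifying value is returned — the
smallest risk-controlled retrieval sets, which is what makes database
prefiltering useful. For losses that grow with the set (the hierarchical
max-loss) the search is mirrored: scan from restrictive to permissive and
return the most permissive qualifying value. Constant (e.g. identically
zero) curves return the most permissive grid value. This direction-aware
reading resolves an ambiguity in how the selection rule is usually written
for a single orientation; both branches are oracle-tested against an
exhaustive scan of the defining inequality.

**Learn-then-Test (LTT).** FDR is not monotone in the threshold (adding a
match dilutes it, adding a non-match raises it), so CRC's guarantee does
not apply. Each grid value is instead treated as a hypothesis and validated
only if a Hoeffding upper confidence bound clears the target:
$R^+(\lambda) = \hat R(\lambda) + B\sqrt{\log(1/\delta)/(2n)} \le \alpha$.
Multiple testing over the grid uses fixed-sequence testing from the most
restrictive to the most permissive threshold, stopping at the first
failure; this preserves the level-$\delta$ guarantee without a Bonferroni
power loss. The choice of fixed-sequence ordering and of the Hoeffding
bound are design decisions of this package (the bound enum is left
extensible); nothing in the guarantee depends on curve monotonicity.

**Hierarchical certificate.** Controlling the expected hierarchical loss
at $\alpha$ simultaneously bounds every mismatch depth:
$c_i\,P(\text{loss}=c_i) \le E[\text{loss}] \le \alpha$, i.e.
$P(\text{loss}=c_i)\le\alpha/c_i$ (with $\alpha/0=\infty$).
`hierarchical_risk_certificate()` reports the ladder of implied bounds
against empirical level frequencies.

**Numerical choices.** The default grid is a 200-point quantile grid of
the calibration scores plus the extremes — resolution scales with data
density and keeps oracle tests cheap. Per-row monotonicity violations up
to $10^{-12}$ are treated as float noise; anything larger routes the
curves to LTT. Among tied qualifying grid values the numerically smallest
canonical value wins, making output deterministic. If no grid value
qualifies, the fully restrictive threshold (all sets empty) is returned
with a warning rather than an unguaranteed guess. Boundary inclusion is
$\ge$ for similarity and $\le$ for distance by default — the published
descriptions of thresholded retrieval are inconsistent about boundary
strictness, so this is a documented choice, with `strict = TRUE`
switching to strict inequality; on continuous scores the two differ with
probability zero.

## Probability calibration

`pava_fit()` solves isotonic least squares — minimize
$\sum_i (\hat p_i - y_i)^2$ subject to $\hat p_1\le\dots\le\hat p_n$ — by
a single linear pool-adjacent-violators pass over score-sorted data. Tied
scores are pooled (weighted average) first, which makes the minimizer
unique and the step function well defined at tied scores. Prediction is
the clamped step function: interior scores take the left-knot value,
out-of-range scores the terminal fitted values.

`venn_abers()` runs two isotonic regressions per test score, one with the
hypothetical label 0 appended and one with label 1, and reads the fitted
value at the test position. The interval $[\hat p^0, \hat p^1]$ is a valid
probability of correctness under exchangeability, at any calibration size;
its width shrinks as $n$ grows. Test points are calibrated one at a time
(the inductive form). The default point estimate is the midpoint; the
log-loss-optimal $p_1/(1-p_0+p_1)$ is a flag. `ece()` provides the usual
equal-width-bin expected calibration error for evaluating either route.

## Synthetic world

The generators state the world the calibration experiments assume; their
defaults are fixed once and are not tuning knobs.

* `gen_flat_instance()`: 400 queries × 2000 lookup proteins. Each protein
  draws one of 50 annotation profiles (1–4 Pfam accessions from a
  30-accession vocabulary), giving a ≈2% exact-match rate — enough true
  matches per query (~40) for FNR to be meaningful, sparse enough that FDR
  control bites. Match pairs draw scores from Beta(8,2), non-match pairs
  from Beta(2,8): stochastically ordered but overlapping, so thresholding
  has a genuine trade-off. `compress_top` applies $s^{1/5}$ to mimic the
  near-1 score pileup of real embedding models (used to stress isotonic
  calibration).
* `gen_hierarchy_instance()`: a 4/3/3/3-branching label tree (108 leaf
  classes, comparable to a few-hundred-class enzyme task at desk scale);
  a query's distance to a class centroid is
  $1 + 2\cdot\text{depth} + N(0, 0.7^2)$ — distances grow with tree
  separation, with enough noise that risk control at the family level is
  non-trivial. A configurable fraction of non-member queries sits far from
  every centroid (the non-enzyme analogue whose correct retrieval is the
  empty set).
* `gen_prefilter_instance()`: homologous pairs (5%) share a latent quality
  $u$ driving both the fast-model similarity and a structural Z-score
  (monotone links plus noise); Z below 2 is reported as 0, as structural
  aligners do. Non-homologs have Z = 0 and background similarities.

Queries are i.i.d., hence exchangeable by construction — a green coverage
test establishes that the calibration machinery delivers its guarantee *in
that world*. It does not establish robustness to the distribution shifts of
real protein databases (taxon sampling bias, annotation quality drift,
missing families); `loss_cdf_compare()` exists precisely to let users check
on their own splits whether losses look exchangeable before trusting the
guarantee, and the generators make no attempt to match real UniProt/AFDB
marginals beyond the qualitative shapes above.

## What the acceptance experiments compute

`scripts/acceptance.R` re-runs, at desk scale, the calibration experiments:
the hierarchical worked example (loss 1 for a retrieved enzyme diverging at
the serial level); 100 calibration/test shuffles of a flat instance with
LTT-FDR control at $\alpha=0.1$ and CRC-FNR control at $\alpha=0.1$; and
CRC family-level FNR control at $\alpha=0.01$ on the hierarchical instance.
The grid is computed once per instance from the pooled scores and shared
across shuffles, mirroring the single-dataset reshuffling design of the
experiments it emulates. Reported values are mean test risks across the
100 trials; they are expected to land *below* their $\alpha$ (CRC/LTT are
conservative: the finite-sample correction, the Hoeffding penalty and the
discrete grid all round toward safety), not at it.

## Known limitations

* Guarantees are marginal over queries, not conditional per family or per
  class; a threshold can over-cover abundant families and under-cover rare
  ones while meeting its marginal target.
* Distribution shift between calibration and deployment voids the
  guarantee; no shift-robust variant is implemented.
* The max-separation and p-value selectors are independent readings of
  one-sentence descriptions of external baselines (candidate window
  $m=10$, add-one p-values); they are baselines for comparison, not
  reproductions of any external codebase.
* The Kneedle elbow is the no-smoothing, sensitivity-1, vertical
  chord-distance form; sequences that never drop below their endpoint
  chord (linear or concave descent) have no elbow and raise an error
  rather than returning an arbitrary point.
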