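---
title: "Methods: chi-square gene ranking, direct classification, and forward selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chi-square gene ranking, direct classification, and forward selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chi2irgdc)
```

## The model

All of the machinery rests on one object: an m×2 contingency table of
class-conditional frequency counts, scored by the Pearson chi-square
statistic in product form,

$$\chi^2 = N\left(\sum_{k=1}^{m}\sum_{q=1}^{2}
  \frac{f_{kq}^2}{n_k\,T_q} - 1\right),$$

with row totals $n_k$, column totals $T_q$ and grand total $N$. Two kinds
of tables are built from a genes × samples matrix with labels
$y_i \in \{C_1,\dots,C_m\}$:

* **Mean-split (single gene).** Column 1 counts samples above the gene's
  mean over all samples, column 2 those below, per class.
* **Ordering (gene pair).** Column 1 counts samples where gene $j$'s value
  exceeds gene $l$'s *within the same sample*, column 2 the reverse.

In both, a sample whose comparison is an exact tie contributes 0.5 to each
column of its class row, so every table's grand total is exactly the
number of samples. All counts are therefore multiples of 0.5 —
exactly representable in floating point, which matters below.

The statistic is used purely as an association score: no p-values, no
degrees-of-freedom correction, no continuity correction anywhere.

### Integrated gene ranking

A gene's integrated weighted score combines its main effect with its share
of every pairwise association:

$$S_j = \chi^2_j + \sum_{l \ne j}
  \frac{\chi^2_j}{\chi^2_j + \chi^2_l}\,\chi^2_{j,l}.$$

The two ends of a pair receive complementary weights summing to 1, so the
total pairwise mass $\sum_{j<l}\chi^2_{j,l}$ is conserved across the
ranking (a property the test suite asserts). Genes are ordered by
descending $S_j$ into the list $\Theta$.

### The direct classifier

With $r \ge 2$ selected genes, classifying a test sample requires no
fitted parameters. For each hypothesized class $C_k$, the sample is
provisionally added to $C_k$: each of the $r(r-1)/2$ ordering tables gains
one unit of mass in row $k$ (placed by the sample's own within-sample
orderings, split in half on ties), giving tables over $n+1$ samples. The
summed statistic $\chi^2_{(C_k)}$ measures how much the hypothesis
strengthens the class-by-ordering association; the prediction is
$\arg\max_k \chi^2_{(C_k)}$. Because only orderings enter, the prediction
is invariant under any strictly increasing transformation of the test
sample's values — the robustness-to-batch-distortion property of the
relative-expression classifier family.

The classifier deliberately uses *ordering* tables only. A mean-split
reading would be incoherent here: adding the test sample would shift every
gene's mean and re-split all $n$ training samples, and the construction
counts exactly $r(r-1)/2$ tables — one per gene pair.

### Forward selection

The wrapper stage scores a gene subset by two numbers from leave-one-out
cross-validation: the accuracy, and the mean margin $\bar h$ where, for a
sample with true class $C_t$,

$$h = \sum_{k \ne t}
  \frac{\chi^2_{(C_t)} - \chi^2_{(C_k)}}{\chi^2_{(C_t)}}
  \;\in\; (-\infty,\, m-1].$$

Selection initializes with $\Theta$'s top two genes, then examines
candidates from the head of $\Theta$ up to a cap of
$\max(2, \mathrm{round}(0.02\,p))$ genes in total. A candidate is accepted
iff LOOCV accuracy strictly increases, or stays equal while $\bar h$
strictly increases; otherwise it is permanently discarded as redundant.
The procedure is purely forward (no backward pass; the initial pair is
never revisited) and completely deterministic.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `tie_tol` | table builders | 0 | absolute tolerance for declaring a comparison tied; 0 = exact floating-point equality. Expression values rarely tie except by design, so near-tie declaration is opt-in. |
| `cap_fraction` | selection | 0.02 | fraction of $\Theta$ examined (initial pair included), `round()`ed, floor 2. |
| `pair_prefilter` | ranking | off | evaluate pairs only among the top-K genes by $\chi^2_j$; genes outside keep $S_j = \chi^2_j$. The full $O(p^2)$ computation is the default and the faithful choice; the prefilter exists for very large $p$ and is recorded in the output header. |
| `orientation`, `delimiter` | loader | auto | matrix layout and TSV/CSV dialect. No log transform, scaling or imputation is ever applied; missing values are an error. |

## Numerical conventions

* **One chi-square kernel.** The scalar statistic, the batch ranking, the
  incremental classifier and the cached LOOCV all call the same summation
  routine. Counts are multiples of 0.5, so removing or adding a sample's
  contribution to cached tables is exact, and the incremental paths agree
  *bit for bit* with from-scratch table reconstruction — the test suite
  asserts identity, not approximate equality.
* **Zero margins.** A cell on a zero row or column total contributes 0 to
  the sum (0/0 := 0), the limit of the textbook
  $\sum (O-E)^2/E$ form; the two forms agree to ≤ 1e−9 relative error on
  random fractional tables, and the statistic stays finite on degenerate
  tables.
* **Zero-weight pairs.** In $S_j$, a pair with $\chi^2_j = \chi^2_l = 0$
  contributes to neither gene: with no marginal effect on either end there
  is no basis for attributing its (necessarily weak) association.
* **Degenerate margins.** If a held-out sample's true-class score is 0,
  its $h$ is taken as 0 with a warning: all-zero scores carry no evidence,
  and propagating NaN into the accept rule would be worse.
* **Tie-breaks, all fixed.** Ranking: $S_j$, then $\chi^2_j$, then gene id
  (lexicographic). Classification argmax: class-set order, which is the
  sorted order of the label strings fixed at load. Two runs on the same
  input are byte-identical, including all written artifacts.
* **Strict comparisons.** The accept rule uses strict `>` with no
  tolerance, as stated; an equal-accuracy, equal-margin candidate is
  rejected. A candidate that duplicates a selected gene provably ties both
  quantities (its pairs either tie everywhere or replicate existing
  tables), so duplicates are always rejected — a test constructs this.

## Open design points, and how they were resolved

* The score sum runs over $l \ne j$: a gene has no ordering table with
  itself, so self-pairing is excluded.
* The 2% cap counts the initial two genes within it, and `round()` (R's
  banker's rounding) maps the fraction to a count with a floor of 2.
* $\Theta$ is computed once on the full training set, not per LOOCV fold.
  This mirrors the procedure's filter-then-wrap structure but means the
  held-out sample influenced the ranking — a mild optimistic bias in
  reported LOOCV, flagged here and not corrected.
* Class labels are opaque strings; their sorted order fixes contingency
  row order and every tie-break, giving determinism without hidden state.

## The synthetic generator

The generator emulates exactly the structure the statistics are built to
detect, with known ground truth:

* **Noise genes**: iid standard Gaussian, class-independent. On null data
  the mean single-gene statistic calibrates to its asymptotic mean of
  $m-1$ (a 2×2 split has one degree of freedom), which the acceptance
  checks verify on 2,000 genes.
* **Planted single genes**: Gaussian with class means
  $\pm(k - (m+1)/2)\,\mathrm{effect}\cdot\sigma$, so adjacent classes
  differ by `effect_size` in units of the noise sd. The sign alternates
  across planted genes (up-, down-regulated, …), as in real differentially
  expressed gene sets; if all planted genes shifted the same way, their
  mutual within-sample orderings would be class-independent and the
  ordering classifier could not see them at all.
* **Planted pairs**: both genes share a per-sample latent level
  $z \sim N(0,1)$ and sit at $z \pm 0.5\,o$, where the orientation
  $o = \pm 1$ follows the class and flips independently per sample with
  probability `flip_prob`. The offset of ±0.5 keeps the two marginals
  nearly class-neutral (the signal lives in the ordering, as for real
  top-scoring pairs) while making the flip probability exact by
  construction rather than a byproduct of noise.
* A log-normal option exponentiates the matrix for positive, skewed
  values; orderings — and hence all pairwise statistics — are unchanged.

The default configuration — two classes of 60 samples split evenly into
train and test, 200 noise genes, two planted singles at effect size 2.0,
one planted pair at flip probability 0.05 — is the study condition used by
the acceptance checks and `scripts/acceptance.R`.

What the generator does **not** emulate: correlated noise between genes,
class-imbalanced designs (supported, but not defaulted), heavy-tailed or
platform-specific measurement error, and batch effects. Passing tests
therefore demonstrate correctness of the machinery and recoverability of
idealized planted signal, not performance on any real cohort.

## Problem sizes

The test suite works at deliberately modest scale: oracle-equivalence
checks use up to 40 samples, 6 genes and 4 classes per instance (100
instances for classification, 20 for LOOCV, 1,000 random tables for the
statistic); recovery and calibration studies use the default 204-gene /
60-sample condition over 20 generator seeds, and null calibration uses
2,000 noise genes on 100 samples. The full suite and the acceptance
script each run in well under a minute on one core.

## Known limitations

* **Margin dilution biases selection toward very small panels.** The
  margin $h$ normalizes the score gap by the true class's total
  $\chi^2_{(C_t)}$, which grows with every added pair while a single
  sample's contribution stays $O(1)$ — so $h$ is $O(1/n)$, and adding a
  gene whose new pairs are weaker than the existing ones *lowers*
  $\bar h$ even when the gene is genuinely informative. Combined with the
  strict accept rule and a LOOCV that is already near ceiling after the
  top-two genes under the default study condition, forward selection
  frequently accepts nothing: the acceptance run reports the resulting
  selection recall of planted genes alongside the (high) independent-test
  accuracy of the panels it does select, and a planted ordering pair is
  only recovered when both halves outrank all noise genes within the 2%
  cap. Users wanting larger panels should raise `cap_fraction` and
  inspect the selection trace rather than trust the default cap.
* **A pair-only gene can be invisible to the ranking.** $S_j$ weights
  every pairwise statistic by relative single-gene strength, so a gene
  whose signal lives purely in orderings (near-zero $\chi^2_j$) receives
  almost none of its own pairwise mass. One half of a planted pair can
  drop far down $\Theta$ when its marginal happens to be weak in a given
  draw.
* **Cost.** Ranking is $O(p^2 n)$ in time and memory over pair
  statistics; at $p$ in the tens of thousands use `pair_prefilter`, at
  the cost of fidelity to the full-pair definition.
* **Mean-split statistics are not distortion-robust.** Only the pairwise
  half of the method is invariant to monotone per-sample transforms; the
  single-gene statistic (and hence the ranking) is not, and a test pins a
  counterexample.
* **LOOCV reuses the full-training ranking** (see above), so reported
  LOOCV slightly flatters the selected subset; the independent test
  accuracy in `run_pipeline()` is the honest number.
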