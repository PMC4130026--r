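# chi2irgdc

Informative-gene selection and multiclass tumor classification from labeled
gene-expression matrices, built entirely on chi-square statistics of m×2
contingency tables.

## The problem and who this is for

Expression studies of tumors routinely face thousands of genes measured on
a few dozen labeled samples, and the goal of picking a small, interpretable
gene panel that still classifies independent samples well. Classifiers in
the relative-expression (top-scoring-pair) family use only *which of two
genes is higher within a sample*, which makes them robust to monotone
per-sample distortions such as batch or platform effects — but they need a
good way to find the informative genes first. This package implements a
filter–wrapper hybrid that does both, for bulk or single-cell matrices with
two or more classes.

## The method

For a training set of *p* genes and *n* samples with labels in
*C = {C₁, …, C_m}*:

1. **Single-gene statistic.** For gene *G_j*, split samples at the gene's
   overall mean x̄·j into an m×2 table of class-conditional counts (above /
   below; a sample exactly at the mean contributes ½ to each column of its
   class row) and score it with the Pearson chi-square statistic in product
   form, χ²_j = N(Σ_k Σ_q f²_kq / (n_k T_q) − 1).
2. **Pairwise statistic.** For genes *(G_j, G_l)*, the m×2 table counts
   samples per class with x_ij > x_il versus x_ij < x_il (within-sample
   ties give ½ each); χ²_{j,l} is the same statistic. Only within-sample
   orderings enter, so χ²_{j,l} is invariant under any strictly increasing
   per-sample transformation.
3. **Integrated weighted score.**
   S_j = χ²_j + Σ_{l≠j} [χ²_j / (χ²_j + χ²_l)] · χ²_{j,l} — each pair's
   association is split between its two genes in proportion to their
   single-gene strengths. Genes are ranked by descending S_j into the
   ordered list Θ.
4. **Direct classifier (no training).** With *r* selected genes, a test
   sample is provisionally assigned to each class in turn; each of the
   r(r−1)/2 pairwise tables is updated to n+1 samples and the statistics
   are summed into χ²_(C_k). The prediction is argmax_k χ²_(C_k).
5. **Forward selection with redundancy removal.** Starting from Θ's top
   two genes, candidates from the top 2% of Θ are introduced one at a
   time; a candidate is kept only if the leave-one-out accuracy strictly
   increases, or ties while the mean margin
   h = Σ_{k≠t} (χ²_(C_t) − χ²_(C_k)) / χ²_(C_t) strictly increases.
   Rejected genes are discarded as redundant.

A synthetic-data generator with planted mean-shift genes and planted
class-dependent ordering pairs (plus pure-noise genes) makes the whole
pipeline testable without any external data.

## Worked example

```r
library(chi2irgdc)

cfg <- synthetic_config(seed = 42)   # 2 shift genes, 1 ordering pair, 200 noise
sim <- generate_dataset(cfg)
sim$train
#> Labeled expression dataset: 204 genes x 60 samples
#> Classes: C1 (n=30), C2 (n=30)

report <- run_pipeline(sim$train, sim$test)
report
#> Pipeline evaluation
#>   selected genes:  2 (SHIFT02, SHIFT01)
#>   train LOOCV:     0.9500
#>   test accuracy:   0.8500
#>   per-class accuracy:
#>     C1     C2
#> 0.8333 0.8667
```

The ranking put the two planted mean-shift genes on top; forward selection
kept the initial pair (their LOOCV was already 0.95 and no candidate
strictly improved it), and the two-gene panel classified 85% of the 30+30
held-out samples correctly — read `report$trace` for the per-candidate
accept/reject record and `report$confusion` for the error structure. The
planted ordering pair can be evaluated directly with
`classify_batch(sim$train, c("PAIR01a", "PAIR01b"), sim$test)`.

A command-line wrapper with `rank`, `select`, `classify`, `evaluate`,
`simulate`, `stats` and `overlap` subcommands is installed at
`system.file("scripts", "chi2irgdc.R", package = "chi2irgdc")`.

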