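# Shared chi-square kernel. F1, F2: n_tables x m matrices of class-conditional
# counts for the two columns of each m x 2 table (fractional counts allowed —
# the half-count tie rule produces multiples of 0.5, all exactly
# representable). Every path in the package (scalar, batch ranking,
# incremental classification, LOOCV) funnels through this one routine so
# that identical tables always give bit-identical statistics.
#
# Statistic: N * (sum_kq f_kq^2 / (n_k * T_q) - 1), algebraically the Pearson
# chi-square without continuity correction. Zero-margin convention: a cell
# whose row or column total is 0 is itself 0 and contributes 0 (0/0 := 0),
# matching the limit of the Pearson form.
chi2_counts <- function(F1, F2) {
  nk <- F1 + F2
  T1 <- rowSums(F1)
  T2 <- rowSums(F2)
  N <- T1 + T2
  d1 <- nk * T1
  d2 <- nk * T2
  t1 <- F1 * F1 / d1
  t1[d1 == 0] <- 0
  t2 <- F2 * F2 / d2
  t2[d2 == 0] <- 0
  pmax(N * (rowSums(t1 + t2) - 1), 0)
}

# Classify each value of d (a signed comparison) as greater / less / tie.
# tie_tol = 0 means exact floating-point equality, the default reading of
# the tie rule; a positive tolerance declares near-ties.
split_comparison <- function(d, tie_tol = 0) {
  g <- d > tie_tol
  l <- d < -tie_tol
  list(greater = g, less = l, tie = !g & !l)
}

# Per-class fractional counts for a logical comparison split, as a 1 x m
# pair of rows (greater-column and less-column counts). `cls` is the
# dataset's label factor; empty classes yield zero rows.
class_counts <- function(split, cls) {
  m <- nlevels(cls)
  idx <- as.integer(cls)
  f1 <- f2 <- numeric(m)
  for (k in seq_len(m)) {
    in_k <- idx == k
    f1[k] <- sum(split$greater[in_k]) + 0.5 * sum(split$tie[in_k])
    f2[k] <- sum(split$less[in_k]) + 0.5 * sum(split$tie[in_k])
  }
  list(f1 = f1, f2 = f2)
}

new_contingency_table <- function(f1, f2, classes) {
  counts <- cbind(greater = f1, less = f2)
  rownames(counts) <- classes
  structure(list(
    counts = counts,
    row_totals = rowSums(counts),
    col_totals = colSums(counts),
    grand_total = sum(counts)
  ), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("m x 2 contingency table (grand total ", x$grand_total, "):\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Single-gene mean-split contingency table
#'
#' Builds the m-by-2 table of class-conditional frequency counts for one
#' gene: column `greater` counts samples whose expression exceeds the gene's
#' mean over *all* samples of the dataset, column `less` counts those below
#' it. A sample exactly at the mean contributes 0.5 to each column of its
#' class row (the half-count tie rule), so the grand total always equals the
#' number of samples.
#'
#' @param dataset An [expression_dataset()].
#' @param gene A gene id present in the dataset.
#' @param tie_tol Absolute tolerance for declaring a value tied with the
#'   mean; default 0 (exact floating-point equality).
#' @return A `contingency_table`: counts matrix plus row, column and grand
#'   totals.
#' @examples
#' d <- expression_dataset(
#'   matrix(c(1, 2, 3, 4), 1, 4,
#'          dimnames = list("g1", paste0("s", 1:4))),
#'   c("A", "A", "B", "B"))
#' single_gene_table(d, "g1")$counts
#' @export
single_gene_table <- function(dataset, gene, tie_tol = 0) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (!gene %in% dataset$gene_ids) stop("unknown gene: ", gene)
  x <- dataset$values[gene, ]
  sp <- split_comparison(x - mean(x), tie_tol)
  cc <- class_counts(sp, dataset$labels)
  new_contingency_table(cc$f1, cc$f2, dataset$classes)
}

#' Pairwise within-sample ordering contingency table
#'
#' Builds the m-by-2 table for a gene pair: column `greater` counts samples
#' where `gene_j`'s expression exceeds `gene_l`'s *within the same sample*,
#' column `less` the reverse; within-sample ties contribute 0.5 to each
#' column of their class row. Because only within-sample orderings enter,
#' this table — and every statistic built on it — is invariant under any
#' strictly increasing transformation applied uniformly within a sample
#' (e.g. monotone normalization or batch distortions).
#'
#' @inheritParams single_gene_table
#' @param gene_j,gene_l Two distinct gene ids.
#' @return A `contingency_table`.
#' @export
pairwise_table <- function(dataset, gene_j, gene_l, tie_tol = 0) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (identical(gene_j, gene_l))
    stop("pairwise table needs two distinct genes")
  for (g in c(gene_j, gene_l))
    if (!g %in% dataset$gene_ids) stop("unknown gene: ", g)
  d <- dataset$values[gene_j, ] - dataset$values[gene_l, ]
  sp <- split_comparison(d, tie_tol)
  cc <- class_counts(sp, dataset$labels)
  new_contingency_table(cc$f1, cc$f2, dataset$classes)
}

#' Chi-square statistic of an m-by-2 contingency table
#'
#' Computes `N * (sum_kq f_kq^2 / (n_k * T_q) - 1)`, the Pearson chi-square
#' statistic without continuity correction, on a table with possibly
#' fractional counts. Cells on a zero row or column margin contribute 0
#' (they are necessarily 0 themselves; 0/0 := 0), which is the limit of the
#' textbook `sum (O - E)^2 / E` form, so the two forms agree everywhere the
#' latter is defined. No p-value and no degrees-of-freedom correction: the
#' statistic is used purely as an association score.
#'
#' @param table A `contingency_table`, or a bare numeric m-by-2 matrix of
#'   non-negative counts.
#' @return A single non-negative number; 0 exactly when every row is
#'   proportional to the column totals.
#' @export
chi_square <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts
            else as.matrix(table)
  if (!is.numeric(counts) || ncol(counts) != 2L)
    stop("expected an m x 2 count table")
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) <= 0) stop("empty table: grand total must be positive")
  chi2_counts(matrix(counts[, 1L], nrow = 1L),
              matrix(counts[, 2L], nrow = 1L))
}

#' Single-gene chi-square statistics for every gene
#'
#' Batch equivalent of `chi_square(single_gene_table(dataset, g))` over all
#' genes, vectorized over the expression matrix.
#'
#' @inheritParams single_gene_table
#' @return Named numeric vector, one statistic per gene, in dataset gene
#'   order.
#' @export
all_single_chi_squares <- function(dataset, tie_tol = 0) {
  stopifnot(inherits(dataset, "expr_dataset"))
  X <- dataset$values
  D <- X - rowMeans(X)
  G <- D > tie_tol
  L <- D < -tie_tol
  Tt <- !G & !L
  m <- length(dataset$classes)
  idx <- as.integer(dataset$labels)
  F1 <- F2 <- matrix(0, nrow(X), m)
  for (k in seq_len(m)) {
    in_k <- idx == k
    half <- 0.5 * rowSums(Tt[, in_k, drop = FALSE])
    F1[, k] <- rowSums(G[, in_k, drop = FALSE]) + half
    F2[, k] <- rowSums(L[, in_k, drop = FALSE]) + half
  }
  stats::setNames(chi2_counts(F1, F2), dataset$gene_ids)
}

#' Pairwise chi-square statistics for all unordered gene pairs
#'
#' Computes `chi_square(pairwise_table(dataset, j, l))` for every unordered
#' pair of the given genes. The statistic is symmetric in the pair (swapping
#' the genes swaps the table's two columns, which leaves it unchanged), so a
#' symmetric matrix is returned with `NA` on the diagonal: a gene has no
#' pairwise table with itself.
#'
#' @inheritParams single_gene_table
#' @param genes Character vector of gene ids to pair up (default: all genes
#'   in the dataset); at least 2.
#' @return Symmetric numeric matrix indexed by gene id, `NA` diagonal.
#' @export
all_pairwise_chi_squares <- function(dataset, genes = NULL, tie_tol = 0) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (is.null(genes)) genes <- dataset$gene_ids
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("need at least 2 genes to form pairs")
  if (!all(genes %in% dataset$gene_ids))
    stop("unknown gene(s): ",
         paste(setdiff(genes, dataset$gene_ids), collapse = ", "))
  X <- dataset$values[genes, , drop = FALSE]
  r <- length(genes)
  m <- length(dataset$classes)
  idx <- as.integer(dataset$labels)
  out <- matrix(NA_real_, r, r, dimnames = list(genes, genes))
  for (j in seq_len(r - 1L)) {
    rest <- (j + 1L):r
    D <- matrix(X[j, ], length(rest), ncol(X), byrow = TRUE) -
      X[rest, , drop = FALSE]
    G <- D > tie_tol
    L <- D < -tie_tol
    Tt <- !G & !L
    F1 <- F2 <- matrix(0, length(rest), m)
    for (k in seq_len(m)) {
      in_k <- idx == k
      half <- 0.5 * rowSums(Tt[, in_k, drop = FALSE])
      F1[, k] <- rowSums(G[, in_k, drop = FALSE]) + half
      F2[, k] <- rowSums(L[, in_k, drop = FALSE]) + half
    }
    chi <- chi2_counts(F1, F2)
    out[j, rest] <- chi
    out[rest, j] <- chi
  }
  out
}
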