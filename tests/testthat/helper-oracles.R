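# Independent oracles and small fixture builders, kept deliberately naive:
# each re-derives its quantity from the definition, never through the code
# path it is checking.

# Textbook Pearson statistic sum (O - E)^2 / E with E = n_k * T_q / N,
# summed over cells with E > 0.
oracle_pearson <- function(counts) {
  N <- sum(counts)
  E <- outer(rowSums(counts), colSums(counts)) / N
  sum(((counts - E)^2 / E)[E > 0])
}

# Direct-classifier oracle: for each hypothesized class, append the test
# sample to the training set with that label and rebuild every pairwise
# table of the (n + 1)-sample dataset from scratch.
oracle_classify <- function(train, genes, test_values) {
  pairs <- utils::combn(genes, 2L)
  scores <- vapply(train$classes, function(k) {
    aug <- cbind(train$values[genes, , drop = FALSE],
                 heldin = test_values[genes])
    ds <- expression_dataset(aug, c(as.character(train$labels), k))
    sum(vapply(seq_len(ncol(pairs)), function(q)
      chi_square(pairwise_table(ds, pairs[1L, q], pairs[2L, q])),
      numeric(1)))
  }, numeric(1))
  list(per_class = scores,
       predicted = train$classes[which.max(scores)])
}

# Naive LOOCV: physically remove each sample and classify it against the
# remaining n - 1 with classify_sample() (which rebuilds its tables from
# scratch). Instances must keep >= 2 samples per class so the class set
# survives every fold.
oracle_loocv <- function(train, genes) {
  n <- length(train$sample_ids)
  correct <- logical(n)
  h <- numeric(n)
  for (i in seq_len(n)) {
    sub <- expression_dataset(train$values[, -i, drop = FALSE],
                              as.character(train$labels)[-i])
    sc <- classify_sample(sub, genes, train$values[, i])
    truth <- as.character(train$labels)[i]
    correct[i] <- sc$predicted == truth
    h[i] <- margin_h(sc, truth, on_zero = "zero")
  }
  list(accuracy = mean(correct), mean_margin = mean(h))
}

# Gaussian-noise dataset with no structure; every class keeps at least
# min_per_class samples so LOOCV folds preserve the class set.
random_dataset <- function(p, n_per_class, seed) {
  set.seed(seed)
  stopifnot(all(n_per_class >= 2L))
  labels <- rep(paste0("K", seq_along(n_per_class)), n_per_class)
  n <- length(labels)
  vals <- matrix(stats::rnorm(p * n), p, n,
                 dimnames = list(sprintf("g%03d", seq_len(p)),
                                 sprintf("s%03d", seq_len(n))))
  expression_dataset(vals, labels)
}

# Tiny dataset from an explicit genes x samples value matrix.
make_ds <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_dataset(values, labels)
}

# Random fractional m x 2 table in half-integer units (what the tie rule
# can produce), occasionally with continuous entries and zero cells.
random_table <- function(m, seed) {
  set.seed(seed)
  repeat {
    counts <- matrix(round(stats::runif(m * 2, 0, 10) * 2) / 2, m, 2)
    if (stats::runif(1) < 0.3)
      counts <- counts + matrix(stats::runif(m * 2, 0, 1), m, 2)
    if (stats::runif(1) < 0.3)
      counts[sample(m * 2, max(1L, m %/% 2))] <- 0
    if (sum(counts) > 0) return(counts)
  }
}
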