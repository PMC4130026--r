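# Cached pairwise-ordering tables for a fixed training set and gene subset.
# Holds, for each of the r(r-1)/2 gene pairs, the m x 2 class-conditional
# counts of the training samples (F1 = gene_j > gene_l, F2 = reverse; ties
# as half-counts), plus the per-sample comparison signs so a single
# sample's contribution can be added or removed in O(1) per pair. All
# counts are multiples of 0.5, so incremental updates are exact.
pair_cache <- function(train, genes) {
  stopifnot(inherits(train, "expr_dataset"))
  genes <- as.character(genes)
  r <- length(genes)
  if (r < 2L) stop("classification needs at least 2 genes")
  if (anyDuplicated(genes)) stop("duplicate gene ids in subset")
  if (!all(genes %in% train$gene_ids))
    stop("gene absent from training matrix: ",
         paste(setdiff(genes, train$gene_ids), collapse = ", "))
  X <- train$values[genes, , drop = FALSE]
  pairs <- utils::combn(r, 2L)
  D <- X[pairs[1L, ], , drop = FALSE] - X[pairs[2L, ], , drop = FALSE]
  sgn <- sign(D)                       # npair x n, in {-1, 0, 1}
  m <- length(train$classes)
  idx <- as.integer(train$labels)
  npair <- ncol(pairs)
  F1 <- F2 <- matrix(0, npair, m)
  for (k in seq_len(m)) {
    in_k <- idx == k
    half <- 0.5 * rowSums(sgn[, in_k, drop = FALSE] == 0)
    F1[, k] <- rowSums(sgn[, in_k, drop = FALSE] > 0) + half
    F2[, k] <- rowSums(sgn[, in_k, drop = FALSE] < 0) + half
  }
  list(genes = genes, pairs = pairs, F1 = F1, F2 = F2, sgn = sgn,
       labels = idx, classes = train$classes, n = ncol(X))
}

# Per-class summed chi-square for one sample given base tables (F1, F2) and
# the sample's pair orientations o (vector over pairs, in {-1, 0, 1}): for
# each hypothesized class the sample's unit of mass is added to that class
# row (split in half on a tie) and the r(r-1)/2 statistics are summed.
score_classes <- function(F1, F2, o) {
  inc1 <- (o > 0) + 0.5 * (o == 0)
  inc2 <- (o < 0) + 0.5 * (o == 0)
  m <- ncol(F1)
  scores <- numeric(m)
  for (k in seq_len(m)) {
    F1k <- F1
    F2k <- F2
    F1k[, k] <- F1k[, k] + inc1
    F2k[, k] <- F2k[, k] + inc2
    scores[k] <- sum(chi2_counts(F1k, F2k))
  }
  scores
}

classify_with_cache <- function(cache, values) {
  v <- values[cache$genes]
  if (anyNA(v))
    stop("missing gene value(s): ",
         paste(cache$genes[is.na(v)], collapse = ", "))
  o <- sign(v[cache$pairs[1L, ]] - v[cache$pairs[2L, ]])
  scores <- score_classes(cache$F1, cache$F2, o)
  names(scores) <- cache$classes
  structure(list(
    per_class = scores,
    predicted = cache$classes[which.max(scores)],
    margin_h = NA_real_
  ), class = "class_scores")
}

#' Classify one sample with the chi-square direct classifier
#'
#' The training-free direct rule: for each candidate class the test sample
#' is provisionally added to that class, every pairwise ordering table over
#' the `r` selected genes is updated to `n + 1` samples (the sample's
#' within-sample orderings add one unit of mass to the hypothesized class
#' row, split in half on ties), and the `r * (r - 1) / 2` chi-square
#' statistics are summed. The sample is assigned to the class whose
#' inclusion maximizes that sum — the hypothesis under which the data show
#' the strongest class-by-ordering association. Ties in the argmax are
#' broken by the class order fixed at load (sorted labels).
#'
#' No parameters are fitted: the only state is the training data and the
#' gene subset. Because only within-sample orderings enter, the prediction
#' is invariant under any strictly increasing transformation of the test
#' sample's values.
#'
#' @param train Training [expression_dataset()].
#' @param genes Character vector of `r >= 2` selected gene ids.
#' @param test_values Named numeric vector covering all `r` genes (extra
#'   names are ignored).
#' @return A `class_scores` object: `per_class` (named vector of summed
#'   chi-squares, one per class), `predicted` (the argmax class), and
#'   `margin_h` (`NA` here; see [margin_h()]).
#' @export
classify_sample <- function(train, genes, test_values) {
  cache <- pair_cache(train, genes)
  classify_with_cache(cache, test_values)
}

#' @export
print.class_scores <- function(x, ...) {
  cat("Per-class summed pairwise chi-square:\n")
  print(x$per_class)
  cat("Predicted:", x$predicted, "\n")
  if (!is.na(x$margin_h)) cat("Margin h:", x$margin_h, "\n")
  invisible(x)
}

#' Normalized score margin of a classified sample
#'
#' Given a sample's per-class scores and its true class `C_t`, the margin is
#' `h = sum_{k != t} (chi2_{C_t} - chi2_{C_k}) / chi2_{C_t}`: the summed
#' gaps between the true class's score and every other class's, normalized
#' by the true class's score. `h` lies in `(-Inf, m - 1]`, is positive when
#' the true class wins every comparison, and 0 when all class scores are
#' equal. Its training-set mean breaks LOOCV-accuracy ties during forward
#' selection.
#'
#' A true-class score of exactly 0 means the scores carry no evidence; by
#' default this is an error, but `on_zero = "zero"` returns `h = 0` instead
#' (the convention used inside [loocv_evaluate()]).
#'
#' @param scores A `class_scores` object.
#' @param true_class The sample's true class label.
#' @param on_zero `"error"` (default) or `"zero"`: behaviour when the true
#'   class's score is 0.
#' @return The margin `h`.
#' @export
margin_h <- function(scores, true_class, on_zero = c("error", "zero")) {
  on_zero <- match.arg(on_zero)
  stopifnot(inherits(scores, "class_scores"))
  if (!true_class %in% names(scores$per_class))
    stop("unknown class: ", true_class)
  chi_t <- scores$per_class[[true_class]]
  if (chi_t == 0) {
    if (on_zero == "error")
      stop("true-class score is 0: margin undefined (degenerate scoring)")
    return(0)
  }
  others <- scores$per_class[names(scores$per_class) != true_class]
  sum((chi_t - others) / chi_t)
}

#' Classify every sample of a test set
#'
#' Each test sample is classified independently against the same training
#' set with [classify_sample()]; the training tables are cached once and
#' never altered by any test sample.
#'
#' @inheritParams classify_sample
#' @param test Test [expression_dataset()] whose genes cover `genes`.
#' @return A `classification_result`: `scores` (list of `class_scores`
#'   named by sample id), `predicted` (character vector), `accuracy`
#'   (fraction of test samples whose predicted class equals their label),
#'   and `confusion` (true x predicted contingency table).
#' @export
classify_batch <- function(train, genes, test) {
  stopifnot(inherits(test, "expr_dataset"))
  genes <- as.character(genes)
  missing <- setdiff(genes, test$gene_ids)
  if (length(missing) > 0L)
    stop("gene absent from test matrix: ", paste(missing, collapse = ", "))
  cache <- pair_cache(train, genes)
  scores <- lapply(test$sample_ids, function(s)
    classify_with_cache(cache, test$values[genes, s]))
  names(scores) <- test$sample_ids
  predicted <- vapply(scores, `[[`, "", "predicted")
  truth <- as.character(test$labels)
  confusion <- table(true = factor(truth, levels = train$classes),
                     predicted = factor(predicted, levels = train$classes))
  structure(list(
    scores = scores,
    predicted = predicted,
    accuracy = mean(predicted == truth),
    confusion = confusion
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Direct-classifier predictions for", length(x$predicted),
      "samples; accuracy", sprintf("%.4f", x$accuracy), "\n")
  print(x$confusion)
  invisible(x)
}
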