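#' Run the full pipeline: rank, select, classify
#'
#' End-to-end composition with strict train/test separation: the ordered
#' gene list and the forward selection are computed from the training set
#' only; the test set enters only at the final, independent classification
#' step. Alongside the overall accuracy, per-class accuracy is
#' reported as a diagnostic for class imbalance.
#'
#' @param train Training [expression_dataset()].
#' @param test Test [expression_dataset()] over the same gene universe.
#' @param cap_fraction Fraction of the ranked list examined during forward
#'   selection (default 0.02).
#' @param pair_prefilter Optional pair-evaluation restriction; see
#'   [rank_genes()].
#' @param genes Optional externally supplied gene subset (character
#'   vector): when given, ranking and selection are skipped and the direct
#'   classifier is evaluated on exactly these genes — the adapter point for
#'   gene lists produced by other selection methods.
#' @return An `evaluation_report`: `train_loocv`, `test_accuracy`,
#'   `n_selected`, `selected_genes`, `per_class_accuracy`, `confusion`,
#'   plus the underlying `ranked` list, selection `trace` and
#'   `predictions` (`NULL` for the skipped stages when `genes` is given).
#' @export
run_pipeline <- function(train, test, cap_fraction = 0.02,
                         pair_prefilter = NULL, genes = NULL) {
  stopifnot(inherits(train, "expr_dataset"), inherits(test, "expr_dataset"))
  if (!setequal(train$gene_ids, test$gene_ids))
    stop("gene-universe mismatch between train and test")
  if (is.null(genes)) {
    ranked <- rank_genes(train, pair_prefilter)
    trace <- select_informative_genes(train, ranked, cap_fraction)
    selected <- trace$selected
    train_loocv <- trace$loocv
  } else {
    ranked <- NULL
    trace <- NULL
    selected <- as.character(genes)
    train_loocv <- loocv_evaluate(train, selected)$accuracy
  }
  res <- classify_batch(train, selected, test)
  truth <- as.character(test$labels)
  per_class <- vapply(train$classes, function(k) {
    in_k <- truth == k
    if (!any(in_k)) return(NA_real_)
    mean(res$predicted[in_k] == k)
  }, numeric(1))
  structure(list(
    train_loocv = train_loocv,
    test_accuracy = res$accuracy,
    n_selected = length(selected),
    selected_genes = selected,
    per_class_accuracy = per_class,
    confusion = res$confusion,
    ranked = ranked,
    trace = trace,
    predictions = res
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Pipeline evaluation\n")
  cat("  selected genes:  ", x$n_selected, " (",
      paste(x$selected_genes, collapse = ", "), ")\n", sep = "")
  cat("  train LOOCV:     ", sprintf("%.4f", x$train_loocv), "\n", sep = "")
  cat("  test accuracy:   ", sprintf("%.4f", x$test_accuracy), "\n",
      sep = "")
  cat("  per-class accuracy:\n")
  print(round(x$per_class_accuracy, 4))
  invisible(x)
}

#' Pairwise overlap counts between gene lists
#'
#' Counts the genes shared by every pair of named lists — used to compare
#' the informative genes selected by different methods. The diagonal holds
#' each list's (deduplicated) size.
#'
#' @param lists Named list of at least two character vectors of gene ids.
#' @return Symmetric integer matrix of intersection counts.
#' @export
overlap_report <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L)
    stop("need at least 2 gene lists")
  if (is.null(names(lists)) || any(names(lists) == ""))
    stop("lists must be named")
  lists <- lapply(lists, function(x) unique(as.character(x)))
  nm <- names(lists)
  k <- length(lists)
  out <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k))
    out[i, j] <- length(intersect(lists[[i]], lists[[j]]))
  out
}
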