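#' Leave-one-out cross-validation of the direct classifier
#'
#' Each training sample is held out in turn and classified against the
#' remaining `n - 1` samples with the chi-square direct classifier on the
#' given gene subset; its correctness and its margin `h` (computed with its
#' true class) are recorded. Returns the LOOCV accuracy and the mean margin
#' over all `n` samples — the pair of quantities that drives forward
#' selection.
#'
#' The implementation caches the full training tables once and removes /
#' re-adds single-sample contributions (exact, since all counts are
#' multiples of 0.5); results are identical to rebuilding every table from
#' scratch per fold. A held-out sample whose true-class score is 0
#' contributes `h = 0` (with one warning per call): all-zero scores carry
#' no evidence either way.
#'
#' @inheritParams classify_sample
#' @return List with `accuracy` (in `[0, 1]`), `mean_margin`, and
#'   per-sample vectors `correct` (logical) and `h` (numeric), named by
#'   sample id.
#' @export
loocv_evaluate <- function(train, genes) {
  cache <- pair_cache(train, genes)
  n <- cache$n
  m <- length(cache$classes)
  if (n < m + 1L)
    stop("LOOCV needs at least m + 1 samples (n = ", n, ", m = ", m, ")")
  correct <- logical(n)
  h <- numeric(n)
  zero_scores <- 0L
  for (i in seq_len(n)) {
    o <- cache$sgn[, i]
    t_i <- cache$labels[i]
    inc1 <- (o > 0) + 0.5 * (o == 0)
    inc2 <- (o < 0) + 0.5 * (o == 0)
    F1 <- cache$F1
    F2 <- cache$F2
    F1[, t_i] <- F1[, t_i] - inc1
    F2[, t_i] <- F2[, t_i] - inc2
    scores <- score_classes(F1, F2, o)
    pred <- which.max(scores)
    correct[i] <- pred == t_i
    chi_t <- scores[t_i]
    if (chi_t == 0) {
      zero_scores <- zero_scores + 1L
      h[i] <- 0
    } else {
      h[i] <- sum((chi_t - scores[-t_i]) / chi_t)
    }
  }
  if (zero_scores > 0L)
    warning(zero_scores, " held-out sample(s) had a zero true-class score;",
            " their margin was taken as 0")
  names(correct) <- names(h) <- colnames(cache$sgn)
  list(accuracy = mean(correct), mean_margin = mean(h),
       correct = correct, h = h)
}

#' Forward selection of informative genes with redundancy removal
#'
#' Starting from the top two genes of the ranked list, candidates are
#' introduced one at a time in rank order, up to a cap of
#' `max(2, round(cap_fraction * p))` genes examined (the head of the list;
#' 2% by default). A candidate is accepted — becomes an informative gene —
#' exactly when adding it strictly increases the LOOCV accuracy, or leaves
#' the accuracy equal and strictly increases the mean margin `h-bar`.
#' Otherwise it is deemed redundant and permanently discarded. Both
#' comparisons are strict with no tolerance, so an equal-accuracy,
#' equal-margin candidate is rejected. The procedure is purely forward:
#' the initial two genes are never revisited, and there is no backward
#' pass. Everything is deterministic — rerunning on the same dataset gives
#' a bit-identical trace.
#'
#' @inheritParams classify_sample
#' @param ranked A `ranked_gene_list` from [rank_genes()] covering the
#'   training genes.
#' @param cap_fraction Fraction of the ranked list to examine (default
#'   0.02).
#' @return A `selection_trace`: `steps` (data frame with one row per
#'   examined candidate: `candidate_gene`, `rank_in_theta`,
#'   `loocv_accuracy`, `mean_margin`, `decision`), `selected` (final
#'   ordered gene subset), `cap` (candidates examined, initial pair
#'   included), and the final subset's `loocv` and `mean_margin`.
#' @export
select_informative_genes <- function(train, ranked, cap_fraction = 0.02) {
  stopifnot(inherits(train, "expr_dataset"),
            inherits(ranked, "ranked_gene_list"))
  theta <- ranked$entries$gene_id
  p <- length(theta)
  if (p < 2L) stop("selection needs at least 2 ranked genes")
  if (!all(theta %in% train$gene_ids))
    stop("ranked list contains genes absent from the training set")
  cap <- max(2L, as.integer(round(cap_fraction * p)))
  cap <- min(cap, p)
  selected <- theta[1:2]
  cur <- loocv_evaluate(train, selected)
  steps <- data.frame(candidate_gene = character(0),
                      rank_in_theta = integer(0),
                      loocv_accuracy = numeric(0),
                      mean_margin = numeric(0),
                      decision = character(0),
                      stringsAsFactors = FALSE)
  if (cap >= 3L) {
    for (pos in 3:cap) {
      cand <- theta[pos]
      ev <- loocv_evaluate(train, c(selected, cand))
      accept <- ev$accuracy > cur$accuracy ||
        (ev$accuracy == cur$accuracy && ev$mean_margin > cur$mean_margin)
      steps[nrow(steps) + 1L, ] <- list(cand, pos, ev$accuracy,
                                        ev$mean_margin,
                                        if (accept) "accept" else "reject")
      if (accept) {
        selected <- c(selected, cand)
        cur <- ev
      }
    }
  }
  structure(list(
    steps = steps,
    selected = selected,
    cap = cap,
    loocv = cur$accuracy,
    mean_margin = cur$mean_margin
  ), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Forward selection: examined", x$cap, "ranked genes, selected",
      length(x$selected), "\n")
  cat("Final LOOCV accuracy", sprintf("%.4f", x$loocv),
      "; mean margin", sprintf("%.4f", x$mean_margin), "\n")
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  if (nrow(x$steps) > 0L) print(x$steps)
  invisible(x)
}
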