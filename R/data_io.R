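#' Construct a labeled expression dataset
#'
#' The universal input container: a numeric genes-by-samples matrix plus a
#' per-sample class label. Class order is fixed once here as the sorted order
#' of the distinct label strings; every downstream tie-break (contingency row
#' order, classifier argmax ties) uses this order, so results are
#' deterministic.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty rownames (gene ids) and colnames (sample ids). All
#'   entries must be finite; missing values are rejected, never imputed.
#' @param labels Character vector (or factor) of class labels, one per
#'   sample, in column order. At least two distinct classes, each with at
#'   least one sample.
#' @return An object of class `expr_dataset`: a list with elements `values`
#'   (the matrix), `labels` (factor with levels in sorted label order),
#'   `gene_ids`, `sample_ids`, `classes`.
#' @seealso [load_dataset()] to read one from delimited text files.
#' @export
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || anyNA(gene_ids) || any(gene_ids == ""))
    stop("matrix must have gene identifiers as rownames")
  if (is.null(sample_ids) || anyNA(sample_ids) || any(sample_ids == ""))
    stop("matrix must have sample identifiers as colnames")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite or missing values")
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("labels length (", length(labels),
         ") does not match number of samples (", ncol(values), ")")
  if (anyNA(labels) || any(labels == ""))
    stop("unlabeled sample: every sample needs a non-empty class label")
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("need at least 2 classes, got ", length(classes))
  structure(list(
    values = values,
    labels = factor(labels, levels = classes),
    gene_ids = gene_ids,
    sample_ids = sample_ids,
    classes = classes
  ), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("Labeled expression dataset:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  cat("Classes:",
      paste(sprintf("%s (n=%d)", x$classes, tabulate(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples, genes and classes of a dataset
#' @param dataset An `expr_dataset`.
#' @return Named integer vector with elements `genes`, `samples`, `classes`.
#' @export
dataset_dim <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  c(genes = length(dataset$gene_ids),
    samples = length(dataset$sample_ids),
    classes = length(dataset$classes))
}

# Sniff tab vs comma from the first line: whichever delimiter splits it into
# more fields wins; ties favour tab.
detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
  n_com <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  if (n_com > n_tab) "," else "\t"
}

#' Load a labeled expression dataset from delimited text
#'
#' Reads an expression matrix (TSV or CSV, delimiter auto-detected unless
#' given) with one header row and one identifier column, plus a two-column
#' labels file (`sample_id`, `class`, with a header row). No transformation,
#' normalization or imputation is applied: values are taken as they are and
#' missing or non-numeric cells are an error.
#'
#' @param matrix_path Path to the expression matrix file.
#' @param labels_path Path to the labels file mapping sample id to class.
#' @param orientation `"genes-by-samples"` (default; rows are genes) or
#'   `"samples-by-genes"` (rows are samples; transposed internally so both
#'   orientations of the same data yield identical datasets).
#' @param delimiter Field delimiter; `NULL` (default) auto-detects tab vs
#'   comma per file.
#' @return An [expression_dataset()].
#' @export
load_dataset <- function(matrix_path, labels_path,
                         orientation = c("genes-by-samples",
                                         "samples-by-genes"),
                         delimiter = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)
  sep_m <- if (is.null(delimiter)) detect_delimiter(matrix_path) else delimiter
  raw <- utils::read.table(matrix_path, header = TRUE, sep = sep_m,
                           row.names = 1L, check.names = FALSE,
                           colClasses = "character",
                           comment.char = "", quote = "\"")
  if (anyDuplicated(rownames(raw)))
    stop("duplicate identifiers in matrix rows")
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw),
           dimnames = dimnames(raw)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing expression cell at row '",
         rownames(vals)[bad[1L]], "', column '", colnames(vals)[bad[2L]], "'")
  }
  if (orientation == "samples-by-genes") vals <- t(vals)

  sep_l <- if (is.null(delimiter)) detect_delimiter(labels_path) else delimiter
  lab <- utils::read.table(labels_path, header = TRUE, sep = sep_l,
                           colClasses = "character", comment.char = "",
                           quote = "\"")
  if (ncol(lab) < 2L)
    stop("labels file must have two columns: sample_id, class")
  lab_map <- stats::setNames(lab[[2L]], lab[[1L]])
  missing <- setdiff(colnames(vals), names(lab_map))
  if (length(missing) > 0L)
    stop("unlabeled sample: ", paste(missing, collapse = ", "))
  expression_dataset(vals, unname(lab_map[colnames(vals)]))
}

#' Write / read a ranked gene list
#'
#' `write_ranked_list()` writes the ordered list as delimited text with
#' columns `rank`, `gene_id`, `score` (the integrated weighted score S_j) and
#' `chi2_single`; scores are printed at full double precision (17 significant
#' digits) so a read/write round trip reproduces them. `read_ranked_list()`
#' reads such a file back.
#'
#' @param ranked A `ranked_gene_list` from [rank_genes()].
#' @param path Output (or input) file path.
#' @param sep Field delimiter (default tab).
#' @return `write_ranked_list()` returns `path` invisibly;
#'   `read_ranked_list()` returns a `ranked_gene_list`.
#' @export
write_ranked_list <- function(ranked, path, sep = "\t") {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  if (nrow(ranked$entries) == 0L) stop("ranked list is empty")
  df <- data.frame(
    rank = seq_len(nrow(ranked$entries)),
    gene_id = ranked$entries$gene_id,
    score = formatC(ranked$entries$score, digits = 17, format = "g"),
    chi2_single = formatC(ranked$entries$chi2_single, digits = 17,
                          format = "g"),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tie_rule: ", ranked$tie_rule), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  header <- readLines(path, n = 1L)
  tie_rule <- sub("^# tie_rule: ", "", header)
  structure(list(
    entries = data.frame(gene_id = as.character(df$gene_id),
                         score = as.numeric(df$score),
                         chi2_single = as.numeric(df$chi2_single),
                         stringsAsFactors = FALSE),
    tie_rule = tie_rule
  ), class = "ranked_gene_list")
}

#' Write a forward-selection trace
#'
#' One row per examined candidate: its gene id, rank in the ordered list,
#' the LOOCV accuracy and mean margin of the tentative subset, and the
#' accept/reject decision.
#'
#' @param trace A `selection_trace` from [select_informative_genes()].
#' @param path Output file path.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(trace, path, sep = "\t") {
  stopifnot(inherits(trace, "selection_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# cap: ", trace$cap),
               paste0("# selected: ", paste(trace$selected, collapse = ","))),
             con)
  df <- trace$steps
  df$loocv_accuracy <- formatC(df$loocv_accuracy, digits = 17, format = "g")
  df$mean_margin <- formatC(df$mean_margin, digits = 17, format = "g")
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-sample predictions
#'
#' @param scores List of `class_scores` (one per sample, named by sample id),
#'   e.g. the `scores` element of [classify_batch()].
#' @param path Output file path.
#' @param true_labels Optional character vector of true classes, parallel to
#'   `scores`.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(scores, path, true_labels = NULL, sep = "\t") {
  stopifnot(is.list(scores), length(scores) > 0L)
  classes <- names(scores[[1L]]$per_class)
  mat <- t(vapply(scores, function(s) s$per_class, numeric(length(classes))))
  df <- data.frame(sample_id = names(scores),
                   predicted_class = vapply(scores, `[[`, "", "predicted"),
                   stringsAsFactors = FALSE)
  if (!is.null(true_labels)) df$true_class <- as.character(true_labels)
  score_df <- as.data.frame(mat)
  names(score_df) <- paste0("chi2_", classes)
  df <- cbind(df, score_df)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
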