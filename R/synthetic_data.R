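#' Configuration for the synthetic expression-data generator
#'
#' Describes a labeled dataset with known ground truth: class-independent
#' noise genes, planted single genes whose class means differ (the signal a
#' mean-split table detects), and planted gene pairs whose within-sample
#' ordering is class-dependent (the signal a pairwise ordering table
#' detects). The defaults describe the study condition used throughout the
#' package's evaluation: two balanced classes of 60 samples split in half
#' into train and test (30 + 30 training samples), 200 noise genes, two
#' planted single genes with a two-standard-deviation mean shift, and one
#' planted pair whose ordering reverses between classes except in 5% of
#' samples.
#'
#' @param n_per_class Integer vector: samples per class (length = number of
#'   classes, each entry positive).
#' @param n_noise_genes Number of pure-noise genes (class-independent
#'   draws).
#' @param planted_single List of `c(effect_size, noise_sd)` pairs, one per
#'   planted single gene: adjacent class means differ by
#'   `effect_size * noise_sd`, with Gaussian noise of sd `noise_sd`.
#' @param planted_pairs List of flip probabilities in `[0, 0.5)`, one per
#'   planted gene pair: the pair's first gene exceeds its second in class 1
#'   and the reverse holds in all other classes, except with this
#'   probability per sample.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param test_fraction Fraction of each class held out as the independent
#'   test set (stratified); 0 for no test set.
#' @param noise_model `"gaussian"` (default) or `"lognormal"`: the latter
#'   exponentiates the whole matrix, giving positive values with a skewed
#'   marginal (planted effects are then specified on the log scale; all
#'   within-sample orderings are unchanged).
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = c(60L, 60L),
                             n_noise_genes = 200L,
                             planted_single = list(c(2, 1), c(2, 1)),
                             planted_pairs = list(0.05),
                             seed = 1L,
                             test_fraction = 0.5,
                             noise_model = c("gaussian", "lognormal")) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(n_per_class) >= 2L, all(n_per_class >= 1L),
            n_noise_genes >= 0L,
            test_fraction >= 0, test_fraction < 1)
  for (ps in planted_single) {
    stopifnot(length(ps) == 2L, is.finite(ps[1L]), ps[2L] > 0)
  }
  for (fp in planted_pairs) {
    stopifnot(length(fp) == 1L, fp >= 0, fp < 0.5)
  }
  if (test_fraction > 0 && any(n_per_class < 2L))
    stop("stratified split needs at least 2 samples per class")
  structure(list(
    n_per_class = as.integer(n_per_class),
    n_noise_genes = as.integer(n_noise_genes),
    planted_single = planted_single,
    planted_pairs = planted_pairs,
    seed = as.integer(seed),
    test_fraction = test_fraction,
    noise_model = noise_model
  ), class = "synthetic_config")
}

#' Generate a labeled expression dataset with planted signals
#'
#' Draws a genes-by-samples matrix according to a [synthetic_config()] and
#' splits it, stratified by class, into training and test sets.
#'
#' Noise genes are iid standard Gaussian, independent of class. A planted
#' single gene for class `k` (of `m`) has mean
#' `(k - (m + 1) / 2) * effect_size * noise_sd` up to sign, so adjacent
#' classes differ by `effect_size` in units of the noise sd; the sign
#' alternates across planted genes (up-regulated, down-regulated, ...), as
#' in real differentially expressed gene sets — same-direction shifts would
#' leave the planted genes' mutual within-sample orderings
#' class-independent. A planted pair shares a
#' per-sample latent level `z ~ N(0, 1)`; the two genes sit at
#' `z +- 0.5 * o`, where the orientation `o` is `+1` in class 1 and `-1`
#' elsewhere, flipped independently per sample with the configured
#' probability — so the within-sample order is class-informative with an
#' exactly controlled error rate, while both genes' marginals stay nearly
#' class-neutral.
#'
#' @param config A `synthetic_config`.
#' @return List with `train` and `test` ([expression_dataset()]s; `test` is
#'   `NULL` when `test_fraction = 0`), `truth` (character vector of planted
#'   gene ids), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  m <- length(config$n_per_class)
  classes <- paste0("C", seq_len(m))
  labels <- rep(classes, config$n_per_class)
  n <- length(labels)
  k_of <- rep(seq_len(m), config$n_per_class)

  blocks <- list()
  truth <- character(0)
  for (g in seq_along(config$planted_single)) {
    eff <- config$planted_single[[g]][1L]
    sdv <- config$planted_single[[g]][2L]
    # alternate up-/down-regulation across planted genes, as in real
    # differentially expressed gene sets; same-direction shifts would make
    # the genes' mutual within-sample ordering class-independent
    dir <- if (g %% 2L == 1L) 1 else -1
    mu <- dir * (k_of - (m + 1) / 2) * eff * sdv
    id <- sprintf("SHIFT%02d", g)
    blocks[[id]] <- mu + stats::rnorm(n, 0, sdv)
    truth <- c(truth, id)
  }
  for (g in seq_along(config$planted_pairs)) {
    fp <- config$planted_pairs[[g]]
    z <- stats::rnorm(n)
    base <- ifelse(k_of == 1L, 1, -1)
    o <- base * (1 - 2 * stats::rbinom(n, 1L, fp))
    ida <- sprintf("PAIR%02da", g)
    idb <- sprintf("PAIR%02db", g)
    blocks[[ida]] <- z + 0.5 * o
    blocks[[idb]] <- z - 0.5 * o
    truth <- c(truth, ida, idb)
  }
  if (config$n_noise_genes > 0L) {
    noise <- matrix(stats::rnorm(config$n_noise_genes * n),
                    config$n_noise_genes, n)
    rownames(noise) <- sprintf("NOISE%04d", seq_len(config$n_noise_genes))
  } else {
    noise <- NULL
  }
  planted <- if (length(blocks) > 0L)
    do.call(rbind, blocks) else NULL
  if (!is.null(planted)) rownames(planted) <- names(blocks)
  values <- rbind(planted, noise)
  if (is.null(values) || nrow(values) < 2L)
    stop("configuration yields fewer than 2 genes")
  colnames(values) <- sprintf("S%04d", seq_len(n))
  if (config$noise_model == "lognormal") values <- exp(values)

  if (config$test_fraction > 0) {
    test_idx <- unlist(lapply(seq_len(m), function(k) {
      in_k <- which(k_of == k)
      sample(in_k, round(config$test_fraction * length(in_k)))
    }))
    test_idx <- sort(test_idx)
    train_idx <- setdiff(seq_len(n), test_idx)
    train <- expression_dataset(values[, train_idx, drop = FALSE],
                                labels[train_idx])
    test <- expression_dataset(values[, test_idx, drop = FALSE],
                               labels[test_idx])
  } else {
    train <- expression_dataset(values, labels)
    test <- NULL
  }
  list(train = train, test = test, truth = truth, config = config)
}

#' Write a generated dataset to delimited text files
#'
#' Writes the training (and, if present, test) matrix and labels as TSV,
#' plus the planted-gene truth list, into a directory — the on-disk form
#' consumed by [load_dataset()].
#'
#' @param generated The list returned by [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(generated, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_one <- function(ds, prefix) {
    mat_path <- file.path(dir, paste0(prefix, "_matrix.tsv"))
    utils::write.table(
      data.frame(gene_id = ds$gene_ids, ds$values, check.names = FALSE),
      mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = ds$sample_ids,
                 class = as.character(ds$labels)),
      file.path(dir, paste0(prefix, "_labels.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_one(generated$train, "train")
  if (!is.null(generated$test)) write_one(generated$test, "test")
  writeLines(generated$truth, file.path(dir, "truth.txt"))
  invisible(dir)
}
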