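write_fixture <- function(dir, sep = "\t") {
  mat <- file.path(dir, "matrix.txt")
  lab <- file.path(dir, "labels.txt")
  rows <- c(paste(c("gene_id", "s1", "s2", "s3", "s4"), collapse = sep),
            paste(c("g1", "1.5", "2", "3", "4"), collapse = sep),
            paste(c("g2", "4", "3", "2", "1"), collapse = sep),
            paste(c("g3", "0", "0", "1", "1"), collapse = sep))
  writeLines(rows, mat)
  writeLines(c(paste(c("sample_id", "class"), collapse = sep),
               paste(c("s1", "A"), collapse = sep),
               paste(c("s2", "A"), collapse = sep),
               paste(c("s3", "B"), collapse = sep),
               paste(c("s4", "B"), collapse = sep)), lab)
  list(mat = mat, lab = lab)
}

test_that("a hand-written TSV fixture round-trips with the right dimensions", {
  dir <- withr::local_tempdir()
  f <- write_fixture(dir)
  d <- load_dataset(f$mat, f$lab)
  expect_equal(unname(dataset_dim(d)), c(3, 4, 2))
  expect_equal(d$values["g1", "s4"], 4)
  expect_equal(as.character(d$labels), c("A", "A", "B", "B"))
})

test_that("both orientations and both delimiters yield identical datasets", {
  dir <- withr::local_tempdir()
  f <- write_fixture(dir)
  d <- load_dataset(f$mat, f$lab)
  # transposed matrix, declared samples-by-genes
  tmat <- file.path(dir, "t.txt")
  dtab <- utils::read.table(f$mat, sep = "\t", header = TRUE,
                            row.names = 1)
  utils::write.table(data.frame(sample_id = colnames(dtab), t(dtab)),
                     tmat, sep = "\t", quote = FALSE, row.names = FALSE)
  dt <- load_dataset(tmat, f$lab, orientation = "samples-by-genes")
  expect_equal(dt$values, d$values)
  expect_equal(dt$labels, d$labels)
  # CSV dialect, auto-detected
  f2 <- write_fixture(withr::local_tempdir(), sep = ",")
  dc <- load_dataset(f2$mat, f2$lab)
  expect_equal(dc$values, d$values)
})

test_that("loader validation rejects malformed inputs", {
  dir <- withr::local_tempdir()
  f <- write_fixture(dir)
  # a sample missing from the labels file
  writeLines(c("sample_id\tclass", "s1\tA", "s2\tA", "s3\tB"),
             f$lab)
  expect_error(load_dataset(f$mat, f$lab), "unlabeled sample: s4")
  # non-numeric cell
  f <- write_fixture(dir)
  lines <- readLines(f$mat)
  lines[2] <- "g1\t1.5\tNA\t3\t4"
  writeLines(lines, f$mat)
  expect_error(load_dataset(f$mat, f$lab), "non-numeric or missing")
  # duplicate gene ids
  f <- write_fixture(dir)
  lines <- readLines(f$mat)
  lines[4] <- sub("^g3", "g1", lines[4])
  writeLines(lines, f$mat)
  expect_error(load_dataset(f$mat, f$lab), "duplicate")
  # single class
  expect_error(expression_dataset(
    matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
    c("A", "A")), "at least 2 classes")
})

test_that("ranked lists round-trip to full printed precision", {
  d <- random_dataset(8, c(5, 5), seed = 301)
  rk <- rank_genes(d)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_list(rk, path)
  back <- read_ranked_list(path)
  expect_identical(back$entries$gene_id, rk$entries$gene_id)
  expect_equal(back$entries$score, rk$entries$score, tolerance = 0)
  expect_equal(back$entries$chi2_single, rk$entries$chi2_single,
               tolerance = 0)
  expect_identical(back$tie_rule, rk$tie_rule)
  # strictly ordered score column after tie-breaking
  expect_true(all(diff(back$entries$score) <= 0))
  empty <- structure(list(entries = data.frame(gene_id = character(0),
                                               score = numeric(0),
                                               chi2_single = numeric(0)),
                          tie_rule = ""), class = "ranked_gene_list")
  expect_error(write_ranked_list(empty, path), "empty")
})

test_that("selection traces and predictions are written as readable tables", {
  g <- generate_dataset(synthetic_config(n_per_class = c(8, 8),
                                         n_noise_genes = 10, seed = 311,
                                         test_fraction = 0.5))
  rk <- rank_genes(g$train)
  tr <- select_informative_genes(g$train, rk, cap_fraction = 0.5)
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_selection_trace(tr, tpath)
  lines <- readLines(tpath)
  expect_match(lines[1], "^# cap: ")
  expect_match(lines[2], "^# selected: ")
  got <- utils::read.table(tpath, sep = "\t", header = TRUE,
                           comment.char = "#")
  expect_equal(nrow(got), nrow(tr$steps))

  res <- classify_batch(g$train, tr$selected, g$test)
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(res$scores, ppath,
                    true_labels = as.character(g$test$labels))
  preds <- utils::read.table(ppath, sep = "\t", header = TRUE)
  expect_equal(nrow(preds), length(g$test$sample_ids))
  expect_true(all(c("sample_id", "predicted_class", "true_class",
                    "chi2_C1", "chi2_C2") %in% names(preds)))
  expect_equal(mean(preds$predicted_class == preds$true_class),
               res$accuracy)
})

test_that("writing a generated dataset produces loadable files", {
  g <- generate_dataset(synthetic_config(n_per_class = c(5, 5),
                                         n_noise_genes = 6, seed = 321,
                                         test_fraction = 0.4))
  dir <- withr::local_tempdir()
  write_synthetic(g, dir)
  d <- load_dataset(file.path(dir, "train_matrix.tsv"),
                    file.path(dir, "train_labels.tsv"))
  expect_equal(d$values, g$train$values)
  expect_equal(d$labels, g$train$labels)
  expect_identical(readLines(file.path(dir, "truth.txt")), g$truth)
})
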