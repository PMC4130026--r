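test_that("single-gene mean-split tables follow the definition and tie rule", {
  d <- make_ds(matrix(c(1, 2, 3, 4), 1, 4), c("A", "A", "B", "B"))
  tab <- single_gene_table(d, "g1")
  expect_equal(unname(tab$counts), rbind(c(0, 2), c(2, 0)))
  expect_equal(tab$grand_total, 4)

  # constant gene: every sample ties the mean, halves everywhere
  dc <- make_ds(matrix(5, 1, 4), c("A", "A", "B", "B"))
  expect_equal(unname(single_gene_table(dc, "g1")$counts),
               rbind(c(1, 1), c(1, 1)))

  # mean 2.4; enumerating the definition: A = (1,1), B = (1,2)
  d5 <- make_ds(matrix(c(1, 3, 2, 2, 4), 1, 5), c("A", "A", "B", "B", "B"))
  expect_equal(unname(single_gene_table(d5, "g1")$counts),
               rbind(c(1, 1), c(1, 2)))

  expect_error(single_gene_table(d, "nope"), "unknown gene")
})

test_that("pairwise ordering tables follow the definition and tie rule", {
  d <- make_ds(rbind(g1 = c(5, 6, 1, 2), g2 = c(1, 2, 5, 6)),
               c("A", "A", "B", "B"))
  tab <- pairwise_table(d, "g1", "g2")
  expect_equal(unname(tab$counts), rbind(c(2, 0), c(0, 2)))

  # identical values (distinct ids): every sample ties, all rows halved
  di <- make_ds(rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4)),
                c("A", "A", "B", "B"))
  expect_equal(unname(pairwise_table(di, "g1", "g2")$counts),
               rbind(c(1, 1), c(1, 1)))

  # sample 3 ties within itself: B row gets 1.5 / 1.5
  d5 <- make_ds(rbind(g1 = c(3, 1, 4, 2, 5), g2 = c(2, 2, 4, 3, 1)),
                c("A", "A", "B", "B", "B"))
  expect_equal(unname(pairwise_table(d5, "g1", "g2")$counts),
               rbind(c(1, 1), c(1.5, 1.5)))

  expect_error(pairwise_table(d, "g1", "g1"), "distinct")
})

test_that("chi-square statistic matches its closed forms and conventions", {
  expect_equal(chi_square(rbind(c(5, 0), c(0, 5))), 10)   # perfect: N
  expect_equal(chi_square(rbind(c(5, 5), c(5, 5))), 0)    # independence
  tab <- rbind(c(3, 1), c(2, 4))
  expect_equal(chi_square(tab), oracle_pearson(tab), tolerance = 1e-12)
  expect_error(chi_square(rbind(c(0, 0), c(0, 0))), "empty table")
  # zero iff rows proportional to column totals
  expect_equal(chi_square(rbind(c(2, 4), c(1, 2), c(3, 6))), 0)
  expect_gt(chi_square(rbind(c(2, 4), c(2, 2), c(3, 6))), 0)
  # zero-margin convention keeps the statistic finite
  expect_equal(chi_square(rbind(c(3, 0), c(5, 0))), 0)
  expect_true(is.finite(chi_square(rbind(c(3, 2), c(0, 0)))))
})

test_that("product form equals textbook Pearson on fractional tables", {
  for (s in 1:60) {
    m <- 2L + (s %% 13L)
    counts <- random_table(m, seed = 1000L + s)
    a <- chi_square(counts)
    b <- oracle_pearson(counts)
    expect_lt(abs(a - b), 1e-9 * max(1, abs(b)))
  }
})

test_that("batch statistics equal per-gene and per-pair loops", {
  d <- random_dataset(20, c(6, 5, 4), seed = 42)
  batch <- all_single_chi_squares(d)
  for (g in d$gene_ids)
    expect_equal(batch[[g]], chi_square(single_gene_table(d, g)),
                 tolerance = 1e-12)
  genes <- d$gene_ids[1:8]
  pm <- all_pairwise_chi_squares(d, genes)
  expect_equal(pm, t(pm))
  expect_true(all(is.na(diag(pm))))
  for (j in 1:7) for (l in (j + 1):8)
    expect_equal(pm[genes[j], genes[l]],
                 chi_square(pairwise_table(d, genes[j], genes[l])),
                 tolerance = 1e-12)
  expect_error(all_pairwise_chi_squares(d, genes[1]), "at least 2")
})

test_that("tables and statistics are invariant to sample order", {
  d <- random_dataset(6, c(5, 5), seed = 7)
  set.seed(8)
  perm <- sample(length(d$sample_ids))
  dp <- expression_dataset(d$values[, perm],
                           as.character(d$labels)[perm])
  expect_equal(all_single_chi_squares(d)[d$gene_ids],
               all_single_chi_squares(dp)[d$gene_ids])
  expect_equal(all_pairwise_chi_squares(d)[d$gene_ids, d$gene_ids],
               all_pairwise_chi_squares(dp)[d$gene_ids, d$gene_ids])
})

test_that("mass is conserved: every table's grand total is n", {
  # values engineered to produce ties against the mean and within samples
  d <- make_ds(rbind(g1 = c(1, 3, 2, 2, 4),
                     g2 = c(2, 2, 2, 2, 2),
                     g3 = c(1, 2, 2, 3, 4)),
               c("A", "A", "B", "B", "B"))
  for (g in d$gene_ids)
    expect_equal(single_gene_table(d, g)$grand_total, 5)
  for (pair in list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3")))
    expect_equal(pairwise_table(d, pair[1], pair[2])$grand_total, 5)
})

test_that("pairwise statistics survive monotone within-sample distortion; single-gene do not", {
  d <- random_dataset(8, c(5, 5), seed = 11)
  # per-sample strictly increasing maps: a_s * x^3 + b_s with a_s > 0
  set.seed(12)
  a <- stats::runif(10, 0.5, 2)
  b <- stats::rnorm(10)
  vt <- sweep(sweep(d$values^3, 2, a, `*`), 2, b, `+`)
  dt <- expression_dataset(vt, as.character(d$labels))
  expect_equal(all_pairwise_chi_squares(d)[d$gene_ids, d$gene_ids],
               all_pairwise_chi_squares(dt)[d$gene_ids, d$gene_ids])
  # counterexample for the mean split: exp() moves values across the mean
  dx <- make_ds(matrix(c(1, 2, 3, 4), 1, 4), c("A", "A", "B", "B"))
  de <- make_ds(matrix(exp(c(1, 2, 3, 4)), 1, 4), c("A", "A", "B", "B"))
  expect_false(isTRUE(all.equal(chi_square(single_gene_table(dx, "g1")),
                                chi_square(single_gene_table(de, "g1")))))
})

test_that("a positive tie tolerance declares near-ties", {
  d <- make_ds(rbind(g1 = c(1, 2.0000001, 3, 2), g2 = c(1, 2, 3, 4)),
               c("A", "A", "B", "B"))
  exact <- pairwise_table(d, "g1", "g2")
  loose <- pairwise_table(d, "g1", "g2", tie_tol = 1e-6)
  # exactly: s1 ties, s2 is greater by 1e-7; with tolerance s2 ties too
  expect_equal(unname(exact$counts[1, ]), c(1.5, 0.5))
  expect_equal(unname(loose$counts[1, ]), c(1, 1))
})
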