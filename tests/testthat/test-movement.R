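test_that("chromosome matching recovers conserved and fused karyotypes", {
  trio <- sim_trio(n_genes = 600, seed = 3)
  corr <- match_chromosomes(trio$out1, trio$focal)
  # conserved 1:1 correspondence, with the outgroup X mapping to the focal
  # F-carrying autosome and the focal X matched by the element-D chromosome
  expect_equal(nrow(corr), 6)
  expect_equal(corr$chrom_b[corr$chrom_a == "o1_chrX"], "f_chrF")
  expect_true("f_chrX" %in% corr$chrom_b)
  expect_true(all(corr$ratio > 1.5))

  # a planted fusion maps two source chromosomes onto one target
  sc <- sim_scenario(n_species = 2, n_genes = 600, mismap_rate = 0,
                     unplaced_rate = 0,
                     events = c("ancestral_X", "X_autosome_fusion"))
  sim <- sim_gene_maps(sc, seed = 4)
  corr_f <- match_chromosomes(sim$maps[[1]], sim$maps[[2]])
  fused_sources <- corr_f$chrom_a[corr_f$chrom_b == "chrX"]
  expect_equal(length(fused_sources), 2)  # old X and the fused autosome
  expect_warning(
    match_chromosomes(sim$maps[[1]], sim$maps[[2]], threshold = 1e6),
    "no chromosome pair")
})

test_that("ancestral locations require outgroup agreement", {
  corr1 <- tibble::tibble(chrom_a = c("o1_c1", "o1_c2"),
                          chrom_b = c("f_c1", "f_c2"))
  corr2 <- tibble::tibble(chrom_a = c("o2_c1", "o2_c2"),
                          chrom_b = c("f_c1", "f_c2"))
  anc <- infer_ancestral_location(
    c("o1_c1", "o1_c1", NA, "o1_unmatched"),
    c("o2_c1", "o2_c2", "o2_c1", "o2_c1"),
    corr1, corr2)
  expect_equal(anc, c("f_c1", NA, NA, NA))
})

test_that("movement calls recover planted truth exactly at zero noise", {
  trio <- sim_trio(n_genes = 1500, n_moves = 120, out_of_x_multiplier = 2,
                   seed = 8)
  calls <- call_movements(trio$focal, trio$out1, trio$out2,
                          trio$x_chromosomes)
  moved <- calls[!calls$category %in% c("none", "undetermined"), ]
  truth <- trio$truth[order(trio$truth$gene_id), ]
  expect_equal(moved$gene_id[order(moved$gene_id)], truth$gene_id)
  expect_equal(
    moved$category[order(moved$gene_id)], truth$category)
  # negative control: conserved trio yields zero movements
  quiet <- sim_trio(n_genes = 500, n_moves = 0, seed = 9)
  calls0 <- call_movements(quiet$focal, quiet$out1, quiet$out2,
                           quiet$x_chromosomes)
  expect_equal(sum(!calls0$category %in% c("none", "undetermined")), 0)
  expect_equal(sum(calls0$category == "undetermined"), 0)
})

test_that("genes on unplaced focal scaffolds are undetermined", {
  trio <- sim_trio(n_genes = 800, n_moves = 0, unplaced_rate = 0.05, seed = 12)
  calls <- call_movements(trio$focal, trio$out1, trio$out2,
                          trio$x_chromosomes)
  placed <- mullerx:::placed_chromosomes(trio$focal)
  unplaced_genes <- trio$focal$gene_id[!trio$focal$chromosome %in% placed]
  expect_true(all(calls$category[calls$gene_id %in% unplaced_genes] ==
                    "undetermined"))
})

test_that("expected movement counts implement the size-weighted null", {
  # two-chromosome toy: p(X->A) = 1/(1 + 0.75) = 4/7
  e <- expected_movement_counts(c(chrX = 100, chr2 = 100),
                                c(chrX = 1e6, chr2 = 1e6), "chrX", 7)
  expect_equal(e$proportion[e$category == "X_to_A"], 4 / 7)
  expect_equal(e$expected[e$category == "X_to_A"], 4)
  expect_equal(sum(e$proportion), 1)
  expect_equal(sum(e$expected), 7)
  # three identical autosomes, no X: everything is A_to_A
  e3 <- expected_movement_counts(c(a = 10, b = 10, c = 10),
                                 c(a = 1e5, b = 1e5, c = 1e5),
                                 character(0), 30)
  expect_equal(e3$category, "A_to_A")
  expect_equal(e3$proportion, 1)
  # zero moves -> zero expectations
  expect_equal(sum(expected_movement_counts(
    c(chrX = 5, c2 = 5), c(chrX = 1e5, c2 = 1e5), "chrX", 0)$expected), 0)
  # scale invariance in lengths
  e_scaled <- expected_movement_counts(c(chrX = 100, chr2 = 100),
                                       c(chrX = 5e8, chr2 = 5e8), "chrX", 7)
  expect_equal(e$proportion, e_scaled$proportion)
  expect_error(expected_movement_counts(c(a = 1), c(a = 1e5), "x", 1),
               "at least two")
})

test_that("movement chi-square matches hand computation and guards inputs", {
  e <- structure(tibble::tibble(category = c("A_to_A", "A_to_X", "X_to_A"),
                                weight = c(1, 1, 1) / 3,
                                proportion = c(1, 1, 1) / 3,
                                expected = c(20, 20, 20)),
                 total_moves = 60,
                 class = c("movement_expectation", class(tibble::tibble())))
  out <- movement_chisq(c(A_to_A = 30, A_to_X = 10, X_to_A = 20), e)
  expect_equal(out$chi2, 10)
  expect_equal(out$df, 2)
  expect_equal(out$p, pchisq(10, 2, lower.tail = FALSE))
  # observed equal to expected -> chi2 = 0, p = 1
  eq <- movement_chisq(c(A_to_A = 20, A_to_X = 20, X_to_A = 20), e)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  expect_error(movement_chisq(c(A_to_A = 10, A_to_X = 10, X_to_A = 10), e),
               "total_moves")
  # zero-expectation bin with observations is an error
  e0 <- e; e0$expected <- c(30, 30, 0)
  attr(e0, "total_moves") <- 60
  expect_error(movement_chisq(c(A_to_A = 30, A_to_X = 10, X_to_A = 20), e0),
               "zero expectation")
  # low expected counts only warn
  e_small <- e; e_small$expected <- c(2, 2, 2)
  attr(e_small, "total_moves") <- 6
  expect_warning(movement_chisq(c(A_to_A = 2, A_to_X = 2, X_to_A = 2),
                                e_small), "below 5")
})

test_that("normalized loss fraction follows the stated arithmetic", {
  expect_equal(normalized_loss_fraction(5, 100, 0.9), 0.05 / 0.9)
  expect_equal(normalized_loss_fraction(0, 50, 0.8), 0)
  expect_equal(normalized_loss_fraction(7, 70, 1), 0.1)
  expect_error(normalized_loss_fraction(1, 0, 0.5), "positive")
  expect_error(normalized_loss_fraction(1, 10, 0), "0, 1")
})

test_that("expression comparison flags planted testis effects only", {
  genes <- sprintf("g%04d", 1:800)
  moved <- genes[1:80]
  expr <- sim_expression(genes, moved, testis_multiplier = 2.5, seed = 20)
  tst <- compare_expression(expr, moved, tissue = "testis")
  expect_lt(tst$p, 1e-4)
  expect_gt(tst$median_group, tst$median_background)
  # somatic tissue untouched
  head_cmp <- compare_expression(expr, moved, tissue = "head")
  expect_gt(head_cmp$p, 0.01)
  # identical group and background -> p = 1
  same <- compare_expression(expr, genes, tissue = "testis")
  expect_equal(same$p, 1)
  expect_error(compare_expression(expr, character(0), tissue = "testis"),
               "empty")
  expect_error(compare_expression(expr, moved, tissue = "antenna"),
               "tissue column")
  expect_error(compare_expression(expr, c("nope", moved), genes, "testis"),
               "subset")
})

test_that("a group strictly above the rest of the background is significant", {
  # inclusive background: the group's own values re-appear on the other side,
  # so the attainable tail is bounded by the self-ties; with the group a
  # small fraction of the background the p-value is still extreme
  expr <- tibble::tibble(gene_id = sprintf("g%d", 1:205),
                         testis = c(1001:1005, seq_len(200)))
  grp <- sprintf("g%d", 1:5)
  out <- compare_expression(expr, grp, tissue = "testis")
  expect_equal(out$p, wilcox.test(c(1001:1005), expr$testis)$p.value)
  expect_lt(out$p, 0.001)
})
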