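test_that("expected shared count is p1 * p2 * n_total", {
  expect_equal(expected_shared_count(0.5, 0.5, 100), 25)
  expect_equal(expected_shared_count(0, 0.7, 1000), 0)
  expect_equal(expected_shared_count(0.2, 0.1, 1000), 20)
  expect_error(expected_shared_count(0.5, 0.5, 0), "positive")
  expect_error(expected_shared_count(1.2, 0.5, 10), "0, 1")
})

test_that("enrichment table recovers planted structure", {
  # all element-A genes on chr1, all F genes on chrX: block diagonal
  gm <- toy_map(20, 5)
  tab <- enrichment_table(gm)
  expect_equal(attr(tab, "n_total"), 25)
  a_chr1 <- tab[tab$ref_unit == "A" & tab$chromosome == "chr1", ]
  expect_equal(a_chr1$observed, 20)
  expect_equal(a_chr1$expected, 20 * 20 / 25)
  # obs/exp = 1/p for a conserved pair (p = proportion on the element)
  expect_equal(a_chr1$ratio, 25 / 20)
  f_x <- tab[tab$ref_unit == "F" & tab$chromosome == "chrX", ]
  expect_equal(f_x$ratio, 25 / 5)
})

test_that("unplaced genes are excluded from margins but reported", {
  rec <- toy_records(list("g1", "A", "chr1", 0, 500, 100),
                     list("g2", "A", "chr1", 1000, 1500, 100),
                     list("g3", "A", "scaf1", 0, 500, 100))
  len <- tibble::tibble(chromosome = c("chr1", "scaf1"),
                        length_bp = 1e6, placed = c(TRUE, FALSE))
  tab <- enrichment_table(gene_map(rec, len, "sp"))
  expect_equal(attr(tab, "n_total"), 2)
  unpl <- tab[tab$chromosome == "unplaced", ]
  expect_equal(unpl$observed, 1)
  expect_true(is.na(unpl$expected))
})

test_that("homology calls use strict ratio and one-sided Fisher p", {
  # observed exactly at expectation -> ratio 1, not homologous
  m_null <- map_from_2x2(25, 25, 25, 25)
  calls <- call_homology(enrichment_table(m_null))
  expect_true(all(calls$ratio == 1))
  expect_false(any(calls$is_homologous))

  # observed exactly 1.5x expected -> strict inequality, not homologous
  # A: 30 genes, chromosome c1: 40 of 120 genes, a = 15 = 1.5 * (30*40/120)
  m_15 <- map_from_2x2(15, 15, 25, 65)
  calls15 <- call_homology(enrichment_table(m_15))
  a_c1 <- calls15[calls15$ref_unit == "A" & calls15$chromosome == "c1", ]
  expect_equal(a_c1$ratio, 1.5)
  expect_false(a_c1$is_homologous)

  # strong enrichment (90,10;10,890): p equals hypergeometric tail sum
  m_sig <- map_from_2x2(90, 10, 10, 890)
  calls_sig <- call_homology(enrichment_table(m_sig))
  a_sig <- calls_sig[calls_sig$ref_unit == "A" & calls_sig$chromosome == "c1", ]
  expect_equal(a_sig$fisher_p, hyper_tail_p(90, 100, 100, 1000),
               tolerance = 1e-12)
  expect_true(a_sig$is_homologous)

  # a single shared gene never supports a call
  rec <- toy_records(list("g1", "F", "chrX", 0, 500, 100),
                     list("g2", "A", "chr1", 0, 500, 100),
                     list("g3", "A", "chr1", 1000, 1500, 100))
  gm1 <- gene_map(rec, toy_lengths(c("chrX", "chr1")), "sp")
  c1 <- call_homology(enrichment_table(gm1))
  expect_false(c1$is_homologous[c1$ref_unit == "F"])
})

test_that("karyotype classification follows element F's fate", {
  mk_calls <- function(pairs) {
    # pairs: list of c(element, chromosome) taken as confident homologies
    df <- dplyr::bind_rows(lapply(pairs, function(p)
      tibble::tibble(ref_unit = p[1], chromosome = p[2], observed = 50,
                     expected = 10, ratio = 5, fisher_p = 1e-10,
                     is_homologous = TRUE)))
    structure(df, species_pair = c("reference", "spX"),
              class = c("homology_calls", class(tibble::tibble())))
  }
  expect_equal(infer_karyotype(mk_calls(list(c("F", "chrX"), c("A", "chr2"))),
                               "chrX")$event_class, "ancestral_X")
  # Myopa testacea-like: X = F + D
  expect_equal(infer_karyotype(mk_calls(list(c("F", "chrX"), c("D", "chrX"))),
                               "chrX")$event_class, "X_autosome_fusion")
  # Thecophora atra-like: B replaced F as X, F fused to an autosome
  k <- infer_karyotype(mk_calls(list(c("B", "chrX"), c("F", "chr2"),
                                     c("D", "chr2"))), "chrX")
  expect_equal(k$event_class, "turnover_with_F_fusion")
  expect_equal(k$f_fate, "fused")
  # plain turnover with F reverted to its own autosome
  k2 <- infer_karyotype(mk_calls(list(c("B", "chrX"), c("F", "chrF"))), "chrX")
  expect_equal(k2$event_class, "turnover")
  expect_equal(k2$f_fate, "reverted_unfused")
  # F nowhere to be found
  k3 <- infer_karyotype(mk_calls(list(c("B", "chrX"))), "chrX")
  expect_equal(k3$event_class, "turnover")
  expect_equal(k3$f_fate, "unresolved")
  # nothing on the X
  expect_warning(
    k4 <- infer_karyotype(mk_calls(list(c("A", "chr2"))), "chrX"),
    "unresolved")
  expect_equal(k4$event_class, "unresolved")
  expect_equal(tidy(k)$event_class, "turnover_with_F_fusion")
})

test_that("fusion origin counting matches exhaustive parsimony", {
  tr <- read_newick("((a:1,b:1):1,c:2);")
  expect_equal(count_fusion_origins(tr, c(a = 1, b = 1)), 1)
  expect_equal(count_fusion_origins(tr, c(a = 1)), 1)
  expect_equal(count_fusion_origins(tr, c(a = 1, c = 1)), 2)
  # ladder with a non-fused tip between two fused ones
  ladder <- read_newick("(((a:1,b:1):1,c:1):1,d:1);")
  expect_equal(count_fusion_origins(ladder, c(a = 1, c = 1)),
               brute_min_origins(ladder, c(a = 1, c = 1)))
  # randomized agreement with the exhaustive oracle
  withr::local_seed(5)
  for (i in 1:25) {
    tr <- rand_tree(sample(4:8, 1))
    pres <- stats::setNames(sample(0:1, length(tr$tip.label), TRUE),
                            tr$tip.label)
    expect_equal(count_fusion_origins(tr, pres),
                 brute_min_origins(tr, pres))
  }
})

test_that("fusion split expectation enumerates element pairs", {
  sp <- expected_fusion_split(8, 6, 1)
  expect_equal(sp$expected_x, 8 * 5 / 15)
  expect_equal(sp$expected_aa, 8 * 10 / 15)
  expect_equal(sp$expected_x + sp$expected_aa, 8)  # conservation
  expect_equal(expected_fusion_split(3, 2, 1)$expected_x, 3)
  expect_equal(expected_fusion_split(15, 6, 1)$expected_x, 5)
  expect_error(expected_fusion_split(5, 6, 6), "n_x_elements")
})

test_that("co-option Monte-Carlo p converges to exact enumeration", {
  # flat counts: observed max is about the expectation, p near 1
  expect_gt(coopt_binomial_test(c(5, 5, 5, 5, 5), seed = 1), 0.8)
  # extreme concentration
  expect_lt(coopt_binomial_test(c(25, 0, 0, 0, 0), seed = 1), 0.001)
  expect_error(coopt_binomial_test(c(0, 0, 0, 0, 0), seed = 1), "zero")
  expect_error(coopt_binomial_test(c(3, 1), n_reps = 10, seed = 1), "1000")
  # convergence to the exhaustive value at a small event total
  exact <- exact_max_multinomial_p(12, 5, 5)
  mc <- coopt_binomial_test(c(5, 3, 2, 1, 1), n_reps = 2e5, seed = 42)
  expect_equal(mc, exact, tolerance = 0.02)
  # reproducibility
  expect_identical(coopt_binomial_test(c(8, 5, 5, 4, 4), seed = 7),
                   coopt_binomial_test(c(8, 5, 5, 4, 4), seed = 7))
})

test_that("gene-fate tracing reproduces a planted Muscidae-like partition", {
  # 55 ancestrally X-linked genes: 10 retained on a minute F-homolog in one
  # species, 18 absent everywhere, 27 present but relocated
  anchors <- sprintf("anc%02d", 1:55)
  on_minute <- anchors[1:10]
  absent <- anchors[11:28]
  elsewhere <- anchors[29:55]
  filler <- tibble::tibble(
    gene_id = sprintf("fill%03d", 1:60),
    muller_element = rep(c("A", "F"), c(40, 20)),
    chromosome = rep(c("chr2", "minuteX"), c(40, 20)),
    start = c(seq(0, by = 1000, length.out = 40),
              seq(0, by = 1000, length.out = 20)),
    end = c(seq(0, by = 1000, length.out = 40),
            seq(0, by = 1000, length.out = 20)) + 500L)
  present <- c(on_minute, elsewhere)
  rec <- tibble::tibble(
    gene_id = present,
    muller_element = "F",
    chromosome = c(rep("minuteX", 10), rep("chr2", 27)),
    start = c(seq(30000, by = 1000, length.out = 10),
              seq(50000, by = 1000, length.out = 27)),
    end = c(seq(30000, by = 1000, length.out = 10),
            seq(50000, by = 1000, length.out = 27)) + 500L)
  rec <- dplyr::bind_rows(rec, filler)
  rec$score <- 300; rec$strand <- "+"
  gm <- gene_map(rec, toy_lengths(c("chr2", "minuteX")), "muscid")
  fate <- trace_gene_fate(anchors, list(gm), target_element = "F")
  part <- fate_partition(fate)
  expect_equal(part$on_target_any, 10)
  expect_equal(part$absent_all, 18)
  expect_equal(part$elsewhere_only, 27)
  expect_true(all(fate$status[fate$gene_id %in% absent] == "absent"))
})
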