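#' Match homologous chromosomes between two species
#'
#' Declares a chromosome of species A homologous to a chromosome of species
#' B when the observed number of shared mapped genes exceeds 1.5-fold the
#' expected number (see [expected_shared_count()]). Each chromosome of A is
#' matched to at most one chromosome of B — the one with the highest
#' observed/expected ratio — while several chromosomes of A may map to the
#' same chromosome of B (a fusion).
#'
#' @param map_a,map_b [gene_map()] objects sharing gene ids.
#' @param threshold Enrichment ratio a pair must exceed (strictly).
#' @return Tibble of class `chrom_correspondence`: `chrom_a`, `chrom_b`,
#'   `observed`, `expected`, `ratio`. Empty (with a warning) when no pair
#'   clears the threshold.
#' @export
match_chromosomes <- function(map_a, map_b, threshold = 1.5) {
  counts <- enrichment_table(map_b, map_ref = map_a)
  cand <- counts[counts$ref_unit != "unplaced" &
                 counts$chromosome != "unplaced" &
                 !is.na(counts$ratio) & counts$ratio > threshold, ]
  cand <- cand |>
    dplyr::group_by(.data$ref_unit) |>
    dplyr::slice_max(.data$ratio, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- tibble(chrom_a = cand$ref_unit, chrom_b = cand$chromosome,
                observed = cand$observed, expected = cand$expected,
                ratio = cand$ratio)
  if (nrow(out) == 0) warn("no chromosome pair exceeds the homology threshold")
  structure(out, class = c("chrom_correspondence", class(tibble())))
}

#' Ancestral location of genes from two outgroup placements
#'
#' Maps each gene's chromosome in the two outgroups through the
#' outgroup-to-focal correspondence maps. The ancestral location (expressed
#' as a focal-species chromosome) is assigned only when the two outgroups
#' agree; disagreement, a missing placement, an unplaced scaffold, or an
#' unmatched chromosome all yield `NA` (the gene is not considered
#' further).
#'
#' @param out1_chrom,out2_chrom Character vectors (parallel over genes) of
#'   chromosome placements in outgroup 1 and 2; `NA` = absent.
#' @param corr1,corr2 `chrom_correspondence` tables mapping outgroup
#'   chromosomes (`chrom_a`) to focal chromosomes (`chrom_b`).
#' @return Character vector of ancestral focal chromosomes (`NA` =
#'   undetermined).
#' @export
infer_ancestral_location <- function(out1_chrom, out2_chrom, corr1, corr2) {
  h1 <- corr1$chrom_b[match(out1_chrom, corr1$chrom_a)]
  h2 <- corr2$chrom_b[match(out2_chrom, corr2$chrom_a)]
  ifelse(!is.na(h1) & !is.na(h2) & h1 == h2, h1, NA_character_)
}

#' Call inter-chromosomal gene movements from a species trio
#'
#' For a focal species with a derived X and two outgroups retaining element
#' F as their X, infers per-gene movement: the ancestral location is the
#' focal chromosome homologous to the (agreeing) outgroup placements, and a
#' movement is called when the focal placement differs. Categories use the
#' X/autosome identity of chromosomes *in the focal species*, so movements
#' are binned as `X_to_A`, `A_to_X`, `A_to_A`; a gene whose ancestral and
#' focal chromosomes coincide is `none`, and genes that are unplaced in the
#' focal assembly, missing or discordant in the outgroups, or on unmatched
#' chromosomes are `undetermined`.
#'
#' @param focal,out1,out2 [gene_map()] objects.
#' @param x_chromosomes X chromosome name(s) of the focal species.
#' @param threshold Homology ratio threshold for [match_chromosomes()].
#' @return Tibble of class `movement_calls`: `gene_id`,
#'   `focal_chromosome`, `ancestral_chromosome`, `ancestral_class`,
#'   `focal_class`, `category`.
#' @export
call_movements <- function(focal, out1, out2, x_chromosomes,
                           threshold = 1.5) {
  corr1 <- match_chromosomes(out1, focal, threshold)
  corr2 <- match_chromosomes(out2, focal, threshold)
  placed_f <- placed_chromosomes(focal)
  placed_1 <- placed_chromosomes(out1)
  placed_2 <- placed_chromosomes(out2)

  g <- tibble(gene_id = focal$gene_id, focal_chromosome = focal$chromosome)
  o1 <- out1$chromosome[match(g$gene_id, out1$gene_id)]
  o2 <- out2$chromosome[match(g$gene_id, out2$gene_id)]
  o1[!is.na(o1) & !o1 %in% placed_1] <- NA
  o2[!is.na(o2) & !o2 %in% placed_2] <- NA
  g$ancestral_chromosome <- infer_ancestral_location(o1, o2, corr1, corr2)

  chrom_class <- function(ch) ifelse(is.na(ch), NA_character_,
                                     ifelse(ch %in% x_chromosomes, "X", "A"))
  g$ancestral_class <- chrom_class(g$ancestral_chromosome)
  g$focal_class <- chrom_class(g$focal_chromosome)
  focal_unplaced <- !g$focal_chromosome %in% placed_f
  g$category <- dplyr::case_when(
    focal_unplaced | is.na(g$ancestral_chromosome) ~ "undetermined",
    g$ancestral_chromosome == g$focal_chromosome ~ "none",
    g$ancestral_class == "X" & g$focal_class == "A" ~ "X_to_A",
    g$ancestral_class == "A" & g$focal_class == "X" ~ "A_to_X",
    g$ancestral_class == "A" & g$focal_class == "A" ~ "A_to_A",
    TRUE ~ "X_to_X")
  structure(g,
            focal_species = species_id(focal),
            x_chromosomes = x_chromosomes,
            class = c("movement_calls", class(tibble())))
}

movement_categories <- c("A_to_A", "A_to_X", "X_to_A")

#' Expected gene-movement counts under the size-weighted null
#'
#' Under the null, the probability that a movement goes from chromosome `i`
#' to chromosome `j` is proportional to `N_i * L_j * f_ij`, where `N_i` is
#' the number of genes on the source chromosome, `L_j` the length of the
#' destination chromosome, and `f_ij` is 1 for an autosomal destination and
#' 0.75 for an X destination (the X spends less time in the population than
#' an autosome). Pair weights (over `i != j`) are normalized and binned
#' into autosome-to-autosome, autosome-to-X and X-to-autosome categories;
#' expected counts are `total_moves` times the binned proportions.
#'
#' @param n_genes Named vector: genes per chromosome (`N_i`).
#' @param lengths_bp Named vector: chromosome length in bp (`L_j`).
#' @param x_chromosomes Names of X chromosome(s).
#' @param total_moves Total number of observed movements to distribute.
#' @return Tibble of class `movement_expectation`: `category`, `weight`,
#'   `proportion`, `expected`; attribute `total_moves`.
#' @export
#' @examples
#' # one X and one autosome of equal gene count and length:
#' # weight(X->A) = 1, weight(A->X) = 0.75, so p(X->A) = 4/7
#' expected_movement_counts(c(chrX = 100, chr2 = 100),
#'                          c(chrX = 1e6, chr2 = 1e6), "chrX", 7)
expected_movement_counts <- function(n_genes, lengths_bp, x_chromosomes,
                                     total_moves) {
  chroms <- names(n_genes)
  if (length(chroms) < 2) abort("need at least two chromosomes")
  if (!all(chroms %in% names(lengths_bp))) {
    abort("every chromosome in n_genes needs a length")
  }
  if (total_moves < 0) abort("total_moves must be non-negative")
  pairs <- expand.grid(i = chroms, j = chroms, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$i != pairs$j, ]
  f <- ifelse(pairs$j %in% x_chromosomes, 0.75, 1)
  w <- n_genes[pairs$i] * lengths_bp[pairs$j] * f
  src_x <- pairs$i %in% x_chromosomes
  dst_x <- pairs$j %in% x_chromosomes
  cat <- dplyr::case_when(!src_x & !dst_x ~ "A_to_A",
                          !src_x & dst_x ~ "A_to_X",
                          src_x & !dst_x ~ "X_to_A",
                          TRUE ~ "X_to_X")
  cats <- intersect(c(movement_categories, "X_to_X"), unique(cat))
  weight <- vapply(cats, function(cc) sum(w[cat == cc]), numeric(1))
  proportion <- weight / sum(weight)
  structure(tibble(category = cats, weight = unname(weight),
                   proportion = unname(proportion),
                   expected = total_moves * unname(proportion)),
            total_moves = total_moves,
            x_chromosomes = x_chromosomes,
            class = c("movement_expectation", class(tibble())))
}

#' Chi-square goodness-of-fit of observed movements to the null
#'
#' Pearson chi-square of the observed per-category movement counts against
#' the size-weighted expectations of [expected_movement_counts()], with
#' `df = (number of categories) - 1`.
#'
#' @param observed Named vector of observed counts per category (or a
#'   `movement_calls` table, in which case the counts are tallied,
#'   dropping `none`/`undetermined`).
#' @param expectation A `movement_expectation` built for the same total.
#' @return One-row tibble of class `movement_test`: `chi2`, `df`, `p`,
#'   plus a per-category attribute table `detail`.
#' @export
movement_chisq <- function(observed, expectation) {
  if (inherits(observed, "movement_calls")) {
    moved <- observed$category[!observed$category %in% c("none", "undetermined")]
    observed <- table(factor(moved, levels = expectation$category))
    observed <- setNames(as.numeric(observed), names(observed))
  }
  obs <- setNames(rep(0, nrow(expectation)), expectation$category)
  extra <- setdiff(names(observed), expectation$category)
  if (length(extra) > 0) {
    abort(paste0("observed categories not in the expectation: ",
                 paste(extra, collapse = ", ")))
  }
  obs[names(observed)] <- observed
  if (abs(sum(obs) - attr(expectation, "total_moves")) > 1e-8) {
    abort("sum of observed counts differs from total_moves of the expectation")
  }
  e <- expectation$expected
  if (any(e == 0 & obs > 0)) {
    abort("observed movements in a category with zero expectation")
  }
  keep <- e > 0
  if (any(e[keep] < 5)) {
    warn("expected count below 5 in at least one category; chi-square approximation may be poor")
  }
  chi2 <- sum((obs[keep] - e[keep])^2 / e[keep])
  df <- sum(keep) - 1L
  detail <- tibble(category = expectation$category[keep],
                   observed = unname(obs[keep]), expected = e[keep])
  structure(tibble(chi2 = chi2, df = df,
                   p = pchisq(chi2, df, lower.tail = FALSE)),
            detail = detail,
            class = c("movement_test", class(tibble())))
}

#' Normalized fraction of genes moved off a chromosome
#'
#' The raw fraction of ancestral genes that left a chromosome is not
#' comparable across species whose remaining genomes differ in size, so it
#' is divided by the fraction of mapped genes found on the other
#' chromosomes.
#'
#' @param moved_out Number of genes that moved off the chromosome.
#' @param ancestral_on_chrom Number of genes ancestrally on it (> 0).
#' @param frac_genes_elsewhere Fraction of all mapped genes on the other
#'   chromosomes, in (0, 1\].
#' @return The normalized loss fraction.
#' @export
#' @examples
#' normalized_loss_fraction(5, 100, 0.9) # 0.0556
normalized_loss_fraction <- function(moved_out, ancestral_on_chrom,
                                     frac_genes_elsewhere) {
  if (ancestral_on_chrom <= 0) abort("ancestral_on_chrom must be positive")
  if (frac_genes_elsewhere <= 0 || frac_genes_elsewhere > 1) {
    abort("frac_genes_elsewhere must be in (0, 1]")
  }
  (moved_out / ancestral_on_chrom) / frac_genes_elsewhere
}

#' Observed versus expected movement counts
#'
#' @param object A `movement_test` result (from [movement_chisq()]).
#' @param ... Unused.
#' @return A ggplot bar chart of observed and expected counts per category.
#' @method autoplot movement_test
#' @export
autoplot.movement_test <- function(object, ...) {
  detail <- attr(object, "detail")
  df <- tidyr::pivot_longer(detail, c("observed", "expected"),
                            names_to = "kind", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$count,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "gene movements", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Compare expression of a gene group against the mapped background
#'
#' Two-sided Wilcoxon rank-sum comparison of one tissue's expression values
#' between a gene group (e.g. genes that moved off the X) and the full
#' mapped background. Following standard practice the background includes
#' the group itself.
#'
#' @param expr Data frame whose first column is `gene_id` and remaining
#'   columns are numeric per-tissue expression values (RPKM-like).
#' @param group Gene ids of the focal group (non-empty, all in
#'   `background`).
#' @param background Gene ids of the comparison set; defaults to all genes
#'   in `expr`.
#' @param tissue Name of the tissue column to compare.
#' @return One-row tibble of class `expression_comparison`: `tissue`,
#'   `n_group`, `n_background`, `median_group`, `median_background`, `p`.
#' @export
compare_expression <- function(expr, group, background = NULL, tissue) {
  expr <- as_tibble(expr)
  if (!tissue %in% names(expr)) {
    abort(paste0("tissue column not found: ", tissue))
  }
  if (length(group) == 0) abort("gene group is empty")
  if (is.null(background)) background <- expr$gene_id
  if (!all(group %in% background)) {
    abort("group must be a subset of the background")
  }
  xg <- expr[[tissue]][expr$gene_id %in% group]
  xb <- expr[[tissue]][expr$gene_id %in% background]
  if (length(xg) == 0) abort("no group gene found in the expression matrix")
  wt <- suppressWarnings(wilcox.test(xg, xb, alternative = "two.sided"))
  structure(tibble(tissue = tissue,
                   n_group = length(xg), n_background = length(xb),
                   median_group = median(xg), median_background = median(xb),
                   p = wt$p.value),
            class = c("expression_comparison", class(tibble())))
}
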