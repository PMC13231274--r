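#' Expected number of genes shared by a chromosome pair under no homology
#'
#' If a fraction `p1` of mapped genes sits on a chromosome of species 1 and
#' a fraction `p2` on a chromosome of species 2, then absent any homology
#' the two chromosomes are expected to share `p1 * p2 * n_total` genes,
#' where `n_total` is the number of genes mapped in both species.
#'
#' @param p1,p2 Proportions of mapped genes on each chromosome, in \[0, 1\].
#' @param n_total Total number of genes mapped in both species.
#' @return The expected shared-gene count (non-negative real).
#' @export
#' @examples
#' expected_shared_count(0.5, 0.5, 100) # 25
expected_shared_count <- function(p1, p2, n_total) {
  if (any(n_total <= 0)) abort("n_total must be positive")
  if (any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1)) {
    abort("proportions must lie in [0, 1]")
  }
  p1 * p2 * n_total
}

#' Observed and expected shared-gene counts per chromosome pair
#'
#' Cross-tabulates gene placements to produce, for every (reference unit,
#' target chromosome) pair, the observed shared-gene count, the expected
#' count under the no-homology null (see [expected_shared_count()]) and
#' their ratio. The reference unit is the Muller element label carried by
#' each gene when `map_ref` is `NULL`, or the chromosome of a second species
#' when `map_ref` is another [gene_map()] (the form used to match
#' chromosomes between outgroup and focal species).
#'
#' Genes on unplaced scaffolds (on either side) are excluded from the counts
#' and the margins, and reported in `"unplaced"` pseudo rows/columns with
#' `expected = NA`.
#'
#' @param map_target A [gene_map()] for the target species.
#' @param map_ref Optional [gene_map()] for a second species; default uses
#'   the reference Muller element labels in `map_target`.
#' @return A tibble of class `shared_gene_counts` with columns `ref_unit`,
#'   `chromosome`, `observed`, `expected`, `ratio`, and attributes
#'   `n_total` (genes placed on both sides), `ref_kind` and `species_pair`.
#' @export
enrichment_table <- function(map_target, map_ref = NULL) {
  placed_t <- placed_chromosomes(map_target)
  tgt <- tibble(gene_id = map_target$gene_id,
                chromosome = ifelse(map_target$chromosome %in% placed_t,
                                    map_target$chromosome, "unplaced"))
  if (is.null(map_ref)) {
    ref <- tibble(gene_id = map_target$gene_id,
                  ref_unit = map_target$muller_element)
    ref <- ref[ref$ref_unit != "unknown", ]
    ref_kind <- "element"
    pair <- c("reference", species_id(map_target))
  } else {
    placed_r <- placed_chromosomes(map_ref)
    ref <- tibble(gene_id = map_ref$gene_id,
                  ref_unit = ifelse(map_ref$chromosome %in% placed_r,
                                    map_ref$chromosome, "unplaced"))
    ref_kind <- "chromosome"
    pair <- c(species_id(map_ref), species_id(map_target))
  }
  shared <- dplyr::inner_join(ref, tgt, by = "gene_id")
  if (nrow(shared) == 0) abort("no shared genes between the two tables")

  core <- shared[shared$ref_unit != "unplaced" &
                 shared$chromosome != "unplaced", ]
  n_total <- nrow(core)
  counts <- shared |>
    dplyr::count(.data$ref_unit, .data$chromosome, name = "observed")
  if (n_total > 0) {
    row_tot <- table(core$ref_unit)
    col_tot <- table(core$chromosome)
    counts$expected <- ifelse(
      counts$ref_unit == "unplaced" | counts$chromosome == "unplaced",
      NA_real_,
      as.numeric(row_tot[counts$ref_unit]) *
        as.numeric(col_tot[counts$chromosome]) / n_total)
  } else {
    counts$expected <- NA_real_
  }
  counts$ratio <- counts$observed / counts$expected
  structure(dplyr::arrange(counts, .data$ref_unit, .data$chromosome),
            n_total = n_total,
            ref_kind = ref_kind,
            species_pair = pair,
            class = c("shared_gene_counts", class(tibble())))
}

#' Call chromosome-element homology from shared-gene enrichment
#'
#' A target chromosome is called homologous to a reference unit when the
#' observed shared-gene count exceeds `ratio_threshold` times the expected
#' count (strictly), the excess is significant by a one-sided (greater)
#' Fisher's exact test on the 2x2 table (on/off reference unit x on/off
#' chromosome, unplaced genes excluded from both margins), and at least
#' `min_observed` genes are shared (a single gene is too few to determine
#' homology).
#'
#' @param counts A `shared_gene_counts` table from [enrichment_table()].
#' @param ratio_threshold Enrichment needed for a call; strict (default 1.5).
#' @param alpha Significance level for the Fisher test.
#' @param min_observed Minimum shared genes supporting a call (default 2).
#' @param p_adjust Multiple-testing correction passed to [stats::p.adjust()];
#'   the default `"none"` applies no correction.
#' @return A tibble of class `homology_calls` with one row per (unit,
#'   chromosome) pair with `observed >= 1`, columns `ref_unit`,
#'   `chromosome`, `observed`, `expected`, `ratio`, `fisher_p`,
#'   `is_homologous`.
#' @export
call_homology <- function(counts, ratio_threshold = 1.5, alpha = 0.05,
                          min_observed = 2, p_adjust = "none") {
  n_total <- attr(counts, "n_total")
  calls <- counts[counts$ref_unit != "unplaced" &
                  counts$chromosome != "unplaced" &
                  counts$observed >= 1, ]
  row_tot <- tapply(calls$observed, calls$ref_unit, sum)
  col_tot <- tapply(calls$observed, calls$chromosome, sum)
  calls$fisher_p <- vapply(seq_len(nrow(calls)), function(i) {
    a <- calls$observed[i]
    b <- row_tot[[calls$ref_unit[i]]] - a
    cc <- col_tot[[calls$chromosome[i]]] - a
    d <- n_total - a - b - cc
    fisher.test(matrix(c(a, cc, b, d), 2), alternative = "greater")$p.value
  }, numeric(1))
  calls$fisher_p <- stats::p.adjust(calls$fisher_p, method = p_adjust)
  calls$is_homologous <- calls$ratio > ratio_threshold &
    calls$fisher_p < alpha & calls$observed >= min_observed
  structure(calls,
            n_total = n_total,
            ref_kind = attr(counts, "ref_kind"),
            species_pair = attr(counts, "species_pair"),
            class = c("homology_calls", class(tibble())))
}

#' Classify the sex-chromosome state of a species
#'
#' Combines per-chromosome homology calls with the identity of the X
#' chromosome(s) (from assembly metadata) into a karyotype call. Element F
#' is the ancestral X of flies, so the event classes are defined by F's
#' relationship to the current X complement:
#'
#' * `ancestral_X` — F is the sole element on the X;
#' * `X_autosome_fusion` — the X carries F plus at least one other element;
#' * `turnover` — F is no longer X-linked; the ancestral X reverted to an
#'   autosome (`f_fate = "reverted_unfused"` when F sits alone on an
#'   autosome, `"unresolved"` when F is not confidently placed);
#' * `turnover_with_F_fusion` — as above, but F's autosome also carries
#'   another element (the reverted F fused to an autosome);
#' * `unresolved` — no element could be assigned to the X.
#'
#' @param calls A `homology_calls` table for one species.
#' @param x_chromosomes Character vector of X chromosome name(s).
#' @param f_is_ancestral_x Logical; the classification above assumes element
#'   F is the ancestral X (the dipteran case).
#' @return An object of class `karyotype_call`: a list with `species_id`,
#'   `element_map` (chromosome -> elements), `x_chromosomes`, `x_elements`,
#'   `event_class` and `f_fate`. Use [tidy()] for a one-row tibble.
#' @export
infer_karyotype <- function(calls, x_chromosomes, f_is_ancestral_x = TRUE) {
  hom <- calls[calls$is_homologous, ]
  element_map <- split(hom$ref_unit, hom$chromosome)
  x_elements <- sort(unique(unlist(element_map[
    names(element_map) %in% x_chromosomes])))
  f_fate <- NA_character_
  if (length(x_elements) == 0) {
    warn("no element confidently assigned to the X; karyotype unresolved")
    event <- "unresolved"
  } else if (!f_is_ancestral_x) {
    event <- if (length(x_elements) == 1) "ancestral_X" else "X_autosome_fusion"
  } else if ("F" %in% x_elements) {
    event <- if (length(x_elements) == 1) "ancestral_X" else "X_autosome_fusion"
  } else {
    # turnover: the ancestral X (F) is no longer sex-linked; find its fate
    f_chroms <- names(element_map)[vapply(element_map, function(e)
      "F" %in% e, logical(1))]
    f_chroms <- setdiff(f_chroms, x_chromosomes)
    if (length(f_chroms) == 0) {
      event <- "turnover"
      f_fate <- "unresolved"
    } else if (any(lengths(element_map[f_chroms]) > 1)) {
      event <- "turnover_with_F_fusion"
      f_fate <- "fused"
    } else {
      event <- "turnover"
      f_fate <- "reverted_unfused"
    }
  }
  structure(list(species_id = attr(calls, "species_pair")[2],
                 element_map = element_map,
                 x_chromosomes = x_chromosomes,
                 x_elements = x_elements,
                 event_class = event,
                 f_fate = f_fate),
            class = "karyotype_call")
}

#' @export
print.karyotype_call <- function(x, ...) {
  cat(sprintf("<karyotype_call> %s: %s (X = %s; elements %s)\n",
              x$species_id %||% "?", x$event_class,
              paste(x$x_chromosomes, collapse = ","),
              if (length(x$x_elements)) paste(x$x_elements, collapse = "+")
              else "none"))
  invisible(x)
}

#' @method tidy karyotype_call
#' @export
tidy.karyotype_call <- function(x, ...) {
  tibble(species_id = x$species_id %||% NA_character_,
         event_class = x$event_class,
         f_fate = x$f_fate,
         x_chromosomes = paste(x$x_chromosomes, collapse = ","),
         x_elements = paste(x$x_elements, collapse = "+"),
         n_chromosomes_called = length(x$element_map))
}

#' Minimum number of independent fusion origins on a tree
#'
#' Counts how many times a fusion (or any binary presence/absence trait)
#' must have arisen, under parsimony with losses allowed and absence as the
#' ancestral state at the root. Among all reconstructions with the minimum
#' number of state changes, the one with the fewest 0 to 1 transitions is
#' reported, so the count is the minimum number of independent origins.
#'
#' @param tree A rooted `phylo` tree (multifurcations allowed).
#' @param presence Named logical or 0/1 vector over (a subset of) tip labels;
#'   tips not named are taken as absent.
#' @return Integer number of origins.
#' @export
count_fusion_origins <- function(tree, presence) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  extra <- setdiff(names(presence), tips)
  if (length(extra) > 0) {
    abort(paste0("presence names not in tree: ", paste(extra, collapse = ", ")))
  }
  state <- setNames(rep(0L, length(tips)), tips)
  state[names(presence)] <- as.integer(as.logical(presence))

  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  eps <- 1e-6
  gain <- 1 + eps  # 0 -> 1 weighted slightly above a loss
  cost <- matrix(Inf, n_node, 2)  # columns: state 0, state 1
  cost[seq_len(n_tip), ] <- Inf
  cost[cbind(seq_len(n_tip), state[tips] + 1L)] <- 0

  tr <- ape::reorder.phylo(tree, "postorder")
  edges <- tr$edge
  # accumulate child contributions into parents, postorder guarantees
  # children are finalized first
  contrib <- matrix(0, n_node, 2)
  choice <- matrix(NA_integer_, nrow(edges), 2)  # best child state per parent state
  for (i in seq_len(nrow(edges))) {
    par <- edges[i, 1]; ch <- edges[i, 2]
    if (ch > n_tip) cost[ch, ] <- contrib[ch, ]  # child subtree finalized
    c0 <- min(cost[ch, 1], cost[ch, 2] + gain)       # parent state 0
    c1 <- min(cost[ch, 1] + 1, cost[ch, 2])          # parent state 1
    choice[i, 1] <- if (cost[ch, 1] <= cost[ch, 2] + gain) 0L else 1L
    choice[i, 2] <- if (cost[ch, 2] <= cost[ch, 1] + 1) 1L else 0L
    contrib[par, 1] <- contrib[par, 1] + c0
    contrib[par, 2] <- contrib[par, 2] + c1
  }
  internal <- setdiff(unique(edges[, 1]), seq_len(n_tip))
  cost[internal, ] <- contrib[internal, ]

  # traceback from the root (fixed absent) counting 0 -> 1 edges
  root <- n_tip + 1L
  assigned <- rep(NA_integer_, n_node)
  assigned[root] <- 0L
  origins <- 0L
  for (i in rev(seq_len(nrow(edges)))) {  # preorder
    par <- edges[i, 1]; ch <- edges[i, 2]
    s <- choice[i, assigned[par] + 1L]
    if (assigned[par] == 0L && s == 1L) origins <- origins + 1L
    assigned[ch] <- s
  }
  origins
}

#' Expected split of fusions between X-involving and autosome-autosome
#'
#' Under random joining of two distinct Muller elements, the chance that a
#' fusion involves the sex chromosome is the fraction of unordered element
#' pairs containing an X-linked element. With 6 elements and one X, 5 of the
#' 15 pairs involve the X, so 8 observed fusions split into an expected
#' 2.67 X-involving and 5.33 autosome-autosome events.
#'
#' @param n_fusions Number of independent fusion events observed.
#' @param n_elements Number of elements that can fuse (default 6).
#' @param n_x_elements How many of them are X-linked (default 1).
#' @return A tibble with `expected_x` and `expected_aa` (summing to
#'   `n_fusions`).
#' @export
#' @examples
#' expected_fusion_split(8) # 2.667 / 5.333
expected_fusion_split <- function(n_fusions, n_elements = 6,
                                  n_x_elements = 1) {
  if (n_elements < 2 || n_x_elements < 1 || n_x_elements >= n_elements ||
      n_fusions < 0) {
    abort("need n_elements >= 2, 1 <= n_x_elements < n_elements, n_fusions >= 0")
  }
  n_pairs <- choose(n_elements, 2)
  n_x_pairs <- n_x_elements * (n_elements - n_x_elements) +
    choose(n_x_elements, 2)
  expected_x <- n_fusions * n_x_pairs / n_pairs
  tibble(n_fusions = n_fusions,
         expected_x = expected_x,
         expected_aa = n_fusions - expected_x)
}

#' Monte-Carlo test for over-representation of a co-opted element
#'
#' Tests whether the most frequently co-opted element (as a new X, by
#' turnover or fusion) is represented more often than expected if each
#' co-option event picked one of the candidate elements uniformly at
#' random. The p-value is the Monte-Carlo probability that the maximum
#' per-element count under uniform multinomial allocation reaches the
#' observed maximum.
#'
#' @param coopt_counts Named (or plain) non-negative integer vector of
#'   co-option events per element.
#' @param n_candidate_elements Number of elements events could fall on
#'   (default 5: the five large elements A-E).
#' @param n_reps Monte-Carlo replicates (at least 1000).
#' @param seed Integer seed for reproducibility.
#' @return Estimated p-value in \[0, 1\].
#' @export
coopt_binomial_test <- function(coopt_counts, n_candidate_elements = 5,
                                n_reps = 10000, seed = NULL) {
  counts <- as.integer(coopt_counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) abort("all co-option counts are zero")
  if (n_reps < 1000) abort("n_reps must be at least 1000")
  obs_max <- max(counts)
  with_seed_if(seed, {
    draws <- rmultinom(n_reps, total,
                       rep(1 / n_candidate_elements, n_candidate_elements))
    mean(apply(draws, 2, max) >= obs_max)
  })
}

#' Trace the fate of anchor genes across species
#'
#' For a set of anchor genes (e.g. genes ancestrally on the X), reports per
#' species whether each gene is found on a chromosome homologous to a target
#' element, elsewhere, on an unplaced scaffold, or absent. Chromosome-element
#' homology per species is taken from `element_maps` when supplied, else
#' computed internally with [enrichment_table()] + [call_homology()].
#'
#' @param anchor_genes Character vector of gene ids.
#' @param tables List of [gene_map()] objects, one per species.
#' @param target_element Element whose retention is traced (default "F").
#' @param element_maps Optional named list (species -> chromosome -> elements)
#'   overriding the internal homology calls.
#' @param ... Passed to [call_homology()].
#' @return A tibble of class `gene_fate` with columns `gene_id`,
#'   `species_id`, `chromosome`, `chrom_elements`, `status` (one of
#'   `on_target`, `elsewhere`, `unplaced`, `absent`). See
#'   [fate_partition()] for the cross-species summary.
#' @export
trace_gene_fate <- function(anchor_genes, tables, target_element = "F",
                            element_maps = NULL, ...) {
  if (length(anchor_genes) == 0) abort("anchor gene set is empty")
  rows <- purrr::map(tables, function(map) {
    sp <- species_id(map)
    emap <- if (!is.null(element_maps)) {
      element_maps[[sp]]
    } else {
      infer_karyotype_element_map(map, ...)
    }
    placed <- placed_chromosomes(map)
    idx <- match(anchor_genes, map$gene_id)
    chrom <- map$chromosome[idx]
    elements <- vapply(chrom, function(ch) {
      if (is.na(ch)) NA_character_
      else paste(sort(unlist(emap[ch])), collapse = "+")
    }, character(1))
    status <- dplyr::case_when(
      is.na(chrom) ~ "absent",
      !chrom %in% placed ~ "unplaced",
      vapply(chrom, function(ch) target_element %in% unlist(emap[ch]),
             logical(1)) ~ "on_target",
      TRUE ~ "elsewhere")
    tibble(gene_id = anchor_genes, species_id = sp, chromosome = chrom,
           chrom_elements = elements, status = status)
  })
  structure(dplyr::bind_rows(rows),
            target_element = target_element,
            class = c("gene_fate", class(tibble())))
}

# chromosome -> homologous elements for one species, via the standard
# enrichment + Fisher pipeline
infer_karyotype_element_map <- function(map, ...) {
  calls <- call_homology(enrichment_table(map), ...)
  hom <- calls[calls$is_homologous, ]
  split(hom$ref_unit, hom$chromosome)
}

#' Cross-species summary of anchor-gene fates
#'
#' Partitions the anchor genes of a [trace_gene_fate()] result into three
#' disjoint classes: found on the target element in at least one species,
#' absent from every species, and present somewhere but never on the target
#' element.
#'
#' @param fate A `gene_fate` tibble.
#' @return A one-row tibble with `n_genes`, `on_target_any`, `absent_all`,
#'   `elsewhere_only`.
#' @export
fate_partition <- function(fate) {
  by_gene <- fate |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      on_target_any = any(.data$status == "on_target"),
      absent_all = all(.data$status == "absent"),
      .groups = "drop")
  tibble(n_genes = nrow(by_gene),
         on_target_any = sum(by_gene$on_target_any),
         absent_all = sum(by_gene$absent_all),
         elsewhere_only = sum(!by_gene$on_target_any & !by_gene$absent_all))
}

#' Heatmap of observed/expected shared-gene enrichment
#'
#' @param object A `shared_gene_counts` table.
#' @param ... Unused.
#' @return A ggplot object (tiles shaded by log2 observed/expected ratio).
#' @method autoplot shared_gene_counts
#' @export
autoplot.shared_gene_counts <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  df$log2_ratio <- log2(df$ratio)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chromosome, y = .data$ref_unit,
                                   fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$observed), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "target chromosome", y = "reference unit",
                  fill = "log2 obs/exp") +
    ggplot2::theme_minimal()
}
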