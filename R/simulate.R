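#' Define a synthetic karyotype-evolution scenario
#'
#' Builds the ground truth for a set of synthetic species: a shared gene
#' complement partitioned over the six Muller elements (element F small —
#' by default 1% of genes, matching its gene-poor dot-chromosome biology;
#' use ~2.5% for a non-schizophoran-like genome), and one karyotype spec
#' per species drawn from the four event classes (ancestral X,
#' X-autosome fusion, turnover, turnover with the reverted F fused to an
#' autosome). Per-gene mismapping and unplaced-scaffold noise rates apply
#' when maps are realized with [sim_gene_maps()].
#'
#' @param n_species Number of species.
#' @param n_genes Shared gene count (default 2000).
#' @param f_prop Proportion of genes on element F (default 0.01); the five
#'   large elements share the rest equally.
#' @param mismap_rate Probability a gene is placed on a uniformly chosen
#'   wrong chromosome (default 0.02).
#' @param unplaced_rate Probability a gene lands on an unplaced scaffold.
#' @param events Event class per species (recycled); default cycles through
#'   the four classes.
#' @return A list of class `sim_scenario`: `genes` (tibble `gene_id`,
#'   `element`), `species` (list of specs with `element_chrom`,
#'   `x_chromosomes`, `event_class`, `f_fate`), and the noise rates.
#' @export
sim_scenario <- function(n_species = 8, n_genes = 2000, f_prop = 0.01,
                         mismap_rate = 0.02, unplaced_rate = 0.01,
                         events = NULL) {
  stopifnot(n_genes >= 60, f_prop > 0, f_prop < 1)
  n_f <- max(2L, round(n_genes * f_prop))
  n_large <- n_genes - n_f
  per <- diff(round(seq(0, n_large, length.out = 6)))
  element <- rep(MULLER_ELEMENTS, times = c(per, n_f))
  genes <- tibble(gene_id = sprintf("g%05d", seq_len(n_genes)),
                  element = element)
  if (is.null(events)) {
    events <- c("ancestral_X", "X_autosome_fusion", "turnover",
                "turnover_with_F_fusion")
  }
  events <- rep(events, length.out = n_species)
  large <- setdiff(MULLER_ELEMENTS, "F")
  species <- purrr::imap(events, function(ev, i) {
    partner <- large[(i - 1) %% 5 + 1]                 # fusion partner / new X
    f_partner <- large[i %% 5 + 1]                     # autosome F fuses to
    chrom <- setNames(paste0("chr", 2:6), large)
    if (ev == "ancestral_X") {
      chrom["F"] <- "chrX"
    } else if (ev == "X_autosome_fusion") {
      chrom["F"] <- "chrX"
      chrom[partner] <- "chrX"
    } else if (ev == "turnover") {
      chrom[partner] <- "chrX"
      chrom["F"] <- "chrF"
    } else if (ev == "turnover_with_F_fusion") {
      chrom[partner] <- "chrX"
      chrom["F"] <- chrom[f_partner]
    } else {
      abort(paste0("unknown event class: ", ev))
    }
    list(species_id = sprintf("sp%03d", i),
         element_chrom = chrom,
         x_chromosomes = "chrX",
         event_class = ev,
         f_fate = switch(ev, turnover = "reverted_unfused",
                         turnover_with_F_fusion = "fused", NA_character_))
  })
  structure(list(genes = genes, species = species,
                 mismap_rate = mismap_rate, unplaced_rate = unplaced_rate),
            class = "sim_scenario")
}

# realize one species table: noisy placements + sequential coordinates
GENE_SLOT_BP <- 3000L
GENE_LEN_BP <- 1000L

realize_species_map <- function(genes, element_chrom, species_id,
                                mismap_rate, unplaced_rate,
                                chrom_length_bp = NULL,
                                forced_chrom = NULL) {
  true_chrom <- unname(element_chrom[genes$element])
  if (!is.null(forced_chrom)) {
    true_chrom <- ifelse(is.na(forced_chrom), true_chrom, forced_chrom)
  }
  placed <- unique(unname(element_chrom))
  scaffolds <- paste0(species_id, "_scaf", 1:3)
  u <- runif(nrow(genes))
  status <- ifelse(u < mismap_rate, "mismapped",
                   ifelse(u < mismap_rate + unplaced_rate, "unplaced", "ok"))
  obs <- true_chrom
  mis <- which(status == "mismapped")
  if (length(mis) > 0) {
    obs[mis] <- vapply(true_chrom[mis], function(tc)
      sample(setdiff(placed, tc), 1), character(1))
  }
  unp <- which(status == "unplaced")
  if (length(unp) > 0) obs[unp] <- sample(scaffolds, length(unp), replace = TRUE)

  # sequential non-overlapping slots per chromosome
  ord <- order(obs, genes$gene_id)
  slot <- stats::ave(seq_along(obs)[ord], obs[ord], FUN = seq_along)
  start <- integer(length(obs)); start[ord] <- (slot - 1L) * GENE_SLOT_BP
  rec <- tibble(gene_id = genes$gene_id,
                muller_element = genes$element,
                chromosome = obs,
                start = start,
                end = start + GENE_LEN_BP,
                score = sample(100:1000, nrow(genes), replace = TRUE),
                strand = sample(c("+", "-"), nrow(genes), replace = TRUE))
  n_per <- table(obs)
  all_chroms <- union(placed, scaffolds)
  need <- as.integer(n_per[all_chroms]); need[is.na(need)] <- 0L
  len <- pmax(need * GENE_SLOT_BP + GENE_LEN_BP, 5000L)
  names(len) <- all_chroms
  if (!is.null(chrom_length_bp)) {
    over <- intersect(names(chrom_length_bp), all_chroms)
    cap <- (chrom_length_bp[over] - GENE_LEN_BP) %/% GENE_SLOT_BP + 1
    if (any(need[match(over, all_chroms)] > cap)) {
      abort("chromosome too short to hold its genes without overlap")
    }
    len[over] <- chrom_length_bp[over]
  }
  cl <- tibble(chromosome = all_chroms, length_bp = as.numeric(len),
               placed = all_chroms %in% placed)
  list(map = gene_map(rec, cl, species_id, check = TRUE),
       truth = tibble(species_id = species_id, gene_id = genes$gene_id,
                      element = genes$element, true_chromosome = true_chrom,
                      observed_chromosome = obs, status = status))
}

#' Generate synthetic gene maps from a scenario
#'
#' Realizes one [gene_map()] per species of a [sim_scenario()]: each gene
#' is placed on its true chromosome with probability
#' `1 - mismap_rate - unplaced_rate`, on a uniformly chosen wrong placed
#' chromosome with probability `mismap_rate`, and on an unplaced scaffold
#' otherwise. Coordinates are laid out in non-overlapping slots, so the
#' tables satisfy the gene-map invariants by construction. The full truth
#' table is returned alongside.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `maps` (named list of [gene_map()]), `truth` (tibble)
#'   and `scenario`.
#' @export
sim_gene_maps <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed_if(seed, {
    res <- purrr::map(scenario$species, function(sp)
      realize_species_map(scenario$genes, sp$element_chrom, sp$species_id,
                          scenario$mismap_rate, scenario$unplaced_rate))
    maps <- purrr::map(res, "map")
    names(maps) <- purrr::map_chr(scenario$species, "species_id")
    list(maps = maps,
         truth = dplyr::bind_rows(purrr::map(res, "truth")),
         scenario = scenario)
  })
}

#' Simulate a binary turnover character along a tree
#'
#' Evolves a 0/1 state from the root to the tips by exponential waiting
#' times with the branch's (regime-specific) gain/loss rates — the exact
#' generative counterpart of [mk_loglik()].
#'
#' @inheritParams mk_loglik
#' @param seed Integer seed.
#' @return Named 0/1 integer vector over tips; the full node states are in
#'   attribute `node_states`.
#' @export
sim_mk_tips <- function(tree, rates, regimes = NULL, root_prior = "flat",
                        seed = NULL) {
  plan <- list(edges = tree$edge, n_tip = length(tree$tip.label),
               edge_order = seq_len(nrow(tree$edge)))
  er <- edge_rates(plan, rates, regimes)
  with_seed_if(seed, {
    n_node <- length(tree$tip.label) + tree$Nnode
    state <- rep(NA_integer_, n_node)
    root <- length(tree$tip.label) + 1L
    prior <- mk_root_prior(root_prior, er$q01[1], er$q10[1])
    state[root] <- sample(c(0L, 1L), 1, prob = prior)
    pre <- rev(ape::postorder(tree))  # edge indices, preorder
    for (i in pre) {
      s <- state[tree$edge[i, 1]]
      t_left <- tree$edge.length[i]
      repeat {
        rate <- if (s == 0L) er$q01[i] else er$q10[i]
        wait <- rexp(1, rate)
        if (wait >= t_left) break
        t_left <- t_left - wait
        s <- 1L - s
      }
      state[tree$edge[i, 2]] <- s
    }
    tips <- setNames(state[seq_len(plan$n_tip)], tree$tip.label)
    attr(tips, "node_states") <- state
    tips
  })
}

#' Simulate a Brownian-motion trait along a tree
#'
#' @param tree Rooted `phylo` tree.
#' @param root_value Trait value at the root.
#' @param sigma2 Diffusion rate (variance per unit branch length), > 0.
#' @param seed Integer seed.
#' @return Named numeric vector over tips; all node values in attribute
#'   `node_values`.
#' @export
sim_bm_tips <- function(tree, root_value = 0, sigma2 = 1, seed = NULL) {
  if (sigma2 <= 0) abort("sigma2 must be positive")
  with_seed_if(seed, {
    n_node <- length(tree$tip.label) + tree$Nnode
    val <- rep(NA_real_, n_node)
    val[length(tree$tip.label) + 1L] <- root_value
    pre <- rev(ape::postorder(tree))
    for (i in pre) {
      val[tree$edge[i, 2]] <- val[tree$edge[i, 1]] +
        rnorm(1, 0, sqrt(sigma2 * tree$edge.length[i]))
    }
    tips <- setNames(val[seq_len(length(tree$tip.label))], tree$tip.label)
    attr(tips, "node_values") <- val
    tips
  })
}

#' Simulate genome sequences with controlled base composition
#'
#' Draws i.i.d. bases per chromosome with `P(G) + P(C)` equal to the
#' requested GC mean (G and C, and A and T, equiprobable). Optionally a run
#' of Ns covering `n_run_frac` of the sequence start emulates an assembly
#' gap.
#'
#' @param gc_means Named vector of per-chromosome GC means in (0, 1\].
#' @param lengths_bp Named vector of sequence lengths.
#' @param n_run_frac Fraction of each sequence masked to N at its start.
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet].
#' @export
sim_fasta <- function(gc_means, lengths_bp, n_run_frac = 0, seed = NULL) {
  if (any(gc_means <= 0 | gc_means > 1)) abort("GC means must be in (0, 1]")
  stopifnot(all(names(gc_means) %in% names(lengths_bp)))
  with_seed_if(seed, {
    seqs <- vapply(names(gc_means), function(nm) {
      gc <- gc_means[[nm]]
      len <- as.integer(lengths_bp[[nm]])
      b <- sample(c("G", "C", "A", "T"), len, replace = TRUE,
                  prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
      if (n_run_frac > 0) b[seq_len(floor(n_run_frac * len))] <- "N"
      paste(b, collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Simulate a focal/outgroup trio with planted gene movement
#'
#' Builds a trio matching the movement-inference design: two outgroups with
#' the ancestral karyotype (element F as the X) and a focal species in
#' which a large element (default D) was co-opted as the X by turnover.
#' `n_moves` relocation events are planted in the focal species, drawn over
#' ordered chromosome pairs with probability proportional to the
#' size-weighted null `N_i * L_j * f_ij`; `out_of_x_multiplier` scales the
#' X-to-autosome pair weights to plant an excess of movement off the X.
#'
#' @param n_genes Shared gene count.
#' @param f_prop Proportion of genes on element F.
#' @param new_x_element Element co-opted as the focal X.
#' @param n_moves Number of planted relocations.
#' @param out_of_x_multiplier Multiplier on X-to-autosome pair weights
#'   (1 = the null itself).
#' @param mismap_rate,unplaced_rate Per-species placement noise.
#' @param seed Integer seed.
#' @return List: `focal`, `out1`, `out2` ([gene_map()]s),
#'   `x_chromosomes` (focal X), `truth` (tibble `gene_id`, `source`,
#'   `dest`, `category` for every planted move), `null_weights` (the pair
#'   table used for drawing).
#' @export
sim_trio <- function(n_genes = 2000, f_prop = 0.01, new_x_element = "D",
                     n_moves = 0, out_of_x_multiplier = 1,
                     mismap_rate = 0, unplaced_rate = 0, seed = NULL) {
  sc <- sim_scenario(n_species = 1, n_genes = n_genes, f_prop = f_prop,
                     mismap_rate = mismap_rate, unplaced_rate = unplaced_rate)
  genes <- sc$genes
  large <- setdiff(MULLER_ELEMENTS, "F")
  focal_chrom <- setNames(paste0("f_chr", 2:6), large)
  focal_chrom[new_x_element] <- "f_chrX"
  focal_chrom["F"] <- "f_chrF"
  out_chrom <- function(p) {
    ch <- setNames(paste0(p, "_chr", 2:6), large)
    ch["F"] <- paste0(p, "_chrX")
    ch
  }
  with_seed_if(seed, {
    anc <- unname(focal_chrom[genes$element])
    n_i <- table(anc)
    len <- setNames(as.numeric(n_i) * GENE_SLOT_BP + GENE_LEN_BP,
                    names(n_i))
    pairs <- expand.grid(i = names(n_i), j = names(n_i),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$i != pairs$j, ]
    f <- ifelse(pairs$j == "f_chrX", 0.75, 1)
    w <- as.numeric(n_i[pairs$i]) * len[pairs$j] * f
    w <- w * ifelse(pairs$i == "f_chrX" & pairs$j != "f_chrX",
                    out_of_x_multiplier, 1)
    dest <- rep(NA_character_, n_genes)
    truth <- NULL
    if (n_moves > 0) {
      moved <- logical(n_genes)
      picks <- sample(nrow(pairs), n_moves, replace = TRUE, prob = w)
      src <- character(n_moves); dst <- character(n_moves)
      gid <- integer(n_moves)
      for (k in seq_len(n_moves)) {
        pk <- picks[k]
        avail <- which(anc == pairs$i[pk] & !moved)
        while (length(avail) == 0) {  # source exhausted: redraw the pair
          pk <- sample(nrow(pairs), 1, prob = w)
          avail <- which(anc == pairs$i[pk] & !moved)
        }
        g <- if (length(avail) == 1) avail else sample(avail, 1)
        moved[g] <- TRUE
        gid[k] <- g; src[k] <- pairs$i[pk]; dst[k] <- pairs$j[pk]
        dest[g] <- pairs$j[pk]
      }
      truth <- tibble(
        gene_id = genes$gene_id[gid], source = src, dest = dst,
        category = dplyr::case_when(
          src == "f_chrX" & dst != "f_chrX" ~ "X_to_A",
          src != "f_chrX" & dst == "f_chrX" ~ "A_to_X",
          TRUE ~ "A_to_A"))
    } else {
      truth <- tibble(gene_id = character(), source = character(),
                      dest = character(), category = character())
    }
    focal <- realize_species_map(genes, focal_chrom, "focal",
                                 mismap_rate, unplaced_rate,
                                 forced_chrom = dest)
    out1 <- realize_species_map(genes, out_chrom("o1"), "out1",
                                mismap_rate, unplaced_rate)
    out2 <- realize_species_map(genes, out_chrom("o2"), "out2",
                                mismap_rate, unplaced_rate)
    list(focal = focal$map, out1 = out1$map, out2 = out2$map,
         x_chromosomes = "f_chrX", truth = truth,
         null_weights = tibble(source = pairs$i, dest = pairs$j, weight = w))
  })
}

#' Simulate an expression matrix with a planted testis effect
#'
#' Log-normal expression values per tissue; genes in `moved_out` get their
#' testis value multiplied by `testis_multiplier`, emulating the
#' testis-biased expression of genes relocated off the X. Somatic tissues
#' are untouched (negative controls).
#'
#' @param gene_ids Character vector of genes.
#' @param moved_out Subset of `gene_ids` carrying the planted effect.
#' @param tissues Tissue column names (must include `"testis"` for the
#'   effect to apply).
#' @param meanlog,sdlog Log-normal baseline parameters.
#' @param testis_multiplier Planted fold effect (default 2).
#' @param seed Integer seed.
#' @return Tibble: `gene_id` plus one numeric column per tissue.
#' @export
sim_expression <- function(gene_ids, moved_out = character(),
                           tissues = c("testis", "ovary", "head", "carcass"),
                           meanlog = 1, sdlog = 1, testis_multiplier = 2,
                           seed = NULL) {
  with_seed_if(seed, {
    out <- tibble(gene_id = gene_ids)
    for (tis in tissues) {
      v <- rlnorm(length(gene_ids), meanlog, sdlog)
      if (tis == "testis") {
        v[gene_ids %in% moved_out] <- v[gene_ids %in% moved_out] *
          testis_multiplier
      }
      out[[tis]] <- v
    }
    out
  })
}
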