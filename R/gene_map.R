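#' Build a per-species gene map table
#'
#' A gene map records, for one target species, where each reference
#' (*D. melanogaster*) gene landed in the target assembly, together with the
#' Muller element the gene belongs to in the reference annotation. It is the
#' input to every homology, karyotype and movement analysis in the package.
#'
#' Coordinates are 0-based half-open throughout (the convention of BLAT PSL
#' output). Muller element labels are inherited from the reference annotation,
#' never inferred from the target placement.
#'
#' @param records A data frame with columns `gene_id`, `muller_element`
#'   (one of A-F or "unknown"), `chromosome`, `start`, `end`, `score`,
#'   `strand` ("+"/"-").
#' @param chrom_lengths A data frame with columns `chromosome`,
#'   `length_bp` (positive integer) and `placed` (logical; `FALSE` marks
#'   unplaced scaffolds).
#' @param species_id Single string naming the target species.
#' @param check If `TRUE` (default), enforce the table invariants: at most
#'   one record per gene, no two records on the same chromosome overlapping
#'   by 20 bp or more, and every chromosome present in `chrom_lengths`.
#'   Set `FALSE` for raw (unfiltered) hit collections.
#'
#' @return A tibble of class `gene_map` with the record columns above and
#'   attributes `species_id` and `chrom_lengths`.
#' @seealso [best_hit_filter()], [overlap_filter()], [load_gene_map()]
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   gene_id = c("g1", "g2"), muller_element = c("A", "F"),
#'   chromosome = c("chr1", "chrX"), start = c(0L, 100L),
#'   end = c(500L, 900L), score = c(480L, 300L), strand = c("+", "-"))
#' len <- tibble::tibble(chromosome = c("chr1", "chrX"),
#'                       length_bp = c(1e6, 5e5), placed = TRUE)
#' gene_map(rec, len, "toy_species")
gene_map <- function(records, chrom_lengths, species_id, check = TRUE) {
  records <- as_tibble(records)
  needed <- c("gene_id", "muller_element", "chromosome", "start", "end",
              "score", "strand")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("gene map records lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  records <- records[needed]
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$score <- as.numeric(records$score)
  chrom_lengths <- as_tibble(chrom_lengths)
  if (!all(c("chromosome", "length_bp") %in% names(chrom_lengths))) {
    abort("chrom_lengths needs columns chromosome and length_bp")
  }
  if (is.null(chrom_lengths$placed)) chrom_lengths$placed <- TRUE

  bad_el <- setdiff(unique(records$muller_element),
                    c(MULLER_ELEMENTS, "unknown"))
  if (length(bad_el) > 0) {
    abort(paste0("unknown Muller element label(s): ",
                 paste(bad_el, collapse = ", ")))
  }
  if (any(records$start >= records$end)) {
    bad <- records$gene_id[records$start >= records$end]
    abort(paste0("start must be < end (0-based half-open); offending gene(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(records$score < 0)) abort("negative alignment score")

  if (isTRUE(check)) {
    dup <- unique(records$gene_id[duplicated(records$gene_id)])
    if (length(dup) > 0) {
      abort(paste0("duplicate gene(s) in gene map: ",
                   paste(head(dup, 5), collapse = ", ")))
    }
    missing_chr <- setdiff(unique(records$chromosome),
                           chrom_lengths$chromosome)
    if (length(missing_chr) > 0) {
      abort(paste0("chromosome(s) absent from the lengths table: ",
                   paste(head(missing_chr, 5), collapse = ", ")))
    }
    viol <- find_overlap_violations(records, max_overlap_bp = 20)
    if (nrow(viol) > 0) {
      abort(paste0("records overlap by >= 20 bp: ",
                   paste(head(paste(viol$gene_a, viol$gene_b, sep = "/"), 5),
                         collapse = ", ")))
    }
  }

  structure(records,
            species_id = as.character(species_id),
            chrom_lengths = chrom_lengths,
            class = c("gene_map", class(tibble())))
}

#' @export
print.gene_map <- function(x, ...) {
  cl <- attr(x, "chrom_lengths")
  cat(sprintf("<gene_map> species '%s': %d genes on %d sequences (%d placed)\n",
              attr(x, "species_id"), nrow(x), nrow(cl), sum(cl$placed)))
  NextMethod()
}

species_id <- function(map) attr(map, "species_id")
chrom_lengths <- function(map) attr(map, "chrom_lengths")

# chromosomes flagged as assembled (non-scaffold) sequences
placed_chromosomes <- function(map) {
  cl <- chrom_lengths(map)
  cl$chromosome[cl$placed]
}

# all >= max_overlap_bp overlapping pairs on a shared chromosome;
# overlap length = max(0, min(end) - max(start)) in 0-based half-open coords
find_overlap_violations <- function(records, max_overlap_bp = 20) {
  out <- list()
  for (chrom in unique(records$chromosome)) {
    r <- records[records$chromosome == chrom, ]
    if (nrow(r) < 2) next
    r <- r[order(r$start, r$end), ]
    # sweep: only neighbours within running max(end) can overlap
    for (i in seq_len(nrow(r) - 1)) {
      j <- i + 1
      while (j <= nrow(r) && r$start[j] < r$end[i]) {
        ov <- min(r$end[i], r$end[j]) - max(r$start[i], r$start[j])
        if (ov >= max_overlap_bp) {
          out[[length(out) + 1]] <- tibble(
            gene_a = r$gene_id[i], gene_b = r$gene_id[j],
            chromosome = chrom, overlap_bp = ov,
            score_a = r$score[i], score_b = r$score[j])
        }
        j <- j + 1
      }
    }
  }
  if (length(out) == 0) {
    tibble(gene_a = character(), gene_b = character(),
           chromosome = character(), overlap_bp = integer(),
           score_a = numeric(), score_b = numeric())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Read translated-BLAT hits from a PSL file
#'
#' Parses the 21-column PSL format produced by BLAT and returns one raw hit
#' per alignment line, carrying the alignment `matches` count as the score
#' and the target coordinates (0-based half-open) as the placement. Muller
#' element labels are attached from a reference annotation lookup; query
#' genes missing from it are kept with element `"unknown"` and a warning.
#'
#' No filtering happens here: use [best_hit_filter()] and [overlap_filter()]
#' afterwards.
#'
#' @param path Path to a PSL file. The optional 5-line psLayout header is
#'   skipped automatically.
#' @param reference_elements Named character vector (or two-column data frame
#'   `gene_id`, `muller_element`) mapping query gene ids to Muller elements.
#'
#' @return A tibble of hit records (possibly several per gene) with columns
#'   `gene_id`, `muller_element`, `chromosome`, `start`, `end`, `score`,
#'   `strand`.
#' @export
read_psl_hits <- function(path, reference_elements) {
  if (is.data.frame(reference_elements)) {
    reference_elements <- setNames(
      as.character(reference_elements$muller_element),
      reference_elements$gene_id)
  }
  lines <- readLines(path, warn = FALSE)
  # strip psLayout header block (ends with a dashed separator line)
  sep <- grep("^-{5,}", lines)
  if (length(sep) > 0) lines <- lines[-seq_len(sep[1])]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(gene_id = character(), muller_element = character(),
                  chromosome = character(), start = integer(),
                  end = integer(), score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21)) {
    bad <- which(nf != 21)[1]
    abort(sprintf("malformed PSL line %d: %d fields (expected 21)", bad, nf[bad]))
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(as.integer(m[, 1]))
  starts <- suppressWarnings(as.integer(m[, 16]))
  ends <- suppressWarnings(as.integer(m[, 17]))
  bad <- which(is.na(num) | is.na(starts) | is.na(ends))
  if (length(bad) > 0) {
    abort(sprintf("malformed PSL line %d: non-numeric coordinate or match count",
                  bad[1]))
  }
  gene_id <- m[, 10]
  element <- unname(reference_elements[gene_id])
  n_unknown <- sum(is.na(element))
  if (n_unknown > 0) {
    warn(sprintf(
      "%d hit(s) from %d gene(s) absent from the reference element table; kept with muller_element = 'unknown'",
      n_unknown, length(unique(gene_id[is.na(element)]))))
    element[is.na(element)] <- "unknown"
  }
  tibble(gene_id = gene_id,
         muller_element = element,
         chromosome = m[, 14],
         start = starts,
         end = ends,
         score = as.numeric(num),
         strand = substr(m[, 9], 1, 1))
}

#' Keep the best-scoring hit per gene
#'
#' Reduces a raw hit collection to exactly one record per gene, the hit with
#' the largest alignment score. Score ties are broken deterministically by
#' the lexicographically smallest (chromosome, start) pair.
#'
#' @param hits A data frame of hit records (as from [read_psl_hits()]).
#' @return A tibble with one row per `gene_id`.
#' @export
best_hit_filter <- function(hits) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$score),
                   .data$chromosome, .data$start) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
}

#' Drop genes whose placements overlap by 20 bp or more
#'
#' Two retained genes on the same chromosome may overlap by strictly less
#' than `max_overlap_bp` (default 20 bp, with overlap measured in 0-based
#' half-open coordinates). An overlap of exactly `max_overlap_bp` is a
#' violation. Conflicts are resolved by dropping the lower-scoring member of
#' each offending pair (ties: the lexicographically larger `gene_id` is
#' dropped), iterating until no violation remains.
#'
#' @param hits Hit records, already reduced to one row per gene.
#' @param max_overlap_bp Smallest overlap considered a violation.
#' @return Filtered tibble satisfying the overlap rule.
#' @export
overlap_filter <- function(hits, max_overlap_bp = 20) {
  hits <- as_tibble(hits)
  if (anyDuplicated(hits$gene_id)) {
    abort("overlap_filter expects best-hit-filtered input (one row per gene)")
  }
  repeat {
    viol <- find_overlap_violations(hits, max_overlap_bp)
    if (nrow(viol) == 0) break
    drop <- ifelse(
      viol$score_a < viol$score_b, viol$gene_a,
      ifelse(viol$score_b < viol$score_a, viol$gene_b,
             pmax(viol$gene_a, viol$gene_b)))
    hits <- hits[!hits$gene_id %in% unique(drop), ]
  }
  hits
}

#' Load a gene map (and chromosome lengths) from TSV files
#'
#' Reads the tab-separated gene table written by [write_gene_map()] (columns
#' `gene_id`, `muller_element`, `chromosome`, `start`, `end`, `score`,
#' `strand`) together with its companion chromosome-lengths table
#' (`chromosome`, `length_bp`, `placed`), and validates the gene-map
#' invariants (unique genes, <20 bp overlaps, known chromosomes).
#'
#' @param path Path to the gene TSV (header row required).
#' @param lengths_path Path to the chromosome-lengths TSV.
#' @param species_id Species label; defaults to the gene file name.
#' @return A validated [gene_map()].
#' @export
load_gene_map <- function(path, lengths_path,
                          species_id = sub("\\.[^.]*$", "", basename(path))) {
  rec <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  len <- readr::read_tsv(lengths_path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(len$placed)) len$placed <- as.logical(len$placed)
  gene_map(rec, len, species_id = species_id, check = TRUE)
}

#' Write a gene map to TSV files
#'
#' @param map A [gene_map()].
#' @param path Destination for the gene table.
#' @param lengths_path Destination for the chromosome-lengths table.
#' @return `map`, invisibly.
#' @export
write_gene_map <- function(map, path, lengths_path) {
  readr::write_tsv(as_tibble(as.data.frame(map)), path, progress = FALSE)
  readr::write_tsv(chrom_lengths(map), lengths_path, progress = FALSE)
  invisible(map)
}

#' Per-chromosome gene scatter for a gene map
#'
#' Draws each mapped gene at its midpoint position along its chromosome,
#' coloured by reference Muller element — a quick visual check of
#' chromosome-element homology (conserved elements appear as single-colour
#' chromosomes; fusions as two-colour ones).
#'
#' @param object A [gene_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_map
#' @export
autoplot.gene_map <- function(object, ...) {
  df <- as_tibble(as.data.frame(object))
  df$mid_mb <- (df$start + df$end) / 2e6
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_mb, y = .data$chromosome,
                                   colour = .data$muller_element)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "Muller element",
                  title = species_id(object)) +
    ggplot2::theme_minimal()
}
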