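#' Windowed GC content along a genome
#'
#' Computes GC fraction in fixed windows (default 100 kb window, 100 kb
#' step) along each sequence. The GC fraction of a window is
#' `(G + C) / (A + C + G + T)` case-insensitively; ambiguous bases (N etc.)
#' are excluded from the denominator. The trailing partial window is
#' computed with its true length. Windows whose unambiguous-base count is
#' below half the nominal window size are flagged (`included = FALSE`) and
#' left out of downstream comparisons.
#'
#' @param fasta Path to a (optionally gzipped) FASTA file, a
#'   [Biostrings::DNAStringSet], or a named character vector of sequences.
#' @param window Window size in bp (default 100000).
#' @param step Step between window starts in bp (default 100000).
#' @param min_valid_frac Minimum `n_valid / window` for a window to enter
#'   comparisons (default 0.5).
#' @return A tibble of class `gc_windows`: `chromosome`, `start`, `end`
#'   (0-based half-open), `gc_fraction` (`NA` when no unambiguous base),
#'   `n_valid`, `included`.
#' @export
gc_windows <- function(fasta, window = 100000, step = 100000,
                       min_valid_frac = 0.5) {
  if (window <= 0 || step <= 0) abort("window and step must be positive")
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta
  else if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    Biostrings::readDNAStringSet(fasta)
  else Biostrings::DNAStringSet(fasta)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))

  out <- purrr::imap(as.list(seqs), function(s, nm) {
    len <- length(s)
    if (len == 0) {
      warn(sprintf("sequence '%s' is empty; no windows", nm))
      return(NULL)
    }
    starts <- seq(1L, len, by = step)
    ends <- pmin(starts + window - 1L, len)
    v <- Biostrings::Views(s, start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    n_valid <- rowSums(freq)
    gc <- ifelse(n_valid > 0, (freq[, "C"] + freq[, "G"]) / n_valid, NA_real_)
    tibble(chromosome = nm, start = starts - 1L, end = ends,
           gc_fraction = gc, n_valid = as.integer(n_valid),
           included = n_valid / window >= min_valid_frac)
  })
  structure(dplyr::bind_rows(out),
            window = window, step = step,
            class = c("gc_windows", class(tibble())))
}

#' Compare GC content of X versus autosomal windows
#'
#' Two-sided Mann-Whitney U test of per-window GC fractions on the X
#' chromosome(s) against all autosomal windows. Only windows with
#' `included = TRUE` enter the test. Note that adjacent windows of one
#' chromosome are not independent observations, so the test can be
#' anticonservative (pseudoreplication); the caveat is carried in the
#' result.
#'
#' @param windows A `gc_windows` tibble.
#' @param x_chromosomes Character vector of X chromosome names.
#' @param alpha Significance level used to set `direction` (default 0.05).
#' @return One-row tibble of class `gc_comparison`: `u_statistic`, `p`,
#'   `median_x`, `median_auto`, `n_x`, `n_auto`, `direction`
#'   (`X_higher` / `X_lower` / `ns`) and a `caveat` attribute.
#' @export
compare_gc_x_autosome <- function(windows, x_chromosomes, alpha = 0.05) {
  w <- windows[windows$included & !is.na(windows$gc_fraction), ]
  gx <- w$gc_fraction[w$chromosome %in% x_chromosomes]
  ga <- w$gc_fraction[!w$chromosome %in% x_chromosomes]
  if (length(gx) < 2 || length(ga) < 2) {
    abort("need at least 2 included windows on each side")
  }
  wt <- suppressWarnings(wilcox.test(gx, ga, alternative = "two.sided"))
  mx <- median(gx); ma <- median(ga)
  structure(
    tibble(u_statistic = unname(wt$statistic), p = wt$p.value,
           median_x = mx, median_auto = ma,
           n_x = length(gx), n_auto = length(ga),
           direction = if (wt$p.value >= alpha) "ns"
           else if (mx > ma) "X_higher" else "X_lower"),
    caveat = "windows within a chromosome are not independent (pseudoreplication)",
    class = c("gc_comparison", class(tibble())))
}

#' Boxplot of window GC, X versus autosomes
#'
#' @param object A `gc_windows` tibble.
#' @param x_chromosomes Optional X chromosome names; when given, windows are
#'   grouped into X and autosome classes, otherwise per chromosome.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gc_windows
#' @export
autoplot.gc_windows <- function(object, x_chromosomes = NULL, ...) {
  df <- as_tibble(as.data.frame(object))
  df <- df[df$included & !is.na(df$gc_fraction), ]
  if (!is.null(x_chromosomes)) {
    df$group <- ifelse(df$chromosome %in% x_chromosomes, "X", "autosomes")
  } else {
    df$group <- df$chromosome
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$gc_fraction)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "GC fraction per window") +
    ggplot2::theme_minimal()
}
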