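#' Ancestral reconstruction of a continuous trait under Brownian motion
#'
#' Maximum-likelihood estimates of internal-node values for a continuous
#' trait (here typically the percentage of mapped genes on element F)
#' evolving by Brownian motion. Estimates are the generalized-least-squares
#' conditional expectations given the tree covariance (shared path lengths),
#' with the root mean and the diffusion rate estimated by ML. Each node
#' carries a variance and a 95% confidence interval
#' (`estimate +/- 1.96 sqrt(variance)`).
#'
#' @param tree Rooted `phylo` tree with strictly positive branch lengths
#'   (zero-length internal branches are collapsed into multifurcations
#'   first).
#' @param tip_values Named numeric vector over all tips.
#' @return A tibble of class `bm_anc` with one row per internal node:
#'   `node` (ape node id), `estimate`, `variance`, `ci95_low`, `ci95_high`;
#'   attributes `sigma2` (ML diffusion rate), `root_estimate` and `tree`.
#' @export
bm_ancestral_states <- function(tree, tip_values) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length == 0)) {
    n_before <- tree$Nnode
    tree <- ape::di2multi(tree, tol = 0)
    inform(sprintf("collapsed %d zero-length internal branch(es)",
                   n_before - tree$Nnode))
  }
  x <- tip_values[tree$tip.label]
  if (anyNA(x)) {
    abort(paste0("missing tip value(s): ",
                 paste(tree$tip.label[is.na(x)], collapse = ", ")))
  }
  n <- length(x)
  C <- ape::vcv(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    abort("singular tree covariance (duplicate zero-length tips?)"))
  one <- rep(1, n)
  denom <- sum(Cinv %*% one * one)
  mu <- sum(Cinv %*% x * one) / denom
  r <- x - mu
  sigma2 <- as.numeric(t(r) %*% Cinv %*% r) / n

  depth <- ape::node.depth.edgelength(tree)
  mrca_all <- ape::mrca(tree, full = TRUE)
  internal <- n + seq_len(tree$Nnode)
  est <- numeric(length(internal))
  vr <- numeric(length(internal))
  for (i in seq_along(internal)) {
    k <- internal[i]
    v <- depth[mrca_all[k, seq_len(n)]]  # shared path with each tip
    h <- Cinv %*% v
    est[i] <- mu + sum(h * r)
    vr[i] <- sigma2 * (depth[k] - sum(v * h) + (1 - sum(h))^2 / denom)
  }
  vr[vr < 0 & vr > -1e-12] <- 0  # numerical floor
  structure(tibble(node = internal,
                   estimate = est,
                   variance = vr,
                   ci95_low = est - 1.96 * sqrt(vr),
                   ci95_high = est + 1.96 * sqrt(vr)),
            sigma2 = sigma2,
            root_estimate = mu,
            tree = tree,
            class = c("bm_anc", class(tibble())))
}

#' @method glance bm_anc
#' @export
glance.bm_anc <- function(x, ...) {
  tree <- attr(x, "tree")
  root <- x[x$node == length(tree$tip.label) + 1L, ]
  tibble(sigma2 = attr(x, "sigma2"),
         root_estimate = root$estimate,
         root_ci95_low = root$ci95_low,
         root_ci95_high = root$ci95_high,
         n_tips = length(tree$tip.label),
         n_nodes = nrow(x))
}

#' @method tidy bm_anc
#' @export
tidy.bm_anc <- function(x, ...) as_tibble(as.data.frame(x))

#' Compare reconstructed node values between two sets of nodes
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of ancestral
#' estimates between two disjoint node sets — e.g. nodes inside versus
#' outside a focal clade.
#'
#' @param est A `bm_anc` reconstruction.
#' @param clade_nodes,other_nodes Disjoint, non-empty vectors of node ids
#'   (as in `est$node`).
#' @return One-row tibble: `n_clade`, `n_other`, `median_clade`,
#'   `median_other`, `u_statistic`, `p`, `direction`.
#' @export
compare_node_sets <- function(est, clade_nodes, other_nodes) {
  if (length(clade_nodes) == 0 || length(other_nodes) == 0) {
    abort("both node sets must be non-empty")
  }
  if (length(intersect(clade_nodes, other_nodes)) > 0) {
    abort("node sets overlap")
  }
  a <- est$estimate[match(clade_nodes, est$node)]
  b <- est$estimate[match(other_nodes, est$node)]
  if (anyNA(a) || anyNA(b)) abort("node id(s) not found in the reconstruction")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble(n_clade = length(a), n_other = length(b),
         median_clade = median(a), median_other = median(b),
         u_statistic = unname(wt$statistic), p = wt$p.value,
         direction = if (median(a) < median(b)) "clade_lower" else
           if (median(a) > median(b)) "clade_higher" else "equal")
}

#' Ancestral-state reconstruction plot
#'
#' Node estimates with 95% confidence bars, ordered by node height
#' (distance from the root).
#'
#' @param object A `bm_anc` reconstruction.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bm_anc
#' @export
autoplot.bm_anc <- function(object, ...) {
  tree <- attr(object, "tree")
  df <- as_tibble(as.data.frame(object))
  df$node_depth <- ape::node.depth.edgelength(tree)[df$node]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node_depth, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci95_low,
                                          ymax = .data$ci95_high),
                             size = 0.3) +
    ggplot2::labs(x = "node depth (distance from root)",
                  y = "reconstructed value") +
    ggplot2::theme_minimal()
}
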