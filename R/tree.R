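#' Read and validate a rooted Newick tree
#'
#' Wraps [ape::read.tree()] with the validation the downstream models need:
#' unique tip labels, branch lengths on every edge, and a root. Basal
#' multifurcations are accepted with a warning (the pruning algorithm
#' handles them natively); zero-length branches are allowed and reported.
#'
#' @param path Path to a Newick file (or a Newick string containing ";").
#' @return An [ape] `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- if (grepl(";", path, fixed = TRUE)) {
    ape::read.tree(text = path)
  } else {
    ape::read.tree(path)
  }
  if (is.null(tree)) abort("could not parse Newick input")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate tip label(s): ", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) "all edges" else {
      i <- which(is.na(tree$edge.length))[1]
      sprintf("edge to node %d", tree$edge[i, 2])
    }
    abort(paste0("missing branch length(s): ", bad))
  }
  if (any(tree$edge.length < 0)) abort("negative branch length")
  if (!ape::is.rooted(tree)) {
    warn("tree has a basal multifurcation; treating it as the root")
  }
  n0 <- sum(tree$edge.length == 0)
  if (n0 > 0) inform(sprintf("%d zero-length branch(es) present", n0))
  tree
}

#' Paint branches of a tree with rate regimes
#'
#' Assigns every branch to one of two regimes: the clade spanned by
#' `focal_tips` (by default including its stem branch) versus the rest of
#' the tree. Used to fit turnover models where, e.g., the Schizophora clade
#' is allowed its own turnover rate.
#'
#' @param tree A rooted `phylo` tree.
#' @param focal_tips Tip labels spanning the focal clade (the regime is
#'   applied to all branches of the most recent common ancestor's clade).
#' @param focal,background Regime labels.
#' @param include_stem Should the branch subtending the focal clade belong
#'   to the focal regime? Default `TRUE`.
#' @return Character vector of regime labels, one per row of `tree$edge`.
#' @export
regime_paint <- function(tree, focal_tips, focal = "focal",
                         background = "background", include_stem = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  missing_tips <- setdiff(focal_tips, tree$tip.label)
  if (length(missing_tips) > 0) {
    abort(paste0("focal tips not in tree: ",
                 paste(missing_tips, collapse = ", ")))
  }
  tip_idx <- match(focal_tips, tree$tip.label)
  mrca <- if (length(tip_idx) == 1) tip_idx else ape::getMRCA(tree, tip_idx)
  clade_nodes <- clade_descendants(tree, mrca)
  in_clade <- tree$edge[, 2] %in% clade_nodes |
    (include_stem & tree$edge[, 2] == mrca)
  ifelse(in_clade, focal, background)
}

# all nodes (tips + internals) descending from `node`, excluding `node` itself
clade_descendants <- function(tree, node) {
  edges <- tree$edge
  out <- integer(0)
  frontier <- node
  while (length(frontier) > 0) {
    children <- edges[edges[, 1] %in% frontier, 2]
    out <- c(out, children)
    frontier <- children[children > length(tree$tip.label)]
  }
  unique(out)
}
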