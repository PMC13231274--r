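# Independent oracles and tiny fixtures shared across tests. Everything here
# is deliberately brute-force / first-principles so it cannot share a bug
# with the package implementation.

# --- fixtures -----------------------------------------------------------

toy_records <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(gene_id = r[[1]], muller_element = r[[2]],
                   chromosome = r[[3]], start = as.integer(r[[4]]),
                   end = as.integer(r[[5]]), score = as.numeric(r[[6]]),
                   strand = if (length(r) >= 7) r[[7]] else "+")
  }))
}

toy_lengths <- function(chroms, length_bp = 1e6, placed = TRUE) {
  tibble::tibble(chromosome = chroms, length_bp = length_bp,
                 placed = rep_len(placed, length(chroms)))
}

# a clean two-chromosome map: n_a element-A genes on chr1, n_f element-F
# genes on chrX
toy_map <- function(n_a = 20, n_f = 5, species = "toy") {
  rec <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_a + n_f)),
    muller_element = c(rep("A", n_a), rep("F", n_f)),
    chromosome = c(rep("chr1", n_a), rep("chrX", n_f)),
    start = c(seq(0, by = 1000, length.out = n_a),
              seq(0, by = 1000, length.out = n_f)),
    end = c(seq(0, by = 1000, length.out = n_a),
            seq(0, by = 1000, length.out = n_f)) + 500L,
    score = 500, strand = "+")
  gene_map(rec, toy_lengths(c("chr1", "chrX")), species)
}

# --- Mk model -----------------------------------------------------------

# likelihood by exhaustive enumeration of internal-state assignments
brute_mk_loglik <- function(tree, states, q01, q10, prior = c(0.5, 0.5)) {
  m <- tree$Nnode
  total <- 0
  for (cfg in 0:(2^m - 1)) {
    st <- c(states[tree$tip.label], as.integer(intToBits(cfg))[seq_len(m)])
    p <- prior[st[length(tree$tip.label) + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      s <- q01 + q10
      decay <- exp(-s * tree$edge.length[e])
      P <- matrix(c(1 - q01 / s * (1 - decay), q10 / s * (1 - decay),
                    q01 / s * (1 - decay), 1 - q10 / s * (1 - decay)), 2, 2)
      p <- p * P[st[tree$edge[e, 1]] + 1, st[tree$edge[e, 2]] + 1]
    }
    total <- total + p
  }
  log(total)
}

# minimum 0->1 origins with root fixed absent, by exhaustive assignment
brute_min_origins <- function(tree, presence) {
  tips <- tree$tip.label
  state <- stats::setNames(rep(0L, length(tips)), tips)
  state[names(presence)] <- as.integer(as.logical(presence))
  m <- tree$Nnode
  n <- length(tips)
  best_changes <- Inf; best_gains <- Inf
  for (cfg in 0:(2^(m - 1) - 1)) {
    internal <- c(0L, as.integer(intToBits(cfg))[seq_len(m - 1)])  # root = 0
    st <- c(state[tips], internal)
    par <- st[tree$edge[, 1]]; ch <- st[tree$edge[, 2]]
    changes <- sum(par != ch)
    gains <- sum(par == 0 & ch == 1)
    if (changes < best_changes ||
        (changes == best_changes && gains < best_gains)) {
      best_changes <- changes; best_gains <- gains
    }
  }
  best_gains
}

# --- Fisher / hypergeometric --------------------------------------------

# one-sided (greater) p for a 2x2 table via explicit tail summation of
# hypergeometric terms (log-binomial arithmetic, no phyper/dhyper)
hyper_tail_p <- function(a, row_tot, col_tot, n_total) {
  kmax <- min(row_tot, col_tot)
  kmin <- max(0, row_tot + col_tot - n_total)
  ks <- max(a, kmin):kmax
  sum(exp(lchoose(row_tot, ks) + lchoose(n_total - row_tot, col_tot - ks) -
            lchoose(n_total, col_tot)))
}

# build a one-species map realizing a given 2x2 shared-gene table:
# elements A/B on chromosomes c1/c2 with cell counts (a, b; c, d)
map_from_2x2 <- function(a, b, cc, d) {
  el <- c(rep("A", a + b), rep("B", cc + d))
  ch <- c(rep("c1", a), rep("c2", b), rep("c1", cc), rep("c2", d))
  n <- length(el)
  ord <- order(ch)
  start <- integer(n)
  start[ord] <- (stats::ave(seq_len(n)[ord], ch[ord], FUN = seq_along) - 1L) *
    1000L
  rec <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(n)),
                        muller_element = el, chromosome = ch,
                        start = start, end = start + 500L,
                        score = 100, strand = "+")
  gene_map(rec, toy_lengths(c("c1", "c2")), "tab")
}

# --- Brownian motion ----------------------------------------------------

# root-to-node edge paths computed by plain recursion (no ape helpers)
node_edge_paths <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  parent_edge <- rep(NA_integer_, n_node)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  lapply(seq_len(n_node), function(nd) {
    path <- integer(0)
    while (!is.na(parent_edge[nd])) {
      path <- c(parent_edge[nd], path)
      nd <- tree$edge[parent_edge[nd], 1]
    }
    path
  })
}

# explicit GLS ancestral states: covariance from shared edge paths, solves
# with base linear algebra
gls_ancestral_oracle <- function(tree, x) {
  n <- length(tree$tip.label)
  paths <- node_edge_paths(tree)
  shared_len <- function(p1, p2)
    sum(tree$edge.length[intersect(p1, p2)])
  C <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) shared_len(paths[[i]], paths[[j]])))
  x <- x[tree$tip.label]
  Cinv <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric(t(one) %*% Cinv %*% x) / as.numeric(t(one) %*% Cinv %*% one)
  r <- x - mu
  sig2 <- as.numeric(t(r) %*% Cinv %*% r) / n
  nodes <- n + seq_len(tree$Nnode)
  est <- vr <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    k <- nodes[i]
    v <- vapply(seq_len(n), function(tp)
      shared_len(paths[[k]], paths[[tp]]), numeric(1))
    ck <- sum(tree$edge.length[paths[[k]]])
    h <- Cinv %*% v
    est[i] <- mu + sum(h * r)
    denom <- as.numeric(t(one) %*% Cinv %*% one)
    vr[i] <- sig2 * (ck - sum(v * h) + (1 - sum(h))^2 / denom)
  }
  list(node = nodes, estimate = est, variance = vr, mu = mu, sigma2 = sig2)
}

# --- multinomial max statistic ------------------------------------------

# exact P(max count >= m) under uniform allocation of `total` events to
# `k` cells, by enumeration of all compositions
exact_max_multinomial_p <- function(total, k, m) {
  compositions <- function(tot, cells) {
    if (cells == 1) return(matrix(tot, 1, 1))
    out <- list()
    for (first in 0:tot) {
      rest <- compositions(tot - first, cells - 1)
      out[[first + 1]] <- cbind(first, rest)
    }
    do.call(rbind, out)
  }
  comp <- compositions(total, k)
  logp <- lgamma(total + 1) - rowSums(lgamma(comp + 1)) + total * log(1 / k)
  sum(exp(logp)[apply(comp, 1, max) >= m])
}

# random tree with positive branch lengths
rand_tree <- function(n, scale = 1) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length * scale + 0.05
  tr
}
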