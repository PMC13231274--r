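#' Transition probabilities of the two-state turnover model
#'
#' Closed-form transition matrix of a continuous-time two-state Markov chain
#' with gain rate `q01` (turnover origin, state 0 to 1) and loss rate `q10`
#' (turnover reversal). With `s = q01 + q10`,
#' `P(0 -> 1) = (q01/s) (1 - exp(-s t))` and symmetrically for `P(1 -> 0)`.
#'
#' @param q01,q10 Positive transition rates.
#' @param t Non-negative elapsed time (branch length).
#' @return A 2x2 row-stochastic matrix with dimnames `c("0","1")`.
#' @export
#' @examples
#' mk_transition_probs(0.3, 0.3, 2)[1, 1] # 1/2 + exp(-1.2)/2
mk_transition_probs <- function(q01, q10, t) {
  if (q01 <= 0 || q10 <= 0) abort("rates must be positive")
  if (t < 0) abort("t must be non-negative")
  s <- q01 + q10
  decay <- exp(-s * t)
  p01 <- (q01 / s) * (1 - decay)
  p10 <- (q10 / s) * (1 - decay)
  matrix(c(1 - p01, p10, p01, 1 - p10), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# precomputed pruning structure reused across likelihood evaluations
mk_plan <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  st <- tip_states[tree$tip.label]
  if (anyNA(st)) {
    abort(paste0("missing tip state(s): ",
                 paste(tree$tip.label[is.na(st)], collapse = ", ")))
  }
  st <- as.integer(st)
  if (!all(st %in% c(0L, 1L))) abort("tip states must be 0/1")
  tr <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  initL <- matrix(1, n_node, 2)
  initL[seq_len(n_tip), ] <- 0
  initL[cbind(seq_len(n_tip), st + 1L)] <- 1
  list(edges = tr$edge, edge_lengths = tr$edge.length,
       n_tip = n_tip, n_node = n_node, root = n_tip + 1L, initL = initL,
       # postorder edge order differs from tree$edge order: keep the map
       edge_order = match(paste(tr$edge[, 1], tr$edge[, 2]),
                          paste(tree$edge[, 1], tree$edge[, 2])))
}

mk_loglik_core <- function(plan, q01_edge, q10_edge, prior) {
  L <- plan$initL
  logf <- numeric(plan$n_node)
  e <- plan$edges
  tl <- plan$edge_lengths
  s <- q01_edge + q10_edge
  decay <- exp(-s * tl)
  p01 <- (q01_edge / s) * (1 - decay)
  p10 <- (q10_edge / s) * (1 - decay)
  for (i in seq_len(nrow(e))) {
    par <- e[i, 1]; ch <- e[i, 2]
    c0 <- (1 - p01[i]) * L[ch, 1] + p01[i] * L[ch, 2]
    c1 <- p10[i] * L[ch, 1] + (1 - p10[i]) * L[ch, 2]
    m <- max(c0, c1)
    if (m <= 0) return(-Inf)
    L[par, 1] <- L[par, 1] * (c0 / m)
    L[par, 2] <- L[par, 2] * (c1 / m)
    logf[par] <- logf[par] + logf[ch] + log(m)
  }
  r <- plan$root
  lik <- prior[1] * L[r, 1] + prior[2] * L[r, 2]
  if (lik <= 0) return(-Inf)
  log(lik) + logf[r]
}

# expand a per-regime rate table to per-edge rate vectors (postorder order)
edge_rates <- function(plan, rates, regimes) {
  if (is.null(regimes)) {
    if (is.data.frame(rates)) {
      if (nrow(rates) != 1) abort("multiple regimes given without a regime map")
      rates <- c(q01 = rates$q01[1], q10 = rates$q10[1])
    }
    list(q01 = rep(unname(rates["q01"]), nrow(plan$edges)),
         q10 = rep(unname(rates["q10"]), nrow(plan$edges)))
  } else {
    if (length(regimes) != nrow(plan$edges)) {
      abort("regimes must have one label per edge of the tree")
    }
    if (!is.data.frame(rates)) abort("per-regime rates must be a data frame")
    idx <- match(regimes[plan$edge_order], rates$regime)
    if (anyNA(idx)) abort("regime label missing from the rate table")
    list(q01 = rates$q01[idx], q10 = rates$q10[idx])
  }
}

mk_root_prior <- function(root_prior, q01, q10) {
  if (identical(root_prior, "flat")) c(0.5, 0.5)
  else if (identical(root_prior, "stationary")) {
    s <- q01 + q10
    c(q10 / s, q01 / s)
  } else abort("root_prior must be 'flat' or 'stationary'")
}

#' Log-likelihood of tip states under the two-state turnover model
#'
#' Felsenstein-pruning likelihood of a binary character on a rooted tree,
#' with optionally branch-specific (regime) transition rates. Conditional
#' likelihoods are combined at the root under a flat (1/2, 1/2) prior by
#' default, or the stationary distribution of the (first-regime) rates.
#'
#' @param tree Rooted `phylo` tree.
#' @param tip_states Named 0/1 vector over all tips (1 = derived state,
#'   e.g. "turnover has happened").
#' @param rates Either a named vector `c(q01 =, q10 =)` (single regime) or a
#'   data frame with columns `regime`, `q01`, `q10`.
#' @param regimes `NULL`, or a character vector of regime labels, one per
#'   row of `tree$edge` (see [regime_paint()]).
#' @param root_prior `"flat"` (default) or `"stationary"`.
#' @return The log-likelihood (a scalar).
#' @export
mk_loglik <- function(tree, tip_states, rates, regimes = NULL,
                      root_prior = "flat") {
  plan <- mk_plan(tree, tip_states)
  er <- edge_rates(plan, rates, regimes)
  if (any(er$q01 <= 0) || any(er$q10 <= 0)) abort("rates must be positive")
  prior <- mk_root_prior(root_prior, er$q01[length(er$q01)],
                         er$q10[length(er$q10)])
  mk_loglik_core(plan, er$q01, er$q10, prior)
}

#' Fit the turnover model by maximum likelihood
#'
#' Estimates the gain (turnover) and loss (reversal) rates of a two-state
#' Markov model on a rooted tree. `model = "ER"` constrains gain and loss to
#' be equal within each regime; `"ARD"` lets each direction have its own
#' rate. With a regime map each regime receives its own rate(s), so the
#' parameter count is 1 (ER single), 2 (ARD single or ER two-regime) or 4
#' (ARD two-regime).
#'
#' Optimization is bounded multi-start search on log rates (box
#' `[1e-8, 1e3]`, relative tolerance 1e-8); the first start is a
#' tree-length heuristic, the rest are jittered from a seedable stream.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"` or `"ARD"`.
#' @param n_starts Number of optimizer starts (default 5).
#' @param seed Seed for the start jitter.
#' @param lower,upper Rate bounds.
#' @return An object of class `mk_fit` (list with `model`, `rates` tibble,
#'   `loglik`, `converged`, `n_params`, `degenerate`). Methods: [tidy()],
#'   [glance()], `print`.
#' @export
fit_mk <- function(tree, tip_states, model = c("ER", "ARD"), regimes = NULL,
                   root_prior = "flat", n_starts = 5, seed = 1,
                   lower = 1e-8, upper = 1e3) {
  model <- match.arg(model)
  plan <- mk_plan(tree, tip_states)
  degenerate <- length(unique(tip_states[tree$tip.label])) < 2
  if (degenerate) {
    warn("all tips share one state; rates are not identifiable (degenerate fit)")
  }
  regime_levels <- if (is.null(regimes)) "all" else unique(regimes)
  k <- length(regime_levels) * (if (model == "ER") 1L else 2L)

  unpack <- function(theta) {
    q <- exp(theta)
    if (model == "ER") {
      tibble(regime = regime_levels, q01 = q, q10 = q)
    } else {
      tibble(regime = regime_levels,
             q01 = q[seq_along(regime_levels)],
             q10 = q[length(regime_levels) + seq_along(regime_levels)])
    }
  }
  negll <- function(theta) {
    rt <- unpack(theta)
    er <- edge_rates(plan, rt, regimes)
    prior <- mk_root_prior(root_prior, er$q01[length(er$q01)],
                           er$q10[length(er$q10)])
    ll <- mk_loglik_core(plan, er$q01, er$q10, prior)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # heuristic scale: one expected change across the mean root-to-tip depth
  depth <- mean(ape::node.depth.edgelength(tree)[seq_len(plan$n_tip)])
  theta0 <- rep(log(max(min(1 / max(depth, 1e-8), upper), lower * 10)), k)
  starts <- with_seed_if(seed, {
    jit <- matrix(rnorm(k * max(n_starts - 1, 0), 0, 1.5), ncol = k)
    rbind(theta0, sweep(jit, 2, theta0, `+`))
  })
  starts <- pmin(pmax(starts, log(lower)), log(upper))

  best <- NULL
  for (i in seq_len(min(n_starts, nrow(starts)))) {
    fit <- tryCatch(
      nlminb(starts[i, ], negll, lower = log(lower), upper = log(upper),
             control = list(rel.tol = 1e-8, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    abort("optimizer failed on every start")
  }
  structure(list(model = model,
                 rates = unpack(best$par),
                 loglik = -best$objective,
                 converged = best$convergence == 0,
                 n_params = k,
                 root_prior = root_prior,
                 degenerate = degenerate,
                 n_tips = plan$n_tip),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("<mk_fit> %s, %d regime(s), logLik = %.4f%s\n",
              x$model, nrow(x$rates), x$loglik,
              if (!x$converged) " (NOT converged)" else ""))
  print(x$rates)
  invisible(x)
}

#' @rdname fit_mk
#' @param x An `mk_fit` object.
#' @param ... Unused.
#' @method tidy mk_fit
#' @export
tidy.mk_fit <- function(x, ...) {
  tidyr::pivot_longer(x$rates, c("q01", "q10"),
                      names_to = "term", values_to = "estimate")
}

#' @rdname fit_mk
#' @method glance mk_fit
#' @export
glance.mk_fit <- function(x, ...) {
  tibble(model = x$model, n_regimes = nrow(x$rates), n_params = x$n_params,
         logLik = x$loglik, AIC = 2 * x$n_params - 2 * x$loglik,
         converged = x$converged, n_tips = x$n_tips)
}

#' Likelihood-ratio test between nested turnover-model fits
#'
#' Compares a restricted fit (e.g. one turnover rate for the whole tree)
#' against a nested richer fit (e.g. separate rates inside and outside a
#' focal clade). The statistic `2 (logLik_alt - logLik_null)` is referred to
#' a chi-square distribution with degrees of freedom equal to the parameter
#' difference.
#'
#' @param fit_null,fit_alt `mk_fit` objects; `fit_null` must have fewer
#'   parameters.
#' @param tol Tolerance for a lower alternative log-likelihood before the
#'   comparison is declared an optimization failure.
#' @return A one-row tibble of class `mk_lrt`: `loglik_null`, `loglik_alt`,
#'   `df`, `statistic`, `p`.
#' @export
lrt <- function(fit_null, fit_alt, tol = 1e-6) {
  df <- fit_alt$n_params - fit_null$n_params
  if (df <= 0) abort("models are not nested (alternative must add parameters)")
  if (fit_alt$loglik < fit_null$loglik - tol) {
    abort(sprintf(
      "alternative log-likelihood (%.6f) below null (%.6f): optimization failure",
      fit_alt$loglik, fit_null$loglik))
  }
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  structure(tibble(loglik_null = fit_null$loglik,
                   loglik_alt = fit_alt$loglik,
                   df = df, statistic = stat,
                   p = pchisq(stat, df, lower.tail = FALSE)),
            class = c("mk_lrt", class(tibble())))
}
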