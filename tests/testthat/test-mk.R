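test_that("transition matrices match the two-state closed form", {
  # t = 0: identity
  expect_equal(mk_transition_probs(0.3, 0.7, 0), diag(2), ignore_attr = TRUE)
  # ER stationary limit: all entries 1/2
  expect_equal(unname(mk_transition_probs(0.3, 0.3, 1e9)),
               matrix(0.5, 2, 2), tolerance = 1e-12)
  # symmetric case closed form: P(stay) = 1/2 + exp(-2qt)/2
  P <- mk_transition_probs(0.3, 0.3, 2)
  expect_equal(P[1, 1], 0.5 + 0.5 * exp(-1.2))
  expect_error(mk_transition_probs(0, 1, 1), "positive")
})

test_that("transition matrices are stochastic and satisfy Chapman-Kolmogorov", {
  withr::local_seed(3)
  for (i in 1:50) {
    q01 <- runif(1, 0.01, 5); q10 <- runif(1, 0.01, 5)
    t1 <- runif(1, 0, 3); t2 <- runif(1, 0, 3)
    P1 <- mk_transition_probs(q01, q10, t1)
    P2 <- mk_transition_probs(q01, q10, t2)
    expect_equal(rowSums(P1), c("0" = 1, "1" = 1), tolerance = 1e-12)
    expect_equal(P1 %*% P2, mk_transition_probs(q01, q10, t1 + t2),
                 tolerance = 1e-12)
  }
})

test_that("pruning log-likelihood equals brute-force state enumeration", {
  # analytic limits on a 2-tip tree
  two <- read_newick("(a:1,b:1);")
  ll_tiny <- mk_loglik(two, c(a = 0, b = 0), c(q01 = 1e-8, q10 = 1e-8))
  expect_equal(ll_tiny, log(0.5), tolerance = 1e-6)
  long <- read_newick("(a:1e9,b:1e9);")
  expect_equal(mk_loglik(long, c(a = 0, b = 1), c(q01 = 1, q10 = 1)),
               log(0.25), tolerance = 1e-9)

  withr::local_seed(8)
  for (i in 1:30) {
    tr <- rand_tree(sample(3:6, 1))
    st <- stats::setNames(sample(0:1, length(tr$tip.label), TRUE),
                          tr$tip.label)
    q01 <- runif(1, 0.05, 3); q10 <- runif(1, 0.05, 3)
    expect_equal(mk_loglik(tr, st, c(q01 = q01, q10 = q10)),
                 brute_mk_loglik(tr, st, q01, q10), tolerance = 1e-10)
    # stationary root prior variant
    pi1 <- q01 / (q01 + q10)
    expect_equal(
      mk_loglik(tr, st, c(q01 = q01, q10 = q10), root_prior = "stationary"),
      brute_mk_loglik(tr, st, q01, q10, prior = c(1 - pi1, pi1)),
      tolerance = 1e-10)
  }
  expect_error(mk_loglik(two, c(a = 0), c(q01 = 1, q10 = 1)), "missing tip")
})

test_that("regime-specific likelihood reduces to single regime when rates agree", {
  tr <- rand_tree(8)
  st <- stats::setNames(rep(c(0, 1), 4), tr$tip.label)
  reg <- regime_paint(tr, tr$tip.label[1:2])
  rates <- tibble::tibble(regime = c("focal", "background"),
                          q01 = 0.4, q10 = 0.9)
  expect_equal(mk_loglik(tr, st, rates, regimes = reg),
               mk_loglik(tr, st, c(q01 = 0.4, q10 = 0.9)))
  # differing rates change the likelihood
  rates2 <- tibble::tibble(regime = c("focal", "background"),
                           q01 = c(2, 0.4), q10 = c(2, 0.9))
  expect_false(isTRUE(all.equal(mk_loglik(tr, st, rates2, regimes = reg),
                                mk_loglik(tr, st, c(q01 = 0.4, q10 = 0.9)))))
})

test_that("fit_mk recovers simulated rates and flags degenerate data", {
  set.seed(21)
  tr <- ape::rcoal(150)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * 60
  st <- sim_mk_tips(tr, c(q01 = 0.5, q10 = 0.5), seed = 2)
  fit <- fit_mk(tr, st, "ER", n_starts = 3)
  expect_true(fit$converged)
  expect_equal(fit$rates$q01, fit$rates$q10)  # ER constraint
  expect_lt(abs(fit$rates$q01 - 0.5), 0.35)
  # ARD nests ER
  fit_ard <- fit_mk(tr, st, "ARD", n_starts = 3)
  expect_gte(fit_ard$loglik, fit$loglik - 1e-6)
  expect_equal(fit_ard$n_params, 2)
  # degenerate: constant tips push the rate to the floor
  flat <- stats::setNames(rep(0, length(tr$tip.label)), tr$tip.label)
  expect_warning(fit0 <- fit_mk(tr, flat, "ER", n_starts = 2), "degenerate")
  expect_equal(fit0$loglik, log(0.5), tolerance = 1e-4)
  expect_true(fit0$degenerate)
  # tidiers
  expect_equal(nrow(tidy(fit_ard)), 2)
  expect_equal(glance(fit)$n_params, 1)
})

test_that("likelihood-ratio test handles nesting, ties and failures", {
  f1 <- structure(list(loglik = -12, n_params = 1), class = "mk_fit")
  f2 <- structure(list(loglik = -10, n_params = 2), class = "mk_fit")
  out <- lrt(f1, f2)
  expect_equal(out$statistic, 4)
  expect_equal(out$df, 1)
  expect_equal(out$p, pchisq(4, 1, lower.tail = FALSE))
  # equal logliks -> statistic 0, p = 1
  f_eq <- structure(list(loglik = -12, n_params = 2), class = "mk_fit")
  expect_equal(lrt(f1, f_eq)$p, 1)
  # non-nested and optimization-failure signals
  expect_error(lrt(f2, f1), "not nested")
  f_bad <- structure(list(loglik = -13, n_params = 2), class = "mk_fit")
  expect_error(lrt(f1, f_bad), "optimization failure")
})

test_that("simulated tip states match transition probabilities empirically", {
  # single branch of known length: empirical transitions vs closed form
  withr::local_seed(31)
  tr <- read_newick("(a:0.8,b:0.8);")
  P <- mk_transition_probs(0.6, 0.3, 0.8)
  hits <- replicate(3000, {
    s <- sim_mk_tips(tr, c(q01 = 0.6, q10 = 0.3))
    root <- attr(s, "node_states")[3]
    c(root, s[["a"]])
  })
  from0 <- hits[2, hits[1, ] == 0]
  expect_equal(mean(from0 == 1), P[1, 2], tolerance = 0.03)
  # near-zero rates: tips inherit the root state
  s0 <- sim_mk_tips(rand_tree(20), c(q01 = 1e-9, q10 = 1e-9), seed = 4)
  expect_equal(length(unique(s0)), 1)
  # huge rates: stationary coin flips
  s1 <- sim_mk_tips(ape::rcoal(1000), c(q01 = 1e4, q10 = 1e4), seed = 5)
  expect_lt(abs(mean(s1) - 0.5), 3 * sqrt(0.25 / 1000))
})
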