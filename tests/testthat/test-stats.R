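test_that("cooperation counts tally (observed, own) pairs directly", {
  # observed/own pairs (C,C),(C,D),(D,C),(D,D),(C,C) after the first slot
  log <- make_log(c("C", "C", "D", "C", "D", "C", "C"))
  # pairs: (C,C),(C,D),(D,C),(C,D),(D,C),(C,C)
  cnt <- cooperation_counts(log)
  oracle <- brute_counts(log)
  expect_equal(cnt$n_CC, oracle$n_CC)
  expect_equal(cnt$n_CD, oracle$n_CD)
  expect_equal(cnt$n_DC, oracle$n_DC)
  expect_equal(cnt$n_DD, oracle$n_DD)
  expect_equal(cnt$n_C_total, 5L)
  expect_equal(cnt$n_decisions, 7L)
})

test_that("chain-first slots count toward totals but no conditional cell", {
  log <- make_log(rep("C", 10), rep("C", 5))
  cnt <- cooperation_counts(log)
  expect_equal(cnt$n_CC, 15L - 2L)  # two chain-first slots have no prior
  expect_equal(cnt$n_C_total, 15L)
  expect_equal(cnt$n_decisions, 15L)
})

test_that("scoped counts partition the total", {
  log <- make_log(c("C", "D", "C", "D"), c("D", "D", "C", "C"),
                  actor = list(c(1L, 2L, 1L, 2L), c(3L, 1L, 3L, 1L)))
  whole <- cooperation_counts(log)
  parts <- lapply(1:3, function(p) cooperation_counts(log, participant = p))
  for (f in c("n_CC", "n_CD", "n_DC", "n_DD", "n_C_total", "n_decisions"))
    expect_equal(sum(vapply(parts, `[[`, 0L, f)), whole[[f]])
  # empty scope is all zeros, not an error
  empty <- cooperation_counts(log, participant = 99)
  expect_equal(empty$n_decisions, 0L)
  expect_equal(empty$n_CC, 0L)
})

test_that("conditional probabilities match the hand-tallied example", {
  cnt <- structure(list(n_CC = 2L, n_CD = 1L, n_DC = 1L, n_DD = 1L,
                        n_C_total = 3L, n_decisions = 5L),
                   class = "coop_counts")
  s <- conditional_probs(cnt)
  expect_equal(s$p_C, 0.6)
  expect_equal(s$p_C_given_C, 2 / 3)
  expect_equal(s$p_C_given_D, 0.5)
})

test_that("undefined conditionals are NA, never zero", {
  log <- make_log(rep("C", 6))      # no observed defection anywhere
  s <- conditional_probs(cooperation_counts(log))
  expect_true(is.na(s$p_C_given_D))
  expect_equal(s$p_C_given_C, 1)
  expect_true(is.na(r_score(s)))
})

test_that("the reciprocity score is the conditional-probability gap", {
  mk <- function(cc, cd) structure(list(p_C = 0.5, p_C_given_C = cc,
                                        p_C_given_D = cd,
                                        counts = list(n_decisions = 0L)),
                                   class = "coop_summary")
  expect_equal(r_score(mk(0.5, 0.5)), 0)
  expect_equal(r_score(mk(0.71, 0.47)), 0.24)
  expect_equal(r_score(mk(1, 0)), 1)
})

test_that("statistics are invariant to record order", {
  set.seed(31)
  log <- make_log(sample(c("C", "D"), 60, replace = TRUE))
  shuffled <- log[sample(nrow(log)), ]
  a <- conditional_probs(cooperation_counts(log))
  b <- conditional_probs(cooperation_counts(shuffled))
  expect_equal(a$p_C, b$p_C)
  expect_equal(a$p_C_given_C, b$p_C_given_C)
  expect_equal(a$p_C_given_D, b$p_C_given_D)
})

test_that("p(C) over prior-observed decisions is the mixture of the conditionals", {
  set.seed(17)
  for (i in 1:25) {
    log <- make_log(sample(c("C", "D"), 40, replace = TRUE, prob = c(0.6, 0.4)))
    cnt <- cooperation_counts(log)
    s <- conditional_probs(cnt)
    n_after_C <- cnt$n_CC + cnt$n_CD
    n_after_D <- cnt$n_DC + cnt$n_DD
    if (n_after_C == 0 || n_after_D == 0) next
    mixture <- (n_after_C * s$p_C_given_C + n_after_D * s$p_C_given_D) /
      (n_after_C + n_after_D)
    p_C_prior <- (cnt$n_CC + cnt$n_DC) / (n_after_C + n_after_D)
    expect_equal(p_C_prior, mixture)
  }
})

test_that("per-round series handles certainty and empty conditioning sets", {
  log <- make_log(rep("C", 8), rep("C", 8))
  ser <- per_round_series(log)
  pc <- ser[ser$statistic == "p_C", ]
  expect_true(all(pc$value == 1))
  expect_true(all(pc$ci_high - pc$ci_low == 0))
  # nobody ever observes a D, so p(C|D) is missing each round
  pcd <- ser[ser$statistic == "p_C_given_D", ]
  expect_true(all(is.na(pcd$value)))
  # chain-first round has no observed prior at all
  pcc1 <- ser[ser$statistic == "p_C_given_C" & ser$round == 1, ]
  expect_equal(pcc1$n, 0L)
})

test_that("per-round confidence intervals match the normal approximation", {
  set.seed(4)
  log <- make_log(sample(c("C", "D"), 30, replace = TRUE),
                  sample(c("C", "D"), 30, replace = TRUE),
                  actor = list(rep(1:5, 6), rep(6:10, 6)))
  log$round <- rep(rep(1:6, each = 5), 2)
  ser <- per_round_series(log)
  r3 <- log[log$round == 3, ]
  x <- as.numeric(r3$decision == "C")
  row <- ser[ser$statistic == "p_C" & ser$round == 3, ]
  expect_equal(row$value, mean(x))
  expect_equal(row$ci_high, mean(x) + 1.96 * sd(x) / sqrt(length(x)))
})

test_that("between-game correlations: identity, degeneracy, residualisation", {
  set.seed(12)
  tab <- data.frame(id = 1:40, p_C = runif(40),
                    p_C_given_C = runif(40), p_C_given_D = runif(40),
                    r_score = runif(40), n_decisions = 45L)
  self <- residual_correlation(tab, tab)
  expect_true(all(abs(self$r_plain - 1) < 1e-12))

  # conditional exactly linear in p(C) in both games -> zero residual variance
  lin <- tab
  lin$p_C_given_C <- 0.2 + 0.5 * lin$p_C
  res <- residual_correlation(lin, lin)
  expect_true(is.na(res$r_residual[res$statistic == "p_C_given_C"]))

  # fewer than 3 complete pairs -> undefined
  small <- tab[1:2, ]
  expect_true(all(is.na(residual_correlation(small, small)$r_plain)))

  # residualisation removes a shared dependence on p(C): conditionals that
  # are (noisy) functions of independent p_C plus a common signal
  n <- 500
  common <- rnorm(n)
  mk <- function() {
    p_C <- runif(n)
    data.frame(id = 1:n, p_C = p_C,
               p_C_given_C = p_C + 0.1 * rnorm(n),
               p_C_given_D = p_C + 0.1 * rnorm(n),
               r_score = 0, n_decisions = 45L)
  }
  a <- mk(); b <- mk()
  # plain correlation tracks nothing (independent p_C) ...
  rr <- residual_correlation(a, b)
  expect_lt(abs(rr$r_residual[rr$statistic == "p_C_given_C"]), 0.15)
  # ... but correlated p_C induces plain correlation of the conditionals
  b2 <- b
  b2$p_C <- a$p_C
  b2$p_C_given_C <- b2$p_C + 0.1 * rnorm(n)
  rr2 <- residual_correlation(a, b2)
  expect_gt(rr2$r_plain[rr2$statistic == "p_C_given_C"], 0.5)
  expect_lt(abs(rr2$r_residual[rr2$statistic == "p_C_given_C"]), 0.15)
})

test_that("shared random intercepts induce between-game p(C) correlation; independent ones do not", {
  pars <- behavior_params(intercept_sd = 1.5)
  n <- 500
  # one 'participant' per chain: p(C) per participant from long Bernoulli
  # chains driven by their intercept
  sim_tab <- function(ri, seed) {
    set.seed(seed)
    p <- plogis(ri)
    p_C <- rbinom(n, 45, p) / 45
    data.frame(id = 1:n, p_C = p_C, p_C_given_C = NA_real_,
               p_C_given_D = NA_real_, r_score = NA_real_, n_decisions = 45L)
  }
  set.seed(61)
  ri_shared <- rnorm(n, 0, 1.5)
  ri_indep <- rnorm(n, 0, 1.5)
  shared <- residual_correlation(sim_tab(ri_shared, 1), sim_tab(ri_shared, 2))
  indep <- residual_correlation(sim_tab(ri_shared, 3), sim_tab(ri_indep, 4))
  expect_gt(shared$r_plain[shared$statistic == "p_C"], 0.5)
  expect_lt(abs(indep$r_plain[indep$statistic == "p_C"]), 0.15)
})
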