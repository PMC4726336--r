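test_that("run extraction matches the worked example and boundary rules", {
  rs <- extract_runs(make_log(c("D", "C", "C", "C", "D")))
  expect_equal(rs$lengths_C, 3L)
  expect_equal(rs$censored_C, FALSE)
  expect_equal(sort(rs$lengths_D), c(1L, 1L))
  expect_true(all(rs$censored_D))

  # a chain of all C is one run, censored at both ends
  rs <- extract_runs(make_log(rep("C", 12)))
  expect_equal(rs$lengths_C, 12L)
  expect_true(rs$censored_C)

  # runs never merge across chains
  rs <- extract_runs(make_log(c("C", "D"), c("D", "C")))
  expect_equal(sort(rs$lengths_C), c(1L, 1L))
  expect_equal(sort(rs$lengths_D), c(1L, 1L))
})

test_that("run lengths conserve chain length", {
  set.seed(23)
  for (i in 1:50) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    log <- make_log(sample(c("C", "D"), n1, replace = TRUE),
                    sample(c("C", "D"), n2, replace = TRUE))
    rs <- extract_runs(log)
    expect_equal(sum(rs$lengths_C) + sum(rs$lengths_D), n1 + n2)
    expect_equal(sum(rs$lengths_C), sum(log$decision == "C"))
  }
})

test_that("geometric pmf has the stated form and sums to one", {
  expect_equal(geometric_pmf(1, 0.3), 0.7)
  expect_equal(geometric_pmf(1, 0), 1)
  expect_equal(geometric_pmf(2, 0), 0)
  expect_equal(geometric_pmf(3, 0.71), 0.71^2 * 0.29)
  for (p in c(0.1, 0.42, 0.71, 0.95)) {
    k <- 1:3000
    # tail beyond k_max is p^k_max; total must be 1
    expect_equal(sum(geometric_pmf(k, p)) + p^3000, 1, tolerance = 1e-12)
  }
  expect_error(geometric_pmf(0, 0.5), "positive")
  expect_error(geometric_pmf(2, 1), "0, 1")
})

test_that("iid fit uses the overall cooperation fraction", {
  set.seed(3)
  dec <- c(rep("C", 42), rep("D", 58))[sample(100)]
  f <- fit_iid(make_log(dec))
  expect_equal(f$C_runs$p, 0.42)
  expect_equal(f$D_runs$p, 0.58)
  expect_error(fit_iid(make_log(rep("C", 10))), "degenerate")
})

test_that("markov fit uses the transition probabilities", {
  # construct a log with known transition tallies
  log <- make_log(c("C", "C", "C", "D", "C", "D", "D"))
  # pairs: CC, CC, CD, DC, CD, DD -> p(C|C) = 2/4... tally via the package
  s <- conditional_probs(cooperation_counts(log))
  f <- fit_markov(log)
  expect_equal(f$C_runs$p, s$p_C_given_C)
  expect_equal(f$D_runs$p, 1 - s$p_C_given_D)
  expect_error(fit_markov(make_log(rep("C", 5))), "Markov")
})

test_that("markov fit reduces to the iid fit when the conditionals are equal", {
  # CCDD blocks plus a trailing C balance the transition tallies exactly:
  # p(C|C) = p(C|D) = 1/2
  log <- make_log(c(rep(c("C", "C", "D", "D"), 10), "C"))
  s <- conditional_probs(cooperation_counts(log))
  expect_equal(s$p_C_given_C, 0.5)
  expect_equal(s$p_C_given_D, 0.5)
  fm <- fit_markov(log)
  expect_equal(fm$C_runs$p, 0.5)
  expect_equal(fm$D_runs$p, 0.5)
  # the iid fit differs only through the chain-first (no-prior) decisions
  fi <- fit_iid(log)
  expect_equal(fm$C_runs$p, fi$C_runs$p, tolerance = 0.03)
})

test_that("iid and markov fits agree on genuinely iid decisions", {
  set.seed(8)
  log <- make_log(sample(c("C", "D"), 1e4, replace = TRUE, prob = c(0.6, 0.4)))
  fi <- fit_iid(log)
  fm <- fit_markov(log)
  se <- sqrt(0.6 * 0.4 / 1e4)
  expect_lt(abs(fi$C_runs$p - fm$C_runs$p), 5 * se)
  expect_lt(abs(fi$D_runs$p - fm$D_runs$p), 5 * se)
})

test_that("fits are invariant to chain processing order", {
  set.seed(9)
  a <- sample(c("C", "D"), 50, replace = TRUE)
  b <- sample(c("C", "D"), 50, replace = TRUE)
  f1 <- fit_markov(make_log(a, b))
  f2 <- fit_markov(make_log(b, a))
  expect_equal(f1$C_runs$p, f2$C_runs$p)
  expect_equal(f1$D_runs$p, f2$D_runs$p)
})

test_that("KS distance is the sup over the integer support", {
  # runs {1,1,1,1} vs p = 0.5: ECDF(1) = 1, CDF(1) = 0.5
  ks <- ks_geometric(c(1, 1, 1, 1), geom_model(0.5, "iid", "C_runs"))
  expect_equal(ks$D, 0.5)
  # large sample from the model: D tends to zero, fixed-p Monte-Carlo and
  # asymptotic p-values are non-significant
  set.seed(5)
  runs <- rgeom(1e5, prob = 0.29) + 1L
  m <- geom_model(0.71, "markov", "C_runs")
  ks <- ks_geometric(runs, m)
  expect_lt(ks$D, 0.01)
  ks_mc <- ks_geometric(runs[1:500], m, method = "monte_carlo", n_mc = 99,
                        seed = 1)
  expect_gt(ks_mc$p_value, 0.05)
})

test_that("asymptotic tail matches standard KS software on continuous data", {
  # at n >= 100 ks.test itself uses the asymptotic Kolmogorov tail
  set.seed(14)
  x <- runif(500)
  ref <- suppressWarnings(stats::ks.test(x, "punif"))
  ours <- chainrecip:::kolmogorov_tail(500, unname(ref$statistic))
  expect_equal(ours, ref$p.value, tolerance = 1e-6)
})

test_that("fixed-parameter Monte-Carlo p-values are roughly uniform under the null", {
  set.seed(26)
  pvals <- replicate(60, {
    runs <- rgeom(80, prob = 0.4) + 1L
    ks_geometric(runs, geom_model(0.6, "iid", "C_runs"),
                 method = "monte_carlo", n_mc = 99)$p_value
  })
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  expect_gt(min(pvals), 0)  # never exactly zero by the +1 correction
})

test_that("run-length table buckets the tail and conserves counts", {
  tab <- run_length_table(c(1, 1, 2, 13))
  expect_equal(tab$count[tab$k == "1"], 2L)
  expect_equal(tab$count[tab$k == "2"], 1L)
  expect_equal(tab$count[tab$k == "> 10"], 1L)
  expect_equal(sum(tab$count), 4L)
  empty <- run_length_table(integer(0))
  expect_true(all(empty$count == 0L))
  set.seed(2)
  runs <- rgeom(200, 0.3) + 1L
  expect_equal(sum(run_length_table(runs)$count), 200L)
})

test_that("censoring option drops boundary runs from the fit's run set", {
  log <- make_log(c("C", "C", "D", "C", "D", "D"))
  f_in <- fit_iid(log, censoring = "include")
  f_ex <- fit_iid(log, censoring = "exclude")
  expect_equal(sort(f_in$runs$lengths_C), c(1L, 2L))
  expect_equal(f_ex$runs$lengths_C, 1L)   # the leading CC run is censored
  expect_lt(length(f_ex$runs$lengths_D), length(f_in$runs$lengths_D))
})

test_that("simulate() on a fit draws geometric run lengths", {
  log <- make_log(rep(c("C", "C", "C", "D"), 20))
  f <- fit_markov(log)
  draws <- simulate(f, nsim = 2000, seed = 3, side = "C_runs")
  expect_true(all(draws >= 1))
  expect_equal(mean(draws), 1 / (1 - f$C_runs$p), tolerance = 0.1)
})
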