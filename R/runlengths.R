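#' Extract C/D run lengths along chains
#'
#' A run is a maximal block of identical decisions along one chain; runs
#' never span chain (or group, or game) boundaries.  The first and last
#' run of each chain are flagged as censored: they are truncated by the
#' chain boundary rather than terminated by the opposite decision.
#'
#' @param log a `decision_log`.
#' @return An object of class `run_set`: a list with integer vectors
#'   `lengths_C`, `lengths_D` and parallel logical vectors `censored_C`,
#'   `censored_D`.
#' @examples
#' # a ...DCCCD... stretch contributes a C-run of length 3
#' @export
extract_runs <- function(log) {
  stopifnot(is.data.frame(log))
  lengths_C <- integer(0); lengths_D <- integer(0)
  censored_C <- logical(0); censored_D <- logical(0)
  key <- interaction(log$group, log$game_type, log$chain_id, drop = TRUE)
  for (k in levels(key)) {
    ch <- log[key == k, , drop = FALSE]
    ch <- ch[order(ch$slot_index), ]
    r <- rle(ch$decision)
    n_runs <- length(r$lengths)
    cens <- seq_len(n_runs) %in% c(1L, n_runs)
    is_C <- r$values == "C"
    lengths_C <- c(lengths_C, r$lengths[is_C])
    censored_C <- c(censored_C, cens[is_C])
    lengths_D <- c(lengths_D, r$lengths[!is_C])
    censored_D <- c(censored_D, cens[!is_C])
  }
  structure(list(lengths_C = as.integer(lengths_C),
                 lengths_D = as.integer(lengths_D),
                 censored_C = censored_C, censored_D = censored_D),
            class = "run_set")
}

#' @export
print.run_set <- function(x, ...) {
  cat(sprintf("Run set: %d C-runs (%d censored), %d D-runs (%d censored)\n",
              length(x$lengths_C), sum(x$censored_C),
              length(x$lengths_D), sum(x$censored_D)))
  invisible(x)
}

#' Geometric run-length probability mass
#'
#' P(k) = p^(k-1) (1 - p) for run length k >= 1; p is the "continue"
#' probability of prolonging the current run by one more decision.
#'
#' @param k positive integer run length(s).
#' @param p continue probability in \[0, 1).
#' @return P(k), vectorised over `k`.
#' @examples
#' geometric_pmf(3, 0.71)  # 0.71^2 * 0.29
#' @export
geometric_pmf <- function(k, p) {
  if (any(k < 1) || any(k != as.integer(k)))
    stopf("`k` must be positive integers")
  if (length(p) != 1L || !is.finite(p) || p < 0 || p >= 1)
    stopf("`p` must be a single number in [0, 1)")
  stats::dgeom(k - 1L, prob = 1 - p)
}

#' A fitted geometric run-length component
#'
#' @param p continue probability in \[0, 1).
#' @param model `"iid"` or `"markov"` -- how `p` was derived.
#' @param side `"C_runs"` or `"D_runs"`.
#' @param n_runs number of runs the fit is based on (`NA` for analytic
#'   constructions).
#' @return An object of class `geom_model`.
#' @export
geom_model <- function(p, model = c("iid", "markov"),
                       side = c("C_runs", "D_runs"), n_runs = NA_integer_) {
  model <- match.arg(model); side <- match.arg(side)
  if (length(p) != 1L || !is.finite(p) || p < 0 || p >= 1)
    stopf("degenerate fit: continue probability must lie in [0, 1), got %s",
          format(p))
  structure(list(p = p, model = model, side = side, n_runs = n_runs),
            class = "geom_model")
}

#' @export
print.geom_model <- function(x, ...) {
  cat(sprintf("Geometric run-length model (%s, %s): p = %.4f\n",
              x$model, x$side, x$p))
  invisible(x)
}

#' Geometric parameters implied by the i.i.d. decision model
#'
#' If decisions are i.i.d. with cooperation probability `p_c`, C-run
#' lengths are geometric with continue probability `p_c` and D-run
#' lengths geometric with continue probability `1 - p_c`.
#'
#' @param p_c overall cooperation fraction, strictly inside (0, 1).
#' @return A list with `p_C_runs` and `p_D_runs`.
#' @export
geom_params_iid <- function(p_c) {
  if (length(p_c) != 1L || !is.finite(p_c) || p_c <= 0 || p_c >= 1)
    stopf("degenerate fit: cooperation fraction must lie strictly in (0, 1), got %s",
          format(p_c))
  list(p_C_runs = p_c, p_D_runs = 1 - p_c)
}

#' Geometric parameters implied by the two-state Markov decision model
#'
#' If each decision depends only on the observed previous decision through
#' the transition probabilities p(C|C) and p(C|D), the chain of decisions
#' is a two-state Markov chain: a C-run continues with probability p(C|C)
#' and a D-run continues with probability p(D|D) = 1 - p(C|D).
#'
#' @param p_cc transition probability p(C|C), in \[0, 1).
#' @param p_cd transition probability p(C|D), in (0, 1\].
#' @return A list with `p_C_runs` and `p_D_runs`.
#' @examples
#' geom_params_markov(0.71, 0.47)  # p_C_runs 0.71, p_D_runs 0.53
#' @export
geom_params_markov <- function(p_cc, p_cd) {
  if (length(p_cc) != 1L || !is.finite(p_cc) || p_cc < 0 || p_cc >= 1)
    stopf("degenerate fit: p(C|C) must lie in [0, 1), got %s", format(p_cc))
  if (length(p_cd) != 1L || !is.finite(p_cd) || p_cd <= 0 || p_cd > 1)
    stopf("degenerate fit: p(C|D) must lie in (0, 1], got %s", format(p_cd))
  list(p_C_runs = p_cc, p_D_runs = 1 - p_cd)
}

new_geom_fit <- function(model, params, runs, estimates, censoring,
                         chain_lengths) {
  structure(list(
    model = model,
    C_runs = geom_model(params$p_C_runs, model, "C_runs",
                        length(runs$lengths_C)),
    D_runs = geom_model(params$p_D_runs, model, "D_runs",
                        length(runs$lengths_D)),
    runs = runs, estimates = estimates, censoring = censoring,
    chain_lengths = chain_lengths),
    class = "geom_fit")
}

chain_lengths_of <- function(log) {
  key <- interaction(log$group, log$game_type, log$chain_id, drop = TRUE)
  as.integer(table(key))
}

filter_runs <- function(runs, censoring) {
  if (censoring == "include") return(runs)
  structure(list(lengths_C = runs$lengths_C[!runs$censored_C],
                 lengths_D = runs$lengths_D[!runs$censored_D],
                 censored_C = runs$censored_C[!runs$censored_C],
                 censored_D = runs$censored_D[!runs$censored_D]),
            class = "run_set")
}

#' Fit the i.i.d. geometric run-length model
#'
#' Under independent, identically distributed decisions, both run-length
#' distributions are geometric; the single parameter is the overall
#' cooperation fraction of the log (not a run-based maximum-likelihood
#' estimate, which would coincide with the Markov self-transition
#' estimate instead).
#'
#' @param log a `decision_log`.
#' @param censoring `"include"` (default) to keep chain-boundary-truncated
#'   runs in the run set, `"exclude"` to drop them.
#' @return An object of class `geom_fit` holding the C-run and D-run
#'   [geom_model()]s, the extracted [extract_runs()] run set, and the
#'   estimates used.
#' @export
fit_iid <- function(log, censoring = c("include", "exclude")) {
  censoring <- match.arg(censoring)
  if (nrow(log) == 0L) stopf("cannot fit on an empty log")
  p_c <- mean(log$decision == "C")
  params <- geom_params_iid(p_c)
  runs <- filter_runs(extract_runs(log), censoring)
  new_geom_fit("iid", params, runs, list(p_C = p_c), censoring,
               chain_lengths_of(log))
}

#' Fit the two-state Markov geometric run-length model
#'
#' Estimates the transition probabilities p(C|C) and p(C|D) from the
#' decisions with an observed prior, then derives the geometric continue
#' parameters: p(C|C) for C-runs and 1 - p(C|D) for D-runs.
#'
#' @inheritParams fit_iid
#' @return An object of class `geom_fit`; its `estimates` element records
#'   p(C|C) and p(C|D).
#' @export
fit_markov <- function(log, censoring = c("include", "exclude")) {
  censoring <- match.arg(censoring)
  if (nrow(log) == 0L) stopf("cannot fit on an empty log")
  s <- conditional_probs(cooperation_counts(log))
  if (is.na(s$p_C_given_C) || is.na(s$p_C_given_D))
    stopf("cannot fit Markov model: no observed-%s transitions in the log",
          if (is.na(s$p_C_given_C)) "C" else "D")
  params <- geom_params_markov(s$p_C_given_C, s$p_C_given_D)
  runs <- filter_runs(extract_runs(log), censoring)
  new_geom_fit("markov", params, runs,
               list(p_C_given_C = s$p_C_given_C,
                    p_C_given_D = s$p_C_given_D), censoring,
               chain_lengths_of(log))
}

#' @export
print.geom_fit <- function(x, ...) {
  cat(sprintf("Geometric run-length fit (%s model, censored runs %sd):\n",
              x$model, x$censoring))
  cat(sprintf("  C runs: p = %.4f  (n = %d)\n", x$C_runs$p, x$C_runs$n_runs))
  cat(sprintf("  D runs: p = %.4f  (n = %d)\n", x$D_runs$p, x$D_runs$n_runs))
  invisible(x)
}

#' @export
summary.geom_fit <- function(object, ks_method = c("asymptotic", "monte_carlo"),
                             seed = NULL, ...) {
  ks_method <- match.arg(ks_method)
  ks_C <- ks_fit(object, "C_runs", method = ks_method, seed = seed)
  ks_D <- ks_fit(object, "D_runs", method = ks_method, seed = seed)
  structure(list(fit = object, ks_C = ks_C, ks_D = ks_D), class = "summary.geom_fit")
}

#' @export
print.summary.geom_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  KS (C runs): D = %.4f, P = %.3f (%s)\n",
              x$ks_C$D, x$ks_C$p_value, x$ks_C$method))
  cat(sprintf("  KS (D runs): D = %.4f, P = %.3f (%s)\n",
              x$ks_D$D, x$ks_D$p_value, x$ks_D$method))
  invisible(x)
}

#' @export
plot.geom_fit <- function(x, side = c("C_runs", "D_runs"), max_k = 10L, ...) {
  side <- match.arg(side)
  runs <- if (side == "C_runs") x$runs$lengths_C else x$runs$lengths_D
  model <- if (side == "C_runs") x$C_runs else x$D_runs
  tab <- run_length_table(runs, max_k = max_k)
  freq <- tab$count / max(1L, sum(tab$count))
  bp <- graphics::barplot(freq[seq_len(max_k)],
                          names.arg = seq_len(max_k),
                          xlab = "run length", ylab = "relative frequency",
                          main = sprintf("%s (%s model, p = %.2f)",
                                         gsub("_", " ", side), x$model,
                                         model$p), ...)
  graphics::lines(bp, geometric_pmf(seq_len(max_k), model$p), type = "b",
                  pch = 19)
  invisible(x)
}

#' @export
simulate.geom_fit <- function(object, nsim = 1L, seed = NULL,
                              side = c("C_runs", "D_runs"), ...) {
  side <- match.arg(side)
  p <- if (side == "C_runs") object$C_runs$p else object$D_runs$p
  draw <- function() stats::rgeom(nsim, prob = 1 - p) + 1L
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Sup distance between the run-length ECDF and a geometric CDF, evaluated
# on the integer support 1..max(runs) (beyond which the discrepancy can
# only shrink, since the ECDF is already 1).
ks_distance_geom <- function(runs, p) {
  kmax <- max(runs)
  k <- seq_len(kmax)
  ecdf_k <- cumsum(tabulate(runs, nbins = kmax)) / length(runs)
  max(abs(ecdf_k - (1 - p^k)))
}

# Asymptotic Kolmogorov tail: P(sqrt(n) D > lambda).
kolmogorov_tail <- function(n, D) {
  lambda2 <- n * D^2
  j <- seq_len(100L)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda2))
  min(1, max(0, p))
}

#' Kolmogorov-Smirnov test of run lengths against a geometric model
#'
#' Compares the empirical distribution of run lengths with the geometric
#' distribution of a [geom_model()], evaluating the sup distance on the
#' integer support.  The p-value is computed either from the classical
#' asymptotic Kolmogorov formula (the default, as produced by standard KS
#' software, which ignores the discreteness of the support) or by
#' Monte-Carlo resampling from the model: each replicate draws `n_runs`
#' lengths from the geometric and recomputes the distance.  Both treat
#' the model's continue probability as known; for a model estimated from
#' the same decision log, use [ks_fit()], whose Monte-Carlo method
#' accounts for parameter estimation and chain-boundary censoring.
#'
#' @param runs integer vector of run lengths (a multiset).
#' @param model a [geom_model()] (or anything with a `p` element).
#' @param method `"asymptotic"` or `"monte_carlo"`.
#' @param n_mc number of Monte-Carlo replicates.
#' @param seed optional integer seed for the Monte-Carlo draw.
#' @return An object of class `ks_result`: `D`, `p_value`, `method`,
#'   `n_runs`.
#' @export
ks_geometric <- function(runs, model, method = c("asymptotic", "monte_carlo"),
                         n_mc = 999L, seed = NULL) {
  method <- match.arg(method)
  runs <- as.integer(runs)
  if (length(runs) < 1L) stopf("need at least one run")
  if (any(runs < 1L)) stopf("run lengths must be positive integers")
  p <- model$p
  n <- length(runs)
  D <- ks_distance_geom(runs, p)
  p_value <- if (method == "asymptotic") {
    kolmogorov_tail(n, D)
  } else {
    draw <- function() {
      exceed <- 0L
      for (b in seq_len(n_mc)) {
        sim <- stats::rgeom(n, prob = 1 - p) + 1L
        if (ks_distance_geom(sim, p) >= D - 1e-12) exceed <- exceed + 1L
      }
      (exceed + 1L) / (n_mc + 1L)
    }
    if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  structure(list(D = D, p_value = p_value, method = method, n_runs = n),
            class = "ks_result")
}

# Simulate the runs of one two-state chain of length L by alternating
# geometric run draws (continue probabilities p_cc for C, p_dd for D),
# truncating the final run at the boundary.  Start state is C with
# probability pi_C.  Returns runs in chain order with states.
sim_chain_runs <- function(L, p_cc, p_dd, pi_C) {
  state <- stats::runif(1) < pi_C
  states <- logical(0)
  lens <- integer(0)
  total <- 0L
  # draw geometric lengths in blocks to avoid per-run rgeom calls
  blk <- function(p, m) stats::rgeom(m, prob = 1 - p) + 1L
  m <- max(8L, ceiling(L * (1 - min(p_cc, p_dd)) / 2) + 8L)
  pool_C <- blk(p_cc, m); i_C <- 0L
  pool_D <- blk(p_dd, m); i_D <- 0L
  while (total < L) {
    if (state) {
      i_C <- i_C + 1L
      if (i_C > length(pool_C)) { pool_C <- blk(p_cc, m); i_C <- 1L }
      k <- pool_C[i_C]
    } else {
      i_D <- i_D + 1L
      if (i_D > length(pool_D)) { pool_D <- blk(p_dd, m); i_D <- 1L }
      k <- pool_D[i_D]
    }
    if (total + k >= L) k <- L - total      # boundary-truncated final run
    states <- c(states, state)
    lens <- c(lens, as.integer(k))
    total <- total + k
    state <- !state
  }
  list(states = states, lens = lens)
}

# Refit the continue probability of one side from simulated chain runs,
# mirroring the estimator of the original fit.
refit_side_p <- function(model, side, chains, fallback) {
  if (model == "iid") {
    n_C <- sum(vapply(chains, function(ch) sum(ch$lens[ch$states]), 0))
    n_tot <- sum(vapply(chains, function(ch) sum(ch$lens), 0))
    p_c <- n_C / n_tot
    if (p_c <= 0 || p_c >= 1) return(fallback)
    if (side == "C_runs") p_c else 1 - p_c
  } else {
    # transition counts recovered from the run structure: within a run of
    # length k there are k - 1 self-transitions; every non-final run is
    # followed by one cross-transition
    n_CC <- n_CD <- n_DC <- n_DD <- 0
    for (ch in chains) {
      m <- length(ch$lens)
      n_CC <- n_CC + sum(ch$lens[ch$states] - 1L)
      n_DD <- n_DD + sum(ch$lens[!ch$states] - 1L)
      if (m > 1L) {
        n_CD <- n_CD + sum(ch$states[-m])
        n_DC <- n_DC + sum(!ch$states[-m])
      }
    }
    if (side == "C_runs") {
      if (n_CC + n_CD == 0) return(fallback)
      n_CC / (n_CC + n_CD)
    } else {
      if (n_DC + n_DD == 0) return(fallback)
      n_DD / (n_DC + n_DD)
    }
  }
}

#' Goodness-of-fit KS test for a fitted run-length model
#'
#' Tests whether the run lengths of one side (C or D) of a [fit_iid()] or
#' [fit_markov()] fit are compatible with the fitted geometric
#' distribution.  The asymptotic method reuses [ks_geometric()].  The
#' Monte-Carlo method is a full parametric bootstrap of the fitted
#' decision process: each replicate resimulates every chain of the
#' original lengths from the fitted process (i.i.d. Bernoulli or
#' two-state Markov, realised as alternating geometric runs truncated at
#' chain boundaries), re-applies the censoring rule, re-estimates the
#' model with the same estimator, and recomputes the sup distance -- so
#' the null distribution reflects discreteness, boundary censoring and
#' parameter estimation.
#'
#' @param fit a `geom_fit` from [fit_iid()] or [fit_markov()].
#' @param side `"C_runs"` or `"D_runs"`.
#' @param method `"asymptotic"` or `"monte_carlo"`.
#' @param n_mc number of bootstrap replicates.
#' @param seed optional integer seed.
#' @return An object of class `ks_result`.
#' @export
ks_fit <- function(fit, side = c("C_runs", "D_runs"),
                   method = c("asymptotic", "monte_carlo"),
                   n_mc = 199L, seed = NULL) {
  stopifnot(inherits(fit, "geom_fit"))
  side <- match.arg(side)
  method <- match.arg(method)
  model <- if (side == "C_runs") fit$C_runs else fit$D_runs
  runs <- if (side == "C_runs") fit$runs$lengths_C else fit$runs$lengths_D
  if (method == "asymptotic")
    return(ks_geometric(runs, model, method = "asymptotic"))
  if (length(runs) < 1L) stopf("need at least one run")
  D <- ks_distance_geom(runs, model$p)
  if (fit$model == "iid") {
    p_cc <- fit$estimates$p_C
    p_dd <- 1 - fit$estimates$p_C
    pi_C <- fit$estimates$p_C
  } else {
    p_cc <- fit$estimates$p_C_given_C
    p_cd <- fit$estimates$p_C_given_D
    p_dd <- 1 - p_cd
    pi_C <- p_cd / (1 - p_cc + p_cd)      # stationary distribution
  }
  want_C <- side == "C_runs"
  draw <- function() {
    exceed <- 0L
    for (b in seq_len(n_mc)) {
      chains <- lapply(fit$chain_lengths, sim_chain_runs,
                       p_cc = p_cc, p_dd = p_dd, pi_C = pi_C)
      p_star <- refit_side_p(fit$model, side, chains, fallback = model$p)
      sim_runs <- unlist(lapply(chains, function(ch) {
        keep <- ch$states == want_C
        if (fit$censoring == "exclude") {
          m <- length(ch$lens)
          keep <- keep & !(seq_len(m) %in% c(1L, m))
        }
        ch$lens[keep]
      }))
      if (length(sim_runs) == 0L) next
      if (ks_distance_geom(sim_runs, min(p_star, 1 - 1e-12)) >= D - 1e-12)
        exceed <- exceed + 1L
    }
    (exceed + 1L) / (n_mc + 1L)
  }
  p_value <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(D = D, p_value = p_value, method = "monte_carlo",
                 n_runs = length(runs)), class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS test vs geometric: D = %.4f, P = %.4g (%s, n = %d)\n",
              x$D, x$p_value, x$method, x$n_runs))
  invisible(x)
}

#' Run-length frequency table with a tail bucket
#'
#' @param runs integer vector of run lengths.
#' @param max_k largest individually tabulated length; longer runs are
#'   pooled into a single `"> max_k"` bucket.
#' @return A data frame with columns `k` (character: `"1"`..`"max_k"`,
#'   then `"> max_k"`) and `count`; counts sum to `length(runs)`.
#' @export
run_length_table <- function(runs, max_k = 10L) {
  runs <- as.integer(runs)
  if (any(runs < 1L)) stopf("run lengths must be positive integers")
  counts <- tabulate(runs[runs <= max_k], nbins = max_k)
  data.frame(k = c(as.character(seq_len(max_k)), paste0("> ", max_k)),
             count = c(counts, sum(runs > max_k)),
             stringsAsFactors = FALSE)
}
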