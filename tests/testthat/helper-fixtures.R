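# Fixtures built in code: hand-rolled decision logs, independent oracles.

# Wrap per-chain decision vectors ("C"/"D") into a decision_log, with the
# in-chain predecessor as the observed decision (chain-first slot observes
# nothing).  Rounds are the within-chain positions; good enough for
# statistics that do not depend on cross-chain interleaving.
make_log <- function(..., game_type = "pay_it_forward", group = 1L,
                     actor = NULL) {
  chains <- list(...)
  out <- lapply(seq_along(chains), function(ci) {
    dec <- chains[[ci]]
    n <- length(dec)
    data.frame(group = group, game_type = game_type, chain_id = ci - 1L,
               slot_index = seq_len(n) - 1L, round = seq_len(n),
               actor = if (is.null(actor)) rep(1L, n) else actor[[ci]],
               recipient = 2L,
               observed_decision = c(NA_character_, dec[-n]),
               decision = dec, svo_class = "pro_self", gender = "female",
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("decision_log", "data.frame"))
}

# Simulate a two-state Markov decision chain directly (independent of the
# package's samplers).
sim_markov_chain <- function(L, p_cc, p_cd) {
  pi_C <- p_cd / (1 - p_cc + p_cd)
  dec <- character(L)
  dec[1] <- if (stats::runif(1) < pi_C) "C" else "D"
  u <- stats::runif(L)
  for (t in seq_len(L)[-1])
    dec[t] <- if (u[t] < (if (dec[t - 1] == "C") p_cc else p_cd)) "C" else "D"
  dec
}

# Brute-force tally oracle: loop over records, count cells one by one.
brute_counts <- function(log) {
  n_CC <- n_CD <- n_DC <- n_DD <- n_C <- 0L
  for (i in seq_len(nrow(log))) {
    own <- log$decision[i]
    obs <- log$observed_decision[i]
    if (own == "C") n_C <- n_C + 1L
    if (!is.na(obs)) {
      if (obs == "C" && own == "C") n_CC <- n_CC + 1L
      if (obs == "C" && own == "D") n_CD <- n_CD + 1L
      if (obs == "D" && own == "C") n_DC <- n_DC + 1L
      if (obs == "D" && own == "D") n_DD <- n_DD + 1L
    }
  }
  list(n_CC = n_CC, n_CD = n_CD, n_DC = n_DC, n_DD = n_DD,
       n_C_total = n_C, n_decisions = nrow(log))
}

# Theil-Sen slope: median of all pairwise slopes.
theil_sen <- function(y, x = seq_along(y)) {
  ok <- !is.na(y)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  slopes <- c()
  for (i in seq_len(n - 1))
    slopes <- c(slopes, (y[(i + 1):n] - y[i]) / (x[(i + 1):n] - x[i]))
  stats::median(slopes)
}

study_schedule <- function(game_type = "pay_it_forward", seed = 1L) {
  build_schedule(group_config(19, 5, 9, game_type, seed = seed))
}
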