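#' Coefficients of the logistic decision model
#'
#' The probability that an actor cooperates is the logistic function of a
#' linear predictor built from: an intercept, the observed previous
#' decision (1 = C), the 1-based round number (raw, uncentred), their
#' interaction, an SVO indicator (1 = pro-social), a gender indicator
#' (1 = male), and the actor's random intercept.  Two extra offsets cover
#' situations the fixed effects cannot: `beta_no_info` replaces the
#' previous-decision terms when no prior decision is observable (the
#' chain-first slot), and `beta_terminal` is added when the actor is told
#' that no upstream neighbour exists (reputation-based game, last chain
#' position).
#'
#' @param beta0 intercept (log-odds).
#' @param beta_prev effect of an observed cooperation.
#' @param beta_round per-round trend.
#' @param beta_prev_round previous-decision-by-round interaction.
#' @param beta_svo effect of being pro-social (pro-self and unclassified
#'   actors score 0 on this covariate).
#' @param beta_gender effect of being male.
#' @param beta_no_info offset applied when no previous decision is shown.
#' @param beta_terminal offset applied when the actor is told no upstream
#'   neighbour exists.
#' @param intercept_sd spread of the per-participant random intercepts
#'   (used by population generation defaults; the roster carries the
#'   realised intercepts).
#' @return An object of class `behavior_params`.
#' @seealso [preset_params()] for coefficient sets read off the study's
#'   per-game regression table.
#' @export
behavior_params <- function(beta0 = 0, beta_prev = 0, beta_round = 0,
                            beta_prev_round = 0, beta_svo = 0,
                            beta_gender = 0, beta_no_info = 0,
                            beta_terminal = -2, intercept_sd = 1.5) {
  vals <- list(beta0 = beta0, beta_prev = beta_prev, beta_round = beta_round,
               beta_prev_round = beta_prev_round, beta_svo = beta_svo,
               beta_gender = beta_gender, beta_no_info = beta_no_info,
               beta_terminal = beta_terminal, intercept_sd = intercept_sd)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stopf("`%s` must be a single finite number", nm)
  }
  if (intercept_sd < 0) stopf("`intercept_sd` must be non-negative")
  structure(vals, class = "behavior_params")
}

#' @export
print.behavior_params <- function(x, ...) {
  cat("Logistic decision model (log-odds coefficients):\n")
  for (nm in setdiff(names(x), "intercept_sd"))
    cat(sprintf("  %-16s % .4f   (odds ratio %.3f)\n", nm, x[[nm]],
                exp(x[[nm]])))
  cat(sprintf("  %-16s % .4f\n", "intercept_sd", x$intercept_sd))
  invisible(x)
}

#' Preset coefficient sets from the per-game regression table
#'
#' Coefficients are the natural logs of the published per-game odds
#' ratios: for the pay-it-forward game intercept 0.200, previous decision
#' 1.290, SVO 7.510, gender 0.776, round 0.977, interaction 0.986; for
#' the reputation-based game intercept 0.482, previous decision 8.481,
#' SVO 1.290, gender 2.863, round 0.998, interaction 0.993.
#' `beta_no_info` (0), `beta_terminal` (-2) and `intercept_sd` (1.5) are
#' package defaults: the source table reports neither the chain-first
#' case, the terminal-information drop, nor the random-intercept
#' variance.
#'
#' @param name `"pif_table1"` (pay-it-forward) or `"rep_table1"`
#'   (reputation-based).
#' @return A [behavior_params()] object.
#' @examples
#' exp(preset_params("rep_table1")$beta_prev)  # 8.481
#' @export
preset_params <- function(name = c("pif_table1", "rep_table1")) {
  name <- match.arg(name)
  switch(name,
    pif_table1 = behavior_params(
      beta0 = log(0.200), beta_prev = log(1.290), beta_round = log(0.977),
      beta_prev_round = log(0.986), beta_svo = log(7.510),
      beta_gender = log(0.776)),
    rep_table1 = behavior_params(
      beta0 = log(0.482), beta_prev = log(8.481), beta_round = log(0.998),
      beta_prev_round = log(0.993), beta_svo = log(1.290),
      beta_gender = log(2.863)))
}

# Linear predictor shared by simulation and the forward computation.
# `prev` is 1, 0 or NA (no observable prior decision).
linear_predictor <- function(params, prev, round, svo_class, gender,
                             random_intercept, terminal) {
  eta <- params$beta0 + random_intercept +
    params$beta_round * round +
    params$beta_svo * as.numeric(svo_class == "pro_social") +
    params$beta_gender * as.numeric(gender == "male") +
    ifelse(terminal, params$beta_terminal, 0)
  prev_part <- ifelse(is.na(prev), params$beta_no_info,
                      prev * (params$beta_prev + params$beta_prev_round * round))
  eta + prev_part
}

#' Probability of cooperation under the logistic decision model
#'
#' @param params a [behavior_params()] object.
#' @param prev observed previous decision: `"C"`, `"D"`, `1`, `0`, or `NA`
#'   when no prior decision is observable.
#' @param round 1-based round number.
#' @param svo_class `"pro_social"`, `"pro_self"` or `"unclassified"`.
#' @param gender `"female"` or `"male"`.
#' @param random_intercept the actor's random intercept (log-odds).
#' @param terminal whether the actor is told no upstream neighbour exists.
#' @return Probability of cooperating, strictly inside (0, 1).  Vectorised
#'   over all decision-level arguments.
#' @examples
#' decision_probability(behavior_params(), prev = "C", round = 1)  # 0.5
#' @export
decision_probability <- function(params, prev, round,
                                 svo_class = "pro_self", gender = "female",
                                 random_intercept = 0, terminal = FALSE) {
  stopifnot(inherits(params, "behavior_params"))
  if (is.character(prev)) {
    bad <- !is.na(prev) & !prev %in% c("C", "D")
    if (any(bad)) stopf("`prev` must be \"C\", \"D\" or NA")
    prev <- ifelse(is.na(prev), NA_real_, as.numeric(prev == "C"))
  }
  if (any(!is.na(prev) & !prev %in% c(0, 1)))
    stopf("numeric `prev` must be 0, 1 or NA")
  if (any(round < 1)) stopf("`round` must be >= 1")
  stats::plogis(linear_predictor(params, prev, round, svo_class, gender,
                                 random_intercept, terminal))
}

#' Simulate one game on a schedule
#'
#' Walks every chain in slot order, drawing each decision from the
#' logistic model given the decision actually realised at the observed
#' slot.  Chains are conditionally independent given the participants'
#' random intercepts; the round covariate follows the schedule's
#' round-robin interleaving.
#'
#' @param schedule a `chain_schedule`.
#' @param participants a roster from [generate_population()] (or any data
#'   frame with `id`, `svo_class`, `gender`, `random_intercept`) covering
#'   every actor id in the schedule.
#' @param params a [behavior_params()] object.
#' @param seed integer seed for the decision draws.
#' @param group group identifier stored in the log.
#' @return An object of class `decision_log`: a data frame with one row
#'   per slot (`group`, `game_type`, `chain_id`, `slot_index`, `round`,
#'   `actor`, `recipient`, `observed_decision` as `"C"`/`"D"`/`NA`,
#'   `decision`, `svo_class`, `gender`).
#' @export
simulate_game <- function(schedule, participants, params, seed = 1L,
                          group = 1L) {
  stopifnot(inherits(schedule, "chain_schedule"),
            inherits(params, "behavior_params"))
  sl <- schedule$slots
  need <- c("id", "svo_class", "gender", "random_intercept")
  if (!all(need %in% names(participants)))
    stopf("`participants` must have columns: %s", paste(need, collapse = ", "))
  if (!all(sl$actor %in% participants$id))
    stopf("schedule actors missing from the roster: %s",
          paste(setdiff(unique(sl$actor), participants$id), collapse = ", "))
  pi_ <- match(sl$actor, participants$id)
  svo <- participants$svo_class[pi_]
  gender <- participants$gender[pi_]
  ri <- participants$random_intercept[pi_]

  # all covariate terms except the previous-decision part
  base_eta <- params$beta0 + ri + params$beta_round * sl$round +
    params$beta_svo * as.numeric(svo == "pro_social") +
    params$beta_gender * as.numeric(gender == "male") +
    ifelse(sl$is_terminal_info, params$beta_terminal, 0)
  prev_slope <- params$beta_prev + params$beta_prev_round * sl$round

  u <- with_seed(seed, stats::runif(nrow(sl)))
  decision <- character(nrow(sl))
  observed <- rep(NA_character_, nrow(sl))
  for (cid in unique(sl$chain_id)) {
    rows <- which(sl$chain_id == cid)
    rows <- rows[order(sl$slot_index[rows])]
    prev_dec <- NA_character_
    for (i in rows) {
      eta <- base_eta[i] +
        if (is.na(sl$observed_slot[i])) params$beta_no_info
        else as.numeric(prev_dec == "C") * prev_slope[i]
      observed[i] <- if (is.na(sl$observed_slot[i])) NA_character_ else prev_dec
      decision[i] <- if (u[i] < stats::plogis(eta)) "C" else "D"
      prev_dec <- decision[i]
    }
  }

  structure(data.frame(group = group,
                       game_type = schedule$config$game_type,
                       chain_id = sl$chain_id, slot_index = sl$slot_index,
                       round = sl$round, actor = sl$actor,
                       recipient = sl$recipient,
                       observed_decision = observed, decision = decision,
                       svo_class = svo, gender = gender,
                       stringsAsFactors = FALSE),
            class = c("decision_log", "data.frame"))
}

#' Model-implied cooperation probabilities by forward recursion
#'
#' Computes, exactly and without simulation, the aggregate cooperation
#' statistics the logistic model implies on a given schedule for a given
#' roster: a dynamic-programming pass propagates the distribution of each
#' chain's running decision state, accumulating expected counts of each
#' (observed, own) decision pair.  Serves as the deterministic oracle that
#' stochastic simulation is checked against.
#'
#' @inheritParams simulate_game
#' @return A list with `p_C`, `p_C_given_C`, `p_C_given_D` (expected-count
#'   ratios) and the expected counts `e_CC`, `e_CD`, `e_DC`, `e_DD`,
#'   `e_C_total`, `n_decisions`.
#' @export
expected_cooperation <- function(schedule, participants, params) {
  stopifnot(inherits(schedule, "chain_schedule"),
            inherits(params, "behavior_params"))
  sl <- schedule$slots
  pi_ <- match(sl$actor, participants$id)
  if (anyNA(pi_)) stopf("schedule actors missing from the roster")
  svo <- participants$svo_class[pi_]
  gender <- participants$gender[pi_]
  ri <- participants$random_intercept[pi_]
  base_eta <- params$beta0 + ri + params$beta_round * sl$round +
    params$beta_svo * as.numeric(svo == "pro_social") +
    params$beta_gender * as.numeric(gender == "male") +
    ifelse(sl$is_terminal_info, params$beta_terminal, 0)
  prev_slope <- params$beta_prev + params$beta_prev_round * sl$round

  e_CC <- e_CD <- e_DC <- e_DD <- e_C <- 0
  for (cid in unique(sl$chain_id)) {
    rows <- which(sl$chain_id == cid)
    rows <- rows[order(sl$slot_index[rows])]
    p_prev_C <- NA_real_
    for (i in rows) {
      if (is.na(sl$observed_slot[i])) {
        qc <- stats::plogis(base_eta[i] + params$beta_no_info)
        p_C_here <- qc
      } else {
        q_after_C <- stats::plogis(base_eta[i] + prev_slope[i])
        q_after_D <- stats::plogis(base_eta[i])
        e_CC <- e_CC + p_prev_C * q_after_C
        e_CD <- e_CD + p_prev_C * (1 - q_after_C)
        e_DC <- e_DC + (1 - p_prev_C) * q_after_D
        e_DD <- e_DD + (1 - p_prev_C) * (1 - q_after_D)
        p_C_here <- p_prev_C * q_after_C + (1 - p_prev_C) * q_after_D
      }
      e_C <- e_C + p_C_here
      p_prev_C <- p_C_here
    }
  }
  list(p_C = e_C / nrow(sl),
       p_C_given_C = e_CC / (e_CC + e_CD),
       p_C_given_D = e_DC / (e_DC + e_DD),
       e_CC = e_CC, e_CD = e_CD, e_DC = e_DC, e_DD = e_DD,
       e_C_total = e_C, n_decisions = nrow(sl))
}
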