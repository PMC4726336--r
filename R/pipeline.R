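#' Configuration of a full simulated experiment
#'
#' Describes the whole study: the groups (sizes; by default seven groups,
#' six of 19 and one of 17, totalling 131 participants), the number of
#' chains and per-chain decisions, the behaviour preset used for each game
#' type, the population mixes, and the analysis options.  Both game types
#' are always played by every group, in counterbalanced order.
#'
#' @param group_sizes integer vector, one entry per group.
#' @param n_chains chains per game.
#' @param decisions decisions per participant per chain, or `NULL` for the
#'   size-dependent default (9 for 19, 8 for 17).
#' @param presets named list mapping `pay_it_forward` and
#'   `reputation_based` to [preset_params()] names.
#' @param svo_mix,gender_mix,intercept_sd population settings, see
#'   [generate_population()].
#' @param shared_intercepts keep each participant's random intercept
#'   identical across the two games (`TRUE`, the default, which induces
#'   between-game correlation of individual cooperativeness) or redraw it
#'   independently per game.
#' @param censoring,ks_method,n_mc,alpha run-length analysis options, see
#'   [fit_iid()] and [ks_geometric()].
#' @param counterbalance alternate which game comes first across groups
#'   (recorded in the report; the generative model has no order effect).
#' @param seed master seed; all sub-module seeds derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(group_sizes = c(rep(19L, 6L), 17L),
                              n_chains = 5L,
                              decisions = NULL,
                              presets = list(pay_it_forward = "pif_table1",
                                             reputation_based = "rep_table1"),
                              svo_mix = c(pro_social = 80, pro_self = 35,
                                          unclassified = 16) / 131,
                              gender_mix = c(female = 0.5, male = 0.5),
                              intercept_sd = 1.5,
                              shared_intercepts = TRUE,
                              censoring = c("include", "exclude"),
                              ks_method = c("asymptotic", "monte_carlo"),
                              n_mc = 999L,
                              alpha = 0.05,
                              counterbalance = TRUE,
                              seed = 1L) {
  censoring <- match.arg(censoring)
  ks_method <- match.arg(ks_method)
  if (!all(vapply(group_sizes, is_count, logical(1))))
    stopf("`group_sizes` must be integers")
  if (!setequal(names(presets), c("pay_it_forward", "reputation_based")))
    stopf("`presets` must name both game types")
  for (p in presets) preset_params(p)  # errors on unknown preset names
  if (!is_count(seed)) stopf("`seed` must be an integer")
  structure(list(group_sizes = as.integer(group_sizes),
                 n_chains = as.integer(n_chains),
                 decisions = if (is.null(decisions)) NULL else as.integer(decisions),
                 presets = presets, svo_mix = svo_mix,
                 gender_mix = gender_mix, intercept_sd = intercept_sd,
                 shared_intercepts = isTRUE(shared_intercepts),
                 censoring = censoring, ks_method = ks_method,
                 n_mc = as.integer(n_mc), alpha = alpha,
                 counterbalance = isTRUE(counterbalance),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @return `path` (write) or an `experiment_config` (read).
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- unclass(config)
  x$svo_mix <- as.list(x$svo_mix)
  x$gender_mix <- as.list(x$gender_mix)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(experiment_config, list(
    group_sizes = unlist(x$group_sizes),
    n_chains = x$n_chains, decisions = x$decisions,
    presets = x$presets, svo_mix = unlist(x$svo_mix),
    gender_mix = unlist(x$gender_mix), intercept_sd = x$intercept_sd,
    shared_intercepts = x$shared_intercepts, censoring = x$censoring,
    ks_method = x$ks_method, n_mc = x$n_mc, alpha = x$alpha,
    counterbalance = x$counterbalance, seed = x$seed))
}

game_types <- c("pay_it_forward", "reputation_based")

#' Run a full simulated experiment and analyse it
#'
#' Executes, for every group and both game types: schedule construction,
#' population generation, decision simulation; then pools logs per game
#' and computes the aggregate cooperation summary, mean per-participant
#' reciprocity score, per-round series, i.i.d. and Markov run-length fits
#' with KS tests, and between-game correlations of per-participant
#' probabilities.  Deterministic given the master seed: every sub-seed is
#' derived from it.
#'
#' @param config an [experiment_config()].
#' @param keep_logs store the pooled decision logs in the report.
#' @return An object of class `reciprocity_report`.
#' @examples
#' \donttest{
#' rep <- run_experiment(experiment_config(group_sizes = 19L, seed = 7L))
#' print(rep)
#' }
#' @export
run_experiment <- function(config, keep_logs = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage %s failed: %s", dQuote(what), conditionMessage(e)))
  }

  logs <- stats::setNames(vector("list", 2L), game_types)
  rosters <- list()
  game_order <- character(length(config$group_sizes))
  id_offset <- 0L
  for (g in seq_along(config$group_sizes)) {
    n <- config$group_sizes[g]
    # simulation uses local ids 1..n; the pooled roster and logs carry
    # globally unique ids (offset by preceding group sizes)
    pop <- stage("population", generate_population(
      n, svo_mix = config$svo_mix, gender_mix = config$gender_mix,
      intercept_sd = config$intercept_sd,
      seed = derive_seed(seed, "pop", g)))
    roster_g <- pop
    roster_g$id <- roster_g$id + id_offset
    rosters[[g]] <- roster_g
    first <- if (config$counterbalance && g %% 2L == 0L)
      "reputation_based" else "pay_it_forward"
    game_order[g] <- first
    for (game in game_types) {
      pop_game <- pop
      if (!config$shared_intercepts && config$intercept_sd > 0) {
        pop_game$random_intercept <- with_seed(
          derive_seed(seed, "ri", g, game),
          stats::rnorm(n, 0, config$intercept_sd))
      }
      gcfg <- stage("schedule-config", group_config(
        group_size = n, n_chains = config$n_chains,
        decisions = config$decisions, game_type = game,
        seed = derive_seed(seed, "sched", g, game)))
      sched <- stage("schedule", build_schedule(gcfg))
      lg <- stage("simulation", simulate_game(
        sched, pop_game, preset_params(config$presets[[game]]),
        seed = derive_seed(seed, "sim", g, game), group = g))
      lg$actor <- lg$actor + id_offset
      lg$recipient <- lg$recipient + id_offset
      logs[[game]] <- rbind(logs[[game]], lg)
    }
    id_offset <- id_offset + n
  }

  per_game <- lapply(logs, function(lg) {
    agg <- conditional_probs(cooperation_counts(lg))
    per_part <- per_participant_summary(lg)
    fits <- lapply(c(iid = "iid", markov = "markov"), function(m) {
      fit <- stage(paste0("runlength-", m),
                   (if (m == "iid") fit_iid else fit_markov)(
                     lg, censoring = config$censoring))
      summary(fit, ks_method = config$ks_method,
              seed = derive_seed(seed, "ks", m, lg$game_type[1L]))
    })
    list(aggregate = agg, r_aggregate = r_score(agg),
         r_mean = mean(per_part$r_score, na.rm = TRUE),
         per_participant = per_part,
         per_round = per_round_series(lg),
         runlength = fits)
  })

  correlations <- stage("correlations", residual_correlation(
    per_game$pay_it_forward$per_participant,
    per_game$reputation_based$per_participant))
  r_cor <- pearson_or_na(per_game$pay_it_forward$per_participant$r_score,
                         per_game$reputation_based$per_participant$r_score)

  structure(list(config = config, game_order = game_order,
                 rosters = do.call(rbind, rosters),
                 games = per_game, correlations = correlations,
                 r_score_correlation = as.list(r_cor),
                 logs = if (keep_logs) logs else NULL),
            class = "reciprocity_report")
}

#' @export
print.reciprocity_report <- function(x, ...) {
  cat(sprintf("Simulated chained-reciprocity experiment: %d group(s) (sizes %s), seed %d\n",
              length(x$config$group_sizes),
              paste(x$config$group_sizes, collapse = ", "),
              x$config$seed))
  for (game in names(x$games)) {
    gm <- x$games[[game]]
    cat(sprintf("\n== %s (preset %s) ==\n", game, x$config$presets[[game]]))
    cat("  aggregate: "); print(gm$aggregate)
    cat(sprintf("  R (aggregate) = %.3f, R (mean over participants) = %.3f\n",
                gm$r_aggregate, gm$r_mean))
    for (m in names(gm$runlength)) {
      s <- gm$runlength[[m]]
      cat(sprintf("  %s run-length model: C p = %.3f (KS D = %.3f, P = %.3f); D p = %.3f (KS D = %.3f, P = %.3f)\n",
                  m, s$fit$C_runs$p, s$ks_C$D, s$ks_C$p_value,
                  s$fit$D_runs$p, s$ks_D$D, s$ks_D$p_value))
    }
  }
  cat("\nBetween-game correlations (per participant):\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  cat(sprintf("R-score correlation: r = %.3f (n = %d)\n",
              x$r_score_correlation$r, as.integer(x$r_score_correlation$n)))
  invisible(x)
}
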