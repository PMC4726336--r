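#' Tally cooperation counts from a decision log
#'
#' Counts the four (observed previous decision, own decision) cells
#' `n_CC`, `n_CD`, `n_DC`, `n_DD` over decisions that had an observable
#' prior, plus the overall cooperation count over all decisions.
#' Decisions with no observed prior (chain-first slots) contribute to
#' `n_C_total` and `n_decisions` but to no conditional cell.
#'
#' @param log a `decision_log`.
#' @param participant optional actor id(s) to restrict to.
#' @param rounds optional round number(s) to restrict to.
#' @param game_type optional game type to restrict to.
#' @return An object of class `coop_counts`.  An empty scope yields
#'   all-zero counts, not an error.
#' @export
cooperation_counts <- function(log, participant = NULL, rounds = NULL,
                               game_type = NULL) {
  stopifnot(is.data.frame(log))
  keep <- rep(TRUE, nrow(log))
  if (!is.null(participant)) keep <- keep & log$actor %in% participant
  if (!is.null(rounds)) keep <- keep & log$round %in% rounds
  if (!is.null(game_type)) keep <- keep & log$game_type %in% game_type
  x <- log[keep, , drop = FALSE]
  obs <- x$observed_decision
  own <- x$decision
  has_prior <- !is.na(obs)
  structure(list(
    n_CC = sum(has_prior & obs == "C" & own == "C"),
    n_CD = sum(has_prior & obs == "C" & own == "D"),
    n_DC = sum(has_prior & obs == "D" & own == "C"),
    n_DD = sum(has_prior & obs == "D" & own == "D"),
    n_C_total = sum(own == "C"),
    n_decisions = nrow(x)), class = "coop_counts")
}

#' Unconditional and conditional cooperation probabilities
#'
#' p(C) is the overall cooperation fraction; p(C|C) and p(C|D) are the
#' cooperation fractions immediately after observing a cooperation or a
#' defection.  A conditional probability whose conditioning count is zero
#' is undefined and reported as `NA`, never as 0.
#'
#' @param counts a [cooperation_counts()] result.
#' @return An object of class `coop_summary` with `p_C`, `p_C_given_C`,
#'   `p_C_given_D` and the underlying counts.
#' @export
conditional_probs <- function(counts) {
  stopifnot(inherits(counts, "coop_counts"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    p_C = ratio(counts$n_C_total, counts$n_decisions),
    p_C_given_C = ratio(counts$n_CC, counts$n_CC + counts$n_CD),
    p_C_given_D = ratio(counts$n_DC, counts$n_DC + counts$n_DD),
    counts = counts), class = "coop_summary")
}

#' @export
print.coop_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("p(C) = %s   p(C|C) = %s   p(C|D) = %s   [n = %d]\n",
              fmt(x$p_C), fmt(x$p_C_given_C), fmt(x$p_C_given_D),
              x$counts$n_decisions))
  invisible(x)
}

#' Reciprocity score
#'
#' R = p(C|C) - p(C|D): positive when cooperation tends to follow
#' observed cooperation and defection follows observed defection.
#' Undefined (`NA`) whenever either conditional probability is undefined.
#'
#' @param summary a [conditional_probs()] result.
#' @return A single number in \[-1, 1\], or `NA`.
#' @export
r_score <- function(summary) {
  stopifnot(inherits(summary, "coop_summary"))
  if (is.na(summary$p_C_given_C) || is.na(summary$p_C_given_D))
    return(NA_real_)
  summary$p_C_given_C - summary$p_C_given_D
}

#' Per-participant cooperation summaries
#'
#' @param log a `decision_log` (one game; may pool several groups).
#' @return A data frame with one row per actor: `id`, `p_C`,
#'   `p_C_given_C`, `p_C_given_D`, `r_score`, `n_decisions`.  Undefined
#'   entries are `NA`.
#' @export
per_participant_summary <- function(log) {
  ids <- sort(unique(log$actor))
  rows <- lapply(ids, function(p) {
    s <- conditional_probs(cooperation_counts(log, participant = p))
    data.frame(id = p, p_C = s$p_C, p_C_given_C = s$p_C_given_C,
               p_C_given_D = s$p_C_given_D, r_score = r_score(s),
               n_decisions = s$counts$n_decisions)
  })
  do.call(rbind, rows)
}

#' Per-round cooperation series with 95% confidence intervals
#'
#' For each round, pools the binary outcomes of all participants and
#' reports p(C), p(C|C) and p(C|D) with normal-approximation intervals
#' mean +/- 1.96 x SE (SE = sample standard deviation of the 0/1
#' outcomes over sqrt(n); no continuity correction).  p(C) includes
#' chain-first decisions made without an observed prior.  A round with an
#' empty conditioning set yields an `NA` row for that statistic.
#'
#' @param log a `decision_log`.
#' @return A long-format data frame: `round`, `statistic` (one of
#'   `"p_C"`, `"p_C_given_C"`, `"p_C_given_D"`), `value`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
per_round_series <- function(log) {
  ci_row <- function(round, statistic, x) {
    n <- length(x)
    if (n == 0L)
      return(data.frame(round = round, statistic = statistic,
                        value = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n = 0L))
    m <- mean(x)
    se <- if (n > 1L) stats::sd(x) / sqrt(n) else 0
    data.frame(round = round, statistic = statistic, value = m,
               ci_low = m - 1.96 * se, ci_high = m + 1.96 * se, n = n)
  }
  out <- lapply(sort(unique(log$round)), function(r) {
    x <- log[log$round == r, , drop = FALSE]
    own <- as.numeric(x$decision == "C")
    after_C <- !is.na(x$observed_decision) & x$observed_decision == "C"
    after_D <- !is.na(x$observed_decision) & x$observed_decision == "D"
    rbind(ci_row(r, "p_C", own),
          ci_row(r, "p_C_given_C", own[after_C]),
          ci_row(r, "p_C_given_D", own[after_D]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Pearson correlation with two-sided p, NA-safe; NA when fewer than 3
# complete pairs or either side is (numerically) constant, as happens to
# residuals of an exact linear relationship.
pearson_or_na <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L || stats::sd(x[ok]) < 1e-10 || stats::sd(y[ok]) < 1e-10)
    return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Between-game correlations of per-participant probabilities
#'
#' For each of p(C), p(C|C) and p(C|D), the Pearson correlation across
#' participants between the two games (`r_plain`).  For the two
#' conditional probabilities, additionally the correlation of residuals
#' (`r_residual`) after regressing, within each game, the conditional
#' probability on p(C) by least squares: the residual is the reciprocal
#' tendency not predicted by unconditional cooperation.  Participants
#' with undefined entries are dropped pairwise; fewer than three complete
#' pairs (or zero residual variance) yields `NA`.
#'
#' @param perparticipant_pif,perparticipant_rep per-participant tables
#'   from [per_participant_summary()] for the two games.
#' @return A data frame: `statistic`, `r_plain`, `p_plain`, `r_residual`,
#'   `p_residual`, `n`.
#' @export
residual_correlation <- function(perparticipant_pif, perparticipant_rep) {
  m <- merge(perparticipant_pif, perparticipant_rep, by = "id",
             suffixes = c("_pif", "_rep"))
  resid_or_na <- function(y, x) {
    # residuals of y ~ x on complete pairs, NA elsewhere
    out <- rep(NA_real_, length(y))
    ok <- stats::complete.cases(x, y)
    if (sum(ok) >= 3L && stats::sd(x[ok]) > 1e-10)
      out[ok] <- stats::residuals(stats::lm(y[ok] ~ x[ok]))
    out
  }
  rows <- lapply(c("p_C", "p_C_given_C", "p_C_given_D"), function(stat) {
    a <- m[[paste0(stat, "_pif")]]
    b <- m[[paste0(stat, "_rep")]]
    plain <- pearson_or_na(a, b)
    if (stat == "p_C") {
      res <- c(r = NA_real_, p = NA_real_, n = NA_integer_)
    } else {
      ra <- resid_or_na(a, m$p_C_pif)
      rb <- resid_or_na(b, m$p_C_rep)
      res <- pearson_or_na(ra, rb)
    }
    data.frame(statistic = stat, r_plain = plain[["r"]], p_plain = plain[["p"]],
               r_residual = res[["r"]], p_residual = res[["p"]],
               n = plain[["n"]])
  })
  do.call(rbind, rows)
}
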