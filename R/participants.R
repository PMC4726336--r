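#' Classify social value orientation by the triple-dominance rule
#'
#' A respondent answers nine allocation items, each time choosing the
#' pro-social, individualistic or competitive option (or leaving the item
#' unanswered).  Respondents choosing at least six consistent options are
#' classified; individualists and competitors are pooled into a single
#' pro-self class.  Everyone else -- inconsistent choosers and
#' non-responders alike -- is unclassified.
#'
#' @param choices character vector of exactly nine items, each one of
#'   `"pro_social"`, `"individualistic"`, `"competitive"`, `"missing"`.
#' @return `"pro_social"`, `"pro_self"` or `"unclassified"`.
#' @examples
#' classify_svo(rep("pro_social", 9))
#' classify_svo(c(rep("individualistic", 6), rep("pro_social", 3)))
#' @export
classify_svo <- function(choices) {
  allowed <- c("pro_social", "individualistic", "competitive", "missing")
  if (length(choices) != 9L)
    stopf("`choices` must contain exactly nine items, got %d", length(choices))
  if (!all(choices %in% allowed))
    stopf("unknown choice value(s): %s",
          paste(unique(setdiff(choices, allowed)), collapse = ", "))
  k <- table(factor(choices, levels = allowed))
  if (k[["pro_social"]] >= 6L) return("pro_social")
  if (k[["individualistic"]] >= 6L || k[["competitive"]] >= 6L) return("pro_self")
  "unclassified"
}

#' Generate a synthetic participant population
#'
#' Draws SVO classes and genders from the given mixes and per-participant
#' random intercepts from a zero-mean normal distribution (the random
#' effect of the logistic behaviour model).  The default SVO mix matches
#' the study composition 80 pro-social / 35 pro-self / 16 unclassified out
#' of 131.
#'
#' @param n number of participants.
#' @param svo_mix named proportions for `pro_social`, `pro_self`,
#'   `unclassified`; must sum to 1.
#' @param gender_mix named proportions for `female`, `male`; must sum to 1.
#' @param intercept_sd standard deviation (log-odds units) of the random
#'   intercepts.
#' @param seed integer seed.
#' @return A data frame of class `participant_roster` with columns `id`,
#'   `svo_class`, `gender`, `random_intercept`.
#' @export
generate_population <- function(n,
                                svo_mix = c(pro_social = 80, pro_self = 35,
                                            unclassified = 16) / 131,
                                gender_mix = c(female = 0.5, male = 0.5),
                                intercept_sd = 1.5,
                                seed = 1L) {
  if (!is_count(n) || n < 1) stopf("`n` must be a positive integer")
  check_mix <- function(mix, levels, what) {
    if (is.null(names(mix)) || !setequal(names(mix), levels))
      stopf("`%s` must be named with exactly: %s", what,
            paste(levels, collapse = ", "))
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
      stopf("`%s` must be non-negative proportions summing to 1", what)
    mix[levels]
  }
  svo_mix <- check_mix(svo_mix, c("pro_social", "pro_self", "unclassified"),
                       "svo_mix")
  gender_mix <- check_mix(gender_mix, c("female", "male"), "gender_mix")
  if (!is.numeric(intercept_sd) || intercept_sd < 0)
    stopf("`intercept_sd` must be a non-negative number")

  with_seed(seed, {
    svo <- sample(names(svo_mix), n, replace = TRUE, prob = svo_mix)
    gender <- sample(names(gender_mix), n, replace = TRUE, prob = gender_mix)
    ri <- if (intercept_sd == 0) rep(0, n) else stats::rnorm(n, 0, intercept_sd)
    structure(data.frame(id = seq_len(n), svo_class = svo, gender = gender,
                         random_intercept = ri, stringsAsFactors = FALSE),
              class = c("participant_roster", "data.frame"))
  })
}
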