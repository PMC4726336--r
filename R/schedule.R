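#' Configuration of one group's chained game
#'
#' Describes a single group playing one game type: how many participants,
#' how many simultaneously running chains, and how many decisions each
#' participant makes per chain.  At the reference scale (19 participants,
#' 5 chains, 9 decisions per chain) every participant makes 45 decisions
#' ("rounds") in the game.
#'
#' @param group_size number of participants (reference values 17 or 19).
#' @param n_chains number of simultaneously running chains (reference 5).
#' @param decisions decisions per participant per chain.  Defaults to 9
#'   for 19-participant groups and 8 for 17-participant groups; must be
#'   supplied explicitly for other sizes.
#' @param game_type `"pay_it_forward"` or `"reputation_based"`.
#' @param seed integer seed controlling the random chain layout.
#'
#' @return An object of class `group_config`.
#' @seealso [build_schedule()]
#' @export
group_config <- function(group_size = 19L,
                         n_chains = 5L,
                         decisions = NULL,
                         game_type = c("pay_it_forward", "reputation_based"),
                         seed = 1L) {
  game_type <- match.arg(game_type)
  if (!is_count(group_size) || group_size < 3)
    stopf("`group_size` must be an integer >= 3, got %s", format(group_size))
  if (!is_count(n_chains) || n_chains < 1)
    stopf("`n_chains` must be a positive integer")
  if (is.null(decisions)) {
    decisions <- switch(as.character(group_size), "19" = 9L, "17" = 8L,
                        stopf("no default `decisions` for group_size %d; supply one",
                              group_size))
  }
  if (!is_count(decisions) || decisions < 1)
    stopf("`decisions` must be a positive integer")
  if (decisions > group_size - 2)
    stopf("infeasible config: decisions per chain (%d) exceeds group_size - 2 (%d); the no-repeat pairing constraint cannot be satisfied",
          decisions, group_size - 2L)
  if (!is_count(seed)) stopf("`seed` must be an integer")
  structure(
    list(group_size = as.integer(group_size),
         n_chains = as.integer(n_chains),
         decisions = as.integer(decisions),
         game_type = game_type,
         seed = as.integer(seed)),
    class = "group_config")
}

#' @export
print.group_config <- function(x, ...) {
  cat(sprintf("Group config: %d participants, %d chain(s), %d decision(s)/participant/chain\n",
              x$group_size, x$n_chains, x$decisions))
  cat(sprintf("  game type: %s, seed: %d, rounds per participant: %d\n",
              x$game_type, x$seed, x$n_chains * x$decisions))
  invisible(x)
}

# Lay out one chain: `decisions` cyclic passes over a random permutation of
# the group, each pass stepping through the permutation with a distinct
# offset coprime to the group size.  Consecutive slots are always separated
# by the current pass's offset (including across pass boundaries), so every
# ordered (actor, next-actor) pair carries a pass-specific offset and can
# never repeat within the chain.  One extra offset is reserved for the
# phantom neighbour off either end of the chain (the final recipient in the
# pay-it-forward game, the initial recipient in the reputation-based game),
# which is why `decisions + 1` distinct offsets are required -- matching the
# feasibility bound decisions <= group_size - 2 for prime group sizes.
chain_actor_indices <- function(n, decisions) {
  units <- which(vapply(seq_len(n - 1), function(s) gcd(s, n) == 1L, logical(1)))
  if (length(units) < decisions + 1L)
    stopf("infeasible config: need %d distinct cyclic offsets coprime to %d, only %d exist",
          decisions + 1L, n, length(units))
  steps <- sample(units, decisions + 1L)
  extra <- steps[decisions + 1L]
  steps <- steps[seq_len(decisions)]
  total <- n * decisions
  pass <- rep(seq_len(decisions), each = n)
  inc <- steps[pass]
  start <- sample.int(n, 1L) - 1L
  idx <- (start + cumsum(c(0L, inc[-total]))) %% n
  list(idx = idx, extra = extra, start = start,
       last = idx[total], steps = steps)
}

#' Build a chained-game schedule
#'
#' Allocates chain positions so that no ordered donor-recipient pair occurs
#' twice within a chain (the constraint that excludes direct reciprocity),
#' wires up the information flow for the requested game type, and numbers
#' each actor's rounds across chains in round-robin arrival order.
#'
#' In the pay-it-forward game the actor at slot `t` is shown the decision
#' made at slot `t - 1`, which was directed at them, and gives to the actor
#' of slot `t + 1`.  In the reputation-based game the actor is shown the
#' decision the slot-`t - 1` actor made toward a third party, and gives to
#' that observed actor; the actor in the last position of each chain is
#' additionally flagged `is_terminal_info` (told that no upstream neighbour
#' exists).
#'
#' @param config a [group_config()].
#' @return An object of class `chain_schedule`: a list with elements
#'   `config` and `slots`, the latter a data frame with one row per
#'   decision slot (`chain_id`, `slot_index` both 0-based, `actor`,
#'   `recipient`, `observed_actor`, `observed_slot`, `is_terminal_info`,
#'   `round` 1-based).
#' @examples
#' sched <- build_schedule(group_config(19, 5, 9, "pay_it_forward", seed = 42))
#' max(sched$slots$round)  # 45
#' @export
build_schedule <- function(config) {
  stopifnot(inherits(config, "group_config"))
  n <- config$group_size
  d <- config$decisions
  rep_game <- config$game_type == "reputation_based"
  total <- n * d

  slots <- with_seed(config$seed, {
    chains <- lapply(seq_len(config$n_chains) - 1L, function(cid) {
      perm <- sample.int(n)           # participant ids in permutation order
      lay <- chain_actor_indices(n, d)
      actor <- perm[lay$idx + 1L]
      t_idx <- seq_len(total) - 1L
      if (!rep_game) {
        recipient <- c(actor[-1L], perm[((lay$last + lay$extra) %% n) + 1L])
        observed_actor <- c(NA_integer_, actor[-total])
        observed_slot <- c(NA_integer_, t_idx[-total])
        terminal <- rep(FALSE, total)
      } else {
        recipient <- c(perm[((lay$idx[1L] - lay$extra) %% n) + 1L], actor[-total])
        observed_actor <- c(NA_integer_, actor[-total])
        observed_slot <- c(NA_integer_, t_idx[-total])
        terminal <- c(rep(FALSE, total - 1L), TRUE)
      }
      data.frame(chain_id = cid, slot_index = t_idx, actor = actor,
                 recipient = recipient, observed_actor = observed_actor,
                 observed_slot = observed_slot, is_terminal_info = terminal)
    })
    do.call(rbind, chains)
  })

  # round-robin interleaving: chains advance in lockstep, so global arrival
  # order is (slot_index, chain_id)
  ord <- order(slots$slot_index, slots$chain_id)
  rounds <- integer(nrow(slots))
  rounds[ord] <- stats::ave(rep(1L, nrow(slots)), slots$actor[ord],
                            FUN = cumsum)
  slots$round <- rounds

  structure(list(config = config, slots = slots), class = "chain_schedule")
}

#' @export
print.chain_schedule <- function(x, ...) {
  cat(sprintf("Chain schedule (%s): %d slots in %d chain(s), %d participants\n",
              x$config$game_type, nrow(x$slots), x$config$n_chains,
              x$config$group_size))
  cat(sprintf("  rounds per participant: %d\n", max(x$slots$round)))
  invisible(x)
}

#' Validate a chain schedule against the protocol invariants
#'
#' Checks every rule the schedule constructor promises: actor counts per
#' chain, no repeated ordered donor-recipient pair within a chain, no
#' self-donation, correct information flow for the game type, no observed
#' decision at chain-first slots, observation preceding action, and
#' consistent round numbering.  Validation never throws; defects are
#' returned as rows.
#'
#' @param schedule a `chain_schedule`.
#' @return A data frame with columns `rule`, `chain_id`, `slot_index`,
#'   `message`; zero rows when the schedule is valid.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "chain_schedule"))
  cfg <- schedule$config
  sl <- schedule$slots
  viol <- list()
  add <- function(rule, chain_id, slot_index, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      rule = rule, chain_id = chain_id, slot_index = slot_index,
      message = message, stringsAsFactors = FALSE)
  }

  for (cid in unique(sl$chain_id)) {
    ch <- sl[sl$chain_id == cid, ]
    ch <- ch[order(ch$slot_index), ]

    cnt <- table(factor(ch$actor, levels = seq_len(cfg$group_size)))
    bad <- which(cnt != cfg$decisions)
    for (p in bad)
      add("actor-count", cid, NA_integer_,
          sprintf("participant %d acts %d times in chain %d (expected %d)",
                  p, cnt[p], cid, cfg$decisions))

    pair <- paste(ch$actor, ch$recipient)
    dup <- which(duplicated(pair))
    for (i in dup)
      add("repeat-pair", cid, ch$slot_index[i],
          sprintf("ordered pair (%d -> %d) occurs more than once in chain %d",
                  ch$actor[i], ch$recipient[i], cid))

    self <- which(ch$actor == ch$recipient)
    for (i in self)
      add("self-recipient", cid, ch$slot_index[i],
          sprintf("participant %d is its own recipient", ch$actor[i]))

    if (!is.na(ch$observed_actor[1L]) || !is.na(ch$observed_slot[1L]))
      add("first-slot-info", cid, ch$slot_index[1L],
          "first slot of a chain must observe nothing")

    later <- ch[-1L, , drop = FALSE]
    for (i in seq_len(nrow(later))) {
      r <- later[i, ]
      if (is.na(r$observed_slot) || is.na(r$observed_actor)) {
        add("info-flow", cid, r$slot_index, "missing observation after first slot")
        next
      }
      if (r$observed_slot >= r$slot_index)
        add("info-order", cid, r$slot_index,
            "observed slot does not precede the acting slot")
      src <- ch[ch$slot_index == r$observed_slot, ]
      if (nrow(src) != 1L || src$actor != r$observed_actor) {
        add("info-flow", cid, r$slot_index,
            "observed actor does not match the actor of the observed slot")
        next
      }
      if (cfg$game_type == "pay_it_forward") {
        if (src$recipient != r$actor)
          add("info-flow", cid, r$slot_index,
              "pay-it-forward: observed decision was not directed at the actor")
      } else {
        if (r$recipient != r$observed_actor)
          add("info-flow", cid, r$slot_index,
              "reputation-based: actor must give to the observed actor")
      }
    }
  }

  ord <- order(sl$slot_index, sl$chain_id)
  expected <- integer(nrow(sl))
  expected[ord] <- stats::ave(rep(1L, nrow(sl)), sl$actor[ord], FUN = cumsum)
  bad <- which(expected != sl$round)
  for (i in bad)
    add("round-numbering", sl$chain_id[i], sl$slot_index[i],
        sprintf("round %d recorded where arrival order implies %d",
                sl$round[i], expected[i]))

  if (length(viol) == 0L)
    return(data.frame(rule = character(), chain_id = integer(),
                      slot_index = integer(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, viol)
}

#' Assign per-decision three-letter pseudonyms
#'
#' Every participant is displayed under a fresh three-letter name for each
#' decision, with names never reused within a chain and disjoint across
#' chains for the same participant (all names are in fact globally
#' distinct, which implies both rules; the 26^3 alphabet leaves ample
#' headroom at study scale).
#'
#' @param schedule a `chain_schedule`.
#' @param seed integer seed.
#' @return An object of class `pseudonym_map`: a data frame with one row
#'   per slot (`chain_id`, `slot_index`, `actor`, `label`).
#' @export
assign_pseudonyms <- function(schedule, seed = schedule$config$seed) {
  stopifnot(inherits(schedule, "chain_schedule"))
  sl <- schedule$slots
  n_needed <- nrow(sl)
  if (n_needed > 26^3)
    stopf("cannot assign %d distinct three-letter labels (alphabet 26^3)", n_needed)
  codes <- with_seed(seed, sample.int(26^3, n_needed) - 1L)
  label <- paste0(LETTERS[codes %/% 676L + 1L],
                  LETTERS[(codes %/% 26L) %% 26L + 1L],
                  LETTERS[codes %% 26L + 1L])
  structure(data.frame(chain_id = sl$chain_id, slot_index = sl$slot_index,
                       actor = sl$actor, label = label,
                       stringsAsFactors = FALSE),
            class = c("pseudonym_map", "data.frame"))
}
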