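# Delimited-text I/O for decision logs, schedules and rosters.
# Comma-separated, UTF-8, one header row; missing observations are written
# as the literal token "none" so files round-trip without NA ambiguity.

log_columns <- c("group", "game_type", "chain_id", "slot_index", "round",
                 "actor", "recipient", "observed_decision", "decision",
                 "svo_class", "gender")

#' Write a decision log to a CSV file
#'
#' @param log a `decision_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_decision_log()]
#' @export
write_decision_log <- function(log, path) {
  stopifnot(is.data.frame(log), all(log_columns %in% names(log)))
  out <- log[, log_columns]
  out$observed_decision[is.na(out$observed_decision)] <- "none"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a decision log from a CSV file
#'
#' Validates the header against the documented column schema and every
#' decision symbol; malformed rows are reported with their line number.
#'
#' @param path file written by [write_decision_log()] (or any file with
#'   the same schema).
#' @return A `decision_log` data frame.
#' @export
read_decision_log <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, log_columns))
    stopf("header mismatch: expected columns %s",
          paste(log_columns, collapse = ", "))
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(
                         group = "character", game_type = "character",
                         chain_id = "integer", slot_index = "integer",
                         round = "integer", actor = "integer",
                         recipient = "integer",
                         observed_decision = "character",
                         decision = "character", svo_class = "character",
                         gender = "character")[log_columns])
  if (!identical(names(x), log_columns))
    stopf("header mismatch: expected columns %s",
          paste(log_columns, collapse = ", "))
  # data line i lives on file line i + 1 (header)
  bad <- which(!x$decision %in% c("C", "D"))
  if (length(bad))
    stopf("line %d: unknown decision symbol %s", bad[1L] + 1L,
          dQuote(x$decision[bad[1L]]))
  bad <- which(!x$observed_decision %in% c("C", "D", "none"))
  if (length(bad))
    stopf("line %d: unknown observed decision symbol %s", bad[1L] + 1L,
          dQuote(x$observed_decision[bad[1L]]))
  x$observed_decision[x$observed_decision == "none"] <- NA_character_
  # numeric-looking group ids come back as numbers
  g <- suppressWarnings(as.integer(x$group))
  if (!anyNA(g)) x$group <- g
  structure(x, class = c("decision_log", "data.frame"))
}

#' Write / read a chain schedule as CSV
#'
#' One row per slot; the group configuration travels in a `#`-prefixed
#' comment line so a schedule file is self-describing.
#'
#' @param schedule a `chain_schedule`.
#' @param path file path.
#' @return `path` (write) or a `chain_schedule` (read).
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "chain_schedule"))
  cfg <- schedule$config
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# group_size=%d n_chains=%d decisions=%d game_type=%s seed=%d",
                     cfg$group_size, cfg$n_chains, cfg$decisions,
                     cfg$game_type, cfg$seed), con)
  utils::write.csv(schedule$slots, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# "))
    stopf("schedule file lacks the configuration comment line")
  kv <- strsplit(strsplit(sub("^# ", "", header), " ")[[1]], "=")
  cfgv <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  slots <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  slots$is_terminal_info <- as.logical(slots$is_terminal_info)
  cfg <- group_config(group_size = as.integer(cfgv[["group_size"]]),
                      n_chains = as.integer(cfgv[["n_chains"]]),
                      decisions = as.integer(cfgv[["decisions"]]),
                      game_type = cfgv[["game_type"]],
                      seed = as.integer(cfgv[["seed"]]))
  structure(list(config = cfg, slots = slots), class = "chain_schedule")
}

#' Write / read a participant roster as CSV
#'
#' @param roster a `participant_roster` data frame.
#' @param path file path.
#' @return `path` (write) or a `participant_roster` (read).
#' @export
write_roster <- function(roster, path) {
  stopifnot(is.data.frame(roster))
  utils::write.csv(roster, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "svo_class", "gender", "random_intercept")
  if (!all(need %in% names(x)))
    stopf("roster must have columns: %s", paste(need, collapse = ", "))
  structure(x, class = c("participant_roster", "data.frame"))
}
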