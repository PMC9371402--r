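#' Session configuration for an adaptive administration
#'
#' @param bank A `tol_item_bank`.
#' @param pass_threshold Successes (out of 3) needed to pass a level.
#' @param start_level_after_perfect_assessment Testing entry level when all
#'   four assessment items are solved.
#' @param consecutive_level_failures_to_stop Consecutive failed levels that
#'   interrupt the test.
#' @param early_stop_within_level Stop administering a level's items once the
#'   2-of-3 outcome is decided (default `TRUE`); `FALSE` always gives all 3.
#' @return An object of class `tol_session_config`.
#' @export
session_config <- function(bank,
                           pass_threshold = 2L,
                           start_level_after_perfect_assessment = 7L,
                           consecutive_level_failures_to_stop = 2L,
                           early_stop_within_level = TRUE) {
  stopifnot(inherits(bank, "tol_item_bank"),
            pass_threshold >= 1L, pass_threshold <= 3L,
            start_level_after_perfect_assessment >= 1L,
            start_level_after_perfect_assessment <= 10L,
            consecutive_level_failures_to_stop >= 1L)
  structure(list(
    bank = bank,
    pass_threshold = as.integer(pass_threshold),
    start_level_after_perfect_assessment =
      as.integer(start_level_after_perfect_assessment),
    consecutive_level_failures_to_stop =
      as.integer(consecutive_level_failures_to_stop),
    early_stop_within_level = isTRUE(early_stop_within_level)),
    class = "tol_session_config")
}

#' Build an item event stream
#'
#' Events are logged in milliseconds from item start: a disc is grabbed,
#' dropped on a peg, and finally the "Done" button is pressed.
#'
#' @param t_ms Non-decreasing integer times.
#' @param kind `"grab"`, `"drop"` or `"done"`.
#' @param disc Disc label for grab/drop events, `NA` for done.
#' @param peg 1-based destination peg for drop events, `NA` otherwise.
#' @return A data frame of class `tol_events`.
#' @export
item_events <- function(t_ms, kind, disc = NA_character_, peg = NA_integer_) {
  ev <- data.frame(t_ms = as.integer(t_ms), kind = as.character(kind),
                   disc = as.character(disc), peg = as.integer(peg),
                   stringsAsFactors = FALSE)
  class(ev) <- c("tol_events", "data.frame")
  ev
}

#' Event stream replaying a move path
#'
#' Converts a `from`/`to` move table (as returned by [bfs_solve()]) into a
#' grab/drop/done event stream on a simulated clock.
#'
#' @param item A `tol_item`; moves replay from its start state.
#' @param path Data frame with `from` and `to` peg columns.
#' @param per_move_latency_ms Simulated milliseconds between consecutive
#'   events.
#' @return A `tol_events` data frame ending with a done event.
#' @export
events_from_path <- function(item, path, per_move_latency_ms = 1500) {
  spec <- variant_spec(item$variant)
  state <- item$start
  t <- 0L
  rows <- list()
  for (r in seq_len(NROW(path))) {
    from <- path$from[r]; to <- path$to[r]
    disc <- state[[from]][length(state[[from]])]
    t <- t + as.integer(per_move_latency_ms)
    rows[[length(rows) + 1L]] <- item_events(t, "grab", disc)
    t <- t + as.integer(per_move_latency_ms)
    rows[[length(rows) + 1L]] <- item_events(t, "drop", disc, to)
    state <- apply_move(state, from, to, spec)
  }
  t <- t + as.integer(per_move_latency_ms)
  rows[[length(rows) + 1L]] <- item_events(t, "done")
  do.call(rbind, rows)
}

#' Score one item from its event stream
#'
#' Replays the grab/drop/done log against the item's start configuration.
#' A move is a completed grab-then-drop transfer between two distinct pegs
#' (dropping a disc back where it was grabbed costs nothing). The answer is
#' wrong if the final layout differs from the goal, if the done press comes
#' after the time limit, or if more than the allowed number of moves were
#' used; flags accumulate and are never cleared, and the whole stream is
#' always replayed. Success requires an empty flag set.
#'
#' @param item A `tol_item`.
#' @param events A `tol_events` data frame ending with a done event.
#' @param config Unused except for validation hooks; may be `NULL`.
#' @return A list of class `tol_item_result` with `item_id`, `level`,
#'   `success`, `moves_used`, `duration_ms` and `flags` (character vector,
#'   subset of `wrong_layout`, `time_exceeded`, `moves_exceeded`).
#' @export
score_item <- function(item, events, config = NULL) {
  stopifnot(inherits(item, "tol_item"))
  ev <- as.data.frame(events)
  if (nrow(ev) == 0L) stop("empty event stream")
  if (is.unsorted(ev$t_ms)) stop("event times must be non-decreasing")
  if (ev$kind[nrow(ev)] != "done" || sum(ev$kind == "done") != 1L)
    stop("event stream must end with exactly one done event")
  spec <- variant_spec(item$variant)
  state <- item$start
  held <- NULL; held_from <- NA_integer_
  moves_used <- 0L
  for (r in seq_len(nrow(ev))) {
    kind <- ev$kind[r]
    if (kind == "grab") {
      if (!is.null(held)) stop("grab while already holding a disc (row ", r, ")")
      disc <- ev$disc[r]
      src <- NA_integer_
      for (p in seq_along(state)) {
        n <- length(state[[p]])
        if (n > 0L && state[[p]][n] == disc) { src <- p; break }
      }
      if (is.na(src)) stop("grab of disc '", disc, "' which is not a top disc")
      state[[src]] <- state[[src]][-length(state[[src]])]
      held <- disc; held_from <- src
    } else if (kind == "drop") {
      if (is.null(held)) stop("drop without a preceding grab (row ", r, ")")
      if (ev$disc[r] != held) stop("drop of a disc that is not being held")
      peg <- ev$peg[r]
      if (is.na(peg) || peg < 1L || peg > spec$n_pegs)
        stop("drop on invalid peg index")
      if (length(state[[peg]]) >= spec$capacities[peg])
        stop("drop on full peg ", peg)
      state[[peg]] <- c(state[[peg]], held)
      if (peg != held_from) moves_used <- moves_used + 1L
      held <- NULL; held_from <- NA_integer_
    } else if (kind == "done") {
      if (!is.null(held)) stop("done pressed while holding a disc")
    } else stop("unknown event kind: ", kind)
  }
  duration_ms <- ev$t_ms[nrow(ev)]
  flags <- character()
  if (!states_equal(state, item$goal)) flags <- c(flags, "wrong_layout")
  if (duration_ms > item$max_time_s * 1000) flags <- c(flags, "time_exceeded")
  if (moves_used > item$max_moves) flags <- c(flags, "moves_exceeded")
  structure(list(item_id = item$item_id, level = item$level,
                 variant = item$variant, success = length(flags) == 0L,
                 moves_used = moves_used,
                 duration_ms = as.integer(duration_ms), flags = flags),
            class = "tol_item_result")
}

#' @export
print.tol_item_result <- function(x, ...) {
  cat(sprintf("<tol_item_result %s> %s, %d moves, %d ms%s\n", x$item_id,
              if (x$success) "success" else "failure", x$moves_used,
              x$duration_ms,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

ask_responder <- function(responder, item, feedback_allowed = FALSE) {
  responder(item, feedback_allowed)
}

give_feedback <- function(responder, item, result) {
  fb <- attr(responder, "feedback")
  if (is.function(fb)) fb(item, result)
  invisible(NULL)
}

#' Run the familiarization phase
#'
#' The two practice items are administered with corrective feedback; nothing
#' here is measured or contributes to scoring, and the session proceeds to
#' assessment regardless of the outcomes.
#'
#' @param responder A responder function, see [run_session()].
#' @param config A [session_config()].
#' @return List with `results` (unscored `tol_item_result`s) and
#'   `comprehension` (logical vector: did each practice item succeed).
#' @export
run_familiarization <- function(responder, config) {
  results <- list()
  for (item in config$bank$familiarization) {
    res <- score_item(item, ask_responder(responder, item, TRUE), config)
    give_feedback(responder, item, res)
    results[[length(results) + 1L]] <- res
  }
  list(results = results,
       comprehension = vapply(results, `[[`, TRUE, "success"))
}

#' Run the assessment phase
#'
#' The four assessment items are administered in increasing difficulty until
#' the first failure. Solving all four starts the testing phase at level 7;
#' otherwise testing starts at the level before the unsolved item's level
#' (floored at 1).
#'
#' @inheritParams run_familiarization
#' @return List with `results` and `start_level`.
#' @export
run_assessment <- function(responder, config) {
  results <- list()
  start_level <- config$start_level_after_perfect_assessment
  for (item in config$bank$assessment) {
    res <- score_item(item, ask_responder(responder, item, FALSE), config)
    results[[length(results) + 1L]] <- res
    if (!res$success) {
      start_level <- max(1L, item$level - 1L)
      break
    }
  }
  list(results = results, start_level = as.integer(start_level))
}

#' Run the adaptive testing phase
#'
#' At each administered level up to three items are given; the level is
#' passed with two successes and failed with two failures (early stop once
#' decided, unless disabled). Passing moves to the next higher
#' unadministered level, failing to the next lower level. The phase ends
#' when two consecutive levels are failed, when level 10 is passed, or when
#' the demotion/promotion target has already been administered or lies below
#' level 1 (the ability is then bracketed). Each level is administered at
#' most once.
#'
#' @inheritParams run_familiarization
#' @param start_level Entry level 1..10 (from [run_assessment()]).
#' @return List with `levels` (per-level results and pass flag, in
#'   administration order), `levels_administered`, `levels_passed`,
#'   `final_score` (highest passed level, 0 if none) and
#'   `termination_reason`.
#' @export
run_testing <- function(responder, start_level, config) {
  start_level <- as.integer(start_level)
  stopifnot(start_level >= 1L, start_level <= 10L)
  bank <- config$bank
  administered <- integer()
  passed <- integer()
  per_level <- list()
  consec_fail <- 0L
  reason <- NULL
  level <- start_level
  while (is.null(reason)) {
    items <- testing_items(bank, level)
    succ <- 0L; fail <- 0L
    results <- list()
    for (item in items) {
      res <- score_item(item, ask_responder(responder, item, FALSE), config)
      results[[length(results) + 1L]] <- res
      if (res$success) succ <- succ + 1L else fail <- fail + 1L
      if (config$early_stop_within_level &&
          (succ >= config$pass_threshold ||
           fail > length(items) - config$pass_threshold)) break
    }
    level_passed <- succ >= config$pass_threshold
    administered <- c(administered, level)
    per_level[[length(per_level) + 1L]] <-
      list(level = level, results = results, passed = level_passed)
    if (level_passed) {
      passed <- c(passed, level)
      consec_fail <- 0L
      if (level == 10L) { reason <- "ceiling_passed"; break }
      higher <- setdiff((level + 1L):10L, administered)
      if (!length(higher)) { reason <- "bracketed"; break }
      level <- min(higher)
    } else {
      consec_fail <- consec_fail + 1L
      if (consec_fail >= config$consecutive_level_failures_to_stop) {
        reason <- "two_consecutive_failures"; break
      }
      target <- level - 1L
      if (target < 1L || target %in% administered) { reason <- "bracketed"; break }
      level <- target
    }
  }
  list(levels = per_level,
       levels_administered = administered,
       levels_passed = passed,
       final_score = if (length(passed)) max(passed) else 0L,
       termination_reason = reason)
}

#' Run a complete three-phase adaptive session
#'
#' Familiarization (two practice items with feedback, unscored), assessment
#' (up to four items fixing the testing entry level), then adaptive testing.
#'
#' A responder is a function `function(item, feedback_allowed)` returning a
#' `tol_events` stream for the presented item; an optional
#' `attr(responder, "feedback")` function receives `(item, result)` after
#' each familiarization item.
#'
#' @param responder Responder function.
#' @param config A [session_config()].
#' @param participant_id Identifier stored in the record.
#' @return An object of class `tol_session`.
#' @export
run_session <- function(responder, config, participant_id = "sim") {
  fam <- run_familiarization(responder, config)
  ass <- run_assessment(responder, config)
  tst <- run_testing(responder, ass$start_level, config)
  structure(list(
    schema_version = 1L,
    participant_id = participant_id,
    familiarization = fam,
    assessment = ass,
    testing = tst,
    levels_administered = tst$levels_administered,
    levels_passed = tst$levels_passed,
    final_score = tst$final_score,
    termination_reason = tst$termination_reason),
    class = "tol_session")
}

#' @export
print.tol_session <- function(x, ...) {
  cat(sprintf("<tol_session %s> start level %d, final score %d (%s)\n",
              x$participant_id, x$assessment$start_level, x$final_score,
              x$termination_reason))
  cat(" levels administered:",
      paste(x$levels_administered, collapse = " "), "\n")
  invisible(x)
}

result_to_row <- function(res, phase) {
  data.frame(phase = phase, item_id = res$item_id, level = res$level,
             variant = res$variant, success = res$success,
             moves_used = res$moves_used, duration_ms = res$duration_ms,
             flags = paste(res$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Flatten a session to one row per administered item
#'
#' @param record A `tol_session`.
#' @return Data frame with columns `phase`, `item_id`, `level`, `variant`,
#'   `success`, `moves_used`, `duration_ms`, `flags` (semicolon-joined).
#' @export
session_rows <- function(record) {
  rows <- list()
  for (res in record$familiarization$results)
    rows[[length(rows) + 1L]] <- result_to_row(res, "familiarization")
  for (res in record$assessment$results)
    rows[[length(rows) + 1L]] <- result_to_row(res, "assessment")
  for (lv in record$testing$levels)
    for (res in lv$results)
      rows[[length(rows) + 1L]] <- result_to_row(res, "testing")
  do.call(rbind, rows)
}

result_to_list <- function(res) {
  list(item_id = res$item_id, level = res$level, variant = res$variant,
       success = res$success, moves_used = res$moves_used,
       duration_ms = res$duration_ms, flags = I(as.list(res$flags)))
}

result_from_list <- function(x) {
  structure(list(item_id = x$item_id, level = as.integer(x$level),
                 variant = x$variant, success = isTRUE(x$success),
                 moves_used = as.integer(x$moves_used),
                 duration_ms = as.integer(x$duration_ms),
                 flags = as.character(unlist(x$flags))),
            class = "tol_item_result")
}

#' Export / import a session record
#'
#' `export_session()` writes a lossless schema-versioned JSON document and,
#' optionally, the flat per-item CSV of [session_rows()];
#' `import_session()` reads the JSON back into an equivalent record.
#'
#' @param record A `tol_session`.
#' @param json_path Path for the JSON document.
#' @param csv_path Optional path for the flat CSV.
#' @return `export_session()` returns `json_path` invisibly;
#'   `import_session()` returns a `tol_session`.
#' @export
export_session <- function(record, json_path, csv_path = NULL) {
  doc <- list(
    schema_version = record$schema_version,
    participant_id = record$participant_id,
    familiarization = list(
      results = lapply(record$familiarization$results, result_to_list),
      comprehension = record$familiarization$comprehension),
    assessment = list(
      results = lapply(record$assessment$results, result_to_list),
      start_level = record$assessment$start_level),
    testing = list(
      levels = lapply(record$testing$levels, function(lv)
        list(level = lv$level, passed = lv$passed,
             results = lapply(lv$results, result_to_list))),
      levels_administered = I(record$levels_administered),
      levels_passed = I(record$levels_passed),
      final_score = record$final_score,
      termination_reason = record$termination_reason))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), json_path)
  if (!is.null(csv_path))
    utils::write.csv(session_rows(record), csv_path, row.names = FALSE)
  invisible(json_path)
}

#' @rdname export_session
#' @export
import_session <- function(json_path) {
  doc <- jsonlite::fromJSON(json_path, simplifyVector = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L)
    stop("unsupported or missing session schema_version")
  tst <- list(
    levels = lapply(doc$testing$levels, function(lv)
      list(level = as.integer(lv$level), passed = isTRUE(lv$passed),
           results = lapply(lv$results, result_from_list))),
    levels_administered = as.integer(unlist(doc$testing$levels_administered)),
    levels_passed = as.integer(unlist(doc$testing$levels_passed)),
    final_score = as.integer(doc$testing$final_score),
    termination_reason = doc$testing$termination_reason)
  structure(list(
    schema_version = 1L,
    participant_id = doc$participant_id,
    familiarization = list(
      results = lapply(doc$familiarization$results, result_from_list),
      comprehension = as.logical(unlist(doc$familiarization$comprehension))),
    assessment = list(
      results = lapply(doc$assessment$results, result_from_list),
      start_level = as.integer(doc$assessment$start_level)),
    testing = tst,
    levels_administered = tst$levels_administered,
    levels_passed = tst$levels_passed,
    final_score = tst$final_score,
    termination_reason = tst$termination_reason),
    class = "tol_session")
}
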