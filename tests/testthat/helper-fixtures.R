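# shared fixtures, built once per test run

test_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- generate_bank(seed = 1)
    bank
  }
})

# always plays the optimal path within limits
perfect_responder <- function() {
  function(item, feedback_allowed = FALSE) {
    sol <- bfs_solve(item$start, item$goal, variant_spec(item$variant))
    events_from_path(item, sol$path)
  }
}

# presses Done immediately: wrong layout on every item
failing_responder <- function() {
  function(item, feedback_allowed = FALSE) item_events(500L, "done")
}

# solves items up to and including max_level, fails above
threshold_responder <- function(max_level) {
  ok <- perfect_responder(); bad <- failing_responder()
  function(item, feedback_allowed = FALSE) {
    if (item$level <= max_level) ok(item) else bad(item)
  }
}

# packaged 2PL parameters as a generating-parameter table (c = 0)
table2_params <- local({
  tp <- NULL
  function() {
    if (is.null(tp)) {
      cal <- packaged_calibration()$parameters
      tp <<- data.frame(item_id = cal$item_id, a = cal$discrimination,
                        b = cal$difficulty, c = 0, stringsAsFactors = FALSE)
    }
    tp
  }
})
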