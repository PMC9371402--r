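test_that("score_item replays events and sets the three flags correctly", {
  bank <- test_bank()
  it2 <- testing_items(bank, 2)[[1]]           # level 2, MA 3
  spec <- variant_spec(it2$variant)
  sol <- bfs_solve(it2$start, it2$goal, spec)

  # optimal replay within limits: clean success
  res <- score_item(it2, events_from_path(it2, sol$path))
  expect_true(res$success)
  expect_identical(res$flags, character(0))
  expect_identical(res$moves_used, 2L)

  # correct layout reached with extra shuttling beyond MA: moves_exceeded only
  mv <- legal_moves(it2$start, spec)[1, ]
  detour <- rbind(mv, data.frame(from = mv$to, to = mv$from), sol$path)
  res2 <- score_item(it2, events_from_path(it2, detour))
  expect_false(res2$success)
  expect_identical(res2$flags, "moves_exceeded")
  expect_identical(res2$moves_used, 4L)

  # done with the start layout: wrong_layout
  res3 <- score_item(it2, item_events(500L, "done"))
  expect_false(res3$success)
  expect_true("wrong_layout" %in% res3$flags)

  # overtime done press: flags accumulate, stream is not truncated
  late <- events_from_path(it2, sol$path,
                           per_move_latency_ms = it2$max_time_s * 1000)
  res4 <- score_item(it2, late)
  expect_identical(res4$flags, "time_exceeded")
  expect_identical(res4$moves_used, 2L)

  # dropping a disc back where it was grabbed costs no move
  src_peg <- which(lengths(it2$start) > 0)[1]
  top_disc <- it2$start[[src_peg]][length(it2$start[[src_peg]])]
  ev <- rbind(item_events(100L, "grab", top_disc),
              item_events(200L, "drop", top_disc, src_peg),
              item_events(300L, "done"))
  res5 <- score_item(it2, ev)
  expect_identical(res5$moves_used, 0L)
})

test_that("malformed event streams are rejected, never silently scored", {
  bank <- test_bank()
  it <- testing_items(bank, 1)[[1]]
  d <- unlist(it$start)[1]
  expect_error(score_item(it, item_events(1L, "grab", d)), "done")
  expect_error(score_item(it, rbind(item_events(1L, "drop", d, 2L),
                                    item_events(2L, "done"))),
               "without a preceding grab")
  expect_error(score_item(it, rbind(item_events(2L, "grab", d),
                                    item_events(1L, "done"))),
               "non-decreasing")
})

test_that("familiarization gives feedback and never contributes to scoring", {
  bank <- test_bank()
  config <- session_config(bank)
  fb_log <- list()
  responder <- failing_responder()
  attr(responder, "feedback") <- function(item, result) {
    fb_log[[length(fb_log) + 1L]] <<- list(id = item$item_id,
                                           success = result$success)
  }
  fam <- run_familiarization(responder, config)
  expect_length(fam$results, 2L)
  expect_identical(fam$comprehension, c(FALSE, FALSE))
  expect_length(fb_log, 2L)       # corrective feedback after each practice item

  # both familiarization items failed: the session still runs to completion
  rec <- run_session(responder, config, "allfail")
  expect_identical(rec$final_score, 0L)
  expect_false(any(vapply(rec$testing$levels, function(l)
    any(grepl("Famil", vapply(l$results, `[[`, "", "item_id"))), TRUE)))
})

test_that("assessment fixes the testing entry level", {
  bank <- test_bank()   # assessment levels 2, 4, 6, 8
  config <- session_config(bank)
  expect_identical(run_assessment(perfect_responder(), config)$start_level, 7L)
  # failure on the 3rd assessment item (level 6) -> start at 5
  expect_identical(run_assessment(threshold_responder(5), config)$start_level, 5L)
  # failure on the 1st assessment item (level 2) -> floor at 1
  expect_identical(run_assessment(threshold_responder(1), config)$start_level, 1L)
  # administration stops at the first failure
  ass <- run_assessment(threshold_responder(3), config)
  expect_length(ass$results, 2L)
})

test_that("testing phase transitions, early stop, and termination reasons", {
  bank <- test_bank()
  config <- session_config(bank)

  # ever-perfect: levels 7..10, ceiling passed, only 2 items per level
  tst <- run_testing(perfect_responder(), 7, config)
  expect_identical(tst$levels_administered, c(7L, 8L, 9L, 10L))
  expect_identical(tst$final_score, 10L)
  expect_identical(tst$termination_reason, "ceiling_passed")
  expect_true(all(vapply(tst$levels, function(l) length(l$results), 0L) == 2L))

  # fail 5 then 4: two consecutive failures
  tst2 <- run_testing(threshold_responder(3), 5, config)
  expect_identical(tst2$levels_administered, c(5L, 4L))
  expect_identical(tst2$final_score, 0L)
  expect_identical(tst2$termination_reason, "two_consecutive_failures")

  # fail 7, pass 6, promoted past the failed level to 8, fail 8: bracketed
  tst3 <- run_testing(threshold_responder(6), 7, config)
  expect_identical(tst3$levels_administered, c(7L, 6L, 8L))
  expect_identical(tst3$final_score, 6L)
  expect_identical(tst3$termination_reason, "bracketed")

  # always failing from level 1: floor, single level, bracketed
  tst4 <- run_testing(failing_responder(), 1, config)
  expect_identical(tst4$levels_administered, 1L)
  expect_identical(tst4$termination_reason, "bracketed")

  # disabling early stop administers all three items of each level
  cfg3 <- session_config(bank, early_stop_within_level = FALSE)
  tst5 <- run_testing(perfect_responder(), 9, cfg3)
  expect_true(all(vapply(tst5$levels, function(l) length(l$results), 0L) == 3L))
})

test_that("any responder terminates within the bank bounds", {
  bank <- test_bank()
  config <- session_config(bank)
  for (s in 1:6) {
    responder <- local({
      rng <- s
      function(item, feedback_allowed = FALSE) {
        rng <<- (rng * 48271) %% 2147483647
        if (rng %% 2 == 0) perfect_responder()(item) else failing_responder()(item)
      }
    })
    rec <- run_session(responder, config, paste0("rand", s))
    expect_lte(sum(vapply(rec$testing$levels, function(l)
      length(l$results), 0L)), 30L)
    expect_lte(length(rec$levels_administered), 10L)
    expect_false(anyDuplicated(rec$levels_administered) > 0)
    expect_identical(rec$final_score,
                     if (length(rec$levels_passed)) max(rec$levels_passed) else 0L)
  }
})

test_that("mean final score is non-decreasing in ability", {
  bank <- test_bank()
  params <- default_item_params(bank)
  thetas <- c(-2, 0, 2)
  means <- vapply(seq_along(thetas), function(k) {
    cohort <- simulate_cat_cohort(bank, params, n = 25,
                                  thetas = rep(thetas[k], 25), seed = 100 + k)
    mean(cohort$summary$final_score)
  }, 0)
  expect_true(all(diff(means) >= 0))
  expect_gt(means[3], means[1])
})

test_that("session export round-trips through JSON and CSV", {
  bank <- test_bank()
  config <- session_config(bank)
  rec <- run_session(threshold_responder(6), config, "P42")
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  export_session(rec, jp, cp)
  rec2 <- import_session(jp)
  # lossless: re-export is identical
  jp2 <- withr::local_tempfile(fileext = ".json")
  export_session(rec2, jp2)
  expect_identical(readLines(jp), readLines(jp2))
  expect_identical(rec2$final_score, rec$final_score)
  expect_identical(rec2$levels_administered, rec$levels_administered)

  rows <- read.csv(cp)
  n_admin <- length(rec$familiarization$results) +
    length(rec$assessment$results) +
    length(unlist(lapply(rec$testing$levels, `[[`, "results"),
                  recursive = FALSE))
  expect_identical(nrow(rows), n_admin)
  expect_identical(names(rows),
                   c("phase", "item_id", "level", "variant", "success",
                     "moves_used", "duration_ms", "flags"))
})
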