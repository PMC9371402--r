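test_that("move limits follow the adjusted table and the legacy doubling rule", {
  expect_identical(move_limit(1, "adjusted"), 1L)
  expect_identical(move_limit(10, "adjusted"), 14L)
  expect_identical(move_limit(10, "legacy"), 20L)
  expect_identical(move_limit(1:10, "adjusted"),
                   c(1L, 3L, 4L, 5L, 7L, 8L, 10L, 11L, 12L, 14L))
  expect_identical(move_limit(1:10, "legacy"), 2L * 1:10)
  # adjusted limits sit between the minimum and the legacy bound
  expect_true(all(move_limit(1:10, "adjusted") >= 1:10))
  expect_true(all(move_limit(1:10, "adjusted") <= 2L * 1:10))
  expect_error(move_limit(0), "1..10")
  expect_error(move_limit(11), "1..10")
})

test_that("bank generation is deterministic and BFS-verified", {
  b1 <- test_bank()
  expect_s3_class(b1, "tol_item_bank")
  expect_length(b1$testing, 30L)
  expect_length(b1$assessment, 4L)
  expect_length(b1$familiarization, 2L)

  # same seed, byte-identical serialization
  expect_identical(as.character(save_bank(generate_bank(seed = 3))),
                   as.character(save_bank(generate_bank(seed = 3))))
  # different seed, different bank
  expect_false(identical(as.character(save_bank(b1)),
                         as.character(save_bank(generate_bank(seed = 3)))))

  # every item's level is its exact minimal distance
  for (it in b1$testing) {
    expect_identical(bfs_solve(it$start, it$goal,
                               variant_spec(it$variant))$distance, it$level)
    expect_gte(it$max_moves, it$level)
    expect_false(identical(state_key(it$start), state_key(it$goal)))
  }
  # legacy scheme stores doubled limits
  b2 <- generate_bank(seed = 1, scheme = "legacy")
  expect_identical(vapply(testing_items(b2, 10), `[[`, 0L, "max_moves"),
                   rep(20L, 3))
})

test_that("levels above 8 are out of reach for the three-disc board", {
  expect_length(pairs_at_distance(tol_board_d3(), 9), 0L)
  expect_gt(length(pairs_at_distance(tol_board_d4(), 9)), 0L)
  # a hand-built level-9 D3 item is rejected
  bank <- test_bank()
  bad <- bank
  it <- bad$testing[[25]]  # an Item_9_* slot
  expect_identical(it$level, 9L)
  it$variant <- "D3"
  it$start <- board_state(list(c("blue", "green", "red"), character(),
                               character()), tol_board_d3())
  it$goal <- board_state(list(c("blue"), c("green"), c("red")),
                         tol_board_d3())
  bad$testing[[25]] <- it
  expect_error(validate_bank(bad, verify_distances = FALSE),
               "four-disc")
})

test_that("bank JSON round-trips and corrupted documents are rejected", {
  bank <- test_bank()
  path <- withr::local_tempfile(fileext = ".json")
  save_bank(bank, path)
  bank2 <- load_bank(path)
  expect_identical(as.character(save_bank(bank2)),
                   as.character(save_bank(bank)))

  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)

  # swap the level fields of a level-4 and a level-5 item: per-level counts
  # stay valid, but BFS re-verification catches the mismatch
  i4 <- which(vapply(doc$testing, `[[`, 0L, "level") == 4L)[1]
  i5 <- which(vapply(doc$testing, `[[`, 0L, "level") == 5L)[1]
  doc_bad <- doc
  doc_bad$testing[[i4]]$level <- 5L
  doc_bad$testing[[i5]]$level <- 4L
  p1 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc_bad, auto_unbox = TRUE), p1)
  expect_error(load_bank(p1), "minimal distance")
  # loads when distance verification is off (structure is still valid)
  expect_s3_class(load_bank(p1, verify_distances = FALSE), "tol_item_bank")
  # a bare level bump instead breaks the per-level count invariant
  doc_cnt <- doc
  doc_cnt$testing[[i4]]$level <- 5L
  p1b <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc_cnt, auto_unbox = TRUE), p1b)
  expect_error(load_bank(p1b), "exactly 3 times")

  # drop a testing item: count invariant
  doc_29 <- doc
  doc_29$testing[[30]] <- NULL
  p2 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc_29, auto_unbox = TRUE), p2)
  expect_error(load_bank(p2), "30 testing items")

  # wrong schema version
  doc_v <- doc
  doc_v$schema_version <- 99L
  p3 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc_v, auto_unbox = TRUE), p3)
  expect_error(load_bank(p3), "schema_version")
})

test_that("packaged calibration tables match the published values", {
  cal <- packaged_calibration()
  par <- cal$parameters
  expect_identical(nrow(par), 25L)
  expect_false(any(c("Item_1_1", "Item_1_3", "Item_2_1", "Item_2_2",
                     "Item_2_3") %in% par$item_id))
  i103 <- par[par$item_id == "Item_10_3", ]
  expect_equal(i103$difficulty, 0.8017)
  expect_equal(i103$discrimination, 2.1448)
  expect_equal(par$difficulty[par$item_id == "Item_1_2"], -4.8904)
  expect_equal(min(par$difficulty), -4.9173)
  expect_identical(par$item_id[which.min(par$difficulty)], "Item_3_1")
  # the published table's own maximum is Item_9_2 at 0.9257, although the
  # accompanying text (and the commonly quoted range) cites 0.8017
  expect_equal(max(par$difficulty), 0.9257)
  expect_identical(par$item_id[which.max(par$difficulty)], "Item_9_2")
  expect_equal(min(par$discrimination), 0.6356)
  expect_identical(par$item_id[which.min(par$discrimination)], "Item_3_3")
  # transcription fix: Item_7_1 discrimination SE is 0.1855, not 1855
  expect_equal(par$discrimination_se[par$item_id == "Item_7_1"], 0.1855)

  fitt <- cal$item_fit
  expect_identical(nrow(fitt), 25L)
  expect_identical(sum(fitt$p_value < 0.05), 9L)
  # printed p-values are consistent with chi-square on 8 df
  expect_equal(fitt$p_value,
               round(pchisq(fitt$chisq, 8, lower.tail = FALSE), 4),
               tolerance = 1e-3)
})
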