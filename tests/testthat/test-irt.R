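test_that("quadrature integrates the standard normal exactly for moments", {
  g <- normal_quadrature(21)
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_equal(sum(g$weights * g$nodes), 0, tolerance = 1e-10)
  expect_equal(sum(g$weights * g$nodes^2), 1, tolerance = 1e-10)
  expect_equal(sum(g$weights * g$nodes^4), 3, tolerance = 1e-8)
  expect_equal(g$nodes, -rev(g$nodes), tolerance = 1e-9)
})

test_that("icc has the logistic midpoint, slope and asymptote properties", {
  expect_equal(icc(0.5, a = 2, b = 0.5), 0.5)
  # frozen from direct evaluation of 1 / (1 + exp(a * b)) at theta = 0
  expect_equal(icc(0, a = 2.1448, b = 0.8017), 0.1519374, tolerance = 1e-6)
  expect_equal(icc(-50, a = 1.3, b = 0, c = 0.2), 0.2, tolerance = 1e-12)
  th <- seq(-4, 4, 0.5)
  expect_true(all(diff(icc(th, a = 1.7, b = -0.3, c = 0.1)) > 0))
})

test_that("information criteria and LRT reproduce the published arithmetic", {
  expect_equal(aic(-2333.38, k = 50), 4766.76, tolerance = 0.005)
  expect_equal(bic(-2333.38, k = 50, n = 214), 4935.06, tolerance = 0.005)
  expect_equal(aic(-2333.38, k = 75), 4816.76, tolerance = 0.005)
  expect_equal(bic(-2333.38, k = 75, n = 214), 5069.21, tolerance = 0.005)
  expect_equal(bic(-2420.46, k = 25, n = 214), 4975.06, tolerance = 0.005)
  expect_equal(aic(-2420.46, k = 25), 4890.91, tolerance = 0.005)
  # 2 * (2420.46 - 2333.38); printed as 174.15 from unrounded values
  expect_equal(2 * (-2333.38 - -2420.46), 174.16, tolerance = 1e-9)
})

test_that("EM fits are monotone, nested, and expose AIC/BIC via logLik", {
  tp <- table2_params()
  set.seed(5)
  X <- simulate_matrix(tp, rnorm(400), seed = 55)
  fr <- suppressWarnings(fit_irt(X, "rasch", se = FALSE))
  f2 <- suppressWarnings(fit_irt(X, "2pl", se = FALSE))
  f3 <- suppressWarnings(fit_irt(X, "3pl", se = FALSE))
  for (f in list(fr, f2, f3))
    expect_true(all(diff(f$ll_trace) > -1e-6))
  expect_gte(f2$log_lik, fr$log_lik - 1e-6)
  expect_gte(f3$log_lik, f2$log_lik - 1e-6)
  expect_identical(c(fr$n_params, f2$n_params, f3$n_params), c(25L, 50L, 75L))

  expect_equal(AIC(f2), aic(f2))
  expect_equal(BIC(f2), bic(f2))
  expect_equal(aic(f2), 2 * 50 - 2 * f2$log_lik)

  lr <- lrt(fr, f2)
  expect_equal(lr$statistic, 2 * (f2$log_lik - fr$log_lik))
  expect_identical(lr$df, 25L)
  expect_error(lrt(f2, fr), "nested")
  # generating discriminations vary widely: Rasch is rejected decisively
  expect_lt(lr$p_value, 0.001)
  # guessing adds nothing on c = 0 data
  lr3 <- lrt(f2, f3)
  expect_lt(lr3$statistic, qchisq(0.95, 25))
  expect_gt(lr3$p_value, 0.5)
})

test_that("standard errors come out finite and plausibly scaled", {
  tp <- table2_params()[10:17, ]   # mid-difficulty items, well identified
  set.seed(6)
  X <- simulate_matrix(tp, rnorm(500), seed = 66)
  f <- fit_irt(X, "2pl")
  expect_true(all(is.finite(f$items$se_a)))
  expect_true(all(is.finite(f$items$se_b)))
  expect_true(all(f$items$se_b > 0.01 & f$items$se_b < 1))
})

test_that("EAP matches brute-force dense-grid integration", {
  tp <- table2_params()[6:15, ]
  set.seed(9)
  X <- simulate_matrix(tp, rnorm(40), seed = 99)
  eap <- eap_ability(X, tp)
  # independent oracle: direct Riemann sum on a fine grid
  th <- seq(-8, 8, by = 0.002)
  w <- dnorm(th); w <- w / sum(w)
  S <- X$scores
  for (j in seq_len(nrow(S))) {
    like <- rep(1, length(th))
    for (i in seq_len(nrow(tp)))
      like <- like * (if (S[j, i] == 1) icc(th, tp$a[i], tp$b[i])
                      else 1 - icc(th, tp$a[i], tp$b[i]))
    post <- like * w; post <- post / sum(post)
    expect_equal(eap$theta[j], sum(post * th), tolerance = 1e-3)
    expect_equal(eap$theta_sd[j],
                 sqrt(sum(post * th^2) - sum(post * th)^2), tolerance = 1e-3)
  }
  # likelihood ordering: all-correct pattern sits above zero
  allc <- matrix(1, 1, nrow(tp), dimnames = list("x", tp$item_id))
  expect_gt(eap_ability(allc, tp)$theta, 0)
})

test_that("item and test information behave as Fisher information", {
  expect_equal(item_information(0.3, a = 1.8, b = 0.3), 1.8^2 / 4)
  th <- seq(-3, 3, 0.25)
  tp <- table2_params()
  ti <- test_information(th, tp[, c("a", "b", "c")])
  by_hand <- rowSums(sapply(seq_len(nrow(tp)), function(i)
    item_information(th, tp$a[i], tp$b[i], tp$c[i])))
  expect_equal(ti, by_hand)
  # 3PL generalization reduces to 2PL at c = 0
  expect_equal(item_information(1, 1.2, 0.4, 0), {
    P <- icc(1, 1.2, 0.4); 1.2^2 * P * (1 - P)
  })
})

test_that("complete_matrix applies the granted / not-reached rules", {
  bank <- test_bank()
  config <- session_config(bank)
  ids <- vapply(testing_items(bank), `[[`, "", "item_id")
  lvs <- vapply(testing_items(bank), `[[`, 0L, "level")

  s_perfect <- run_session(perfect_responder(), config, "perfect")
  s_mid <- run_session(threshold_responder(4), config, "mid")
  M <- complete_matrix(list(s_perfect, s_mid), bank)
  expect_identical(dim(M), c(2L, 30L))

  # perfect: starts at 7, passes everything; levels 1-6 granted correct
  expect_true(all(M$status[1, lvs <= 6] == "granted"))
  expect_true(all(M$scores[1, ] == 1L))
  # mid (fails assessment level 6 -> starts 5, passes 5 fails 6 after...):
  # levels above the administered band are not reached and scored 0
  top <- max(s_mid$levels_administered)
  expect_true(all(M$scores[2, lvs > top] == 0L))
  expect_true(all(M$status[2, lvs > top] == "not_reached"))
  # skipped third item of a passed level is granted
  for (lv in s_mid$testing$levels) {
    given <- vapply(lv$results, `[[`, "", "item_id")
    skipped <- setdiff(ids[lvs == lv$level], given)
    if (lv$passed && length(skipped))
      expect_true(all(M$status[2, skipped] == "granted"))
  }
})

test_that("near-perfect items are excluded by the 2-incorrect rule", {
  set.seed(31)
  n <- 214
  S <- cbind(easy0 = rep(1L, n),                        # 100% correct
             easy2 = c(rep(0L, 2), rep(1L, n - 2)),     # 212/214 correct
             keep3 = c(rep(0L, 3), rep(1L, n - 3)),     # boundary: retained
             mid = rbinom(n, 1, 0.6))
  ex <- exclude_easy_items(response_matrix(S))
  expect_setequal(ex$dropped, c("easy0", "easy2"))
  expect_identical(colnames(ex$matrix$scores), c("keep3", "mid"))
})

test_that("response matrices round-trip through CSV with status sidecar", {
  tp <- table2_params()[1:6, ]
  set.seed(12)
  X <- simulate_matrix(tp, rnorm(15), seed = 13)
  X$status[2, 3] <- "granted"; X$scores[2, 3] <- 1L
  X$status[3, 4] <- "not_reached"; X$scores[3, 4] <- 0L
  X <- response_matrix(X$scores, X$status)
  p <- withr::local_tempfile(fileext = ".csv")
  write_response_matrix(X, p)
  X2 <- read_response_matrix(p)
  expect_identical(unname(X2$scores), unname(X$scores))
  expect_identical(unname(X2$status), unname(X$status))
  expect_identical(colnames(X2$scores), colnames(X$scores))
})

test_that("granted cells must be correct and not_reached incorrect", {
  S <- matrix(c(1L, 0L), 1, 2, dimnames = list("r1", c("i1", "i2")))
  expect_error(response_matrix(S, matrix(c("granted", "granted"), 1, 2)),
               "granted")
  expect_error(response_matrix(S, matrix(c("not_reached", "not_reached"), 1, 2)),
               "not_reached")
  expect_silent(response_matrix(S, matrix(c("granted", "not_reached"), 1, 2)))
})
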