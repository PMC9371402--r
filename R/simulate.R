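# evaluate `f()` under a private RNG stream, leaving the global stream intact
local_rng <- function(seed) {
  state <- NULL
  function(f) {
    g <- globalenv()
    old <- if (exists(".Random.seed", g, inherits = FALSE))
      get(".Random.seed", g) else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, g)
    res <- f()
    state <<- get(".Random.seed", g)
    if (is.null(old)) rm(".Random.seed", envir = g)
    else assign(".Random.seed", old, g)
    res
  }
}

#' Simulate a full binary response matrix under an IRT model
#'
#' Independent Bernoulli draws with success probability `icc(theta_j, item_i)`
#' for every respondent-item pair; the complete (non-adaptive) design.
#'
#' @param items Data frame with columns `item_id`, `a`, `b` and optionally
#'   `c`.
#' @param thetas Numeric vector of latent abilities.
#' @param seed Integer seed; the matrix is a pure function of its arguments.
#' @return A `tol_response_matrix`, all cells `"administered"`.
#' @export
simulate_matrix <- function(items, thetas, seed) {
  items <- as.data.frame(items)
  if (is.null(items$c)) items$c <- 0
  stopifnot(nrow(items) >= 1L, length(thetas) >= 1L)
  P <- t(prob_matrix(items, thetas))   # N x I
  rng <- local_rng(as.integer(seed))
  draws <- rng(function() matrix(stats::runif(length(P)), nrow(P), ncol(P)))
  scores <- (draws < P) + 0L
  dimnames(scores) <- list(paste0("R", seq_along(thetas)), items$item_id)
  response_matrix(scores)
}

#' Default item parameters for a bank
#'
#' Items whose ids appear in the packaged calibration receive the published
#' difficulty and discrimination; the remaining (easy, excluded-from-
#' calibration) items get synthetic defaults on the rough linear
#' difficulty-in-level trend, `b = (level - 5.5) / 1.5`, `a = 1.2`.
#'
#' @param bank A `tol_item_bank`.
#' @return Data frame with `item_id`, `level`, `a`, `b`, `c` and `source`
#'   (`"calibrated"` or `"synthetic"`), in bank testing-item order.
#' @export
default_item_params <- function(bank) {
  cal <- packaged_calibration()$parameters
  items <- testing_items(bank)
  out <- data.frame(
    item_id = vapply(items, `[[`, "", "item_id"),
    level = vapply(items, `[[`, 0L, "level"),
    a = 1.2, b = NA_real_, c = 0, source = "synthetic",
    stringsAsFactors = FALSE)
  out$b <- (out$level - 5.5) / 1.5
  hit <- match(out$item_id, cal$item_id)
  out$a[!is.na(hit)] <- cal$discrimination[hit[!is.na(hit)]]
  out$b[!is.na(hit)] <- cal$difficulty[hit[!is.na(hit)]]
  out$source[!is.na(hit)] <- "calibrated"
  out
}

#' Respondent profile for the noisy-optimal agent
#'
#' @param move_error_rate Probability that a planned optimal move is
#'   replaced by a uniformly random legal move.
#' @param per_move_latency_ms Simulated clock increment per grab/drop event.
#' @return A list of class `tol_respondent_profile`.
#' @export
respondent_profile <- function(move_error_rate = 0.1,
                               per_move_latency_ms = 1500) {
  stopifnot(move_error_rate >= 0, move_error_rate <= 1,
            per_move_latency_ms > 0)
  structure(list(move_error_rate = move_error_rate,
                 per_move_latency_ms = per_move_latency_ms),
            class = "tol_respondent_profile")
}

#' Responder driven by item characteristic curves
#'
#' Decides each item by a Bernoulli draw with probability `icc(theta)` at
#' the item's parameters, then emits a legal event stream: an optimal-path
#' replay on success, an immediate done press (wrong layout) on failure.
#' Binds the 2PL response model to the adaptive engine.
#'
#' @param item_params Data frame with `item_id`, `a`, `b` and optionally
#'   `c`, covering every bank item the session may present (see
#'   [default_item_params()]; assessment and familiarization items fall
#'   back to the synthetic level trend if absent).
#' @param theta Latent ability of the simulated respondent.
#' @param seed Integer seed for the private response stream.
#' @param per_move_latency_ms Simulated per-event latency.
#' @return A responder function for [run_session()].
#' @export
bernoulli_cat_responder <- function(item_params, theta, seed,
                                    per_move_latency_ms = 1500) {
  item_params <- as.data.frame(item_params)
  if (is.null(item_params$c)) item_params$c <- 0
  rng <- local_rng(as.integer(seed))
  function(item, feedback_allowed = FALSE) {
    j <- match(item$item_id, item_params$item_id)
    if (is.na(j)) {
      if (is.null(item$level)) stop("no parameters for item ", item$item_id)
      a <- 1.2; b <- (item$level - 5.5) / 1.5; cc <- 0
    } else {
      a <- item_params$a[j]; b <- item_params$b[j]; cc <- item_params$c[j]
    }
    p <- icc(theta, a, b, cc)
    ok <- rng(function() stats::runif(1) < p)
    if (ok) {
      sol <- bfs_solve(item$start, item$goal, variant_spec(item$variant))
      events_from_path(item, sol$path, per_move_latency_ms)
    } else {
      item_events(500L, "done")
    }
  }
}

#' Noisy-optimal puzzle-playing agent
#'
#' Replays the breadth-first optimal solution but, with probability
#' `move_error_rate` per move, substitutes a uniformly random legal move and
#' replans from the resulting position. Play stops when the goal is reached
#' or one move past the item's limit (the scorer then raises the
#' appropriate flag). With a zero error rate the agent always solves within
#' the limit; with heavy noise it wanders and fails, emulating
#' trial-and-error behavior.
#'
#' @param profile A [respondent_profile()].
#' @param seed Integer seed for the private move stream.
#' @return A responder function for [run_session()].
#' @export
noisy_optimal_agent <- function(profile = respondent_profile(), seed = 1L) {
  stopifnot(inherits(profile, "tol_respondent_profile"))
  rng <- local_rng(as.integer(seed))
  lat <- as.integer(profile$per_move_latency_ms)
  function(item, feedback_allowed = FALSE) {
    spec <- variant_spec(item$variant)
    state <- item$start
    t <- 0L
    rows <- list()
    moves_done <- 0L
    while (!states_equal(state, item$goal) && moves_done <= item$max_moves) {
      plan <- bfs_solve(state, item$goal, spec)$path
      mv <- c(plan$from[1L], plan$to[1L])
      err <- rng(function() stats::runif(1) < profile$move_error_rate)
      if (err) {
        lm <- legal_moves(state, spec)
        r <- rng(function() sample.int(nrow(lm), 1L))
        mv <- c(lm$from[r], lm$to[r])
      }
      disc <- state[[mv[1L]]][length(state[[mv[1L]]])]
      t <- t + lat
      rows[[length(rows) + 1L]] <- item_events(t, "grab", disc)
      t <- t + lat
      rows[[length(rows) + 1L]] <- item_events(t, "drop", disc, mv[2L])
      state <- apply_move(state, mv[1L], mv[2L], spec)
      moves_done <- moves_done + 1L
    }
    t <- t + lat
    rows[[length(rows) + 1L]] <- item_events(t, "done")
    do.call(rbind, rows)
  }
}

#' Simulate a cohort of adaptive sessions
#'
#' Draws `n` abilities from the standard-normal prior (or uses the supplied
#' vector), builds a Bernoulli responder per participant, and runs the full
#' three-phase session for each.
#'
#' @param bank A `tol_item_bank`.
#' @param item_params Per-item parameters, see [default_item_params()].
#' @param n Number of respondents.
#' @param thetas Optional ability vector overriding the N(0,1) draw.
#' @param seed Integer seed controlling abilities and all response streams.
#' @return List with `sessions` (list of `tol_session`), `thetas`, and
#'   `summary` (data frame: participant, theta, start level, final score,
#'   termination reason).
#' @export
simulate_cat_cohort <- function(bank, item_params = default_item_params(bank),
                                n = 214L, thetas = NULL, seed = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  rng <- local_rng(as.integer(seed))
  if (is.null(thetas)) thetas <- rng(function() stats::rnorm(n))
  stopifnot(length(thetas) == n)
  sub_seeds <- rng(function() sample.int(2147483000L, n))
  config <- session_config(bank)
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    responder <- bernoulli_cat_responder(item_params, thetas[i], sub_seeds[i])
    sessions[[i]] <- run_session(responder, config,
                                 participant_id = sprintf("P%03d", i))
  }
  summary <- data.frame(
    participant_id = vapply(sessions, `[[`, "", "participant_id"),
    theta = thetas,
    start_level = vapply(sessions, function(s) s$assessment$start_level, 0L),
    final_score = vapply(sessions, `[[`, 0L, "final_score"),
    termination_reason = vapply(sessions, `[[`, "", "termination_reason"),
    stringsAsFactors = FALSE)
  list(sessions = sessions, thetas = thetas, summary = summary,
       metadata = list(seed = as.integer(seed), n = n))
}

#' Parameter-recovery experiment
#'
#' Simulates a complete response matrix from known generating parameters
#' (by default the packaged 25-item calibration), refits the model, and
#' reports per-parameter bias, root-mean-square error and Pearson
#' correlation between true and estimated values.
#'
#' @param n_respondents Sample size (>= 200).
#' @param model `"2pl"`, `"rasch"` or `"3pl"`.
#' @param seed Integer seed.
#' @param true_params Generating parameters (`item_id`, `a`, `b`, optional
#'   `c`); default is the packaged calibration.
#' @param se Compute standard errors in the refit (default `FALSE`; the
#'   recovery metrics do not use them).
#' @param ... Passed to [fit_irt()].
#' @return An object of class `tol_recovery`: `table` (true vs estimated per
#'   item), `stats` (bias/RMSE/r per parameter), `fit`, and metadata.
#' @export
recovery_experiment <- function(n_respondents = 2000L, model = "2pl",
                                seed = 1L, true_params = NULL, se = FALSE,
                                ...) {
  n_respondents <- as.integer(n_respondents)
  stopifnot(n_respondents >= 200L)
  if (is.null(true_params)) {
    cal <- packaged_calibration()$parameters
    true_params <- data.frame(item_id = cal$item_id, a = cal$discrimination,
                              b = cal$difficulty, c = 0,
                              stringsAsFactors = FALSE)
  }
  rng <- local_rng(as.integer(seed))
  thetas <- rng(function() stats::rnorm(n_respondents))
  mat_seed <- rng(function() sample.int(2147483000L, 1L))
  X <- simulate_matrix(true_params, thetas, mat_seed)
  fit <- fit_irt(X, model = model, se = se, ...)
  tab <- data.frame(item_id = true_params$item_id,
                    a_true = true_params$a, a_est = fit$items$a,
                    b_true = true_params$b, b_est = fit$items$b,
                    flagged = true_params$item_id %in% fit$flagged_items,
                    stringsAsFactors = FALSE)
  stat_for <- function(true, est) {
    c(bias = mean(est - true), rmse = sqrt(mean((est - true)^2)),
      r = stats::cor(true, est))
  }
  stats_of <- function(t) as.data.frame(rbind(a = stat_for(t$a_true, t$a_est),
                                              b = stat_for(t$b_true, t$b_est)))
  clean <- tab[!tab$flagged, ]
  structure(list(table = tab, stats = stats_of(tab),
                 stats_clean = stats_of(clean),
                 n_flagged = sum(tab$flagged), fit = fit,
                 metadata = list(n = n_respondents, model = model,
                                 seed = as.integer(seed))),
            class = "tol_recovery")
}

#' @export
print.tol_recovery <- function(x, ...) {
  cat(sprintf("<tol_recovery> %s, N = %d, seed %d\n",
              toupper(x$metadata$model), x$metadata$n, x$metadata$seed))
  cat(" all items:\n"); print(round(x$stats, 4))
  cat(sprintf(" excluding %d flagged item(s):\n", x$n_flagged))
  print(round(x$stats_clean, 4))
  invisible(x)
}
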