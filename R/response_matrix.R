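#' Construct a response matrix
#'
#' A respondents-by-items binary score matrix with a parallel administration
#' status for every cell: `"administered"` (observed), `"granted"` (credited
#' correct without administration) or `"not_reached"` (scored incorrect).
#'
#' @param scores Integer 0/1 matrix with respondent row names and item
#'   column names.
#' @param status Character matrix of the same shape, or `NULL` for all
#'   `"administered"`.
#' @return An object of class `tol_response_matrix`.
#' @export
response_matrix <- function(scores, status = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (anyNA(scores) || !all(scores %in% c(0L, 1L)))
    stop("scores must be complete 0/1")
  if (is.null(status)) {
    status <- matrix("administered", nrow(scores), ncol(scores),
                     dimnames = dimnames(scores))
  }
  status <- as.matrix(status)
  if (!identical(dim(status), dim(scores)))
    stop("status matrix shape must match scores")
  if (!all(status %in% c("administered", "granted", "not_reached")))
    stop("invalid status value")
  if (any(status == "granted" & scores != 1L))
    stop("granted cells must score 1")
  if (any(status == "not_reached" & scores != 0L))
    stop("not_reached cells must score 0")
  structure(list(scores = scores, status = status),
            class = "tol_response_matrix")
}

#' @export
print.tol_response_matrix <- function(x, ...) {
  cat(sprintf("<tol_response_matrix> %d respondents x %d items\n",
              nrow(x$scores), ncol(x$scores)))
  print(table(status = x$status))
  invisible(x)
}

#' @export
dim.tol_response_matrix <- function(x) dim(x$scores)

#' Complete a response matrix from adaptive sessions
#'
#' The adaptive procedure administers only a band of levels per participant.
#' For analysis the matrix is completed: administered testing items keep
#' their observed scores; every item at a level below the participant's
#' lowest administered level is granted correct (the procedure only starts
#' above levels the participant is assumed to master); all remaining
#' unreached items — levels above termination, and the unadministered items
#' of a failed level — are scored incorrect. The skipped third item of a
#' passed level is granted correct.
#'
#' @param sessions List of `tol_session` records from the same bank.
#' @param bank The `tol_item_bank` that produced them.
#' @return A `tol_response_matrix` with `length(sessions)` rows and 30
#'   columns (the testing items in bank order).
#' @export
complete_matrix <- function(sessions, bank) {
  items <- testing_items(bank)
  ids <- vapply(items, `[[`, "", "item_id")
  lvs <- vapply(items, `[[`, 0L, "level")
  n <- length(sessions)
  scores <- matrix(0L, n, length(ids), dimnames = list(
    vapply(sessions, `[[`, "", "participant_id"), ids))
  status <- matrix("not_reached", n, length(ids), dimnames = dimnames(scores))
  for (s in seq_len(n)) {
    rec <- sessions[[s]]
    lowest <- min(rec$levels_administered)
    below <- lvs < lowest
    scores[s, below] <- 1L
    status[s, below] <- "granted"
    for (lv in rec$testing$levels) {
      seen <- character()
      for (res in lv$results) {
        j <- match(res$item_id, ids)
        if (is.na(j)) stop("session references unknown item ", res$item_id)
        if (status[s, j] == "administered")
          stop("conflicting duplicate score for item ", res$item_id)
        scores[s, j] <- as.integer(res$success)
        status[s, j] <- "administered"
        seen <- c(seen, res$item_id)
      }
      if (lv$passed) {
        skipped <- setdiff(ids[lvs == lv$level], seen)
        scores[s, match(skipped, ids)] <- 1L
        status[s, match(skipped, ids)] <- "granted"
      }
    }
  }
  response_matrix(scores, status)
}

#' Drop near-perfect easy items
#'
#' Items answered incorrectly by at most `max_incorrect` respondents carry
#' almost no information and produce extreme difficulty estimates; they are
#' removed before calibration. With the published data this rule drops the
#' five easiest items and retains 25.
#'
#' @param X A `tol_response_matrix` or binary matrix.
#' @param max_incorrect Drop items with this many or fewer incorrect
#'   responses (default 2).
#' @return List with `matrix` (reduced `tol_response_matrix`) and `dropped`
#'   (character vector of removed item ids).
#' @export
exclude_easy_items <- function(X, max_incorrect = 2L) {
  rm_ <- if (inherits(X, "tol_response_matrix")) X else response_matrix(X)
  wrong <- colSums(rm_$scores == 0L)
  drop <- which(wrong <= max_incorrect)
  keep <- setdiff(seq_len(ncol(rm_$scores)), drop)
  if (length(keep) < 2L) stop("fewer than 2 items would remain")
  list(matrix = response_matrix(rm_$scores[, keep, drop = FALSE],
                                rm_$status[, keep, drop = FALSE]),
       dropped = colnames(rm_$scores)[drop])
}

#' Write / read a response matrix as CSV
#'
#' The score file has a `respondent_id` column followed by one 0/1 column
#' per item; the status sidecar (`<path>` with `_status` suffix, or
#' `status_path`) has the same layout with status strings.
#'
#' @param X A `tol_response_matrix`.
#' @param path CSV path for the scores.
#' @param status_path CSV path for the status sidecar; default derives from
#'   `path`.
#' @return `write_response_matrix()` returns `path` invisibly;
#'   `read_response_matrix()` returns a `tol_response_matrix`.
#' @export
write_response_matrix <- function(X, path, status_path = default_status_path(path)) {
  stopifnot(inherits(X, "tol_response_matrix"))
  df <- data.frame(respondent_id = rownames(X$scores) %||%
                     as.character(seq_len(nrow(X$scores))),
                   X$scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  dfs <- data.frame(respondent_id = df$respondent_id, X$status,
                    check.names = FALSE)
  utils::write.csv(dfs, status_path, row.names = FALSE)
  invisible(path)
}

default_status_path <- function(path) {
  sub("(\\.[^.]*)?$", "_status\\1", path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path, status_path = default_status_path(path)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  status <- NULL
  if (file.exists(status_path)) {
    dfs <- utils::read.csv(status_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    status <- as.matrix(dfs[, -1, drop = FALSE])
    rownames(status) <- dfs[[1]]
  }
  response_matrix(m, status)
}
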