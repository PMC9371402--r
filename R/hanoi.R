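#' Tower of Hanoi minimal solution length by search
#'
#' The Hanoi puzzle uses three pegs and size-ordered discs: a larger disc may
#' never rest on a smaller one. The minimal transfer of an n-disc pile to
#' another peg is known in closed form to take `2^n - 1` moves; this function
#' recomputes it by breadth-first search over the legal state graph, so the
#' closed form can serve as an independent check of the search machinery.
#'
#' @param n Number of discs (positive integer).
#' @param to Goal peg index (2 or 3); the pile starts on peg 1.
#' @return Minimal number of moves (integer).
#' @examples
#' hanoi_min_moves(3) # 7
#' @export
hanoi_min_moves <- function(n, to = 3L) {
  n <- as.integer(n)
  stopifnot(n >= 1L, to %in% c(2L, 3L))
  # state: per peg, disc sizes bottom->top (strictly decreasing); key by string
  start <- list(rev(seq_len(n)), integer(), integer())
  goal_key <- hanoi_key(`[[<-`(list(integer(), integer(), integer()), to,
                               rev(seq_len(n))))
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  assign(hanoi_key(start), TRUE, envir = seen)
  frontier <- list(start)
  depth <- 0L
  repeat {
    if (identical(hanoi_key(start), goal_key)) return(0L)
    depth <- depth + 1L
    nxt <- list()
    for (st in frontier) {
      for (i in 1:3) {
        li <- length(st[[i]])
        if (li == 0L) next
        disc <- st[[i]][li]
        for (j in 1:3) {
          if (j == i) next
          lj <- length(st[[j]])
          if (lj > 0L && st[[j]][lj] < disc) next  # no large on small
          s2 <- st
          s2[[i]] <- s2[[i]][-li]
          s2[[j]] <- c(s2[[j]], disc)
          k2 <- hanoi_key(s2)
          if (!is.null(seen[[k2]])) next
          if (identical(k2, goal_key)) return(depth)
          assign(k2, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- s2
        }
      }
    }
    if (!length(nxt)) stop("Hanoi goal unreachable (cannot happen)")
    frontier <- nxt
  }
}

hanoi_key <- function(st) {
  paste(vapply(st, paste, "", collapse = ","), collapse = "|")
}
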