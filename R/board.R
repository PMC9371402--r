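#' Board geometry for a Tower of London puzzle
#'
#' A Tower of London board is a row of pegs with fixed, possibly unequal
#' capacities, holding discs that are all the same size and distinguished
#' only by color. The classic board has one peg of height three and two pegs
#' of height two, which is the default here.
#'
#' @param capacities Integer vector of peg heights, left to right. At least
#'   two pegs, every capacity at least 1.
#' @param discs Character vector of distinct disc labels (colors). Its length
#'   is the number of discs; must not exceed the total board capacity.
#' @return An object of class `tol_board_spec`.
#' @examples
#' spec <- board_spec(c(3, 2, 2), c("red", "green", "blue"))
#' spec$n_discs
#' @export
board_spec <- function(capacities = c(3L, 2L, 2L),
                       discs = c("red", "green", "blue")) {
  capacities <- as.integer(capacities)
  discs <- as.character(discs)
  if (length(capacities) < 2L || anyNA(capacities) || any(capacities < 1L))
    stop("need at least 2 pegs, every capacity >= 1")
  if (length(discs) < 1L || anyDuplicated(discs))
    stop("disc labels must be non-empty and distinct")
  if (length(discs) > sum(capacities))
    stop("more discs than total board capacity")
  structure(
    list(capacities = capacities, discs = discs,
         n_pegs = length(capacities), n_discs = length(discs)),
    class = "tol_board_spec")
}

#' Construct and validate a board state
#'
#' @param pegs List of character vectors, one per peg, each giving the discs
#'   on that peg from bottom to top.
#' @param spec A [board_spec()].
#' @return An object of class `tol_board_state` (a list of peg stacks).
#' @examples
#' spec <- board_spec()
#' s <- board_state(list(c("red", "green", "blue"), character(), character()), spec)
#' @export
board_state <- function(pegs, spec) {
  stopifnot(inherits(spec, "tol_board_spec"))
  if (length(pegs) != spec$n_pegs)
    stop("state has ", length(pegs), " pegs; spec has ", spec$n_pegs)
  pegs <- lapply(pegs, as.character)
  st <- structure(pegs, class = "tol_board_state")
  validate_state(st, spec)
  st
}

#' Check board-state invariants
#'
#' Verifies that every disc of the spec appears exactly once and that no
#' stack exceeds its peg's capacity.
#'
#' @param state A `tol_board_state`.
#' @param spec The matching [board_spec()].
#' @return Invisibly `TRUE`; signals an error describing the first violation.
#' @export
validate_state <- function(state, spec) {
  if (length(state) != spec$n_pegs) stop("wrong number of pegs")
  lens <- lengths(state)
  over <- which(lens > spec$capacities)
  if (length(over))
    stop("peg ", over[1L], " holds ", lens[over[1L]], " discs; capacity ",
         spec$capacities[over[1L]])
  all_discs <- unlist(state, use.names = FALSE)
  if (length(all_discs) != spec$n_discs ||
      !setequal(all_discs, spec$discs) || anyDuplicated(all_discs))
    stop("discs on board do not match spec (duplicate or missing disc)")
  invisible(TRUE)
}

#' Canonical string key of a board state
#'
#' Pegs joined with `"|"`, discs within a peg (bottom to top) with `","`.
#' Used for hashing states during search and for JSON round-tripping.
#'
#' @param state A `tol_board_state`.
#' @return A single string.
#' @export
state_key <- function(state) {
  paste(vapply(state, paste, "", collapse = ","), collapse = "|")
}

#' @export
print.tol_board_state <- function(x, ...) {
  for (i in seq_along(x))
    cat(sprintf("peg %d: %s\n", i,
                if (length(x[[i]])) paste(x[[i]], collapse = " < ") else "-"))
  invisible(x)
}

#' @export
format.tol_board_state <- function(x, ...) state_key(x)

states_equal <- function(a, b) identical(state_key(a), state_key(b))

#' Legal moves from a board state
#'
#' A move takes the top disc of a non-empty source peg to a different peg
#' with free capacity. Only top discs can move, one disc at a time.
#'
#' @param state A valid `tol_board_state`.
#' @param spec The matching [board_spec()].
#' @return A data frame with integer columns `from` and `to` (1-based peg
#'   indices), one row per legal move. Zero rows if the state is frozen
#'   (cannot happen on a board with spare capacity).
#' @export
legal_moves <- function(state, spec) {
  validate_state(state, spec)
  lens <- lengths(state)
  from <- integer(0); to <- integer(0)
  for (i in which(lens > 0L)) {
    dest <- which(lens < spec$capacities)
    dest <- dest[dest != i]
    from <- c(from, rep.int(i, length(dest)))
    to <- c(to, dest)
  }
  data.frame(from = from, to = to)
}

#' Apply a single move to a board state
#'
#' @param state A valid `tol_board_state`.
#' @param from,to 1-based peg indices; `from != to`.
#' @param spec The matching [board_spec()].
#' @return The resulting `tol_board_state`.
#' @export
apply_move <- function(state, from, to, spec) {
  from <- as.integer(from); to <- as.integer(to)
  if (from == to) stop("illegal move: from and to pegs are identical")
  if (from < 1L || from > spec$n_pegs || to < 1L || to > spec$n_pegs)
    stop("illegal move: peg index out of range")
  if (length(state[[from]]) == 0L)
    stop("illegal move: source peg ", from, " is empty")
  if (length(state[[to]]) >= spec$capacities[to])
    stop("illegal move: destination peg ", to, " is full")
  n <- length(state[[from]])
  disc <- state[[from]][n]
  state[[from]] <- state[[from]][-n]
  state[[to]] <- c(state[[to]], disc)
  state
}

#' Enumerate all valid board states
#'
#' Generates every assignment of the distinct discs to peg stacks that
#' respects the peg capacities: for each feasible occupancy vector, every
#' ordering of the discs within the occupied slots is a distinct state
#' (discs differ only by color, so order within a stack matters).
#'
#' @param spec A [board_spec()].
#' @return A list of `tol_board_state` objects, no duplicates.
#' @export
enumerate_states <- function(spec) {
  occs <- occupancy_vectors(spec$n_discs, spec$capacities)
  perms <- permutations_of(spec$discs)
  out <- vector("list", nrow(occs) * nrow(perms))
  k <- 0L
  for (o in seq_len(nrow(occs))) {
    occ <- occs[o, ]
    ends <- cumsum(occ)
    starts <- ends - occ + 1L
    for (p in seq_len(nrow(perms))) {
      ordering <- perms[p, ]
      pegs <- vector("list", spec$n_pegs)
      for (g in seq_len(spec$n_pegs)) {
        pegs[[g]] <- if (occ[g] > 0L) ordering[starts[g]:ends[g]] else character()
      }
      k <- k + 1L
      out[[k]] <- structure(pegs, class = "tol_board_state")
    }
  }
  out
}

# all non-negative integer vectors summing to n with componentwise caps
occupancy_vectors <- function(n, caps) {
  grid <- expand.grid(lapply(caps, function(cp) 0:cp))
  m <- as.matrix(grid[rowSums(grid) == n, , drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L, 1L))
  sub <- permutations_of(x[-1L])
  out <- matrix(x[1L], nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], x[1L], after = pos - 1L)
    }
  }
  out
}

#' Minimal-move solve by breadth-first search
#'
#' Finds the minimum number of single-disc moves transforming `start` into
#' `goal`, together with one optimal move sequence.
#'
#' @param start,goal Valid `tol_board_state` objects.
#' @param spec The matching [board_spec()].
#' @return A list with elements `distance` (non-negative integer, or `NA` if
#'   the goal is unreachable), `path` (data frame of `from`/`to` moves of
#'   length `distance`), and `reachable` (logical).
#' @export
bfs_solve <- function(start, goal, spec) {
  validate_state(start, spec)
  validate_state(goal, spec)
  goal_key <- state_key(goal)
  start_key <- state_key(start)
  if (identical(start_key, goal_key))
    return(list(distance = 0L, path = data.frame(from = integer(), to = integer()),
                reachable = TRUE))
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  assign(start_key, TRUE, envir = seen)
  # frontier entries carry the state and the move list that produced it
  frontier <- list(list(state = start, moves = list()))
  depth <- 0L
  while (length(frontier)) {
    depth <- depth + 1L
    nxt <- list()
    for (node in frontier) {
      mv <- legal_moves(node$state, spec)
      for (r in seq_len(nrow(mv))) {
        s2 <- apply_move(node$state, mv$from[r], mv$to[r], spec)
        k2 <- state_key(s2)
        if (!is.null(seen[[k2]])) next
        moves2 <- c(node$moves, list(c(mv$from[r], mv$to[r])))
        if (identical(k2, goal_key)) {
          pm <- do.call(rbind, moves2)
          return(list(distance = depth,
                      path = data.frame(from = pm[, 1L], to = pm[, 2L]),
                      reachable = TRUE))
        }
        assign(k2, TRUE, envir = seen)
        nxt[[length(nxt) + 1L]] <- list(state = s2, moves = moves2)
      }
    }
    frontier <- nxt
  }
  list(distance = NA_integer_, path = NULL, reachable = FALSE)
}

.graph_cache <- new.env(parent = emptyenv())

#' Full state graph of a board
#'
#' Enumerates all states and precomputes the move adjacency list. Cached per
#' board geometry, since the engine and the bank generator solve on the same
#' small graphs repeatedly (36-state three-disc board, 192-state four-disc
#' board).
#'
#' @param spec A [board_spec()].
#' @return A list with `states` (list of `tol_board_state`), `keys`
#'   (canonical string per state), and `adj` (list of integer neighbor
#'   indices per state).
#' @export
state_graph <- function(spec) {
  cache_key <- paste(paste(spec$capacities, collapse = ","),
                     paste(spec$discs, collapse = ","), sep = ";")
  hit <- .graph_cache[[cache_key]]
  if (!is.null(hit)) return(hit)
  states <- enumerate_states(spec)
  keys <- vapply(states, state_key, "")
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(keys)) assign(keys[i], i, envir = idx)
  adj <- vector("list", length(states))
  for (i in seq_along(states)) {
    mv <- legal_moves(states[[i]], spec)
    nb <- integer(nrow(mv))
    for (r in seq_len(nrow(mv)))
      nb[r] <- idx[[state_key(apply_move(states[[i]], mv$from[r], mv$to[r], spec))]]
    adj[[i]] <- nb
  }
  g <- list(states = states, keys = keys, adj = adj)
  assign(cache_key, g, envir = .graph_cache)
  g
}

# single-source BFS over a precomputed adjacency list (NA = unreachable)
graph_distances <- function(graph, source) {
  d <- rep(NA_integer_, length(graph$adj))
  d[source] <- 0L
  queue <- source
  while (length(queue)) {
    nxt <- integer(0)
    for (i in queue) {
      for (j in graph$adj[[i]]) {
        if (is.na(d[j])) {
          d[j] <- d[i] + 1L
          nxt <- c(nxt, j)
        }
      }
    }
    queue <- nxt
  }
  d
}

#' Distribution of minimal distances over all ordered state pairs
#'
#' Runs breadth-first search from every state of the board and tabulates how
#' many ordered (start, goal) pairs lie at each minimal distance. The
#' diameter (largest finite distance) determines the hardest item a given
#' board geometry can supply: the graded-peg three-disc board tops out at
#' eight moves, which is why higher levels require the four-disc variant.
#'
#' @param spec A [board_spec()].
#' @return A list with `counts` (named integer vector, names are distances
#'   `0..diameter`), `diameter`, `n_states`, `connected`, and
#'   `component_sizes` when the graph is disconnected.
#' @export
distance_distribution <- function(spec) {
  g <- state_graph(spec)
  n <- length(g$states)
  counts <- integer(0)
  connected <- TRUE
  comp_sizes <- NULL
  dmax <- 0L
  for (i in seq_len(n)) {
    d <- graph_distances(g, i)
    if (anyNA(d)) {
      connected <- FALSE
      comp_sizes <- table(factor(is.na(d), c(FALSE, TRUE),
                                 c("reachable", "unreachable")))
    }
    dd <- d[!is.na(d)]
    tab <- tabulate(dd + 1L)
    if (length(tab) > length(counts))
      counts <- c(counts, integer(length(tab) - length(counts)))
    counts[seq_along(tab)] <- counts[seq_along(tab)] + tab
    dmax <- max(dmax, max(dd))
  }
  names(counts) <- as.character(seq_along(counts) - 1L)
  if (!connected)
    warning("state graph is disconnected; diameter covers reachable pairs only")
  list(counts = counts, diameter = dmax, n_states = n,
       connected = connected, component_sizes = comp_sizes)
}

#' All (start, goal) pairs at a given minimal distance
#'
#' Enumerates ordered pairs of states exactly `level` moves apart; the raw
#' material for item-bank construction.
#'
#' @param spec A [board_spec()].
#' @param level Target minimal distance (positive integer).
#' @return A list of `list(start =, goal =)` pairs (possibly empty).
#' @export
pairs_at_distance <- function(spec, level) {
  level <- as.integer(level)
  stopifnot(level >= 1L)
  g <- state_graph(spec)
  out <- list()
  for (i in seq_along(g$states)) {
    d <- graph_distances(g, i)
    hit <- which(!is.na(d) & d == level)
    for (j in hit)
      out[[length(out) + 1L]] <- list(start = g$states[[i]], goal = g$states[[j]])
  }
  out
}

#' Default Tower of London board geometries
#'
#' The three-disc task uses the classic graded-peg board (capacities 3, 2, 1:
#' 36 states, hardest problem 8 moves). The four-disc task uses the wider
#' board with one three-high and two two-high pegs (capacities 3, 2, 2:
#' 192 states, hardest problem 10 moves). Together the two arrangements
#' supply start/goal pairs at every difficulty level from 1 to 10 moves.
#'
#' @return A `tol_board_spec`.
#' @examples
#' distance_distribution(tol_board_d3())$diameter # 8
#' @export
tol_board_d3 <- function() board_spec(c(3L, 2L, 1L), c("red", "green", "blue"))

#' @rdname tol_board_d3
#' @export
tol_board_d4 <- function() {
  board_spec(c(3L, 2L, 2L), c("red", "green", "blue", "yellow"))
}

#' Board spec for an item variant label
#'
#' @param variant `"D3"` (three discs) or `"D4"` (four discs).
#' @return The corresponding [board_spec()].
#' @export
variant_spec <- function(variant) {
  switch(as.character(variant),
         D3 = tol_board_d3(),
         D4 = tol_board_d4(),
         stop("unknown variant: ", variant))
}
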