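# Abstract 4x4 navigation task: grid combinatorics, session generation,
# behavioural agent, and the novelty / tortuosity bookkeeping.

.checkCell <- function(cell, side) {
  if (length(cell) != 2L || any(cell < 0) || any(cell > side - 1L))
    stop("cell (", paste(cell, collapse = ","), ") is off the ", side, "x",
         side, " grid")
  invisible(as.integer(cell))
}

#' Manhattan distance between two grid cells
#'
#' The length of the shortest possible path on the 4-adjacent grid, i.e. the
#' number of button presses an optimal route needs.
#'
#' @param a,b integer vectors `c(row, col)`, 0-based.
#' @param side grid side; cells must lie on the grid.
#' @return integer number of steps.
#' @export
manhattanDistance <- function(a, b, side = 4L) {
  .checkCell(a, side); .checkCell(b, side)
  as.integer(abs(a[1] - b[1]) + abs(a[2] - b[2]))
}

#' Number of distinct shortest paths between two cells
#'
#' Shortest paths are exactly the monotone lattice paths interleaving
#' `|drow|` row steps and `|dcol|` column steps, so the count is
#' `choose(d, |drow|)` with `d` the Manhattan distance. Agrees with
#' exhaustive enumeration ([enumerateShortestPaths()]) for every pair.
#'
#' @inheritParams manhattanDistance
#' @return integer path count (1 when `a == b`: the empty path).
#' @export
countShortestPaths <- function(a, b, side = 4L) {
  d <- manhattanDistance(a, b, side)
  as.integer(choose(d, abs(a[1] - b[1])))
}

#' Exhaustively enumerate all shortest paths between two cells
#'
#' Depth-first enumeration of every monotone step ordering; the brute-force
#' counterpart of [countShortestPaths()]. Exponential in distance, intended
#' for validation at grid scale (d <= 6).
#'
#' @inheritParams manhattanDistance
#' @return list of paths, each an integer matrix with `(row, col)` rows from
#'   `a` to `b` inclusive.
#' @export
enumerateShortestPaths <- function(a, b, side = 4L) {
  .checkCell(a, side); .checkCell(b, side)
  out <- list()
  recurse <- function(cell, trail) {
    if (all(cell == b)) { out[[length(out) + 1L]] <<- trail; return(invisible()) }
    dr <- sign(b[1] - cell[1]); dc <- sign(b[2] - cell[2])
    if (dr != 0) {
      nxt <- cell + c(dr, 0)
      recurse(nxt, rbind(trail, nxt))
    }
    if (dc != 0) {
      nxt <- cell + c(0, dc)
      recurse(nxt, rbind(trail, nxt))
    }
  }
  recurse(a, matrix(a, 1L))
  out
}

.allCells <- function(side)
  as.matrix(expand.grid(row = 0:(side - 1L), col = 0:(side - 1L)))

#' Enumerate valid start-goal pairs and their shortest-path counts
#'
#' Lists every ordered pair of cells at Manhattan distance at least
#' `minDistance` (the task's goal-selection rule) together with the number
#' of distinct shortest paths joining each pair. On the default 4x4 grid
#' with `minDistance = 3` there are 124 ordered pairs carrying 592 shortest
#' paths in total.
#'
#' @param map a [GridMap-class] (or integer side).
#' @param minDistance minimum start-to-goal distance (task default 3).
#' @return data.frame with columns `start_row`, `start_col`, `goal_row`,
#'   `goal_col`, `distance`, `n_paths`; attributes `nPairs` and
#'   `totalPaths` hold the totals.
#' @export
enumerateValidPairs <- function(map = gridMap(), minDistance = 3L) {
  side <- if (is(map, "GridMap")) map@side else as.integer(map)
  stopifnot(minDistance >= 0L)
  cells <- .allCells(side)
  n <- nrow(cells)
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  d <- abs(cells[i, 1] - cells[j, 1]) + abs(cells[i, 2] - cells[j, 2])
  keep <- d >= minDistance
  out <- data.frame(
    start_row = cells[i[keep], 1], start_col = cells[i[keep], 2],
    goal_row = cells[j[keep], 1], goal_col = cells[j[keep], 2],
    distance = d[keep])
  out$n_paths <- as.integer(choose(out$distance,
                                   abs(out$start_row - out$goal_row)))
  attr(out, "nPairs") <- nrow(out)
  attr(out, "totalPaths") <- sum(out$n_paths)
  out
}

#' Generate a session skeleton (starts and goals only)
#'
#' Draws the trial sequence the task uses: the goal of every trial is chosen
#' uniformly at random from all cells at least `minDistance` steps from the
#' start, and the start of every trial is the previous trial's goal, except
#' at block boundaries where a fresh random start is drawn.
#'
#' @param map [GridMap-class] or integer side.
#' @param nTrials,nBlocks session size (task defaults 100 trials, 3 blocks).
#' @param minDistance goal-selection rule (default 3 steps).
#' @param seed integer; the draw is reproducible under it.
#' @return a [SessionLog-class] skeleton (no chosen paths yet).
#' @export
generateSession <- function(map = gridMap(), nTrials = 100L, nBlocks = 3L,
                            minDistance = 3L, seed = NULL) {
  side <- if (is(map, "GridMap")) map@side else as.integer(map)
  stopifnot(nTrials >= 1L, nBlocks >= 1L)
  cells <- .allCells(side)
  valid <- lapply(seq_len(nrow(cells)), function(i) {
    d <- abs(cells[, 1] - cells[i, 1]) + abs(cells[, 2] - cells[i, 2])
    which(d >= minDistance)
  })
  if (any(lengths(valid) == 0L))
    stop("some cells have no goal at distance >= ", minDistance)
  blocks <- sort(rep_len(seq_len(nBlocks), nTrials))
  withSeed(seed, {
    startIdx <- goalIdx <- integer(nTrials)
    for (t in seq_len(nTrials)) {
      startIdx[t] <- if (t == 1L || blocks[t] != blocks[t - 1L])
        sample.int(nrow(cells), 1L) else goalIdx[t - 1L]
      cand <- valid[[startIdx[t]]]
      goalIdx[t] <- cand[sample.int(length(cand), 1L)]
    }
    trials <- data.frame(
      trial_index = seq_len(nTrials), block = blocks,
      start_row = cells[startIdx, 1], start_col = cells[startIdx, 2],
      goal_row = cells[goalIdx, 1], goal_col = cells[goalIdx, 2])
    trials$shortest_distance <- abs(trials$start_row - trials$goal_row) +
      abs(trials$start_col - trials$goal_col)
    new("SessionLog", trials = trials, side = side, experienced = character())
  })
}

# Canonical key of an undirected transition between two adjacent cells.
.edgeKeys <- function(path) {
  a <- path[-nrow(path), , drop = FALSE]
  b <- path[-1, , drop = FALSE]
  ka <- paste(a[, 1], a[, 2], sep = ",")
  kb <- paste(b[, 1], b[, 2], sep = ",")
  ifelse(ka < kb, paste(ka, kb, sep = "|"), paste(kb, ka, sep = "|"))
}

#' Path tortuosity
#'
#' Total number of steps taken divided by the shortest possible path length;
#' equal to 1 for correct (optimal) trials and greater than 1 otherwise.
#'
#' @param path integer matrix of `(row, col)` cells visited, in order.
#' @param goal the trial's goal cell; the path must end there.
#' @param side grid side.
#' @return tortuosity ratio (>= 1).
#' @export
pathTortuosity <- function(path, goal = path[nrow(path), ], side = 4L) {
  stopifnot(nrow(path) >= 2L)
  step <- abs(diff(path[, 1])) + abs(diff(path[, 2]))
  if (any(step != 1L)) stop("path steps must be 4-adjacent single moves")
  if (!all(path[nrow(path), ] == goal)) stop("path does not reach the goal")
  d <- manhattanDistance(path[1, ], goal, side)
  (nrow(path) - 1L) / d
}

#' Classify a path as novel or familiar
#'
#' A path is novel when at least one of its transitions has not been
#' experienced before, in either direction; familiarity is the fraction of
#' its transitions previously experienced. `experienced` must reflect the
#' history before the trial only.
#'
#' @param path integer matrix of cells visited.
#' @param experienced character vector of undirected transition keys (as
#'   accumulated in a [SessionLog-class]).
#' @return list with `novel` (logical), `familiarity` (fraction in [0, 1]),
#'   and `keys` (this path's transition keys, for updating the history).
#' @export
classifyNovelty <- function(path, experienced = character()) {
  keys <- .edgeKeys(path)
  fam <- mean(keys %in% experienced)
  list(novel = fam < 1, familiarity = fam, keys = keys)
}

# Uniform draw over the shortest paths from a to b: a uniformly shuffled
# interleaving of the row and column steps.
.randomShortestPath <- function(a, b) {
  dr <- b[1] - a[1]; dc <- b[2] - a[2]
  moves <- c(rep(sign(dr), abs(dr)), rep(2L * sign(dc), abs(dc)))
  if (length(moves) > 1L) moves <- sample(moves)
  path <- matrix(0L, length(moves) + 1L, 2L)
  path[1, ] <- a
  for (k in seq_along(moves)) {
    step <- if (abs(moves[k]) == 1L) c(moves[k], 0L) else c(0L, moves[k] %/% 2L)
    path[k + 1L, ] <- path[k, ] + step
  }
  path
}

# Insert a single backtrack detour (step back to the previous cell and
# forward again) at a random position; adds exactly two steps.
.detourPath <- function(path) {
  k <- if (nrow(path) > 2L) sample(2:(nrow(path) - 1L), 1L) else 2L
  rbind(path[1:k, , drop = FALSE],
        path[k - 1L, , drop = FALSE],
        path[k:nrow(path), , drop = FALSE])
}

#' Walk a session with a stochastic agent
#'
#' Completes a session skeleton with chosen paths: with probability
#' `pCorrect` the agent walks a uniformly drawn shortest path, otherwise it
#' inserts a backtrack detour (tortuosity > 1). Fills in tortuosity,
#' correctness, novelty, familiarity, per-step times (log-normal) and the
#' running set of experienced transitions.
#'
#' @param session a [SessionLog-class] skeleton from [generateSession()].
#' @param pCorrect probability of taking a shortest path.
#' @param seed integer for reproducibility.
#' @param rtMeanLog,rtSdLog log-normal parameters of per-step times (s);
#'   plumbing only, no analysis depends on them.
#' @return the completed [SessionLog-class].
#' @export
simulateAgent <- function(session, pCorrect = 0.85, seed = NULL,
                          rtMeanLog = log(0.5), rtSdLog = 0.4) {
  stopifnot(is(session, "SessionLog"), pCorrect >= 0, pCorrect <= 1)
  tr <- session@trials
  withSeed(seed, {
    experienced <- character()
    paths <- character(nrow(tr))
    tort <- numeric(nrow(tr)); nov <- logical(nrow(tr)); fam <- numeric(nrow(tr))
    stepTimes <- character(nrow(tr)); nSteps <- integer(nrow(tr))
    for (t in seq_len(nrow(tr))) {
      a <- c(tr$start_row[t], tr$start_col[t])
      b <- c(tr$goal_row[t], tr$goal_col[t])
      p <- .randomShortestPath(a, b)
      if (stats::runif(1) > pCorrect) p <- .detourPath(p)
      cls <- classifyNovelty(p, experienced)
      experienced <- union(experienced, cls$keys)
      paths[t] <- paste(paste(p[, 1], p[, 2], sep = ","), collapse = ";")
      nSteps[t] <- nrow(p) - 1L
      tort[t] <- nSteps[t] / tr$shortest_distance[t]
      nov[t] <- cls$novel; fam[t] <- cls$familiarity
      stepTimes[t] <- paste(
        round(stats::rlnorm(nSteps[t], rtMeanLog, rtSdLog), 4), collapse = ";")
    }
    tr$path <- paths
    tr$n_steps <- nSteps
    tr$tortuosity <- tort
    tr$correct <- tort == 1
    tr$novel <- nov
    tr$familiarity <- fam
    tr$step_times <- stepTimes
    new("SessionLog", trials = tr, side = session@side, experienced = experienced)
  })
}

#' Parse a serialized path string back into a cell matrix
#'
#' @param pathString semicolon-joined "row,col" cells as stored in a
#'   SessionLog / session CSV.
#' @return integer matrix of cells.
#' @export
parsePath <- function(pathString) {
  cells <- strsplit(strsplit(pathString, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  matrix(as.integer(unlist(cells)), ncol = 2L, byrow = TRUE)
}

#' Read and write session logs as CSV
#'
#' Columns: trial_index, block, start_row, start_col, goal_row, goal_col,
#' path (semicolon-joined "row,col" cells), shortest_distance, tortuosity,
#' correct, novel, familiarity, step_times.
#'
#' @param session a walked [SessionLog-class].
#' @param file path to a CSV file.
#' @param side grid side (stored as a comment-free extra column on write).
#' @return `readSessionLog` returns a [SessionLog-class].
#' @export
writeSessionLog <- function(session, file) {
  tr <- session@trials
  tr$side <- session@side
  utils::write.csv(tr, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSessionLog
#' @export
readSessionLog <- function(file, side = NULL) {
  tr <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (is.null(side)) side <- if ("side" %in% names(tr)) tr$side[1] else 4L
  tr$side <- NULL
  experienced <- character()
  if ("path" %in% names(tr))
    for (p in tr$path) experienced <- union(experienced, .edgeKeys(parsePath(p)))
  new("SessionLog", trials = tr, side = as.integer(side),
      experienced = experienced)
}
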