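# Grid combinatorics, session generation, the behavioural agent, and the
# novelty / tortuosity bookkeeping.

test_that("Manhattan distance follows the 4-adjacent metric and rejects off-grid cells", {
  expect_identical(manhattanDistance(c(0, 0), c(3, 3)), 6L)
  expect_identical(manhattanDistance(c(1, 1), c(1, 1)), 0L)
  expect_identical(manhattanDistance(c(0, 1), c(2, 2)), 3L)
  expect_error(manhattanDistance(c(0, 4), c(1, 1)), "off the")
  expect_error(manhattanDistance(c(-1, 0), c(1, 1)), "off the")
})

test_that("shortest-path counts equal brute-force enumeration for every ordered pair", {
  cells <- gridCells(4)
  for (i in seq_len(nrow(cells))) for (j in seq_len(nrow(cells))) {
    a <- cells[i, ]; b <- cells[j, ]
    cnt <- countShortestPaths(a, b)
    expect_identical(cnt, oracleCountPaths(a, b))
    expect_identical(cnt, length(enumerateShortestPaths(a, b)))
  }
  # spec's spot values
  expect_identical(countShortestPaths(c(0, 0), c(0, 3)), 1L)
  expect_identical(countShortestPaths(c(0, 0), c(1, 2)), 3L)
  expect_identical(countShortestPaths(c(0, 0), c(3, 3)), 20L)
})

test_that("enumerated paths are valid, distinct, and end at the goal", {
  paths <- enumerateShortestPaths(c(1, 0), c(3, 2))
  expect_length(paths, 6L)
  keys <- vapply(paths, function(p) paste(t(p), collapse = ";"), "")
  expect_false(anyDuplicated(keys) > 0)
  for (p in paths) {
    expect_equal(p[1, ], c(1, 0), ignore_attr = TRUE)
    expect_equal(p[nrow(p), ], c(3, 2), ignore_attr = TRUE)
    expect_true(all(abs(diff(p[, 1])) + abs(diff(p[, 2])) == 1))
  }
})

test_that("valid start-goal pairs on the task grid match the exhaustive totals", {
  vp <- enumerateValidPairs(4, minDistance = 3)
  expect_identical(attr(vp, "nPairs"), 124L)
  expect_identical(attr(vp, "totalPaths"), 592L)
  expect_true(all(vp$distance >= 3))
  # degenerate grids
  expect_identical(nrow(enumerateValidPairs(2, minDistance = 3)), 0L)
  expect_identical(attr(enumerateValidPairs(4, minDistance = 0), "nPairs"), 256L)
})

test_that("pair totals are invariant under grid rotation of the labelling", {
  vp <- enumerateValidPairs(4, minDistance = 3)
  rot <- function(r, c) cbind(c, 3 - r)   # 90-degree rotation
  key <- function(sr, sc, gr, gc) paste(sr, sc, gr, gc)
  s2 <- rot(vp$start_row, vp$start_col); g2 <- rot(vp$goal_row, vp$goal_col)
  orig <- setNames(vp$n_paths, key(vp$start_row, vp$start_col,
                                   vp$goal_row, vp$goal_col))
  expect_identical(unname(orig[key(s2[, 1], s2[, 2], g2[, 1], g2[, 2])]),
                   vp$n_paths)
})

test_that("generated sessions obey the distance rule, chaining, and determinism", {
  s1 <- generateSession(nTrials = 90, nBlocks = 3, seed = 7)
  s2 <- generateSession(nTrials = 90, nBlocks = 3, seed = 7)
  expect_identical(sessionTrials(s1), sessionTrials(s2))
  tr <- sessionTrials(s1)
  expect_true(all(tr$shortest_distance %in% 3:6))
  # start chaining holds within blocks (validity also enforces it)
  inBlock <- tr$block[-1] == tr$block[-nrow(tr)]
  expect_true(all(tr$start_row[-1][inBlock] == tr$goal_row[-nrow(tr)][inBlock]))
  expect_true(validObject(s1))
})

test_that("goal selection is uniform over valid cells", {
  s <- generateSession(nTrials = 10000, nBlocks = 1, seed = 21)
  tr <- sessionTrials(s)
  # condition on one start cell; its valid goal set has a known size
  sel <- tr$start_row == 0 & tr$start_col == 0
  goals <- paste(tr$goal_row[sel], tr$goal_col[sel])
  valid <- gridCells(4)
  valid <- valid[abs(valid[, 1]) + abs(valid[, 2]) >= 3, ]
  expect_identical(sort(unique(goals)), sort(paste(valid[, 1], valid[, 2])))
  p <- suppressWarnings(stats::chisq.test(table(goals))$p.value)
  expect_gt(p, 1e-3)
})

test_that("long-run distance distribution matches the goal-selection chain's stationary law", {
  side <- 4; cells <- gridCells(side)
  d <- as.matrix(dist(cells, method = "manhattan"))
  P <- (d >= 3) / rowSums(d >= 3)
  ev <- eigen(t(P))
  pi0 <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi0 <- pi0 / sum(pi0)
  expected <- vapply(3:6, function(k) {
    sum(pi0 * rowSums(d == k) / rowSums(d >= 3))
  }, numeric(1))
  s <- generateSession(nTrials = 20000, nBlocks = 1, seed = 31)
  emp <- as.numeric(table(factor(sessionTrials(s)$shortest_distance, 3:6))) / 20000
  expect_lt(max(abs(emp - expected)), 0.015)
})

test_that("the agent is optimal exactly when told to be, with calibrated accuracy in between", {
  s <- generateSession(nTrials = 60, seed = 3)
  all1 <- simulateAgent(s, pCorrect = 1, seed = 4)
  expect_true(all(sessionTrials(all1)$tortuosity == 1))
  expect_true(all(sessionTrials(all1)$correct))
  all0 <- simulateAgent(s, pCorrect = 0, seed = 5)
  expect_true(all(sessionTrials(all0)$tortuosity > 1))
  big <- simulateAgent(generateSession(nTrials = 1000, seed = 6),
                       pCorrect = 0.85, seed = 7)
  frac <- mean(sessionTrials(big)$correct)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.85) / 1000
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
  # every chosen path is valid and terminates at the goal
  tr <- sessionTrials(big)
  for (t in sample(nrow(tr), 50)) {
    p <- parsePath(tr$path[t])
    expect_true(all(abs(diff(p[, 1])) + abs(diff(p[, 2])) == 1))
    expect_equal(p[nrow(p), ], c(tr$goal_row[t], tr$goal_col[t]),
                 ignore_attr = TRUE)
  }
})

test_that("tortuosity is steps over shortest distance and validates the path", {
  p3 <- rbind(c(0, 0), c(0, 1), c(0, 2), c(0, 3))
  expect_equal(pathTortuosity(p3, c(0, 3)), 1)
  p6 <- rbind(c(0, 0), c(1, 0), c(0, 0), c(0, 1), c(0, 2), c(0, 3), c(1, 3))
  expect_error(pathTortuosity(p6, c(0, 3)), "reach the goal")
  p6ok <- rbind(c(0, 0), c(1, 0), c(0, 0), c(0, 1), c(0, 2), c(1, 2), c(0, 2), c(0, 3))
  expect_equal(pathTortuosity(p6ok, c(0, 3)), 7 / 3)
  p5 <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(2, 2), c(3, 2))
  expect_equal(pathTortuosity(p5, c(3, 2)), 1)
})

test_that("novelty matches transitions in either direction and familiarity is the experienced fraction", {
  p <- rbind(c(0, 0), c(0, 1), c(0, 2), c(0, 3))
  first <- classifyNovelty(p, character())
  expect_true(first$novel); expect_equal(first$familiarity, 0)
  # exact reverse retrace is fully familiar
  rev <- classifyNovelty(p[4:1, ], first$keys)
  expect_false(rev$novel); expect_equal(rev$familiarity, 1)
  # 4-step path with 3 previously walked transitions
  p4 <- rbind(c(0, 0), c(0, 1), c(0, 2), c(0, 3), c(1, 3))
  part <- classifyNovelty(p4, first$keys)
  expect_true(part$novel); expect_equal(part$familiarity, 0.75)
})

test_that("novelty is monotone in the experienced history", {
  set.seed(11)
  hist1 <- classifyNovelty(rbind(c(1, 1), c(1, 2), c(2, 2)), character())$keys
  for (i in 1:20) {
    a <- gridCells(4)[sample(16, 1), ]
    b <- gridCells(4)[sample(16, 1), ]
    if (all(a == b)) next
    moves <- c(rep(sign(b[1] - a[1]), abs(b[1] - a[1])) * 1,
               rep(sign(b[2] - a[2]) * 2, abs(b[2] - a[2])))
    p <- matrix(a, 1); cur <- a
    for (mv in sample(moves)) {
      cur <- cur + if (abs(mv) == 1) c(mv, 0) else c(0, mv / 2)
      p <- rbind(p, cur)
    }
    r1 <- classifyNovelty(p, hist1)
    r2 <- classifyNovelty(p, union(hist1, classifyNovelty(p, character())$keys))
    if (!r1$novel) expect_false(r2$novel)
    expect_gte(r2$familiarity, r1$familiarity)
  }
})

test_that("session logs round-trip through CSV", {
  s <- simulateAgent(generateSession(nTrials = 25, seed = 9), seed = 10)
  f <- tempfile(fileext = ".csv")
  writeSessionLog(s, f)
  s2 <- readSessionLog(f)
  expect_equal(sessionTrials(s2), sessionTrials(s), tolerance = 1e-12)
  expect_setequal(s2@experienced, s@experienced)
  unlink(f)
})
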