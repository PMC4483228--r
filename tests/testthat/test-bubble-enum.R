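test_that("compatible-pair existence follows the two-tree criterion", {
  g <- weightedDigraph(c("s1", "s2"), c("t", "t"))
  expect_true(existsCompatiblePair(g, vid(g, "s1"), vid(g, "s2"), 1, 1))
  expect_false(existsCompatiblePair(g, vid(g, "s1"), vid(g, "s2"), 1, 0.5))
  expect_error(existsCompatiblePair(g, 1, 1, 1, 1), "differ")

  dbg <- fig1DBG()
  tgg <- vid(dbg, "TGG"); tgc <- vid(dbg, "TGC")
  expect_true(existsCompatiblePair(dbg, tgg, tgc, 4, 1))
  expect_false(existsCompatiblePair(dbg, tgg, tgc, 3, 1))
})

test_that("bubble existence from a source is decided correctly", {
  dbg <- fig1DBG()
  expect_true(existsBubbleFrom(dbg, vid(dbg, "CTG"), 5, 2))
  expect_false(existsBubbleFrom(dbg, vid(dbg, "ACT"), 5, 2))
  dia <- diamondGraph()
  expect_true(existsBubbleFrom(dia, vid(dia, "s"), 2, 2))
  expect_false(existsBubbleFrom(dia, vid(dia, "s"), 2, 1))
  # a two-cycle offers no bubble even though s has a successor loop
  cyc <- weightedDigraph(c(1, 2), c(2, 1))
  expect_false(existsBubbleFrom(cyc, 1, 10, 10))
  # agreement with the enumerator across random graphs
  for (seed in 1:20) {
    g <- randomDigraph(7, 0.35, seed = seed + 300)
    for (s in 1:7)
      expect_equal(existsBubbleFrom(g, s, 6, 6),
                   length(enumerateBubbles(g, s, 6, 6)) > 0)
  }
})

test_that("extension feasibility answers every out-neighbor from two trees", {
  dbg <- fig1DBG()
  tgc <- vid(dbg, "TGC"); tgg <- vid(dbg, "TGG")
  f <- extensionFeasibility(dbg, tgc, tgg, remU = 1, remOther = 4)
  expect_identical(f, stats::setNames(TRUE, as.character(vid(dbg, "GCG"))))
  # tighter budget on the extension side flips the answer
  f0 <- extensionFeasibility(dbg, tgc, tgg, remU = 0.5, remOther = 4)
  expect_false(f0[[1]])
  # no out-arcs: empty mapping
  expect_length(extensionFeasibility(dbg, vid(dbg, "GCG"), tgg, 3, 3), 0L)
  expect_error(extensionFeasibility(dbg, tgc, tgc, 1, 1), "differ")
  # cross-check against the pairwise test on random graphs
  for (seed in 1:15) {
    g <- randomDigraph(7, 0.4, seed = seed + 700)
    e <- g@data
    u <- 1 + seed %% 7; other <- 1 + (seed + 3) %% 7
    if (u == other) next
    f <- extensionFeasibility(g, u, other, 5, 5)
    heads <- as.integer(names(f))
    pushCheckpoint(g)
    removeVertex(g, u)
    for (i in seq_along(f)) {
      if (heads[i] == other) next   # immediate meeting, not a pair query
      a <- which(e$from == u & e$to == heads[i])
      expect_equal(f[[i]],
                   existsCompatiblePair(g, other, heads[i], 5, 5 - e$w[a]))
    }
    restoreCheckpoint(g)
  }
})

test_that("the worked DBG yields exactly the one known bubble", {
  g <- fig1DBG()
  s <- vid(g, "CTG")
  bs <- expect_state_preserved(g, enumerateBubbles(g, s, 5, 2))
  expect_length(bs, 1L)
  b <- bs[[1]]
  expect_equal(vertexLabels(g)[b@t], "GCG")
  expect_equal(vertexLabels(g)[b@path1],
               c("CTG", "TGG", "GGA", "GAG", "AGC", "GCG"))
  expect_equal(vertexLabels(g)[b@path2], c("CTG", "TGC", "GCG"))
  expect_equal(b@len1, 5)
  expect_equal(b@len2, 2)
  expect_length(b@path2, 3L)  # one internal vertex on the junction path
  # the length lower bound filters it out
  expect_length(enumerateBubbles(g, s, 5, 2, beta = 3), 0L)
  # a branch-free graph has nothing to enumerate
  path <- weightedDigraph(1:4, 2:5)
  expect_length(enumerateBubbles(path, 1, 10, 10), 0L)
})

test_that("enumeration equals the brute-force oracle on random digraphs", {
  settings <- list(c(6, 6, 0), c(8, 4, 0), c(6, 6, 2), c(10, 10, 0))
  for (seed in 1:60) {
    g <- randomDigraph(4 + seed %% 7, 0.3, seed = seed + 1000)
    cfg <- settings[[1 + seed %% 4]]
    for (s in seq_len(4 + seed %% 7)) {
      fast <- enumerateBubbles(g, s, cfg[1], cfg[2], beta = cfg[3])
      slow <- bruteForceBubbles(g, s, cfg[1], cfg[2], beta = cfg[3])
      expect_identical(bubbleKeys(fast), bubbleKeys(slow))
      expect_false(anyDuplicated(bubbleKeys(fast)) > 0)
    }
  }
})

test_that("bubble sets are monotone in the bounds and in beta", {
  for (seed in 1:15) {
    g <- randomDigraph(8, 0.3, seed = seed + 2000)
    for (s in c(1, 4, 7)) {
      small <- bubbleKeys(enumerateBubbles(g, s, 4, 4))
      large <- bubbleKeys(enumerateBubbles(g, s, 7, 7))
      expect_true(all(small %in% large))
      filt <- bubbleKeys(enumerateBubbles(g, s, 7, 7, beta = 3))
      expect_true(all(filt %in% large))
    }
  }
})

test_that("every emitted bubble satisfies the definition invariants", {
  for (seed in 1:10) {
    g <- randomDigraph(8, 0.35, seed = seed + 3000)
    arcs <- arcTable(g)
    arcW <- stats::setNames(arcs$weight, paste(arcs$from, arcs$to))
    pathLen <- function(p) {
      w <- arcW[paste(p[-length(p)], p[-1])]
      if (anyNA(w)) NA_real_ else sum(w)   # NA = a claimed arc is missing
    }
    ok <- TRUE
    for (s in 1:8) {
      bs <- enumerateBubbles(g, s, 7, 7)
      for (b in bs@bubbles) {
        ok <- ok && isTRUE(validObject(b, test = TRUE)) &&
          b@len1 <= 7 && b@len2 <= 7 &&
          isTRUE(pathLen(b@path1) == b@len1) &&
          isTRUE(pathLen(b@path2) == b@len2)
      }
    }
    expect_true(ok)
  }
})

test_that("stop conditions fire and are reported without corrupting state", {
  g <- nCorridors(6)              # choose(6, 2) = 15 bubbles from the source
  full <- enumerateBubbles(g, 1, 10, 10)
  expect_length(full, 15L)
  expect_equal(full@status, "complete")

  capped <- expect_state_preserved(g, enumerateBubbles(g, 1, 10, 10,
                                                       maxBubbles = 4))
  expect_length(capped, 4L)
  expect_equal(capped@status, "max_bubbles")
  expect_true(all(bubbleKeys(capped@bubbles) %in% bubbleKeys(full)))

  big <- nCorridors(40)
  timed <- expect_state_preserved(big, enumerateBubbles(big, 1, 10, 10,
                                                        timeout = 0))
  expect_equal(timed@status, "timeout")
  expect_lt(length(timed), choose(40, 2))
})

test_that("recursion instrumentation respects the polynomial-delay accounting", {
  for (seed in 1:25) {
    n <- 5 + seed %% 6
    g <- randomDigraph(n, 0.35, seed = seed + 4000)
    for (s in seq_len(n)) {
      bs <- enumerateBubbles(g, s, 7, 7)
      st <- bs@stats
      # every leaf is accounted for: reported, or dropped by exactly one
      # output filter; beta = 0 never filters
      expect_equal(st$leaves, st$emitted + st$droppedOrientation)
      expect_equal(st$droppedBeta, 0L)
      if (st$leaves > 0) expect_lte(st$maxGap, 4 * n)
    }
  }
})

test_that("all-source enumeration unions per-source output", {
  dia <- diamondGraph()
  expect_length(enumerateAllSources(dia, 2, 2), 1L)
  g <- fig1DBG()
  expect_length(enumerateAllSources(g, 5, 2), 1L)
  empty <- weightedDigraph(integer(0), integer(0), numeric(0), nVertices = 3)
  expect_length(enumerateAllSources(empty, 5, 5), 0L)
})
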