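test_that("the split network has the expected size and structure", {
  dia <- diamondGraph()
  net <- splitTransform(dia, vid(dia, "s"), vid(dia, "t"))
  expect_length(net@from, 4L + 4L)           # m + n arcs
  expect_equal(max(c(net@from, net@to)), 8L) # 2n nodes
  expect_error(splitTransform(dia, 1, 1), "differ")
  noArcs <- weightedDigraph(integer(0), integer(0), numeric(0), nVertices = 3)
  net2 <- splitTransform(noArcs, 1, 2)
  expect_length(net2@from, 3L)               # only the internal vertex arcs
})

test_that("max-flow counts internally disjoint paths (Menger)", {
  dia <- diamondGraph()
  s <- vid(dia, "s"); t <- vid(dia, "t")
  r2 <- maxDisjointPaths(dia, s, t, 2)
  expect_equal(r2$count, 2L)
  expect_length(r2$paths, 2L)
  expect_equal(maxDisjointPaths(dia, s, t, 3)$count, 2L)
  # no s -> t path at all
  expect_equal(maxDisjointPaths(dia, t, s, 2)$count, 0L)
  # three corridors admit three pairwise internally disjoint paths
  tc <- threeCorridors()
  r3 <- maxDisjointPaths(tc, 1, 8, 3)
  expect_equal(r3$count, 3L)
  for (i in 2:3) for (j in seq_len(i - 1))
    expect_identical(intersect(r3$paths[[i]], r3$paths[[j]]), c(1L, 8L))
})

test_that("achieved flow equals the brute-force disjoint-path maximum", {
  for (seed in 1:40) {
    n <- 4 + seed %% 4
    g <- randomDigraph(n, 0.35, seed = seed + 5000)
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t) next
      r <- maxDisjointPaths(g, s, t, n)
      expect_equal(r$count, bruteForceDisjointPaths(g, s, t)$max)
      # returned paths actually verify pairwise internal disjointness
      if (r$count >= 2)
        expect_true(validObject(new("DBubble", s = as.integer(s),
                                    t = as.integer(t), paths = r$paths),
                                test = TRUE))
    }
  }
})

test_that("an independent max-flow implementation confirms the counts", {
  for (seed in 1:10) {
    g <- randomDigraph(6, 0.4, seed = seed + 6000)
    net <- splitTransform(g, 1, 6)
    ig <- igraph::graph_from_edgelist(cbind(net@from, net@to))
    ref <- igraph::max_flow(ig, source = igraph::V(ig)[1 + 6],
                            target = igraph::V(ig)[6],
                            capacity = net@cap)$value
    expect_equal(maxDisjointPaths(g, 1, 6, 12)$count, as.integer(ref))
  }
})

test_that("compatible-set feasibility handles multiplicity and t-members", {
  dia <- diamondGraph()
  t <- vid(dia, "t")
  expect_true(existsCompatibleSet(dia, t, t))                    # S = {t}
  expect_true(existsCompatibleSet(dia, c(vid(dia, "a"), vid(dia, "b")), t))
  # two paths from a single out-degree-1 vertex must collide
  chain <- weightedDigraph(c(1, 2), c(2, 3))
  expect_false(existsCompatibleSet(chain, c(1L, 1L), 3L))
  # but a vertex with two disjoint routes supports multiplicity 2
  dia2 <- diamondGraph()
  expect_true(existsCompatibleSet(dia2, rep(vid(dia2, "s"), 2), vid(dia2, "t")))
  expect_error(existsCompatibleSet(dia, integer(0), t), "at least one")
})

test_that("d-bubble enumeration equals brute-force family enumeration", {
  tc <- threeCorridors()
  expect_length(enumerateDBubbles(tc, 1, 8, 2), 3L)
  expect_length(enumerateDBubbles(tc, 1, 8, 3), 1L)
  dia <- diamondGraph()
  expect_length(enumerateDBubbles(dia, vid(dia, "s"), vid(dia, "t"), 2), 1L)
  # graphs whose disjoint-path maximum is below d yield nothing
  chain <- weightedDigraph(c(1, 2), c(2, 3))
  expect_length(enumerateDBubbles(chain, 1, 3, 2), 0L)

  for (seed in 1:20) {
    n <- 5 + seed %% 4
    g <- randomDigraph(n, 0.4, seed = seed + 7000)
    for (d in 2:3) {
      fast <- enumerateDBubbles(g, 1, n, d)
      slow <- bruteForceDisjointPaths(g, 1, n, d = d)$families
      expect_identical(dbubbleKeys(fast), dbubbleKeys(slow))
      for (b in fast) expect_true(validObject(b, test = TRUE))
    }
  }
})

test_that("d-bubble enumeration restores its input graph", {
  g <- randomDigraph(7, 0.45, seed = 8100)
  expect_state_preserved(g, enumerateDBubbles(g, 1, 7, 2))
})

test_that("length-constrained d-bubbles are refused at the API", {
  tc <- threeCorridors()
  expect_error(enumerateDBubbles(tc, 1, 8, 2, lengthBounds = c(4, 4)),
               "NP-hard")
})
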