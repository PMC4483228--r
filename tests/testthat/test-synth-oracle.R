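test_that("random digraphs are simple, sized as expected, and seed-stable", {
  expect_equal(numArcs(randomDigraph(5, 0, seed = 1)), 0L)
  expect_equal(numArcs(randomDigraph(4, 1, seed = 1)), 12L)   # n(n-1)
  g1 <- randomDigraph(9, 0.4, seed = 77)
  g2 <- randomDigraph(9, 0.4, seed = 77)
  expect_true(digraphIdentical(g1, g2))
  expect_false(digraphIdentical(g1, randomDigraph(9, 0.4, seed = 78)))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(randomDigraph(5, 0.5, seed = 3)); b <- runif(1)
  expect_identical(a, b)
  w <- arcTable(randomDigraph(8, 0.6, weightRange = c(2, 5), seed = 5))$weight
  expect_true(all(w %in% 2:5))
})

test_that("planted events satisfy the flank and k-mer-disjointness contract", {
  for (seed in 1:15) {
    ev <- plantASEvent(k = 5, seed = seed)
    expect_equal(ev$seq1, paste0(ev$a, ev$w, ev$b))
    expect_equal(ev$seq2, paste0(ev$a, ev$wp, ev$b))
    expect_gte(nchar(ev$a), ev$k)
    expect_gte(nchar(ev$b), ev$k)
    # w and w' share no k-mer
    kmerize <- function(s, k) if (nchar(s) < k) character(0) else
      substring(s, seq_len(nchar(s) - k + 1), seq_len(nchar(s) - k + 1) + k - 1)
    expect_length(intersect(kmerize(ev$w, 5), kmerize(ev$wp, 5)), 0L)
    expect_equal(ev$sKmer, substring(ev$a, nchar(ev$a) - 4))
    expect_equal(ev$tKmer, substring(ev$b, 1, 5))
  }
  expect_error(plantASEvent(k = 5, aLen = 3), ">= k")
  expect_error(plantASEvent(k = 5, wLen = 0, wpLen = 0), "empty")
})

test_that("planted events are recovered as bubbles between the predicted k-mers", {
  for (seed in 1:20) {
    wp <- if (seed %% 2) 3 else 0
    ev <- plantASEvent(k = 5, wpLen = wp, seed = seed + 100)
    dbg <- buildDBG(countKmers(c(ev$seq1, ev$seq2), ev$k, minCount = 1))
    s <- vid(dbg, ev$sKmer); t <- vid(dbg, ev$tKmer)
    expect_false(anyNA(c(s, t)))
    bs <- enumerateBubbles(dbg, s, 25, 25)
    hits <- Filter(function(b) b@t == t, bs@bubbles)
    expect_gte(length(hits), 1L)
    if (wp == 0) {
      shortest <- min(vapply(hits, function(b)
        min(length(b@path1), length(b@path2)), 1L))
      expect_lte(shortest - 2L, ev$k - 1L)   # junction-path vertex bound
    }
  }
})

test_that("the Hamiltonian stress instance couples beta to Hamiltonicity", {
  # construction arithmetic: |V| = 3 gives 3 + 2 + 3 = 8 vertices
  base <- weightedDigraph(c(1, 2), c(2, 3))
  h <- hamiltonianReductionInstance(base, 1, 3)
  expect_equal(numVertices(h$graph), 8L)
  expect_equal(numArcs(h$graph), 2L + 3L + 3L)

  # 1 -> 2 -> 3 is Hamiltonian: the filtered enumeration finds the witness
  bs <- enumerateBubbles(h$graph, h$source, h$alpha, h$alpha, beta = h$beta)
  expect_length(bs, 1L)
  expect_equal(bs[[1]]@len1, bs[[1]]@len2)

  # a star from 1 has no Hamiltonian 1 -> 3 path
  star <- weightedDigraph(c(1, 1), c(2, 3))
  h2 <- hamiltonianReductionInstance(star, 1, 3)
  expect_length(enumerateBubbles(h2$graph, h2$source, h2$alpha, h2$alpha,
                                 beta = h2$beta), 0L)

  # randomized agreement with an exhaustive Hamiltonian-path search
  hamExists <- function(g, s, t) {
    e <- g@data
    n <- numVertices(g)
    found <- FALSE
    walk <- function(v, seen) {
      if (found) return(invisible(NULL))
      if (length(seen) == n) { if (v == t) found <<- TRUE; return(invisible(NULL)) }
      for (a in DBGbubbles:::.aliveOutArcs(e, FALSE, v)) {
        x <- e$to[a]
        if (!x %in% seen) walk(x, c(seen, x))
      }
    }
    walk(s, s)
    found
  }
  for (seed in 1:12) {
    g <- randomDigraph(5, 0.35, weightRange = c(1, 1), seed = seed + 8000)
    h <- hamiltonianReductionInstance(g, 1, 5)
    got <- length(enumerateBubbles(h$graph, h$source, h$alpha, h$alpha,
                                   beta = h$beta)) > 0
    expect_equal(got, hamExists(g, 1, 5))
  }
})

test_that("the brute-force bubble oracle reproduces known answers", {
  g <- fig1DBG()
  bs <- bruteForceBubbles(g, vid(g, "CTG"), 5, 2)
  expect_length(bs, 1L)
  expect_equal(vertexLabels(g)[bs[[1]]@path2], c("CTG", "TGC", "GCG"))
  expect_length(bruteForceBubbles(diamondGraph(), 1, 5, 5), 1L)
  expect_length(bruteForceBubbles(diamondGraph(), 1, 5, 5, beta = 10), 0L)
  big <- randomDigraph(15, 0.2, seed = 1)
  expect_error(bruteForceBubbles(big, 1, 5, 5), "too large")
})

test_that("the brute-force disjoint-path oracle reproduces known answers", {
  r <- bruteForceDisjointPaths(diamondGraph(), 1, 4)
  expect_equal(r$max, 2L)
  tc <- threeCorridors()
  r3 <- bruteForceDisjointPaths(tc, 1, 8, d = 2)
  expect_equal(r3$max, 3L)
  expect_length(r3$families, 3L)
  disc <- weightedDigraph(1, 2, nVertices = 3)
  expect_equal(bruteForceDisjointPaths(disc, 1, 3)$max, 0L)
})
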