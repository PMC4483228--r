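# Fixture builders and comparison helpers shared across the suite.
# Everything is generated in code; no data files.

fig1Sequences <- c("ACTGGAGCG", "ACTGCG")

fig1DBG <- function()
  buildDBG(countKmers(fig1Sequences, k = 3, minCount = 1))

vid <- function(g, lab) match(lab, vertexLabels(g))

# s -> {a, b} -> t
diamondGraph <- function()
  weightedDigraph(c("s", "s", "a", "b"), c("a", "b", "t", "t"))

# three parallel length-2 corridors from 1 to 8
threeCorridors <- function()
  weightedDigraph(c(1, 1, 1, 2, 3, 4, 5, 6, 7),
                  c(2, 3, 4, 5, 6, 7, 8, 8, 8))

nCorridors <- function(m) {
  mids <- 1L + seq_len(m)
  weightedDigraph(c(rep(1L, m), mids), c(mids, rep(m + 2L, m)))
}

bubbleKeys <- function(bs) {
  bubbles <- if (is(bs, "BubbleSet")) bs@bubbles else bs
  sort(vapply(bubbles, function(b)
    paste(b@s, paste(b@path1, collapse = ","),
          paste(b@path2, collapse = ","), sep = "|"), ""))
}

dbubbleKeys <- function(fams) {
  sort(vapply(fams, function(f) {
    paths <- if (is(f, "DBubble")) f@paths else f
    paste(sort(vapply(paths, paste, "", collapse = ",")), collapse = "|")
  }, ""))
}

expect_state_preserved <- function(g, expr) {
  before <- cloneDigraph(g)
  force(expr)
  expect_true(digraphIdentical(g, before))
  invisible(expr)
}

# independent Bellman-Ford distances (oracle for the Dijkstra variants);
# deliberately written against the arc table, not the package internals
bellmanFordDist <- function(g, s, n = length(g@data$aliveV)) {
  arcs <- arcTable(g)
  dist <- rep(Inf, n)
  dist[s] <- 0
  for (it in seq_len(n + 1L)) {
    nd <- pmin(dist, Inf)
    for (i in seq_len(nrow(arcs)))
      nd[arcs$to[i]] <- min(nd[arcs$to[i]], dist[arcs$from[i]] + arcs$weight[i])
    if (identical(nd, dist)) break
    dist <- nd
  }
  dist
}
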