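test_that("k-mer counting slides windows with the abundance filter", {
  t1 <- countKmers(fig1Sequences, k = 3, minCount = 1)
  expect_setequal(names(t1@counts),
                  c("ACT", "CTG", "TGG", "GGA", "GAG", "AGC", "GCG", "TGC"))
  t2 <- countKmers(fig1Sequences, k = 3, minCount = 2)
  expect_setequal(names(t2@counts), c("ACT", "CTG", "GCG"))
  # k longer than every sequence: empty table, not an error
  expect_length(countKmers(c("ACGT"), k = 9, minCount = 1)@counts, 0L)
  # windows containing N are skipped
  tn <- countKmers("ACTNGGA", k = 3, minCount = 1)
  expect_setequal(names(tn@counts), c("ACT", "GGA"))
  expect_error(countKmers("ACXT", k = 3), "outside ACGTN")
})

test_that("DBG arcs are exactly the (k-1)-overlaps among retained k-mers", {
  g <- fig1DBG()
  expect_equal(numVertices(g), 8L)
  expect_equal(numArcs(g), 8L)
  arcs <- arcTable(g, useLabels = TRUE)
  expected <- rbind(c("ACT", "CTG"), c("CTG", "TGG"), c("CTG", "TGC"),
                    c("TGG", "GGA"), c("GGA", "GAG"), c("GAG", "AGC"),
                    c("AGC", "GCG"), c("TGC", "GCG"))
  expect_setequal(paste(arcs$from, arcs$to), paste(expected[, 1], expected[, 2]))
  expect_true(all(arcs$weight == 1))

  # single k-mer, and the self-loop rule
  one <- buildDBG(countKmers("ACG", 3, 1))
  expect_equal(numVertices(one), 1L)
  expect_equal(numArcs(one), 0L)
  loop <- buildDBG(countKmers("AAA", 3, 1))
  expect_equal(numVertices(loop), 1L)
  expect_equal(numArcs(loop), 0L)
})

test_that("arc rule totality holds on random k-mer tables", {
  set.seed(11)
  for (rep in 1:10) {
    seqs <- vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""), "")
    tab <- countKmers(seqs, k = 4, minCount = 1)
    g <- buildDBG(tab)
    kmers <- vertexLabels(g)
    arcs <- arcTable(g)
    suf <- substring(kmers, 2)
    pre <- substring(kmers, 1, 3)
    pairs <- expand.grid(u = seq_along(kmers), v = seq_along(kmers))
    pairs <- pairs[pairs$u != pairs$v, ]
    shouldExist <- pairs[suf[pairs$u] == pre[pairs$v], ]
    expect_setequal(paste(arcs$from, arcs$to),
                    paste(shouldExist$u, shouldExist$v))
  }
})

test_that("linear-path compression merges unitigs losslessly", {
  cd <- compressDBG(fig1DBG(), 3)
  g <- cd@graph
  expect_setequal(vertexLabels(g), c("ACTG", "TGGAGC", "TGC", "GCG"))
  arcs <- arcTable(g, useLabels = TRUE)
  expect_setequal(paste(arcs$from, arcs$to, arcs$weight),
                  c("ACTG TGGAGC 4", "ACTG TGC 1", "TGGAGC GCG 1", "TGC GCG 1"))
  # the two compressed paths preserve the uncompressed arc counts 5 and 2
  s <- vid(g, "ACTG")
  d <- spDistances(dijkstraTruncated(g, s))
  expect_equal(d[vid(g, "GCG")], 2)
  bs <- enumerateBubbles(g, s, 5, 2)
  expect_length(bs, 1L)
  expect_equal(sort(c(bs[[1]]@len1, bs[[1]]@len2)), c(2, 5))

  # a simple directed path of 5 k-mers collapses to one vertex
  path5 <- buildDBG(countKmers("ACTGGTAC", 4, 1))
  expect_equal(numVertices(path5), 5L)
  c5 <- compressDBG(path5, 4)
  expect_equal(numVertices(c5@graph), 1L)
  expect_equal(numArcs(c5@graph), 0L)
  expect_equal(vertexLabels(c5@graph), "ACTGGTAC")
})

test_that("compression preserves all pairwise path lengths on random input", {
  set.seed(5)
  for (rep in 1:8) {
    seqs <- vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""), "")
    tab <- countKmers(seqs, k = 4, minCount = 1)
    g <- buildDBG(tab)
    cd <- compressDBG(g, 4)
    cg <- cd@graph
    # the last k-mer of each unitig label marks the chain's exit vertex;
    # distances between exits must match the uncompressed unit-arc counts
    labs <- vertexLabels(cg)
    ends <- substring(labs, nchar(labs) - 3L)
    endIds <- match(ends, vertexLabels(g))
    expect_false(anyNA(endIds))
    got <- want <- numeric(0)
    for (x in seq_along(labs)) {
      dc <- spDistances(dijkstraTruncated(cg, x))
      du <- spDistances(dijkstraTruncated(g, endIds[x]))
      got <- c(got, dc[-x])
      want <- c(want, du[endIds[-x]])
    }
    expect_identical(got, want)
  }
})

test_that("BCC decomposition is lossless for bubbles and drops small parts", {
  # diamond: one 4-vertex component, retained
  bc <- bccDecompose(diamondGraph(), 4)
  expect_length(bc, 1L)
  expect_length(bc[[1]]$vertices, 4L)

  # a directed path: five 2-vertex components, all discarded
  expect_length(bccDecompose(weightedDigraph(1:5, 2:6), 4), 0L)

  # the worked DBG splits into a 7-vertex cycle component and a discarded
  # 2-vertex bridge
  g <- fig1DBG()
  bc <- bccDecompose(g, 4)
  expect_length(bc, 1L)
  expect_setequal(vertexLabels(g)[bc[[1]]$vertices],
                  c("CTG", "TGG", "GGA", "GAG", "AGC", "GCG", "TGC"))
  expect_length(bccDecompose(g, 1), 2L)

  # bubble preservation: whole-graph enumeration equals the union over
  # components (minVertices = 1 makes the comparison exact)
  for (seed in 1:12) {
    g <- randomDigraph(8, 0.3, seed = seed + 500)
    whole <- enumerateAllSources(g, 6, 6)
    per <- enumerateAllSources(g, 6, 6, bccs = bccDecompose(g, 1))
    expect_identical(bubbleKeys(whole), bubbleKeys(per))
  }
})
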