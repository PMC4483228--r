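## Polynomial-delay enumeration of (s,t,alpha1,alpha2)-bubbles for a fixed
## source, by binary partition of the space of pairs of compatible paths.
##
## A state of the recursion is a pair of partial paths with endpoints
## (s1, s2) and remaining budgets (rem1, rem2); the interiors of both
## prefixes are removed from the working graph.  While the second endpoint
## still has out-arcs, the solution space is partitioned into: the pairs
## whose next second-path arc is (s2, v), one class per out-neighbor v
## (recursed with s2 removed, so the prefix interior stays protected); and
## the pairs using none of them, i.e. those where the second path stops at
## s2 (recursed with the out-neighborhood of s2 removed).  Every class is
## certified non-empty before recursing -- the include classes through one
## shortest-path-tree + reverse-sink-distance computation shared by all
## out-neighbors, the exclusion class through a two-tree compatible-pair
## test -- so every leaf of the recursion yields exactly one bubble and the
## number of nodes visited between two leaves stays linear in n.

## two-truncated-tree emptiness test for a pair of compatible paths
.existsPair <- function(e, rev, s1, s2, a1, a2, heap) {
  d1 <- .dijkstra(e, rev, s1, a1, heap)$dist
  d2 <- .dijkstra(e, rev, s2, a2, heap)$dist
  any(!is.na(d1) & !is.na(d2))
}

#' Test for a pair of compatible paths
#'
#' A pair of compatible paths for endpoints (s1, s2) and budgets
#' (alpha1, alpha2) is two internally vertex-disjoint paths from s1 and s2
#' to a common end vertex, with lengths within the respective budgets
#' (either path may be empty, its start then being the common end).  Such a
#' pair exists iff some vertex t satisfies d(s1,t) <= alpha1 and
#' d(s2,t) <= alpha2: shortening two within-budget paths at their first
#' common vertex makes them internally disjoint without increasing either
#' length.  Implemented as two truncated Dijkstra trees and a reached-set
#' intersection test.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param s1,s2 distinct alive vertex ids.
#' @param alpha1,alpha2 non-negative budgets.
#' @param heap priority-queue variant (see \code{\link{dijkstraTruncated}}).
#' @return logical.
#' @export
existsCompatiblePair <- function(g, s1, s2, alpha1, alpha2,
                                 heap = "bin-no-dec") {
  e <- g@data
  s1 <- .checkVertex(e, s1); s2 <- .checkVertex(e, s2)
  if (s1 == s2) stop("s1 and s2 must differ (the root case is handled by ",
                     "enumerateBubbles)")
  .existsPair(e, g@reversed, s1, s2, alpha1, alpha2, heap)
}

#' Feasibility of every one-arc extension
#'
#' For each out-neighbor v of \code{u}, decides whether a pair of compatible
#' paths for (\code{other}, v) with budgets (\code{remOther},
#' \code{remU} - w(u,v)) exists in the graph minus \code{u}.  All answers
#' come from one truncated shortest-path tree rooted at \code{other} plus
#' one reverse multi-source tree towards its reached set, so the whole
#' neighborhood costs two Dijkstra runs rather than two per neighbor.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param u alive vertex about to be extended past.
#' @param other the other path endpoint (alive, different from \code{u}).
#' @param remU,remOther remaining budgets.
#' @param heap priority-queue variant.
#' @return named logical vector over the out-neighbors of \code{u} (empty
#'   if \code{u} has none).
#' @export
extensionFeasibility <- function(g, u, other, remU, remOther,
                                 heap = "bin-no-dec") {
  e <- g@data; rev <- g@reversed
  u <- .checkVertex(e, u); other <- .checkVertex(e, other)
  if (u == other) stop("'u' and 'other' must differ")
  outs <- .aliveOutArcs(e, rev, u)
  if (!length(outs))
    return(stats::setNames(logical(0), character(0)))
  pushCheckpoint(g)
  removeVertex(g, u)
  dOther <- .dijkstra(e, rev, other, remOther, heap)$dist
  V <- which(!is.na(dOther))
  dr <- if (length(V)) .reverseDistFull(e, rev, V, heap)
        else rep(NA_real_, e$nV)
  restoreCheckpoint(g)
  heads <- vapply(outs, function(a) .arcHead(e, rev, a), 1L)
  ok <- !is.na(dr[heads]) & dr[heads] <= remU - e$w[outs]
  stats::setNames(as.logical(ok), heads)
}

#' Does any bubble start at s?
#'
#' Decides whether at least one (s,t,alpha1,alpha2)-bubble exists for some
#' t, i.e. whether the enumeration from \code{s} would output anything.
#' The test iterates over ordered pairs of distinct out-arcs of \code{s}
#' (the two first arcs of a bubble are necessarily distinct) and checks the
#' corresponding compatible-pair subproblem in the graph minus \code{s},
#' sharing the shortest-path trees across the pairs with a common
#' second-path arc.
#'
#' @inheritParams existsCompatiblePair
#' @param s alive source vertex.
#' @return logical.
#' @export
existsBubbleFrom <- function(g, s, alpha1, alpha2, heap = "bin-no-dec") {
  e <- g@data; rev <- g@reversed
  s <- .checkVertex(e, s)
  outs <- .aliveOutArcs(e, rev, s)
  if (length(outs) < 2L) return(FALSE)
  heads <- vapply(outs, function(a) .arcHead(e, rev, a), 1L)
  found <- FALSE
  pushCheckpoint(g)
  removeVertex(g, s)
  for (i in seq_along(outs)) {
    rem2 <- alpha2 - e$w[outs[i]]
    if (rem2 < 0) next
    d2 <- .dijkstra(e, rev, heads[i], rem2, heap)$dist
    V <- which(!is.na(d2))
    if (!length(V)) next
    dr <- .reverseDistFull(e, rev, V, heap)
    for (j in seq_along(outs)) {
      if (j == i) next
      rem1 <- alpha1 - e$w[outs[j]]
      if (rem1 < 0) next
      if (!is.na(dr[heads[j]]) && dr[heads[j]] <= rem1) {
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  restoreCheckpoint(g)
  found
}

## ---- the recursion -------------------------------------------------------

.emitLeaf <- function(E, t, path1, path2, len1, len2) {
  st <- E$st
  st$visits <- st$visits + 1L          # the singleton class is a leaf node
  gap <- st$visits - st$lastLeafVisit
  if (gap > st$maxGap) st$maxGap <- gap
  st$lastLeafVisit <- st$visits
  st$leaves <- st$leaves + 1L
  ## unordered-pair canonicalization: a bubble valid under both role
  ## assignments is reported only with the smaller first-arc head as p1
  if (len1 <= E$alpha2 && len2 <= E$alpha1 && path1[2L] > path2[2L]) {
    st$dropOrient <- st$dropOrient + 1L
    return()
  }
  if (len1 < E$beta || len2 < E$beta) {          # lower-bound output filter
    st$dropBeta <- st$dropBeta + 1L
    return()
  }
  b <- new("Bubble", s = E$s, t = as.integer(t),
           path1 = as.integer(path1), path2 = as.integer(path2),
           len1 = len1, len2 = len2)
  st$nb <- st$nb + 1L
  if (st$nb > length(st$bubbles))
    st$bubbles <- c(st$bubbles, vector("list", length(st$bubbles)))
  st$bubbles[[st$nb]] <- b
  if (st$nb >= E$maxBubbles) {
    st$status <- "max_bubbles"
    st$stop <- TRUE
  }
}

.enumRec <- function(E, s1, s2, rem1, rem2, p1, p2) {
  st <- E$st
  if (st$stop) return(invisible(NULL))
  st$visits <- st$visits + 1L
  if (proc.time()[[3L]] - st$t0 > E$timeout) {
    st$status <- "timeout"; st$stop <- TRUE
    return(invisible(NULL))
  }
  e <- E$e; rev <- E$rev; g <- E$g
  outs <- .aliveOutArcs(e, rev, s2)
  if (length(outs)) {
    side2 <- TRUE
    u <- s2; other <- s1; remU <- rem2; remOther <- rem1
  } else {
    side2 <- FALSE
    u <- s1; other <- s2; remU <- rem1; remOther <- rem2
    outs <- .aliveOutArcs(e, rev, s1)
    if (!length(outs)) return(invisible(NULL))   # cannot happen if certified
  }
  ## shared feasibility structure for all one-arc extensions of u, in G - u
  pushCheckpoint(g)
  removeVertex(g, u)
  dOther <- .dijkstra(e, rev, other, remOther, E$heap)$dist
  V <- which(!is.na(dOther))
  dr <- if (length(V)) .reverseDistFull(e, rev, V, E$heap) else NULL
  restoreCheckpoint(g)
  for (a in outs) {
    if (st$stop) break
    v <- .arcHead(e, rev, a)
    rb <- remU - e$w[a]
    if (rb < 0) next
    if (v == other) {
      ## the class of pairs whose next arc is (u, other) is the singleton
      ## where both paths end at t = other
      if (side2)
        .emitLeaf(E, v, p1, c(p2, v), E$alpha1 - rem1, E$alpha2 - rb)
      else
        .emitLeaf(E, v, c(p1, v), p2, E$alpha1 - rb, E$alpha2 - rem2)
    } else if (!is.null(dr) && !is.na(dr[v]) && dr[v] <= rb) {
      pushCheckpoint(g)
      removeVertex(g, u)
      if (side2) .enumRec(E, s1, v, rem1, rb, p1, c(p2, v))
      else .enumRec(E, v, s2, rb, rem2, c(p1, v), p2)
      restoreCheckpoint(g)
    }
  }
  if (st$stop) return(invisible(NULL))
  ## exclusion class: the path at u stops here; certified by a
  ## compatible-pair test in the graph minus the out-neighborhood of u
  pushCheckpoint(g)
  if (removeOutArcs(g, u) > 0L &&
      .existsPair(e, rev, s1, s2, rem1, rem2, E$heap))
    .enumRec(E, s1, s2, rem1, rem2, p1, p2)
  restoreCheckpoint(g)
  invisible(NULL)
}

#' Enumerate all (s,t,alpha1,alpha2)-bubbles from a source
#'
#' Emits every bubble rooted at \code{s} whose first path has length at most
#' \code{alpha1} and second path at most \code{alpha2} (lengths are sums of
#' arc weights), each exactly once as an unordered pair of paths.  The
#' enumeration is a binary partition over pairs of compatible paths; every
#' recursive subspace is certified non-empty with truncated shortest-path
#' trees before it is entered, which bounds the work between two successive
#' outputs by a polynomial of the graph size (polynomial delay).
#'
#' The lower bound \code{beta} is applied as an output filter, exactly as in
#' practical splicing-event callers: bubbles with a path shorter than
#' \code{beta} are computed but not reported.  Pruning on \code{beta}
#' \emph{inside} the recursion would void the delay guarantee, since
#' deciding existence under the lower bound is NP-hard.
#'
#' Two stop conditions mirror practical usage: a cap on the number of
#' reported bubbles (graphs with vastly more are dominated by repeats) and
#' a wall-clock timeout.  Hitting either sets the \code{status} of the
#' returned \code{\linkS4class{BubbleSet}}; the graph is always restored to
#' its input state.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param s source vertex id (alive).
#' @param alpha1,alpha2 non-negative path-length bounds (by convention
#'   \code{alpha1 >= alpha2}; any non-negative pair is accepted).
#' @param beta minimum length required of both paths (output filter;
#'   default 0).
#' @param maxBubbles stop after this many reported bubbles (default 10000).
#' @param timeout wall-clock limit in seconds (default 900).
#' @param heap priority-queue variant for all internal Dijkstra runs.
#' @return a \code{\linkS4class{BubbleSet}}.
#' @examples
#' dbg <- buildDBG(countKmers(c("ACTGGAGCG", "ACTGCG"), k = 3, minCount = 1))
#' s <- match("CTG", vertexLabels(dbg))
#' bs <- enumerateBubbles(dbg, s, alpha1 = 5, alpha2 = 2)
#' bubbleTable(bs, labels = vertexLabels(dbg))
#' @export
enumerateBubbles <- function(g, s, alpha1, alpha2, beta = 0,
                             maxBubbles = 10000, timeout = 900,
                             heap = c("bin-no-dec", "bin", "radix")) {
  heap <- match.arg(heap)
  e <- g@data; rev <- g@reversed
  s <- .checkVertex(e, s)
  if (alpha1 < 0 || alpha2 < 0) stop("alpha bounds must be non-negative")
  if (beta < 0) stop("beta must be non-negative")
  if (maxBubbles < 1) stop("maxBubbles must be >= 1")

  st <- new.env(parent = emptyenv())
  st$bubbles <- vector("list", 64L)
  st$nb <- 0L; st$visits <- 0L; st$lastLeafVisit <- 0L
  st$maxGap <- 0L; st$leaves <- 0L
  st$dropOrient <- 0L; st$dropBeta <- 0L
  st$stop <- FALSE; st$status <- "complete"
  st$t0 <- proc.time()[[3L]]
  E <- list2env(list(g = g, e = e, rev = rev, heap = heap, st = st,
                     s = s, alpha1 = alpha1, alpha2 = alpha2, beta = beta,
                     maxBubbles = as.integer(maxBubbles), timeout = timeout),
                parent = emptyenv())

  st$visits <- 1L                       # root node
  outs <- .aliveOutArcs(e, rev, s)
  if (length(outs) >= 2L) {
    heads <- vapply(outs, function(a) .arcHead(e, rev, a), 1L)
    pushCheckpoint(g)
    removeVertex(g, s)
    ## root case: s1 = s2 = s cannot enter the generic recursion (removing
    ## s would destroy both paths), so branch over ordered pairs of
    ## distinct first arcs, sharing trees across a common second-path arc
    for (i in seq_along(outs)) {
      if (st$stop) break
      rem2 <- alpha2 - e$w[outs[i]]
      if (rem2 < 0) next
      d2 <- .dijkstra(e, rev, heads[i], rem2, heap)$dist
      V <- which(!is.na(d2))
      if (!length(V)) next
      dr <- .reverseDistFull(e, rev, V, heap)
      for (j in seq_along(outs)) {
        if (st$stop) break
        if (j == i) next
        rem1 <- alpha1 - e$w[outs[j]]
        if (rem1 < 0) next
        if (is.na(dr[heads[j]]) || dr[heads[j]] > rem1) next
        .enumRec(E, heads[j], heads[i], rem1, rem2,
                 c(s, heads[j]), c(s, heads[i]))
      }
    }
    restoreCheckpoint(g)
  }
  new("BubbleSet",
      bubbles = st$bubbles[seq_len(st$nb)],
      status = st$status,
      stats = list(nodeVisits = st$visits, leaves = st$leaves,
                   maxGap = st$maxGap, emitted = st$nb,
                   droppedOrientation = st$dropOrient,
                   droppedBeta = st$dropBeta, n = e$nV))
}

#' Enumerate bubbles from every source
#'
#' Union of \code{\link{enumerateBubbles}} over all alive vertices, or over
#' each biconnected component when a decomposition from
#' \code{\link{bccDecompose}} is supplied (every bubble lies entirely inside
#' one component, so per-component enumeration is lossless and cheaper).
#' Output is deduplicated on the canonical path pair.
#'
#' @inheritParams enumerateBubbles
#' @param bccs optional list from \code{\link{bccDecompose}}.
#' @return a \code{\linkS4class{BubbleSet}}; \code{status} is
#'   \code{"complete"} only if every per-source run completed.
#' @export
enumerateAllSources <- function(g, alpha1, alpha2, beta = 0,
                                maxBubbles = 10000, timeout = 900,
                                heap = "bin-no-dec", bccs = NULL) {
  collect <- list(); status <- "complete"
  maxGap <- 0L; visits <- 0L; leaves <- 0L
  dropOrient <- 0L; dropBeta <- 0L
  seen <- character(0)
  addAll <- function(bs, map = NULL) {
    for (b in bs@bubbles) {
      if (!is.null(map))
        b <- new("Bubble", s = map[b@s], t = map[b@t],
                 path1 = map[b@path1], path2 = map[b@path2],
                 len1 = b@len1, len2 = b@len2)
      key <- .bubbleKey(b)
      if (key %in% seen) next
      seen <<- c(seen, key)
      collect[[length(collect) + 1L]] <<- b
    }
    if (bs@status != "complete") status <<- bs@status
    maxGap <<- max(maxGap, bs@stats$maxGap)
    visits <<- visits + bs@stats$nodeVisits
    leaves <<- leaves + bs@stats$leaves
    dropOrient <<- dropOrient + bs@stats$droppedOrientation
    dropBeta <<- dropBeta + bs@stats$droppedBeta
  }
  if (is.null(bccs)) {
    for (s in sort(aliveVertices(g)))
      addAll(enumerateBubbles(g, s, alpha1, alpha2, beta,
                              maxBubbles, timeout, heap))
  } else {
    for (comp in bccs) {
      map <- comp$vertices
      for (s in seq_along(map))
        addAll(enumerateBubbles(comp$graph, s, alpha1, alpha2, beta,
                                maxBubbles, timeout, heap), map = map)
    }
  }
  new("BubbleSet", bubbles = collect, status = status,
      stats = list(nodeVisits = visits, leaves = leaves, maxGap = maxGap,
                   emitted = length(collect), droppedOrientation = dropOrient,
                   droppedBeta = dropBeta, n = g@data$nV))
}
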