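## Truncated single-source shortest paths (Dijkstra) with pluggable priority
## queues, plus the auxiliary-sink reverse-distance construction that lets
## the enumeration answer "can this out-neighbor still reach a meeting
## point within budget?" in O(1) per neighbor.

.HEAPS <- c("bin-no-dec", "bin", "radix")

## Core Dijkstra on the raw environment.  `sources` all start at distance 0;
## expansion stops at distance `alpha` (truncation).  Ties are broken by
## ascending vertex id: the comparison key is lexicographic (dist, id), so
## every heap variant settles vertices in the same deterministic order.
.dijkstra <- function(e, rev, sources, alpha = Inf, heap = "bin-no-dec") {
  n <- e$nV
  dist <- rep(NA_real_, n)
  parent <- rep(NA_integer_, n)
  settled <- logical(n)
  dist[sources] <- 0

  if (heap == "radix") {
    wAlive <- e$w[e$aliveA]
    if (any(wAlive != floor(wAlive)))
      stop("the radix heap requires non-negative integer weights")
    maxD <- if (is.finite(alpha)) floor(alpha) else sum(wAlive)
    buckets <- vector("list", maxD + 1L)
    for (s in sources) buckets[[1L]] <- c(buckets[[1L]], s)
    d <- 0L
    while (d <= maxD) {
      b <- buckets[[d + 1L]]
      if (!length(b)) { d <- d + 1L; next }
      v <- min(b)
      buckets[[d + 1L]] <- b[-which.min(b)]
      if (settled[v] || is.na(dist[v]) || dist[v] != d) next
      settled[v] <- TRUE
      for (a in .outArcIds(e, rev, v)) {
        if (!e$aliveA[a]) next
        u <- if (rev) e$from[a] else e$to[a]
        if (!e$aliveV[u] || settled[u]) next
        nd <- d + e$w[a]
        if (nd > alpha) next
        if (is.na(dist[u]) || nd < dist[u]) {
          dist[u] <- nd
          parent[u] <- a
          buckets[[nd + 1L]] <- c(buckets[[nd + 1L]], u)
        }
      }
    }
    return(list(dist = dist, parent = parent))
  }

  if (heap == "bin") {
    ## binary heap with decrease-key: pos[] tracks each vertex's slot
    cap <- max(8L, length(sources))
    hv <- integer(cap); hk <- numeric(cap); hn <- 0L
    pos <- integer(n)
    less <- function(i, j)
      hk[i] < hk[j] || (hk[i] == hk[j] && hv[i] < hv[j])
    swap <- function(i, j) {
      tv <- hv[i]; hv[i] <<- hv[j]; hv[j] <<- tv
      tk <- hk[i]; hk[i] <<- hk[j]; hk[j] <<- tk
      pos[hv[i]] <<- i; pos[hv[j]] <<- j
    }
    siftUp <- function(i) {
      while (i > 1L) {
        p <- i %/% 2L
        if (less(i, p)) { swap(i, p); i <- p } else break
      }
    }
    siftDown <- function(i) {
      repeat {
        l <- 2L * i; r <- l + 1L; m <- i
        if (l <= hn && less(l, m)) m <- l
        if (r <= hn && less(r, m)) m <- r
        if (m == i) break
        swap(i, m); i <- m
      }
    }
    pushOrDecrease <- function(v, key) {
      if (pos[v] > 0L) {
        i <- pos[v]; hk[i] <<- key; siftUp(i)
      } else {
        hn <<- hn + 1L
        if (hn > length(hv)) {
          hv <<- c(hv, integer(length(hv))); hk <<- c(hk, numeric(length(hk)))
        }
        hv[hn] <<- v; hk[hn] <<- key; pos[v] <<- hn
        siftUp(hn)
      }
    }
    for (s in sort(sources)) pushOrDecrease(s, 0)
    while (hn > 0L) {
      u <- hv[1L]
      swap(1L, hn); hn <- hn - 1L; pos[u] <- 0L
      if (hn > 0L) siftDown(1L)
      if (settled[u]) next
      settled[u] <- TRUE
      du <- dist[u]
      for (a in .outArcIds(e, rev, u)) {
        if (!e$aliveA[a]) next
        v <- if (rev) e$from[a] else e$to[a]
        if (!e$aliveV[v] || settled[v]) next
        nd <- du + e$w[a]
        if (nd > alpha) next
        if (is.na(dist[v]) || nd < dist[v]) {
          dist[v] <- nd
          parent[v] <- a
          pushOrDecrease(v, nd)
        }
      }
    }
    return(list(dist = dist, parent = parent))
  }

  ## default: binary heap without decrease-key (lazy duplicates)
  cap <- max(8L, length(sources))
  hv <- integer(cap); hk <- numeric(cap); hn <- 0L
  push <- function(v, key) {
    hn <<- hn + 1L
    if (hn > length(hv)) {
      hv <<- c(hv, integer(length(hv))); hk <<- c(hk, numeric(length(hk)))
    }
    i <- hn; hv[i] <<- v; hk[i] <<- key
    while (i > 1L) {
      p <- i %/% 2L
      if (hk[i] < hk[p] || (hk[i] == hk[p] && hv[i] < hv[p])) {
        tv <- hv[i]; hv[i] <<- hv[p]; hv[p] <<- tv
        tk <- hk[i]; hk[i] <<- hk[p]; hk[p] <<- tk
        i <- p
      } else break
    }
  }
  pop <- function() {
    v <- hv[1L]
    hv[1L] <<- hv[hn]; hk[1L] <<- hk[hn]; hn <<- hn - 1L
    i <- 1L
    while (TRUE) {
      l <- 2L * i; r <- l + 1L; m <- i
      if (l <= hn && (hk[l] < hk[m] || (hk[l] == hk[m] && hv[l] < hv[m])))
        m <- l
      if (r <= hn && (hk[r] < hk[m] || (hk[r] == hk[m] && hv[r] < hv[m])))
        m <- r
      if (m == i) break
      tv <- hv[i]; hv[i] <<- hv[m]; hv[m] <<- tv
      tk <- hk[i]; hk[i] <<- hk[m]; hk[m] <<- tk
      i <- m
    }
    v
  }
  for (s in sort(sources)) push(s, 0)
  while (hn > 0L) {
    u <- pop()
    if (settled[u]) next
    settled[u] <- TRUE
    du <- dist[u]
    for (a in .outArcIds(e, rev, u)) {
      if (!e$aliveA[a]) next
      v <- if (rev) e$from[a] else e$to[a]
      if (!e$aliveV[v] || settled[v]) next
      nd <- du + e$w[a]
      if (nd > alpha) next
      if (is.na(dist[v]) || nd < dist[v]) {
        dist[v] <- nd
        parent[v] <- a
        push(v, nd)
      }
    }
  }
  list(dist = dist, parent = parent)
}

#' ShortestPathTree: a truncated Dijkstra result
#'
#' @slot root the source vertex id(s).
#' @slot dist numeric vector over all vertex ids; \code{NA} for vertices not
#'   reached within the truncation bound.
#' @slot parent integer arc id leading into each reached non-root vertex.
#' @slot alpha the truncation bound: only vertices at distance <= alpha are
#'   expanded.
#' @slot heap which priority-queue variant produced the tree.
#' @export
setClass("ShortestPathTree",
         representation(root = "integer", dist = "numeric",
                        parent = "integer", alpha = "numeric",
                        heap = "character"))

setMethod("show", "ShortestPathTree", function(object) {
  cat(sprintf(
    "ShortestPathTree from %s: %d vertices within alpha = %s (%s heap)\n",
    paste(object@root, collapse = ","), length(reachedSet(object)),
    format(object@alpha), object@heap))
})

#' @describeIn dijkstraTruncated distances of a tree (NA = unreached).
#' @param tree a \code{ShortestPathTree}.
#' @export
spDistances <- function(tree) tree@dist

#' @describeIn dijkstraTruncated ids of the vertices within the bound.
#' @export
reachedSet <- function(tree) which(!is.na(tree@dist))

#' Truncated Dijkstra shortest-path tree
#'
#' Computes shortest-path distances from \code{s}, expanding only vertices
#' at distance at most \code{alpha}.  All heap variants return identical
#' distances; they differ only in the priority-queue mechanics:
#' \describe{
#'   \item{bin-no-dec}{binary heap without decrease-key (lazy duplicate
#'     entries); the default, empirically fastest on sparse compressed de
#'     Bruijn graphs.}
#'   \item{bin}{binary heap with decrease-key.}
#'   \item{radix}{monotone integer bucket queue (single-level radix
#'     structure); requires integer weights, with key bound equal to the
#'     truncation bound.}
#' }
#' Ties are resolved by ascending vertex id, so results are deterministic.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param s source vertex id (alive).
#' @param alpha truncation bound (default \code{Inf} = no truncation).
#' @param heap one of \code{"bin-no-dec"}, \code{"bin"}, \code{"radix"}.
#' @return a \code{\linkS4class{ShortestPathTree}}.
#' @export
dijkstraTruncated <- function(g, s, alpha = Inf,
                              heap = c("bin-no-dec", "bin", "radix")) {
  heap <- match.arg(heap)
  e <- g@data
  s <- .checkVertex(e, s)
  if (alpha < 0) stop("alpha must be non-negative")
  r <- .dijkstra(e, g@reversed, s, alpha, heap)
  new("ShortestPathTree", root = s, dist = r$dist, parent = r$parent,
      alpha = as.numeric(alpha), heap = heap)
}

#' Remove arcs heavier than the path bound
#'
#' An arc with weight greater than \code{alpha1} cannot lie on either path
#' of any (s,t,alpha1,alpha2)-bubble with alpha2 <= alpha1, so it can be
#' removed up front; this also bounds the integer keys of the radix heap by
#' alpha1.  Removals are logged into the current checkpoint.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param alpha1 the larger path-length bound.
#' @return number of arcs removed.
#' @export
pruneHeavyArcs <- function(g, alpha1) {
  e <- g@data
  arcs <- which(e$aliveA & e$w > alpha1)
  if (length(arcs)) {
    e$aliveA[arcs] <- FALSE
    e$mAlive <- e$mAlive - length(arcs)
    .logRemoval(e, arcs = arcs)
  }
  length(arcs)
}

#' Distance from every vertex to a virtual sink
#'
#' Adds (conceptually) a sink r with zero-weight arcs from every vertex of
#' \code{sources}, and returns d(v, r) for all v: the distance from v to the
#' nearest member of \code{sources}.  Computed with one multi-source
#' Dijkstra on the reverse view; no truncation is applied.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param sources non-empty vertex subset placed at distance 0.
#' @param heap priority-queue variant (see \code{\link{dijkstraTruncated}}).
#' @return named numeric vector over the vertices that can reach the sink;
#'   vertices with no path are absent.
#' @export
reverseDistToSink <- function(g, sources, heap = "bin-no-dec") {
  e <- g@data
  if (!length(sources)) stop("'sources' must be non-empty")
  for (s in sources) .checkVertex(e, s)
  r <- .dijkstra(e, !g@reversed, as.integer(sources), Inf, heap)
  d <- r$dist
  names(d) <- seq_along(d)
  d[!is.na(d)]
}

## internal: full vector form used by the enumeration hot path
.reverseDistFull <- function(e, rev, sources, heap) {
  .dijkstra(e, !rev, sources, Inf, heap)$dist
}
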