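## Exhaustive brute-force oracles.  These define ground truth on small
## instances directly from the definitions (two internally vertex-disjoint
## bounded-length paths; d pairwise internally disjoint paths) and share no
## code with the fast algorithms, so agreement between the two is a
## meaningful check.

## all simple paths out of s with total weight <= maxLen, by plain DFS
.allSimplePaths <- function(e, rev, s, maxLen = Inf, target = NULL) {
  paths <- list()
  walk <- function(path, len, onPath) {
    v <- path[length(path)]
    for (a in .aliveOutArcs(e, rev, v)) {
      x <- .arcHead(e, rev, a)
      if (onPath[x]) next
      nl <- len + e$w[a]
      if (nl > maxLen) next
      np <- c(path, x)
      if (is.null(target) || x == target)
        paths[[length(paths) + 1L]] <<- list(path = np, len = nl)
      onPath[x] <- TRUE
      walk(np, nl, onPath)
      onPath[x] <- FALSE
    }
  }
  onPath <- logical(e$nV)
  onPath[s] <- TRUE
  walk(s, 0, onPath)
  paths
}

#' Brute-force bubble enumeration (oracle)
#'
#' Enumerates every simple path out of \code{s} by exhaustive DFS, then
#' tests all pairs with a common terminal vertex for internal disjointness
#' and the length bounds, applying the same orientation canonicalization
#' and lower-bound filter as \code{\link{enumerateBubbles}}.  Intended as
#' an independent ground truth for small graphs; refuses large ones.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param s source vertex.
#' @param alpha1,alpha2 path-length bounds.
#' @param beta length lower bound for both paths (default 0).
#' @param maxVertices guard: refuse graphs with more alive vertices.
#' @return a \code{\linkS4class{BubbleSet}} (stats empty).
#' @export
bruteForceBubbles <- function(g, s, alpha1, alpha2, beta = 0,
                              maxVertices = 12) {
  e <- g@data
  s <- .checkVertex(e, s)
  if (numVertices(g) > maxVertices)
    stop("instance too large for the brute-force oracle (",
         numVertices(g), " > ", maxVertices, " vertices)")
  ps <- .allSimplePaths(e, g@reversed, s, max(alpha1, alpha2))
  ends <- vapply(ps, function(p) p$path[length(p$path)], 1L)
  bubbles <- list()
  for (t in unique(ends)) {
    if (t == s) next
    idx <- which(ends == t)
    if (length(idx) < 2L) next
    for (ii in seq_along(idx)[-1L]) for (jj in seq_len(ii - 1L)) {
      p <- ps[[idx[ii]]]; q <- ps[[idx[jj]]]
      if (!setequal(intersect(p$path, q$path), c(s, t))) next
      pqOk <- p$len <= alpha1 && q$len <= alpha2
      qpOk <- q$len <= alpha1 && p$len <= alpha2
      if (pqOk && qpOk) {
        ## both orientations in bounds: canonical one has the smaller
        ## first-arc head as path1 (mirrors the enumerator)
        if (p$path[2L] > q$path[2L]) { tmp <- p; p <- q; q <- tmp }
      } else if (qpOk) {
        tmp <- p; p <- q; q <- tmp
      } else if (!pqOk) next
      if (p$len < beta || q$len < beta) next
      bubbles[[length(bubbles) + 1L]] <-
        new("Bubble", s = s, t = as.integer(t),
            path1 = as.integer(p$path), path2 = as.integer(q$path),
            len1 = p$len, len2 = q$len)
    }
  }
  new("BubbleSet", bubbles = bubbles, status = "complete", stats = list())
}

#' Brute-force internally disjoint path families (oracle)
#'
#' Enumerates all simple s->t paths, then searches subsets of pairwise
#' internally vertex-disjoint paths exhaustively.  Returns the maximum
#' family size, one witness family of that size, and (optionally) every
#' family of a requested size.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param s,t distinct vertices.
#' @param d if not \code{NULL}, also return all families of exactly
#'   \code{d} paths.
#' @param maxVertices guard against large instances.
#' @return list with \code{max} (maximum number of pairwise internally
#'   disjoint s->t paths), \code{witness} (one maximum family), and, when
#'   \code{d} is given, \code{families} (list of all size-d families, each
#'   a list of vertex paths).
#' @export
bruteForceDisjointPaths <- function(g, s, t, d = NULL, maxVertices = 8) {
  e <- g@data
  s <- .checkVertex(e, s); t <- .checkVertex(e, t)
  if (s == t) stop("s and t must differ")
  if (numVertices(g) > maxVertices)
    stop("instance too large for the brute-force oracle")
  ps <- .allSimplePaths(e, g@reversed, s, Inf, target = t)
  paths <- lapply(ps, `[[`, "path")
  np <- length(paths)
  compat <- matrix(FALSE, np, np)
  if (np > 1L) for (i in 2:np) for (j in 1:(i - 1L)) {
    compat[i, j] <- compat[j, i] <-
      setequal(intersect(paths[[i]], paths[[j]]), c(s, t))
  }
  best <- if (np) 1L else 0L
  witness <- if (np) list(paths[[1L]]) else list()
  families <- list()
  extend <- function(members, candidates) {
    if (length(members) > best) {
      best <<- length(members)
      witness <<- paths[members]
    }
    if (!is.null(d) && length(members) == d)
      families[[length(families) + 1L]] <<- paths[members]
    for (c0 in candidates) {
      extend(c(members, c0), candidates[candidates > c0 & compat[c0,
                                         candidates]])
    }
    invisible(NULL)
  }
  if (np) for (i in seq_len(np))
    extend(i, which(seq_len(np) > i & compat[i, ]))
  res <- list(max = best, witness = witness)
  if (!is.null(d)) res$families <- families
  res
}

## Bellman-Ford distances; independent oracle for the Dijkstra variants
.bellmanFord <- function(e, rev, s) {
  n <- e$nV
  dist <- rep(NA_real_, n)
  dist[s] <- 0
  keep <- which(e$aliveA)
  u <- e$from[keep]; v <- e$to[keep]
  if (rev) { tmp <- u; u <- v; v <- tmp }
  aliveEnd <- e$aliveV[u] & e$aliveV[v]
  u <- u[aliveEnd]; v <- v[aliveEnd]; w <- e$w[keep][aliveEnd]
  for (iter in seq_len(n)) {
    changed <- FALSE
    for (i in seq_along(u)) {
      if (!is.na(dist[u[i]])) {
        nd <- dist[u[i]] + w[i]
        if (is.na(dist[v[i]]) || nd < dist[v[i]]) {
          dist[v[i]] <- nd
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist
}
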