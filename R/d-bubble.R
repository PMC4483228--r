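## (s,t)-d-bubbles: d pairwise internally vertex-disjoint s->t paths, with
## no length constraints (the length-constrained variant is NP-hard already
## for the decision problem, so it is deliberately not offered).  Existence
## and extraction reduce to unit-capacity max-flow on a vertex-split
## network; enumeration reuses the binary-partition scheme with the flow
## test as the subspace-emptiness certificate.

## ---- minimal BFS augmenting-path max-flow --------------------------------
## Arc-array residual representation: forward arc i occupies slot 2i-1,
## its residual twin slot 2i.  Shortest (fewest-arc) augmenting paths keep
## the search deterministic.
.maxflow <- function(nNodes, from, to, cap, src, snk, limit) {
  m <- length(from)
  head <- integer(2L * m); resid <- numeric(2L * m)
  head[2L * seq_len(m) - 1L] <- to
  head[2L * seq_len(m)] <- from
  resid[2L * seq_len(m) - 1L] <- cap
  adj <- vector("list", nNodes)
  for (i in seq_len(m)) {
    adj[[from[i]]] <- c(adj[[from[i]]], 2L * i - 1L)
    adj[[to[i]]] <- c(adj[[to[i]]], 2L * i)
  }
  flow <- 0
  while (flow < limit) {
    prevArc <- integer(nNodes)
    prevArc[src] <- -1L
    queue <- src; qi <- 1L
    while (qi <= length(queue) && prevArc[snk] == 0L) {
      x <- queue[qi]; qi <- qi + 1L
      for (ai in adj[[x]]) {
        y <- head[ai]
        if (resid[ai] > 0 && prevArc[y] == 0L && y != src) {
          prevArc[y] <- ai
          queue <- c(queue, y)
        }
      }
    }
    if (prevArc[snk] == 0L) break
    ## bottleneck and augment
    bn <- Inf; x <- snk
    while (x != src) {
      ai <- prevArc[x]
      bn <- min(bn, resid[ai])
      x <- head[if (ai %% 2L) ai + 1L else ai - 1L]
    }
    x <- snk
    while (x != src) {
      ai <- prevArc[x]
      tw <- if (ai %% 2L) ai + 1L else ai - 1L
      resid[ai] <- resid[ai] - bn
      resid[tw] <- resid[tw] + bn
      x <- head[tw]
    }
    flow <- flow + bn
  }
  fwd <- 2L * seq_len(m) - 1L
  list(flow = flow, f = cap - resid[fwd])
}

#' SplitNetwork: unit-capacity vertex-split flow network
#'
#' The network used to search for internally vertex-disjoint paths: each
#' original vertex v becomes v_in -> v_out with capacity 1 (so at most one
#' path can pass through v), each original arc (u,v) becomes
#' u_out -> v_in with capacity 1.  Node ids: v_in = v, v_out = n + v.
#' The endpoints s and t get internal capacity \code{dCap} so that up to
#' \code{dCap} paths may start/end there.  Arc-disjoint flow paths in this
#' network correspond one-to-one to internally vertex-disjoint paths in the
#' original graph.
#'
#' @slot nOrig number of vertices of the original graph.
#' @slot from,to,cap the network arcs (internal vertex arcs first).
#' @slot s,t the original endpoint ids.
#' @export
setClass("SplitNetwork",
         representation(nOrig = "integer", from = "integer", to = "integer",
                        cap = "numeric", s = "integer", t = "integer"))

setMethod("show", "SplitNetwork", function(object) {
  cat(sprintf("SplitNetwork: %d nodes, %d arcs (s = %d, t = %d)\n",
              2L * object@nOrig, length(object@from), object@s, object@t))
})

## raw arrays for the working (alive) part of g; sources/terminals handled
## by the callers
.splitArrays <- function(e, rev, capOf) {
  n <- e$nV
  alive <- which(e$aliveV)
  from <- alive; to <- alive + n
  cap <- capOf(alive)
  keep <- which(e$aliveA)
  u <- e$from[keep]; v <- e$to[keep]
  if (rev) { tmp <- u; u <- v; v <- tmp }
  list(from = c(from, u + n), to = c(to, v), cap = c(cap, rep(1, length(u))))
}

#' Build the vertex-split network for disjoint-path queries
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param s,t distinct alive vertices.
#' @param dCap internal capacity granted to s and t (the number of paths
#'   sought); defaults to the vertex count, i.e. effectively unbounded.
#' @return a \code{\linkS4class{SplitNetwork}}.
#' @export
splitTransform <- function(g, s, t, dCap = numVertices(g)) {
  e <- g@data
  s <- .checkVertex(e, s); t <- .checkVertex(e, t)
  if (s == t) stop("s and t must differ")
  arr <- .splitArrays(e, g@reversed,
                      function(v) ifelse(v == s | v == t, dCap, 1))
  new("SplitNetwork", nOrig = e$nV, from = as.integer(arr$from),
      to = as.integer(arr$to), cap = as.numeric(arr$cap),
      s = s, t = t)
}

## decompose an integral flow on the split network into original-vertex
## paths from s to t
.decomposeFlow <- function(n, from, to, f, s, t) {
  use <- f > 0
  paths <- list()
  repeat {
    node <- s + n                       # start at s_out
    path <- s
    repeat {
      i <- which(use & from == node)[1L]
      if (is.na(i)) { path <- NULL; break }
      use[i] <- FALSE
      node <- to[i]
      if (node == t) { path <- c(path, t); break }   # t_in reached
      if (node <= n) path <- c(path, node)           # interior v_in
      ## node > n is the v_in -> v_out hop: nothing to record
    }
    if (is.null(path)) break
    paths[[length(paths) + 1L]] <- path
  }
  paths
}

#' Maximum set of internally vertex-disjoint (s,t)-paths
#'
#' Runs at most \code{dCap} unit augmentations of a shortest-augmenting-path
#' max-flow on the vertex-split network, then decomposes the flow into
#' explicit paths.  The achieved count is min(\code{dCap}, maximum number
#' of internally vertex-disjoint s->t paths) by the max-flow/min-cut
#' (Menger) correspondence on the split network.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param s,t distinct alive vertices.
#' @param dCap number of paths requested.
#' @return list with \code{count} (achieved number of paths) and
#'   \code{paths} (list of vertex sequences s -> t, pairwise internally
#'   disjoint).
#' @export
maxDisjointPaths <- function(g, s, t, dCap) {
  e <- g@data
  s <- .checkVertex(e, s); t <- .checkVertex(e, t)
  if (s == t) stop("s and t must differ")
  if (dCap < 1) stop("dCap must be >= 1")
  n <- e$nV
  arr <- .splitArrays(e, g@reversed, function(v) rep(1, length(v)))
  r <- .maxflow(2L * n, arr$from, arr$to, arr$cap,
                src = s + n, snk = t, limit = dCap)
  paths <- if (r$flow > 0)
    .decomposeFlow(n, arr$from, arr$to, r$f, s, t) else list()
  list(count = as.integer(r$flow), paths = paths)
}

#' Can every source of a multiset reach t disjointly?
#'
#' Tests whether there exist internally vertex-disjoint paths p_i from the
#' members of the multiset \code{S} (with multiplicity) to \code{t}.
#' Members equal to \code{t} contribute empty paths and are trivially
#' satisfiable.  Implemented as a max-flow from a super-source with an arc
#' of capacity = multiplicity into each member's split-out node; the
#' members' own internal capacity is withheld, so no path may route
#' \emph{through} another path's start.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param S integer vector (multiset) of alive source vertices.
#' @param t alive target vertex.
#' @return logical.
#' @export
existsCompatibleSet <- function(g, S, t) {
  e <- g@data
  t <- .checkVertex(e, t)
  if (!length(S)) stop("S must contain at least one source")
  for (v in S) .checkVertex(e, v)
  S <- as.integer(S[S != t])
  if (!length(S)) return(TRUE)
  n <- e$nV
  mult <- table(S)
  srcIds <- as.integer(names(mult))
  arr <- .splitArrays(e, g@reversed,
                      function(v) ifelse(v %in% srcIds, 0, 1))
  sigma <- 2L * n + 1L
  from <- c(arr$from, rep(sigma, length(srcIds)))
  to <- c(arr$to, srcIds + n)
  cap <- c(arr$cap, as.numeric(mult))
  r <- .maxflow(sigma, from, to, cap, src = sigma, snk = t,
                limit = length(S))
  r$flow == length(S)
}

#' DBubble: d pairwise internally vertex-disjoint (s,t)-paths
#'
#' @slot s,t endpoint vertex ids.
#' @slot paths list of d integer vertex sequences s -> t, pairwise sharing
#'   exactly \{s, t\}.
#' @export
setClass("DBubble",
         representation(s = "integer", t = "integer", paths = "list"))

setValidity("DBubble", function(object) {
  ps <- object@paths
  if (length(ps) < 2L) return("a d-bubble needs d >= 2 paths")
  for (p in ps) {
    if (p[1L] != object@s || p[length(p)] != object@t)
      return("every path must run from s to t")
    if (anyDuplicated(p)) return("paths must be simple")
  }
  for (i in seq_along(ps)[-1L]) for (j in seq_len(i - 1L)) {
    if (!setequal(intersect(ps[[i]], ps[[j]]), c(object@s, object@t)))
      return("paths must pairwise share exactly {s, t}")
  }
  TRUE
})

setMethod("show", "DBubble", function(object) {
  cat(sprintf("DBubble %d -> %d with %d paths\n", object@s, object@t,
              length(object@paths)))
  for (p in object@paths) cat(" ", paste(p, collapse = ","), "\n")
})

.dbubbleKey <- function(paths)
  paste(sort(vapply(paths, paste, "", collapse = ",")), collapse = "|")

#' Enumerate all (s,t)-d-bubbles
#'
#' Emits every set of d pairwise internally vertex-disjoint s->t paths
#' exactly once (as an unordered set).  The recursion partitions the space
#' of compatible path sets by the next arc of the smallest-id unfinished
#' endpoint, certifying each branch non-empty with the flow test of
#' \code{\link{existsCompatibleSet}} -- flows themselves are never
#' enumerated, since many flows can map to the same path set.  Requests for
#' per-path length bounds are refused: even deciding the existence of a
#' length-constrained d-bubble generalizes the NP-complete min-max
#' two-disjoint-paths problem.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param s,t distinct alive vertices.
#' @param d number of paths, >= 2.
#' @param lengthBounds must be \code{NULL}; present only to document the
#'   refusal of the NP-hard variant at the API boundary.
#' @return list of \code{\linkS4class{DBubble}} objects.
#' @export
enumerateDBubbles <- function(g, s, t, d, lengthBounds = NULL) {
  if (!is.null(lengthBounds))
    stop("length-constrained d-bubbles are not supported: deciding their ",
         "existence is NP-hard (min-max two-disjoint-paths) already for ",
         "d = 2 with both endpoints fixed")
  e <- g@data; rev <- g@reversed
  s <- .checkVertex(e, s); t <- .checkVertex(e, t)
  if (s == t) stop("s and t must differ")
  d <- as.integer(d)
  if (d < 2L) stop("d must be >= 2")
  out <- list()

  recurse <- function(paths, active) {
    act <- which(active)
    if (!length(act)) {
      b <- new("DBubble", s = s, t = t, paths = paths)
      out[[length(out) + 1L]] <<- b
      return(invisible(NULL))
    }
    ends <- vapply(act, function(i) paths[[i]][length(paths[[i]])], 1L)
    pi <- act[which.min(ends)]
    u <- min(ends)
    arcs <- .aliveOutArcs(e, rev, u)
    otherEnds <- ends[ends != u]
    for (a in arcs) {
      v <- .arcHead(e, rev, a)
      newPaths <- paths
      newPaths[[pi]] <- c(paths[[pi]], v)
      newActive <- active
      if (v == t) {
        newActive[pi] <- FALSE
      } else if (v %in% otherEnds) {
        next                           # would collide with another path
      }
      pushCheckpoint(g)
      removeVertex(g, u)
      newEnds <- vapply(which(newActive), function(i)
        newPaths[[i]][length(newPaths[[i]])], 1L)
      feasible <- !length(newEnds) || existsCompatibleSet(g, newEnds, t)
      if (feasible) recurse(newPaths, newActive)
      restoreCheckpoint(g)
    }
    invisible(NULL)
  }

  arcs0 <- .aliveOutArcs(e, rev, s)
  if (length(arcs0) >= d) {
    combos <- utils::combn(seq_along(arcs0), d)
    for (ci in seq_len(ncol(combos))) {
      sel <- arcs0[combos[, ci]]
      heads <- vapply(sel, function(a) .arcHead(e, rev, a), 1L)
      paths <- lapply(heads, function(h) c(s, h))
      active <- heads != t
      pushCheckpoint(g)
      removeVertex(g, s)
      ends <- heads[active]
      feasible <- !length(ends) || existsCompatibleSet(g, ends, t)
      if (feasible) recurse(paths, active)
      restoreCheckpoint(g)
    }
  }
  out
}
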