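#' @import methods
NULL

#' WeightedDigraph: a mutable digraph with non-negative arc weights
#'
#' The central container of the package: a simple directed graph with
#' non-negative numeric arc weights, dense integer vertex ids \code{1..n},
#' optional string labels per vertex (k-mer or unitig sequences in the
#' de Bruijn graph use case), and a reversible deletion log.  All enumeration
#' algorithms in the package mutate one shared copy of the graph and undo
#' their changes through checkpoints (see \code{\link{pushCheckpoint}}),
#' which is what keeps the recursive bubble enumeration within linear space.
#'
#' Objects have reference semantics: the graph data live in an environment
#' shared by all views of the object.  Use \code{\link{cloneDigraph}} for an
#' independent copy.
#'
#' @slot data environment holding the arc table, adjacency, liveness flags
#'   and the deletion log.
#' @slot reversed logical; \code{TRUE} for the reverse view returned by
#'   \code{\link{reverseView}}, which presents every arc (u,v) as (v,u)
#'   without copying anything.
#'
#' @seealso \code{\link{weightedDigraph}}, \code{\link{removeVertex}},
#'   \code{\link{reverseView}}, \code{\link{readEdgeList}}
#' @export
setClass("WeightedDigraph",
         representation(data = "environment", reversed = "logical"),
         prototype(reversed = FALSE))

setValidity("WeightedDigraph", function(object) {
  e <- object@data
  msgs <- character(0)
  if (!all(c("nV", "from", "to", "w", "aliveV", "aliveA", "out", "inn",
             "log", "nAlive", "mAlive") %in% ls(e)))
    return("internal graph environment is incomplete")
  if (any(e$w < 0)) msgs <- c(msgs, "negative arc weight")
  if (any(e$from == e$to)) msgs <- c(msgs, "self-loop present")
  if (e$nAlive != sum(e$aliveV)) msgs <- c(msgs, "stale alive-vertex count")
  if (e$mAlive != sum(e$aliveA)) msgs <- c(msgs, "stale alive-arc count")
  if (length(msgs)) msgs else TRUE
})

#' Construct a WeightedDigraph
#'
#' Builds a simple weighted digraph from parallel arc vectors.  Vertex
#' identity may be given as arbitrary strings (mapped to dense integer ids in
#' first-appearance order) or as integers \code{1..n}.  Parallel arcs are
#' rejected and self-loops are dropped with a warning: neither can occur on a
#' simple path of a bubble, and de Bruijn graph construction cannot produce
#' parallel arcs.
#'
#' @param from,to vectors of arc tails/heads (character names or integer ids).
#' @param weight numeric vector of non-negative arc weights, recycled to the
#'   number of arcs; defaults to 1.
#' @param labels optional character vector of vertex labels (e.g. k-mers).
#'   When \code{from}/\code{to} are character and \code{labels} is missing,
#'   the vertex names themselves are kept as labels.
#' @param nVertices optional total vertex count, to allow isolated vertices
#'   beyond those mentioned by arcs (integer ids only).
#' @return a \code{\linkS4class{WeightedDigraph}}.
#' @examples
#' g <- weightedDigraph(c("s", "s", "a", "b"), c("a", "b", "t", "t"))
#' numArcs(g)
#' @export
weightedDigraph <- function(from, to, weight = 1, labels = NULL,
                            nVertices = NULL) {
  if (length(from) != length(to))
    stop("'from' and 'to' must have equal length")
  if (is.character(from) || is.character(to)) {
    from <- as.character(from); to <- as.character(to)
    names <- unique(c(from, to))
    if (is.null(labels)) labels <- names
    from <- match(from, names)
    to <- match(to, names)
    n <- length(names)
  } else {
    from <- as.integer(from); to <- as.integer(to)
    n <- max(c(from, to, 0L, nVertices))
  }
  w <- rep_len(as.numeric(weight), length(from))
  if (any(w < 0)) stop("arc weights must be non-negative")
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]; to <- to[!loops]; w <- w[!loops]
  }
  if (anyDuplicated(cbind(from, to)))
    stop("parallel arcs are not allowed")
  if (!is.null(labels) && length(labels) != n)
    stop("'labels' must have one entry per vertex")

  e <- new.env(parent = emptyenv())
  e$nV <- as.integer(n)
  e$from <- from
  e$to <- to
  e$w <- w
  e$aliveV <- rep(TRUE, n)
  e$aliveA <- rep(TRUE, length(from))
  e$out <- lapply(seq_len(n), function(v) which(from == v))
  e$inn <- lapply(seq_len(n), function(v) which(to == v))
  e$labels <- labels
  e$log <- list()
  e$nAlive <- as.integer(n)
  e$mAlive <- length(from)
  new("WeightedDigraph", data = e, reversed = FALSE)
}

#' @describeIn weightedDigraph number of alive vertices.
#' @param g a \code{WeightedDigraph}.
#' @export
numVertices <- function(g) g@data$nAlive

#' @describeIn weightedDigraph number of alive arcs.
#' @export
numArcs <- function(g) g@data$mAlive

#' @describeIn weightedDigraph vertex labels (\code{NULL} if none).
#' @export
vertexLabels <- function(g) g@data$labels

#' @describeIn weightedDigraph integer ids of the alive vertices.
#' @export
aliveVertices <- function(g) which(g@data$aliveV)

#' Alive arcs as a data frame
#'
#' @param g a \code{WeightedDigraph}.
#' @param useLabels replace integer ids by vertex labels when available.
#' @return data.frame with columns \code{from}, \code{to}, \code{weight},
#'   sorted by (from, to) for deterministic serialization.
#' @export
arcTable <- function(g, useLabels = FALSE) {
  e <- g@data
  keep <- which(e$aliveA)
  from <- e$from[keep]; to <- e$to[keep]
  if (g@reversed) { tmp <- from; from <- to; to <- tmp }
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]
  d <- data.frame(from = from, to = to, weight = e$w[keep][ord])
  if (useLabels && !is.null(e$labels)) {
    d$from <- e$labels[d$from]
    d$to <- e$labels[d$to]
  }
  d
}

setMethod("show", "WeightedDigraph", function(object) {
  cat(sprintf("WeightedDigraph: %d vertices, %d arcs%s%s\n",
              numVertices(object), numArcs(object),
              if (object@reversed) " (reverse view)" else "",
              if (!is.null(vertexLabels(object))) ", labeled" else ""))
  if (length(object@data$log))
    cat(sprintf("  %d open checkpoint(s)\n", length(object@data$log)))
})

## ---- internal accessors used by every algorithm ---------------------------
## These take the raw environment plus the reversal flag so the hot loops
## never touch S4 dispatch.

.outArcIds <- function(e, rev, v) if (rev) e$inn[[v]] else e$out[[v]]
.arcHead <- function(e, rev, a) if (rev) e$from[a] else e$to[a]

## alive out-arcs of v, ordered by ascending head id (deterministic iteration)
.aliveOutArcs <- function(e, rev, v) {
  a <- .outArcIds(e, rev, v)
  a <- a[e$aliveA[a]]
  if (length(a) > 1L) {
    h <- if (rev) e$from[a] else e$to[a]
    a <- a[order(h)]
  }
  a
}

.checkVertex <- function(e, v) {
  if (length(v) != 1L || is.na(v) || v < 1L || v > e$nV)
    stop("unknown vertex id: ", v)
  if (!e$aliveV[v]) stop("vertex ", v, " is not alive")
  invisible(as.integer(v))
}
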