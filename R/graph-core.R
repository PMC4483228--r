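## Reversible mutation of a WeightedDigraph.
##
## The bubble enumeration recursion repeatedly removes a vertex or an
## out-neighborhood, recurses, and puts everything back.  Removals are marked
## on liveness flags and logged into the top checkpoint, so restoring a
## checkpoint is O(size of the difference) and the total log along any
## root-to-leaf removal sequence holds each arc at most once (linear space).

.logRemoval <- function(e, arcs = integer(0), verts = integer(0)) {
  k <- length(e$log)
  if (k == 0L) return(invisible(NULL))  # no checkpoint: removal is permanent
  ck <- e$log[[k]]
  ck$arcs <- c(ck$arcs, arcs)
  ck$verts <- c(ck$verts, verts)
  invisible(NULL)
}

#' Open a restore checkpoint on the deletion log
#'
#' Subsequent \code{\link{removeVertex}} / \code{\link{removeOutArcs}} calls
#' are recorded; \code{\link{restoreCheckpoint}} undoes them (LIFO).  Removals
#' made while no checkpoint is open are permanent.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @return the checkpoint depth, invisibly.
#' @export
pushCheckpoint <- function(g) {
  e <- g@data
  ck <- new.env(parent = emptyenv())
  ck$arcs <- integer(0)
  ck$verts <- integer(0)
  e$log[[length(e$log) + 1L]] <- ck
  invisible(length(e$log))
}

#' Restore the graph to its state at the last checkpoint
#'
#' Pops the top checkpoint and revives every vertex and arc removed since it
#' was pushed, returning the graph bit-identically to its earlier state.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @return \code{g}, invisibly.
#' @export
restoreCheckpoint <- function(g) {
  e <- g@data
  k <- length(e$log)
  if (k == 0L) stop("no checkpoint to restore")
  ck <- e$log[[k]]
  e$log[[k]] <- NULL
  if (length(ck$arcs)) {
    e$aliveA[ck$arcs] <- TRUE
    e$mAlive <- e$mAlive + length(ck$arcs)
  }
  if (length(ck$verts)) {
    e$aliveV[ck$verts] <- TRUE
    e$nAlive <- e$nAlive + length(ck$verts)
  }
  invisible(g)
}

#' Remove a vertex and all incident arcs (reversibly)
#'
#' Marks \code{v} and every alive arc incident to it dead, logging the
#' removals into the current checkpoint.  This realizes the recursion step
#' "G - v" of the binary partition: once a partial bubble path advances past
#' a vertex, no other path may use it.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param v alive vertex id.
#' @return \code{g}, invisibly.
#' @export
removeVertex <- function(g, v) {
  e <- g@data
  v <- .checkVertex(e, v)
  arcs <- c(e$out[[v]], e$inn[[v]])
  arcs <- arcs[e$aliveA[arcs]]
  e$aliveA[arcs] <- FALSE
  e$aliveV[v] <- FALSE
  e$mAlive <- e$mAlive - length(arcs)
  e$nAlive <- e$nAlive - 1L
  .logRemoval(e, arcs = arcs, verts = v)
  invisible(g)
}

#' Remove every out-arc of a vertex (reversibly)
#'
#' The vertex itself and its in-arcs stay alive.  This is the exclusion
#' branch of the binary partition: the partial path ending at \code{v} is
#' frozen by deleting its possible continuations.  Applied to a reverse view,
#' it removes the underlying in-arcs.
#'
#' @inheritParams removeVertex
#' @return number of arcs removed, invisibly.
#' @export
removeOutArcs <- function(g, v) {
  e <- g@data
  v <- .checkVertex(e, v)
  arcs <- .outArcIds(e, g@reversed, v)
  arcs <- arcs[e$aliveA[arcs]]
  e$aliveA[arcs] <- FALSE
  e$mAlive <- e$mAlive - length(arcs)
  .logRemoval(e, arcs = arcs)
  invisible(length(arcs))
}

#' Reverse view of a digraph
#'
#' Returns a view presenting every arc (u,v,w) as (v,u,w).  The view shares
#' all state (liveness, checkpoints) with the original; nothing is copied.
#' Reversing twice yields the original orientation.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @return a \code{WeightedDigraph} view.
#' @export
reverseView <- function(g) new("WeightedDigraph", data = g@data,
                               reversed = !g@reversed)

#' Deep copy of a digraph
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @return an independent copy sharing no state with \code{g} (the deletion
#'   log is not copied; the copy starts with an empty log).
#' @export
cloneDigraph <- function(g) {
  e <- g@data
  e2 <- new.env(parent = emptyenv())
  for (nm in c("nV", "from", "to", "w", "aliveV", "aliveA", "out", "inn",
               "labels", "nAlive", "mAlive"))
    assign(nm, get(nm, envir = e), envir = e2)
  e2$log <- list()
  new("WeightedDigraph", data = e2, reversed = g@reversed)
}

#' Compare two digraphs for exact state equality
#'
#' Arc-by-arc, vertex-by-vertex comparison of structure, weights, labels and
#' liveness.  Used by the state-hygiene tests to verify that enumeration
#' leaves its input graph bit-identical.
#'
#' @param g1,g2 \code{\linkS4class{WeightedDigraph}} objects.
#' @return logical.
#' @export
digraphIdentical <- function(g1, g2) {
  a <- g1@data; b <- g2@data
  identical(a$nV, b$nV) &&
    identical(a$from, b$from) && identical(a$to, b$to) &&
    identical(a$w, b$w) &&
    identical(a$aliveV, b$aliveV) && identical(a$aliveA, b$aliveA) &&
    identical(a$labels, b$labels) &&
    g1@reversed == g2@reversed
}

## snapshot of the mutable state, for cheap before/after comparisons in tests
.graphState <- function(g) {
  e <- g@data
  list(aliveV = e$aliveV, aliveA = e$aliveA, depth = length(e$log))
}
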