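## De Bruijn graph front-end: k-mer counting with an abundance filter,
## all-overlap arc construction, linear-path (unitig) compression, and
## biconnected-component decomposition of the underlying undirected graph.

#' KmerTable: k-mer multiplicities over a read set
#'
#' @slot k k-mer length (nt).
#' @slot counts named integer vector, k-mer string -> multiplicity summed
#'   over all input sequences (single-stranded; no reverse-complement
#'   canonicalization).
#' @seealso \code{\link{countKmers}}
#' @export
setClass("KmerTable", representation(k = "integer", counts = "integer"))

setValidity("KmerTable", function(object) {
  if (length(object@counts) &&
      any(nchar(names(object@counts)) != object@k))
    return("k-mer key length differs from k")
  if (any(object@counts < 1L)) return("counts must be >= 1")
  TRUE
})

setMethod("show", "KmerTable", function(object) {
  cat(sprintf("KmerTable: %d distinct %d-mers\n",
              length(object@counts), object@k))
})

#' Count k-mers with an abundance filter
#'
#' Slides a window of length \code{k} over every sequence independently and
#' keeps the k-mers seen at least \code{minCount} times in total.  The
#' abundance filter is the standard guard against sequencing errors: an
#' erroneous base creates up to k spurious k-mers that are usually rare.
#' Windows containing \code{N} are skipped.  Counting is single-stranded.
#'
#' @param sequences character vector of DNA sequences over A,C,G,T,N
#'   (lower case accepted).
#' @param k k-mer length, >= 2.
#' @param minCount minimum total multiplicity for a k-mer to be retained;
#'   the default 3 is the usual error-filter setting for read data (use 1
#'   for error-free input such as transcript sequences).
#' @return a \code{\linkS4class{KmerTable}}.
#' @examples
#' countKmers(c("ACTGGAGCG", "ACTGCG"), k = 3, minCount = 1)
#' @export
countKmers <- function(sequences, k, minCount = 3) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  sequences <- toupper(as.character(sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence ", which(bad)[1L], " contains characters outside ACGTN")
  kmers <- unlist(lapply(sequences, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  tab <- table(kmers)
  tab <- tab[tab >= minCount]
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  new("KmerTable", k = k, counts = counts)
}

#' Build the de Bruijn graph of a k-mer table
#'
#' One vertex per retained k-mer; an arc (u,v) for \emph{every} ordered pair
#' whose length-(k-1) suffix/prefix match, not only pairs adjacent in some
#' read.  All arc weights are 1 (each arc extends a walk by one nucleotide).
#' A k-mer whose prefix equals its own suffix (e.g. a homopolymer) would be
#' a self-loop and is dropped: no simple bubble path can use it.
#'
#' @param table a \code{\linkS4class{KmerTable}}.
#' @return a unit-weight \code{\linkS4class{WeightedDigraph}} whose vertex
#'   labels are the k-mers (sorted, so vertex ids are reproducible).
#' @export
buildDBG <- function(table) {
  stopifnot(is(table, "KmerTable"))
  kmers <- sort(names(table@counts))
  if (!length(kmers)) stop("empty k-mer table")
  k <- table@k
  suf <- substring(kmers, 2L, k)
  pre <- substring(kmers, 1L, k - 1L)
  byPre <- split(seq_along(kmers), pre)
  from <- integer(0); to <- integer(0)
  for (u in seq_along(kmers)) {
    vs <- byPre[[suf[u]]]
    if (is.null(vs)) next
    vs <- vs[vs != u]            # self-loop rule
    from <- c(from, rep.int(u, length(vs)))
    to <- c(to, vs)
  }
  weightedDigraph(from, to, 1, labels = kmers, nVertices = length(kmers))
}

#' CompressedDBG: de Bruijn graph with unitigs merged
#'
#' A de Bruijn graph whose maximal non-branching linear paths have each been
#' merged into a single vertex labeled by the path sequence (overlaps
#' removed).  Arcs still denote (k-1)-overlaps; the arc weight
#' \code{weight(u,v) = nchar(label(v)) - (k-1)} counts the k-mers the arc
#' adds, so path lengths in the compressed graph equal arc counts in the
#' uncompressed one (lossless for bubble length constraints).
#'
#' @slot graph the compressed \code{\linkS4class{WeightedDigraph}} with
#'   unitig sequence labels.
#' @slot k the k-mer length of the underlying graph.
#' @export
setClass("CompressedDBG",
         representation(graph = "WeightedDigraph", k = "integer"))

setMethod("show", "CompressedDBG", function(object) {
  cat(sprintf("CompressedDBG (k = %d): %d unitigs, %d arcs\n", object@k,
              numVertices(object@graph), numArcs(object@graph)))
})

#' Compress maximal non-branching linear paths of a de Bruijn graph
#'
#' Merges every maximal chain u1 -> ... -> up with out-degree(ui) = 1 for
#' i < p and in-degree(ui) = 1 for i > 1 into a single vertex whose label is
#' the concatenation of the k-mer labels minus the (k-1)-overlaps.  Isolated
#' directed cycles in which every vertex has in- and out-degree 1 have no
#' canonical start vertex and are left uncompressed; they cannot contain a
#' bubble.
#'
#' @param g a unit-weight labeled DBG from \code{\link{buildDBG}} (all
#'   vertices and arcs alive).
#' @param k the k-mer length.
#' @return a \code{\linkS4class{CompressedDBG}}.
#' @export
compressDBG <- function(g, k) {
  e <- g@data
  k <- as.integer(k)
  labs <- e$labels
  if (is.null(labs)) stop("compression requires vertex labels")
  n <- e$nV
  indeg <- tabulate(e$to[e$aliveA], n)
  outdeg <- tabulate(e$from[e$aliveA], n)
  ## an arc is mergeable iff it is the unique continuation on both sides
  mergeIn <- rep(NA_integer_, n)   # unique mergeable predecessor arc head
  for (a in which(e$aliveA)) {
    u <- e$from[a]; v <- e$to[a]
    if (outdeg[u] == 1L && indeg[v] == 1L) mergeIn[v] <- u
  }
  comp <- rep(NA_integer_, n)      # unitig id per vertex
  chains <- list()
  starts <- which(e$aliveV & is.na(mergeIn))
  for (s0 in starts) {
    chain <- s0
    v <- s0
    repeat {
      if (outdeg[v] != 1L) break
      a <- e$out[[v]]; a <- a[e$aliveA[a]]
      nxt <- e$to[a]
      if (indeg[nxt] != 1L) break
      chain <- c(chain, nxt)
      v <- nxt
    }
    chains[[length(chains) + 1L]] <- chain
    comp[chain] <- length(chains)
  }
  ## leftovers are vertices on all-mergeable directed cycles: keep singletons
  for (v in which(e$aliveV & is.na(comp))) {
    chains[[length(chains) + 1L]] <- v
    comp[v] <- length(chains)
  }
  newLabs <- vapply(chains, function(ch)
    paste0(labs[ch[1L]], paste(substring(labs[ch[-1L]], k), collapse = "")),
    FUN.VALUE = "")
  ## an arc survives iff its endpoints fall in different unitigs; an arc
  ## that would close a chain on itself becomes a self-loop on the merged
  ## vertex and cannot lie on any simple path, so it is dropped
  keepArc <- which(e$aliveA)
  cf <- comp[e$from[keepArc]]; ct <- comp[e$to[keepArc]]
  cross <- cf != ct
  from <- cf[cross]; to <- ct[cross]
  w <- nchar(newLabs[to]) - (k - 1L)
  cg <- weightedDigraph(from, to, w, labels = newLabs,
                        nVertices = length(chains))
  new("CompressedDBG", graph = cg, k = k)
}

#' Biconnected-component decomposition
#'
#' Decomposes the underlying undirected graph into biconnected components
#' and discards components with fewer than \code{minVertices} vertices.
#' Every bubble lies entirely within exactly one component (its two paths
#' form an undirected cycle), so per-component enumeration is lossless; the
#' default threshold 4 discards components that cannot contain a bubble.
#' Articulation vertices appear in several components.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param minVertices discard components smaller than this (default 4).
#' @return list of components, each a list with \code{vertices} (original
#'   ids) and \code{graph} (induced \code{WeightedDigraph} whose attribute
#'   \code{"origIds"} maps its ids back to \code{g}).
#' @export
bccDecompose <- function(g, minVertices = 4) {
  e <- g@data
  keep <- which(e$aliveA)
  if (!length(keep)) return(list())
  u <- e$from[keep]; v <- e$to[keep]
  ## collapse the two orientations onto one undirected edge
  lo <- pmin(u, v); hi <- pmax(u, v)
  und <- !duplicated(paste(lo, hi))
  ig <- igraph::graph_from_edgelist(cbind(lo[und], hi[und]), directed = FALSE)
  bc <- igraph::biconnected_components(ig)
  out <- list()
  for (comp in bc$components) {
    ids <- sort(as.integer(comp))
    if (length(ids) < minVertices) next
    inComp <- logical(e$nV)
    inComp[ids] <- TRUE
    sel <- keep[inComp[e$from[keep]] & inComp[e$to[keep]]]
    sub <- weightedDigraph(match(e$from[sel], ids), match(e$to[sel], ids),
                           e$w[sel],
                           labels = if (!is.null(e$labels)) e$labels[ids],
                           nVertices = length(ids))
    attr(sub, "origIds") <- ids
    out[[length(out) + 1L]] <- list(vertices = ids, graph = sub)
  }
  out
}
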