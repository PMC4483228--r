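## Edge-list TSV and GFA1 serialization of weighted digraphs.

#' Read a weighted digraph from an edge-list TSV
#'
#' One arc per line, \code{u<TAB>v<TAB>weight}; the weight column may be
#' omitted (defaults to 1); lines starting with \code{#} are comments.
#' Vertex names are arbitrary strings, mapped to dense integer ids in order
#' of first appearance.  Duplicate arcs and negative weights are rejected
#' with the offending line number.
#'
#' @param path edge-list file.
#' @param labelsPath optional sidecar TSV \code{vertex<TAB>label} attaching
#'   sequence labels to vertices.
#' @return a \code{\linkS4class{WeightedDigraph}}.
#' @seealso \code{\link{writeEdgeList}}, \code{\link{readGFA}}
#' @export
readEdgeList <- function(path, labelsPath = NULL) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no arcs in ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("malformed arc line ", keep[which(nf < 2L)[1L]], " in ", path)
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  w <- ifelse(nf >= 3L, vapply(parts, function(p) p[3L], ""), "1")
  w <- suppressWarnings(as.numeric(w))
  if (anyNA(w))
    stop("non-numeric weight on line ", keep[which(is.na(w))[1L]], " in ", path)
  if (any(w < 0))
    stop("negative weight on line ", keep[which(w < 0)[1L]], " in ", path)
  dup <- duplicated(paste(from, to, sep = "\r"))
  if (any(dup))
    stop("duplicate arc on line ", keep[which(dup)[1L]], " in ", path)
  names <- unique(c(from, to))
  labels <- names
  if (!is.null(labelsPath)) {
    lab <- utils::read.table(labelsPath, sep = "\t", header = FALSE,
                             comment.char = "#", colClasses = "character")
    hit <- match(names, lab[[1L]])
    labels <- ifelse(is.na(hit), names, lab[[2L]][hit])
  }
  weightedDigraph(from, to, w, labels = labels)
}

#' Write a weighted digraph as an edge-list TSV
#'
#' Alive arcs only, sorted by vertex id for byte-deterministic output.
#' Vertex labels are used as names when present, else integer ids.
#'
#' @param g a \code{\linkS4class{WeightedDigraph}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(g, path) {
  d <- arcTable(g, useLabels = TRUE)
  writeLines(sprintf("%s\t%s\t%s", d$from, d$to,
                     format(d$weight, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Write a labeled digraph as GFA1
#'
#' Emits one \code{S}-line per alive vertex (its sequence label) and one
#' \code{L}-line per alive arc with overlap CIGAR \code{(k-1)M}, the
#' suffix-prefix overlap of the de Bruijn graph.
#'
#' @param g a labeled \code{\linkS4class{WeightedDigraph}} (vertex labels are
#'   the segment sequences).
#' @param path output file.
#' @param k the k-mer size used to build the graph.
#' @return \code{path}, invisibly.
#' @export
writeGFA <- function(g, path, k) {
  labs <- vertexLabels(g)
  if (is.null(labs)) stop("GFA output requires vertex labels")
  vs <- aliveVertices(g)
  d <- arcTable(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  writeLines(sprintf("S\t%s\t%s", labs[vs], labs[vs]), con)
  writeLines(sprintf("L\t%s\t+\t%s\t+\t%dM", labs[d$from], labs[d$to],
                     as.integer(k) - 1L), con)
  invisible(path)
}

#' Read a GFA1 file into a weighted digraph
#'
#' Supports \code{S}/\code{L} lines with forward (\code{+}) orientations and
#' a uniform \code{(k-1)M} overlap.  Arc weights follow the compressed de
#' Bruijn graph convention: weight(u,v) = nchar(label(v)) - (k-1).
#'
#' @param path GFA1 file.
#' @return a labeled \code{\linkS4class{WeightedDigraph}}; the inferred k is
#'   attached as attribute \code{"k"}.
#' @export
readGFA <- function(path) {
  lines <- readLines(path)
  recs <- strsplit(lines, "\t", fixed = TRUE)
  type <- vapply(recs, `[[`, "", 1L)
  segs <- recs[type == "S"]
  links <- recs[type == "L"]
  if (!length(segs)) stop("no S-lines in ", path)
  names <- vapply(segs, `[[`, "", 2L)
  labels <- vapply(segs, `[[`, "", 3L)
  ov <- unique(vapply(links, `[[`, "", 6L))
  if (length(ov) > 1L) stop("heterogeneous overlaps in ", path)
  k <- if (length(ov)) as.integer(sub("M$", "", ov)) + 1L else NA_integer_
  if (length(links)) {
    from <- vapply(links, `[[`, "", 2L)
    to <- vapply(links, `[[`, "", 4L)
    if (any(vapply(links, `[[`, "", 3L) != "+") ||
        any(vapply(links, `[[`, "", 5L) != "+"))
      stop("only forward (+/+) links are supported")
    fi <- match(from, names); ti <- match(to, names)
    if (anyNA(fi) || anyNA(ti)) stop("link references unknown segment")
    w <- nchar(labels[ti]) - (k - 1L)
    g <- weightedDigraph(fi, ti, w, labels = labels,
                         nVertices = length(names))
  } else {
    g <- weightedDigraph(integer(0), integer(0), numeric(0),
                         labels = labels, nVertices = length(names))
  }
  attr(g, "k") <- k
  g
}
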