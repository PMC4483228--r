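#' Bubble: two internally vertex-disjoint (s,t)-paths with lengths
#'
#' A bubble is the graph signature of a variant: two directed paths from a
#' common source \code{s} to a common target \code{t} that share no other
#' vertex.  In a de Bruijn graph the two paths spell the two alternative
#' sequences of an allele or splicing event.  Path lengths are sums of arc
#' weights (nucleotides in the DBG use case); under the constraints they
#' were enumerated with, \code{len1 <= alpha1} and \code{len2 <= alpha2}.
#'
#' @slot s,t source and target vertex ids.
#' @slot path1,path2 integer vertex sequences from s to t (each simple,
#'   at least one arc, sharing exactly \{s, t\}).
#' @slot len1,len2 path lengths.
#' @export
setClass("Bubble",
         representation(s = "integer", t = "integer",
                        path1 = "integer", path2 = "integer",
                        len1 = "numeric", len2 = "numeric"))

setValidity("Bubble", function(object) {
  p1 <- object@path1; p2 <- object@path2
  if (length(p1) < 2L || length(p2) < 2L)
    return("each path needs at least one arc")
  if (p1[1L] != object@s || p2[1L] != object@s ||
      p1[length(p1)] != object@t || p2[length(p2)] != object@t)
    return("paths must run from s to t")
  if (object@s == object@t) return("s and t must differ")
  if (anyDuplicated(p1) || anyDuplicated(p2))
    return("paths must be simple")
  shared <- intersect(p1, p2)
  if (!setequal(shared, c(object@s, object@t)))
    return("paths must share exactly {s, t}")
  TRUE
})

setMethod("show", "Bubble", function(object) {
  cat(sprintf("Bubble %d -> %d  (lengths %s / %s)\n  p1: %s\n  p2: %s\n",
              object@s, object@t, format(object@len1), format(object@len2),
              paste(object@path1, collapse = ","),
              paste(object@path2, collapse = ",")))
})

## canonical text key for set comparisons / dedup
.bubbleKey <- function(b)
  paste(paste(b@path1, collapse = ","), paste(b@path2, collapse = ","),
        sep = "|")

#' BubbleSet: result of a bubble enumeration
#'
#' Holds the enumerated bubbles, the stop status, and the delay
#' instrumentation collected during the run.
#'
#' \code{stats} is a list with \code{nodeVisits} (recursion nodes visited),
#' \code{leaves} (recursion leaves; each yields exactly one candidate
#' bubble), \code{maxGap} (largest number of node visits between two
#' consecutive leaves, the empirical enumeration delay), and
#' \code{candidates} (candidate bubbles before the length lower-bound and
#' orientation filters).
#'
#' @slot bubbles list of \code{\linkS4class{Bubble}}.
#' @slot status \code{"complete"}, \code{"max_bubbles"} or \code{"timeout"}.
#' @slot stats instrumentation list (see above).
#' @export
setClass("BubbleSet",
         representation(bubbles = "list", status = "character",
                        stats = "list"))

#' @export
setMethod("length", "BubbleSet", function(x) length(x@bubbles))

#' @export
setMethod("[[", "BubbleSet", function(x, i) x@bubbles[[i]])

setMethod("show", "BubbleSet", function(object) {
  cat(sprintf("BubbleSet: %d bubble(s), status = %s\n", length(object),
              object@status))
})

#' @describeIn enumerateBubbles bubbles of a \code{BubbleSet} as a
#'   data.frame with columns s, t, len1, len2, path1, path2 (paths
#'   comma-separated, labels used when available).
#' @param x a \code{BubbleSet}.
#' @param labels optional character vector translating vertex ids.
#' @export
bubbleTable <- function(x, labels = NULL) {
  fmt <- function(p) {
    if (!is.null(labels)) p <- labels[p]
    paste(p, collapse = ",")
  }
  name1 <- function(v) if (!is.null(labels)) labels[v] else v
  bs <- x@bubbles
  data.frame(
    s = vapply(bs, function(b) name1(b@s), if (is.null(labels)) 1L else ""),
    t = vapply(bs, function(b) name1(b@t), if (is.null(labels)) 1L else ""),
    len1 = vapply(bs, function(b) b@len1, 1),
    len2 = vapply(bs, function(b) b@len2, 1),
    path1 = vapply(bs, function(b) fmt(b@path1), ""),
    path2 = vapply(bs, function(b) fmt(b@path2), ""),
    stringsAsFactors = FALSE
  )
}
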