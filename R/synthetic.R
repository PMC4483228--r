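## Seeded generators for test inputs: random digraphs, planted
## alternative-splicing events, and Hamiltonian-path stress instances.
## Every generator is a pure function of its arguments including the seed;
## the caller's RNG state is left untouched.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random simple weighted digraph
#'
#' Erdos-Renyi style: each ordered pair (u, v), u != v, carries an arc
#' independently with probability \code{p}; weights are uniform integers in
#' \code{weightRange}.  Identical seeds give identical graphs.
#'
#' @param n number of vertices (>= 1).
#' @param p arc probability in [0, 1].
#' @param weightRange integer bounds \code{c(lo, hi)} for the uniform arc
#'   weights; default 1..3.
#' @param seed RNG seed.
#' @return a \code{\linkS4class{WeightedDigraph}}.
#' @export
randomDigraph <- function(n, p, weightRange = c(1, 3), seed = 1) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  .withSeed(seed, {
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    keep <- stats::runif(nrow(pairs)) < p
    from <- pairs$from[keep]; to <- pairs$to[keep]
    w <- sample(seq(weightRange[1L], weightRange[2L]), length(from),
                replace = TRUE)
    weightedDigraph(from, to, as.numeric(w), nVertices = n)
  })
}

.randomDNA <- function(len)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

.kmersOf <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(s, starts, starts + k - 1L)
}

#' Plant an alternative-splicing-like event in a sequence pair
#'
#' Generates the sequence pair awb / aw'b that models a variant: common
#' flanks a and b (each at least k long) around two alternative inner
#' segments w and w'.  Such a pair creates a bubble in the de Bruijn graph
#' between the last k-mer of a (the branch point) and the first k-mer of b
#' (the rejoin point).  With \code{wpLen = 0} the second path is the pure
#' ab junction, whose number of internal vertices is at most k - 1.
#'
#' Instances are rejection-sampled until the planted bubble is clean: every
#' k-mer occurs at most once within each sequence, and the two variable
#' regions (w and w' with their flank-straddling windows) share no k-mer.
#' This guarantees that the two paths diverge immediately after the branch
#' k-mer and first rejoin at the first k-mer of b.
#'
#' @param k k-mer length.
#' @param aLen,bLen flank lengths (>= k).
#' @param wLen,wpLen inner segment lengths (wpLen may be 0; not both 0).
#' @param seed RNG seed.
#' @param maxTries rejection budget before giving up.
#' @return list with \code{seq1} (awb), \code{seq2} (aw'b), the parts
#'   \code{a}, \code{b}, \code{w}, \code{wp}, the predicted endpoint k-mers
#'   \code{sKmer}, \code{tKmer}, and \code{k}.
#' @export
plantASEvent <- function(k = 5, aLen = 8, bLen = 8, wLen = 6, wpLen = 3,
                         seed = 1, maxTries = 1000) {
  k <- as.integer(k)
  if (aLen < k || bLen < k) stop("flanks must satisfy |a| >= k and |b| >= k")
  if (wLen == 0 && wpLen == 0) stop("w and w' cannot both be empty")
  .withSeed(seed, {
    for (try in seq_len(maxTries)) {
      a <- .randomDNA(aLen); b <- .randomDNA(bLen)
      w <- if (wLen > 0) .randomDNA(wLen) else ""
      wp <- if (wpLen > 0) .randomDNA(wpLen) else ""
      if (w == wp) next
      seq1 <- paste0(a, w, b); seq2 <- paste0(a, wp, b)
      k1 <- .kmersOf(seq1, k); k2 <- .kmersOf(seq2, k)
      if (anyDuplicated(k1) || anyDuplicated(k2)) next
      shared <- union(.kmersOf(a, k), .kmersOf(b, k))
      mid1 <- setdiff(k1, shared); mid2 <- setdiff(k2, shared)
      if (length(intersect(mid1, mid2))) next
      return(list(seq1 = seq1, seq2 = seq2, a = a, b = b, w = w, wp = wp,
                  sKmer = substring(a, aLen - k + 1L, aLen),
                  tKmer = substring(b, 1L, k), k = k))
    }
    stop("could not plant a clean event in ", maxTries,
         " tries; lengths/alphabet too constrained")
  })
}

#' Hamiltonian-path stress instance
#'
#' Builds the classical hardness construction that couples the length
#' lower bound to Hamiltonicity: two fresh endpoints s' and t' are attached
#' with arcs (s', s) and (t, t'), plus a fresh path from s' to t' through
#' |V| new vertices, all added arcs of weight 1.  In the augmented graph
#' the only bubbles whose two paths both have |V| + 2 vertices (= |V| + 1
#' unit arcs) are those pairing the fresh path with
#' s' -> s -> (Hamiltonian path) -> t -> t', so enumeration from s' with
#' alpha1 = alpha2 = beta = |V| + 1 is non-empty iff \code{g} has a
#' Hamiltonian s,t-path.  Useful as a stress test of the length lower-bound
#' filter.
#'
#' @param g a unit-weight \code{\linkS4class{WeightedDigraph}}.
#' @param s,t distinct vertices of \code{g}.
#' @return list with \code{graph} (the augmented graph), \code{source}
#'   (s'), \code{target} (t'), and the arc-length parameters \code{alpha}
#'   and \code{beta} (= |V| + 1) that encode the vertex-count bound
#'   |V| + 2.
#' @export
hamiltonianReductionInstance <- function(g, s, t) {
  e <- g@data
  s <- .checkVertex(e, s); t <- .checkVertex(e, t)
  if (s == t) stop("s and t must differ")
  if (any(e$w[e$aliveA] != 1))
    stop("the reduction requires unit arc weights (path length must ",
         "count arcs)")
  n <- e$nV
  keep <- which(e$aliveA)
  from <- e$from[keep]; to <- e$to[keep]; w <- e$w[keep]
  sP <- n + 1L; tP <- n + 2L
  mid <- n + 2L + seq_len(n)
  from2 <- c(from, sP, t, sP, mid)
  to2 <- c(to, s, tP, mid[1L], c(mid[-1L], tP))
  w2 <- c(w, rep(1, length(from2) - length(from)))
  labels <- c(if (!is.null(e$labels)) e$labels else as.character(seq_len(n)),
              "s'", "t'", paste0("h", seq_len(n)))
  g2 <- weightedDigraph(from2, to2, w2, labels = labels,
                        nVertices = n + 2L + n)
  list(graph = g2, source = sP, target = tP,
       alpha = n + 1, beta = n + 1)
}
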