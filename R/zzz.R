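#' DBGbubbles: length-bounded bubble enumeration in de Bruijn graphs
#'
#' Reference-free detection of alternative-splicing events and small
#' variants from RNA-seq reads, via polynomial-delay enumeration of
#' length-constrained bubbles in the de Bruijn graph.  See the package
#' vignette for the model and algorithm.
#'
#' @importFrom igraph graph_from_edgelist biconnected_components
#' @importFrom Biostrings readDNAStringSet
#' @importFrom stats runif setNames
#' @importFrom utils combn read.table write.table
#' @keywords internal
"_PACKAGE"
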