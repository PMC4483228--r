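## Sequence input and bubble report output.

#' Read DNA sequences from FASTA or FASTQ
#'
#' Sniffs the format from the first byte (\code{>} FASTA, \code{@} FASTQ),
#' transparently decompressing gzip.  Sequences are upper-cased; records
#' consisting only of N are dropped with a message.
#'
#' @param path input file.
#' @return named character vector of sequences (possibly empty).
#' @export
readSequences <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) {
    warning("no sequence records in ", path)
    return(character(0))
  }
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop("cannot sniff sequence format of ", path,
                   " (expected '>' or '@' on line 1)")
  xs <- Biostrings::readDNAStringSet(path, format = fmt)
  seqs <- toupper(as.character(xs))
  onlyN <- grepl("^N*$", seqs)
  if (any(onlyN)) {
    message("dropped ", sum(onlyN), " record(s) consisting only of N")
    seqs <- seqs[!onlyN]
  }
  seqs
}

## spell the nucleotide sequence of a path from vertex labels:
## first label in full, then each subsequent label minus its (k-1) overlap
.spellPath <- function(labels, path, k)
  paste0(labels[path[1L]],
         paste(substring(labels[path[-1L]], k), collapse = ""))

#' Write enumerated bubbles to TSV (and optionally FASTA)
#'
#' The TSV has one row per bubble (columns s, t, len1, len2, path1, path2,
#' paths comma-separated), sorted by source id then canonical path key, and
#' a footer comment recording the bubble count and which stop condition, if
#' any, fired.  With vertex labels and \code{k}, a FASTA with two records
#' per bubble (\code{bubble<i>_upper} = path1, \code{bubble<i>_lower} =
#' path2) spells the two alternative sequences.
#'
#' @param bs a \code{\linkS4class{BubbleSet}}.
#' @param file TSV output path.
#' @param labels optional vertex labels (used in both TSV and FASTA).
#' @param k k-mer length (required for FASTA output).
#' @param fastaFile optional FASTA output path.
#' @return \code{file}, invisibly.
#' @export
writeBubbles <- function(bs, file, labels = NULL, k = NULL,
                         fastaFile = NULL) {
  ord <- order(vapply(bs@bubbles, function(b) b@s, 1L),
               vapply(bs@bubbles, .bubbleKey, ""))
  bubbles <- bs@bubbles[ord]
  tab <- bubbleTable(new("BubbleSet", bubbles = bubbles,
                         status = bs@status, stats = list()),
                     labels = labels)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  if (nrow(tab))
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("# bubbles=%d", length(bubbles)), con)
  if (bs@status != "complete")
    writeLines(sprintf("# stopped=%s", bs@status), con)
  if (!is.null(fastaFile)) {
    if (is.null(labels) || is.null(k))
      stop("FASTA output requires vertex labels and k")
    recs <- character(0)
    for (i in seq_along(bubbles)) {
      b <- bubbles[[i]]
      recs <- c(recs,
                sprintf(">bubble%d_upper", i), .spellPath(labels, b@path1, k),
                sprintf(">bubble%d_lower", i), .spellPath(labels, b@path2, k))
    }
    writeLines(recs, fastaFile)
  }
  invisible(file)
}
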