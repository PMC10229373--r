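#' Read a genome assembly from FASTA
#'
#' Reads a (possibly line-wrapped, CRLF, mixed-case) multi-record FASTA file
#' and returns a [Biostrings::DNAStringSet]. Sequence identifiers are the
#' first whitespace-delimited token of each header, which is how all
#' evidence-file reconciliation in this package matches sequences.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` with unique names.
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("FASTA file contains no sequences: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in assembly: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}
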