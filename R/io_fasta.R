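# FASTA IO via Biostrings.

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector (or single string with `name`).
#' @param path Output path.
#' @param name Sequence name used when `sequences` is unnamed.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, name = "seq") {
  if (is.null(names(sequences)))
    names(sequences) <- if (length(sequences) == 1L) name
                        else paste0(name, "_", seq_along(sequences))
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
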