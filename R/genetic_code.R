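# Genetic-code registry and codon bookkeeping shared by the codon-usage,
# rate and Pcl modules. Family structure is always derived from the code
# table itself, never hard-coded per amino acid.

.code_cache <- new.env(parent = emptyenv())

#' Genetic-code table by NCBI translation-table number
#'
#' Thin registry over [Biostrings::getGeneticCode()]. The package default is
#' code 4 (mold mitochondrial), in which `TGA` encodes tryptophan and the
#' stops are `TAA`/`TAG`.
#'
#' @param code_id Integer NCBI translation-table number (default 4).
#' @return Named character vector of length 64 mapping codons (DNA alphabet)
#'   to one-letter amino acids, with `"*"` for stops.
#' @examples
#' genetic_code(4)[c("TGA", "TAA", "ATG")]
#' @export
genetic_code <- function(code_id = 4) {
  key <- as.character(code_id)
  if (!is.null(.code_cache[[key]])) return(.code_cache[[key]])
  gc <- tryCatch(Biostrings::getGeneticCode(key),
                 error = function(e) stop("unknown genetic code id: ", code_id,
                                          call. = FALSE))
  gc <- setNames(as.character(gc), names(gc))
  .code_cache[[key]] <- gc
  gc
}

#' All 64 codons in fixed lexicographic (TCAG-free, A<C<G<T) order
#' @noRd
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Sense (non-stop) codons under a code
#' @noRd
sense_codons <- function(code_id = 4) {
  gc <- genetic_code(code_id)
  names(gc)[gc != "*"]
}

#' Synonymous families under a code
#'
#' @param code_id NCBI translation-table number.
#' @return Named list: one character vector of codons per amino acid
#'   (stops excluded).
#' @export
synonymous_families <- function(code_id = 4) {
  gc <- genetic_code(code_id)
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

#' Translate a CDS string under a numbered genetic code
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @param code_id NCBI translation-table number.
#' @return One-letter amino-acid string (stops as `*`).
#' @export
translate_cds <- function(cds, code_id = 4) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length not divisible by 3", call. = FALSE)
  paste(genetic_code(code_id)[split_codons(cds)], collapse = "")
}

#' Split a nucleotide string into codons
#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Reverse complement of a DNA string (IUPAC-safe via Biostrings)
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Complement (no reversal)
#' @noRd
complement_seq <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

#' Reverse (no complement)
#' @noRd
reverse_seq <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}
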