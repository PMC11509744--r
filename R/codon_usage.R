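# Codon counting, RSCU and terminal-codon extraction under a selectable
# NCBI genetic code (default 4, mold mitochondrial).

#' Count codons over a set of CDS sequences
#'
#' Counting is invariant to the order and grouping of the input sequences.
#' Codons containing `N` are excluded from the 64-codon counts and reported
#' in the `n_containing` attribute.
#'
#' @param cds_set Character vector (or list) of CDS strings, each of length
#'   divisible by 3.
#' @param code_id NCBI genetic-code number (default 4).
#' @return `data.frame` of class `codon_usage_table` with one row per codon:
#'   `codon`, `amino_acid` (one-letter, `*` for stop), `count`; attributes
#'   `code_id`, `n_containing`.
#' @examples
#' codon_counts("ATGTAA")
#' @export
codon_counts <- function(cds_set, code_id = 4) {
  cds_set <- toupper(unlist(cds_set, use.names = FALSE))
  gc <- genetic_code(code_id)
  codons <- all_codons()
  counts <- setNames(integer(64), codons)
  n_containing <- 0L
  for (i in seq_along(cds_set)) {
    s <- cds_set[i]
    if (nchar(s) %% 3L != 0L)
      stop("CDS ", i, " length ", nchar(s), " not divisible by 3",
           call. = FALSE)
    cc <- split_codons(s)
    withN <- grepl("N", cc, fixed = TRUE)
    n_containing <- n_containing + sum(withN)
    tab <- table(factor(cc[!withN], levels = codons))
    counts <- counts + as.integer(tab)
  }
  structure(data.frame(codon = codons, amino_acid = unname(gc[codons]),
                       count = unname(counts)),
            class = c("codon_usage_table", "data.frame"),
            code_id = code_id, n_containing = n_containing)
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = family size x count(c) / total count of c's synonymous family.
#' Uniform usage within a family gives RSCU 1 for all members. Stop codons
#' are excluded; a family with zero total count has `NA` (undefined) RSCU.
#' The family structure is derived from the active code table, so e.g.
#' tryptophan is a 2-fold family (`TGA`,`TGG`) under code 4.
#'
#' @param table A `codon_usage_table` from [codon_counts()].
#' @return The table with an `rscu` column added (NA for stop codons and
#'   unused families).
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  code_id <- attr(table, "code_id")
  fams <- synonymous_families(code_id)
  table$rscu <- NA_real_
  for (fam in fams) {
    idx <- match(fam, table$codon)
    tot <- sum(table$count[idx])
    if (tot > 0L)
      table$rscu[idx] <- length(fam) * table$count[idx] / tot
  }
  table
}

#' First and last codon of a CDS
#'
#' @param cds CDS string, length at least 6 and divisible by 3.
#' @return Character vector `c(start, stop)`.
#' @examples
#' terminal_codons("ATGTAA")
#' @export
terminal_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 6L) stop("CDS shorter than two codons", call. = FALSE)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  c(start = substr(cds, 1L, 3L), stop = substr(cds, n - 2L, n))
}

#' Genome-level codon usage table
#'
#' Splices and pools the coding sequences of a genome. The default CDS set
#' is all protein-coding features (typical PCGs plus free-standing ORFs);
#' `pcg_only = TRUE` restricts it to the typical PCGs.
#'
#' @param genome An [annotated_genome()] with sequence.
#' @param code_id NCBI genetic-code number.
#' @param pcg_only Restrict to category `"PCG"` features.
#' @return A `codon_usage_table` with RSCU column ([rscu()] applied).
#' @export
genome_codon_usage <- function(genome, code_id = 4, pcg_only = FALSE) {
  cats <- if (pcg_only) "PCG" else c("PCG", "ORF")
  nm <- vapply(genome$features, `[[`, character(1), "name")
  keep <- vapply(genome$features, `[[`, character(1), "category") %in% cats
  cds <- vapply(nm[keep], function(x) splice_cds(genome, x, code_id),
                character(1))
  rscu(codon_counts(cds, code_id))
}
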