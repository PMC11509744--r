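# Base composition, strand skews, exclusive region partition, and the
# between-genome contribution-rate decomposition of size differences.

#' Base composition and strand skews
#'
#' Counts A/C/G/T/N (case-insensitive) and computes GC/AT percentages and
#' the strand skews AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C) on
#' the forward strand. `N` bases are excluded from percentages and skew
#' denominators. A skew whose denominator is zero is reported as `NA`
#' (explicitly undefined), never silently 0.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N`.
#' @return List of class `composition_stats`: counts `a,c,g,t,n`, `length`,
#'   `gc_percent`, `at_percent`, `at_skew`, `gc_skew`.
#' @examples
#' base_composition("GGGC")$gc_skew  # (3-1)/4 = 0.5
#' @export
base_composition <- function(sequence) {
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L)
    stop("invalid character '", substr(sequence, bad, bad),
         "' at position ", bad, call. = FALSE)
  counts <- vapply(c(a = "A", c = "C", g = "G", t = "T", n = "N"),
                   function(b) {
                     lengths(regmatches(sequence, gregexpr(b, sequence,
                                                           fixed = TRUE)))
                   }, integer(1))
  a <- counts[["a"]]; c_ <- counts[["c"]]; g <- counts[["g"]]
  t_ <- counts[["t"]]
  acgt <- a + c_ + g + t_
  structure(list(
    a = a, c = c_, g = g, t = t_, n = counts[["n"]],
    length = nchar(sequence),
    gc_percent = if (acgt > 0) 100 * (g + c_) / acgt else NA_real_,
    at_percent = if (acgt > 0) 100 * (a + t_) / acgt else NA_real_,
    at_skew = if (a + t_ > 0) (a - t_) / (a + t_) else NA_real_,
    gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_),
    class = "composition_stats")
}

REGION_CATEGORIES <- c("pcg_exon", "intron", "trna", "rrna_exon", "free_orf",
                       "intergenic")

#' Exclusive region partition of a genome
#'
#' Assigns every base of the genome to exactly one category: PCG exon,
#' intron (intronic ORFs folded in), tRNA, rRNA exon, free-standing ORF, or
#' intergenic. Categories are exhaustive: their lengths sum to the genome
#' length.
#'
#' @param genome A validated [annotated_genome()].
#' @return Named list of class `region_partition` with the six category
#'   lengths (bp) and `total`.
#' @export
region_partition <- function(genome) {
  iss <- validate_genome(genome)
  if (any(iss$code %in% c("overlap", "intron_overlap", "bounds", "coords")))
    stop("cannot partition an invalid genome:\n  ",
         paste(iss$message[iss$severity == "error"], collapse = "\n  "),
         call. = FALSE)
  out <- setNames(numeric(length(REGION_CATEGORIES)), REGION_CATEGORIES)
  for (f in genome$features) {
    span <- f$end - f$start + 1L
    intron_bp <- sum(vapply(f$introns, function(i) i$end - i$start + 1L,
                            integer(1)))
    out["intron"] <- out["intron"] + intron_bp
    exon_bp <- span - intron_bp
    key <- switch(f$category, PCG = "pcg_exon", tRNA = "trna",
                  rRNA = "rrna_exon", ORF = "free_orf")
    out[key] <- out[key] + exon_bp
  }
  out["intergenic"] <- genome$length - sum(out)
  out <- setNames(as.list(as.integer(out)), names(out))
  structure(c(out, list(total = genome$length)),
            class = "region_partition")
}

#' Contribution of each region to a between-genome size difference
#'
#' For two region partitions with different totals, computes per category
#' the signed size difference (b minus a) and its contribution percent,
#' size difference of the region / size difference of the entire genome x
#' 100. The percents sum to 100 whenever the total difference is nonzero;
#' equal totals yield an explicitly undefined table (`NA` percents), not a
#' division by zero.
#'
#' @param partition_a,partition_b [region_partition()] results.
#' @return `data.frame` of class `contribution_table`: `category`,
#'   `size_a`, `size_b`, `difference`, `contribution_percent`.
#' @export
contribution_rates <- function(partition_a, partition_b) {
  stopifnot(inherits(partition_a, "region_partition"),
            inherits(partition_b, "region_partition"))
  delta_total <- partition_b$total - partition_a$total
  size_a <- unlist(partition_a[REGION_CATEGORIES])
  size_b <- unlist(partition_b[REGION_CATEGORIES])
  delta <- size_b - size_a
  pct <- if (delta_total == 0) rep(NA_real_, length(delta))
         else 100 * delta / delta_total
  structure(data.frame(category = REGION_CATEGORIES, size_a = size_a,
                       size_b = size_b, difference = delta,
                       contribution_percent = pct, row.names = NULL),
            class = c("contribution_table", "data.frame"))
}
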