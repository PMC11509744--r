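# Long-repeat detection in four orientations with Hamming mismatch
# tolerance (REPuter parameter semantics) and MISA-style SSR detection.

#' Find long repeats in four orientations
#'
#' Reports maximal repeat pairs: windows that cannot be extended on either
#' side without exceeding `max_mismatch` Hamming mismatches or running off
#' the sequence. Orientations: `F` compares the sequence against itself,
#' `R` against its reverse, `C` against its complement, `P` against its
#' reverse complement (palindromic). `N` never matches. Trivial
#' self-identity (a window paired with itself on the forward strand) is
#' excluded and symmetric duplicates are collapsed to `pos1 <= pos2`.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N`.
#' @param min_length Minimum repeat length in bp (default 30; values below
#'   8 are rejected as degenerate parameterizations).
#' @param max_mismatch Maximum Hamming distance between the two copies
#'   (default 3).
#' @param orientations Subset of `c("F","R","C","P")`.
#' @param cap Maximum number of hits returned, longest first (default 5000).
#' @param circular If `TRUE`, a `min_length - 1` bp wrap pad is appended and
#'   wrap hits are mapped back onto the circle.
#' @return `data.frame` of class `repeat_hits`: `orientation`, `pos1`,
#'   `pos2` (1-based starts of the two copies on the input sequence),
#'   `length`, `mismatches`; sorted by length descending.
#' @export
find_repeats <- function(sequence, min_length = 30, max_mismatch = 3,
                         orientations = c("F", "R", "C", "P"), cap = 5000,
                         circular = FALSE) {
  sequence <- toupper(sequence)
  if (min_length < 8)
    stop("min_length must be >= 8", call. = FALSE)
  orientations <- match.arg(orientations, c("F", "R", "C", "P"),
                            several.ok = TRUE)
  n0 <- nchar(sequence)
  s <- sequence
  if (circular && n0 >= min_length)
    s <- paste0(sequence, substr(sequence, 1L, min_length - 1L))
  n <- nchar(s)
  res <- list()
  for (ori in orientations) {
    t <- switch(ori, F = s, R = reverse_seq(s), C = complement_seq(s),
                P = revcomp(s))
    drange <- if (ori == "F") c(1L, n - 1L)
              else if (ori == "C") c(1L, n - 1L)
              else c(-(n - 1L), n - 1L)
    hits <- .diagonal_maximal_pairs(s, t, as.integer(min_length),
                                    as.integer(max_mismatch),
                                    drange[1], drange[2])
    if (nrow(hits) == 0L) next
    i <- hits[, "i"]; j <- hits[, "j"]; len <- hits[, "len"]
    pos2 <- switch(ori, F = j, C = j, R = n - j - len + 2L,
                   P = n - j - len + 2L)
    pos1 <- pmin(i, pos2); pos2 <- pmax(i, pos2)
    df <- data.frame(orientation = ori, pos1 = pos1, pos2 = pos2,
                     length = len, mismatches = hits[, "mm"])
    df <- df[!duplicated(df), , drop = FALSE]
    if (ori == "F") df <- df[df$pos1 != df$pos2, , drop = FALSE]
    if (circular) {
      # map pad coordinates back and drop duplicates of in-range hits
      df <- df[df$pos1 <= n0, , drop = FALSE]
      df$pos2 <- ifelse(df$pos2 > n0, df$pos2 - n0, df$pos2)
      p1 <- pmin(df$pos1, df$pos2); df$pos2 <- pmax(df$pos1, df$pos2)
      df$pos1 <- p1
      df <- df[!duplicated(df), , drop = FALSE]
    }
    res[[ori]] <- df
  }
  out <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(orientation = character(0), pos1 = integer(0),
               pos2 = integer(0), length = integer(0),
               mismatches = integer(0))
  out <- out[order(-out$length, out$pos1, out$pos2, out$orientation), ,
             drop = FALSE]
  rownames(out) <- NULL
  out <- head(out, cap)
  class(out) <- c("repeat_hits", "data.frame")
  out
}

MISA_DEFAULT_THRESHOLDS <- c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L,
                             `5` = 5L, `6` = 5L)

#' Find microsatellites (SSRs), MISA-style
#'
#' Detects maximal perfect tandem runs of 1-6 bp units meeting per-unit
#' copy-number thresholds. Runs whose motif is itself periodic (a tandem of
#' a shorter unit) are suppressed: they are reported at the shorter unit
#' length. Only complete copies are counted, so `end - start + 1 =
#' unit_length * copies`. Runs separated by at most `compound_distance` bp
#' share a `compound_group` id.
#'
#' @param sequence Nucleotide string.
#' @param thresholds Named integer vector of minimum copy numbers per unit
#'   length 1..6 (MISA defaults `10/6/5/5/5/5`).
#' @param compound_distance Maximum interruption distance (bp) for two SSRs
#'   to form a compound SSR (default 100).
#' @return `data.frame` of class `ssr_hits`: `motif` (unit as it occurs),
#'   `motif_class` (canonical class such as `"AAT/ATT"`), `unit_length`,
#'   `copies`, `start`, `end`, `compound_group` (NA for singletons).
#' @export
find_ssrs <- function(sequence, thresholds = MISA_DEFAULT_THRESHOLDS,
                      compound_distance = 100) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  x <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(x)
  valid <- x %in% c("A", "C", "G", "T")
  rows <- list()
  for (u in as.integer(names(thresholds))) {
    min_copies <- thresholds[[as.character(u)]]
    if (n < u * min_copies) next
    eq <- x[seq_len(n - u)] == x[(u + 1L):n] &
      valid[seq_len(n - u)] & valid[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= u * (min_copies - 1L))) {
      run_start <- starts[k]
      copies <- r$lengths[k] %/% u + 1L
      if (copies < min_copies) next
      motif <- substr(sequence, run_start, run_start + u - 1L)
      if (!is_primitive_motif(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, motif_class = motif_class(motif),
        unit_length = u, copies = copies, start = run_start,
        end = run_start + copies * u - 1L)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(motif = character(0), motif_class = character(0),
               unit_length = integer(0), copies = integer(0),
               start = integer(0), end = integer(0))
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out$compound_group <- rep(NA_integer_, nrow(out))
  if (nrow(out) > 1L) {
    gap_ok <- out$start[-1] - out$end[-nrow(out)] - 1L <= compound_distance
    grp <- cumsum(c(TRUE, !gap_ok))
    sizes <- table(grp)
    multi <- as.integer(names(sizes)[sizes > 1L])
    ids <- match(grp, multi)
    out$compound_group <- ids
  }
  class(out) <- c("ssr_hits", "data.frame")
  out
}

#' Is a motif primitive (not a tandem of a shorter unit)?
#' @noRd
is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (paste(rep(unit, u %/% d), collapse = "") == motif) return(FALSE)
  }
  TRUE
}

#' Canonical SSR motif class (rotations and reverse complement)
#'
#' Lexicographic minimum over rotations of the motif and of its reverse
#' complement, MISA-style, e.g. `motif_class("TTA")` is `"AAT/ATT"`.
#'
#' @param motif Unit string (1-6 bp).
#' @return Class label `"X/Y"`.
#' @export
motif_class <- function(motif) {
  motif <- toupper(motif)
  canon_rot <- function(m) {
    u <- nchar(m)
    rots <- vapply(seq_len(u), function(k)
      paste0(substr(m, k, u), substr(m, 1, k - 1L)), character(1))
    min(rots)
  }
  paste(sort(c(canon_rot(motif), canon_rot(revcomp(motif)))), collapse = "/")
}

#' Assign detector hits to genomic region categories
#'
#' Labels each repeat or SSR hit with the region categories (see
#' [region_partition()]) that its span(s) overlap. Repeat hits contribute
#' both copies; a hit spanning a boundary reports every category touched.
#'
#' @param hits A `repeat_hits` or `ssr_hits` data.frame.
#' @param genome A validated [annotated_genome()] for the same sequence.
#' @return `hits` with a `regions` character column (comma-separated
#'   category labels, in [REGION_CATEGORIES] order).
#' @export
locate_hits <- function(hits, genome) {
  spans <- if (all(c("pos1", "pos2", "length") %in% names(hits))) {
    rbind(data.frame(row = seq_len(nrow(hits)), start = hits$pos1,
                     end = hits$pos1 + hits$length - 1L),
          data.frame(row = seq_len(nrow(hits)), start = hits$pos2,
                     end = hits$pos2 + hits$length - 1L))
  } else if (all(c("start", "end") %in% names(hits))) {
    data.frame(row = seq_len(nrow(hits)), start = hits$start,
               end = hits$end)
  } else stop("hits must carry pos1/pos2/length or start/end columns",
              call. = FALSE)
  if (nrow(spans) > 0L && (min(spans$start) < 1L ||
                           max(spans$end) > genome$length))
    stop("hit coordinates outside genome bounds", call. = FALSE)
  regions <- region_ranges(genome)
  hit_ir <- IRanges::IRanges(start = spans$start, end = spans$end)
  labels <- rep(list(character(0)), nrow(hits))
  for (cat in names(regions)) {
    ov <- IRanges::findOverlaps(hit_ir, regions[[cat]])
    for (q in unique(S4Vectors::queryHits(ov))) {
      r <- spans$row[q]
      labels[[r]] <- union(labels[[r]], cat)
    }
  }
  hits$regions <- vapply(labels, function(l)
    paste(REGION_CATEGORIES[REGION_CATEGORIES %in% l], collapse = ","),
    character(1))
  hits
}

#' Region category intervals of a genome as IRanges
#' @noRd
region_ranges <- function(genome) {
  acc <- setNames(vector("list", length(REGION_CATEGORIES)),
                  REGION_CATEGORIES)
  add <- function(cat, start, end) {
    acc[[cat]][[length(acc[[cat]]) + 1L]] <<- c(start, end)
  }
  for (f in genome$features) {
    key <- switch(f$category, PCG = "pcg_exon", tRNA = "trna",
                  rRNA = "rrna_exon", ORF = "free_orf")
    seg <- exon_segments(f)
    for (k in seq_len(nrow(seg))) add(key, seg$start[k], seg$end[k])
    for (it in f$introns) add("intron", it$start, it$end)
  }
  out <- list()
  genic <- IRanges::IRanges()
  for (cat in setdiff(REGION_CATEGORIES, "intergenic")) {
    m <- if (is.null(acc[[cat]])) NULL else do.call(rbind, acc[[cat]])
    out[[cat]] <- if (is.null(m)) IRanges::IRanges() else
      IRanges::IRanges(start = m[, 1], end = m[, 2])
    genic <- c(genic, out[[cat]])
  }
  out$intergenic <- IRanges::setdiff(
    IRanges::IRanges(start = 1L, end = genome$length),
    IRanges::reduce(genic))
  out
}
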