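# In-memory model of a circular annotated mitogenome: an ordered feature
# list with nested introns and intronic ORFs. Coordinates are 1-based,
# inclusive, on the deposited (forward) strand; no top-level feature wraps
# the origin.

FEATURE_CATEGORIES <- c("PCG", "tRNA", "rRNA", "ORF")
INTRON_GROUPS <- c("IA", "IB", "IC1", "IC2", "ID", "I-derived", "II", "unknown")
ORF_PRODUCT_CLASSES <- c("L", "G", "R", "H", "U")

#' Intronic ORF record
#'
#' @param id ORF identifier (e.g. `"orf315"`).
#' @param start,end 1-based inclusive genome coordinates.
#' @param product_class One of `"L"` (LAGLIDADG endonuclease), `"G"`
#'   (GIY-YIG endonuclease), `"R"` (ribosomal protein), `"H"` (hypothetical
#'   protein), `"U"` (unknown).
#' @param start_codon,stop_codon Optional 3-letter codons.
#' @return A `mito_orf` list.
#' @export
mito_orf <- function(id, start, end, product_class = "U",
                     start_codon = NA_character_, stop_codon = NA_character_) {
  product_class <- match.arg(product_class, ORF_PRODUCT_CLASSES)
  structure(list(id = as.character(id), start = as.integer(start),
                 end = as.integer(end), product_class = product_class,
                 start_codon = as.character(start_codon),
                 stop_codon = as.character(stop_codon)),
            class = "mito_orf")
}

#' Intron record
#'
#' @param id Intron identifier (e.g. `"cox1-i3"`).
#' @param start,end 1-based inclusive genome coordinates.
#' @param group Intron group: one of `"IA"`, `"IB"`, `"IC1"`, `"IC2"`,
#'   `"ID"`, `"I-derived"`, `"II"`, `"unknown"` (`"unknown"` corresponds to
#'   "not identified" annotations).
#' @param standard_name Optional published name (e.g. `"cox1P281"`).
#' @param note Optional one-letter product annotation carried by the intron
#'   row of an annotation table (same vocabulary as ORF product classes).
#' @param orfs List of [mito_orf()] records.
#' @return A `mito_intron` list.
#' @export
mito_intron <- function(id, start, end, group = "unknown",
                        standard_name = NA_character_, note = NA_character_,
                        orfs = list()) {
  group <- match.arg(group, INTRON_GROUPS)
  structure(list(id = as.character(id), start = as.integer(start),
                 end = as.integer(end), group = group,
                 standard_name = as.character(standard_name),
                 note = as.character(note), orfs = orfs),
            class = "mito_intron")
}

#' Top-level feature record
#'
#' @param name Feature name (e.g. `"cox1"`, `"trnV-UAC"`).
#' @param category One of `"PCG"`, `"tRNA"`, `"rRNA"`, `"ORF"`.
#' @param start,end 1-based inclusive genome coordinates (no wrap).
#' @param strand `"+"` or `"-"`.
#' @param anticodon Optional 3-letter anticodon (tRNAs).
#' @param start_codon,stop_codon Optional 3-letter codons (PCGs/ORFs).
#' @param introns List of [mito_intron()] records, genome coordinates.
#' @return A `mito_feature` list.
#' @export
mito_feature <- function(name, category, start, end, strand = "+",
                         anticodon = NA_character_,
                         start_codon = NA_character_,
                         stop_codon = NA_character_, introns = list()) {
  category <- match.arg(category, FEATURE_CATEGORIES)
  stopifnot(strand %in% c("+", "-"))
  structure(list(name = as.character(name), category = category,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, anticodon = as.character(anticodon),
                 start_codon = as.character(start_codon),
                 stop_codon = as.character(stop_codon), introns = introns),
            class = "mito_feature")
}

#' Annotated circular mitogenome
#'
#' @param id Genome identifier.
#' @param length Genome length in bp.
#' @param features List of [mito_feature()] records; sorted by start on
#'   construction.
#' @param sequence Optional nucleotide string over `A,C,G,T,N` of length
#'   `length` (table-only genomes carry `NULL`).
#' @param circular Logical; the model targets circular molecules.
#' @param check If `TRUE` (default), stop on any error-severity issue from
#'   [validate_genome()]; warnings are signalled but do not stop.
#' @return An `annotated_genome` object.
#' @export
annotated_genome <- function(id, length, features = list(), sequence = NULL,
                             circular = TRUE, check = TRUE) {
  length <- as.integer(length)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    bad <- regexpr("[^ACGTN]", sequence)
    if (bad > 0L)
      stop("invalid character in sequence at position ", bad, call. = FALSE)
  }
  ord <- order(vapply(features, `[[`, integer(1), "start"))
  g <- structure(list(id = as.character(id), length = length,
                      sequence = sequence, circular = isTRUE(circular),
                      features = features[ord]),
                 class = "annotated_genome")
  if (check) {
    iss <- validate_genome(g)
    err <- iss[iss$severity == "error", , drop = FALSE]
    if (nrow(err) > 0L)
      stop("invalid genome '", id, "':\n  ",
           paste(err$message, collapse = "\n  "), call. = FALSE)
    for (m in iss$message[iss$severity == "warning"]) warning(m, call. = FALSE)
  }
  g
}

#' @export
print.annotated_genome <- function(x, ...) {
  cats <- table(factor(vapply(x$features, `[[`, character(1), "category"),
                       levels = FEATURE_CATEGORIES))
  cat(sprintf("annotated_genome '%s': %s bp, %s, %d features (%s)%s\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              length(x$features),
              paste(names(cats), cats, sep = "=", collapse = ", "),
              if (is.null(x$sequence)) ", table-only" else ""))
  invisible(x)
}

#' Validate an annotated genome
#'
#' Checks the model invariants and returns an issue list without raising:
#' coordinates within `[1, length]`, `end >= start`, no top-level feature
#' overlap, introns strictly inside their host and mutually non-overlapping,
#' PCG exonic length divisible by 3 (frame), intronic ORFs contained in their
#' host intron (boundary spill-over is a warning, as printed annotation
#' tables contain such rows), and sequence length agreement.
#'
#' @param genome An [annotated_genome()].
#' @return `data.frame` with columns `severity` (`"error"`/`"warning"`),
#'   `code`, `message`; zero rows when clean.
#' @export
validate_genome <- function(genome) {
  iss <- list()
  add <- function(severity, code, message)
    iss[[length(iss) + 1L]] <<- data.frame(severity = severity, code = code,
                                           message = message)
  if (!is.null(genome$sequence) && nchar(genome$sequence) != genome$length)
    add("error", "seq_length", sprintf(
      "sequence length %d != declared length %d",
      nchar(genome$sequence), genome$length))
  if (length(genome$features) == 0L)
    add("warning", "empty", "genome has no features")
  nm <- vapply(genome$features, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    add("error", "dup_name", paste("duplicate feature names:",
        paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  prev_end <- 0L; prev_name <- NA_character_
  for (f in genome$features) {
    if (f$end < f$start)
      add("error", "coords", sprintf("%s: end %d < start %d",
                                     f$name, f$end, f$start))
    if (f$start < 1L || f$end > genome$length)
      add("error", "bounds", sprintf(
        "%s: span %d..%d outside [1, %d]", f$name, f$start, f$end,
        genome$length))
    if (f$start <= prev_end)
      add("error", "overlap", sprintf("features %s and %s overlap",
                                      prev_name, f$name))
    prev_end <- f$end; prev_name <- f$name
    ints <- f$introns
    if (length(ints) > 0L) {
      io <- order(vapply(ints, `[[`, integer(1), "start"))
      ints <- ints[io]
      ip_end <- -1L
      for (it in ints) {
        if (it$end < it$start)
          add("error", "coords", sprintf("%s: end %d < start %d",
                                         it$id, it$end, it$start))
        if (it$start <= f$start || it$end >= f$end)
          add("error", "intron_bounds", sprintf(
            "%s: intron %d..%d not strictly inside host %s (%d..%d)",
            it$id, it$start, it$end, f$name, f$start, f$end))
        if (it$start <= ip_end)
          add("error", "intron_overlap",
              sprintf("overlapping introns in %s at %s", f$name, it$id))
        ip_end <- it$end
        for (o in it$orfs) {
          if (o$start < it$start || o$end > it$end)
            add("warning", "orf_spill", sprintf(
              "intronic ORF %s (%d..%d) not contained in intron %s (%d..%d)",
              o$id, o$start, o$end, it$id, it$start, it$end))
        }
      }
    }
    if (f$category == "PCG") {
      ex <- tryCatch(exonic_length(f), error = function(e) NA_integer_)
      if (!is.na(ex) && ex %% 3L != 0L)
        # warning, not error: foreign annotations (pseudogenes, frameshifted
        # CDSs) do occur; splicing such a feature still fails loudly
        add("warning", "frame", sprintf(
          "PCG %s: exonic length %d not divisible by 3", f$name, ex))
    }
  }
  if (length(iss) == 0L)
    return(data.frame(severity = character(0), code = character(0),
                      message = character(0)))
  do.call(rbind, iss)
}

#' Exonic (spliced) length of a feature in bp
#'
#' Span length minus the summed lengths of its introns.
#'
#' @param feature A [mito_feature()].
#' @return Integer bp.
#' @export
exonic_length <- function(feature) {
  ints <- feature$introns
  if (length(ints) > 1L) {
    st <- vapply(ints, `[[`, integer(1), "start")
    en <- vapply(ints, `[[`, integer(1), "end")
    o <- order(st)
    if (any(st[o][-1] <= en[o][-length(o)]))
      stop("overlapping introns in feature ", feature$name, call. = FALSE)
  }
  intron_bp <- sum(vapply(ints, function(i) i$end - i$start + 1L, integer(1)))
  (feature$end - feature$start + 1L) - as.integer(intron_bp)
}

#' Exon segments of a feature (genome coordinates, ascending)
#' @noRd
exon_segments <- function(feature) {
  ints <- feature$introns
  if (length(ints) == 0L)
    return(data.frame(start = feature$start, end = feature$end))
  st <- sort(vapply(ints, `[[`, integer(1), "start"))
  en <- sort(vapply(ints, `[[`, integer(1), "end"))
  data.frame(start = c(feature$start, en + 1L), end = c(st - 1L, feature$end))
}

#' Intergenic gap table of a circular genome
#'
#' One gap per adjacent top-level feature pair, including the wrap-around gap
#' from the last feature back to the first. On a valid circular genome the
#' conservation invariant holds: sum of feature spans plus sum of gaps equals
#' the genome length.
#'
#' @param genome A validated circular [annotated_genome()].
#' @return `data.frame` with columns `upstream_feature`, `downstream_feature`,
#'   `gap_length`, `wraps_origin`.
#' @export
gap_table <- function(genome) {
  f <- genome$features
  if (length(f) == 0L) stop("genome has no features", call. = FALSE)
  iss <- validate_genome(genome)
  if (any(iss$code == "overlap"))
    stop("overlapping features: gaps undefined", call. = FALSE)
  nm <- vapply(f, `[[`, character(1), "name")
  st <- vapply(f, `[[`, integer(1), "start")
  en <- vapply(f, `[[`, integer(1), "end")
  n <- length(f)
  if (n == 1L) {
    return(data.frame(upstream_feature = nm, downstream_feature = nm,
                      gap_length = genome$length - (en - st + 1L),
                      wraps_origin = TRUE))
  }
  data.frame(
    upstream_feature = nm,
    downstream_feature = c(nm[-1], nm[1]),
    gap_length = c(st[-1] - en[-n] - 1L,
                   (genome$length - en[n]) + (st[1] - 1L)),
    wraps_origin = c(rep(FALSE, n - 1L), TRUE))
}

#' Extract and splice the coding sequence of a feature
#'
#' Concatenates the exon segments 5' to 3' (reverse-complementing
#' minus-strand features). For PCGs the result is checked for frame and for
#' internal stop codons under the active genetic code; the recorded start
#' codon, when present, is compared with a warning on mismatch.
#'
#' @param genome An [annotated_genome()] carrying a sequence.
#' @param feature_name Name of the feature to splice.
#' @param code_id NCBI genetic-code number used for the stop check.
#' @param check_stops If `TRUE` (default), error on internal stops in PCGs.
#' @return Nucleotide string.
#' @export
splice_cds <- function(genome, feature_name, code_id = 4, check_stops = TRUE) {
  if (is.null(genome$sequence))
    stop("genome '", genome$id, "' has no sequence", call. = FALSE)
  f <- find_feature(genome, feature_name)
  seg <- exon_segments(f)
  cds <- paste(substring(genome$sequence, seg$start, seg$end), collapse = "")
  if (f$strand == "-") cds <- revcomp(cds)
  if (f$category %in% c("PCG", "ORF")) {
    if (nchar(cds) %% 3L != 0L)
      stop(feature_name, ": exonic length ", nchar(cds),
           " not divisible by 3", call. = FALSE)
    aa <- strsplit(translate_cds(cds, code_id), "", fixed = TRUE)[[1]]
    internal <- which(aa[-length(aa)] == "*")
    if (check_stops && length(internal) > 0L)
      stop(feature_name, ": internal stop codon(s) at codon index ",
           paste(internal, collapse = ", "), call. = FALSE)
    first <- substr(cds, 1L, 3L)
    if (!is.na(f$start_codon) && nzchar(f$start_codon) &&
        first != toupper(f$start_codon))
      warning(feature_name, ": first codon ", first,
              " differs from recorded start codon ", f$start_codon,
              call. = FALSE)
  }
  cds
}

#' Find a top-level feature by name
#' @noRd
find_feature <- function(genome, name) {
  for (f in genome$features) if (f$name == name) return(f)
  stop("no feature named '", name, "' in genome '", genome$id, "'",
       call. = FALSE)
}

#' Flat data.frame view of the top-level features of a genome
#'
#' @param genome An [annotated_genome()].
#' @return `data.frame` with one row per feature: name, category, start,
#'   end, strand, length, n_introns, intron_bp, exonic_length.
#' @export
feature_summary <- function(genome) {
  f <- genome$features
  data.frame(
    name = vapply(f, `[[`, character(1), "name"),
    category = vapply(f, `[[`, character(1), "category"),
    start = vapply(f, `[[`, integer(1), "start"),
    end = vapply(f, `[[`, integer(1), "end"),
    strand = vapply(f, `[[`, character(1), "strand"),
    length = vapply(f, function(x) x$end - x$start + 1L, integer(1)),
    n_introns = vapply(f, function(x) length(x$introns), integer(1)),
    intron_bp = vapply(f, function(x)
      as.integer(sum(vapply(x$introns, function(i) i$end - i$start + 1L,
                            integer(1)))), integer(1)),
    exonic_length = vapply(f, exonic_length, integer(1)))
}

#' Flat data.frame view of all introns of a genome
#'
#' @param genome An [annotated_genome()].
#' @return `data.frame` with one row per intron: host, id, start, end,
#'   length, group, standard_name, note, n_orfs.
#' @export
intron_summary <- function(genome) {
  rows <- list()
  for (f in genome$features) for (it in f$introns) {
    rows[[length(rows) + 1L]] <- data.frame(
      host = f$name, id = it$id, start = it$start, end = it$end,
      length = it$end - it$start + 1L, group = it$group,
      standard_name = it$standard_name, note = it$note,
      n_orfs = length(it$orfs))
  }
  if (length(rows) == 0L)
    return(data.frame(host = character(0), id = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), group = character(0),
                      standard_name = character(0), note = character(0),
                      n_orfs = integer(0)))
  do.call(rbind, rows)
}

#' Flat data.frame view of all intronic ORFs of a genome
#'
#' @param genome An [annotated_genome()].
#' @return `data.frame`: host gene, intron id, orf id, start, end, length,
#'   product_class.
#' @export
intronic_orf_summary <- function(genome) {
  rows <- list()
  for (f in genome$features) for (it in f$introns) for (o in it$orfs) {
    rows[[length(rows) + 1L]] <- data.frame(
      host = f$name, intron = it$id, id = o$id, start = o$start,
      end = o$end, length = o$end - o$start + 1L,
      product_class = o$product_class)
  }
  if (length(rows) == 0L)
    return(data.frame(host = character(0), intron = character(0),
                      id = character(0), start = integer(0), end = integer(0),
                      length = integer(0), product_class = character(0)))
  do.call(rbind, rows)
}
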