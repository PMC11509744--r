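# Minimal GenBank flat-file reader/writer for annotated mitogenomes.
# The writer emits gene/CDS/tRNA/rRNA/intron features with key=value /note
# qualifiers that the reader maps back onto the data model, so generator
# output round-trips exactly. Foreign files parse on a best-effort basis:
# unknown feature kinds are skipped with a message, records without an
# ORIGIN block yield a table-only genome with a warning.

#' Write a genome as a GenBank flat file
#'
#' Each top-level feature becomes a `gene` plus a `CDS`/`tRNA`/`rRNA`
#' feature whose location is the `join()` of its exon segments
#' (`complement()` on the minus strand). Introns are emitted as `intron`
#' features and intronic ORFs as nested `CDS` features, both with
#' `key=value` notes carrying group, standard name and product class.
#'
#' @param genome An [annotated_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   UNA 01-JAN-2024",
                   genome$id, genome$length,
                   if (genome$circular) "circular" else "linear"),
           sprintf("DEFINITION  %s mitochondrial genome.", genome$id),
           "FEATURES             Location/Qualifiers",
           feature_line("source", sprintf("1..%d", genome$length)),
           qualifier_line("organelle", "mitochondrion"))
  for (f in genome$features) {
    seg <- exon_segments(f)
    loc <- paste(sprintf("%d..%d", seg$start, seg$end), collapse = ",")
    if (nrow(seg) > 1L) loc <- sprintf("join(%s)", loc)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    span <- sprintf("%d..%d", f$start, f$end)
    if (f$strand == "-") span <- sprintf("complement(%s)", span)
    kind <- switch(f$category, PCG = "CDS", ORF = "CDS", tRNA = "tRNA",
                   rRNA = "rRNA")
    out <- c(out, feature_line("gene", span), qualifier_line("gene", f$name))
    notes <- c(sprintf("category=%s", f$category),
               if (!is.na(f$anticodon)) sprintf("anticodon=%s", f$anticodon),
               if (!is.na(f$start_codon)) sprintf("start_codon=%s", f$start_codon),
               if (!is.na(f$stop_codon)) sprintf("stop_codon=%s", f$stop_codon))
    out <- c(out, feature_line(kind, loc), qualifier_line("gene", f$name),
             qualifier_line("note", paste(notes, collapse = "; ")))
    for (it in f$introns) {
      notes <- c(sprintf("id=%s", it$id), sprintf("group=%s", it$group),
                 if (!is.na(it$standard_name))
                   sprintf("standard_name=%s", it$standard_name),
                 if (!is.na(it$note)) sprintf("product_note=%s", it$note))
      out <- c(out, feature_line("intron", sprintf("%d..%d", it$start, it$end)),
               qualifier_line("gene", f$name),
               qualifier_line("note", paste(notes, collapse = "; ")))
      for (o in it$orfs) {
        notes <- c("intronic_orf", sprintf("intron=%s", it$id),
                   sprintf("product_class=%s", o$product_class),
                   if (!is.na(o$start_codon))
                     sprintf("start_codon=%s", o$start_codon),
                   if (!is.na(o$stop_codon))
                     sprintf("stop_codon=%s", o$stop_codon))
        out <- c(out, feature_line("CDS", sprintf("%d..%d", o$start, o$end)),
                 qualifier_line("gene", o$id),
                 qualifier_line("note", paste(notes, collapse = "; ")))
      }
    }
  }
  if (!is.null(genome$sequence)) {
    out <- c(out, "ORIGIN", origin_block(genome$sequence))
  }
  writeLines(c(out, "//"), path)
  invisible(path)
}

feature_line <- function(kind, loc) sprintf("     %-16s%s", kind, loc)
qualifier_line <- function(key, value)
  sprintf('                     /%s="%s"', key, value)

origin_block <- function(seq) {
  n <- nchar(seq)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                             nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(groups, collapse = " ")))
  }, character(1))
}

#' Read a GenBank flat file into the genome model
#'
#' Parses the `LOCUS` line (length, topology), the feature table and the
#' `ORIGIN` block. `join()` locations of `CDS`/`tRNA`/`rRNA` features are
#' converted to a host span plus introns at the skipped segments;
#' free-standing `intron` features override/annotate those implied introns
#' when their coordinates agree. Feature kinds outside
#' `gene/CDS/tRNA/rRNA/intron/source` are skipped with a message.
#'
#' @param path Path to a GenBank flat file (single record).
#' @return An [annotated_genome()]; table-only (with a warning) when the
#'   record carries no sequence.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) stop("not a GenBank file: no LOCUS line", call. = FALSE)
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  len <- as.integer(toks[which(toks == "bp") - 1L][1])
  circular <- any(tolower(toks) == "circular")

  feat_start <- grep("^FEATURES", lines)[1]
  origin_at <- grep("^ORIGIN", lines)[1]
  end_at <- if (is.na(origin_at)) length(lines) else origin_at - 1L
  ftl <- if (!is.na(feat_start) && feat_start < end_at)
    lines[(feat_start + 1L):end_at] else character(0)

  # fold the feature table into (kind, location, qualifiers) entries
  entries <- list(); cur <- NULL
  for (ln in ftl) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      kind <- sub("^ +", "", substr(ln, 1, 20))
      kind <- strsplit(kind, "\\s+")[[1]][1]
      cur <- list(kind = kind, loc = trimws(substr(ln, 21, nchar(ln))),
                  quals = character(0))
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
      else if (length(cur$quals) > 0L)
        cur$quals[length(cur$quals)] <-
          paste0(cur$quals[length(cur$quals)], " ", txt)
      else cur$loc <- paste0(cur$loc, txt)
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur

  seq <- NULL
  if (!is.na(origin_at)) {
    body <- lines[(origin_at + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    if (!nzchar(seq)) seq <- NULL
  }
  if (is.null(seq))
    warning("GenBank record '", id, "' has no sequence; table-only genome",
            call. = FALSE)

  features <- list(); intron_extras <- list()
  for (e in entries) {
    if (e$kind %in% c("source", "gene")) next
    q <- parse_qualifiers(e$quals)
    if (e$kind %in% c("CDS", "tRNA", "rRNA")) {
      loc <- parse_location(e$loc)
      notes <- parse_kv_note(q[["note"]])
      if (identical(notes[["intronic_orf"]], "") ||
          "intronic_orf" %in% names(notes)) {
        intron_extras[[length(intron_extras) + 1L]] <- list(
          type = "orf", intron = notes[["intron"]],
          orf = mito_orf(q[["gene"]] %||% "orf", loc$segments$start[1],
                         loc$segments$end[nrow(loc$segments)],
                         product_class = notes[["product_class"]] %||% "U",
                         start_codon = notes[["start_codon"]] %||% NA_character_,
                         stop_codon = notes[["stop_codon"]] %||% NA_character_))
        next
      }
      name <- q[["gene"]] %||% q[["locus_tag"]] %||% q[["product"]] %||%
        sprintf("feat_%d", length(features) + 1L)
      category <- notes[["category"]] %||%
        switch(e$kind, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")
      span_start <- loc$segments$start[1]
      span_end <- loc$segments$end[nrow(loc$segments)]
      introns <- list()
      if (nrow(loc$segments) > 1L) {
        for (k in seq_len(nrow(loc$segments) - 1L)) {
          introns[[k]] <- mito_intron(
            sprintf("%s-i%d", name, k),
            loc$segments$end[k] + 1L, loc$segments$start[k + 1L] - 1L)
        }
      }
      features[[length(features) + 1L]] <- mito_feature(
        name, category, span_start, span_end,
        strand = if (loc$complement) "-" else "+",
        anticodon = notes[["anticodon"]] %||% NA_character_,
        start_codon = notes[["start_codon"]] %||% NA_character_,
        stop_codon = notes[["stop_codon"]] %||% NA_character_,
        introns = introns)
    } else if (e$kind == "intron") {
      loc <- parse_location(e$loc)
      notes <- parse_kv_note(q[["note"]])
      intron_extras[[length(intron_extras) + 1L]] <- list(
        type = "intron", gene = q[["gene"]],
        start = loc$segments$start[1], end = loc$segments$end[1],
        id = notes[["id"]], group = notes[["group"]],
        standard_name = notes[["standard_name"]],
        product_note = notes[["product_note"]])
    } else {
      message("read_genbank: skipping feature of kind '", e$kind, "'")
    }
  }

  # annotate implied introns with free-standing intron records
  for (x in intron_extras) {
    if (x$type != "intron") next
    for (fi in seq_along(features)) {
      f <- features[[fi]]
      if (!is.null(x$gene) && !identical(f$name, x$gene)) next
      for (ii in seq_along(f$introns)) {
        it <- f$introns[[ii]]
        if (it$start == x$start && it$end == x$end) {
          if (!is.null(x$id)) it$id <- x$id
          if (!is.null(x$group)) it$group <- .norm_group(x$group)
          if (!is.null(x$standard_name)) it$standard_name <- x$standard_name
          if (!is.null(x$product_note)) it$note <- x$product_note
          features[[fi]]$introns[[ii]] <- it
        }
      }
    }
  }
  # attach intronic ORFs by intron id (or containment as fallback)
  for (x in intron_extras) {
    if (x$type != "orf") next
    placed <- FALSE
    for (fi in seq_along(features)) {
      for (ii in seq_along(features[[fi]]$introns)) {
        it <- features[[fi]]$introns[[ii]]
        hit <- if (!is.null(x$intron)) identical(it$id, x$intron)
               else x$orf$start >= it$start && x$orf$end <= it$end
        if (hit) {
          features[[fi]]$introns[[ii]]$orfs <-
            c(it$orfs, list(x$orf))
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed)
      warning("intronic ORF '", x$orf$id, "' could not be attached",
              call. = FALSE)
  }
  annotated_genome(id = id, length = len, features = features,
                   sequence = seq, circular = circular)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_qualifiers <- function(quals) {
  out <- list()
  for (qq in quals) {
    m <- regmatches(qq, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', qq))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

parse_kv_note <- function(note) {
  if (is.null(note)) return(list())
  parts <- trimws(strsplit(note, ";", fixed = TRUE)[[1]])
  out <- list()
  for (p in parts) {
    if (grepl("=", p, fixed = TRUE)) {
      kv <- strsplit(p, "=", fixed = TRUE)[[1]]
      out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    } else if (nzchar(p)) out[[p]] <- ""
  }
  out
}

#' Parse a GenBank location string (join/complement of simple ranges)
#' @noRd
parse_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  complement <- grepl("^complement\\(", loc)
  if (complement) loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  joined <- grepl("^join\\(", loc)
  if (joined) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  seg <- lapply(parts, function(p) {
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else se <- rep(as.integer(p), 2L)
    if (any(is.na(se))) stop("cannot parse location '", p, "'", call. = FALSE)
    data.frame(start = se[1], end = se[2])
  })
  seg <- do.call(rbind, seg)
  seg <- seg[order(seg$start), , drop = FALSE]
  list(segments = seg, complement = complement)
}
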