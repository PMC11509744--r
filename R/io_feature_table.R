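# Tabular feature-table dialect: a TSV that transcribes the layout of
# printed mitogenome annotation tables (one gene row per feature, intron
# rows keyed to their host gene, intronic-ORF rows keyed to their host
# intron). Genome metadata travels in '#key=value' comment lines.

FEATURE_TABLE_COLUMNS <- c("record", "name", "host", "category", "start",
                           "end", "strand", "anticodon", "start_codon",
                           "stop_codon", "group", "standard_name", "note")

.norm_group <- function(x) {
  x <- trimws(x)
  x[x %in% c("", "NA")] <- "unknown"
  map <- c("not identified" = "unknown", "I(derived)" = "I-derived",
           "I (derived)" = "I-derived", "derived" = "I-derived",
           "IA(5')" = "IA", "IA(5′)" = "IA")
  hit <- match(x, names(map))
  x[!is.na(hit)] <- map[hit[!is.na(hit)]]
  bad <- setdiff(unique(x), INTRON_GROUPS)
  if (length(bad) > 0L)
    stop("unknown intron group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  x
}

#' Read a genome from a feature-table TSV
#'
#' The dialect has `#key=value` header comment lines (`id`, `length`,
#' `circular`), a TSV header, and one row per record with a `record` column
#' of `gene`, `intron` (with `host` = gene name) or `orf` (with `host` =
#' intron id). Sequences are not stored in the table; the result is a
#' table-only genome unless `sequence` is supplied.
#'
#' @param path Path to the TSV.
#' @param sequence Optional nucleotide string to attach.
#' @return A validated [annotated_genome()] (structural warnings signalled).
#' @export
read_feature_table <- function(path, sequence = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in sub("^#\\s*", "", meta_lines)) {
    kv <- strsplit(m, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (is.null(meta$id) || is.null(meta$length))
    stop("feature table missing '#id=' / '#length=' header lines",
         call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L)
    stop("feature table has no header row", call. = FALSE)
  tab <- read.delim(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(FEATURE_TABLE_COLUMNS, names(tab))
  if (length(missing_cols) > 0L)
    stop("feature table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  # line numbers in the original file, for parse errors
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  line_no <- body_idx[-1]  # first body line is the header

  parse_int <- function(x, i, what) {
    v <- suppressWarnings(as.integer(x))
    if (is.na(v))
      stop(sprintf("line %d: malformed %s '%s'", line_no[i], what, x),
           call. = FALSE)
    v
  }

  features <- list(); feat_of <- character(0)   # name -> index
  introns_by_gene <- list(); intron_host <- character(0)
  orfs_by_intron <- list()

  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    rec <- row$record
    start <- parse_int(row$start, i, "start")
    end <- parse_int(row$end, i, "end")
    if (end < start)
      stop(sprintf("line %d: end %d < start %d for '%s'",
                   line_no[i], end, start, row$name), call. = FALSE)
    opt <- function(x) if (is.na(x) || !nzchar(trimws(x))) NA_character_
                       else trimws(x)
    if (rec == "gene") {
      if (row$name %in% feat_of)
        stop(sprintf("line %d: duplicate feature name '%s'",
                     line_no[i], row$name), call. = FALSE)
      feat_of <- c(feat_of, row$name)
      strand <- opt(row$strand); if (is.na(strand)) strand <- "+"
      features[[row$name]] <- mito_feature(
        row$name, row$category, start, end, strand,
        anticodon = opt(row$anticodon), start_codon = opt(row$start_codon),
        stop_codon = opt(row$stop_codon))
    } else if (rec == "intron") {
      host <- trimws(row$host)
      if (!nzchar(host))
        stop(sprintf("line %d: intron '%s' has no host gene",
                     line_no[i], row$name), call. = FALSE)
      if (row$name %in% names(intron_host))
        stop(sprintf("line %d: duplicate intron id '%s'",
                     line_no[i], row$name), call. = FALSE)
      intron_host[row$name] <- host
      introns_by_gene[[host]] <- c(introns_by_gene[[host]], list(mito_intron(
        row$name, start, end, group = .norm_group(row$group),
        standard_name = opt(row$standard_name), note = opt(row$note))))
    } else if (rec == "orf") {
      host <- trimws(row$host)
      if (!nzchar(host))
        stop(sprintf("line %d: orf '%s' has no host intron",
                     line_no[i], row$name), call. = FALSE)
      pc <- opt(row$note); if (is.na(pc)) pc <- "U"
      orfs_by_intron[[host]] <- c(orfs_by_intron[[host]], list(mito_orf(
        row$name, start, end, product_class = pc,
        start_codon = opt(row$start_codon), stop_codon = opt(row$stop_codon))))
    } else {
      stop(sprintf("line %d: unknown record type '%s'", line_no[i], rec),
           call. = FALSE)
    }
  }
  # attach ORFs to introns, introns to genes
  for (host in names(introns_by_gene)) {
    if (is.null(features[[host]]))
      stop("intron host gene '", host, "' has no gene row", call. = FALSE)
    ints <- introns_by_gene[[host]]
    for (k in seq_along(ints)) {
      id <- ints[[k]]$id
      if (!is.null(orfs_by_intron[[id]])) ints[[k]]$orfs <- orfs_by_intron[[id]]
    }
    features[[host]]$introns <- ints
  }
  unattached <- setdiff(names(orfs_by_intron), names(intron_host))
  if (length(unattached) > 0L)
    stop("intronic ORF host intron(s) not found: ",
         paste(unattached, collapse = ", "), call. = FALSE)
  annotated_genome(
    id = meta$id, length = as.integer(meta$length),
    features = unname(features), sequence = sequence,
    circular = is.null(meta$circular) ||
      tolower(meta$circular) %in% c("true", "yes", "1"))
}

#' Write a genome to a feature-table TSV
#'
#' Inverse of [read_feature_table()]; `read_feature_table(write_feature_table(g))`
#' reproduces `g` up to the (unstored) sequence.
#'
#' @param genome An [annotated_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  rows <- list()
  blank <- function() NA_character_
  for (f in genome$features) {
    rows[[length(rows) + 1L]] <- data.frame(
      record = "gene", name = f$name, host = blank(), category = f$category,
      start = f$start, end = f$end, strand = f$strand,
      anticodon = f$anticodon, start_codon = f$start_codon,
      stop_codon = f$stop_codon, group = blank(), standard_name = blank(),
      note = blank())
    for (it in f$introns) {
      rows[[length(rows) + 1L]] <- data.frame(
        record = "intron", name = it$id, host = f$name, category = blank(),
        start = it$start, end = it$end, strand = blank(),
        anticodon = blank(), start_codon = blank(), stop_codon = blank(),
        group = it$group, standard_name = it$standard_name, note = it$note)
      for (o in it$orfs) {
        rows[[length(rows) + 1L]] <- data.frame(
          record = "orf", name = o$id, host = it$id, category = blank(),
          start = o$start, end = o$end, strand = blank(), anticodon = blank(),
          start_codon = o$start_codon, stop_codon = o$stop_codon,
          group = blank(), standard_name = blank(), note = o$product_class)
      }
    }
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(FEATURE_TABLE_COLUMNS)),
                           FEATURE_TABLE_COLUMNS))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#id=", genome$id),
               paste0("#length=", genome$length),
               paste0("#circular=", tolower(as.character(genome$circular)))),
             con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ""))
  invisible(path)
}
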