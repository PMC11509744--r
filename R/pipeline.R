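# Orchestration: per-genome summaries, pairwise contribution tables, rate
# tables, Pcl matrices and gene-order matrices, with per-genome failure
# isolation and diffable TSV output.

#' Product-annotation tally of introns and intronic ORFs
#'
#' Counts the one-letter product annotations (L LAGLIDADG, G GIY-YIG,
#' R ribosomal protein, H hypothetical, U unknown) over intron notes and
#' intronic-ORF product classes of a genome.
#'
#' @param genome An [annotated_genome()].
#' @return Named integer vector over `L,G,R,H,U`.
#' @export
intron_annotation_counts <- function(genome) {
  letters_ <- c("L", "G", "R", "H", "U")
  out <- setNames(integer(5), letters_)
  for (f in genome$features) for (it in f$introns) {
    if (!is.na(it$note) && it$note %in% letters_)
      out[it$note] <- out[it$note] + 1L
    for (o in it$orfs)
      if (o$product_class %in% letters_)
        out[o$product_class] <- out[o$product_class] + 1L
  }
  out
}

#' One-row organization summary of a genome
#'
#' Feature/intron counts and region partition always; composition fields
#' (`gc_percent`, skews) only when the genome carries a sequence, `NA`
#' otherwise.
#'
#' @param genome An [annotated_genome()].
#' @return One-row `data.frame`.
#' @export
summarize_genome <- function(genome) {
  fs <- feature_summary(genome)
  ints <- intron_summary(genome)
  part <- region_partition(genome)
  comp <- if (!is.null(genome$sequence)) base_composition(genome$sequence)
          else NULL
  gaps <- if (nrow(fs) > 0L) gap_table(genome) else NULL
  data.frame(
    id = genome$id, length = genome$length,
    gc_percent = if (is.null(comp)) NA_real_ else comp$gc_percent,
    at_skew = if (is.null(comp)) NA_real_ else comp$at_skew,
    gc_skew = if (is.null(comp)) NA_real_ else comp$gc_skew,
    n_features = nrow(fs),
    n_pcg = sum(fs$category == "PCG"),
    n_trna = sum(fs$category == "tRNA"),
    n_rrna = sum(fs$category == "rRNA"),
    n_free_orf = sum(fs$category == "ORF"),
    trna_bp = sum(fs$length[fs$category == "tRNA"]),
    n_introns = nrow(ints),
    n_intron_hosts = length(unique(ints$host)),
    intron_bp = if (nrow(ints) > 0L) sum(ints$length) else 0L,
    longest_gap = if (is.null(gaps)) NA_integer_ else max(gaps$gap_length),
    pcg_exon_bp = part$pcg_exon, rrna_exon_bp = part$rrna_exon,
    free_orf_bp = part$free_orf, intergenic_bp = part$intergenic)
}

#' Core genes used by default in the rate analysis (14 typical PCGs + rps3)
#' @export
RATE_GENES <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
                "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
                "rps3")

#' Run the full comparative analysis over a set of genomes
#'
#' Produces the per-genome organization summary, all pairwise
#' contribution-rate tables, the per-gene rate/selection table over the
#' core genes, the Pcl matrix (when a reference CDS is supplied), and the
#' pairwise gene-order comparison. A stage failure for one genome or pair is
#' logged and does not abort the others; `status` is nonzero when anything
#' failed.
#'
#' @param genomes List of [annotated_genome()] objects (or paths to GenBank
#'   `.gb`/feature-table `.tsv` files).
#' @param reference_cds Optional reference CDS string (or FASTA path) for
#'   Pcl assignment.
#' @param pcl_gene Host gene for Pcl analysis (default `"cox1"`).
#' @param rate_genes Genes entering the rate analysis (default
#'   [RATE_GENES]).
#' @param code_id NCBI genetic-code number (default 4).
#' @param out_dir If non-`NULL`, writes `summary.tsv`, `contributions.tsv`,
#'   `rates.tsv`, `pcl_matrix.tsv`, `gene_orders.tsv`, `order_matrix.tsv`
#'   and `run_log.json` there (fixed 4-decimal floats, deterministic row
#'   order).
#' @return List of class `mito_comparison`: `summary`, `contributions`,
#'   `rates`, `pcl`, `orders`, `order_matrix`, `log`, `status`.
#' @export
run_compare <- function(genomes, reference_cds = NULL, pcl_gene = "cox1",
                        rate_genes = RATE_GENES, code_id = 4,
                        out_dir = NULL) {
  if (length(genomes) < 1L) stop("need at least one genome", call. = FALSE)
  genomes <- lapply(genomes, function(g) {
    if (is.character(g)) {
      if (grepl("\\.(gb|gbk|genbank)$", g, ignore.case = TRUE))
        read_genbank(g)
      else read_feature_table(g)
    } else g
  })
  ids <- vapply(genomes, `[[`, character(1), "id")
  log <- list(); status <- 0L
  note <- function(stage, id, msg) {
    log[[length(log) + 1L]] <<- list(stage = stage, genome = id,
                                     message = msg)
    status <<- 1L
  }
  skip_note <- function(stage, id, msg)
    log[[length(log) + 1L]] <<- list(stage = stage, genome = id,
                                     message = msg, skipped = TRUE)

  # --- per-genome summaries ------------------------------------------------
  summaries <- list()
  for (g in genomes) {
    s <- tryCatch(summarize_genome(g), error = function(e) {
      note("summary", g$id, conditionMessage(e)); NULL })
    if (!is.null(s)) summaries[[length(summaries) + 1L]] <- s
  }
  summary_tab <- if (length(summaries) > 0L) do.call(rbind, summaries)
                 else NULL
  if (!is.null(summary_tab))
    summary_tab <- summary_tab[order(summary_tab$id), , drop = FALSE]

  # --- pairwise contribution tables ---------------------------------------
  contribs <- list()
  if (length(genomes) >= 2L) {
    parts <- lapply(genomes, function(g)
      tryCatch(region_partition(g), error = function(e) NULL))
    for (i in seq_along(genomes)) for (j in seq_along(genomes)) {
      if (i >= j) next
      if (is.null(parts[[i]]) || is.null(parts[[j]])) next
      ct <- contribution_rates(parts[[i]], parts[[j]])
      ct$genome_a <- ids[i]; ct$genome_b <- ids[j]
      contribs[[length(contribs) + 1L]] <- ct
    }
  }
  contrib_tab <- if (length(contribs) > 0L) do.call(rbind, contribs) else NULL

  # --- per-gene pairwise rates --------------------------------------------
  with_seq <- vapply(genomes, function(g) !is.null(g$sequence), logical(1))
  for (id in ids[!with_seq])
    skip_note("rates", id, "no sequence: rate analysis skipped")
  rates_tab <- NULL
  if (sum(with_seq) >= 2L) {
    gs <- genomes[with_seq]
    est <- list()
    for (gene in rate_genes) {
      cds <- list()
      for (g in gs) {
        x <- tryCatch(splice_cds(g, gene, code_id),
                      error = function(e) NULL)
        if (!is.null(x)) cds[[g$id]] <- x
      }
      if (length(cds) < 2L) next
      pair_est <- list()
      sp <- names(cds)
      for (i in seq_along(sp)) for (j in seq_along(sp)) {
        if (i >= j) next
        r <- tryCatch(pairwise_rates(cds[[i]], cds[[j]], code_id),
                      error = function(e) {
                        note("rates", paste(sp[i], sp[j], sep = ":"),
                             conditionMessage(e)); NULL })
        if (!is.null(r)) pair_est[[length(pair_est) + 1L]] <- r
      }
      if (length(pair_est) > 0L) est[[gene]] <- pair_est
    }
    if (length(est) > 0L) {
      rates_tab <- selection_summary(est)
      rates_tab <- rates_tab[order(rates_tab$gene), , drop = FALSE]
    }
  }

  # --- Pcl matrix ----------------------------------------------------------
  pcl <- NULL
  if (!is.null(reference_cds)) {
    if (is.character(reference_cds) && file.exists(reference_cds))
      reference_cds <- read_fasta(reference_cds)[[1]]
    assignments <- list()
    for (g in genomes) {
      if (is.null(g$sequence)) {
        skip_note("pcl", g$id, "no sequence: Pcl assignment skipped")
        next
      }
      f <- tryCatch(find_feature(g, pcl_gene), error = function(e) NULL)
      if (is.null(f) || length(f$introns) == 0L) next
      a <- tryCatch(assign_pcls(g, pcl_gene, reference_cds, code_id),
                    error = function(e) {
                      note("pcl", g$id, conditionMessage(e)); NULL })
      if (!is.null(a)) assignments[[length(assignments) + 1L]] <- a
    }
    if (length(assignments) > 0L && sum(with_seq) >= 2L)
      pcl <- pcl_matrix(do.call(rbind, assignments),
                        species = ids[with_seq])
  }

  # --- gene orders ---------------------------------------------------------
  orders <- list()
  for (g in genomes) {
    o <- tryCatch(suppressWarnings(canonicalize(extract_order(g))),
                  error = function(e) {
                    note("gene_order", g$id, conditionMessage(e)); NULL })
    if (!is.null(o)) orders[[g$id]] <- o
  }
  order_matrix <- NULL
  if (length(orders) >= 2L) {
    onm <- names(orders)
    order_matrix <- matrix(NA_integer_, length(onm), length(onm),
                           dimnames = list(onm, onm))
    for (i in seq_along(onm)) for (j in seq_along(onm)) {
      order_matrix[i, j] <- if (i == j) 0L else
        compare_orders(orders[[i]], orders[[j]])$breakpoints
    }
  }

  out <- structure(list(summary = summary_tab, contributions = contrib_tab,
                        rates = rates_tab, pcl = pcl, orders = orders,
                        order_matrix = order_matrix, log = log,
                        status = status),
                   class = "mito_comparison")
  if (!is.null(out_dir)) write_comparison(out, out_dir)
  out
}

#' Write a comparison result bundle as diffable TSVs
#' @noRd
write_comparison <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    if (is.null(df)) return(NULL)
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.4f", v))
    df
  }
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    write.table(fmt(df), file.path(out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
  }
  wr(x$summary, "summary.tsv")
  wr(x$contributions, "contributions.tsv")
  wr(x$rates, "rates.tsv")
  if (!is.null(x$pcl)) wr(x$pcl$table, "pcl_matrix.tsv")
  if (length(x$orders) > 0L) {
    ot <- data.frame(id = names(x$orders),
                     order = vapply(x$orders, function(o)
                       paste(o$markers, collapse = ","), character(1)))
    wr(ot[order(ot$id), ], "gene_orders.tsv")
  }
  if (!is.null(x$order_matrix)) {
    om <- data.frame(id = rownames(x$order_matrix), x$order_matrix,
                     check.names = FALSE)
    wr(om, "order_matrix.tsv")
  }
  jsonlite::write_json(list(package = "mitocompare",
                            version = as.character(utils::packageVersion("mitocompare")),
                            status = x$status, log = x$log),
                       file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
print.mito_comparison <- function(x, ...) {
  cat("mito_comparison:", nrow(x$summary), "genome(s); status", x$status,
      "\n")
  print(x$summary)
  invisible(x)
}
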