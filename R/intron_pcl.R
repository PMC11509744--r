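# Intron position classes (Pcls): naming introns by their insertion site on
# a reference coding sequence, cross-species presence/absence, and
# common/rare classification.

#' Map coding-sequence coordinates onto a reference CDS
#'
#' Protein-guided global alignment of the two coding sequences; returns for
#' every nucleotide of the species CDS the coordinate of the aligned
#' reference nucleotide. Species positions inserted relative to the
#' reference (reference gap) map to the nearest aligned reference position
#' 5'-ward and are flagged as not exactly mapped.
#'
#' @param species_cds,reference_cds CDS strings (stop-free internally under
#'   the active code).
#' @param code_id NCBI genetic-code number (default 4).
#' @param min_identity Minimum amino-acid identity over aligned columns
#'   (default 0.5); below it the reference is rejected as unsuitable.
#' @return List of class `ref_coordinate_map`: `map` (integer vector, one
#'   entry per species CDS nucleotide), `exact` (logical vector),
#'   `aa_identity`.
#' @export
map_to_reference <- function(species_cds, reference_cds, code_id = 4,
                             min_identity = 0.5) {
  ca <- prep_cds(species_cds, code_id, "species_cds")
  cb <- prep_cds(reference_cds, code_id, "reference_cds")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(translate_cds(ca, code_id)),
    Biostrings::AAString(translate_cds(cb, code_id)),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- pat != "-" & sub != "-"
  ident <- sum(pat == sub & both) / max(1L, sum(both))
  if (ident < min_identity)
    stop(sprintf(
      "reference unsuitable: amino-acid identity %.1f%% below %.1f%%",
      100 * ident, 100 * min_identity), call. = FALSE)
  n_a <- nchar(ca)
  map <- integer(n_a); exact <- logical(n_a)
  ia <- 0L; ib <- 0L
  for (k in seq_along(pat)) {
    if (sub[k] != "-") ib <- ib + 1L
    if (pat[k] != "-") {
      ia <- ia + 1L
      nt_a <- (3L * (ia - 1L) + 1L):(3L * ia)
      if (sub[k] != "-") {
        map[nt_a] <- (3L * (ib - 1L) + 1L):(3L * ib)
        exact[nt_a] <- TRUE
      } else {
        map[nt_a] <- 3L * ib   # 3'-most reference nt seen so far (5'-ward)
        exact[nt_a] <- FALSE
      }
    }
  }
  # nucleotides of a trailing stop codon (dropped by prep_cds) map 3'-ward
  full <- nchar(toupper(species_cds))
  if (full > n_a) {
    map <- c(map, rep(if (n_a > 0L) map[n_a] else 0L, full - n_a))
    exact <- c(exact, rep(FALSE, full - n_a))
  }
  structure(list(map = map, exact = exact, aa_identity = ident),
            class = "ref_coordinate_map")
}

PCL_PREFIX <- c(IA = "P", IB = "P", IC1 = "P", IC2 = "P", ID = "P",
                `I-derived` = "P", II = "S", unknown = "U")

#' Assign position classes (Pcls) to the introns of a gene
#'
#' Each intron's insertion point, the exonic nucleotide immediately 5' of
#' the intron in the spliced CDS, is mapped to reference coordinates; the
#' Pcl name is the prefix (`P` for group I introns including derived forms,
#' `S` for group II, `U` for unknown type) followed by the reference site,
#' e.g. `P731`. Unmappable insertion points are flagged, not dropped.
#'
#' @param genome An [annotated_genome()] with sequence.
#' @param gene_name Host gene (must carry introns).
#' @param reference_cds Reference CDS string (e.g. a cox1 CDS).
#' @param code_id NCBI genetic-code number (default 4).
#' @return `data.frame` of class `pcl_assignments`: `species`, `gene`,
#'   `intron_id`, `group`, `ref_site`, `prefix`, `name`, `mapped_exactly`.
#' @export
assign_pcls <- function(genome, gene_name, reference_cds, code_id = 4) {
  f <- find_feature(genome, gene_name)
  if (length(f$introns) == 0L)
    stop("gene '", gene_name, "' has no introns", call. = FALSE)
  cds <- splice_cds(genome, gene_name, code_id)
  cmap <- map_to_reference(cds, reference_cds, code_id)
  seg <- exon_segments(f)
  rows <- lapply(f$introns, function(it) {
    # exonic bases 5' of the intron, in transcript orientation
    if (f$strand == "+") {
      off <- sum(pmax(0L, pmin(seg$end, it$start - 1L) - seg$start + 1L))
    } else {
      off <- sum(pmax(0L, seg$end - pmax(seg$start, it$end + 1L) + 1L))
    }
    site <- if (off >= 1L && off <= length(cmap$map)) cmap$map[off] else 0L
    exact <- if (off >= 1L && off <= length(cmap$exact)) cmap$exact[off]
             else FALSE
    prefix <- unname(PCL_PREFIX[it$group])
    data.frame(species = genome$id, gene = gene_name, intron_id = it$id,
               group = it$group, ref_site = as.integer(site),
               prefix = prefix, name = paste0(prefix, site),
               mapped_exactly = exact && site > 0L)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pcl_assignments", "data.frame")
  out
}

#' Cross-species Pcl presence/absence matrix with common/rare status
#'
#' Rows are Pcl sites (reference coordinates); introns at the same mapped
#' site across species form one Pcl and are treated as homologous. A Pcl is
#' `common` when present in strictly more than one-fifth of the species,
#' otherwise `rare`.
#'
#' @param assignments Row-bound [assign_pcls()] results from at least two
#'   species.
#' @param species Optional character vector of all species considered
#'   (defaults to those present in `assignments`; species without introns
#'   must be listed here to count toward the denominator).
#' @param tolerance Sites closer than this many nucleotides are merged into
#'   one Pcl (keyed by the smallest site). Default 0: exact site equality,
#'   the convention for curated annotations.
#' @return List of class `pcl_matrix`: `table` (data.frame, one row per
#'   site: `ref_site`, one prefix column per species, `n_present`,
#'   `status`), `n_species`, `threshold`.
#' @export
pcl_matrix <- function(assignments, species = NULL, tolerance = 0) {
  if (is.null(species)) species <- unique(assignments$species)
  if (length(species) < 2L)
    stop("need at least two species", call. = FALSE)
  if (tolerance > 0) {
    us <- sort(unique(assignments$ref_site))
    anchor <- us[1]; key <- setNames(integer(length(us)), us)
    for (s in us) {
      if (s - anchor > tolerance) anchor <- s
      key[as.character(s)] <- anchor
    }
    assignments$ref_site <- unname(key[as.character(assignments$ref_site)])
  }
  dup <- duplicated(assignments[, c("species", "intron_id")])
  if (any(dup))
    stop("duplicate intron ids within a species: ",
         paste(unique(assignments$intron_id[dup]), collapse = ", "),
         call. = FALSE)
  sites <- sort(unique(assignments$ref_site))
  mat <- matrix(NA_character_, nrow = length(sites), ncol = length(species),
                dimnames = list(as.character(sites), species))
  for (r in seq_len(nrow(assignments))) {
    a <- assignments[r, ]
    key <- as.character(a$ref_site)
    if (!is.na(mat[key, a$species]))
      stop("two introns of species '", a$species, "' map to site ",
           a$ref_site, call. = FALSE)
    mat[key, a$species] <- a$prefix
  }
  n_present <- rowSums(!is.na(mat))
  thr <- length(species) / 5
  tab <- data.frame(ref_site = sites, as.data.frame(mat, optional = TRUE),
                    n_present = as.integer(n_present),
                    status = ifelse(n_present > thr, "common", "rare"),
                    row.names = NULL, check.names = FALSE)
  structure(list(table = tab, n_species = length(species), threshold = thr),
            class = "pcl_matrix")
}

#' @export
print.pcl_matrix <- function(x, ...) {
  cat(sprintf("pcl_matrix: %d Pcls x %d species (common iff count > %.1f)\n",
              nrow(x$table), x$n_species, x$threshold))
  print(x$table, ...)
  invisible(x)
}
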