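# Pairwise codon-aware alignment, Kimura-2-parameter distance, and
# Nei-Gojobori (1986) Ka/Ks with selection classification.

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Aligns the two translated proteins globally (standard substitution matrix,
#' affine gaps) and back-maps the alignment to codons; columns containing a
#' gap in either sequence are dropped and counted.
#'
#' @param cds_a,cds_b CDS strings, length divisible by 3, no internal stop
#'   under the active code.
#' @param code_id NCBI genetic-code number (default 4).
#' @param substitution_matrix Protein scoring matrix name (default
#'   `"BLOSUM62"`).
#' @param gap_opening,gap_extension Affine gap penalties (defaults 10, 0.5;
#'   opening much larger than extension).
#' @return List of class `codon_alignment`: `codons_a`, `codons_b`
#'   (character vectors of paired codons), `n_codons`, `n_gap_columns`,
#'   `code_id`.
#' @export
align_codons <- function(cds_a, cds_b, code_id = 4,
                         substitution_matrix = "BLOSUM62",
                         gap_opening = 10, gap_extension = 0.5) {
  ca <- prep_cds(cds_a, code_id, "cds_a")
  cb <- prep_cds(cds_b, code_id, "cds_b")
  aa_a <- sub("\\*$", "", translate_cds(ca, code_id))
  aa_b <- sub("\\*$", "", translate_cds(cb, code_id))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cod_a <- split_codons(ca)
  cod_b <- split_codons(cb)
  ia <- 0L; ib <- 0L
  keep_a <- integer(0); keep_b <- integer(0)
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ia <- ia + 1L
    if (sub[k] != "-") ib <- ib + 1L
    if (pat[k] != "-" && sub[k] != "-") {
      keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
    }
  }
  if (length(keep_a) == 0L)
    stop("no aligned codon columns remain after gap removal", call. = FALSE)
  structure(list(codons_a = cod_a[keep_a], codons_b = cod_b[keep_b],
                 n_codons = length(keep_a),
                 n_gap_columns = sum(pat == "-" | sub == "-"),
                 code_id = code_id),
            class = "codon_alignment")
}

prep_cds <- function(cds, code_id, what) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop(what, ": length not divisible by 3", call. = FALSE)
  aa <- strsplit(translate_cds(cds, code_id), "", fixed = TRUE)[[1]]
  if (any(aa[-length(aa)] == "*"))
    stop(what, ": internal stop codon", call. = FALSE)
  # drop a terminal stop so it does not enter the alignment
  if (length(aa) > 0L && aa[length(aa)] == "*")
    cds <- substr(cds, 1L, nchar(cds) - 3L)
  cds
}

#' Kimura-2-parameter distance over the nucleotide columns of an alignment
#'
#' P is the transition fraction (A<->G, C<->T), Q the transversion fraction,
#' over all gap-free nucleotide columns (all three codon positions). The
#' distance is `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))`; saturated inputs
#' (non-positive log argument) yield an `NA` distance with a diagnostic
#' attribute rather than an error.
#'
#' @param alignment A `codon_alignment` from [align_codons()].
#' @return List of class `rate_estimate` with `P`, `Q`, `k2p`, `n_sites`.
#' @export
k2p <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  a <- strsplit(paste(alignment$codons_a, collapse = ""), "")[[1]]
  b <- strsplit(paste(alignment$codons_b, collapse = ""), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 1L) stop("no comparable nucleotide columns", call. = FALSE)
  diff <- a != b
  transition <- diff & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                        (a %in% c("C", "T") & b %in% c("C", "T")))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  d <- if (arg1 <= 0 || arg2 <= 0) NA_real_ else
    -0.5 * log(arg1 * sqrt(arg2))
  out <- structure(list(P = P, Q = Q, k2p = d, n_sites = n),
                   class = "rate_estimate")
  if (is.na(d)) attr(out, "diagnostic") <- "saturated (log argument <= 0)"
  out
}

# ---- Nei-Gojobori (1986) ------------------------------------------------

.ng_cache <- new.env(parent = emptyenv())

#' Per-code NG86 lookup tables: synonymous sites per codon and pairwise
#' pathway-averaged synonymous/nonsynonymous differences.
#' @noRd
ng86_tables <- function(code_id = 4) {
  key <- as.character(code_id)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  gc <- genetic_code(code_id)
  codons <- all_codons()
  bases <- c("A", "C", "G", "T")
  # synonymous sites: per position, the denominator is the number of
  # single-nt changes that do not create a stop (stop-creating changes are
  # excluded from the mutational opportunity); each position contributes one
  # site in total, so S + N = 3 per codon.
  syn_sites <- setNames(numeric(64), codons)
  for (cod in codons) {
    if (gc[cod] == "*") { syn_sites[cod] <- NA_real_; next }
    s <- 0
    for (p in 1:3) {
      alts <- vapply(setdiff(bases, substr(cod, p, p)), function(b) {
        x <- cod; substr(x, p, p) <- b; x
      }, character(1))
      nonstop <- alts[gc[alts] != "*"]
      if (length(nonstop) > 0L)
        s <- s + sum(gc[nonstop] == gc[cod]) / length(nonstop)
    }
    syn_sites[cod] <- s
  }
  # pathway-averaged differences for every ordered codon pair
  sd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd <- sd
  unresolved <- matrix(FALSE, 64, 64, dimnames = list(codons, codons))
  for (c1 in codons) {
    if (gc[c1] == "*") next
    for (c2 in codons) {
      if (gc[c2] == "*") next
      res <- codon_path_diffs(c1, c2, gc)
      sd[c1, c2] <- res$sd
      nd[c1, c2] <- res$nd
      unresolved[c1, c2] <- res$unresolved
    }
  }
  out <- list(syn_sites = syn_sites, sd = sd, nd = nd,
              unresolved = unresolved)
  .ng_cache[[key]] <- out
  out
}

#' Average synonymous/nonsynonymous differences between two codons over all
#' minimal mutational pathways, excluding pathways through stop codons.
#' @noRd
codon_path_diffs <- function(c1, c2, gc) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  ndiff <- length(pos)
  if (ndiff == 0L) return(list(sd = 0, nd = 0, unresolved = FALSE))
  paths <- permutations_of(pos)
  tot_s <- 0; tot_n <- 0; valid <- 0L
  for (ord in paths) {
    cur <- c1; s <- 0L; n <- 0L; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[nxt] == "*") { ok <- FALSE; break }
      if (gc[nxt] == gc[cur]) s <- s + 1L else n <- n + 1L
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; valid <- valid + 1L }
  }
  if (valid == 0L)
    return(list(sd = 0, nd = 0, unresolved = TRUE))
  list(sd = tot_s / valid, nd = tot_n / valid, unresolved = FALSE)
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v))
    for (rest in permutations_of(v[-k]))
      out[[length(out) + 1L]] <- c(v[k], rest)
  out
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous substitution rates
#'
#' Synonymous/nonsynonymous site counts per codon (stop-creating single-nt
#' changes excluded from the mutational opportunity) are averaged over the
#' two sequences; observed differences are averaged over all equally
#' weighted minimal pathways, discarding pathways through stop codons.
#' Codon pairs whose pathways all cross a stop contribute to an
#' `unresolved_codons` tally and are excluded from the difference counts.
#' The Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)` is applied to the
#' proportions pS and pN; `omega = Ka/Ks` is `NA` when `Ks` is 0 or either
#' correction saturates (p >= 3/4).
#'
#' @param alignment A `codon_alignment` from [align_codons()].
#' @return List of class `rate_estimate`: `S`, `N` (site counts), `Sd`,
#'   `Nd` (difference counts), `pS`, `pN`, `Ka`, `Ks`, `omega`,
#'   `selection_label`, `unresolved_codons`, `n_codons`.
#' @export
ng86 <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  tabs <- ng86_tables(alignment$code_id)
  ca <- alignment$codons_a; cb <- alignment$codons_b
  ok <- !grepl("N", ca, fixed = TRUE) & !grepl("N", cb, fixed = TRUE)
  ca <- ca[ok]; cb <- cb[ok]
  S <- sum((tabs$syn_sites[ca] + tabs$syn_sites[cb]) / 2)
  N <- 3 * length(ca) - S
  unres <- tabs$unresolved[cbind(ca, cb)]
  Sd <- sum(tabs$sd[cbind(ca, cb)][!unres])
  Nd <- sum(tabs$nd[cbind(ca, cb)][!unres])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS); Ka <- jc(pN)
  omega <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ka = Ka, Ks = Ks, omega = omega,
                 selection_label = selection_label(omega),
                 unresolved_codons = sum(unres), n_codons = length(ca)),
            class = "rate_estimate")
}

#' Selection label from an omega value
#' @noRd
selection_label <- function(omega, tol = 1e-9) {
  if (is.na(omega)) return("undefined")
  if (abs(omega - 1) <= tol) return("neutral")
  if (omega < 1) "purifying" else "positive"
}

#' Combined pairwise rate estimate for two coding sequences
#'
#' Convenience wrapper: [align_codons()], then [k2p()] and [ng86()].
#'
#' @inheritParams align_codons
#' @return List of class `rate_estimate` merging the K2P and NG86 fields.
#' @export
pairwise_rates <- function(cds_a, cds_b, code_id = 4) {
  aln <- align_codons(cds_a, cds_b, code_id)
  k <- k2p(aln)
  n <- ng86(aln)
  structure(c(k[c("P", "Q", "k2p")], n[setdiff(names(n), "n_codons")],
              list(n_codons = aln$n_codons)),
            class = "rate_estimate")
}

#' Per-gene selection summary across species pairs
#'
#' Averages pairwise K2P, Ka, Ks and omega per gene across all sequence
#' pairs, excluding undefined values (their count is reported), and labels
#' each gene: omega < 1 purifying, omega = 1 (within 1e-9) neutral,
#' omega > 1 positive.
#'
#' @param estimates Named list: per gene, a list of `rate_estimate`s (one
#'   per species pair).
#' @return `data.frame`: gene, n_pairs, n_undefined_omega, mean_k2p,
#'   mean_ka, mean_ks, mean_omega, selection_label.
#' @export
selection_summary <- function(estimates) {
  rows <- lapply(names(estimates), function(g) {
    es <- estimates[[g]]
    get <- function(field) vapply(es, function(e)
      if (is.null(e[[field]])) NA_real_ else as.numeric(e[[field]]),
      numeric(1))
    om <- get("omega")
    data.frame(gene = g, n_pairs = length(es),
               n_undefined_omega = sum(is.na(om)),
               mean_k2p = mean(get("k2p"), na.rm = TRUE),
               mean_ka = mean(get("Ka"), na.rm = TRUE),
               mean_ks = mean(get("Ks"), na.rm = TRUE),
               mean_omega = if (all(is.na(om))) NA_real_ else
                 mean(om, na.rm = TRUE),
               selection_label = selection_label(
                 if (all(is.na(om))) NA_real_ else mean(om, na.rm = TRUE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
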