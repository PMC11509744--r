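# Core mitochondrial gene arrangement: extraction, circular canonical form,
# and signed breakpoint comparison.

CORE_MARKERS <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
                  "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
                  "rps3", "rnl", "rns")

#' Extract the core gene arrangement of a genome
#'
#' Collects the 15 core protein-coding genes and 2 rRNA genes in circular
#' order with strand signs. Non-core features (tRNAs, free ORFs) are
#' skipped. `rps3` is recognised either free-standing or as an intronic ORF
#' (in many fungi it sits inside an `rnl` intron) and is promoted to an
#' arrangement slot at its coordinate.
#'
#' @param genome A validated [annotated_genome()].
#' @return List of class `gene_order`: `markers` (character vector, `-`
#'   prefix for reverse strand), `canonical` (logical).
#' @export
extract_order <- function(genome) {
  nm <- character(0); st <- integer(0)
  seen <- character(0)
  for (f in genome$features) {
    base <- f$name
    if (!(base %in% CORE_MARKERS)) next
    if (base %in% seen)
      stop("duplicated core marker '", base, "'", call. = FALSE)
    seen <- c(seen, base)
    nm <- c(nm, if (f$strand == "-") paste0("-", base) else base)
    st <- c(st, f$start)
  }
  if (!("rps3" %in% seen)) {
    for (f in genome$features) for (it in f$introns) for (o in it$orfs) {
      if (o$id == "rps3" && !("rps3" %in% seen)) {
        seen <- c(seen, "rps3")
        nm <- c(nm, "rps3")     # intronic rps3 inherits the host strand (+)
        st <- c(st, o$start)
      }
    }
  }
  missing <- setdiff(CORE_MARKERS, seen)
  if (length(missing) > 0L)
    warning("core markers missing from '", genome$id, "': ",
            paste(missing, collapse = ", "), call. = FALSE)
  structure(list(markers = nm[order(st)], canonical = FALSE),
            class = "gene_order")
}

#' Construct a gene order from a marker vector
#'
#' @param markers Character vector of signed marker labels (`-` prefix for
#'   reverse strand).
#' @param canonical Logical flag.
#' @return A `gene_order` object.
#' @export
gene_order <- function(markers, canonical = FALSE) {
  base <- sub("^-", "", markers)
  if (anyDuplicated(base))
    stop("duplicated marker(s): ",
         paste(unique(base[duplicated(base)]), collapse = ", "),
         call. = FALSE)
  structure(list(markers = as.character(markers), canonical = canonical),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(paste(x$markers, collapse = " - "),
      if (x$canonical) " [canonical]\n" else "\n")
  invisible(x)
}

flip_marker <- function(m) ifelse(startsWith(m, "-"), sub("^-", "", m),
                                  paste0("-", m))

#' Canonicalize a circular gene order
#'
#' Rotates the arrangement so it starts at `rnl`; if `rnl` lies on the
#' reverse strand the whole order is reversed and all signs flipped first.
#' Idempotent, and invariant under rotation and reflection of the input.
#'
#' @param order A `gene_order` containing `rnl`.
#' @return The canonical `gene_order`.
#' @export
canonicalize <- function(order) {
  m <- order$markers
  base <- sub("^-", "", m)
  at <- match("rnl", base)
  if (is.na(at)) stop("order contains no rnl marker", call. = FALSE)
  if (startsWith(m[at], "-")) {
    m <- rev(flip_marker(m))
    base <- sub("^-", "", m)
    at <- match("rnl", base)
  }
  if (at > 1L) m <- c(m[at:length(m)], m[seq_len(at - 1L)])
  gene_order(m, canonical = TRUE)
}

#' Signed circular adjacency set of an order
#' @noRd
adjacency_set <- function(markers) {
  n <- length(markers)
  nxt <- c(markers[-1], markers[1])
  fwd <- paste(markers, nxt, sep = "|")
  rev_ <- paste(flip_marker(nxt), flip_marker(markers), sep = "|")
  # an adjacency (u,v) is the same gene junction as (-v,-u)
  pmin(fwd, rev_)
}

#' Compare two circular gene orders
#'
#' Restricted to the shared markers, counts breakpoints: signed circular
#' adjacencies of `a` absent from `b` (an adjacency `u,v` is identified with
#' `-v,-u`). The comparison is symmetric and two orders are identical iff
#' they share all markers and have zero breakpoints.
#'
#' @param a,b Canonical `gene_order`s (canonicalized here if not already).
#' @return List of class `order_comparison`: `identical`, `breakpoints`,
#'   `shared_markers`.
#' @export
compare_orders <- function(a, b) {
  if (!a$canonical) a <- canonicalize(a)
  if (!b$canonical) b <- canonicalize(b)
  base_a <- sub("^-", "", a$markers)
  base_b <- sub("^-", "", b$markers)
  shared <- intersect(base_a, base_b)
  if (length(shared) < 3L)
    return(structure(list(identical = NA, breakpoints = NA_integer_,
                          shared_markers = length(shared)),
                     class = "order_comparison"))
  ma <- a$markers[base_a %in% shared]
  mb <- b$markers[base_b %in% shared]
  bp <- sum(!(adjacency_set(ma) %in% adjacency_set(mb)))
  structure(list(
    identical = bp == 0L && setequal(base_a, base_b),
    breakpoints = as.integer(bp),
    shared_markers = length(shared)), class = "order_comparison")
}
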