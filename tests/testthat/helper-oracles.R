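# Independent oracles: brute-force repeat scan and NG86 pathway enumeration.
# These reimplement the semantics from scratch (different algorithmic
# formulation) and are only run at toy scale.

oracle_complement <- function(x) chartr("ACGTN", "TGCAN", x)
oracle_reverse <- function(x)
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
oracle_revcomp <- function(x) oracle_reverse(oracle_complement(x))

# All maximal Hamming-bounded windows between s and t on every diagonal,
# found by a start-indexed furthest-end sweep (not the mismatch-delimited
# enumeration used by the implementation).
oracle_diagonal_hits <- function(s, t, min_len, max_mm, dmin, dmax) {
  sv <- strsplit(s, "")[[1]]; tv <- strsplit(t, "")[[1]]
  n <- length(sv); m <- length(tv)
  valid_s <- sv %in% c("A", "C", "G", "T")
  out <- list()
  for (d in dmin:dmax) {
    i0 <- max(1L, 1L - d); i1 <- min(n, m - d)
    L <- i1 - i0 + 1L
    if (L < min_len) next
    a <- sv[i0:i1]; b <- tv[(i0 + d):(i1 + d)]
    mism <- !(a == b & valid_s[i0:i1])
    v <- which(mism); tmm <- length(v)
    cum <- c(0L, cumsum(mism))
    # furthest feasible end for each start (blocking-mismatch lookup)
    s0 <- seq_len(L)
    idx <- cum[s0] + max_mm + 1L
    e_star <- ifelse(idx > tmm, L, v[pmin(idx, max(tmm, 1L))] - 1L)
    e_star[idx > tmm] <- L
    maximal <- c(TRUE, e_star[-L] < e_star[-1])
    len <- e_star - s0 + 1L
    keep <- maximal & len >= min_len
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        i = i0 + s0[keep] - 1L, j = i0 + s0[keep] - 1L + d,
        len = len[keep], mm = cum[e_star[keep] + 1L] - cum[s0[keep]])
    }
  }
  if (length(out) == 0L)
    return(data.frame(i = integer(0), j = integer(0), len = integer(0),
                      mm = integer(0)))
  do.call(rbind, out)
}

# Full four-orientation brute-force repeat scan with the same coordinate
# conventions as find_repeats().
oracle_find_repeats <- function(sequence, min_length = 30, max_mismatch = 3,
                                orientations = c("F", "R", "C", "P")) {
  s <- toupper(sequence); n <- nchar(s)
  res <- list()
  for (ori in orientations) {
    t <- switch(ori, F = s, R = oracle_reverse(s), C = oracle_complement(s),
                P = oracle_revcomp(s))
    dr <- if (ori %in% c("F", "C")) c(1L, n - 1L) else c(-(n - 1L), n - 1L)
    h <- oracle_diagonal_hits(s, t, min_length, max_mismatch, dr[1], dr[2])
    if (nrow(h) == 0L) next
    pos2 <- switch(ori, F = h$j, C = h$j, R = n - h$j - h$len + 2L,
                   P = n - h$j - h$len + 2L)
    df <- data.frame(orientation = ori, pos1 = pmin(h$i, pos2),
                     pos2 = pmax(h$i, pos2), length = h$len,
                     mismatches = h$mm)
    df <- df[!duplicated(df), , drop = FALSE]
    if (ori == "F") df <- df[df$pos1 != df$pos2, , drop = FALSE]
    res[[ori]] <- df
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(orientation = character(0), pos1 = integer(0),
               pos2 = integer(0), length = integer(0),
               mismatches = integer(0))
  rownames(out) <- NULL
  out
}

hit_key <- function(df)
  sort(sprintf("%s:%d:%d:%d:%d", df$orientation, df$pos1, df$pos2,
               df$length, df$mismatches))

# NG86 per-codon-pair oracle: exhaustive recursive pathway enumeration and
# direct site counting from the Biostrings code table.
oracle_ng86_pair <- function(c1, c2, code_id = 4) {
  gc <- Biostrings::getGeneticCode(as.character(code_id))
  aa <- function(x) unname(gc[[x]])
  sites <- function(cod) {
    s <- 0
    for (p in 1:3) {
      cur <- substr(cod, p, p)
      alts <- setdiff(c("A", "C", "G", "T"), cur)
      alt_cod <- vapply(alts, function(b) {
        y <- cod; substr(y, p, p) <- b; y
      }, character(1))
      keep <- vapply(alt_cod, function(y) aa(y) != "*", logical(1))
      if (any(keep))
        s <- s + sum(vapply(alt_cod[keep], function(y) aa(y) == aa(cod),
                            logical(1))) / sum(keep)
    }
    s
  }
  walk <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (length(pos) == 0L)
      return(list(data.frame(s = 0, n = 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      if (aa(nxt) == "*") next
      step_syn <- aa(nxt) == aa(cur)
      for (tail in walk(nxt, target)) {
        out[[length(out) + 1L]] <- data.frame(
          s = tail$s + as.integer(step_syn),
          n = tail$n + as.integer(!step_syn))
      }
    }
    out
  }
  paths <- walk(c1, c2)
  if (length(paths) == 0L)
    return(list(S1 = sites(c1), S2 = sites(c2), sd = 0, nd = 0,
                unresolved = TRUE))
  pm <- do.call(rbind, paths)
  list(S1 = sites(c1), S2 = sites(c2), sd = mean(pm$s), nd = mean(pm$n),
       unresolved = FALSE)
}
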