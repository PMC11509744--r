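# Codon-aware alignment, K2P distance, NG86 Ka/Ks and selection labels.

make_alignment <- function(codons_a, codons_b, code_id = 4) {
  structure(list(codons_a = codons_a, codons_b = codons_b,
                 n_codons = length(codons_a), n_gap_columns = 0L,
                 code_id = code_id), class = "codon_alignment")
}

test_that("align_codons pairs codons and drops gap columns", {
  a <- "ATGGCTAAAGGTTGA"          # M A K G W (code 4)
  aln <- align_codons(a, a)
  expect_equal(aln$n_codons, 5L)
  expect_equal(aln$codons_a, aln$codons_b)
  # deleting one codon gives len/3 - 1 aligned columns
  b <- "ATGGCTGGTTGA"             # K deleted
  aln2 <- align_codons(a, b)
  expect_equal(aln2$n_codons, 4L)
  expect_equal(aln2$n_gap_columns, 1L)
  # internal stops are rejected
  expect_error(align_codons("ATGTAAGCTTAA", a), "internal stop")
  # an evolved pair without indels keeps every column
  ev <- evolve_cds_pair(60, 0.1, 0.5, seed = 3)
  aln3 <- align_codons(ev$cds_a, ev$cds_b)
  expect_equal(aln3$n_codons, 59L)   # terminal stop dropped
})

test_that("K2P matches its closed form", {
  # identical pair
  base <- rep("GCT", 100)
  expect_equal(k2p(make_alignment(base, base))$k2p, 0)
  # P = 0.1, Q = 0: 30 A->G transitions over 300 nt
  a <- rep("ACT", 100)
  b <- c(rep("GCT", 30), rep("ACT", 70))
  est <- k2p(make_alignment(a, b))
  expect_equal(c(est$P, est$Q), c(0.1, 0))
  expect_equal(est$k2p, -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(est$k2p, 0.1116, tolerance = 1e-3)
  # P = Q = 0.25: per 4 columns one transition (A->G) and one
  # transversion (A->T)
  cod_a <- rep(c("AA", "CC"), 75)
  cod_b <- rep(c("GT", "CC"), 75)
  est2 <- k2p(make_alignment(cod_a, cod_b))
  expect_equal(c(est2$P, est2$Q), c(0.25, 0.25))
  expect_equal(est2$k2p, -0.5 * log(0.25 * sqrt(0.5)), tolerance = 1e-12)
  expect_equal(est2$k2p, 0.8664, tolerance = 1e-3)
  # saturated alignments give NA with a diagnostic, not an error
  sat <- k2p(make_alignment(rep("AAA", 10), rep("GGG", 10)))
  expect_true(is.na(sat$k2p))
  expect_match(attr(sat, "diagnostic"), "saturated")
})

test_that("K2P agrees with an established phylogenetics implementation", {
  for (seed in c(77, 78)) {
    ev <- evolve_cds_pair(200, 0.3, 0.5, seed = seed)
    aln <- align_codons(ev$cds_a, ev$cds_b)
    mine <- k2p(aln)$k2p
    m <- rbind(strsplit(tolower(paste(aln$codons_a, collapse = "")), "")[[1]],
               strsplit(tolower(paste(aln$codons_b, collapse = "")), "")[[1]])
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("NG86 equals the exhaustive pathway oracle on all codon pairs", {
  tabs <- mitocompare:::ng86_tables(4)
  sense <- mitocompare:::sense_codons(4)
  set.seed(99)
  # sites for every sense codon
  for (cod in sense) {
    expect_equal(tabs$syn_sites[[cod]], oracle_ng86_pair(cod, cod)$S1,
                 tolerance = 1e-12, info = cod)
  }
  # pathway-averaged differences for every ordered pair
  for (c1 in sense) for (c2 in sense) {
    want <- oracle_ng86_pair(c1, c2)
    expect_equal(tabs$sd[c1, c2], want$sd, tolerance = 1e-12,
                 info = paste(c1, c2))
    expect_equal(tabs$nd[c1, c2], want$nd, tolerance = 1e-12,
                 info = paste(c1, c2))
    expect_equal(tabs$unresolved[c1, c2], want$unresolved,
                 info = paste(c1, c2))
  }
})

test_that("NG86 behaves on canonical small cases", {
  # identical pair: zero rates, undefined omega
  aln <- make_alignment(rep("GCT", 50), rep("GCT", 50))
  est <- ng86(aln)
  expect_equal(c(est$Ka, est$Ks), c(0, 0))
  expect_true(is.na(est$omega))
  expect_equal(est$selection_label, "undefined")
  # TTT vs TTC: one synonymous difference (Phe/Phe under code 4)
  est2 <- ng86(make_alignment(c("TTT", rep("AAA", 49)),
                              c("TTC", rep("AAA", 49))))
  expect_equal(est2$Ka, 0)
  expect_gt(est2$Ks, 0)
  # estimates are symmetric in the two sequences
  ev <- evolve_cds_pair(100, 0.15, 0.5, seed = 8)
  aln_ab <- align_codons(ev$cds_a, ev$cds_b)
  aln_ba <- align_codons(ev$cds_b, ev$cds_a)
  ab <- ng86(aln_ab); ba <- ng86(aln_ba)
  expect_equal(ab$Ka, ba$Ka)
  expect_equal(ab$Ks, ba$Ks)
  expect_equal(k2p(aln_ab)$k2p, k2p(aln_ba)$k2p)
})

test_that("selection_summary averages pairs and labels genes", {
  mk <- function(omega) structure(list(k2p = 0.1, Ka = 0.01 * omega,
                                       Ks = 0.1, omega = omega),
                                  class = "rate_estimate")
  est <- list(g1 = list(mk(0.2), mk(0.2)),
              g2 = list(mk(2), mk(4)),
              g3 = list(mk(0.5), structure(list(k2p = 0.1, Ka = 0, Ks = 0,
                                                omega = NA_real_),
                                           class = "rate_estimate")))
  tab <- selection_summary(est)
  expect_equal(tab$selection_label[tab$gene == "g1"], "purifying")
  expect_equal(tab$selection_label[tab$gene == "g2"], "positive")
  expect_equal(tab$n_undefined_omega[tab$gene == "g3"], 1L)
  expect_equal(tab$mean_omega[tab$gene == "g3"], 0.5)
})
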