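# MISA-style SSR detection and hit-to-region assignment.

test_that("planted tandem runs are found with canonical motif classes", {
  set.seed(501)
  s <- random_dna(3000)
  run <- paste(rep("A", 12), collapse = "")
  s2 <- paste0(substr(s, 1, 999), "C", run, "C", substr(s, 1022, 3000))
  hits <- find_ssrs(s2)
  mono <- hits[hits$unit_length == 1 & hits$start == 1001, ]
  expect_equal(nrow(mono), 1L)
  expect_equal(mono$motif_class, "A/T")
  expect_gte(mono$copies, 12L)
})

test_that("motif classes canonicalize over rotations and both strands", {
  expect_equal(motif_class("AAT"), "AAT/ATT")
  expect_equal(motif_class("TTA"), "AAT/ATT")   # rotation of revcomp
  expect_equal(motif_class("ATT"), "AAT/ATT")
  expect_equal(motif_class("AT"), "AT/AT")
  expect_equal(motif_class("A"), "A/T")
  expect_equal(motif_class("GA"), "AG/CT")
})

test_that("per-unit thresholds and sub-period suppression apply", {
  pad <- function(x) paste0("GCGCGGC", x, "CGGCGCG")
  # AAT x5 meets the trinucleotide threshold
  h <- find_ssrs(pad(strrep("AAT", 5)))
  tri <- h[h$unit_length == 3, ]
  expect_equal(nrow(tri), 1L)
  expect_equal(tri$motif_class, "AAT/ATT")
  expect_equal(tri$copies, 5L)
  # AT x5 (10 bp) is below the dinucleotide threshold of 6
  expect_equal(nrow(find_ssrs(pad(strrep("AT", 5)))), 0L)
  # a mononucleotide run is not additionally reported as AA/AAA/... runs
  h2 <- find_ssrs(pad(strrep("A", 30)))
  expect_true(all(h2$unit_length == 1))
  expect_equal(nrow(h2), 1L)
})

test_that("copies are complete units and coordinates are consistent", {
  h <- find_ssrs(paste0("G", strrep("AATG", 5), "AA", "CCCCCCCCCCCC"))
  tet <- h[h$unit_length == 4, ]
  expect_equal(tet$end - tet$start + 1L, tet$unit_length * tet$copies)
  expect_equal(tet$copies, 5L)    # the trailing partial AA is not a copy
})

test_that("nearby runs share a compound group", {
  spacer1 <- random_dna(20, seed = 601,
                        probs = c(A = .25, C = .25, G = .25, T = .25))
  spacer2 <- random_dna(200, seed = 602,
                        probs = c(A = .25, C = .25, G = .25, T = .25))
  s <- paste0(strrep("AAT", 5), spacer1, strrep("CT", 7),
              spacer2, strrep("A", 10))
  h <- find_ssrs(s, compound_distance = 100)
  expect_equal(nrow(h), 3L)
  grp <- h$compound_group[order(h$start)]
  expect_equal(grp[1], grp[2])     # 20 bp apart: compound
  expect_true(is.na(grp[3]))       # 200 bp apart: singleton
})

test_that("planted generator SSRs are recovered exactly (closure)", {
  sp <- data.frame(motif = c("A", "AT", "AAT", "AATT"),
                   copies = c(12L, 6L, 5L, 5L))
  res <- generate_genome(small_config(seed = 12, ssr_plan = sp))
  hits <- find_ssrs(res$genome$sequence)
  m <- res$manifest$ssrs
  found <- merge(m, hits[, names(m)])
  expect_equal(nrow(found), nrow(m))
})

test_that("locate_hits labels hits with the regions they overlap", {
  res <- generate_genome(small_config(seed = 13))
  g <- res$genome
  ints <- intron_summary(g)
  fs <- feature_summary(g)
  hits <- data.frame(start = c(ints$start[1] + 5L, fs$start[1]),
                     end = c(ints$start[1] + 25L, fs$start[1] + 10L))
  lab <- locate_hits(hits, g)
  expect_equal(lab$regions[1], "intron")
  expect_true(grepl("rrna_exon|pcg_exon", lab$regions[2]))
  # a span crossing a gene boundary reports both categories
  gap <- gap_table(g)
  big <- which(gap$gap_length > 10 & !gap$wraps_origin)[1]
  up <- fs[fs$name == gap$upstream_feature[big], ]
  cross <- data.frame(start = up$end - 3L, end = up$end + 3L)
  lab2 <- locate_hits(cross, g)
  expect_true(grepl(",", lab2$regions) || lab2$regions == "intergenic,")
  expect_true(grepl("intergenic", lab2$regions))
  expect_error(locate_hits(data.frame(start = -5, end = 10), g), "bounds")
})
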