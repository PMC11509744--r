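# Data model: validation, coordinate arithmetic, gaps, splicing.

test_that("the transcribed annotation-table fixture is structurally clean", {
  g <- fixture_genome()
  expect_s3_class(g, "annotated_genome")
  expect_equal(g$length, 112465L)
  expect_length(g$features, 44L)
  cats <- table(vapply(g$features, `[[`, character(1), "category"))
  expect_equal(as.integer(cats[c("PCG", "tRNA", "rRNA", "ORF")]),
               c(14L, 26L, 2L, 2L))
  iss <- validate_genome(g)
  # printed-table boundary spill of two intronic ORFs is tolerated as a
  # warning; nothing else is flagged
  expect_true(all(iss$severity == "warning"))
  expect_setequal(unique(iss$code), "orf_spill")
  expect_equal(sum(iss$code == "orf_spill"), 2L)
})

test_that("validate_genome reports bounds, overlap and frame issues", {
  g <- annotated_genome(
    "bad", 100, check = FALSE,
    features = list(
      mito_feature("a", "PCG", 1, 29, "+"),     # 29 bp: frame issue
      mito_feature("b", "tRNA", 25, 60, "+"),   # overlaps a
      mito_feature("c", "tRNA", 90, 130, "+"))) # out of bounds
  iss <- validate_genome(g)
  expect_true(any(iss$code == "overlap"))
  expect_true(any(iss$code == "bounds"))
  expect_true(any(iss$code == "frame"))
  # constructor refuses error-severity issues
  expect_error(annotated_genome("bad", 100, features = g$features),
               "overlap")
})

test_that("intron invariants are enforced", {
  f_out <- mito_feature("x", "PCG", 10, 60, "+", introns = list(
    mito_intron("x-i1", 5, 20)))            # not strictly inside
  g <- annotated_genome("g", 100, features = list(f_out), check = FALSE)
  expect_true(any(validate_genome(g)$code == "intron_bounds"))
  f_ovl <- mito_feature("y", "PCG", 1, 90, "+", introns = list(
    mito_intron("y-i1", 10, 40), mito_intron("y-i2", 35, 60)))
  g2 <- annotated_genome("g2", 100, features = list(f_ovl), check = FALSE)
  expect_true(any(validate_genome(g2)$code == "intron_overlap"))
  expect_error(exonic_length(f_ovl), "overlapping introns")
})

test_that("exonic_length matches table arithmetic on the fixture", {
  g <- fixture_genome()
  fs <- feature_summary(g)
  expect_equal(fs$exonic_length[fs$name == "cox1"], 1587L)   # 19280 - 17693
  expect_equal(fs$exonic_length[fs$name == "nad2"], 1680L)   # 11775 - 10095
  expect_equal(fs$exonic_length[fs$name == "nad3"], 414L)    # intron-free
  # frame invariant for all 14 typical PCGs
  pcg <- fs[fs$category == "PCG", ]
  expect_equal(nrow(pcg), 14L)
  expect_true(all(pcg$exonic_length %% 3L == 0L))
})

test_that("gap_table reproduces the printed intergenic structure", {
  g <- fixture_genome()
  gt <- gap_table(g)
  expect_equal(nrow(gt), 44L)
  expect_equal(max(gt$gap_length), 1593L)
  longest <- gt[which.max(gt$gap_length), ]
  expect_equal(longest$upstream_feature, "trnV-UAC")
  expect_equal(longest$downstream_feature, "trnI-GAU")
  wrap <- gt[gt$wraps_origin, ]
  expect_equal(wrap$gap_length, 87L)   # trnP-UGG end 112378 -> rnl start 1
  expect_equal(wrap$downstream_feature, "rnl")
  # conservation invariant
  expect_equal(sum(gt$gap_length) + sum(feature_summary(g)$length),
               g$length)
  # abutting features (trnK starts right after trnF) give gap 0
  expect_equal(gt$gap_length[gt$upstream_feature == "trnF-GAA"], 0L)
})

test_that("splice_cds splices, reverse-complements and checks frame", {
  g <- toy_genome()
  cds1 <- splice_cds(g, "gene1")
  expect_equal(nchar(cds1), 39L)
  expect_equal(substr(cds1, 1, 3), "ATG")
  expect_false(grepl("TTTT", cds1))   # intron removed
  # minus-strand gene returns the coding strand back
  expect_equal(splice_cds(g, "gene2"), "ATGGCTGCTGCTGCTTAA")
  # frame violation errors
  gbad <- annotated_genome(
    "gbad", 50, sequence = paste(rep("A", 50), collapse = ""),
    features = list(mito_feature("z", "PCG", 1, 10, "+")), check = FALSE)
  expect_error(splice_cds(gbad, "z"), "divisible by 3")
  # internal stop is reported with its codon index
  gstop <- annotated_genome(
    "gstop", 30, sequence = paste0("ATGTAAGCTTAA",
                                   paste(rep("G", 18), collapse = "")),
    features = list(mito_feature("w", "PCG", 1, 12, "+")))
  expect_error(splice_cds(gstop, "w"), "codon index 2")
  # table-only genome cannot splice
  expect_error(splice_cds(fixture_genome(), "cox1"), "no sequence")
})

test_that("conservation holds on generator output", {
  res <- generate_genome(small_config(seed = 42))
  gt <- gap_table(res$genome)
  expect_equal(sum(gt$gap_length) + sum(feature_summary(res$genome)$length),
               res$genome$length)
})
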