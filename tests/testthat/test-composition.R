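# Base composition, skews, region partition, contribution rates.

test_that("base_composition computes counts and skews", {
  s <- base_composition("AATT")
  expect_equal(c(s$a, s$t), c(2L, 2L))
  expect_equal(s$at_skew, 0)
  expect_equal(base_composition("GGGC")$gc_skew, 0.5)   # (3-1)/4
  expect_error(base_composition("ACGTX"), "position 5")
  # undefined skew is NA, never 0
  expect_true(is.na(base_composition("GGCC")$at_skew))
  expect_true(is.na(base_composition("AATT")$gc_skew))
  # N excluded from denominators
  sn <- base_composition("AANN")
  expect_equal(sn$n, 2L)
  expect_equal(sn$at_percent, 100)
})

test_that("an AT-rich mitogenome composition implies its strand skews", {
  # counts realizing A 38.75%, T 34.26%, G 15.06%, C 11.92%
  s <- paste(c(rep("A", 3875), rep("T", 3426), rep("G", 1506),
               rep("C", 1192)), collapse = "")
  comp <- base_composition(s)
  expect_equal(comp$at_skew, 0.0615, tolerance = 2e-3)
  expect_equal(comp$gc_skew, 0.1164, tolerance = 2e-3)
  expect_equal(comp$gc_percent, 26.98, tolerance = 1e-3)
})

test_that("skews are bounded and negate under reverse complement", {
  for (seed in 1:5) {
    s <- random_dna(300, seed = seed)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    a <- base_composition(s); b <- base_composition(rc)
    expect_true(abs(a$at_skew) <= 1 && abs(a$gc_skew) <= 1)
    expect_equal(a$at_skew, -b$at_skew)
    expect_equal(a$gc_skew, -b$gc_skew)
  }
})

test_that("region partition reproduces the fixture region totals", {
  part <- region_partition(fixture_genome())
  expect_equal(part$intron, 78922L)        # intronic ORFs folded in
  expect_equal(part$trna, 1936L)
  expect_equal(part$free_orf, 2658L)       # orf733 + orf151
  cats <- unlist(part[mitocompare:::REGION_CATEGORIES])
  expect_equal(sum(cats), part$total)
  expect_equal(part$total, 112465L)
  # shares match the printed proportions
  expect_equal(100 * part$intron / part$total, 70.17, tolerance = 1e-4)
  expect_equal(100 * part$trna / part$total, 1.72, tolerance = 1e-2)
})

test_that("a genome that is a single intron-free PCG is all pcg_exon", {
  g <- annotated_genome("one", 300, features = list(
    mito_feature("solo", "PCG", 1, 300, "+")))
  part <- region_partition(g)
  expect_equal(part$pcg_exon, 300L)
  expect_equal(part$intergenic, 0L)
  expect_equal(part$intron + part$trna + part$rrna_exon + part$free_orf, 0L)
})

test_that("partition conservation holds on generator output", {
  for (seed in c(3, 8)) {
    res <- generate_genome(small_config(seed = seed))
    part <- region_partition(res$genome)
    cats <- unlist(part[mitocompare:::REGION_CATEGORIES])
    expect_equal(sum(cats), res$genome$length)
    expect_equal(unclass(part)[names(res$manifest$expected_partition)],
                 res$manifest$expected_partition)
  }
})

test_that("contribution rates decompose size differences", {
  g1 <- annotated_genome("a", 1000, features = list(
    mito_feature("p", "PCG", 1, 301, "+",
                 introns = list(mito_intron("p-i1", 101, 200)))))
  p1 <- region_partition(g1)
  # same but intron larger by 10 kb and genome longer by the same amount
  g2 <- annotated_genome("b", 11000, features = list(
    mito_feature("p", "PCG", 1, 10301, "+",
                 introns = list(mito_intron("p-i1", 101, 10200)))))
  p2 <- region_partition(g2)
  ct <- contribution_rates(p1, p2)
  expect_equal(ct$contribution_percent[ct$category == "intron"], 100)
  expect_equal(sum(ct$contribution_percent), 100, tolerance = 1e-9)
  # swapping the genomes leaves percentages unchanged
  ct_sw <- contribution_rates(p2, p1)
  expect_equal(ct_sw$contribution_percent, ct$contribution_percent)
  # hand-computed split 90/10
  mk <- function(intron, intergenic) {
    structure(list(pcg_exon = 300L, intron = intron, trna = 0L,
                   rrna_exon = 0L, free_orf = 0L, intergenic = intergenic,
                   total = 300L + intron + intergenic),
              class = "region_partition")
  }
  ct2 <- contribution_rates(mk(1000L, 500L), mk(10000L, 1500L))
  expect_equal(ct2$contribution_percent[ct2$category == "intron"], 90)
  expect_equal(ct2$contribution_percent[ct2$category == "intergenic"], 10)
  # equal totals: explicitly undefined
  ct3 <- contribution_rates(p1, p1)
  expect_true(all(is.na(ct3$contribution_percent)))
})
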