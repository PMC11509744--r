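# Reference coordinate mapping, Pcl assignment, presence/absence matrix.

test_that("map_to_reference is the identity on the reference itself", {
  ev <- evolve_cds_pair(100, 0.1, 0.2, seed = 31)
  m <- map_to_reference(ev$cds_a, ev$cds_a)
  n <- nchar(ev$cds_a) - 3L    # terminal stop dropped internally
  expect_equal(m$map[seq_len(n)], seq_len(n))
  expect_true(all(m$exact[seq_len(n)]))
  expect_equal(m$aa_identity, 1)
})

test_that("a codon deletion shifts downstream positions by 3", {
  # codon 10 is the only tryptophan, so the alignment gap is unambiguous
  ref <- paste(c("ATG", rep("GCT", 8), "TGG", rep("GCT", 38), "TAA"),
               collapse = "")
  cods <- mitocompare:::split_codons(ref)
  spec <- paste(cods[-10], collapse = "")    # delete codon 10
  m <- map_to_reference(spec, ref)
  expect_equal(m$map[1:27], 1:27)            # before the deletion
  expect_equal(m$map[28:30], 31:33)          # first codon after it
  expect_equal(m$map[58], 61L)
})

test_that("low-identity references are rejected", {
  set.seed(32)
  a <- mitocompare:::random_cds(80, mitocompare:::base_probs(50, 0, 0))
  b <- mitocompare:::random_cds(80, mitocompare:::base_probs(50, 0, 0))
  expect_error(map_to_reference(a, b), "reference unsuitable")
})

test_that("assign_pcls names introns prefix + reference site", {
  res <- generate_genome(small_config(seed = 33,
    intron_plan = data.frame(host = "cox1", after = c(281L, 731L, 500L),
                             length = 120L,
                             group = c("unknown", "IB", "II"))))
  g <- res$genome
  ref <- splice_cds(g, "cox1")   # self-reference: literal coordinates
  asn <- assign_pcls(g, "cox1", ref)
  asn <- asn[order(asn$ref_site), ]
  expect_equal(asn$ref_site, c(281L, 500L, 731L))
  expect_equal(asn$name, c("U281", "S500", "P731"))
  expect_true(all(asn$mapped_exactly))
  # idempotence
  asn2 <- assign_pcls(g, "cox1", ref)
  expect_equal(asn2[order(asn2$ref_site), ], asn)
  expect_error(assign_pcls(g, "nad3", ref), "no introns")
})

test_that("pcl_matrix applies the strict > n/5 common threshold", {
  mk <- function(species, site, prefix = "P")
    data.frame(species = species, gene = "cox1",
               intron_id = paste0("cox1-", site, "-", species),
               group = "IB", ref_site = site, prefix = prefix,
               name = paste0(prefix, site), mapped_exactly = TRUE)
  species <- sprintf("sp%02d", 1:22)
  asn <- rbind(
    do.call(rbind, lapply(species[1:12], mk, site = 731L)),
    do.call(rbind, lapply(species[1], mk, site = 50L, prefix = "S")),
    do.call(rbind, lapply(species[1:5], mk, site = 212L)),
    do.call(rbind, lapply(species[1:4], mk, site = 900L)))
  pm <- pcl_matrix(asn, species = species)
  tab <- pm$table
  expect_equal(tab$status[tab$ref_site == 731], "common")  # 12 > 4.4
  expect_equal(tab$status[tab$ref_site == 50], "rare")     # 1
  expect_equal(tab$status[tab$ref_site == 212], "common")  # 5 > 4.4
  expect_equal(tab$status[tab$ref_site == 900], "rare")    # 4 < 4.4
  expect_equal(tab$sp01[tab$ref_site == 50], "S")
  # duplicate intron ids within a species are rejected
  dup <- rbind(mk("sp01", 100L), mk("sp01", 100L))
  expect_error(pcl_matrix(dup, species = species), "duplicate intron ids")
  # an optional tolerance merges near-identical sites into one Pcl
  near <- rbind(mk("sp01", 400L), mk("sp02", 401L), mk("sp03", 420L))
  pm0 <- pcl_matrix(near, species = species)
  expect_equal(nrow(pm0$table), 3L)
  pm2 <- pcl_matrix(near, species = species, tolerance = 2)
  expect_equal(pm2$table$ref_site, c(400L, 420L))
  expect_equal(pm2$table$n_present, c(2L, 1L))
})

test_that("a generated clade reproduces its Pcl truth manifest", {
  cl <- generate_clade(n_species = 8, seed = 34,
                       pcl_plan = data.frame(
                         site = c(212L, 731L, 1057L, 50L),
                         group = c("I-derived", "IB", "IB", "II"),
                         count = c(8L, 3L, 2L, 1L)))
  asn <- list()
  for (g in cl$genomes) {
    f <- tryCatch(mitocompare:::find_feature(g, "cox1"),
                  error = function(e) NULL)
    if (!is.null(f) && length(f$introns) > 0)
      asn[[g$id]] <- assign_pcls(g, "cox1", cl$reference_cds)
  }
  pm <- pcl_matrix(do.call(rbind, asn), species = cl$manifest$species)
  tab <- pm$table
  m <- cl$manifest$pcl[order(cl$manifest$pcl$site), ]
  expect_equal(tab$ref_site, m$site)
  expect_equal(tab$n_present, m$count)
  expect_equal(tab$status, m$status)
  # prefixes follow the planted groups in every carrier species
  for (r in seq_len(nrow(tab))) {
    cells <- unlist(tab[r, cl$manifest$species])
    expect_setequal(unique(cells[!is.na(cells)]), m$prefix[r])
  }
})
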