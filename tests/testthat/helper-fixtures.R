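# Shared fixtures: the transcribed annotation-table genome and small toy
# genomes built in code.

fixture_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) {
      path <- system.file("extdata", "patypicola_feature_table.tsv",
                          package = "mitocompare")
      g <<- suppressWarnings(read_feature_table(path))
    }
    g
  }
})

# a tiny fully-specified genome with sequence, used across IO/model tests:
# 1..60 PCG gene1 (+, one intron), 71..82 tRNA, 91..108 PCG gene2 (-), 120 bp
toy_genome <- function() {
  # gene1 exons: 1..12 (ATGGCTGCTAAA...) wait: exon1 1..9, intron 10..30,
  # exon2 31..60: exonic 39 bp (13 codons)
  exon1 <- "ATGGCTGCT"
  intron <- paste(rep("T", 21), collapse = "")
  exon2 <- paste0(paste(rep("GCT", 9), collapse = ""), "TAA")
  gene1 <- paste0(exon1, intron, exon2)
  stopifnot(nchar(gene1) == 60)
  trna <- paste(rep("ACGT", 3), collapse = "")
  # gene2 on minus strand, 18 bp: revcomp(ATGGCTGCTGCTGCTTAA)
  gene2_cds <- "ATGGCTGCTGCTGCTTAA"
  gene2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gene2_cds)))
  seq <- paste0(gene1,
                paste(rep("A", 10), collapse = ""),   # 61..70
                trna,                                  # 71..82
                paste(rep("C", 8), collapse = ""),     # 83..90
                gene2,                                 # 91..108
                paste(rep("G", 12), collapse = ""))    # 109..120
  stopifnot(nchar(seq) == 120)
  annotated_genome(
    id = "toy", length = 120, sequence = seq, circular = TRUE,
    features = list(
      mito_feature("gene1", "PCG", 1, 60, "+", start_codon = "ATG",
                   stop_codon = "TAA",
                   introns = list(mito_intron("gene1-i1", 10, 30,
                                              group = "IB"))),
      mito_feature("trnX", "tRNA", 71, 82, "+", anticodon = "UAC"),
      mito_feature("gene2", "PCG", 91, 108, "-", start_codon = "ATG",
                   stop_codon = "TAA")))
}

# small marker set reused by generator-based tests
small_exons <- c(rnl = 900L, rps3 = 300L, nad2 = 300L, nad3 = 300L,
                 atp9 = 225L, cox2 = 300L, nad4L = 300L, nad5 = 300L,
                 cob = 300L, cox1 = 1587L, nad1 = 300L, nad4 = 300L,
                 atp8 = 147L, atp6 = 300L, rns = 450L, cox3 = 300L,
                 nad6 = 300L)

small_config <- function(seed = 1,
                         intron_plan = data.frame(
                           host = "cox1", after = c(212L, 731L),
                           length = 150L, group = c("IB", "II")), ...) {
  sim_config(seed = seed, genome_length = NA, exon_lengths = small_exons,
             n_trna = 5L, intron_plan = intron_plan, ...)
}

random_dna <- function(n, seed = NULL,
                       probs = c(A = .35, C = .15, G = .15, T = .35)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}
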