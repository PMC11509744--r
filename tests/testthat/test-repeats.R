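# Long-repeat detection: planted cases, orientation semantics, brute-force
# oracle equivalence.

plant <- function(host, segment, at) {
  stopifnot(at + nchar(segment) - 1L <= nchar(host))
  paste0(substr(host, 1, at - 1L), segment,
         substr(host, at + nchar(segment), nchar(host)))
}

test_that("a planted exact duplication is found as an F hit", {
  set.seed(101)
  s <- random_dna(5000)
  seg <- random_dna(40)
  s <- plant(plant(s, seg, 1000), seg, 3000)
  hits <- find_repeats(s)
  f <- hits[hits$orientation == "F", ]
  expect_true(any(f$pos1 <= 1000 & f$pos1 + f$length - 1 >= 1039 &
                  f$pos2 <= 3000 & f$pos2 + f$length - 1 >= 3039))
})

test_that("a planted reverse complement is found as a P hit", {
  set.seed(102)
  s <- random_dna(4000)
  seg <- random_dna(35)
  s <- plant(plant(s, seg, 500), oracle_revcomp(seg), 2500)
  hits <- find_repeats(s)
  p <- hits[hits$orientation == "P", ]
  expect_true(any(p$pos1 <= 500 & p$pos1 + p$length - 1 >= 534 &
                  p$pos2 <= 2500 & p$pos2 + p$length - 1 >= 2534))
})

test_that("mismatch budget separates 3 from 4 substitutions", {
  set.seed(103)
  s <- random_dna(2000)
  seg <- random_dna(33)
  mutate_at <- function(x, at) {
    for (p in at) {
      old <- substr(x, p, p)
      substr(x, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    x
  }
  s3 <- plant(plant(s, seg, 200), mutate_at(seg, c(5, 15, 25)), 1200)
  h3 <- find_repeats(s3, min_length = 33)
  f3 <- h3[h3$orientation == "F" & h3$pos1 <= 200 &
           h3$pos1 + h3$length - 1 >= 232, ]
  expect_true(any(f3$mismatches == 3))
  # the same copy with 4 substitutions cannot be covered by one hit
  s4 <- plant(plant(s, seg, 200), mutate_at(seg, c(5, 13, 21, 29)), 1200)
  h4 <- find_repeats(s4, min_length = 33)
  covering <- h4[h4$pos1 <= 200 & h4$pos1 + h4$length - 1 >= 232 &
                 h4$pos2 <= 1200 & h4$pos2 + h4$length - 1 >= 1232, ]
  expect_equal(nrow(covering), 0L)
  # and the brute-force oracle agrees with both scans
  expect_identical(hit_key(h3), hit_key(oracle_find_repeats(s3, 33, 3)))
  expect_identical(hit_key(h4), hit_key(oracle_find_repeats(s4, 33, 3)))
})

test_that("output equals the brute-force oracle on random sequences", {
  for (seed in 1:3) {
    s <- random_dna(400, seed = 200 + seed,
                    probs = c(A = .4, C = .1, G = .1, T = .4))
    got <- find_repeats(s, min_length = 10, max_mismatch = 2, cap = 1e6)
    want <- oracle_find_repeats(s, min_length = 10, max_mismatch = 2)
    expect_identical(hit_key(got), hit_key(want))
  }
})

test_that("P hits are stable under reverse complementing the sequence", {
  s <- random_dna(600, seed = 301, probs = c(A = .4, C = .1, G = .1, T = .4))
  h1 <- find_repeats(s, min_length = 12, max_mismatch = 1,
                     orientations = "P", cap = 1e6)
  rc <- oracle_revcomp(s)
  h2 <- find_repeats(rc, min_length = 12, max_mismatch = 1,
                     orientations = "P", cap = 1e6)
  # reflect coordinates of the revcomp scan back onto s
  n <- nchar(s)
  refl1 <- n - h2$pos2 - h2$length + 2L
  refl2 <- n - h2$pos1 - h2$length + 2L
  k1 <- sort(sprintf("%d:%d:%d:%d", h1$pos1, h1$pos2, h1$length,
                     h1$mismatches))
  k2 <- sort(sprintf("%d:%d:%d:%d", pmin(refl1, refl2), pmax(refl1, refl2),
                     h2$length, h2$mismatches))
  expect_identical(k1, k2)
})

test_that("parameter guards and output contract hold", {
  expect_error(find_repeats("ACGTACGT", min_length = 5), ">= 8")
  s <- random_dna(800, seed = 400, probs = c(A = .45, C = .05, G = .05,
                                             T = .45))
  h <- find_repeats(s, min_length = 10, max_mismatch = 1, cap = 5)
  expect_lte(nrow(h), 5L)
  expect_true(!is.unsorted(rev(h$length)))   # sorted by length descending
  expect_true(all(h$pos1 <= h$pos2))
  # N never matches, not even itself
  hn <- find_repeats(paste(rep("N", 100), collapse = ""), min_length = 10)
  expect_equal(nrow(hn), 0L)
})

test_that("planted generator repeats are recovered (closure)", {
  rp <- data.frame(length = c(40L, 35L, 33L, 30L),
                   orientation = c("F", "P", "R", "C"),
                   mismatches = c(0L, 1L, 3L, 2L))
  res <- generate_genome(small_config(seed = 11, repeat_plan = rp))
  hits <- find_repeats(res$genome$sequence)
  m <- res$manifest$repeats
  for (r in seq_len(nrow(m))) {
    covered <- any(
      hits$orientation == m$orientation[r] &
      hits$pos1 <= m$pos1[r] &
      hits$pos1 + hits$length - 1 >= m$pos1[r] + m$length[r] - 1 &
      hits$pos2 <= m$pos2[r] &
      hits$pos2 + hits$length - 1 >= m$pos2[r] + m$length[r] - 1)
    expect_true(covered, info = sprintf("row %d (%s)", r, m$orientation[r]))
  }
  # a copy planted with the full mismatch budget is recovered exactly
  exact <- merge(m[m$mismatches == 3L, ], hits)
  expect_equal(nrow(exact), sum(m$mismatches == 3L))
})
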