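test_that("a planted perfect dinucleotide array is recovered exactly", {
  g <- plant_repeats(1000, data.frame(unit = "AG", copies = 20), seed = 42)
  loci <- scan_repeats(g$sequences, scan_params("strict"))
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$canonical_class, "AG")
  expect_equal(loci$percent_match, 100L)
  expect_true(abs(loci$copy_number - 20) <= 0.5)
  expect_gte(overlap_frac(loci$start, loci$end, g$truth$start, g$truth$end),
             0.9)
})

test_that("score arithmetic: a perfect array of span L scores match_weight * L", {
  for (spec in list(c("AG", 20), c("TTCAA", 12), c("AAC", 10))) {
    seq <- strrep(spec[1], as.integer(spec[2]))
    span <- nchar(seq)
    loci <- scan_repeats(setNames(seq, "s"),
                         scan_params("loose", min_score = 10))
    expect_equal(loci$score, 2L * span)
  }
})

test_that("threshold semantics: a 12 bp perfect tetramer array passes loose but not strict", {
  s <- c(s = "ACGTACGTACGT")
  expect_equal(nrow(scan_repeats(s, scan_params("strict"))), 0L)
  loose <- scan_repeats(s, scan_params("loose"))
  expect_equal(nrow(loose), 1L)
  expect_equal(loose$score, 24L)
  expect_equal(loose$copy_number, 3)
})

test_that("sequences without a recurring k-mer yield no loci", {
  expect_equal(nrow(scan_repeats(c(s = "ACGT"), scan_params("loose"))), 0L)
  expect_equal(nrow(scan_repeats(c(s = ""), scan_params("loose"))), 0L)
})

test_that("planted-repeat recall is complete with >= 90% interval overlap", {
  spec <- data.frame(
    unit = c("AG", "AAT", "ACAT", "TTCAA", "AT"),
    copies = c(30, 20, 25, 15, 40),
    percent_match = c(100, 100, 95, 100, 90)
  )
  g <- plant_repeats(20000, spec, seed = 9)
  loci <- scan_repeats(g$sequences, scan_params("loose"))
  for (i in seq_len(nrow(g$truth))) {
    ov <- overlap_frac(loci$start, loci$end,
                       g$truth$start[i], g$truth$end[i])
    hit <- which(ov >= 0.9)
    expect_length(hit, 1L)
    expect_equal(loci$canonical_class[hit], canonical_motif(g$truth$unit[i]))
  }
})

test_that("raising min_score never adds loci, and strict loci are found by loose", {
  spec <- data.frame(unit = c("AG", "ACAT", "AAT"),
                     copies = c(30, 25, 20),
                     percent_match = c(100, 95, 100))
  g <- plant_repeats(15000, spec, seed = 5)
  lo <- scan_repeats(g$sequences, scan_params("loose"))
  hi <- scan_repeats(g$sequences, scan_params("loose", min_score = 60))
  key <- function(x) paste(x$seq_id, x$start, x$end, x$unit_length)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lte(nrow(hi), nrow(lo))

  strict <- scan_repeats(g$sequences, scan_params("strict"))
  loose <- scan_repeats(g$sequences, scan_params("loose"))
  for (i in seq_len(nrow(strict))) {
    ov <- overlap_frac(loose$start, loose$end, strict$start[i], strict$end[i])
    j <- which(ov >= 0.9 & loose$canonical_class == strict$canonical_class[i])
    expect_gte(length(j), 1L)
  }
})

test_that("scanning the reverse complement preserves the canonical class multiset", {
  spec <- data.frame(unit = c("AG", "AAT", "TTCAA", "ACAT"),
                     copies = c(30, 20, 15, 25))
  g <- plant_repeats(15000, spec, seed = 13)
  fwd <- scan_repeats(g$sequences, scan_params("strict"))
  rc <- vapply(g$sequences, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1))
  rev <- scan_repeats(rc, scan_params("strict"))
  expect_equal(sort(fwd$canonical_class), sort(rev$canonical_class))
})

test_that("loci never span runs of N", {
  s <- c(s = paste0(strrep("AG", 15), "NN", strrep("AG", 15)))
  loci <- scan_repeats(s, scan_params("loose"))
  n_start <- 31L; n_end <- 32L
  expect_true(all(loci$end < n_start | loci$start > n_end))
  expect_equal(nrow(loci), 2L)
})

test_that("non-primitive seed units are reported as their primitive class", {
  s <- c(s = paste0("TTTT", strrep("AC", 12), "GGG"))
  loci <- scan_repeats(s, scan_params("loose", unit_lengths = 4))
  expect_equal(loci$unit_length, 2L)
  expect_equal(loci$canonical_class, "AC")
})

test_that("invalid parameters and alphabets are rejected", {
  expect_error(scan_params("strict", min_copies = 2), "at least 3")
  expect_error(scan_params(match_weight = 2, mismatch_weight = 7,
                           indel_weight = 7, min_score = -1), "positive")
  expect_error(scan_repeats(c(s = "ACGU"), scan_params("loose")), "non-ACGTN")
})
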