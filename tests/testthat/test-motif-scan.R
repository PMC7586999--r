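# PWM construction, strand-aware scanning, -8 base extraction, best-match
# selection and position enrichment.

# deterministic 6-mer PWM: each column puts weight 1 on the consensus base,
# so at an 85% threshold only exact matches score in
cons_pfm <- function(consensus = "ACGCGA") {
  b <- strsplit(consensus, "")[[1]]
  m <- matrix(0, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(b, rownames(m)), seq_along(b))] <- 1
  m
}

test_that("pfm_to_pwm normalizes columns and reports score bounds", {
  pfm <- matrix(c(3, 1, 0, 0,
                  0, 0, 2, 2), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(pfm)
  expect_equal(pwm$weights[, 1], c(A = 750, C = 250, G = 0, T = 0))
  expect_equal(pwm$weights[, 2], c(A = 0, C = 0, G = 500, T = 500))
  expect_equal(pwm$max_score, 1250)
  expect_equal(pwm$min_score, 0)
  expect_equal(pwm$length, 2L)
  expect_equal(pwm_consensus(pwm), "AG")

  expect_error(pfm_to_pwm(matrix(0, 4, 2)), "all-zero")
  expect_error(pfm_to_pwm(matrix(1, 3, 2)), "4 rows")
})

test_that("PFM files round-trip through both accepted formats", {
  pfm <- abf1_like_pfm()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pfm(pfm, f)
  expect_equal(unname(read_pfm(f)), unname(as.matrix(pfm)),
               tolerance = 1e-12)

  j <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001 test",
               "A [ 3 10 0 ]",
               "C [ 1  0 5 ]",
               "G [ 0  0 5 ]",
               "T [ 6  0 0 ]"), j)
  m <- read_pfm(j)
  expect_equal(m["A", ], c(3, 10, 0))
  expect_equal(m["T", ], c(6, 0, 0))
})

test_that("plus-strand match reports midpoint and the -8 base", {
  pwm <- pfm_to_pwm(cons_pfm())        # ACGCGA, L = 6, midpoint index 3
  chars <- rep("T", 46)
  chars[21:26] <- strsplit("ACGCGA", "")[[1]]   # 0-based start 20
  chars[16] <- "G"                               # 0-based 15 = mid(23) - 8
  hits <- scan_pwm(paste(chars, collapse = ""), pwm)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 20)
  expect_equal(hits$midpoint, 23)
  expect_equal(hits$score, pwm$max_score)
  expect_equal(hits$score_frac, 1)
  expect_equal(hits$minus8_base, "G")
})

test_that("minus-strand match maps coordinates back to the plus strand", {
  pwm <- pfm_to_pwm(cons_pfm())
  chars <- rep("A", 46)
  chars[21:26] <- strsplit(revcomp("ACGCGA"), "")[[1]]  # TCGCGT at 20
  # motif midpoint in motif orientation lands at plus position
  # 20 + 6 - 1 - 3 = 22; the -8 base is read at 22 + 8 = 30, complemented
  chars[31] <- "C"
  hits <- scan_pwm(paste(chars, collapse = ""), pwm)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 20)
  expect_equal(hits$midpoint, 22)
  expect_equal(hits$minus8_base, "G")   # complement of the planted C
  expect_equal(hits$score, pwm$max_score)
})

test_that("offset shifts reported coordinates and N degrades the score", {
  pwm <- pfm_to_pwm(cons_pfm())
  seq <- paste0(strrep("T", 10), "ACGCGA", strrep("T", 10))
  h <- scan_pwm(seq, pwm, chrom = "chrII", offset = 5000L)
  expect_equal(h$chrom, "chrII")
  expect_equal(h$start, 5010)
  expect_equal(h$midpoint, 5013)

  # one N inside the motif takes the column minimum (0 here): 5/6 of the
  # maximum misses a 0.85 threshold but passes 0.8
  seqN <- sub("ACGCGA", "ACGNGA", seq)
  expect_equal(nrow(scan_pwm(seqN, pwm, min_score_frac = 0.85)), 0L)
  hN <- scan_pwm(seqN, pwm, min_score_frac = 0.8)
  expect_equal(hN$score[hN$strand == "+"], 5000)

  # N at the -8 position is reported verbatim
  chars <- rep("N", 46); chars[21:26] <- strsplit("ACGCGA", "")[[1]]
  hNN <- scan_pwm(paste(chars, collapse = ""), pwm)
  expect_equal(hNN$minus8_base[hNN$strand == "+"], "N")
})

test_that("scanning is reverse-complement symmetric", {
  set.seed(19)
  pwm <- pfm_to_pwm(abf1_like_pfm())
  seq <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
               collapse = "")
  fwd <- scan_pwm(seq, pwm, min_score_frac = 0.75)
  rev <- scan_pwm(revcomp(seq), pwm, min_score_frac = 0.75)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(fwd$score), sort(rev$score))
  # a + match at start p maps to a - match at start n - p - L and vice versa
  n <- nchar(seq); L <- pwm$length
  expect_equal(sort(n - fwd$start - L), sort(rev$start))
  expect_setequal(paste(fwd$strand, fwd$score),
                  paste(chartr("+-", "-+", rev$strand), rev$score))
})

test_that("scan_pwm agrees with exhaustive enumeration (with Ns)", {
  set.seed(23)
  pwm <- pfm_to_pwm(abf1_like_pfm())
  seq <- paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
  got <- scan_pwm(seq, pwm, min_score_frac = 0.7)
  want <- enumerate_scan(seq, pwm, min_score_frac = 0.7)
  expect_gt(nrow(want), 0)
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$score, want$score, tolerance = 1e-9)
})

test_that("plus-strand hits agree with Biostrings::matchPWM", {
  set.seed(29)
  pwm <- pfm_to_pwm(abf1_like_pfm())
  seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  got <- scan_pwm(seq, pwm, min_score_frac = 0.75, both_strands = FALSE)
  subject <- Biostrings::DNAString(seq)
  hits <- Biostrings::matchPWM(pwm$weights, subject,
                               min.score = 0.75 * pwm$max_score)
  starts0 <- sort(BiocGenerics::start(hits) - 1L)
  expect_gt(length(starts0), 0)
  expect_equal(got$start, starts0)
  bs_scores <- Biostrings::PWMscoreStartingAt(pwm$weights, subject,
                                              starting.at = starts0 + 1L)
  expect_equal(got$score, as.numeric(bs_scores), tolerance = 1e-9)
})

test_that("best_match prefers score, then summit proximity, then plus", {
  m <- data.frame(chrom = "c", start = c(0, 30, 60),
                  midpoint = c(3, 33, 63),
                  strand = c("+", "-", "+"),
                  score = c(900, 1000, 1000), score_frac = 1,
                  minus8_base = "G")
  expect_equal(best_match(m, summit = 60)$start, 60)   # closer of the 1000s
  expect_equal(best_match(m, summit = 40)$start, 30)
  tie <- m; tie$score <- 1000
  expect_equal(best_match(tie, summit = 48)$strand, "+")  # equidistant -> +
  expect_error(best_match(m[0, ]), "no motif matches")
})

test_that("consensus_counts aligns motifs in motif orientation", {
  genome <- c(chr = "GGGGGGGGACGCGAGGGGGGGG")  # motif at 0-based 8..13
  sites <- data.frame(chrom = "chr", midpoint = 11, strand = "+")
  cc <- consensus_counts(sites, genome, motif_length = 6L,
                         flank_5p = 2L, flank_3p = 1L)
  expect_equal(colnames(cc), as.character(-5:3))
  expect_equal(unname(cc["A", "0"]), 0L)
  expect_equal(unname(cc["C", "0"]), 1L)      # midpoint base of ACGCGA
  expect_equal(unname(cc["G", "-5"]), 1L)     # flank
  # the same motif read from the minus strand gives identical aligned counts
  g2 <- c(chr = paste0("GGGGGGGG", revcomp("ACGCGA"), "GGGGGGGG"))
  # minus-strand midpoint index: start 8, L 6 -> mid at 8 + 6 - 1 - 3 = 10
  s2 <- data.frame(chrom = "chr", midpoint = 10, strand = "-")
  cc2 <- consensus_counts(s2, g2, motif_length = 6L,
                          flank_5p = 2L, flank_3p = 1L)
  expect_equal(cc2[, as.character(-3:2)], cc[, as.character(-3:2)])
})

test_that("position enrichment matches a hand-built Fisher table", {
  g <- c(A = 1, C = 9, G = 8, T = 2)
  r <- c(A = 10, C = 5, G = 5, T = 10)
  out <- position_enrichment_test(g, r, "C")
  ft <- stats::fisher.test(matrix(c(9, 11, 5, 25), 2, 2))
  expect_equal(out$p_value, ft$p.value)
  expect_match(out$method, "Fisher")
  expect_equal(sum(out$table), sum(g) + sum(r))
  expect_error(position_enrichment_test(g * 0, r, "C"), "zero-total")
})

test_that("revcomp is an involution and handles N", {
  expect_equal(revcomp("ACGTN"), "NACGT")
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE), collapse = "")
  expect_equal(revcomp(revcomp(s)), s)
})
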