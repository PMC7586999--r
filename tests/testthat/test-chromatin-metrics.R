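# Meta profiles, MNase protection, NFR width, roadblock index, group tests.

gauss <- function(offsets, center, amp, sd) {
  amp * exp(-(offsets - center)^2 / (2 * sd^2))
}

profile_df <- function(mean, flank = 500) {
  structure(data.frame(offset = -flank:flank, mean = mean,
                       sem = 0, n_sites = 1L),
            class = c("meta_profile", "data.frame"))
}

test_that("smooth_ma averages with truncated end windows", {
  expect_equal(smooth_ma(c(1, 2, 3, 4, 5), 3), c(1.5, 2, 3, 4, 4.5))
  expect_equal(smooth_ma(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(smooth_ma(rep(7, 10), 5), rep(7, 10))
  expect_error(smooth_ma(1:5, 4), "odd")
  # interior windows equal the plain mean
  set.seed(43)
  x <- runif(50)
  s <- smooth_ma(x, 7)
  expect_equal(s[10], mean(x[7:13]))
})

test_that("aggregate_profile reorients minus-strand anchors", {
  v <- numeric(200); v[101:121] <- 1:21        # asymmetric feature at 100..120
  tr <- coverage_track(list(c = v))
  plus <- aggregate_profile(tr, data.frame(chrom = "c", midpoint = 110,
                                           strand = "+"), flank = 15)
  minus <- aggregate_profile(tr, data.frame(chrom = "c", midpoint = 110,
                                            strand = "-"), flank = 15)
  expect_equal(plus$offset, -15:15)
  expect_equal(plus$mean[plus$offset == 0], 11)     # base 110 holds value 11
  expect_equal(plus$mean[plus$offset == 5], 16)
  expect_equal(minus$mean[minus$offset == 5], 6)    # mirrored
  expect_equal(minus$mean, rev(plus$mean))
})

test_that("aggregate_profile averages anchors and reports sem", {
  v <- numeric(300); v[96:105] <- 2; v[196:205] <- 4
  tr <- coverage_track(list(c = v))
  anchors <- data.frame(chrom = "c", midpoint = c(100, 200), strand = "+")
  pr <- aggregate_profile(tr, anchors, flank = 3)
  expect_equal(pr$mean, rep(3, 7))                  # mean of 2 and 4
  expect_equal(pr$sem, rep(sd(c(2, 4)) / sqrt(2), 7))
  expect_equal(pr$n_sites, rep(2L, 7))

  near_end <- rbind(anchors, data.frame(chrom = "c", midpoint = 1,
                                        strand = "+"))
  expect_warning(pr2 <- aggregate_profile(tr, near_end, flank = 3),
                 "dropped")
  expect_equal(pr2$mean, pr$mean)
})

test_that("stranded profiles keep sense as sense for minus anchors", {
  p <- numeric(400); m <- numeric(400)
  p[151:161] <- 9                                  # plus-strand signal
  m[241:251] <- 5                                  # minus-strand signal
  st <- stranded_track(coverage_track(list(c = p)),
                       coverage_track(list(c = m)))
  pr_plus <- aggregate_profile(st, data.frame(chrom = "c", midpoint = 155,
                                              strand = "+"), flank = 10)
  expect_equal(max(pr_plus$mean), 9)
  pr_minus <- aggregate_profile(st, data.frame(chrom = "c", midpoint = 245,
                                               strand = "-"), flank = 10)
  expect_equal(max(pr_minus$mean), 5)              # reads the minus track
})

test_that("MNase protection ratio is the footprint cut-density ratio", {
  before <- coverage_track(list(c = rep(2, 200)))
  after <- coverage_track(list(c = rep(1, 200)))
  r <- mnase_protection_ratio(before, after, "c", 100)
  expect_equal(r$ratio, 0.5)
  expect_false(r$excluded)

  # only the 17-base footprint matters
  a2 <- rep(1, 200); a2[c(92, 110)] <- 100          # just outside -8..+8
  r2 <- mnase_protection_ratio(before, coverage_track(list(c = a2)), "c", 100)
  expect_equal(r2$ratio, 0.5)
  a3 <- rep(1, 200); a3[93] <- 18                   # offset -8: mean 2 -> ratio 1
  r3 <- mnase_protection_ratio(before, coverage_track(list(c = a3)), "c", 100)
  expect_equal(r3$ratio, 1)

  zero <- coverage_track(list(c = rep(0, 200)))
  rz <- mnase_protection_ratio(before, zero, "c", 100)
  expect_true(rz$excluded)
  expect_true(is.na(rz$ratio))
  expect_error(mnase_protection_ratio(before, after, "c", 3),
               "too close")
})

test_that("NFR width is the distance between flanking nucleosome maxima", {
  off <- -500:500
  y <- gauss(off, -150, 1, 30) + gauss(off, 150, 1, 30) + 0.01
  res <- nfr_width(profile_df(y))
  expect_equal(res$minus1_offset, -150)
  expect_equal(res$plus1_offset, 150)
  expect_equal(res$width_bp, 300)

  # asymmetric spacing
  y2 <- gauss(off, -180, 1, 30) + gauss(off, 120, 0.8, 30) + 0.01
  res2 <- nfr_width(profile_df(y2))
  expect_equal(res2$width_bp, 300)
  expect_equal(res2$minus1_offset, -180)
})

test_that("NFR peak calling applies prominence and exclusion-zone rules", {
  off <- -500:500
  base <- gauss(off, -150, 1, 30) + gauss(off, 150, 1, 30) + 0.01
  # low-prominence decoy nearer the anchor is ignored at the default 0.1
  decoy <- base + gauss(off, -60, 0.08, 5)
  res <- nfr_width(profile_df(decoy), smooth_bp = 1)
  expect_equal(res$minus1_offset, -150)
  res_loose <- nfr_width(profile_df(decoy), smooth_bp = 1,
                         min_prominence = 0.05)
  expect_equal(res_loose$minus1_offset, -60)

  # a prominent peak inside the +/- 30 bp dead zone never counts
  inzone <- base + gauss(off, -20, 0.5, 5)
  res_in <- nfr_width(profile_df(inzone), smooth_bp = 1)
  expect_equal(res_in$minus1_offset, -150)

  # nearest qualifying peak wins over a larger, farther one
  two_left <- gauss(off, -350, 1, 30) + gauss(off, -120, 0.5, 30) +
    gauss(off, 150, 1, 30) + 0.01
  expect_equal(nfr_width(profile_df(two_left))$minus1_offset, -120)
})

test_that("NFR dyad override and input validation work", {
  off <- -500:500
  y <- gauss(off, -150, 1, 30) + gauss(off, 150, 1, 30) + 0.01
  d <- nfr_width(profile_df(y), dyads = c(-130, 170))
  expect_equal(d$width_bp, 300)
  expect_equal(d$minus1_offset, -130)

  short <- data.frame(offset = -100:100, mean = y[401:601])
  expect_error(nfr_width(short), "400 bp")
  neg <- profile_df(y); neg$mean[3] <- -1
  expect_error(nfr_width(neg), "non-negative")
  onesided <- profile_df(gauss(off, 150, 1, 30) + 0.01)
  expect_error(nfr_width(onesided), "no flanking nucleosome")
})

test_that("roadblock index divides stalled by incoming signal, strictly > 2", {
  n <- 2000; mid <- 1000
  mk_sense <- function(stalled) {
    v <- numeric(n)
    v[(mid - 300):(mid - 100) + 1] <- 1            # incoming window, mean 1
    v[(mid - 42):(mid - 32) + 1] <- stalled        # stalled window
    v
  }
  zero <- coverage_track(list(c = numeric(n)))
  for (s in c(1, 2, 3)) {
    st <- stranded_track(coverage_track(list(c = mk_sense(s))), zero)
    r <- roadblock_index(st, "c", mid, "+")
    expect_equal(r$index, s)
    expect_equal(r$is_roadblock, s > 2)            # exactly 2 is not one
  }

  # minus-strand anchor: same geometry mirrored on the minus track
  vminus <- numeric(n)
  vminus[(mid + 100):(mid + 300) + 1] <- 1
  vminus[(mid + 32):(mid + 42) + 1] <- 3
  stm <- stranded_track(zero, coverage_track(list(c = vminus)))
  rm_ <- roadblock_index(stm, "c", mid, "-")
  expect_equal(rm_$index, 3)
  expect_true(rm_$is_roadblock)
  # reading the same site as a plus anchor sees only the empty plus track
  rp <- roadblock_index(stm, "c", mid, "+")
  expect_true(rp$excluded)

  expect_error(roadblock_index(stm, "c", 100, "+"), "too close")
})

test_that("group_compare dispatches to the right tests", {
  set.seed(47)
  g <- rep(c("a", "b", "c"), each = 10)
  x <- c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 3))
  an <- group_compare(x, g, "anova_tukey")
  expect_match(an$method, "ANOVA")
  expect_equal(nrow(an$pairwise), 3L)
  ref <- summary(stats::aov(x ~ factor(g)))[[1]][["Pr(>F)"]][1]
  expect_equal(an$p_value, ref)
  expect_true(all(an$pairwise$p_adj >= 0 & an$pairwise$p_adj <= 1))

  x2 <- x[1:20]; g2 <- g[1:20]
  tt <- group_compare(x2, g2, "ttest")
  expect_equal(tt$p_value, stats::t.test(x2[1:10], x2[11:20])$p.value)

  wx <- c(1.1, 2.3, 3.7, 5.2, 8.1, 9.4); wy <- c(0.5, 4.4, 6.6, 7.7)
  wc <- group_compare(c(wx, wy), rep(c("a", "b"), c(6, 4)), "wilcoxon")
  expect_equal(wc$p_value, exact_wilcox_p(wx, wy))

  expect_error(group_compare(x, g, "ttest"), "exactly 2")
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b"), "ttest"),
               "degenerate group")
  # NA metric values are dropped, not propagated
  x3 <- x2; x3[1] <- NA
  expect_silent(group_compare(x3, g2, "wilcoxon"))
})
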