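# Residence-time-stratified functional metrics around motif anchors:
# aggregate profiles, MNase protection, NFR width, Pol II roadblock index,
# and the group-comparison statistics.

# Offset sign convention (everywhere in this file): negative offsets are 5'
# of the motif midpoint ON THE MOTIF STRAND. For minus-strand anchors the
# extracted window is reversed, and for stranded track pairs the plus/minus
# sub-tracks are swapped before reversal.

# extract signal at anchor + offsets (motif orientation); out-of-range -> NA
.extract_offsets <- function(values, midpoint, strand, offsets) {
  pos <- if (strand == "+") midpoint + offsets else midpoint - offsets
  ok <- pos >= 0 & pos < length(values)
  out <- rep(NA_real_, length(offsets))
  out[ok] <- values[pos[ok] + 1]
  out
}

# pick the track carrying the anchor's sense-strand signal
.sense_values <- function(track, chrom, strand) {
  if (inherits(track, "StrandedTrack")) {
    tt <- if (strand == "+") track$plus else track$minus
    tt$values[[chrom]]
  } else track$values[[chrom]]
}

#' Motif-anchored aggregate signal profile
#'
#' Extracts `anchor +/- flank` from the track for every anchor, reorients
#' minus-strand anchors (reversing the window; for a stranded pair the
#' plus/minus sub-tracks are swapped first so sense stays sense), and
#' averages across anchors. Anchors too close to a chromosome end are
#' dropped with a warning.
#'
#' @param track a `CoverageTrack` or `StrandedTrack`. For a stranded pair the
#'   profile is of the sense strand.
#' @param anchors data.frame with columns `chrom`, `midpoint`, `strand`.
#' @param flank half window in bp.
#' @param smooth_bp optional odd moving-average window (NULL = none).
#' @return data.frame of class `meta_profile`: `offset` (-flank..flank),
#'   `mean`, `sem`, `n_sites`.
#' @export
aggregate_profile <- function(track, anchors, flank = 500L,
                              smooth_bp = NULL) {
  if (!nrow(anchors)) stop("empty anchor set")
  offsets <- seq.int(-flank, flank)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(anchors))) {
    v <- .sense_values(track, anchors$chrom[i], anchors$strand[i])
    if (is.null(v)) stop("unknown chromosome: ", anchors$chrom[i])
    if (anchors$midpoint[i] - flank < 0 ||
        anchors$midpoint[i] + flank >= length(v)) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <-
      .extract_offsets(v, anchors$midpoint[i], anchors$strand[i], offsets)
  }
  if (dropped) warning(dropped, " anchor(s) within flank of chromosome ends dropped")
  if (!length(rows)) stop("no usable anchors")
  m <- do.call(rbind, rows)
  mu <- colMeans(m)
  sem <- apply(m, 2, stats::sd) / sqrt(nrow(m))
  if (nrow(m) == 1) sem <- rep(0, ncol(m))
  if (!is.null(smooth_bp)) {
    if (smooth_bp %% 2 == 0) stop("smooth_bp must be odd")
    mu <- smooth_ma(mu, smooth_bp)
  }
  structure(data.frame(offset = offsets, mean = mu, sem = sem,
                       n_sites = nrow(m)),
            class = c("meta_profile", "data.frame"))
}

#' Centered moving average (window truncated at the ends)
#' @param x numeric vector.
#' @param window odd window width.
#' @return smoothed vector of the same length.
#' @export
smooth_ma <- function(x, window) {
  if (window %% 2 == 0) stop("window must be odd")
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' MNase protection ratio at one site
#'
#' Mean per-base cut density in the motif footprint (midpoint -8..+8 bp, 17
#' bases, motif orientation) after depletion divided by the same before
#' depletion. Sites with zero cuts in either condition are excluded
#' (ratio `NA`, `excluded = TRUE`).
#'
#' @param cuts_before,cuts_after `CoverageTrack`s of MNase cut-site density
#'   with the factor present / depleted.
#' @param chrom,midpoint,strand the motif anchor.
#' @param inner footprint half width in bp (default 8).
#' @return list with `ratio` and `excluded`.
#' @export
mnase_protection_ratio <- function(cuts_before, cuts_after, chrom, midpoint,
                                   strand = "+", inner = 8L) {
  offs <- seq.int(-inner, inner)
  b <- .extract_offsets(cuts_before$values[[chrom]], midpoint, strand, offs)
  a <- .extract_offsets(cuts_after$values[[chrom]], midpoint, strand, offs)
  if (anyNA(b) || anyNA(a)) stop("anchor too close to chromosome end")
  mb <- mean(b); ma <- mean(a)
  if (mb == 0 || ma == 0) return(list(ratio = NA_real_, excluded = TRUE))
  list(ratio = ma / mb, excluded = FALSE)
}

# local maxima with scipy-style topographic prominence
.peak_prominences <- function(x) {
  n <- length(x)
  is_max <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(is_max)) return(data.frame(pos = integer(), prominence = numeric()))
  prom <- vapply(is_max, function(i) {
    # walk left until a higher point; base = min in between
    lmin <- x[i]; j <- i
    while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1; lmin <- min(lmin, x[j]) }
    left_base <- if (j == 1 && x[j] <= x[i]) min(x[1:i]) else lmin
    rmin <- x[i]; j <- i
    while (j < n && x[j + 1] <= x[i]) { j <- j + 1; rmin <- min(rmin, x[j]) }
    right_base <- if (j == n && x[j] <= x[i]) min(x[i:n]) else rmin
    x[i] - max(left_base, right_base)
  }, numeric(1))
  data.frame(pos = is_max, prominence = prom)
}

#' Nucleosome-free region width from an occupancy profile
#'
#' After moving-average smoothing, the -1 (+1) nucleosome midpoint is the
#' local maximum nearest the anchor at offset < -`exclude_bp`
#' (> +`exclude_bp`) with topographic prominence at least `min_prominence`
#' times the profile maximum; the NFR width is the distance between the two
#' maxima in bp. Externally annotated dyad positions, when given, take
#' precedence over peak calling.
#'
#' @param profile a `meta_profile` (or data.frame with `offset`, `mean`)
#'   covering at least +/- 400 bp of non-negative occupancy.
#' @param smooth_bp smoothing window (default 31).
#' @param exclude_bp dead zone around the anchor (default 30).
#' @param min_prominence prominence threshold as a fraction of the profile
#'   maximum (default 0.1).
#' @param dyads optional numeric `c(minus1, plus1)` offsets overriding peak
#'   detection.
#' @return list with `width_bp`, `minus1_offset`, `plus1_offset`.
#' @export
nfr_width <- function(profile, smooth_bp = 31L, exclude_bp = 30L,
                      min_prominence = 0.1, dyads = NULL) {
  if (!is.null(dyads)) {
    stopifnot(length(dyads) == 2, dyads[1] < 0, dyads[2] > 0)
    return(list(width_bp = dyads[2] - dyads[1], minus1_offset = dyads[1],
                plus1_offset = dyads[2]))
  }
  if (min(profile$offset) > -400 || max(profile$offset) < 400)
    stop("profile must cover at least +/- 400 bp")
  if (any(profile$mean < 0)) stop("occupancy must be non-negative")
  y <- smooth_ma(profile$mean, smooth_bp)
  pk <- .peak_prominences(y)
  pk <- pk[pk$prominence >= min_prominence * max(y), , drop = FALSE]
  pk$offset <- profile$offset[pk$pos]
  left <- pk[pk$offset < -exclude_bp, , drop = FALSE]
  right <- pk[pk$offset > exclude_bp, , drop = FALSE]
  if (!nrow(left) || !nrow(right))
    stop("no flanking nucleosome on one side of the anchor")
  m1 <- left$offset[which.max(left$offset)]    # nearest on the left
  p1 <- right$offset[which.min(right$offset)]  # nearest on the right
  list(width_bp = p1 - m1, minus1_offset = m1, plus1_offset = p1)
}

#' Pol II roadblock index at one site
#'
#' Mean sense-strand Pol II signal in the stalled-polymerase window
#' (default -37 +/- 5 bp, i.e. offsets [-42, -32]) divided by the mean in
#' the incoming-transcription window (default [-300, -100]); offsets are in
#' motif orientation with the plus/minus tracks swapped for minus-strand
#' anchors. A site is a roadblock when the index strictly exceeds
#' `threshold`.
#'
#' @param polII a `StrandedTrack` of Pol II signal.
#' @param chrom,midpoint,strand the motif anchor.
#' @param peak_window integer c(lo, hi) offsets of the stalled window.
#' @param upstream_window integer c(lo, hi) offsets of the incoming window.
#' @param threshold roadblock cutoff (default 2, strict).
#' @return list with `index`, `is_roadblock`, `excluded` (TRUE when the
#'   upstream window has zero signal).
#' @export
roadblock_index <- function(polII, chrom, midpoint, strand = "+",
                            peak_window = c(-42L, -32L),
                            upstream_window = c(-300L, -100L),
                            threshold = 2) {
  v <- .sense_values(polII, chrom, strand)
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  pw <- .extract_offsets(v, midpoint, strand,
                         seq.int(peak_window[1], peak_window[2]))
  uw <- .extract_offsets(v, midpoint, strand,
                         seq.int(upstream_window[1], upstream_window[2]))
  if (anyNA(pw) || anyNA(uw)) stop("anchor too close to chromosome end")
  up <- mean(uw)
  if (up == 0)
    return(list(index = NA_real_, is_roadblock = NA, excluded = TRUE))
  idx <- mean(pw) / up
  list(index = idx, is_roadblock = idx > threshold, excluded = FALSE)
}

#' Compare a per-site metric between residence-time groups
#'
#' @param values numeric per-site metric.
#' @param groups group label per site (e.g. quartiles).
#' @param test `"anova_tukey"` (one-way ANOVA followed by Tukey's HSD over
#'   all pairwise contrasts), `"ttest"` (two-tailed Welch t-test, 2 groups),
#'   or `"wilcoxon"` (rank-sum, 2 groups, exact where possible).
#' @return list with `method`, `p_value` (global or two-group), and for
#'   ANOVA a `pairwise` data.frame (contrast, diff, adjusted p).
#' @export
group_compare <- function(values, groups,
                          test = c("anova_tukey", "ttest", "wilcoxon")) {
  test <- match.arg(test)
  groups <- as.factor(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (test %in% c("anova_tukey", "ttest")) {
    small <- names(sizes)[sizes < 2]
    if (length(small)) stop("degenerate group: ", small[1])
  }
  if (test == "anova_tukey") {
    fit <- stats::aov(values ~ groups)
    tuk <- stats::TukeyHSD(fit)$groups
    list(method = "one-way ANOVA + Tukey HSD",
         p_value = summary(fit)[[1]][["Pr(>F)"]][1],
         pairwise = data.frame(contrast = rownames(tuk),
                               diff = tuk[, "diff"],
                               p_adj = tuk[, "p adj"],
                               row.names = NULL))
  } else if (test == "ttest") {
    if (length(sizes) != 2) stop("ttest requires exactly 2 groups")
    ht <- stats::t.test(values ~ groups, alternative = "two.sided")
    list(method = "two-tailed t-test", p_value = ht$p.value,
         statistic = unname(ht$statistic))
  } else {
    if (length(sizes) != 2) stop("wilcoxon requires exactly 2 groups")
    ht <- stats::wilcox.test(values ~ groups, alternative = "two.sided",
                             exact = all(sizes < 50))
    list(method = "Wilcoxon rank-sum test", p_value = ht$p.value,
         statistic = unname(ht$statistic))
  }
}
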