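# PWM construction and strand-aware scanning with a percent-of-maximum score
# threshold, plus the -8 bp cross-linkability base extraction.

BASES <- c("A", "C", "G", "T")

#' Read a position frequency matrix
#'
#' Accepts a 4-row TSV (rows A, C, G, T; optional row names) or a
#' JASPAR-style file where rows look like `A [ 3 10 ... ]`.
#'
#' @param path file path.
#' @return 4 x L numeric matrix with rownames A, C, G, T.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^>", lines)]
  if (length(lines) != 4) stop("PFM must have exactly 4 data rows")
  parse_row <- function(ln) {
    ln <- gsub("[][]", " ", ln)
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (f[1] %in% BASES) f <- f[-1]
    as.numeric(f)
  }
  rows <- lapply(lines, parse_row)
  if (length(unique(lengths(rows))) != 1) stop("ragged PFM rows")
  m <- do.call(rbind, rows)
  rownames(m) <- BASES
  if (any(m < 0) || anyNA(m)) stop("PFM entries must be non-negative numbers")
  m
}

#' Write a PFM as a 4-row TSV
#' @param pfm 4 x L matrix.
#' @param path output path.
#' @export
write_pfm <- function(pfm, path) {
  utils::write.table(cbind(BASES, matrix(sprintf("%.15g", pfm), nrow = 4)),
                     path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Convert a position frequency matrix to a position weight matrix
#'
#' Frequencies are multiplied by `scale` and used directly as additive column
#' scores (no log transform, no background model): the score of a window is
#' the sum over motif positions of the weight of the observed base.
#'
#' @param pfm 4 x L non-negative matrix, rows A, C, G, T; no all-zero column.
#' @param scale multiplier applied to the (column-normalized) frequencies
#'   (default 1000).
#' @return object of class `pwm`: list with `weights` (4 x L), `max_score`,
#'   `min_score`, `length`.
#' @export
pfm_to_pwm <- function(pfm, scale = 1000) {
  if (nrow(pfm) != 4) stop("PFM must have 4 rows (A, C, G, T)")
  cs <- colSums(pfm)
  if (any(cs <= 0)) stop("all-zero PFM column at position ", which(cs <= 0)[1])
  w <- sweep(pfm, 2, cs, "/") * scale
  rownames(w) <- BASES
  structure(list(weights = w,
                 max_score = sum(apply(w, 2, max)),
                 min_score = sum(apply(w, 2, min)),
                 length = ncol(w)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM of length", x$length, "- max score", format(x$max_score),
      ", min score", format(x$min_score), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-weight base per column)
#' @param pwm a `pwm` object.
#' @return character string of length `pwm$length`.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$weights, 2, which.max)], collapse = "")
}

# integer codes 1..4 for A,C,G,T; 0 for anything else (N)
.encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], BASES, nomatch = 0L)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string (N-safe)
#' @param seq DNA string over A,C,G,T,N.
#' @return reverse complement string.
#' @export
revcomp <- function(seq) {
  paste(rev(.COMPLEMENT[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# score every window of an encoded sequence against pwm weights; N (code 0)
# contributes the column minimum (worst case)
.score_windows <- function(codes, pwm) {
  L <- pwm$length
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  colmin <- apply(pwm$weights, 2, min)
  s <- numeric(n)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + n - 1L)]
    wj <- ifelse(cj == 0L, colmin[j], pwm$weights[cbind(pmax(cj, 1L), j)])
    s <- s + wj
  }
  s
}

#' Scan a sequence with a PWM on both strands
#'
#' Reports every window whose additive score reaches
#' `min_score_frac * max_score`. Minus-strand windows are scored on the
#' reverse complement. The motif midpoint is the base at 0-based index
#' `floor(L/2)` in motif orientation; `minus8_base` is the genome base 8 bp
#' 5' of the midpoint on the motif strand (complemented for minus-strand
#' matches). Windows containing N take the column-minimum weight at those
#' positions.
#'
#' @param seq DNA string.
#' @param pwm a `pwm` object.
#' @param min_score_frac minimum score as a fraction of `max_score`
#'   (default 0.85).
#' @param both_strands scan the minus strand too (default TRUE).
#' @param chrom chromosome label recorded in the output.
#' @param offset 0-based genomic position of `seq`'s first base.
#' @return data.frame with columns `chrom`, `start` (window start, 0-based),
#'   `midpoint`, `strand`, `score`, `score_frac`, `minus8_base`.
#' @export
scan_pwm <- function(seq, pwm, min_score_frac = 0.85, both_strands = TRUE,
                     chrom = "seq", offset = 0L) {
  L <- pwm$length
  threshold <- min_score_frac * pwm$max_score
  chars <- strsplit(toupper(seq), "")[[1]]
  nbase <- length(chars)
  mid_idx <- L %/% 2L                        # 0-based index in motif orientation
  empty <- data.frame(chrom = character(), start = numeric(),
                      midpoint = numeric(), strand = character(),
                      score = numeric(), score_frac = numeric(),
                      minus8_base = character(), stringsAsFactors = FALSE)
  if (nbase < L) return(empty)
  base_at <- function(pos, comp = FALSE) {
    # pos: 0-based within seq; out of range -> N
    b <- ifelse(pos >= 0 & pos < nbase, chars[pos + 1L], "N")
    b[!b %in% BASES] <- "N"
    if (comp) b <- unname(.COMPLEMENT[b])
    b
  }
  res <- list()
  codes <- match(chars, BASES, nomatch = 0L)
  sp <- .score_windows(codes, pwm)
  hit <- which(sp >= threshold)
  if (length(hit)) {
    p <- hit - 1L                            # 0-based window starts
    mid <- p + mid_idx
    res[["+"]] <- data.frame(chrom = chrom, start = offset + p,
                             midpoint = offset + mid, strand = "+",
                             score = sp[hit], score_frac = sp[hit] / pwm$max_score,
                             minus8_base = base_at(mid - 8L),
                             stringsAsFactors = FALSE)
  }
  if (both_strands) {
    rc_codes <- rev(ifelse(codes == 0L, 0L, 5L - codes))
    sm <- .score_windows(rc_codes, pwm)
    hit <- which(sm >= threshold)
    if (length(hit)) {
      # window i (1-based) on the RC covers original bases
      # [nbase - (i-1) - L, nbase - (i-1)); motif-orientation index m sits at
      # original position p + L - 1 - m
      p <- nbase - (hit - 1L) - L            # 0-based start on original strand
      mid <- p + L - 1L - mid_idx
      res[["-"]] <- data.frame(chrom = chrom, start = offset + p,
                               midpoint = offset + mid, strand = "-",
                               score = sm[hit],
                               score_frac = sm[hit] / pwm$max_score,
                               minus8_base = base_at(mid + 8L, comp = TRUE),
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Best motif match of a set
#'
#' Maximal score; ties broken by smaller distance to the peak summit, then by
#' plus strand.
#'
#' @param matches data.frame as returned by [scan_pwm()].
#' @param summit summit position used for the distance tie-break (optional).
#' @return single-row data.frame.
#' @export
best_match <- function(matches, summit = NULL) {
  if (!nrow(matches)) stop("no motif matches to choose from")
  dist <- if (is.null(summit)) rep(0, nrow(matches)) else
    abs(matches$midpoint - summit)
  ord <- order(-matches$score, dist, matches$strand != "+")
  matches[ord[1], , drop = FALSE]
}

#' Aligned base counts over the best motifs of a site set
#'
#' Extracts each site's best-match motif in motif orientation, extended by
#' `flank_5p` bases 5' (covering the -8 context and position -1) and
#' `flank_3p` bases 3', and tabulates base counts per aligned position.
#'
#' @param sites data.frame with columns `chrom`, `midpoint`, `strand`
#'   (best-match anchors).
#' @param genome named character vector of chromosome sequences.
#' @param motif_length motif length L.
#' @param flank_5p,flank_3p flanking bases included (default 8 and 2).
#' @return matrix of counts, 5 rows (A, C, G, T, N) by aligned position;
#'   column names give the offset from the motif midpoint (motif
#'   orientation), so column "-1" is one base 5' of the midpoint.
#' @export
consensus_counts <- function(sites, genome, motif_length,
                             flank_5p = 8L, flank_3p = 2L) {
  mid_idx <- motif_length %/% 2L
  offs <- seq.int(-(mid_idx + flank_5p), motif_length - 1L - mid_idx + flank_3p)
  counts <- matrix(0L, 5, length(offs),
                   dimnames = list(c(BASES, "N"), as.character(offs)))
  for (i in seq_len(nrow(sites))) {
    s <- genome[[sites$chrom[i]]]
    n <- nchar(s)
    pos <- if (sites$strand[i] == "+") sites$midpoint[i] + offs
           else sites$midpoint[i] - offs
    ok <- pos >= 0 & pos < n
    b <- rep("N", length(offs))
    b[ok] <- substring(s, pos[ok] + 1, pos[ok] + 1)
    if (sites$strand[i] == "-") b <- unname(.COMPLEMENT[b])
    b[!b %in% BASES] <- "N"
    counts[cbind(b, as.character(offs))] <-
      counts[cbind(b, as.character(offs))] + 1L
  }
  counts
}

#' Base enrichment of one group at one motif position
#'
#' Two-sided Fisher exact test on the 2x2 table (base vs not-base) x (group
#' vs rest).
#'
#' @param group_counts named counts (A, C, G, T, optionally N) at one
#'   position for the group of interest.
#' @param rest_counts same for the remaining sites.
#' @param base the nucleotide tested for enrichment.
#' @return list with `p_value`, `odds_ratio`, `table`, and `method`
#'   (metadata naming the test applied).
#' @export
position_enrichment_test <- function(group_counts, rest_counts, base) {
  g <- sum(group_counts); r <- sum(rest_counts)
  if (g == 0 || r == 0) stop("zero-total margin in enrichment test")
  tab <- matrix(c(group_counts[[base]], g - group_counts[[base]],
                  rest_counts[[base]], r - rest_counts[[base]]),
                2, 2, dimnames = list(c(base, paste0("not_", base)),
                                      c("group", "rest")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate), table = tab,
       method = "two-sided Fisher exact test")
}
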