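# Filter a called peak set down to the analyzable binding-site list:
# fold enrichment, motif presence, G/C at -8 bp, telomere exclusion.

#' Filter peaks into analyzable binding sites
#'
#' Applies, in bookkeeping order, the four site filters: (1) fold enrichment
#' at least `fe_min`; (2) at least one PWM match with score fraction at least
#' `min_score_frac` whose midpoint lies within `motif_flank` bp of the peak
#' summit; (3) every such match must carry a G or C at the -8 bp
#' cross-linkability position (N fails); (4) the summit must not fall inside
#' a telomere interval. Each filter is a pure predicate, so final membership
#' is order-independent; the recorded drop reason is the first failing filter
#' in the order above.
#'
#' The motif midpoint of an even-length motif is the base at 0-based index
#' `floor(L/2)` in motif orientation, and -8 bp is measured 5' of the
#' midpoint on the motif strand.
#'
#' @param peaks peak table from [read_peaks()].
#' @param genome named character vector of chromosome sequences.
#' @param pwm a `pwm` object.
#' @param fe_min minimum fold enrichment (default 4).
#' @param motif_flank maximum distance (bp) of a motif midpoint from the peak
#'   summit (default 100).
#' @param min_score_frac minimum PWM score fraction (default 0.85).
#' @param telomere_intervals optional interval table of telomeric regions.
#' @return list with:
#'   \describe{
#'     \item{sites}{peak rows that pass all filters, plus columns
#'       `best_midpoint`, `best_strand`, `best_score`, `best_score_frac`,
#'       `n_motifs`.}
#'     \item{dropped}{dropped peak rows with an `excluded_reason` column
#'       (`fold_enrichment`, `no_motif`, `minus8_AT`, `telomeric`).}
#'     \item{matches}{all qualifying motif matches with a `peak_id` column.}
#'     \item{cascade}{named integer vector of surviving counts after each
#'       filter, starting at the input count.}
#'   }
#' @export
filter_sites <- function(peaks, genome, pwm, fe_min = 4, motif_flank = 100L,
                         min_score_frac = 0.85, telomere_intervals = NULL) {
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing)) stop("no sequence for chromosome ", missing[1])
  n <- nrow(peaks)
  reason <- rep(NA_character_, n)
  best <- data.frame(best_midpoint = rep(NA_real_, n),
                     best_strand = NA_character_, best_score = NA_real_,
                     best_score_frac = NA_real_, n_motifs = 0L)
  all_matches <- list()

  pass_fe <- peaks$fold_enrichment >= fe_min
  pass_motif <- pass_gc <- logical(n)
  for (i in seq_len(n)) {
    s <- genome[[peaks$chrom[i]]]
    # scan wide enough that any motif whose MIDPOINT is within motif_flank of
    # the summit is fully contained in the scanned substring
    lo <- max(peaks$summit[i] - motif_flank - pwm$length, 0)
    hi <- min(peaks$summit[i] + motif_flank + pwm$length, nchar(s) - 1)
    m <- scan_pwm(substring(s, lo + 1, hi + 1), pwm,
                  min_score_frac = min_score_frac, chrom = peaks$chrom[i],
                  offset = lo)
    m <- m[abs(m$midpoint - peaks$summit[i]) <= motif_flank, , drop = FALSE]
    pass_motif[i] <- nrow(m) > 0
    pass_gc[i] <- nrow(m) > 0 && all(m$minus8_base %in% c("G", "C"))
    if (nrow(m)) {
      bm <- best_match(m, summit = peaks$summit[i])
      best$best_midpoint[i] <- bm$midpoint
      best$best_strand[i] <- bm$strand
      best$best_score[i] <- bm$score
      best$best_score_frac[i] <- bm$score_frac
      best$n_motifs[i] <- nrow(m)
      m$peak_id <- peaks$id[i]
      all_matches[[length(all_matches) + 1L]] <- m
    }
  }
  pass_telo <- rep(TRUE, n)
  if (!is.null(telomere_intervals) && nrow(telomere_intervals)) {
    summits <- genomic_intervals(peaks$chrom, peaks$summit, peaks$summit + 1)
    ov <- interval_overlap(summits, telomere_intervals)
    pass_telo[unique(ov$a_idx)] <- FALSE
  }
  reason[!pass_telo] <- "telomeric"
  reason[!pass_gc] <- "minus8_AT"
  reason[!pass_motif] <- "no_motif"
  reason[!pass_fe] <- "fold_enrichment"

  keep <- pass_fe & pass_motif & pass_gc & pass_telo
  sites <- cbind(peaks[keep, , drop = FALSE], best[keep, , drop = FALSE])
  dropped <- cbind(peaks[!keep, , drop = FALSE],
                   data.frame(excluded_reason = reason[!keep]))
  cascade <- c(called = n,
               fold_enrichment = sum(pass_fe),
               motif_and_minus8 = sum(pass_fe & pass_motif & pass_gc),
               non_telomeric = sum(keep))
  rownames(sites) <- rownames(dropped) <- NULL
  list(sites = sites, dropped = dropped,
       matches = if (length(all_matches)) do.call(rbind, all_matches) else
         NULL,
       cascade = cascade)
}
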