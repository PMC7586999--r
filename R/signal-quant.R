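# Fragment evidence -> comparable per-site binding values across a depletion
# time course.

#' Fragment-midpoint coverage with boxcar smoothing
#'
#' Each paired-end fragment contributes weight 1 spread uniformly over a
#' window of `window_bp` bases centred on its midpoint: the coverage at base
#' x equals the number of fragment midpoints within x +/- (window_bp-1)/2.
#' Windows are truncated at chromosome ends, so the total signal is at most
#' `n_fragments * window_bp`.
#'
#' @param fragments interval table of fragment spans (0-based half-open).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window_bp odd smoothing window width in bp (default 101).
#' @return a `CoverageTrack`.
#' @export
build_midpoint_coverage <- function(fragments, chrom_sizes, window_bp = 101L) {
  window_bp <- as.integer(window_bp)
  if (window_bp < 1L || window_bp %% 2L == 0L)
    stop("window_bp must be a positive odd integer")
  half <- (window_bp - 1L) %/% 2L
  bad <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(bad)) stop("fragments on unknown chromosome: ", bad[1])
  vals <- lapply(chrom_sizes, function(n) numeric(n))
  # midpoint of [start, end): central base, lower of the two for even lengths
  mids <- (fragments$start + fragments$end - 1) %/% 2
  for (ch in unique(fragments$chrom)) {
    n <- chrom_sizes[[ch]]
    m <- mids[fragments$chrom == ch]
    lo <- pmax(m - half, 0)              # first covered base
    hi <- pmin(m + half, n - 1)          # last covered base
    # difference-array accumulation, then cumsum
    add <- tabulate(lo + 1L, nbins = n + 1L)
    sub <- tabulate(hi + 2L, nbins = n + 1L)
    vals[[ch]] <- cumsum(add - sub)[seq_len(n)]
  }
  coverage_track(vals)
}

#' Scale a track to a fixed fragment count
#'
#' Multiplies every base by `target_fragments / actual_fragments` so that
#' samples sequenced to different depths become comparable (total genome
#' coverage equalized across samples built from identically placed
#' fragments).
#'
#' @param track a `CoverageTrack`.
#' @param actual_fragments number of (deduplicated) fragments the track was
#'   built from; must be > 0.
#' @param target_fragments reference count, default one million.
#' @return scaled `CoverageTrack`.
#' @export
scale_track <- function(track, actual_fragments, target_fragments = 1e6) {
  if (actual_fragments <= 0) stop("actual_fragments must be > 0")
  f <- target_fragments / actual_fragments
  coverage_track(lapply(track$values, function(v) v * f))
}

#' Total signal in a window around a peak summit
#'
#' Sums the per-base signal over `[summit - half_width, summit + half_width]`
#' (inclusive; 101 bases at the default), clipped at chromosome ends.
#'
#' @param track a `CoverageTrack`.
#' @param chrom chromosome of the summit.
#' @param summit absolute 0-based summit position.
#' @param half_width window half width in bp (default 50).
#' @return numeric window sum.
#' @export
quantify_peak <- function(track, chrom, summit, half_width = 50L) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  if (summit < 0 || summit >= length(v))
    stop("summit ", summit, " off chromosome ", chrom)
  lo <- max(summit - half_width, 0)
  hi <- min(summit + half_width, length(v) - 1)
  sum(v[(lo + 1):(hi + 1)])
}

#' Quantify all peaks of a sample
#'
#' @param track a `CoverageTrack` (already depth-scaled).
#' @param peaks peak table from [read_peaks()].
#' @param half_width window half width (default 50).
#' @return numeric vector of window sums named by peak id.
#' @export
quantify_peaks <- function(track, peaks, half_width = 50L) {
  stats::setNames(
    vapply(seq_len(nrow(peaks)), function(i)
      quantify_peak(track, peaks$chrom[i], peaks$summit[i], half_width),
      numeric(1)),
    peaks$id)
}

#' Normalize per-peak values to the background read fraction
#'
#' The background fraction of a sample is the fraction of its fragments whose
#' midpoints fall outside every peak of the full (unfiltered) peak set. Each
#' raw window sum is divided by this fraction, equalizing background levels
#' across samples while preserving within-sample ratios exactly.
#'
#' @param raw_values numeric vector of per-peak raw window sums.
#' @param total_reads total fragment count of the sample (> 0).
#' @param reads_in_peaks fragments with midpoint inside any peak of the full
#'   peak set; must not exceed `total_reads`.
#' @return list with `background_fraction` and `normalized` (same names as
#'   `raw_values`).
#' @export
background_normalize <- function(raw_values, total_reads, reads_in_peaks) {
  if (total_reads <= 0) stop("total_reads must be > 0")
  if (reads_in_peaks > total_reads)
    stop("reads_in_peaks exceeds total_reads")
  bf <- (total_reads - reads_in_peaks) / total_reads
  if (bf == 0) stop("background fraction is zero (all reads inside peaks)")
  list(background_fraction = bf, normalized = raw_values / bf)
}

#' Count fragments whose midpoint lies inside any peak
#'
#' @param fragments fragment interval table.
#' @param peaks peak table.
#' @return integer count.
#' @export
count_fragments_in_peaks <- function(fragments, peaks) {
  if (!nrow(fragments) || !nrow(peaks)) return(0L)
  mids <- (fragments$start + fragments$end - 1) %/% 2
  midints <- genomic_intervals(fragments$chrom, mids, mids + 1)
  ov <- interval_overlap(midints, genomic_intervals(peaks$chrom, peaks$start,
                                                    peaks$end))
  length(unique(ov$a_idx))
}

#' Flag outlier samples by cross-replicate median absolute deviation
#'
#' For every sample, the deviation score is the median over peaks of the
#' absolute difference between the sample's value and the per-peak median
#' across replicates at the same time point. A sample is flagged when its
#' score strictly exceeds `fold_threshold` times the median score of the
#' other replicates at that time point. Time points with a single replicate
#' are skipped with a warning.
#'
#' @param values matrix of normalized per-peak values, peaks in rows, samples
#'   in columns.
#' @param time_min numeric vector of sample time points (one per column).
#' @param replicate integer vector of replicate labels (one per column).
#' @param fold_threshold flag multiplier (default 6).
#' @return data.frame with one row per sample: `time_min`, `replicate`,
#'   `mad_score`, `mad_ratio`, `flagged`.
#' @export
flag_outlier_samples <- function(values, time_min, replicate,
                                 fold_threshold = 6) {
  stopifnot(ncol(values) == length(time_min),
            length(time_min) == length(replicate))
  out <- data.frame(time_min = time_min, replicate = replicate,
                    mad_score = NA_real_, mad_ratio = NA_real_,
                    flagged = FALSE)
  for (t in unique(time_min)) {
    cols <- which(time_min == t)
    if (length(cols) < 2L) {
      warning("time point ", t, " has a single replicate; skipped")
      next
    }
    med <- apply(values[, cols, drop = FALSE], 1, stats::median)
    scores <- vapply(cols, function(j)
      stats::median(abs(values[, j] - med)), numeric(1))
    out$mad_score[cols] <- scores
    for (k in seq_along(cols)) {
      ref <- stats::median(scores[-k])
      out$mad_ratio[cols[k]] <- if (ref > 0) scores[k] / ref else
        ifelse(scores[k] > 0, Inf, 1)
      out$flagged[cols[k]] <- scores[k] > fold_threshold * ref
    }
  }
  out
}

#' Build the normalized site-by-sample binding matrix from a sample sheet
#'
#' Runs midpoint coverage, depth scaling, window quantification and
#' background normalization for every sample of a depletion time course.
#'
#' @param sample_sheet data.frame with columns `path` (fragment BED),
#'   `time_min`, `replicate`; optional `total_fragments` (defaults to the
#'   fragment count in the file).
#' @param peaks full (unfiltered) peak table; background fractions are
#'   computed against it.
#' @param chrom_sizes named chromosome lengths.
#' @param site_ids peak ids to quantify (default: all peaks).
#' @param window_bp,half_width,target_fragments see the stage functions.
#' @return list with `matrix` (sites x samples, normalized),
#'   `raw` (same shape, pre-normalization), `samples` (per-sample metadata
#'   incl. background fraction).
#' @export
quantify_samples <- function(sample_sheet, peaks, chrom_sizes,
                             site_ids = peaks$id, window_bp = 101L,
                             half_width = 50L, target_fragments = 1e6) {
  keep <- match(site_ids, peaks$id)
  if (anyNA(keep)) stop("unknown site id: ", site_ids[which(is.na(keep))[1]])
  n <- nrow(sample_sheet)
  raw <- norm <- matrix(NA_real_, length(site_ids), n,
                        dimnames = list(site_ids, NULL))
  meta <- cbind(sample_sheet,
                data.frame(total_fragments = NA_real_,
                           background_fraction = NA_real_))
  for (j in seq_len(n)) {
    frags <- read_fragments(sample_sheet$path[j])
    tot <- if ("total_fragments" %in% names(sample_sheet) &&
               !is.na(sample_sheet$total_fragments[j]))
      sample_sheet$total_fragments[j] else nrow(frags)
    track <- scale_track(build_midpoint_coverage(frags, chrom_sizes,
                                                 window_bp),
                         actual_fragments = tot,
                         target_fragments = target_fragments)
    rawj <- quantify_peaks(track, peaks[keep, , drop = FALSE], half_width)
    in_pk <- count_fragments_in_peaks(frags, peaks)
    bn <- background_normalize(rawj, tot, in_pk)
    raw[, j] <- rawj
    norm[, j] <- bn$normalized
    meta$total_fragments[j] <- tot
    meta$background_fraction[j] <- bn$background_fraction
  }
  colnames(raw) <- colnames(norm) <-
    paste0("t", sample_sheet$time_min, "_r", sample_sheet$replicate)
  list(matrix = norm, raw = raw, samples = meta)
}
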