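# Nascent-RNA time-course processing: median normalization, responsive-gene
# selection, promoter assignment, and synthesis-rate decay fitting with the
# same model as binding.

#' Median-of-totals count normalization
#'
#' Removes rRNA genes, then scales every sample so its post-filter total
#' equals the median of the per-sample totals.
#'
#' @param counts gene x sample numeric matrix with rownames = gene ids.
#' @param biotypes named character vector gene id -> biotype; genes with
#'   biotype `"rRNA"` are dropped before totals are computed.
#' @return list with `matrix` (normalized, rRNA-free) and `scale_factors`.
#' @export
normalize_counts_median <- function(counts, biotypes) {
  keep <- rownames(counts)[biotypes[rownames(counts)] != "rRNA"]
  if (!length(keep)) stop("no non-rRNA genes left after filtering")
  m <- counts[keep, , drop = FALSE]
  totals <- colSums(m)
  if (any(totals == 0)) stop("sample with zero total counts")
  sf <- stats::median(totals) / totals
  list(matrix = sweep(m, 2, sf, "*"), scale_factors = sf)
}

#' Select genes responsive to depletion
#'
#' A gene is downregulated (upregulated) when its fold change is below
#' 1/`fc_min` (above `fc_min`) with adjusted p < `p_max` at every required
#' time point (strict inequalities). Downregulated genes get a magnitude
#' sub-label from the fold change at the first required time: `"strong"`
#' (FC > 2 down), `"weak"` (1.5 <= FC <= 2 down), otherwise `"no_change"`.
#'
#' @param de data.frame with columns `gene_id`, `time_min`, `fold_change`
#'   (linear, relative to t = 0) and `padj`.
#' @param fc_min fold-change threshold (default 1.5).
#' @param p_max adjusted-p threshold (default 0.01).
#' @param required_times time points at which the thresholds must all hold
#'   (default 20 and 30 min).
#' @return list with character vectors `down`, `up`, `unchanged` and a
#'   data.frame `labels` (gene_id, class, magnitude).
#' @export
select_responsive_genes <- function(de, fc_min = 1.5, p_max = 0.01,
                                    required_times = c(20, 30)) {
  rows <- lapply(unique(de$gene_id), function(g) {
    sub <- de[de$gene_id == g & de$time_min %in% required_times, ,
              drop = FALSE]
    if (length(unique(sub$time_min)) < length(required_times)) {
      warning("gene ", g, " missing a required time point; skipped")
      return(NULL)
    }
    down <- all(sub$fold_change < 1 / fc_min & sub$padj < p_max)
    up <- all(sub$fold_change > fc_min & sub$padj < p_max)
    fc1 <- sub$fold_change[sub$time_min == required_times[1]][1]
    mag <- if (!down) "no_change" else
      if (fc1 < 1 / 2) "strong" else
      if (fc1 <= 1 / 1.5) "weak" else "no_change"
    data.frame(gene_id = g,
               class = if (down) "down" else if (up) "up" else "unchanged",
               magnitude = mag, stringsAsFactors = FALSE)
  })
  labels <- do.call(rbind, rows)
  if (is.null(labels))
    labels <- data.frame(gene_id = character(), class = character(),
                         magnitude = character())
  list(down = labels$gene_id[labels$class == "down"],
       up = labels$gene_id[labels$class == "up"],
       unchanged = labels$gene_id[labels$class == "unchanged"],
       labels = labels)
}

#' Assign binding sites to gene promoters
#'
#' A gene is linked to a site when the site's peak summit lies in the
#' promoter window: `[tss - promoter_bp, tss)` for plus-strand genes,
#' `(tss, tss + promoter_bp]` for minus-strand genes (the TSS itself is
#' excluded). When several sites qualify, the one whose summit is nearest
#' the TSS wins.
#'
#' @param sites site table with columns `id`, `chrom`, `summit`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @param promoter_bp promoter length upstream of the TSS (default 500).
#' @return named character vector gene_id -> site id (only assigned genes).
#' @export
assign_peak_to_gene <- function(sites, genes, promoter_bp = 500L) {
  out <- character(0)
  for (i in seq_len(nrow(genes))) {
    cand <- sites[sites$chrom == genes$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    d <- cand$summit - genes$tss[i]
    inside <- if (genes$strand[i] == "+") d >= -promoter_bp & d < 0
              else d > 0 & d <= promoter_bp
    if (!any(inside)) next
    cand <- cand[inside, , drop = FALSE]
    out[genes$gene_id[i]] <- cand$id[which.min(abs(cand$summit -
                                                     genes$tss[i]))]
  }
  out
}

#' Fit the synthesis-decay model to one gene
#'
#' Delegates to [fit_decay()]: the same first-order exponential decay model
#' describes the decrease of nascent-RNA synthesis after depletion, with y0
#' the pre-depletion expression, yf the final level and the rate constant
#' the expression decrease rate.
#'
#' @param gene_tc a `timecourse` of normalized transcript counts.
#' @return a `decay_fit` row; `converged = FALSE` marks unfittable genes.
#' @export
fit_synthesis_decay <- function(gene_tc) {
  fit_decay(gene_tc)
}
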