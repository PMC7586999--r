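# Seeded generators for every input the pipeline consumes, with known ground
# truth, so the full method is testable without any external download.

#' Default depletion time grid
#'
#' Eleven time points spanning 90 minutes of depletion (t = 0 is the
#' mock-treated sample). The count and span follow the study design; the
#' intermediate spacing is denser early, where the fast sites decay.
#'
#' @return numeric vector of minutes.
#' @export
default_times <- function() c(0, 2.5, 5, 7.5, 10, 15, 20, 30, 45, 60, 90)

#' Observation noise model for simulated time courses
#'
#' @param kind `"lognormal"` (multiplicative, exact curve at sd = 0) or
#'   `"poisson"` (counting noise around the expectation).
#' @param sd lognormal sigma (ignored for poisson).
#' @param replicate_sd sigma of the per-replicate multiplicative effect.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(kind = c("lognormal", "poisson"), sd = 0.1,
                        replicate_sd = 0.05) {
  kind <- match.arg(kind)
  structure(list(kind = kind, sd = sd, replicate_sd = replicate_sd),
            class = "noise_model")
}

#' Exponential-decay expectation
#' @param t times (min).
#' @param y0,yf,koff model parameters.
#' @return expected binding at each time.
#' @export
decay_curve <- function(t, y0, yf, koff) yf + (y0 - yf) * exp(-koff * t)

#' Simulate one site's depletion time course
#'
#' Expected value follows the first-order decay curve; replicate effects are
#' multiplicative and constant within a replicate; observation noise is
#' applied per measurement.
#'
#' @param site_id site label.
#' @param y0,yf,koff true parameters (y0 > yf >= 0, koff > 0).
#' @param times time grid including 0 (default [default_times()]).
#' @param n_reps replicates (default 3).
#' @param noise a `noise_model` (default noiseless lognormal).
#' @param seed optional integer seed (set before any random draw).
#' @return a `timecourse`.
#' @export
simulate_timecourse <- function(site_id, y0, yf, koff,
                                times = default_times(), n_reps = 3,
                                noise = noise_model(sd = 0, replicate_sd = 0),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- decay_curve(times, y0, yf, koff)
  rep_eff <- exp(stats::rnorm(n_reps, 0, noise$replicate_sd))
  vals <- matrix(NA_real_, n_reps, length(times))
  for (r in seq_len(n_reps)) {
    m <- mu * rep_eff[r]
    vals[r, ] <- switch(noise$kind,
      lognormal = m * exp(stats::rnorm(length(m), 0, noise$sd)),
      poisson = stats::rpois(length(m), m))
  }
  timecourse(site_id, times, vals)
}

#' Abf1-like position frequency matrix (synthetic)
#'
#' A 13-column matrix built from the consensus RTCRYNNNNNACG of the factor's
#' binding site: strong flanks, five degenerate middle positions. It is a
#' constructed stand-in for a curated matrix, suitable for simulation and
#' testing, not a published motif.
#'
#' @param strength weight of the consensus base at informative positions
#'   (0.5 < strength <= 1).
#' @return 4 x 13 PFM.
#' @export
abf1_like_pfm <- function(strength = 0.9) {
  cols <- c("R", "T", "C", "R", "Y", "N", "N", "N", "N", "N", "A", "C", "G")
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), N = c("A", "C", "G", "T"))
  m <- matrix(0, 4, length(cols), dimnames = list(BASES, NULL))
  for (j in seq_along(cols)) {
    allowed <- iupac[[cols[j]]]
    if (length(allowed) == 4) {
      m[, j] <- 0.25
    } else {
      m[allowed, j] <- strength / length(allowed)
      m[setdiff(BASES, allowed), j] <- (1 - strength) / (4 - length(allowed))
    }
  }
  m
}

# uniform random DNA
.random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                 collapse = "")

# overwrite genome string s with `sub` at 0-based position pos
.plant <- function(s, sub, pos) {
  paste0(substring(s, 1, pos), sub, substring(s, pos + nchar(sub) + 1))
}

#' Simulate a full depletion ChIP-seq experiment
#'
#' Builds a synthetic genome with motif-bearing binding sites of known
#' off-rates, then draws per-sample fragments: site fragments Poisson around
#' the site's decayed expectation with midpoints jittered around the summit,
#' plus uniform background fragments. Sites are constructed to exercise every
#' selection filter: `n_low_fe` get a sub-threshold fold enrichment,
#' `n_no_motif` carry no motif, `n_at_minus8` have an A or T planted at the
#' -8 bp position, and `n_telomeric` sit inside the declared telomere
#' intervals; the rest are clean.
#'
#' @param n_sites total sites.
#' @param koff_range uniform sampling range for true off-rates (min^-1),
#'   default the observed span 0.03-0.24.
#' @param times,n_reps depletion design.
#' @param y0_range uniform range of expected t = 0 site fragment counts.
#' @param yf_frac plateau as a fraction of y0 (default 0.1).
#' @param background_rate expected background fragments per bp per sample.
#' @param n_low_fe,n_no_motif,n_at_minus8,n_telomeric planted failure counts.
#' @param fragment_len simulated fragment length (bp).
#' @param seed integer seed.
#' @param fragments draw per-sample fragments (set FALSE when only the
#'   genome, peaks and truth are needed, e.g. for filter tests).
#' @param out_dir optional directory; when given, FASTA, per-sample fragment
#'   BEDs, a narrowPeak file, a sample sheet, telomere BED, PFM and the truth
#'   table are written there.
#' @return list with `genome`, `peaks`, `truth`, `sample_sheet`, `fragments`
#'   (list of interval tables), `telomeres`, `pfm`, `chrom_sizes`, `times`,
#'   and `paths` when `out_dir` is given.
#' @export
simulate_chip_experiment <- function(n_sites = 30, koff_range = c(0.03, 0.24),
                                     times = default_times(), n_reps = 3,
                                     y0_range = c(200, 800), yf_frac = 0.1,
                                     background_rate = 0.9,
                                     n_low_fe = 5, n_no_motif = 4,
                                     n_at_minus8 = 3, n_telomeric = 1,
                                     fragment_len = 150, seed = 1,
                                     fragments = TRUE, out_dir = NULL) {
  set.seed(seed)
  n_fail <- n_low_fe + n_no_motif + n_at_minus8 + n_telomeric
  if (n_fail > n_sites) stop("more planted failures than sites")
  spacing <- 2000L
  telo_len <- 1500L
  glen <- telo_len * 2L + spacing * (n_sites + 1L)
  if (glen < (n_sites * spacing)) stop("genome too small for site spacing")
  chrom <- "chrS"
  g <- .random_dna(glen)

  pfm <- abf1_like_pfm()
  pwm <- pfm_to_pwm(pfm)
  consensus <- pwm_consensus(pwm)
  L <- nchar(consensus)
  mid_idx <- L %/% 2L

  classes <- sample(c(rep("low_fe", n_low_fe), rep("no_motif", n_no_motif),
                      rep("at_minus8", n_at_minus8),
                      rep("telomeric", n_telomeric),
                      rep("clean", n_sites - n_fail)))
  # non-telomeric summits on a regular grid, telomeric ones inside telomeres
  telomeres <- genomic_intervals(c(chrom, chrom), c(0, glen - telo_len),
                                 c(telo_len, glen))
  interior <- telo_len + spacing * seq_len(n_sites)
  summits <- interior
  telo_slots <- which(classes == "telomeric")
  if (length(telo_slots))
    summits[telo_slots] <- round(seq(500, telo_len - 500,
                                     length.out = length(telo_slots)))
  truth <- data.frame(
    site_id = sprintf("site_%03d", seq_len(n_sites)),
    chrom = chrom, summit = summits,
    strand = sample(c("+", "-"), n_sites, replace = TRUE),
    class = classes,
    koff_true = stats::runif(n_sites, koff_range[1], koff_range[2]),
    y0_true = stats::runif(n_sites, y0_range[1], y0_range[2]),
    stringsAsFactors = FALSE)
  truth$yf_true <- yf_frac * truth$y0_true
  truth$fold_enrichment_true <-
    ifelse(classes == "low_fe", stats::runif(n_sites, 2, 3.9),
           stats::runif(n_sites, 4.5, 12))
  truth$minus8_base <- ifelse(classes == "at_minus8",
                              sample(c("A", "T"), n_sites, replace = TRUE),
                              sample(c("G", "C"), n_sites, replace = TRUE))

  # plant motifs (consensus, so score_frac = 1) and the -8 base
  for (i in seq_len(n_sites)) {
    if (classes[i] == "no_motif") next
    motif <- if (truth$strand[i] == "+") consensus else revcomp(consensus)
    start <- truth$summit[i] - mid_idx          # midpoint at the summit
    g <- .plant(g, motif, start)
    # -8 bp 5' of the midpoint on the motif strand
    m8 <- if (truth$strand[i] == "+")
      truth$minus8_base[i] else unname(.COMPLEMENT[truth$minus8_base[i]])
    m8pos <- if (truth$strand[i] == "+") truth$summit[i] - 8L
             else truth$summit[i] + 8L
    g <- .plant(g, m8, m8pos)
  }
  # scrub accidental motif matches near every summit so the only match per
  # motif-bearing site is the planted one (and none at no_motif sites);
  # protected positions (planted motif span, -8 base) are never mutated
  worst <- BASES[apply(pwm$weights, 2, which.min)]
  for (i in seq_len(n_sites)) {
    keep_mid <- if (classes[i] == "no_motif") -1L else truth$summit[i]
    protect <- if (classes[i] == "no_motif") integer(0) else {
      span <- (truth$summit[i] - mid_idx):(truth$summit[i] - mid_idx + L - 1L)
      c(span, if (truth$strand[i] == "+") truth$summit[i] - 8L else
        truth$summit[i] + 8L)
    }
    for (iter in 1:25) {
      lo <- max(truth$summit[i] - 100L - L, 0)
      hi <- min(truth$summit[i] + 100L + L, glen - 1)
      m <- scan_pwm(substring(g, lo + 1, hi + 1), pwm, chrom = chrom,
                    offset = lo)
      m <- m[abs(m$midpoint - truth$summit[i]) <= 100L &
               m$midpoint != keep_mid, , drop = FALSE]
      if (!nrow(m)) break
      # mutate one unprotected base of the first spurious window to the
      # worst-scoring base for its PWM column
      p <- m$start[1]
      idx <- 0:(L - 1L)
      gpos <- p + idx
      motif_j <- if (m$strand[1] == "+") idx else L - 1L - idx
      free <- which(!(gpos %in% protect))
      if (!length(free)) break
      # mutate the free position where switching to the worst base cuts the
      # window score the most
      cur <- substring(g, gpos[free] + 1, gpos[free] + 1)
      if (m$strand[1] == "-") cur <- unname(.COMPLEMENT[cur])
      colw <- pwm$weights
      red <- vapply(seq_along(free), function(k) {
        col <- motif_j[free[k]] + 1L
        w <- if (cur[k] %in% BASES) colw[cur[k], col] else min(colw[, col])
        w - min(colw[, col])
      }, numeric(1))
      j <- free[which.max(red)]
      b <- worst[motif_j[j] + 1L]
      if (m$strand[1] == "-") b <- unname(.COMPLEMENT[b])
      g <- .plant(g, b, gpos[j])
    }
  }
  genome <- stats::setNames(g, chrom)
  chrom_sizes <- stats::setNames(glen, chrom)

  peaks <- data.frame(chrom = chrom, start = truth$summit - 100,
                      end = truth$summit + 101, id = truth$site_id,
                      score = 0, strand = ".",
                      fold_enrichment = truth$fold_enrichment_true,
                      summit = truth$summit, stringsAsFactors = FALSE)

  design <- expand.grid(replicate = seq_len(n_reps), time_min = times)
  frag_list <- if (fragments) vector("list", nrow(design)) else NULL
  half <- fragment_len %/% 2L
  n_bg <- round(background_rate * glen)
  for (j in seq_len(if (fragments) nrow(design) else 0L)) {
    t <- design$time_min[j]
    mids <- integer(0)
    for (i in seq_len(n_sites)) {
      lam <- decay_curve(t, truth$y0_true[i], truth$yf_true[i],
                         truth$koff_true[i])
      k <- stats::rpois(1, lam)
      if (k) mids <- c(mids, truth$summit[i] +
                         sample(-30:30, k, replace = TRUE))
    }
    mids <- c(mids, sample.int(glen, n_bg, replace = TRUE) - 1L)
    start <- pmax(mids - half, 0)
    end <- pmin(mids + half, glen)
    frag_list[[j]] <- genomic_intervals(chrom, start, end)
  }
  sample_sheet <- data.frame(time_min = design$time_min,
                             replicate = design$replicate,
                             role = "IP", stringsAsFactors = FALSE)

  out <- list(genome = genome, peaks = peaks, truth = truth,
              sample_sheet = sample_sheet, fragments = frag_list,
              telomeres = telomeres, pfm = pfm, chrom_sizes = chrom_sizes,
              times = times)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(out_dir, "genome.fa"),
      peaks = file.path(out_dir, "peaks.narrowPeak"),
      truth = file.path(out_dir, "site_truth.tsv"),
      telomeres = file.path(out_dir, "telomeres.bed"),
      pfm = file.path(out_dir, "pfm.tsv"),
      chrom_sizes = file.path(out_dir, "chrom.sizes"),
      sample_sheet = file.path(out_dir, "sample_sheet.tsv"))
    write_genome(genome, paths$genome)
    with(peaks, writeLines(sprintf(
      "%s\t%d\t%d\t%s\t%d\t%s\t%.4g\t-1\t-1\t%d", chrom, start, end, id,
      as.integer(score), strand, fold_enrichment, summit - start),
      paths$peaks))
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_fragments(telomeres, paths$telomeres)
    write_pfm(pfm, paths$pfm)
    writeLines(sprintf("%s\t%d", chrom, glen), paths$chrom_sizes)
    if (fragments) {
      frag_paths <- character(nrow(design))
      for (j in seq_len(nrow(design))) {
        frag_paths[j] <- file.path(out_dir, sprintf("fragments_t%g_r%d.bed",
                                                    design$time_min[j],
                                                    design$replicate[j]))
        write_fragments(frag_list[[j]], frag_paths[j])
      }
      sheet <- cbind(path = frag_paths, sample_sheet)
      utils::write.table(sheet, paths$sample_sheet, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      out$sample_sheet <- sheet
    }
    out$paths <- paths
  }
  out
}

#' Simulate auxiliary chromatin tracks with planted metric values
#'
#' For each anchor, constructs (in motif orientation, mirrored for
#' minus-strand anchors): a nucleosome occupancy profile with Gaussian bumps
#' at +/- the given NFR half width; an MNase cut track pair where the
#' post-depletion track equals the pre-depletion track with the footprint
#' window (midpoint -8..+8) multiplied by the planted protection depth (so
#' the measured after/before ratio equals the depth); and a stranded Pol II
#' pair with a uniform sense plateau and the stalled window at -37 +/- 5 bp
#' set so the roadblock index equals its planted value.
#'
#' @param anchors data.frame with `chrom`, `midpoint`, `strand`; all on one
#'   chromosome.
#' @param chrom_sizes named chromosome lengths.
#' @param nfr_half_widths per-anchor half width of the nucleosome-free
#'   region (bp).
#' @param protection_depths per-anchor planted MNase protection ratio.
#' @param roadblock_indices per-anchor planted Pol II roadblock index.
#' @param bump_sd Gaussian nucleosome bump sd (default 40 bp).
#' @param noise_sd multiplicative lognormal noise on all tracks (default 0).
#' @param seed integer seed.
#' @param out_dir optional directory for bedGraph output.
#' @return list with `occupancy` (`CoverageTrack`), `mnase_before`,
#'   `mnase_after` (`CoverageTrack`s), `polII` (`StrandedTrack`), `truth`.
#' @export
simulate_profiles <- function(anchors, chrom_sizes, nfr_half_widths,
                              protection_depths, roadblock_indices,
                              bump_sd = 40, noise_sd = 0, seed = 1,
                              out_dir = NULL) {
  set.seed(seed)
  n <- nrow(anchors)
  stopifnot(length(nfr_half_widths) == n, length(protection_depths) == n,
            length(roadblock_indices) == n)
  zero <- lapply(chrom_sizes, function(len) numeric(len))
  occ <- zero
  mnase_b <- lapply(chrom_sizes, function(len) rep(1, len))
  mnase_a <- mnase_b
  pol_plus <- lapply(chrom_sizes, function(len) rep(0.05, len))
  pol_minus <- pol_plus
  for (i in seq_len(n)) {
    ch <- anchors$chrom[i]; mid <- anchors$midpoint[i]
    sgn <- if (anchors$strand[i] == "+") 1 else -1
    len <- chrom_sizes[[ch]]
    pos <- seq.int(0, len - 1)
    off <- (pos - mid) * sgn                    # motif-orientation offsets
    near <- abs(off) <= 600
    occ[[ch]][near] <- occ[[ch]][near] +
      exp(-(off[near] - nfr_half_widths[i])^2 / (2 * bump_sd^2)) +
      exp(-(off[near] + nfr_half_widths[i])^2 / (2 * bump_sd^2))
    foot <- which(off >= -8 & off <= 8)
    mnase_a[[ch]][foot] <- mnase_b[[ch]][foot] * protection_depths[i]
    sense <- if (anchors$strand[i] == "+") "pol_plus" else "pol_minus"
    upstream <- which(off >= -300 & off <= -100)
    stalled <- which(off >= -42 & off <= -32)
    if (sense == "pol_plus") {
      pol_plus[[ch]][upstream] <- 1
      pol_plus[[ch]][stalled] <- roadblock_indices[i]
    } else {
      pol_minus[[ch]][upstream] <- 1
      pol_minus[[ch]][stalled] <- roadblock_indices[i]
    }
  }
  jitter <- function(vals) {
    if (noise_sd == 0) return(vals)
    lapply(vals, function(v) v * exp(stats::rnorm(length(v), 0, noise_sd)))
  }
  out <- list(
    occupancy = coverage_track(jitter(occ)),
    mnase_before = coverage_track(jitter(mnase_b)),
    mnase_after = coverage_track(jitter(mnase_a)),
    polII = stranded_track(coverage_track(jitter(pol_plus)),
                           coverage_track(jitter(pol_minus))),
    truth = cbind(anchors,
                  data.frame(nfr_half_width = nfr_half_widths,
                             protection_depth = protection_depths,
                             roadblock_index = roadblock_indices)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_track(out$occupancy, file.path(out_dir, "occupancy.bedgraph"))
    write_track(out$mnase_before, file.path(out_dir, "mnase_before.bedgraph"))
    write_track(out$mnase_after, file.path(out_dir, "mnase_after.bedgraph"))
    write_track(out$polII$plus, file.path(out_dir, "polII_plus.bedgraph"))
    write_track(out$polII$minus, file.path(out_dir, "polII_minus.bedgraph"))
  }
  out
}

#' Simulate a nascent-RNA depletion time course
#'
#' Gene-level transcript counts decay with known rates for responsive genes;
#' a matching differential-expression table (true fold changes, small
#' adjusted p for responsive genes at the required times) and a TSS
#' annotation whose promoters contain the given site summits are produced.
#'
#' @param sites site table (`id`, `chrom`, `summit`) to link genes to.
#' @param n_unresponsive extra flat genes (plus one rRNA gene).
#' @param decrease_rate_range uniform range of true decrease rates.
#' @param times,n_reps design.
#' @param noise a `noise_model`.
#' @param seed integer seed.
#' @return list with `counts` (gene x sample), `biotypes`, `genes` (TSS
#'   annotation), `de` (per-time fold change / padj table), `truth`,
#'   `sample_info`.
#' @export
simulate_rna_experiment <- function(sites, n_unresponsive = 10,
                                    decrease_rate_range = c(0.03, 0.24),
                                    times = default_times(), n_reps = 3,
                                    noise = noise_model("poisson"),
                                    seed = 1) {
  set.seed(seed)
  n_resp <- nrow(sites)
  gene_ids <- c(sprintf("gene_resp_%03d", seq_len(n_resp)),
                sprintf("gene_flat_%03d", seq_len(n_unresponsive)),
                "gene_rRNA_001")
  # responsive genes: TSS 200 bp downstream of the site summit (+ strand)
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = c(sites$chrom, rep(sites$chrom[1], n_unresponsive + 1)),
    tss = c(sites$summit + 200,
            seq(10, by = 7, length.out = n_unresponsive + 1)),
    strand = "+",
    biotype = c(rep("mRNA", n_resp + n_unresponsive), "rRNA"),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = gene_ids,
    responsive = c(rep(TRUE, n_resp), rep(FALSE, n_unresponsive + 1)),
    rate_true = c(stats::runif(n_resp, decrease_rate_range[1],
                               decrease_rate_range[2]),
                  rep(0, n_unresponsive + 1)),
    y0_true = stats::runif(length(gene_ids), 500, 2000),
    stringsAsFactors = FALSE)
  truth$yf_true <- ifelse(truth$responsive, 0.15 * truth$y0_true,
                          truth$y0_true)
  design <- expand.grid(replicate = seq_len(n_reps), time_min = times)
  counts <- matrix(0, length(gene_ids), nrow(design),
                   dimnames = list(gene_ids, paste0("t", design$time_min,
                                                    "_r", design$replicate)))
  for (i in seq_along(gene_ids)) {
    mu <- decay_curve(design$time_min, truth$y0_true[i], truth$yf_true[i],
                      max(truth$rate_true[i], 1e-9))
    counts[i, ] <- if (noise$kind == "poisson") stats::rpois(length(mu), mu)
                   else mu * exp(stats::rnorm(length(mu), 0, noise$sd))
  }
  de <- do.call(rbind, lapply(c(20, 30), function(t) {
    fc <- decay_curve(t, truth$y0_true, truth$yf_true,
                      pmax(truth$rate_true, 1e-9)) / truth$y0_true
    data.frame(gene_id = gene_ids, time_min = t, fold_change = fc,
               padj = ifelse(truth$responsive, 1e-4, 0.9),
               stringsAsFactors = FALSE)
  }))
  biotypes <- stats::setNames(genes$biotype, genes$gene_id)
  list(counts = counts, biotypes = biotypes, genes = genes, de = de,
       truth = truth,
       sample_info = data.frame(time_min = design$time_min,
                                replicate = design$replicate))
}
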