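# ---- GenomicInterval -------------------------------------------------------

#' Construct a table of genomic intervals
#'
#' Intervals are the coordinate currency of the package: 0-based, half-open
#' `[start, end)`, optionally stranded. All public functions accept and return
#' this representation; 1-based external formats (wiggle `fixedStep`) are
#' converted at the I/O boundary.
#'
#' @param chrom character vector of chromosome names (nonempty strings).
#' @param start integer vector, 0-based inclusive start.
#' @param end integer vector, 0-based exclusive end; must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval (recycled).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be nonempty")
  if (any(!strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at row ", bad[1])
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Overlapping pairs between two interval sets
#'
#' Reports every pair `(i, j)` such that `a[i]` and `b[j]` share at least one
#' base under half-open semantics; adjacent intervals (`end == start`) do not
#' overlap.
#'
#' @param a,b interval tables as returned by [genomic_intervals()].
#' @return a `data.frame` with integer columns `a_idx`, `b_idx` (1-based row
#'   indices), ordered by `a_idx` then `b_idx`.
#' @export
interval_overlap <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(a_idx = integer(), b_idx = integer()))
  hits <- data.frame(a_idx = integer(), b_idx = integer())
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    # half-open [start, end) -> 1-based closed [start + 1, end]
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    ov <- IRanges::findOverlaps(ra, rb)
    if (length(ov))
      hits <- rbind(hits, data.frame(
        a_idx = ia[S4Vectors::queryHits(ov)],
        b_idx = ib[S4Vectors::subjectHits(ov)]))
  }
  hits[order(hits$a_idx, hits$b_idx), , drop = FALSE]
}

# ---- CoverageTrack ---------------------------------------------------------

#' Construct a per-base coverage track
#'
#' @param values named list of numeric vectors, one per chromosome, holding
#'   non-negative per-base signal. Chromosome lengths are fixed at
#'   construction.
#' @return an object of class `CoverageTrack` with fields `values` and
#'   `total_signal` (the sum of all per-base values).
#' @export
coverage_track <- function(values) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("coverage values must be a named list of per-chromosome vectors")
  values <- lapply(values, as.numeric)
  if (any(vapply(values, function(v) any(v < 0 | !is.finite(v)), logical(1))))
    stop("coverage values must be finite and non-negative")
  structure(list(values = values,
                 total_signal = sum(vapply(values, sum, numeric(1)))),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$values), "chromosomes, total signal",
      format(x$total_signal), "\n")
  invisible(x)
}

#' Chromosome lengths of a coverage track
#' @param track a `CoverageTrack`.
#' @return named integer vector of lengths.
#' @export
track_chrom_sizes <- function(track) {
  vapply(track$values, length, integer(1))
}

#' A stranded plus/minus track pair
#'
#' @param plus,minus `CoverageTrack` objects over the same chromosomes.
#' @return an object of class `StrandedTrack`.
#' @export
stranded_track <- function(plus, minus) {
  if (!identical(track_chrom_sizes(plus), track_chrom_sizes(minus)))
    stop("plus and minus tracks must share chromosome lengths")
  structure(list(plus = plus, minus = minus), class = "StrandedTrack")
}

# ---- readers / writers -----------------------------------------------------

#' Read a chrom.sizes file
#' @param path two-column TSV (chrom, length).
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$size, tab$chrom)
}

#' Read peaks from a narrowPeak or TSV file
#'
#' Accepts MACS2 narrowPeak (10 columns; the 10th is the summit offset
#' relative to `start`) or a headerless 5+-column TSV with chrom, start, end,
#' summit offset, fold enrichment. Summits are converted to absolute 0-based
#' coordinates.
#'
#' @param path file path (may be gzip-compressed).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `id`,
#'   `score`, `strand`, `fold_enrichment`, `summit` (absolute, 0-based), in
#'   file order.
#' @export
read_peaks <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), id = character(), score = numeric(),
                      strand = character(), fold_enrichment = numeric(),
                      summit = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  parse_line <- function(i) {
    f <- fields[[i]]
    if (length(f) >= 10L) {        # narrowPeak
      out <- list(chrom = f[1], start = as.numeric(f[2]),
                  end = as.numeric(f[3]), id = f[4], score = as.numeric(f[5]),
                  strand = f[6], fold_enrichment = as.numeric(f[7]),
                  offset = as.numeric(f[10]))
    } else if (length(f) >= 5L) {  # minimal TSV
      out <- list(chrom = f[1], start = as.numeric(f[2]),
                  end = as.numeric(f[3]), id = paste0("peak_", i), score = 0,
                  strand = ".", fold_enrichment = as.numeric(f[5]),
                  offset = as.numeric(f[4]))
    } else {
      stop("malformed peak line ", i, ": expected >= 5 fields, got ",
           length(f))
    }
    with(out, {
      if (anyNA(c(start, end, fold_enrichment, offset)))
        stop("malformed peak line ", i, ": non-numeric field")
      if (!(start >= 0 && start < end))
        stop("malformed peak line ", i, ": invalid interval")
      summit <- start + offset
      if (summit < start || summit >= end)
        stop("peak line ", i, ": summit offset ", offset,
             " falls outside the interval")
      data.frame(chrom = chrom, start = start, end = end, id = id,
                 score = score, strand = strand,
                 fold_enrichment = fold_enrichment, summit = summit,
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, lapply(seq_along(fields), parse_line))
}

#' Read a bedGraph or wiggle file into a coverage track
#'
#' bedGraph records are 0-based half-open; wiggle `fixedStep`/`variableStep`
#' records are 1-based and converted on read. Bases covered by no record are
#' 0; overlapping records sum.
#'
#' @param path bedGraph (`.bedgraph`/`.bg`) or wiggle (`.wig`) file, possibly
#'   gzip-compressed.
#' @param chrom_sizes named vector of chromosome lengths covering every
#'   chromosome in the file.
#' @return a `CoverageTrack`.
#' @export
read_track <- function(path, chrom_sizes) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#|browser)", lines)]
  vals <- lapply(chrom_sizes, function(n) numeric(n))
  is_wig <- grepl("\\.wig(\\.gz)?$", path) ||
    any(grepl("^(fixedStep|variableStep)", lines))
  if (is_wig) {
    chrom <- NULL; pos <- NA_real_; step <- 1; span <- 1; mode <- "none"
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (grepl("^(fixedStep|variableStep)", ln)) {
        kv <- strsplit(strsplit(ln, "[ \t]+")[[1]][-1], "=")
        kv <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
        chrom <- kv[["chrom"]]
        if (!chrom %in% names(vals))
          stop("wig line ", i, ": unknown chromosome ", chrom)
        span <- if ("span" %in% names(kv)) as.numeric(kv[["span"]]) else 1
        if (startsWith(ln, "fixedStep")) {
          mode <- "fixed"
          pos <- as.numeric(kv[["start"]]) - 1  # 1-based -> 0-based
          step <- as.numeric(kv[["step"]])
        } else mode <- "variable"
      } else {
        f <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
        if (mode == "fixed") { at <- pos; v <- f[1]; pos <- pos + step }
        else if (mode == "variable") { at <- f[1] - 1; v <- f[2] }
        else stop("wig line ", i, ": data before declaration")
        if (at + span > length(vals[[chrom]]))
          stop("wig line ", i, ": record beyond chromosome end")
        idx <- (at + 1):(at + span)
        vals[[chrom]][idx] <- vals[[chrom]][idx] + v
      }
    }
  } else {
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t| +")[[1]]
      if (length(f) < 4) stop("bedGraph line ", i, ": expected 4 fields")
      ch <- f[1]; s <- as.numeric(f[2]); e <- as.numeric(f[3])
      v <- as.numeric(f[4])
      if (anyNA(c(s, e, v))) stop("bedGraph line ", i, ": non-numeric field")
      if (!ch %in% names(vals))
        stop("bedGraph line ", i, ": unknown chromosome ", ch)
      if (e > length(vals[[ch]]))
        stop("bedGraph line ", i, ": record beyond chromosome end")
      if (s < e) vals[[ch]][(s + 1):e] <- vals[[ch]][(s + 1):e] + v
    }
  }
  coverage_track(vals)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are merged; zero runs are omitted. The written file
#' round-trips through [read_track()] to identical per-base values.
#'
#' @param track a `CoverageTrack`.
#' @param path output path (gzip if it ends in `.gz`).
#' @export
write_track <- function(track, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths      # 0-based
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.10g", ch, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

#' Read fragment intervals from a BED file
#' @param path BED3+ file (0-based half-open), possibly gzipped.
#' @return interval table as from [genomic_intervals()].
#' @export
read_fragments <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (!length(lines)) return(genomic_intervals(character(), numeric(), numeric()))
  f <- strsplit(lines, "\t| +")
  short <- which(lengths(f) < 3)
  if (length(short)) stop("malformed BED line ", short[1])
  genomic_intervals(vapply(f, `[`, "", 1),
                    as.numeric(vapply(f, `[`, "", 2)),
                    as.numeric(vapply(f, `[`, "", 3)),
                    vapply(f, function(x) if (length(x) >= 6) x[6] else ".", ""))
}

#' Write intervals as BED
#' @param intervals interval table.
#' @param path output path.
#' @export
write_fragments <- function(intervals, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(intervals))
    writeLines(sprintf("%s\t%d\t%d\t.\t0\t%s", intervals$chrom,
                       as.integer(intervals$start), as.integer(intervals$end),
                       intervals$strand), con)
  invisible(path)
}

#' Read a genome FASTA into uppercase per-chromosome strings
#' @param path FASTA file, possibly gzipped.
#' @return named character vector of uppercase sequences over A,C,G,T,N.
#' @export
read_genome <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a genome FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path)
  invisible(path)
}
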