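# Independent oracles used across test files. These deliberately use naive
# algorithms (full enumeration, brute force) so they stay independent of the
# implementation paths they check.

# all-pairs interval overlap under half-open semantics
brute_overlap <- function(a, b) {
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i])
      hits[[length(hits) + 1L]] <- c(i, j)
  }
  if (!length(hits)) return(data.frame(a_idx = integer(), b_idx = integer()))
  m <- do.call(rbind, hits)
  out <- data.frame(a_idx = m[, 1], b_idx = m[, 2])
  out[order(out$a_idx, out$b_idx), , drop = FALSE]
}

# exhaustive PWM scan: score every window on both strands position by
# position (N scores the column minimum)
enumerate_scan <- function(seq, pwm, min_score_frac) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  L <- pwm$length
  chars <- strsplit(toupper(seq), "")[[1]]
  score_window <- function(w) {
    s <- 0
    for (j in seq_len(L)) {
      b <- w[j]
      s <- s + if (b %in% bases) pwm$weights[b, j] else min(pwm$weights[, j])
    }
    s
  }
  out <- list()
  for (p in seq_len(length(chars) - L + 1)) {
    w <- chars[p:(p + L - 1)]
    sp <- score_window(w)
    if (sp >= min_score_frac * pwm$max_score)
      out[[length(out) + 1L]] <- data.frame(start = p - 1, strand = "+",
                                            score = sp)
    sm <- score_window(rev(unname(comp[w])))
    if (sm >= min_score_frac * pwm$max_score)
      out[[length(out) + 1L]] <- data.frame(start = p - 1, strand = "-",
                                            score = sm)
  }
  if (!length(out)) return(data.frame(start = integer(), strand = character(),
                                      score = numeric()))
  o <- do.call(rbind, out)
  o[order(o$start, o$strand), , drop = FALSE]
}

# minimum SSE of the decay model over a dense (y0, yf, log koff) grid; the
# quadratic structure in (y0, yf) is used only to evaluate grid points
# exactly, the grid itself is the oracle
grid_min_sse <- function(times, y, y0_true, yf_true, koff_true, n = 60) {
  y0g <- seq(y0_true / 3, y0_true * 3, length.out = n)
  yfg <- seq(max(yf_true / 3, 1e-9), yf_true * 3, length.out = n)
  lkg <- seq(log(koff_true / 3), log(koff_true * 3), length.out = n)
  best <- Inf
  sy2 <- sum(y^2)
  for (lk in lkg) {
    e <- exp(-exp(lk) * times)
    u <- 1 - e
    a1 <- sum(y * u); a2 <- sum(y * e)
    b11 <- sum(u^2); b12 <- sum(u * e); b22 <- sum(e^2)
    # SSE(yf, y0) = sy2 - 2(yf a1 + y0 a2) + yf^2 b11 + 2 y0 yf b12 + y0^2 b22
    sse <- outer(yfg, y0g, function(f, o)
      sy2 - 2 * (f * a1 + o * a2) + f^2 * b11 + 2 * o * f * b12 + o^2 * b22)
    best <- min(best, min(sse))
  }
  best
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
exact_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

sse_of_fit <- function(fit, times, y) {
  pred <- fit$yf + (fit$y0 - fit$yf) * exp(-fit$koff * times)
  sum((y - pred)^2)
}
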