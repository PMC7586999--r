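# Per-site first-order exponential decay fitting:
#   y(t) = yf + (y0 - yf) * exp(-koff * t)
# with mean residence time 1/koff and a pseudo-R-squared goodness of fit.

#' Construct a per-site depletion time course
#'
#' @param site_id site identifier.
#' @param times strictly increasing time points in minutes, starting at 0.
#' @param values replicate-by-time matrix of normalized binding values;
#'   NA marks flagged/missing samples.
#' @return object of class `timecourse`.
#' @export
timecourse <- function(site_id, times, values) {
  values <- as.matrix(values)
  if (is.null(dim(values)) || ncol(values) != length(times))
    stop("values must be a replicate x time matrix matching times")
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (times[1] != 0) stop("times must start at 0")
  with_data <- sum(colSums(!is.na(values)) > 0)
  if (with_data < 4) stop("need >= 4 distinct time points with data")
  structure(list(site_id = site_id, times = times, values = values),
            class = "timecourse")
}

#' Starting values for the decay fit
#'
#' The plateau starts at the smallest time-point mean (floored at 0), the
#' initial level at the t = 0 mean, and the rate from the slope of a
#' regression of `log(max(mean_t - 0.9 * yf_init, eps))` on time.
#'
#' @param tc a `timecourse`.
#' @return list with `y0`, `yf`, `log_koff`.
#' @export
initialize_decay <- function(tc) {
  means <- colMeans(tc$values, na.rm = TRUE)
  if (stats::var(means[is.finite(means)]) == 0)
    stop("non-identifiable: flat time course")
  yf0 <- max(min(means, na.rm = TRUE), 0)
  y00 <- means[1]
  eps <- max(1e-8, 1e-6 * max(abs(means)))
  z <- log(pmax(means - 0.9 * yf0, eps))
  sl <- stats::coef(stats::lm(z ~ tc$times))[2]
  k0 <- max(-sl, 1e-4)
  list(y0 = unname(y00), yf = unname(yf0), log_koff = unname(log(k0)))
}

#' Fit the exponential decay model to one site
#'
#' Minimizes the sum of squared residuals over all replicate observations
#' (no pre-averaging), with the rate parameterized as log(koff) so koff > 0.
#' Fitting goes through `stats::nls` with the asymptotic self-start model
#' `SSasymp(time, yf, y0, log_koff)`; if that fails, a BFGS minimization
#' seeded by [initialize_decay()] is used. Goodness of fit is the
#' pseudo-R-squared against the grand mean of the observations used.
#'
#' @param tc a `timecourse`.
#' @return one-row data.frame of class `decay_fit`: `site_id`, `y0`, `yf`,
#'   `koff` (min^-1), `residence_time_min` (= 1/koff), `r2`, `converged`,
#'   `n_points`.
#' @export
fit_decay <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  d <- data.frame(time = rep(tc$times, each = nrow(tc$values)),
                  y = as.vector(tc$values))
  d <- d[is.finite(d$y), , drop = FALSE]
  if (length(unique(d$time)) < 4)
    stop("need >= 4 distinct time points with data")
  sse <- function(p) {
    pred <- p[2] + (p[1] - p[2]) * exp(-exp(p[3]) * d$time)
    sum((d$y - pred)^2)
  }
  # variable projection: for fixed koff the model is linear in (y0, yf)
  # (y = yf * (1 - e) + y0 * e with e = exp(-koff t)), so profile the SSE
  # over log(koff) alone and recover the linear pair in closed form
  varpro <- function(lk) {
    e <- exp(-exp(lk) * d$time)
    cf <- tryCatch(stats::lm.fit(cbind(yf = 1 - e, y0 = e), d$y)$coefficients,
                   error = function(err) c(yf = NA_real_, y0 = NA_real_))
    if (anyNA(cf)) cf[is.na(cf)] <- mean(d$y)
    list(par = c(unname(cf["y0"]), unname(cf["yf"]), lk),
         sse = sse(c(unname(cf["y0"]), unname(cf["yf"]), lk)))
  }
  tpos <- min(d$time[d$time > 0]); tmax <- max(d$time)
  lk_lo <- log(0.01 / tmax); lk_hi <- log(20 / tpos)
  # coarse scan then local refinement keeps the 1-D profile search off
  # secondary minima
  grid <- seq(lk_lo, lk_hi, length.out = 60)
  prof <- vapply(grid, function(l) varpro(l)$sse, numeric(1))
  j <- which.min(prof)
  opt <- stats::optimize(function(l) varpro(l)$sse,
                         lower = grid[max(j - 1, 1)],
                         upper = grid[min(j + 1, length(grid))],
                         tol = 1e-10)
  candidates <- list(varpro = c(varpro(opt$minimum), converged = TRUE))
  # polish with the paper's asymptotic-regression nls fit, self-start first,
  # then explicitly started at the projected optimum
  fit <- tryCatch(
    stats::nls(y ~ SSasymp(time, yf, y0, log_koff), data = d,
               control = stats::nls.control(maxiter = 200, tol = 1e-9,
                                            minFactor = 1e-10,
                                            scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) {
    vp <- candidates$varpro$par
    fit <- tryCatch(
      stats::nls(y ~ yf + (y0 - yf) * exp(-exp(log_koff) * time), data = d,
                 start = list(y0 = vp[1], yf = vp[2], log_koff = vp[3]),
                 control = stats::nls.control(maxiter = 200, tol = 1e-9,
                                              minFactor = 1e-10,
                                              scaleOffset = 1)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    p <- unname(cf[c("y0", "yf", "log_koff")])
    candidates$nls <- list(par = p, sse = sse(p), converged = TRUE)
  }
  best <- candidates[[which.min(vapply(candidates, `[[`, numeric(1),
                                       "sse"))]]
  y0 <- best$par[1]; yf <- best$par[2]; lk <- best$par[3]
  converged <- isTRUE(best$converged)
  koff <- exp(lk)
  pred <- yf + (y0 - yf) * exp(-koff * d$time)
  r2 <- pseudo_r2(d$y, pred)
  out <- data.frame(site_id = tc$site_id, y0 = y0, yf = yf, koff = koff,
                    residence_time_min = 1 / koff, r2 = r2,
                    converged = converged && all(is.finite(c(y0, yf, koff))),
                    n_points = nrow(d), stringsAsFactors = FALSE)
  class(out) <- c("decay_fit", class(out))
  out
}

#' Pseudo-R-squared of a fit
#'
#' `1 - sum(residuals^2) / sum((y - mean(y))^2)`; at most 1, unbounded below.
#'
#' @param observed,fitted numeric vectors of equal length >= 2.
#' @return numeric scalar.
#' @export
pseudo_r2 <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2)
    stop("observed and fitted must have equal length >= 2")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("zero total variance: pseudo-R2 undefined")
  1 - sum((observed - fitted)^2) / sst
}

#' Assign residence-time quartile labels
#'
#' Sites are ranked by residence time descending and split into four
#' contiguous groups; when n is not divisible by 4 the extra sites go to the
#' earlier (longer-residence) groups, e.g. 191 sites -> 48/48/48/47. Ties
#' spanning a boundary are broken by site id (lexical), making the
#' assignment deterministic.
#'
#' @param fits data.frame with columns `site_id` and `residence_time_min`
#'   (rows with `converged == FALSE` are excluded if the column is present).
#' @return named character vector site_id -> one of `"longest"`, `"long"`,
#'   `"short"`, `"shortest"`.
#' @export
assign_quartiles <- function(fits) {
  if ("converged" %in% names(fits)) fits <- fits[fits$converged, , drop = FALSE]
  n <- nrow(fits)
  if (n < 4) stop("need >= 4 fits to form quartiles")
  ord <- order(-fits$residence_time_min, fits$site_id)
  sizes <- rep(n %/% 4L, 4L)
  extra <- n %% 4L
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(c("longest", "long", "short", "shortest"), times = sizes)
  stats::setNames(labels, fits$site_id[ord])
}

#' Fit all sites of a binding matrix
#'
#' One decay fit per site, using every unflagged replicate observation;
#' per-site failures are recorded without aborting the batch, and quartile
#' labels are assigned over the converged fits.
#'
#' @param mat sites x samples matrix of normalized binding values.
#' @param time_min,replicate per-column sample annotations.
#' @param exclude logical per-column flag (e.g. from
#'   [flag_outlier_samples()]); flagged columns are dropped before fitting.
#' @return list with `fits` (one row per site incl. `quartile`),
#'   `residuals` (site x observation matrix for QC), and `summary`
#'   (median/min r2, residence-time range, counts).
#' @export
fit_all_sites <- function(mat, time_min, replicate,
                          exclude = rep(FALSE, ncol(mat))) {
  stopifnot(ncol(mat) == length(time_min))
  use <- !exclude
  times <- sort(unique(time_min[use]))
  reps <- sort(unique(replicate[use]))
  fits <- list(); resid <- list()
  for (i in seq_len(nrow(mat))) {
    vals <- matrix(NA_real_, length(reps), length(times),
                   dimnames = list(reps, times))
    for (j in which(use))
      vals[as.character(replicate[j]), as.character(time_min[j])] <- mat[i, j]
    f <- tryCatch(fit_decay(timecourse(rownames(mat)[i], times, vals)),
                  error = function(e)
                    data.frame(site_id = rownames(mat)[i], y0 = NA_real_,
                               yf = NA_real_, koff = NA_real_,
                               residence_time_min = NA_real_, r2 = NA_real_,
                               converged = FALSE, n_points = sum(!is.na(vals)),
                               stringsAsFactors = FALSE))
    fits[[i]] <- f
    if (f$converged) {
      pred <- f$yf + (f$y0 - f$yf) * exp(-f$koff *
                                           rep(times, each = length(reps)))
      resid[[i]] <- as.vector(vals) - pred
    } else resid[[i]] <- rep(NA_real_, length(vals))
  }
  fits <- do.call(rbind, fits)
  q <- assign_quartiles(fits)
  fits$quartile <- unname(q[fits$site_id])
  resid <- do.call(rbind, resid)
  rownames(resid) <- fits$site_id
  ok <- fits$converged
  list(fits = fits, residuals = resid,
       summary = list(n_sites = nrow(fits), n_converged = sum(ok),
                      median_r2 = stats::median(fits$r2[ok]),
                      min_r2 = min(fits$r2[ok]),
                      residence_time_range =
                        range(fits$residence_time_min[ok])))
}
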