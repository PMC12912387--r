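## Fixed-period harmonic regression, rhythmicity testing, robust hormone
## fitting, circular phase utilities and descriptive circadian summaries.

#' Absolute sampling time in hours
#'
#' Clock times are hours-of-day in `[0, 24)`; consecutive sampling days are
#' unrolled onto one axis as `24*(day - 1) + time_h`.
#'
#' @param day integer day index (1-based).
#' @param time_h clock time in hours.
#' @return absolute hours since the start of day 1.
#' @export
absoluteTime <- function(day, time_h) 24 * (day - 1) + time_h

.newHarmonicFit <- function(mu, a, b, period_h, rss_full, rss_null, n,
                            lrt_stat = NA_real_, lrt_p = NA_real_,
                            lrt_method = "none", saturated = FALSE,
                            perfect_fit = FALSE, converged = TRUE,
                            robust = FALSE) {
  new("HarmonicFit", mu = mu, a = a, b = b,
      amplitude = sqrt(a^2 + b^2),
      acrophase_h = (atan2(b, a) * period_h / (2 * pi)) %% period_h,
      period_h = period_h, rss_full = rss_full, rss_null = rss_null,
      n_points = as.integer(n), lrt_stat = lrt_stat, lrt_p = lrt_p,
      lrt_method = lrt_method, saturated = saturated,
      perfect_fit = perfect_fit, converged = converged, robust = robust)
}

.harmonicOLS <- function(t, y, period_h = 24, lrt_method = "ftest") {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  n <- length(y)
  if (n < 3L) stop("harmonic fit needs at least 3 points")
  w <- 2 * pi / period_h
  phase_id <- round(((t %% period_h) / period_h) * 1e9)
  if (length(unique(phase_id)) < 3L)
    stop("singular design: fewer than 3 distinct phases modulo the period")
  X <- cbind(1, cos(w * t), sin(w * t))
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("singular design: fewer than 3 distinct phases modulo the period")
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rss_full <- sum(res^2)
  rss_null <- sum((y - mean(y))^2)
  rss_full <- min(rss_full, rss_null)  # guard FP noise on constant series
  fit <- .newHarmonicFit(beta[1L], beta[2L], beta[3L], period_h,
                         rss_full, rss_null, n, saturated = (n == 3L))
  rhythmicityTest(fit, method = lrt_method)
}

#' Fit a fixed-period harmonic regression
#'
#' Ordinary least-squares fit of the cosinor model
#' `y = mu + a*cos(w t) + b*sin(w t)` with `w = 2*pi/period_h` and `t` the
#' absolute sampling hour. Requires at least 3 points at 3 distinct phases
#' modulo the period. A 3-point fit interpolates the data exactly and is
#' returned with `saturated = TRUE` and no rhythmicity p-value.
#'
#' Methods exist for a numeric time vector plus `values`, for a
#' [HormoneSeries-class] (above-ULOQ samples excluded), and for one
#' participant x gene of an [ExpressionSeriesSet-class] (see
#' [fitCohortRhythms()] for fitting all series at once).
#'
#' @param x numeric vector of times in hours (absolute, see
#'   [absoluteTime()]), or a supported object.
#' @param values numeric observations (numeric-time method only).
#' @param period_h fixed period in hours; default 24.
#' @param lrt_method rhythmicity test form, `"ftest"` (exact F, the
#'   package default for small series) or `"chisq"` (asymptotic likelihood
#'   ratio); see [rhythmicityTest()].
#' @param ... passed through.
#' @return A [HarmonicFit-class].
#' @examples
#' t <- c(0, 6, 12, 18)
#' fitHarmonic(t, 2 + cos(2 * pi * t / 24))  # mesor 2, amplitude 1, peak 0 h
#' @export
setMethod("fitHarmonic", "numeric",
          function(x, values, period_h = 24, lrt_method = "ftest", ...) {
  .harmonicOLS(x, values, period_h = period_h, lrt_method = lrt_method)
})

#' @rdname fitHarmonic-numeric-method
#' @export
setMethod("fitHarmonic", "HormoneSeries",
          function(x, period_h = 24, lrt_method = "ftest", ...) {
  s <- hormoneAnalysisSet(x)
  .harmonicOLS(s$time_h, s$value, period_h = period_h, lrt_method = lrt_method)
})

#' @rdname fitHarmonic-numeric-method
#' @export
setMethod("fitHarmonic", "ExpressionSeriesSet",
          function(x, participant, gene, period_h = 24, lrt_method = "ftest",
                   value = "fold_change", ...) {
  p <- seriesPoints(x)
  p <- p[p$participant == participant & p$gene == gene, ]
  .harmonicOLS(absoluteTime(p$day, p$time_h), p[[value]],
               period_h = period_h, lrt_method = lrt_method)
})

#' Rhythmicity test for a harmonic fit
#'
#' Compares the harmonic model against the intercept-only model. Two forms
#' are provided:
#' \describe{
#'   \item{`"chisq"`}{the asymptotic likelihood-ratio statistic
#'     `n * ln(RSS_null / RSS_full)` referred to a chi-square distribution
#'     with 2 degrees of freedom. Anticonservative for very short series.}
#'   \item{`"ftest"`}{the exact nested-model F test,
#'     `F = ((RSS_null - RSS_full)/2) / (RSS_full/(n-3))` on (2, n-3)
#'     degrees of freedom; exact under Gaussian noise and the package
#'     default for cohort-scale series (n of order 8).}
#' }
#' Saturated fits (n = 3) have no residual degrees of freedom and return
#' `NA` with the `saturated` flag; fits with
#' `RSS_full < 1e-12 * RSS_null` are flagged `perfect_fit` and report
#' `p = 0` rather than dividing by a vanishing residual. A constant series
#' (`RSS_null = RSS_full = 0`) yields statistic 0 and `p = 1`.
#'
#' @param fit a [HarmonicFit-class] from [fitHarmonic()].
#' @param method `"ftest"` or `"chisq"`.
#' @return The fit with `lrt_stat`, `lrt_p` and `lrt_method` filled in.
#' @export
rhythmicityTest <- function(fit, method = c("ftest", "chisq")) {
  method <- match.arg(method)
  stopifnot(is(fit, "HarmonicFit"))
  if (fit@robust) stop("rhythmicity test is defined for OLS fits only")
  fit@lrt_method <- method
  n <- fit@n_points
  rss0 <- fit@rss_null; rss1 <- fit@rss_full
  if (fit@saturated) {
    fit@lrt_stat <- NA_real_; fit@lrt_p <- NA_real_
    return(fit)
  }
  if (rss0 <= 0 || rss1 <= 0 && rss0 <= 0) {  # constant series
    fit@lrt_stat <- 0; fit@lrt_p <- 1
    return(fit)
  }
  if (rss1 < 1e-12 * rss0) {
    fit@perfect_fit <- TRUE
    fit@lrt_stat <- Inf; fit@lrt_p <- 0
    return(fit)
  }
  if (method == "chisq") {
    fit@lrt_stat <- n * log(rss0 / rss1)
    fit@lrt_p <- pchisq(fit@lrt_stat, df = 2, lower.tail = FALSE)
  } else {
    fit@lrt_stat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
    fit@lrt_p <- pf(fit@lrt_stat, 2, n - 3, lower.tail = FALSE)
  }
  fit
}

## soft-L1 objective: sum_i f^2 * rho((r_i/f)^2), rho(z) = 2(sqrt(1+z)-1).
## Convex in (mu, a, b) because the pseudo-Huber function is convex in r and
## r is linear in the parameters.
.softL1Cost <- function(par, X, y, fscale) {
  r <- y - as.vector(X %*% par)
  sum(2 * fscale^2 * (sqrt(1 + (r / fscale)^2) - 1))
}

.softL1Grad <- function(par, X, y, fscale) {
  r <- y - as.vector(X %*% par)
  wgt <- 2 * r / sqrt(1 + (r / fscale)^2)
  -as.vector(crossprod(X, wgt))
}

#' Robust harmonic regression with soft-L1 loss
#'
#' Fits `mu + a*cos(w t) + b*sin(w t)` by minimizing the robustified sum
#' `sum f^2 * rho((r_i/f)^2)` with `rho(z) = 2*(sqrt(1+z)-1)` (soft-L1 /
#' pseudo-Huber): quadratic for residuals well below the scale `f_scale`,
#' linear for gross outliers. Intended for salivary cortisol profiles
#' indexed by time since awakening, where single aberrant samples are
#' common. The default starting point
#' `x0 = (a = -0.31084448, b = 2.33838041, mu = 6.33268443)` and
#' `f_scale = 0.1` are the published cortisol initialization; because the
#' objective is convex in `(mu, a, b)`, the optimum does not depend on the
#' start.
#'
#' @param x numeric times in hours, or a [HormoneSeries-class] (above-ULOQ
#'   samples excluded; cortisol times are hours since awakening).
#' @param values numeric observations (numeric-time method only).
#' @param f_scale soft-L1 scale, series units; default 0.1.
#' @param x0 named start vector `c(a=, b=, mu=)`.
#' @param period_h fixed period, default 24.
#' @param ... passed through.
#' @return A [HarmonicFit-class] with `robust = TRUE`; `converged` is
#'   `FALSE` when the optimizer fails (no fabricated fit: the returned
#'   coefficients are the optimizer's last iterate, flagged).
#' @export
setMethod("fitHarmonicRobust", "numeric",
          function(x, values,
                   f_scale = 0.1,
                   x0 = c(a = -0.31084448, b = 2.33838041, mu = 6.33268443),
                   period_h = 24, ...) {
  ok <- is.finite(x) & is.finite(values)
  t <- x[ok]; y <- values[ok]
  n <- length(y)
  if (n < 3L) stop("robust harmonic fit needs at least 3 points")
  stopifnot(all(is.finite(x0)), f_scale > 0)
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * t), sin(w * t))
  par0 <- c(x0[["mu"]], x0[["a"]], x0[["b"]])
  opt <- optim(par0, .softL1Cost, gr = .softL1Grad, X = X, y = y, fscale = f_scale,
               method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  beta <- opt$par
  res <- y - as.vector(X %*% beta)
  .newHarmonicFit(beta[1L], beta[2L], beta[3L], period_h,
                  rss_full = sum(res^2), rss_null = sum((y - mean(y))^2),
                  n = n, converged = (opt$convergence == 0L), robust = TRUE)
})

#' @rdname fitHarmonicRobust-numeric-method
#' @export
setMethod("fitHarmonicRobust", "HormoneSeries", function(x, ...) {
  s <- hormoneAnalysisSet(x)
  fitHarmonicRobust(s$time_h, s$value, ...)
})

#' Circular difference between two phases
#'
#' Phase is circular: times just before and just after midnight are close.
#' Returns `min(|d|, 24 - |d|)`, in `[0, 12]` for a 24-h period.
#'
#' @param phase1_h,phase2_h phases in hours, `[0, 24)`.
#' @param period_h period, default 24.
#' @return hours in `[0, period/2]`.
#' @examples
#' circularDiff(23.5, 0.5)  # 1
#' @export
circularDiff <- function(phase1_h, phase2_h, period_h = 24) {
  d <- abs(phase1_h - phase2_h) %% period_h
  pmin(d, period_h - d)
}

#' Restrict a series to absolute-time windows
#'
#' Keeps points whose absolute time (`24*(day-1) + time_h`) lies in any of
#' the given closed intervals, e.g. the two waking windows 4-14 h and
#' 26-38 h since wake used when matching a dense reference series to the
#' human sampling interval. Windows must not overlap. An empty result is
#' allowed and signalled with a warning.
#'
#' @param series an [ExpressionSeriesSet-class] or a data.frame of points.
#' @param windows list of `c(start_h, end_h)` in absolute hours.
#' @return object of the same kind, restricted.
#' @export
restrictToInterval <- function(series, windows) {
  stopifnot(length(windows) >= 1L)
  wmat <- do.call(rbind, windows)
  if (any(wmat[, 1] > wmat[, 2])) stop("window start must be <= end")
  if (nrow(wmat) > 1L) {
    o <- order(wmat[, 1])
    if (any(wmat[o, 1][-1] <= wmat[o, 2][-nrow(wmat)]))
      stop("windows must be non-overlapping")
  }
  p <- if (is(series, "ExpressionSeriesSet")) seriesPoints(series) else series
  at <- absoluteTime(p$day, p$time_h)
  keep <- Reduce(`|`, lapply(seq_len(nrow(wmat)),
                             function(i) at >= wmat[i, 1] & at <= wmat[i, 2]))
  out <- p[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("restriction produced an empty series")
  if (is(series, "ExpressionSeriesSet")) ExpressionSeriesSet(out, exclusionLog(series))
  else out
}

#' Descriptive circadian summary of a sampled series
#'
#' Model-free summaries used alongside the harmonic fit: `max_min` (the
#' difference between maximal and minimal observed values), `max_val`,
#' `mean_val`, `peak_time_h` (clock time of the first observed maximum;
#' ties resolved to the earliest time) and
#' `rel_amplitude = max_min / mean_val`. Note `max_min` is a range, not
#' the harmonic amplitude; for a noiseless cosine
#' `max_min <= 2 * amplitude` with equality only when peak and trough are
#' both sampled.
#'
#' @param series an [ExpressionSeriesSet-class] restricted to one series,
#'   or a data.frame of points with `day`, `time_h` and the value column.
#' @param scope `"both_days"` (default) or `"per_day"`.
#' @param value value column, default `"fold_change"`.
#' @param min_points minimum points required in scope (default 2).
#' @return data.frame with one row per scope unit.
#' @export
circadianSummary <- function(series, scope = c("both_days", "per_day"),
                             value = "fold_change", min_points = 2L) {
  scope <- match.arg(scope)
  p <- if (is(series, "ExpressionSeriesSet")) seriesPoints(series) else series
  if (nrow(p) == 0L) stop("empty scope: no points to summarize")
  groups <- if (scope == "per_day") split(p, p$day) else list(all = p)
  rows <- lapply(names(groups), function(g) {
    q <- groups[[g]]
    if (nrow(q) < min_points)
      stop(sprintf("scope '%s' has fewer than %d points", g, min_points))
    v <- q[[value]]
    ord <- order(absoluteTime(q$day, q$time_h))
    q <- q[ord, ]; v <- v[ord]
    data.frame(scope = g, n = length(v),
               max_min = max(v) - min(v), max_val = max(v),
               mean_val = mean(v),
               peak_time_h = q$time_h[which.max(v)],
               rel_amplitude = (max(v) - min(v)) / mean(v))
  })
  do.call(rbind, rows)
}

#' Fit harmonic regressions for every series of a cohort
#'
#' One OLS harmonic fit per participant x gene, returned as a flat table
#' with all fit fields plus the descriptive summaries. Series that cannot
#' be fitted (fewer than 3 usable points or degenerate phases) are
#' returned with `NA` coefficients and a reason.
#'
#' @param x an [ExpressionSeriesSet-class].
#' @param period_h fixed period, default 24.
#' @param lrt_method `"ftest"` (default) or `"chisq"`.
#' @param value value column fitted, default `"fold_change"`.
#' @return data.frame, one row per participant x gene.
#' @export
fitCohortRhythms <- function(x, period_h = 24, lrt_method = "ftest",
                             value = "fold_change") {
  p <- seriesPoints(x)
  keys <- unique(p[, c("participant", "gene")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    q <- p[p$participant == keys$participant[i] & p$gene == keys$gene[i], ]
    base <- data.frame(participant = keys$participant[i], gene = keys$gene[i],
                       n = nrow(q), stringsAsFactors = FALSE)
    fit <- tryCatch(
      .harmonicOLS(absoluteTime(q$day, q$time_h), q[[value]],
                   period_h = period_h, lrt_method = lrt_method),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(cbind(base, mesor = NA_real_, amplitude = NA_real_,
                   acrophase_h = NA_real_, rss_full = NA_real_,
                   rss_null = NA_real_, lrt_stat = NA_real_, lrt_p = NA_real_,
                   saturated = NA, mean_rel_expr = mean(q$rel_expr),
                   max_min = NA_real_, peak_time_h = NA_real_,
                   note = conditionMessage(fit)))
    }
    cs <- circadianSummary(q, value = value, min_points = 2L)
    cbind(base, mesor = fit@mu, amplitude = fit@amplitude,
          acrophase_h = fit@acrophase_h, rss_full = fit@rss_full,
          rss_null = fit@rss_null, lrt_stat = fit@lrt_stat, lrt_p = fit@lrt_p,
          saturated = fit@saturated, mean_rel_expr = mean(q$rel_expr),
          max_min = cs$max_min, peak_time_h = cs$peak_time_h, note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
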