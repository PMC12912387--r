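## Cross-layer association statistics: Spearman matrices, regression lines,
## mutual information / maximal information coefficient, cell-composition
## ratios and ANOVA, chronotype classification, and the participant-level
## feature table tying the layers together.

#' Pairwise Spearman correlation matrix
#'
#' Rank correlation (midranks for ties) with pairwise-complete
#' observations and the two-sided p-value of `cor.test`. Circular columns
#' (acrophases) can be unwrapped before ranking by cutting the circle at a
#' reference hour far from the phase distribution (`circular` +
#' `circular_cut`, default 4 h, the typical human activity trough): values
#' become signed offsets from the cut's antipode, removing the artificial
#' 0/24 discontinuity. The uncentered mode (`circular = NULL`)
#' rank-correlates phases directly, as in replication runs. Constant
#' columns yield `NA` with no error.
#'
#' @param features data.frame, one row per participant.
#' @param pairs optional 2-column character matrix restricting the
#'   variable pairs tested.
#' @param circular character vector of circular columns.
#' @param circular_cut hour at which circular columns are cut: scalar or
#'   named vector keyed by column (default 4).
#' @return data.frame: `var1`, `var2`, `r`, `p`, `n` (long format, upper
#'   triangle).
#' @export
spearmanMatrix <- function(features, pairs = NULL, circular = NULL,
                           circular_cut = 4) {
  num <- features[, vapply(features, is.numeric, TRUE), drop = FALSE]
  for (cc in intersect(circular, names(num))) {
    cut_h <- if (length(circular_cut) > 1L) circular_cut[[cc]] else circular_cut
    num[[cc]] <- centerPhase(num[[cc]], (cut_h + 12) %% 24)
  }
  vars <- names(num)
  if (is.null(pairs)) {
    idx <- which(upper.tri(matrix(0, length(vars), length(vars))), arr.ind = TRUE)
    pairs <- cbind(vars[idx[, 1]], vars[idx[, 2]])
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- num[[pairs[i, 1]]]; y <- num[[pairs[i, 2]]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(data.frame(var1 = pairs[i, 1], var2 = pairs[i, 2],
                        r = NA_real_, p = NA_real_, n = n))
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    data.frame(var1 = pairs[i, 1], var2 = pairs[i, 2],
               r = unname(ct$estimate), p = ct$p.value, n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Least-squares regression line with two-sided slope p-value
#'
#' Simple linear regression; the p-value is the two-sided t-test on the
#' slope. A perfect fit reports `p = 0` with `perfect_fit = TRUE` rather
#' than an ill-defined t statistic.
#'
#' @param x,y numeric vectors.
#' @return list: `slope`, `intercept`, `r`, `p`, `stderr`, `n`,
#'   `perfect_fit`.
#' @export
linregressWithP <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("regression needs at least 3 points")
  if (sd(x) == 0) stop("x is constant: slope undefined")
  fit <- lm(y ~ x)
  co <- coef(fit)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r <- unname(sign(co[2]) * sqrt(max(0, 1 - rss / tss)))
  if (rss < 1e-12 * max(tss, 1e-300)) {
    return(list(slope = unname(co[2]), intercept = unname(co[1]), r = r,
                p = 0, stderr = 0, n = n, perfect_fit = TRUE))
  }
  se <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  tstat <- co[2] / se
  list(slope = unname(co[2]), intercept = unname(co[1]), r = r,
       p = unname(2 * pt(abs(tstat), n - 2, lower.tail = FALSE)),
       stderr = unname(se), n = n, perfect_fit = FALSE)
}

## Equal-frequency discretization via first-occurrence ranks: every bin gets
## floor(n/k) or ceiling(n/k) observations even under heavy ties.
.discretize <- function(x, n_bins, binning = "equal-frequency") {
  n <- length(x)
  if (binning == "equal-frequency") {
    r <- rank(x, ties.method = "first")
    as.integer(ceiling(r * n_bins / n))
  } else {
    br <- seq(min(x), max(x), length.out = n_bins + 1L)
    br[1] <- br[1] - 1e-9
    as.integer(cut(x, br))
  }
}

.plugInMI <- function(ix, iy, r, c) {
  tab <- tabulate((iy - 1L) * r + ix, nbins = r * c)
  p <- matrix(tab / sum(tab), r, c)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Plug-in mutual information of two variables
#'
#' Discretizes both variables (default: equal-frequency bins,
#' `n_bins = round(n^(1/3))`) and computes the plug-in mutual information
#' of the joint distribution, in nats. MI is 0 for independent variables
#' (up to small positive plug-in bias) and equals the marginal entropy
#' `ln(n_bins)` for a deterministic monotone relationship with uniform
#' bins.
#'
#' @param x,y numeric vectors of equal length, `n >= 8`.
#' @param binning `"equal-frequency"` (default) or `"equal-width"`.
#' @param n_bins number of bins per axis; default `round(n^(1/3))`.
#' @return MI in nats.
#' @examples
#' x <- 1:64
#' mutualInformation(x, x, n_bins = 4)  # log(4)
#' @export
mutualInformation <- function(x, y, binning = c("equal-frequency", "equal-width"),
                              n_bins = NULL) {
  binning <- match.arg(binning)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8L) stop("mutual information needs n >= 8")
  if (is.null(n_bins)) n_bins <- max(2L, round(n^(1/3)))
  if (n_bins < 2L) stop("n_bins must be >= 2")
  .plugInMI(.discretize(x, n_bins, binning), .discretize(y, n_bins, binning),
            n_bins, n_bins)
}

## Hill-climbing refinement of one axis's cut vector (cuts are rank
## thresholds; bin of rank r is findInterval(r, cuts)+1). Returns best MI.
.optimizeGrid <- function(rx, ry, r, c, n, max_pass = 3L, max_cand = 16L) {
  cutsFor <- function(k) round(seq_len(k - 1L) * n / k)
  binify <- function(rk, cuts) findInterval(rk, cuts + 0.5) + 1L
  cx <- cutsFor(r); cy <- cutsFor(c)
  mi <- .plugInMI(binify(rx, cx), binify(ry, cy), r, c)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (axis in 1:2) {
      cuts <- if (axis == 1) cx else cy
      k <- length(cuts)
      for (j in seq_len(k)) {
        lo <- if (j == 1L) 1L else cuts[j - 1L] + 1L
        hi <- if (j == k) n - 1L else cuts[j + 1L] - 1L
        if (hi <= lo) next
        cand <- unique(round(seq(lo, hi, length.out = min(max_cand, hi - lo + 1L))))
        best_v <- cuts[j]; best_mi <- mi
        for (v in cand) {
          if (v == cuts[j]) next
          trial <- cuts; trial[j] <- v
          m <- if (axis == 1) .plugInMI(binify(rx, trial), binify(ry, cy), r, c)
               else .plugInMI(binify(rx, cx), binify(ry, trial), r, c)
          if (m > best_mi + 1e-12) { best_mi <- m; best_v <- v }
        }
        if (best_v != cuts[j]) {
          cuts[j] <- best_v; mi <- best_mi; improved <- TRUE
          if (axis == 1) cx <- cuts else cy <- cuts
        }
      }
    }
    if (!improved) break
  }
  mi
}

#' Maximal information coefficient
#'
#' Searches grids of `r x c` bins with `r*c <= n^grid_limit_exponent`
#' (and `r, c >= 2`) for the partition maximizing the normalized plug-in
#' mutual information `MI / ln(min(r, c))`; the maximum over grids is the
#' MIC, in `[0, 1]`. Axis partitions start from equal-frequency cuts and
#' are refined by hill-climbing over cut positions. Values near 1 indicate
#' a strong (possibly non-linear) functional association; a noiseless
#' functional relationship scores 1 by construction of the normalization.
#'
#' @param x,y numeric vectors, `n >= 20` recommended.
#' @param grid_limit_exponent grid-size budget exponent, default 0.6.
#' @return list: `mic` in `[0, 1]`, `best_grid` (c(r, c)), `degenerate`.
#' @export
maximalInformationCoefficient <- function(x, y, grid_limit_exponent = 0.6) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8L) stop("MIC needs n >= 8")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(mic = 0, best_grid = c(NA_integer_, NA_integer_), degenerate = TRUE))
  B <- max(4, n^grid_limit_exponent)
  rx <- rank(x, ties.method = "first")
  ry <- rank(y, ties.method = "first")
  best <- 0; best_grid <- c(2L, 2L)
  for (r in 2:max(2L, floor(B / 2))) {
    cmax <- floor(B / r)
    if (cmax < 2L) break
    for (c in 2:cmax) {
      mi <- .optimizeGrid(rx, ry, r, c, n)
      val <- mi / log(min(r, c))
      if (val > best) { best <- val; best_grid <- c(r, c) }
    }
  }
  list(mic = min(1, best), best_grid = best_grid, degenerate = FALSE)
}

#' Leukocyte / epithelial ratio per slide
#'
#' Sums counts over the (up to 8) fields of each slide (participant x day
#' x time) and returns leukocytes / epithelial. A slide with zero
#' epithelial total is reported `NA` with `defined = FALSE`.
#'
#' @param counts a [CellCountTable-class].
#' @return data.frame: `participant`, `day`, `time_h`, `leukocytes`,
#'   `epithelial`, `le_ratio`, `defined`.
#' @export
leRatio <- function(counts) {
  d <- cellCounts(counts)
  key <- interaction(d$participant, d$day, d$time_h, drop = TRUE)
  agg <- do.call(rbind, lapply(split(d, key), function(q) {
    L <- sum(q$leukocytes); E <- sum(q$epithelial)
    data.frame(participant = q$participant[1L], day = q$day[1L],
               time_h = q$time_h[1L], leukocytes = L, epithelial = E,
               le_ratio = if (E > 0) L / E else NA_real_, defined = E > 0)
  }))
  rownames(agg) <- NULL
  agg[order(agg$participant, agg$day, agg$time_h), ]
}

#' One-way ANOVA across timepoint groups
#'
#' Classical one-way F test (equal-variance) of values grouped by sampling
#' time, as used for time-dependency of cell composition.
#'
#' @param groups named list of numeric vectors (one per timepoint), or a
#'   data.frame with `value` and `group` columns.
#' @return list: `f`, `p`, `df1`, `df2`, `degenerate`.
#' @export
onewayAnova <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  groups <- groups[vapply(groups, length, 0L) > 0L]
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L)) stop("need >= 2 values per group")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  k <- length(groups); n <- length(v)
  ssb <- sum(vapply(groups, function(q) length(q) * (mean(q) - mean(v))^2, 0))
  ssw <- sum(vapply(groups, function(q) sum((q - mean(q))^2), 0))
  if (ssw == 0 && ssb == 0)
    return(list(f = NA_real_, p = NA_real_, df1 = k - 1L, df2 = n - k,
                degenerate = TRUE))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE),
       df1 = k - 1L, df2 = n - k, degenerate = FALSE)
}

#' Classify chronotype from an MEQ score
#'
#' Standard Morningness-Eveningness Questionnaire cut-offs: scores of 41
#' or below are evening types, 42-58 intermediate, 59 and above morning
#' types. Valid scores span 16..86.
#'
#' @param meq_score integer in 16..86.
#' @return `"evening"`, `"intermediate"` or `"morning"`.
#' @export
classifyChronotype <- function(meq_score) {
  if (is.na(meq_score) || meq_score < 16 || meq_score > 86)
    stop("MEQ score must lie in 16..86")
  if (meq_score <= 41) "evening" else if (meq_score <= 58) "intermediate" else "morning"
}

#' Participant-level feature table across data layers
#'
#' Builds one row per participant from the cohort's expression series,
#' hormone series and covariates: per-gene mesor (mean reference-normalized
#' expression), harmonic amplitude and acrophase; cortisol mesor, amplitude
#' and acrophase from the robust soft-L1 fit; mean melatonin (above-ULOQ
#' values excluded); bedtime, MEQ and mean L/E ratio where available.
#' Acrophase columns are circular and flagged as such in the
#' `"circular_columns"` attribute.
#'
#' @param series an [ExpressionSeriesSet-class].
#' @param hormones list of [HormoneSeries-class] (optional).
#' @param participants data.frame with `participant` plus covariates such
#'   as `bedtime_h` and `meq` (optional).
#' @param cells a [CellCountTable-class] (optional).
#' @param lrt_method passed to [fitCohortRhythms()].
#' @return data.frame, one row per participant.
#' @export
cohortFeatures <- function(series, hormones = NULL, participants = NULL,
                           cells = NULL, lrt_method = "ftest") {
  fits <- fitCohortRhythms(series, lrt_method = lrt_method)
  ids <- sort(unique(fits$participant))
  out <- data.frame(participant = ids, stringsAsFactors = FALSE)
  for (g in sort(unique(fits$gene))) {
    sub <- fits[fits$gene == g, ]
    m <- match(ids, sub$participant)
    out[[paste0(g, "_mesor")]] <- sub$mean_rel_expr[m]
    out[[paste0(g, "_amplitude")]] <- sub$amplitude[m]
    out[[paste0(g, "_acrophase_h")]] <- sub$acrophase_h[m]
  }
  circ <- grep("_acrophase_h$", names(out), value = TRUE)
  if (!is.null(hormones)) {
    cort_m <- cort_a <- cort_p <- mel <- setNames(rep(NA_real_, length(ids)), ids)
    for (h in hormones) {
      pid <- participant(h)
      if (!pid %in% ids) next
      if (analyte(h) == "cortisol") {
        s <- hormoneAnalysisSet(h)
        if (nrow(s) >= 4L) {
          fit <- fitHarmonicRobust(h)
          cort_m[pid] <- mesor(fit)
          cort_a[pid] <- amplitude(fit)
          cort_p[pid] <- acrophase(fit)
        }
      } else {
        s <- hormoneAnalysisSet(h)
        if (nrow(s) >= 1L) mel[pid] <- mean(s$value)
      }
    }
    out$cortisol_mesor <- unname(cort_m)
    out$cortisol_amplitude <- unname(cort_a)
    out$cortisol_acrophase_h <- unname(cort_p)
    out$melatonin <- unname(mel)
    circ <- c(circ, "cortisol_acrophase_h")
  }
  if (!is.null(participants)) {
    m <- match(ids, participants$participant)
    for (cv in setdiff(names(participants), "participant"))
      if (is.numeric(participants[[cv]])) out[[cv]] <- participants[[cv]][m]
  }
  if (!is.null(cells)) {
    lr <- leRatio(cells)
    agg <- vapply(split(lr$le_ratio, lr$participant),
                  function(v) mean(v, na.rm = TRUE), 0)
    out$le_ratio <- unname(agg[match(ids, names(agg))])
  }
  attr(out, "circular_columns") <- circ
  out
}
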