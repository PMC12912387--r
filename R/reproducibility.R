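## Day-1 vs Day-2 consistency: pairing, error metrics, paired nonparametric
## testing and cohort mean profiles.

#' Pair Day-1 and Day-2 values at identical clock times
#'
#' For every participant x gene series, matches observations at identical
#' clock times on the two days (the protocol fixes sampling times, so no
#' nearest-neighbour matching is attempted). Series with `min_points` or
#' fewer total points over the two days are excluded and logged (default 2,
#' i.e. series with two or fewer datapoints are dropped). Day 1 plays the
#' role of "predicted" and Day 2 of "observed" in the error metrics.
#'
#' @param series an [ExpressionSeriesSet-class].
#' @param min_points exclusion threshold on total points (default 2).
#' @param value value column, default `"fold_change"`.
#' @param days which two day indices to pair, default `c(1, 2)`.
#' @return data.frame (PairedDayTable) with columns `participant`, `gene`,
#'   `time_h`, `value_day1`, `value_day2`; excluded/unpairable series are
#'   recorded in the `"exclusions"` attribute.
#' @export
pairDays <- function(series, min_points = 2L, value = "fold_change",
                     days = c(1L, 2L)) {
  p <- seriesPoints(series)
  keys <- unique(p[, c("participant", "gene")])
  out <- list(); excl <- list()
  for (i in seq_len(nrow(keys))) {
    q <- p[p$participant == keys$participant[i] & p$gene == keys$gene[i], ]
    if (nrow(q) <= min_points) {
      excl[[length(excl) + 1L]] <- data.frame(
        participant = keys$participant[i], gene = keys$gene[i],
        reason = sprintf("%d points <= exclusion threshold %d", nrow(q), min_points))
      next
    }
    d1 <- q[q$day == days[1L], ]; d2 <- q[q$day == days[2L], ]
    common <- intersect(d1$time_h, d2$time_h)
    if (length(common) == 0L) {
      excl[[length(excl) + 1L]] <- data.frame(
        participant = keys$participant[i], gene = keys$gene[i],
        reason = "no overlapping clock times between days")
      next
    }
    common <- sort(common)
    out[[length(out) + 1L]] <- data.frame(
      participant = keys$participant[i], gene = keys$gene[i], time_h = common,
      value_day1 = d1[[value]][match(common, d1$time_h)],
      value_day2 = d2[[value]][match(common, d2$time_h)],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(participant = character(), gene = character(), time_h = numeric(),
               value_day1 = numeric(), value_day2 = numeric())
  rownames(res) <- NULL
  attr(res, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(participant = character(), gene = character(), reason = character())
  res
}

#' Between-day error metrics
#'
#' With `d = value_day2 - value_day1` (Day 1 predicted, Day 2 observed):
#' `MAE = mean(|d|)`, `MSE = mean(d^2)`, `RMSE = sqrt(MSE)`,
#' `MBE = mean(d)`. MAE ignores error direction; MSE weights large errors
#' more; RMSE is on the scale of the data; a positive MBE means Day 2 runs
#' higher than Day 1. For every input `RMSE >= MAE >= |MBE|`.
#'
#' @param pairs a PairedDayTable from [pairDays()], or any data.frame with
#'   `value_day1`/`value_day2`.
#' @return named list with `mae`, `mse`, `rmse`, `mbe`, `n`.
#' @examples
#' errorMetrics(data.frame(value_day1 = c(1, 2), value_day2 = c(2, 4)))
#' @export
errorMetrics <- function(pairs) {
  if (nrow(pairs) == 0L) stop("no pairs: error metrics undefined")
  d <- pairs$value_day2 - pairs$value_day1
  list(mae = mean(abs(d)), mse = mean(d^2), rmse = sqrt(mean(d^2)),
       mbe = mean(d), n = length(d))
}

#' Paired Wilcoxon tests per gene with Bonferroni correction
#'
#' Two-sided Wilcoxon signed-rank test of Day 2 vs Day 1 per gene (zeros
#' dropped, the Wilcoxon convention; exact distribution when `n <= 25` and
#' no ties among the ranked magnitudes, normal approximation with
#' continuity correction otherwise), followed by Bonferroni adjustment
#' `p_adj = min(1, p * n_genes)`. A gene whose paired differences are all
#' zero has no defined statistic and is reported with `p = 1` and
#' `degenerate = TRUE`.
#'
#' @param pairs a PairedDayTable from [pairDays()].
#' @return data.frame: `gene`, `n_pairs`, `n_nonzero`, `statistic`,
#'   `p_value`, `p_adjusted`, `degenerate`.
#' @export
wilcoxonBonferroni <- function(pairs) {
  if (nrow(pairs) == 0L) stop("no pairs to test")
  groups <- split(pairs, pairs$gene)
  rows <- lapply(names(groups), function(g) {
    q <- groups[[g]]
    d <- q$value_day2 - q$value_day1
    nz <- sum(d != 0)
    if (nz == 0L)
      return(data.frame(gene = g, n_pairs = nrow(q), n_nonzero = 0L,
                        statistic = NA_real_, p_value = 1, degenerate = TRUE))
    wt <- suppressWarnings(
      wilcox.test(q$value_day2, q$value_day1, paired = TRUE,
                  exact = (nz <= 25L), correct = TRUE))
    data.frame(gene = g, n_pairs = nrow(q), n_nonzero = nz,
               statistic = unname(wt$statistic), p_value = wt$p.value,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "bonferroni")
  rownames(out) <- NULL
  out[, c("gene", "n_pairs", "n_nonzero", "statistic", "p_value",
          "p_adjusted", "degenerate")]
}

#' Cohort mean profile with SEM per timepoint
#'
#' Mean and standard error of the mean at each grid timepoint, treating
#' each contributing series (participant x day pair) as one statistically
#' independent unit. Timepoints contributed by a single unit report the
#' mean with `SEM = NA`.
#'
#' @param series an [ExpressionSeriesSet-class].
#' @param grid clock-time grid; default: all observed times.
#' @param value value column, default `"fold_change"`.
#' @param gene optional gene restriction.
#' @return data.frame: `time_h`, `mean`, `sem`, `n`.
#' @export
meanProfileWithSem <- function(series, grid = NULL, value = "fold_change",
                               gene = NULL) {
  p <- seriesPoints(series)
  if (!is.null(gene)) p <- p[p$gene %in% gene, ]
  if (is.null(grid)) grid <- sort(unique(p$time_h))
  rows <- lapply(grid, function(tm) {
    v <- p[[value]][p$time_h == tm]
    n <- length(v)
    data.frame(time_h = tm, mean = if (n) mean(v) else NA_real_,
               sem = if (n >= 2L) sd(v) / sqrt(n) else NA_real_, n = n)
  })
  do.call(rbind, rows)
}
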