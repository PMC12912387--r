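## Relative quantification of qPCR CT tables (Livak delta-delta-CT).

#' Delta-delta-CT relative quantification
#'
#' Converts a CT table into relative-expression time series using the
#' two-step Livak scheme: per timepoint, `dCT = CT_target - CT_ref`
#' (normalization to the reference gene, typically GAPDH); then per
#' participant x gene, `ddCT = dCT - mean(dCT)` over that participant's
#' timepoints (normalization to the mean expression of the target gene),
#' and `fold_change = 2^(-ddCT)` (so lower CT means higher expression; set
#' `sign = +1` for the opposite convention). By construction the geometric
#' mean of the fold changes over the normalization window is 1.
#'
#' Each point also carries `rel_expr = 2^(-dCT)`, the reference-normalized
#' expression before mean-centering, which retains between-participant
#' level differences and is the quantity averaged for participant-level
#' mean expression.
#'
#' Timepoints lacking a reference CT (or with a missing target CT) are
#' excluded and logged, never silently dropped; a gene left with no usable
#' point yields an empty, logged series.
#'
#' @param ct a [CtTable-class].
#' @param reference_gene reference (housekeeping) gene symbol; default
#'   `"GAPDH"`.
#' @param sign `-1` (default, Livak `2^(-ddCT)`) or `+1`.
#' @param normalization_scope `"overall"` (default: one mean over both
#'   days, per participant x gene) or `"per_day"`.
#' @return An [ExpressionSeriesSet-class].
#' @examples
#' ct <- CtTable(data.frame(
#'   participant = "P01", day = 1L, time_h = c(9, 13, 17, 21, 9, 13, 17, 21),
#'   gene = rep(c("PER2", "GAPDH"), each = 4),
#'   ct = c(25, 24, 26, 25, 20, 20, 20, 20)))
#' seriesPoints(deltaDeltaCt(ct))$fold_change  # 1, 2, 0.5, 1
#' @export
deltaDeltaCt <- function(ct, reference_gene = "GAPDH", sign = -1,
                         normalization_scope = c("overall", "per_day")) {
  normalization_scope <- match.arg(normalization_scope)
  stopifnot(sign %in% c(-1, 1))
  d <- ctData(ct)
  ref <- d[d$gene == reference_gene & !is.na(d$ct), ]
  if (nrow(ref) == 0L) stop("reference gene '", reference_gene, "' not found in CT table")
  refkey <- paste(ref$participant, ref$day, ref$time_h, sep = "\r")
  targets <- d[d$gene != reference_gene, ]
  tkey <- paste(targets$participant, targets$day, targets$time_h, sep = "\r")
  targets$ct_ref <- ref$ct[match(tkey, refkey)]

  usable <- !is.na(targets$ct) & !is.na(targets$ct_ref)
  log <- data.frame(participant = targets$participant[!usable],
                    gene = targets$gene[!usable],
                    day = targets$day[!usable],
                    time_h = targets$time_h[!usable],
                    reason = ifelse(is.na(targets$ct[!usable]),
                                    "missing target CT", "missing reference CT"),
                    stringsAsFactors = FALSE)
  u <- targets[usable, ]
  if (nrow(u) == 0L)
    return(ExpressionSeriesSet(data.frame(participant = character(), gene = character(),
                                          day = integer(), time_h = numeric(),
                                          rel_expr = numeric(), fold_change = numeric()),
                               log = log))
  u$dct <- u$ct - u$ct_ref
  grp <- if (normalization_scope == "overall") paste(u$participant, u$gene, sep = "\r")
         else paste(u$participant, u$gene, u$day, sep = "\r")
  u$ddct <- u$dct - ave(u$dct, grp)
  pts <- data.frame(participant = u$participant, gene = u$gene, day = u$day,
                    time_h = u$time_h,
                    rel_expr = 2^(sign * u$dct),
                    fold_change = 2^(sign * u$ddct),
                    stringsAsFactors = FALSE)
  ExpressionSeriesSet(pts, log = log)
}

#' Mean relative expression over a window
#'
#' Arithmetic mean of the fold changes of one participant x gene series,
#' either over all points or per day.
#'
#' @param series an [ExpressionSeriesSet-class] restricted to one
#'   participant x gene, or a data.frame of its points.
#' @param window `"overall"` (default) or `"per_day"`.
#' @param value column to average: `"fold_change"` (default) or
#'   `"rel_expr"`.
#' @return For `"overall"`, a single number; for `"per_day"`, a named
#'   numeric vector keyed by day.
#' @export
meanExpression <- function(series, window = c("overall", "per_day"),
                           value = c("fold_change", "rel_expr")) {
  window <- match.arg(window)
  value <- match.arg(value)
  p <- if (is(series, "ExpressionSeriesSet")) seriesPoints(series) else series
  if (nrow(p) == 0L) stop("empty window: no points to average")
  if (window == "overall") return(mean(p[[value]]))
  vapply(split(p[[value]], p$day), mean, 0)
}
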