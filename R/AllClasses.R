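#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats coef complete.cases cor cor.test lm median optim p.adjust
#'   pchisq pf pnorm pt qt quantile rnorm rlnorm rpois runif sd setNames var
#'   wilcox.test oneway.test
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

## --------------------------------------------------------------------------
## Central data containers.
##
## Flat observational tables are held in validated S4 wrappers around a
## data.frame so that invariants (key uniqueness, value ranges) are checked at
## construction, while downstream code can always fall back to
## as.data.frame(). Dense gene x timepoint matrices extend
## SummarizedExperiment.
## --------------------------------------------------------------------------

#' CtTable: raw qPCR cycle-threshold observations
#'
#' Long-format container for cycle-threshold (CT) values keyed by
#' participant, sampling day, clock time and gene. One row per measurement;
#' the reference gene (typically GAPDH) appears as ordinary rows.
#'
#' Invariants enforced by the validity method: the
#' (participant, day, time_h, gene) key is unique, `day >= 1`, and
#' `time_h` lies in `[0, 24)`. CT values may be `NA` (missing measurements
#' are preserved, not dropped).
#'
#' @slot data data.frame with columns `participant` (character), `day`
#'   (integer), `time_h` (numeric hours-of-day), `gene` (character),
#'   `ct` (numeric cycles, may be `NA`).
#' @seealso [readCtTable()], [deltaDeltaCt()]
#' @export
setClass("CtTable", representation(data = "data.frame"))

setValidity("CtTable", function(object) {
  d <- object@data
  need <- c("participant", "day", "time_h", "gene", "ct")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (any(d$day < 1L)) return("day indices must be >= 1")
  if (any(d$time_h < 0 | d$time_h >= 24)) return("time_h must lie in [0, 24)")
  key <- paste(d$participant, d$day, d$time_h, d$gene, sep = "\r")
  if (anyDuplicated(key)) {
    k <- d[which(duplicated(key))[1L], ]
    return(sprintf("duplicate (participant, day, time_h, gene) key: (%s, %d, %g, %s)",
                   k$participant, k$day, k$time_h, k$gene))
  }
  TRUE
})

#' Construct a CtTable
#'
#' @param data data.frame with columns `participant`, `day`, `time_h`,
#'   `gene`, `ct`.
#' @return A [CtTable-class] object.
#' @examples
#' CtTable(data.frame(participant = "P01", day = 1L, time_h = 9,
#'                    gene = "ARNTL1", ct = 28.4))
#' @export
CtTable <- function(data) {
  data$participant <- as.character(data$participant)
  data$day <- as.integer(data$day)
  data$gene <- as.character(data$gene)
  data$time_h <- as.numeric(data$time_h)
  data$ct <- as.numeric(data$ct)
  rownames(data) <- NULL
  new("CtTable", data = data[, c("participant", "day", "time_h", "gene", "ct")])
}

#' HormoneSeries: one participant's hormone profile
#'
#' Cortisol profiles are sampled at up to seven offsets relative to awakening
#' (directly after waking and 0.5, 1, 2, 5, 8 and 12 h later); melatonin is a
#' single bedtime value per day. Censored measurements keep the raw token
#' (e.g. `"<2"`, `">100"`) alongside the substituted numeric value and a
#' censoring flag, so no row is silently dropped at parse time.
#'
#' @slot participant character scalar.
#' @slot analyte `"cortisol"` or `"melatonin"`.
#' @slot samples data.frame with columns `day` (integer), `time_h`
#'   (hours since awakening for cortisol; clock time or `NA` for melatonin),
#'   `value` (numeric), `censor` (`"none"`, `"below_lod"`, `"above_uloq"`),
#'   `raw` (original token).
#' @export
setClass("HormoneSeries",
         representation(participant = "character", analyte = "character",
                        samples = "data.frame"))

setValidity("HormoneSeries", function(object) {
  if (!object@analyte %in% c("cortisol", "melatonin"))
    return("analyte must be 'cortisol' or 'melatonin'")
  s <- object@samples
  need <- c("day", "time_h", "value", "censor", "raw")
  if (!all(need %in% names(s)))
    return(paste("missing sample columns:", paste(setdiff(need, names(s)), collapse = ", ")))
  if (!all(s$censor %in% c("none", "below_lod", "above_uloq")))
    return("invalid censor flag")
  if (object@analyte == "cortisol" && any(table(s$day) > 7L))
    return("cortisol series must have <= 7 samples per day")
  if (object@analyte == "melatonin" && any(table(s$day) > 1L))
    return("melatonin series must have one sample per day")
  TRUE
})

#' Construct a HormoneSeries
#'
#' @param participant participant identifier.
#' @param analyte `"cortisol"` or `"melatonin"`.
#' @param samples data.frame with at least `day`, `time_h`, `value`;
#'   `censor` and `raw` are filled in when absent.
#' @return A [HormoneSeries-class] object.
#' @export
HormoneSeries <- function(participant, analyte, samples) {
  if (is.null(samples$censor)) samples$censor <- "none"
  if (is.null(samples$raw)) samples$raw <- as.character(samples$value)
  samples$day <- as.integer(samples$day)
  rownames(samples) <- NULL
  new("HormoneSeries", participant = as.character(participant),
      analyte = analyte,
      samples = samples[, c("day", "time_h", "value", "censor", "raw")])
}

#' CellCountTable: leukocyte / epithelial counts per microscopy field
#'
#' Eight fields are counted per stained slide (one slide per participant,
#' day and sampling time); counts are non-negative integers.
#'
#' @slot data data.frame with columns `participant`, `day`, `time_h`,
#'   `field_index` (1..8), `leukocytes`, `epithelial`.
#' @seealso [leRatio()]
#' @export
setClass("CellCountTable", representation(data = "data.frame"))

setValidity("CellCountTable", function(object) {
  d <- object@data
  need <- c("participant", "day", "time_h", "field_index", "leukocytes", "epithelial")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (any(d$leukocytes < 0) || any(d$epithelial < 0)) return("counts must be >= 0")
  if (any(d$leukocytes != floor(d$leukocytes)) || any(d$epithelial != floor(d$epithelial)))
    return("counts must be integers")
  if (any(!d$field_index %in% 1:8)) return("field_index must be in 1..8")
  TRUE
})

#' Construct a CellCountTable
#' @param data data.frame; see [CellCountTable-class].
#' @return A [CellCountTable-class] object.
#' @export
CellCountTable <- function(data) {
  rownames(data) <- NULL
  new("CellCountTable", data = data)
}

#' ExpressionSeriesSet: relative-expression time series
#'
#' The central time-series currency: per participant x gene points on the
#' fold-change scale. Each point carries both the reference-normalized
#' relative expression `rel_expr` = 2^(-dCT) (retains between-participant
#' level information) and the fully normalized fold change
#' `fold_change` = 2^(-ddCT), whose geometric mean over the normalization
#' window is 1 by construction.
#'
#' @slot points data.frame with columns `participant`, `gene`, `day`,
#'   `time_h`, `rel_expr`, `fold_change`; sorted by participant, gene and
#'   absolute time `24*(day-1) + time_h`.
#' @slot log data.frame of excluded timepoints (participant, gene, day,
#'   time_h, reason); accountability for censoring/missing-data drops.
#' @seealso [deltaDeltaCt()], [fitCohortRhythms()]
#' @export
setClass("ExpressionSeriesSet",
         representation(points = "data.frame", log = "data.frame"))

setValidity("ExpressionSeriesSet", function(object) {
  p <- object@points
  need <- c("participant", "gene", "day", "time_h", "rel_expr", "fold_change")
  if (!all(need %in% names(p)))
    return(paste("missing columns:", paste(setdiff(need, names(p)), collapse = ", ")))
  if (nrow(p) == 0L) return(TRUE)
  if (any(p$fold_change <= 0, na.rm = TRUE)) return("fold changes must be > 0")
  ord <- order(p$participant, p$gene, 24 * (p$day - 1) + p$time_h)
  if (!identical(ord, seq_len(nrow(p)))) return("points must be sorted by absolute time")
  TRUE
})

#' Construct an ExpressionSeriesSet
#' @param points data.frame; see [ExpressionSeriesSet-class]. `rel_expr`
#'   defaults to `fold_change` when absent.
#' @param log data.frame of exclusions (optional).
#' @return An [ExpressionSeriesSet-class] object.
#' @export
ExpressionSeriesSet <- function(points, log = NULL) {
  if (is.null(points$rel_expr)) points$rel_expr <- points$fold_change
  points <- points[order(points$participant, points$gene,
                         24 * (points$day - 1) + points$time_h), ]
  rownames(points) <- NULL
  if (is.null(log))
    log <- data.frame(participant = character(), gene = character(),
                      day = integer(), time_h = numeric(), reason = character())
  new("ExpressionSeriesSet",
      points = points[, c("participant", "gene", "day", "time_h",
                          "rel_expr", "fold_change")],
      log = log)
}

#' ExpressionMatrix: dense gene x timepoint expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single `exprs`
#' assay whose columns are timepoints; `colData(x)$time_h` holds the
#' sampling hour of each column. Gene labels (rownames) are unique and
#' timepoints strictly increasing. Used for dense reference series such as
#' cell-line time courses sampled every few hours.
#'
#' @seealso [readExpressionMatrix()], [filterLowExpression()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("must carry an 'exprs' assay")
  if (!"time_h" %in% names(SummarizedExperiment::colData(object)))
    return("colData must contain time_h")
  th <- SummarizedExperiment::colData(object)$time_h
  if (ncol(object) > 1L && any(diff(th) <= 0))
    return("timepoints must be strictly increasing")
  if (anyDuplicated(rownames(object))) return("duplicate gene labels")
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param exprs numeric matrix, genes in rows, timepoints in columns.
#' @param time_h numeric vector of timepoint hours, one per column,
#'   strictly increasing.
#' @param gene_metadata optional data.frame of per-gene annotation.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(exprs, time_h, gene_metadata = NULL) {
  exprs <- as.matrix(exprs)
  cd <- S4Vectors::DataFrame(time_h = as.numeric(time_h))
  rd <- if (is.null(gene_metadata)) S4Vectors::DataFrame(row.names = rownames(exprs))
        else S4Vectors::DataFrame(gene_metadata, row.names = rownames(exprs))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd, rowData = rd)
  new("ExpressionMatrix", se)
}

#' HarmonicFit: fitted fixed-period harmonic regression
#'
#' Result of fitting `y = mu + a*cos(w t) + b*sin(w t)` with
#' `w = 2*pi/period_h` to a single series, by ordinary least squares
#' ([fitHarmonic()]) or by robust soft-L1 minimization
#' ([fitHarmonicRobust()]). Derived quantities: `amplitude = sqrt(a^2+b^2)`
#' and `acrophase_h = (period_h/2/pi) * atan2(b, a) mod period_h`, the clock
#' time of the fitted peak.
#'
#' A fit with exactly as many points as parameters is flagged `saturated`
#' (`rss_full = 0`, no p-value); a fit with `rss_full < 1e-12 * rss_null`
#' is flagged `perfect_fit` and reports `p = 0` rather than dividing by a
#' vanishing residual.
#'
#' @slot mu mesor (rhythm-adjusted mean), series units.
#' @slot a,b cosine and sine coefficients.
#' @slot amplitude,acrophase_h derived amplitude and peak time (hours).
#' @slot period_h fixed period, default 24.
#' @slot rss_full,rss_null residual sums of squares of the harmonic and
#'   intercept-only models.
#' @slot n_points number of observations used.
#' @slot lrt_stat,lrt_p rhythmicity test statistic and p-value for the
#'   configured `lrt_method` (`NA` for saturated or robust fits).
#' @slot lrt_method `"ftest"`, `"chisq"` or `"none"`.
#' @slot saturated,perfect_fit,converged,robust logical flags.
#' @export
setClass("HarmonicFit",
         representation(mu = "numeric", a = "numeric", b = "numeric",
                        amplitude = "numeric", acrophase_h = "numeric",
                        period_h = "numeric",
                        rss_full = "numeric", rss_null = "numeric",
                        n_points = "integer",
                        lrt_stat = "numeric", lrt_p = "numeric",
                        lrt_method = "character",
                        saturated = "logical", perfect_fit = "logical",
                        converged = "logical", robust = "logical"))

setValidity("HarmonicFit", function(object) {
  if (object@amplitude < 0) return("amplitude must be >= 0")
  if (object@acrophase_h < 0 || object@acrophase_h >= object@period_h)
    return("acrophase_h must lie in [0, period)")
  if (!object@robust && is.finite(object@rss_full) && is.finite(object@rss_null) &&
      object@rss_full > object@rss_null + 1e-8 * (1 + object@rss_null))
    return("rss_full must not exceed rss_null")  # OLS only; robust fits do not minimize RSS
  if (is.finite(object@lrt_p) && (object@lrt_p < 0 || object@lrt_p > 1))
    return("lrt_p must lie in [0, 1]")
  TRUE
})

setMethod("show", "CtTable", function(object) {
  d <- object@data
  cat(sprintf("CtTable: %d records | %d participants | genes: %s\n",
              nrow(d), length(unique(d$participant)),
              paste(sort(unique(d$gene)), collapse = ", ")))
})

setMethod("show", "HormoneSeries", function(object) {
  cat(sprintf("HormoneSeries: %s, participant %s, %d samples (%d censored)\n",
              object@analyte, object@participant, nrow(object@samples),
              sum(object@samples$censor != "none")))
})

setMethod("show", "CellCountTable", function(object) {
  cat(sprintf("CellCountTable: %d field counts, %d slides\n",
              nrow(object@data),
              nrow(unique(object@data[, c("participant", "day", "time_h")]))))
})

setMethod("show", "ExpressionSeriesSet", function(object) {
  p <- object@points
  cat(sprintf("ExpressionSeriesSet: %d points | %d series | %d logged exclusions\n",
              nrow(p), nrow(unique(p[, c("participant", "gene")])),
              nrow(object@log)))
})

setMethod("show", "HarmonicFit", function(object) {
  cat(sprintf("HarmonicFit (%s): mesor %.4g, amplitude %.4g, acrophase %.2f h (period %g h)\n",
              if (object@robust) "soft-L1" else "OLS",
              object@mu, object@amplitude, object@acrophase_h, object@period_h))
  if (object@saturated) {
    cat("  saturated fit: rhythmicity p-value undefined\n")
  } else if (!is.na(object@lrt_p)) {
    cat(sprintf("  rhythmicity test (%s): stat %.3g, p %.3g%s\n",
                object@lrt_method, object@lrt_stat, object@lrt_p,
                if (object@perfect_fit) " [perfect fit]" else ""))
  }
})
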