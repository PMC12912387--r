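## Readers and writers for every table the pipeline touches. All files are
## plain delimited text (comma or tab, auto-detected); decimal points only.

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

.readDelim <- function(path) {
  sep <- .detectSep(path)
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

## Accept "9", "9.5", "9:30", "9 h", "9h"; returns NA for unparseable input.
.parseTimeToken <- function(tok) {
  tok <- trimws(as.character(tok))
  out <- rep(NA_real_, length(tok))
  plain <- grepl("^[0-9]+(\\.[0-9]+)?$", tok)
  out[plain] <- as.numeric(tok[plain])
  hsuf <- grepl("^[0-9]+(\\.[0-9]+)?\\s*h$", tok, ignore.case = TRUE)
  out[hsuf] <- as.numeric(sub("\\s*h$", "", tok[hsuf], ignore.case = TRUE))
  clock <- grepl("^[0-9]{1,2}:[0-9]{2}$", tok)
  if (any(clock)) {
    parts <- strsplit(tok[clock], ":", fixed = TRUE)
    out[clock] <- vapply(parts, function(p) as.numeric(p[1]) + as.numeric(p[2]) / 60, 0)
  }
  out
}

.matchCol <- function(nms, candidates) {
  hit <- match(candidates, tolower(nms))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Read a long-format qPCR CT table
#'
#' Expects a delimited text file (comma or tab, auto-detected) with a header
#' naming participant, day, time, gene and CT columns (case-insensitive;
#' common synonyms accepted). Times may be given as `"9"`, `"9:00"` or
#' `"9 h"`. Missing CT values (empty cells or `NA`) are preserved as `NA`,
#' never dropped.
#'
#' @param path path to the file.
#' @param dialect optional list; currently supports `na_tokens` (character
#'   vector of tokens read as missing CT, default `c("", "NA", "ND")`).
#' @return A [CtTable-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("participant,day,time,gene,ct",
#'              "P01,1,9 h,ARNTL1,28.4",
#'              "P01,1,9 h,GAPDH,20.1"), f)
#' readCtTable(f)
#' @export
readCtTable <- function(path, dialect = list()) {
  na_tokens <- dialect$na_tokens %||% c("", "NA", "ND")
  d <- .readDelim(path)
  nms <- tolower(names(d))
  ip <- .matchCol(nms, c("participant", "participant_id", "subject", "id"))
  id <- .matchCol(nms, c("day"))
  it <- .matchCol(nms, c("time_h", "time", "clock_time", "hour"))
  ig <- .matchCol(nms, c("gene", "target", "gene_symbol"))
  ic <- .matchCol(nms, c("ct", "cq", "cycle_threshold"))
  if (anyNA(c(ip, id, it, ig, ic)))
    stop("CT table header must name participant, day, time, gene and ct columns")
  time_h <- .parseTimeToken(d[[it]])
  time_raw <- trimws(as.character(d[[it]]))
  bad <- which(is.na(time_h) & !(is.na(time_raw) | time_raw %in% na_tokens))
  if (length(bad))
    stop(sprintf("unparseable time '%s' at data row %d", d[[it]][bad[1L]], bad[1L]))
  ct_raw <- trimws(as.character(d[[ic]]))
  ct <- suppressWarnings(as.numeric(ct_raw))
  notnum <- which(is.na(ct) & !(is.na(ct_raw) | ct_raw %in% na_tokens))
  if (length(notnum))
    stop(sprintf("unparseable CT '%s' at data row %d", ct_raw[notnum[1L]], notnum[1L]))
  CtTable(data.frame(participant = d[[ip]], day = d[[id]], time_h = time_h,
                     gene = d[[ig]], ct = ct, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a hormone table with censoring tokens
#'
#' Parses a delimited table with columns participant, analyte, day, time and
#' value. Value cells may contain plain numbers or the assay's censoring
#' dialect: `"<x"` marks a value below the limit of detection and `">x"` a
#' value above the upper limit of quantification. Below-LOD values are
#' substituted (default: the value 1, the convention used for salivary
#' cortisol reported as `"<2"`; alternatively half the stated limit);
#' above-ULOQ rows are retained with their flag and excluded by default from
#' downstream statistics, never silently deleted.
#'
#' @param path path to the file.
#' @param below_lod_policy `"one"` (substitute 1) or `"half_lod"`
#'   (substitute half the stated limit).
#' @return A list of [HormoneSeries-class] objects, one per
#'   participant x analyte.
#' @export
readHormoneTable <- function(path, below_lod_policy = c("one", "half_lod")) {
  below_lod_policy <- match.arg(below_lod_policy)
  d <- .readDelim(path)
  nms <- tolower(names(d))
  ip <- .matchCol(nms, c("participant", "participant_id", "subject", "id"))
  ia <- .matchCol(nms, c("analyte", "hormone"))
  idy <- .matchCol(nms, c("day"))
  it <- .matchCol(nms, c("time_since_wake_h", "time_h", "time"))
  iv <- .matchCol(nms, c("value", "concentration", "conc"))
  if (anyNA(c(ip, ia, idy, it, iv)))
    stop("hormone table header must name participant, analyte, day, time and value columns")
  raw <- trimws(as.character(d[[iv]]))
  value <- suppressWarnings(as.numeric(raw))
  censor <- rep("none", length(raw))
  below <- grepl("^<\\s*[0-9.]+$", raw)
  above <- grepl("^>\\s*[0-9.]+$", raw)
  lim <- suppressWarnings(as.numeric(sub("^[<>]\\s*", "", raw)))
  value[below] <- if (below_lod_policy == "one") 1 else lim[below] / 2
  censor[below] <- "below_lod"
  value[above] <- lim[above]
  censor[above] <- "above_uloq"
  unknown <- which(is.na(value) & !(raw %in% c("", "NA")))
  if (length(unknown))
    stop(sprintf("unknown hormone value token '%s'", raw[unknown[1L]]))
  tab <- data.frame(participant = as.character(d[[ip]]),
                    analyte = tolower(as.character(d[[ia]])),
                    day = d[[idy]], time_h = .parseTimeToken(d[[it]]),
                    value = value, censor = censor, raw = raw,
                    stringsAsFactors = FALSE)
  keys <- unique(tab[, c("participant", "analyte")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$participant == keys$participant[i] & tab$analyte == keys$analyte[i], ]
    HormoneSeries(keys$participant[i], keys$analyte[i],
                  sub[, c("day", "time_h", "value", "censor", "raw")])
  })
}

#' Drop above-ULOQ samples from a hormone series
#'
#' Returns the analysis set of a hormone series: all samples whose censor
#' flag is not `above_uloq` (those measurements are retained in the object
#' but omitted from statistics, matching the handling of melatonin values
#' reported as `">100"`).
#'
#' @param series a [HormoneSeries-class].
#' @return data.frame of usable samples.
#' @export
hormoneAnalysisSet <- function(series) {
  s <- hormoneSamples(series)
  s[s$censor != "above_uloq", , drop = FALSE]
}

#' Read a dense expression matrix (series-matrix style TSV)
#'
#' First column: gene label; remaining column names carry the timepoint in
#' hours (plain numbers or labels with a trailing number such as `"ZT18"` or
#' `"CT_18"`).
#'
#' @param path path to the TSV/CSV file.
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path) {
  d <- .readDelim(path)
  genes <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  labels <- colnames(m)
  time_h <- suppressWarnings(as.numeric(labels))
  needs <- is.na(time_h)
  time_h[needs] <- suppressWarnings(as.numeric(sub("^.*?([0-9]+(\\.[0-9]+)?)$", "\\1",
                                                   labels[needs])))
  if (anyNA(time_h)) stop("could not parse timepoint hours from column labels")
  rownames(m) <- genes
  ExpressionMatrix(m, time_h)
}

#' Filter genes by mean expression
#'
#' Retains genes whose mean over all timepoints is at least `threshold`
#' (inclusive), e.g. at least 0.5 CPM on average over the entire time
#' series. Gene order is preserved; an empty matrix passes through.
#'
#' @param x an [ExpressionMatrix-class].
#' @param threshold mean-expression cutoff on the scale of the matrix.
#' @return The filtered [ExpressionMatrix-class].
#' @export
filterLowExpression <- function(x, threshold = 0.5) {
  if (nrow(x) == 0L) return(x)
  m <- SummarizedExperiment::assay(x, "exprs")
  x[rowMeans(m) >= threshold, ]
}

#' Write result tables with a run manifest
#'
#' Writes one tab-separated file per table plus `manifest.json` recording
#' the file list, a configuration hash, the seed, and package/R versions,
#' so a run can be reproduced exactly.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param config optional configuration object echoed (and hashed) into the
#'   manifest.
#' @param seed optional integer seed recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
writeResults <- function(tables, out_dir, config = NULL, seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(
    files = files,
    n_tables = length(tables),
    config = config,
    config_hash = rlang::hash(config),
    seed = seed,
    package_version = as.character(packageVersion("SalivaClock")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Read back a result table written by writeResults
#' @param path path to a `.tsv` written by [writeResults()].
#' @return data.frame.
#' @export
readResultTable <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
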