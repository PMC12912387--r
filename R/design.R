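## In-silico sampling-design evaluation: which reduced schedules still
## recover a circadian profile from dense synthetic series.

#' Construct a sampling design
#'
#' @param times_h within-day clock times (hours), unique, inside the wake
#'   window.
#' @param n_days number of days the schedule is repeated.
#' @param wake_window `c(start_h, end_h)` of feasible sampling.
#' @return a `SamplingDesign` list.
#' @export
samplingDesign <- function(times_h, n_days = 1L, wake_window = c(9, 21)) {
  times_h <- sort(unique(times_h))
  if (any(times_h < wake_window[1] | times_h > wake_window[2]))
    stop("design times must lie within the wake window")
  structure(list(times_h = times_h, points_per_day = length(times_h),
                 n_days = as.integer(n_days), wake_window = wake_window),
            class = "SamplingDesign")
}

#' Sampling design from explicit (day, time) offsets
#'
#' For schedules that differ between days, e.g. five points spread over
#' two days (three on day 1, two on day 2).
#'
#' @param day integer day indices (1-based).
#' @param time_h clock times, one per offset.
#' @param wake_window feasible window, default `c(9, 21)`.
#' @return a `SamplingDesign` with an `offsets` component.
#' @export
samplingOffsets <- function(day, time_h, wake_window = c(9, 21)) {
  stopifnot(length(day) == length(time_h))
  if (any(time_h < wake_window[1] | time_h > wake_window[2]))
    stop("design times must lie within the wake window")
  off <- unique(data.frame(day = as.integer(day), time_h = time_h))
  off <- off[order(off$day, off$time_h), ]
  structure(list(times_h = sort(unique(off$time_h)),
                 points_per_day = max(table(off$day)),
                 n_days = max(off$day), wake_window = wake_window,
                 offsets = off),
            class = "SamplingDesign")
}

#' k points spanning the wake window evenly
#'
#' `seq(start, end, length.out = k)`; for a 9-21 h window and `k = 4` this
#' is the saliva protocol design 9, 13, 17, 21 h.
#'
#' @param k points per day.
#' @param wake_window window, default `c(9, 21)`.
#' @param n_days days, default 1.
#' @return a [samplingDesign()].
#' @export
spanDesign <- function(k, wake_window = c(9, 21), n_days = 1L) {
  stopifnot(k >= 2L)
  samplingDesign(seq(wake_window[1], wake_window[2], length.out = k),
                 n_days = n_days, wake_window = wake_window)
}

#' Enumerate evenly spaced candidate designs on a grid
#'
#' All designs with `k` points at constant spacing (a multiple of
#' `grid_step_h`) starting on the grid and fitting inside the wake window,
#' for every `k` and day count in range; the protocol design (4 points at
#' 9/13/17/21 h over 2 days) is appended when it fits the window and is
#' not already present.
#'
#' @param points_per_day integer vector of k values.
#' @param n_days integer vector of day counts.
#' @param wake_window `c(start_h, end_h)` within `[0, 24)`.
#' @param grid_step_h grid step; must divide the window length.
#' @return list of [samplingDesign()] objects.
#' @export
enumerateDesigns <- function(points_per_day, n_days = 1L,
                             wake_window = c(9, 21), grid_step_h = 1) {
  if (wake_window[2] <= wake_window[1]) stop("empty wake window")
  span <- wake_window[2] - wake_window[1]
  if (abs(span / grid_step_h - round(span / grid_step_h)) > 1e-9)
    stop("grid_step_h must divide the wake window")
  grid <- seq(wake_window[1], wake_window[2], by = grid_step_h)
  designs <- list()
  for (nd in n_days) for (k in points_per_day) {
    if (k < 2L) next
    for (mult in seq_len(length(grid) - 1L)) {
      d <- mult * grid_step_h
      span_k <- (k - 1) * d
      if (span_k > span + 1e-9) break
      starts <- grid[grid + span_k <= wake_window[2] + 1e-9]
      for (s in starts)
        designs[[length(designs) + 1L]] <-
          samplingDesign(s + d * (0:(k - 1)), n_days = nd, wake_window = wake_window)
    }
  }
  proto <- c(9, 13, 17, 21)
  if (all(proto >= wake_window[1] & proto <= wake_window[2])) {
    have <- vapply(designs, function(x)
      x$n_days == 2L && length(x$times_h) == 4L && all(x$times_h == proto), TRUE)
    if (!any(have))
      designs[[length(designs) + 1L]] <-
        samplingDesign(proto, n_days = 2L, wake_window = wake_window)
  }
  designs
}

#' Monte-Carlo evaluation of a sampling design
#'
#' Per replicate, obtains noisy observations of a known circadian truth at
#' the design's sampling times — either freshly simulated at the exact
#' offsets (`mode = "simulate"`) or subsampled from a dense synthetic
#' series by nearest-timepoint matching (`mode = "subsample"`, emulating
#' in-silico reduction of a series sampled every `dense_interval_h` hours
#' over `dense_duration_h`) — then fits the fixed-period harmonic model
#' and records feasibility (non-saturated, non-singular fit), rhythm
#' detection (test p < `alpha`) and the circular acrophase and relative
#' amplitude errors against the truth.
#'
#' A design is scored successful when every fit is feasible, the detection
#' rate is at least `detect_threshold`, and the median circular acrophase
#' error is at most `phase_tol_h` (the paper-scale criterion is
#' operationalized by these three configurable thresholds).
#'
#' @param truth one row of [geneParams()]: the generating cosine.
#' @param design a [samplingDesign()].
#' @param noise_sd multiplicative noise sd (fraction of local mean).
#' @param n_replicates Monte-Carlo replicates.
#' @param alpha detection level, default 0.05.
#' @param phase_tol_h acrophase tolerance (hours), default 2.
#' @param detect_threshold required detection rate, default 0.8.
#' @param seed integer seed.
#' @param mode `"simulate"` or `"subsample"`.
#' @param dense_interval_h,dense_duration_h dense-series geometry for
#'   `mode = "subsample"` (default every 3 h over 30 h).
#' @param test rhythmicity test form passed to the fit; default `"chisq"`,
#'   the likelihood-ratio form used in the published subsampling analysis.
#' @return one-row data.frame (DesignEvaluation): design descriptors,
#'   `feasible_fraction`, `detection_rate`, `median_phase_error_h`,
#'   `median_rel_amp_error`, `success`.
#' @export
evaluateDesign <- function(truth, design, noise_sd, n_replicates = 200L,
                           alpha = 0.05, phase_tol_h = 2,
                           detect_threshold = 0.8, seed = 1L,
                           mode = c("simulate", "subsample"),
                           dense_interval_h = 3, dense_duration_h = 30,
                           test = "chisq") {
  mode <- match.arg(mode)
  stopifnot(n_replicates >= 1L)
  set.seed(seed)
  t_design <- if (!is.null(design$offsets)) {
    absoluteTime(design$offsets$day, design$offsets$time_h)
  } else {
    as.vector(vapply(seq_len(design$n_days),
                     function(d) absoluteTime(d, design$times_h),
                     numeric(length(design$times_h))))
  }
  if (mode == "subsample") {
    t_dense <- seq(0, dense_duration_h, by = dense_interval_h)
    t_use <- sort(unique(vapply(t_design, function(tt)
      t_dense[which.min(abs(t_dense - tt))], 0)))
  } else {
    t_use <- sort(t_design)
  }
  feasible <- detected <- logical(n_replicates)
  phase_err <- amp_err <- rep(NA_real_, n_replicates)
  true_amp <- truth$rel_amplitude * truth$mesor
  for (i in seq_len(n_replicates)) {
    if (mode == "subsample") {
      e <- .cosine(t_dense, truth$mesor, truth$rel_amplitude, truth$acrophase_h)
      y_dense <- e * (1 + rnorm(length(t_dense), 0, noise_sd))
      y <- y_dense[match(t_use, t_dense)]
    } else {
      e <- .cosine(t_use, truth$mesor, truth$rel_amplitude, truth$acrophase_h)
      y <- e * (1 + rnorm(length(t_use), 0, noise_sd))
    }
    fit <- tryCatch(.harmonicOLS(t_use, y, lrt_method = test),
                    error = function(e) NULL)
    if (is.null(fit) || fit@saturated) next
    feasible[i] <- TRUE
    detected[i] <- is.finite(fit@lrt_p) && fit@lrt_p < alpha ||
      fit@perfect_fit
    phase_err[i] <- circularDiff(fit@acrophase_h, truth$acrophase_h %% 24)
    amp_err[i] <- abs(fit@amplitude - true_amp) / true_amp
  }
  ff <- mean(feasible)
  dr <- if (any(feasible)) mean(detected[feasible]) else 0
  mpe <- if (any(feasible)) median(phase_err[feasible]) else NA_real_
  mae <- if (any(feasible)) median(amp_err[feasible]) else NA_real_
  data.frame(points_per_day = design$points_per_day, n_days = design$n_days,
             times = paste(design$times_h, collapse = ","),
             n_replicates = n_replicates, noise_sd = noise_sd,
             feasible_fraction = ff, detection_rate = dr,
             median_phase_error_h = mpe, median_rel_amp_error = mae,
             success = ff == 1 && dr >= detect_threshold &&
               !is.na(mpe) && mpe <= phase_tol_h,
             stringsAsFactors = FALSE)
}

#' Smallest sufficient sampling density
#'
#' From a table of design evaluations, the smallest `points_per_day`
#' scored successful, reported per day count; `NA` when no evaluated
#' design succeeds.
#'
#' @param evaluations data.frame of rows from [evaluateDesign()].
#' @return data.frame: `n_days`, `min_points_per_day` (NA = none).
#' @export
minimalSufficientDesign <- function(evaluations) {
  rows <- lapply(split(evaluations, evaluations$n_days), function(q) {
    ok <- q$points_per_day[q$success]
    data.frame(n_days = q$n_days[1L],
               min_points_per_day = if (length(ok)) min(ok) else NA_integer_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
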