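## Synthetic-cohort generator: cohorts with the statistical structure the
## downstream analysis assumes (gene-specific acrophases, amplitude-mean
## coupling, bedtime-phase coupling, cortisol/melatonin couplings, CT-scale
## measurement noise), plus dense reference series, with a known truth table.

#' Gene-level generative parameters
#'
#' Expression is generated on the fold-change scale as
#' `E(t) = mesor * (1 + rel_amplitude * cos(2*pi*(t - acrophase_h)/24))`,
#' so expression stays positive as long as `rel_amplitude < 1`.
#'
#' @param gene gene symbol.
#' @param mesor positive fold-change-scale mean.
#' @param rel_amplitude relative amplitude in `[0, 1)`.
#' @param acrophase_h peak clock time in `[0, 24)`.
#' @param acrophase_sd_h between-participant acrophase jitter (hours).
#' @return one-row data.frame.
#' @export
geneParams <- function(gene, mesor, rel_amplitude, acrophase_h, acrophase_sd_h = 1.5) {
  stopifnot(mesor > 0, rel_amplitude >= 0, rel_amplitude < 1,
            acrophase_h >= 0, acrophase_h < 24, acrophase_sd_h >= 0)
  data.frame(gene = gene, mesor = mesor, rel_amplitude = rel_amplitude,
             acrophase_h = acrophase_h, acrophase_sd_h = acrophase_sd_h,
             stringsAsFactors = FALSE)
}

#' Default core-clock gene parameters
#'
#' ARNTL1 peaks in the evening (prior Normal(18, 1.5^2) h wrapped), PER2
#' and NR1D1 in the morning (Normal(10, 1.5^2) h), matching the saliva
#' cohort's observed peak pattern; relative amplitude 0.4 (about 2.3-fold
#' peak/trough) for all three genes, a typical peripheral-clock effect
#' size.
#'
#' @return data.frame of [geneParams()] rows.
#' @export
defaultGeneParams <- function() {
  rbind(geneParams("ARNTL1", mesor = 1.0, rel_amplitude = 0.4, acrophase_h = 18),
        geneParams("PER2",   mesor = 1.2, rel_amplitude = 0.4, acrophase_h = 10),
        geneParams("NR1D1",  mesor = 0.8, rel_amplitude = 0.4, acrophase_h = 10))
}

#' Cohort simulation configuration
#'
#' Bundles every knob of the generator. Defaults emulate the saliva study
#' protocol: sampling at 9, 13, 17 and 21 h over 2 consecutive days,
#' cortisol at seven offsets since awakening, one bedtime melatonin value
#' per day, eight counted microscopy fields per slide with a 64%/36%
#' leukocyte/epithelial composition, and MEQ scores centred in the
#' intermediate band.
#'
#' @param n_participants number of participants.
#' @param sampling_times_h clock times sampled each day.
#' @param n_days number of consecutive days.
#' @param ct_noise_sd qPCR measurement noise, cycles (additive on the CT
#'   scale, hence lognormal on the fold-change scale).
#' @param day_effect_sd per participant x day x gene CT offset, cycles.
#' @param bedtime_mean_h,bedtime_sd_h bedtime distribution (hours; values
#'   past midnight exceed 24 and are kept unwrapped).
#' @param phase_bedtime_slope acrophase shift per hour of bedtime shift.
#' @param mesor_log_sd between-participant lognormal mesor spread.
#' @param rel_amp_sd between-participant relative-amplitude jitter.
#' @param genes data.frame of [geneParams()] rows.
#' @param gene_ct_offset named baseline CT offsets of the targets relative
#'   to the reference gene.
#' @param ref_ct_mean mean reference-gene (GAPDH) CT.
#' @param cortisol list: `mesor_mean`, `mesor_log_sd`, `rel_amplitude`,
#'   `phase_mean_h` (peak, hours since awakening), `phase_sd_h`,
#'   `arntl1_phase_coupling` (h per h, negative), `noise_sd`, `offsets_h`,
#'   `lod`, `uloq`.
#' @param melatonin list: `base` (pg/mL), `cortisol_coupling` (negative,
#'   on the log scale), `per2_coupling` (positive), `log_sd`, `uloq`.
#' @param cells list: `lambda_leukocytes`, `lambda_epithelial` (Poisson
#'   means per field), `times_h`.
#' @param meq_mean,meq_sd MEQ score distribution (rounded, clamped to
#'   16..86).
#' @param seed mandatory integer seed.
#' @return a `CohortConfig` list.
#' @export
cohortConfig <- function(n_participants = 20L,
                         sampling_times_h = c(9, 13, 17, 21),
                         n_days = 2L,
                         ct_noise_sd = 0.2,
                         day_effect_sd = 0.1,
                         bedtime_mean_h = 23, bedtime_sd_h = 1,
                         phase_bedtime_slope = 1,
                         mesor_log_sd = 0.3,
                         rel_amp_sd = 0.05,
                         genes = defaultGeneParams(),
                         gene_ct_offset = c(ARNTL1 = 8, PER2 = 7, NR1D1 = 9),
                         ref_ct_mean = 20,
                         cortisol = list(),
                         melatonin = list(),
                         cells = list(),
                         meq_mean = 50, meq_sd = 8,
                         seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory for cohort simulation")
  if (any(genes$mesor <= 0)) stop("gene mesors must be positive")
  stopifnot(ct_noise_sd >= 0, day_effect_sd >= 0, bedtime_sd_h >= 0,
            all(sampling_times_h >= 0 & sampling_times_h < 24))
  cort <- utils::modifyList(list(mesor_mean = 6, mesor_log_sd = 0.3,
                                 rel_amplitude = 0.65, phase_mean_h = 0.75,
                                 phase_sd_h = 0.75, arntl1_phase_coupling = -0.8,
                                 noise_sd = 0.5,
                                 offsets_h = c(0, 0.5, 1, 2, 5, 8, 12),
                                 lod = 2, uloq = 100), cortisol)
  mel <- utils::modifyList(list(base = 20, cortisol_coupling = -1.2,
                                per2_coupling = 1.2, log_sd = 0.3, uloq = 100),
                           melatonin)
  cel <- utils::modifyList(list(lambda_leukocytes = 32, lambda_epithelial = 18,
                                times_h = c(9, 13, 17)), cells)
  list(n_participants = as.integer(n_participants),
       sampling_times_h = sampling_times_h, n_days = as.integer(n_days),
       ct_noise_sd = ct_noise_sd, day_effect_sd = day_effect_sd,
       bedtime_mean_h = bedtime_mean_h, bedtime_sd_h = bedtime_sd_h,
       phase_bedtime_slope = phase_bedtime_slope,
       mesor_log_sd = mesor_log_sd, rel_amp_sd = rel_amp_sd,
       genes = genes, gene_ct_offset = gene_ct_offset,
       ref_ct_mean = ref_ct_mean,
       cortisol = cort, melatonin = mel, cells = cel,
       meq_mean = meq_mean, meq_sd = meq_sd, seed = as.integer(seed))
}

.cosine <- function(t, mesor, rel_amp, acro, period = 24) {
  mesor * (1 + rel_amp * cos(2 * pi * (t - acro) / period))
}

#' Map a circular phase to a signed offset from a reference hour
#'
#' Rank statistics on raw wrapped phases break down when the phase
#' distribution straddles the 0/24 boundary; re-centering on a reference
#' hour near the distribution's antipode yields a continuous variable in
#' `(-12, 12]`.
#'
#' @param phase_h phases in hours.
#' @param center_h reference hour.
#' @param period_h period, default 24.
#' @return signed hours in `(-period/2, period/2]`.
#' @export
centerPhase <- function(phase_h, center_h, period_h = 24) {
  ((phase_h - center_h + period_h / 2) %% period_h) - period_h / 2
}

#' Generate a synthetic saliva cohort
#'
#' Draws participant-level circadian parameters with the couplings the
#' analysis is meant to detect, then simulates every observable table:
#'
#' * qPCR CT values: target CT is
#'   `CT_ref + offset_gene - log2(E(t)) + day_effect + noise`, with the
#'   reference gene drawn around `ref_ct_mean`; noise is additive in
#'   cycles (so lognormal in fold change).
#' * per-gene acrophase = gene prior + `phase_bedtime_slope *
#'   (bedtime - bedtime_mean)` + jitter (positive bedtime-phase coupling).
#' * cortisol acrophase is coupled to the participant's ARNTL1 acrophase
#'   with a negative sign; melatonin is log-linearly coupled negatively to
#'   the cortisol mesor and positively to the PER2 mesor.
#' * cortisol values below the LOD are recorded as the token `"<lod"`
#'   (value substituted with 1, flagged `below_lod`); melatonin above the
#'   ULOQ as `">uloq"` (flagged `above_uloq`).
#' * cell counts: Poisson per field with time-independent composition.
#'
#' Identical config and seed give identical output.
#'
#' @param config a [cohortConfig()] list.
#' @return list with elements `ct` ([CtTable-class]), `hormones` (list of
#'   [HormoneSeries-class]), `cells` ([CellCountTable-class]),
#'   `participants` (data.frame: participant, bedtime_h, meq, chronotype)
#'   and `truth` (data.frame, one row per participant x gene, carrying the
#'   generative mesor/amplitude/acrophase and the participant-level
#'   bedtime, cortisol parameters and melatonin level).
#' @export
generateCohort <- function(config) {
  set.seed(config$seed)
  np <- config$n_participants
  ids <- sprintf("P%02d", seq_len(np))
  genes <- config$genes
  ng <- nrow(genes)

  bedtime <- rnorm(np, config$bedtime_mean_h, config$bedtime_sd_h)

  ## participant x gene generative parameters
  truth <- do.call(rbind, lapply(seq_len(np), function(i) {
    acro <- (genes$acrophase_h +
               config$phase_bedtime_slope * (bedtime[i] - config$bedtime_mean_h) +
               rnorm(ng, 0, genes$acrophase_sd_h)) %% 24
    mes <- genes$mesor * exp(rnorm(ng, 0, config$mesor_log_sd))
    ra <- pmin(pmax(genes$rel_amplitude + rnorm(ng, 0, config$rel_amp_sd), 0.05), 0.95)
    data.frame(participant = ids[i], gene = genes$gene, mesor = mes,
               rel_amplitude = ra, amplitude = ra * mes, acrophase_h = acro,
               stringsAsFactors = FALSE)
  }))

  cortP <- config$cortisol
  gene_a <- if ("ARNTL1" %in% genes$gene) "ARNTL1" else genes$gene[1L]
  arntl1_prior <- genes$acrophase_h[match(gene_a, genes$gene)]
  sub_a <- truth[truth$gene == gene_a, ]
  acro_a <- sub_a$acrophase_h[match(ids, sub_a$participant)]
  cort_mesor <- exp(rnorm(np, log(cortP$mesor_mean), cortP$mesor_log_sd))
  cort_amp <- cortP$rel_amplitude * cort_mesor
  cort_phase <- cortP$phase_mean_h +
    cortP$arntl1_phase_coupling * centerPhase(acro_a, arntl1_prior) +
    rnorm(np, 0, cortP$phase_sd_h)

  melP <- config$melatonin
  gene_p <- if ("PER2" %in% genes$gene) "PER2" else genes$gene[1L]
  per2_ref <- genes$mesor[match(gene_p, genes$gene)]
  sub_p <- truth[truth$gene == gene_p, ]
  per2_mes <- sub_p$mesor[match(ids, sub_p$participant)]
  melatonin <- melP$base * exp(melP$cortisol_coupling * log(cort_mesor / cortP$mesor_mean) +
                               melP$per2_coupling * log(per2_mes / per2_ref) +
                               rnorm(np, 0, melP$log_sd))

  ## CT table
  ct_rows <- list()
  for (i in seq_len(np)) {
    tr <- truth[truth$participant == ids[i], ]
    for (d in seq_len(config$n_days)) {
      day_eff <- rnorm(ng, 0, config$day_effect_sd)
      for (tm in config$sampling_times_h) {
        tabs <- absoluteTime(d, tm)
        ct_ref <- rnorm(1, config$ref_ct_mean, config$ct_noise_sd)
        e <- .cosine(tabs, tr$mesor, tr$rel_amplitude, tr$acrophase_h)
        off <- config$gene_ct_offset[tr$gene]
        off[is.na(off)] <- 8
        ct_t <- ct_ref + off - log2(e) + day_eff +
          rnorm(ng, 0, config$ct_noise_sd)
        ct_rows[[length(ct_rows) + 1L]] <-
          data.frame(participant = ids[i], day = d,
                     time_h = tm, gene = c(tr$gene, "GAPDH"),
                     ct = c(ct_t, ct_ref), stringsAsFactors = FALSE)
      }
    }
  }
  ct <- CtTable(do.call(rbind, ct_rows))

  ## hormone series
  hormones <- list()
  for (i in seq_len(np)) {
    rows <- do.call(rbind, lapply(seq_len(config$n_days), function(d) {
      v <- cort_mesor[i] +
        cort_amp[i] * cos(2 * pi * (cortP$offsets_h - cort_phase[i]) / 24) +
        rnorm(length(cortP$offsets_h), 0, cortP$noise_sd)
      data.frame(day = d, time_h = cortP$offsets_h, value = v,
                 stringsAsFactors = FALSE)
    }))
    rows$raw <- formatC(rows$value, format = "g")
    rows$censor <- "none"
    low <- rows$value < cortP$lod
    rows$raw[low] <- paste0("<", cortP$lod)
    rows$value[low] <- 1
    rows$censor[low] <- "below_lod"
    hormones[[length(hormones) + 1L]] <- HormoneSeries(ids[i], "cortisol", rows)

    mrows <- do.call(rbind, lapply(seq_len(config$n_days), function(d) {
      v <- melatonin[i] * exp(rnorm(1, 0, 0.1))
      data.frame(day = d, time_h = (bedtime[i] - 0.5) %% 24, value = v,
                 stringsAsFactors = FALSE)
    }))
    mrows$raw <- formatC(mrows$value, format = "g")
    mrows$censor <- "none"
    hi <- mrows$value > melP$uloq
    mrows$raw[hi] <- paste0(">", melP$uloq)
    mrows$value[hi] <- melP$uloq
    mrows$censor[hi] <- "above_uloq"
    hormones[[length(hormones) + 1L]] <- HormoneSeries(ids[i], "melatonin", mrows)
  }

  ## cell counts (time-independent composition)
  celP <- config$cells
  cell_rows <- expand.grid(participant = ids, day = seq_len(config$n_days),
                           time_h = celP$times_h, field_index = 1:8,
                           stringsAsFactors = FALSE)
  cell_rows <- cell_rows[order(cell_rows$participant, cell_rows$day,
                               cell_rows$time_h, cell_rows$field_index), ]
  cell_rows$leukocytes <- rpois(nrow(cell_rows), celP$lambda_leukocytes)
  cell_rows$epithelial <- rpois(nrow(cell_rows), celP$lambda_epithelial)
  cells <- CellCountTable(cell_rows)

  meq <- pmin(pmax(round(rnorm(np, config$meq_mean, config$meq_sd)), 16L), 86L)
  participants <- data.frame(participant = ids, bedtime_h = bedtime,
                             meq = as.integer(meq),
                             chronotype = vapply(meq, classifyChronotype, ""),
                             stringsAsFactors = FALSE)

  truth$bedtime_h <- bedtime[match(truth$participant, ids)]
  truth$cortisol_mesor <- cort_mesor[match(truth$participant, ids)]
  truth$cortisol_amplitude <- cort_amp[match(truth$participant, ids)]
  truth$cortisol_acrophase_h <- cort_phase[match(truth$participant, ids)]
  truth$melatonin <- melatonin[match(truth$participant, ids)]
  rownames(truth) <- NULL

  list(ct = ct, hormones = hormones, cells = cells,
       participants = participants, truth = truth)
}

#' Generate one dense synthetic expression series
#'
#' Samples a noiseless cosine every `interval_h` hours from 0 to
#' `duration_h` inclusive (`floor(duration/interval) + 1` points) and
#' applies multiplicative Gaussian noise, emulating dense cell-line
#' reference time courses (e.g. sampling every 3 h over 30 h).
#'
#' @param params one row of [geneParams()].
#' @param interval_h sampling interval, hours (> 0).
#' @param duration_h total duration, hours (>= interval).
#' @param noise_sd multiplicative noise sd as a fraction of the local mean
#'   (so, of order `noise_sd * mesor` in absolute units).
#' @param seed optional integer seed; `NULL` leaves the RNG state alone.
#' @return An [ExpressionSeriesSet-class] with participant `"sim"`.
#' @export
generateDenseSeries <- function(params, interval_h, duration_h, noise_sd = 0,
                                seed = NULL) {
  stopifnot(interval_h > 0, duration_h >= interval_h)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_h, by = interval_h)
  e <- .cosine(t, params$mesor, params$rel_amplitude, params$acrophase_h)
  v <- e * (1 + rnorm(length(t), 0, noise_sd))
  ExpressionSeriesSet(data.frame(
    participant = "sim", gene = params$gene,
    day = as.integer(t %/% 24 + 1), time_h = t %% 24,
    rel_expr = v, fold_change = v, stringsAsFactors = FALSE))
}
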