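## End-to-end orchestration: synthesize (or ingest) a cohort, compute
## vibration + spectral + wall-shear metrics, aggregate over JAV slices,
## run the group statistics and correlations, and write report tables with
## a reproducibility manifest.

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[vesselvib] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort synthesis (or ingestion of supplied patients),
#' high-pass vibration amplitude and strain maps, JAV-mean displacement
#' spectrograms with band detection, wall-shear indices, slice aggregation,
#' group summaries and mixed-model comparisons, WSS-vibration correlations,
#' and report tables. A stage failure aborts with the stage name; outputs
#' written so far are retained.
#'
#' @param config a [pipeline_config()].
#' @param input either `NULL` (synthesize the default six-patient cohort
#'   using `config$rng_seed`), a list of cohort entries as returned by
#'   [make_cohort()], or a list with `n_per_group`, `presets`, `dt`,
#'   `n_cycles`, `mesh_args` passed to [make_cohort()].
#' @param out_dir output directory for report tables (`NULL` to skip
#'   writing).
#' @param verbose log stage boundaries.
#' @return A list with `manifest`, `slice_table`, `group_stats`, `models`,
#'   `bands`, `wss`, `correlations`, `patients` and `report_paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), input = NULL,
                         out_dir = NULL, verbose = TRUE) {
  stage <- "setup"
  result <- tryCatch({
    stage <- "synthesize"
    is_cohort <- is.list(input) && length(input) > 0L &&
      is.list(input[[1L]]) && !is.null(input[[1L]]$patient_id)
    cohort <- if (is.null(input)) {
      pipeline_log(verbose, "stage synthesize: default cohort, seed %d", config$rng_seed)
      make_cohort(seed = config$rng_seed)
    } else if (!is_cohort) {
      pipeline_log(verbose, "stage synthesize: custom cohort, seed %d", config$rng_seed)
      do.call(make_cohort, c(input, list(seed = config$rng_seed)))
    } else {
      pipeline_log(verbose, "stage ingest: %d supplied patients", length(input))
      input
    }

    slice_rows <- list()
    bands_all <- list()
    wss_all <- list()
    for (p in cohort) {
      stage <- paste0("vibration:", p$patient_id)
      vs <- vibration_summary(p$mesh, p$displacement,
                              cutoff_hz = config$highpass_cutoff_hz,
                              q = config$percentile_q)
      pipeline_log(verbose, "stage vibration %s: peak %.1f um, cycle-average %.1f um",
                   p$patient_id, vs$peak_amp_um, vs$cycleavg_amp_um)

      stage <- paste0("slices:", p$patient_id)
      sa <- assign_nodes_to_slices(p$mesh, p$centerline,
                                   config$slice_extent_mm, config$slice_spacing_mm)
      slice_rows[[paste0(p$patient_id, ":amp")]] <-
        slice_means(vs$amp_map, sa, "amp_um", p$patient_id, p$group_label)
      slice_rows[[paste0(p$patient_id, ":strain")]] <-
        slice_means(vs$strain_map, sa, "strain", p$patient_id, p$group_label)

      stage <- paste0("spectral:", p$patient_id)
      tr <- jav_mean_trace(vs$series_hp, p$mesh, p$centerline,
                           config$slice_extent_mm)
      sp <- spectrogram(tr, p$displacement$dt, config$spectrogram_window_s,
                        config$spectrogram_overlap_frac)
      bs <- detect_bands(sp, threshold_db = config$band_threshold_db,
                         mode = config$band_threshold_mode,
                         cutoff_hz = config$highpass_cutoff_hz,
                         fmax_hz = config$band_fmax_hz,
                         min_width_hz = config$band_min_width_hz,
                         min_gap_hz = config$band_min_gap_hz,
                         prominence_drop_db = config$band_prominence_db)
      bands_all[[p$patient_id]] <- bs
      pipeline_log(verbose, "stage spectral %s: %d band(s)%s", p$patient_id, nrow(bs),
                   if (nrow(bs)) paste0(" at ", paste(sprintf("%.0f Hz", bs$f_center_hz),
                                                      collapse = ", ")) else "")

      if (!is.null(p$traction)) {
        stage <- paste0("wss:", p$patient_id)
        ws <- wall_shear_summary(p$traction, p$mesh, p$centerline,
                                 cutoff_hz = config$highpass_cutoff_hz,
                                 extent_mm = config$slice_extent_mm)
        wss_all[[p$patient_id]] <- ws
        for (m in c("tawss", "osi", "spi"))
          slice_rows[[paste0(p$patient_id, ":", m)]] <-
            slice_means(ws[[m]], sa, m, p$patient_id, p$group_label)
      }
    }
    slice_table <- do.call(rbind, slice_rows)
    rownames(slice_table) <- NULL

    stage <- "group_stats"
    gs <- summarize_groups(slice_table)
    models <- list()
    n_groups <- length(unique(slice_table$group_label))
    for (resp in intersect(c("amp_um", "strain"), unique(slice_table$metric_name))) {
      models[[paste0(resp, "_two_group")]] <- fit_lmm(slice_table, resp, "two_group")
      if (n_groups >= 3L)
        models[[paste0(resp, "_three_group")]] <- fit_lmm(slice_table, resp, "three_group")
    }
    pipeline_log(verbose, "stage group_stats: %d models fitted", length(models))

    stage <- "correlations"
    correlations <- NULL
    if (length(wss_all) && length(unique(slice_table$patient_id)) >= 2L) {
      correlations <- rbind(correlate_indices(slice_table, log10_vib = FALSE),
                            correlate_indices(slice_table, log10_vib = TRUE))
    }

    stage <- "report"
    model_summ <- lapply(models, function(m)
      list(family = m$model_family, shapiro_p = m$shapiro_p,
           conditional_R = m$conditional_R, alpha_adjusted = m$alpha_adjusted,
           contrasts = m$fixed_effects))
    band_summ <- lapply(bands_all, function(b) as.data.frame(b))
    report_paths <- NULL
    if (!is.null(out_dir)) {
      report_paths <- write_report_tables(
        list(slice_table = slice_table, group_stats = gs,
             correlations = correlations, models = model_summ,
             bands = band_summ, config = config),
        out_dir)
      pipeline_log(verbose, "stage report: wrote %d files to %s",
                   length(report_paths), out_dir)
    }

    manifest <- list(
      tool = "vesselvib",
      version = as.character(utils::packageVersion("vesselvib")),
      seed = config$rng_seed,
      config = unclass(config),
      n_patients = length(cohort),
      patients = vapply(cohort, function(p) p$patient_id, character(1L)),
      output_paths = as.list(report_paths),
      output_hashes = if (!is.null(report_paths))
        as.list(tools::md5sum(unname(report_paths))) else NULL)

    list(manifest = manifest, slice_table = slice_table, group_stats = gs,
         models = models, bands = bands_all, wss = wss_all,
         correlations = correlations, patients = cohort,
         report_paths = report_paths)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}
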