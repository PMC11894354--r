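#' Pipeline run configuration
#'
#' Bundles every stage's tunable constant with its conventional default:
#' 70% participant-inclusion threshold, 15-s gap rule, LF 0.04--0.15 Hz and
#' HF 0.15--1.0 Hz bands, ln-variance censoring at \[2.5, 9.0\], nominal
#' degradation levels 10/20/35/60%, and the bootstrap replicate count.
#' A configuration can also be read from YAML with [read_pipeline_config()].
#'
#' @param synth A [synth_config()] describing the cohort to generate (or
#'   `NULL` to ingest external files listed in `ibi_files`).
#' @param qc_threshold Participant inclusion threshold, percent.
#' @param gap_threshold_s Gap rule threshold, seconds.
#' @param censor Ln-variance censoring bounds.
#' @param levels Degradation levels, subset of `c(10, 20, 35, 60)`.
#' @param n_boot Bootstrap replicates for the mixed-model CIs.
#' @param seed Integer seed governing degradation placement and bootstrap.
#' @param contrast_metrics Metrics to run missingness contrasts for.
#' @param contrast_activities Activity classes to contrast.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            qc_threshold = 70,
                            gap_threshold_s = 15,
                            censor = c(2.5, 9.0),
                            levels = c(10, 20, 35, 60),
                            n_boot = 1000,
                            seed = 1L,
                            contrast_metrics = c("median_ibi", "stdrr", "rmsdrr",
                                                 "lf", "hf", "lf_hf"),
                            contrast_activities = c("rest", "light")) {
  bad <- setdiff(levels, c(10, 20, 35, 60))
  if (length(bad)) {
    abort(sprintf("Unknown degradation level(s) %s; valid levels are 10, 20, 35, 60.",
                  paste(bad, collapse = ", ")))
  }
  if (qc_threshold < 0 || qc_threshold > 100) abort("`qc_threshold` must be in [0, 100].")
  if (gap_threshold_s <= 0) abort("`gap_threshold_s` must be positive.")
  if (length(censor) != 2 || censor[1] >= censor[2]) {
    abort("`censor` must be c(lower, upper) with lower < upper.")
  }
  structure(
    list(synth = synth, qc_threshold = qc_threshold,
         gap_threshold_s = gap_threshold_s, censor = censor,
         levels = levels, n_boot = n_boot, seed = as.integer(seed),
         contrast_metrics = contrast_metrics,
         contrast_activities = contrast_activities),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `synth`
#' block mirrors [synth_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth <- if (!is.null(y$synth)) do.call(synth_config, y$synth) else synth_config()
  args <- y[setdiff(names(y), "synth")]
  do.call(pipeline_config, c(list(synth = synth), args))
}

#' Run the full missingness/agreement pipeline
#'
#' Orchestrates: synthetic-cohort generation, artifact filtering, windowing
#' and QC, HRV metric extraction for both devices, semisimulated degradation
#' of the PPG reference windows at each configured level, mixed-model
#' missingness contrasts, and PPG-vs-ECG agreement. All stage outputs are
#' written as CSV under `out_dir` together with a JSON manifest recording
#' the configuration and seed; re-running with the same configuration
#' reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage outputs (`qc`, `metrics_ref`,
#'   `metrics_degraded`, `contrasts`, `agreement`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("hrvrun")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message(sprintf(...))

  msg("[synth] generating cohort: %d participants, %.2f days",
      config$synth$participant_count, config$synth$duration_days)
  cohort <- generate_cohort(config$synth)

  msg("[qc] filtering artifacts, windowing, computing inclusion")
  streams <- cohort$ibi |>
    dplyr::group_by(.data$participant_id, .data$device) |>
    dplyr::group_split()
  windows_all <- purrr::map(streams, function(s) {
    filt <- filter_artifacts(s)
    w <- segment_windows(filt) |>
      find_gaps(config$gap_threshold_s) |>
      classify_activity(cohort$steps[cohort$steps$participant_id ==
                                       s$participant_id[1], ])
    w
  })
  qc <- purrr::map_dfr(windows_all, participant_inclusion,
                       threshold = config$qc_threshold)
  readr::write_csv(qc, file.path(out_dir, "qc.csv"))

  included <- qc$participant_id[qc$included & qc$device == "ppg"]
  windows_all <- purrr::keep(windows_all,
                             ~ .x$participant_id[1] %in% included)

  msg("[metrics] computing HRV metrics for %d streams", length(windows_all))
  metrics_all <- purrr::map(
    windows_all, compute_hrv,
    gap_threshold_s = config$gap_threshold_s, censor = config$censor)
  metrics_ref <- dplyr::bind_rows(purrr::map(metrics_all, metrics_table))
  readr::write_csv(metrics_ref, file.path(out_dir, "metrics_reference.csv"))

  msg("[degrade] levels %s", paste(config$levels, collapse = ", "))
  ppg_windows <- purrr::keep(windows_all, ~ .x$device[1] == "ppg")
  metrics_deg <- purrr::map_dfr(ppg_windows, function(w) {
    degrade_dataset(w, config$levels, config$seed) |>
      compute_hrv(config$gap_threshold_s, censor = config$censor) |>
      metrics_table()
  })
  readr::write_csv(metrics_deg, file.path(out_dir, "metrics_degraded.csv"))

  msg("[analyze] missingness contrasts (%d bootstrap reps)", config$n_boot)
  ppg_ref <- dplyr::filter(metrics_ref, .data$device == "ppg")
  long <- metrics_long(ppg_ref, metrics_deg)
  contrasts <- purrr::map_dfr(config$contrast_activities, function(act) {
    purrr::map_dfr(config$contrast_metrics, function(m) {
      has <- long |>
        dplyr::filter(.data$metric == m, .data$activity == act)
      if (dplyr::n_distinct(has$level) < 2 ||
          dplyr::n_distinct(has$participant_id) < 2) {
        return(tibble::tibble())
      }
      tidy(fit_missingness_contrasts(long, m, act, n_boot = config$n_boot,
                                     seed = config$seed))
    })
  })
  readr::write_csv(contrasts, file.path(out_dir, "contrasts.csv"))

  msg("[analyze] between-device agreement")
  ecg_ref <- dplyr::filter(metrics_ref, .data$device == "ecg")
  agreement <- agreement_analysis(align_devices(ppg_ref, ecg_ref))
  readr::write_csv(agreement, file.path(out_dir, "agreement.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("hrvgaps")),
    seed = config$seed,
    qc_threshold = config$qc_threshold,
    gap_threshold_s = config$gap_threshold_s,
    censor = config$censor,
    levels = config$levels,
    n_boot = config$n_boot,
    synth = config$synth[setdiff(names(config$synth),
                                 c("wear_schedule", "activity_blocks"))],
    outputs = c("qc.csv", "metrics_reference.csv", "metrics_degraded.csv",
                "contrasts.csv", "agreement.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  msg("[done] outputs in %s", out_dir)
  invisible(list(qc = qc, metrics_ref = metrics_ref,
                 metrics_degraded = metrics_deg, contrasts = contrasts,
                 agreement = agreement, manifest = manifest,
                 out_dir = out_dir))
}
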