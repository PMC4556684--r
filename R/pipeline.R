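#' Pipeline configuration
#'
#' Bundles the generator settings, sample entropy parameters and statistics
#' options consumed by [run_pipeline()]. The default demo configuration uses
#' 20 synthetic patients with 2-hour recordings; at that length the 90-300 s
#' scales have few coarse-grained points, so the minimum-points threshold is
#' lowered to keep the VLF2 band defined.
#'
#' @param synth A [synth_config()].
#' @param m,r Sample entropy parameters.
#' @param min_points Minimum coarse-grained points per defined scale.
#' @param cv_folds Cross-validation folds.
#' @param seed Statistics-stage seed (fold assignment).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(n_patients = 20,
                                                 duration_h = 2),
                            m = 2, r = 0.15, min_points = 20,
                            cv_folds = 4, seed = 1) {
  structure(list(synth = synth, m = m, r = r, min_points = min_points,
                 cv_folds = cv_folds, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments, with `synth`
#' holding [synth_config()] fields.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth <- do.call(synth_config, y$synth %||% list())
  args <- y[setdiff(names(y), "synth")]
  do.call(pipeline_config, c(list(synth = synth), args))
}

#' Simulation stage: write per-patient beat CSVs and the cohort table
#'
#' Generates the synthetic cohort (covariates, outcomes and one beat series
#' per patient) and writes `beats/<patient>.csv` plus `cohort.csv` under
#' `out_dir`. The configuration is echoed to `config.yaml` for provenance.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, the cohort table (without the latent entropy target).
#' @export
pipeline_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(file.path(out_dir, "beats"), recursive = TRUE,
             showWarnings = FALSE)
  cfg_echo <- config
  cfg_echo$synth <- unclass(cfg_echo$synth)
  yaml::write_yaml(unclass(cfg_echo), file.path(out_dir, "config.yaml"))

  cohort <- suppressWarnings(
    generate_cohort(config$synth, features = "draw", keep_beats = TRUE))
  beats_list <- attr(cohort, "beats")
  for (i in seq_len(nrow(cohort)))
    write_beats_csv(beats_list[[i]],
                    file.path(out_dir, "beats",
                              sprintf("%s.csv", cohort$patient_id[i])))
  out <- as.data.frame(cohort)[, setdiff(names(cohort), "mean_en_vlf2")]
  write.csv(out, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  invisible(out)
}

#' Feature stage: extract HRV/MSE features for every beat CSV
#'
#' Reads each `beats/*.csv`, extracts the full feature row and joins it to
#' the cohort table. A recording whose extraction fails is quarantined (the
#' patient id and reason are appended to `quarantine.csv`) and processing
#' continues with the remaining patients.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory containing the simulate-stage outputs.
#' @return Invisibly, the feature table (also written to `features.csv`).
#' @export
pipeline_features <- function(config, out_dir) {
  cohort <- read.csv(file.path(out_dir, "cohort.csv"),
                     stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cohort))
  quarantine <- data.frame(patient_id = character(0), reason = character(0))
  for (i in seq_len(nrow(cohort))) {
    path <- file.path(out_dir, "beats", sprintf("%s.csv", cohort$patient_id[i]))
    rows[[i]] <- tryCatch(
      extract_features(read_beats_csv(path), m = config$m, r = config$r,
                       min_points = config$min_points),
      error = function(e) {
        quarantine <<- rbind(quarantine,
                             data.frame(patient_id = cohort$patient_id[i],
                                        reason = conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(rows, is.null, logical(1))
  feats <- cbind(cohort[ok, setdiff(names(cohort),
                                    c("follow_up_months", "event"))],
                 do.call(rbind, rows[ok]),
                 cohort[ok, c("follow_up_months", "event")])
  write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(quarantine, file.path(out_dir, "quarantine.csv"),
            row.names = FALSE)
  invisible(feats)
}

#' Statistics stage: cohort-level risk analyses
#'
#' Runs the group comparison, C-statistic, adjusted Cox fits, Nelson-Aalen
#' curves and cross-validation on `features.csv`, writing `stats/report.json`
#' and `stats/nelson_aalen.csv`. Analyses that are not estimable on the given
#' cohort (e.g. too few events) are reported as null rather than aborting the
#' run.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory containing the feature-stage outputs.
#' @return Invisibly, the list of results.
#' @export
pipeline_stats <- function(config, out_dir) {
  feats <- read.csv(file.path(out_dir, "features.csv"),
                    stringsAsFactors = FALSE)
  dir.create(file.path(out_dir, "stats"), showWarnings = FALSE)
  try_or_null <- function(expr) tryCatch(expr, error = function(e) NULL)
  stats <- list(
    n = nrow(feats), n_events = sum(feats$event),
    group_comparison = try_or_null(compare_groups(feats, "mean_en_vlf2")),
    c_statistic = try_or_null(c_statistic(feats, "mean_en_vlf2")),
    cox = try_or_null(cox_table(feats)),
    nelson_aalen = try_or_null(cumulative_incidence(feats)),
    cross_validation = try_or_null(
      cross_validate(feats, k = config$cv_folds, seed = config$seed))
  )
  json <- list(
    n = stats$n, n_events = stats$n_events,
    group_comparison = stats$group_comparison[c("mean_1", "sd_1", "mean_0",
                                                "sd_0", "p")],
    c_statistic = stats$c_statistic,
    cox = stats$cox,
    logrank_p = stats$nelson_aalen$logrank_p,
    cross_validation = stats$cross_validation[c("sensitivity", "specificity")]
  )
  jsonlite::write_json(json, file.path(out_dir, "stats", "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(stats$nelson_aalen))
    write.csv(stats$nelson_aalen$curves,
              file.path(out_dir, "stats", "nelson_aalen.csv"),
              row.names = FALSE)
  invisible(stats)
}

#' Run the full analysis pipeline
#'
#' Executes [pipeline_simulate()], [pipeline_features()] and
#' [pipeline_stats()] in order inside `out_dir`. All outputs are plain
#' CSV/JSON; a re-run with the same configuration and seed is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the statistics-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("simulate: %d patients, %.1f h recordings",
      config$synth$n_patients, config$synth$duration_h)
  pipeline_simulate(config, out_dir)
  say("features: extracting recordings")
  feats <- pipeline_features(config, out_dir)
  say("cohort-stats: %d analysed patients, %d events",
      nrow(feats), sum(feats$event))
  invisible(pipeline_stats(config, out_dir))
}
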