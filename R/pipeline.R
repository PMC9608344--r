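#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]: the cohort simulator
#' config, the descriptive threshold and sweep grid, the statistical pairs,
#' and the classification experiments. One global seed fans out to
#' deterministic per-stage sub-seeds.
#'
#' @param cohort A [cohort_config()]; its seed is overridden by `seed`.
#' @param tau Descriptive binarization threshold (default 0.7).
#' @param sweep_taus Threshold grid for the CV sweep (`NULL` to skip).
#' @param stat_pairs `"all"` or a list of profile pairs for group
#'   comparisons.
#' @param experiments List of pair specifications to classify (each becomes
#'   an [experiment_config()]); `minimal` and `taus` apply to all.
#' @param taus Classification threshold grid.
#' @param minimal Use one-point learner grids.
#' @param k Cross-validation folds per experiment.
#' @param seed Global seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            tau = 0.7,
                            sweep_taus = seq(0.05, 0.95, by = 0.05),
                            stat_pairs = "all",
                            experiments = list("RR:PP"),
                            taus = seq(0.6, 0.8, by = 0.05),
                            minimal = FALSE,
                            k = 10,
                            seed = 1L) {
  structure(list(cohort = cohort, tau = tau, sweep_taus = sweep_taus,
                 stat_pairs = stat_pairs, experiments = experiments,
                 taus = taus, minimal = minimal, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML document
#'
#' Top-level sections `cohort`, `pipeline` (`tau`, `sweep_taus`,
#' `experiments`, `taus`, `minimal`) and `seed`; unknown cohort fields abort
#' with the offending path.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cc_args <- y$cohort %||% list()
  known <- names(formals(cohort_config))
  bad <- setdiff(names(cc_args), known)
  if (length(bad) > 0) {
    abort(paste0("config: unknown cohort field(s): ",
                 paste0("cohort.", bad, collapse = ", ")))
  }
  for (f in c("n_patients", "n_scans", "mean_scans_per_patient",
              "atrophy_frac", "atrophy_depth", "longitudinal_rate",
              "age_mean", "age_sd", "sex_frac_female")) {
    if (!is.null(cc_args[[f]])) cc_args[[f]] <- unlist(cc_args[[f]])
  }
  cohort <- do.call(cohort_config, cc_args)
  pl <- y$pipeline %||% list()
  pipeline_config(
    cohort = cohort,
    tau = pl$tau %||% 0.7,
    sweep_taus = pl$sweep_taus %||% seq(0.05, 0.95, by = 0.05),
    stat_pairs = pl$stat_pairs %||% "all",
    experiments = pl$experiments %||% list("RR:PP"),
    taus = pl$taus %||% seq(0.6, 0.8, by = 0.05),
    minimal = isTRUE(pl$minimal),
    k = pl$k %||% 10,
    seed = y$seed %||% 1L
  )
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> build -> binarize -> metrics -> sweep -> stats ->
#' classify with explicit intermediate files under `out_dir`, and writes a
#' run record (stage timings, output digests, config snapshot, package
#' version) as `run_record.json`. Rerunning with the same config and seed
#' reproduces byte-identical metric tables and reports.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The run record list, invisibly; stage outputs are also returned
#'   in the `results` element.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  cc <- config$cohort
  cc$seed <- derive_seed(config$seed, "simulate")
  cohort <- stage("simulate", simulate_cohort(cc))
  stage("write_cohort", write_cohort(cohort, file.path(out_dir, "cohort")))
  cohort <- stage("build", cohort_connectomes(cohort))

  metrics <- stage("metrics", compute_metrics(cohort, tau = config$tau))
  write_metrics(metrics, file.path(out_dir, "metrics.csv"))

  sweep <- NULL
  if (!is.null(config$sweep_taus)) {
    sweep <- stage("sweep", cv_sweep(cohort, taus = config$sweep_taus))
    readr::write_csv(sweep, file.path(out_dir, "cv_sweep.csv"), progress = FALSE)
  }

  stats_tbl <- NULL
  if (!is.null(config$stat_pairs)) {
    stats_tbl <- stage("stats", {
      if (identical(config$stat_pairs, "all")) {
        compare_all_pairs(metrics)
      } else {
        purrr::map_dfr(config$stat_pairs, compare_pair, metrics = metrics)
      }
    })
    readr::write_csv(stats_tbl, file.path(out_dir, "group_stats.csv"),
                     progress = FALSE)
  }
  summary_tbl <- group_summary(metrics)
  readr::write_csv(summary_tbl, file.path(out_dir, "group_summary.csv"),
                   progress = FALSE)

  reports <- list()
  for (pair in config$experiments) {
    ec <- experiment_config(pair, taus = config$taus,
                            minimal = config$minimal, k = config$k,
                            seed = derive_seed(config$seed, paste0("clf_", pair)))
    rep <- stage(paste0("classify_", pair), run_experiment(cohort, ec))
    reports[[ec$pair$label]] <- rep
    readr::write_csv(tidy(rep),
                     file.path(out_dir, paste0("report_", ec$pair$label, ".csv")),
                     progress = FALSE)
  }

  out_files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  out_files <- out_files[!grepl("run_record", out_files)]
  digests <- as.list(tools::md5sum(sort(out_files)))
  names(digests) <- sub(paste0("^", out_dir, "/?"), "", names(digests))
  record <- list(
    package_version = as.character(utils::packageVersion("gmconnect")),
    seed = config$seed,
    tau = config$tau,
    n_scans = nrow(cohort),
    n_patients = length(unique(cohort$patient_id)),
    timings = timings,
    digests = digests
  )
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  record$results <- list(metrics = metrics, sweep = sweep, stats = stats_tbl,
                         summary = summary_tbl, reports = reports)
  invisible(record)
}
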