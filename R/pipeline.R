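#' Pipeline configuration
#'
#' Collects the file paths and parameters for an end-to-end run:
#' outcome classification, binarization, (optionally stratified) mining,
#' Bayesian path characterization, and reports.
#'
#' @param cohort,life_table,coding,schedule Paths to the cohort CSV, the
#'   life-table CSV, the coding config and the schedule config.
#' @param out_dir Output directory.
#' @param buffer_months Primary buffer for the outcome (default 9).
#' @param sensitivity_buffers Buffers for the sensitivity report (default
#'   `c(3, 6, 9)`).
#' @param stratify_by Optional attribute name for stratified mining.
#' @param seed Integer seed (drives the Bayesian draws).
#' @param bayes_level,bayes_draws Credible level and draws for
#'   [paths_posterior()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, life_table, coding, schedule, out_dir,
                            buffer_months = 9,
                            sensitivity_buffers = c(3, 6, 9),
                            stratify_by = NULL, seed = 1L,
                            bayes_level = 0.95, bayes_draws = 1e4) {
  cfg <- list(cohort = cohort, life_table = life_table, coding = coding,
              schedule = schedule, out_dir = out_dir,
              buffer_months = buffer_months,
              sensitivity_buffers = sensitivity_buffers,
              stratify_by = stratify_by, seed = as.integer(seed),
              bayes_level = bayes_level, bayes_draws = bayes_draws)
  for (f in c("cohort", "life_table", "coding", "schedule")) {
    if (!is.character(cfg[[f]]) || length(cfg[[f]]) != 1L) {
      stop("pipeline config field '", f, "' must be a single file path")
    }
    if (!file.exists(cfg[[f]])) {
      stop("pipeline input not found (", f, "): ", cfg[[f]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline config from YAML/JSON
#'
#' @param path Path to the config file; relative input paths are resolved
#'   against the config file's directory.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("pipeline config not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(p)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  pipeline_config(
    cohort = resolve(raw$cohort), life_table = resolve(raw$life_table),
    coding = resolve(raw$coding), schedule = resolve(raw$schedule),
    out_dir = raw$out_dir %||% file.path(base_dir, "out"),
    buffer_months = raw$buffer_months %||% 9,
    sensitivity_buffers = unlist(raw$sensitivity_buffers) %||% c(3, 6, 9),
    stratify_by = raw$stratify_by, seed = raw$seed %||% 1L,
    bayes_level = raw$bayes_level %||% 0.95,
    bayes_draws = raw$bayes_draws %||% 1e4
  )
}

#' Run the end-to-end pipeline
#'
#' Executes outcome classification, binarization, the mining schedule
#' (optionally stratified), the Bayesian path characterization, and writes
#' all reports plus a `manifest.json` provenance record (input digests,
#' counts, seed, package version, output digests). Any stage failure aborts
#' with a stage-named error. The run is a pure function of (input files,
#' configs, seed): repeated runs produce identical manifests.
#'
#' @param config A [pipeline_config()] or the path to one.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_stage(name, conditionMessage(e))
    })
  }

  inputs <- c(cohort = config$cohort, life_table = config$life_table,
              coding = config$coding, schedule = config$schedule)
  cohort <- stage("load", read_cohort(config$cohort))
  lt <- stage("load", read_life_table(config$life_table))
  codings <- stage("load", read_coding(config$coding))
  tasks <- stage("load", read_schedule(config$schedule))

  outcomes <- stage("outcome", compute_outcomes(
    cohort, lt, buffer_months = config$buffer_months
  ))
  sens <- stage("outcome", buffer_sensitivity(
    outcomes, buffer_months = config$sensitivity_buffers
  ))
  utils::write.csv(
    outcomes[, c("id", "ale", "years_survived", "excess", "premature")],
    file.path(out_dir, "outcomes.csv"), row.names = FALSE
  )
  jsonlite::write_json(sens, file.path(out_dir, "sensitivity.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  pm <- stage("binarize", binarize(cohort, codings, outcomes))
  write_predicate_matrix(pm, file.path(out_dir, "predicate_matrix.csv"),
                         file.path(out_dir, "predicate_meta.json"))

  per_task <- list()
  if (is.null(config$stratify_by)) {
    sched <- stage("mine", run_schedule(pm, tasks))
    write_paths(sched, file.path(out_dir, "paths.tsv"),
                file.path(out_dir, "paths.json"))
    write_predicate_frequency(predicate_frequency(sched),
                              file.path(out_dir, "predicate_frequency.tsv"))
    post <- stage("bayes", paths_posterior(
      sched, pm, p_task = max_task_p(sched, tasks),
      level = config$bayes_level, draws = config$bayes_draws,
      seed = config$seed
    ))
    utils::write.table(post, file.path(out_dir, "posterior.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    per_task <- as.list(sched$per_task)
    n_paths <- nrow(sched$paths)
    verifications <- sum(vapply(sched$task_results, `[[`, numeric(1),
                                "verifications"))
  } else {
    res <- stage("mine", stratified_run(pm, tasks, config$stratify_by))
    n_paths <- 0L
    verifications <- 0
    for (lb in names(res)) {
      sdir <- file.path(out_dir, paste0("stratum_", lb))
      dir.create(sdir, showWarnings = FALSE)
      write_paths(res[[lb]], file.path(sdir, "paths.tsv"),
                  file.path(sdir, "paths.json"))
      write_predicate_frequency(predicate_frequency(res[[lb]]),
                                file.path(sdir, "predicate_frequency.tsv"))
      per_task[[lb]] <- as.list(res[[lb]]$per_task)
      n_paths <- n_paths + nrow(res[[lb]]$paths)
      verifications <- verifications +
        sum(vapply(res[[lb]]$task_results, `[[`, numeric(1), "verifications"))
    }
  }

  manifest <- list(
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(inputs)),
    seed = config$seed,
    buffer_months = config$buffer_months,
    sensitivity_buffers = config$sensitivity_buffers,
    stratify_by = config$stratify_by,
    n_rows = nrow(cohort),
    n_predicates = sum(!pm$meta$is_outcome),
    n_deaths = sum(outcomes$vital_status == "died"),
    n_premature = sum(outcomes$premature),
    per_task_paths = per_task,
    n_unique_paths = n_paths,
    verifications = verifications,
    package_version = as.character(utils::packageVersion("guhapaths"))
  )
  root <- sub("/+$", "", out_dir)
  out_files <- sort(setdiff(
    list.files(root, recursive = TRUE, full.names = TRUE),
    file.path(root, "manifest.json")
  ))
  md5 <- tools::md5sum(out_files)
  names(md5) <- substring(out_files, nchar(root) + 2L)
  manifest$output_md5 <- as.list(md5)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# most stringent frequency coefficient among the tasks that found each path
max_task_p <- function(sched, tasks) {
  p_by_label <- setNames(vapply(tasks, `[[`, numeric(1), "p"),
                         vapply(tasks, `[[`, character(1), "label"))
  if (!nrow(sched$paths)) return(numeric(0))
  vapply(strsplit(sched$paths$tasks, ";", fixed = TRUE),
         function(lbs) max(p_by_label[lbs]), numeric(1))
}
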