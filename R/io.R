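# File-format plumbing: cohort/life-table CSVs, coding and schedule
# configs, predicate-matrix export, path and frequency reports.

#' Read a cohort CSV
#'
#' Requires columns `id`, `sex`, `age`, `vital_status`, `years_survived`;
#' any further columns are treated as attributes.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age", "vital_status", "years_survived")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  cohort
}

#' Read a task schedule config
#'
#' YAML or JSON list of `{label, base, p, alpha, min_length, max_length,
#' row_filter}` entries; missing optional fields take [task_config()]
#' defaults.
#'
#' @param path Path to the config file.
#' @return A list of [task_config()] objects.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule config not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(raw, function(e) {
    task_config(label = e$label, base = e$base, p = e$p,
                alpha = e$alpha %||% 0.001,
                min_length = e$min_length %||% 1L,
                max_length = e$max_length %||% 5L,
                row_filter = e$row_filter)
  })
}

#' Export / import a predicate matrix
#'
#' The matrix is written as a 0/1 CSV with header `attribute::label` and a
#' JSON sidecar holding the column metadata and succedent.
#'
#' @param pm A [predicate_matrix()].
#' @param path_csv Path for the 0/1 CSV.
#' @param path_meta Path for the JSON sidecar.
#' @return `write_predicate_matrix()` returns the paths invisibly;
#'   `read_predicate_matrix()` returns a [predicate_matrix()].
#' @export
write_predicate_matrix <- function(pm, path_csv, path_meta) {
  stopifnot(inherits(pm, "predicate_matrix"))
  df <- as.data.frame(pm$values * 1L, check.names = FALSE)
  utils::write.csv(df, path_csv, row.names = FALSE)
  jsonlite::write_json(
    list(columns = pm$meta, succedent = pm$succedent),
    path_meta, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(c(path_csv, path_meta))
}

#' @rdname write_predicate_matrix
#' @export
read_predicate_matrix <- function(path_csv, path_meta) {
  if (!file.exists(path_csv)) stop("matrix file not found: ", path_csv)
  if (!file.exists(path_meta)) stop("matrix metadata not found: ", path_meta)
  df <- utils::read.csv(path_csv, check.names = FALSE)
  meta <- jsonlite::read_json(path_meta, simplifyVector = TRUE)
  values <- as.matrix(df) == 1L
  predicate_matrix(values, meta$columns$attribute, meta$succedent)
}

#' Write path and frequency reports
#'
#' `write_paths()` writes the deduplicated path list as TSV (one row per
#' path: `";"`-joined predicates, the table cells, achieved frequency
#' coefficient, Fisher p, tasks) and as JSON. `write_predicate_frequency()`
#' writes the per-task predicate-frequency table as TSV.
#'
#' @param x A `guha_schedule_result`.
#' @param path_tsv,path_json Output paths (JSON optional).
#' @return The paths, invisibly.
#' @export
write_paths <- function(x, path_tsv, path_json = NULL) {
  stopifnot(inherits(x, "guha_schedule_result"))
  utils::write.table(x$paths, path_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(paths = x$paths, per_task = as.list(x$per_task)),
      path_json, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(c(path_tsv, path_json))
}

#' @rdname write_paths
#' @param freq Output of [predicate_frequency()].
#' @export
write_predicate_frequency <- function(freq, path_tsv) {
  utils::write.table(freq, path_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path_tsv)
}

#' Write synthetic-cohort bundle to a directory
#'
#' Writes `cohort.csv`, `life_table.csv`, `coding.yaml` and
#' `ground_truth.json` for a generated synthetic cohort.
#'
#' @param gen A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_bundle <- function(gen, dir) {
  stopifnot(inherits(gen, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cohort = file.path(dir, "cohort.csv"),
    life_table = file.path(dir, "life_table.csv"),
    coding = file.path(dir, "coding.yaml"),
    truth = file.path(dir, "ground_truth.json")
  )
  utils::write.csv(gen$cohort, paths["cohort"], row.names = FALSE)
  utils::write.csv(as.data.frame(gen$life_table), paths["life_table"],
                   row.names = FALSE)
  yaml::write_yaml(codings_to_list(gen$codings), paths["coding"])
  truth <- gen$truth
  truth$spec <- unclass(truth$spec)
  truth$spec$planted_paths <- lapply(truth$spec$planted_paths, unclass)
  truth$psi <- as.integer(truth$psi)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

codings_to_list <- function(codings) {
  lapply(codings, function(cd) {
    list(attribute = cd$attribute, predicates = lapply(
      cd$predicates, function(p) {
        if (p$type == "categorical") {
          list(label = p$label, categories = as.list(p$categories))
        } else {
          list(label = p$label,
               interval = list(
                 if (is.finite(p$low)) p$low else NULL,
                 if (is.finite(p$high)) p$high else NULL
               ))
        }
      }
    ))
  })
}
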