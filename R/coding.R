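#' Attribute coding helpers
#'
#' An attribute coding splits one cohort attribute into 2-4 mutually
#' exclusive Boolean predicates, either by category sets (categorical
#' attributes) or by half-open numeric intervals `[low, high)` (numeric
#' attributes; use `-Inf`/`Inf` for open ends). Missing values leave all of
#' the attribute's predicate columns FALSE.
#'
#' @param attribute Attribute (column) name in the cohort table.
#' @param predicates A list of predicates built with [pred_cat()] or
#'   [pred_interval()].
#' @return A list of class `attribute_coding`.
#' @examples
#' attribute_coding("bmi", list(
#'   pred_interval("<20", -Inf, 20),
#'   pred_interval("20-<25", 20, 25),
#'   pred_interval("25-<30", 25, 30),
#'   pred_interval("30-", 30, Inf)
#' ))
#' @export
attribute_coding <- function(attribute, predicates) {
  stopifnot(is.character(attribute), length(attribute) == 1L,
            is.list(predicates))
  labels <- vapply(predicates, function(p) p$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate predicate labels in ", attribute)
  structure(list(attribute = attribute, predicates = predicates),
            class = "attribute_coding")
}

#' @rdname attribute_coding
#' @param label Predicate label (used in the column name
#'   `attribute::label`).
#' @param categories Character vector of raw values mapped to this
#'   predicate.
#' @export
pred_cat <- function(label, categories) {
  stopifnot(is.character(label), length(label) == 1L,
            length(categories) >= 1L)
  list(label = label, type = "categorical",
       categories = as.character(categories))
}

#' @rdname attribute_coding
#' @param low,high Interval bounds; the predicate is `low <= x < high`.
#' @export
pred_interval <- function(label, low, high) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(low), is.numeric(high), low < high)
  list(label = label, type = "interval", low = low, high = high)
}

#' Read an attribute-coding config
#'
#' Reads a YAML or JSON list of entries `{attribute, predicates:
#' [{label, categories} | {label, interval: [low, high]}]}` (extension
#' decides the parser). `null` interval ends map to `-Inf`/`Inf`.
#'
#' @param path Path to the config file.
#' @return A list of [attribute_coding()] objects.
#' @export
read_coding <- function(path) {
  if (!file.exists(path)) stop("coding config not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(raw, function(entry) {
    preds <- lapply(entry$predicates, function(p) {
      if (!is.null(p$interval)) {
        lo <- p$interval[[1]] %||% -Inf
        hi <- p$interval[[2]] %||% Inf
        pred_interval(p$label, as.numeric(lo), as.numeric(hi))
      } else {
        pred_cat(p$label, unlist(p$categories))
      }
    })
    attribute_coding(entry$attribute, preds)
  })
}

#' Validate attribute codings
#'
#' Report-only checks: the 2-4 predicates-per-attribute bound, pairwise
#' disjointness of category sets / intervals, interval coverage gaps, and
#' (when cohort data are supplied) observed values not covered by any
#' predicate.
#'
#' @param codings A list of [attribute_coding()] objects.
#' @param data Optional cohort data frame to check observed values against.
#' @return A `data.frame` with columns `attribute`, `issue`, `detail`
#'   (zero rows when nothing is flagged).
#' @export
validate_coding <- function(codings, data = NULL) {
  issues <- list()
  note <- function(attribute, issue, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      attribute = attribute, issue = issue, detail = detail,
      stringsAsFactors = FALSE
    )
  }
  for (cd in codings) {
    preds <- cd$predicates
    np <- length(preds)
    if (np < 2L || np > 4L) {
      note(cd$attribute, "predicate_count",
           sprintf("%d predicates (allowed 2-4)", np))
    }
    types <- vapply(preds, function(p) p$type, character(1))
    if (length(unique(types)) > 1L) {
      note(cd$attribute, "mixed_types", paste(types, collapse = ","))
    }
    if (all(types == "categorical")) {
      cats <- unlist(lapply(preds, function(p) p$categories))
      dup <- unique(cats[duplicated(cats)])
      if (length(dup)) {
        note(cd$attribute, "overlap",
             paste("categories in several predicates:",
                   paste(dup, collapse = ", ")))
      }
    } else if (all(types == "interval")) {
      lo <- vapply(preds, function(p) p$low, numeric(1))
      hi <- vapply(preds, function(p) p$high, numeric(1))
      o <- order(lo)
      lo <- lo[o]; hi <- hi[o]
      for (i in seq_len(np - 1L)) {
        if (hi[i] > lo[i + 1L]) {
          note(cd$attribute, "overlap",
               sprintf("[%g,%g) overlaps [%g,%g)",
                       lo[i], hi[i], lo[i + 1L], hi[i + 1L]))
        } else if (hi[i] < lo[i + 1L]) {
          note(cd$attribute, "gap",
               sprintf("values in [%g,%g) match no predicate",
                       hi[i], lo[i + 1L]))
        }
      }
    }
    if (!is.null(data) && cd$attribute %in% names(data)) {
      v <- data[[cd$attribute]]
      v <- v[!is.na(v)]
      covered <- Reduce(`|`, lapply(preds, predicate_match, values = v),
                        accumulate = FALSE)
      if (length(v) && any(!covered)) {
        note(cd$attribute, "uncovered_values",
             paste(unique(utils::head(v[!covered], 5)), collapse = ", "))
      }
    }
  }
  if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(attribute = character(0), issue = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  }
}

predicate_match <- function(pred, values) {
  if (pred$type == "categorical") {
    as.character(values) %in% pred$categories
  } else {
    v <- suppressWarnings(as.numeric(values))
    !is.na(v) & v >= pred$low & v < pred$high
  }
}

#' Construct a predicate matrix directly
#'
#' Low-level constructor mainly used by [binarize()] and in tests/synthetic
#' setups: wraps a logical matrix whose columns are predicates, with per
#' column attribute provenance and a designated succedent column.
#'
#' @param values Logical matrix (rows = participants, columns =
#'   predicates), with column names.
#' @param attributes Character vector: the source attribute of each column.
#' @param succedent Column name of the succedent (outcome) predicate.
#' @return An object of class `predicate_matrix`: a list with `values`,
#'   `meta` (data frame `column`, `attribute`, `label`, `is_outcome`) and
#'   `succedent`.
#' @export
predicate_matrix <- function(values, attributes, succedent) {
  stopifnot(is.matrix(values), is.logical(values),
            !is.null(colnames(values)),
            length(attributes) == ncol(values),
            succedent %in% colnames(values))
  if (anyNA(values)) stop("predicate matrix must not contain NA")
  if (anyDuplicated(colnames(values))) stop("duplicate predicate column names")
  labels <- sub("^[^:]*::", "", colnames(values))
  meta <- data.frame(
    column = colnames(values), attribute = as.character(attributes),
    label = labels, is_outcome = colnames(values) == succedent,
    stringsAsFactors = FALSE
  )
  # within one attribute's column group at most one TRUE per row
  for (at in unique(meta$attribute[!meta$is_outcome])) {
    grp <- meta$column[meta$attribute == at & !meta$is_outcome]
    if (length(grp) > 1L &&
        any(rowSums(values[, grp, drop = FALSE]) > 1L)) {
      stop("predicates of attribute '", at, "' overlap (two TRUE in one row)")
    }
  }
  structure(list(values = values, meta = meta, succedent = succedent),
            class = "predicate_matrix")
}

#' @export
print.predicate_matrix <- function(x, ...) {
  cat(sprintf(
    "predicate_matrix: %d rows x %d predicates (%d attributes), succedent '%s'\n",
    nrow(x$values), sum(!x$meta$is_outcome),
    length(unique(x$meta$attribute[!x$meta$is_outcome])), x$succedent
  ))
  invisible(x)
}

#' Binarize a cohort table into a predicate matrix
#'
#' Converts each coded attribute into its Boolean predicate columns (column
#' names `attribute::label`) and appends the succedent column
#' `premature_death::yes` taken from the outcome records. Interval
#' predicates are half-open `[low, high)`; missing raw values leave all of
#' an attribute's columns FALSE; a non-missing value covered by no
#' predicate is a coding-gap error.
#'
#' @param cohort Cohort data frame (one row per participant, `id` column
#'   required).
#' @param codings List of [attribute_coding()] objects.
#' @param outcomes Outcome records from [compute_outcomes()], aligned by
#'   `id`.
#' @return A [predicate_matrix()].
#' @export
binarize <- function(cohort, codings, outcomes) {
  stopifnot(is.data.frame(cohort), "id" %in% names(cohort),
            is.data.frame(outcomes),
            all(c("id", "premature") %in% names(outcomes)))
  ord <- match(cohort$id, outcomes$id)
  if (anyNA(ord)) stop("outcomes missing for ids: ",
                       paste(utils::head(cohort$id[is.na(ord)], 5),
                             collapse = ", "))
  val <- validate_coding(codings)
  hard <- val[val$issue %in% c("overlap", "predicate_count", "mixed_types"), ]
  if (nrow(hard)) {
    stop("invalid coding config: ",
         paste(sprintf("%s [%s: %s]", hard$attribute, hard$issue, hard$detail),
               collapse = "; "))
  }
  if (any(val$issue == "gap")) {
    warning("coding has interval gaps: ",
            paste(unique(val$attribute[val$issue == "gap"]), collapse = ", "))
  }
  n <- nrow(cohort)
  cols <- list()
  attrs <- character(0)
  for (cd in codings) {
    if (!cd$attribute %in% names(cohort)) {
      stop("coded attribute not in cohort table: ", cd$attribute)
    }
    v <- cohort[[cd$attribute]]
    colgrp <- vapply(cd$predicates, function(p) {
      out <- predicate_match(p, v)
      out[is.na(v)] <- FALSE
      out
    }, logical(n))
    if (n == 1L) colgrp <- matrix(colgrp, nrow = 1L)
    hit <- rowSums(colgrp)
    bad <- which(!is.na(v) & hit == 0L)
    if (length(bad)) {
      stop(sprintf("coding gap: attribute '%s' value '%s' matches no predicate",
                   cd$attribute, as.character(v[bad[1]])))
    }
    colnames(colgrp) <- paste0(cd$attribute, "::",
                               vapply(cd$predicates, `[[`, character(1),
                                      "label"))
    cols[[length(cols) + 1L]] <- colgrp
    attrs <- c(attrs, rep(cd$attribute, ncol(colgrp)))
  }
  psi <- matrix(outcomes$premature[ord], ncol = 1,
                dimnames = list(NULL, "premature_death::yes"))
  values <- cbind(do.call(cbind, cols), psi)
  predicate_matrix(values, c(attrs, "premature_death"),
                   succedent = "premature_death::yes")
}
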