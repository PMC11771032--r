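#' Mining task configuration
#'
#' One GUHA mining run is parameterized by the minimum support `base`
#' (least admissible `a`), the Above Average frequency coefficient `p`, the
#' Fisher level `alpha`, antecedent length bounds, and an optional row
#' filter (e.g. a sex stratum).
#'
#' @param label Task name (unique within a schedule).
#' @param base Positive integer minimum support.
#' @param p Frequency coefficient, real > 0.
#' @param alpha Fisher level in (0, 0.5]; default 0.001.
#' @param min_length,max_length Antecedent length bounds, `1 <= min <= max
#'   <= 5`.
#' @param row_filter Optional: a predicate column name (rows where it is
#'   TRUE are kept) or a logical row mask.
#' @return A list of class `task_config`.
#' @export
task_config <- function(label, base, p, alpha = 0.001,
                        min_length = 1L, max_length = 5L, row_filter = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is_count(base) || base < 1) stop("base must be a positive integer")
  if (!is_scalar_number(p) || p <= 0) stop("p must be a real > 0")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 0.5) {
    stop("alpha must lie in (0, 0.5]")
  }
  if (!is_count(min_length) || !is_count(max_length) ||
      min_length < 1 || min_length > max_length || max_length > 5) {
    stop("need 1 <= min_length <= max_length <= 5")
  }
  structure(list(label = label, base = as.integer(base), p = p, alpha = alpha,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 row_filter = row_filter),
            class = "task_config")
}

resolve_row_filter <- function(pm, row_filter) {
  if (is.null(row_filter)) return(rep(TRUE, nrow(pm$values)))
  if (is.character(row_filter)) {
    stopifnot(length(row_filter) == 1L)
    if (!row_filter %in% colnames(pm$values)) {
      stop("row_filter column not in predicate matrix: ", row_filter)
    }
    return(pm$values[, row_filter])
  }
  if (is.logical(row_filter)) {
    stopifnot(length(row_filter) == nrow(pm$values))
    return(row_filter)
  }
  stop("row_filter must be NULL, a column name, or a logical mask")
}

#' Enumerate candidate antecedent conjunctions
#'
#' Walks conjunctions of predicate columns depth-first in lexicographic
#' order of column indices, never combining two predicates of one
#' attribute, and (when `prune = TRUE`) cutting any branch whose phi-count
#' `a + b` falls below `base` -- supersets of an unsupported conjunction
#' cannot reach `a >= base`.
#'
#' @param pm A [predicate_matrix()].
#' @param min_length,max_length Length window of emitted conjunctions.
#' @param base Support threshold used for pruning (default 1).
#' @param prune Apply support pruning (default TRUE).
#' @param row_filter Optional row filter as in [task_config()].
#' @return Character vector of conjunctions, predicate column names joined
#'   by `";"`, in DFS preorder.
#' @export
enumerate_antecedents <- function(pm, min_length = 1L, max_length = 5L,
                                  base = 1L, prune = TRUE, row_filter = NULL) {
  stopifnot(inherits(pm, "predicate_matrix"))
  keep <- resolve_row_filter(pm, row_filter)
  vals <- pm$values[keep, , drop = FALSE]
  acols <- pm$meta$column[!pm$meta$is_outcome]
  if (!length(acols)) stop("predicate matrix has no antecedent columns")
  attr_of <- pm$meta$attribute[!pm$meta$is_outcome]
  out <- new.env(parent = emptyenv())
  out$keys <- character(0)
  recurse <- function(idx, chosen, cand) {
    for (i in seq_along(cand)) {
      ci <- cand[i]
      nidx <- idx[vals[idx, acols[ci]]]
      depth <- length(chosen) + 1L
      key <- c(chosen, acols[ci])
      if (depth >= min_length && depth <= max_length) {
        out$keys <- c(out$keys, paste(key, collapse = ";"))
      }
      if (depth < max_length && length(nidx) &&
          (!prune || length(nidx) >= base)) {
        nxt <- cand[-seq_len(i)]
        nxt <- nxt[attr_of[nxt] != attr_of[ci]]
        if (length(nxt)) recurse(nidx, key, nxt)
      }
    }
  }
  recurse(seq_len(nrow(vals)), character(0), seq_along(acols))
  out$keys
}

#' Run one mining task
#'
#' Enumerates admissible antecedent conjunctions (up to five predicates,
#' at most one per attribute) over the predicate matrix and returns every
#' conjunction whose four-fold table against the succedent passes both the
#' Above Average quantifier ([above_average_truth()]) and the Fisher
#' quantifier ([fisher_truth()]) under the task configuration.
#'
#' Support pruning (Apriori-style) is sound: the phi-count `a + b` is
#' non-increasing under conjunction extension and a path needs
#' `a >= base`, so no true path is lost; `prune = FALSE` explores the full
#' space and must return the identical path set.
#'
#' @param pm A [predicate_matrix()].
#' @param config A [task_config()].
#' @param prune Apply support pruning (default TRUE).
#' @return A list of class `guha_task_result`: `label`, `config`, `paths`
#'   (data frame: `antecedent`, `length`, `a`, `b`, `c`, `d`,
#'   `freq_coefficient`, `fisher_p`), `verifications` (tables evaluated,
#'   including internal nodes below `min_length`), `pruned` (branches cut
#'   by support), `n_rows`, `n_predicates`.
#' @export
run_task <- function(pm, config, prune = TRUE) {
  stopifnot(inherits(pm, "predicate_matrix"), inherits(config, "task_config"))
  keep <- resolve_row_filter(pm, config$row_filter)
  vals <- pm$values[keep, , drop = FALSE]
  m <- nrow(vals)
  if (m == 0L) stop("row filter leaves no rows")
  psi <- vals[, pm$succedent]
  acols <- pm$meta$column[!pm$meta$is_outcome]
  if (!length(acols)) stop("predicate matrix has no antecedent columns")
  attr_of <- pm$meta$attribute[!pm$meta$is_outcome]
  k <- sum(psi)
  base <- config$base; p <- config$p; alpha <- config$alpha
  minL <- config$min_length; maxL <- config$max_length
  st <- new.env(parent = emptyenv())
  st$verif <- 0; st$pruned <- 0; st$paths <- vector("list", 64L); st$np <- 0L

  recurse <- function(idx, chosen, cand) {
    sub <- vals[idx, acols[cand], drop = FALSE]
    nphi <- .colSums(sub, length(idx), length(cand))
    na <- .colSums(sub & psi[idx], length(idx), length(cand))
    st$verif <- st$verif + length(cand)
    depth <- length(chosen) + 1L
    in_window <- depth >= minL && depth <= maxL
    # Above Average in multiplied-out form, vectorized over the children;
    # same boundary tolerance as above_average_truth()
    lhs <- na * m
    rhs <- (1 + p) * k * nphi
    pass_aa <- (na >= base) & (nphi > 0) &
      (lhs >= rhs - 1e-12 * pmax(lhs, rhs))
    for (i in seq_along(cand)) {
      ci <- cand[i]
      if (in_window && pass_aa[i]) {
        aa <- na[i]; bb <- nphi[i] - aa
        cc <- k - aa; dd <- m - nphi[i] - cc
        if (aa * dd > bb * cc) {
          pv <- fisher_upper_tail(aa, bb, cc, dd)
          if (pv <= alpha) {
            st$np <- st$np + 1L
            if (st$np > length(st$paths)) {
              st$paths <- c(st$paths, vector("list", length(st$paths)))
            }
            st$paths[[st$np]] <- list(
              antecedent = paste(c(chosen, acols[ci]), collapse = ";"),
              length = depth, a = aa, b = bb, c = cc, d = dd,
              freq_coefficient = (aa / nphi[i]) / (k / m) - 1,
              fisher_p = pv
            )
          }
        }
      }
      if (depth < maxL) {
        if (nphi[i] == 0) next
        if (prune && nphi[i] < base) {
          st$pruned <- st$pruned + 1
          next
        }
        nxt <- cand[-seq_len(i)]
        nxt <- nxt[attr_of[nxt] != attr_of[ci]]
        if (length(nxt)) {
          recurse(idx[sub[, i]], c(chosen, acols[ci]), nxt)
        }
      }
    }
  }
  recurse(seq_len(m), character(0), seq_along(acols))

  paths <- if (st$np > 0L) {
    recs <- st$paths[seq_len(st$np)]
    data.frame(
      antecedent = vapply(recs, `[[`, character(1), "antecedent"),
      length = vapply(recs, `[[`, numeric(1), "length"),
      a = vapply(recs, `[[`, numeric(1), "a"),
      b = vapply(recs, `[[`, numeric(1), "b"),
      c = vapply(recs, `[[`, numeric(1), "c"),
      d = vapply(recs, `[[`, numeric(1), "d"),
      freq_coefficient = vapply(recs, `[[`, numeric(1), "freq_coefficient"),
      fisher_p = vapply(recs, `[[`, numeric(1), "fisher_p"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(antecedent = character(0), length = numeric(0),
               a = numeric(0), b = numeric(0), c = numeric(0), d = numeric(0),
               freq_coefficient = numeric(0), fisher_p = numeric(0),
               stringsAsFactors = FALSE)
  }
  structure(list(label = config$label, config = config, paths = paths,
                 verifications = st$verif, pruned = st$pruned,
                 n_rows = m, n_predicates = length(acols)),
            class = "guha_task_result")
}

#' @export
print.guha_task_result <- function(x, ...) {
  cat(sprintf(
    "task '%s' (base %d, p %g, alpha %g, length %d..%d): %d paths, %g verifications, %g pruned\n",
    x$label, x$config$base, x$config$p, x$config$alpha, x$config$min_length,
    x$config$max_length, nrow(x$paths), x$verifications, x$pruned
  ))
  invisible(x)
}

#' Run a schedule of mining tasks
#'
#' Runs each task and merges the results into one deduplicated path list
#' keyed by antecedent set; a path found by several tasks is a single row
#' listing all of them. Task labels must be unique.
#'
#' @param pm A [predicate_matrix()].
#' @param tasks List of [task_config()] objects.
#' @param prune Apply support pruning (default TRUE).
#' @return A list of class `guha_schedule_result`: `paths` (the dedup data
#'   frame with a `tasks` column, `";"`-joined labels), `per_task` (named
#'   path counts), `task_results` (the individual `guha_task_result`s).
#' @export
run_schedule <- function(pm, tasks, prune = TRUE) {
  stopifnot(length(tasks) >= 1L,
            all(vapply(tasks, inherits, logical(1), "task_config")))
  labels <- vapply(tasks, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate task labels in schedule")
  results <- lapply(tasks, function(tc) run_task(pm, tc, prune = prune))
  names(results) <- labels
  merged <- NULL
  found_in <- list()
  for (lb in labels) {
    pt <- results[[lb]]$paths
    if (!nrow(pt)) next
    for (key in pt$antecedent) {
      found_in[[key]] <- c(found_in[[key]], lb)
    }
    new <- pt[!(pt$antecedent %in% merged$antecedent), , drop = FALSE]
    merged <- rbind(merged, new)
  }
  if (is.null(merged)) {
    merged <- results[[1]]$paths # empty frame with the right columns
    merged$tasks <- character(0)
  } else {
    merged$tasks <- vapply(merged$antecedent, function(key) {
      paste(found_in[[key]], collapse = ";")
    }, character(1))
    rownames(merged) <- NULL
  }
  per_task <- vapply(results, function(r) nrow(r$paths), numeric(1))
  structure(list(paths = merged, per_task = per_task,
                 task_results = results),
            class = "guha_schedule_result")
}

#' @export
print.guha_schedule_result <- function(x, ...) {
  cat(sprintf("schedule: %d unique paths across %d tasks\n",
              nrow(x$paths), length(x$task_results)))
  print(x$per_task)
  invisible(x)
}

#' Predicate frequencies across mined paths
#'
#' Counts, for each predicate, the number of unique paths containing it,
#' overall and per task (a path found by several tasks counts once in the
#' total and once in each of those tasks' columns).
#'
#' @param x A `guha_schedule_result` from [run_schedule()].
#' @return A `data.frame` with columns `predicate`, one count column per
#'   task label, and `total`, sorted by decreasing `total`.
#' @export
predicate_frequency <- function(x) {
  stopifnot(inherits(x, "guha_schedule_result"))
  labels <- names(x$task_results)
  split_preds <- function(keys) strsplit(keys, ";", fixed = TRUE)
  all_preds <- sort(unique(unlist(split_preds(x$paths$antecedent))))
  if (!length(all_preds)) {
    out <- data.frame(predicate = character(0), stringsAsFactors = FALSE)
    for (lb in labels) out[[lb]] <- numeric(0)
    out$total <- numeric(0)
    return(out)
  }
  count_in <- function(keys) {
    tab <- table(unlist(split_preds(keys)))
    out <- setNames(rep(0, length(all_preds)), all_preds)
    out[names(tab)] <- as.numeric(tab)
    out
  }
  out <- data.frame(predicate = all_preds, stringsAsFactors = FALSE)
  for (lb in labels) {
    out[[lb]] <- count_in(x$task_results[[lb]]$paths$antecedent)
  }
  out$total <- count_in(x$paths$antecedent)
  out <- out[order(-out$total, out$predicate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a schedule per stratum of one attribute
#'
#' Applies, for each predicate of the stratum attribute (e.g. `sex::male`,
#' `sex::female`), a row filter selecting that stratum and runs the full
#' schedule inside it. The stratum attribute's own columns are removed from
#' the antecedent pool (they are constant within a stratum). A stratum with
#' zero rows is a validation error.
#'
#' @param pm A [predicate_matrix()].
#' @param tasks List of [task_config()] objects.
#' @param stratum_attribute Attribute name that is binarized in `pm`.
#' @param strata_labels Optional subset of the attribute's predicate labels
#'   to run.
#' @param prune Apply support pruning (default TRUE).
#' @return Named list (by predicate label) of `guha_schedule_result`s.
#' @export
stratified_run <- function(pm, tasks, stratum_attribute,
                           strata_labels = NULL, prune = TRUE) {
  stopifnot(inherits(pm, "predicate_matrix"))
  meta <- pm$meta
  rows <- meta[meta$attribute == stratum_attribute & !meta$is_outcome, ,
               drop = FALSE]
  if (!nrow(rows)) stop("stratum attribute not in matrix: ", stratum_attribute)
  if (!is.null(strata_labels)) {
    rows <- rows[rows$label %in% strata_labels, , drop = FALSE]
    if (!nrow(rows)) stop("no matching strata for given labels")
  }
  keep_cols <- meta$column[meta$attribute != stratum_attribute]
  sub_pm <- predicate_matrix(
    pm$values[, keep_cols, drop = FALSE],
    meta$attribute[meta$attribute != stratum_attribute],
    succedent = pm$succedent
  )
  out <- list()
  for (i in seq_len(nrow(rows))) {
    mask <- pm$values[, rows$column[i]]
    if (!any(mask)) {
      stop("stratum '", rows$column[i], "' has zero rows")
    }
    stratum_tasks <- lapply(tasks, function(tc) {
      tc$row_filter <- mask
      tc
    })
    out[[rows$label[i]]] <- run_schedule(sub_pm, stratum_tasks, prune = prune)
  }
  out
}
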