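#' Posterior characterization of a path's prevalence ratio
#'
#' Beta-Binomial Monte-Carlo reconstruction: with independent uniform
#' Beta(1, 1) priors, the premature-death rate among antecedent rows,
#' `pi_phi`, has posterior Beta(a + 1, b + 1) and the rate among the
#' complement, `pi_nphi`, Beta(c + 1, d + 1). The quantity reported is the
#' prevalence ratio against the whole-matrix rate (the same denominator the
#' Above Average quantifier uses):
#' `rho = pi_phi / ((r * pi_phi + s * pi_nphi) / m)`.
#' Draws of `rho` give its posterior mean, an equal-tailed credible
#' interval, and the certainty `P(rho >= 1 + p_task)` that the path's
#' prevalence ratio exceeds the task's Above Average threshold.
#'
#' @param t A [fourfold_table()] with `a + b >= 1` and `c + d >= 1`.
#' @param p_task Frequency coefficient of the task the path came from; the
#'   exceedance probability targets `1 + p_task`.
#' @param level Credible level (default 0.95).
#' @param draws Number of Monte-Carlo draws (at least 10,000; default
#'   100,000).
#' @param seed Integer seed; draws are reproducible under a fixed seed and
#'   the caller's RNG state is untouched.
#' @return A list of class `path_posterior`: `ratio_mean`, `ci_low`,
#'   `ci_high`, `level`, `prob_exceeds`, `p_task`, `draws`, `seed`.
#' @examples
#' path_posterior(fourfold_table(50, 50, 50, 50), p_task = 0.5, seed = 1)
#' @export
path_posterior <- function(t, p_task, level = 0.95, draws = 1e5, seed) {
  stopifnot(inherits(t, "fourfold_table"))
  if (t$r < 1 || t$s < 1) {
    stop("degenerate margins: need a+b >= 1 and c+d >= 1")
  }
  if (!is_scalar_number(p_task) || p_task <= 0) stop("p_task must be > 0")
  if (!is_scalar_number(level) || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)")
  }
  if (!is_count(draws) || draws < 1e4) stop("draws must be an integer >= 10000")
  if (missing(seed)) stop("an explicit seed is required")
  rho <- with_seed(seed, {
    pf <- stats::rbeta(draws, t$a + 1, t$b + 1)
    pn <- stats::rbeta(draws, t$c + 1, t$d + 1)
    pf / ((t$r * pf + t$s * pn) / t$m)
  })
  qs <- stats::quantile(rho, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(ratio_mean = mean(rho), ci_low = qs[1], ci_high = qs[2],
                 level = level, prob_exceeds = mean(rho >= 1 + p_task),
                 p_task = p_task, draws = as.integer(draws),
                 seed = as.integer(seed)),
            class = "path_posterior")
}

#' @export
print.path_posterior <- function(x, ...) {
  cat(sprintf(
    "prevalence ratio: mean %.3f, %d%% CrI [%.3f, %.3f]; P(ratio >= %.2f) = %.4f (%d draws, seed %d)\n",
    x$ratio_mean, round(100 * x$level), x$ci_low, x$ci_high,
    1 + x$p_task, x$prob_exceeds, x$draws, x$seed
  ))
  invisible(x)
}

#' Posterior summaries for a set of mined paths
#'
#' Rebuilds each path's four-fold table from the predicate matrix
#' (re-verifying the stored counts) and applies [path_posterior()]. Each
#' path draws under its own derived seed `seed + row index`.
#'
#' @param paths A path data frame as in `guha_schedule_result$paths`
#'   (columns `antecedent`, `a`, `b`, `c`, `d`), or a
#'   `guha_schedule_result`.
#' @param pm The [predicate_matrix()] the paths were mined from.
#' @param p_task Scalar frequency coefficient, or a vector (one per path).
#' @param level,draws As in [path_posterior()].
#' @param seed Integer base seed.
#' @param row_filter Optional row filter used when the paths were mined.
#' @return A `data.frame`: one row per path with the posterior summary
#'   columns.
#' @export
paths_posterior <- function(paths, pm, p_task, level = 0.95, draws = 1e5,
                            seed, row_filter = NULL) {
  if (inherits(paths, "guha_schedule_result")) paths <- paths$paths
  stopifnot(is.data.frame(paths), inherits(pm, "predicate_matrix"))
  if (missing(seed)) stop("an explicit seed is required")
  n <- nrow(paths)
  p_task <- rep_len(p_task, n)
  keep <- resolve_row_filter(pm, row_filter)
  vals <- pm$values[keep, , drop = FALSE]
  psi <- vals[, pm$succedent]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    preds <- strsplit(paths$antecedent[i], ";", fixed = TRUE)[[1]]
    tbl <- build_table(vals[, preds, drop = FALSE], psi)
    if (!identical(c(tbl$a, tbl$b, tbl$c, tbl$d),
                   as.numeric(c(paths$a[i], paths$b[i],
                                paths$c[i], paths$d[i])))) {
      stop("stored counts do not re-verify for path: ", paths$antecedent[i])
    }
    ps <- path_posterior(tbl, p_task = p_task[i], level = level,
                         draws = draws, seed = seed + i)
    out[[i]] <- data.frame(
      antecedent = paths$antecedent[i], ratio_mean = ps$ratio_mean,
      ci_low = ps$ci_low, ci_high = ps$ci_high, level = ps$level,
      prob_exceeds = ps$prob_exceeds, p_task = ps$p_task,
      draws = ps$draws, seed = ps$seed, stringsAsFactors = FALSE
    )
  }
  if (n == 0L) {
    return(data.frame(antecedent = character(0), ratio_mean = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      level = numeric(0), prob_exceeds = numeric(0),
                      p_task = numeric(0), draws = integer(0),
                      seed = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
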