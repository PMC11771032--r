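#' Synthetic cohort specification
#'
#' Describes a cohort with the statistical structure the mining pipeline
#' assumes: categorical midlife attributes split into 2-4 categories, a sex
#' attribute, a premature-death outcome with a target marginal prevalence,
#' life-table-consistent survival times, and optional planted antecedent
#' conjunctions whose confidence is elevated to a target lift.
#'
#' Defaults emulate the published study conditions: 6,257 participants,
#' 55.3% women, premature-death prevalence 0.247, 80 attributes, a 29-year
#' censoring horizon, and a non-premature death rate among the
#' non-premature (0.138) that reproduces roughly 2,200 deaths of which
#' ~70% are premature.
#'
#' @param n Number of participants.
#' @param n_attributes Number of attributes including `sex`.
#' @param predicate_probs Probabilities of an attribute having 2, 3 or 4
#'   categories (named `"2"`, `"3"`, `"4"`).
#' @param baseline_prevalence Marginal premature-death probability absent
#'   planted effects.
#' @param planted_paths List of [planted_path()] specifications; attribute
#'   sets must be pairwise disjoint.
#' @param sex_mix Fraction female.
#' @param censor_years Follow-up horizon in years.
#' @param nonpremature_death_rate Probability that a non-premature
#'   participant dies (within the buffer window before their life
#'   expectancy) rather than being censored alive.
#' @param age_mean,age_sd,age_range Baseline-age distribution: a normal
#'   truncated to `[age_range[1], age_range[2])`.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 6257, n_attributes = 80,
                           predicate_probs = c("2" = 0.10, "3" = 0.25,
                                               "4" = 0.65),
                           baseline_prevalence = 0.247,
                           planted_paths = list(), sex_mix = 0.553,
                           censor_years = 29,
                           nonpremature_death_rate = 0.138,
                           age_mean = 50.5, age_sd = 3.6,
                           age_range = c(44, 59)) {
  stopifnot(is_count(n), n >= 10, is_count(n_attributes), n_attributes >= 2,
            length(predicate_probs) == 3L, all(predicate_probs >= 0),
            sum(predicate_probs) > 0,
            is_scalar_number(baseline_prevalence),
            baseline_prevalence > 0, baseline_prevalence < 1,
            is_scalar_number(sex_mix), sex_mix > 0, sex_mix < 1,
            is_scalar_number(censor_years), censor_years > 1,
            is_scalar_number(nonpremature_death_rate),
            nonpremature_death_rate >= 0, nonpremature_death_rate <= 1)
  used <- character(0)
  for (pp in planted_paths) {
    stopifnot(inherits(pp, "planted_path"))
    if (pp$lift * baseline_prevalence > 1) {
      stop("infeasible planted path: lift * baseline_prevalence > 1")
    }
    if (pp$carrier_fraction * n < 1) {
      stop("infeasible planted path: carrier_fraction * n < 1")
    }
    if (!is.null(pp$attributes)) {
      if (any(pp$attributes %in% used)) {
        stop("planted paths must use pairwise disjoint attribute sets")
      }
      used <- c(used, pp$attributes)
    }
  }
  structure(list(n = as.integer(n), n_attributes = as.integer(n_attributes),
                 predicate_probs = predicate_probs,
                 baseline_prevalence = baseline_prevalence,
                 planted_paths = planted_paths, sex_mix = sex_mix,
                 censor_years = censor_years,
                 nonpremature_death_rate = nonpremature_death_rate,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range),
            class = "synthetic_spec")
}

#' Planted antecedent conjunction
#'
#' A conjunction of up to five predicates (one category of each of up to
#' five distinct attributes) planted in a synthetic cohort: a fraction
#' `carrier_fraction` of rows is made to satisfy the conjunction exactly
#' (coincidental satisfiers outside the carrier set are re-drawn away, so
#' `carrier_fraction` is P(phi)), and carriers receive premature-death
#' probability `lift * baseline_prevalence` while the rest of the cohort is
#' recalibrated to keep the marginal at the baseline.
#'
#' @param lift Target lift (> 1) of the conjunction against the marginal
#'   prevalence.
#' @param carrier_fraction Fraction of rows satisfying the conjunction.
#' @param length Number of predicates (1-5), used when `attributes` is
#'   NULL.
#' @param attributes Optional attribute names (distinct); defaults to the
#'   first free non-sex attributes.
#' @param categories Optional category per attribute; defaults to the first
#'   category of each.
#' @param stratum Optional named character like `c(sex = "female")`:
#'   carriers are drawn inside that stratum only.
#' @return A list of class `planted_path`.
#' @export
planted_path <- function(lift, carrier_fraction, length = 5L,
                         attributes = NULL, categories = NULL,
                         stratum = NULL) {
  stopifnot(is_scalar_number(lift), lift > 1,
            is_scalar_number(carrier_fraction),
            carrier_fraction > 0, carrier_fraction < 1,
            is_count(length), length >= 1, length <= 5)
  if (!is.null(attributes)) {
    stopifnot(!anyDuplicated(attributes), length(attributes) <= 5)
    length <- length(attributes)
    if (!is.null(categories)) stopifnot(length(categories) == length)
  }
  if (!is.null(stratum)) {
    stopifnot(is.character(stratum), !is.null(names(stratum)),
              length(stratum) == 1L)
  }
  structure(list(lift = lift, carrier_fraction = carrier_fraction,
                 length = as.integer(length), attributes = attributes,
                 categories = categories, stratum = stratum),
            class = "planted_path")
}

# Piecewise-linear period life table over the baseline age range, female
# expectancies above male as in national tables.
synthetic_life_table <- function(age_range = c(44, 59)) {
  ages <- seq(floor(age_range[1]), ceiling(age_range[2]) - 1L)
  as_life_table(data.frame(
    sex = rep(c("male", "female"), each = length(ages)),
    age = rep(ages, 2L),
    ex = c(27.0 - 0.5 * (ages - 44), 33.5 - 0.5 * (ages - 44))
  ))
}

#' Generate a synthetic cohort
#'
#' Draws attributes independently and uniformly per category (except where
#' planted conjunctions force joint placement), plants each planted path at
#' exactly its carrier fraction, assigns the premature-death indicator with
#' probability `lift * baseline_prevalence` for carriers and a recalibrated
#' rate elsewhere so the marginal matches the baseline, and back-constructs
#' survival times and a period life table so that [compute_outcomes()] at
#' the 9-month buffer reproduces the assigned outcome exactly (premature
#' deaths get excess > 0.76 years; non-premature deaths die within
#' (-3, 0.74) years of their life expectancy; the rest are censored alive).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; identical (spec, seed) pairs give identical
#'   output.
#' @return A list of class `synthetic_cohort`: `cohort` (data frame),
#'   `life_table`, `codings` (list of [attribute_coding()]), `truth`
#'   (planted conjunctions with their predicate column names and realized
#'   carrier counts, the assigned outcome, seed and spec).
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (missing(seed)) stop("an explicit seed is required")
  with_seed(seed, {
    n <- spec$n
    n_other <- spec$n_attributes - 1L
    ncat <- sample(2:4, n_other, replace = TRUE,
                   prob = spec$predicate_probs / sum(spec$predicate_probs))
    attr_names <- sprintf("attr%03d", seq_len(n_other))
    df <- data.frame(
      sex = sample(c("female", "male"), n, replace = TRUE,
                   prob = c(spec$sex_mix, 1 - spec$sex_mix)),
      stringsAsFactors = FALSE
    )
    for (j in seq_len(n_other)) {
      df[[attr_names[j]]] <- sample(paste0("c", seq_len(ncat[j])), n,
                                    replace = TRUE)
    }

    # resolve and plant conjunctions
    free <- attr_names
    planted <- list()
    for (pp in spec$planted_paths) {
      attrs <- pp$attributes
      if (is.null(attrs)) {
        attrs <- free[seq_len(pp$length)]
      }
      free <- setdiff(free, attrs)
      cats <- pp$categories %||% rep("c1", length(attrs))
      eligible <- seq_len(n)
      if (!is.null(pp$stratum)) {
        eligible <- which(df[[names(pp$stratum)]] == pp$stratum)
      }
      n_car <- round(pp$carrier_fraction * n)
      if (n_car > length(eligible)) {
        stop("stratum too small for requested carrier fraction")
      }
      carriers <- sample(eligible, n_car)
      for (i in seq_along(attrs)) df[carriers, attrs[i]] <- cats[i]
      # carrier_fraction is P(phi): redraw coincidental satisfiers
      sat <- rowSums(mapply(function(at, ct) df[[at]] == ct,
                            attrs, cats)) == length(attrs)
      if (!is.null(pp$stratum)) {
        # satisfaction outside the stratum is also redrawn away
        extra <- setdiff(which(sat), carriers)
      } else {
        extra <- setdiff(which(sat), carriers)
      }
      if (length(extra)) {
        k1 <- ncat[match(attrs[1], attr_names)]
        others <- setdiff(paste0("c", seq_len(k1)), cats[1])
        df[extra, attrs[1]] <- sample(others, length(extra), replace = TRUE)
      }
      planted[[length(planted) + 1L]] <- list(
        attributes = attrs, categories = cats,
        predicates = paste0(attrs, "::", cats),
        lift = pp$lift, carrier_fraction = pp$carrier_fraction,
        carriers = sort(carriers), stratum = pp$stratum
      )
    }

    # outcome: carriers at lift * pi0, everyone else recalibrated so the
    # marginal stays at the baseline prevalence
    pi0 <- spec$baseline_prevalence
    rate <- rep(NA_real_, n)
    for (pl in planted) {
      r <- pl$lift * pi0
      idx <- pl$carriers
      rate[idx] <- pmax(rate[idx], r, na.rm = TRUE)
    }
    covered <- !is.na(rate)
    pi_nc <- (pi0 * n - sum(rate[covered])) / (n - sum(covered))
    if (is.nan(pi_nc) || pi_nc < 0 || pi_nc > 1) {
      stop("infeasible spec: recalibrated background rate outside [0, 1]")
    }
    rate[!covered] <- pi_nc
    psi <- stats::rbinom(n, 1L, rate) == 1L

    # ages: truncated normal on [age_range)
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    while (any(bad <- age < spec$age_range[1] | age >= spec$age_range[2])) {
      age[bad] <- stats::rnorm(sum(bad), spec$age_mean, spec$age_sd)
    }

    lt <- synthetic_life_table(spec$age_range)
    ale <- lookup_ale(lt, df$sex, age)

    # survival back-construction (buffer 9 months = 0.75 years)
    years <- rep(spec$censor_years, n)
    vital <- rep("alive_at_censor", n)
    i1 <- which(psi)
    if (length(i1)) {
      lo <- pmax(0.76, ale[i1] - spec$censor_years)
      e <- stats::runif(length(i1), lo, ale[i1])
      years[i1] <- ale[i1] - e
      vital[i1] <- "died"
    }
    i0 <- which(!psi)
    if (length(i0)) {
      u <- stats::runif(length(i0), -3, 0.74)
      wants_death <- stats::runif(length(i0)) < spec$nonpremature_death_rate
      feasible <- (ale[i0] - u) <= spec$censor_years & (ale[i0] - u) >= 0
      dies <- wants_death & feasible
      years[i0[dies]] <- ale[i0][dies] - u[dies]
      vital[i0[dies]] <- "died"
    }

    cohort <- data.frame(
      id = sprintf("P%05d", seq_len(n)), sex = df$sex, age = age,
      vital_status = vital, years_survived = years,
      stringsAsFactors = FALSE
    )
    for (at in attr_names) cohort[[at]] <- df[[at]]

    codings <- c(
      list(attribute_coding("sex", list(pred_cat("male", "male"),
                                        pred_cat("female", "female")))),
      lapply(seq_len(n_other), function(j) {
        attribute_coding(attr_names[j], lapply(
          paste0("c", seq_len(ncat[j])),
          function(ct) pred_cat(ct, ct)
        ))
      })
    )

    structure(list(
      cohort = cohort, life_table = lt, codings = codings,
      truth = list(planted = planted, psi = psi,
                   baseline_prevalence = pi0,
                   realized_prevalence = mean(psi),
                   background_rate = pi_nc,
                   seed = as.integer(seed), spec = spec)
    ), class = "synthetic_cohort")
  })
}

#' Realized properties of planted conjunctions
#'
#' Recomputes, from the generated cohort, each planted conjunction's
#' four-fold table against the premature-death outcome (classified at the
#' given buffer), its empirical lift / frequency coefficient, and whether
#' it passes a task's (base, p, alpha) thresholds -- the bridge between the
#' generator's ground truth and the miner.
#'
#' @param gen A `synthetic_cohort` from [generate_cohort()].
#' @param base,p,alpha Task thresholds to check against.
#' @param buffer_months Buffer for the outcome classification (default 9).
#' @return A `data.frame`: one row per planted conjunction with columns
#'   `predicates`, `a`, `b`, `c`, `d`, `lift`, `target_lift`,
#'   `freq_coefficient`, `fisher_p`, `pass_above_average`, `pass_fisher`,
#'   `passes`.
#' @export
realized_truth <- function(gen, base, p, alpha, buffer_months = 9) {
  stopifnot(inherits(gen, "synthetic_cohort"))
  outcomes <- compute_outcomes(gen$cohort, gen$life_table,
                               buffer_months = buffer_months)
  psi <- outcomes$premature
  planted <- gen$truth$planted
  out <- lapply(planted, function(pl) {
    sat <- rowSums(mapply(function(at, ct) gen$cohort[[at]] == ct,
                          pl$attributes, pl$categories)) ==
      length(pl$attributes)
    tbl <- build_table(sat, psi)
    fc <- frequency_coefficient(tbl)
    aa <- above_average_truth(tbl, p = p, base = base)
    fp <- fisher_pvalue(tbl)
    ft <- fisher_truth(tbl, alpha = alpha)
    data.frame(
      predicates = paste(pl$predicates, collapse = ";"),
      a = tbl$a, b = tbl$b, c = tbl$c, d = tbl$d,
      lift = fc + 1, target_lift = pl$lift,
      freq_coefficient = fc, fisher_p = fp,
      pass_above_average = aa, pass_fisher = ft, passes = aa && ft,
      stringsAsFactors = FALSE
    )
  })
  if (!length(out)) {
    return(data.frame(predicates = character(0), a = numeric(0),
                      b = numeric(0), c = numeric(0), d = numeric(0),
                      lift = numeric(0), target_lift = numeric(0),
                      freq_coefficient = numeric(0), fisher_p = numeric(0),
                      pass_above_average = logical(0),
                      pass_fisher = logical(0), passes = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
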