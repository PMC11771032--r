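#' Read a period life table
#'
#' Expects a CSV with columns `sex` (`male`/`female`), `age` (completed age
#' in years) and `ex` (remaining life expectancy in years).
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with columns `sex`, `age`, `ex` (class
#'   `life_table`).
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life-table file not found: ", path)
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_life_table(lt)
}

#' Validate a life-table data frame
#'
#' @param lt A data frame with columns `sex`, `age`, `ex`.
#' @return The validated data frame with class `life_table`.
#' @export
as_life_table <- function(lt) {
  stopifnot(is.data.frame(lt))
  need <- c("sex", "age", "ex")
  miss <- setdiff(need, names(lt))
  if (length(miss)) stop("life table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(lt$sex %in% c("male", "female"))) {
    stop("life-table sex must be 'male' or 'female'")
  }
  if (anyNA(lt$age) || anyNA(lt$ex)) stop("life table contains missing values")
  if (any(lt$ex < 0)) stop("life expectancy (ex) must be nonnegative")
  if (anyDuplicated(paste(lt$sex, lt$age))) {
    stop("duplicated (sex, age) entries in life table")
  }
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Look up actuarial life expectancy
#'
#' Returns the remaining life expectancy for each participant's sex and
#' completed age (the floor of `age`), as period life tables are indexed by
#' completed age.
#'
#' @param life_table A life table from [read_life_table()] or
#'   [as_life_table()].
#' @param sex Character vector, `male`/`female`.
#' @param age Numeric vector of ages at baseline in years.
#' @return Numeric vector of remaining life expectancies (years).
#' @examples
#' lt <- as_life_table(data.frame(sex = "female", age = 50, ex = 33))
#' lookup_ale(lt, "female", 50.7) # 33
#' @export
lookup_ale <- function(life_table, sex, age) {
  life_table <- as_life_table(as.data.frame(life_table))
  stopifnot(length(sex) == length(age))
  if (any(is.na(age)) || any(age < 0)) stop("age must be nonnegative and known")
  key <- paste(sex, floor(age))
  idx <- match(key, paste(life_table$sex, life_table$age))
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("no life-table entry for (sex, completed age): ",
         paste0("(", sub(" ", ", ", bad), ")", collapse = ", "))
  }
  life_table$ex[idx]
}

#' Classify deaths as premature
#'
#' A death is premature when it occurs at least the buffer period before
#' the participant's actuarial life expectancy: `excess = ale -
#' years_survived >= buffer_months / 12`. A death exactly at the buffer is
#' premature; deaths less than the buffer before the life expectancy are
#' not. Participants alive at censoring are never premature.
#'
#' @param vital_status Character vector, `died` or `alive_at_censor`.
#' @param years_survived Nonnegative numeric vector: years from baseline to
#'   death, or to the censor date for the living.
#' @param ale Numeric vector of actuarial life expectancies at baseline
#'   (years), e.g. from [lookup_ale()].
#' @param buffer_months Positive integer buffer in months (1..120;
#'   default 9). `buffer_years = buffer_months / 12` exactly.
#' @return A `data.frame` with columns `excess` (years; `NA` for the
#'   living) and `premature` (logical).
#' @examples
#' classify_premature("died", 20, 26.30) # excess 6.30, premature
#' @export
classify_premature <- function(vital_status, years_survived, ale,
                               buffer_months = 9) {
  if (!is_count(buffer_months) || buffer_months < 1 || buffer_months > 120) {
    stop("buffer_months must be an integer in 1..120")
  }
  n <- length(vital_status)
  stopifnot(length(years_survived) == n, length(ale) == n)
  if (!all(vital_status %in% c("died", "alive_at_censor"))) {
    stop("vital_status must be 'died' or 'alive_at_censor'")
  }
  if (anyNA(years_survived) || any(years_survived < 0)) {
    stop("years_survived must be nonnegative and known")
  }
  died <- vital_status == "died"
  excess <- ifelse(died, ale - years_survived, NA_real_)
  premature <- died & !is.na(excess) & excess >= buffer_months / 12
  data.frame(excess = excess, premature = premature)
}

#' Compute per-participant premature-death outcomes
#'
#' Joins a cohort table to a period life table by sex and completed age and
#' classifies each death as premature or not under the given buffer.
#'
#' @param cohort A data frame with columns `id`, `sex`, `age`,
#'   `vital_status`, `years_survived` (plus any attribute columns, ignored
#'   here).
#' @param life_table A life table ([as_life_table()]).
#' @param buffer_months Buffer period in months (default 9).
#' @return A `data.frame` with columns `id`, `sex`, `age`, `vital_status`,
#'   `years_survived`, `ale`, `excess`, `premature`.
#' @export
compute_outcomes <- function(cohort, life_table, buffer_months = 9) {
  stopifnot(is.data.frame(cohort))
  need <- c("id", "sex", "age", "vital_status", "years_survived")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$id)) stop("duplicated participant ids")
  ale <- lookup_ale(life_table, cohort$sex, cohort$age)
  cls <- classify_premature(cohort$vital_status, cohort$years_survived, ale,
                            buffer_months = buffer_months)
  data.frame(
    id = cohort$id, sex = cohort$sex, age = cohort$age,
    vital_status = cohort$vital_status,
    years_survived = cohort$years_survived,
    ale = ale, excess = cls$excess, premature = cls$premature,
    stringsAsFactors = FALSE
  )
}

#' Buffer sensitivity of the premature classification
#'
#' Re-classifies deaths under several buffer periods and reports, per
#' buffer, the premature count and the share among deaths, plus the
#' absolute percentage-point difference in that share between adjacent
#' buffers. Premature sets are nested: a longer buffer classifies a subset
#' of the deaths a shorter one does.
#'
#' @param outcomes Output of [compute_outcomes()] (any buffer; only
#'   `vital_status` and `excess` are used).
#' @param buffer_months Numeric vector of buffers in months
#'   (default `c(3, 6, 9)`).
#' @return A list with `by_buffer` (data frame: `buffer_months`,
#'   `premature`, `deaths`, `share`) and `adjacent` (data frame:
#'   `from_months`, `to_months`, `diff_pct_points`).
#' @export
buffer_sensitivity <- function(outcomes, buffer_months = c(3, 6, 9)) {
  stopifnot(is.data.frame(outcomes),
            all(c("vital_status", "excess") %in% names(outcomes)))
  if (!length(buffer_months)) stop("buffer_months must be non-empty")
  buffer_months <- sort(unique(buffer_months))
  died <- outcomes$vital_status == "died"
  n_deaths <- sum(died)
  counts <- vapply(buffer_months, function(b) {
    sum(died & outcomes$excess >= b / 12, na.rm = TRUE)
  }, numeric(1))
  share <- if (n_deaths > 0) counts / n_deaths else rep(0, length(counts))
  by_buffer <- data.frame(
    buffer_months = buffer_months, premature = counts,
    deaths = n_deaths, share = share
  )
  adjacent <- if (length(buffer_months) > 1) {
    i <- seq_len(length(buffer_months) - 1)
    data.frame(
      from_months = buffer_months[i], to_months = buffer_months[i + 1],
      diff_pct_points = abs(share[i] - share[i + 1]) * 100
    )
  } else {
    data.frame(from_months = numeric(0), to_months = numeric(0),
               diff_pct_points = numeric(0))
  }
  list(by_buffer = by_buffer, adjacent = adjacent)
}
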