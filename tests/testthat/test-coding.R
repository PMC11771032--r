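make_outcomes <- function(ids, premature) {
  data.frame(id = ids, premature = premature)
}

test_that("interval binarization is half-open and closes the printed BMI gap", {
  cohort <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    bmi = c(26.0, NA, 19.9, 29.5, 30.0)
  )
  out <- make_outcomes(cohort$id, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  pm <- binarize(cohort, list(bmi_coding()), out)
  v <- pm$values
  # BMI 26 is true only for the third predicate
  expect_equal(unname(v["a" == cohort$id, 1:4]),
               c(FALSE, FALSE, TRUE, FALSE))
  # missing value leaves the whole group FALSE
  expect_equal(unname(v[2, 1:4]), rep(FALSE, 4))
  # [29,30) falls in the closed 25-<30 predicate; 30 starts the last one
  expect_true(v[4, "bmi::25-<30"])
  expect_true(v[5, "bmi::30-"])
  # succedent column mirrors the outcome records
  expect_equal(unname(v[, "premature_death::yes"]), out$premature)
})

test_that("categorical partitions give exactly one TRUE per observed row", {
  cohort <- data.frame(id = 1:6,
                       sex = c("male", "female", "male", NA, "female", "male"))
  coding <- list(attribute_coding("sex", list(
    pred_cat("male", "male"), pred_cat("female", "female")
  )))
  pm <- binarize(cohort, coding, make_outcomes(1:6, rep(FALSE, 6)))
  sums <- rowSums(pm$values[, 1:2])
  expect_equal(sums, c(1, 1, 1, 0, 1, 1))
})

test_that("coding-gap and overlap violations are surfaced", {
  cohort <- data.frame(id = 1:2, bmi = c(29.5, 22))
  gappy <- list(attribute_coding("bmi", list(
    pred_interval("20-<25", 20, 25),
    pred_interval("25-<29", 25, 29),
    pred_interval("30-", 30, Inf)
  )))
  expect_warning(
    expect_error(
      binarize(cohort, gappy, make_outcomes(1:2, c(FALSE, FALSE))),
      "coding gap.*bmi.*29.5"
    ),
    "gap"
  )
  overlapping <- list(attribute_coding("x", list(
    pred_interval("lo", 20, 25), pred_interval("hi", 24, 29)
  )))
  expect_error(
    binarize(data.frame(id = 1, x = 21), overlapping,
             make_outcomes(1, FALSE)),
    "overlap"
  )
})

test_that("validate_coding reports gaps, overlaps and the 2-4 bound", {
  ok <- validate_coding(list(bmi_coding()))
  expect_equal(nrow(ok), 0)

  rep1 <- validate_coding(list(attribute_coding("x", list(
    pred_interval("a", 20, 25), pred_interval("b", 24, 29)
  ))))
  expect_true("overlap" %in% rep1$issue)

  rep2 <- validate_coding(list(attribute_coding("y", lapply(
    1:5, function(i) pred_cat(paste0("c", i), paste0("c", i))
  ))))
  expect_true("predicate_count" %in% rep2$issue)

  rep3 <- validate_coding(list(attribute_coding("z", list(
    pred_cat("ab", c("a", "b")), pred_cat("bc", c("b", "c"))
  ))))
  expect_true("overlap" %in% rep3$issue)

  # observed-value coverage against data
  rep4 <- validate_coding(
    list(attribute_coding("w", list(pred_cat("a", "a"), pred_cat("b", "b")))),
    data = data.frame(w = c("a", "b", "q"))
  )
  expect_true("uncovered_values" %in% rep4$issue)
})

test_that("binarize is a pure, order-invariant function with a faithful round-trip", {
  set.seed(7)
  n <- 50
  cohort <- data.frame(
    id = sprintf("p%02d", 1:n),
    bmi = round(runif(n, 17, 35), 1),
    grp = sample(c("a", "b", "c"), n, TRUE)
  )
  cohort$bmi[sample(n, 4)] <- NA
  coding <- list(
    bmi_coding(),
    attribute_coding("grp", list(pred_cat("a", "a"), pred_cat("b", "b"),
                                 pred_cat("c", "c")))
  )
  out <- make_outcomes(cohort$id, runif(n) < 0.3)
  pm1 <- binarize(cohort, coding, out)
  # per-row sums within an attribute group are 0 or 1
  expect_true(all(rowSums(pm1$values[, 1:4]) %in% 0:1))
  # column sums invariant to row order
  perm <- sample.int(n)
  pm2 <- binarize(cohort[perm, ], coding, out)
  expect_equal(colSums(pm2$values), colSums(pm1$values))
  # round-trip: TRUE rows are exactly the rows whose raw value is in range
  expect_equal(unname(which(pm1$values[, "bmi::20-<25"])),
               which(!is.na(cohort$bmi) & cohort$bmi >= 20 & cohort$bmi < 25))
  # column order follows (attribute order in config, predicate order within)
  expect_equal(colnames(pm1$values)[1:7],
               c("bmi::<20", "bmi::20-<25", "bmi::25-<30", "bmi::30-",
                 "grp::a", "grp::b", "grp::c"))
})

test_that("coding configs survive a YAML round-trip", {
  coding <- list(
    bmi_coding(),
    attribute_coding("sex", list(pred_cat("male", "male"),
                                 pred_cat("female", "female")))
  )
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  yaml::write_yaml(guhapaths:::codings_to_list(coding), path)
  back <- read_coding(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$predicates[[1]]$low, -Inf)
  expect_equal(back[[1]]$predicates[[3]]$high, 30)
  expect_equal(back[[2]]$predicates[[2]]$categories, "female")
})
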