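toy_pm <- function() {
  # 3 attributes x 2 predicates over 8 rows, every column supported
  set.seed(5)
  cat <- replicate(3, sample(1:2, 8, replace = TRUE))
  cols <- do.call(cbind, lapply(1:3, function(j) {
    grp <- cbind(cat[, j] == 1, cat[, j] == 2)
    colnames(grp) <- sprintf("a%d::c%d", j, 1:2)
    grp
  }))
  psi <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
                ncol = 1, dimnames = list(NULL, "premature_death::yes"))
  predicate_matrix(cbind(cols, psi),
                   c(rep(sprintf("a%d", 1:3), each = 2), "premature_death"),
                   succedent = "premature_death::yes")
}

test_that("antecedent enumeration respects attributes, lengths and pruning", {
  pm <- toy_pm()
  # 6 singletons + 3 attribute pairs x 4 predicate combos = 18 candidates
  cand <- enumerate_antecedents(pm, max_length = 2, prune = FALSE)
  expect_length(cand, 18)
  expect_length(unique(cand), 18)
  # no conjunction mixes predicates of one attribute
  attrs <- lapply(strsplit(cand, ";"), function(x) sub("::.*", "", x))
  expect_true(all(vapply(attrs, anyDuplicated, integer(1)) == 0))
  # length window
  expect_length(enumerate_antecedents(pm, min_length = 1, max_length = 1), 6)
  # base above every column sum: only singletons are visited
  expect_length(enumerate_antecedents(pm, max_length = 3, base = 9,
                                      prune = TRUE), 6)
})

test_that("run_task equals brute force on random matrices, with and without pruning", {
  for (seed in 1:30) {
    pm <- random_pm(seed, n_rows = 30 + (seed %% 4) * 10,
                    n_attrs = 3 + (seed %% 3))
    set.seed(seed + 1000)
    cfg <- task_config(
      "t", base = sample(1:5, 1), p = runif(1, 0.05, 1.2),
      alpha = sample(c(0.05, 0.2, 0.5), 1),
      min_length = 1, max_length = 3
    )
    got <- run_task(pm, cfg)
    got_np <- run_task(pm, cfg, prune = FALSE)
    want <- brute_force_paths(pm, cfg)
    expect_equal(sort(got$paths$antecedent), want, info = paste("seed", seed))
    expect_equal(sort(got_np$paths$antecedent), want)
  }
})

test_that("every emitted path re-verifies against its stored table", {
  pm <- random_pm(77, n_rows = 60, n_attrs = 5)
  cfg <- task_config("t", base = 2, p = 0.2, alpha = 0.5, max_length = 3)
  res <- run_task(pm, cfg)
  expect_gt(nrow(res$paths), 0)
  psi <- pm$values[, pm$succedent]
  for (i in seq_len(nrow(res$paths))) {
    preds <- strsplit(res$paths$antecedent[i], ";")[[1]]
    tbl <- build_table(pm$values[, preds, drop = FALSE], psi)
    expect_equal(c(tbl$a, tbl$b, tbl$c, tbl$d),
                 as.numeric(res$paths[i, c("a", "b", "c", "d")]))
    expect_true(above_average_truth(tbl, cfg$p, cfg$base))
    expect_true(fisher_truth(tbl, cfg$alpha))
    expect_equal(frequency_coefficient(tbl), res$paths$freq_coefficient[i])
  }
})

test_that("raising p or base never adds a path and results are deterministic", {
  pm <- random_pm(123, n_rows = 80, n_attrs = 5)
  lo <- run_task(pm, task_config("lo", base = 2, p = 0.2, alpha = 0.5,
                                 max_length = 3))
  hi_p <- run_task(pm, task_config("hp", base = 2, p = 0.6, alpha = 0.5,
                                   max_length = 3))
  hi_b <- run_task(pm, task_config("hb", base = 6, p = 0.2, alpha = 0.5,
                                   max_length = 3))
  expect_true(all(hi_p$paths$antecedent %in% lo$paths$antecedent))
  expect_true(all(hi_b$paths$antecedent %in% lo$paths$antecedent))
  again <- run_task(pm, task_config("lo", base = 2, p = 0.2, alpha = 0.5,
                                    max_length = 3))
  expect_identical(again$paths, lo$paths)
})

test_that("an all-false succedent yields zero paths", {
  pm <- random_pm(9, n_rows = 40, n_attrs = 4, psi_rate = 0)
  res <- run_task(pm, task_config("t", base = 1, p = 0.1, alpha = 0.5,
                                  max_length = 2))
  expect_equal(nrow(res$paths), 0)
})

test_that("schedules deduplicate across tasks and keep per-task provenance", {
  pm <- random_pm(55, n_rows = 80, n_attrs = 5)
  t1 <- task_config("t1", base = 2, p = 0.3, alpha = 0.5, max_length = 3)
  t2 <- task_config("t2", base = 2, p = 0.3, alpha = 0.5, max_length = 3)
  same <- run_schedule(pm, list(t1, t2))
  expect_equal(unname(same$per_task), rep(nrow(same$paths), 2))
  expect_true(all(same$paths$tasks == "t1;t2"))

  # lower base at equal p is weaker: task-1 paths form a subset
  s <- run_schedule(pm, list(
    task_config("strict", base = 5, p = 0.3, alpha = 0.5, max_length = 3),
    task_config("loose", base = 2, p = 0.3, alpha = 0.5, max_length = 3)
  ))
  strict <- s$task_results$strict$paths$antecedent
  loose <- s$task_results$loose$paths$antecedent
  expect_true(all(strict %in% loose))
  expect_equal(nrow(s$paths), length(unique(c(strict, loose))))
  expect_lte(nrow(s$paths), sum(s$per_task))
  expect_error(run_schedule(pm, list(t1, t1)), "duplicate task labels")
})

test_that("predicate frequencies count unique paths overall and per task", {
  fake <- structure(list(
    paths = data.frame(
      antecedent = c("A;B", "A;C", "B;C"),
      tasks = c("t1;t2", "t1", "t2"), stringsAsFactors = FALSE
    ),
    per_task = c(t1 = 2, t2 = 2),
    task_results = list(
      t1 = list(paths = data.frame(antecedent = c("A;B", "A;C"))),
      t2 = list(paths = data.frame(antecedent = c("A;B", "B;C")))
    )
  ), class = "guha_schedule_result")
  freq <- predicate_frequency(fake)
  expect_equal(freq$total[match(c("A", "B", "C"), freq$predicate)],
               c(2, 2, 2))
  expect_equal(freq$t1[match(c("A", "B", "C"), freq$predicate)], c(2, 1, 1))
  expect_equal(freq$t2[match(c("A", "B", "C"), freq$predicate)], c(1, 2, 1))

  empty <- structure(list(
    paths = data.frame(antecedent = character(0), tasks = character(0)),
    per_task = c(t1 = 0),
    task_results = list(t1 = list(paths = data.frame(
      antecedent = character(0)
    )))
  ), class = "guha_schedule_result")
  expect_equal(nrow(predicate_frequency(empty)), 0)
})

test_that("stratified runs recover strata-specific structure and flag empty strata", {
  gen <- generate_cohort(recovery_spec(2.8, stratum = c(sex = "female"),
                                       carrier_fraction = 0.04),
                         seed = 21)
  pm <- pm_from_gen(gen)
  # within the stratum the prevalence is elevated, so the effective lift is
  # below the planted 2.8; a required lift of 1 + p = 2 leaves clear margin
  tasks <- list(task_config("t", base = 60, p = 1.0, alpha = 0.001,
                            max_length = 5))
  res <- stratified_run(pm, tasks, "sex")
  expect_named(res, c("male", "female"))
  expect_true(planted_key %in% res$female$paths$antecedent)
  expect_false(planted_key %in% res$male$paths$antecedent)

  # a stratum with zero rows is a validation error
  all_male <- gen$cohort
  all_male$sex <- "male"
  pm2 <- binarize(all_male, gen$codings,
                  compute_outcomes(all_male, gen$life_table))
  expect_error(stratified_run(pm2, tasks, "sex"), "zero rows")
})

test_that("a stratum covering all rows reproduces the unstratified schedule", {
  pm <- random_pm(88, n_rows = 60, n_attrs = 4)
  n <- nrow(pm$values)
  whole <- cbind(pm$values,
                 `cohort::all` = rep(TRUE, n),
                 `cohort::none` = rep(FALSE, n))
  # move succedent last for clarity; predicate_matrix is order-agnostic
  pm2 <- predicate_matrix(
    whole, c(pm$meta$attribute, "cohort", "cohort"),
    succedent = pm$succedent
  )
  tasks <- list(task_config("t", base = 2, p = 0.3, alpha = 0.5,
                            max_length = 3))
  strat <- stratified_run(pm2, tasks, "cohort", strata_labels = "all")
  plain <- run_schedule(pm, tasks)
  expect_equal(strat$all$paths, plain$paths)
})
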