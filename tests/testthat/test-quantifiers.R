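test_that("four-fold tables count conjunctions and conserve the total", {
  t1 <- build_table(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(t1[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  t2 <- build_table(cbind(c(TRUE, TRUE, FALSE, FALSE),
                          c(TRUE, FALSE, TRUE, FALSE)),
                    rep(TRUE, 4))
  expect_equal(unlist(t2[c("a", "b", "c", "d")]),
               c(a = 1, b = 0, c = 3, d = 0))
  t3 <- build_table(rep(FALSE, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(t3$a + t3$b, 0)
  expect_equal(t3$c + t3$d, 5)
  expect_equal(t3$m, 5)
  expect_error(build_table(list(), rep(TRUE, 3)), "empty antecedent")
  expect_error(fourfold_table(-1, 0, 0, 2), "nonnegative")
  expect_error(fourfold_table(0, 0, 0, 0), "m >= 1")
})

test_that("Above Average truth is inclusive at the boundary and gated by base", {
  boundary <- fourfold_table(10, 10, 90, 890) # confidence 0.5 = 5 x 0.1
  expect_true(above_average_truth(boundary, p = 4, base = 10))
  expect_false(above_average_truth(fourfold_table(50, 50, 100, 800),
                                   p = 4, base = 10)) # lift ~3.33 < 5
  expect_false(above_average_truth(boundary, p = 4, base = 11)) # a < base
  # no phi rows cannot exceed the average
  expect_false(above_average_truth(fourfold_table(0, 0, 10, 90),
                                   p = 0.5, base = 1))
  expect_error(above_average_truth(boundary, p = 0, base = 1), "p must")
})

test_that("frequency coefficient is lift minus one and matches the quantifier", {
  expect_equal(frequency_coefficient(fourfold_table(10, 10, 90, 890)), 4.0)
  expect_equal(frequency_coefficient(fourfold_table(25, 75, 225, 675)), 0.0)
  # a predicate with p = 1.00 means the outcome is twice as common under it
  smoking <- fourfold_table(287, 287, 1277, 4405) # confidence 2 x prevalence
  expect_equal(frequency_coefficient(smoking), 1.00, tolerance = 1e-12)
  expect_true(is.na(frequency_coefficient(fourfold_table(0, 0, 5, 5))))
  expect_true(is.na(frequency_coefficient(fourfold_table(0, 5, 0, 5))))
})

test_that("frequency coefficient is the supremum p of the Above Average truth", {
  set.seed(31)
  for (i in 1:50) {
    t <- random_table(120)
    if (t$r == 0 || t$k == 0 || t$a == 0) next
    fc <- frequency_coefficient(t)
    if (fc <= 0) next
    expect_true(above_average_truth(t, p = fc, base = 1))
    expect_true(above_average_truth(t, p = fc * 0.9, base = 1))
    expect_false(above_average_truth(t, p = fc + 1e-9 + fc * 1e-9, base = 1))
  }
})

test_that("Fisher tail matches closed forms on small tables", {
  expect_equal(fisher_pvalue(fourfold_table(5, 0, 0, 5)), 1 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_pvalue(fourfold_table(1, 1, 1, 1)), 5 / 6,
               tolerance = 1e-12)
  # no psi rows: A is degenerate at 0
  expect_equal(fisher_pvalue(fourfold_table(0, 3, 0, 7)), 1.0)
})

test_that("Fisher truth needs strict positive association and p <= alpha", {
  expect_true(fisher_truth(fourfold_table(5, 0, 0, 5), alpha = 0.01))
  expect_false(fisher_truth(fourfold_table(5, 0, 0, 5), alpha = 0.001))
  expect_false(fisher_truth(fourfold_table(1, 1, 1, 1), alpha = 0.5))
  expect_error(fisher_truth(fourfold_table(1, 1, 1, 1), alpha = 0.6),
               "alpha")
})

test_that("Fisher tail agrees with stats::fisher.test and is count-only", {
  set.seed(99)
  for (i in 1:100) {
    t <- random_table(150)
    ft <- stats::fisher.test(matrix(c(t$a, t$c, t$b, t$d), 2),
                             alternative = "greater")
    expect_equal(fisher_pvalue(t), ft$p.value, tolerance = 1e-9)
  }
  # row-permutation invariance: the value depends on counts only
  set.seed(100)
  phi <- runif(60) < 0.4
  psi <- runif(60) < 0.3
  perm <- sample.int(60)
  expect_identical(fisher_pvalue(build_table(phi, psi)),
                   fisher_pvalue(build_table(phi[perm], psi[perm])))
})

test_that("Above Average truth is monotone non-increasing in p and base", {
  set.seed(17)
  for (i in 1:40) {
    t <- random_table(100)
    ps <- sort(runif(2, 0.1, 3))
    if (above_average_truth(t, p = ps[2], base = 1)) {
      expect_true(above_average_truth(t, p = ps[1], base = 1))
    }
    if (t$a >= 2 && above_average_truth(t, p = ps[1], base = t$a)) {
      expect_true(above_average_truth(t, p = ps[1], base = t$a - 1))
    }
  }
})

test_that("frequency-coefficient conversions follow the (1 + p) convention", {
  expect_equal(prevalence_multiplier(4), 5)
  expect_equal(excess_percent(4), 400)
  expect_equal(prevalence_multiplier(2), 3)
  expect_error(prevalence_multiplier(0), "p must")
})
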