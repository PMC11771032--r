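# Independent oracles and fixture builders used across the suite.

# Exhaustive one-sided Fisher tail by direct binomial-coefficient
# arithmetic (safe for m <= ~200): P(A >= a) with margins fixed.
fisher_tail_exhaustive <- function(a, b, c, d) {
  r <- a + b; k <- a + c; l <- b + d; m <- a + b + c + d
  j <- a:min(r, k)
  sum(choose(k, j) * choose(l, r - j)) / choose(m, r)
}

# Brute-force evaluation of every admissible antecedent conjunction
# (at most one predicate per attribute, lengths min..max), independent of
# the miner: direct confidence comparison and stats::phyper for the Fisher
# tail. Returns the sorted set of ";"-joined antecedent keys that pass both
# quantifiers.
brute_force_paths <- function(pm, cfg) {
  vals <- pm$values
  if (!is.null(cfg$row_filter)) {
    keep <- if (is.character(cfg$row_filter)) {
      vals[, cfg$row_filter]
    } else {
      cfg$row_filter
    }
    vals <- vals[keep, , drop = FALSE]
  }
  psi <- vals[, pm$succedent]
  m <- nrow(vals)
  k <- sum(psi)
  acols <- pm$meta$column[!pm$meta$is_outcome]
  attr_of <- pm$meta$attribute[!pm$meta$is_outcome]
  attrs <- unique(attr_of)
  found <- character(0)
  for (len in cfg$min_length:cfg$max_length) {
    if (len > length(attrs)) break
    attr_sets <- utils::combn(attrs, len, simplify = FALSE)
    for (aset in attr_sets) {
      choices <- lapply(aset, function(at) which(attr_of == at))
      grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
      for (g in seq_len(nrow(grid))) {
        cols <- sort(unlist(grid[g, ]))
        phi <- rowSums(vals[, acols[cols], drop = FALSE]) == len
        a <- sum(phi & psi)
        if (a < cfg$base) next
        nphi <- sum(phi)
        if (nphi == 0) next
        if (a / nphi < (1 + cfg$p) * k / m) next
        b <- nphi - a; cc <- k - a; d <- m - nphi - cc
        if (!(a * d > b * cc)) next
        pv <- stats::phyper(a - 1, k, m - k, nphi, lower.tail = FALSE)
        if (pv <= cfg$alpha) {
          found <- c(found, paste(acols[cols], collapse = ";"))
        }
      }
    }
  }
  sort(found)
}

# Random predicate matrix: n_attrs attributes with 2-3 mutually exclusive
# predicates each (one-hot per row, occasionally missing -> all FALSE) and
# a random succedent.
random_pm <- function(seed, n_rows = 40, n_attrs = 4, max_preds = 3,
                      psi_rate = 0.4, miss_rate = 0.05) {
  set.seed(seed)
  cols <- list()
  attrs <- character(0)
  for (j in seq_len(n_attrs)) {
    kp <- sample(2:max_preds, 1)
    cat <- sample.int(kp, n_rows, replace = TRUE)
    cat[runif(n_rows) < miss_rate] <- NA
    grp <- vapply(seq_len(kp), function(ci) !is.na(cat) & cat == ci,
                  logical(n_rows))
    colnames(grp) <- sprintf("a%d::c%d", j, seq_len(kp))
    cols[[j]] <- grp
    attrs <- c(attrs, rep(sprintf("a%d", j), kp))
  }
  psi <- matrix(runif(n_rows) < psi_rate, ncol = 1,
                dimnames = list(NULL, "premature_death::yes"))
  predicate_matrix(cbind(do.call(cbind, cols), psi),
                   c(attrs, "premature_death"),
                   succedent = "premature_death::yes")
}

# Random four-fold table with total at most m_max.
random_table <- function(m_max = 200) {
  m <- sample(4:m_max, 1)
  cuts <- sort(sample(0:m, 3, replace = TRUE))
  fourfold_table(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], m - cuts[3])
}

# Shipped-style BMI coding with the [29,30) gap closed as [25,30).
bmi_coding <- function() {
  attribute_coding("bmi", list(
    pred_interval("<20", -Inf, 20),
    pred_interval("20-<25", 20, 25),
    pred_interval("25-<30", 25, 30),
    pred_interval("30-", 30, Inf)
  ))
}

# Small synthetic spec used by miner-facing tests: 10 attributes of 4
# categories, one planted 5-predicate conjunction.
recovery_spec <- function(lift, carrier_fraction = 0.05, n = 6257,
                          stratum = NULL) {
  synthetic_spec(
    n = n, n_attributes = 10,
    predicate_probs = c("2" = 0, "3" = 0, "4" = 1),
    planted_paths = list(planted_path(
      lift = lift, carrier_fraction = carrier_fraction, length = 5,
      attributes = sprintf("attr%03d", 1:5), stratum = stratum
    ))
  )
}

planted_key <- paste(sprintf("attr%03d::c1", 1:5), collapse = ";")

pm_from_gen <- function(gen, buffer_months = 9) {
  outcomes <- compute_outcomes(gen$cohort, gen$life_table,
                               buffer_months = buffer_months)
  binarize(gen$cohort, gen$codings, outcomes)
}
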