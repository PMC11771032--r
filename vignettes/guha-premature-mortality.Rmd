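---
title: "Mining paths to premature mortality with generalized quantifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining paths to premature mortality with generalized quantifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guhapaths)
```

## The problem and the approach

Cohort studies of premature mortality usually regress the outcome on a
handful of pre-selected predictors. When many midlife attributes are
available, that design both exaggerates single-predictor effects and
misses joint ones. `guhapaths` takes the opposite, exploratory route: it
defines an *individual* premature-death outcome from a period life table,
turns every attribute into a small set of mutually exclusive Boolean
predicates, and then enumerates antecedent conjunctions of those
predicates, labelling each TRUE or FALSE under two generalized quantifiers
evaluated on the conjunction's four-fold table. TRUE conjunctions are
called **paths**. The output is the full list of supported paths — an
exploratory map of the data, not a causal model; every statistical
statement below is associational.

## The premature-death outcome

For a participant of a given sex and baseline age, the actuarial life
expectancy (ALE) is read from a sex × completed-age life table
(`lookup_ale()`; completed age means `floor(age)`, the convention period
life tables are indexed by). With `years_survived` the observed years from
baseline to death (or to the censoring date), a death is premature iff

\[
\text{excess} = \text{ALE} - \text{years\_survived} \ge
  \text{buffer\_months}/12 .
\]

* **Buffer.** The default buffer is 9 months (0.75 years, exactly
  `buffer_months/12`; no calendar-day arithmetic). It absorbs minor
  discrepancies and measurement limitations near the ALE that should not
  count as premature death. The tie is inclusive: a death exactly at the
  buffer *is* premature, the direct negation of "less than the buffer
  before the ALE is not premature". `buffer_sensitivity()` re-classifies
  under alternative buffers (3/6/9 months by default); because the rule is
  a threshold on a fixed `excess`, the premature sets are nested and
  counts are non-increasing in the buffer length — a property the tests
  assert rather than assume.
* **The censored.** Participants alive at censoring are retained with
  `premature = FALSE`; they contribute to the ¬ψ side of every table. A
  participant whose ALE extends past the censoring horizon could still die
  prematurely afterwards; the classification deliberately ignores this
  (the four-fold margins must cover all rows), and analyses should read
  ψ as "died prematurely *within follow-up*".

## Predicate coding

Each attribute maps to 2–4 mutually exclusive predicates
(`attribute_coding()`): category sets for categorical attributes,
half-open intervals `[low, high)` for numeric ones (so adjacent cuts like
20/25/30 partition cleanly). Conventions that matter downstream:

* Missing raw values leave *all* of an attribute's columns FALSE — Boolean
  matrices have no third value, so a missing row simply never supports a
  conjunction involving that attribute.
* A non-missing value covered by no predicate is a hard error
  (`binarize()` names the attribute and value); interval *gaps* in a
  config are flagged as warnings by `validate_coding()` before that can
  happen. The shipped BMI example closes the commonly printed but
  uncoverable `[29, 30)` gap as `25-<30`.
* Column order is (attribute order in the config, predicate order within
  the attribute). This fixes the miner's enumeration order and hence makes
  results byte-reproducible.

## The quantifiers

For an antecedent φ and the succedent ψ, the four-fold table has cells
`a, b, c, d` and margins `r = a+b`, `s = c+d`, `k = a+c`, `l = b+d`,
`m = a+b+c+d`.

**Above Average** (`above_average_truth()`): TRUE iff

\[
\frac{a}{a+b} \ge (1+p)\,\frac{a+c}{m}, \qquad p > 0,\ a \ge \text{Base}.
\]

The frequency coefficient `p` says the outcome is at least \(1+p\) times
more common under φ than on average (`p = 4` → 5×, i.e. 400% excess;
`p = 2` → 3×). `Base` is the minimum support: the least number of rows
satisfying both φ and ψ for the association to have any general
significance. `frequency_coefficient()` returns the achieved
`lift − 1`, the supremum of `p` at which the quantifier holds.

**Fisher** (`fisher_truth()`): TRUE iff `ad > bc` strictly *and* the
one-sided exact tail with fixed margins,

\[
P(A \ge a) = \sum_{j=a}^{\min(r,k)}
  \binom{k}{j}\binom{l}{r-j} \Big/ \binom{m}{r},
\]

is at most α (default 0.001). Numerical choices: the observed table is
included in the tail (the standard exact-test convention); terms are
computed as `exp(lchoose(...))` with a log-sum-exp guard, so there is no
factorial overflow at any realistic `m`; degenerate margins give the
correct limits (`k = 0` → p-value 1). The tests check the implementation
against exhaustive binomial-coefficient enumeration and against
`stats::fisher.test(alternative = "greater")`.

A boundary subtlety: `above_average_truth()` compares in the
multiplied-out form \(a\,m \ge (1+p)\,k\,r\) with a \(10^{-12}\) relative
tolerance. The tolerance only absorbs floating-point rounding when `p`
itself was derived by division (count granularity is many orders of
magnitude larger), keeping the printed "≥" inclusive in both forms.

## Mining

`run_task()` walks conjunctions depth-first in lexicographic column order,
lengths 1–5, never combining two predicates of one attribute: predicates
of one attribute are mutually exclusive, so a mixed conjunction has
`a = 0` and can never reach `Base ≥ 1`; excluding them up front only
shrinks the space. Support pruning is Apriori-style: `a + b` is
non-increasing under extension and a path needs `a ≥ Base ≥ 1`, so a
branch whose φ-count falls below `Base` is cut without loss — with
pruning disabled the path set is provably identical (asserted against a
brute-force oracle on randomized matrices). Verification counts (tables
evaluated) and prune counts are reported for logging; they are *not*
comparable with other GUHA implementations, whose traversal internals
differ.

`run_schedule()` runs a list of tasks — typically decreasing `Base` with
increasing `p`, mirroring the published six-task design (Base 400/…/75
against p 0.55/…/1.5) — and deduplicates paths across tasks while keeping
per-task provenance. `predicate_frequency()` tabulates how often each
predicate appears across the unique paths, overall and per task.
`stratified_run()` repeats a schedule inside each stratum of one
attribute (e.g. sex); the stratum attribute's own columns are dropped from
the antecedent pool because they are constant within a stratum (the
all-true column would otherwise pad every path without changing any
table). No multiple-testing correction is applied beyond the deliberately
conservative α = 0.001; the path list is exploratory output, and the
null-cohort test below quantifies the false-discovery behaviour.

## Bayesian path characterization

The published analyses accompany each path with a posterior certainty
statement but no formulas; this package implements a transparent
reconstruction and labels it as such. With independent uniform priors,

\[
\pi_\varphi \sim \mathrm{Beta}(a+1,\ b+1), \qquad
\pi_{\neg\varphi} \sim \mathrm{Beta}(c+1,\ d+1),
\]

Monte-Carlo draws give the prevalence ratio against the whole-matrix rate
(the same denominator the Above Average quantifier uses, rather than the
¬φ rate):

\[
\rho = \frac{\pi_\varphi}{(r\,\pi_\varphi + s\,\pi_{\neg\varphi})/m}.
\]

`path_posterior()` reports the posterior mean, an equal-tailed credible
interval (default 95%), and \(P(\rho \ge 1 + p_{\text{task}})\). Draws
default to 100,000 and may not go below 10,000; a seed is mandatory and
the caller's RNG state is untouched. In batch mode (`paths_posterior()`)
every stored path is first re-verified against the matrix. Calibration is
tested: on tables simulated from known rates the 95% intervals cover the
true ratio at the nominal level within binomial error, and the posterior
mean converges to the empirical lift as counts grow.

## The synthetic cohort generator

Registry-linked cohorts of this kind are not publicly deposited, so the
generator (`synthetic_spec()` / `generate_cohort()`) is first-class,
tested code, not a fixture. Its defaults are the study conditions the
analysis assumes: n = 6257, 55.3% women, baseline ages normal(50.5, 3.6)
truncated to [44, 59), premature-death prevalence 0.247, a 29-year
censoring horizon, 80 attributes with a {2, 3, 4}-category mix (the often
quoted 333 predicates from 80 attributes is unattainable under the 2–4
bound — the maximum is 320 — so the default mix yields ≈ 280 and the
package always uses the actual input dimensions), and a non-premature
death rate of 0.138 chosen so that total deaths (~2,200) and the
premature share among deaths (~70%) match the emulated cohort.

Mechanism and its deliberate simplifications:

* ψ is generated directly and survival is back-constructed: premature
  deaths draw `excess` uniformly in `(0.76, ALE)` (clearing the 9-month
  buffer with margin against CSV round-tripping), non-premature deaths
  draw `excess` in `(−3, 0.74)` (deaths shortly before or after the ALE,
  feasible within the horizon), everyone else is censored at 29 years.
  `compute_outcomes()` at the 9-month buffer therefore reproduces the
  assigned ψ exactly, and the 3/6/9-month nesting is non-trivial because
  some non-premature deaths fall inside the shorter buffers.
* A planted path forces its categories onto a random carrier subset and
  re-draws coincidental satisfiers away, so `carrier_fraction` is exactly
  P(φ). Carriers get \(P(\psi) = \lambda \pi_0\) (an error, never a silent
  clip, if that exceeds 1); the background rate is lowered so the marginal
  stays at \(\pi_0\). Planted paths must use pairwise-disjoint attribute
  sets; where carrier sets overlap, the larger lift wins. An optional
  stratum confines carriers to e.g. females.
* Non-planted attributes are independent and uniform. Real questionnaire
  data are correlated, have structured missingness, and have informative
  marginals; passing tests on these cohorts therefore validates the
  *machinery* (counting, quantifier logic, pruning, calibration), not the
  field behaviour of the method on real data.

`realized_truth()` closes the loop: it recomputes each planted
conjunction's table, lift and quantifier verdicts, which is what the
recovery tests assert against the miner's output.

A consequence worth stating precisely: if a conjunction is planted at
target lift λ and mined with a task requiring lift `1 + p = λ`, the
realized confidence is centred *on* the decision boundary, so per-seed
recovery is a coin flip (with ~313 carriers the confidence has a standard
deviation of about 0.028 around the threshold). Reliable recovery needs
the planted lift to clear `1 + p` by a few sampling standard deviations —
the loop-closure property test plants λ = 2.8 against a required 2.4 for
exactly that reason, and the package makes no claim of recovering
boundary-lift effects.

## Problem sizes used by the tests

The suite validates at sizes chosen to make the oracles exhaustive: the
Fisher oracle enumerates tables up to m = 200; miner-vs-brute-force runs
use ≤ 6 attributes / ≤ 15 predicates / conjunction length ≤ 3 over 200
randomized matrices and configurations; recovery runs use the full
n = 6257 with 10 attributes of 4 categories (the planted five plus five
noise attributes); null-control runs use 20 cohorts of n = 2000 with 8
attributes. These are the package's own validation scales; the pipeline
itself has no such limits beyond memory and patience (the search space
grows combinatorially with attributes and maximum length, which is what
support pruning and the at-most-one-predicate-per-attribute rule keep in
check).

## Known limitations

* The outcome treats censoring crudely (alive ⇒ not premature within
  follow-up); no competing risks, no cause-specific mortality, no
  life-table construction from raw death counts.
* Path lists are exploratory associations: overlapping paths share rows,
  sub-conjunctions of a strong path typically pass as well, and no
  causal reading is supported.
* The Bayesian summary is a documented Beta-Binomial reconstruction, not
  a replication of any specific tool's internal variant; hierarchical
  priors across paths are out of scope.
* Verification counters are implementation-specific and unsuitable for
  cross-tool comparison.
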