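#' Four-fold contingency table
#'
#' The 2x2 table of an antecedent conjunction `phi` against the succedent
#' `psi`: `a` rows satisfy both, `b` satisfy `phi` only, `c` satisfy `psi`
#' only and `d` neither. Margins are derived: `r = a + b` (phi rows),
#' `s = c + d`, `k = a + c` (psi rows), `l = b + d`, `m = a + b + c + d`.
#'
#' @param a,b,c,d Nonnegative integer cell counts; `m` must be >= 1.
#' @return An object of class `fourfold_table`: a list with elements
#'   `a,b,c,d,r,s,k,l,m`.
#' @examples
#' fourfold_table(10, 10, 90, 890)
#' @export
fourfold_table <- function(a, b, c, d) {
  for (v in list(a = a, b = b, c = c, d = d)) {
    if (!is_count(v)) stop("fourfold_table cells must be nonnegative integers")
  }
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  m <- a + b + c + d
  if (m < 1) stop("fourfold_table requires at least one observation (m >= 1)")
  structure(
    list(a = a, b = b, c = c, d = d,
         r = a + b, s = c + d, k = a + c, l = b + d, m = m),
    class = "fourfold_table"
  )
}

#' @export
print.fourfold_table <- function(x, ...) {
  cat("Four-fold table (phi x psi)\n")
  mat <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
                dimnames = list(c("phi", "not phi"), c("psi", "not psi")))
  print(mat)
  cat(sprintf("margins: r=%g s=%g k=%g l=%g m=%g\n", x$r, x$s, x$k, x$l, x$m))
  invisible(x)
}

#' Build a four-fold table from Boolean columns
#'
#' The antecedent `phi` is the conjunction of all supplied antecedent
#' columns; the table counts rows by `phi` x `psi`.
#'
#' @param antecedent A logical vector, a logical matrix (one column per
#'   predicate), or a list of logical vectors. Must be non-empty.
#' @param succedent A logical vector of the same length.
#' @return A [fourfold_table()].
#' @examples
#' build_table(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
#' @export
build_table <- function(antecedent, succedent) {
  if (is.list(antecedent)) {
    if (length(antecedent) == 0L) stop("empty antecedent: phi is undefined")
    antecedent <- do.call(cbind, antecedent)
  }
  if (is.matrix(antecedent)) {
    if (ncol(antecedent) == 0L) stop("empty antecedent: phi is undefined")
    stopifnot(is.logical(antecedent))
    phi <- rowSums(antecedent) == ncol(antecedent)
  } else {
    if (length(antecedent) == 0L) stop("empty antecedent: phi is undefined")
    stopifnot(is.logical(antecedent))
    phi <- antecedent
  }
  stopifnot(is.logical(succedent), length(succedent) == length(phi))
  if (anyNA(phi) || anyNA(succedent)) stop("NA values in Boolean columns")
  a <- sum(phi & succedent)
  b <- sum(phi & !succedent)
  c <- sum(!phi & succedent)
  d <- sum(!phi & !succedent)
  fourfold_table(a, b, c, d)
}

#' Above Average quantifier truth value
#'
#' TRUE iff the succedent is at least `(1 + p)` times more common among
#' antecedent rows than in the whole data matrix, with support at least
#' `base`: `a >= base` and `a/(a+b) >= (1+p) * (a+c) / m`. The boundary
#' (exact equality) is TRUE. A table with no phi rows is FALSE.
#'
#' @param t A [fourfold_table()].
#' @param p Frequency coefficient, a real > 0.
#' @param base Minimum support: the least admissible value of `a`
#'   (positive integer).
#' @return Logical scalar.
#' @examples
#' above_average_truth(fourfold_table(10, 10, 90, 890), p = 4, base = 10)
#' @export
above_average_truth <- function(t, p, base) {
  stopifnot(inherits(t, "fourfold_table"))
  if (!is_scalar_number(p) || p <= 0) stop("p must be a real > 0")
  if (!is_count(base) || base < 1) stop("base must be a positive integer")
  # multiplied-out form avoids division; counts up to ~1e7 stay exact in
  # doubles. The relative tolerance only absorbs rounding in (1 + p) * k * r
  # (count granularity is many orders larger), keeping the printed ">="
  # boundary inclusive also when p itself was derived by division.
  if (t$a < base || t$r == 0) return(FALSE)
  lhs <- t$a * t$m
  rhs <- (1 + p) * t$k * t$r
  lhs >= rhs - 1e-12 * max(lhs, rhs)
}

#' Achieved frequency coefficient (lift minus one)
#'
#' The supremum of `p` at which the Above Average quantifier holds for the
#' table (ignoring `base`): `a/(a+b) / ((a+c)/m) - 1`. The succedent is
#' `(1 + p)` times more common under phi than on average.
#'
#' @param t A [fourfold_table()].
#' @return A real, or `NA_real_` when undefined (`a+b = 0` or `a+c = 0`).
#' @examples
#' frequency_coefficient(fourfold_table(10, 10, 90, 890)) # 4
#' @export
frequency_coefficient <- function(t) {
  stopifnot(inherits(t, "fourfold_table"))
  if (t$r == 0 || t$k == 0) return(NA_real_)
  (t$a / t$r) / (t$k / t$m) - 1
}

#' One-sided Fisher exact tail probability
#'
#' Upper tail P(A >= a) of the hypergeometric distribution of the `a` cell
#' with all margins fixed, including the observed table:
#' sum over j = a..min(r,k) of C(k,j) C(l,r-j) / C(m,r). Terms are computed
#' with log-gamma arithmetic, so there is no factorial overflow.
#'
#' @param t A [fourfold_table()].
#' @return A probability in (0, 1].
#' @examples
#' fisher_pvalue(fourfold_table(5, 0, 0, 5)) # 1/252
#' @export
fisher_pvalue <- function(t) {
  stopifnot(inherits(t, "fourfold_table"))
  fisher_upper_tail(t$a, t$b, t$c, t$d)
}

# scalar counts version used in the miner's inner loop
fisher_upper_tail <- function(a, b, c, d) {
  r <- a + b
  k <- a + c
  l <- b + d
  m <- a + b + c + d
  jmax <- min(r, k)
  if (a > jmax) stop("inconsistent table")
  j <- a:jmax
  lt <- lchoose(k, j) + lchoose(l, r - j) - lchoose(m, r)
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

#' Fisher quantifier truth value
#'
#' TRUE iff the table shows a positive association in the strict sense
#' `ad > bc` and the one-sided Fisher exact tail [fisher_pvalue()] is at
#' most `alpha`.
#'
#' @param t A [fourfold_table()].
#' @param alpha Significance level in (0, 0.5].
#' @return Logical scalar.
#' @examples
#' fisher_truth(fourfold_table(5, 0, 0, 5), alpha = 0.01)
#' @export
fisher_truth <- function(t, alpha) {
  stopifnot(inherits(t, "fourfold_table"))
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 0.5) {
    stop("alpha must lie in (0, 0.5]")
  }
  t$a * t$d > t$b * t$c && fisher_pvalue(t) <= alpha
}

#' Frequency-coefficient conversions
#'
#' `prevalence_multiplier()` maps the Above Average frequency coefficient
#' `p` to the implied minimal prevalence multiplier `1 + p` (the succedent
#' is at least `1 + p` times more common among antecedent rows than on
#' average); `excess_percent()` expresses the same threshold as the minimal
#' percentage excess over the whole-matrix rate, `100 * p`.
#'
#' @param p Frequency coefficient, a real > 0.
#' @return A scalar: the multiplier (fold) or the excess (percent).
#' @examples
#' prevalence_multiplier(4) # 5
#' excess_percent(4)        # 400
#' @export
prevalence_multiplier <- function(p) {
  if (!is_scalar_number(p) || p <= 0) stop("p must be a real > 0")
  1 + p
}

#' @rdname prevalence_multiplier
#' @export
excess_percent <- function(p) {
  100 * (prevalence_multiplier(p) - 1)
}
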