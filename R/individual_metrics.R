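#' Per-cause metrics for individual cause assignment
#'
#' For each cause `j` with at least one true death:
#'
#' * **sensitivity** (= per-cause concordance): diagonal count over the row
#'   total, the fraction of true `j` deaths assigned to `j`;
#' * **specificity**: the fraction of deaths from other causes *not* assigned
#'   to `j`;
#' * **chance-corrected concordance** `CCC_j = (sens_j - 1/N) / (1 - 1/N)`,
#'   which rescales sensitivity so that 0 is the level a method achieves by
#'   assigning causes uniformly at random (`1/N` correct) and 1 is perfect.
#'   `CCC_j` is negative when a method does worse than chance.
#'
#' Chance correction uses the naive `1/N` level rather than Cohen's
#' marginal-product expectation: a method that cannot see the test set has no
#' business knowing its cause composition, and `1/N` is what makes the metric
#' invariant to that composition.
#'
#' A metric whose denominator is empty (no true deaths of the cause, or no
#' deaths of other causes) is *undefined* and returned as `NA`, which is
#' deliberately distinct from 0 so that averages can exclude it.
#'
#' @param conf A `va_confusion` object (integer tallies from
#'   [confusion_table()] or fractional expected counts from
#'   [analytic_confusion()]).
#' @return A tibble with one row per cause: `cause`, `n_true`, `sensitivity`,
#'   `specificity`, `ccc`.
#' @examples
#' conf <- analytic_confusion(va_method("method1"), rep(1 / 3, 3))
#' cause_metrics(conf)
#' @export
cause_metrics <- function(conf) {
  stopifnot(inherits(conf, "va_confusion"))
  cl <- conf$causes
  N <- length(cl)
  if (N < 2) abort("Metrics need at least two causes.")
  cm <- conf$counts
  rt <- rowSums(cm)
  ct <- colSums(cm)
  g <- sum(cm)
  sens <- ifelse(rt > 0, diag(cm) / rt, NA_real_)
  off <- g - rt # deaths of other causes
  spec <- ifelse(off > 0, 1 - (ct - diag(cm)) / off, NA_real_)
  tibble(
    cause = cl,
    n_true = as.vector(rt),
    sensitivity = as.vector(sens),
    specificity = as.vector(spec),
    ccc = ccc_from_sensitivity(as.vector(sens), N)
  )
}

# CCC_j = (sens - 1/N) / (1 - 1/N); NA propagates for undefined sensitivity
ccc_from_sensitivity <- function(sensitivity, n_causes) {
  if (n_causes < 2) abort("Chance correction needs at least two causes.")
  (sensitivity - 1 / n_causes) / (1 - 1 / n_causes)
}

#' Overall chance-corrected concordance
#'
#' A weighted mean of the per-cause chance-corrected concordances. Equal
#' weights are the default and the recommended summary: test-set CSMF weights
#' make results incomparable across studies with different compositions, and a
#' global cause-of-death distribution is awkward whenever a study's cause list
#' is partial. Causes with undefined CCC (no true deaths) are excluded from
#' the average with a warning; weights are renormalized over included causes.
#'
#' @param conf A `va_confusion` object.
#' @param weights `"equal"` (default), `"test-set"` (true-cause composition of
#'   the table), or a numeric vector of per-cause weights summing to 1 (e.g. a
#'   global CSMF distribution), in cause-list order or named by cause.
#' @return A single number in `[-1/(N-1), 1]`.
#' @export
overall_ccc <- function(conf, weights = "equal") {
  m <- cause_metrics(conf)
  w <- resolve_weights(weights, conf)
  ok <- !is.na(m$ccc)
  if (!any(ok)) abort("CCC is undefined for every cause.")
  if (!all(ok)) {
    warn(sprintf("CCC undefined for %d cause(s) (%s); excluded from the average.",
                 sum(!ok), paste(m$cause[!ok], collapse = ", ")))
  }
  if (sum(w[ok]) <= 0) abort("All weight falls on causes with undefined CCC.")
  sum(w[ok] * m$ccc[ok]) / sum(w[ok])
}

resolve_weights <- function(weights, conf) {
  cl <- conf$causes
  if (is.character(weights) && length(weights) == 1) {
    w <- switch(weights,
      "equal" = rep(1 / length(cl), length(cl)),
      "test-set" = {
        g <- grand_total(conf)
        if (g <= 0) abort("Empty confusion table.")
        row_totals(conf) / g
      },
      abort(sprintf("Unknown weight scheme '%s'.", weights))
    )
    return(unname(w))
  }
  w <- as.numeric(weights)
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), cl)) {
      abort("Weight names do not match the cause list.")
    }
    w <- setNames(w, names(weights))[cl]
  }
  if (length(w) != length(cl)) abort("Need one weight per cause.")
  if (any(w < 0)) abort("Weights must be non-negative.")
  if (abs(sum(w) - 1) > SUM_TOL) abort("Weights must sum to 1.")
  unname(w)
}

#' Cohen's kappa for a multiclass confusion table
#'
#' `kappa = (P_obs - P_exp) / (1 - P_exp)` where `P_obs` is the overall
#' agreement fraction (diagonal over total) and `P_exp` the agreement expected
#' from the product of the true and predicted marginals. Kappa corrects for a
#' chance assigner that knows the test set's composition, which is exactly why
#' it varies with that composition; it is reported here as the legacy
#' comparator to [overall_ccc()].
#'
#' @param conf A `va_confusion` object.
#' @return A single number `<= 1`; `NA` when `P_exp = 1` (all mass in one cell).
#' @export
cohen_kappa <- function(conf) {
  stopifnot(inherits(conf, "va_confusion"))
  g <- grand_total(conf)
  if (g <= 0) abort("Empty confusion table.")
  p_obs <- sum(diag(conf$counts)) / g
  p_exp <- sum(row_totals(conf) * col_totals(conf)) / g^2
  if (1 - p_exp <= SUM_TOL) return(NA_real_)
  (p_obs - p_exp) / (1 - p_exp)
}

#' Top-k concordance for ranked predictions
#'
#' The fraction of deaths whose true cause appears among the `k` causes the
#' method ranked highest. Single-cause predictions are treated as rank-1
#' lists. Monotone non-decreasing in `k` by construction.
#'
#' @param data A `va_data` object.
#' @param k Vector of positive integers, each `<= N`.
#' @return A tibble `(k, concordance)`.
#' @export
top_k_concordance <- function(data, k) {
  stopifnot(inherits(data, "va_data"))
  N <- n_causes(data)
  k <- as.integer(k)
  if (any(k < 1) || any(k > N)) {
    abort(sprintf("`k` must lie in 1..%d (the number of causes).", N))
  }
  rank_of_true <- true_cause_rank(data)
  tibble(k = k,
         concordance = vapply(k, function(kk) {
           mean(!is.na(rank_of_true) & rank_of_true <= kk)
         }, numeric(1)))
}

# rank position of the true cause in each death's list (NA if unlisted)
true_cause_rank <- function(data) {
  if (!is_ranked(data)) {
    return(ifelse(data$predicted_cause == data$true_cause, 1L, NA_integer_))
  }
  mapply(function(p, tc) {
    r <- match(tc, p$cause)
    if (is.na(r)) NA_integer_ else as.integer(r)
  }, data$prediction, data$true_cause)
}

#' Chance level of top-k concordance under random assignment
#'
#' `PC(k)` is the probability that the true cause lands in the top `k` of a
#' ranking produced with no information. Under the default `"rank"` convention
#' a random ranking is a uniform random permutation of the cause list, giving
#' `PC(k) = k/N`; this satisfies both anchor points `PC(1) = 1/N` and
#' `PC(N) = 1`. The `"replacement"` convention instead draws `k` independent
#' guesses with replacement, `PC(k) = 1 - ((N-1)/N)^k`; it is offered for
#' sensitivity analysis but does not reach 1 at `k = N`.
#'
#' @param k Vector of positive integers `<= n_causes`.
#' @param n_causes Number of causes N (`>= 2`).
#' @param convention `"rank"` (default) or `"replacement"`.
#' @return Numeric vector of chance concordances.
#' @export
partial_chance_concordance <- function(k, n_causes,
                                       convention = c("rank", "replacement")) {
  convention <- match.arg(convention)
  n_causes <- as.integer(n_causes)
  if (n_causes < 2) abort("Need at least two causes.")
  k <- as.integer(k)
  if (any(k < 1) || any(k > n_causes)) {
    abort(sprintf("`k` must lie in 1..%d.", n_causes))
  }
  switch(convention,
         rank = k / n_causes,
         replacement = 1 - ((n_causes - 1) / n_causes)^k)
}

#' Partial chance-corrected concordance PCCC(k)
#'
#' `PCCC(k) = (C(k) - PC(k)) / (1 - PC(k))` where `C(k)` is the observed
#' top-k concordance and `PC(k)` its chance level. At `k = N` every ranking
#' contains the true cause, `PC(N) = 1`, and the metric is undefined, so
#' `k = N` is rejected. PCCC(k) need not increase with `k` even though `C(k)`
#' does.
#'
#' @inheritParams top_k_concordance
#' @inheritParams partial_chance_concordance
#' @return A tibble `(k, concordance, chance, pccc)`.
#' @export
pccc <- function(data, k, convention = c("rank", "replacement")) {
  convention <- match.arg(convention)
  N <- n_causes(data)
  k <- as.integer(k)
  if (any(k == N)) {
    abort(sprintf(
      "PCCC(k) is not defined at k = N = %d (chance concordance is 1).", N))
  }
  ck <- top_k_concordance(data, k)
  pc <- partial_chance_concordance(k, N, convention)
  tibble(k = ck$k, concordance = ck$concordance, chance = pc,
         pccc = (ck$concordance - pc) / (1 - pc))
}
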