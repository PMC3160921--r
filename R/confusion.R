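#' Tally a confusion table from a validation dataset
#'
#' Cross-tabulates true against predicted causes. For ranked data the
#' top-ranked cause is used. Publishing this full N x N table alongside any
#' summary metric is part of the recommended reporting standard: readers who
#' distrust a one-number summary can recompute anything from it.
#'
#' @param data A `va_data` object.
#' @return A `va_confusion` object: a list with `counts` (N x N numeric matrix,
#'   rows = true cause, columns = predicted cause, cause dimnames) and the
#'   cause list. Marginals are available via [row_totals()] / [col_totals()].
#' @examples
#' d <- va_data(data.frame(id = 1:3, true_cause = c("A", "A", "B"),
#'                         predicted_cause = c("A", "B", "B")))
#' confusion_table(d)
#' @export
confusion_table <- function(data) {
  stopifnot(inherits(data, "va_data"))
  cl <- causes(data)
  tr <- factor(data$true_cause, levels = cl)
  pr <- factor(top_cause(data), levels = cl)
  counts <- unclass(table(tr, pr))
  dimnames(counts) <- list(cl, cl)
  new_va_confusion(counts + 0, cl)
}

#' Expected confusion table for a misclassification matrix
#'
#' Given a method's misclassification matrix and a test-set cause composition,
#' the expected (infinite-sample) confusion table has fractional "counts"
#' `total * composition[i] * p[i, j]`. This analytic mode removes all Monte
#' Carlo noise: metrics computed from it are the exact values a simulated
#' dataset converges to as the number of deaths grows.
#'
#' @param method A `misclass_matrix`.
#' @param composition True cause composition: a `(cause, csmf)` tibble or a
#'   (named) numeric vector over the method's cause list, summing to 1.
#' @param total Scale for the table (default 1, i.e. fractions of deaths).
#' @return A `va_confusion` object with fractional counts.
#' @export
analytic_confusion <- function(method, composition, total = 1) {
  stopifnot(inherits(method, "misclass_matrix"))
  p <- as_csmf(composition, causes(method))
  counts <- total * p * unclass(method)  # recycles p down columns = diag(p) %*% M
  new_va_confusion(counts, causes(method))
}

new_va_confusion <- function(counts, cl) {
  structure(list(counts = counts, causes = cl),
            causes = cl, class = "va_confusion")
}

#' Confusion-table marginals
#'
#' @param conf A `va_confusion` object.
#' @return Named numeric vector of true-cause (row) or predicted-cause
#'   (column) totals; `grand_total()` returns the number of deaths.
#' @export
row_totals <- function(conf) rowSums(conf$counts)

#' @rdname row_totals
#' @export
col_totals <- function(conf) colSums(conf$counts)

#' @rdname row_totals
#' @export
grand_total <- function(conf) sum(conf$counts)

#' @export
as.matrix.va_confusion <- function(x, ...) x$counts

#' @export
print.va_confusion <- function(x, ...) {
  cat("Confusion table (rows = true cause, columns = predicted cause)\n")
  print(x$counts)
  invisible(x)
}

#' @describeIn confusion_table long-format tibble `(true_cause,
#'   predicted_cause, n)`, one row per cell.
#' @param x A `va_confusion` object.
#' @param ... Unused.
#' @export
tidy.va_confusion <- function(x, ...) {
  cl <- x$causes
  tibble(
    true_cause = rep(cl, times = length(cl)),
    predicted_cause = rep(cl, each = length(cl)),
    n = as.vector(x$counts)
  )
}

#' True and predicted cause-specific mortality fractions
#'
#' `csmf_true()` is the observed composition of the dataset's gold-standard
#' causes; `csmf_predicted()` is the composition the VA method implies. For
#' single-cause predictions the predicted CSMF is the fraction of deaths
#' assigned to each cause (the confusion table's column marginals divided by
#' the total); for ranked data it is the mean of the per-death probability
#' vectors.
#'
#' @param data A `va_data` object.
#' @return A tibble `(cause, csmf)` over the full cause list, summing to 1.
#' @export
csmf_true <- function(data) {
  stopifnot(inherits(data, "va_data"))
  cl <- causes(data)
  n <- table(factor(data$true_cause, levels = cl))
  tibble(cause = cl, csmf = as.vector(n) / nrow(data))
}

#' @rdname csmf_true
#' @export
csmf_predicted <- function(data) {
  stopifnot(inherits(data, "va_data"))
  cl <- causes(data)
  if (!is_ranked(data)) {
    n <- table(factor(data$predicted_cause, levels = cl))
    return(tibble(cause = cl, csmf = as.vector(n) / nrow(data)))
  }
  acc <- setNames(numeric(length(cl)), cl)
  for (p in data$prediction) acc[p$cause] <- acc[p$cause] + p$prob
  tibble(cause = cl, csmf = as.vector(acc) / nrow(data))
}

# coerce a composition given as (cause, csmf) tibble or (named) numeric into a
# validated numeric vector ordered by `cl`
as_csmf <- function(x, cl) {
  if (is.data.frame(x)) {
    if (!all(c("cause", "csmf") %in% names(x))) {
      abort("A CSMF data frame needs columns `cause` and `csmf`.")
    }
    if (!setequal(x$cause, cl) || nrow(x) != length(cl)) {
      abort("CSMF causes do not match the expected cause list.")
    }
    v <- setNames(x$csmf, x$cause)[cl]
  } else {
    v <- as.numeric(x)
    if (!is.null(names(x))) {
      if (!setequal(names(x), cl)) {
        abort("CSMF causes do not match the expected cause list.")
      }
      v <- setNames(v, names(x))[cl]
    } else if (length(v) != length(cl)) {
      abort("CSMF vector length does not match the cause list.")
    } else {
      names(v) <- cl
    }
  }
  if (any(is.na(v)) || any(v < -SUM_TOL) || any(v > 1 + SUM_TOL)) {
    abort("CSMF fractions must lie in [0, 1].")
  }
  if (abs(sum(v) - 1) > SUM_TOL) {
    abort(sprintf("CSMF fractions sum to %.12g, not 1 (tolerance 1e-9).", sum(v)))
  }
  pmin(pmax(v, 0), 1)
}
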