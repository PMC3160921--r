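#' Construct a VA validation dataset
#'
#' A validation dataset pairs a true (gold standard) cause of death with the
#' cause(s) a VA method assigned, one row per death. Two layouts are accepted:
#'
#' * **single-cause**: columns `id`, `true_cause`, `predicted_cause`;
#' * **ranked**: columns `id`, `true_cause`, then pairs `cause_1`, `prob_1`,
#'   `cause_2`, `prob_2`, ... giving a probability distribution over causes for
#'   each death. Probabilities must be non-negative and sum to one per death
#'   (tolerance `1e-9`); malformed rows are rejected, never renormalized.
#'
#' Cause labels are matched case-sensitively after trimming surrounding
#' whitespace, so `" Stroke "` and `"Stroke"` are the same cause but
#' `"stroke"` is not.
#'
#' @param data A data frame in one of the two layouts above.
#' @param causes Optional character vector fixing the cause list and its
#'   order. Defaults to the sorted set of causes observed in `data`. The cause
#'   list must have at least two entries for any metric computation.
#' @return A tibble of class `va_data`. Ranked input is stored in a
#'   `prediction` list-column of per-death tibbles (`cause`, `prob`), ordered
#'   by decreasing probability with ties broken by cause-list order. The cause
#'   list is carried in `attr(x, "causes")`.
#' @examples
#' d <- va_data(data.frame(
#'   id = 1:3, true_cause = c("A", "A", "B"),
#'   predicted_cause = c("A", "B", "B")
#' ))
#' causes(d)
#' @export
va_data <- function(data, causes = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) {
    abort("A validation dataset needs at least one death record.")
  }
  need <- c("id", "true_cause")
  if (!all(need %in% names(data))) {
    abort("`data` must have columns `id` and `true_cause`.")
  }
  ranked <- !("predicted_cause" %in% names(data))
  id <- as.character(data$id)
  if (anyDuplicated(id)) abort("Death identifiers must be unique.")
  true_cause <- trimws(as.character(data$true_cause))

  if (is.null(causes)) {
    seen <- true_cause
    if (!ranked) {
      seen <- c(seen, trimws(as.character(data$predicted_cause)))
    } else {
      cc <- grep("^cause_[0-9]+$", names(data), value = TRUE)
      seen <- c(seen, trimws(unlist(lapply(data[cc], as.character), use.names = FALSE)))
    }
    causes <- sort(unique(seen[!is.na(seen) & nzchar(seen)]))
  } else {
    causes <- trimws(as.character(causes))
  }
  validate_cause_list(causes)
  check_membership(true_cause, causes, id, what = "true cause")

  if (!ranked) {
    predicted_cause <- trimws(as.character(data$predicted_cause))
    check_membership(predicted_cause, causes, id, what = "predicted cause")
    out <- tibble(id = id, true_cause = true_cause,
                  predicted_cause = predicted_cause)
  } else {
    cause_cols <- grep("^cause_[0-9]+$", names(data), value = TRUE)
    prob_cols <- sub("^cause_", "prob_", cause_cols)
    if (length(cause_cols) == 0 || !all(prob_cols %in% names(data))) {
      abort(paste("Ranked input needs paired `cause_k`/`prob_k` columns",
                  "(or a `predicted_cause` column for single-cause input)."))
    }
    ord <- order(as.integer(sub("^cause_", "", cause_cols)))
    cause_cols <- cause_cols[ord]
    prob_cols <- prob_cols[ord]
    cmat <- vapply(data[cause_cols], function(x) trimws(as.character(x)),
                   character(nrow(data)))
    pmat <- vapply(data[prob_cols], as.numeric, numeric(nrow(data)))
    cmat <- matrix(cmat, nrow = nrow(data))
    pmat <- matrix(pmat, nrow = nrow(data))
    prediction <- lapply(seq_len(nrow(data)), function(i) {
      keep <- !is.na(cmat[i, ]) & nzchar(cmat[i, ])
      ranked_prediction(cmat[i, keep], pmat[i, keep], causes, id[i])
    })
    out <- tibble(id = id, true_cause = true_cause, prediction = prediction)
  }
  new_va_data(out, causes, ranked)
}

new_va_data <- function(tbl, causes, ranked) {
  structure(as_tibble(tbl),
            causes = causes, ranked = ranked,
            class = c("va_data", class(as_tibble(tbl))))
}

validate_cause_list <- function(causes) {
  if (length(causes) < 2) abort("The cause list needs at least two causes.")
  if (anyDuplicated(causes)) abort("Cause labels must be unique.")
  if (any(is.na(causes) | !nzchar(causes))) {
    abort("Cause labels must be non-empty strings.")
  }
  invisible(causes)
}

check_membership <- function(x, causes, id, what) {
  bad <- which(!(x %in% causes))
  if (length(bad)) {
    abort(sprintf("Record '%s' has %s '%s' which is not in the cause list.",
                  id[bad[1]], what, x[bad[1]]))
  }
  invisible(x)
}

# one death's ranked prediction: validated, sorted by decreasing probability,
# ties broken by cause-list order (deterministic)
ranked_prediction <- function(cs, ps, causes, id) {
  if (anyDuplicated(cs)) {
    abort(sprintf("Record '%s' lists a cause more than once.", id))
  }
  check_membership(cs, causes, rep(id, length(cs)), what = "predicted cause")
  if (any(is.na(ps)) || any(ps < 0)) {
    abort(sprintf("Record '%s' has negative or missing probabilities.", id))
  }
  if (abs(sum(ps) - 1) > SUM_TOL) {
    abort(sprintf(
      "Record '%s': probabilities sum to %.12g, not 1 (tolerance 1e-9).",
      id, sum(ps)))
  }
  ord <- order(-ps, match(cs, causes))
  tibble(cause = cs[ord], prob = ps[ord])
}

#' Cause list of a VA object
#'
#' @param x A `va_data`, `va_confusion`, or misclassification matrix object.
#' @return Character vector of cause labels in their fixed order.
#' @export
causes <- function(x) {
  out <- attr(x, "causes")
  if (is.null(out) && is.matrix(x)) out <- rownames(x)
  if (is.null(out)) abort("No cause list attached to this object.")
  out
}

#' @rdname causes
#' @export
n_causes <- function(x) length(causes(x))

#' Is a dataset ranked (probabilistic)?
#'
#' @param x A `va_data` object.
#' @return `TRUE` when each death carries a ranked probability distribution
#'   over causes, `FALSE` for single-cause predictions.
#' @export
is_ranked <- function(x) isTRUE(attr(x, "ranked"))

#' Top-ranked predicted cause per death
#'
#' For single-cause data this is the predicted cause; for ranked data, the
#' cause with the highest probability (ties broken by cause-list order).
#'
#' @param x A `va_data` object.
#' @return Character vector, one cause per record.
#' @export
top_cause <- function(x) {
  stopifnot(inherits(x, "va_data"))
  if (!is_ranked(x)) return(x$predicted_cause)
  vapply(x$prediction, function(p) p$cause[[1]], character(1))
}

#' Read / write validation datasets as CSV
#'
#' The on-disk dialect is UTF-8 CSV with a header row: either
#' `id,true_cause,predicted_cause` or the ranked layout
#' `id,true_cause,cause_1,prob_1,cause_2,prob_2,...`.
#'
#' @param path File path.
#' @param causes Optional cause list passed to [va_data()].
#' @return `read_va_csv()` returns a `va_data` tibble; `write_va_csv()`
#'   invisibly returns `path`.
#' @export
read_va_csv <- function(path, causes = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  va_data(df, causes = causes)
}

#' @rdname read_va_csv
#' @param x A `va_data` object to write.
#' @export
write_va_csv <- function(x, path) {
  stopifnot(inherits(x, "va_data"))
  if (!is_ranked(x)) {
    df <- as.data.frame(x[c("id", "true_cause", "predicted_cause")])
  } else {
    kmax <- max(vapply(x$prediction, nrow, integer(1)))
    df <- data.frame(id = x$id, true_cause = x$true_cause,
                     stringsAsFactors = FALSE)
    for (k in seq_len(kmax)) {
      df[[paste0("cause_", k)]] <-
        vapply(x$prediction, function(p) {
          if (nrow(p) >= k) p$cause[[k]] else NA_character_
        }, character(1))
      df[[paste0("prob_", k)]] <-
        vapply(x$prediction, function(p) {
          if (nrow(p) >= k) p$prob[[k]] else NA_real_
        }, numeric(1))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Misclassification matrix of a VA method
#'
#' The row-stochastic matrix `p[i, j] = P(predicted cause j | true cause i)`
#' is the fundamental attribute of a cause-assignment method: together with a
#' test-set cause composition it determines every standard validation metric.
#'
#' @param probs Numeric N x N matrix; rows index the true cause, columns the
#'   predicted cause. Each row must sum to 1 (tolerance `1e-9`).
#' @param causes Character vector of cause labels; defaults to `rownames(probs)`.
#' @return A numeric matrix of class `misclass_matrix` with cause dimnames.
#' @seealso [va_method()] for the bundled hypothetical methods.
#' @export
misclass_matrix <- function(probs, causes = rownames(probs)) {
  probs <- as.matrix(probs)
  if (is.null(causes)) abort("Supply cause labels (or name the matrix rows).")
  causes <- trimws(as.character(causes))
  validate_cause_list(causes)
  if (nrow(probs) != length(causes) || ncol(probs) != length(causes)) {
    abort("`probs` must be square with one row/column per cause.")
  }
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("Misclassification probabilities must lie in [0, 1].")
  }
  bad <- which(abs(rowSums(probs) - 1) > SUM_TOL)
  if (length(bad)) {
    abort(sprintf("Row '%s' sums to %.12g, not 1 (tolerance 1e-9).",
                  causes[bad[1]], rowSums(probs)[bad[1]]))
  }
  dimnames(probs) <- list(causes, causes)
  structure(probs, causes = causes,
            class = c("misclass_matrix", "matrix", "array"))
}

#' @rdname misclass_matrix
#' @param path File path. The CSV has cause labels in the first row and first
#'   column and the row-stochastic probabilities in the body.
#' @export
read_misclass_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        row.names = 1)
  misclass_matrix(as.matrix(df), causes = rownames(df))
}

#' @rdname misclass_matrix
#' @param m A `misclass_matrix` to write.
#' @export
write_misclass_csv <- function(m, path) {
  stopifnot(inherits(m, "misclass_matrix"))
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
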