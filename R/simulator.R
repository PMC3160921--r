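#' Bundled hypothetical VA methods
#'
#' Two three-cause misclassification matrices used throughout the package's
#' worked examples. Method 2 differs from method 1 only in assigning deaths
#' from cause A to cause A with higher probability (0.80 vs 0.70), so it is
#' unambiguously the better method — which is what makes single-test-set
#' comparisons that favour method 1 so instructive.
#'
#' @param name `"method1"` or `"method2"`.
#' @return A [misclass_matrix()] over causes A, B, C.
#' @examples
#' va_method("method1")
#' @export
va_method <- function(name = c("method1", "method2")) {
  name <- match.arg(name)
  cl <- c("A", "B", "C")
  m <- switch(name,
    method1 = rbind(c(0.700, 0.030, 0.270),
                    c(0.040, 0.600, 0.360),
                    c(0.065, 0.585, 0.350)),
    method2 = rbind(c(0.800, 0.020, 0.180),
                    c(0.040, 0.600, 0.360),
                    c(0.065, 0.585, 0.350)))
  dimnames(m) <- list(cl, cl)
  misclass_matrix(m)
}

#' Simulate a method's predictions for given true causes
#'
#' Each death's predicted cause is drawn independently from the
#' misclassification-matrix row of its true cause. This is how a hypothetical
#' method with known behaviour is turned into a concrete validation dataset.
#'
#' @param method A `misclass_matrix`.
#' @param true_causes Character vector of true causes (members of the
#'   method's cause list).
#' @return A single-cause `va_data` object with ids `"d1"`, `"d2"`, ...
#' @export
simulate_predictions <- function(method, true_causes) {
  stopifnot(inherits(method, "misclass_matrix"))
  cl <- causes(method)
  true_causes <- trimws(as.character(true_causes))
  idx <- match(true_causes, cl)
  if (anyNA(idx)) {
    abort(sprintf("True cause '%s' is not in the method's cause list.",
                  true_causes[which(is.na(idx))[1]]))
  }
  pred <- integer(length(idx))
  for (i in seq_along(cl)) {
    at <- which(idx == i)
    if (length(at)) {
      pred[at] <- sample.int(length(cl), length(at), replace = TRUE,
                             prob = method[i, ])
    }
  }
  va_data(tibble(id = paste0("d", seq_along(idx)),
                 true_cause = true_causes,
                 predicted_cause = cl[pred]),
          causes = cl)
}

#' Run the misclassification-matrix validation experiment
#'
#' The full study design: draw `n_draws` cause compositions from an
#' uninformative Dirichlet, build a test dataset per composition, score every
#' method on the *same* datasets (paired design), and collect every metric per
#' draw. Two evaluation modes:
#'
#' * `deaths_per_dataset = "analytic"` (default): expected fractions — the
#'   confusion table is `diag(p) %*% M` exactly, with no sampling noise. In
#'   this mode per-cause sensitivity and chance-corrected concordance are
#'   constant across draws (the composition-invariance that motivates CCC),
#'   while specificity, kappa and all CSMF error metrics still swing widely.
#' * an integer: that many deaths are sampled multinomially from the drawn
#'   composition and each method's predictions are simulated from its matrix
#'   rows; all methods share the same true-cause sequence per draw.
#'
#' @param methods Methods to evaluate: names of bundled methods (see
#'   [va_method()]) and/or a named list of `misclass_matrix` objects sharing
#'   one cause list.
#' @param n_draws Number of Dirichlet draws (default 500).
#' @param deaths_per_dataset `"analytic"` or a positive integer.
#' @param dirichlet_alpha Concentration parameter(s), default 1.
#' @param seed Root seed; each draw uses a derived substream.
#' @return A `va_experiment` object with elements `cause_results` (tibble:
#'   draw, method, cause, true_csmf, predicted_csmf, sensitivity,
#'   specificity, ccc, absolute_error, relative_error), `overall` (tibble:
#'   draw, method, kappa, overall_ccc, total_absolute_error, csmf_accuracy,
#'   n_undefined_ccc), and `config`. Undefined per-cause CCCs (causes with no
#'   true deaths in a draw) are excluded from that draw's equal-weight overall
#'   CCC; the exclusion count is reported per draw.
#' @seealso [compare_methods()], [summary_table()], [experiment_regressions()]
#' @export
run_validation_experiment <- function(methods = c("method1", "method2"),
                                      n_draws = 500,
                                      deaths_per_dataset = "analytic",
                                      dirichlet_alpha = 1, seed = 1) {
  methods <- normalize_methods(methods)
  cl <- causes(methods[[1]])
  for (m in methods) {
    if (!identical(causes(m), cl)) {
      abort("All methods must share the same cause list.")
    }
  }
  N <- length(cl)
  analytic <- identical(deaths_per_dataset, "analytic")
  if (!analytic) {
    deaths_per_dataset <- as.integer(deaths_per_dataset)
    if (is.na(deaths_per_dataset) || deaths_per_dataset < 1) {
      abort("`deaths_per_dataset` must be a positive integer or \"analytic\".")
    }
  }
  n_draws <- as.integer(n_draws)
  if (n_draws < 2) abort("`n_draws` must be >= 2.")

  cause_rows <- vector("list", n_draws)
  overall_rows <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    set.seed(draw_seed(seed, d))
    p <- rdirichlet(1, dirichlet_alpha, n_causes = N)[1, ]
    if (analytic) {
      true_frac <- p
      confs <- lapply(methods, analytic_confusion,
                      composition = setNames(p, cl))
    } else {
      n <- deaths_per_dataset
      true_idx <- sample.int(N, n, replace = TRUE, prob = p)
      true_frac <- tabulate(true_idx, N) / n
      confs <- lapply(methods, function(m) {
        pred <- integer(n)
        for (i in seq_len(N)) {
          at <- which(true_idx == i)
          if (length(at)) {
            pred[at] <- sample.int(N, length(at), replace = TRUE, prob = m[i, ])
          }
        }
        counts <- matrix(tabulate((true_idx - 1L) * N + pred, N * N),
                         N, N, byrow = TRUE, dimnames = list(cl, cl))
        new_va_confusion(counts, cl)
      })
    }
    cause_rows[[d]] <- purrr::imap(confs, function(conf, nm) {
      est <- col_totals(conf) / grand_total(conf)
      cm <- cause_metrics(conf)
      cm$draw <- d
      cm$method <- nm
      cm$true_csmf <- unname(true_frac)
      cm$predicted_csmf <- unname(est)
      cm$absolute_error <- abs(cm$predicted_csmf - cm$true_csmf)
      cm$relative_error <- ifelse(cm$true_csmf > 0,
                                  cm$absolute_error / cm$true_csmf, NA_real_)
      cm
    }) %>% bind_rows()
    overall_rows[[d]] <- purrr::imap(confs, function(conf, nm) {
      cm <- cause_metrics(conf)
      est <- col_totals(conf) / grand_total(conf)
      abs_err <- abs(est - true_frac)
      tibble(draw = d, method = nm,
             kappa = cohen_kappa(conf),
             overall_ccc = mean(cm$ccc, na.rm = TRUE),
             total_absolute_error = sum(abs_err),
             csmf_accuracy = 1 - sum(abs_err) / (2 * (1 - min(true_frac))),
             n_undefined_ccc = sum(is.na(cm$ccc)))
    }) %>% bind_rows()
  }
  cause_results <- bind_rows(cause_rows) %>%
    dplyr::select("draw", "method", "cause", "n_true", "true_csmf",
                  "predicted_csmf", "sensitivity", "specificity", "ccc",
                  "absolute_error", "relative_error")
  structure(list(cause_results = cause_results,
                 overall = bind_rows(overall_rows),
                 config = list(methods = names(methods), causes = cl,
                               n_draws = n_draws,
                               deaths_per_dataset =
                                 if (analytic) "analytic" else deaths_per_dataset,
                               dirichlet_alpha = dirichlet_alpha, seed = seed)),
            class = "va_experiment")
}

normalize_methods <- function(methods) {
  if (inherits(methods, "misclass_matrix")) methods <- list(method = methods)
  if (is.character(methods)) {
    methods <- setNames(lapply(methods, va_method), methods)
  }
  if (!is.list(methods) || !length(methods)) {
    abort("Supply method names or a named list of misclassification matrices.")
  }
  if (is.null(names(methods)) || any(!nzchar(names(methods)))) {
    abort("Methods must be named.")
  }
  for (m in methods) {
    if (!inherits(m, "misclass_matrix")) {
      abort("Each method must be a `misclass_matrix`.")
    }
  }
  methods
}

#' Paired per-cause win counts between two methods
#'
#' For every draw of a paired experiment, which method had the strictly
#' smaller per-cause error? Ties (probability ~0 for continuous compositions,
#' but possible in finite-sample mode) are reported separately rather than
#' silently assigned. This is the comparison showing that an inferior method
#' can "win" on a sizeable share of single test sets.
#'
#' @param experiment A `va_experiment` containing both methods.
#' @param method_a,method_b Method names to compare.
#' @param metric Per-cause column to compare, smaller is better (default
#'   `"absolute_error"`).
#' @return A tibble `(cause, wins_a, wins_b, ties, share_a)` where `share_a`
#'   is `wins_a / n_draws`.
#' @export
compare_methods <- function(experiment, method_a, method_b,
                            metric = "absolute_error") {
  stopifnot(inherits(experiment, "va_experiment"))
  cr <- experiment$cause_results
  if (!metric %in% names(cr)) abort(sprintf("No per-cause metric '%s'.", metric))
  for (m in c(method_a, method_b)) {
    if (!m %in% cr$method) abort(sprintf("Method '%s' not in the experiment.", m))
  }
  a <- cr[cr$method == method_a, c("draw", "cause", metric)]
  b <- cr[cr$method == method_b, c("draw", "cause", metric)]
  names(a)[3] <- "va"
  names(b)[3] <- "vb"
  j <- dplyr::inner_join(a, b, by = c("draw", "cause"))
  if (nrow(j) != nrow(a) || nrow(j) != nrow(b)) {
    abort("Methods are not paired draw-for-draw.")
  }
  j %>%
    group_by(.data$cause) %>%
    summarise(wins_a = sum(.data$va < .data$vb),
              wins_b = sum(.data$vb < .data$va),
              ties = sum(.data$va == .data$vb),
              share_a = mean(.data$va < .data$vb),
              .groups = "drop")
}

#' Table-2-style metric summary of an experiment
#'
#' Mean, median, max and min of every per-cause and overall metric across
#' draws, per method — the layout that exposes which metrics are stable
#' across cause compositions (sensitivity, CCC) and which are not
#' (specificity, kappa, CSMF errors).
#'
#' @param experiment A `va_experiment`.
#' @return A tibble `(method, cause, metric, mean, median, max, min)`;
#'   overall metrics carry `cause = "(overall)"`. Undefined values are
#'   excluded from the statistics.
#' @export
summary_table <- function(experiment) {
  stopifnot(inherits(experiment, "va_experiment"))
  per_cause <- experiment$cause_results %>%
    tidyr::pivot_longer(c("sensitivity", "specificity", "ccc",
                          "absolute_error", "relative_error"),
                        names_to = "metric", values_to = "value") %>%
    group_by(.data$method, .data$cause, .data$metric)
  overall <- experiment$overall %>%
    tidyr::pivot_longer(c("kappa", "overall_ccc", "total_absolute_error",
                          "csmf_accuracy"),
                        names_to = "metric", values_to = "value") %>%
    mutate(cause = "(overall)") %>%
    group_by(.data$method, .data$cause, .data$metric)
  bind_rows(
    summarise(per_cause, mean = mean(.data$value, na.rm = TRUE),
              median = median(.data$value, na.rm = TRUE),
              max = suppressWarnings(max(.data$value, na.rm = TRUE)),
              min = suppressWarnings(min(.data$value, na.rm = TRUE)),
              .groups = "drop"),
    summarise(overall, mean = mean(.data$value, na.rm = TRUE),
              median = median(.data$value, na.rm = TRUE),
              max = suppressWarnings(max(.data$value, na.rm = TRUE)),
              min = suppressWarnings(min(.data$value, na.rm = TRUE)),
              .groups = "drop")
  )
}

#' Estimated-versus-true regressions for an experiment
#'
#' Per method and cause, OLS of the estimated CSMF on the true CSMF across
#' draws (see [csmf_regression()]).
#'
#' @param experiment A `va_experiment`.
#' @inheritParams csmf_regression
#' @return A tibble `(method, cause, n, intercept, slope, rmse)`.
#' @export
experiment_regressions <- function(experiment, df_correction = FALSE) {
  stopifnot(inherits(experiment, "va_experiment"))
  experiment$cause_results %>%
    group_by(.data$method, .data$cause) %>%
    summarise(fit_one_csmf_ols(.data$true_csmf, .data$predicted_csmf,
                               df_correction), .groups = "drop")
}

#' @describeIn run_validation_experiment per-draw, per-method, per-cause
#'   results as a long tibble.
#' @param x A `va_experiment` object.
#' @param ... Unused.
#' @export
tidy.va_experiment <- function(x, ...) x$cause_results

#' @describeIn run_validation_experiment one-row-per-method headline summary:
#'   median CSMF accuracy, mean overall CCC, mean kappa, mean total absolute
#'   CSMF error.
#' @export
glance.va_experiment <- function(x, ...) {
  x$overall %>%
    group_by(.data$method) %>%
    summarise(n_draws = dplyr::n(),
              median_csmf_accuracy = median(.data$csmf_accuracy),
              mean_overall_ccc = mean(.data$overall_ccc),
              mean_kappa = mean(.data$kappa, na.rm = TRUE),
              mean_total_absolute_error = mean(.data$total_absolute_error),
              .groups = "drop")
}

#' @export
print.va_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("VA validation experiment: %d draws, %s deaths/dataset, methods: %s\n",
              cfg$n_draws, as.character(cfg$deaths_per_dataset),
              paste(cfg$methods, collapse = ", ")))
  print(glance(x))
  invisible(x)
}
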