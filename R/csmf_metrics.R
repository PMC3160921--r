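#' Per-cause CSMF errors
#'
#' Absolute error `|pred_j - true_j|` and relative error
#' `|pred_j - true_j| / true_j` for each cause. The relative error is
#' undefined (`NA`) for causes with a true fraction of zero, which is why its
#' summaries explode across resampled compositions; the absolute error is the
#' quantity whose public-health consequences scale with misallocated deaths.
#'
#' @param true,pred Cause compositions over the same cause list: `(cause,
#'   csmf)` tibbles (e.g. from [csmf_true()] / [csmf_predicted()]) or (named)
#'   numeric vectors summing to 1.
#' @return A tibble `(cause, true_csmf, predicted_csmf, absolute_error,
#'   relative_error)`.
#' @export
csmf_errors <- function(true, pred) {
  cl <- csmf_cause_list(true, pred)
  t_ <- as_csmf(true, cl)
  p_ <- as_csmf(pred, cl)
  tibble(
    cause = cl,
    true_csmf = unname(t_),
    predicted_csmf = unname(p_),
    absolute_error = abs(unname(p_ - t_)),
    relative_error = unname(ifelse(t_ > 0, abs(p_ - t_) / t_, NA_real_))
  )
}

csmf_cause_list <- function(true, pred) {
  cl <- if (is.data.frame(true)) true$cause else names(true)
  if (is.null(cl)) {
    cl2 <- if (is.data.frame(pred)) pred$cause else names(pred)
    cl <- if (is.null(cl2)) as.character(seq_along(as.numeric(true))) else cl2
  }
  validate_cause_list(cl)
  cl
}

#' Maximum possible total absolute CSMF error
#'
#' The worst possible prediction assigns 100% of deaths to the cause with the
#' smallest true fraction; its total absolute error, `2 * (1 - min_j true_j)`,
#' bounds the total absolute error of *any* prediction and is the
#' normalizing denominator of [csmf_accuracy()].
#'
#' @param true True cause composition (tibble or numeric vector, N >= 2).
#' @return A single number in `(1, 2]`.
#' @export
csmf_max_error <- function(true) {
  cl <- csmf_cause_list(true, true)
  if (length(cl) < 2) abort("The maximum-error bound needs at least two causes.")
  t_ <- as_csmf(true, cl)
  2 * (1 - min(t_))
}

#' CSMF accuracy
#'
#' `1 - sum_j |pred_j - true_j| / (2 * (1 - min_j true_j))`: total absolute
#' CSMF error rescaled against the worst possible assignment, so that 1 means
#' the predicted composition is exact and 0 means the method is no better
#' than putting every death on the smallest true cause. Because the
#' denominator adapts to the cause list, accuracies are comparable across
#' studies with different numbers of causes.
#'
#' @inheritParams csmf_errors
#' @return A single number in `[0, 1]`.
#' @examples
#' csmf_accuracy(c(A = 0.5, B = 0.3, C = 0.2), c(A = 0.4, B = 0.3, C = 0.3))
#' @export
csmf_accuracy <- function(true, pred) {
  cl <- csmf_cause_list(true, pred)
  t_ <- as_csmf(true, cl)
  p_ <- as_csmf(pred, cl)
  1 - sum(abs(p_ - t_)) / csmf_max_error(t_)
}

#' Estimated-versus-true CSMF regression diagnostics
#'
#' Across many test datasets with varying composition, ordinary least squares
#' of the estimated CSMF on the true CSMF summarizes a method's behaviour per
#' cause: the intercept (alpha) is how much of the cause the method reports
#' when the cause is absent; the slope (beta) is how much the estimate rises
#' per unit of true fraction (below 1 for essentially all real methods, which
#' therefore overestimate small causes and underestimate large ones); the
#' RMSE is the residual standard deviation. RMSE uses the maximum-likelihood
#' denominator `n` by default; set `df_correction = TRUE` for the usual
#' regression denominator `n - 2`.
#'
#' @param draws Long-format tibble with columns `cause`, `true_csmf`,
#'   `predicted_csmf`, one row per (draw, cause) — e.g. `tidy()` of a
#'   [run_validation_experiment()] result, or the per-draw trace of
#'   [median_over_draws()].
#' @param df_correction Use `n - 2` in the RMSE denominator (default `FALSE`).
#' @return A tibble `(cause, n, intercept, slope, rmse)`.
#' @export
csmf_regression <- function(draws, df_correction = FALSE) {
  stopifnot(is.data.frame(draws))
  need <- c("cause", "true_csmf", "predicted_csmf")
  if (!all(need %in% names(draws))) {
    abort("`draws` needs columns cause, true_csmf, predicted_csmf.")
  }
  draws %>%
    group_by(.data$cause) %>%
    summarise(fit_one_csmf_ols(.data$true_csmf, .data$predicted_csmf,
                               df_correction), .groups = "drop")
}

fit_one_csmf_ols <- function(x, y, df_correction) {
  n <- length(x)
  if (n < 3) abort("CSMF regression needs at least 3 dataset pairs per cause.")
  if (stats::var(x) <= 0) {
    abort("True fractions are constant; the slope is unidentifiable.")
  }
  fit <- lm(y ~ x)
  denom <- if (df_correction) n - 2 else n
  tibble(n = n,
         intercept = unname(coef(fit)[1]),
         slope = unname(coef(fit)[2]),
         rmse = sqrt(sum(stats::residuals(fit)^2) / denom))
}
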