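#' Build a metric report for one validation dataset
#'
#' Bundles everything the reporting standard asks for: the full N x N
#' confusion matrix (so any reader can recompute whatever summary they
#' prefer), per-cause sensitivity/specificity/CCC, Cohen's kappa, the overall
#' chance-corrected concordance with the weights actually used, PCCC(k) for
#' requested `k`, the true and predicted CSMFs with per-cause errors, and
#' CSMF accuracy — plus metadata echoing every configuration choice so each
#' number is traceable.
#'
#' @param data A `va_data` object.
#' @param k Integer vector of top-k values for PCCC (ranked data; `k = N` is
#'   rejected as undefined). Default `NULL` skips PCCC.
#' @param weights Weight scheme for [overall_ccc()].
#' @param pc_convention Chance convention for [partial_chance_concordance()].
#' @param seed Optional seed to record in the metadata (the metrics
#'   themselves are deterministic given the data).
#' @return A list of class `va_report`.
#' @export
va_report <- function(data, k = NULL, weights = "equal",
                      pc_convention = "rank", seed = NULL) {
  stopifnot(inherits(data, "va_data"))
  conf <- confusion_table(data)
  per_cause <- cause_metrics(conf)
  n_undef <- sum(is.na(per_cause$sensitivity)) +
    sum(is.na(per_cause$specificity))
  occ <- withCallingHandlers(
    overall_ccc(conf, weights = weights),
    warning = function(w) invokeRestart("muffleWarning"))
  true <- csmf_true(data)
  pred <- csmf_predicted(data)
  errs <- csmf_errors(true, pred)
  pccc_block <- NULL
  if (!is.null(k)) {
    pccc_block <- pccc(data, k, convention = pc_convention)
  }
  structure(list(
    metadata = list(
      tool = "vametrics", version = as.character(utils::packageVersion("vametrics")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed, weights = if (is.character(weights)) weights else "user",
      pc_convention = pc_convention,
      prediction_mode = if (is_ranked(data)) "ranked" else "single",
      n_records = nrow(data), n_causes = n_causes(data),
      n_undefined_metrics = n_undef
    ),
    causes = causes(data),
    confusion = unclass(as.matrix(conf)),
    per_cause = per_cause,
    overall = list(
      kappa = cohen_kappa(conf),
      overall_ccc = occ,
      weights_used = resolve_weights(weights, conf),
      pccc = pccc_block
    ),
    csmf = list(true = true, predicted = pred, errors = errs,
                accuracy = csmf_accuracy(true, pred))
  ), class = "va_report")
}

#' Resampled metric report for a validation dataset
#'
#' Applies the Dirichlet-resampling protocol to a dataset and reports the
#' median overall chance-corrected concordance and median CSMF accuracy
#' across draws — the recommended headline numbers — together with the draw
#' traces, running medians, and stabilization indices.
#'
#' @param data A `va_data` object with at least one death per cause.
#' @param config A [resampling_config()].
#' @return A list of class `va_resample_report`: the base [va_report()] for
#'   the source data plus a `medians` block and the two `va_resampling`
#'   objects (`ccc_runs`, `accuracy_runs`).
#' @export
resample_report <- function(data, config = resampling_config()) {
  stopifnot(inherits(data, "va_data"))
  have <- table(factor(data$true_cause, levels = causes(data)))
  if (any(have == 0)) {
    abort(sprintf("Cause '%s' has no deaths in the source dataset.",
                  causes(data)[which(have == 0)[1]]))
  }
  eval_ccc <- function(d) {
    withCallingHandlers(
      overall_ccc(confusion_table(d)),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  eval_acc <- function(d) csmf_accuracy(csmf_true(d), csmf_predicted(d))
  ccc_runs <- withCallingHandlers(
    median_over_draws(data, eval_ccc, config),
    warning = function(w) invokeRestart("muffleWarning"))
  acc_runs <- withCallingHandlers(
    median_over_draws(data, eval_acc, config),
    warning = function(w) invokeRestart("muffleWarning"))
  base <- va_report(data, seed = config$seed)
  structure(list(
    report = base,
    config = unclass(config),
    medians = list(
      overall_ccc = ccc_runs$median,
      csmf_accuracy = acc_runs$median,
      n_draws = acc_runs$n_draws_used,
      n_undefined_ccc = ccc_runs$n_undefined,
      ccc_stabilized_at = ccc_runs$stabilized_at,
      accuracy_stabilized_at = acc_runs$stabilized_at
    ),
    ccc_runs = ccc_runs,
    accuracy_runs = acc_runs
  ), class = "va_resample_report")
}

#' Write / read a metric report as JSON
#'
#' Values are written at full precision; rounding is a presentation concern
#' left to rendered tables. `NA` (undefined metric) becomes JSON `null`.
#' Reports round-trip: reading a written report and writing it again yields
#' identical bytes.
#'
#' @param report A `va_report` or `va_resample_report`.
#' @param path Output path.
#' @return `write_va_report()` invisibly returns `path`; `read_va_report()`
#'   returns the parsed report as nested lists/data frames.
#' @export
write_va_report <- function(report, path) {
  x <- serialize_report(report)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

serialize_report <- function(report) {
  if (inherits(report, "va_resample_report")) {
    return(list(report = serialize_report(report$report),
                config = report$config,
                medians = report$medians,
                ccc_trace = as.data.frame(report$ccc_runs$trace),
                accuracy_trace = as.data.frame(report$accuracy_runs$trace),
                ccc_running_median = as.data.frame(report$ccc_runs$running_median),
                accuracy_running_median =
                  as.data.frame(report$accuracy_runs$running_median)))
  }
  x <- unclass(report)
  x$confusion <- as.data.frame(x$confusion)
  x$per_cause <- as.data.frame(x$per_cause)
  x$overall$pccc <- if (is.null(x$overall$pccc)) NULL else
    as.data.frame(x$overall$pccc)
  x$csmf$true <- as.data.frame(x$csmf$true)
  x$csmf$predicted <- as.data.frame(x$csmf$predicted)
  x$csmf$errors <- as.data.frame(x$csmf$errors)
  x
}

#' @rdname write_va_report
#' @export
read_va_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Export a per-draw trace as CSV
#'
#' Writes the long per-draw table (draw id, composition, metric value) of a
#' resampling run, or the running-median curve, for external plotting.
#'
#' @param runs A `va_resampling` object.
#' @param path Output path.
#' @param what `"trace"` (default) or `"running_median"`.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(runs, path, what = c("trace", "running_median")) {
  stopifnot(inherits(runs, "va_resampling"))
  what <- match.arg(what)
  utils::write.csv(as.data.frame(runs[[what]]), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.va_report <- function(x, ...) {
  cat(sprintf("VA metric report (%s mode, %d deaths, %d causes)\n",
              x$metadata$prediction_mode, x$metadata$n_records,
              x$metadata$n_causes))
  cat(sprintf("  Overall CCC (%s weights): %.4f | kappa: %.4f | CSMF accuracy: %.4f\n",
              x$metadata$weights, x$overall$overall_ccc, x$overall$kappa,
              x$csmf$accuracy))
  print(x$per_cause, n = Inf)
  invisible(x)
}
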