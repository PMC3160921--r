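#' Draw cause compositions from a Dirichlet distribution
#'
#' An *uninformative* Dirichlet (all concentration parameters 1) is uniform on
#' the simplex: it covers every possible cause composition evenly, with mean
#' equal cause fractions. This is the distribution used to vary the test-set
#' composition in the validation protocol. Draws use the gamma representation
#' (`G_i ~ Gamma(alpha_i, 1)`, normalized).
#'
#' @param n Number of draws.
#' @param alpha Positive concentration parameters, one per cause (a scalar is
#'   recycled).
#' @param n_causes Number of causes when `alpha` is scalar.
#' @return `rdirichlet()` returns an `n x N` matrix of compositions;
#'   `draw_composition()` returns a single draw as a `(cause, csmf)` tibble.
#' @export
rdirichlet <- function(n, alpha, n_causes = length(alpha)) {
  if (length(alpha) == 1) alpha <- rep(alpha, n_causes)
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    abort("Dirichlet concentration parameters must be positive.")
  }
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' @rdname rdirichlet
#' @param causes Character vector of cause labels (N >= 2).
#' @export
draw_composition <- function(causes, alpha = 1) {
  validate_cause_list(causes)
  p <- rdirichlet(1, alpha, n_causes = length(causes))[1, ]
  tibble(cause = causes, csmf = p)
}

#' Configuration for Dirichlet resampling runs
#'
#' @param n_draws Number of resampled test datasets (default 500; the
#'   protocol calls for at least 100).
#' @param deaths_per_dataset Deaths per resampled dataset (default 1000), or
#'   `"analytic"` to evaluate expected fractions instead of sampled deaths
#'   where the consumer supports it.
#' @param dirichlet_alpha Concentration parameter(s); 1 = uniform simplex.
#' @param seed Integer root seed; every random step of a run derives from it.
#' @param median_tolerance Relative change in the running median below which
#'   the median is considered stabilized (default 0.005, i.e. 0.5%).
#' @param check_interval Draws between running-median checkpoints (default 10).
#' @param stop_when_stable Stop a [median_over_draws()] run at the first
#'   stabilization checkpoint instead of completing `n_draws` (default
#'   `FALSE`: fixed-length runs, with stabilization monitored).
#' @return A list of class `resampling_config`.
#' @export
resampling_config <- function(n_draws = 500, deaths_per_dataset = 1000,
                              dirichlet_alpha = 1, seed = 1,
                              median_tolerance = 0.005, check_interval = 10,
                              stop_when_stable = FALSE) {
  analytic <- identical(deaths_per_dataset, "analytic")
  if (!analytic) {
    deaths_per_dataset <- as.integer(deaths_per_dataset)
    if (is.na(deaths_per_dataset) || deaths_per_dataset < 1) {
      abort("`deaths_per_dataset` must be a positive integer or \"analytic\".")
    }
  }
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 2) abort("`n_draws` must be >= 2.")
  if (n_draws < 100) {
    warn("Fewer than 100 draws; the protocol recommends 100 or more.")
  }
  if (any(dirichlet_alpha <= 0)) abort("`dirichlet_alpha` must be positive.")
  if (median_tolerance <= 0) abort("`median_tolerance` must be positive.")
  check_interval <- as.integer(check_interval)
  if (is.na(check_interval) || check_interval < 1) {
    abort("`check_interval` must be a positive integer.")
  }
  structure(list(n_draws = n_draws, deaths_per_dataset = deaths_per_dataset,
                 dirichlet_alpha = dirichlet_alpha, seed = as.integer(seed),
                 median_tolerance = median_tolerance,
                 check_interval = check_interval,
                 stop_when_stable = isTRUE(stop_when_stable)),
            class = "resampling_config")
}

# deterministic per-draw substream seed: draw results do not depend on the
# order in which draws are evaluated (kept below 2^31 - 1)
draw_seed <- function(seed, draw) {
  as.integer((as.double(seed) %% 2147483647) * 48271 %% 2147483647 +
               draw * 7919) %% 2147483647L
}

#' Resample a validation dataset to a target cause composition
#'
#' Cause counts are drawn multinomially from `target`, then records are
#' sampled uniformly with replacement within each true cause. Because the
#' per-cause prediction structure travels with the records, the method's
#' misclassification behaviour is preserved in expectation while the cause
#' composition changes — the core move of the validation protocol.
#'
#' @param source A `va_data` object; must contain at least one death for every
#'   cause with positive target fraction.
#' @param target Target composition (tibble or numeric vector over the source
#'   cause list).
#' @param n Number of deaths in the resampled dataset.
#' @return A `va_data` object with `n` records and fresh ids
#'   `"<orig>#<copy>"`.
#' @export
resample_dataset <- function(source, target, n) {
  stopifnot(inherits(source, "va_data"))
  cl <- causes(source)
  p <- as_csmf(target, cl)
  n <- as.integer(n)
  if (is.na(n) || n < 1) abort("`n` must be a positive integer.")
  have <- table(factor(source$true_cause, levels = cl))
  missing <- cl[p > 0 & as.vector(have) == 0]
  if (length(missing)) {
    abort(sprintf("Cause '%s' has positive target fraction but no source deaths.",
                  missing[1]))
  }
  counts <- as.vector(rmultinom(1, n, p))
  rows <- unlist(lapply(seq_along(cl), function(i) {
    if (counts[i] == 0) return(integer(0))
    pool <- which(source$true_cause == cl[i])
    pool[sample.int(length(pool), counts[i], replace = TRUE)]
  }))
  out <- source[rows, , drop = FALSE]
  out$id <- paste0(out$id, "#", seq_len(nrow(out)))
  new_va_data(out, cl, is_ranked(source))
}

#' Median of a metric across Dirichlet-resampled datasets
#'
#' Runs the full resampling protocol: draw a composition from the Dirichlet,
#' resample the source dataset to it, evaluate the metric, and report the
#' median across draws (the median, not the mean, because metrics such as
#' CSMF accuracy take extreme values for some compositions). Draws where the
#' evaluator returns `NA` are excluded from the median with their count
#' reported. The running median is checkpointed every `check_interval` draws
#' so stabilization can be assessed or (with `stop_when_stable = TRUE`)
#' acted upon.
#'
#' @param source A `va_data` object covering every cause.
#' @param evaluator Function taking a `va_data` object and returning a single
#'   numeric value (or `NA` when undefined), e.g.
#'   `function(d) csmf_accuracy(csmf_true(d), csmf_predicted(d))`.
#' @param config A [resampling_config()].
#' @return A list of class `va_resampling`: `median`, `n_draws_used`,
#'   `n_undefined`, `stabilized_at` (first checkpoint draw index where the
#'   running median moved by less than the tolerance; `NA` if never), `trace`
#'   (tibble: draw, one composition column per cause, value), and
#'   `running_median` (tibble: draw, median).
#' @export
median_over_draws <- function(source, evaluator, config = resampling_config()) {
  stopifnot(inherits(source, "va_data"), is.function(evaluator),
            inherits(config, "resampling_config"))
  cl <- causes(source)
  n_deaths <- config$deaths_per_dataset
  if (identical(n_deaths, "analytic")) {
    abort("median_over_draws() resamples records; use a finite deaths_per_dataset.")
  }
  values <- numeric(0)
  comps <- matrix(numeric(0), ncol = length(cl))
  running <- tibble(draw = integer(0), median = numeric(0))
  stabilized_at <- NA_integer_
  for (d in seq_len(config$n_draws)) {
    set.seed(draw_seed(config$seed, d))
    p <- rdirichlet(1, config$dirichlet_alpha, n_causes = length(cl))[1, ]
    ds <- resample_dataset(source, setNames(p, cl), n_deaths)
    values[d] <- evaluator(ds)
    comps <- rbind(comps, p)
    if (d %% config$check_interval == 0 || d == config$n_draws) {
      running <- bind_rows(running,
                           tibble(draw = d, median = median(values, na.rm = TRUE)))
      st <- is_stabilized(running, config$median_tolerance)
      if (is.na(stabilized_at) && st$stabilized) {
        stabilized_at <- st$at
        if (config$stop_when_stable) break
      }
    }
  }
  n_undef <- sum(is.na(values))
  if (n_undef == length(values)) abort("The metric was undefined on every draw.")
  if (n_undef > 0) {
    warn(sprintf("Metric undefined on %d of %d draws; excluded from the median.",
                 n_undef, length(values)))
  }
  comp_tbl <- as_tibble(as.data.frame(comps, row.names = NULL))
  names(comp_tbl) <- cl
  trace <- dplyr::bind_cols(tibble(draw = seq_along(values)), comp_tbl)
  trace$value <- values
  structure(list(median = median(values, na.rm = TRUE),
                 n_draws_used = length(values), n_undefined = n_undef,
                 stabilized_at = stabilized_at, trace = trace,
                 running_median = running, config = config),
            class = "va_resampling")
}

#' Has a running median stabilized?
#'
#' The stopping rule: once an additional batch of draws changes the running
#' median by no more than `tolerance` in relative terms (default 0.5%), the
#' median is considered stable. Requires at least two checkpoints.
#'
#' @param running_median Tibble `(draw, median)` of checkpointed running
#'   medians (as produced by [median_over_draws()]), or a `va_resampling`
#'   object.
#' @param tolerance Maximum relative change (default 0.005).
#' @return A list: `stabilized` (logical) and `at` (the first checkpoint draw
#'   index at which the criterion held, `NA` if it never did).
#' @export
is_stabilized <- function(running_median, tolerance = 0.005) {
  if (inherits(running_median, "va_resampling")) {
    running_median <- running_median$running_median
  }
  stopifnot(is.data.frame(running_median),
            all(c("draw", "median") %in% names(running_median)))
  m <- running_median$median
  if (length(m) < 2) return(list(stabilized = FALSE, at = NA_integer_))
  prev <- m[-length(m)]
  curr <- m[-1]
  denom <- ifelse(abs(prev) > 0, abs(prev), 1)
  rel <- abs(curr - prev) / denom
  hit <- which(rel <= tolerance)
  if (!length(hit)) return(list(stabilized = FALSE, at = NA_integer_))
  list(stabilized = TRUE, at = running_median$draw[hit[1] + 1])
}

#' @export
print.va_resampling <- function(x, ...) {
  cat(sprintf("Resampling summary: median %.4f over %d draws (%d undefined)\n",
              x$median, x$n_draws_used, x$n_undefined))
  if (!is.na(x$stabilized_at)) {
    cat(sprintf("Running median stabilized at draw %d\n", x$stabilized_at))
  }
  invisible(x)
}

#' @describeIn median_over_draws per-draw trace as a tibble.
#' @param x A `va_resampling` object.
#' @param ... Unused.
#' @export
tidy.va_resampling <- function(x, ...) x$trace

#' @describeIn median_over_draws one-row summary tibble.
#' @export
glance.va_resampling <- function(x, ...) {
  tibble(median = x$median, n_draws = x$n_draws_used,
         n_undefined = x$n_undefined, stabilized_at = x$stabilized_at)
}
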