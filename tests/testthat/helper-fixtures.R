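# Shared fixtures and independent oracles. Oracles deliberately use explicit
# per-record loops / enumeration, never the package's confusion-table code.

tiny_single <- function() {
  va_data(data.frame(
    id = paste0("d", 1:6),
    true_cause = c("A", "A", "A", "B", "B", "C"),
    predicted_cause = c("A", "B", "A", "B", "C", "C"),
    stringsAsFactors = FALSE
  ))
}

ranked_fixture <- function() {
  # three deaths over four causes with full probability rankings
  va_data(data.frame(
    id = c("r1", "r2", "r3"),
    true_cause = c("pneumonia", "tb", "aids"),
    cause_1 = c("tb", "tb", "stroke"),
    prob_1 = c(0.5, 0.6, 0.4),
    cause_2 = c("pneumonia", "stroke", "aids"),
    prob_2 = c(0.3, 0.3, 0.35),
    cause_3 = c("aids", "pneumonia", "tb"),
    prob_3 = c(0.15, 0.06, 0.15),
    cause_4 = c("stroke", "aids", "pneumonia"),
    prob_4 = c(0.05, 0.04, 0.1),
    stringsAsFactors = FALSE
  ))
}

random_single_dataset <- function(n_causes, n_records) {
  cl <- LETTERS[seq_len(n_causes)]
  va_data(data.frame(
    id = seq_len(n_records),
    true_cause = sample(cl, n_records, replace = TRUE),
    predicted_cause = sample(cl, n_records, replace = TRUE),
    stringsAsFactors = FALSE
  ), causes = cl)
}

random_simplex <- function(n) {
  x <- rexp(n)
  x / sum(x)
}

# oracle: per-cause sensitivity/specificity and overall kappa by looping over
# individual records
brute_force_metrics <- function(data) {
  cl <- causes(data)
  tr <- data$true_cause
  pr <- top_cause(data)
  sens <- spec <- setNames(rep(NA_real_, length(cl)), cl)
  for (j in cl) {
    in_j <- tr == j
    if (any(in_j)) sens[j] <- mean(pr[in_j] == j)
    if (any(!in_j)) spec[j] <- mean(pr[!in_j] != j)
  }
  po <- mean(pr == tr)
  pe <- 0
  for (j in cl) pe <- pe + mean(tr == j) * mean(pr == j)
  list(sensitivity = sens, specificity = spec,
       kappa = (po - pe) / (1 - pe))
}

# oracle: all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
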