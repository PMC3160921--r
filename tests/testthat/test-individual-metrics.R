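test_that("sensitivity, specificity and CCC match hand-computed values", {
  m1 <- va_method("method1")
  conf <- analytic_confusion(m1, rep(1 / 3, 3))
  cm <- cause_metrics(conf)
  expect_equal(cm$sensitivity, c(0.70, 0.60, 0.35))
  # cause A: off-cause deaths assigned to A at rates 0.04 and 0.065
  expect_equal(cm$specificity[cm$cause == "A"], 1 - (0.04 + 0.065) / 2)
  expect_equal(cm$ccc, (c(0.70, 0.60, 0.35) - 1 / 3) / (2 / 3))

  # a diagonal table is perfect on every metric
  d <- va_data(data.frame(id = 1:4, true_cause = c("A", "A", "B", "B"),
                          predicted_cause = c("A", "A", "B", "B")))
  cm2 <- cause_metrics(confusion_table(d))
  expect_equal(cm2$sensitivity, c(1, 1))
  expect_equal(cm2$ccc, c(1, 1))
  expect_equal(cohen_kappa(confusion_table(d)), 1)

  # counts row (35, 40, 25) -> sensitivity 0.35
  conf3 <- vametrics:::new_va_confusion(
    matrix(c(35, 40, 25, 0, 50, 0, 0, 0, 50), 3, 3, byrow = TRUE,
           dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
    c("A", "B", "C"))
  expect_equal(cause_metrics(conf3)$sensitivity[1], 0.35)
})

test_that("CCC is zero at chance and negative below it", {
  for (N in 2:6) {
    expect_equal(vametrics:::ccc_from_sensitivity(1 / N, N), 0)
  }
  expect_lt(vametrics:::ccc_from_sensitivity(0.2, 3), 0)
  expect_equal(vametrics:::ccc_from_sensitivity(0, 3), -0.5) # floor -1/(N-1)
})

test_that("undefined metrics are NA, excluded from averages with a warning", {
  d <- va_data(data.frame(id = 1:3, true_cause = c("A", "A", "B"),
                          predicted_cause = c("A", "A", "B")),
               causes = c("A", "B", "C"))
  cm <- cause_metrics(confusion_table(d))
  expect_true(is.na(cm$sensitivity[cm$cause == "C"]))
  expect_true(is.na(cm$ccc[cm$cause == "C"]))
  expect_warning(occ <- overall_ccc(confusion_table(d)), "excluded")
  expect_equal(occ, 1) # both defined causes perfect
})

test_that("overall CCC weight schemes behave as documented", {
  conf <- analytic_confusion(va_method("method1"), rep(1 / 3, 3))
  ccc <- cause_metrics(conf)$ccc
  expect_equal(overall_ccc(conf), mean(ccc))
  expect_equal(overall_ccc(conf), (0.55 + 0.40 + 0.025) / 3)
  # degenerate weights pick out a single cause
  expect_equal(overall_ccc(conf, weights = c(1, 0, 0)), 0.55)
  # test-set weights on an equal composition coincide with equal weights
  expect_equal(overall_ccc(conf, weights = "test-set"), mean(ccc))
  # equal-weight overall CCC lies between per-cause extremes
  for (s in 1:10) {
    set.seed(s)
    dd <- random_single_dataset(4, 80)
    cc <- cause_metrics(confusion_table(dd))$ccc
    o <- suppressWarnings(overall_ccc(confusion_table(dd)))
    expect_gte(o, min(cc, na.rm = TRUE) - 1e-12)
    expect_lte(o, max(cc, na.rm = TRUE) + 1e-12)
  }
  expect_error(overall_ccc(conf, weights = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("Cohen's kappa matches hand-verified arithmetic", {
  mk <- function(counts) vametrics:::new_va_confusion(
    matrix(counts, 2, 2, byrow = TRUE,
           dimnames = list(c("A", "B"), c("A", "B"))), c("A", "B"))
  # P_obs = 0.7, P_exp = 0.5 -> kappa 0.4
  expect_equal(cohen_kappa(mk(c(20, 5, 10, 15))), 0.4)
  # independence -> 0
  expect_equal(cohen_kappa(mk(c(25, 25, 25, 25))), 0)
  # all mass in one cell -> undefined
  expect_true(is.na(cohen_kappa(mk(c(10, 0, 0, 0)))))
})

test_that("confusion-table metrics equal brute-force per-record loops", {
  set.seed(2024)
  for (rep in 1:50) {
    d <- random_single_dataset(sample(2:5, 1), sample(5:50, 1))
    oracle <- brute_force_metrics(d)
    conf <- confusion_table(d)
    cm <- cause_metrics(conf)
    expect_equal(setNames(cm$sensitivity, cm$cause), oracle$sensitivity,
                 tolerance = 1e-12)
    expect_equal(setNames(cm$specificity, cm$cause), oracle$specificity,
                 tolerance = 1e-12)
    expect_equal(cohen_kappa(conf), oracle$kappa, tolerance = 1e-12)
  }
})

test_that("top-k concordance counts ranked hits and is monotone in k", {
  # worked example: true cause ranked second -> in top-1 no, top-2 yes
  d <- va_data(data.frame(
    id = "w1", true_cause = "pneumonia",
    cause_1 = "tb", prob_1 = 0.5,
    cause_2 = "pneumonia", prob_2 = 0.2,
    cause_3 = "lung cancer", prob_3 = 0.1,
    cause_4 = "aids", prob_4 = 0.1,
    cause_5 = "heart failure", prob_5 = 0.05,
    cause_6 = "other", prob_6 = 0.05))
  tk <- top_k_concordance(d, 1:6)
  expect_equal(tk$concordance[tk$k == 1], 0)
  expect_equal(tk$concordance[tk$k == 2], 1)
  expect_equal(tk$concordance[tk$k == 6], 1) # k = N exhaustive

  # 4 deaths with true cause ranked 1st, 2nd, 2nd, 3rd
  d4 <- va_data(data.frame(
    id = 1:4, true_cause = c("A", "B", "C", "D"),
    cause_1 = c("A", "A", "A", "A"), prob_1 = c(0.4, 0.4, 0.4, 0.4),
    cause_2 = c("B", "B", "C", "B"), prob_2 = c(0.3, 0.3, 0.3, 0.3),
    cause_3 = c("C", "C", "B", "D"), prob_3 = c(0.2, 0.2, 0.2, 0.2),
    cause_4 = c("D", "D", "D", "C"), prob_4 = c(0.1, 0.1, 0.1, 0.1)))
  tk4 <- top_k_concordance(d4, 1:2)
  expect_equal(tk4$concordance, c(0.25, 0.75))

  # property: monotone non-decreasing in k on random ranked data
  set.seed(5)
  for (rep in 1:20) {
    N <- sample(3:6, 1)
    cl <- LETTERS[1:N]
    n <- 15
    rows <- lapply(1:n, function(i) {
      p <- random_simplex(N)
      out <- data.frame(id = i, true_cause = sample(cl, 1))
      for (k in 1:N) {
        out[[paste0("cause_", k)]] <- cl[k]
        out[[paste0("prob_", k)]] <- p[k]
      }
      out
    })
    dr <- va_data(do.call(rbind, rows), causes = cl)
    cc <- top_k_concordance(dr, 1:N)$concordance
    expect_true(all(diff(cc) >= 0))
    expect_equal(cc[N], 1)
  }
  expect_error(top_k_concordance(d4, 5), "must lie in")
})

test_that("chance concordance PC(k) honours its anchor points and oracle", {
  expect_equal(partial_chance_concordance(1, 5), 0.2)
  for (N in 2:6) {
    expect_equal(partial_chance_concordance(N, N), 1)
    expect_equal(partial_chance_concordance(1, N), 1 / N)
    expect_true(all(diff(partial_chance_concordance(1:N, N)) > 0))
  }
  # enumeration oracle: over all random rankings (permutations), the true
  # cause lands in the top k with probability k/N
  for (N in 3:4) {
    perms <- all_perms(N)
    for (k in 1:N) {
      hit <- mean(apply(perms, 1, function(ord) match(1, ord) <= k))
      expect_equal(partial_chance_concordance(k, N), hit)
    }
  }
  # with-replacement alternative: correct formula, does not reach 1 at k = N
  expect_equal(partial_chance_concordance(2, 3, "replacement"), 1 - (2 / 3)^2)
  expect_lt(partial_chance_concordance(3, 3, "replacement"), 1)
  expect_error(partial_chance_concordance(4, 3), "must lie in")
})

test_that("PCCC rescales top-k concordance and rejects k = N", {
  d4 <- va_data(data.frame(
    id = 1:4, true_cause = c("A", "B", "C", "D"),
    cause_1 = c("A", "A", "A", "A"), prob_1 = rep(0.4, 4),
    cause_2 = c("B", "B", "C", "B"), prob_2 = rep(0.3, 4),
    cause_3 = c("C", "C", "B", "D"), prob_3 = rep(0.2, 4),
    cause_4 = c("D", "D", "D", "C"), prob_4 = rep(0.1, 4)))
  out <- pccc(d4, 1:3)
  expect_equal(out$pccc, (out$concordance - out$k / 4) / (1 - out$k / 4))
  expect_error(pccc(d4, 4), "not defined")
  # C = PC(k) gives 0; C = 1 gives 1 (reduces to single-cause CCC at k = 1)
  expect_equal((0.25 - 0.25) / (1 - 0.25), 0)
  d1 <- va_data(data.frame(id = 1:2, true_cause = c("A", "B"),
                           predicted_cause = c("A", "B")),
                causes = c("A", "B", "C"))
  expect_equal(pccc(d1, 1)$pccc, 1)
})
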