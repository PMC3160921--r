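test_that("single-cause datasets validate and tally correctly", {
  d <- va_data(data.frame(id = 1:3, true_cause = c("A", "A", "B"),
                          predicted_cause = c("A", "B", "B")))
  expect_s3_class(d, "va_data")
  expect_equal(causes(d), c("A", "B"))
  expect_false(is_ranked(d))
  cm <- as.matrix(confusion_table(d))
  expect_equal(unname(cm), rbind(c(1, 1), c(0, 1)))
  expect_equal(grand_total(confusion_table(d)), 3)
})

test_that("cause labels are trimmed but matched case-sensitively", {
  d <- va_data(data.frame(id = 1:2, true_cause = c(" A", "B "),
                          predicted_cause = c("A ", " B")))
  expect_equal(causes(d), c("A", "B"))
  expect_error(
    va_data(data.frame(id = 1, true_cause = "a", predicted_cause = "a"),
            causes = c("A", "B")),
    "'a'")
})

test_that("malformed input fails loudly with the offending record named", {
  expect_error(va_data(data.frame(id = character(0),
                                  true_cause = character(0),
                                  predicted_cause = character(0))),
               "at least one")
  expect_error(
    va_data(data.frame(id = c("x1", "x2"), true_cause = c("A", "Z"),
                       predicted_cause = c("A", "A")),
            causes = c("A", "B")),
    "'x2'.*'Z'")
  expect_error(
    va_data(data.frame(id = "p1", true_cause = "A",
                       cause_1 = "A", prob_1 = 0.6,
                       cause_2 = "B", prob_2 = 0.5)),
    "sum to")
  expect_error(
    va_data(data.frame(id = "p1", true_cause = "A",
                       cause_1 = "A", prob_1 = 0.5,
                       cause_2 = "A", prob_2 = 0.5),
            causes = c("A", "B")),
    "more than once")
})

test_that("ranked predictions sort by probability with cause-order tie-break", {
  d <- va_data(data.frame(id = "p1", true_cause = "A",
                          cause_1 = "C", prob_1 = 0.4,
                          cause_2 = "B", prob_2 = 0.4,
                          cause_3 = "A", prob_3 = 0.2),
               causes = c("A", "B", "C"))
  expect_true(is_ranked(d))
  expect_equal(d$prediction[[1]]$cause, c("B", "C", "A"))
  expect_equal(top_cause(d), "B")
})

test_that("probability sum tolerance is strict at 1e-9", {
  base <- data.frame(id = "p1", true_cause = "A",
                     cause_1 = "A", prob_1 = 0.5, cause_2 = "B")
  ok <- base; ok$prob_2 <- 0.5 + 1e-10
  expect_s3_class(va_data(ok), "va_data")
  bad <- base; bad$prob_2 <- 0.5 + 1e-6
  expect_error(va_data(bad), "sum to")
})

test_that("CSV round-trip reproduces identical confusion tables", {
  d <- tiny_single()
  path <- withr::local_tempfile(fileext = ".csv")
  write_va_csv(d, path)
  d2 <- read_va_csv(path, causes = causes(d))
  expect_identical(as.matrix(confusion_table(d)),
                   as.matrix(confusion_table(d2)))

  r <- ranked_fixture()
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_va_csv(r, path2)
  r2 <- read_va_csv(path2, causes = causes(r))
  expect_identical(as.matrix(confusion_table(r)),
                   as.matrix(confusion_table(r2)))
  expect_equal(r2$prediction, r$prediction)
})

test_that("misclassification matrices must be row-stochastic", {
  m <- va_method("method1")
  expect_equal(unname(rowSums(unclass(m))), rep(1, 3))
  expect_error(misclass_matrix(rbind(c(0.9, 0.2), c(0.5, 0.5)),
                               causes = c("A", "B")),
               "sums to")
  expect_error(misclass_matrix(rbind(c(1.1, -0.1), c(0.5, 0.5)),
                               causes = c("A", "B")),
               "\\[0, 1\\]")
  path <- withr::local_tempfile(fileext = ".csv")
  write_misclass_csv(m, path)
  expect_equal(unclass(read_misclass_csv(path)), unclass(m))
})

test_that("true and predicted CSMFs count and average correctly", {
  d <- va_data(data.frame(id = 1:4, true_cause = c("A", "A", "B", "C"),
                          predicted_cause = c("A", "B", "B", "C")))
  expect_equal(csmf_true(d)$csmf, c(0.5, 0.25, 0.25))
  expect_equal(csmf_predicted(d)$csmf, c(0.25, 0.5, 0.25))
  expect_equal(sum(csmf_true(d)$csmf), 1, tolerance = 1e-12)

  # degenerate: every record one cause
  d1 <- va_data(data.frame(id = 1:3, true_cause = "A",
                           predicted_cause = "A"), causes = c("A", "B", "C"))
  expect_equal(csmf_true(d1)$csmf, c(1, 0, 0))

  # probabilistic predictions average per-death probability vectors
  r <- va_data(data.frame(id = 1:2, true_cause = c("A", "B"),
                          cause_1 = c("A", "A"), prob_1 = c(0.6, 0.2),
                          cause_2 = c("B", "B"), prob_2 = c(0.4, 0.4),
                          cause_3 = c("C", "C"), prob_3 = c(0.0, 0.4)))
  expect_equal(csmf_predicted(r)$csmf, c(0.4, 0.4, 0.2))
})

test_that("single-cause predicted CSMF equals confusion column marginals", {
  for (s in 1:5) {
    set.seed(s)
    d <- random_single_dataset(4, 60)
    conf <- confusion_table(d)
    expect_equal(csmf_predicted(d)$csmf,
                 unname(col_totals(conf) / grand_total(conf)))
    # conservation: cells sum to the record count
    expect_equal(grand_total(conf), nrow(d))
  }
})

test_that("multinomial resampling to a target composition concentrates on it", {
  set.seed(99)
  src <- random_single_dataset(3, 300)
  target <- c(A = 0.2, B = 0.3, C = 0.5)
  out <- resample_dataset(src, target, 1000)
  obs <- csmf_true(out)$csmf
  se <- sqrt(target * (1 - target) / 1000)
  expect_true(all(abs(obs - target) < 3 * se))
})
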