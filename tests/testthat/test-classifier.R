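test_that("the quadrature metric follows Pythagoras and its domain", {
  expect_equal(overlap_metric(0, 0), 0)
  expect_equal(overlap_metric(0.3, 0.4), 0.5)
  expect_equal(overlap_metric(0.164, 0.220), 0.2744, tolerance = 1e-4 / 0.2744)
  expect_error(overlap_metric(-0.1, 0.5), class = "overlaptriage_domain_error")
  expect_error(overlap_metric(0.2, 1.2), class = "overlaptriage_domain_error")
  # monotone in each argument, dominated by neither component
  f <- seq(0, 1, by = 0.25)
  expect_true(all(diff(overlap_metric(f, 0.4)) > 0))
  expect_true(all(overlap_metric(f, 0.4) >= pmax(f, 0.4)))
})

test_that("threshold classification is boundary-inclusive toward ineligible", {
  m <- threshold_model(0.278)
  expect_equal(as.character(classify_threshold(0.278, m)), "ineligible")
  expect_equal(as.character(classify_threshold(0, m)), "eligible")
  expect_equal(as.character(classify_threshold(0.305, threshold_model(0.274))),
               "ineligible")
})

test_that("threshold fitting finds the separating midpoint and reports accuracy", {
  d <- cohort_from_metrics(c(0.1, 0.2, 0.4, 0.5), c(TRUE, TRUE, FALSE, FALSE))
  fit <- fit_threshold(d)
  expect_equal(fit$threshold, 0.3)
  expect_equal(attr(fit, "train_accuracy"), 1.0)
  # anti-separated two-patient cohort: best accuracy 0.5, smallest optimum
  d2 <- cohort_from_metrics(c(0.1, 0.2), c(FALSE, TRUE))
  fit2 <- fit_threshold(d2)
  expect_equal(attr(fit2, "train_accuracy"), 0.5)
  expect_lt(fit2$threshold, 0.1)
  # any separated cohort trains to accuracy exactly 1
  set.seed(5)
  me <- runif(20, 0, 0.2); mi <- runif(15, 0.25, 0.5)
  d3 <- cohort_from_metrics(c(me, mi), rep(c(TRUE, FALSE), c(20, 15)))
  expect_equal(attr(fit_threshold(d3), "train_accuracy"), 1.0)
})

test_that("fitted thresholds are optimal against exhaustive enumeration", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    v <- round(runif(n, 0, 0.6), sample(2:4, 1))  # rounding induces ties
    lab <- runif(n) < 0.6
    if (length(unique(lab)) < 2) next
    d <- cohort_from_metrics(pmin(v, 1), lab)
    fit <- fit_threshold(d)
    expect_equal(attr(fit, "train_accuracy"), best_threshold_accuracy(v, lab))
  }
})

test_that("degenerate cohorts are rejected and missing labels warned about", {
  expect_error(fit_threshold(cohort_from_metrics(c(0.1, 0.2), c(TRUE, TRUE))),
               class = "overlaptriage_degenerate_cohort_error")
  d <- cohort_from_metrics(c(0.1, 0.2, 0.3), c(TRUE, NA, FALSE))
  expect_warning(fit <- fit_threshold(d), "missing eligibility")
  expect_equal(attr(fit, "n_train"), 2L)
})

test_that("evaluation counts partition the cohort with the documented rates", {
  d <- cohort_from_metrics(c(0.05, 0.1, 0.4, 0.5), c(TRUE, TRUE, FALSE, FALSE))
  # threshold below every value: everyone predicted ineligible
  ev <- evaluate_threshold(d, threshold_model(0.01))
  expect_equal(unlist(ev[c("tp", "fn", "tn", "fp")]),
               c(tp = 0, fn = 2, tn = 2, fp = 0))
  expect_equal(ev$sensitivity, 0)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$accuracy, 0.5)
  # perfect separation
  ev2 <- evaluate_threshold(d, threshold_model(0.3))
  expect_equal(c(ev2$sensitivity, ev2$specificity, ev2$accuracy), c(1, 1, 1))
  # accuracy equals the mean per-patient correctness, counts sum to n
  set.seed(2)
  for (i in 1:10) {
    dd <- cohort_from_metrics(runif(12), runif(12) < 0.5)
    if (length(unique(dd$eligible)) < 2) next
    t <- runif(1)
    ev3 <- evaluate_threshold(dd, threshold_model(t))
    expect_equal(ev3$tp + ev3$fp + ev3$tn + ev3$fn, 12)
    expect_equal(ev3$accuracy, mean((dd$metric >= t) == !dd$eligible))
  }
})

test_that("label-flip duality swaps sensitivity and specificity", {
  set.seed(3)
  d <- cohort_from_metrics(runif(30), runif(30) < 0.5)
  ev <- evaluate_threshold(d, threshold_model(0.5))
  flipped <- d
  flipped$eligible <- !d$eligible
  flipped$f_bw <- 1 - d$f_bw          # flip the rule polarity by reflecting values
  flipped$metric <- NULL
  flipped <- as_cohort(flipped)
  ev_f <- evaluate_threshold(flipped, threshold_model(1 - 0.5 + 1e-12))
  expect_equal(ev_f$sensitivity, ev$specificity)
  expect_equal(ev_f$specificity, ev$sensitivity)
})

test_that("rank-sum test matches symmetry, exact enumeration and wilcox.test", {
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  r <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sum(rank(c(1, 2, 3, 10, 11, 12))[1:3]), 6)  # minimum rank-sum
  expect_lt(abs(r$p.value - exact_rank_sum_p(c(1, 2, 3), c(10, 11, 12))), 0.05)
  # symmetric in the group order
  expect_equal(rank_sum_test(c(10, 11, 12), c(1, 2, 3))$p.value, r$p.value)
  # agrees with the reference normal-approximation implementation, with ties
  set.seed(8)
  for (i in 1:10) {
    a <- round(rnorm(sample(5:25, 1)), 1)
    b <- round(rnorm(sample(5:25, 1), 0.5), 1)
    expect_equal(rank_sum_test(a, b)$p.value,
                 stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(rank_sum_test(numeric(0), 1:3), class = "overlaptriage_domain_error")
})

test_that("group comparison reports a rank-sum row per feature", {
  co <- generate_cohort(seed = 4)
  cmp <- compare_groups(co)
  expect_setequal(cmp$feature, c("ptv_volume_cc", "f_bw", "f_rw", "metric"))
  expect_true(all(cmp$p.value >= 0 & cmp$p.value <= 1))
  # overlap features separate the labelled groups sharply by construction
  expect_lt(cmp$p.value[cmp$feature == "metric"], 1e-6)
})

test_that("threshold model JSON round-trips", {
  f <- withr::local_tempfile(fileext = ".json")
  write_threshold_json(threshold_model(0.278, "metric"), f)
  m <- read_threshold_json(f)
  expect_equal(m$threshold, 0.278)
  expect_equal(m$feature, "metric")
  expect_equal(tidy(m)$threshold, 0.278)
})
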