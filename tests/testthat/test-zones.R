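test_that("zone boundaries derive from the class extrema and normalize when inverted", {
  co <- cohort_from_metrics(c(0.10, 0.28, 0.30, 0.35),
                            c(TRUE, TRUE, FALSE, FALSE))
  zb <- derive_zones(co)
  expect_equal(zb$r_inner, 0.28)
  expect_equal(zb$r_outer, 0.30)
  expect_true(zb$separable)   # min ineligible (0.30) > max eligible (0.28)
  zb2 <- derive_zones(cohort_from_metrics(c(0.1, 0.5), c(TRUE, FALSE)))
  expect_equal(c(zb2$r_inner, zb2$r_outer), c(0.1, 0.5))
  expect_true(zb2$separable)
  # attained extrema in the non-separable case
  co3 <- generate_cohort(seed = 6)
  zb3 <- derive_zones(co3)
  expect_true(zb3$r_inner %in% co3$metric[!co3$eligible])
  expect_true(zb3$r_outer %in% co3$metric[co3$eligible])
  expect_false(zb3$separable)
  expect_error(derive_zones(cohort_from_metrics(c(0.1, 0.2), c(TRUE, TRUE))),
               class = "overlaptriage_degenerate_cohort_error")
})

test_that("zone classification is radial and boundary-inclusive toward uncertain", {
  zb <- reference_zone_boundaries()
  expect_equal(c(zb$r_inner, zb$r_outer), c(0.274, 0.305))
  expect_equal(as.character(zone_of(overlap_metric(0.1, 0.1), zb)), "feasible")
  expect_equal(as.character(zone_of(0.274, zb)), "uncertain")
  expect_equal(as.character(zone_of(0.305, zb)), "uncertain")
  expect_equal(as.character(zone_of(overlap_metric(0.25, 0.25), zb)), "not_feasible")
  # rotation invariance: equal metric, equal zone
  set.seed(14)
  for (i in 1:20) {
    m <- runif(1, 0, 0.6)
    th <- runif(2, 0, pi / 2)
    z1 <- zone_of(overlap_metric(m * cos(th[1]), m * sin(th[1])), zb)
    z2 <- zone_of(overlap_metric(m * cos(th[2]), m * sin(th[2])), zb)
    expect_identical(z1, z2)
  }
  # monotonicity: growing either overlap never improves the zone
  worse <- function(z) as.integer(z)
  f <- cbind(runif(50, 0, 0.7), runif(50, 0, 0.7))
  z0 <- zone_of(overlap_metric(f[, 1], f[, 2]), zb)
  z1 <- zone_of(overlap_metric(pmin(f[, 1] + 0.1, 1), f[, 2]), zb)
  expect_true(all(worse(z1) >= worse(z0)))
})

test_that("zone census tallies, partitions and is pure at the extremes", {
  co <- cohort_from_metrics(c(0.05, 0.1, 0.2, 0.28, 0.33, 0.5),
                            c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  zb <- zone_boundaries(0.15, 0.4)
  cz <- zone_census(co, zb)
  expect_equal(cz$n[cz$zone == "feasible"], 2L)
  expect_equal(cz$n[cz$zone == "uncertain"], 3L)
  expect_equal(cz$n[cz$zone == "not_feasible"], 1L)
  expect_equal(cz$n_eligible[cz$zone == "uncertain"], 2L)
  expect_equal(sum(cz$n), nrow(co))
  # zones derived from a cohort leave no ineligible patient feasible and no
  # eligible patient beyond the outer radius
  for (s in 1:5) {
    co2 <- generate_cohort(n_patients = 120, seed = s)
    zb2 <- derive_zones(co2)
    if (zb2$separable) next
    cz2 <- zone_census(co2, zb2)
    expect_equal(cz2$n_ineligible[cz2$zone == "feasible"], 0L)
    expect_equal(cz2$n_eligible[cz2$zone == "not_feasible"], 0L)
    expect_equal(sum(cz2$n), 120L)
  }
})

test_that("zones agree with any compatible threshold classifier", {
  co <- generate_cohort(n_patients = 100, seed = 31)
  zb <- derive_zones(co)
  d <- classify_zones(co, zb)
  feas <- d$metric[d$zone == "feasible"]
  notf <- d$metric[d$zone == "not_feasible"]
  for (t in c(zb$r_inner, zb$r_inner + 0.02, zb$r_outer)) {
    expect_true(all(classify_threshold(feas, threshold_model(t)) == "eligible"))
  }
  for (t in c(zb$r_outer, zb$r_outer - 0.02, zb$r_inner)) {
    expect_true(all(classify_threshold(notf, threshold_model(t)) == "ineligible"))
  }
})

test_that("the decision plot renders and matches the zone rule", {
  zb <- reference_zone_boundaries()
  f <- withr::local_tempfile(fileext = ".png")
  render_decision_plot(0.1, 0.1, zb, path = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  # the marker's zone under the same rule used for colouring
  expect_equal(as.character(zone_of(overlap_metric(0.1, 0.1), zb)), "feasible")
  expect_equal(as.character(zone_of(overlap_metric(0.3, 0.3), zb)), "not_feasible")
  p <- plot_decision(0.3, 0.3, zb, cohort = generate_cohort(n_patients = 30, seed = 1))
  expect_s3_class(p, "ggplot")
  expect_error(render_decision_plot(0.1, 0.1, zb, path = "/nonexistent/dir/x.png"),
               class = "overlaptriage_io_error")
})

test_that("zone boundaries JSON round-trips and rejects invalid files", {
  f <- withr::local_tempfile(fileext = ".json")
  write_zones_json(zone_boundaries(0.2, 0.31, source = "fitted"), f)
  zb <- read_zones_json(f)
  expect_equal(c(zb$r_inner, zb$r_outer), c(0.2, 0.31))
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"nope\": 1}", bad)
  expect_error(read_zones_json(bad), class = "overlaptriage_config_error")
})
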