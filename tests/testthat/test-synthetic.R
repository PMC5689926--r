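test_that("noiseless cohorts are labelled exactly by the planted threshold", {
  co <- generate_cohort(n_patients = 80, seed = 3, label_noise_sd = 0,
                        true_threshold = 0.28)
  expect_identical(co$eligible, co$metric < 0.28)
  expect_true(all(co$f_bw >= 0 & co$f_bw <= 1))
  expect_true(all(co$f_rw >= 0 & co$f_rw <= 1))
})

test_that("default cohorts realize the calibrated ineligibility rate", {
  fracs <- vapply(1:200, function(s) {
    mean(!generate_cohort(n_patients = 150, seed = s)$eligible)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.293), 0.05)
})

test_that("cohort generation is seed-deterministic and warns on one-class draws", {
  expect_identical(generate_cohort(seed = 12), generate_cohort(seed = 12))
  expect_false(identical(generate_cohort(seed = 12), generate_cohort(seed = 13)))
  expect_warning(generate_cohort(n_patients = 20, seed = 1, true_threshold = 2),
                 "single eligibility class")
})

test_that("ineligible patients skew toward larger PTV volumes", {
  co <- dplyr::bind_rows(lapply(1:20, function(s) generate_cohort(seed = s)))
  expect_gt(median(co$ptv_volume_cc[!co$eligible]),
            median(co$ptv_volume_cc[co$eligible]))
})

test_that("planted full-cohort thresholds are recovered within the straddling gap", {
  for (t_star in c(0.2, 0.28, 0.35)) {
    co <- generate_cohort(n_patients = 150, seed = 8, label_noise_sd = 0,
                          true_threshold = t_star)
    fit <- fit_threshold(co)
    m <- sort(co$metric)
    below <- max(m[m < t_star]); above <- min(m[m >= t_star])
    expect_gte(fit$threshold, below)
    expect_lte(fit$threshold, above)
    expect_equal(attr(fit, "train_accuracy"), 1.0)
  }
})

test_that("synthetic anatomy matches its analytic descriptors", {
  an <- generate_anatomy(spacing = 2)
  desc <- an$descriptors
  vol <- function(q) desc$value[desc$quantity == q]
  expect_lt(abs(structure_volume(an$ctv) - vol("prostate_volume_cc")) /
              vol("prostate_volume_cc"), 0.02)
  expect_lt(abs(structure_volume(an$bladder) - vol("bladder_volume_cc")) /
              vol("bladder_volume_cc"), 0.02)
  # walls are shells of their organs
  expect_true(all(an$rectum$voxels[an$rectal_wall$voxels]))
  expect_true(all(an$bladder$voxels[an$bladder_wall$voxels]))
})

test_that("a distant rectum has zero overlap and proximity increases it monotonically", {
  far <- generate_anatomy(spacing = 3, grid_mm = 200, rectum_posterior_offset = 60)
  ptv <- expand_margin(far$ctv)
  expect_equal(fractional_overlap(far$rectal_wall, ptv), 0)
  f_rw <- vapply(c(40, 32, 26, 21, 17), function(off) {
    an <- generate_anatomy(spacing = 3, grid_mm = 200, rectum_posterior_offset = off)
    fractional_overlap(an$rectal_wall, expand_margin(an$ctv))
  }, numeric(1))
  expect_true(all(diff(f_rw) >= 0))
  expect_gt(f_rw[5], f_rw[1])
})

test_that("structures that escape the grid raise an extent error", {
  expect_error(generate_anatomy(spacing = 3, grid_mm = 100, bladder_superior_offset = 45),
               class = "overlaptriage_extent_error")
})

test_that("generated DVHs encode the overlap-to-dose mechanism", {
  low <- generate_dvhs(0, 0, seed = 1)
  expect_true(check_eligibility(low)$eligible)
  high <- generate_dvhs(0.45, 0.45, seed = 1)
  chk <- check_eligibility(high)
  expect_false(chk$eligible)
  failed <- chk$report[!chk$report$pass, ]
  expect_true(any(failed$structure %in% c("rectal_wall", "bladder_wall") &
                    failed$x_percent == 30))
  # D30 sweeps monotonically with the overlap at fixed seed
  d30 <- vapply(seq(0, 0.45, by = 0.05), function(f) {
    dvh <- generate_dvhs(f, 0, noise_sd = 0, seed = 1)
    dose_at_volume(dvh[dvh$structure == "bladder_wall", ], 30)
  }, numeric(1))
  expect_true(all(diff(d30) > 0))
})

test_that("generated DVHs are valid cumulative curves across seeds", {
  set.seed(44)
  for (s in sample.int(1e6, 50)) {
    fbw <- runif(1); frw <- runif(1)
    dvhs <- generate_dvhs(fbw, frw, seed = s)
    for (st in unique(dvhs$structure)) {
      d <- dvhs[dvhs$structure == st, ]
      expect_true(all(diff(d$dose_cgy) > 0))
      expect_true(all(diff(d$fractional_volume) <= 0))
      expect_equal(d$fractional_volume[1], 1)
      expect_equal(d$dose_cgy[1], 0)
    }
  }
})

test_that("the end-to-end geometric pipeline yields an overlap-predictable cohort", {
  co <- simulate_planning_cohort(n_patients = 48, seed = 77)
  expect_equal(nrow(co), 48)
  expect_true(all(c(TRUE, FALSE) %in% co$eligible))
  cv <- cross_validate(co, n_repetitions = 50, seed = 77)
  expect_gte(cv$summary$mean[cv$summary$statistic == "accuracy"], 85)
  # byte-identical regeneration from the same seed
  co2 <- simulate_planning_cohort(n_patients = 6, seed = 5)
  co3 <- simulate_planning_cohort(n_patients = 6, seed = 5)
  expect_identical(co2, co3)
})
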