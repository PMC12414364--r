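# Agreement statistics, mixed-model fit, dataset prediction, generator.

test_that("RMSE matches hand arithmetic and is scale-equivariant", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  set.seed(21)
  o <- rnorm(20); p <- rnorm(20)
  expect_equal(rmse(3 * o, 3 * p), 3 * rmse(o, p))
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("Lin's CCC matches the population-moment definition", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  # independent moment arithmetic: var = 2/3 each, cov = 2/3, mean shift 1
  o <- c(1, 2, 3); p <- c(2, 3, 4)
  mo <- mean(o); mp <- mean(p)
  expected <- 2 * mean((o - mo) * (p - mp)) /
    (mean((o - mo)^2) + mean((p - mp)^2) + (mo - mp)^2)
  expect_equal(ccc(o, p), expected)
  expect_equal(ccc(o, p), 4 / 7)
  expect_warning(ccc(c(1, 1), c(1, 1)), "constant")
})

test_that("CCC never exceeds |Pearson r| and is permutation-invariant", {
  set.seed(7)
  for (i in 1:20) {
    o <- rnorm(15, 50, 10)
    p <- o + rnorm(15, sd = runif(1, 0.5, 8)) + runif(1, -5, 5)
    expect_lte(ccc(o, p), abs(cor(o, p)) + 1e-12)
    perm <- sample(15)
    expect_equal(ccc(o[perm], p[perm]), ccc(o, p))
  }
})

test_that("ICC is the study share of study-plus-residual variance", {
  expect_equal(icc(1, 1), 0.5)
  expect_equal(icc(3, 1), 0.75)
  expect_equal(icc(0, 2), 0)
  expect_warning(out <- icc(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(icc(-1, 1), ">= 0")
})

test_that("dataset prediction lies on the simulated trajectory", {
  recs <- rbind(flat_record(age_d = 0), flat_record(age_d = 14),
                flat_record(age_d = 56), flat_record(age_d = 84))
  p <- predict_dataset(recs)
  expect_equal(p$predicted_bw[1], 40) # age 0 is the initial BW
  sc <- scenario_from_record(recs[1, ])
  tr <- simulate_calf(sc)
  expect_equal(p$predicted_bw, bw_at_age(tr, c(0, 14, 56, 84)))
})

test_that("ages beyond the horizon are skipped with a warning", {
  recs <- rbind(flat_record(age_d = 14), flat_record(age_d = 120))
  expect_warning(p <- predict_dataset(recs), "horizon")
  expect_equal(nrow(p), 1)
  expect_equal(p$age_d, 14)
})

test_that("a perfectly self-consistent dataset yields the identity fit", {
  recs <- generate_synthetic_studies(n_studies = 6, treatments_per_study = 2,
                                     sigma_study = 0, sigma_res = 0, seed = 3)
  expect_equal(recs$observed_bw, recs$predicted_bw)
  p <- predict_dataset(recs)
  expect_equal(p$predicted_bw, recs$predicted_bw) # self-consistency oracle
  fit <- fit_obs_on_pred(p)
  expect_true(fit$degenerate)
  expect_equal(fit$beta0, 0, tolerance = 1e-8)
  expect_equal(fit$beta1, 1, tolerance = 1e-10)
  expect_equal(fit$sigma2_res, 0)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  expect_equal(fit$r2_conditional, 1)
  expect_equal(fit$ccc, 1, tolerance = 1e-10)
})

test_that("pure study shifts land in the study variance, not the residual", {
  recs <- generate_synthetic_studies(n_studies = 8, treatments_per_study = 2,
                                     sigma_study = 0, sigma_res = 0, seed = 5)
  shifts <- c(-6, -3, -1, 0, 1, 2, 4, 8)
  names(shifts) <- sprintf("S%02d", 1:8)
  recs$observed_bw <- recs$predicted_bw + shifts[recs$study]
  fit <- fit_obs_on_pred(recs)
  expect_equal(fit$beta1, 1, tolerance = 1e-8)
  expect_equal(fit$sigma2_res, 0, tolerance = 1e-6)
  expect_equal(fit$sigma2_study, var(shifts), tolerance = 1e-6)
})

test_that("the mixed-model fit recovers slope and variance components", {
  recs <- generate_synthetic_studies(seed = 42)
  fit <- fit_obs_on_pred(recs)
  expect_lt(abs(fit$beta1 - 1), 3 * fit$se_beta1 + 0.02) # within ~3 SE
  expect_false(fit$treatment_kept) # no treatment effect was simulated
  expect_gt(fit$icc, 0.3)
  expect_lt(fit$icc, 0.85)
  expect_gt(fit$ccc, 0.8)
  expect_gt(fit$r2_conditional, 0.9)
  expect_true(is.finite(fit$p_beta0_eq_0) && is.finite(fit$p_beta1_eq_1))
  expect_true(is.finite(fit$lrt_treatment_p))
})

test_that("a real treatment-within-study effect is kept by the LRT", {
  set.seed(9)
  recs <- generate_synthetic_studies(n_studies = 15, treatments_per_study = 4,
                                     sigma_study = 6, sigma_res = 2, seed = 9)
  trt_shift <- rnorm(length(unique(paste(recs$study, recs$treatment))), 0, 12)
  names(trt_shift) <- unique(paste(recs$study, recs$treatment))
  recs$observed_bw <- recs$observed_bw +
    trt_shift[paste(recs$study, recs$treatment)]
  fit <- fit_obs_on_pred(recs)
  expect_lt(fit$lrt_treatment_p, 0.05)
  expect_true(fit$treatment_kept)
  expect_gt(fit$sigma2_treatment, 0)
})

test_that("fit preconditions are enforced", {
  recs <- generate_synthetic_studies(n_studies = 1, seed = 2)
  expect_error(fit_obs_on_pred(recs), ">= 2 studies")
  two <- generate_synthetic_studies(n_studies = 2, treatments_per_study = 1,
                                    seed = 2)
  expect_error(fit_obs_on_pred(two[1:6, ]), ">= 10")
})

test_that("the generator is reproducible and samples the stated ranges", {
  a <- generate_synthetic_studies(n_studies = 10, seed = 99)
  b <- generate_synthetic_studies(n_studies = 10, seed = 99)
  expect_identical(a, b)
  expect_true(all(a$initial_bw >= 34.1 & a$initial_bw <= 48.9))
  expect_true(all(a$weaning_age >= 42 & a$weaning_age <= 90))
  expect_true(all(a$liquid_me_density >= 3.67 & a$liquid_me_density <= 5.76))
  expect_true(all(a$allowance_l >= 1 & a$allowance_l <= 13.5))
  expect_true(all(a$temperature == 20))
  expect_true(all(a$age_d <= a$horizon))
  expect_true(all(a$observed_bw > 0))
  # treatments nested within study
  expect_equal(length(unique(paste(a$study, a$treatment))), 30)
})

test_that("observed-record sets round-trip through CSV", {
  recs <- generate_synthetic_studies(n_studies = 3, seed = 17)
  path <- tempfile(fileext = ".csv")
  write_observed_records(recs, path)
  back <- read_observed_records(path)
  expect_equal(back$observed_bw, recs$observed_bw)
  expect_equal(back$study, recs$study)
  expect_equal(back$allowance_l, recs$allowance_l)
  p1 <- predict_dataset(recs)
  p2 <- predict_dataset(back)
  expect_equal(p2$predicted_bw, p1$predicted_bw)
  expect_error(write_observed_records(recs[, 1:3], path), "missing columns")
})

test_that("assessment results serialize to JSON", {
  recs <- generate_synthetic_studies(n_studies = 5, seed = 31)
  fit <- fit_obs_on_pred(recs)
  path <- tempfile(fileext = ".json")
  write_assessment(fit, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$beta1, fit$beta1, tolerance = 1e-12)
  expect_equal(parsed$icc, fit$icc, tolerance = 1e-12)
})
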