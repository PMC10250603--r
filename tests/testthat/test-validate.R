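# External validation, forecasting and target attainment.

test_that("prediction-error metrics follow their definitions", {
  expect_equal(mpe(c(12, 10), c(11, 12)), -0.5)
  expect_equal(ape(c(12, 10), c(11, 12)), 1.5)
  expect_equal(mpe(c(5, 7), c(5, 7)), 0)
  expect_equal(ape(c(5, 7), c(5, 7)), 0)
  expect_equal(ape(3, 7), abs(mpe(3, 7)))
  # a zero-error record shrinks the mean bias
  expect_lt(abs(mpe(c(12, 10, 8), c(11, 12, 8))), abs(mpe(c(12, 10),
                                                          c(11, 12))))
  expect_error(mpe(1:3, 1:2), "equal-length")
  expect_error(ape(numeric(0), numeric(0)), "non-empty")
})

test_that("APE dominates |MPE| on arbitrary record sets", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    pred <- runif(n, 0, 50)
    obs <- runif(n, 0, 50)
    expect_gte(ape(pred, obs), abs(mpe(pred, obs)))
  }
})

test_that("validating a model against its own simulations is unbiased", {
  sim <- simulate_cohort(cohort_design(n = 150), pza_model(), seed = 71)
  dat <- impute_blq(sim$data)
  val <- external_validate(dat, pza_model(), mode = "population")
  expect_equal(val$n, sum(sim$data$EVID == 0))
  expect_true(val$mpe_ci[1] <= 0 && 0 <= val$mpe_ci[2])
  expect_gte(val$ape, abs(val$mpe))
  # intervals nest: percentile interval inside the min-max range
  expect_gte(val$mpe_ci[1], val$range[1])
  expect_lte(val$mpe_ci[2], val$range[2])
})

test_that("an inflated-clearance model under-predicts concentrations", {
  sim <- simulate_cohort(cohort_design(n = 100), pza_model(), seed = 73)
  dat <- impute_blq(sim$data)
  fast <- pza_model(theta_cl = 2 * 4.49)
  val <- external_validate(dat, fast, mode = "population")
  expect_lt(val$mpe, 0)
})

test_that("individual prediction beats population prediction with rich
           sampling", {
  d <- cohort_design(n = 80, sampling = "fixed",
                     fixed_times = c(1, 2, 5, 8, 12))
  sim <- simulate_cohort(d, pza_model(), seed = 79)
  dat <- impute_blq(sim$data)
  pop <- external_validate(dat, pza_model(), mode = "population")
  ind <- external_validate(dat, pza_model(), mode = "individual")
  expect_lte(ind$ape, pop$ape)
})

test_that("the comparator registry validates, rejects duplicates and
           round-trips", {
  reg <- model_registry()
  register_model(reg, "final", pza_model())
  perturbed <- pza_model(theta_cl = 6.5, theta_v = 30, theta_ka = 0.8)
  register_model(reg, "perturbed", perturbed)
  expect_error(register_model(reg, "final", pza_model()), "duplicate")
  expect_setequal(registry_labels(reg), c("final", "perturbed"))

  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_registry(reg, path)
  back <- read_model_registry(path)
  expect_setequal(registry_labels(back), registry_labels(reg))
  expect_equal(registry_get(back, "final")$theta,
               registry_get(reg, "final")$theta)
  expect_equal(registry_get(back, "perturbed")$omega2,
               perturbed$omega2)

  # the generating model out-predicts a perturbed comparator on its own
  # simulations
  sim <- simulate_cohort(cohort_design(n = 80), pza_model(), seed = 83)
  dat <- impute_blq(sim$data)
  apes <- vapply(registry_labels(back), function(lb)
    external_validate(dat, registry_get(back, lb),
                      mode = "population", label = lb)$ape, 0)
  expect_equal(names(which.min(apes)), "final")
})

test_that("Bayesian forecasting reports dose-normalised exposure", {
  t <- c(1, 2, 5)
  m <- pza_model()
  typ <- data.frame(ID = 1, TIME = t,
                    DV = conc_ss(t, 1500, 4.49, 44.2, 1.49),
                    DOSE = 1500, LBW = 48, AGE = 40, DM = 0)
  fc <- forecast_individual(typ, m, normalization_dose = 1200)
  expect_equal(fc$auc, 1200 / 4.49, tolerance = 1e-3)
  expect_equal(fc$group, "age<70, no DM")

  gdm <- data.frame(ID = 1, TIME = t,
                    DV = conc_ss(t, 1500, 5.9268, 44.2, 1.49),
                    DOSE = 1500, LBW = 48, AGE = 75, DM = 1)
  fc2 <- forecast_individual(gdm, m, normalization_dose = 1200)
  expect_equal(fc2$auc, 1200 / 5.9268, tolerance = 1e-3)
  expect_equal(fc2$group, "age>=70, DM")
  # doubling clearance halves the normalised AUC
  expect_equal(fc$auc / fc2$auc, 5.9268 / 4.49, tolerance = 1e-3)
  # Cmax at the normalisation dose, individual parameters
  expect_equal(fc$cmax, cmax_ss(1200, fc$cl, fc$v, fc$ka)[["cmax"]],
               tolerance = 1e-6)
})

test_that("target attainment uses inclusive thresholds", {
  est <- data.frame(auc = c(267.3, 363, 400), cmax = c(29, 30, 35))
  ta <- target_attainment(est)
  expect_equal(unname(ta["auc"]), 2 / 3)
  expect_equal(unname(ta["cmax"]), 2 / 3)
  expect_equal(unname(ta["both"]), 2 / 3)
  # the typical patient at 1200 mg misses the AUC target
  expect_lt(auc_ss(1200, 4.49), 363)
  expect_error(target_attainment(est[0, ]), "non-empty")
})

test_that("subgroup summaries report medians, IQRs and sizes per group", {
  est <- data.frame(auc = rep(200, 8), cmax = rep(25, 8),
                    cl = rep(6, 8),
                    group = rep(c("a", "b"), each = 4))
  s <- subgroup_summary(est)
  expect_equal(s$n, c(4, 4))
  expect_equal(s$auc_median, c(200, 200))
  expect_equal(s$auc_q3 - s$auc_q1, c(0, 0))

  # a built-in geriatric-DM effect puts the highest clearance in that group
  sim <- simulate_cohort(cohort_design(n = 250, dm_prob_old = 0.6),
                         pza_model(), seed = 89)
  dat <- impute_blq(sim$data)
  fc <- forecast_individual(dat, pza_model())
  ss <- subgroup_summary(fc)
  expect_equal(ss$group[which.max(ss$cl_median)], "age>=70, DM")
  expect_equal(sum(ss$n), length(unique(dat$ID)))
})
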