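# Structural model and covariate machinery.

test_that("steady-state concentration matches explicit dose superposition", {
  # final-model typical parameters, 1500 mg once daily
  expect_equal(conc_ss(2, 1500, 4.49, 44.2, 1.49),
               conc_superpose(2, 1500, 4.49, 44.2, 1.49, ndose = 60),
               tolerance = 1e-4)
  expect_equal(conc_ss(2, 1500, 4.49, 44.2, 1.49), 30.718,
               tolerance = 1e-4)
  # random parameter grid with ke*tau > 0.5
  set.seed(4)
  for (i in 1:20) {
    cl <- runif(1, 2, 8); v <- runif(1, 20, 80)
    if (cl / v * 24 < 0.5) next
    ka <- runif(1, 0.5, 3); d <- sample(c(1000, 1500, 2000), 1)
    t <- runif(1, 0, 24)
    expect_equal(conc_ss(t, d, cl, v, ka),
                 conc_superpose(t, d, cl, v, ka, ndose = 60),
                 tolerance = 1e-4)
  }
})

test_that("steady-state profile is periodic and vanishes at zero dose", {
  expect_equal(conc_ss(0, 1500, 4.49, 44.2, 1.49),
               conc_ss(24, 1500, 4.49, 44.2, 1.49))
  expect_equal(conc_ss(c(0, 3, 12), 0, 4.49, 44.2, 1.49), c(0, 0, 0))
})

test_that("concentration is continuous across the flip-flop boundary", {
  v <- 44.2; cl <- 4.49; ke <- cl / v
  # straddle the branch switch at |ka - ke| = 1e-6 ka: the limit form just
  # inside must agree with the exact form just outside
  for (t in c(0.5, 2, 10, 23)) {
    inside <- conc_ss(t, 1500, cl, v, ke * (1 + 0.999e-6))
    outside <- conc_ss(t, 1500, cl, v, ke * (1 + 1.001e-6))
    expect_lt(abs(inside - outside), 1e-6)
  }
  expect_error(conc_ss(2, 1500, -1, 44.2, 1.49), "positive")
  expect_error(conc_ss(2, 1500, 4.49, 44.2, 0), "positive")
})

test_that("AUC over one interval equals dose/CL and the trapezoid integral", {
  expect_equal(auc_ss(1500, 4.49), 334.075723, tolerance = 1e-6)
  expect_equal(auc_ss(1200, 5.9268), 202.470203, tolerance = 1e-6)
  expect_equal(auc_ss(1500, 8.98), auc_ss(1500, 4.49) / 2)
  set.seed(7)
  for (i in 1:10) {
    cl <- runif(1, 2, 8); v <- runif(1, 20, 80); ka <- runif(1, 0.4, 3)
    num <- auc_trapezoid(function(tt) conc_ss(tt, 1500, cl, v, ka))
    expect_equal(num, auc_ss(1500, cl), tolerance = 1e-3)
  }
})

test_that("peak concentration matches the fine-grid oracle", {
  pk <- cmax_ss(1500, 4.49, 44.2, 1.49)
  # oracle: grid search at 1e-3 h resolution
  g <- seq(0, 24, by = 1e-3)
  cg <- conc_ss(g, 1500, 4.49, 44.2, 1.49)
  expect_equal(unname(pk["cmax"]), max(cg), tolerance = 1e-6)
  expect_equal(unname(pk["tmax"]), g[which.max(cg)], tolerance = 1e-3)
  # cmax dominates the profile at any sampled time
  expect_true(all(pk["cmax"] >= conc_ss(seq(0, 24, by = 0.25),
                                        1500, 4.49, 44.2, 1.49)))
})

test_that("peak approaches the accumulation-corrected bolus limit as ka grows", {
  cl <- 4.49; v <- 44.2; ke <- cl / v
  bolus <- 1500 / v / (1 - exp(-ke * 24))
  pk <- cmax_ss(1500, cl, v, 500)
  expect_equal(unname(pk["cmax"]), bolus, tolerance = 0.01)
  expect_lt(pk["tmax"], 0.1)
})

test_that("peak strictly decreases in volume", {
  vs <- seq(25, 80, by = 5)
  cm <- vapply(vs, function(v) cmax_ss(1500, 4.49, v, 1.49)[["cmax"]], 0)
  expect_true(all(diff(cm) < 0))
})

test_that("covariate factors follow the power and categorical forms", {
  expect_equal(power_factor(50, 50, 0.75), 1)
  expect_equal(power_factor(200, 50, 0.75), 2 * sqrt(2), tolerance = 1e-6)
  expect_equal(power_factor(37, 50, 0), 1)
  expect_error(power_factor(-1, 50, 1), "positive")

  expect_equal(categorical_factor(0.32, 0), 1)
  expect_equal(categorical_factor(0.32, 1), 1.32)
  expect_equal(categorical_factor(0, 1), 1)
  expect_error(categorical_factor(-1.2, 1), "-1")
  expect_equal(4.49 * categorical_factor(0.32, 1), 5.9268)

  expect_equal(allometric_factor(48, 48, 0.75), 1)
  expect_equal(allometric_factor(24, 48, 0.75), 0.5^0.75, tolerance = 1e-6)
  expect_equal(allometric_factor(24, 48, 1), 0.5)
})

test_that("covariate factors compose to 1 for the reference subject", {
  m <- pza_model()
  ip <- individual_parameters(m, list(lbw = 48, age = 45, dm = FALSE))
  expect_equal(ip$cl, 4.49)
  expect_equal(ip$v, 44.2)
  expect_equal(ip$ka, 1.49)
})

test_that("geriatric-DM indicator uses an inclusive age cutoff", {
  expect_true(is_geriatric_dm(70, TRUE))
  expect_false(is_geriatric_dm(69, TRUE))
  expect_false(is_geriatric_dm(85, FALSE))
  expect_error(is_geriatric_dm(15, TRUE), "18")
  # configurable cutoff
  expect_true(is_geriatric_dm(62, TRUE, cutoff = 60))
})

test_that("individual parameters combine allometry, covariate and eta", {
  m <- pza_model()
  expect_equal(individual_parameters(m, list(lbw = 48, gdm = TRUE))$cl,
               5.9268)
  half <- individual_parameters(m, list(lbw = 24, gdm = FALSE))
  expect_equal(half$cl, 4.49 * 0.5^0.75, tolerance = 1e-6)
  expect_equal(half$v, 22.1)
  ip <- individual_parameters(m, list(lbw = 48, gdm = FALSE),
                              eta = c(0.2, -0.1, 0.3))
  expect_equal(ip$cl, 4.49 * exp(0.2))
  expect_equal(ip$v, 44.2 * exp(-0.1))
  expect_equal(ip$ka, 1.49 * exp(0.3))
})

test_that("model constructor validates its inputs and omega scales", {
  expect_error(pza_model(theta_cl = -1), "positive")
  expect_error(pza_model(gdm_effect = -1), "-1")
  expect_error(pza_model(omega = c(cl = -1, v = 3, ka = 100)),
               "non-negative")
  m_cv <- pza_model(omega = c(cl = 100, v = 3, ka = 100))
  expect_equal(unname(m_cv$omega2["cl"]), log(2), tolerance = 1e-12)
  m_sd <- pza_model(omega = c(cl = 0.5, v = 0.1, ka = 0.8),
                    omega_scale = "sd")
  expect_equal(unname(m_sd$omega2["ka"]), 0.64)
  m_var <- pza_model(omega = c(cl = 0.25, v = 0.01, ka = 0.64),
                     omega_scale = "variance")
  expect_equal(m_sd$omega2[["cl"]], m_var$omega2[["cl"]])
})

test_that("lean body weight helper reproduces the sex-specific formula", {
  bmi <- 70 / 1.75^2
  expect_equal(lbw_janmahasatian(70, 175, TRUE),
               9270 * 70 / (6680 + 216 * bmi))
  expect_equal(lbw_janmahasatian(60, 160, FALSE),
               9270 * 60 / (8780 + 244 * 60 / 1.6^2))
  expect_lt(lbw_janmahasatian(65, 170, FALSE),
            lbw_janmahasatian(65, 170, TRUE))
})
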