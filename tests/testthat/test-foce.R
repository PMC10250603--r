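# FOCE-I objective: limits, closed forms and the quadrature oracle.

# observation table for hand-built subjects at the reference covariates
ref_obs <- function(subjects) {
  do.call(rbind, lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    data.frame(ID = i, TIME = s$t, DV = s$y, DOSE = s$dose, LBW = 48,
               AGE = 40, DM = 0)
  }))
}

test_that("with no random effects the OFV is the pooled -2 log-likelihood", {
  m <- pza_model(omega = c(cl = 0, v = 0, ka = 0), omega_scale = "sd",
                 sigma_add = 3)
  subj <- list(list(t = c(1, 2, 5), y = c(25, 33, 27), dose = 1500),
               list(t = c(2, 8), y = c(31, 20), dose = 1000))
  obs <- ref_obs(subj)
  pred <- conc_ss(obs$TIME, obs$DOSE, 4.49, 44.2, 1.49)
  pooled <- sum(log(3^2) + (obs$DV - pred)^2 / 3^2)
  expect_equal(foce_ofv(obs, m, terms = list()), pooled, tolerance = 1e-8)
})

test_that("one subject, one observation at the population prediction has a
           closed-form OFV", {
  m <- pza_model(omega = c(cl = 0.4, v = 0, ka = 0), omega_scale = "sd")
  pred <- conc_ss(2, 1500, 4.49, 44.2, 1.49)
  obs <- ref_obs(list(list(t = 2, y = pred, dose = 1500)))
  # eta_hat = 0 (zero residual and zero prior gradient); the linearised
  # marginal variance is G^2 omega^2 + sigma^2 with G = df/deta_cl
  h <- 1e-5
  G <- (conc_ss(2, 1500, 4.49 * exp(h), 44.2, 1.49) -
        conc_ss(2, 1500, 4.49 * exp(-h), 44.2, 1.49)) / (2 * h)
  expect_equal(foce_ofv(obs, m, terms = list()),
               log(G^2 * 0.4^2 + 3.41^2), tolerance = 1e-6)
})

test_that("FOCE matches the adaptive-quadrature marginal likelihood on a
           single-eta toy", {
  subj <- list(list(t = c(1, 5), y = c(28, 24), dose = 1500,
                    cl = 4.49, v = 44.2, ka = 1.49),
               list(t = c(2, 8), y = c(38, 29), dose = 1500,
                    cl = 4.49, v = 44.2, ka = 1.49))
  obs <- ref_obs(subj)
  for (om in c(0.3, 0.5)) {
    m1 <- pza_model(omega = c(cl = om, v = 0, ka = 0), omega_scale = "sd")
    ofv <- foce_ofv(obs, m1, terms = list())
    oracle <- ofv_quadrature_cl(subj, m1, om)
    expect_equal(ofv, oracle, tolerance = 0.02)
  }
  # OFV differences (the quantity used in likelihood-ratio tests) agree
  # too; three samples per subject, 20% clearance IIV
  subj3 <- list(list(t = c(1, 2, 5), y = c(28, 33, 24), dose = 1500,
                     cl = 4.49, v = 44.2, ka = 1.49),
                list(t = c(2, 5, 8), y = c(38, 30, 26), dose = 1500,
                     cl = 4.49, v = 44.2, ka = 1.49))
  obs3 <- ref_obs(subj3)
  m_a <- pza_model(omega = c(cl = 0.2, v = 0, ka = 0), omega_scale = "sd")
  m_b <- pza_model(theta_cl = 5.0, omega = c(cl = 0.2, v = 0, ka = 0),
                   omega_scale = "sd")
  d_foce <- foce_ofv(obs3, m_b, terms = list()) -
    foce_ofv(obs3, m_a, terms = list())
  subj_b <- lapply(subj3, function(s) { s$cl <- 5.0; s })
  d_quad <- ofv_quadrature_cl(subj_b, m_b, 0.2) -
    ofv_quadrature_cl(subj3, m_a, 0.2)
  expect_lt(abs(d_foce - d_quad) / abs(d_quad), 0.02)
})

test_that("a covariate term fixed at the null leaves the OFV unchanged", {
  obs <- toy_obs(n = 8)
  m <- pza_model()
  base <- foce_ofv(obs, m, terms = list())
  null_term <- foce_ofv(obs, m, terms = list(
    cov_term("cl", "DM", "categorical", start = 0)))
  expect_equal(base, null_term, tolerance = 1e-10)
})

test_that("empirical Bayes estimates sit at the penalised-likelihood mode", {
  m <- pza_model(omega = c(cl = 30, v = 3, ka = 50))
  # observations exactly on the typical profile: the mode is eta = 0
  t <- c(1, 2, 5)
  onprof <- data.frame(ID = 1, TIME = t,
                       DV = conc_ss(t, 1500, 4.49, 44.2, 1.49),
                       DOSE = 1500, LBW = 48, AGE = 40, DM = 0)
  ebe <- estimate_ebe(onprof, m, terms = list())
  expect_equal(max(abs(ebe$eta)), 0, tolerance = 1e-5)
  expect_equal(ebe$params$cl, 4.49, tolerance = 1e-4)

  # one observation above the population prediction late in the interval
  # implies slower elimination: eta_cl < 0; 1-D grid oracle (only the
  # clearance effect active)
  m1 <- pza_model(omega = c(cl = 0.4, v = 0, ka = 0), omega_scale = "sd")
  hi <- data.frame(ID = 1, TIME = 5,
                   DV = conc_ss(5, 1500, 4.49, 44.2, 1.49) + 8,
                   DOSE = 1500, LBW = 48, AGE = 40, DM = 0)
  ebe1 <- estimate_ebe(hi, m1, terms = list())
  expect_lt(ebe1$eta[1, 1], 0)
  grid <- seq(-1.5, 1.5, by = 1e-4)
  pen <- vapply(grid, function(e) {
    f <- conc_ss(5, 1500, 4.49 * exp(e), 44.2, 1.49)
    (hi$DV - f)^2 / 3.41^2 + e^2 / 0.4^2
  }, 0)
  expect_equal(ebe1$eta[1, 1], grid[which.min(pen)], tolerance = 1e-3)

  # deterministic given inputs
  ebe2 <- estimate_ebe(hi, m1, terms = list())
  expect_identical(ebe1$eta, ebe2$eta)
})

test_that("eta shrinkage follows 100 (1 - SD(eta)/omega), clipped", {
  omega <- c(cl = 0.5, v = 0.2, ka = 0.8)
  set.seed(2)
  eta <- cbind(rnorm(200, 0, 0.5), rnorm(200, 0, 0.2), rnorm(200, 0, 0.8))
  shr <- eta_shrinkage(eta, omega)
  expect_equal(unname(shr),
               unname(pmin(pmax(100 * (1 - apply(eta, 2, sd) / omega), 0),
                           100)))
  expect_equal(unname(eta_shrinkage(matrix(0, 5, 3), omega)),
               c(100, 100, 100))
  # SD(eta) = 0.82 omega -> 18%
  eta1 <- matrix(scale(rnorm(500)) * 0.82 * 0.5, ncol = 1)
  expect_equal(unname(eta_shrinkage(eta1, 0.5)), 18, tolerance = 1e-6)
  expect_error(eta_shrinkage(matrix(0, 1, 3), omega), "2 subjects")
})
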