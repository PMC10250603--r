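# Independent oracles used against the package implementation.

# steady-state concentration by explicit superposition of single doses
conc_superpose <- function(t, dose, cl, v, ka, tau = 24, ndose = 60) {
  ke <- cl / v
  total <- 0
  for (k in 0:(ndose - 1)) {
    tt <- t + k * tau
    total <- total + dose * ka / (v * (ka - ke)) *
      (exp(-ke * tt) - exp(-ka * tt))
  }
  total
}

# trapezoid AUC of a concentration function over [0, tau]
auc_trapezoid <- function(f, tau = 24, n = 1e4) {
  g <- seq(0, tau, length.out = n + 1)
  y <- f(g)
  sum((y[-1] + y[-length(y)]) / 2) * (tau / n)
}

# exact marginal -2 log-likelihood by adaptive quadrature for subjects
# with a single random effect on clearance; same additive-constant
# convention as the engine (2*pi terms dropped)
ofv_quadrature_cl <- function(subjects, model, omega_cl) {
  total <- 0
  for (s in subjects) {
    integrand <- function(eta) {
      vapply(eta, function(e) {
        f <- conc_ss(s$t, s$dose, s$cl * exp(e), s$v, s$ka, model$tau)
        lik <- prod(stats::dnorm(s$y, f, model$sigma_add))
        lik * stats::dnorm(e, 0, omega_cl)
      }, 0)
    }
    marg <- stats::integrate(integrand, -6 * omega_cl, 6 * omega_cl,
                             rel.tol = 1e-10)$value
    total <- total - 2 * log(marg) - length(s$y) * log(2 * pi)
  }
  total
}

# small deterministic observation table for io/fit plumbing tests
toy_obs <- function(n = 6, times = c(1, 2, 5), model = pza_model(),
                    seed = 99) {
  set.seed(seed)
  lbw <- seq(40, 56, length.out = n)
  age <- rep(c(45, 75), length.out = n)
  dm <- rep(c(0, 1), each = ceiling(n / 2))[seq_len(n)]
  rows <- list()
  for (i in seq_len(n)) {
    ip <- individual_parameters(model, list(lbw = lbw[i], age = age[i],
                                            dm = dm[i]))
    dv <- conc_ss(times, 1500, ip$cl, ip$v, ip$ka, model$tau) +
      rnorm(length(times), 0, model$sigma_add)
    rows[[i]] <- data.frame(ID = i, TIME = times, DV = pmax(dv, 0.1),
                            DOSE = 1500, AGE = age[i], DM = dm[i],
                            LBW = lbw[i], BW = lbw[i] * 1.26)
  }
  do.call(rbind, rows)
}
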