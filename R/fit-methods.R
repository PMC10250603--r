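# S3 methods for "pza_fit" objects.

#' @export
print.pza_fit <- function(x, ...) {
  cat("Population PK fit (FOCE-I), one-compartment oral steady state\n")
  cat(sprintf("  %d subjects, %d observations; OFV = %.3f%s\n",
              x$n_subjects, x$n_obs, x$ofv,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- x$coefficients
  cat("  estimates:",
      paste(sprintf("%s=%.4g", names(est), est), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pza_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients, se = object$se,
                    rse_pct = object$rse)
  omega <- sqrt(object$model$omega2)
  shr <- rep(NA_real_, nrow(tab))
  names(shr) <- rownames(tab)
  shr[c("omega_cl", "omega_v", "omega_ka")] <- object$shrinkage
  tab$shrinkage_pct <- shr
  out <- list(table = tab, ofv = object$ofv, converged = object$converged,
              n_subjects = object$n_subjects, n_obs = object$n_obs,
              omega_cv_pct = 100 * sqrt(exp(omega^2) - 1))
  class(out) <- "summary.pza_fit"
  out
}

#' @export
print.summary.pza_fit <- function(x, ...) {
  cat(sprintf("FOCE-I fit: %d subjects, %d observations, OFV %.3f%s\n\n",
              x$n_subjects, x$n_obs, x$ofv,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.pza_fit <- function(object, ...) object$coefficients

#' @export
vcov.pza_fit <- function(object, ...) object$vcov

#' @export
logLik.pza_fit <- function(object, ...) {
  # OFV is -2 logLik up to the dropped 2*pi constant
  val <- -(object$ofv + object$n_obs * log(2 * pi)) / 2
  structure(val, df = length(object$free), nobs = object$n_obs,
            class = "logLik")
}

#' Predicted concentrations from a population fit
#'
#' @param object A [pza_fit()].
#' @param newdata Optional long-format dataset or observation table; the
#'   fitted data are used when omitted.
#' @param type `"individual"` (at the empirical Bayes eta) or
#'   `"population"` (eta = 0).
#' @param ... Unused.
#' @return Data frame `ID`, `TIME`, `DV`, `PRED` or `IPRED`.
#' @export
predict.pza_fit <- function(object, newdata = NULL,
                            type = c("individual", "population"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    det <- object$detail
    obs <- object$prob$obs
  } else {
    ebe <- estimate_ebe(newdata, object$model,
                        terms = object$prob$terms,
                        allometry = object$prob$allometry)
    det <- ebe
    obs <- ebe$obs
  }
  out <- data.frame(ID = obs$ID, TIME = obs$TIME, DV = obs$DV)
  if (type == "individual") out$IPRED <- det$ipred else out$PRED <- det$pred
  out
}

#' Residual table for goodness-of-fit diagnostics
#'
#' Per observation: population prediction PRED (eta = 0), individual
#' prediction IPRED (at the conditional mode), raw residual, IWRES
#' (`(DV - IPRED) / sigma` for the additive error model) and CWRES
#' (residual standardised by the FOCE-linearised marginal covariance).
#'
#' @param fit A [pza_fit()].
#' @return Data frame with columns `ID`, `TIME`, `DV`, `PRED`, `IPRED`,
#'   `RES`, `IWRES`, `CWRES`.
#' @export
compute_residuals <- function(fit) {
  stopifnot(inherits(fit, "pza_fit"))
  obs <- fit$prob$obs
  det <- fit$detail
  data.frame(ID = obs$ID, TIME = obs$TIME, DV = obs$DV, PRED = det$pred,
             IPRED = det$ipred, RES = obs$DV - det$pred,
             IWRES = det$iwres, CWRES = det$cwres)
}

#' @export
residuals.pza_fit <- function(object,
                              type = c("cwres", "iwres", "response"), ...) {
  type <- match.arg(type)
  det <- object$detail
  switch(type,
         cwres = det$cwres,
         iwres = det$iwres,
         response = object$prob$obs$DV - det$ipred)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new random effects and residual errors at the fitted design (same
#' subjects, covariates, doses and sampling times); concentrations are
#' truncated at zero, matching the generator used throughout the package.
#'
#' @param object A [pza_fit()].
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with columns `sim`, `ID`, `TIME`, `DV`.
#' @export
simulate.pza_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  prob <- object$prob
  base <- .subject_base(prob)
  m <- object$model
  omega <- sqrt(m$omega2)
  n <- length(prob$ids)
  idx <- match(prob$obs$ID, prob$ids)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    eta <- matrix(stats::rnorm(3 * n), n, 3) %*% diag(omega)
    conc <- conc_ss(prob$obs$TIME, prob$pk$dose[idx],
                    base$cl[idx] * exp(eta[idx, 1]),
                    base$v[idx] * exp(eta[idx, 2]),
                    base$ka[idx] * exp(eta[idx, 3]), m$tau)
    dv <- pmax(conc + stats::rnorm(length(conc), 0, m$sigma_add), 0)
    out[[s]] <- data.frame(sim = s, ID = prob$obs$ID, TIME = prob$obs$TIME,
                           DV = dv)
  }
  do.call(rbind, out)
}

#' Goodness-of-fit plots for a population fit
#'
#' Four base-graphics panels: observed vs population predictions, observed
#' vs individual predictions, CWRES vs PRED and IWRES vs IPRED.
#'
#' @param x A [pza_fit()].
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.pza_fit <- function(x, ...) {
  r <- compute_residuals(x)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lim <- range(c(r$DV, r$PRED, r$IPRED))
  plot(r$PRED, r$DV, xlab = "Population predicted (ug/mL)",
       ylab = "Observed (ug/mL)", xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, col = 2)
  plot(r$IPRED, r$DV, xlab = "Individual predicted (ug/mL)",
       ylab = "Observed (ug/mL)", xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, col = 2)
  plot(r$PRED, r$CWRES, xlab = "Population predicted (ug/mL)",
       ylab = "CWRES", ...)
  graphics::abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = c(4, 2, 4))
  plot(r$IPRED, r$IWRES, xlab = "Individual predicted (ug/mL)",
       ylab = "IWRES", ...)
  graphics::abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = c(4, 2, 4))
  invisible(x)
}
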