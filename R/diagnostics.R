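# Internal validation: prediction-corrected visual predictive check and
# nonparametric bootstrap.

#' Prediction-corrected visual predictive check
#'
#' Observations are binned by sampling time (quantile-based bins) and each
#' observation is scaled by `median(PRED in bin) / PRED`, where PRED is
#' the population prediction (eta = 0); the same correction is applied to
#' every simulated replicate of the design. Observed 5th/50th/95th
#' prediction-corrected percentiles per bin are compared with the
#' simulation-based confidence bands of the same percentiles. BLQ rows
#' imputed by the M5 rule enter as ordinary data.
#'
#' @param data Long-format dataset or observation table.
#' @param model A [pza_model()] (typically the fitted model) or a
#'   [pza_fit()].
#' @param n_sim Number of simulated replicates (>= 100 recommended; must
#'   be >= 1).
#' @param bins Number of quantile time bins (empty bins are merged with a
#'   neighbour).
#' @param seed Integer seed for the simulation.
#' @param probs Percentiles summarised per bin.
#' @param ci Confidence level of the simulated percentile bands.
#' @param terms,allometry Covariate structure, as in [pza_fit()].
#' @return Object of class `"pza_vpc"`: per-bin observed percentiles,
#'   simulated percentile medians and CI bands, bin boundaries and counts.
#' @export
pc_vpc <- function(data, model, n_sim = 1000, bins = 8, seed = NULL,
                   probs = c(0.05, 0.5, 0.95), ci = 0.95,
                   terms = NULL, allometry = "lbw") {
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (inherits(model, "pza_fit")) {
    if (is.null(terms)) terms <- model$prob$terms
    allometry <- model$prob$allometry
    model <- model$model
  }
  if (is.null(terms)) terms <- list(gdm_term(model$gdm_effect))
  obs <- .as_observations(data)
  prob <- .foce_problem(obs, model, terms, allometry)
  det <- .foce_eval(prob, prob$par, detail = TRUE)
  obs <- prob$obs
  pred <- det$pred
  tt <- obs$TIME

  # quantile bins on time; merge bins left empty by ties
  edges <- unique(stats::quantile(tt, probs = seq(0, 1, length.out =
                                                    bins + 1)))
  if (length(edges) < 2) edges <- range(tt) + c(-1e-9, 1e-9)
  bin <- cut(tt, breaks = edges, include.lowest = TRUE)
  keep <- table(bin) > 0
  if (any(!keep)) bin <- droplevels(bin)

  pcf <- stats::ave(pred, bin, FUN = stats::median) / pred
  pc_obs <- obs$DV * pcf
  obs_q <- t(vapply(split(pc_obs, bin),
                    stats::quantile, numeric(length(probs)), probs = probs))

  if (!is.null(seed)) set.seed(seed)
  base <- .subject_base(prob)
  idx <- match(obs$ID, prob$ids)
  omega <- sqrt(model$omega2)
  n <- length(prob$ids)
  nb <- nlevels(bin)
  sim_q <- array(NA_real_, c(n_sim, nb, length(probs)))
  for (s in seq_len(n_sim)) {
    eta <- matrix(stats::rnorm(3 * n), n, 3) %*% diag(omega)
    conc <- conc_ss(tt, prob$pk$dose[idx],
                    base$cl[idx] * exp(eta[idx, 1]),
                    base$v[idx] * exp(eta[idx, 2]),
                    base$ka[idx] * exp(eta[idx, 3]), model$tau)
    dv <- pmax(conc + stats::rnorm(length(tt), 0, model$sigma_add), 0)
    sim_q[s, , ] <- t(vapply(split(dv * pcf, bin), stats::quantile,
                             numeric(length(probs)), probs = probs))
  }
  a <- (1 - ci) / 2
  band_lo <- apply(sim_q, c(2, 3), stats::quantile, probs = a)
  band_hi <- apply(sim_q, c(2, 3), stats::quantile, probs = 1 - a)
  band_med <- apply(sim_q, c(2, 3), stats::median)
  dimnames(obs_q) <- list(levels(bin), paste0("p", probs * 100))
  dimnames(band_lo) <- dimnames(band_hi) <- dimnames(band_med) <-
    dimnames(obs_q)
  mids <- vapply(split(tt, bin), stats::median, 0)
  structure(list(obs_q = obs_q, band_lo = band_lo, band_hi = band_hi,
                 band_med = band_med, bin_mid = mids,
                 bin_n = as.integer(table(bin)), probs = probs, ci = ci,
                 n_sim = n_sim, edges = edges),
            class = "pza_vpc")
}

#' @export
print.pza_vpc <- function(x, ...) {
  cat(sprintf("pcVPC: %d bins, %d simulations, %g%% bands\n",
              nrow(x$obs_q), x$n_sim, 100 * x$ci))
  print(round(cbind(mid_h = x$bin_mid, n = x$bin_n, x$obs_q), 3))
  invisible(x)
}

#' @export
plot.pza_vpc <- function(x, ...) {
  k <- which(x$probs == 0.5)
  ylim <- range(c(x$obs_q, x$band_lo, x$band_hi), na.rm = TRUE)
  plot(x$bin_mid, x$obs_q[, k], type = "b", pch = 16, ylim = ylim,
       xlab = "Time after dose (h)",
       ylab = "Prediction-corrected concentration (ug/mL)", ...)
  for (j in seq_along(x$probs)) {
    graphics::polygon(c(x$bin_mid, rev(x$bin_mid)),
                      c(x$band_lo[, j], rev(x$band_hi[, j])),
                      col = grDevices::adjustcolor(j + 1, 0.25),
                      border = NA)
    graphics::lines(x$bin_mid, x$obs_q[, j], lty = if (j == k) 1 else 2,
                    type = "b", pch = 16)
  }
  invisible(x)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement to the original cohort size,
#' refits the model on each replicate, and summarises per-parameter
#' medians and percentile confidence intervals over converged replicates.
#' Non-converged replicates are dropped and counted.
#'
#' @param data Long-format dataset or observation table.
#' @param start Starting [pza_model()].
#' @param n_resamples Number of bootstrap replicates (>= 1). 1000 is
#'   conventional for reporting; 50-200 is a practical desk scale.
#' @param seed Integer seed; resample indices are reproducible from it.
#' @param terms,allometry,fixed,control As in [pza_fit()].
#' @param ci Confidence level of the percentile interval.
#' @return Object of class `"pza_boot"`: `summary` (median and CI per
#'   parameter), `estimates` (replicate-by-parameter matrix),
#'   `convergence_fraction`, `n_resamples`.
#' @export
pza_bootstrap <- function(data, start = pza_model(), n_resamples = 200,
                          seed = NULL, terms =
                            list(gdm_term(start$gdm_effect)),
                          allometry = "lbw", fixed = NULL,
                          control = list(), ci = 0.95) {
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  obs <- .as_observations(data)
  ids <- unique(obs$ID)
  n <- length(ids)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(sample(ids, n * n_resamples, replace = TRUE),
                  n, n_resamples)
  rows_by_id <- split(seq_len(nrow(obs)), obs$ID)[as.character(ids)]
  est <- NULL
  ok <- logical(n_resamples)
  for (b in seq_len(n_resamples)) {
    take <- draws[, b]
    pieces <- vector("list", n)
    for (i in seq_len(n)) {
      block <- obs[rows_by_id[[match(take[i], ids)]], , drop = FALSE]
      block$ID <- i  # re-key so duplicated subjects stay distinct
      pieces[[i]] <- block
    }
    rep_obs <- do.call(rbind, pieces)
    fit <- tryCatch(pza_fit(rep_obs, start = start, terms = terms,
                            allometry = allometry, fixed = fixed,
                            se = FALSE, control = control),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      if (is.null(est))
        est <- matrix(NA_real_, n_resamples, length(fit$coefficients),
                      dimnames = list(NULL, names(fit$coefficients)))
      est[b, ] <- fit$coefficients
      ok[b] <- TRUE
    }
  }
  if (!any(ok)) stop("no bootstrap replicate converged")
  est_ok <- est[ok, , drop = FALSE]
  a <- (1 - ci) / 2
  summ <- data.frame(
    median = apply(est_ok, 2, stats::median),
    lower = apply(est_ok, 2, stats::quantile, probs = a),
    upper = apply(est_ok, 2, stats::quantile, probs = 1 - a))
  structure(list(summary = summ, estimates = est_ok,
                 convergence_fraction = mean(ok),
                 n_resamples = n_resamples, ci = ci, draws = draws),
            class = "pza_boot")
}

#' @export
print.pza_boot <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d resamples, %.0f%% converged\n",
              x$n_resamples, 100 * x$convergence_fraction))
  print(round(x$summary, 4))
  invisible(x)
}
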