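# Likelihood-ratio covariate search: forward selection then backward
# elimination over candidate covariate-parameter pairs, one covariate on
# one parameter per tested step.

#' Likelihood-ratio inclusion decision
#'
#' A candidate is accepted when the objective function drops by at least
#' the threshold (inclusive): `ofv_reduced - ofv_full >= threshold`.
#' 3.84 corresponds to p < 0.05 and 6.63 to p < 0.01 on 1 df.
#'
#' @param ofv_reduced OFV of the model without the covariate.
#' @param ofv_full OFV of the model with the covariate.
#' @param threshold Chi-squared threshold (1 df).
#' @return Logical.
#' @export
lrt_decision <- function(ofv_reduced, ofv_full, threshold = 3.84) {
  (ofv_reduced - ofv_full) >= threshold
}

#' Stepwise covariate search by forward selection and backward elimination
#'
#' Forward pass: every remaining candidate is fitted on top of the current
#' model (one covariate on one parameter per step); the largest OFV drop
#' meeting the forward threshold is accepted; repeats until no candidate
#' qualifies. The first forward step uses `forward_first` (3.84, p < 0.05,
#' 1 df) and later steps `forward_next` (6.63, p < 0.01), reflecting the
#' stricter criterion for sequential additions. Backward pass: each
#' retained covariate is deleted in turn; covariates whose deletion raises
#' the OFV by less than `backward` (6.63) are removed, iterating until all
#' survive. Ties are broken by candidate order; candidates whose fit fails
#' are skipped with a warning.
#'
#' @param data Long-format dataset or observation table.
#' @param base_model A [pza_model()] with starting values for the base
#'   (covariate-free) structure.
#' @param candidates List of [cov_term()] candidates.
#' @param base_terms Terms always kept in the base model (none by
#'   default).
#' @param forward_first,forward_next,backward OFV thresholds.
#' @param allometry Body-size scaling passed to [pza_fit()].
#' @param control Optimiser control list.
#' @return List of class `"pza_selection"`: `trace` (data frame of step,
#'   candidate, delta-OFV, decision), `selected` (final term list),
#'   `final` (final [pza_fit()]), `base_ofv`.
#' @export
stepwise_search <- function(data, base_model, candidates,
                            base_terms = list(),
                            forward_first = 3.84, forward_next = 6.63,
                            backward = 6.63, allometry = "lbw",
                            control = list()) {
  obs <- .as_observations(data)
  fit_cur <- pza_fit(obs, start = base_model, terms = base_terms,
                     allometry = allometry, se = FALSE, control = control)
  base_ofv <- fit_cur$ofv
  selected <- list()
  remaining <- candidates
  trace <- list()
  step <- 0L

  safe_fit <- function(terms, start) {
    tryCatch(pza_fit(obs, start = start, terms = terms,
                     allometry = allometry, se = FALSE, control = control),
             error = function(e) {
               warning("candidate fit failed: ", conditionMessage(e))
               NULL
             })
  }

  repeat {
    if (!length(remaining)) break
    thr <- if (length(selected) == 0) forward_first else forward_next
    fits <- lapply(remaining, function(cand)
      safe_fit(c(base_terms, selected, list(cand)), fit_cur$model))
    dofv <- vapply(fits, function(f)
      if (is.null(f)) -Inf else fit_cur$ofv - f$ofv, 0)
    best <- which.max(dofv)
    step <- step + 1L
    accepted <- length(best) && dofv[best] >= thr
    for (j in seq_along(remaining))
      trace[[length(trace) + 1L]] <- data.frame(
        phase = "forward", step = step,
        candidate = remaining[[j]]$label, dofv = dofv[j],
        decision = if (accepted && j == best) "accept" else "reject")
    if (!accepted) break
    selected <- c(selected, remaining[best])
    fit_cur <- fits[[best]]
    remaining <- remaining[-best]
  }

  repeat {
    if (!length(selected)) break
    dropped <- FALSE
    for (j in seq_along(selected)) {
      fit_wo <- safe_fit(c(base_terms, selected[-j]), fit_cur$model)
      if (is.null(fit_wo)) next
      rise <- fit_wo$ofv - fit_cur$ofv
      step <- step + 1L
      keep <- rise >= backward
      trace[[length(trace) + 1L]] <- data.frame(
        phase = "backward", step = step,
        candidate = selected[[j]]$label, dofv = rise,
        decision = if (keep) "retain" else "remove")
      if (!keep) {
        selected <- selected[-j]
        fit_cur <- fit_wo
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }

  structure(list(trace = if (length(trace)) do.call(rbind, trace)
                 else data.frame(phase = character(0), step = integer(0),
                                 candidate = character(0), dofv = numeric(0),
                                 decision = character(0)),
                 selected = selected, final = fit_cur,
                 base_ofv = base_ofv),
            class = "pza_selection")
}

#' @export
print.pza_selection <- function(x, ...) {
  cat("Stepwise covariate search\n")
  cat(sprintf("  base OFV %.3f -> final OFV %.3f\n", x$base_ofv,
              x$final$ofv))
  cat("  selected:",
      if (length(x$selected))
        paste(vapply(x$selected, `[[`, "", "label"), collapse = ", ")
      else "(none)", "\n")
  if (nrow(x$trace)) print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Compare total vs lean body weight as the allometric size descriptor
#'
#' Fits the base structure without allometry, with allometric scaling on
#' lean body weight, and with allometric scaling on total body weight
#' (fixed exponents 0.75 on CL and 1 on V throughout), and tabulates the
#' OFV drop of each size descriptor relative to the no-allometry base.
#'
#' @param data Long-format dataset or observation table with `LBW` and
#'   `BW` columns.
#' @param model Starting [pza_model()].
#' @param terms Covariate terms included in all three fits.
#' @param control Optimiser control.
#' @return List: `table` (data frame of descriptor, OFV, delta-OFV) and
#'   `selected` (descriptor with the larger drop).
#' @export
compare_body_size_predictors <- function(data, model, terms = list(),
                                         control = list()) {
  obs <- .as_observations(data)
  fits <- list(
    none = pza_fit(obs, model, terms = terms, allometry = "none",
                   se = FALSE, control = control),
    lbw = pza_fit(obs, model, terms = terms, allometry = "lbw",
                  se = FALSE, control = control),
    bw = pza_fit(obs, model, terms = terms, allometry = "bw",
                 se = FALSE, control = control))
  ofv <- vapply(fits, `[[`, 0, "ofv")
  tab <- data.frame(descriptor = c("none", "lbw", "bw"), ofv = ofv,
                    dofv = ofv["none"] - ofv)
  rownames(tab) <- NULL
  list(table = tab,
       selected = c("lbw", "bw")[which.max(tab$dofv[2:3])],
       fits = fits)
}
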