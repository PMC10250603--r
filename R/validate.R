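# External validation (MPE/APE under population and individual
# prediction), comparator-model registry, Bayesian exposure forecasting
# and PK/PD target attainment.

#' Mean prediction error
#'
#' `MPE = sum(C_pred - C_obs) / N` (ug/mL): the signed bias of the
#' predictions.
#'
#' @param pred Predicted concentrations.
#' @param obs Observed concentrations (same length, N >= 1).
#' @return Scalar MPE.
#' @export
mpe <- function(pred, obs) {
  if (length(pred) != length(obs) || !length(pred))
    stop("pred and obs must be equal-length, non-empty")
  mean(pred - obs)
}

#' Absolute prediction error
#'
#' `APE = sum(|C_pred - C_obs|) / N` (ug/mL): the imprecision companion of
#' [mpe()]; always `>= |MPE|`.
#'
#' @inheritParams mpe
#' @return Scalar APE.
#' @export
ape <- function(pred, obs) {
  if (length(pred) != length(obs) || !length(pred))
    stop("pred and obs must be equal-length, non-empty")
  mean(abs(pred - obs))
}

#' External validation of a population model on a test dataset
#'
#' Computes per-observation prediction errors under population prediction
#' (eta = 0) or individual prediction (each subject's own empirical Bayes
#' eta, estimated from that subject's observations), and summarises MPE
#' and APE. Intervals are reported two ways: the 2.5-97.5 percentile
#' interval of the per-observation errors and the min-max range, since
#' published error tables are often empirical ranges rather than
#' standard-error intervals. Note the individual mode re-uses the same
#' observations for eta estimation and error computation, which is how
#' sparse TDM validation is conventionally reported; both modes are
#' therefore provided.
#'
#' @param test_data Long-format dataset or observation table (disjoint
#'   from the training data).
#' @param model A [pza_model()] or [pza_fit()].
#' @param mode `"population"` or `"individual"`.
#' @param label Model label carried into the summary.
#' @param terms,allometry Covariate structure, as in [pza_fit()].
#' @return List of class `"pza_validation"`: `mpe`, `ape`, percentile and
#'   range intervals, `n`, `mode`, `label`, per-observation `errors`.
#' @export
external_validate <- function(test_data, model,
                              mode = c("population", "individual"),
                              label = "model", terms = NULL,
                              allometry = "lbw") {
  mode <- match.arg(mode)
  if (inherits(model, "pza_fit")) {
    if (is.null(terms)) terms <- model$prob$terms
    allometry <- model$prob$allometry
    model <- model$model
  }
  if (is.null(terms)) terms <- list(gdm_term(model$gdm_effect))
  ebe <- estimate_ebe(test_data, model, terms = terms,
                      allometry = allometry)
  pred <- if (mode == "population") ebe$pred else ebe$ipred
  err <- pred - ebe$obs$DV
  qs <- stats::quantile(err, c(0.025, 0.975))
  structure(list(mpe = mean(err), ape = mean(abs(err)),
                 mpe_ci = unname(qs), range = range(err),
                 ape_ci = unname(stats::quantile(abs(err), c(0.025, 0.975))),
                 n = length(err), mode = mode, label = label,
                 errors = err),
            class = "pza_validation")
}

#' @export
print.pza_validation <- function(x, ...) {
  cat(sprintf("%s, %s prediction, N = %d\n", x$label, x$mode, x$n))
  cat(sprintf("  MPE %.3f (2.5-97.5%%: %.3f to %.3f; range %.3f to %.3f)\n",
              x$mpe, x$mpe_ci[1], x$mpe_ci[2], x$range[1], x$range[2]))
  cat(sprintf("  APE %.3f (2.5-97.5%%: %.3f to %.3f)\n", x$ape,
              x$ape_ci[1], x$ape_ci[2]))
  invisible(x)
}

#' Comparator-model registry
#'
#' Holds labelled [pza_model()] parameter sets (e.g. previously published
#' population models supplied by the user; no third-party parameter values
#' are built in) for side-by-side external validation. Registries
#' round-trip through YAML.
#'
#' @return An empty registry of class `"pza_registry"`.
#' @export
model_registry <- function() {
  structure(list(env = new.env(parent = emptyenv())),
            class = "pza_registry")
}

#' @rdname model_registry
#' @param registry A registry.
#' @param label Unique model label.
#' @param model A [pza_model()].
#' @export
register_model <- function(registry, label, model) {
  stopifnot(inherits(registry, "pza_registry"),
            inherits(model, "pza_model"))
  if (exists(label, envir = registry$env, inherits = FALSE))
    stop("duplicate label: ", label)
  assign(label, model, envir = registry$env)
  invisible(registry)
}

#' @rdname model_registry
#' @export
registry_labels <- function(registry) {
  sort(ls(registry$env))
}

#' @rdname model_registry
#' @export
registry_get <- function(registry, label) {
  if (!exists(label, envir = registry$env, inherits = FALSE))
    stop("no model registered under label: ", label)
  get(label, envir = registry$env)
}

#' @rdname model_registry
#' @param path YAML file path.
#' @export
write_model_registry <- function(registry, path) {
  out <- lapply(registry_labels(registry), function(lb) {
    m <- registry_get(registry, lb)
    list(theta_cl = unname(m$theta["cl"]), theta_v = unname(m$theta["v"]),
         theta_ka = unname(m$theta["ka"]), gdm_effect = m$gdm_effect,
         omega = as.list(m$omega2), omega_scale = "variance",
         omega_fixed = as.list(m$omega_fixed), sigma_add = m$sigma_add,
         lbw_ref = m$lbw_ref, age_cutoff = m$age_cutoff, tau = m$tau)
  })
  names(out) <- registry_labels(registry)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname model_registry
#' @export
read_model_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  reg <- model_registry()
  for (lb in names(raw)) {
    a <- raw[[lb]]
    m <- pza_model(theta_cl = a$theta_cl, theta_v = a$theta_v,
                   theta_ka = a$theta_ka, gdm_effect = a$gdm_effect,
                   omega = unlist(a$omega), omega_scale = a$omega_scale,
                   omega_fixed = unlist(a$omega_fixed),
                   sigma_add = a$sigma_add, lbw_ref = a$lbw_ref,
                   age_cutoff = a$age_cutoff, tau = a$tau)
    register_model(reg, lb, m)
  }
  reg
}

#' Bayesian exposure forecasting for individual subjects
#'
#' Estimates each subject's empirical Bayes PK parameters from their own
#' observations, then reports dose-normalised steady-state exposure:
#' `AUC(0-24) = normalization_dose / CL_i` and the peak from [cmax_ss()]
#' at the normalisation dose with the individual parameters. Subjects are
#' labelled by the four age-by-DM subgroups.
#'
#' @param data Long-format dataset or observation table (each subject with
#'   at least one observation).
#' @param model A [pza_model()] or [pza_fit()].
#' @param normalization_dose Dose (mg) to which exposure is normalised.
#' @param terms,allometry Covariate structure, as in [pza_fit()].
#' @return Data frame: `ID`, `cl`, `v`, `ka`, `auc`, `cmax`,
#'   `norm_dose`, `group`.
#' @export
forecast_individual <- function(data, model, normalization_dose = 1200,
                                terms = NULL, allometry = "lbw") {
  if (inherits(model, "pza_fit")) {
    if (is.null(terms)) terms <- model$prob$terms
    allometry <- model$prob$allometry
    model <- model$model
  }
  if (is.null(terms)) terms <- list(gdm_term(model$gdm_effect))
  ebe <- estimate_ebe(data, model, terms = terms, allometry = allometry)
  p <- ebe$params
  subj <- .as_observations(data)
  subj <- subj[match(p$ID, subj$ID), , drop = FALSE]
  group <- .age_dm_group(subj$AGE, subj$DM, model$age_cutoff)
  cmax <- vapply(seq_len(nrow(p)), function(i)
    cmax_ss(normalization_dose, p$cl[i], p$v[i], p$ka[i], model$tau)[["cmax"]],
    0)
  data.frame(ID = p$ID, cl = p$cl, v = p$v, ka = p$ka,
             auc = auc_ss(normalization_dose, p$cl), cmax = cmax,
             norm_dose = normalization_dose, group = group)
}

.age_dm_group <- function(age, dm, cutoff = 70) {
  if (is.null(age) || is.null(dm)) return(rep(NA_character_, length(age)))
  old <- age >= cutoff
  ifelse(old & dm == 1, sprintf("age>=%g, DM", cutoff),
  ifelse(old, sprintf("age>=%g, no DM", cutoff),
  ifelse(dm == 1, sprintf("age<%g, DM", cutoff),
         sprintf("age<%g, no DM", cutoff))))
}

#' PK/PD efficacy target attainment
#'
#' Fractions of subjects meeting the commonly used pyrazinamide efficacy
#' targets AUC(0-24) >= 363 ug.h/mL and Cmax >= 30 ug/mL (both
#' inclusive), and both jointly.
#'
#' @param estimates Data frame from [forecast_individual()] (columns `auc`
#'   and `cmax`), non-empty.
#' @param auc_target,cmax_target Target thresholds.
#' @return Named vector: `auc`, `cmax`, `both` attainment fractions.
#' @export
target_attainment <- function(estimates, auc_target = 363,
                              cmax_target = 30) {
  if (!nrow(estimates)) stop("estimates must be non-empty")
  c(auc = mean(estimates$auc >= auc_target),
    cmax = mean(estimates$cmax >= cmax_target),
    both = mean(estimates$auc >= auc_target &
                  estimates$cmax >= cmax_target))
}

#' Exposure summaries by age-by-DM subgroup
#'
#' Medians and interquartile ranges of AUC, Cmax and clearance in the four
#' age-by-DM groups, with group sizes.
#'
#' @param estimates Data frame from [forecast_individual()] with a `group`
#'   column.
#' @return Data frame with one row per group.
#' @export
subgroup_summary <- function(estimates) {
  if (is.null(estimates$group)) stop("estimates must carry a group column")
  sp <- split(estimates, estimates$group)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    e <- sp[[g]]
    q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75))
    qa <- q(e$auc); qc <- q(e$cmax); ql <- q(e$cl)
    data.frame(group = g, n = nrow(e),
               auc_median = qa[2], auc_q1 = qa[1], auc_q3 = qa[3],
               cmax_median = qc[2], cmax_q1 = qc[1], cmax_q3 = qc[3],
               cl_median = ql[2], cl_q1 = ql[1], cl_q3 = ql[3])
  }))
  rownames(out) <- NULL
  out
}
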