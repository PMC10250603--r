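#' Population pharmacokinetic model specification for pyrazinamide
#'
#' Constructs the population model object: a one-compartment model with
#' first-order absorption and elimination at steady state, allometric
#' scaling of apparent clearance (exponent 0.75) and central volume
#' (exponent 1) on lean body weight, a categorical geriatric
#' diabetes-mellitus (DM) covariate on clearance, log-normal
#' interindividual variability (IIV) and additive residual error.
#' Bioavailability is not separately identifiable after oral dosing, so all
#' parameters are apparent (CL/F, Vd/F).
#'
#' Defaults are the final-model estimates for a typical patient with lean
#' body weight 48 kg: CL/F 4.49 L/h, Vd/F 44.2 L, Ka 1.49 1/h, a +32%
#' clearance shift for patients aged >= 70 years with DM, and additive
#' residual SD 3.41 ug/mL.
#'
#' @param theta_cl Typical apparent clearance (L/h) at the reference lean
#'   body weight, without the geriatric-DM shift.
#' @param theta_v Typical apparent central volume (L).
#' @param theta_ka Typical absorption rate constant (1/h).
#' @param gdm_effect Fractional clearance shift for geriatric-DM patients
#'   (dimensionless; CL is multiplied by `1 + gdm_effect`). Must be > -1.
#' @param omega Named numeric vector of IIV magnitudes for `cl`, `v`, `ka`,
#'   interpreted according to `omega_scale`.
#' @param omega_scale How `omega` is read: `"cv_percent"` (percent
#'   coefficient of variation of the log-normal effect, the default;
#'   variance = log(1 + (cv/100)^2)), `"sd"` (SD of eta) or `"variance"`
#'   (variance of eta).
#' @param omega_fixed Logical vector; `TRUE` entries are held constant
#'   during estimation (the volume IIV is fixed in the final model).
#' @param sigma_add Additive residual error SD (ug/mL).
#' @param lbw_ref Reference lean body weight (kg) at which the typical
#'   values apply.
#' @param allo_exp_cl,allo_exp_v Fixed allometric exponents for clearance
#'   and volume; never estimated.
#' @param age_cutoff Age (years) at or above which a DM patient carries the
#'   geriatric-DM covariate.
#' @param tau Dosing interval (h); once-daily dosing by default.
#' @return An object of class `"pza_model"`.
#' @examples
#' m <- pza_model()
#' individual_parameters(m, list(lbw = 48, age = 75, dm = TRUE))$cl
#' @export
pza_model <- function(theta_cl = 4.49, theta_v = 44.2, theta_ka = 1.49,
                      gdm_effect = 0.32,
                      omega = c(cl = 1, v = 3, ka = 100),
                      omega_scale = c("cv_percent", "sd", "variance"),
                      omega_fixed = c(cl = FALSE, v = TRUE, ka = FALSE),
                      sigma_add = 3.41,
                      lbw_ref = 48, allo_exp_cl = 0.75, allo_exp_v = 1,
                      age_cutoff = 70, tau = 24) {
  omega_scale <- match.arg(omega_scale)
  if (any(c(theta_cl, theta_v, theta_ka, sigma_add) <= 0))
    stop("theta_cl, theta_v, theta_ka and sigma_add must be strictly positive")
  if (gdm_effect <= -1)
    stop("gdm_effect must be > -1 (clearance must remain positive)")
  omega <- .named3(omega, "omega")
  omega_fixed <- .named3(omega_fixed, "omega_fixed")
  if (any(omega < 0)) stop("omega entries must be non-negative")
  omega2 <- switch(omega_scale,
    cv_percent = log(1 + (omega / 100)^2),
    sd = omega^2,
    variance = omega)
  structure(list(
    theta = c(cl = theta_cl, v = theta_v, ka = theta_ka),
    gdm_effect = gdm_effect,
    omega2 = omega2,
    omega_fixed = stats::setNames(as.logical(omega_fixed),
                                  names(omega_fixed)),
    sigma_add = sigma_add,
    lbw_ref = lbw_ref,
    allo_exp = c(cl = allo_exp_cl, v = allo_exp_v),
    age_cutoff = age_cutoff,
    tau = tau
  ), class = "pza_model")
}

.named3 <- function(x, what) {
  nm <- c("cl", "v", "ka")
  if (is.null(names(x))) {
    if (length(x) != 3) stop(what, " must have 3 entries (cl, v, ka)")
    names(x) <- nm
  }
  if (!all(nm %in% names(x))) stop(what, " must be named cl, v, ka")
  x[nm]
}

#' @export
print.pza_model <- function(x, ...) {
  cat("One-compartment oral steady-state population PK model\n")
  cat(sprintf("  CL/F %.4g L/h  Vd/F %.4g L  Ka %.4g 1/h  (lbw ref %g kg)\n",
              x$theta["cl"], x$theta["v"], x$theta["ka"], x$lbw_ref))
  cat(sprintf("  geriatric-DM (age >= %g y, DM) effect on CL: %+.3g (x%.4g)\n",
              x$age_cutoff, x$gdm_effect, 1 + x$gdm_effect))
  cat(sprintf("  IIV omega^2 (log scale): cl %.3g%s, v %.3g%s, ka %.3g%s\n",
              x$omega2["cl"], if (x$omega_fixed["cl"]) " (fix)" else "",
              x$omega2["v"], if (x$omega_fixed["v"]) " (fix)" else "",
              x$omega2["ka"], if (x$omega_fixed["ka"]) " (fix)" else ""))
  cat(sprintf("  additive residual SD: %.4g ug/mL; tau = %g h\n",
              x$sigma_add, x$tau))
  invisible(x)
}

#' Steady-state concentration of the one-compartment oral model
#'
#' Closed-form superposition solution for repeated dosing every `tau` hours
#' at steady state:
#' \deqn{C(t) = \frac{D k_a}{V (k_a - k_e)}
#'   \left[\frac{e^{-k_e t}}{1 - e^{-k_e \tau}} -
#'         \frac{e^{-k_a t}}{1 - e^{-k_a \tau}}\right],\quad k_e = CL/V.}
#' The removable singularity at \eqn{k_a = k_e} ("flip-flop" boundary) is
#' evaluated by its analytic limit when |ka - ke| < 1e-6 ka, so the profile
#' is continuous in all parameters.
#'
#' @param t Time since last dose (h), in `[0, tau]`. `t = 0` equals the
#'   trough at `t = tau` (steady-state periodicity).
#' @param dose Dose amount (mg). A zero dose gives zero concentration.
#' @param cl,v,ka Individual apparent clearance (L/h), volume (L) and
#'   absorption rate constant (1/h); strictly positive.
#' @param tau Dosing interval (h).
#' @return Concentration (ug/mL); vectorised with recycling.
#' @examples
#' conc_ss(2, dose = 1500, cl = 4.49, v = 44.2, ka = 1.49)
#' @export
conc_ss <- function(t, dose, cl, v, ka, tau = 24) {
  .conc_check(t, dose, cl, v, ka, tau)
  n <- max(length(t), length(dose), length(cl), length(v), length(ka),
           length(tau))
  .conc_cpp(rep_len(as.numeric(t), n), rep_len(as.numeric(dose), n),
            rep_len(as.numeric(tau), n), rep_len(as.numeric(cl), n),
            rep_len(as.numeric(v), n), rep_len(as.numeric(ka), n), TRUE)
}

#' Concentration after a single oral dose
#'
#' Single-dose counterpart of [conc_ss()] (no accumulation); used mainly for
#' testing the steady-state solution against explicit dose superposition.
#'
#' @inheritParams conc_ss
#' @param t Time since the dose (h), any non-negative value.
#' @return Concentration (ug/mL).
#' @export
conc_single <- function(t, dose, cl, v, ka) {
  .conc_check(t, dose, cl, v, ka, 24)
  n <- max(length(t), length(dose), length(cl), length(v), length(ka))
  .conc_cpp(rep_len(as.numeric(t), n), rep_len(as.numeric(dose), n),
            rep_len(24, n), rep_len(as.numeric(cl), n),
            rep_len(as.numeric(v), n), rep_len(as.numeric(ka), n), FALSE)
}

.conc_check <- function(t, dose, cl, v, ka, tau) {
  if (any(cl <= 0) || any(v <= 0) || any(ka <= 0))
    stop("cl, v and ka must be strictly positive")
  if (any(tau <= 0)) stop("tau must be positive")
  if (any(dose < 0)) stop("dose must be non-negative")
  if (any(t < 0)) stop("t must be non-negative")
}

#' Steady-state AUC over one dosing interval
#'
#' At steady state the area under the curve over `[0, tau]` equals
#' `dose / cl` exactly, independent of volume and absorption rate.
#'
#' @param dose Dose amount (mg).
#' @param cl Apparent clearance (L/h).
#' @return AUC over one dosing interval (ug.h/mL).
#' @examples
#' auc_ss(1500, 4.49)
#' @export
auc_ss <- function(dose, cl) {
  if (any(cl <= 0)) stop("cl must be strictly positive")
  if (any(dose < 0)) stop("dose must be non-negative")
  dose / cl
}

#' Steady-state peak concentration and time of peak
#'
#' No closed form exists for the peak under repeated dosing; the maximum of
#' [conc_ss()] is located on a dense grid over `[0, tau]` and refined by
#' bounded golden-section maximisation.
#'
#' @inheritParams conc_ss
#' @return Named vector `c(cmax, tmax)` (ug/mL, h).
#' @examples
#' cmax_ss(1500, 4.49, 44.2, 1.49)
#' @export
cmax_ss <- function(dose, cl, v, ka, tau = 24) {
  .conc_check(0, dose, cl, v, ka, tau)
  if (dose == 0) return(c(cmax = 0, tmax = 0))
  grid <- seq(0, tau, length.out = 481)
  cg <- conc_ss(grid, dose, cl, v, ka, tau)
  i <- which.max(cg)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(tt) conc_ss(tt, dose, cl, v, ka, tau),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-6)
  if (opt$objective >= cg[i])
    c(cmax = opt$objective, tmax = opt$maximum)
  else c(cmax = cg[i], tmax = grid[i])
}

#' Power-function covariate factor
#'
#' Multiplicative factor `(value / median)^exponent` used for continuous
#' covariates; equals 1 at the covariate median.
#'
#' @param value Covariate value for the subject (> 0).
#' @param median Population median of the covariate (> 0).
#' @param exponent Power exponent.
#' @return Dimensionless positive factor.
#' @export
power_factor <- function(value, median, exponent) {
  if (any(value <= 0) || any(median <= 0))
    stop("value and median must be strictly positive")
  (value / median)^exponent
}

#' Categorical covariate factor
#'
#' Multiplicative factor `1 + effect * flag` used for binary covariates:
#' 1 when the flag is off, `1 + effect` when on.
#'
#' @param effect Fractional shift (must be > -1 so the factor stays
#'   positive).
#' @param flag Binary indicator (0/1 or logical).
#' @return Dimensionless positive factor.
#' @export
categorical_factor <- function(effect, flag) {
  flag <- as.numeric(flag)
  if (any(flag != 0 & effect <= -1))
    stop("effect must be > -1 where the flag is set")
  1 + effect * flag
}

#' Allometric body-size factor
#'
#' `(size / ref)^exponent` with a fixed exponent (0.75 for clearance, 1 for
#' volume); the exponent is structural, never estimated.
#'
#' @param size Body-size measure, typically lean body weight (kg, > 0).
#' @param ref Reference size (kg); 48 kg for the typical patient.
#' @param exponent Fixed allometric exponent.
#' @return Dimensionless positive factor.
#' @export
allometric_factor <- function(size, ref = 48, exponent) {
  if (any(size <= 0) || any(ref <= 0))
    stop("size and ref must be strictly positive")
  (size / ref)^exponent
}

#' Geriatric-DM covariate indicator
#'
#' TRUE for patients at or above the age cutoff (default 70 years) who have
#' diabetes mellitus.
#'
#' @param age Age in years (study inclusion required age > 18).
#' @param dm Logical/0-1 diabetes indicator.
#' @param cutoff Age cutoff in years.
#' @return Logical vector.
#' @export
is_geriatric_dm <- function(age, dm, cutoff = 70) {
  if (any(age < 18)) stop("age must be >= 18")
  (age >= cutoff) & as.logical(dm)
}

#' Individual PK parameters from population model, covariates and eta
#'
#' Applies the final-model covariate structure:
#' `CL = theta_cl * (lbw/ref)^0.75 * (1 + gdm_effect * GDM) * exp(eta_cl)`,
#' `V = theta_v * (lbw/ref)^1 * exp(eta_v)`, `Ka = theta_ka * exp(eta_ka)`.
#'
#' @param model A [pza_model()].
#' @param covariates List or one-row data frame with `lbw` (kg) and either
#'   `gdm` (logical) or `age` plus `dm`.
#' @param eta Numeric length-3 random-effect vector (log scale), default 0.
#' @return List with elements `cl`, `v`, `ka`, `eta`.
#' @export
individual_parameters <- function(model, covariates, eta = c(0, 0, 0)) {
  stopifnot(inherits(model, "pza_model"), length(eta) == 3)
  cv <- as.list(covariates)
  if (is.null(cv$lbw)) stop("covariates must include lbw")
  gdm <- if (!is.null(cv$gdm)) as.logical(cv$gdm)
         else if (!is.null(cv$age) && !is.null(cv$dm))
           is_geriatric_dm(cv$age, cv$dm, model$age_cutoff)
         else stop("covariates must include gdm, or age and dm")
  cl <- model$theta["cl"] *
    allometric_factor(cv$lbw, model$lbw_ref, model$allo_exp["cl"]) *
    categorical_factor(model$gdm_effect, gdm) * exp(eta[1])
  v <- model$theta["v"] *
    allometric_factor(cv$lbw, model$lbw_ref, model$allo_exp["v"]) *
    exp(eta[2])
  ka <- model$theta["ka"] * exp(eta[3])
  list(cl = unname(cl), v = unname(v), ka = unname(ka), eta = eta)
}

#' Lean body weight by the Janmahasatian formula
#'
#' Convenience helper for datasets that record only total body weight and
#' height: `LBW = 9270 W / (6680 + 216 BMI)` for males and
#' `9270 W / (8780 + 244 BMI)` for females, with BMI in kg/m^2.
#'
#' @param weight Total body weight (kg).
#' @param height Height (cm).
#' @param male Logical; TRUE for male.
#' @return Lean body weight (kg).
#' @export
lbw_janmahasatian <- function(weight, height, male) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  bmi <- weight / (height / 100)^2
  ifelse(as.logical(male),
         9270 * weight / (6680 + 216 * bmi),
         9270 * weight / (8780 + 244 * bmi))
}
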