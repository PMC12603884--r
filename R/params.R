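#' Default population parameter sets
#'
#' Typical values, interindividual variability (IIV) and residual-error
#' parameters for the clonidine and midazolam pharmacokinetic models and the
#' joint COMFORT-B pharmacodynamic model in ventilated children, standardized
#' to a 70-kg reference by allometry. These are the package defaults used by
#' the synthetic-trial generator and the regimen simulator; every entry can be
#' overridden.
#'
#' Units: clearances L/h/70 kg, volumes L/70 kg, EC50 ng/mL, scores in
#' COMFORT-B points (scale range 6-31), times in hours. IIV entries are
#' percent coefficients of variation of the lognormal random effects
#' (see [cv_to_omega()]); residual proportional errors are fractional
#' standard deviations, additive errors in ng/mL.
#'
#' @return A named list of parameters.
#' @seealso [individualize_pk()], [simulate_trial()]
#' @export
clonidine_pk_params <- function() {
  list(
    cl = 28.0,          # typical clearance, L/h/70 kg
    v = 202.4,          # typical volume, L/70 kg
    iiv_cl = 49.6,      # %CV
    iiv_v = 87.7,       # %CV
    err_prop = 0.436,   # proportional residual SD (fraction)
    pma50 = 61.6,       # maturation half-point, weeks (fixed)
    hill = 2.42         # maturation shape (fixed)
  )
}

#' @rdname clonidine_pk_params
#' @export
midazolam_pk_params <- function() {
  list(
    v = 85.8,            # parent volume, L/70 kg
    clm = 33.4,          # metabolite formation clearance, L/h/70 kg
    vm = 90.8,           # metabolite volume, L/70 kg
    clom = 211.6,        # clearance out of metabolite compartment, L/h/70 kg
    iiv_clm = 91.7,      # %CV
    iiv_v = 133.4,       # %CV
    err_prop = 0.469,    # parent proportional SD
    err_add = 1.24,      # parent additive SD, ng/mL
    err_prop_m = 0.574,  # metabolite proportional SD
    err_add_m = 0.023,   # metabolite additive SD, ng/mL
    pma50 = 73.6,        # maturation half-point, weeks (fixed)
    hill = 3             # maturation shape (fixed)
  )
}

#' @rdname clonidine_pk_params
#' @export
clonidine_pd_params <- function() {
  list(
    ec50 = 2.73,        # ng/mL
    emax = 6,           # maximal drug effect, score points (fixed)
    gamma = 1,          # sigmoid shape (Emax model)
    b0 = 15.6,          # nonsurgical baseline score
    base = 6,           # score at end of surgery (fixed, scale minimum)
    paemax = 11.8,      # maximal postanesthesia effect (fixed in joint model)
    tps50 = 0.11,       # h, time after surgery at half postanesthesia effect
    iiv_ec50 = 525,     # %CV
    err_prop = 0.282    # proportional residual SD on scores
  )
}

#' @rdname clonidine_pk_params
#' @export
midazolam_pd_params <- function() {
  list(
    ec50 = 186.0,
    emax = 6,
    gamma = 1,
    b0 = 15.6,          # latent nonsurgical baseline used for simulation
    base = 6,
    paemax = 9.3,
    tps50 = 0.11,
    iiv_ec50 = 246.6,
    err_prop = 0.249
  )
}

#' Propofol K-PD constants
#'
#' Parameters of the kinetic-pharmacodynamic (K-PD) model for the bridging
#' propofol effect on the COMFORT-B score: a virtual compartment with
#' first-order rate constant `kde` whose elimination flux (the infusion-rate
#' equivalent, IRE) drives an Emax effect. Concentrations of propofol were
#' never assayed in the emulated design, so these are synthetic placeholder
#' constants chosen to give a plausible, rapidly washing-out bridging effect;
#' they are treated as fixed (never estimated).
#'
#' @return Named list with `kde` (1/h), `emax_cm` (score points) and
#'   `ec50_cm` (ug/h infusion-rate equivalent).
#' @export
propofol_kpd_params <- function() {
  list(kde = 2, emax_cm = 3, ec50_cm = 8000)
}

#' Convert between percent CV and lognormal standard deviation
#'
#' IIV magnitudes are reported as percent coefficients of variation of the
#' lognormal distribution: `cv_pct = 100 * sqrt(exp(omega^2) - 1)`, where
#' `omega` is the standard deviation of the random effect on the log scale.
#' The simpler convention `100 * omega` is also displayed by
#' [summary.pkpd_fit()] for comparability.
#'
#' @param cv_pct percent CV (nonnegative)
#' @param omega lognormal SD on the log scale (nonnegative)
#' @return the converted value
#' @export
cv_to_omega <- function(cv_pct) {
  stopifnot(all(cv_pct >= 0))
  sqrt(log(1 + (cv_pct / 100)^2))
}

#' @rdname cv_to_omega
#' @export
omega_to_cv <- function(omega) {
  stopifnot(all(omega >= 0))
  100 * sqrt(exp(omega^2) - 1)
}
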