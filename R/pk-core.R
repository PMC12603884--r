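#' Sigmoidal maturation of clearance with postmenstrual age
#'
#' Fraction of mature (adult) clearance at a given postmenstrual age (PMA):
#' `pma^hill / (pma50^hill + pma^hill)`. The function is strictly increasing
#' in PMA, equals 0.5 at `pma50` and tends to 1 as PMA grows. Maturation
#' multiplies clearances only, never volumes.
#'
#' @param pma postmenstrual age in weeks (> 0); vectorized
#' @param pma50 PMA at 50% maturation, weeks (> 0)
#' @param hill dimensionless shape parameter (> 0)
#' @return maturation fraction in (0, 1)
#' @examples
#' maturation(61.6, 61.6, 2.42)  # 0.5 at the half-point
#' @export
maturation <- function(pma, pma50, hill) {
  if (any(!is.finite(pma)) || any(pma <= 0))
    stop("'pma' must be positive and finite")
  if (pma50 <= 0 || hill <= 0) stop("'pma50' and 'hill' must be positive")
  r <- (pma / pma50)^hill
  r / (1 + r)
}

#' Individual pharmacokinetic parameters from covariates
#'
#' Scales typical (70-kg standardized) parameters to an individual using
#' allometric weight scaling (exponent 0.75 for clearances, 1 for volumes), a
#' PMA-based sigmoidal maturation function on clearances, and lognormal
#' random effects: `CL_i = CL_std * (WT/70)^0.75 * MF(PMA) * exp(eta_CL)` and
#' `V_i = V_std * (WT/70) * exp(eta_V)`.
#'
#' For midazolam, maturation applies by default to both the metabolite
#' formation clearance (`clm`) and the clearance out of the metabolite
#' compartment (`clom`); set `mature_clom = FALSE` to restrict it to `clm`.
#'
#' @param drug `"clonidine"` or `"midazolam"`
#' @param theta named list of typical values (see [clonidine_pk_params()])
#' @param covariates list or one-row data.frame with `wt` (kg, > 0) and
#'   `pma` (weeks, > 0); both mandatory
#' @param eta named numeric of random effects; missing entries default to 0.
#'   Recognized names: `cl`, `v` (clonidine); `clm`, `v` (midazolam).
#' @param mature_clom logical; apply maturation to `clom` as well (default TRUE)
#' @return named list of individual parameters (`cl`, `v` for clonidine;
#'   `v`, `clm`, `vm`, `clom` for midazolam)
#' @export
individualize_pk <- function(drug = c("clonidine", "midazolam"), theta,
                             covariates, eta = numeric(0),
                             mature_clom = TRUE) {
  drug <- match.arg(drug)
  wt <- covariates$wt
  pma <- covariates$pma
  if (is.null(wt) || is.na(wt)) stop("covariate 'wt' is missing")
  if (is.null(pma) || is.na(pma)) stop("covariate 'pma' is missing")
  if (wt <= 0) stop("'wt' must be positive")
  e <- function(nm) if (nm %in% names(eta)) eta[[nm]] else 0
  asz_cl <- (wt / 70)^0.75
  asz_v <- wt / 70
  mf <- maturation(pma, theta$pma50, theta$hill)
  if (drug == "clonidine") {
    list(cl = theta$cl * asz_cl * mf * exp(e("cl")),
         v = theta$v * asz_v * exp(e("v")))
  } else {
    list(v = theta$v * asz_v * exp(e("v")),
         clm = theta$clm * asz_cl * mf * exp(e("clm")),
         vm = theta$vm * asz_v,
         clom = theta$clom * asz_cl * (if (mature_clom) mf else 1))
  }
}

## ---- analytic infusion kernels -------------------------------------------
## Vectorized over "pairs" (observation time x dose event). All doses are
## zero-order infusions; a bolus is a short infusion. Amounts in ug, times h.

# one-compartment amount at time t from an infusion (t0, rate, dur),
# elimination rate constant k; all arguments same length
.amt_1cpt <- function(t, t0, rate, dur, k) {
  u <- t - t0
  pos <- (u > 0)
  u <- u * pos                      # clamp to 0 before the event
  over <- u > dur
  ue <- u + (dur - u) * over        # time spent infusing, min(u, dur)
  v <- (u - dur) * over             # time since infusion end
  (rate / k) * (1 - exp(-k * ue)) * exp(-k * v) * pos
}

# parent + metabolite amounts for the catenary model: input -> A1 (k1 out)
# -> A2 (k2 out). Returns list(a1, a2). Handles k1 ~ k2 by a limit branch.
.amt_catenary <- function(t, t0, rate, dur, k1, k2) {
  n <- max(length(t), length(t0), length(rate), length(dur),
           length(k1), length(k2))
  t <- rep_len(t, n); t0 <- rep_len(t0, n); rate <- rep_len(rate, n)
  dur <- rep_len(dur, n); k1 <- rep_len(k1, n); k2 <- rep_len(k2, n)
  u <- t - t0
  pos <- (u > 0)
  u <- u * pos
  over <- u > dur
  ue <- u + (dur - u) * over
  v <- (u - dur) * over
  e1e <- exp(-k1 * ue); e2e <- exp(-k2 * ue)
  dk <- k2 - k1
  near <- abs(dk) < 1e-8
  de <- (e1e - e2e) / (dk + near)   # guarded; overwritten where near
  if (any(near)) de[near] <- (ue * e1e)[near]
  a1e <- (rate / k1) * (1 - e1e)
  a2e <- (rate / k2) * (1 - e2e) - rate * de
  e1v <- exp(-k1 * v); e2v <- exp(-k2 * v)
  dv <- (e1v - e2v) / (dk + near)
  if (any(near)) dv[near] <- (v * e1v)[near]
  a1 <- a1e * e1v
  a2 <- (a2e * e2v + k1 * a1e * dv)
  list(a1 = a1 * pos, a2 = a2 * pos)
}

.check_doses <- function(doses) {
  if (is.null(doses) || nrow(doses) == 0) return(invisible(NULL))
  stopifnot(all(c("start", "rate", "dur") %in% names(doses)))
  if (any(doses$rate < 0)) stop("dose rates must be nonnegative")
  if (any(doses$dur <= 0)) stop("dose durations must be positive")
  invisible(NULL)
}

#' Clonidine concentration profile
#'
#' Analytic solution of the one-compartment infusion model
#' `dA/dt = input(t) - (CL/V) A`, `C = A/V`, by superposition over dose
#' events. Units: doses ug, rates ug/h, volumes L, concentrations ng/mL
#' (1 ug into 1 L gives 1 ng/mL).
#'
#' @param params list with `cl` (L/h) and `v` (L), both positive
#' @param doses data.frame with columns `start` (h), `rate` (ug/h),
#'   `dur` (h); zero rows allowed
#' @param times numeric vector of ascending times (h)
#' @return data.frame with `time` and `conc` (ng/mL)
#' @export
conc_clonidine <- function(params, doses, times) {
  if (params$cl <= 0 || params$v <= 0) stop("PK parameters must be positive")
  .check_doses(doses)
  if (is.unsorted(times)) stop("'times' must be ascending")
  conc <- numeric(length(times))
  if (!is.null(doses) && nrow(doses) > 0) {
    k <- params$cl / params$v
    for (i in seq_len(nrow(doses)))
      conc <- conc + .amt_1cpt(times, doses$start[i], doses$rate[i],
                               doses$dur[i], k)
    conc <- conc / params$v
  }
  data.frame(time = times, conc = conc)
}

#' Midazolam parent and 1-OH metabolite concentration profile
#'
#' Analytic solution of the catenary model with complete conversion of parent
#' to metabolite: `dA1/dt = input - (CLm/V) A1`,
#' `dA2/dt = (CLm/V) A1 - (CLom/Vm) A2`; `C1 = A1/V`, `C2 = A2/Vm`.
#'
#' @param params list with `v`, `clm`, `vm`, `clom`, all positive
#' @inheritParams conc_clonidine
#' @return data.frame with `time`, `conc` (parent, ng/mL) and `conc_m`
#'   (metabolite, ng/mL)
#' @export
conc_midazolam <- function(params, doses, times) {
  if (any(unlist(params[c("v", "clm", "vm", "clom")]) <= 0))
    stop("PK parameters must be positive")
  .check_doses(doses)
  if (is.unsorted(times)) stop("'times' must be ascending")
  a1 <- a2 <- numeric(length(times))
  if (!is.null(doses) && nrow(doses) > 0) {
    k1 <- params$clm / params$v
    k2 <- params$clom / params$vm
    for (i in seq_len(nrow(doses))) {
      a <- .amt_catenary(times, doses$start[i], doses$rate[i], doses$dur[i],
                         k1, k2)
      a1 <- a1 + a$a1
      a2 <- a2 + a$a2
    }
  }
  data.frame(time = times, conc = a1 / params$v, conc_m = a2 / params$vm)
}

#' ODE cross-check of the analytic concentration profiles
#'
#' Integrates the same structural differential equations with a general-purpose
#' stiff solver (\pkg{deSolve}) as an independent check of the analytic
#' piecewise solutions used everywhere else. Intended for validation, not for
#' the estimation inner loop.
#'
#' @inheritParams conc_clonidine
#' @param drug `"clonidine"` or `"midazolam"`
#' @param params drug-specific parameter list
#' @param atol,rtol solver tolerances
#' @return data.frame shaped like the corresponding analytic function's output
#' @export
conc_ode <- function(drug = c("clonidine", "midazolam"), params, doses, times,
                     atol = 1e-10, rtol = 1e-10) {
  drug <- match.arg(drug)
  if (!requireNamespace("deSolve", quietly = TRUE))
    stop("the ODE cross-check needs the 'deSolve' package")
  .check_doses(doses)
  # integrate segment-wise between dose-event boundaries so the solver never
  # steps across a discontinuity in the input rate
  bounds <- sort(unique(c(0, times,
                          if (!is.null(doses) && nrow(doses) > 0)
                            c(doses$start, doses$start + doses$dur))))
  bounds <- bounds[bounds <= max(times) & bounds >= 0]
  input_in <- function(t) {
    if (is.null(doses) || nrow(doses) == 0) return(0)
    sum(doses$rate * (t >= doses$start & t < doses$start + doses$dur))
  }
  if (drug == "clonidine") {
    k <- params$cl / params$v
    y <- 0
  } else {
    k1 <- params$clm / params$v
    k2 <- params$clom / params$vm
    y <- c(0, 0)
  }
  sol_t <- numeric(0)
  sol_y <- NULL
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    rate <- input_in((t0 + t1) / 2)
    dyn <- if (drug == "clonidine")
      function(t, y, p) list(rate - k * y[1])
    else
      function(t, y, p) list(c(rate - k1 * y[1], k1 * y[1] - k2 * y[2]))
    seg <- deSolve::lsoda(y, c(t0, t1), dyn, parms = NULL,
                          atol = atol, rtol = rtol)
    y <- seg[nrow(seg), -1]
    sol_t <- c(sol_t, t1)
    sol_y <- rbind(sol_y, seg[nrow(seg), -1, drop = FALSE])
  }
  amt <- rbind(if (drug == "clonidine") 0 else c(0, 0), sol_y)
  tt <- c(bounds[1], sol_t)
  idx <- match(times, tt)
  if (drug == "clonidine")
    data.frame(time = times, conc = amt[idx, 1] / params$v)
  else
    data.frame(time = times, conc = amt[idx, 1] / params$v,
               conc_m = amt[idx, 2] / params$vm)
}
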