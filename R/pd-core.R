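#' Postanesthesia washout of the COMFORT-B score
#'
#' After major surgery under anesthesia the score starts at the scale
#' minimum (`base`, fixed to 6) and washes out toward an awake ceiling
#' `smax = base + paemax` following an Emax function of the time after
#' surgery: `PA(tps) = base + paemax * tps / (tps50 + tps)`.
#'
#' @param tps time after end of surgery, h (>= 0); vectorized
#' @param p parameter list with `base`, `paemax`, `tps50`
#'   (see [clonidine_pd_params()])
#' @return score value; `base` at `tps = 0`, `base + paemax/2` at
#'   `tps = tps50`, tending to `base + paemax`
#' @export
postanesthesia <- function(tps, p) {
  if (any(tps < 0)) stop("'tps' must be nonnegative")
  if (p$tps50 <= 0) stop("'tps50' must be positive")
  p$base + p$paemax * tps / (p$tps50 + tps)
}

#' Inhibitory sigmoid Emax drug effect on the score
#'
#' Score reduction attributable to the sedative:
#' `emax * conc^gamma / (ec50^gamma + conc^gamma)`, bounded in `[0, emax)`.
#' `emax` is fixed to 6 (the full scale depth) in the shipped models and
#' `gamma` defaults to 1.
#'
#' @param conc drug concentration, ng/mL (>= 0); vectorized
#' @param p parameter list with `emax`, `ec50`, `gamma`
#' @return score reduction
#' @export
imp_effect <- function(conc, p) {
  if (any(conc < 0)) stop("'conc' must be nonnegative")
  if (p$ec50 <= 0) stop("'ec50' must be positive")
  g <- if (is.null(p$gamma)) 1 else p$gamma
  cg <- conc^g
  p$emax * cg / (p$ec50^g + cg)
}

#' K-PD co-medication effect (propofol)
#'
#' Propofol concentrations are not measured, so its effect is driven by dose
#' alone through a virtual compartment `dA/dt = rate(t) - kde * A`. The
#' elimination flux `IRE = kde * A` (infusion-rate equivalent, ug/h) drives
#' an Emax effect: `emax_cm * IRE / (ec50_cm + IRE)`.
#'
#' @param doses data.frame of propofol infusions with columns `start`,
#'   `rate` (ug/h), `dur` (h); zero rows give a zero effect
#' @param kp K-PD constants, see [propofol_kpd_params()]
#' @param times evaluation times, h (ascending)
#' @return data.frame with `time` and `effect` (score points)
#' @export
kpd_effect <- function(doses, kp, times) {
  .check_doses(doses)
  a <- numeric(length(times))
  if (!is.null(doses) && nrow(doses) > 0) {
    for (i in seq_len(nrow(doses)))
      a <- a + .amt_1cpt(times, doses$start[i], doses$rate[i], doses$dur[i],
                         kp$kde)
  }
  ire <- kp$kde * a
  data.frame(time = times, effect = kp$emax_cm * ire / (kp$ec50_cm + ire))
}

#' Expected COMFORT-B score
#'
#' Composes the additive score model. Surgical subjects start from the
#' postanesthesia washout `PA(tps)`; nonsurgical subjects from the baseline
#' score `b0`. The sedative effect (driven by the subject's assigned drug
#' concentration) and any co-medication effect are subtracted, and the result
#' is floored at the scale minimum of 6 before residual error would apply:
#' `score = max(6, PA_or_b0 - IMPEFF - CMEFF)`.
#'
#' @param t study time, h (surgery is taken to end at `tsurg`, so
#'   `tps = t - tsurg`); vectorized
#' @param p parameter list (see [clonidine_pd_params()]); `b0` is the
#'   nonsurgical baseline
#' @param conc drug concentration at `t`, ng/mL
#' @param surgical logical flag (scalar)
#' @param tsurg end-of-surgery time, h; required when `surgical`
#' @param cmeff co-medication score reduction at `t` (default 0)
#' @return continuous expected score, >= 6
#' @export
predict_score <- function(t, p, conc, surgical = FALSE, tsurg = 0,
                          cmeff = 0) {
  if (surgical) {
    if (is.null(tsurg) || is.na(tsurg))
      stop("surgical subject needs an end-of-surgery time 'tsurg'")
    base <- postanesthesia(pmax(t - tsurg, 0), p)
  } else {
    base <- rep(p$b0, length.out = length(t))
  }
  pmax(base - imp_effect(conc, p) - cmeff, 6)
}
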