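## Forward dose-regimen evaluation in a virtual population.

#' Define a dose regimen
#'
#' A weight-based loading dose infused over `loading_dur` followed by a
#' continuous maintenance infusion for the rest of the simulation horizon.
#'
#' @param drug `"clonidine"` or `"midazolam"`
#' @param loading loading dose, ug/kg
#' @param rate maintenance infusion rate, ug/kg/h
#' @param loading_dur loading infusion duration, h (default 15 min)
#' @param horizon simulation duration, h (default 12)
#' @return list of class `regimen`
#' @export
regimen <- function(drug = c("clonidine", "midazolam"), loading, rate,
                    loading_dur = 0.25, horizon = 12) {
  drug <- match.arg(drug)
  stopifnot(loading >= 0, rate >= 0, loading_dur > 0, horizon > loading_dur)
  structure(list(drug = drug, loading = loading, rate = rate,
                 loading_dur = loading_dur, horizon = horizon),
            class = "regimen")
}

#' Simulate a dose regimen in a virtual population
#'
#' Generates a virtual population (by default children with postnatal age
#' above 28 days, weights from the weight-for-PMA growth curve),
#' individualizes the PK parameters (lognormal IIV unless `iiv = FALSE`),
#' simulates the concentration trajectory of the regimen on a fixed time
#' grid and the corresponding latent COMFORT-B score from the given
#' baseline (an Emax drug effect on top of `baseline`, floored at 6, no
#' residual error unless `residual = TRUE`), and summarizes both as
#' 5th/50th/95th percentile bands.
#'
#' @param reg a [regimen()]
#' @param n number of virtual patients
#' @param seed integer seed (deterministic output)
#' @param design population design; defaults to [trial_design()] with a
#'   28-day postnatal-age floor
#' @param pk,pd generating parameter sets; defaults chosen by drug
#' @param baseline score before treatment (default 15)
#' @param dt grid step, h
#' @param iiv draw interindividual variability (FALSE collapses all bands
#'   onto the typical trajectory)
#' @param residual add proportional residual noise to the reported scores
#' @return object of class `regimen_sim` with `times`, percentile matrices
#'   `conc` and `score` (rows p5/p50/p95), and the inputs
#' @export
simulate_regimen <- function(reg, n = 1000, seed = 1,
                             design = trial_design(pna_min = 28),
                             pk = NULL, pd = NULL, baseline = 15,
                             dt = 0.1, iiv = TRUE, residual = FALSE) {
  stopifnot(inherits(reg, "regimen"), n >= 1)
  if (is.null(pk))
    pk <- if (reg$drug == "clonidine") clonidine_pk_params()
          else midazolam_pk_params()
  if (is.null(pd))
    pd <- if (reg$drug == "clonidine") clonidine_pd_params()
          else midazolam_pd_params()
  pop <- generate_population(n, design, seed = seed)
  set.seed(seed + 911117L)
  times <- seq(0, reg$horizon, by = dt)
  conc <- matrix(NA_real_, n, length(times))
  score <- matrix(NA_real_, n, length(times))
  for (i in seq_len(n)) {
    s <- pop[i, ]
    half <- if (isTRUE(design$neonatal_halving) && s$pna < 28) 0.5 else 1
    eta <- if (!iiv) numeric(0) else if (reg$drug == "clonidine")
      c(cl = stats::rnorm(1, 0, cv_to_omega(pk$iiv_cl)),
        v = stats::rnorm(1, 0, cv_to_omega(pk$iiv_v)))
    else
      c(clm = stats::rnorm(1, 0, cv_to_omega(pk$iiv_clm)),
        v = stats::rnorm(1, 0, cv_to_omega(pk$iiv_v)))
    ip <- individualize_pk(reg$drug, pk, list(wt = s$wt, pma = s$pma), eta)
    doses <- data.frame(
      start = c(0, reg$loading_dur),
      rate = c(reg$loading * half * s$wt / reg$loading_dur,
               reg$rate * half * s$wt),
      dur = c(reg$loading_dur, reg$horizon - reg$loading_dur))
    ci <- if (reg$drug == "clonidine") conc_clonidine(ip, doses, times)$conc
          else conc_midazolam(ip, doses, times)$conc
    conc[i, ] <- ci
    pdi <- pd
    pdi$b0 <- baseline
    pdi$ec50 <- pd$ec50 *
      (if (iiv) exp(stats::rnorm(1, 0, cv_to_omega(pd$iiv_ec50))) else 1)
    sc <- predict_score(times, pdi, ci, surgical = FALSE)
    if (residual)
      sc <- pmin(pmax(sc * (1 + stats::rnorm(length(sc), 0,
                                             pd$err_prop)), 6), 31)
    score[i, ] <- sc
  }
  probs <- c(0.05, 0.5, 0.95)
  qmat <- function(m) apply(m, 2, stats::quantile, probs = probs)
  structure(list(times = times,
                 conc = qmat(conc), score = qmat(score),
                 regimen = reg, n = n, seed = seed, baseline = baseline,
                 iiv = iiv),
            class = "regimen_sim")
}

#' @export
print.regimen_sim <- function(x, ...) {
  r <- x$regimen
  cat(sprintf(paste0("Regimen simulation: %s %g ug/kg loading (%g h) + ",
                     "%g ug/kg/h, %d virtual patients, %g h horizon\n"),
              r$drug, r$loading, r$loading_dur, r$rate, x$n, r$horizon))
  cat(sprintf("Median concentration at end: %.3g ng/mL; median score: %.3g\n",
              x$conc[2, ncol(x$conc)], x$score[2, ncol(x$score)]))
  invisible(x)
}

#' @export
plot.regimen_sim <- function(x, target = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(m, ylab) {
    graphics::plot(x$times, m[2, ], type = "l", lwd = 2, ylab = ylab,
                   xlab = "time (h)", ylim = range(m, finite = TRUE), ...)
    graphics::polygon(c(x$times, rev(x$times)), c(m[1, ], rev(m[3, ])),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(x$times, m[2, ], lwd = 2)
  }
  panel(x$conc, "concentration (ng/mL)")
  if (!is.null(target)) graphics::abline(h = target, col = "red")
  panel(x$score, "COMFORT-B score")
  invisible(x)
}

#' Time for the median concentration to reach a target
#'
#' First grid time at which the median simulated concentration is at or
#' above the target (for example the model EC50); `NA` when the target is
#' never reached within the horizon.
#'
#' @param sim a `regimen_sim`
#' @param target target concentration, ng/mL
#' @return time in hours, or `NA`
#' @export
time_to_target <- function(sim, target) {
  stopifnot(inherits(sim, "regimen_sim"))
  med <- sim$conc[2, ]
  i <- which(med >= target)
  if (!length(i)) return(NA_real_)
  sim$times[i[1]]
}
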