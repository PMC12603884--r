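#' Virtual trial design
#'
#' Collects the design constants of the emulated blinded randomized sedation
#' trial: a PICU population of term neonates and infants (postmenstrual age
#' 36-372 weeks, heavily weighted toward term neonates), 1:1 randomization
#' between clonidine and midazolam, loading dose plus titrated continuous
#' infusion (doses halved for neonates younger than 28 days), 2-4 sparse PK
#' samples per subject (one after the loading dose, one just before the end
#' of treatment), COMFORT-B scores every 3 h, surgery and bridging propofol
#' in a subset of each arm.
#'
#' @param n number of subjects
#' @param ... overrides for any design field; see the function body for the
#'   complete list and defaults
#' @return list of class `trial_design`
#' @export
trial_design <- function(n = 28, ...) {
  d <- list(
    n = n,
    p_clonidine = 0.5,        # randomization ratio
    pma_range = c(36, 372),   # weeks (gestational-age floor 36 on entry)
    pma_shape = c(0.25, 3),   # beta shape of PMA within the range
    ga_range = c(36, 40),     # gestational age, weeks
    wt_max = 20,              # asymptote of the weight-for-PMA curve, kg
    wt_pma50 = 150,           # PMA at half asymptotic weight, weeks
    wt_hill = 1.2,            # shape of the growth curve
    wt_cv = 0.13,             # lognormal individual weight variability
    p_surgery = c(clonidine = 7 / 15, midazolam = 11 / 13),
    p_propofol = c(clonidine = 10 / 15, midazolam = 6 / 13),
    n_pk_samples = 2:4,       # sparse samples per subject
    pk_dense = FALSE,         # add a denser nominal sampling schedule
    score_interval = 3,       # h between COMFORT-B assessments
    followup_range = c(24, 96),  # h of treatment per subject
    loq = c(clonidine = 0.05, midazolam = 1, mid_metabolite = 0.1),
    titration = TRUE,
    titration_band = c(11, 22),  # adequate-sedation score band
    extra_assessments = TRUE,    # scores 30 min after start / rate changes
    protocols = list(
      clonidine = list(ld = 2, ld_dur = 0.25, rate = 1,
                       step = 0.5, rate_min = 0.25, rate_max = 3),
      midazolam = list(ld = 200, ld_dur = 0.25, rate = 100,
                       step = 50, rate_min = 25, rate_max = 300)),
    propofol_rate = 2000,     # bridging propofol, ug/kg/h for the first 30 min
    propofol_dur = 0.5,
    neonatal_halving = TRUE,
    pna_min = NULL,           # optional postnatal-age floor, days
    cov_effect = NULL         # optional true exponential covariate effect on
                              # a clearance, e.g. list(param = "cl",
                              # name = "CREA", ref = 45, beta = 0.02,
                              # sd_log = 0.35)
  )
  structure(utils::modifyList(d, list(...)), class = "trial_design")
}

#' Median weight-for-age growth curve
#'
#' Monotone sigmoidal weight-for-PMA function used to generate virtual
#' covariates: `wt_max * pma^h / (pma50^h + pma^h)`. Coefficients are design
#' fields; the defaults trace the weights of a critically ill PICU
#' population (about 3 kg at term, about 15 kg at six years).
#'
#' @param pma postmenstrual age, weeks; vectorized
#' @param design a [trial_design()]
#' @return median weight, kg
#' @export
wt_for_pma <- function(pma, design = trial_design()) {
  r <- (pma / design$wt_pma50)^design$wt_hill
  design$wt_max * r / (1 + r)
}

#' Generate a virtual patient population
#'
#' Draws PMA from a scaled beta distribution over the design range,
#' gestational age uniformly (capped at PMA), derives postnatal age, and
#' generates weight from the monotone weight-for-PMA curve with lognormal
#' individual variability. Arm, surgery and bridging-propofol status are
#' randomized per the design probabilities. Reproducible by seed.
#'
#' @param n number of subjects
#' @param design a [trial_design()]
#' @param seed integer seed
#' @return data.frame with one row per subject: `id`, `pma` (weeks), `ga`
#'   (weeks), `pna` (days), `wt` (kg), `sex`, `arm`, `surg`, `propofol`
#' @export
generate_population <- function(n, design = trial_design(), seed = 1) {
  if (n < 1) stop("'n' must be at least 1")
  rng <- design$pma_range
  if (rng[2] <= rng[1]) stop("empty PMA range")
  set.seed(seed)
  draw <- function(m) {
    pma <- rng[1] + (rng[2] - rng[1]) *
      stats::rbeta(m, design$pma_shape[1], design$pma_shape[2])
    ga <- pmin(stats::runif(m, design$ga_range[1], design$ga_range[2]), pma)
    pna <- (pma - ga) * 7
    data.frame(pma = pma, ga = ga, pna = pna)
  }
  acc <- draw(n)
  if (!is.null(design$pna_min)) {
    for (it in 1:200) {
      ok <- acc$pna > design$pna_min
      if (all(ok)) break
      acc[!ok, ] <- draw(sum(!ok))
    }
    if (!all(acc$pna > design$pna_min))
      stop("could not satisfy the postnatal-age floor; widen the PMA range")
  }
  wt <- wt_for_pma(acc$pma, design) *
    exp(stats::rnorm(n, 0, sqrt(log(1 + design$wt_cv^2))))
  arm <- ifelse(stats::runif(n) < design$p_clonidine,
                "clonidine", "midazolam")
  surg <- as.integer(stats::runif(n) < design$p_surgery[arm])
  prop <- as.integer(stats::runif(n) < design$p_propofol[arm])
  data.frame(id = seq_len(n), pma = acc$pma, ga = acc$ga, pna = acc$pna,
             wt = wt, sex = stats::rbinom(n, 1, 0.5), arm = arm,
             surg = surg, propofol = prop)
}

#' Starting dose events for one subject
#'
#' Builds the loading-dose infusion (given over `ld_dur`, default 15 min)
#' and the continuous maintenance infusion at the protocol starting rate,
#' with both halved for neonates with postnatal age below 28 days.
#' Titration (rate adjustment every 3 h against the score band) is applied
#' during trial simulation, not here; with titration off the maintenance
#' rate is constant for the whole follow-up.
#'
#' @param subject one-row data.frame with at least `wt` (kg) and `pna` (days)
#' @param drug `"clonidine"` or `"midazolam"`
#' @param design a [trial_design()]
#' @param followup treatment duration, h
#' @return data.frame of dose events: `start`, `rate` (ug/h), `dur` (h)
#' @export
generate_dosing <- function(subject, drug, design = trial_design(),
                            followup = 48) {
  pr <- design$protocols[[drug]]
  half <- if (isTRUE(design$neonatal_halving) && subject$pna < 28) 0.5 else 1
  wt <- subject$wt
  ld_rate <- pr$ld * half * wt / pr$ld_dur
  data.frame(
    start = c(0, pr$ld_dur),
    rate = c(ld_rate, pr$rate * half * wt),
    dur = c(pr$ld_dur, followup - pr$ld_dur))
}

#' Generate a genotype matrix
#'
#' Subjects x SNPs minor-allele counts drawn binomially at the configured
#' minor allele frequencies (Hardy-Weinberg proportions).
#'
#' @param n subjects
#' @param maf numeric vector of minor allele frequencies, one per SNP
#' @param seed integer seed
#' @param snp_names optional column names
#' @return integer matrix with values in 0/1/2
#' @export
generate_genotypes <- function(n, maf, seed = 1, snp_names = NULL) {
  set.seed(seed)
  g <- vapply(maf, function(p) stats::rbinom(n, 2, p), integer(n))
  colnames(g) <- if (is.null(snp_names))
    paste0("snp", seq_along(maf)) else snp_names
  g
}

# residual draw for a concentration observation
.conc_obs <- function(f, prop, add) {
  f * (1 + stats::rnorm(length(f), 0, 1) * prop) +
    stats::rnorm(length(f), 0, 1) * add
}

#' Simulate a complete virtual trial dataset
#'
#' Generates the population, assigns starting doses, steps through the
#' follow-up adjusting the infusion rate every assessment against the
#' titration band (using the noisy observed score, as a bedside algorithm
#' would), samples 2-4 PK observations per subject and COMFORT-B scores at
#' the assessment grid, applies the per-class residual-error models, flags
#' concentrations below the limit of quantification as BLQ (value withheld),
#' and rounds and clamps reported scores into the 6-31 scale. The latent
#' score model is continuous; `CONC` on score rows carries the individual
#' model concentration driving the effect.
#'
#' @param design a [trial_design()]
#' @param seed integer seed (full reproducibility)
#' @param pk_clon,pk_mid,pd_clon,pd_mid generating population parameter sets
#'   (see [clonidine_pk_params()] and friends)
#' @param kpd propofol K-PD constants
#' @return a `pkpd_dataset` data.frame; attribute `"truth"` holds the
#'   generating parameters, the per-subject random effects and individual PK
#'   parameters
#' @export
simulate_trial <- function(design = trial_design(), seed = 1,
                           pk_clon = clonidine_pk_params(),
                           pk_mid = midazolam_pk_params(),
                           pd_clon = clonidine_pd_params(),
                           pd_mid = midazolam_pd_params(),
                           kpd = propofol_kpd_params()) {
  pop <- generate_population(design$n, design, seed = seed)
  set.seed(seed + 499979L)
  n <- nrow(pop)
  followup <- stats::runif(n, design$followup_range[1],
                           design$followup_range[2])
  rows <- vector("list", n)
  etas <- vector("list", n)
  ipk <- vector("list", n)
  for (i in seq_len(n)) {
    s <- pop[i, ]
    drug <- s$arm
    pk <- if (drug == "clonidine") pk_clon else pk_mid
    pd <- if (drug == "clonidine") pd_clon else pd_mid
    Tf <- followup[i]
    cov <- list(wt = s$wt, pma = s$pma)
    if (drug == "clonidine") {
      eta <- c(cl = stats::rnorm(1, 0, cv_to_omega(pk$iiv_cl)),
               v = stats::rnorm(1, 0, cv_to_omega(pk$iiv_v)))
    } else {
      eta <- c(clm = stats::rnorm(1, 0, cv_to_omega(pk$iiv_clm)),
               v = stats::rnorm(1, 0, cv_to_omega(pk$iiv_v)))
    }
    eta_ec50 <- stats::rnorm(1, 0, cv_to_omega(pd$iiv_ec50))
    ip <- individualize_pk(drug, pk, cov, eta)
    ce <- design$cov_effect
    cov_val <- NA_real_
    if (!is.null(ce)) {
      cov_val <- ce$ref * exp(stats::rnorm(1, 0, ce$sd_log))
      if (!is.null(ip[[ce$param]]))
        ip[[ce$param]] <- ip[[ce$param]] * exp(ce$beta * (cov_val - ce$ref))
    }
    conc_at <- function(times, doses)
      if (drug == "clonidine") conc_clonidine(ip, doses, times)$conc
      else conc_midazolam(ip, doses, times)$conc
    # propofol bridging events
    prop_ev <- if (s$propofol == 1)
      data.frame(start = 0, rate = design$propofol_rate * s$wt,
                 dur = design$propofol_dur)
    else data.frame(start = numeric(0), rate = numeric(0), dur = numeric(0))
    cmeff_at <- function(times)
      if (nrow(prop_ev)) kpd_effect(prop_ev, kpd, times)$effect else
        numeric(length(times))
    pdi <- pd
    pdi$ec50 <- pd$ec50 * exp(eta_ec50)
    score_latent <- function(t, doses)
      predict_score(t, pdi, conc_at(t, doses), surgical = s$surg == 1,
                    tsurg = 0, cmeff = cmeff_at(t))
    obs_score <- function(f) {
      y <- f * (1 + stats::rnorm(length(f), 0, 1) * pd$err_prop)
      pmin(pmax(round(y), 6), 31)
    }
    # dose events with stepwise titration against the observed score
    pr <- design$protocols[[drug]]
    half <- if (isTRUE(design$neonatal_halving) && s$pna < 28) 0.5 else 1
    grid <- seq(0, Tf, by = design$score_interval)
    ld <- generate_dosing(s, drug, design, followup = Tf)
    if (!isTRUE(design$titration)) {
      doses <- ld
      sc_f <- score_latent(grid, doses)
      sc_y <- obs_score(sc_f)
    } else {
      doses <- ld[1, , drop = FALSE]           # loading infusion
      rate <- ld$rate[2]                        # maintenance, ug/h
      seg_start <- pr$ld_dur
      sc_y <- numeric(length(grid))
      for (gi in seq_along(grid)) {
        tg <- grid[gi]
        dcur <- rbind(doses,
                      data.frame(start = seg_start, rate = rate,
                                 dur = max(tg - seg_start, 1e-6)))
        sc_y[gi] <- obs_score(score_latent(tg, dcur))
        if (tg > 0 && tg < Tf) {
          newr <- rate
          if (sc_y[gi] > design$titration_band[2])
            newr <- min(rate + pr$step * half * s$wt,
                        pr$rate_max * half * s$wt)
          if (sc_y[gi] < design$titration_band[1])
            newr <- max(rate - pr$step * half * s$wt,
                        pr$rate_min * half * s$wt)
          if (newr != rate && tg > seg_start) {
            doses <- rbind(doses,
                           data.frame(start = seg_start, rate = rate,
                                      dur = tg - seg_start))
            rate <- newr
            seg_start <- tg
          }
        }
      }
      doses <- rbind(doses,
                     data.frame(start = seg_start, rate = rate,
                                dur = Tf - seg_start))
    }
    # additional assessments 30 min after treatment start and 30 min after
    # every infusion-rate adjustment (not used by the titration rule)
    extra_t <- numeric(0)
    if (isTRUE(design$extra_assessments)) {
      chg <- doses$start[-1]              # maintenance segment starts
      extra_t <- sort(unique(c(0.5, chg[chg > pr$ld_dur] + 0.5)))
      extra_t <- extra_t[extra_t < Tf & !(extra_t %in% grid)]
      if (length(extra_t)) {
        ex_f <- score_latent(extra_t, doses)
        ex_y <- obs_score(ex_f)
        grid <- c(grid, extra_t)
        sc_y <- c(sc_y, ex_y)
        ord <- order(grid)
        grid <- grid[ord]
        sc_y <- sc_y[ord]
      }
    }
    # sparse PK sampling: one after the loading dose, one just before the
    # end of treatment, extras uniform
    ns <- if (length(design$n_pk_samples) == 1) design$n_pk_samples
          else sample(design$n_pk_samples, 1)
    pk_t <- c(pr$ld_dur + stats::runif(1, 0.05, 0.75),
              Tf - stats::runif(1, 0.05, 0.5))
    if (ns > 2) pk_t <- c(pk_t, stats::runif(ns - 2, 1, Tf - 1))
    if (isTRUE(design$pk_dense))
      pk_t <- c(pk_t, c(1, 2, 4, 8, 12, 24)[c(1, 2, 4, 8, 12, 24) < Tf])
    pk_t <- sort(pk_t)
    subrow <- function(nr) data.frame(
      ID = rep(s$id, nr), TIME = NA_real_, EVID = 0, AMT = NA_real_,
      RATE = NA_real_, DV = NA_real_, DVID = NA_character_, BLQ = 0,
      MDV = 0, CONC = NA_real_, WT = s$wt, PMA = s$pma, PNA = s$pna,
      SEX = s$sex, ARM = drug, SURG = s$surg,
      TSURG = if (s$surg == 1) 0 else NA_real_)
    if (!is.null(design$cov_effect)) {
      subrow0 <- subrow
      subrow <- function(nr) {
        d <- subrow0(nr)
        d[[design$cov_effect$name]] <- cov_val
        d
      }
    }
    out <- list()
    # dose rows (study drug + propofol)
    dr <- subrow(nrow(doses))
    dr$TIME <- doses$start; dr$EVID <- 1; dr$AMT <- doses$rate * doses$dur
    dr$RATE <- doses$rate; dr$DVID <- drug; dr$MDV <- 1
    out$dose <- dr
    if (nrow(prop_ev)) {
      pp <- subrow(nrow(prop_ev))
      pp$TIME <- prop_ev$start; pp$EVID <- 1
      pp$AMT <- prop_ev$rate * prop_ev$dur; pp$RATE <- prop_ev$rate
      pp$DVID <- "propofol"; pp$MDV <- 1
      out$prop <- pp
    }
    # concentration observations
    if (drug == "clonidine") {
      f <- conc_clonidine(ip, doses, pk_t)$conc
      y <- .conc_obs(f, pk$err_prop, 0)
      cr <- subrow(length(pk_t))
      cr$TIME <- pk_t; cr$DVID <- "clonidine"
      blq <- y < design$loq["clonidine"]
      cr$DV <- ifelse(blq, NA_real_, y)
      cr$BLQ <- as.integer(blq); cr$MDV <- as.integer(blq)
      out$conc <- cr
    } else {
      prof <- conc_midazolam(ip, doses, pk_t)
      yp <- .conc_obs(prof$conc, pk$err_prop, pk$err_add)
      ym <- .conc_obs(prof$conc_m, pk$err_prop_m, pk$err_add_m)
      cr <- subrow(2 * length(pk_t))
      cr$TIME <- c(pk_t, pk_t)
      cr$DVID <- rep(c("midazolam", "mid_metabolite"), each = length(pk_t))
      yy <- c(yp, ym)
      lq <- rep(design$loq[c("midazolam", "mid_metabolite")],
                each = length(pk_t))
      blq <- yy < lq
      cr$DV <- ifelse(blq, NA_real_, yy)
      cr$BLQ <- as.integer(blq); cr$MDV <- as.integer(blq)
      cr <- cr[order(cr$TIME), ]
      out$conc <- cr
    }
    # score observations (the titrated path already produced sc_y)
    sr <- subrow(length(grid))
    sr$TIME <- grid; sr$DVID <- "comfortb"; sr$DV <- sc_y
    sr$CONC <- conc_at(grid, doses)
    out$score <- sr
    all <- do.call(rbind, out)
    all <- all[order(all$TIME, -all$EVID), ]
    rows[[i]] <- all
    etas[[i]] <- c(eta, ec50 = eta_ec50)
    ipk[[i]] <- ip
  }
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  class(ds) <- c("pkpd_dataset", "data.frame")
  attr(ds, "truth") <- list(
    design = design, seed = seed, population = pop, followup = followup,
    pk_clon = pk_clon, pk_mid = pk_mid, pd_clon = pd_clon, pd_mid = pd_mid,
    etas = etas, ipk = ipk)
  ds
}
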