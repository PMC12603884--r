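## Concrete model specifications consumed by pkpd_fit().

# subject-level covariate table in ID order of first appearance
.sub_table <- function(data) {
  ids <- unique(data$ID)
  i <- match(ids, data$ID)
  data.frame(id = ids, wt = data$WT[i], pma = data$PMA[i],
             pna = data$PNA[i], sex = data$SEX[i], arm = data$ARM[i],
             surg = data$SURG[i], tsurg = data$TSURG[i])
}

# dose events of one drug as parallel vectors with subject index
.dose_events <- function(data, drug, ids) {
  d <- data[data$EVID == 1 & data$DVID == drug & data$ID %in% ids, ,
            drop = FALSE]
  if (nrow(d) && any(d$RATE <= 0))
    stop("dose rows need a positive RATE (a bolus is a short infusion)")
  list(sub = match(d$ID, ids), start = d$TIME, rate = d$RATE,
       dur = if (nrow(d)) d$AMT / d$RATE else numeric(0))
}

# observation-row x dose-event pair index structure for superposition
.make_pairs <- function(obs_sub, obs_time, ev) {
  nsub <- max(c(obs_sub, ev$sub, 1))
  ord <- order(ev$sub)
  es <- ev$sub[ord]
  cnt <- tabulate(es, nbins = nsub)
  off <- cumsum(c(0L, cnt))
  nper <- cnt[obs_sub]
  pobs <- rep(seq_along(obs_sub), nper)
  pev <- ord[sequence(nper) + off[obs_sub][pobs]]
  list(pobs = pobs, psub = obs_sub[pobs],
       pt = obs_time[pobs], pt0 = ev$start[pev],
       prate = ev$rate[pev], pdur = ev$dur[pev],
       # pairs are contiguous blocks per observation: block sums come from
       # differences of the cumulative sum at the block ends
       ends = cumsum(nper), has = nper > 0)
}

.accumulate <- function(contrib, pairs, nobs) {
  a <- numeric(nobs)
  if (length(contrib)) {
    cs <- c(0, cumsum(contrib))[pairs$ends + 1L]  # 0 for leading empty blocks
    a[pairs$has] <- diff(c(0, cs))[pairs$has]
  }
  a
}

# exponential covariate multipliers: specs is a list of
# list(param=, col=, ref=); returns function(pars, param) -> per-subject mult
.cov_mult <- function(specs, subtab, data) {
  if (!length(specs)) return(function(pars, param, nsub) 1)
  vals <- lapply(specs, function(s) {
    v <- data[[s$col]][match(subtab$id, data$ID)]
    if (any(is.na(v))) stop("missing covariate column '", s$col, "'")
    v - s$ref
  })
  function(pars, param, nsub) {
    m <- rep(1, nsub)
    for (j in seq_along(specs)) {
      if (specs[[j]]$param == param) {
        beta <- pars[[paste0("beta_", specs[[j]]$param, "_",
                             tolower(specs[[j]]$col))]]
        m <- m * exp(beta * vals[[j]])
      }
    }
    m
  }
}

.cov_pars <- function(specs) {
  if (!length(specs)) return(NULL)
  do.call(rbind, lapply(specs, function(s)
    .par_row(paste0("beta_", s$param, "_", tolower(s$col)), 0,
             trans = "id")))
}

#' Clonidine population PK model specification
#'
#' One-compartment infusion model with allometric weight scaling, PMA
#' maturation on clearance, lognormal IIV on clearance and volume, and a
#' proportional residual error. Typical values are standardized to 70 kg.
#' The maturation constants are fixed by default.
#'
#' @param covariates optional list of exponential covariate specifications,
#'   each `list(param = "cl", col = "CREA", ref = <reference value>)`,
#'   entering as `theta * exp(beta * (cov - ref))`
#' @param fix character vector of parameter names to hold at their initial
#'   values (FIX semantics)
#' @param init named list of initial values overriding the defaults
#' @return a `pkpd_model`
#' @export
pk_model_clonidine <- function(covariates = list(), fix = character(0),
                               init = list()) {
  pars <- rbind(
    .par_row("cl", 20), .par_row("v", 150),
    .par_row("omega_cl", 0.4), .par_row("omega_v", 0.4),
    .par_row("sigma_prop", 0.3),
    .par_row("pma50", 61.6, fixed = TRUE),
    .par_row("hill", 2.42, fixed = TRUE),
    .cov_pars(covariates))
  for (nm in names(init)) pars$init[pars$name == nm] <- init[[nm]]
  pars$fixed[pars$name %in% fix] <- TRUE
  build <- function(model, data) {
    st <- .sub_table(data)
    obs <- data[data$EVID == 0 & data$DVID == "clonidine", , drop = FALSE]
    if (!nrow(obs)) stop("no clonidine concentration observations")
    sub <- match(obs$ID, st$id)
    if (any(is.na(st$wt) | is.na(st$pma)))
      stop("missing WT or PMA covariate for subject(s): ",
           paste(st$id[is.na(st$wt) | is.na(st$pma)], collapse = ", "))
    ev <- .dose_events(data, "clonidine", st$id)
    pr <- .make_pairs(sub, obs$TIME, ev)
    cm <- .cov_mult(covariates, st, data)
    list(y = obs$DV, sub = sub, nsub = nrow(st), ids = st$id,
         time = obs$TIME,
         wt75 = (st$wt / 70)^0.75, wtn = st$wt / 70, pma = st$pma,
         pairs = pr, nobs = nrow(obs), covmult = cm)
  }
  predict_f <- function(pars, eta, prep) {
    mf <- (prep$pma / pars$pma50)^pars$hill
    mf <- mf / (1 + mf)
    cl <- pars$cl * prep$wt75 * mf * exp(eta[, 1]) *
      prep$covmult(pars, "cl", prep$nsub)
    v <- pars$v * prep$wtn * exp(eta[, 2]) *
      prep$covmult(pars, "v", prep$nsub)
    k <- cl / v
    pr <- prep$pairs
    contrib <- .amt_1cpt(pr$pt, pr$pt0, pr$prate, pr$pdur, k[pr$psub])
    .accumulate(contrib, pr, prep$nobs) / v[prep$sub]
  }
  sd_f <- function(pars, f, prep) pars$sigma_prop * abs(f)
  new_pkpd_model("clonidine PK", pars, c("cl", "v"), build, predict_f, sd_f)
}

#' Midazolam parent + 1-OH metabolite population PK model specification
#'
#' One-compartment parent with complete conversion into a metabolite
#' compartment, allometric scaling, PMA maturation on both clearances
#' (restrict to the formation clearance with `mature_clom = FALSE`),
#' lognormal IIV on the formation clearance and parent volume, and combined
#' additive + proportional residual error per analyte.
#'
#' @inheritParams pk_model_clonidine
#' @param mature_clom apply maturation to the metabolite elimination
#'   clearance as well (default TRUE)
#' @return a `pkpd_model`
#' @export
pk_model_midazolam <- function(covariates = list(), fix = character(0),
                               init = list(), mature_clom = TRUE) {
  pars <- rbind(
    .par_row("v", 60), .par_row("clm", 20),
    .par_row("vm", 60), .par_row("clom", 150),
    .par_row("omega_clm", 0.4), .par_row("omega_v", 0.4),
    .par_row("sigma_prop", 0.3), .par_row("sigma_add", 0.5),
    .par_row("sigma_prop_m", 0.3), .par_row("sigma_add_m", 0.02),
    .par_row("pma50", 73.6, fixed = TRUE),
    .par_row("hill", 3, fixed = TRUE),
    .cov_pars(covariates))
  for (nm in names(init)) pars$init[pars$name == nm] <- init[[nm]]
  pars$fixed[pars$name %in% fix] <- TRUE
  build <- function(model, data) {
    st <- .sub_table(data)
    obs <- data[data$EVID == 0 &
                  data$DVID %in% c("midazolam", "mid_metabolite"), ,
                drop = FALSE]
    if (!nrow(obs)) stop("no midazolam concentration observations")
    sub <- match(obs$ID, st$id)
    is_parent <- obs$DVID == "midazolam"
    ev <- .dose_events(data, "midazolam", st$id)
    pr <- .make_pairs(sub, obs$TIME, ev)
    cm <- .cov_mult(covariates, st, data)
    list(y = obs$DV, sub = sub, nsub = nrow(st), ids = st$id,
         time = obs$TIME,
         wt75 = (st$wt / 70)^0.75, wtn = st$wt / 70, pma = st$pma,
         pairs = pr, nobs = nrow(obs), is_parent = is_parent,
         par_pair = is_parent[pr$pobs], covmult = cm)
  }
  predict_f <- function(pars, eta, prep) {
    mf <- (prep$pma / pars$pma50)^pars$hill
    mf <- mf / (1 + mf)
    clm <- pars$clm * prep$wt75 * mf * exp(eta[, 1]) *
      prep$covmult(pars, "clm", prep$nsub)
    v <- pars$v * prep$wtn * exp(eta[, 2])
    clom <- pars$clom * prep$wt75 * (if (mature_clom) mf else 1) *
      prep$covmult(pars, "clom", prep$nsub)
    vm <- pars$vm * prep$wtn
    k1 <- clm / v
    k2 <- clom / vm
    pr <- prep$pairs
    a <- .amt_catenary(pr$pt, pr$pt0, pr$prate, pr$pdur,
                       k1[pr$psub], k2[pr$psub])
    contrib <- ifelse(prep$par_pair, a$a1, a$a2)
    amt <- .accumulate(contrib, pr, prep$nobs)
    denom <- ifelse(prep$is_parent, v[prep$sub], vm[prep$sub])
    amt / denom
  }
  sd_f <- function(pars, f, prep) {
    sp <- ifelse(prep$is_parent, pars$sigma_prop, pars$sigma_prop_m)
    sa <- ifelse(prep$is_parent, pars$sigma_add, pars$sigma_add_m)
    sqrt((sp * f)^2 + sa^2)
  }
  new_pkpd_model("midazolam PK", pars, c("clm", "v"), build, predict_f, sd_f)
}

#' COMFORT-B score model specification (inhibitory sigmoid Emax)
#'
#' Concentration-effect model for the COMFORT-B score driven by the
#' individual predicted concentration of the assigned drug (the `CONC`
#' column of the dataset): surgical subjects start from the postanesthesia
#' washout, nonsurgical subjects from a baseline score; the drug effect
#' (Emax fixed to 6) and the K-PD propofol effect are subtracted and the
#' result floored at the scale minimum of 6. IIV is on EC50 only; the
#' residual error is proportional.
#'
#' For the clonidine arm the baseline `b0` is an estimated parameter and the
#' postanesthesia amplitude `paemax` is fixed; for the midazolam arm the
#' baseline of each nonsurgical subject is their observed score at the first
#' assessment and `paemax` is estimated. The joint specification combines
#' both arms additively (each subject only ever has one drug) with a shared
#' `tps50` and per-arm EC50, IIV and residual error.
#'
#' @param arm `"clonidine"`, `"midazolam"` or `"joint"`
#' @param fix character vector of parameter names to fix
#' @param init named list of initial-value overrides
#' @param kpd fixed K-PD constants for the propofol effect
#' @param gamma sigmoid shape (fixed constant, default 1)
#' @return a `pkpd_model`
#' @export
pd_model <- function(arm = c("clonidine", "midazolam", "joint"),
                     fix = character(0), init = list(),
                     kpd = propofol_kpd_params(), gamma = 1) {
  arm <- match.arg(arm)
  pars <- switch(arm,
    clonidine = rbind(
      .par_row("ec50", 5), .par_row("b0", 14),
      .par_row("paemax", 11.8, fixed = TRUE),
      .par_row("tps50", 0.3),
      .par_row("omega_ec50", 0.5), .par_row("sigma_score", 0.25),
      .par_row("emax", 6, fixed = TRUE), .par_row("base", 6, fixed = TRUE)),
    midazolam = rbind(
      .par_row("ec50", 100), .par_row("paemax", 8),
      .par_row("tps50", 0.3),
      .par_row("omega_ec50", 0.5), .par_row("sigma_score", 0.25),
      .par_row("emax", 6, fixed = TRUE), .par_row("base", 6, fixed = TRUE)),
    joint = rbind(
      .par_row("ec50_clon", 5), .par_row("ec50_mid", 100),
      .par_row("b0", 14),
      .par_row("paemax_clon", 11.8, fixed = TRUE),
      .par_row("paemax_mid", 8),
      .par_row("tps50", 0.3),
      .par_row("omega_ec50_clon", 0.5), .par_row("omega_ec50_mid", 0.5),
      .par_row("sigma_clon", 0.25), .par_row("sigma_mid", 0.25),
      .par_row("emax", 6, fixed = TRUE), .par_row("base", 6, fixed = TRUE)))
  for (nm in names(init)) pars$init[pars$name == nm] <- init[[nm]]
  pars$fixed[pars$name %in% fix] <- TRUE
  build <- function(model, data) {
    st <- .sub_table(data)
    if (arm != "joint") {
      keep_ids <- st$id[st$arm == arm]
      if (!length(keep_ids)) stop("no subjects in arm '", arm, "'")
      st <- st[st$arm == arm, , drop = FALSE]
    }
    obs <- data[data$EVID == 0 & data$DVID == "comfortb" &
                  data$ID %in% st$id, , drop = FALSE]
    if (!nrow(obs)) stop("no COMFORT-B observations")
    sub <- match(obs$ID, st$id)
    if (any(is.na(obs$CONC)))
      stop("score rows need the driver concentration column CONC ",
           "(individual predicted concentration of the assigned drug)")
    surg_sub <- st$surg %in% 1
    if (any(surg_sub & (is.na(st$tsurg))))
      stop("surgical subject without an end-of-surgery time TSURG: ",
           paste(st$id[surg_sub & is.na(st$tsurg)], collapse = ", "))
    surg_obs <- surg_sub[sub]
    tps <- pmax(obs$TIME - ifelse(is.na(st$tsurg[sub]), 0, st$tsurg[sub]), 0)
    # individual observed baseline (first assessment) per subject
    b0i <- vapply(seq_len(nrow(st)), function(i) {
      oi <- obs$DV[sub == i]
      ti <- obs$TIME[sub == i]
      oi[which.min(ti)]
    }, numeric(1))
    # fixed K-PD propofol effect, precomputed once
    ev <- .dose_events(data, "propofol", st$id)
    cmeff <- numeric(nrow(obs))
    if (length(ev$sub)) {
      pr <- .make_pairs(sub, obs$TIME, ev)
      a <- .accumulate(.amt_1cpt(pr$pt, pr$pt0, pr$prate, pr$pdur, kpd$kde),
                       pr, nrow(obs))
      ire <- kpd$kde * a
      cmeff <- kpd$emax_cm * ire / (kpd$ec50_cm + ire)
    }
    is_mid <- st$arm == "midazolam"
    list(y = obs$DV, sub = sub, nsub = nrow(st), ids = st$id,
         time = obs$TIME,
         conc = obs$CONC, tps = tps, surg_obs = surg_obs,
         is_mid_sub = is_mid, is_mid_obs = is_mid[sub],
         b0i = b0i, cmeff = cmeff, nobs = nrow(obs))
  }
  predict_f <- function(pars, eta, prep) {
    if (arm == "joint") {
      ec50_t <- ifelse(prep$is_mid_sub, pars$ec50_mid, pars$ec50_clon)
      paemax <- ifelse(prep$is_mid_obs, pars$paemax_mid, pars$paemax_clon)
    } else {
      ec50_t <- rep(pars$ec50, prep$nsub)
      paemax <- pars$paemax
    }
    ec50_i <- ec50_t * exp(eta[, 1])
    cg <- prep$conc^gamma
    ipf <- pars$emax * cg / (ec50_i[prep$sub]^gamma + cg)
    use_b0i <- if (arm == "midazolam") rep(TRUE, length(prep$sub))
               else prep$is_mid_obs
    b0 <- ifelse(use_b0i, prep$b0i[prep$sub], pars$b0)
    base <- ifelse(prep$surg_obs,
                   pars$base + paemax * prep$tps / (pars$tps50 + prep$tps),
                   b0)
    pmax(base - ipf - prep$cmeff, 6)
  }
  sd_f <- function(pars, f, prep) {
    if (arm == "joint")
      ifelse(prep$is_mid_obs, pars$sigma_mid, pars$sigma_clon) * abs(f)
    else
      pars$sigma_score * abs(f)
  }
  omega_f <- if (arm == "joint") {
    function(pars, prep)
      cbind(ifelse(prep$is_mid_sub, pars$omega_ec50_mid,
                   pars$omega_ec50_clon))
  } else NULL
  new_pkpd_model(paste("COMFORT-B", arm), pars, "ec50", build, predict_f,
                 sd_f, omega_f = omega_f)
}
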