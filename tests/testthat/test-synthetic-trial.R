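test_that("population generation is reproducible and plausible", {
  des <- trial_design(n = 1000)
  p1 <- generate_population(1000, des, seed = 9)
  p2 <- generate_population(1000, des, seed = 9)
  expect_identical(p1, p2)
  # weight grows monotonically with PMA in the median
  dec <- cut(p1$pma, stats::quantile(p1$pma, 0:10 / 10),
             include.lowest = TRUE)
  med <- tapply(p1$wt, dec, stats::median)
  expect_true(all(diff(med) > 0))
  # plausibility corridor for a PICU population
  expect_true(all(p1$wt > 1 & p1$wt < 25))
  expect_true(all(p1$pma >= 36 & p1$pma <= 372))
  expect_true(all(p1$pna >= 0))
  # postnatal-age floor by rejection
  p3 <- generate_population(200, trial_design(pna_min = 28), seed = 4)
  expect_true(all(p3$pna > 28))
})

test_that("starting doses follow the weight-based protocol with halving", {
  des <- trial_design()
  s <- data.frame(wt = 4, pna = 40)
  d <- generate_dosing(s, "clonidine", des, followup = 48)
  expect_equal(d$rate[1] * d$dur[1], 8)     # 2 ug/kg loading over 15 min
  expect_equal(d$dur[1], 0.25)
  expect_equal(d$rate[2], 4)                # 1 ug/kg/h maintenance
  # neonatal halving below 28 days
  s2 <- data.frame(wt = 4, pna = 10)
  d2 <- generate_dosing(s2, "clonidine", des, followup = 48)
  expect_equal(d2$rate[1] * d2$dur[1], 4)   # 1 ug/kg equivalent
  expect_equal(d2$rate[2], 2)
  dm <- generate_dosing(s, "midazolam", des, followup = 48)
  expect_equal(dm$rate[1] * dm$dur[1], 800) # 200 ug/kg loading
  expect_equal(dm$rate[2], 400)             # 100 ug/kg/h
})

test_that("trial simulation honors the design contracts", {
  des <- trial_design(n = 24)
  ds <- simulate_trial(des, seed = 31)
  expect_identical(ds, {
    d2 <- simulate_trial(des, seed = 31)
    attr(d2, "truth") <- attr(ds, "truth")
    d2
  })
  # 2-4 PK samples per subject (parent analyte)
  pk <- ds[ds$EVID == 0 & ds$DVID %in% c("clonidine", "midazolam"), ]
  cnt <- table(pk$ID)
  expect_true(all(cnt >= 2 & cnt <= 4))
  # scores are integers within the scale
  sc <- ds$DV[ds$EVID == 0 & ds$DVID == "comfortb"]
  expect_true(all(sc >= 6 & sc <= 31))
  expect_true(all(sc == round(sc)))
  # titration keeps rates within the protocol band
  dose <- ds[ds$EVID == 1 & ds$DVID == "clonidine" & ds$TIME > 0, ]
  expect_true(all(dose$RATE / dose$WT <= 3 + 1e-9))
})

test_that("titration off yields one constant maintenance rate", {
  des <- trial_design(n = 6, titration = FALSE, p_clonidine = 1)
  ds <- simulate_trial(des, seed = 12)
  for (id in unique(ds$ID)) {
    d <- ds[ds$ID == id & ds$EVID == 1 & ds$DVID == "clonidine", ]
    expect_equal(nrow(d), 2)  # loading + one maintenance segment
  }
})

test_that("noise-free generator reproduces the model predictions exactly", {
  des <- trial_design(n = 8, titration = FALSE,
                      loq = c(clonidine = 0, midazolam = 0,
                              mid_metabolite = 0))
  ds <- simulate_trial(des, seed = 8,
                       pk_clon = no_noise(clonidine_pk_params()),
                       pk_mid = no_noise(midazolam_pk_params()),
                       pd_clon = no_noise(clonidine_pd_params()),
                       pd_mid = no_noise(midazolam_pd_params()))
  tr <- attr(ds, "truth")
  for (i in seq_along(tr$ipk)) {
    id <- tr$population$id[i]
    drug <- tr$population$arm[i]
    sub <- ds[ds$ID == id, ]
    doses <- sub[sub$EVID == 1 & sub$DVID == drug, ]
    dd <- data.frame(start = doses$TIME, rate = doses$RATE,
                     dur = doses$AMT / doses$RATE)
    obs <- sub[sub$EVID == 0 & sub$DVID == drug, ]
    pred <- if (drug == "clonidine")
      conc_clonidine(tr$ipk[[i]], dd, obs$TIME)$conc
    else conc_midazolam(tr$ipk[[i]], dd, obs$TIME)$conc
    expect_equal(obs$DV, pred, tolerance = 1e-10)
  }
  # scores equal the rounded latent prediction (no residual error, no IIV)
  kp <- propofol_kpd_params()
  for (i in seq_along(tr$ipk)) {
    id <- tr$population$id[i]
    drug <- tr$population$arm[i]
    pd <- if (drug == "clonidine") no_noise(clonidine_pd_params())
          else no_noise(midazolam_pd_params())
    sub <- ds[ds$ID == id, ]
    sc <- sub[sub$EVID == 0 & sub$DVID == "comfortb", ]
    pe <- sub[sub$EVID == 1 & sub$DVID == "propofol", ]
    cm <- if (nrow(pe))
      kpd_effect(data.frame(start = pe$TIME, rate = pe$RATE,
                            dur = pe$AMT / pe$RATE), kp, sc$TIME)$effect
    else 0
    lat <- predict_score(sc$TIME, pd, sc$CONC,
                         surgical = sc$SURG[1] == 1, tsurg = 0, cmeff = cm)
    expect_equal(sc$DV, pmin(pmax(round(lat), 6), 31))
  }
})

test_that("genotype generation is reproducible with the right frequencies", {
  g <- generate_genotypes(500, maf = c(0.1, 0.3, 0.45), seed = 6)
  expect_identical(g, generate_genotypes(500, maf = c(0.1, 0.3, 0.45),
                                         seed = 6))
  expect_true(all(g %in% 0:2))
  expect_true(all(abs(colMeans(g) / 2 - c(0.1, 0.3, 0.45)) < 0.05))
})
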