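test_that("postanesthesia washout identities", {
  p <- midazolam_pd_params()   # paemax 9.3, base 6
  expect_equal(postanesthesia(0, p), 6)
  # half-maximum at tps50: base + paemax/2 = 10.65
  expect_equal(postanesthesia(p$tps50, p), 6 + 9.3 / 2)
  expect_equal(postanesthesia(1e9, p), 6 + 9.3, tolerance = 1e-6)
  tps <- seq(0, 24, by = 0.5)
  expect_true(all(diff(postanesthesia(tps, p)) > 0))
  expect_error(postanesthesia(-0.1, p), "nonnegative")
})

test_that("inhibitory Emax drug effect", {
  p <- clonidine_pd_params()
  expect_equal(imp_effect(0, p), 0)
  expect_equal(imp_effect(p$ec50, p), 3)       # half of the fixed Emax 6
  expect_equal(imp_effect(3 * p$ec50, p), 4.5) # 6 * 3/4 at gamma = 1
  expect_lt(imp_effect(1e9, p), 6)
  # a steeper sigmoid keeps the half-maximum identity
  p2 <- utils::modifyList(p, list(gamma = 2.5))
  expect_equal(imp_effect(p2$ec50, p2), 3)
  expect_error(imp_effect(-1, p), "nonnegative")
})

test_that("K-PD propofol effect: zero dose, steady state, washout", {
  kp <- propofol_kpd_params()
  empty <- data.frame(start = numeric(0), rate = numeric(0),
                      dur = numeric(0))
  expect_true(all(kpd_effect(empty, kp, 0:12)$effect == 0))
  # at steady state IRE -> R so effect -> emax_cm R / (ec50_cm + R)
  R <- 5000
  ss <- kpd_effect(data.frame(start = 0, rate = R, dur = 3000),
                   kp, c(0, 2999))$effect[2]
  expect_equal(ss, kp$emax_cm * R / (kp$ec50_cm + R), tolerance = 1e-6)
  # after a short infusion the virtual amount decays single-exponentially
  d <- data.frame(start = 0, rate = 8000, dur = 0.5)
  tt <- c(1, 2, 3, 5)
  eff <- kpd_effect(d, kp, tt)$effect
  ire <- kp$ec50_cm * eff / (kp$emax_cm - eff)  # invert the Emax curve
  a_end <- (8000 / kp$kde) * (1 - exp(-kp$kde * 0.5))
  expect_equal(ire, kp$kde * a_end * exp(-kp$kde * (tt - 0.5)),
               tolerance = 1e-8)
})

test_that("score composition, floor, and monotonicity", {
  p <- clonidine_pd_params()  # b0 15.6
  # nonsurgical identity with no drug and no co-medication
  expect_equal(predict_score(5, p, conc = 0), 15.6)
  # surgical limit composition: tps -> Inf, conc = EC50 gives smax - 3
  smax <- p$base + p$paemax
  expect_equal(predict_score(1e9, p, conc = p$ec50, surgical = TRUE,
                             tsurg = 0), smax - 3, tolerance = 1e-5)
  # flooring at the scale minimum
  expect_gte(predict_score(0.01, p, conc = 1e6, surgical = TRUE, tsurg = 0),
             6)
  expect_error(predict_score(1, p, conc = 1, surgical = TRUE, tsurg = NA),
               "end-of-surgery")
  # nonincreasing in concentration, everything else fixed
  cc <- seq(0, 50, by = 0.5)
  sc <- predict_score(rep(6, length(cc)), p, conc = cc)
  expect_true(all(diff(sc) <= 1e-12))
  # degenerate surgical case: paemax = 0 pins the base at 6
  p0 <- utils::modifyList(p, list(paemax = 0))
  expect_equal(predict_score(c(1, 10, 100), p0, conc = 0, surgical = TRUE,
                             tsurg = 0), rep(6, 3))
})

test_that("joint score model reduces to the per-arm models", {
  des <- trial_design(n = 16)
  ds <- simulate_trial(des, seed = 5)
  joint <- pd_model("joint")
  pj <- joint$build(joint, ds)
  eta0 <- matrix(0, pj$nsub, 1)
  pars_j <- stats::setNames(as.list(joint$pars$init), joint$pars$name)
  fj <- joint$predict_f(pars_j, eta0, pj)
  for (arm in c("clonidine", "midazolam")) {
    m <- pd_model(arm)
    pp <- m$build(m, ds)
    pars_a <- stats::setNames(as.list(m$pars$init), m$pars$name)
    # align shared parameter values with the joint specification
    pars_a$ec50 <- pars_j[[paste0("ec50_",
                                  if (arm == "clonidine") "clon" else "mid")]]
    pars_a$paemax <- pars_j[[paste0("paemax_",
                                    if (arm == "clonidine") "clon" else "mid")]]
    pars_a$b0 <- pars_j$b0
    pars_a$tps50 <- pars_j$tps50
    fa <- m$predict_f(pars_a, matrix(0, pp$nsub, 1), pp)
    # joint predictions restricted to this arm equal the arm model's
    idx <- pj$is_mid_obs == (arm == "midazolam")
    expect_equal(fj[idx], fa, tolerance = 1e-12)
  }
})
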