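test_that("maturation identities and monotonicity", {
  # half-maturation at the PMA half-point, saturation in the limit
  expect_equal(maturation(61.6, 61.6, 2.42), 0.5)
  expect_gt(maturation(616, 61.6, 2.42), 0.99)
  # direct arithmetic: 40^3 / (73.6^3 + 40^3)
  expect_equal(maturation(40, 73.6, 3), 40^3 / (73.6^3 + 40^3))
  expect_equal(maturation(40, 73.6, 3), 0.1383, tolerance = 1e-3)
  pma <- seq(30, 400, by = 5)
  expect_true(all(diff(maturation(pma, 61.6, 2.42)) > 0))
  expect_error(maturation(-1, 61.6, 2.42), "positive")
})

test_that("individual parameters follow allometry and maturation", {
  th <- clonidine_pk_params()
  # reference-size identity: 70 kg, fully matured
  p <- individualize_pk("clonidine", th, list(wt = 70, pma = 1e6))
  expect_equal(p$cl, 28.0, tolerance = 1e-6)
  expect_equal(p$v, 202.4)
  # volumes scale linearly with weight, no maturation
  p35 <- individualize_pk("clonidine", th, list(wt = 35, pma = 1e6))
  expect_equal(p35$v, 101.2)
  # composed arithmetic for a 3.5-kg term infant
  p1 <- individualize_pk("clonidine", th, list(wt = 3.5, pma = 40))
  expect_equal(p1$cl, 28.0 * (3.5 / 70)^0.75 * maturation(40, 61.6, 2.42))
  # random effects act multiplicatively on the log scale
  pe <- individualize_pk("clonidine", th, list(wt = 3.5, pma = 40),
                         eta = c(cl = 0.3))
  expect_equal(pe$cl, p1$cl * exp(0.3))
  expect_equal(pe$v, p1$v)
  # maturation applies to both midazolam clearances by default, not volumes
  tm <- midazolam_pk_params()
  pm <- individualize_pk("midazolam", tm, list(wt = 7, pma = 50))
  mf <- maturation(50, 73.6, 3)
  expect_equal(pm$clm, 33.4 * (0.1)^0.75 * mf)
  expect_equal(pm$clom, 211.6 * (0.1)^0.75 * mf)
  expect_equal(pm$vm, 90.8 * 0.1)
  pm2 <- individualize_pk("midazolam", tm, list(wt = 7, pma = 50),
                          mature_clom = FALSE)
  expect_equal(pm2$clom, 211.6 * (0.1)^0.75)
  expect_error(individualize_pk("clonidine", th, list(pma = 40)),
               "'wt' is missing")
})

test_that("clonidine concentrations: zero dose, steady state, linearity", {
  par <- list(cl = 28, v = 202.4)
  times <- seq(0, 24, by = 0.5)
  empty <- data.frame(start = numeric(0), rate = numeric(0),
                      dur = numeric(0))
  expect_true(all(conc_clonidine(par, empty, times)$conc == 0))
  # Css = rate / CL at a constant infusion
  css <- conc_clonidine(par, data.frame(start = 0, rate = 210, dur = 5000),
                        c(0, 4999))$conc[2]
  expect_equal(css, 210 / 28, tolerance = 1e-6)
  # superposition: doubling every rate doubles every concentration
  d <- fixture_doses(rate = 100, ld = 280)
  c1 <- conc_clonidine(par, d, times)$conc
  d2 <- d; d2$rate <- 2 * d2$rate
  expect_equal(conc_clonidine(par, d2, times)$conc, 2 * c1)
  expect_error(conc_clonidine(list(cl = -1, v = 2), d, times), "positive")
})

test_that("analytic clonidine solution matches the ODE integrator", {
  skip_if_not_installed("deSolve")
  par <- list(cl = 28, v = 202.4)
  times <- seq(0, 24, by = 0.25)
  d <- data.frame(start = 0, rate = 280 / 0.25, dur = 0.25)
  ca <- conc_clonidine(par, d, times)$conc
  co <- conc_ode("clonidine", par, d, times)$conc
  expect_equal(ca, co, tolerance = 1e-6)
  # property: random multi-event regimens and parameters
  set.seed(42)
  for (r in 1:5) {
    pr <- list(cl = stats::runif(1, 0.5, 30), v = stats::runif(1, 5, 250))
    nd <- sample(1:4, 1)
    dd <- data.frame(start = sort(stats::runif(nd, 0, 20)),
                     rate = stats::runif(nd, 1, 300),
                     dur = stats::runif(nd, 0.1, 10))
    tt <- sort(stats::runif(12, 0, 30))
    expect_equal(conc_clonidine(pr, dd, tt)$conc,
                 conc_ode("clonidine", pr, dd, tt)$conc,
                 tolerance = 1e-6)
  }
})

test_that("midazolam model: steady state, AUC identity, ODE equivalence", {
  par <- list(v = 85.8, clm = 33.4, vm = 90.8, clom = 211.6)
  empty <- data.frame(start = numeric(0), rate = numeric(0),
                      dur = numeric(0))
  z <- conc_midazolam(par, empty, c(0, 1, 2))
  expect_true(all(z$conc == 0) && all(z$conc_m == 0))
  # full conversion: parent Css = R/CLm, metabolite Css = R/CLom
  R <- 330
  ss <- conc_midazolam(par, data.frame(start = 0, rate = R, dur = 5000),
                       c(0, 4999))
  expect_equal(ss$conc[2], R / 33.4, tolerance = 1e-6)
  expect_equal(ss$conc_m[2], R / 211.6, tolerance = 1e-6)
  # integral identity: total metabolite exposure AUC = D / CLom
  D <- 660
  d <- data.frame(start = 0, rate = D / 0.25, dur = 0.25)
  auc <- stats::integrate(function(t)
    conc_midazolam(par, d, sort(t))$conc_m[order(order(t))],
    0, Inf, rel.tol = 1e-9)$value
  expect_equal(auc, D / 211.6, tolerance = 1e-5)
  skip_if_not_installed("deSolve")
  tt <- seq(0, 24, by = 0.5)
  ca <- conc_midazolam(par, d, tt)
  co <- conc_ode("midazolam", par, d, tt)
  expect_equal(ca$conc, co$conc, tolerance = 1e-6)
  expect_equal(ca$conc_m, co$conc_m, tolerance = 1e-6)
  # near-equal rate constants exercise the limit branch
  pe <- list(v = 10, clm = 5, vm = 20, clom = 10.0000001)
  ce <- conc_midazolam(pe, d, tt)
  coe <- conc_ode("midazolam", pe, d, tt)
  expect_equal(ce$conc_m, coe$conc_m, tolerance = 1e-5)
})

test_that("midazolam mass balance: dose fully accounted for", {
  par <- list(v = 85.8, clm = 33.4, vm = 90.8, clom = 211.6)
  D <- 500
  d <- data.frame(start = 0, rate = D / 0.5, dur = 0.5)
  # eliminated from the metabolite compartment = CLom * integral of Cm;
  # at a late time the remaining amounts are negligible
  tt <- c(0, 300)
  rem <- conc_midazolam(par, d, tt)
  a_rem <- rem$conc[2] * par$v + rem$conc_m[2] * par$vm
  elim <- 211.6 * stats::integrate(function(t)
    conc_midazolam(par, d, sort(t))$conc_m[order(order(t))],
    0, 300, rel.tol = 1e-9)$value
  expect_equal(elim + a_rem, D, tolerance = 1e-4)
})
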