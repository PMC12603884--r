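test_that("Laplace engine is exact on the linear one-observation model", {
  set.seed(4)
  y <- stats::rnorm(40, 2, sqrt(1.5^2 + 0.8^2))
  model <- linear_oracle_model()
  prep <- model$build(model, list(y = y))
  for (pg in list(c(2, 1.5, 0.8), c(1.5, 1, 1), c(3, 0.5, 2))) {
    pars <- list(mu = pg[1], omega_mu = pg[2], sigma = pg[3])
    res <- sedpkpd:::.inner_modes(pars, prep, model,
                                  matrix(0, prep$nsub, 1))
    ofv <- sedpkpd:::.ofv_from_modes(res, 1)
    expect_equal(ofv, linear_marginal_ofv(y, pg[1], pg[2], pg[3]),
                 tolerance = 1e-6)
  }
})

test_that("linear-model fit matches the lme4 oracle", {
  skip_if_not_installed("lme4")
  set.seed(11)
  n <- 60; m <- 4
  id <- rep(seq_len(n), each = m)
  b <- stats::rnorm(n, 0, 1.2)
  y <- 5 + b[id] + stats::rnorm(n * m, 0, 0.7)
  # repeated-measures variant of the oracle model
  pars <- rbind(
    data.frame(name = "mu", init = 1, fixed = FALSE, trans = "id"),
    data.frame(name = "omega_mu", init = 1, fixed = FALSE, trans = "log"),
    data.frame(name = "sigma", init = 1, fixed = FALSE, trans = "log"))
  model <- new_pkpd_model(
    "linear rm", pars, "mu",
    build = function(model, data)
      list(y = data$y, sub = data$id, nsub = max(data$id),
           ids = seq_len(max(data$id)), nobs = length(data$y)),
    predict_f = function(pars, eta, prep) pars$mu + eta[prep$sub, 1],
    sd_f = function(pars, f, prep) rep(pars$sigma, length(f)))
  fit <- pkpd_fit(list(y = y, id = id), model, settings = list(se = FALSE))
  lm4 <- lme4::lmer(y ~ 1 + (1 | id), REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(fit$estimates$mu, unname(lme4::fixef(lm4)), tolerance = 1e-4)
  expect_equal(fit$estimates$omega_mu, vc$sdcor[1], tolerance = 1e-3)
  expect_equal(fit$estimates$sigma, vc$sdcor[2], tolerance = 1e-3)
  expect_equal(as.numeric(logLik(fit)), as.numeric(logLik(lm4)),
               tolerance = 1e-6)
})

test_that("noiseless data return the generating values", {
  des <- fixture_clon_design(n = 14, titration = FALSE,
                             loq = c(clonidine = 0, midazolam = 0,
                                     mid_metabolite = 0),
                             n_pk_samples = 4)
  ds <- simulate_trial(des, seed = 3,
                       pk_clon = no_noise(clonidine_pk_params()),
                       pd_clon = no_noise(clonidine_pd_params()))
  small <- list(omega_cl = 0.05, omega_v = 0.05, sigma_prop = 0.02)
  fit <- pkpd_fit(ds, pk_model_clonidine(
    fix = c("omega_cl", "omega_v", "sigma_prop"), init = small),
    settings = list(se = FALSE))
  expect_equal(fit$estimates$cl, 28.0, tolerance = 0.01)
  expect_equal(fit$estimates$v, 202.4, tolerance = 0.01)
})

test_that("the fit improves on its starting point and is deterministic", {
  des <- fixture_clon_design(n = 12)
  ds <- blq_impute(simulate_trial(des, seed = 9), loq = des$loq)
  f1 <- pkpd_fit(ds, pk_model_clonidine(), settings = list(se = FALSE))
  expect_lte(f1$ofv, f1$ofv_init)
  f2 <- pkpd_fit(ds, pk_model_clonidine(), settings = list(se = FALSE))
  expect_identical(coef(f1), coef(f2))
})

test_that("missing BLQ imputation is refused with a clear message", {
  des <- fixture_clon_design(n = 25)
  ds <- simulate_trial(des, seed = 1)
  expect_gt(sum(ds$BLQ == 1), 0)
  expect_error(pkpd_fit(ds, pk_model_clonidine()), "impute")
})

test_that("covariate likelihood-ratio test finds a real clearance effect", {
  des <- fixture_clon_design(
    n = 40, cov_effect = list(param = "cl", name = "CREA", ref = 45,
                              beta = 0.03, sd_log = 0.4))
  ds <- blq_impute(simulate_trial(des, seed = 18), loq = des$loq)
  base <- pkpd_fit(ds, pk_model_clonidine(), settings = list(se = FALSE))
  ext <- pkpd_fit(ds, pk_model_clonidine(
    covariates = list(list(param = "cl", col = "CREA", ref = 45))),
    settings = list(se = FALSE))
  ct <- covariate_test(base, ext)
  expect_equal(ct$df, 1)
  expect_gt(ct$delta_ofv, 3.84)
  expect_true(ct$include)
  # identical fits give a zero ofv change and no inclusion
  ct0 <- covariate_test(base, base)
  expect_equal(ct0$delta_ofv, 0)
  expect_false(ct0$include)
  # reversed nesting is refused
  expect_error(covariate_test(ext, base), "not nested")
})

test_that("null covariate delta-OFV behaves like a chi-square", {
  # degenerate linear model: restricting the mean to its true value is the
  # null; the ofv drop when freeing it should be chi-square(1)
  model_free <- linear_oracle_model()
  model_fix <- linear_oracle_model()
  model_fix$pars$fixed[model_fix$pars$name == "mu"] <- TRUE
  model_fix$pars$init[model_fix$pars$name == "mu"] <- 0
  hits <- 0
  reps <- 40
  drops <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(200 + r)
    y <- stats::rnorm(30, 0, sqrt(2))
    f0 <- pkpd_fit(list(y = y), model_fix, settings = list(se = FALSE))
    f1 <- pkpd_fit(list(y = y), model_free, settings = list(se = FALSE))
    ct <- covariate_test(f0, f1, alpha = 0.05)
    drops[r] <- ct$delta_ofv
    if (ct$include) hits <- hits + 1
  }
  expect_true(all(drops > -1e-4))     # freeing a parameter never hurts
  expect_lt(hits / reps, 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))
  expect_lt(abs(mean(drops) - 1), 0.8)  # E[chi2_1] = 1, generous bound
})

test_that("standard errors are reported on the natural scale", {
  des <- fixture_clon_design(n = 30)
  ds <- blq_impute(simulate_trial(des, seed = 23), loq = des$loq)
  fit <- pkpd_fit(ds, pk_model_clonidine())
  expect_true(all(is.finite(fit$se)))
  expect_true(all(fit$se > 0))
  # a sane relative precision for a well-designed study
  expect_lt(fit$se[["cl"]] / fit$estimates$cl, 0.5)
  s <- summary(fit)
  expect_s3_class(s, "summary.pkpd_fit")
  expect_true(all(c("cv_pct", "omega_pct") %in% names(s$iiv)))
  v <- vcov(fit)
  expect_equal(sqrt(diag(v))[["cl"]], fit$se[["cl"]], tolerance = 1e-6)
})
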