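make_small_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    des <- fixture_clon_design(n = 18)
    ds <- blq_impute(simulate_trial(des, seed = 42), loq = des$loq)
    cache <<- pkpd_fit(ds, pk_model_clonidine(), settings = list(se = FALSE))
    cache
  }
})

test_that("bootstrap is reproducible and centered on the fit", {
  fit <- make_small_fit()
  b1 <- bootstrap(fit, n_resamples = 6, seed = 7)
  b2 <- bootstrap(fit, n_resamples = 6, seed = 7)
  expect_identical(b1$estimates, b2$estimates)
  expect_equal(b1$n_fail, 0)
  # median of a handful of resamples sits within a loose factor of the fit
  expect_lt(abs(log(b1$median[["cl"]] / coef(fit)[["cl"]])), log(2))
  expect_true(all(b1$lower <= b1$median & b1$median <= b1$upper))
})

test_that("bootstrap of identical subjects has zero-width intervals", {
  des <- fixture_clon_design(n = 1, titration = FALSE)
  one <- blq_impute(simulate_trial(des, seed = 2), loq = des$loq)
  copies <- lapply(1:8, function(i) { d <- one; d$ID <- i; d })
  ds <- do.call(rbind, copies)
  fit <- pkpd_fit(ds, pk_model_clonidine(
    fix = c("omega_cl", "omega_v"),
    init = list(omega_cl = 0.2, omega_v = 0.2)),
    settings = list(se = FALSE))
  b <- bootstrap(fit, n_resamples = 5, seed = 3)
  expect_lt(max(b$upper - b$lower, na.rm = TRUE), 1e-6)
})

test_that("pcVPC is self-consistent for data from the fitted model", {
  fit <- make_small_fit()
  v1 <- pc_vpc(fit, n_sim = 120, bins = 5, seed = 9)
  v2 <- pc_vpc(fit, n_sim = 120, bins = 5, seed = 9)
  expect_identical(v1$summary, v2$summary)
  # the observed data came from the very model family being simulated,
  # so the observed percentiles should mostly sit inside the bands
  expect_gte(mean(v1$coverage), 0.7)
  s <- v1$summary
  expect_true(all(s$obs_p5 <= s$obs_p50 & s$obs_p50 <= s$obs_p95))
})

test_that("prediction correction is inert for exchangeable subjects", {
  # identical covariates, doses and sampling times: the correction factor
  # is constant so corrected and uncorrected checks coincide
  des <- fixture_clon_design(n = 1, titration = FALSE,
                             pma_range = c(60, 60.0001), wt_cv = 0,
                             followup_range = c(48, 48), n_pk_samples = 4)
  one <- blq_impute(simulate_trial(des, seed = 5), loq = des$loq)
  obs <- one[one$EVID == 0 & one$DVID == "clonidine", ]
  obs$TIME <- c(1, 6, 24, 40)   # nominal times shared by every copy
  dose <- one[one$EVID == 1, ]
  copies <- lapply(1:12, function(i) {
    d <- rbind(dose, obs)
    d <- d[order(d$TIME, -d$EVID), ]
    d$ID <- i
    d
  })
  ds <- do.call(rbind, copies)
  # fresh noise per copy so the observed percentiles are not degenerate
  set.seed(31)
  cc <- ds$EVID == 0 & ds$DVID == "clonidine"
  ds$DV[cc] <- abs(ds$DV[cc] * (1 + 0.3 * stats::rnorm(sum(cc))))
  fit <- pkpd_fit(ds, pk_model_clonidine(), settings = list(se = FALSE))
  vp <- pc_vpc(fit, n_sim = 100, bins = 4, seed = 2, pc = TRUE)
  vu <- pc_vpc(fit, n_sim = 100, bins = 4, seed = 2, pc = FALSE)
  expect_equal(vp$summary, vu$summary, tolerance = 1e-10)
})

test_that("simulate() draws new noise under the fitted design", {
  fit <- make_small_fit()
  s1 <- simulate(fit, nsim = 3, seed = 1)
  s2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(fit$nobs, 3))
  expect_gt(stats::sd(s1[, 1] - s1[, 2]), 0)
})

test_that("fit methods expose predictions and residuals coherently", {
  fit <- make_small_fit()
  fp <- predict(fit, "population")
  fi <- predict(fit, "individual")
  expect_length(fp, fit$nobs)
  # individual predictions must fit at least as well in total
  rp <- residuals(fit, "population")
  ri <- residuals(fit, "individual")
  expect_lt(sum(ri^2), sum(rp^2) + 1e-9)
  expect_output(print(fit), "OFV")
  expect_silent(grDevices::pdf(NULL))
  plot(fit)
  grDevices::dev.off()
})
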