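# Small fixtures shared across tests; everything generated in code.

fixture_clon_design <- function(n = 20, ...) {
  trial_design(n = n, p_clonidine = 1, ...)
}

fixture_mid_design <- function(n = 20, ...) {
  trial_design(n = n, p_clonidine = 0, ...)
}

# noiseless variants of the generating parameter sets
no_noise <- function(p) {
  p[grep("^iiv|^err", names(p))] <- 0
  p
}

# one subject with a simple loading + maintenance schedule
fixture_doses <- function(rate = 210, ld = 0, ld_dur = 0.25, horizon = 48) {
  d <- data.frame(start = 0.25, rate = rate, dur = horizon - 0.25)
  if (ld > 0) d <- rbind(data.frame(start = 0, rate = ld / ld_dur,
                                    dur = ld_dur), d)
  d
}

# a degenerate linear mixed model (one observation per subject,
# y_i = mu + eta_i + eps) expressed as a pkpd_model, used to pit the Laplace
# engine against the closed-form marginal likelihood
linear_oracle_model <- function() {
  pars <- rbind(
    data.frame(name = "mu", init = 0, fixed = FALSE, trans = "id"),
    data.frame(name = "omega_mu", init = 1, fixed = FALSE, trans = "log"),
    data.frame(name = "sigma", init = 1, fixed = FALSE, trans = "log"))
  build <- function(model, data) {
    list(y = data$y, sub = seq_along(data$y), nsub = length(data$y),
         ids = seq_along(data$y), nobs = length(data$y))
  }
  predict_f <- function(pars, eta, prep) pars$mu + eta[prep$sub, 1]
  sd_f <- function(pars, f, prep) rep(pars$sigma, length(f))
  new_pkpd_model("linear oracle", pars, "mu", build, predict_f, sd_f)
}

# closed-form -2 log likelihood of that linear model
linear_marginal_ofv <- function(y, mu, omega, sigma) {
  v <- omega^2 + sigma^2
  sum(log(2 * pi * v) + (y - mu)^2 / v)
}
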