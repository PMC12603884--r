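## S3 methods for fitted models.

#' @export
print.pkpd_fit <- function(x, ...) {
  cat("Population PKPD fit:", x$model$name, "\n")
  cat(sprintf("  %d observations, %d subjects; OFV = %.3f\n",
              x$nobs, x$prep$nsub, x$ofv))
  if (!x$converged) cat("  WARNING: optimizer did not converge:",
                        x$message, "\n")
  est <- names(which(x$est))
  v <- unlist(x$estimates[est])
  tab <- data.frame(estimate = signif(v, 4),
                    se = signif(x$se[est], 3),
                    `rse%` = signif(100 * x$se[est] / abs(v), 3),
                    check.names = FALSE)
  print(tab)
  fx <- names(which(!x$est))
  if (length(fx))
    cat("Fixed:", paste(sprintf("%s = %g", fx, unlist(x$estimates[fx])),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a population fit
#'
#' Reports estimates with asymptotic standard errors, interindividual
#' variability on both conventions (percent CV of the lognormal,
#' `100 sqrt(exp(omega^2) - 1)`, and the simpler `100 omega`), and residual
#' error magnitudes.
#'
#' @param object a `pkpd_fit`
#' @param ... unused
#' @return object of class `summary.pkpd_fit`
#' @export
summary.pkpd_fit <- function(object, ...) {
  est <- names(which(object$est))
  v <- unlist(object$estimates[est])
  tab <- data.frame(parameter = est, estimate = v, se = object$se[est],
                    rse_pct = 100 * object$se[est] / abs(v),
                    row.names = NULL)
  om <- grep("^omega_", est, value = TRUE)
  iiv <- if (length(om))
    data.frame(parameter = sub("^omega_", "", om),
               cv_pct = omega_to_cv(unlist(object$estimates[om])),
               omega_pct = 100 * unlist(object$estimates[om]),
               row.names = NULL)
  else NULL
  structure(list(name = object$model$name, tab = tab, iiv = iiv,
                 ofv = object$ofv, nobs = object$nobs,
                 nsub = object$prep$nsub, converged = object$converged),
            class = "summary.pkpd_fit")
}

#' @export
print.summary.pkpd_fit <- function(x, ...) {
  cat("Model:", x$name, "\n")
  cat(sprintf("OFV (-2 log marginal likelihood): %.3f  [%d obs, %d subjects]\n",
              x$ofv, x$nobs, x$nsub))
  if (!x$converged) cat("WARNING: not converged\n")
  cat("\nEstimates:\n")
  tab <- x$tab
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$rse_pct <- signif(tab$rse_pct, 3)
  print(tab)
  if (!is.null(x$iiv)) {
    cat("\nInterindividual variability (%):\n")
    iiv <- x$iiv
    iiv$cv_pct <- signif(iiv$cv_pct, 4)
    iiv$omega_pct <- signif(iiv$omega_pct, 4)
    print(iiv)
  }
  invisible(x)
}

#' @export
coef.pkpd_fit <- function(object, ...) {
  est <- names(which(object$est))
  unlist(object$estimates[est])
}

#' @export
logLik.pkpd_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = object$n_est, nobs = object$nobs,
            class = "logLik")
}

#' @export
vcov.pkpd_fit <- function(object, ...) {
  est <- names(which(object$est))
  if (is.null(object$vcov_x)) {
    m <- matrix(NA_real_, length(est), length(est),
                dimnames = list(est, est))
    return(m)
  }
  tr <- object$model$pars$trans[object$est]
  v <- unlist(object$estimates[est])
  D <- diag(ifelse(tr == "log", v, 1), length(est))
  m <- D %*% object$vcov_x %*% D
  dimnames(m) <- list(est, est)
  m
}

#' Predictions from a population fit
#'
#' @param object a `pkpd_fit`
#' @param type `"population"` (random effects at zero) or `"individual"`
#'   (empirical Bayes estimates)
#' @param ... unused
#' @return numeric vector of predictions, one per observation row in scope
#' @export
predict.pkpd_fit <- function(object, type = c("population", "individual"),
                             ...) {
  type <- match.arg(type)
  eta <- if (type == "population")
    matrix(0, object$prep$nsub, ncol(object$eta)) else object$eta
  object$model$predict_f(object$estimates, eta, object$prep)
}

#' Standardized residuals
#'
#' @param object a `pkpd_fit`
#' @param type prediction level for the residual, as in [predict.pkpd_fit()]
#' @param ... unused
#' @return `(y - f) / sd(f)` per observation
#' @export
residuals.pkpd_fit <- function(object, type = c("population", "individual"),
                               ...) {
  f <- predict(object, type = match.arg(type))
  sd <- pmax(object$model$sd_f(object$estimates, f, object$prep), 1e-12)
  (object$prep$y - f) / sd
}

#' Simulate observation vectors from a fitted (or specified) model
#'
#' Draws new lognormal random effects and residual errors at the fitted
#' parameters and returns simulated dependent values on the original
#' design (same subjects, doses and sampling times).
#'
#' @param object a `pkpd_fit`
#' @param nsim number of replicate simulations
#' @param seed integer seed
#' @param ... unused
#' @return matrix (observations x `nsim`)
#' @export
simulate.pkpd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- object$model
  prep <- object$prep
  pars <- object$estimates
  d <- ncol(object$eta)
  om <- .omega_mat(model, pars, prep)
  out <- matrix(NA_real_, length(prep$y), nsim)
  for (s in seq_len(nsim)) {
    eta <- matrix(stats::rnorm(prep$nsub * d), prep$nsub, d) * om
    f <- model$predict_f(pars, eta, prep)
    sd <- model$sd_f(pars, f, prep)
    out[, s] <- f + stats::rnorm(length(f), 0, 1) * sd
  }
  out
}

#' Goodness-of-fit plots
#'
#' Observations against population and individual predictions, and
#' standardized population residuals against time.
#'
#' @param x a `pkpd_fit`
#' @param ... passed to [graphics::plot()]
#' @return `x`, invisibly
#' @export
plot.pkpd_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  y <- x$prep$y
  fp <- predict(x, "population")
  fi <- predict(x, "individual")
  tt <- if (!is.null(x$prep$time)) x$prep$time else seq_along(y)
  lim <- range(c(y, fp, fi), finite = TRUE)
  graphics::plot(fp, y, xlab = "population prediction", ylab = "observed",
                 xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, col = "grey50")
  graphics::plot(fi, y, xlab = "individual prediction", ylab = "observed",
                 xlim = lim, ylim = lim, ...)
  graphics::abline(0, 1, col = "grey50")
  graphics::plot(tt, residuals(x), xlab = "time (h)",
                 ylab = "standardized residual", ...)
  graphics::abline(h = 0, col = "grey50")
  invisible(x)
}
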