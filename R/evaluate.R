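## Model evaluation: nonparametric bootstrap and prediction-corrected VPC.

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement, refits the model to each resampled
#' dataset (starting from the original estimates), and summarizes every
#' estimated parameter by its median and 90% percentile interval.
#' Reproducible given the seed. Resamples whose fit fails are counted and
#' skipped; if every resample fails an error reports the count.
#'
#' @param fit a `pkpd_fit`
#' @param n_resamples number of bootstrap datasets (>= 1)
#' @param seed integer seed
#' @param level confidence level of the percentile interval (default 0.90)
#' @return object of class `pkpd_boot` with the estimate matrix, medians and
#'   interval bounds
#' @export
bootstrap <- function(fit, n_resamples = 200, seed = 1, level = 0.90) {
  stopifnot(n_resamples >= 1)
  set.seed(seed)
  data <- fit$data
  ids <- unique(data$ID)
  rows_of <- split(seq_len(nrow(data)), factor(data$ID, levels = ids))
  init <- fit$estimates[fit$model$pars$name[!fit$model$pars$fixed]]
  res <- matrix(NA_real_, n_resamples, length(coef(fit)),
                dimnames = list(NULL, names(coef(fit))))
  nfail <- 0
  for (b in seq_len(n_resamples)) {
    take <- sample(ids, length(ids), replace = TRUE)
    parts <- lapply(seq_along(take), function(j) {
      d <- data[rows_of[[as.character(take[j])]], , drop = FALSE]
      d$ID <- j
      d
    })
    bd <- do.call(rbind, parts)
    ft <- try(pkpd_fit(bd, fit$model, init = init,
                       settings = utils::modifyList(fit$settings,
                                                    list(se = FALSE,
                                                         n_starts = 1))),
              silent = TRUE)
    if (inherits(ft, "try-error")) nfail <- nfail + 1
    else res[b, ] <- coef(ft)
  }
  if (all(is.na(res[, 1])))
    stop("all ", nfail, " bootstrap resamples failed to fit")
  qs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  sm <- apply(res, 2, stats::quantile, probs = qs, na.rm = TRUE)
  structure(list(estimates = res, median = sm[2, ], lower = sm[1, ],
                 upper = sm[3, ], level = level, n_fail = nfail,
                 seed = seed),
            class = "pkpd_boot")
}

#' @export
print.pkpd_boot <- function(x, ...) {
  cat(sprintf("Bootstrap (%d successful resamples, %d failed):\n",
              sum(!is.na(x$estimates[, 1])), x$n_fail))
  tab <- data.frame(median = signif(x$median, 4),
                    lower = signif(x$lower, 4),
                    upper = signif(x$upper, 4))
  names(tab)[2:3] <- paste0(c("lo", "hi"), format(100 * x$level))
  print(tab)
  invisible(x)
}

#' Prediction-corrected visual predictive check
#'
#' Bins observations in time, rescales each observation and each simulated
#' value by the ratio of the bin median population prediction to the
#' record's own population prediction (prediction correction), and compares
#' the observed 5th/50th/95th percentiles per bin with the corresponding
#' simulation-based confidence bands. When every subject shares covariates
#' and doses, the correction factor is constant and the result equals an
#' uncorrected VPC.
#'
#' @param fit a `pkpd_fit`
#' @param n_sim number of simulated replicates (>= 100)
#' @param bins number of time bins (quantile-spaced), or a vector of breaks
#' @param seed integer seed
#' @param pc logical, apply prediction correction (default TRUE)
#' @param conf level of the simulation band (default 0.95)
#' @return object of class `pkpd_vpc`: per-bin observed percentiles with
#'   simulated confidence bands
#' @export
pc_vpc <- function(fit, n_sim = 200, bins = 8, seed = 1, pc = TRUE,
                   conf = 0.95) {
  stopifnot(n_sim >= 100)
  tt <- fit$prep$time
  if (is.null(tt)) stop("the fitted model carries no observation times")
  y <- fit$prep$y
  pred <- predict(fit, "population")
  if (length(bins) == 1) {
    br <- unique(stats::quantile(tt, probs = seq(0, 1, length.out = bins + 1)))
  } else br <- unique(sort(bins))
  bin <- cut(tt, br, include.lowest = TRUE)
  keep <- !is.na(bin)
  if (any(!keep)) {
    warning(sum(!keep), " observations outside the bin breaks dropped")
  }
  lv <- levels(droplevels(bin[keep]))
  empty <- setdiff(levels(bin), lv)
  if (length(empty)) warning("empty bins dropped: ",
                             paste(empty, collapse = ", "))
  bin <- droplevels(bin[keep])
  y <- y[keep]; tt <- tt[keep]; pred <- pred[keep]
  corr <- if (pc) {
    med_bin <- tapply(pred, bin, stats::median)
    as.numeric(med_bin[bin]) / pmax(pred, 1e-12)
  } else rep(1, length(y))
  probs <- c(0.05, 0.5, 0.95)
  pcs <- function(v) vapply(split(v, bin), stats::quantile,
                            numeric(3), probs = probs)
  obs_p <- pcs(y * corr)
  sims <- simulate(fit, nsim = n_sim, seed = seed)[keep, , drop = FALSE]
  sim_p <- array(NA_real_, c(3, nlevels(bin), n_sim))
  for (s in seq_len(n_sim)) sim_p[, , s] <- pcs(sims[, s] * corr)
  a <- (1 - conf) / 2
  lo <- apply(sim_p, c(1, 2), stats::quantile, probs = a)
  hi <- apply(sim_p, c(1, 2), stats::quantile, probs = 1 - a)
  md <- apply(sim_p, c(1, 2), stats::median)
  tmid <- tapply(tt, bin, stats::median)
  out <- data.frame(bin = lv, t_mid = as.numeric(tmid),
                    obs_p5 = obs_p[1, ], obs_p50 = obs_p[2, ],
                    obs_p95 = obs_p[3, ],
                    sim_p5_lo = lo[1, ], sim_p5_hi = hi[1, ],
                    sim_p50_lo = lo[2, ], sim_p50_hi = hi[2, ],
                    sim_p95_lo = lo[3, ], sim_p95_hi = hi[3, ],
                    sim_p5_md = md[1, ], sim_p50_md = md[2, ],
                    sim_p95_md = md[3, ], row.names = NULL)
  cover <- c(p5 = mean(out$obs_p5 >= out$sim_p5_lo &
                         out$obs_p5 <= out$sim_p5_hi),
             p50 = mean(out$obs_p50 >= out$sim_p50_lo &
                          out$obs_p50 <= out$sim_p50_hi),
             p95 = mean(out$obs_p95 >= out$sim_p95_lo &
                          out$obs_p95 <= out$sim_p95_hi))
  structure(list(summary = out, coverage = cover, n_sim = n_sim,
                 pc = pc, conf = conf, seed = seed),
            class = "pkpd_vpc")
}

#' @export
print.pkpd_vpc <- function(x, ...) {
  cat(sprintf("%s visual predictive check (%d simulations)\n",
              if (x$pc) "Prediction-corrected" else "Uncorrected", x$n_sim))
  cat(sprintf("Bins with observed percentile inside the %g%% band: %s\n",
              100 * x$conf,
              paste(sprintf("%s %.0f%%", names(x$coverage),
                            100 * x$coverage), collapse = ", ")))
  print(x$summary[, c("bin", "t_mid", "obs_p5", "obs_p50", "obs_p95")])
  invisible(x)
}

#' @export
plot.pkpd_vpc <- function(x, ...) {
  s <- x$summary
  ylim <- range(s[, -1], finite = TRUE)
  graphics::plot(s$t_mid, s$obs_p50, type = "n", ylim = ylim,
                 xlab = "time (h)", ylab = "prediction-corrected value", ...)
  band <- function(lo, hi, col)
    graphics::polygon(c(s$t_mid, rev(s$t_mid)), c(lo, rev(hi)),
                      col = col, border = NA)
  band(s$sim_p5_lo, s$sim_p5_hi, grDevices::adjustcolor("steelblue", 0.3))
  band(s$sim_p95_lo, s$sim_p95_hi, grDevices::adjustcolor("steelblue", 0.3))
  band(s$sim_p50_lo, s$sim_p50_hi, grDevices::adjustcolor("firebrick", 0.3))
  graphics::lines(s$t_mid, s$obs_p50, lwd = 2)
  graphics::lines(s$t_mid, s$obs_p5, lty = 2)
  graphics::lines(s$t_mid, s$obs_p95, lty = 2)
  invisible(x)
}
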