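## Two-step pharmacogenetic screening of SNPs against individual clearances.

#' Minor allele frequency and Hardy-Weinberg filter
#'
#' First screening step: computes per-SNP minor allele frequency (MAF) from
#' the allele counts (missing genotypes excluded) and excludes SNPs with
#' MAF below `maf_min` (default 5%). The remaining SNPs are tested for
#' Hardy-Weinberg equilibrium with a 1-df chi-square test on the genotype
#' counts against the expected proportions at the estimated allele
#' frequency; SNPs with an equilibrium p-value below `hwe_min_p` are also
#' excluded. Monomorphic SNPs get MAF 0 and are excluded, not an error.
#'
#' @param g genotype matrix, subjects x SNPs, minor-allele counts in 0/1/2
#'   (NA allowed)
#' @param maf_min exclusion threshold, in (0, 0.5]
#' @param hwe_min_p Hardy-Weinberg p-value below which a SNP is excluded
#' @return list with `g` (the filtered matrix) and `screen`, a data.frame
#'   with per-SNP `maf`, `hwe_chisq`, `hwe_p`, `maf_pass`, `hwe_pass`
#' @export
maf_hwe_filter <- function(g, maf_min = 0.05, hwe_min_p = 0.001) {
  stopifnot(maf_min > 0, maf_min <= 0.5)
  g <- as.matrix(g)
  if (!all(g %in% c(0, 1, 2, NA)))
    stop("genotypes must be coded 0/1/2 (minor-allele count)")
  snames <- colnames(g)
  if (is.null(snames)) snames <- paste0("snp", seq_len(ncol(g)))
  res <- lapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    x <- x[!is.na(x)]
    n <- length(x)
    p <- if (n) sum(x) / (2 * n) else NA_real_
    maf <- min(p, 1 - p)
    cnt <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    if (is.na(maf) || maf == 0 || n == 0)
      return(data.frame(snp = snames[j], maf = maf, hwe_chisq = NA_real_,
                        hwe_p = NA_real_))
    ex <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chisq <- sum((cnt - ex)^2 / ex)
    data.frame(snp = snames[j], maf = maf, hwe_chisq = chisq,
               hwe_p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
  })
  screen <- do.call(rbind, res)
  screen$maf_pass <- !is.na(screen$maf) & screen$maf >= maf_min
  screen$hwe_pass <- screen$maf_pass &
    (!is.na(screen$hwe_p) & screen$hwe_p >= hwe_min_p)
  list(g = g[, screen$maf_pass & screen$hwe_pass, drop = FALSE],
       screen = screen)
}

#' Screen SNPs against individual clearances
#'
#' Second step: for every SNP surviving the MAF and Hardy-Weinberg filter,
#' regresses the log individual clearance (an empirical Bayes estimate from
#' the population fit) on the additive genotype code by ordinary linear
#' regression (complete-case per SNP). A SNP is selected when its p-value
#' falls below the Bonferroni-corrected threshold `alpha / m` for the `m`
#' SNPs tested (family-wise level `alpha`, default 0.2). Selected SNPs are
#' then testable inside the population model as a two-category carrier
#' covariate (see [group_carriers()]).
#'
#' @param log_cl numeric vector of log individual clearances, one per subject
#' @param g genotype matrix (subjects x SNPs, 0/1/2)
#' @param maf_min,hwe_min_p filter thresholds, see [maf_hwe_filter()]
#' @param alpha family-wise significance level before Bonferroni correction
#' @return object of class `pgx_screen`: per-SNP table with MAF, HWE and
#'   regression results, the Bonferroni threshold and the selected SNP set
#' @export
screen_snps <- function(log_cl, g, maf_min = 0.05, hwe_min_p = 0.001,
                        alpha = 0.2) {
  g <- as.matrix(g)
  stopifnot(length(log_cl) == nrow(g))
  flt <- maf_hwe_filter(g, maf_min = maf_min, hwe_min_p = hwe_min_p)
  tab <- flt$screen
  tab$beta <- NA_real_
  tab$p_value <- NA_real_
  gkeep <- flt$g
  m <- ncol(gkeep)
  if (m == 0) {
    warning("no SNPs left after the MAF/HWE filter")
    thr <- NA_real_
  } else {
    thr <- alpha / m
    for (snp in colnames(gkeep)) {
      x <- gkeep[, snp]
      ok <- !is.na(x) & !is.na(log_cl)
      if (sum(ok) >= 3 && stats::var(x[ok]) > 0) {
        fm <- stats::lm(log_cl[ok] ~ x[ok])
        cf <- summary(fm)$coefficients
        i <- tab$snp == snp
        tab$beta[i] <- cf[2, 1]
        tab$p_value[i] <- cf[2, 4]
      }
    }
  }
  tab$selected <- !is.na(tab$p_value) & tab$p_value < thr
  structure(list(table = tab, m_tested = m, alpha = alpha, threshold = thr,
                 selected = tab$snp[tab$selected]),
            class = "pgx_screen")
}

#' @export
print.pgx_screen <- function(x, ...) {
  cat(sprintf(paste0("SNP screen: %d SNPs tested, Bonferroni threshold ",
                     "%.4g (family-wise alpha %.2g)\n"),
              x$m_tested, x$threshold, x$alpha))
  print(x$table, digits = 4)
  if (length(x$selected))
    cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  else cat("No SNP selected\n")
  invisible(x)
}

#' Collapse a genotype into a two-category carrier covariate
#'
#' Heterozygous and homozygous mutant genotypes are grouped into a single
#' carrier category for testing inside the population model, so the
#' covariate never has more than two levels.
#'
#' @param g_snp genotype vector in 0/1/2 (NA allowed)
#' @return integer vector, 0 = wild type, 1 = carrier
#' @export
group_carriers <- function(g_snp) {
  as.integer(g_snp > 0)
}

#' Read a genotype table from delimited text
#'
#' Expects a header with a subject identifier column (`ID`) followed by one
#' column per SNP, coded 0/1/2 with `"."` or empty for missing.
#'
#' @param path file path
#' @return matrix of minor-allele counts with subject IDs as row names
#' @export
read_genotypes <- function(path) {
  raw <- utils::read.csv(path, na.strings = c(".", "", "NA"))
  if (!"ID" %in% names(raw)) stop("genotype table needs an ID column")
  g <- as.matrix(raw[, setdiff(names(raw), "ID"), drop = FALSE])
  if (!all(g %in% c(0, 1, 2, NA)))
    stop("genotypes must be coded 0/1/2")
  rownames(g) <- raw$ID
  g
}
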