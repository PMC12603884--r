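## Dataset format: one delimited text table in NONMEM-like long format.
## Columns (comma separated, header mandatory):
##   ID    subject identifier (integer)
##   TIME  h since first study-drug dose (>= 0)
##   EVID  1 = dose event, 0 = observation
##   AMT   dose amount, ug (dose rows only)
##   RATE  infusion rate, ug/h (dose rows only; duration = AMT/RATE)
##   DV    observed value (conc ng/mL or COMFORT-B score; obs rows only)
##   DVID  record class: clonidine | midazolam | mid_metabolite | comfortb
##         on observation rows; drug name on dose rows (incl. propofol)
##   BLQ   1 if the observation was below the limit of quantification
##   MDV   1 if DV missing
##   CONC  driver drug concentration for score rows (individual prediction)
##   WT, PMA, PNA, SEX, ARM, SURG, TSURG  subject-level covariates repeated
##         on every row (weight kg, PMA weeks, PNA days, sex 0/1, arm label,
##         surgery 0/1, end-of-surgery time h)
## Missing numeric fields are written as "." and read as NA ("." or empty).

.ds_cols <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "DVID", "BLQ",
              "MDV", "CONC", "WT", "PMA", "PNA", "SEX", "ARM", "SURG",
              "TSURG")
.ds_num <- setdiff(.ds_cols, c("DVID", "ARM"))
.obs_classes <- c("clonidine", "midazolam", "mid_metabolite", "comfortb")
.dose_classes <- c("clonidine", "midazolam", "propofol")

#' Validate a longitudinal trial dataset
#'
#' Checks the structural invariants of the long-format dataset: required
#' columns, nonnegative and within-subject nondecreasing times, dose rows
#' without DV, observation rows without AMT, known record classes, and
#' mandatory covariates.
#'
#' @param ds data.frame in the package's dataset layout
#' @return character vector of problems (length zero when valid)
#' @export
validate_pkpd_dataset <- function(ds) {
  probs <- character(0)
  miss <- setdiff(.ds_cols, names(ds))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(is.na(ds$TIME)) || any(ds$TIME < 0))
    probs <- c(probs, "TIME must be nonnegative and nonmissing")
  for (id in unique(ds$ID)) {
    tt <- ds$TIME[ds$ID == id]
    if (is.unsorted(tt))
      probs <- c(probs, sprintf("times not nondecreasing for subject %s", id))
  }
  dose <- ds$EVID == 1
  if (any(!is.na(ds$DV[dose])))
    probs <- c(probs, "dose rows must have empty DV")
  if (any(!is.na(ds$AMT[!dose])))
    probs <- c(probs, "observation rows must have empty AMT")
  if (any(is.na(ds$AMT[dose]) | is.na(ds$RATE[dose])))
    probs <- c(probs, "dose rows need AMT and RATE")
  bad_obs <- !dose & !(ds$DVID %in% .obs_classes)
  if (any(bad_obs))
    probs <- c(probs, paste("unknown observation class:",
                            paste(unique(ds$DVID[bad_obs]), collapse = ", ")))
  bad_dose <- dose & !(ds$DVID %in% .dose_classes)
  if (any(bad_dose))
    probs <- c(probs, paste("unknown dose drug:",
                            paste(unique(ds$DVID[bad_dose]), collapse = ", ")))
  if (any(is.na(ds$WT) | is.na(ds$PMA)))
    probs <- c(probs, "covariates WT and PMA are mandatory on every row")
  obs <- !dose
  nodv <- obs & is.na(ds$DV) & !(ds$BLQ %in% 1)
  if (any(nodv & !(ds$MDV %in% 1)))
    probs <- c(probs, "observation rows without DV must be flagged MDV=1 or BLQ=1")
  probs
}

#' Read a trial dataset from delimited text
#'
#' Parses the comma-separated long-format dataset (see
#' [write_pkpd_dataset()] for the layout), converting `"."` and empty cells
#' to `NA`, and validates it. Malformed numeric fields raise an error naming
#' the offending line.
#'
#' @param path file path
#' @param validate stop on validation problems (default TRUE)
#' @return data.frame of class `pkpd_dataset`
#' @export
read_pkpd_dataset <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c(".", "", "NA"))
  miss <- setdiff(.ds_cols, names(raw))
  if (length(miss))
    stop("invalid header, missing columns: ", paste(miss, collapse = ", "))
  for (cc in .ds_num) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(!is.na(raw[[cc]]) & is.na(v))
    if (length(bad))
      stop(sprintf("malformed numeric value in column %s at line %d: '%s'",
                   cc, bad[1] + 1L, raw[[cc]][bad[1]]))
    raw[[cc]] <- v
  }
  if (validate) {
    probs <- validate_pkpd_dataset(raw)
    if (length(probs))
      stop("dataset validation failed:\n  ", paste(probs, collapse = "\n  "))
  }
  class(raw) <- c("pkpd_dataset", "data.frame")
  raw
}

#' Write a trial dataset as delimited text
#'
#' Writes the long-format dataset with missing numeric fields encoded as
#' `"."`. `read_pkpd_dataset(write_pkpd_dataset(ds, f))` preserves all
#' values up to float formatting.
#'
#' @param ds dataset (data.frame)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pkpd_dataset <- function(ds, path) {
  out <- ds[, .ds_cols]
  for (cc in names(out)) {
    v <- out[[cc]]
    v <- if (is.character(v)) ifelse(is.na(v), ".", v)
         else ifelse(is.na(v), ".", format(v, digits = 12, trim = TRUE,
                                           scientific = FALSE))
    out[[cc]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Impute observations below the limit of quantification
#'
#' Replaces the dependent value of every BLQ-flagged concentration record by
#' half the analyte's limit of quantification; all other records are
#' untouched and no record is dropped.
#'
#' @param ds dataset
#' @param loq named numeric vector of limits of quantification (ng/mL) by
#'   observation class, e.g. `c(clonidine = 0.05)`
#' @return the dataset with BLQ values imputed (MDV cleared on those rows)
#' @export
blq_impute <- function(ds, loq) {
  stopifnot(all(loq > 0))
  idx <- which(ds$EVID == 0 & ds$BLQ %in% 1)
  if (!length(idx)) return(ds)
  cls <- ds$DVID[idx]
  unknown <- setdiff(unique(cls), names(loq))
  if (length(unknown))
    stop("BLQ records present but no LOQ configured for: ",
         paste(unknown, collapse = ", "))
  ds$DV[idx] <- loq[cls] / 2
  ds$MDV[idx] <- 0
  ds
}
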