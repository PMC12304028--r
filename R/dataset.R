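## Event-record dataset dialect (NONMEM column conventions): one row per
## dose (EVID 1) or observation (EVID 0), missing values written as ".".

.DATASET_COLS <- c("ID", "TIME", "AMT", "DUR", "DV", "EVID", "MDV", "BLQ",
                   "ROUTE", "DOSENO", "BSA", "WT", "SEX", "POP", "ADA",
                   "RISK", "AGE")
.NUM_COLS <- c("TIME", "AMT", "DUR", "DV", "BSA", "WT", "AGE")
.INT_COLS <- c("EVID", "MDV", "BLQ", "DOSENO", "SEX", "POP", "ADA")

#' Validate an event-record table
#'
#' Checks the dataset invariants: required columns, dose rows with positive
#' `AMT` and no `DV`, observation rows with `EVID` 0, non-decreasing `TIME`
#' within subject, covariates constant within subject. Errors name the
#' offending rows.
#' @param d data frame.
#' @return `d`, invisibly, if valid.
#' @export
validate_dataset <- function(d) {
  miss <- setdiff(.DATASET_COLS, names(d))
  if (length(miss)) stop("validation error: missing columns ",
                         paste(miss, collapse = ", "))
  bad <- which(d$EVID == 1 & (!is.finite(d$AMT) | d$AMT <= 0))
  if (length(bad)) stop("validation error: dose rows without positive AMT: rows ",
                        paste(bad, collapse = ", "))
  bad <- which(d$EVID == 1 & !is.na(d$DV))
  if (length(bad)) stop("validation error: DV present on dose rows: rows ",
                        paste(bad, collapse = ", "))
  bad <- which(d$EVID == 0 & is.na(d$DV) & d$MDV == 0)
  if (length(bad)) stop("validation error: non-missing-flagged observations without DV: rows ",
                        paste(bad, collapse = ", "))
  for (id in unique(d$ID)) {
    rows <- which(d$ID == id)
    if (is.unsorted(d$TIME[rows]))
      stop("validation error: TIME not non-decreasing within subject ", id)
    for (cc in c("BSA", "WT", "SEX", "POP", "ADA", "RISK"))
      if (length(unique(d[[cc]][rows])) > 1)
        stop("validation error: covariate ", cc, " varies within subject ", id)
  }
  invisible(d)
}

#' Write an event-record dataset
#'
#' Deterministic column order, missing values encoded as `"."`, numeric
#' activities serialised with 6 significant digits, UTF-8.
#' @param d validated event-record data frame; @param path output CSV path.
#' @export
write_dataset <- function(d, path) {
  if (nrow(d)) validate_dataset(d)
  d <- d[, .DATASET_COLS, drop = FALSE]
  for (cc in .NUM_COLS) d[[cc]] <- ifelse(is.na(d[[cc]]), ".",
                                          formatC(d[[cc]], format = "g", digits = 6))
  for (cc in .INT_COLS) d[[cc]] <- ifelse(is.na(d[[cc]]), ".", as.character(d[[cc]]))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate an event-record dataset
#'
#' @param path CSV path in the dialect written by [write_dataset()].
#' @return typed, validated data frame.
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  miss <- setdiff(.DATASET_COLS, names(d))
  if (length(miss)) stop("validation error: missing columns ",
                         paste(miss, collapse = ", "))
  d[d == "."] <- NA
  for (cc in .NUM_COLS) d[[cc]] <- as.numeric(d[[cc]])
  for (cc in .INT_COLS) d[[cc]] <- as.integer(d[[cc]])
  d$ID <- type.convert(d$ID, as.is = TRUE)
  validate_dataset(d)
  message(sprintf("read_dataset: %d rows (%d subjects, %d observations) from %s",
                  nrow(d), length(unique(d$ID)), sum(d$EVID == 0), path))
  d
}
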