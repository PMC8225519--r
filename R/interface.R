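# Dataset reader/writer for the NONMEM-style longitudinal CSV dialect.
#
# Columns: ID, TIME (h), EVID (1 dose / 0 observation), CMT (1 serum sUA
# mg/dL / 2 urine interval amount mg), AMT (dose mg), DRUG
# (verinurad_ER8 / verinurad_MR4 / febuxostat / allopurinol), DV, MDV,
# TSTART (urine collection start, h), covariates EGFR, WEIGHT, ASIAN (0/1),
# STATUS (0 healthy / 1 asymptomatic / 2 symptomatic), ARM (label).
# Unknown extra columns are preserved on round trip. Files begin with a
# '#'-prefixed units block.

ua_units_block <- c(
  "# uric acid longitudinal dataset",
  "# units: TIME h; AMT mg; DV mg/dL (CMT 1, serum) or mg (CMT 2, urine",
  "#   interval amount over [TSTART, TIME]); EGFR mL/min/1.73m2; WEIGHT kg",
  "# codes: EVID 1 dose / 0 observation; CMT 1 serum / 2 urine;",
  "#   STATUS 0 healthy / 1 asymptomatic / 2 symptomatic")

#' Validate a longitudinal uric acid dataset
#'
#' Checks the column dialect, value codes and per-subject consistency
#' (non-decreasing times, well-formed urine collection intervals without
#' overlap, doses carrying amounts and no DV, observations carrying
#' exactly one value). All violations are aggregated into one error
#' message with row indices.
#'
#' @param df A data.frame in the dataset dialect.
#' @return The validated data.frame with class `ua_dataset`, invisibly
#'   usable downstream.
#' @export
validate_ua_dataset <- function(df) {
  required <- c("ID", "TIME", "EVID", "CMT", "AMT", "DRUG", "DV", "MDV",
                "TSTART", "EGFR", "WEIGHT", "ASIAN", "STATUS")
  problems <- character(0)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(df)) stop("no records")
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx))
      problems <<- c(problems, paste0(msg, " (rows ",
                                      paste(head(idx, 10), collapse = ", "),
                                      if (length(idx) > 10) ", ..." else "",
                                      ")"))
  }
  bad(!df$EVID %in% c(0L, 1L), "EVID must be 0 or 1")
  bad(df$TIME < 0, "negative TIME")
  is_dose <- df$EVID == 1
  bad(is_dose & (is.na(df$AMT) | df$AMT <= 0), "dose row without AMT")
  bad(is_dose & !is.na(df$DV), "dose row carries DV")
  bad(is_dose & !df$DRUG %in% c("verinurad_ER8", "verinurad_MR4",
                                "febuxostat", "allopurinol"),
      "dose row with unknown DRUG")
  is_obs <- df$EVID == 0
  bad(is_obs & is.na(df$DV), "observation row without DV")
  bad(is_obs & !df$CMT %in% c(1L, 2L), "observation CMT must be 1 or 2")
  is_urine <- is_obs & df$CMT == 2
  bad(is_urine & (is.na(df$TSTART) | df$TSTART >= df$TIME),
      "urine row needs TSTART < TIME")
  for (id in unique(df$ID)) {
    d <- df[df$ID == id, , drop = FALSE]
    if (is.unsorted(d$TIME))
      problems <- c(problems, paste0("non-monotone times for subject ", id))
    u <- d[d$EVID == 0 & d$CMT == 2, , drop = FALSE]
    if (nrow(u) > 1) {
      o <- order(u$TSTART)
      if (any(u$TSTART[o][-1] < u$TIME[o][-nrow(u)]))
        problems <- c(problems,
                      paste0("overlapping urine intervals for subject ", id))
    }
  }
  if (length(problems))
    stop("dataset validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  if (!inherits(df, "ua_dataset")) class(df) <- c("ua_dataset", "data.frame")
  df
}

#' Write a dataset in the longitudinal CSV dialect
#'
#' Deterministic column order and float formatting, so two writes of the
#' same dataset are byte-identical. A truth sidecar (when present as
#' `attr(dataset, "truth")`) is written next to the file as JSON.
#'
#' @param dataset A `ua_dataset`.
#' @param path Output CSV path; the sidecar (if any) goes to
#'   `paste0(path, ".truth.json")`.
#' @return `path`, invisibly.
#' @export
write_ua_dataset <- function(dataset, path) {
  df <- as.data.frame(dataset)
  known <- c("ID", "TIME", "EVID", "CMT", "AMT", "DRUG", "DV", "MDV",
             "TSTART", "EGFR", "WEIGHT", "ASIAN", "STATUS", "ARM")
  cols <- c(intersect(known, names(df)), setdiff(names(df), known))
  df <- df[, cols, drop = FALSE]
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", sprintf("%.12g", x))
    else as.character(x)
  }
  body <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) body <- matrix(body, nrow = 1)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(ua_units_block, con)
  writeLines(paste(cols, collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  truth <- attr(dataset, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         dataframe = "columns", digits = NA, na = "null")
  invisible(path)
}

#' Read a dataset in the longitudinal CSV dialect
#'
#' Skips the '#'-prefixed units block, validates the dialect (aggregated
#' per-row error reporting) and attaches the truth sidecar when one sits
#' next to the file.
#'
#' @param path CSV path written by [write_ua_dataset()] (or compatible).
#' @return A validated `ua_dataset` data.frame.
#' @export
read_ua_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no records")
  df <- validate_ua_dataset(df)
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    tr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(df, "truth") <- as.data.frame(tr)
  }
  df
}
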