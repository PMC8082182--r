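#' @keywords internal
tdm_columns <- function() {
  c("ID", "TIME", "AMT", "RATE", "EVID", "MDV", "DV", "BLQ", "LLOQ",
    "AGE", "WT", "HT", "SCR", "CLCR", "SEX")
}

required_tdm_columns <- function() {
  c("ID", "TIME", "AMT", "RATE", "EVID", "MDV", "DV", "AGE", "WT")
}

#' Construct a TDM event dataset
#'
#' Wraps a data.frame of dose and observation events in the NONMEM-style
#' column dialect (\code{ID, TIME, AMT, RATE, EVID, MDV, DV} plus covariate
#' columns) as a \code{tdm_dataset}. \code{EVID = 1} rows are doses
#' (\code{AMT} mg infused at \code{RATE} mg/h), \code{EVID = 0} rows are
#' concentration observations (\code{DV} mg/L). \code{BLQ} flags
#' observations below the lower limit of quantification \code{LLOQ}.
#'
#' @param df a data.frame with at least the required columns.
#' @param source character label recording provenance (file path or
#'   \code{"synthetic"}).
#' @param seed integer seed when the dataset is synthetic.
#' @return A data.frame of class \code{tdm_dataset}.
#' @export
tdm_dataset <- function(df, source = "in-memory", seed = NULL) {
  miss <- setdiff(required_tdm_columns(), names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"BLQ" %in% names(df)) df$BLQ <- 0L
  if (!"LLOQ" %in% names(df)) df$LLOQ <- NA_real_
  key <- interaction(df$ID, df$TIME, df$EVID, drop = TRUE)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (subject, time, evid) records at row(s): ",
         paste(utils::head(rows, 10), collapse = ", "), call. = FALSE)
  }
  df <- df[order(match(df$ID, unique(df$ID)), df$TIME, -df$EVID), ,
           drop = FALSE]
  rownames(df) <- NULL
  attr(df, "source") <- source
  attr(df, "seed") <- seed
  class(df) <- c("tdm_dataset", "data.frame")
  df
}

#' Read a TDM event dataset from delimited text
#'
#' Reads a comma-delimited NONMEM-style event file (header row; \code{"."}
#' for missing values). Observation rows with \code{DV} below \code{LLOQ}
#' are flagged \code{BLQ}; the BLQ handling policy itself is applied
#' downstream (fitting excludes BLQ rows by default).
#'
#' @param path path to a CSV file.
#' @return A \code{\link{tdm_dataset}}.
#' @export
read_tdm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, na.strings = c(".", "NA", ""))
  miss <- setdiff(required_tdm_columns(), names(raw))
  if (length(miss))
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(intersect(tdm_columns(), names(raw)), "SEX")
  for (nm in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(!is.na(raw[[nm]]) & is.na(v))
    if (length(bad))
      stop("unparseable value in column ", nm, " at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    raw[[nm]] <- v
  }
  raw$EVID <- as.integer(raw$EVID)
  raw$MDV <- as.integer(raw$MDV)
  if ("BLQ" %in% names(raw)) raw$BLQ <- as.integer(raw$BLQ)
  ds <- tdm_dataset(raw, source = path)
  obs <- ds$EVID == 0
  lloq_known <- !is.na(ds$LLOQ)
  ds$BLQ[obs & lloq_known & !is.na(ds$DV) & ds$DV < ds$LLOQ] <- 1L
  ds
}

#' Write a TDM event dataset as delimited text
#'
#' Lossless, stable-column-order serialization; missing values are written
#' as \code{"."}. \code{write_tdm} followed by \code{\link{read_tdm}} is an
#' identity on the numeric content.
#'
#' @param ds a \code{\link{tdm_dataset}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_tdm <- function(ds, path) {
  cols <- c(intersect(tdm_columns(), names(ds)),
            setdiff(names(ds), tdm_columns()))
  out <- as.data.frame(ds)[, cols, drop = FALSE]
  for (nm in names(out)) {
    v <- out[[nm]]
    out[[nm]] <- ifelse(is.na(v), ".", format(v, trim = TRUE, digits = 15,
                                              scientific = FALSE))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a TDM dataset
#'
#' Pure reporting operation: returns an ordered table of diagnostics with
#' severity \code{"fatal"} or \code{"warning"} and never modifies the data.
#' Fatal issues include observations before any dose, subjects without dose
#' records, non-positive weights, and dose rows with non-positive amounts.
#'
#' @param ds a \code{\link{tdm_dataset}}.
#' @return A data.frame with columns \code{severity}, \code{subject},
#'   \code{message}; zero rows when the dataset is clean.
#' @export
validate_tdm <- function(ds) {
  issues <- list()
  add <- function(severity, subject, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, subject = as.character(subject),
      message = message, stringsAsFactors = FALSE)
  }
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, , drop = FALSE]
    doses <- sub[sub$EVID == 1, , drop = FALSE]
    obs <- sub[sub$EVID == 0, , drop = FALSE]
    if (nrow(doses) == 0)
      add("fatal", id, "subject has no dose records")
    if (any(doses$AMT <= 0, na.rm = TRUE) || any(is.na(doses$AMT)))
      add("fatal", id, "dose record with missing or non-positive AMT")
    if (any(doses$MDV != 1, na.rm = TRUE))
      add("warning", id, "dose record with MDV != 1")
    if (nrow(doses) > 0 && nrow(obs) > 0 &&
        any(obs$TIME < min(doses$TIME)))
      add("fatal", id, "observation before first dose")
    if (any(obs$MDV == 0 & is.na(obs$DV) & obs$BLQ != 1))
      add("fatal", id, "observation with missing DV not flagged BLQ")
    if (any(obs$DV < 0, na.rm = TRUE))
      add("fatal", id, "negative observed concentration")
    if (any(sub$TIME < 0))
      add("fatal", id, "negative event time")
    if (is.unsorted(sub$TIME))
      add("warning", id, "event times not non-decreasing")
    for (nm in intersect(c("AGE", "WT", "HT", "SCR", "CLCR", "SEX"),
                         names(sub))) {
      if (length(unique(sub[[nm]][!is.na(sub[[nm]])])) > 1)
        add("fatal", id, paste0("time-varying covariate ", nm))
    }
    if (any(sub$WT <= 0, na.rm = TRUE))
      add("fatal", id, "non-positive weight (WT)")
  }
  if (length(issues) == 0)
    return(data.frame(severity = character(), subject = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Per-subject covariate table of a TDM dataset
#'
#' @param ds a \code{\link{tdm_dataset}}.
#' @return A \code{\link{patient_covariates}} table with one row per subject
#'   in order of first appearance.
#' @export
tdm_covariates <- function(ds) {
  first <- ds[!duplicated(ds$ID), , drop = FALSE]
  patient_covariates(age = first$AGE, weight = first$WT,
                     height = if ("HT" %in% names(first)) first$HT else NA,
                     scr = if ("SCR" %in% names(first)) first$SCR else NA,
                     clcr = if ("CLCR" %in% names(first)) first$CLCR else NA,
                     sex = if ("SEX" %in% names(first)) first$SEX else NA,
                     id = first$ID)
}

#' Read or write a structured configuration file
#'
#' Configuration files (YAML) carry fitting and simulation settings:
#' parameter values, seeds, regimen grids, sampling-design fields. The
#' reader returns the raw named list; interpreting it (e.g. building a
#' \code{\link{fit_config}} or \code{\link{pta_grid_spec}}) is the
#' caller's responsibility.
#'
#' @param path file path.
#' @return \code{read_config}: a named list. \code{write_config}:
#'   invisibly, \code{path}.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config a named list to serialize.
#' @export
write_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write configuration files",
         call. = FALSE)
  yaml::write_yaml(config, path)
  invisible(path)
}
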