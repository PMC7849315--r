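#' @title Tidy observation tables
#'
#' @description The pipeline's single measurement format: one row per
#' observation with columns `condition` (`ammonium`/`nitrate`), `tissue`
#' (`epidermis`/`cortex`), `position` (integer 1-20 from the QC),
#' `replicate` (root id), `measurement` and `value`. Recognized
#' measurements are `length` (micrometres, > 0), `pin2_apical`,
#' `pin2_basal`, `pin2_outer` (membrane fluorescence, >= 0) and
#' `relative_auxin` (in [0, 1]).
#'
#' @param df a data frame to validate.
#' @return `df` with canonical column order, invisibly classed as valid;
#'   errors list the offending row numbers.
#' @export
validate_observations <- function(df) {
  cols <- c("condition", "tissue", "position", "replicate", "measurement",
            "value")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("observation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, cols, drop = FALSE]
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      stop("invalid observation rows (", what, "): ",
           paste(utils::head(rows, 10), collapse = ", "),
           if (length(rows) > 10) " ..." else "", call. = FALSE)
    }
  }
  bad(!df$condition %in% c("ammonium", "nitrate"), "condition")
  bad(!df$tissue %in% c("epidermis", "cortex"), "tissue")
  bad(!is.finite(df$position) | df$position < 1 |
        df$position != round(df$position), "position")
  meas <- c("length", "pin2_apical", "pin2_basal", "pin2_outer",
            "relative_auxin")
  bad(!df$measurement %in% meas, "measurement")
  bad(!is.finite(df$value), "non-finite value")
  bad(df$measurement == "length" & df$value <= 0, "non-positive length")
  bad(df$measurement %in% c("pin2_apical", "pin2_basal", "pin2_outer") &
        df$value < 0, "negative intensity")
  bad(df$measurement == "relative_auxin" & (df$value < 0 | df$value > 1),
      "relative_auxin outside [0, 1]")
  invisible(df)
}

#' Read / write observation tables as CSV
#'
#' Plain UTF-8 CSV with the canonical column order; values round-trip at
#' full precision. Reading validates the schema and errors with offending
#' row numbers.
#'
#' @param df an observation table.
#' @param path file path.
#' @return `read_observations()` returns the validated data frame;
#'   `write_observations()` returns `path` invisibly.
#' @export
write_observations <- function(df, path) {
  validate_observations(df)
  cols <- c("condition", "tissue", "position", "replicate", "measurement",
            "value")
  utils::write.csv(df[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8",
                        colClasses = c(condition = "character",
                                       tissue = "character",
                                       position = "integer",
                                       replicate = "character",
                                       measurement = "character",
                                       value = "numeric"))
  validate_observations(df)
  df
}
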