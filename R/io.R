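# Tidy delimited I/O for observation tables, plus input validation.

tc_columns <- c("time_s", "value", "mode", "variant", "dtnb_uM",
                "coenzyme", "co_mM", "replicate", "seed")

#' Write time courses to a tidy CSV
#'
#' One row per observation, columns `time_s`, `value`, `mode`, `variant`,
#' `dtnb_uM`, `coenzyme`, `co_mM`, `replicate`, `seed`.
#'
#' @param x a `study`, a list of `time_course` objects, a single
#'   `time_course`, or a data frame already in the tidy layout.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(x, path) {
  df <- if (is.data.frame(x)) {
    x
  } else if (inherits(x, "study") || inherits(x, "time_course")) {
    as.data.frame(x)
  } else if (is.list(x)) {
    do.call(rbind, lapply(x, as.data.frame))
  } else {
    stop_shprotect("cannot coerce input to a time-course table",
                   "shprotect_usage_error")
  }
  missing_cols <- setdiff(setdiff(tc_columns, c("replicate", "seed")),
                          names(df))
  if (length(missing_cols)) {
    stop_shprotect(paste("missing columns:",
                         paste(missing_cols, collapse = ", ")),
                   "shprotect_schema_error")
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (!"seed" %in% names(df)) df$seed <- NA_integer_
  write.csv(df[, tc_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy time-course CSV
#'
#' @param path file written by [write_timecourses] (or hand-assembled in
#'   the same layout).
#' @return data frame of observations.
#' @export
read_timecourses <- function(path) {
  if (!file.exists(path)) {
    stop_shprotect(sprintf("cannot read '%s': no such file", path),
                   "shprotect_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(tc_columns, c("replicate", "seed")),
                          names(df))
  if (length(missing_cols)) {
    stop_shprotect(paste0("schema error in '", path, "': missing columns ",
                          paste(missing_cols, collapse = ", ")),
                   "shprotect_schema_error")
  }
  df
}

series_label <- function(df) {
  paste0(df$variant, "/", df$mode, "/DTNB ", df$dtnb_uM, " uM/",
         df$coenzyme, " ", df$co_mM, " mM/rep ",
         if ("replicate" %in% names(df)) df$replicate else 1L)
}

#' Validate an observation table before analysis
#'
#' Checks the column schema, per-series time monotonicity, duplicate
#' observations, concentration signs and value ranges. Problems are
#' collected rather than thrown, separated into errors (analysis would be
#' wrong) and warnings (suspicious but fittable).
#'
#' @param path CSV file, or a data frame already read.
#' @return an object of class `validation_report`: data frame with columns
#'   `severity`, `check`, `series`, `message`, and attribute `ok` (TRUE
#'   when no errors). An unreadable file is an immediate error condition.
#' @export
validate_inputs <- function(path) {
  df <- if (is.data.frame(path)) path else read_timecourses(path)
  issues <- list()
  note <- function(severity, check, series, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, check = check, series = series,
      message = message, stringsAsFactors = FALSE)
  }
  if (!"replicate" %in% names(df)) {
    note("warning", "schema", NA_character_,
         "no replicate column; assuming a single replicate")
    df$replicate <- 1L
  }
  bad_mode <- setdiff(unique(df$mode), c("activity", "absorbance"))
  if (length(bad_mode)) {
    note("error", "schema", NA_character_,
         paste("unknown mode value(s):", paste(bad_mode, collapse = ", ")))
  }
  if (any(!is.finite(df$time_s) | df$time_s < 0)) {
    note("error", "times", NA_character_, "negative or non-finite times")
  }
  if (any(df$dtnb_uM <= 0, na.rm = TRUE)) {
    note("error", "concentrations", NA_character_,
         "non-positive DTNB concentrations")
  }
  if (any(df$co_mM < 0, na.rm = TRUE)) {
    note("error", "concentrations", NA_character_,
         "negative coenzyme concentrations")
  }
  key <- interaction(df$variant, df$mode, df$dtnb_uM, df$coenzyme,
                     df$co_mM, df$replicate, drop = TRUE)
  for (g in split(df, key)) {
    lab <- series_label(g[1, ])
    if (anyDuplicated(g$time_s)) {
      note("error", "duplicates", lab, "duplicate time points within series")
    } else if (is.unsorted(g$time_s, strictly = TRUE)) {
      note("error", "monotonicity", lab,
           "times are not strictly increasing")
    }
    if (nrow(g) < 3) {
      note("warning", "size", lab, "fewer than 3 observations")
    }
    if (g$mode[1] == "activity" && any(g$value > 1.5)) {
      note("warning", "range", lab, "activity fractions above 1.5")
    }
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), check = character(),
               series = character(), message = character(),
               stringsAsFactors = FALSE)
  attr(out, "ok") <- !any(out$severity == "error")
  class(out) <- c("validation_report", class(out))
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("validation: clean (no issues)\n")
  } else {
    cat(sprintf("validation: %d error(s), %d warning(s)\n",
                sum(x$severity == "error"), sum(x$severity == "warning")))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}
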