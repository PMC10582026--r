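# The subject x timepoint outcome matrix feeding the trial statistics.

#' Construct a trial table
#'
#' Long-format outcome table with one row per (subject, timepoint) and one
#' column per named outcome; every outcome column must declare a unit.
#'
#' @param data a data.frame with columns `subject_id`, `group`
#'   (`"COMB"`/`"MICT"`), `timepoint` (`"W0"`/`"W3"`) and numeric outcome
#'   columns.
#' @param units named character vector mapping every outcome column to its
#'   unit string.
#' @return a data.frame of class `trial_table` with a `units` attribute.
#' @export
trial_table <- function(data, units) {
  need <- c("subject_id", "group", "timepoint")
  if (!all(need %in% names(data)))
    stop_domain("trial table needs subject_id, group and timepoint columns")
  if (anyDuplicated(data[, c("subject_id", "timepoint")]))
    stop_domain("at most one row per (subject_id, timepoint)")
  if (!all(data$timepoint %in% c("W0", "W3")))
    stop_domain("timepoint must be W0 or W3")
  outcomes <- setdiff(names(data), need)
  missing_units <- setdiff(outcomes, names(units))
  if (length(missing_units))
    stop_domain("no unit declared for outcome(s): ",
                paste(missing_units, collapse = ", "))
  attr(data, "units") <- units[outcomes]
  class(data) <- c("trial_table", "data.frame")
  data
}

#' Outcome columns of a trial table
#' @param table a [trial_table()].
#' @return character vector of outcome column names.
#' @export
trial_outcomes <- function(table) {
  setdiff(names(table), c("subject_id", "group", "timepoint"))
}

#' Write a trial table as tidy CSV with a units sidecar header
#'
#' The first line is a `# units:` comment (`name=unit` pairs); numeric
#' cells are written with 17 significant digits so the file re-imports
#' bit-identically.
#'
#' @param table a [trial_table()].
#' @param path destination.
#' @export
write_trial_table <- function(table, path) {
  units <- attr(table, "units")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ",
                    paste(names(units), units, sep = "=", collapse = ";")),
             con)
  out <- as.data.frame(table)
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trial_table()]
#' @param path file to read.
#' @return a [trial_table()].
#' @export
read_trial_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# units:", first))
    stop_domain("missing '# units:' sidecar header in ", path)
  pairs <- strsplit(trimws(sub("^# units:", "", first)), ";")[[1L]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  units <- setNames(vapply(kv, `[[`, character(1), 2L),
                    vapply(kv, `[[`, character(1), 1L))
  data <- read.table(path, header = TRUE, sep = ",", skip = 1L,
                     stringsAsFactors = FALSE,
                     colClasses = c(subject_id = "character"))
  trial_table(data, units)
}
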