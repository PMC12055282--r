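#' Read and validate an event table
#'
#' Reads a comma-delimited event table (one row per signalling event x
#' behaviour x observation window) and validates it against the schema:
#' required columns `individual_id`, `site`, `activity`, `period`,
#' `duration_s`, `behaviour`, `occurred` (an `event_id` column is
#' optional but needed by [collapse_periods()]); `activity` in
#' drum / stone_and_drum / stone, `period` in before / after / combined,
#' `occurred` in 0/1, `duration_s >= 1`, no missing values. Violations are
#' reported with the offending file line numbers.
#'
#' @param path path to a UTF-8 CSV file with a header row
#' @return validated data frame; attribute `counts` holds the record
#'   counts per (behaviour, period, activity)
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8"),
                error = function(e) stop("cannot read '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (nrow(d) == 0) stop("empty event table: ", path, call. = FALSE)
  required <- c("individual_id", "site", "activity", "period", "duration_s",
                "behaviour", "occurred")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  line <- seq_len(nrow(d)) + 1L # header is file line 1

  fail <- function(what, bad, values = NULL) {
    stop(what,
         if (!is.null(values)) paste0(" (offending values: ",
                                      paste(unique(values), collapse = ", "), ")"),
         " on line(s) ", paste(head(line[bad], 10), collapse = ", "),
         if (sum(bad) > 10) " ...", call. = FALSE)
  }
  na_bad <- !complete.cases(d[required])
  if (any(na_bad)) fail("missing values in model columns", na_bad)
  bad <- !(d$activity %in% .ACTIVITIES)
  if (any(bad)) fail("unknown activity label", bad, d$activity[bad])
  bad <- !(d$period %in% .PERIODS)
  if (any(bad)) fail("unknown period label", bad, d$period[bad])
  bad <- !(d$behaviour %in% .BEHAVIOURS)
  if (any(bad)) fail("unknown behaviour label", bad, d$behaviour[bad])
  occ <- suppressWarnings(as.numeric(d$occurred))
  bad <- is.na(occ) | !(occ %in% c(0, 1))
  if (any(bad)) fail("'occurred' must be 0 or 1", bad, d$occurred[bad])
  dur <- suppressWarnings(as.numeric(d$duration_s))
  bad <- is.na(dur) | dur < 1
  if (any(bad)) fail("'duration_s' must be a duration >= 1", bad,
                     d$duration_s[bad])
  d$occurred <- as.integer(occ)
  d$duration_s <- dur
  # canonical factor coding: drumming is the reference level
  d$activity <- factor(d$activity, levels = .ACTIVITIES)
  counts <- as.data.frame(table(behaviour = d$behaviour, period = d$period,
                                activity = d$activity),
                          responseName = "n")
  attr(d, "counts") <- counts[counts$n > 0, ]
  d
}

#' Write an event table
#'
#' Writes the comma-delimited event-table format read back by
#' [read_events()].
#'
#' @param data event-table data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_events <- function(data, path) {
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Record counts per behaviour, period and activity
#'
#' @param data event-table data frame
#' @return data frame of non-zero counts
#' @export
event_counts <- function(data) {
  counts <- as.data.frame(table(behaviour = data$behaviour,
                                period = data$period,
                                activity = data$activity),
                          responseName = "n")
  counts[counts$n > 0, ]
}
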