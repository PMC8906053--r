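# Fluorescence time-series records and tabular results I/O.
# A trace record is a tibble with a `time_s` column plus either a single
# intensity column `F` (Fluo-4 style) or the pair `F410`, `F485`
# (ratiometric Indo-1). Per-channel backgrounds and the stimulation
# frequency ride along as attributes.

#' Create a trace record
#'
#' @param time_s Strictly increasing sample times (seconds).
#' @param channels Named list of one (`F`) or two (`F410`, `F485`)
#'   numeric intensity series, all the same length as `time_s`.
#' @param background Optional named per-channel background scalars.
#' @param stim_freq_hz Optional field-stimulation frequency (Hz).
#' @return A `trace_record` tibble.
#' @export
trace_record <- function(time_s, channels, background = NULL,
                         stim_freq_hz = NULL) {
  if (!is.numeric(time_s) || length(time_s) < 2L) {
    stop_contract("`time_s` must be a numeric vector of length >= 2")
  }
  if (any(diff(time_s) <= 0)) stop_contract("`time_s` must be strictly increasing")
  if (!is.list(channels) || !length(channels) %in% 1:2) {
    stop_contract("`channels` must be a named list of 1 or 2 series")
  }
  nm <- names(channels)
  if (length(channels) == 1L && !identical(nm, "F")) {
    stop_contract("a single channel must be named 'F'")
  }
  if (length(channels) == 2L && !setequal(nm, c("F410", "F485"))) {
    stop_contract("two channels must be named exactly 'F410' and 'F485'")
  }
  for (ch in nm) {
    if (length(channels[[ch]]) != length(time_s)) {
      stop_contract("channel '%s' length %d != time length %d",
                    ch, length(channels[[ch]]), length(time_s))
    }
  }
  out <- tibble::tibble(time_s = time_s, !!!channels)
  structure(out,
            background = background,
            stim_freq_hz = stim_freq_hz,
            class = c("trace_record", class(out)))
}

trace_channels <- function(t) setdiff(names(t), "time_s")

#' Read a fluorescence trace from CSV
#'
#' Expects a `time_s` column and either one intensity column (renamed to
#' `F` if needed) or the ratiometric pair `F410`/`F485`. Rows are sorted
#' by time with a log message if out of order.
#'
#' @param path Path to a CSV file.
#' @param stim_freq_hz Optional stimulation frequency to attach.
#' @return A [trace_record()].
#' @export
read_trace_csv <- function(path, stim_freq_hz = NULL) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_format("cannot read CSV '%s': %s",
                                                 path, conditionMessage(e)))
  if (!"time_s" %in% names(df)) stop_format("'%s' has no 'time_s' column", path)
  val_cols <- setdiff(names(df), "time_s")
  if (length(val_cols) == 0L) stop_format("'%s' has no intensity columns", path)
  for (cl in c("time_s", val_cols)) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) stop_format("non-numeric value in column '%s', row %d",
                                   cl, bad[1])
      df[[cl]] <- vn
    }
    if (anyNA(df[[cl]])) {
      stop_format("missing value in column '%s', row %d", cl,
                  which(is.na(df[[cl]]))[1])
    }
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    cq_log("rows of '%s' not time-sorted; sorting", path)
    df <- df[order(df$time_s), , drop = FALSE]
  }
  if (length(val_cols) == 1L) {
    channels <- list(F = df[[val_cols]])
  } else if (setequal(val_cols, c("F410", "F485"))) {
    channels <- list(F410 = df$F410, F485 = df$F485)
  } else {
    stop_format("intensity columns must be a single channel or F410/F485; got: %s",
                paste(val_cols, collapse = ", "))
  }
  trace_record(df$time_s, channels, stim_freq_hz = stim_freq_hz)
}

#' Write a results table to CSV
#'
#' Accepts a data frame or a list of flat named records sharing one key
#' set; numeric values are written at full float precision.
#'
#' @param records Data frame, or list of named lists/vectors.
#' @param path Output path.
#' @param schema Optional character vector of column names; required to
#'   write a header-only file from an empty record list.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, schema = NULL) {
  if (is.data.frame(records)) {
    df <- tibble::as_tibble(records)
  } else if (is.list(records)) {
    if (length(records) == 0L) {
      if (is.null(schema)) {
        stop_contract("empty record list requires an explicit `schema`")
      }
      df <- tibble::as_tibble(setNames(rep(list(numeric(0)), length(schema)),
                                       schema))
    } else {
      keys <- names(records[[1]])
      for (i in seq_along(records)) {
        miss <- setdiff(keys, names(records[[i]]))
        extra <- setdiff(names(records[[i]]), keys)
        if (length(miss) || length(extra)) {
          stop_contract("record %d key mismatch; missing: [%s], extra: [%s]", i,
                        paste(miss, collapse = ", "),
                        paste(extra, collapse = ", "))
        }
      }
      df <- dplyr::bind_rows(lapply(records, function(r)
        tibble::as_tibble(as.list(r))))
    }
  } else {
    stop_contract("`records` must be a data frame or list of records")
  }
  readr::write_csv(df, path, na = "NaN")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("NA", "NaN"))
}
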