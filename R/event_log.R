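# Event-log containers and CSV / XES input-output.
#
# An event log is the universal currency of the package: a set of process
# cases, each an ordered sequence of (activity, timestamp) events with
# optional per-case context attributes.  Timestamps are stored as plain
# numbers in the log's declared unit (seconds or hours) from an arbitrary
# epoch; ISO-8601 strings are converted on read.

PAD_LABEL <- "[pad]"

#' Construct a process case
#'
#' @param case_id Case identifier (coerced to character).
#' @param activities Character vector of activity labels.
#' @param timestamps Numeric vector of event timestamps (same length as
#'   `activities`), non-decreasing after sorting.
#' @param contexts Optional named list of per-case context attributes.
#' @return A `process_case` object.
#' @export
process_case <- function(case_id, activities, timestamps, contexts = NULL) {
  stopifnot(length(activities) == length(timestamps),
            length(activities) >= 1L)
  if (any(!nzchar(activities)) || anyNA(activities)) {
    stop("activity labels must be non-empty")
  }
  if (any(!is.finite(timestamps))) stop("timestamps must be finite")
  ord <- order(timestamps)  # stable: ties keep input order
  structure(list(case_id = as.character(case_id),
                 activities = as.character(activities)[ord],
                 timestamps = as.numeric(timestamps)[ord],
                 contexts = contexts),
            class = "process_case")
}

#' Total duration of a process case
#'
#' Defined as the last event timestamp minus the first.  Single-event cases
#' have duration 0, and the value is invariant under shifting all
#' timestamps by a constant.
#'
#' @param case A `process_case`.
#' @return Non-negative numeric duration in the log's time unit.
#' @export
case_duration <- function(case) {
  ts <- case$timestamps
  ts[length(ts)] - ts[1L]
}

#' Build an activity vocabulary
#'
#' Labels are the sorted distinct activities plus a reserved padding token
#' `"[pad]"` appended as the last index, so encodings are deterministic
#' across runs.
#'
#' @param labels Character vector of observed activity labels.
#' @return A list with `labels` (length `N_v + 1`) and `pad_index`.
#' @export
activity_vocabulary <- function(labels) {
  labels <- sort(unique(as.character(labels)))
  if (PAD_LABEL %in% labels) {
    stop("the label '", PAD_LABEL, "' is reserved for padding")
  }
  all <- c(labels, PAD_LABEL)
  list(labels = all, pad_index = length(all), n_real = length(labels))
}

#' Construct an event log from a list of cases
#'
#' @param cases List of `process_case` objects.
#' @param time_unit `"seconds"` or `"hours"` (metadata only).
#' @return An `event_log` with a vocabulary (including the pad token) and
#'   duration bounds `(T_min, T_max)` computed from the case durations.
#' @export
event_log <- function(cases, time_unit = "seconds") {
  if (length(cases) == 0L) stop("event log must contain at least one case")
  time_unit <- match.arg(time_unit, c("seconds", "hours"))
  vocab <- activity_vocabulary(unlist(lapply(cases, `[[`, "activities")))
  durs <- vapply(cases, case_duration, numeric(1))
  structure(list(cases = cases,
                 vocabulary = vocab,
                 duration_bounds = c(min(durs), max(durs)),
                 time_unit = time_unit),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  lens <- vapply(x$cases, function(cs) length(cs$activities), integer(1))
  cat(sprintf("event_log: %d cases, %d activity types (+pad), lengths %d-%d\n",
              length(x$cases), x$vocabulary$n_real, min(lens), max(lens)))
  cat(sprintf("  duration bounds: [%.4g, %.4g] %s\n",
              x$duration_bounds[1L], x$duration_bounds[2L], x$time_unit))
  ctx <- context_names(x)
  if (length(ctx)) cat("  contexts:", paste(ctx, collapse = ", "), "\n")
  invisible(x)
}

#' Names of the context attributes present in a log
#' @param log An `event_log`.
#' @return Character vector (possibly empty).
#' @export
context_names <- function(log) {
  unique(unlist(lapply(log$cases, function(cs) names(cs$contexts))))
}

#' Case lengths of a log
#' @param log An `event_log`.
#' @return Integer vector of event counts per case.
#' @export
case_lengths <- function(log) {
  vapply(log$cases, function(cs) length(cs$activities), integer(1))
}

#' Case durations of a log
#' @param log An `event_log`.
#' @return Numeric vector of durations.
#' @export
case_durations <- function(log) {
  vapply(log$cases, case_duration, numeric(1))
}

#' Convert an event log to a long data frame
#'
#' One row per event, columns `case_id`, `activity`, `timestamp` and one
#' `context_<name>` column per context attribute (constant within a case).
#'
#' @param x An `event_log`.
#' @param ... Unused.
#' @return A `data.frame` sorted by case (order of appearance) then time.
#' @export
as.data.frame.event_log <- function(x, ...) {
  ctx <- context_names(x)
  rows <- lapply(x$cases, function(cs) {
    df <- data.frame(case_id = cs$case_id,
                     activity = cs$activities,
                     timestamp = cs$timestamps,
                     stringsAsFactors = FALSE)
    for (nm in ctx) {
      val <- cs$contexts[[nm]]
      df[[paste0("context_", nm)]] <- if (is.null(val)) NA else val
    }
    df
  })
  do.call(rbind, rows)
}

parse_timestamps <- function(x, path) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  # fall back to ISO-8601; report the first offending row on failure
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d")
  parse1 <- function(xx) {
    tryCatch(as.numeric(as.POSIXct(xx, tz = "UTC", tryFormats = fmts)),
             error = function(e) NA_real_)
  }
  tm <- tryCatch(
    as.numeric(as.POSIXct(x, tz = "UTC", tryFormats = fmts)),
    error = function(e) vapply(x, parse1, numeric(1), USE.NAMES = FALSE))
  tm[is.na(tm)] <- num[is.na(tm)]
  bad <- which(is.na(tm))
  if (length(bad)) {
    stop(sprintf("unparseable timestamp '%s' at row %d of %s",
                 x[bad[1L]], bad[1L], path))
  }
  tm
}

#' Read an event log from CSV
#'
#' Expects a UTF-8 CSV with a header.  Timestamps may be numeric or
#' ISO-8601; ISO-8601 values are converted to numeric seconds (or hours)
#' from the epoch.  Columns named `context_<name>` are attached as per-case
#' context attributes (they must be constant within a case; the first value
#' is used).  Cases are grouped by case id (order of first appearance) and
#' events sorted by timestamp with a stable sort.
#'
#' @param path CSV file path.
#' @param mapping Named character vector mapping the internal column roles
#'   `case_id`, `activity`, `timestamp` to the file's column names.
#' @param time_unit `"seconds"` or `"hours"`.  ISO-8601 input is converted
#'   into this unit.
#' @return An `event_log`.
#' @export
read_event_log <- function(path,
                           mapping = c(case_id = "case_id",
                                       activity = "activity",
                                       timestamp = "timestamp"),
                           time_unit = "seconds") {
  if (!file.exists(path)) stop("file not found: ", path)
  time_unit <- match.arg(time_unit, c("seconds", "hours"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- unname(mapping[c("case_id", "activity", "timestamp")])
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty event log: ", path)
  ts <- parse_timestamps(as.character(df[[mapping[["timestamp"]]]]), path)
  iso <- anyNA(suppressWarnings(as.numeric(df[[mapping[["timestamp"]]]])))
  if (iso && time_unit == "hours") ts <- ts / 3600
  cid <- as.character(df[[mapping[["case_id"]]]])
  act <- as.character(df[[mapping[["activity"]]]])
  ctx_cols <- grep("^context_", names(df), value = TRUE)
  ids <- unique(cid)
  cases <- lapply(ids, function(id) {
    sel <- cid == id
    contexts <- NULL
    if (length(ctx_cols)) {
      contexts <- stats::setNames(
        lapply(ctx_cols, function(cc) df[[cc]][sel][1L]),
        sub("^context_", "", ctx_cols))
    }
    process_case(id, act[sel], ts[sel], contexts)
  })
  event_log(cases, time_unit = time_unit)
}

#' Write an event log to CSV
#'
#' Emits `case_id, activity, timestamp[, context_*]`, sorted by case then
#' timestamp.  Numeric timestamps round-trip within 1e-9.
#'
#' @param log An `event_log`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_event_log <- function(log, path) {
  df <- as.data.frame(log)
  df$timestamp <- formatC(df$timestamp, format = "g", digits = 17)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write event log to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read an XES event log
#'
#' Minimal import of the XES standard: `concept:name` becomes the activity,
#' `time:timestamp` the timestamp; trace-level `concept:name` becomes the
#' case id.  Other attributes are ignored.
#'
#' @param path XES file path.
#' @param time_unit `"seconds"` or `"hours"`.
#' @return An `event_log`.
#' @export
read_xes <- function(path, time_unit = "seconds") {
  if (!file.exists(path)) stop("file not found: ", path)
  time_unit <- match.arg(time_unit, c("seconds", "hours"))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  traces <- xml2::xml_find_all(doc, ".//trace")
  if (length(traces) == 0L) stop("empty XES log: ", path)
  cases <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    id_node <- xml2::xml_find_first(tr, "./string[@key='concept:name']")
    cid <- if (inherits(id_node, "xml_missing")) paste0("trace_", i) else
      xml2::xml_attr(id_node, "value")
    evs <- xml2::xml_find_all(tr, "./event")
    acts <- vapply(evs, function(ev) {
      xml2::xml_attr(xml2::xml_find_first(ev, "./string[@key='concept:name']"),
                     "value")
    }, character(1))
    tss <- vapply(evs, function(ev) {
      xml2::xml_attr(xml2::xml_find_first(ev, "./date[@key='time:timestamp']"),
                     "value")
    }, character(1))
    ts <- parse_timestamps(tss, path)
    if (time_unit == "hours") ts <- ts / 3600
    process_case(cid, acts, ts)
  })
  event_log(cases, time_unit = time_unit)
}
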