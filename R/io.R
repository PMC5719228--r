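#' Read and write clinical event streams and ADT tables
#'
#' Events are serialised as JSON Lines (one object per line with fields
#' `patient_id`, `encounter_id`, `timestamp` in ISO-8601 UTC, `category`,
#' `attribute`, `value` — number or string — and `unit`); ADT segments and the
#' encounter companion table as CSV. `read_events()` reports malformed records
#' with their line number.
#'
#' @param events events tibble as produced by [generate_ehr()].
#' @param path file path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   an events tibble.
#' @name event_io
NULL

format_ts <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_ts <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' @rdname event_io
#' @export
write_events <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    rec <- list(
      patient_id = events$patient_id[i],
      encounter_id = events$encounter_id[i],
      timestamp = format_ts(events$timestamp[i]),
      category = events$category[i],
      attribute = events$attribute[i],
      value = if (!is.na(events$value_num[i])) events$value_num[i] else
        events$value_chr[i],
      unit = events$unit[i]
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname event_io
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  required <- c("patient_id", "encounter_id", "timestamp", "category", "attribute")
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i]),
      error = function(e) {
        stop(sprintf("line %d: malformed JSON record (%s)",
                     i, conditionMessage(e)), call. = FALSE)
      }
    )
    missing <- setdiff(required, names(rec))
    if (length(missing) > 0) {
      stop(sprintf("line %d: missing field(s) %s",
                   i, paste(missing, collapse = ", ")), call. = FALSE)
    }
    ts <- parse_ts(rec$timestamp)
    if (is.na(ts)) {
      stop(sprintf("line %d: unparseable timestamp '%s'", i, rec$timestamp),
           call. = FALSE)
    }
    val <- rec$value
    tibble::tibble(
      patient_id = rec$patient_id,
      encounter_id = rec$encounter_id,
      timestamp = ts,
      category = rec$category,
      attribute = rec$attribute,
      value_num = if (is.numeric(val)) as.numeric(val) else NA_real_,
      value_chr = if (is.character(val)) val else NA_character_,
      unit = rec$unit %||% NA_character_
    )
  })
  if (length(recs) == 0) return(empty_events())
  dplyr::bind_rows(recs)
}

ts_cols <- function(tbl, cols) {
  for (cl in cols) tbl[[cl]] <- parse_ts(tbl[[cl]])
  tbl
}

#' @rdname event_io
#' @param adt,encounters tibbles as produced by [generate_ehr()].
#' @export
write_adt <- function(adt, path) {
  out <- adt
  out$start <- format_ts(out$start)
  out$end <- format_ts(out$end)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname event_io
#' @export
read_adt <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    patient_id = "c", encounter_id = "c", unit_type = "c",
    start = "c", end = "c"
  ))
  ts_cols(tibble::as_tibble(tbl), c("start", "end"))
}

#' @rdname event_io
#' @export
write_encounters <- function(encounters, path) {
  out <- encounters
  out$admit_time <- format_ts(out$admit_time)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname event_io
#' @export
read_encounters <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    patient_id = "c", encounter_id = "c", admit_time = "c",
    age_years = "d", diagnosis_group = "c"
  ))
  ts_cols(tibble::as_tibble(tbl), "admit_time")
}

#' Write or read a full synthetic EHR extract to or from a directory
#'
#' Writes `events.jsonl`, `adt.csv` and `encounters.csv` under `dir`.
#'
#' @param x list with `events`, `adt`, `encounters` components (the `truth`
#'   component, if present, is not serialised).
#' @param dir directory path; created if absent.
#' @return `write_ehr()` returns `dir` invisibly; `read_ehr()` the list of
#'   three tibbles.
#' @export
write_ehr <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_events(x$events, file.path(dir, "events.jsonl"))
  write_adt(x$adt, file.path(dir, "adt.csv"))
  write_encounters(x$encounters, file.path(dir, "encounters.csv"))
  invisible(dir)
}

#' @rdname write_ehr
#' @export
read_ehr <- function(dir) {
  list(
    encounters = read_encounters(file.path(dir, "encounters.csv")),
    adt = read_adt(file.path(dir, "adt.csv")),
    events = read_events(file.path(dir, "events.jsonl"))
  )
}
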