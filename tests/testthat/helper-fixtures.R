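# Shared fixtures: a small synthetic world generated once per test run, and
# hand-built ADT/event constructors anchored at a fixed origin.

t0 <- as.POSIXct("2012-06-01 00:00:00", tz = "UTC")

at_hours <- function(h) t0 + h * 3600

ww_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_ehr(synth_config(
        n_case_encounters = 40, n_control_encounters = 200, seed = 101
      ))
    }
    cache
  }
})

# adt segments from (unit, start_h, end_h) triples
make_adt <- function(eid, ...) {
  segs <- list(...)
  tibble::tibble(
    patient_id = paste0("P", eid),
    encounter_id = eid,
    unit_type = vapply(segs, `[[`, character(1), 1),
    start = at_hours(vapply(segs, function(s) as.numeric(s[[2]]), numeric(1))),
    end = at_hours(vapply(segs, function(s) as.numeric(s[[3]]), numeric(1)))
  )
}

make_event <- function(eid, hour, category, attribute,
                       value_num = NA_real_, value_chr = NA_character_,
                       unit = "") {
  tibble::tibble(
    patient_id = paste0("P", eid), encounter_id = eid,
    timestamp = at_hours(hour), category = category, attribute = attribute,
    value_num = value_num, value_chr = value_chr, unit = unit
  )
}

make_events <- function(...) dplyr::bind_rows(...)
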