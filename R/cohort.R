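#' Extract candidate floor-to-ICU transfers from ADT segments
#'
#' A candidate is any floor segment immediately followed by an ICU segment.
#' Transfers originating from the ED, OR, PACU or ICU are excluded by
#' construction (the origin must be a nursing floor) and transfers whose
#' destination is the NICU are excluded explicitly. An encounter can
#' contribute several candidates; the unit of analysis is the transfer.
#'
#' @param adt ADT tibble with `encounter_id`, `unit_type`, `start`, `end`.
#' @return tibble with `encounter_id` and `transfer_time` (start of the ICU
#'   segment), one row per qualifying transfer.
#' @export
extract_candidate_transfers <- function(adt) {
  validate_adt(adt)
  adt |>
    dplyr::arrange(.data$encounter_id, .data$start) |>
    dplyr::group_by(.data$encounter_id) |>
    dplyr::mutate(next_unit = dplyr::lead(.data$unit_type),
                  next_start = dplyr::lead(.data$start)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$unit_type == "floor", .data$next_unit == "ICU") |>
    dplyr::transmute(encounter_id = .data$encounter_id,
                     transfer_time = .data$next_start)
}

validate_adt <- function(adt) {
  stopifnot(all(c("encounter_id", "unit_type", "start", "end") %in% names(adt)))
  if (any(adt$start >= adt$end)) {
    stop("ADT segments must have start < end", call. = FALSE)
  }
  bad <- adt |>
    dplyr::arrange(.data$encounter_id, .data$start) |>
    dplyr::group_by(.data$encounter_id) |>
    dplyr::summarise(
      overlap = any(utils::head(.data$end, -1) > utils::tail(.data$start, -1)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$overlap)
  if (nrow(bad) > 0) {
    stop(sprintf("overlapping ADT segments in encounter(s): %s",
                 paste(bad$encounter_id, collapse = ", ")), call. = FALSE)
  }
  invisible(adt)
}

#' Default criteria for classifying an ICU transfer as unplanned
#'
#' Five named boolean predicates evaluated over events in a closed window
#' around the transfer (default 2 hours before to 12 hours after): initiation
#' of CPAP/BiPAP or invasive ventilation; vasopressor administration; an NS/LR
#' fluid bolus at or above a volume-per-weight threshold; an emergent
#' procedure or resuscitation event; and an ICU-only medication appearing on
#' the medication administration record. A transfer meeting one or more
#' criteria is an unplanned transfer (a case). All windows and attribute lists
#' are configurable; [read_criteria()] loads the same structure from YAML.
#'
#' @param window numeric length-2: window around the transfer in hours.
#' @param fluid_bolus_min_ml_per_kg volume threshold for the bolus criterion.
#' @return named list of criterion definitions.
#' @export
default_criteria <- function(window = c(-2, 12), fluid_bolus_min_ml_per_kg = 20) {
  list(
    respiratory_support = list(
      category = "resp_support",
      attributes = c("CPAP initiation", "BiPAP initiation",
                     "invasive ventilation initiation"),
      min_value = NULL, window = window
    ),
    vasopressor = list(
      category = "med",
      attributes = c("epinephrine infusion", "norepinephrine infusion",
                     "dopamine infusion"),
      min_value = NULL, window = window
    ),
    fluid_bolus = list(
      category = "med",
      attributes = c("NS bolus", "LR bolus"),
      min_value = fluid_bolus_min_ml_per_kg, window = window
    ),
    emergent_procedure = list(
      category = "med",
      attributes = c("CPR", "rapid response activation"),
      min_value = NULL, window = window
    ),
    icu_medication = list(
      category = "med",
      attributes = c("milrinone infusion", "vasopressin infusion"),
      min_value = NULL, window = window
    )
  )
}

#' Load unplanned-transfer criteria from a YAML file
#'
#' @param path YAML file; each top-level key is a criterion with fields
#'   `category`, `attributes`, optional `min_value` and `window`.
#' @return named list of criterion definitions (same shape as
#'   [default_criteria()]).
#' @export
read_criteria <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(cr) {
    list(
      category = cr$category,
      attributes = as.character(cr$attributes),
      min_value = cr$min_value,
      window = as.numeric(cr$window %||% c(-2, 12))
    )
  })
}

criterion_met <- function(criterion, events, transfer_time) {
  lo <- add_hours(transfer_time, criterion$window[1])
  hi <- add_hours(transfer_time, criterion$window[2])
  hit <- events$category == criterion$category &
    events$attribute %in% criterion$attributes &
    events$timestamp >= lo & events$timestamp <= hi
  if (!is.null(criterion$min_value)) {
    hit <- hit & !is.na(events$value_num) &
      events$value_num >= criterion$min_value
  }
  any(hit)
}

#' Evaluate the unplanned-transfer criteria over candidate transfers
#'
#' @param candidates tibble from [extract_candidate_transfers()].
#' @param events events tibble covering the candidates' encounters.
#' @param criteria named list of criterion definitions; unknown structure is
#'   rejected.
#' @return `candidates` with one logical column per criterion (`c1` ... `c5`
#'   in list order) and `is_case = c1 | ... | c5`.
#' @export
apply_unplanned_criteria <- function(candidates, events,
                                     criteria = default_criteria()) {
  stopifnot(is.list(criteria), length(criteria) > 0)
  for (nm in names(criteria)) {
    cr <- criteria[[nm]]
    if (!all(c("category", "attributes", "window") %in% names(cr))) {
      stop(sprintf("criterion '%s' is missing required fields", nm),
           call. = FALSE)
    }
  }
  ev_by_enc <- split(events, events$encounter_id)
  flags <- matrix(FALSE, nrow(candidates), length(criteria))
  for (i in seq_len(nrow(candidates))) {
    ev <- ev_by_enc[[candidates$encounter_id[i]]]
    if (is.null(ev)) next
    flags[i, ] <- vapply(criteria, criterion_met, logical(1),
                         events = ev,
                         transfer_time = candidates$transfer_time[i])
  }
  out <- candidates
  for (j in seq_along(criteria)) out[[paste0("c", j)]] <- flags[, j]
  out$is_case <- rowSums(flags) > 0
  out
}

# event types that qualify a case as a critical deterioration event:
# positive-pressure ventilation, vasopressors, fluid resuscitation, emergent
# procedures -- in the closed window [transfer - 2 h, transfer + 12 h]
cde_criteria <- function(window = c(-2, 12)) {
  default_criteria(window = window)[
    c("respiratory_support", "vasopressor", "fluid_bolus", "emergent_procedure")
  ]
}

#' Flag critical deterioration events among cases
#'
#' @param cases tibble with `encounter_id` and `transfer_time`.
#' @param events events tibble.
#' @param window closed window around the transfer, in hours.
#' @return logical vector, one element per case row.
#' @export
identify_cde <- function(cases, events, window = c(-2, 12)) {
  crit <- cde_criteria(window)
  ev_by_enc <- split(events, events$encounter_id)
  vapply(seq_len(nrow(cases)), function(i) {
    ev <- ev_by_enc[[cases$encounter_id[i]]]
    if (is.null(ev)) return(FALSE)
    any(vapply(crit, criterion_met, logical(1),
               events = ev, transfer_time = cases$transfer_time[i]))
  }, logical(1))
}

# total hours spent on floor segments before `at` (segments truncated at `at`)
floor_hours_before <- function(adt_enc, at) {
  fl <- adt_enc[adt_enc$unit_type == "floor", , drop = FALSE]
  if (nrow(fl) == 0) return(0)
  dur <- pmax(0, hours_between(pmin(fl$end, at), fl$start))
  sum(dur)
}

floor_hours_tbl <- function(records, adt) {
  adt_by_enc <- split(adt, adt$encounter_id)
  vapply(seq_len(nrow(records)), function(i) {
    floor_hours_before(adt_by_enc[[records$encounter_id[i]]],
                       records$event_time[i])
  }, numeric(1))
}

#' Remove records with insufficient floor exposure
#'
#' Cases and controls with less than 8 hours on the floor before their event
#' time are removed (the 8-hour boundary is inclusive: a record with exactly
#' 8 hours is retained).
#'
#' @param records cohort tibble with a `floor_hours` column.
#' @param min_hours inclusive lower bound, default 8.
#' @return filtered tibble.
#' @export
apply_time_filters <- function(records, min_hours = 8) {
  dplyr::filter(records, .data$floor_hours >= min_hours)
}

#' Select matched controls for a case set
#'
#' The control pool consists of encounters with at least 24 hours of floor
#' time and no ICU segment. Controls are sampled stratified over
#' (age bin x diagnosis group) cells proportional to the case distribution at
#' roughly `ratio` controls per case; an empty stratum falls back to the
#' nearest age bin within the same diagnosis group (then to any diagnosis),
#' with a message. Sampling is deterministic under a fixed seed. Each
#' control's event time is its floor departure (end of its last floor
#' segment).
#'
#' @param encounters encounters tibble (`encounter_id`, `age_years`,
#'   `diagnosis_group`).
#' @param adt ADT tibble.
#' @param cases tibble of case records with `age_years`, `diagnosis_group`.
#' @param ratio target controls per case, default 5.
#' @param seed integer seed.
#' @return tibble of control records: `encounter_id`, `event_time`,
#'   `floor_hours`, `age_years`, `diagnosis_group`.
#' @export
select_controls <- function(encounters, adt, cases, ratio = 5, seed = 1L) {
  assert_positive(ratio, "ratio")
  pool <- control_pool(encounters, adt)
  if (nrow(pool) == 0 || nrow(cases) == 0) return(pool[0, ])
  n_target <- round(ratio * nrow(cases))

  case_strata <- table(age_bin(cases$age_years), cases$diagnosis_group)
  case_prop <- case_strata / sum(case_strata)
  pool$age_bin <- age_bin(pool$age_years)

  # largest-remainder allocation of the control budget across strata
  exact <- n_target * case_prop
  alloc <- floor(exact)
  short <- n_target - sum(alloc)
  if (short > 0) {
    frac_order <- order(exact - alloc, decreasing = TRUE)
    alloc[frac_order[seq_len(short)]] <- alloc[frac_order[seq_len(short)]] + 1
  }

  withr::with_seed(seed, {
    picked <- character(0)
    draw <- function(ids, k) {
      ids <- ids[!(ids %in% picked)]
      if (length(ids) == 0 || k == 0) return(character(0))
      sample(ids, min(k, length(ids)))
    }
    for (ab in rownames(case_prop)) {
      for (dg in colnames(case_prop)) {
        want <- alloc[ab, dg]
        if (want == 0) next
        got <- draw(pool$encounter_id[pool$age_bin == ab &
                                        pool$diagnosis_group == dg], want)
        picked <- c(picked, got)
        # exhausted stratum: fill the deficit from the nearest age bins
        # within the same diagnosis group, then from the age bin at large
        for (ab2 in nearest_bins(ab)) {
          deficit <- want - length(got)
          if (deficit == 0) break
          more <- draw(pool$encounter_id[pool$age_bin == ab2 &
                                           pool$diagnosis_group == dg],
                       deficit)
          if (length(more) > 0) {
            message(sprintf(
              "control stratum (%s, %s) short by %d: falling back to age bin %s",
              ab, dg, deficit, ab2))
            got <- c(got, more)
            picked <- c(picked, more)
          }
        }
        deficit <- want - length(got)
        if (deficit > 0) {
          more <- draw(pool$encounter_id[pool$age_bin == ab], deficit)
          picked <- c(picked, more)
          if (length(more) > 0) {
            message(sprintf(
              "control stratum (%s, %s) short by %d: sampling age bin %s at large",
              ab, dg, deficit, ab))
          }
        }
      }
    }
    # top up from the remaining pool if the strata could not fill the target
    deficit <- n_target - length(picked)
    if (deficit > 0) {
      picked <- c(picked, draw(pool$encounter_id, deficit))
    }
  })
  pool[match(picked, pool$encounter_id), setdiff(names(pool), "age_bin")]
}

nearest_bins <- function(ab) {
  bins <- age_bins()
  i <- match(ab, bins)
  bins[setdiff(order(abs(seq_along(bins) - i)), i)]
}

control_pool <- function(encounters, adt) {
  adt_by_enc <- split(adt, adt$encounter_id)
  info <- lapply(encounters$encounter_id, function(eid) {
    seg <- adt_by_enc[[eid]]
    if (is.null(seg)) return(NULL)
    if (any(seg$unit_type == "ICU")) return(NULL)
    fl <- seg[seg$unit_type == "floor", , drop = FALSE]
    if (nrow(fl) == 0) return(NULL)
    fh <- sum(hours_between(fl$end, fl$start))
    if (fh < 24) return(NULL)
    tibble::tibble(encounter_id = eid, event_time = max(fl$end),
                   floor_hours = fh)
  })
  out <- dplyr::bind_rows(info)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      encounter_id = character(),
      event_time = as.POSIXct(character(), tz = "UTC"),
      floor_hours = numeric(), age_years = numeric(),
      diagnosis_group = character()
    ))
  }
  dplyr::left_join(
    out,
    dplyr::select(encounters, "encounter_id", "age_years", "diagnosis_group"),
    by = "encounter_id"
  )
}

#' Build a labeled case/control cohort from ADT and event streams
#'
#' Runs the full cohort construction: candidate floor-to-ICU transfers,
#' the five unplanned-transfer criteria, the critical-deterioration-event
#' flag, matched control selection at roughly 1:`ratio`, floor-hour
#' computation, and the 8-hour floor-time filter.
#'
#' @param adt ADT tibble.
#' @param events events tibble.
#' @param encounters encounters tibble.
#' @param criteria criterion definitions, see [default_criteria()].
#' @param ratio target controls per case.
#' @param seed integer seed for control sampling.
#' @return cohort tibble: `encounter_id`, `label` ("case"/"control"),
#'   `event_time`, `c1`..`c5`, `cde`, `floor_hours`, `age_years`,
#'   `diagnosis_group`.
#' @export
build_cohort <- function(adt, events, encounters,
                         criteria = default_criteria(),
                         ratio = 5, seed = 1L) {
  cand <- extract_candidate_transfers(adt)
  cand <- apply_unplanned_criteria(cand, events, criteria)
  cases <- dplyr::filter(cand, .data$is_case)
  cases <- dplyr::left_join(
    cases,
    dplyr::select(encounters, "encounter_id", "age_years", "diagnosis_group"),
    by = "encounter_id"
  )
  cases$cde <- identify_cde(cases, events)
  cases$event_time <- cases$transfer_time
  cases$floor_hours <- floor_hours_tbl(cases, adt)
  cases$label <- "case"

  # the matching sampler sees cases after the 8 h filter so ratios refer to
  # the analyzable case set
  cases <- apply_time_filters(cases)

  ctrl <- select_controls(encounters, adt, cases, ratio = ratio, seed = seed)
  if (nrow(ctrl) > 0) {
    ctrl$label <- "control"
    for (j in 1:5) ctrl[[paste0("c", j)]] <- FALSE
    ctrl$cde <- FALSE
  }

  cols <- c("encounter_id", "label", "event_time", paste0("c", 1:5),
            "cde", "floor_hours", "age_years", "diagnosis_group")
  out <- dplyr::bind_rows(cases[cols], if (nrow(ctrl) > 0) ctrl[cols])
  apply_time_filters(out)
}

#' Write or read a cohort table as CSV
#' @param cohort cohort tibble from [build_cohort()].
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$event_time <- format_ts(out$event_time)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    encounter_id = "c", label = "c", event_time = "c",
    c1 = "l", c2 = "l", c3 = "l", c4 = "l", c5 = "l", cde = "l",
    floor_hours = "d", age_years = "d", diagnosis_group = "c"
  ))
  ts_cols(tibble::as_tibble(tbl), "event_time")
}
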