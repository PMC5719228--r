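#' Configuration for the synthetic EHR generator
#'
#' Builds a validated configuration object for [generate_ehr()]. The generator
#' emulates multi-unit hospital encounters with a latent deterioration process:
#' case encounters end their floor stay with an ICU transfer and carry a
#' severity ramp that pulls vitals, labs, acuity scores and nursing-assessment
#' values toward abnormal as the transfer approaches; control encounters stay
#' on the floor and carry no signal.
#'
#' @param n_case_encounters,n_control_encounters number of case / control
#'   encounters to simulate.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   generated streams exactly.
#' @param vitals_sampling_interval_hours mean of the exponential gap between
#'   successive observations of each vital type (hours).
#' @param lab_rate_per_day expected observations per day for each lab analyte.
#' @param acuity_rate_per_day expected observations per day for each acuity
#'   score type.
#' @param assessment_rate_per_day expected observations per day for each
#'   nursing-assessment attribute.
#' @param deterioration_onset_hours_before_transfer hours before the ICU
#'   transfer at which the severity ramp of a case leaves zero.
#' @param effect_size standardized drift magnitude: at the moment of transfer a
#'   case's vitals have drifted `effect_size` within-type standard deviations
#'   toward abnormal. `0` generates label-free noise.
#' @param missingness_fraction fraction of observation events dropped uniformly
#'   at random (interventions are never dropped).
#' @param intervention_probability probability that a case encounter receives
#'   at least one intervention event near its transfer.
#' @param age_distribution named probability vector over [age_bins()].
#' @param diagnosis_distribution named probability vector over diagnosis
#'   groups.
#' @return a `ward_synth_config` list.
#' @export
synth_config <- function(n_case_encounters = 100,
                         n_control_encounters = 500,
                         seed = 1L,
                         vitals_sampling_interval_hours = 2,
                         lab_rate_per_day = 1,
                         acuity_rate_per_day = 4,
                         assessment_rate_per_day = 4,
                         deterioration_onset_hours_before_transfer = 8,
                         effect_size = 2,
                         missingness_fraction = 0.1,
                         intervention_probability = 1,
                         age_distribution = NULL,
                         diagnosis_distribution = NULL) {
  assert_count(n_case_encounters, "n_case_encounters")
  assert_count(n_control_encounters, "n_control_encounters")
  assert_positive(vitals_sampling_interval_hours, "vitals_sampling_interval_hours")
  assert_positive(lab_rate_per_day, "lab_rate_per_day")
  assert_positive(acuity_rate_per_day, "acuity_rate_per_day")
  assert_positive(assessment_rate_per_day, "assessment_rate_per_day")
  assert_positive(deterioration_onset_hours_before_transfer,
                  "deterioration_onset_hours_before_transfer")
  if (!is.numeric(effect_size) || effect_size < 0) {
    stop("`effect_size` must be nonnegative", call. = FALSE)
  }
  assert_fraction(missingness_fraction, "missingness_fraction")
  assert_fraction(intervention_probability, "intervention_probability")

  age_distribution <- age_distribution %||%
    setNames(c(0.15, 0.30, 0.25, 0.20, 0.10), age_bins())
  diagnosis_distribution <- diagnosis_distribution %||%
    setNames(c(0.28, 0.10, 0.12, 0.10, 0.15, 0.15, 0.10), diagnosis_groups())
  stopifnot(
    abs(sum(age_distribution) - 1) < 1e-8,
    abs(sum(diagnosis_distribution) - 1) < 1e-8
  )

  structure(
    list(
      n_case_encounters = as.integer(n_case_encounters),
      n_control_encounters = as.integer(n_control_encounters),
      seed = as.integer(seed),
      vitals_sampling_interval_hours = vitals_sampling_interval_hours,
      lab_rate_per_day = lab_rate_per_day,
      acuity_rate_per_day = acuity_rate_per_day,
      assessment_rate_per_day = assessment_rate_per_day,
      deterioration_onset_hours_before_transfer =
        deterioration_onset_hours_before_transfer,
      effect_size = effect_size,
      missingness_fraction = missingness_fraction,
      intervention_probability = intervention_probability,
      age_distribution = age_distribution,
      diagnosis_distribution = diagnosis_distribution
    ),
    class = "ward_synth_config"
  )
}

# severity ramp: 0 before onset, rising linearly to `effect_size` at the
# event; identically 0 for controls. `tte` = hours until the event (>= 0 on
# the floor, < 0 after transfer, where severity stays at its maximum).
severity_at <- function(tte, onset_hours, effect_size, is_case) {
  if (!is_case) return(rep(0, length(tte)))
  effect_size * clamp(1 - pmax(tte, 0) / onset_hours, 0, 1)
}

sample_age_years <- function(bin) {
  switch(bin,
    "<1"    = runif(1, 0.02, 1),
    "1-4"   = runif(1, 1, 5),
    "5-11"  = runif(1, 5, 12),
    "12-17" = runif(1, 12, 18),
    ">=18"  = runif(1, 18, 25)
  )
}

# Poisson observation times over (0, dur_hours], returned sorted
poisson_times <- function(rate_per_hour, dur_hours) {
  n <- rpois(1, rate_per_hour * dur_hours)
  sort(runif(n, 0, dur_hours))
}

empty_events <- function() {
  tibble::tibble(
    patient_id = character(), encounter_id = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    category = character(), attribute = character(),
    value_num = numeric(), value_chr = character(), unit = character()
  )
}

#' Generate a synthetic cohort of encounters and clinical event streams
#'
#' @param config a [synth_config()] object.
#' @return a list of four tibbles:
#'   \describe{
#'     \item{encounters}{one row per encounter: `patient_id`, `encounter_id`,
#'       `admit_time`, `age_years`, `diagnosis_group`.}
#'     \item{adt}{unit-stay segments: `patient_id`, `encounter_id`,
#'       `unit_type` (floor/ED/OR/PACU/ICU/NICU), `start`, `end`.}
#'     \item{events}{timestamped observations: `category` in
#'       vital/lab/acuity/assessment/med/resp_support, `attribute`,
#'       `value_num` or `value_chr`, `unit`.}
#'     \item{truth}{ground truth per encounter: `is_case`, `event_time`
#'       (ICU-transfer time for cases, floor-departure time for controls),
#'       `onset_hours`, `effect_size`.}
#'   }
#' @export
generate_ehr <- function(config = synth_config()) {
  stopifnot(inherits(config, "ward_synth_config"))
  withr::with_seed(config$seed, generate_ehr_impl(config))
}

generate_ehr_impl <- function(config) {
  n_total <- config$n_case_encounters + config$n_control_encounters
  if (n_total == 0) {
    return(list(
      encounters = tibble::tibble(
        patient_id = character(), encounter_id = character(),
        admit_time = as.POSIXct(character(), tz = "UTC"),
        age_years = numeric(), diagnosis_group = character()
      ),
      adt = tibble::tibble(
        patient_id = character(), encounter_id = character(),
        unit_type = character(),
        start = as.POSIXct(character(), tz = "UTC"),
        end = as.POSIXct(character(), tz = "UTC")
      ),
      events = empty_events(),
      truth = tibble::tibble(
        encounter_id = character(), is_case = logical(),
        event_time = as.POSIXct(character(), tz = "UTC"),
        onset_hours = numeric(), effect_size = numeric()
      )
    ))
  }

  is_case <- c(
    rep(TRUE, config$n_case_encounters),
    rep(FALSE, config$n_control_encounters)
  )
  ids <- sprintf("E%05d", seq_len(n_total))
  pids <- sprintf("P%05d", seq_len(n_total))
  admit <- round_time(.ww_origin() + runif(n_total, 0, 4 * 365 * 86400))
  bins <- sample(names(config$age_distribution), n_total,
                 replace = TRUE, prob = config$age_distribution)
  ages <- vapply(bins, sample_age_years, numeric(1))
  dx <- sample(names(config$diagnosis_distribution), n_total,
               replace = TRUE, prob = config$diagnosis_distribution)

  per <- lapply(seq_len(n_total), function(i) {
    simulate_encounter(pids[i], ids[i], admit[i], is_case[i], config)
  })

  encounters <- tibble::tibble(
    patient_id = pids, encounter_id = ids, admit_time = admit,
    age_years = unname(ages), diagnosis_group = dx
  )
  adt <- dplyr::bind_rows(lapply(per, `[[`, "adt"))
  events <- dplyr::bind_rows(lapply(per, `[[`, "events"))
  truth <- dplyr::bind_rows(lapply(per, `[[`, "truth"))
  list(encounters = encounters, adt = adt, events = events, truth = truth)
}

simulate_encounter <- function(pid, eid, admit, is_case, config) {
  has_ed <- runif(1) < 0.3
  ed_dur <- if (has_ed) runif(1, 2, 8) else 0
  floor_dur <- if (is_case) {
    clamp(rlnorm(1, log(48), 0.4), 20, 240)
  } else {
    clamp(rlnorm(1, log(60), 0.4), 26, 240)
  }
  floor_start <- ed_dur
  floor_end <- ed_dur + floor_dur
  stay_end <- floor_end
  units <- c(if (has_ed) "ED", "floor")
  starts <- c(if (has_ed) 0, floor_start)
  ends <- c(if (has_ed) floor_start, floor_end)
  if (is_case) {
    icu_dur <- runif(1, 24, 120)
    units <- c(units, "ICU")
    starts <- c(starts, floor_end)
    ends <- c(ends, floor_end + icu_dur)
    stay_end <- floor_end + icu_dur
  }
  adt <- tibble::tibble(
    patient_id = pid, encounter_id = eid, unit_type = units,
    start = round_time(add_hours(admit, starts)),
    end = round_time(add_hours(admit, ends))
  )
  # event_time: transfer for cases, floor departure for controls
  event_h <- floor_end
  onset <- config$deterioration_onset_hours_before_transfer
  eff <- config$effect_size
  sev <- function(t_h) severity_at(event_h - t_h, onset, eff, is_case)

  ev <- list(
    sim_vitals(t_max = stay_end, sev, config),
    sim_labs(t_max = stay_end, sev, config),
    sim_acuity(t_max = stay_end, sev, config),
    sim_assessments(t_max = stay_end, sev, config)
  )
  obs <- do.call(rbind, ev)
  if (nrow(obs) > 0 && config$missingness_fraction > 0) {
    keep <- runif(nrow(obs)) >= config$missingness_fraction
    obs <- obs[keep, , drop = FALSE]
  }
  if (is_case && runif(1) < config$intervention_probability) {
    obs <- rbind(obs, sim_interventions(event_h))
  }
  events <- if (nrow(obs) == 0) empty_events() else {
    obs <- obs[stable_time_order(obs$t_h), , drop = FALSE]
    tibble::tibble(
      patient_id = pid, encounter_id = eid,
      timestamp = round_time(add_hours(admit, obs$t_h)),
      category = obs$category, attribute = obs$attribute,
      value_num = obs$value_num, value_chr = obs$value_chr, unit = obs$unit
    )
  }
  truth <- tibble::tibble(
    encounter_id = eid, is_case = is_case,
    event_time = round_time(add_hours(admit, event_h)),
    onset_hours = onset, effect_size = if (is_case) eff else 0
  )
  list(adt = adt, events = events, truth = truth)
}

sim_frame <- function(t_h, category, attribute, value_num, value_chr, unit) {
  data.frame(
    t_h = t_h, category = category, attribute = attribute,
    value_num = value_num, value_chr = value_chr, unit = unit,
    stringsAsFactors = FALSE
  )
}

sim_vitals <- function(t_max, sev, config) {
  cat <- vital_catalog()
  out <- lapply(seq_len(nrow(cat)), function(j) {
    t_h <- poisson_times(1 / config$vitals_sampling_interval_hours, t_max)
    if (length(t_h) == 0) return(NULL)
    v <- cat$mean[j] + cat$dir[j] * sev(t_h) * cat$sd[j] +
      rnorm(length(t_h), 0, cat$sd[j])
    v <- round(v, cat$digits[j])
    if (cat$attribute[j] == "Oxygen saturation") v <- pmin(v, 100)
    sim_frame(t_h, "vital", cat$attribute[j], v, NA_character_, cat$unit[j])
  })
  do.call(rbind, out)
}

sim_labs <- function(t_max, sev, config) {
  cat <- lab_catalog()
  out <- lapply(seq_len(nrow(cat)), function(j) {
    t_h <- poisson_times(config$lab_rate_per_day / 24, t_max)
    if (length(t_h) == 0) return(NULL)
    v <- cat$center[j] + cat$dir[j] * sev(t_h) * cat$sd[j] +
      rnorm(length(t_h), 0, cat$sd[j])
    v <- round(pmax(v, 0.01), 2)
    sim_frame(t_h, "lab", cat$attribute[j], v, NA_character_, cat$unit[j])
  })
  do.call(rbind, out)
}

sim_acuity <- function(t_max, sev, config) {
  cat <- acuity_catalog()
  out <- lapply(seq_len(nrow(cat)), function(j) {
    t_h <- poisson_times(config$acuity_rate_per_day / 24, t_max)
    if (length(t_h) == 0) return(NULL)
    latent <- cat$base_mean[j] + sev(t_h) * cat$gain[j] +
      rnorm(length(t_h), 0, cat$base_sd[j])
    v <- clamp(round(latent), cat$min[j], cat$max[j])
    sim_frame(t_h, "acuity", cat$attribute[j], v, NA_character_, "score")
  })
  do.call(rbind, out)
}

sim_assessments <- function(t_max, sev, config) {
  cat <- assessment_catalog()
  out <- lapply(names(cat), function(attr) {
    vals <- cat[[attr]]
    t_h <- poisson_times(config$assessment_rate_per_day / 24, t_max)
    if (length(t_h) == 0) return(NULL)
    idx <- 1 + pmin(
      length(vals) - 1,
      floor(abs(rnorm(length(t_h), 0, 0.55)) + sev(t_h) * 0.9)
    )
    sim_frame(t_h, "assessment", attr, NA_real_, vals[idx], "")
  })
  do.call(rbind, out)
}

# intervention events placed inside the critical window around the transfer
sim_interventions <- function(transfer_h) {
  cat <- intervention_catalog()
  n_iv <- 1 + rbinom(1, 1, 0.5)
  rows <- sample.int(nrow(cat), n_iv, replace = TRUE, prob = cat$weight)
  out <- lapply(rows, function(r) {
    attrs <- cat$attributes[[r]][[1]]
    attr <- sample(attrs, 1)
    t_h <- transfer_h + runif(1, -1, 8)
    if (cat$kind[r] == "fluid_bolus") {
      sim_frame(t_h, cat$category[r], attr, round(runif(1, 20, 40), 1),
                NA_character_, "mL/kg")
    } else {
      sim_frame(t_h, cat$category[r], attr, NA_real_, "administered", "")
    }
  })
  do.call(rbind, out)
}
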