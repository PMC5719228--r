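#' Lookback window specification for feature extraction
#'
#' Vitals are featurized over the 24 hours before the prediction time; labs,
#' acuity scores and nursing assessments over 72 hours; acuity recency
#' features use a nested 6-hour sub-window. All windows are open intervals
#' ending at the prediction time: an observation charted at or after the
#' prediction time never enters a feature.
#'
#' @param vitals_hours,other_hours,sub_window_hours positive window lengths.
#' @return a `ward_window_spec` list.
#' @export
window_spec <- function(vitals_hours = 24, other_hours = 72,
                        sub_window_hours = 6) {
  assert_positive(vitals_hours, "vitals_hours")
  assert_positive(other_hours, "other_hours")
  assert_positive(sub_window_hours, "sub_window_hours")
  structure(
    list(vitals_hours = vitals_hours, other_hours = other_hours,
         sub_window_hours = sub_window_hours),
    class = "ward_window_spec"
  )
}

#' Load a binning table for vitals and labs
#'
#' Maps numeric vital values to risk categories C1-C4 via age-stratified,
#' strictly increasing boundaries (three boundaries define four categories;
#' vitals where low values are worse reverse the category order) and lab
#' values to Low/Normal/High via reference ranges.
#'
#' @param path YAML file; `default_binning()` loads the table shipped with the
#'   package.
#' @return a `ward_binning` list with `vitals` and `labs` components.
#' @export
read_binning <- function(path) {
  raw <- yaml::read_yaml(path)
  for (v in names(raw$vitals)) {
    for (band in raw$vitals[[v]]$bands) {
      b <- as.numeric(band$bounds)
      if (length(b) != 3 || any(diff(b) <= 0)) {
        stop(sprintf("bounds for '%s' must be 3 strictly increasing numbers", v),
             call. = FALSE)
      }
    }
  }
  structure(raw, class = "ward_binning")
}

#' @rdname read_binning
#' @export
default_binning <- function() {
  read_binning(system.file("extdata", "binning.yaml", package = "wardwatch"))
}

# C1..C4 category index for a numeric vital value; NA for unknown types
bin_vital <- function(values, attribute, age_years, binning) {
  cfg <- binning$vitals[[attribute]]
  if (is.null(cfg)) return(rep(NA_integer_, length(values)))
  band <- NULL
  for (b in cfg$bands) {
    if (age_years < b$max_age) { band <- b; break }
  }
  if (is.null(band)) band <- cfg$bands[[length(cfg$bands)]]
  k <- findInterval(values, as.numeric(band$bounds)) + 1L
  if (isTRUE(cfg$descending)) k <- 5L - k
  k
}

# Low/Normal/High category for a lab value; "Normal" for unknown analytes
bin_lab <- function(values, attribute, binning) {
  rng <- binning$labs[[attribute]]
  if (is.null(rng)) return(rep("Normal", length(values)))
  ifelse(values < rng$low, "Low", ifelse(values > rng$high, "High", "Normal"))
}

#' Restrict an event stream to the per-category lookback windows
#'
#' @param events events tibble (any set of encounters).
#' @param prediction_time POSIXct prediction time.
#' @param spec a [window_spec()].
#' @return named list of tibbles `vitals`, `labs`, `acuity`, `assessments`,
#'   each restricted to `(prediction_time - window, prediction_time)`. No
#'   event at or after the prediction time ever enters a feature.
#' @export
window_events <- function(events, prediction_time, spec = window_spec()) {
  win <- function(category, hours) {
    lo <- add_hours(prediction_time, -hours)
    events[events$category == category & events$timestamp > lo &
             events$timestamp < prediction_time, , drop = FALSE]
  }
  list(
    vitals = win("vital", spec$vitals_hours),
    labs = win("lab", spec$other_hours),
    acuity = win("acuity", spec$other_hours),
    assessments = win("assessment", spec$other_hours)
  )
}

# ---- feature fragment builders -------------------------------------------
# All fragment builders consume plain vectors already restricted to the
# window and sorted in stable (time, arrival) order, and return a named
# numeric vector. Missing data contribute no features; nothing is imputed.

ls_slope <- function(hours, values) {
  if (length(values) < 2) return(NA_real_)
  vh <- var(hours)
  if (vh == 0) return(NA_real_)
  cov(hours, values) / vh
}

#' Feature fragment builders for one clinical element type
#'
#' Each builder turns the in-window observations of one element type into a
#' sparse named feature fragment. Scalar features (slopes in units per hour
#' and their magnitudes) enter as real values; everything else as 0/1
#' indicators. Category histograms are normalized to sum to 1. Types with no
#' observations emit nothing; vitals/acuity with fewer than two observations
#' emit no slope features; labs with a single observation emit only presence
#' and last-category features.
#'
#' @param hours observation times in hours from the window start, in stable
#'   chronological order.
#' @param values numeric values (vitals, labs, acuity) in the same order.
#' @param attribute element name, e.g. `"Heart rate"`.
#' @param age_years patient age, used for vital risk-category binning.
#' @param binning a [read_binning()] table.
#' @return named numeric vector (possibly empty).
#' @name feature_fragments
NULL

#' @rdname feature_fragments
#' @export
vitals_fragment <- function(hours, values, attribute, age_years,
                            binning = default_binning()) {
  n <- length(values)
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  sl <- ls_slope(hours, values)
  if (!is.na(sl)) {
    out[paste(attribute, "slope")] <- sl
    out[paste(attribute, "slope magnitude")] <- abs(sl)
    if (sl > 0) out[paste(attribute, "slope is positive")] <- 1
    if (sl < 0) out[paste(attribute, "slope is negative")] <- 1
  }
  cats <- bin_vital(values, attribute, age_years, binning)
  if (!anyNA(cats)) {
    pick <- c(
      Maximum = cats[which.max(values)],
      Minimum = cats[which.min(values)],
      Average = bin_vital(mean(values), attribute, age_years, binning),
      Newest = cats[n],
      Oldest = cats[1]
    )
    for (nm in names(pick)) {
      out[sprintf("%s %s is C%d", nm, attribute, pick[[nm]])] <- 1
    }
    hist <- tabulate(cats, nbins = 4) / n
    for (k in which(hist > 0)) {
      out[sprintf("%s C%d histogram", attribute, k)] <- hist[k]
    }
  }
  out
}

lab_ratio_bins <- function(ratio, attribute, label) {
  out <- numeric(0)
  for (th in c(1.25, 1.5, 2, 3)) {
    if (ratio > th) out[sprintf("%s %s > %s", attribute, label, format(th))] <- 1
  }
  for (th in c(0.8, 0.67, 0.5, 0.33)) {
    if (ratio < th) out[sprintf("%s %s < %s", attribute, label, format(th))] <- 1
  }
  out
}

#' @rdname feature_fragments
#' @export
labs_fragment <- function(values, attribute, binning = default_binning()) {
  n <- length(values)
  if (n == 0) return(numeric(0))
  cats <- bin_lab(values, attribute, binning)
  out <- numeric(0)
  out[paste(attribute, "is present")] <- 1
  out[sprintf("Last %s is %s", attribute, cats[n])] <- 1
  if (n >= 2) {
    out[sprintf("%s %s->%s", attribute, tolower(cats[n - 1]),
                tolower(cats[n]))] <- 1
    out[paste(attribute, "category",
              if (cats[n] == cats[n - 1]) "unchanged" else "changed")] <- 1
    if (values[1] != 0) {
      out <- c(out, lab_ratio_bins(values[n] / values[1], attribute,
                                   "newest/oldest"))
    }
    if (values[n - 1] != 0) {
      out <- c(out, lab_ratio_bins(values[n] / values[n - 1], attribute,
                                   "newest/2nd-newest"))
    }
  }
  out
}

acuity_threshold_bins <- function(value, attribute, which) {
  out <- numeric(0)
  if (value == 0) {
    out[sprintf("%s %s is 0", which, attribute)] <- 1
  }
  for (k in 0:9) {
    if (value > k) out[sprintf("%s %s > %d", which, attribute, k)] <- 1
  }
  out
}

#' @rdname feature_fragments
#' @param spec a [window_spec()]; supplies the 6-hour recency sub-window.
#' @export
acuity_fragment <- function(hours, values, attribute, spec = window_spec()) {
  n <- length(values)
  if (n == 0) return(numeric(0))
  out <- c(
    acuity_threshold_bins(min(values), attribute, "Minimum"),
    acuity_threshold_bins(max(values), attribute, "Maximum"),
    acuity_threshold_bins(values[n], attribute, "Newest")
  )
  sl <- ls_slope(hours, values)
  if (!is.na(sl)) {
    out[paste(attribute, "slope")] <- sl
    out[paste(attribute, "slope magnitude")] <- abs(sl)
  }
  sub_start <- spec$other_hours - spec$sub_window_hours
  sub <- hours > sub_start
  sl6 <- ls_slope(hours[sub], values[sub])
  if (!is.na(sl6)) {
    out[paste(attribute, "slope last 6 hours")] <- sl6
    out[paste(attribute, "slope magnitude last 6 hours")] <- abs(sl6)
  }
  m <- sum(sub)
  for (k in c(0, 1, 2, 4, 6, 10)) {
    if (m > k) {
      out[sprintf("Number of %s measurements in last 6 hours > %d",
                  attribute, k)] <- 1
    }
  }
  out
}

#' @rdname feature_fragments
#' @param attributes,values_chr character vectors of attribute names and
#'   charted values in stable chronological order (all assessment attributes
#'   together).
#' @export
assessments_fragment <- function(attributes, values_chr) {
  if (length(attributes) == 0) return(numeric(0))
  out <- numeric(0)
  pairs <- unique(sprintf("%s is %s", attributes, values_chr))
  out[pairs] <- 1
  for (attr in unique(attributes)) {
    idx <- which(attributes == attr)
    out[sprintf("Newest %s is %s", attr, values_chr[idx[length(idx)]])] <- 1
  }
  out
}

# ---- per-instance featurizer ---------------------------------------------

# ev: data.frame with numeric time `t` (seconds), category, attribute,
# value_num, value_chr, sorted in stable (t, arrival) order. pt: numeric
# prediction time in seconds.
featurize_one <- function(ev, pt, age_years, binning, spec,
                          categories = feature_categories()) {
  feats <- list()
  if ("vitals" %in% categories) {
    lo <- pt - spec$vitals_hours * 3600
    sel <- ev$category == "vital" & ev$t > lo & ev$t < pt
    if (any(sel)) {
      sub <- ev[sel, , drop = FALSE]
      for (attr in unique(sub$attribute)) {
        j <- sub$attribute == attr
        feats[[length(feats) + 1]] <- vitals_fragment(
          (sub$t[j] - lo) / 3600, sub$value_num[j], attr, age_years, binning
        )
      }
    }
  }
  lo72 <- pt - spec$other_hours * 3600
  if ("labs" %in% categories) {
    sel <- ev$category == "lab" & ev$t > lo72 & ev$t < pt
    if (any(sel)) {
      sub <- ev[sel, , drop = FALSE]
      for (attr in unique(sub$attribute)) {
        feats[[length(feats) + 1]] <- labs_fragment(
          sub$value_num[sub$attribute == attr], attr, binning
        )
      }
    }
  }
  if ("acuity" %in% categories) {
    sel <- ev$category == "acuity" & ev$t > lo72 & ev$t < pt
    if (any(sel)) {
      sub <- ev[sel, , drop = FALSE]
      for (attr in unique(sub$attribute)) {
        j <- sub$attribute == attr
        feats[[length(feats) + 1]] <- acuity_fragment(
          (sub$t[j] - lo72) / 3600, sub$value_num[j], attr, spec
        )
      }
    }
  }
  if ("assessments" %in% categories) {
    sel <- ev$category == "assessment" & ev$t > lo72 & ev$t < pt
    if (any(sel)) {
      sub <- ev[sel, , drop = FALSE]
      vals <- ifelse(is.na(sub$value_chr), as.character(sub$value_num),
                     sub$value_chr)
      feats[[length(feats) + 1]] <- assessments_fragment(sub$attribute, vals)
    }
  }
  if (length(feats) == 0) return(numeric(0))
  unlist(feats)
}

#' The four clinical element categories
#' @return character vector `c("vitals", "labs", "acuity", "assessments")`.
#' @export
feature_categories <- function() c("vitals", "labs", "acuity", "assessments")

# pre-split numeric event index for fast repeated featurization
event_index <- function(events) {
  ord <- stable_time_order(events$timestamp)
  ev <- data.frame(
    t = as.numeric(events$timestamp)[ord],
    category = events$category[ord],
    attribute = events$attribute[ord],
    value_num = events$value_num[ord],
    value_chr = events$value_chr[ord],
    stringsAsFactors = FALSE
  )
  split(ev, events$encounter_id[ord])
}

#' Build prediction instances from a cohort at a fixed horizon
#'
#' For each cohort record the prediction time is `event_time - horizon`
#' (the event is the ICU transfer for cases and the floor departure for
#' controls). Records whose prediction time falls before their floor arrival
#' (horizon exceeding `floor_hours`) are dropped with a message. Features are
#' extracted from events in the per-category lookback windows ending at the
#' prediction time.
#'
#' @param cohort cohort tibble from [build_cohort()] (needs `encounter_id`,
#'   `label`, `event_time`, `floor_hours`, `age_years`).
#' @param events events tibble.
#' @param horizon_hours positive prediction horizon in hours.
#' @param binning a [read_binning()] table.
#' @param spec a [window_spec()].
#' @param categories subset of [feature_categories()] to extract.
#' @return tibble with `encounter_id`, `y` (1 = case), `horizon_hours`,
#'   `prediction_time`, and a `features` list-column of named numeric
#'   vectors.
#' @export
build_instances <- function(cohort, events, horizon_hours,
                            binning = default_binning(),
                            spec = window_spec(),
                            categories = feature_categories()) {
  assert_positive(horizon_hours, "horizon_hours")
  idx <- event_index(events)
  build_instances_indexed(cohort, idx, horizon_hours, binning, spec, categories)
}

build_instances_indexed <- function(cohort, idx, horizon_hours, binning,
                                    spec, categories, quiet = FALSE) {
  keep <- cohort$floor_hours >= horizon_hours
  if (any(!keep) && !quiet) {
    message(sprintf(
      "dropping %d record(s) whose prediction time precedes floor arrival at horizon %g h",
      sum(!keep), horizon_hours))
  }
  ch <- cohort[keep, , drop = FALSE]
  pt <- as.numeric(ch$event_time) - horizon_hours * 3600
  feats <- lapply(seq_len(nrow(ch)), function(i) {
    ev <- idx[[ch$encounter_id[i]]]
    if (is.null(ev)) return(numeric(0))
    featurize_one(ev, pt[i], ch$age_years[i], binning, spec, categories)
  })
  tibble::tibble(
    encounter_id = ch$encounter_id,
    y = as.integer(ch$label == "case"),
    horizon_hours = horizon_hours,
    prediction_time = round_time(as.POSIXct(pt, origin = "1970-01-01",
                                            tz = "UTC")),
    features = feats
  )
}

#' Fit a feature vocabulary on training instances
#'
#' The vocabulary maps feature names to column indices and must be fit on
#' training instances only; at evaluation time features absent from the
#' vocabulary are dropped.
#'
#' @param instances instance tibble from [build_instances()].
#' @return tibble with `index` and `feature`.
#' @export
fit_vocabulary <- function(instances) {
  nms <- sort(unique(unlist(lapply(instances$features, names))))
  tibble::tibble(index = seq_along(nms), feature = nms)
}

#' Materialize instances as a sparse design matrix
#'
#' @param instances instance tibble.
#' @param vocab vocabulary tibble from [fit_vocabulary()]; feature names not
#'   in the vocabulary are silently dropped.
#' @return a `dgCMatrix` of dimension `n x nrow(vocab)` with feature names as
#'   column names.
#' @export
as_instance_matrix <- function(instances, vocab) {
  n <- nrow(instances)
  trips <- lapply(seq_len(n), function(i) {
    f <- instances$features[[i]]
    if (length(f) == 0) return(NULL)
    j <- match(names(f), vocab$feature)
    ok <- !is.na(j)
    list(i = rep.int(i, sum(ok)), j = j[ok], x = unname(f[ok]))
  })
  Matrix::sparseMatrix(
    i = unlist(lapply(trips, `[[`, "i")),
    j = unlist(lapply(trips, `[[`, "j")),
    x = unlist(lapply(trips, `[[`, "x")),
    dims = c(n, nrow(vocab)),
    dimnames = list(NULL, vocab$feature)
  )
}

#' Write or read instances in SVMlight sparse format
#'
#' One line per instance: `label index:value ...` with 1-based ascending
#' indices; the vocabulary is a two-column TSV (`index`, `feature`).
#'
#' @param instances instance tibble.
#' @param vocab vocabulary tibble.
#' @param path output file.
#' @export
write_instances <- function(instances, vocab, path) {
  lines <- vapply(seq_len(nrow(instances)), function(i) {
    f <- instances$features[[i]]
    j <- match(names(f), vocab$feature)
    ok <- !is.na(j)
    ordj <- order(j[ok])
    paste(
      c(instances$y[i],
        sprintf("%d:%.10g", j[ok][ordj], unname(f[ok])[ordj])),
      collapse = " "
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_instances
#' @export
read_instances <- function(path, vocab) {
  lines <- readLines(path)
  feats <- lapply(lines, function(ln) {
    parts <- strsplit(trimws(ln), " ", fixed = TRUE)[[1]]
    if (length(parts) < 2) return(numeric(0))
    kv <- strsplit(parts[-1], ":", fixed = TRUE)
    idx <- as.integer(vapply(kv, `[`, character(1), 1))
    val <- as.numeric(vapply(kv, `[`, character(1), 2))
    setNames(val, vocab$feature[idx])
  })
  tibble::tibble(
    y = as.integer(vapply(strsplit(lines, " ", fixed = TRUE), `[`,
                          character(1), 1)),
    features = feats
  )
}

#' @rdname write_instances
#' @export
write_vocabulary <- function(vocab, path) {
  readr::write_tsv(vocab, path)
  invisible(path)
}

#' @rdname write_instances
#' @export
read_vocabulary <- function(path) {
  tibble::as_tibble(readr::read_tsv(path, col_types = readr::cols(
    index = "i", feature = "c"
  )))
}
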