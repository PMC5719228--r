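# Independent oracles, deliberately written as naive transcriptions that
# share no code with the package implementation.

# auROC by exhaustive pair counting
pair_count_auroc <- function(cases, controls) {
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(cases) * length(controls))
}

# straight transcription of the penalized log-likelihood for a single
# logistic layer: sum log p(y|x) - a1*||w||_1 - a2*||w||_2^2
naive_penalized_ll_logistic <- function(w, b, X, y, a1, a2) {
  total <- 0
  for (i in seq_len(nrow(X))) {
    s <- sum(X[i, ] * w) + b
    p1 <- 1 / (1 + exp(-s))
    total <- total + log(if (y[i] == 1) p1 else 1 - p1)
  }
  total - a1 * sum(abs(w)) - a2 * sum(w^2)
}

# brute-force transcription of the feature operator families, built directly
# from the feature-type table: lm() for slopes, table() for histograms,
# explicit threshold loops for ratio and acuity bins.
brute_force_features <- function(events, prediction_time, age_years, binning,
                                 vitals_hours = 24, other_hours = 72,
                                 sub_hours = 6) {
  out <- list()
  add <- function(name, value) out[[name]] <<- value
  keep <- function(category, hours) {
    lo <- prediction_time - hours * 3600
    ev <- events[events$category == category & events$timestamp > lo &
                   events$timestamp < prediction_time, , drop = FALSE]
    ev[order(ev$timestamp), , drop = FALSE]
  }
  vital_cat <- function(v, attr) {
    cfg <- binning$vitals[[attr]]
    band <- NULL
    for (b in cfg$bands) if (age_years < b$max_age) { band <- b; break }
    if (is.null(band)) band <- cfg$bands[[length(cfg$bands)]]
    k <- sum(v >= as.numeric(band$bounds)) + 1
    if (isTRUE(cfg$descending)) k <- 5 - k
    k
  }
  lab_cat <- function(v, attr) {
    rng <- binning$labs[[attr]]
    if (v < rng$low) "Low" else if (v > rng$high) "High" else "Normal"
  }

  vit <- keep("vital", vitals_hours)
  for (attr in unique(vit$attribute)) {
    sub <- vit[vit$attribute == attr, ]
    v <- sub$value_num
    h <- as.numeric(sub$timestamp - (prediction_time - vitals_hours * 3600),
                    units = "hours")
    if (length(v) >= 2 && length(unique(h)) > 1) {
      sl <- unname(coef(lm(v ~ h))[2])
      add(paste(attr, "slope"), sl)
      add(paste(attr, "slope magnitude"), abs(sl))
      if (sl > 0) add(paste(attr, "slope is positive"), 1)
      if (sl < 0) add(paste(attr, "slope is negative"), 1)
    }
    cats <- vapply(v, vital_cat, numeric(1), attr = attr)
    add(sprintf("Maximum %s is C%d", attr, cats[which.max(v)]), 1)
    add(sprintf("Minimum %s is C%d", attr, cats[which.min(v)]), 1)
    add(sprintf("Average %s is C%d", attr, vital_cat(mean(v), attr)), 1)
    add(sprintf("Newest %s is C%d", attr, cats[length(v)]), 1)
    add(sprintf("Oldest %s is C%d", attr, cats[1]), 1)
    tab <- table(cats) / length(cats)
    for (k in names(tab)) {
      add(sprintf("%s C%s histogram", attr, k), as.numeric(tab[[k]]))
    }
  }

  lab <- keep("lab", other_hours)
  for (attr in unique(lab$attribute)) {
    sub <- lab[lab$attribute == attr, ]
    v <- sub$value_num
    n <- length(v)
    cats <- vapply(v, lab_cat, character(1), attr = attr)
    add(paste(attr, "is present"), 1)
    add(sprintf("Last %s is %s", attr, cats[n]), 1)
    if (n >= 2) {
      add(sprintf("%s %s->%s", attr, tolower(cats[n - 1]), tolower(cats[n])), 1)
      add(paste(attr, "category",
                if (cats[n] == cats[n - 1]) "unchanged" else "changed"), 1)
      ratios <- list(c("newest/oldest", v[1]), c("newest/2nd-newest", v[n - 1]))
      for (r in ratios) {
        ref <- as.numeric(r[2])
        if (ref == 0) next
        ratio <- v[n] / ref
        for (th in c(1.25, 1.5, 2, 3)) {
          if (ratio > th) add(sprintf("%s %s > %s", attr, r[1], format(th)), 1)
        }
        for (th in c(0.8, 0.67, 0.5, 0.33)) {
          if (ratio < th) add(sprintf("%s %s < %s", attr, r[1], format(th)), 1)
        }
      }
    }
  }

  acu <- keep("acuity", other_hours)
  for (attr in unique(acu$attribute)) {
    sub <- acu[acu$attribute == attr, ]
    v <- sub$value_num
    h <- as.numeric(sub$timestamp - (prediction_time - other_hours * 3600),
                    units = "hours")
    stats <- c(Minimum = min(v), Maximum = max(v), Newest = v[length(v)])
    for (which in names(stats)) {
      if (stats[[which]] == 0) add(sprintf("%s %s is 0", which, attr), 1)
      for (k in 0:9) {
        if (stats[[which]] > k) add(sprintf("%s %s > %d", which, attr, k), 1)
      }
    }
    if (length(v) >= 2 && length(unique(h)) > 1) {
      sl <- unname(coef(lm(v ~ h))[2])
      add(paste(attr, "slope"), sl)
      add(paste(attr, "slope magnitude"), abs(sl))
    }
    in6 <- sub$timestamp > prediction_time - sub_hours * 3600
    if (sum(in6) >= 2 && length(unique(h[in6])) > 1) {
      sl6 <- unname(coef(lm(v[in6] ~ h[in6]))[2])
      add(paste(attr, "slope last 6 hours"), sl6)
      add(paste(attr, "slope magnitude last 6 hours"), abs(sl6))
    }
    for (k in c(0, 1, 2, 4, 6, 10)) {
      if (sum(in6) > k) {
        add(sprintf("Number of %s measurements in last 6 hours > %d", attr, k), 1)
      }
    }
  }

  ass <- keep("assessment", other_hours)
  if (nrow(ass) > 0) {
    vals <- ifelse(is.na(ass$value_chr), as.character(ass$value_num),
                   ass$value_chr)
    for (i in seq_len(nrow(ass))) {
      add(sprintf("%s is %s", ass$attribute[i], vals[i]), 1)
    }
    for (attr in unique(ass$attribute)) {
      i <- max(which(ass$attribute == attr))
      add(sprintf("Newest %s is %s", attr, vals[i]), 1)
    }
  }
  unlist(out)
}
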