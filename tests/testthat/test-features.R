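test_that("windowing respects per-category lookbacks and never leaks the future", {
  pt <- at_hours(100)
  ev <- make_events(
    make_event("E1", 100 - 25, "vital", "Heart rate", 120),      # outside 24 h
    make_event("E1", 100 - 23, "vital", "Heart rate", 125),
    make_event("E1", 100 - 25, "lab", "Glucose", 90),            # inside 72 h
    make_event("E1", 100 - 73, "lab", "Glucose", 95),            # outside 72 h
    make_event("E1", 100 + 1 / 3600, "vital", "Heart rate", 180),# 1 s later
    make_event("E1", 100, "acuity", "PEWS total score", 3),      # at pt: out
    make_event("E1", 99.5, "acuity", "PEWS total score", 2)
  )
  w <- window_events(ev, pt)
  expect_equal(nrow(w$vitals), 1)
  expect_equal(w$vitals$value_num, 125)
  expect_equal(nrow(w$labs), 1)
  expect_equal(w$labs$value_num, 90)
  expect_equal(nrow(w$acuity), 1)
  expect_equal(w$acuity$value_num, 2)
})

test_that("vital features reproduce the closed-form line and histogram", {
  # HR at (0 h, 120), (6 h, 132), (12 h, 144): slope exactly +2/h
  f <- vitals_fragment(c(0, 6, 12), c(120, 132, 144), "Heart rate",
                       age_years = 6)
  expect_equal(f[["Heart rate slope"]], 2)
  expect_equal(f[["Heart rate slope magnitude"]], 2)
  expect_equal(f[["Heart rate slope is positive"]], 1)
  expect_false("Heart rate slope is negative" %in% names(f))

  # categories C1,C2,C2,C4 at age 6 -> histogram 0.25/0.50/0.25
  f2 <- vitals_fragment(1:4, c(110, 125, 130, 150), "Heart rate",
                        age_years = 6)
  expect_equal(f2[["Heart rate C1 histogram"]], 0.25)
  expect_equal(f2[["Heart rate C2 histogram"]], 0.50)
  expect_equal(f2[["Heart rate C4 histogram"]], 0.25)
  expect_false("Heart rate C3 histogram" %in% names(f2))
  expect_equal(f2[["Maximum Heart rate is C4"]], 1)
  expect_equal(f2[["Minimum Heart rate is C1"]], 1)
  expect_equal(f2[["Newest Heart rate is C4"]], 1)
  expect_equal(f2[["Oldest Heart rate is C1"]], 1)
  # average of 110,125,130,150 = 128.75 -> C2 (bin of the mean, not mean bin)
  expect_equal(f2[["Average Heart rate is C2"]], 1)

  # fewer than two points: no slope features, but binned features remain
  f1 <- vitals_fragment(3, 150, "Heart rate", age_years = 6)
  expect_false(any(grepl("slope", names(f1))))
  expect_equal(f1[["Newest Heart rate is C4"]], 1)
  expect_length(vitals_fragment(numeric(0), numeric(0), "Heart rate", 6), 0)
})

test_that("random series slopes equal the normal-equations fit", {
  set.seed(31)
  for (rep in 1:5) {
    h <- sort(runif(50, 0, 24))
    v <- 100 + 0.7 * h + rnorm(50, 0, 5)
    f <- vitals_fragment(h, v, "Heart rate", age_years = 6)
    beta <- solve(t(cbind(1, h)) %*% cbind(1, h), t(cbind(1, h)) %*% v)[2]
    expect_equal(f[["Heart rate slope"]], unname(beta), tolerance = 1e-10)
  }
})

test_that("lab features encode category transitions and printed ratio bins", {
  # glucose Low then Normal
  f <- labs_fragment(c(60, 100), "Glucose")
  expect_equal(f[["Glucose low->normal"]], 1)
  expect_equal(f[["Glucose category changed"]], 1)
  expect_equal(f[["Glucose is present"]], 1)
  expect_equal(f[["Last Glucose is Normal"]], 1)

  # WBC oldest 5.0 newest 8.0: ratio 1.6 fires >1.25 and >1.5, not >2
  f2 <- labs_fragment(c(5, 8), "White blood cell count")
  expect_equal(f2[["White blood cell count newest/oldest > 1.25"]], 1)
  expect_equal(f2[["White blood cell count newest/oldest > 1.5"]], 1)
  expect_false("White blood cell count newest/oldest > 2" %in% names(f2))

  # shrinking values fire the < bins
  f3 <- labs_fragment(c(10, 4), "White blood cell count")
  expect_equal(f3[["White blood cell count newest/oldest < 0.8"]], 1)
  expect_equal(f3[["White blood cell count newest/oldest < 0.67"]], 1)
  expect_equal(f3[["White blood cell count newest/oldest < 0.5"]], 1)
  expect_false("White blood cell count newest/oldest < 0.33" %in% names(f3))

  # newest vs 2nd-newest uses the 2nd newest as reference
  f4 <- labs_fragment(c(5, 3, 8), "White blood cell count")
  expect_equal(f4[["White blood cell count newest/2nd-newest > 2"]], 1)
  expect_equal(f4[["White blood cell count newest/oldest > 1.5"]], 1)

  # a single measurement gives presence and last-category only
  f5 <- labs_fragment(160, "Glucose")
  expect_setequal(names(f5), c("Glucose is present", "Last Glucose is High"))

  # zero reference value: ratio features omitted
  f6 <- labs_fragment(c(0, 5), "Glucose")
  expect_false(any(grepl("newest/oldest", names(f6))))
})

test_that("acuity features cover threshold, slope and recency-count families", {
  # all-zero scores: the 'is 0' indicators fire and no '> 0' feature exists
  f <- acuity_fragment(c(60, 66, 70), c(0, 0, 0), "PEWS total score")
  expect_equal(f[["Minimum PEWS total score is 0"]], 1)
  expect_equal(f[["Maximum PEWS total score is 0"]], 1)
  expect_equal(f[["Newest PEWS total score is 0"]], 1)
  expect_false(any(grepl("> 0$", names(f)[grepl("Maximum|Minimum|Newest",
                                                names(f))])))

  # min 3 fires > 0,1,2 only
  f2 <- acuity_fragment(c(60, 70), c(3, 5), "PEWS total score")
  expect_true(all(c("Minimum PEWS total score > 0",
                    "Minimum PEWS total score > 1",
                    "Minimum PEWS total score > 2") %in% names(f2)))
  expect_false("Minimum PEWS total score > 3" %in% names(f2))
  expect_true("Maximum PEWS total score > 4" %in% names(f2))
  expect_true("Newest PEWS total score > 4" %in% names(f2))

  # two points 4 h apart inside the 6 h sub-window: slope (4-2)/4 = +0.5/h
  f3 <- acuity_fragment(c(68, 72), c(2, 4), "PEWS total score")
  expect_equal(f3[["PEWS total score slope last 6 hours"]], 0.5)
  expect_equal(f3[["PEWS total score slope"]], 0.5)
  expect_equal(f3[["PEWS total score slope magnitude last 6 hours"]], 0.5)

  # 3 measurements in the last 6 h fire > 0, > 1, > 2 and not > 4
  f4 <- acuity_fragment(c(67, 69, 71), c(1, 2, 1), "PEWS total score")
  cnt <- function(k) sprintf(
    "Number of PEWS total score measurements in last 6 hours > %d", k)
  expect_true(all(c(cnt(0), cnt(1), cnt(2)) %in% names(f4)))
  expect_false(cnt(4) %in% names(f4))
  # measurements outside the sub-window do not count
  f5 <- acuity_fragment(c(10, 20, 70), c(1, 2, 1), "PEWS total score")
  expect_true(cnt(0) %in% names(f5))
  expect_false(cnt(1) %in% names(f5))
})

test_that("assessment features are presence indicators plus a newest marker", {
  f <- assessments_fragment(
    c("Cough", "Mobility", "Mobility"),
    c("productive", "1", "2")
  )
  expect_equal(f[["Cough is productive"]], 1)
  expect_equal(f[["Mobility is 1"]], 1)
  expect_equal(f[["Mobility is 2"]], 1)
  expect_equal(f[["Newest Mobility is 2"]], 1)
  expect_false("Newest Mobility is 1" %in% names(f))
  expect_length(assessments_fragment(character(0), character(0)), 0)
  # repeated pairs stay 0/1 presence indicators
  f2 <- assessments_fragment(rep("Cough", 3), rep("dry", 3))
  expect_equal(f2[["Cough is dry"]], 1)
})

test_that("instance construction sets prediction times and drops infeasible records", {
  co <- tibble::tibble(
    encounter_id = c("A", "B"), label = c("case", "control"),
    event_time = at_hours(c(48, 30)),
    floor_hours = c(48, 30), age_years = c(4, 4),
    diagnosis_group = "other"
  )
  ev <- make_events(
    make_event("A", 40, "vital", "Heart rate", 130),
    make_event("B", 10, "vital", "Heart rate", 110)
  )
  inst <- build_instances(co, ev, horizon_hours = 6)
  expect_equal(inst$prediction_time, at_hours(c(42, 24)))
  expect_equal(inst$y, c(1L, 0L))

  inst16 <- build_instances(co, ev, horizon_hours = 16)
  expect_equal(inst16$prediction_time[2], at_hours(30 - 16))

  # horizon beyond the floor stay drops the record with a message
  expect_message(
    inst40 <- build_instances(co, ev, horizon_hours = 40),
    "dropping 1 record"
  )
  expect_equal(inst40$encounter_id, "A")
  expect_error(build_instances(co, ev, horizon_hours = 0), "positive")
})

test_that("featurization is invariant to input row order", {
  x <- ww_world()
  co <- suppressMessages(build_cohort(x$adt, x$events, x$encounters, seed = 2))
  co <- head(co[order(co$encounter_id), ], 20)
  ev <- x$events[x$events$encounter_id %in% co$encounter_id, ]
  set.seed(8)
  shuffled <- ev[sample.int(nrow(ev)), ]
  a <- build_instances(co, ev, horizon_hours = 6)
  b <- build_instances(co, shuffled, horizon_hours = 6)
  expect_equal(a$features, b$features)
})

test_that("events at or after the prediction time never affect features", {
  x <- ww_world()
  co <- suppressMessages(build_cohort(x$adt, x$events, x$encounters, seed = 2))
  co <- head(co, 30)
  ev <- x$events[x$events$encounter_id %in% co$encounter_id, ]
  base <- build_instances(co, ev, horizon_hours = 6)

  # perturb every event at or after each record's prediction time
  pt <- co$event_time - 6 * 3600
  cut <- pt[match(ev$encounter_id, co$encounter_id)]
  perturbed <- ev
  late <- perturbed$timestamp >= cut
  expect_gt(sum(late), 0)
  perturbed$value_num[late] <- perturbed$value_num[late] * 10 + 999
  perturbed$value_chr[late] <- "perturbed"
  after <- build_instances(co, perturbed, horizon_hours = 6)
  expect_equal(after$features, base$features)
})

test_that("the vocabulary is frozen at fit time and unseen features are dropped", {
  inst <- tibble::tibble(
    y = c(1L, 0L),
    features = list(c(a = 1, b = 2), c(b = 1, c = 3))
  )
  vocab <- fit_vocabulary(inst)
  expect_equal(vocab$feature, c("a", "b", "c"))
  new_inst <- tibble::tibble(
    y = 0L, features = list(c(b = 5, zz_unseen = 9))
  )
  X <- as_instance_matrix(new_inst, vocab)
  expect_equal(dim(X), c(1L, 3L))
  expect_equal(as.numeric(X), c(0, 5, 0))
})

test_that("instances round-trip through SVMlight format", {
  x <- ww_world()
  co <- suppressMessages(build_cohort(x$adt, x$events, x$encounters, seed = 2))
  inst <- build_instances(head(co, 15), x$events, horizon_hours = 6)
  vocab <- fit_vocabulary(inst)
  f <- withr::local_tempfile(fileext = ".svmlight")
  vf <- withr::local_tempfile(fileext = ".tsv")
  write_instances(inst, vocab, f)
  write_vocabulary(vocab, vf)
  back <- read_instances(f, read_vocabulary(vf))
  expect_equal(back$y, inst$y)
  X1 <- as_instance_matrix(inst, vocab)
  X2 <- as_instance_matrix(back, vocab)
  expect_equal(as.matrix(X1), as.matrix(X2), tolerance = 1e-9)
})

test_that("binning tables validate and map values on both scales", {
  b <- default_binning()
  # ascending vital: higher heart rate, higher risk category
  expect_equal(bin_vital(c(100, 125, 140, 150), "Heart rate", 6, b),
               c(1L, 2L, 3L, 4L))
  # descending vital: lower blood pressure, higher risk category
  expect_equal(bin_vital(c(60, 75, 85, 120), "Systolic blood pressure", 6, b),
               c(4L, 3L, 2L, 1L))
  expect_equal(bin_lab(c(60, 100, 200), "Glucose", b),
               c("Low", "Normal", "High"))
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "vitals:",
    "  \"Heart rate\":",
    "    bands:",
    "      - {max_age: .inf, bounds: [120, 110, 130]}",
    "labs: {}"
  ), bad)
  expect_error(read_binning(bad), "strictly increasing")
})
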