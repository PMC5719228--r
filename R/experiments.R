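#' Temporal train/test split of a cohort
#'
#' Mirrors a calendar-based evaluation design: encounters admitted before the
#' `prop` quantile of admit times form the training split, the remainder the
#' test split.
#'
#' @param cohort cohort tibble.
#' @param encounters encounters tibble with `admit_time`.
#' @param prop fraction of encounters assigned to training, default 0.75.
#' @return `cohort` with a `.split` column ("train"/"test").
#' @export
temporal_split <- function(cohort, encounters, prop = 0.75) {
  assert_fraction(prop, "prop")
  adm <- encounters$admit_time[match(cohort$encounter_id,
                                     encounters$encounter_id)]
  cut <- quantile(as.numeric(encounters$admit_time), prop, names = FALSE)
  dplyr::mutate(cohort, .split = ifelse(as.numeric(adm) <= cut,
                                        "train", "test"))
}

#' Subsample controls to a target case:control ratio
#'
#' Keeps all cases and a simple random subsample of controls so that the
#' result has roughly 1:`ratio` cases to controls. If fewer controls are
#' available than the target, all are kept.
#'
#' @param cohort cohort tibble (or a split of one).
#' @param ratio controls per case, default 5.
#' @param seed integer seed.
#' @return subsampled tibble.
#' @export
subsample_controls <- function(cohort, ratio = 5, seed = 1L) {
  cases <- dplyr::filter(cohort, .data$label == "case")
  ctrl <- dplyr::filter(cohort, .data$label == "control")
  n_want <- round(ratio * nrow(cases))
  if (nrow(ctrl) > n_want) {
    keep <- withr::with_seed(seed, sample.int(nrow(ctrl), n_want))
    ctrl <- ctrl[keep, , drop = FALSE]
  }
  dplyr::bind_rows(cases, ctrl)
}

# train on the training split and evaluate on the test split at fixed
# horizon(s), reusing a prebuilt event index
fit_and_eval <- function(split_cohort, idx, train_horizon, eval_horizons,
                         hp, binning, spec, categories, prevalence) {
  tr <- dplyr::filter(split_cohort, .data$.split == "train")
  te <- dplyr::filter(split_cohort, .data$.split == "test")
  tr_inst <- build_instances_indexed(tr, idx, train_horizon, binning, spec,
                                     categories, quiet = TRUE)
  vocab <- fit_vocabulary(tr_inst)
  model <- train_model(tr_inst, hp, vocab = vocab)
  evals <- lapply(eval_horizons, function(h) {
    te_inst <- build_instances_indexed(te, idx, h, binning, spec,
                                       categories, quiet = TRUE)
    sc <- predict_proba(model, te_inst)
    res <- roc_result(sc[te_inst$y == 1], sc[te_inst$y == 0],
                      prevalence = prevalence)
    dplyr::mutate(res, horizon_train = train_horizon, horizon_eval = h,
                  .before = 1)
  })
  list(model = model, results = dplyr::bind_rows(evals))
}

feature_set_configs <- function() {
  all_sets <- feature_categories()
  singles <- lapply(all_sets, function(s) {
    list(name = s, kind = "single", categories = s)
  })
  additive <- lapply(seq_along(all_sets), function(i) {
    list(
      name = paste(all_sets[seq_len(i)], collapse = "+"),
      kind = "additive", categories = all_sets[seq_len(i)]
    )
  })
  ablation <- lapply(all_sets, function(s) {
    list(name = paste0("All-", s), kind = "ablation",
         categories = setdiff(all_sets, s))
  })
  full <- list(list(name = "All features", kind = "full",
                    categories = all_sets))
  c(singles, additive, ablation, full)
}

#' Additive and ablation feature-set experiments at a fixed horizon
#'
#' Trains one regularized logistic model per feature-set configuration —
#' each single element type, the additive ladder
#' vitals, vitals+labs, vitals+labs+acuity, vitals+labs+acuity+assessments,
#' each All-minus-one ablation, and the full model — at a shared prediction
#' horizon and seed, and evaluates each on the temporal test split.
#'
#' @param cohort cohort tibble.
#' @param events events tibble.
#' @param encounters encounters tibble.
#' @param horizon_hours shared prediction horizon, default 6.
#' @param hp model hyperparameters.
#' @param sets optional character vector restricting the single-set
#'   configurations; unknown names are an error.
#' @param ratio training-split control subsampling ratio.
#' @param prop temporal-split training fraction.
#' @param prevalence prevalence for PPV estimates.
#' @param binning,spec feature-extraction configuration.
#' @param seed integer seed shared across configurations.
#' @return tibble: one row per configuration with `feature_set`, `kind` and
#'   the [roc_result()] columns.
#' @export
run_feature_set_experiments <- function(cohort, events, encounters,
                                        horizon_hours = 6,
                                        hp = model_hyperparams(),
                                        sets = NULL,
                                        ratio = 5, prop = 0.75,
                                        prevalence = 0.013,
                                        binning = default_binning(),
                                        spec = window_spec(),
                                        seed = 1L) {
  if (!is.null(sets)) {
    unknown <- setdiff(sets, feature_categories())
    if (length(unknown) > 0) {
      stop(sprintf("unknown feature set(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  configs <- feature_set_configs()
  if (!is.null(sets)) {
    configs <- Filter(function(cf) cf$kind != "single" ||
                        cf$name %in% sets, configs)
  }
  idx <- event_index(events)
  split_cohort <- temporal_split(cohort, encounters, prop)
  split_cohort <- dplyr::bind_rows(
    subsample_controls(
      dplyr::filter(split_cohort, .data$.split == "train"), ratio, seed),
    dplyr::filter(split_cohort, .data$.split == "test")
  )
  rows <- lapply(configs, function(cf) {
    fe <- fit_and_eval(split_cohort, idx, horizon_hours, horizon_hours,
                       hp, binning, spec, cf$categories, prevalence)
    dplyr::mutate(fe$results, feature_set = cf$name, kind = cf$kind,
                  .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Prediction-horizon sweep and cross-horizon grid
#'
#' `horizon_sweep()` trains one model per horizon and evaluates it at the
#' same horizon on the temporal test split. `cross_horizon()` additionally
#' evaluates every trained model at every horizon, returning the full
#' train-by-eval auROC grid.
#'
#' @inheritParams run_feature_set_experiments
#' @param horizons positive, ascending horizons in hours, default 1..16.
#' @param categories feature categories to use.
#' @return `horizon_sweep()`: tibble with one [roc_result()] row per horizon
#'   (class `ward_sweep`). `cross_horizon()`: long tibble with
#'   `horizon_train`, `horizon_eval`, `auroc` (class `ward_grid`).
#' @export
horizon_sweep <- function(cohort, events, encounters, horizons = 1:16,
                          hp = model_hyperparams(),
                          categories = feature_categories(),
                          ratio = 5, prop = 0.75, prevalence = 0.013,
                          binning = default_binning(), spec = window_spec(),
                          seed = 1L) {
  out <- sweep_impl(cohort, events, encounters, horizons, hp, categories,
                    ratio, prop, prevalence, binning, spec, seed,
                    full_grid = FALSE)
  structure(out$diag, class = c("ward_sweep", class(out$diag)))
}

#' @rdname horizon_sweep
#' @export
cross_horizon <- function(cohort, events, encounters, horizons = 1:16,
                          hp = model_hyperparams(),
                          categories = feature_categories(),
                          ratio = 5, prop = 0.75, prevalence = 0.013,
                          binning = default_binning(), spec = window_spec(),
                          seed = 1L) {
  out <- sweep_impl(cohort, events, encounters, horizons, hp, categories,
                    ratio, prop, prevalence, binning, spec, seed,
                    full_grid = TRUE)
  structure(out$grid, class = c("ward_grid", class(out$grid)))
}

sweep_impl <- function(cohort, events, encounters, horizons, hp, categories,
                       ratio, prop, prevalence, binning, spec, seed,
                       full_grid) {
  stopifnot(all(horizons > 0), !is.unsorted(horizons))
  idx <- event_index(events)
  split_cohort <- temporal_split(cohort, encounters, prop)
  split_cohort <- dplyr::bind_rows(
    subsample_controls(
      dplyr::filter(split_cohort, .data$.split == "train"), ratio, seed),
    dplyr::filter(split_cohort, .data$.split == "test")
  )
  tr <- dplyr::filter(split_cohort, .data$.split == "train")
  te <- dplyr::filter(split_cohort, .data$.split == "test")
  # evaluation instance sets are horizon-specific but model-independent:
  # build each once and score every trained model against it
  te_sets <- lapply(horizons, function(h) {
    build_instances_indexed(te, idx, h, binning, spec, categories,
                            quiet = TRUE)
  })
  rows <- lapply(seq_along(horizons), function(i) {
    h <- horizons[i]
    tr_inst <- build_instances_indexed(tr, idx, h, binning, spec, categories,
                                       quiet = TRUE)
    model <- train_model(tr_inst, hp)
    eval_at <- if (full_grid) seq_along(horizons) else i
    dplyr::bind_rows(lapply(eval_at, function(j) {
      te_inst <- te_sets[[j]]
      sc <- predict_proba(model, te_inst)
      res <- roc_result(sc[te_inst$y == 1], sc[te_inst$y == 0],
                        prevalence = prevalence)
      dplyr::mutate(res, horizon_train = h, horizon_eval = horizons[j],
                    .before = 1)
    }))
  })
  all_rows <- dplyr::bind_rows(rows)
  list(
    diag = dplyr::filter(all_rows, .data$horizon_train == .data$horizon_eval),
    grid = dplyr::select(all_rows, "horizon_train", "horizon_eval", "auroc")
  )
}
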