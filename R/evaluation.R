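#' Area under the ROC curve as the Mann-Whitney statistic
#'
#' Computed via ranks: the mean over all case-control score pairs of 1 if the
#' case outscores the control, 1/2 on ties, 0 otherwise.
#'
#' @param scores_cases,scores_controls numeric score vectors; both must be
#'   nonempty.
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(scores_cases, scores_controls) {
  n1 <- length(scores_cases)
  n0 <- length(scores_controls)
  if (n1 == 0 || n0 == 0) {
    stop("both score groups must be nonempty", call. = FALSE)
  }
  r <- rank(c(scores_cases, scores_controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

delong_roc <- function(scores_cases, scores_controls) {
  pROC::roc(
    response = c(rep(1, length(scores_cases)), rep(0, length(scores_controls))),
    predictor = c(scores_cases, scores_controls),
    levels = c(0, 1), direction = "<", quiet = TRUE
  )
}

#' DeLong confidence interval for the auROC
#'
#' Uses the DeLong structural-components variance; the interval is truncated
#' to \[0, 1\]. Degenerate zero-variance inputs (e.g. perfectly separated
#' groups) collapse to a point interval, flagged via the `degenerate`
#' attribute.
#'
#' @param scores_cases,scores_controls numeric score vectors.
#' @param level confidence level, default 0.95.
#' @return numeric `c(lo, hi)`.
#' @export
delong_ci <- function(scores_cases, scores_controls, level = 0.95) {
  a <- auroc(scores_cases, scores_controls)
  ci <- tryCatch(
    suppressWarnings(
      as.numeric(pROC::ci.auc(delong_roc(scores_cases, scores_controls),
                              conf.level = level, method = "delong"))[c(1, 3)]
    ),
    error = function(e) c(a, a)
  )
  if (any(!is.finite(ci))) ci <- c(a, a)
  out <- clamp(ci, 0, 1)
  attr(out, "degenerate") <- ci[1] == ci[2]
  out
}

#' Paired or unpaired DeLong test comparing two models' auROCs
#'
#' The paired form requires both models to be scored on the identical
#' instance set (same response vector in the same order) and uses the
#' covariance of the two models' DeLong structural components.
#'
#' @param a_cases,a_controls scores of model A on cases / controls.
#' @param b_cases,b_controls scores of model B on the same (paired) or
#'   separate (unpaired) instances.
#' @param paired logical, default `TRUE`.
#' @return p-value.
#' @export
delong_test <- function(a_cases, a_controls, b_cases, b_controls,
                        paired = TRUE) {
  if (paired && (length(a_cases) != length(b_cases) ||
                 length(a_controls) != length(b_controls))) {
    stop("paired test requires identical instance sets", call. = FALSE)
  }
  ra <- delong_roc(a_cases, a_controls)
  rb <- delong_roc(b_cases, b_controls)
  if (paired && isTRUE(all.equal(c(a_cases, a_controls),
                                 c(b_cases, b_controls)))) {
    return(1)  # a model against itself
  }
  as.numeric(pROC::roc.test(ra, rb, method = "delong", paired = paired)$p.value)
}

#' Specificity at a target sensitivity
#'
#' The threshold is the largest score cutoff whose sensitivity (fraction of
#' case scores at or above the cutoff) still reaches the target; returns the
#' specificity (fraction of control scores below the cutoff) at that
#' threshold.
#'
#' @param scores_cases,scores_controls numeric score vectors.
#' @param target_sens target sensitivity in \[0, 1\], default 0.80.
#' @return list with `specificity`, `sensitivity` and `threshold`.
#' @export
spec_at_sensitivity <- function(scores_cases, scores_controls,
                                target_sens = 0.80) {
  stopifnot(length(scores_cases) > 0, length(scores_controls) > 0,
            target_sens >= 0, target_sens <= 1)
  if (target_sens == 0) {
    return(list(specificity = 1, sensitivity = 0, threshold = Inf))
  }
  n1 <- length(scores_cases)
  srt <- sort(scores_cases, decreasing = TRUE)
  thr <- srt[ceiling(target_sens * n1)]
  list(
    specificity = mean(scores_controls < thr),
    sensitivity = mean(scores_cases >= thr),
    threshold = thr
  )
}

#' Positive predictive value from sensitivity, specificity and prevalence
#'
#' `sens * prev / (sens * prev + (1 - spec) * (1 - prev))`; defined as 0 when
#' the numerator is 0 (including the degenerate denominator-zero case).
#'
#' @param sens,spec,prevalence values in \[0, 1\].
#' @return PPV in \[0, 1\].
#' @export
estimated_ppv <- function(sens, spec, prevalence) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            prevalence >= 0, prevalence <= 1)
  num <- sens * prevalence
  if (num == 0) return(0)
  num / (num + (1 - spec) * (1 - prevalence))
}

#' Full ROC summary for one evaluation
#'
#' @param scores_cases,scores_controls numeric score vectors.
#' @param prevalence assumed population prevalence for the PPV estimate,
#'   default 0.013.
#' @param target_sens operating-point sensitivity, default 0.80.
#' @param level confidence level for the DeLong interval.
#' @return one-row tibble: `auroc`, `ci_lo`, `ci_hi`, `spec80`, `sens80`,
#'   `ppv80`, `threshold`, `n_case`, `n_control`.
#' @export
roc_result <- function(scores_cases, scores_controls, prevalence = 0.013,
                       target_sens = 0.80, level = 0.95) {
  ci <- delong_ci(scores_cases, scores_controls, level)
  op <- spec_at_sensitivity(scores_cases, scores_controls, target_sens)
  tibble::tibble(
    auroc = auroc(scores_cases, scores_controls),
    ci_lo = ci[1], ci_hi = ci[2],
    spec80 = op$specificity, sens80 = op$sensitivity,
    ppv80 = estimated_ppv(op$sensitivity, op$specificity, prevalence),
    threshold = op$threshold,
    n_case = length(scores_cases), n_control = length(scores_controls)
  )
}
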