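# Aggregation of a subject's many per-slice predictions into one brain age:
# mean, median, or the grouped (class-interval) mode, plus the stack-wise
# mean used for cross-architecture comparisons.

#' Grouped mode of continuous values
#'
#' Bins the values into classes of width `class_interval` with edges anchored
#' at zero (half-open intervals `[k*i, (k+1)*i)`), finds the unique modal
#' class, and interpolates
#' `M = L + i * (f1 - f0) / (2*f1 - f0 - f2)`,
#' where `L` is the modal class's lower edge, `f1` its count, and `f0`, `f2`
#' the counts of the neighbouring classes (0 outside the observed range).
#' With two or more tied modal classes the fallback `3*median - 2*mean` is
#' returned. If the interpolation denominator vanishes (tie-adjacent
#' degenerate case), the modal-class midpoint `L + i/2` is returned with a
#' message.
#'
#' The zero anchoring and half-open edge convention are package decisions
#' (the mode value depends on them); they are pinned by unit tests.
#'
#' @param values Numeric vector (non-empty).
#' @param class_interval Bin width `i` (> 0), in the units of `values`.
#' @return The grouped mode (scalar).
#' @export
grouped_mode <- function(values, class_interval = 0.2) {
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  if (!is.finite(class_interval) || class_interval <= 0)
    stop("class_interval must be > 0", call. = FALSE)
  assert_finite(values, "values")
  i <- class_interval
  # nudge against representation error so k*i lands in bin k
  bin <- floor(values / i + 1e-8)
  rng <- range(bin)
  counts <- tabulate(bin - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  mx <- max(counts)
  modal <- which(counts == mx)
  if (length(modal) > 1L)
    return(3 * stats::median(values) - 2 * mean(values))
  f1 <- counts[modal]
  f0 <- if (modal > 1L) counts[modal - 1L] else 0
  f2 <- if (modal < length(counts)) counts[modal + 1L] else 0
  L <- (rng[1] + modal - 1L) * i
  den <- 2 * f1 - f0 - f2
  if (den == 0) {
    message("grouped_mode: zero interpolation denominator; ",
            "returning modal-class midpoint")
    return(L + i / 2)
  }
  L + i * (f1 - f0) / den
}

#' Aggregate one subject's predictions into a brain age
#'
#' Applies the chosen central-tendency measure to the TTA-averaged per-slice
#' predictions pooled over all of the subject's stacks, and records the
#' predicted age difference PAD = GA - brain age.
#'
#' @param predictions Numeric vector of per-slice `p_tta` values (weeks).
#' @param ga_weeks The subject's chronological gestational age.
#' @param measure `"mean"`, `"median"`, or `"mode"`.
#' @param class_interval Class interval for the mode, weeks.
#' @param subject_id Optional identifier carried through.
#' @return A list of class `aggregation_result`: `subject_id`, `measure`,
#'   `class_interval`, `brain_age_weeks`, `pad_weeks`, `n_predictions_used`.
#' @export
aggregate_subject <- function(predictions, ga_weeks,
                              measure = c("mean", "median", "mode"),
                              class_interval = 0.2, subject_id = NA_character_) {
  measure <- match.arg(measure)
  if (!length(predictions)) stop("need >= 1 prediction", call. = FALSE)
  ba <- switch(measure,
               mean = mean(predictions),
               median = stats::median(predictions),
               mode = grouped_mode(predictions, class_interval))
  structure(list(subject_id = subject_id, measure = measure,
                 class_interval = if (measure == "mode") class_interval else NA_real_,
                 brain_age_weeks = ba, pad_weeks = ga_weeks - ba,
                 n_predictions_used = length(predictions)),
            class = "aggregation_result")
}

#' Aggregate a predictions table per subject
#'
#' @param preds Data frame from [predict_tta_dataset()] (columns
#'   `subject_id`, `ga_weeks`, `p_tta`).
#' @param measure,class_interval As in [aggregate_subject()].
#' @return Data frame with one row per subject: `subject_id`, `ga_weeks`,
#'   `measure`, `class_interval`, `brain_age`, `pad`, `n`.
#' @export
aggregate_cohort <- function(preds, measure = "mode", class_interval = 0.2) {
  sp <- split(preds, preds$subject_id)
  rows <- lapply(sp, function(d) {
    r <- aggregate_subject(d$p_tta, d$ga_weeks[1], measure, class_interval,
                           subject_id = d$subject_id[1])
    data.frame(subject_id = r$subject_id, ga_weeks = d$ga_weeks[1],
               measure = r$measure, class_interval = r$class_interval,
               brain_age = r$brain_age_weeks, pad = r$pad_weeks,
               n = r$n_predictions_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stack-wise brain age
#'
#' Arithmetic mean of the selected slices' TTA-averaged predictions of one
#' stack; the unit used when comparing the per-slice network against the
#' multi-channel and volumetric variants.
#'
#' @param predictions Per-slice `p_tta` values of one stack.
#' @return The stack's predicted age.
#' @export
stackwise_age <- function(predictions) mean(predictions)

#' Stack-wise ages for a predictions table
#'
#' @param preds Data frame from [predict_tta_dataset()].
#' @return Data frame: `subject_id`, `stack_id`, `ga_weeks`, `brain_age`,
#'   `pad`, `n_slices`.
#' @export
stackwise_cohort <- function(preds) {
  sp <- split(preds, preds$stack_id)
  rows <- lapply(sp, function(d) data.frame(
    subject_id = d$subject_id[1], stack_id = d$stack_id[1],
    ga_weeks = d$ga_weeks[1], brain_age = stackwise_age(d$p_tta),
    pad = d$ga_weeks[1] - stackwise_age(d$p_tta), n_slices = nrow(d),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Class-interval sweep for the grouped mode
#'
#' Recomputes the cohort MAE of the mode aggregate for each class interval,
#' reproducing the interval-selection experiment design.
#'
#' @param preds Predictions table.
#' @param intervals Class intervals (weeks) to evaluate.
#' @return Data frame `class_interval`, `mae`, `sd` (of absolute PADs).
#' @export
sweep_class_interval <- function(preds, intervals = seq(0.1, 1.0, by = 0.1)) {
  rows <- lapply(intervals, function(i) {
    agg <- aggregate_cohort(preds, "mode", i)
    ms <- mae_sd(agg$pad)
    data.frame(class_interval = i, mae = ms[["mae"]], sd = ms[["sd"]])
  })
  do.call(rbind, rows)
}
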