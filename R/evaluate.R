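# Cohort-level accuracy metrics and the statistical comparison procedures:
# MAE/SD of absolute PADs, nine gestational age groups, random-selection
# tests against single-slice/single-stack prediction, and nonparametric
# comparisons across aggregation measures and network input strategies.

#' MAE and SD of absolute predicted-age differences
#'
#' @param pads Vector of PADs (weeks), one per subject.
#' @return Named vector `mae`, `sd` (sample SD of the absolute PADs; 0 for a
#'   single subject by convention).
#' @export
mae_sd <- function(pads) {
  if (!length(pads)) stop("need >= 1 PAD", call. = FALSE)
  a <- abs(pads)
  c(mae = mean(a), sd = if (length(a) > 1) stats::sd(a) else 0)
}

#' Gestational age group (nine groups)
#'
#' Group 1 pools everything under 23 weeks; groups 2-9 are 2-week periods
#' `[23,25), [25,27), ..., [37,39)`.
#'
#' @param ga_weeks Gestational age in weeks.
#' @return Integer group id in 1..9.
#' @export
age_group_label <- function(ga_weeks) {
  if (!is.finite(ga_weeks) || ga_weeks < 15.9 || ga_weeks >= 39)
    stop("gestational age outside [15.9, 39)", call. = FALSE)
  if (ga_weeks < 23) return(1L)
  as.integer(2L + floor((ga_weeks - 23) / 2))
}

#' Random-selection test: multiplanar aggregate vs a random slice or stack
#'
#' Per replicate, one random slice (or one random stack, whose age is the
#' mean of its selected slices) is drawn per subject and the cohort MAE and
#' SD of absolute PADs recomputed, forming null distributions for the
#' single-slice / single-stack strategies. The empirical p-values are the
#' strict proportions of replicates beating the multiplanar reference:
#' `p = #{replicate < reference} / n_rep` (ties count against rejection).
#'
#' @param preds Predictions table from [predict_tta_dataset()].
#' @param reference_mae,reference_sd Reference MAE and SD of the multiplanar
#'   aggregate (e.g. from [aggregate_cohort()] + [mae_sd()]).
#' @param unit `"single_slice"` or `"single_stack"`. Stacks with fewer
#'   selected slices than `min_stack_slices` are excluded from the draw (the
#'   number excluded is reported).
#' @param n_rep Number of random selections.
#' @param seed RNG seed.
#' @param min_stack_slices Minimum usable slices for a stack to enter the
#'   single-stack draw.
#' @return A list of class `random_selection_test`: `null_mae`, `null_sd`
#'   (length `n_rep`), `p_mae`, `p_sd`, `unit`, `n_rep`,
#'   `n_excluded_stacks`, and the references.
#' @export
random_selection_test <- function(preds, reference_mae, reference_sd,
                                  unit = c("single_slice", "single_stack"),
                                  n_rep = 10000L, seed = 1L,
                                  min_stack_slices = 4L) {
  unit <- match.arg(unit)
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)
  n_excluded <- 0L
  if (unit == "single_stack") {
    st <- stackwise_cohort(preds)
    keep <- st$n_slices >= min_stack_slices
    n_excluded <- sum(!keep)
    st <- st[keep, , drop = FALSE]
    values <- split(st$brain_age, st$subject_id)
    ga <- vapply(split(st$ga_weeks, st$subject_id), `[`, numeric(1), 1)
  } else {
    values <- split(preds$p_tta, preds$subject_id)
    ga <- vapply(split(preds$ga_weeks, preds$subject_id), `[`, numeric(1), 1)
  }
  if (any(!lengths(values))) stop("subject without predictions", call. = FALSE)
  ns <- length(values)
  with_seed(derive_seed(seed, paste0("rst_", unit)), {
    # draw matrix: one prediction per subject per replicate
    draw <- matrix(0, ns, n_rep)
    for (s in seq_len(ns)) {
      v <- values[[s]]
      draw[s, ] <- if (length(v) == 1) v else v[sample.int(length(v), n_rep,
                                                           replace = TRUE)]
    }
    aerr <- abs(draw - ga)
    null_mae <- colMeans(aerr)
    null_sd <- apply(aerr, 2, stats::sd)
    structure(list(null_mae = null_mae, null_sd = null_sd,
                   p_mae = sum(null_mae < reference_mae) / n_rep,
                   p_sd = sum(null_sd < reference_sd) / n_rep,
                   unit = unit, n_rep = n_rep,
                   n_excluded_stacks = n_excluded,
                   reference_mae = reference_mae, reference_sd = reference_sd),
              class = "random_selection_test")
  })
}

#' Compare aggregation measures (paired, nonparametric)
#'
#' Friedman omnibus over the measures' absolute PADs (same subjects in every
#' column), followed by pairwise Wilcoxon signed-rank tests.
#'
#' @param abs_pads Matrix of absolute PADs: one row per subject, one named
#'   column per measure.
#' @return A list of class `measure_comparison`: `friedman` (statistic, df,
#'   p), `pairwise` (data frame with n, statistic, p per pair).
#' @export
compare_measures <- function(abs_pads) {
  abs_pads <- as.matrix(abs_pads)
  if (is.null(colnames(abs_pads)) || ncol(abs_pads) < 2)
    stop("abs_pads needs >= 2 named measure columns", call. = FALSE)
  if (anyNA(abs_pads)) stop("unpaired subjects (NA) in abs_pads", call. = FALSE)
  fr <- stats::friedman.test(abs_pads)
  if (is.nan(fr$statistic)) {   # fully tied ranks (identical columns)
    fr$statistic[] <- 0
    fr$p.value <- 1
  }
  pairs <- utils::combn(colnames(abs_pads), 2)
  pw <- apply(pairs, 2, function(pr) {
    wt <- suppressWarnings(stats::wilcox.test(abs_pads[, pr[1]],
                                              abs_pads[, pr[2]],
                                              paired = TRUE, exact = FALSE))
    data.frame(measure_a = pr[1], measure_b = pr[2], n = nrow(abs_pads),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  structure(list(friedman = list(statistic = unname(fr$statistic),
                                 df = unname(fr$parameter), p = fr$p.value),
                 pairwise = do.call(rbind, pw)),
            class = "measure_comparison")
}

#' Compare absolute PADs across gestational age groups
#'
#' Kruskal-Wallis test of the absolute PADs over the nine age groups.
#'
#' @param abs_pads Absolute PADs, one per subject.
#' @param ga_weeks Matching gestational ages.
#' @return List with `statistic`, `df`, `p`, and the per-group counts.
#' @export
compare_age_groups <- function(abs_pads, ga_weeks) {
  stopifnot(length(abs_pads) == length(ga_weeks))
  grp <- vapply(ga_weeks, age_group_label, integer(1))
  kw <- stats::kruskal.test(abs_pads, factor(grp))
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, group_counts = table(grp))
}

#' Compare network input strategies on stack-wise errors
#'
#' Pairwise Wilcoxon signed-rank tests of stack-wise absolute PADs between
#' architectures, on the same stacks.
#'
#' @param stack_abs_pads Matrix: one row per stack, one named column per
#'   architecture.
#' @return Data frame with `arch_a`, `arch_b`, `n`, `statistic`, `p`,
#'   `median_a`, `median_b` per pair.
#' @export
compare_architectures <- function(stack_abs_pads) {
  stack_abs_pads <- as.matrix(stack_abs_pads)
  if (is.null(colnames(stack_abs_pads)) || ncol(stack_abs_pads) < 2)
    stop("need >= 2 named architecture columns", call. = FALSE)
  if (anyNA(stack_abs_pads)) stop("mismatched stack sets (NA)", call. = FALSE)
  pairs <- utils::combn(colnames(stack_abs_pads), 2)
  out <- apply(pairs, 2, function(pr) {
    wt <- suppressWarnings(stats::wilcox.test(stack_abs_pads[, pr[1]],
                                              stack_abs_pads[, pr[2]],
                                              paired = TRUE, exact = FALSE))
    data.frame(arch_a = pr[1], arch_b = pr[2], n = nrow(stack_abs_pads),
               statistic = unname(wt$statistic), p = wt$p.value,
               median_a = stats::median(stack_abs_pads[, pr[1]]),
               median_b = stats::median(stack_abs_pads[, pr[2]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a per-slice prediction cohort
#'
#' Generates synthetic per-slice brain-age predictions around known
#' gestational ages: Gaussian slice noise plus a contaminated fraction of
#' outlier slices shifted by a fixed offset (emulating motion-corrupted
#' slices). Used to study aggregation robustness and the random-selection
#' test without training a network.
#'
#' @param n_subjects Number of subjects.
#' @param n_pred Predictions (slices) per subject.
#' @param noise_sd SD of the per-slice prediction noise, weeks.
#' @param contam_rate Fraction of slices contaminated.
#' @param contam_shift Contamination offset, weeks.
#' @param ga_range Gestational-age range (uniform draw).
#' @param slices_per_stack Grouping used to form stacks.
#' @param seed RNG seed.
#' @return A predictions table shaped like [predict_tta_dataset()] output.
#' @export
simulate_prediction_cohort <- function(n_subjects = 200L, n_pred = 36L,
                                       noise_sd = 0.3, contam_rate = 0.2,
                                       contam_shift = 2,
                                       ga_range = c(16, 38.5),
                                       slices_per_stack = 4L, seed = 1L) {
  with_seed(derive_seed(seed, "simcohort"), {
    ga <- stats::runif(n_subjects, ga_range[1], ga_range[2])
    n_stacks <- ceiling(n_pred / slices_per_stack)
    rows <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      p <- ga[s] + stats::rnorm(n_pred, 0, noise_sd)
      bad <- stats::runif(n_pred) < contam_rate
      p[bad] <- p[bad] + contam_shift
      sid <- sprintf("sub%03d", s)
      rows[[s]] <- data.frame(
        subject_id = sid,
        stack_id = sprintf("%s_s%02d", sid,
                           rep(seq_len(n_stacks), each = slices_per_stack,
                               length.out = n_pred)),
        slice_index = seq_len(n_pred), plane = NA_character_,
        ga_weeks = ga[s], n_tta = NA_integer_, p_tta = p,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Full evaluation report for a predictions table
#'
#' Computes per-measure aggregates (mean, median, mode at the configured
#' class interval), MAE/SD, the measure and age-group comparisons, and the
#' random-selection tests, in one structured object.
#'
#' @param preds Predictions table.
#' @param class_interval Mode class interval, weeks.
#' @param n_rep Random-selection replicates.
#' @param seed RNG seed.
#' @return A list of class `evaluation_report`.
#' @export
evaluation_report <- function(preds, class_interval = 0.2, n_rep = 10000L,
                              seed = 1L) {
  aggs <- lapply(c(mean = "mean", median = "median", mode = "mode"),
                 function(m) aggregate_cohort(preds, m, class_interval))
  ms <- lapply(aggs, function(a) mae_sd(a$pad))
  abs_pads <- do.call(cbind, lapply(aggs, function(a) abs(a$pad)))
  colnames(abs_pads) <- names(aggs)
  ref <- ms$mode
  rst_slice <- random_selection_test(preds, ref[["mae"]], ref[["sd"]],
                                     "single_slice", n_rep, seed)
  rst_stack <- random_selection_test(preds, ref[["mae"]], ref[["sd"]],
                                     "single_stack", n_rep, seed)
  structure(list(
    per_measure = data.frame(measure = names(ms),
                             mae = vapply(ms, `[[`, numeric(1), "mae"),
                             sd = vapply(ms, `[[`, numeric(1), "sd"),
                             row.names = NULL),
    class_interval = class_interval,
    measure_comparison = compare_measures(abs_pads),
    age_groups = compare_age_groups(abs_pads[, "mode"],
                                    aggs$mode$ga_weeks),
    random_selection = list(single_slice = rst_slice,
                            single_stack = rst_stack),
    n_subjects = nrow(aggs$mode), n_rep = n_rep, seed = seed),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation over", x$n_subjects, "subjects\n")
  cat(sprintf("  %-7s MAE %.3f +/- %.3f weeks\n", x$per_measure$measure,
              x$per_measure$mae, x$per_measure$sd), sep = "")
  cat(sprintf("  Friedman chi^2 = %.2f, p = %.3g\n",
              x$measure_comparison$friedman$statistic,
              x$measure_comparison$friedman$p))
  cat(sprintf("  random selection (mode ref): slice p_mae = %.4g, stack p_mae = %.4g\n",
              x$random_selection$single_slice$p_mae,
              x$random_selection$single_stack$p_mae))
  invisible(x)
}
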