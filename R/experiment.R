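# End-to-end desk-scale study: simulate a phantom cohort, train the
# single-channel (and optionally volumetric) regressors, predict held-out
# subjects with TTA, aggregate, and run the evaluation probes. This is the
# one-call reproduction of the package's whole pipeline at CPU scale.

#' Run the desk-scale end-to-end experiment
#'
#' Generates a training and a held-out phantom cohort, trains the 2D
#' single-channel regressor (and the volumetric variant for the
#' input-strategy comparison), computes TTA predictions for the held-out
#' subjects, aggregates them per subject (mean/median/grouped mode), and
#' runs the TTA-variance, saliency-contrast and brain-size probes.
#'
#' @param seed Master seed; every stage derives its stream from it.
#' @param n_train,n_test Cohort sizes (subjects).
#' @param n_tta Test-time augmentations per slice.
#' @param epochs_max,patience Training schedule of the desk profile.
#' @param include_volumetric Train the 3D variant and compare stack-wise
#'   errors.
#' @param n_var_reps Repetitions for the TTA variance-reduction estimate.
#' @param verbose Print progress.
#' @return A list with the fitted models, the held-out predictions table,
#'   per-measure aggregates and MAEs, stack-wise comparison, TTA variance
#'   ratio, saliency contrast, and size-probe results.
#' @export
desk_experiment <- function(seed = 1L, n_train = 120L, n_test = 15L,
                            n_tta = 20L, epochs_max = 15L, patience = 5L,
                            include_volumetric = TRUE, n_var_reps = 200L,
                            verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating %d + %d subjects", n_train, n_test)
  coh_tr <- generate_cohort(n_train, seed = derive_seed(seed, "train_cohort"))
  coh_te <- generate_cohort(n_test, seed = derive_seed(seed, "test_cohort"))
  say("preprocessing")
  pp_tr <- preprocess_cohort(coh_tr)
  pp_te <- preprocess_cohort(coh_te)
  ds_tr <- assemble_dataset(pp_tr, "single_channel_2d")
  ds_te <- assemble_dataset(pp_te, "single_channel_2d")

  cfg <- train_config("desk", epochs_max = epochs_max, patience = patience)
  say("training single-channel 2D on %d slices", length(ds_tr$x))
  fit1 <- fit_brainage(ds_tr, model_spec("single_channel_2d"), cfg,
                       seed = derive_seed(seed, "fit_single"),
                       verbose = verbose)

  say("TTA predictions on %d held-out slices", length(ds_te$x))
  preds <- predict_tta_dataset(fit1, ds_te, n_tta = n_tta,
                               seed = derive_seed(seed, "tta"))
  aggs <- lapply(c(mean = "mean", median = "median", mode = "mode"),
                 function(m) aggregate_cohort(preds, m, 0.2))
  maes <- vapply(aggs, function(a) mae_sd(a$pad)[["mae"]], numeric(1))
  heldout_spearman <- stats::cor(aggs$mode$ga_weeks, aggs$mode$brain_age,
                                 method = "spearman")

  st1 <- stackwise_cohort(preds)

  out <- list(fit_single = fit1, preds = preds, aggregates = aggs,
              mae_by_measure = maes, heldout_spearman = heldout_spearman,
              stackwise_single = st1,
              stackwise_mae_single = mean(abs(st1$pad)))

  if (include_volumetric) {
    ds3_tr <- assemble_dataset(pp_tr, "volumetric_3d")
    ds3_te <- assemble_dataset(pp_te, "volumetric_3d")
    say("training volumetric 3D on %d stacks", length(ds3_tr$x))
    fit3 <- fit_brainage(ds3_tr, model_spec("volumetric_3d"), cfg,
                         seed = derive_seed(seed, "fit_vol"),
                         verbose = verbose)
    preds3 <- predict_tta_dataset(fit3, ds3_te, n_tta = n_tta,
                                  seed = derive_seed(seed, "tta3"))
    m <- match(st1$stack_id, preds3$stack_id)
    apad <- cbind(single_channel = abs(st1$pad),
                  volumetric = abs(preds3$ga_weeks - preds3$p_tta)[m])
    out$fit_volumetric <- fit3
    out$stackwise_mae_volumetric <- mean(apad[, "volumetric"])
    out$architecture_comparison <- compare_architectures(apad)
  }

  # TTA variance reduction on one fixed held-out slice
  say("TTA variance probe")
  sl <- ds_te$x[[1L]]
  v20 <- vapply(seq_len(n_var_reps), function(r)
    predict_tta(fit1, sl, n_tta = n_tta,
                seed = derive_seed(seed, paste0("v20_", r)))$p_tta, numeric(1))
  v1 <- vapply(seq_len(n_var_reps), function(r)
    predict_tta(fit1, sl, n_tta = 1L,
                seed = derive_seed(seed, paste0("v1_", r)))$p_tta, numeric(1))
  out$tta_variance <- c(var_n20 = stats::var(v20), var_n1 = stats::var(v1),
                        ratio = stats::var(v20) / stats::var(v1))

  # saliency contrast: cortical rim + ventricles vs remaining interior
  say("saliency probe")
  sal_slices <- list()
  for (subj in pp_te$subjects)
    for (stk in subj$stacks)
      for (s in stk$slices) if (!is.null(s$truth))
        sal_slices[[length(sal_slices) + 1]] <- s
  sal_slices <- sal_slices[seq_len(min(12L, length(sal_slices)))]
  ratios <- vapply(sal_slices, function(s) {
    sal <- compute_saliency(fit1, s)
    roi <- (s$truth$rim + s$truth$ventricle) > 0.3
    if (!any(roi) || !any(s$mask & !roi)) return(NA_real_)
    saliency_region_contrast(sal, roi, s$mask)[["ratio"]]
  }, numeric(1))
  out$saliency_ratios <- ratios[is.finite(ratios)]
  out$saliency_mean_ratio <- mean(out$saliency_ratios)

  # brain-size scaling probe on held-out slices
  say("size probe")
  probe_slices <- list()
  for (subj in pp_te$subjects)
    for (stk in subj$stacks)
      for (s in stk$slices)
        probe_slices[[length(probe_slices) + 1]] <- s
  idx <- round(seq(1, length(probe_slices), length.out = min(30, length(probe_slices))))
  out$size_probe <- size_scaling_probe(fit1, probe_slices[idx],
                                       scales = c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0))
  out$seed <- seed
  out
}
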