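# Model module: loss, augmentation, architecture geometry, and the training
# harness contracts (subject-level splits, oversampling, early stopping).

test_that("Huber loss follows its closed forms and rejects bad input", {
  expect_equal(huber_loss(30, 30, 1), 0)
  expect_equal(huber_loss(30, 30.5, 1), 0.125)
  expect_equal(huber_loss(30, 32, 1), 1.5)
  # continuity and differentiability at the switch point
  d <- 1e-8
  expect_equal(huber_loss(0, 1 - d, 1), huber_loss(0, 1 + d, 1),
               tolerance = 1e-6)
  expect_error(huber_loss(NA, 30), "finite")
  expect_error(huber_loss(30, 30, delta = 0), "delta")
})

test_that("augmentation is identity under identity draws and scales intensities exactly", {
  set.seed(1)
  img <- matrix(runif(64 * 64), 64)
  expect_identical(augment_slice(img, fetalage:::identity_draw()), img)
  d <- fetalage:::identity_draw(); d$gain <- 0.5
  expect_equal(augment_slice(img, d), img / 2)
  # flips are exact and involutive
  d <- fetalage:::identity_draw(); d$vflip <- TRUE
  expect_identical(augment_slice(augment_slice(img, d), d), img)
})

test_that("pure rotations preserve mask area within interpolation tolerance", {
  stk <- quick_stack(seed = 5)
  pp <- preprocess_stack(stk)
  msk <- pp$slices[[pp$selected[2]]]$mask + 0   # binary support
  a0 <- sum(msk)
  set.seed(42)
  for (r in 1:10) {
    d <- fetalage:::identity_draw()
    d$angle <- runif(1, 0, 360)
    rot <- augment_slice(msk, d)
    expect_equal(sum(rot > 0.5), a0, tolerance = 0.02)
  }
})

test_that("built models emit one scalar per sample and the desk profile is tiny", {
  f1 <- stub_fit(shape = c(64L, 64L))
  x <- lapply(1:3, function(i) matrix(runif(64 * 64), 64))
  expect_length(fetalage:::net_predict(f1$net, x, "single_channel_2d"), 3)
  fm <- stub_fit(mode = "multi_channel_2d")
  xm <- lapply(1:2, function(i) array(runif(4 * 64 * 64), c(4, 64, 64)))
  expect_length(fetalage:::net_predict(fm$net, xm, "multi_channel_2d"), 2)
  f3 <- stub_fit(mode = "volumetric_3d")
  expect_length(fetalage:::net_predict(f3$net, xm, "volumetric_3d"), 2)

  n_desk <- fetalage:::nn_count_params(build_model(model_spec(), seed = 1))
  n_paper <- fetalage:::nn_count_params(
    build_model(model_spec(depth_profile = "paper"), seed = 1))
  expect_gt(n_paper, 4e7)                 # 101-layer bottleneck scale
  expect_lt(n_desk / n_paper, 0.05)
})

test_that("subject-level folds never split a subject and stratify over age groups", {
  set.seed(9)
  subj <- sprintf("s%02d", 1:40)
  ga <- runif(40, 16, 38.5)
  fold <- make_folds(subj, ga, folds = 5, seed = 2)
  expect_length(fold, 40)
  expect_setequal(unique(fold), 1:5)
  # near-balanced: within-stratum assignment is even up to one subject,
  # so fold sizes differ by at most the number of strata
  expect_lte(max(table(fold)) - min(table(fold)), 9)
  # oversampling balances the nine age-group bins
  os <- fetalage:::oversample_subjects(subj, ga)
  bins <- vapply(ga[match(os, subj)], age_group_label, integer(1))
  tab <- table(bins)
  expect_lte(max(tab) / min(tab), 1.25)
})

test_that("training reduces loss quickly on a clean small cohort and stops early", {
  coh <- generate_cohort(12, ga_range = c(17, 38), seed = 61,
                         params_fn = function(ga)
                           phantom_params(ga, noise_sigma = 0.01,
                                          motion_jitter_mm = 0.2,
                                          motion_jitter_deg = 0.5))
  pp <- preprocess_cohort(coh)
  ds <- assemble_dataset(pp, "single_channel_2d")
  cfg <- train_config("desk", epochs_max = 10, patience = 3)
  fit <- fit_brainage(ds, model_spec(), cfg, seed = 8)
  expect_s3_class(fit, "brainage_fit")
  expect_lt(utils::tail(fit$log$train_loss, 1), fit$log$train_loss[1])
  # early stopping: no more than `patience` epochs beyond the best one
  expect_lte(nrow(fit$log) - fit$best_epoch, cfg$patience)
  # validation subjects never appear in the training stream
  expect_true(all(fit$val_subjects %in% ds$subject_id))
  # per-fold CV keeps each subject's slices in exactly one test fold
  cv <- fit_brainage_cv(ds, model_spec(),
                        train_config("desk", epochs_max = 1, patience = 1,
                                     folds = 2),
                        seed = 3)
  ts <- unname(unlist(cv$test_subjects))
  expect_setequal(unique(ds$subject_id), ts)
  expect_false(any(duplicated(ts)))
  # deterministic retraining
  fit2 <- fit_brainage(ds, model_spec(), cfg, seed = 8)
  expect_identical(fit$log, fit2$log)
})
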