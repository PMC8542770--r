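# Preprocessing chain: masking accuracy, bias-correction and denoising
# contracts, resampling geometry, and center-slice selection.

test_that("masking recovers the true brain support on clean and noisy phantoms", {
  p0 <- clean_params(26)
  stk0 <- quick_stack(params = p0, seed = 3)
  mk0 <- mask_brain(stk0)
  mid <- which.max(vapply(stk0$truth$support, sum, numeric(1)))
  truth <- stk0$truth$support[[mid]] > 0.5
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gt(dice(mk0$masks[[mid]], truth), 0.98)   # noiseless: near-exact

  # default noise level: Dice >= 0.9 over several seeds
  p1 <- quick_params(26)
  dices <- vapply(1:8, function(sd_) {
    stk <- quick_stack(params = p1, seed = sd_)
    mk <- mask_brain(stk)
    mid <- which.max(vapply(stk$truth$support, sum, numeric(1)))
    dice(mk$masks[[mid]], stk$truth$support[[mid]] > 0.5)
  }, numeric(1))
  expect_true(all(dices >= 0.9))

  # all-zero slice is flagged unusable, not fatal
  stk0$slices[[1]] <- matrix(0, 48, 48)
  mk <- mask_brain(stk0)
  expect_false(mk$usable[1])
})

test_that("bias correction reduces rim inhomogeneity and passes clean stacks through", {
  p0 <- clean_params(26)
  vol <- generate_volume(p0, seed = 3, n_vox = 48)
  covs <- vapply(1:10, function(sd_) {
    pb <- phantom_params(26, noise_sigma = 0, bias_strength = 0.4,
                         motion_jitter_mm = 0, motion_jitter_deg = 0)
    stk <- acquire_stack(vol, "axial", pb, seed = sd_)
    cb <- correct_bias(stk, mask_brain(stk))
    # single-tissue region: parenchyma (inside the brain, away from the
    # textured ribbon and the ventricles)
    cov_of <- function(s) {
      v <- unlist(lapply(seq_along(s$slices), function(i) {
        reg <- s$truth$support[[i]] > 0.95 & s$truth$rim[[i]] < 0.05 &
          s$truth$ventricle[[i]] < 0.05
        s$slices[[i]][reg]
      }))
      stats::sd(v) / mean(v)
    }
    c(before = cov_of(stk), after = cov_of(cb))
  }, numeric(2))
  expect_true(all(covs["after", ] < covs["before", ]))

  stk <- acquire_stack(vol, "axial", p0, seed = 4)
  mk <- mask_brain(stk)
  cb <- correct_bias(stk, mk)
  rel <- max(abs(unlist(cb$slices) - unlist(stk$slices))) / max(unlist(stk$slices))
  expect_lt(rel, 0.01)
})

test_that("denoising halves flat-region noise, preserves masks, is deterministic", {
  p <- phantom_params(26, noise_sigma = 0.07, bias_strength = 0,
                      motion_jitter_mm = 0, motion_jitter_deg = 0)
  stk <- quick_stack(params = p, seed = 11)
  mk <- mask_brain(stk)
  dn <- denoise(stk, mk$usable)
  mid <- which.max(vapply(stk$truth$support, sum, numeric(1)))
  # flat single-intensity region: deep parenchyma (away from ribbon and
  # ventricles), where the only variation is the injected noise
  flat <- stk$truth$support[[mid]] > 0.95 & stk$truth$rim[[mid]] < 0.05 &
    stk$truth$ventricle[[mid]] < 0.05
  expect_gt(sum(flat), 100)
  expect_lt(stats::sd(dn$slices[[mid]][flat]),
            0.5 * stats::sd(stk$slices[[mid]][flat]))
  # mask stability: re-masking the denoised stack stays almost identical
  mk2 <- mask_brain(dn)
  dice <- 2 * sum(mk$masks[[mid]] & mk2$masks[[mid]]) /
    (sum(mk$masks[[mid]]) + sum(mk2$masks[[mid]]))
  expect_gte(dice, 0.99)
  expect_identical(denoise(stk, mk$usable)$slices, dn$slices)
  # zero-noise input passes through (nearly) unchanged
  p0 <- clean_params(26)
  stk0 <- quick_stack(params = p0, seed = 11)
  dn0 <- denoise(stk0)
  expect_equal(dn0$slices, stk0$slices, tolerance = 1e-6)
})

test_that("resampling preserves physical size and pads with exact zeros", {
  p0 <- clean_params(26)
  stk <- quick_stack(params = p0, seed = 3)
  mk <- mask_brain(stk)
  pp <- resample_crop_pad(stk, mk, shape = c(64L, 64L))
  expect_true(length(pp) >= 1)
  for (s in pp) {
    expect_identical(dim(s$image), c(64L, 64L))
    expect_equal(s$spacing, c(1, 1))
    expect_true(all(s$image[!s$mask] == 0))
    expect_true(all(s$image[1, ] == 0) && all(s$image[, 1] == 0))
  }
  # physical width: mask extent in px at 1 mm ~ extent in mm at 1.5 mm/px
  mid <- which.max(vapply(pp, function(s) sum(s$mask), numeric(1)))
  w_mm_in <- max(rowSums(mk$masks[[which.max(vapply(mk$masks, sum, numeric(1)))]] > 0))
  w_px_out <- max(rowSums(pp[[mid]]$mask))
  expect_equal(w_px_out, w_mm_in * 1.5, tolerance = 0.1)
  # over-large brain is a configuration error naming the stack
  expect_error(resample_crop_pad(stk, mk, shape = c(16L, 16L)),
               "exceeds canonical shape")
})

test_that("center-slice selection picks the mask-weighted center with low-index ties", {
  # synthetic symmetric mask profile: 11 usable slices
  stk <- list(positions_mm = seq(0, 30, by = 3), stack_id = "t",
              subject_id = "t")
  areas <- c(1, 2, 4, 8, 12, 14, 12, 8, 4, 2, 1)
  masks <- lapply(areas, function(a) matrix(rep(TRUE, a), nrow = a, ncol = 1))
  mk <- list(masks = masks, usable = rep(TRUE, 11))
  # centroid is at slice 6; distance ties at slices 4 vs 8 resolve low
  expect_identical(select_center_slices(stk, mk, k = 4), c(4L, 5L, 6L, 7L))
  expect_identical(select_center_slices(stk, mk, k = 1), 6L)
  mk3 <- list(masks = masks[1:3], usable = c(TRUE, TRUE, TRUE))
  stk3 <- list(positions_mm = seq(0, 6, by = 3), stack_id = "t", subject_id = "t")
  expect_warning(out <- select_center_slices(stk3, mk3, k = 4), "usable")
  expect_identical(out, c(1L, 2L, 3L))
})

test_that("cohort preprocessing drops oversized stacks with a warning, not an error", {
  coh <- generate_cohort(2, ga_range = c(30, 34), seed = 12, n_vox = 48)
  ws <- capture_warnings(pp <- preprocess_cohort(coh, shape = c(24L, 24L)))
  expect_true(any(grepl("dropping stack", ws)))
  expect_s3_class(pp, "preprocessed_cohort")
})

test_that("the full chain is deterministic with constant shape and zeroed background", {
  stk <- quick_stack(seed = 21)
  a <- preprocess_stack(stk, shape = c(64L, 64L))
  b <- preprocess_stack(stk, shape = c(64L, 64L))
  expect_identical(a$slices, b$slices)
  expect_length(a$selected, 4L)
  for (s in a$slices) {
    expect_identical(dim(s$image), c(64L, 64L))
    expect_true(all(s$image[!s$mask] == 0))
  }
})
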