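# Phantom generator: determinism, gestational growth, acquisition geometry
# and corruption hooks.

test_that("parameter validation rejects out-of-range and degenerate values", {
  expect_error(phantom_params(14), "15.9")
  expect_error(phantom_params(39), "15.9")
  expect_error(phantom_params(25, base_radius_mm = -1), "positive")
  expect_error(phantom_params(25, noise_sigma = -0.1), "non-negative")
  p <- phantom_params(30)
  expect_s3_class(p, "phantom_params")
  # GA schedules: folding grows, ventricles shrink after their peak
  expect_gt(phantom_params(35)$fold_amplitude, phantom_params(20)$fold_amplitude)
  expect_lt(phantom_params(35)$ventricle_scale, phantom_params(22)$ventricle_scale)
})

test_that("volume generation is deterministic and degenerates to a smooth ellipsoid", {
  p <- phantom_params(24, fold_amplitude = 0, ventricle_scale = 1e-9,
                      noise_sigma = 0)
  v1 <- generate_volume(p, seed = 5, n_vox = 48)
  v2 <- generate_volume(p, seed = 5, n_vox = 48)
  expect_identical(v1$img, v2$img)
  expect_equal(sum(v1$ventricle), 0)
  # smooth ellipsoid: mask matches the analytic ellipsoid voxel count closely
  R <- 11 + 0.55 * (24 - 16)
  co <- (seq_len(48) - 1 - 23.5) * 1.5
  X <- array(co, c(48, 48, 48))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  inside <- (X / R)^2 + (Y / (0.85 * R))^2 + (Z / (0.9 * R))^2 <= 1
  expect_equal(sum(v1$mask), sum(inside), tolerance = 0.02)
})

test_that("brain-mask volume grows strictly with gestational age", {
  vols <- vapply(seq(16, 38, by = 2), function(g) {
    sum(generate_volume(phantom_params(g, noise_sigma = 0), seed = 3)$mask)
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("uncorrupted acquisition is an exact slab average with the right slice count", {
  p <- clean_params(24)
  vol <- generate_volume(p, seed = 5, n_vox = 48)
  stk <- acquire_stack(vol, "axial", p, seed = 9)
  per_slab <- round(p$slice_thickness_mm / p$inplane_mm)  # 2 voxels
  expect_length(stk$slices, ceiling(dim(vol$img)[3] / per_slab))
  # oracle: direct averaging of the two voxel layers of slab 3
  expect_equal(stk$slices[[3]], (vol$img[, , 5] + vol$img[, , 6]) / 2)
  expect_error(acquire_stack(vol, "oblique", p), "arg")
})

test_that("acquisition planes resample along the three orthogonal normals", {
  p <- clean_params(30)
  vol <- generate_volume(p, seed = 2, n_vox = 48)
  ns <- vapply(c("axial", "coronal", "sagittal"), function(pl)
    length(acquire_stack(vol, pl, p, seed = 1)$slices), numeric(1))
  expect_true(all(ns >= 12 & ns <= 60))
  # different planes see different slice content
  a <- acquire_stack(vol, "axial", p, seed = 1)
  s <- acquire_stack(vol, "sagittal", p, seed = 1)
  expect_false(isTRUE(all.equal(a$slices[[12]], s$slices[[12]])))
})

test_that("motion jitter moves per-slice mask centroids with about the configured SD", {
  p <- phantom_params(30, noise_sigma = 0, bias_strength = 0,
                      motion_jitter_mm = 3, motion_jitter_deg = 0)
  vol <- generate_volume(p, seed = 4, n_vox = 48)
  devs <- unlist(lapply(1:30, function(sd_) {
    stk <- acquire_stack(vol, "axial", p, seed = sd_)
    mid <- which.max(vapply(stk$truth$support, sum, numeric(1)))
    idx <- (mid - 2):(mid + 2)   # central slices: stable true centroid
    vapply(idx, function(s) {
      m <- stk$truth$support[[s]] > 0.5
      w <- which(m, arr.ind = TRUE)
      mean(w[, 1]) * p$inplane_mm
    }, numeric(1))
  }))
  # per-slice jitter SD in mm (row coordinate); compare to configured 3 mm
  expect_equal(stats::sd(devs), 3, tolerance = 0.25)
})

test_that("cohort generation is reproducible, stratified and writes valid NIfTI", {
  td <- withr::local_tempdir()
  c1 <- generate_cohort(8, ga_range = c(17, 37), stacks_per_subject = 2,
                        seed = 33, out_dir = td, n_vox = 48)
  expect_error(generate_cohort(8, seed = 33, out_dir = td), "overwrite")
  expect_equal(nrow(c1$manifest), 16)
  expect_length(unique(c1$manifest$subject_id), 8)
  # stratification: 2 subjects in each of the 4 GA quarters
  edges <- seq(17, 37, length.out = 5)
  ga <- c1$manifest$ga_weeks[!duplicated(c1$manifest$subject_id)]
  expect_equal(unname(table(cut(ga, edges))), rep(2L, 4),
               ignore_attr = TRUE)
  # round-trip through NIfTI preserves voxels and spacing
  stk <- read_stack_nifti(c1$manifest$path[1], plane = c1$manifest$plane[1])
  expect_equal(stk$inplane_spacing_mm, c(1.5, 1.5), ignore_attr = TRUE)
  expect_equal(stk$thickness_mm, 3, ignore_attr = TRUE)
  # manifest round-trip rebuilds the cohort in memory
  rc <- read_cohort(file.path(td, "manifest.csv"))
  expect_length(rc$subjects, 8)
  expect_equal(rc$subjects[[1]]$ga_weeks,
               c1$manifest$ga_weeks[c1$manifest$subject_id ==
                                      rc$subjects[[1]]$subject_id][1])
  expect_length(rc$subjects[[1]]$stacks, 2)
  c2 <- generate_cohort(8, ga_range = c(17, 37), stacks_per_subject = 2,
                        seed = 33, n_vox = 48)
  expect_equal(c2$subjects[[1]]$stacks[[1]]$slices,
               lapply(seq_along(stk$slices), function(i) stk$slices[[i]]),
               tolerance = 1e-6)  # float32 storage
  # in-memory generation is bit-reproducible
  c3 <- generate_cohort(8, ga_range = c(17, 37), stacks_per_subject = 2,
                        seed = 33, n_vox = 48)
  expect_identical(c2$subjects[[3]]$stacks[[2]]$slices,
                   c3$subjects[[3]]$stacks[[2]]$slices)
  expect_identical(c2$manifest$ga_weeks, c3$manifest$ga_weeks)
})
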