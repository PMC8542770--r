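# Synthetic fetal-brain MRI phantoms.
#
# The phantom is a geometric stand-in for the developing fetal brain, not an
# anatomical atlas. It encodes the three image cues known to track gestation:
# overall brain size (monotone growth), cortical-ribbon folding complexity
# (increasing), and ventricle prominence (waning after a mid-gestation peak).
# Acquisition artifacts -- thick slices, per-slice rigid motion jitter, smooth
# intensity inhomogeneity, additive noise -- are applied when a volume is
# resampled into a stack, mirroring how multiplanar T2-weighted stacks are
# collected clinically.

#' Phantom simulation parameters
#'
#' Builds a validated parameter set for the fetal-brain phantom at a given
#' gestational age (GA). Folding amplitude/frequency and ventricle scale
#' default to GA-dependent schedules so that each cue carries independent age
#' information; any of them can be overridden.
#'
#' @param ga_weeks Gestational age in weeks, within the modeled range
#'   (15.9-38.7).
#' @param base_radius_mm Major brain semi-axis at the 16-week reference, mm.
#' @param growth_rate Radius growth per gestational week, mm/week.
#' @param fold_amplitude Cortical ribbon radial perturbation amplitude, mm.
#'   Default grows linearly with GA.
#' @param fold_frequency Angular frequency of the cortical perturbation.
#'   Default grows linearly with GA.
#' @param ventricle_scale Ventricle size relative to brain radius. Default
#'   peaks at 22 weeks and declines thereafter.
#' @param noise_sigma Additive Gaussian noise SD (intensity units; tissue
#'   intensities are on a 0-1 scale).
#' @param bias_strength Peak-to-trough relative amplitude of the smooth
#'   multiplicative bias field.
#' @param motion_jitter_mm SD of the per-slice in-plane rigid translation, mm.
#' @param motion_jitter_deg SD of the per-slice in-plane rotation, degrees.
#' @param slice_thickness_mm Slice thickness of acquired stacks (2-4 mm).
#' @param inplane_mm In-plane spacing of the acquired slices, mm.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(ga_weeks,
                           base_radius_mm = 11,
                           growth_rate = 0.55,
                           fold_amplitude = NULL,
                           fold_frequency = NULL,
                           ventricle_scale = NULL,
                           noise_sigma = 0.05,
                           bias_strength = 0.2,
                           motion_jitter_mm = 0.5,
                           motion_jitter_deg = 1,
                           slice_thickness_mm = 3,
                           inplane_mm = 1.5) {
  assert_finite(ga_weeks, "ga_weeks")
  if (ga_weeks < 15.9 || ga_weeks > 38.7)
    stop("ga_weeks must lie in [15.9, 38.7]", call. = FALSE)
  if (is.null(fold_amplitude)) fold_amplitude <- max(0, 0.08 * (ga_weeks - 16))
  if (is.null(fold_frequency)) fold_frequency <- 4 + 0.35 * (ga_weeks - 16)
  if (is.null(ventricle_scale)) {
    ventricle_scale <- if (ga_weeks <= 22) 0.45 - 0.02 * (22 - ga_weeks)
                       else max(0.1, 0.45 - 0.012 * (ga_weeks - 22))
  }
  p <- list(ga_weeks = ga_weeks, base_radius_mm = base_radius_mm,
            growth_rate = growth_rate, fold_amplitude = fold_amplitude,
            fold_frequency = fold_frequency, ventricle_scale = ventricle_scale,
            noise_sigma = noise_sigma, bias_strength = bias_strength,
            motion_jitter_mm = motion_jitter_mm,
            motion_jitter_deg = motion_jitter_deg,
            slice_thickness_mm = slice_thickness_mm, inplane_mm = inplane_mm)
  for (nm in c("base_radius_mm", "growth_rate", "slice_thickness_mm", "inplane_mm")) {
    assert_finite(p[[nm]], nm)
    if (p[[nm]] <= 0) stop(nm, " must be strictly positive", call. = FALSE)
  }
  for (nm in c("fold_amplitude", "fold_frequency", "ventricle_scale",
               "noise_sigma", "bias_strength", "motion_jitter_mm",
               "motion_jitter_deg")) {
    assert_finite(p[[nm]], nm)
    if (p[[nm]] < 0) stop(nm, " must be non-negative", call. = FALSE)
  }
  if (p$slice_thickness_mm < p$inplane_mm)
    stop("slice_thickness_mm must be at least the in-plane spacing", call. = FALSE)
  class(p) <- "phantom_params"
  p
}

#' Generate a 3D phantom brain volume
#'
#' Renders the phantom at isotropic resolution `params$inplane_mm`:
#' a bright brain ellipsoid (mean major semi-axis
#' `base_radius_mm + growth_rate * (ga_weeks - 16)`), a brighter cortical rim
#' whose outer boundary is radially perturbed by
#' `fold_amplitude * sin(fold_frequency * theta)` patterns and whose
#' intensity is textured by the same angular pattern (folding complexity as
#' an image cue), darker paired ventricles scaled by `ventricle_scale`, and
#' zero background. The only
#' randomness is the fold/ventricle phase, drawn from `seed`; the output is a
#' pure function of `(params, seed)`.
#'
#' @param params A [phantom_params()] object.
#' @param seed Integer seed controlling the fold phase.
#' @param n_vox Grid size per axis (isotropic).
#' @return A list of class `phantom_volume`: `img` (3D array), `voxel_mm`,
#'   ground-truth region indicators `mask`, `rim`, `ventricle`, and `params`.
#' @export
generate_volume <- function(params, seed = 1L, n_vox = 64L) {
  stopifnot(inherits(params, "phantom_params"))
  R <- params$base_radius_mm + params$growth_rate * (params$ga_weeks - 16)
  if (!is.finite(R) || R <= 0) stop("non-positive brain radius", call. = FALSE)
  ax <- c(R, 0.85 * R, 0.9 * R)          # semi-axes, mm
  v <- params$inplane_mm
  half <- (n_vox - 1) / 2
  co <- (seq_len(n_vox) - 1 - half) * v   # mm, centered
  if (max(ax) + params$fold_amplitude >= max(co))
    stop("brain does not fit in the volume; increase n_vox", call. = FALSE)

  phase <- with_seed(seed, stats::runif(4, 0, 2 * pi))

  X <- array(co, c(n_vox, n_vox, n_vox))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  # normalized ellipsoidal radius and angles
  rho <- sqrt((X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2)
  theta <- atan2(Y, X)
  phi <- atan2(Z, sqrt(X^2 + Y^2))
  pert <- (params$fold_amplitude / R) *
    sin(params$fold_frequency * theta + phase[1]) *
    cos(params$fold_frequency * 0.5 * phi + phase[2])
  rim_mm <- 2.5                             # cortical ribbon thickness, mm
  outer_b <- 1 + pert
  inner_b <- outer_b - rim_mm / R
  mask <- rho <= outer_b
  rim <- mask & rho > inner_b

  # paired ventricles: ellipsoids offset laterally, scaled by ventricle_scale
  vs <- params$ventricle_scale
  vax <- vs * R * c(0.55, 0.3, 0.65)
  off <- 0.25 * R
  vent <- (((X) / vax[1])^2 + ((Y - off) / vax[2])^2 + (Z / vax[3])^2 <= 1) |
          (((X) / vax[1])^2 + ((Y + off) / vax[2])^2 + (Z / vax[3])^2 <= 1)
  vent <- vent & mask & !rim

  img <- array(0, dim(mask))
  img[mask] <- 0.7
  # cortical ribbon: bright, with intensity texture following the fold
  # pattern so folding complexity is an image cue, not just a boundary wiggle
  tex_amp <- 0.25 * tanh(params$fold_amplitude)   # vanishes with the folds
  rimtex <- 1 + tex_amp * sin(params$fold_frequency * theta + phase[3]) *
    cos(params$fold_frequency * 0.5 * phi + phase[4])
  img[rim] <- rimtex[rim]
  img[vent] <- 0.35
  structure(list(img = img, voxel_mm = v, mask = mask, rim = rim,
                 ventricle = vent, params = params),
            class = "phantom_volume")
}

#' Acquire a thick-slice stack from a phantom volume
#'
#' Resamples the volume into thick slices along the normal of the requested
#' plane (averaging within each slab of `slice_thickness_mm`), then corrupts
#' each slice with an independent in-plane rigid jitter (translation SD
#' `motion_jitter_mm`, rotation SD `motion_jitter_deg`), a smooth low-order
#' multiplicative bias field shared by the stack, and additive Gaussian noise.
#' Ground-truth region indicators follow the same slab averaging and rigid
#' jitter, so downstream probes can be scored against them.
#'
#' @param volume A `phantom_volume`.
#' @param plane One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param params A [phantom_params()] object (usually the volume's).
#' @param seed Integer seed for jitter, bias and noise.
#' @param stack_id,subject_id Identifiers recorded in the stack.
#' @return A list of class `fetal_stack`: `slices` (list of matrices),
#'   `plane`, `inplane_spacing_mm`, `thickness_mm`, `positions_mm` (slab
#'   centers along the normal), identifiers, and ground-truth indicator
#'   slices `truth` (`support`, `rim`, `ventricle`).
#' @export
acquire_stack <- function(volume, plane = c("axial", "coronal", "sagittal"),
                          params = volume$params, seed = 1L,
                          stack_id = "stk1", subject_id = "subj1") {
  stopifnot(inherits(volume, "phantom_volume"))
  plane <- match.arg(plane)
  v <- volume$voxel_mm
  perm <- switch(plane, axial = c(1, 2, 3), coronal = c(1, 3, 2),
                 sagittal = c(2, 3, 1))
  img <- aperm(volume$img, perm)
  tmask <- aperm(volume$mask, perm)
  trim <- aperm(volume$rim, perm)
  tvent <- aperm(volume$ventricle, perm)

  d <- dim(img)
  per_slab <- max(1L, as.integer(round(params$slice_thickness_mm / v)))
  if (d[3] < per_slab) stop("volume smaller than one slab", call. = FALSE)
  n_slices <- as.integer(ceiling(d[3] / per_slab))

  slab_mean <- function(a, lo, hi) {
    s <- a[, , lo]
    if (hi > lo) for (j in (lo + 1):hi) s <- s + a[, , j]
    s / (hi - lo + 1)
  }

  with_seed(seed, {
    # smooth low-order bias field, peak-to-trough amplitude = bias_strength
    bias <- matrix(1, d[1], d[2])
    if (params$bias_strength > 0) {
      cf <- stats::runif(5, -1, 1)
      u <- seq(-1, 1, length.out = d[1]); w <- seq(-1, 1, length.out = d[2])
      g <- outer(u, w, function(a, b)
        cf[1] * a + cf[2] * b + cf[3] * a * b + cf[4] * a^2 + cf[5] * b^2)
      rg <- range(g)
      if (diff(rg) > 0) g <- (g - mean(rg)) / diff(rg)  # in [-1/2, 1/2]
      bias <- 1 + params$bias_strength * g
    }
    slices <- vector("list", n_slices)
    tsup <- vector("list", n_slices); tri <- vector("list", n_slices)
    tve <- vector("list", n_slices)
    positions <- numeric(n_slices)
    for (s in seq_len(n_slices)) {
      lo <- (s - 1L) * per_slab + 1L
      hi <- min(s * per_slab, d[3])
      positions[s] <- v * ((lo + hi) / 2 - 1)
      sl <- slab_mean(img, lo, hi)
      ms <- slab_mean(tmask + 0, lo, hi)
      rs <- slab_mean(trim + 0, lo, hi)
      vs <- slab_mean(tvent + 0, lo, hi)
      ang <- stats::rnorm(1, 0, params$motion_jitter_deg)
      sh <- stats::rnorm(2, 0, params$motion_jitter_mm) / v
      if (params$motion_jitter_deg > 0 || params$motion_jitter_mm > 0) {
        sl <- warp_rigid(sl, ang, sh)
        ms <- warp_rigid(ms, ang, sh)
        rs <- warp_rigid(rs, ang, sh)
        vs <- warp_rigid(vs, ang, sh)
      }
      sl <- sl * bias
      if (params$noise_sigma > 0)
        sl <- sl + matrix(stats::rnorm(length(sl), 0, params$noise_sigma),
                          nrow(sl), ncol(sl))
      slices[[s]] <- sl
      tsup[[s]] <- ms; tri[[s]] <- rs; tve[[s]] <- vs
    }
    structure(list(slices = slices, plane = plane,
                   inplane_spacing_mm = c(v, v),
                   thickness_mm = params$slice_thickness_mm,
                   positions_mm = positions,
                   stack_id = stack_id, subject_id = subject_id,
                   truth = list(support = tsup, rim = tri, ventricle = tve)),
              class = "fetal_stack")
  })
}

#' Simulate one subject (volume + multiplanar stacks)
#'
#' @param subject_id Identifier.
#' @param ga_weeks Gestational age, weeks.
#' @param seed Integer master seed for this subject.
#' @param planes Planes to acquire (one stack per entry).
#' @param params Optional [phantom_params()]; defaults to the GA schedule.
#' @param n_vox Volume grid size.
#' @return A list of class `fetal_subject`: `subject_id`, `ga_weeks`,
#'   `stacks` (list of `fetal_stack`), and the `phantom_volume`.
#' @export
simulate_subject <- function(subject_id, ga_weeks, seed = 1L,
                             planes = c("axial", "coronal", "sagittal"),
                             params = NULL, n_vox = 64L) {
  if (is.null(params)) params <- phantom_params(ga_weeks)
  vol <- generate_volume(params, seed = derive_seed(seed, paste0(subject_id, "_vol")),
                         n_vox = n_vox)
  stacks <- vector("list", length(planes))
  for (i in seq_along(planes)) {
    sid <- sprintf("%s_s%02d", subject_id, i)
    stacks[[i]] <- acquire_stack(vol, planes[i], params,
                                 seed = derive_seed(seed, sid),
                                 stack_id = sid, subject_id = subject_id)
  }
  structure(list(subject_id = subject_id, ga_weeks = ga_weeks,
                 stacks = stacks, volume = vol),
            class = "fetal_subject")
}

#' Generate a synthetic multiplanar cohort
#'
#' Draws gestational ages stratified-uniformly over `n_bins` equal-width bins
#' of `ga_range` and simulates each subject. With `out_dir` set, writes one
#' NIfTI file per stack plus a `manifest.csv` (subject_id, ga_weeks,
#' stack_id, plane, path); otherwise keeps the cohort in memory.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param ga_range Gestational-age range, within [15.9, 38.7].
#' @param stacks_per_subject Number of stacks (planes cycle
#'   axial/coronal/sagittal).
#' @param seed Integer master seed; the cohort is a pure function of it.
#' @param out_dir Optional output directory for NIfTI stacks + manifest.
#' @param overwrite Refuse to overwrite an existing manifest unless `TRUE`.
#' @param params_fn Function `ga -> phantom_params`, defaulting to
#'   [phantom_params()] schedules.
#' @param n_bins Number of strata for the GA draw.
#' @param n_vox Volume grid size per subject.
#' @return A list of class `fetal_cohort`: `subjects` (list of
#'   `fetal_subject`, NULL if written to disk), `manifest` (data frame).
#' @export
generate_cohort <- function(n_subjects, ga_range = c(16, 38.5),
                            stacks_per_subject = 3L, seed = 1L,
                            out_dir = NULL, overwrite = FALSE,
                            params_fn = phantom_params, n_bins = 4L,
                            n_vox = 64L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (ga_range[1] < 15.9 || ga_range[2] > 38.7 || diff(ga_range) <= 0)
    stop("ga_range must be increasing and within [15.9, 38.7]", call. = FALSE)
  planes <- rep_len(c("axial", "coronal", "sagittal"), stacks_per_subject)

  ga <- with_seed(derive_seed(seed, "ga_draw"), {
    edges <- seq(ga_range[1], ga_range[2], length.out = n_bins + 1)
    bin <- rep_len(seq_len(n_bins), n_subjects)   # balanced strata
    stats::runif(n_subjects, edges[bin], edges[bin + 1])
  })

  if (!is.null(out_dir)) {
    manifest_path <- file.path(out_dir, "manifest.csv")
    if (file.exists(manifest_path) && !overwrite)
      stop("manifest already exists at ", manifest_path,
           " (use overwrite = TRUE)", call. = FALSE)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  subjects <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("sub%03d", i)
    subj <- simulate_subject(sid, ga[i], seed = derive_seed(seed, sid),
                             planes = planes, params = params_fn(ga[i]),
                             n_vox = n_vox)
    paths <- rep(NA_character_, length(subj$stacks))
    if (!is.null(out_dir)) {
      for (k in seq_along(subj$stacks)) {
        paths[k] <- file.path(out_dir, paste0(subj$stacks[[k]]$stack_id, ".nii.gz"))
        write_stack_nifti(subj$stacks[[k]], paths[k])
      }
    }
    rows[[i]] <- data.frame(subject_id = sid, ga_weeks = ga[i],
                            stack_id = vapply(subj$stacks, `[[`, "", "stack_id"),
                            plane = vapply(subj$stacks, `[[`, "", "plane"),
                            path = paths, stringsAsFactors = FALSE)
    subjects[[i]] <- if (is.null(out_dir)) subj else NULL
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  structure(list(subjects = if (is.null(out_dir)) subjects else NULL,
                 manifest = manifest, seed = seed),
            class = "fetal_cohort")
}

#' Write a stack as a NIfTI file
#'
#' Slices become the third dimension; the affine encodes the in-plane spacing
#' and slice thickness.
#' @param stack A `fetal_stack`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_stack_nifti <- function(stack, path) {
  arr <- simplify2array(stack$slices)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(stack$inplane_spacing_mm, stack$thickness_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort back from a manifest
#'
#' Rebuilds an in-memory `fetal_cohort` from a `manifest.csv` written by
#' [generate_cohort()] (or any manifest with columns `subject_id`,
#' `ga_weeks`, `stack_id`, `plane`, `path`). Ground-truth region indicators
#' are not stored in NIfTI and are absent from the result.
#'
#' @param manifest_path Path to the manifest CSV; stack paths are resolved
#'   relative to its directory when not absolute.
#' @return A `fetal_cohort` with in-memory subjects.
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  subjects <- lapply(split(man, man$subject_id), function(d) {
    stacks <- lapply(seq_len(nrow(d)), function(i) {
      p <- d$path[i]
      if (!file.exists(p)) p <- file.path(base, basename(p))
      read_stack_nifti(p, plane = d$plane[i], stack_id = d$stack_id[i],
                       subject_id = d$subject_id[i])
    })
    structure(list(subject_id = d$subject_id[1], ga_weeks = d$ga_weeks[1],
                   stacks = stacks, volume = NULL), class = "fetal_subject")
  })
  structure(list(subjects = unname(subjects[unique(man$subject_id)]),
                 manifest = man, seed = NA_integer_),
            class = "fetal_cohort")
}

#' Read a stack from a NIfTI file
#'
#' @param path NIfTI path.
#' @param plane,stack_id,subject_id Metadata to attach (a manifest row).
#' @return A `fetal_stack`.
#' @export
read_stack_nifti <- function(path, plane = "axial", stack_id = basename(path),
                             subject_id = NA_character_) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  n <- dim(arr)[3]
  structure(list(slices = lapply(seq_len(n), function(s) arr[, , s]),
                 plane = plane, inplane_spacing_mm = pd[1:2],
                 thickness_mm = pd[3],
                 positions_mm = (seq_len(n) - 0.5) * pd[3],
                 stack_id = stack_id, subject_id = subject_id,
                 truth = NULL),
            class = "fetal_stack")
}
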