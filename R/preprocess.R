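# Slice preprocessing: brain masking, bias-field correction, denoising,
# resampling to 1 x 1 mm, per-stack cropping and zero padding to the
# canonical network input shape, and center-slice selection.

#' Default threshold-based brain masker
#'
#' Otsu threshold on the positive intensities, largest connected component,
#' hole filling. Any callable `function(slice) -> logical matrix` can be
#' supplied to [mask_brain()] in its place (e.g. an external segmentation
#' tool).
#'
#' @return A masking function.
#' @export
masker_otsu <- function() {
  function(slice) {
    mx <- max(slice)
    if (!is.finite(mx) || mx <= 0) return(matrix(FALSE, nrow(slice), ncol(slice)))
    sc <- pmin(pmax(slice / mx, 0), 1)
    th <- EBImage::otsu(EBImage::Image(sc))
    bw <- sc > th
    if (!any(bw)) return(matrix(FALSE, nrow(slice), ncol(slice)))
    lab <- EBImage::bwlabel(EBImage::Image(bw + 0))
    tab <- tabulate(as.integer(EBImage::imageData(lab)))
    keep <- which.max(tab)
    comp <- EBImage::imageData(lab) == keep
    filled <- EBImage::fillHull(EBImage::Image(comp + 0))
    matrix(EBImage::imageData(filled) > 0.5, nrow(slice), ncol(slice))
  }
}

#' Brain-mask every slice of a stack
#'
#' @param stack A `fetal_stack`.
#' @param masker A callable mapping a slice matrix to a logical mask;
#'   defaults to [masker_otsu()].
#' @param min_pixels Masks smaller than this are flagged unusable.
#' @param min_rel_area Masks smaller than this fraction of the stack's
#'   largest mask are flagged unusable (suppresses spurious noise components
#'   on slices beyond the brain).
#' @param min_rel_intensity Slices whose median masked intensity falls below
#'   this fraction of the reference (the largest-area slice's median masked
#'   intensity) are flagged unusable; on brain-free slices a threshold
#'   masker segments the upper noise tail, which is much darker than tissue.
#' @return List with `masks` (list of logical matrices) and `usable`
#'   (logical vector; empty/tiny/dark masks are flagged, not fatal).
#' @export
mask_brain <- function(stack, masker = masker_otsu(), min_pixels = 20L,
                       min_rel_area = 0.15, min_rel_intensity = 0.4) {
  stopifnot(length(stack$slices) > 0)
  masks <- lapply(stack$slices, masker)
  areas <- vapply(masks, sum, numeric(1))
  medint <- vapply(seq_along(masks), function(s) {
    if (areas[s] == 0) return(0)
    stats::median(stack$slices[[s]][masks[[s]]])
  }, numeric(1))
  ref <- medint[which.max(areas)]
  usable <- areas >= max(min_pixels, min_rel_area * max(areas)) &
    medint >= min_rel_intensity * ref
  list(masks = masks, usable = usable)
}

#' Correct smooth intensity inhomogeneity within the brain mask
#'
#' Homomorphic correction: a second-order 2D polynomial surface is fitted to
#' the log intensity of the dominant-tissue pixels (those within 25% of the
#' stack's masked median), shared across the stack's slices; the
#' exponentiated surface, normalized to unit mean inside the mask, divides
#' the masked intensities. Fitting only near-median pixels keeps anatomy out
#' of the estimated field, so a bias-free stack passes through nearly
#' unchanged.
#'
#' @param stack A `fetal_stack`.
#' @param masks Masks from [mask_brain()].
#' @return The stack with corrected slices.
#' @export
correct_bias <- function(stack, masks) {
  npix <- sum(vapply(seq_along(stack$slices),
                     function(s) sum(masks$masks[[s]]), numeric(1)))
  if (npix < 50) {
    warning("masked region too small (<50 pixels); bias correction skipped")
    return(stack)
  }
  d <- dim(stack$slices[[1]])
  u <- matrix(seq(-1, 1, length.out = d[1]), d[1], d[2])
  w <- matrix(seq(-1, 1, length.out = d[2]), d[1], d[2], byrow = TRUE)
  kern <- EBImage::makeBrush(5, "disc")
  xs <- list(); ys <- list()
  for (s in seq_along(stack$slices)) {
    m <- masks$masks[[s]]
    if (!any(m)) next
    # erode away partial-volume edge pixels so the fit sees pure tissue
    me <- EBImage::imageData(EBImage::erode(EBImage::Image(m + 0), kern)) > 0.5
    if (sum(me) < 25) me <- m
    val <- stack$slices[[s]][me]
    ok <- val > 0
    xs[[length(xs) + 1]] <- cbind(u[me][ok], w[me][ok])
    ys[[length(ys) + 1]] <- log(val[ok])
  }
  X <- do.call(rbind, xs); yv <- unlist(ys)
  med <- stats::median(yv)
  sel <- abs(yv - med) < log(1.15)          # dominant tissue class only
  if (sum(sel) < 50) return(stack)
  B <- cbind(1, X[sel, 1], X[sel, 2], X[sel, 1] * X[sel, 2],
             X[sel, 1]^2, X[sel, 2]^2)
  cf <- stats::lm.fit(B, yv[sel])$coefficients
  cf[is.na(cf)] <- 0
  field <- exp(cf[1] + cf[2] * u + cf[3] * w + cf[4] * u * w +
               cf[5] * u^2 + cf[6] * w^2)
  for (s in seq_along(stack$slices)) {
    m <- masks$masks[[s]]
    if (!any(m)) next
    f <- field / mean(field[m])
    sl <- stack$slices[[s]]
    sl[m] <- sl[m] / f[m]
    stack$slices[[s]] <- sl
  }
  stack
}

# Robust noise estimate from the Laplacian pseudo-residual (median/MAD
# variant: a structured but noise-free image, where most pseudo-residuals
# are exactly zero, yields zero, so denoising is the identity there).
estimate_noise_sd <- function(slice) {
  k <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  d <- dim(slice)
  acc <- matrix(0, d[1] - 2, d[2] - 2)
  for (i in 1:3) for (j in 1:3)
    acc <- acc + k[i, j] * slice[i:(d[1] - 3 + i), j:(d[2] - 3 + j)]
  # |L*n| ~ half-normal with SD 6*sigma (sum of squared stencil weights 36)
  stats::median(abs(acc)) / (0.6745 * 6)
}

# Windowed non-local means on one slice: weights from patchwise SSDs over a
# (2r+1)^2 search window, 3x3 patches, noise-compensated exponential kernel.
nlm_slice <- function(slice, search_radius = 2L, h_factor = 1.2) {
  sigma <- estimate_noise_sd(slice)
  if (!is.finite(sigma) || sigma <= 1e-8) return(slice)
  h2 <- (h_factor * sigma)^2 * 9           # 9 = patch size
  d <- dim(slice)
  pad <- search_radius + 1L
  P <- matrix(0, d[1] + 2 * pad, d[2] + 2 * pad)
  P[pad + seq_len(d[1]), pad + seq_len(d[2])] <- slice
  box3 <- function(m) {
    dm <- dim(m)
    acc <- matrix(0, dm[1] - 2, dm[2] - 2)
    for (i in 1:3) for (j in 1:3)
      acc <- acc + m[i:(dm[1] - 3 + i), j:(dm[2] - 3 + j)]
    acc
  }
  num <- matrix(0, d[1], d[2]); den <- matrix(0, d[1], d[2])
  rowsU <- pad + seq.int(0L, d[1] + 1L)     # window rows incl. 1-px border
  colsU <- pad + seq.int(0L, d[2] + 1L)
  for (di in -search_radius:search_radius) {
    for (dj in -search_radius:search_radius) {
      S <- P[pad + di + seq_len(d[1]), pad + dj + seq_len(d[2])]
      if (di == 0 && dj == 0) { wgt <- matrix(1, d[1], d[2]) } else {
        D <- (P[rowsU + di, colsU + dj] - P[rowsU, colsU])^2
        ssd <- box3(D)
        wgt <- exp(-pmax(ssd - 2 * 9 * sigma^2, 0) / h2)
      }
      num <- num + wgt * S
      den <- den + wgt
    }
  }
  num / den
}

#' Denoise a stack (non-local means)
#'
#' Per-slice windowed non-local means with a noise-adaptive kernel; a
#' noise-free slice passes through unchanged. Deterministic.
#'
#' @param stack A `fetal_stack`.
#' @param usable Optional logical vector; only these slices are denoised.
#' @return The stack with denoised slices.
#' @export
denoise <- function(stack, usable = NULL) {
  idx <- if (is.null(usable)) seq_along(stack$slices) else which(usable)
  for (s in idx) stack$slices[[s]] <- nlm_slice(stack$slices[[s]])
  stack
}

#' Resample, crop and zero-pad a stack to the canonical input shape
#'
#' Each slice is bilinearly resampled to 1 x 1 mm in-plane, cropped to the
#' stack-level bounding box of the brain masks, background-zeroed, intensity
#' normalized (divide by the 99th-percentile masked intensity, clip to
#' [0, 1.5]), and zero-padded symmetrically to `shape`.
#'
#' @param stack A `fetal_stack`.
#' @param masks Masks from [mask_brain()].
#' @param shape Canonical output shape (rows, cols).
#' @return List of `preprocessed_slice` objects (`image`, `mask`, `spacing`,
#'   `provenance`), one per usable slice, plus the resampled ground-truth
#'   indicators when the stack carries them.
#' @export
resample_crop_pad <- function(stack, masks, shape = c(64L, 64L)) {
  sp <- stack$inplane_spacing_mm
  d0 <- dim(stack$slices[[1]])
  d1 <- as.integer(round(d0 * sp))          # physical extent at 1 mm
  rs_img <- function(m, dims = d1) {
    if (all(dims == dim(m)) && all(abs(sp - 1) < 1e-12)) return(m)
    matrix(EBImage::imageData(EBImage::resize(EBImage::Image(m),
                                              w = dims[1], h = dims[2])),
           dims[1], dims[2])
  }
  usable <- masks$usable
  imgs <- lapply(stack$slices, rs_img)
  msk <- lapply(masks$masks, function(m) rs_img(m + 0) > 0.5)
  truth <- NULL
  if (!is.null(stack$truth)) {
    truth <- lapply(stack$truth, function(tl) lapply(tl, rs_img))
  }

  # per-stack bounding box over usable masks
  any_mask <- Reduce(`|`, msk[usable])
  if (is.null(any_mask) || !any(any_mask))
    stop("no usable mask in stack ", stack$stack_id, call. = FALSE)
  rr <- range(which(rowSums(any_mask) > 0))
  cc <- range(which(colSums(any_mask) > 0))
  bh <- diff(rr) + 1L; bw <- diff(cc) + 1L
  if (bh > shape[1] || bw > shape[2])
    stop(sprintf("brain bounding box %dx%d of stack %s exceeds canonical shape %dx%d",
                 bh, bw, stack$stack_id, shape[1], shape[2]), call. = FALSE)
  po <- c((shape[1] - bh) %/% 2, (shape[2] - bw) %/% 2)

  embed <- function(m) {
    out <- matrix(0, shape[1], shape[2])
    out[po[1] + seq_len(bh), po[2] + seq_len(bw)] <-
      m[rr[1]:rr[2], cc[1]:cc[2]]
    out
  }
  out <- vector("list", length(imgs))
  for (s in seq_along(imgs)) {
    if (!usable[s]) next
    m <- msk[[s]]
    img <- imgs[[s]]
    img[!m] <- 0                             # background exactly zero
    q <- stats::quantile(img[m], 0.99, names = FALSE)
    if (is.finite(q) && q > 0) img <- pmin(pmax(img / q, 0), 1.5)
    ps <- list(image = embed(img), mask = embed(m + 0) > 0.5,
               spacing = c(1, 1),
               provenance = list(subject_id = stack$subject_id,
                                 stack_id = stack$stack_id,
                                 slice_index = s, plane = stack$plane))
    if (!is.null(truth))
      ps$truth <- lapply(truth, function(tl) embed(tl[[s]]))
    class(ps) <- "preprocessed_slice"
    out[[s]] <- ps
  }
  out[usable]
}

#' Select the k slices nearest the brain center
#'
#' The brain center is the mask-area-weighted centroid of slice positions
#' along the stack normal; the `k` usable slices nearest to it are returned
#' (ties broken toward the lower index), sorted by index. If fewer than `k`
#' usable slices exist, all are returned with a warning.
#'
#' @param stack A `fetal_stack`.
#' @param masks Masks from [mask_brain()].
#' @param k Number of slices to select.
#' @return Integer vector of slice indices (into the stack's slice list).
#' @export
select_center_slices <- function(stack, masks, k = 4L) {
  usable <- which(masks$usable)
  if (length(usable) == 0) stop("no usable slices", call. = FALSE)
  areas <- vapply(masks$masks[usable], sum, numeric(1))
  pos <- stack$positions_mm[usable]
  centroid <- sum(areas * pos) / sum(areas)
  if (length(usable) < k) {
    warning(sprintf("only %d usable slices (< k = %d); returning all",
                    length(usable), k))
    return(sort(usable))
  }
  ord <- order(abs(pos - centroid), usable)  # tie -> lower index
  sort(usable[ord[seq_len(k)]])
}

#' Run the full preprocessing chain on one stack
#'
#' Masking, bias correction, denoising, resampling/cropping/padding, in that
#' order, then center-slice selection.
#'
#' @param stack A `fetal_stack`.
#' @param masker Masking strategy for [mask_brain()].
#' @param shape Canonical output shape.
#' @param k Number of center slices to select.
#' @param denoise_selected_only Restrict the (costly) denoising step to the
#'   selected center slices; slice selection depends only on the masks, so
#'   the slices used downstream are identical either way.
#' @return List with `slices` (all usable `preprocessed_slice`s), `selected`
#'   (indices into `slices` of the center-nearest k), `usable`, and
#'   `selected_slice_index` (original stack slice indices).
#' @export
preprocess_stack <- function(stack, masker = masker_otsu(),
                             shape = c(64L, 64L), k = 4L,
                             denoise_selected_only = FALSE) {
  mk <- mask_brain(stack, masker)
  stack <- correct_bias(stack, mk)
  sel_orig <- select_center_slices(stack, mk, k)
  dn <- mk$usable
  if (denoise_selected_only) dn <- dn & seq_along(dn) %in% sel_orig
  stack <- denoise(stack, usable = dn)
  pp <- resample_crop_pad(stack, mk, shape)
  orig_idx <- vapply(pp, function(p) p$provenance$slice_index, numeric(1))
  list(slices = pp, selected = match(sel_orig, orig_idx),
       usable = mk$usable, selected_slice_index = sel_orig)
}

#' Preprocess every stack of a cohort
#'
#' @param cohort A `fetal_cohort` with in-memory subjects.
#' @param shape Canonical input shape.
#' @param k Center slices per stack.
#' @param selected_only Keep only the selected center slices (the training
#'   configuration).
#' @return A list of class `preprocessed_cohort`: per-subject `ga_weeks` and
#'   per-stack preprocessed slices.
#' @export
preprocess_cohort <- function(cohort, shape = c(64L, 64L), k = 4L,
                              selected_only = TRUE) {
  stopifnot(!is.null(cohort$subjects))
  subjects <- lapply(cohort$subjects, function(subj) {
    stacks <- lapply(subj$stacks, function(stk) {
      pp <- tryCatch(
        preprocess_stack(stk, shape = shape, k = k,
                         denoise_selected_only = selected_only),
        error = function(e) {
          warning("dropping stack ", stk$stack_id, ": ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
      if (is.null(pp)) return(NULL)
      if (selected_only) {
        pp$slices <- pp$slices[pp$selected]
        pp$selected <- seq_along(pp$slices)
      }
      pp
    })
    list(subject_id = subj$subject_id, ga_weeks = subj$ga_weeks,
         stacks = Filter(Negate(is.null), stacks))
  })
  structure(list(subjects = subjects, shape = shape, k = k),
            class = "preprocessed_cohort")
}
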