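# Gradient saliency and the brain-size scaling probe: which image regions
# drive the age prediction, and how the prediction responds to isometric
# shrinking of the brain.

#' Gradient saliency map for one slice
#'
#' Backpropagates the scalar age output to the input pixels, takes the
#' absolute gradient, smooths it with a Gaussian (sigma 1.5 px), and
#' normalizes by the maximum. Deterministic given `(model, slice)`; a
#' constant (all-zero-gradient) map is returned as zeros with a warning and
#' normalization skipped.
#'
#' @param fit A `brainage_fit` (single-channel 2D).
#' @param slice Matrix at the canonical shape, or a `preprocessed_slice`.
#' @param sigma Gaussian smoothing SD in pixels.
#' @return A list of class `saliency_map`: `grid` (values in [0, 1], max
#'   exactly 1 for any non-constant map) and `provenance`.
#' @export
compute_saliency <- function(fit, slice, sigma = 1.5) {
  prov <- NULL
  if (inherits(slice, "preprocessed_slice")) {
    prov <- slice$provenance
    slice <- slice$image
  }
  xb <- batch_array(list(slice), fit$spec$input_mode)
  fw <- nn_forward(fit$net, xb, training = FALSE)
  bk <- nn_backward(fit$net, fw$caches, matrix(1, 1, 1))
  g <- abs(bk$dx[1, , , 1])
  sm <- matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(g),
                                                 sigma = sigma)),
               nrow(g), ncol(g))
  sm <- pmax(sm, 0)            # FFT smoothing can leave -1e-16 residues
  mx <- max(sm)
  if (mx <= 0) {
    warning("constant saliency map (zero gradient); normalization skipped")
  } else sm <- sm / mx
  structure(list(grid = sm, sigma = sigma, provenance = prov),
            class = "saliency_map")
}

#' Region contrast of a saliency map
#'
#' Mean normalized saliency inside a region of interest versus the rest of
#' the brain interior (both within the brain mask).
#'
#' @param sal A `saliency_map`.
#' @param roi Logical matrix: region of interest (e.g. cortical rim +
#'   ventricles).
#' @param brain Logical matrix: whole brain support.
#' @return Named vector `roi_mean`, `other_mean`, `ratio`.
#' @export
saliency_region_contrast <- function(sal, roi, brain) {
  other <- brain & !roi
  rm_ <- mean(sal$grid[roi]); om <- mean(sal$grid[other])
  c(roi_mean = rm_, other_mean = om, ratio = rm_ / om)
}

#' Brain-size scaling probe
#'
#' Isometrically shrinks the brain in each slice about its mask centroid
#' (bilinear, zero fill), predicts each scaled copy, and regresses the
#' prediction on the scale factor. A model that uses brain size as an age
#' cue predicts smaller ages at smaller scales.
#'
#' @param fit A `brainage_fit`.
#' @param slices List of `preprocessed_slice` objects (or matrices).
#' @param scales Scale factors in (0, 1].
#' @return A list of class `size_probe`: `table` (slice, scale, prediction),
#'   `mean_by_scale`, and `slope` (weeks per unit scale, from the pooled
#'   linear regression).
#' @export
size_scaling_probe <- function(fit, slices, scales = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  if (any(scales <= 0 | scales > 1))
    stop("scales must lie in (0, 1]", call. = FALSE)
  rows <- list()
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    img <- if (inherits(s, "preprocessed_slice")) s$image else s
    msk <- if (inherits(s, "preprocessed_slice")) s$mask else img > 0
    ctr <- if (any(msk)) {
      w <- which(msk, arr.ind = TRUE)
      colMeans(w)
    } else dim(img) / 2
    for (sc in scales) {
      scaled <- if (sc == 1) img else warp_scale(img, sc, center = ctr)
      p <- net_predict(fit$net, list(scaled), fit$spec$input_mode)
      rows[[length(rows) + 1]] <- data.frame(slice = i, scale = sc,
                                             prediction = p)
    }
  }
  tab <- do.call(rbind, rows)
  mbs <- stats::aggregate(prediction ~ scale, tab, mean)
  slope <- unname(stats::coef(stats::lm(prediction ~ scale, tab))[2])
  structure(list(table = tab, mean_by_scale = mbs, slope = slope),
            class = "size_probe")
}
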