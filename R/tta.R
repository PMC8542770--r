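# Test-time augmentation: each slice is predicted under multiple independent
# augmentation draws (the same family used in training) and the predictions
# are averaged, removing the effect of arbitrary brain orientation, position
# and single-prediction noise.

#' Test-time-augmented prediction for one slice
#'
#' Applies `n_tta` independent draws of the augmentation scheme, predicts
#' each in one batched forward pass, and returns all predictions and their
#' mean. Deterministic given `(model, slice, seed)`.
#'
#' @param fit A `brainage_fit`.
#' @param slice Matrix (or array for stack modes) at the canonical shape, or
#'   a `preprocessed_slice`.
#' @param n_tta Number of augmentations (>= 1).
#' @param seed Seed for the augmentation draws.
#' @param identity_augment Use identity draws (diagnostic).
#' @return A list of class `slice_prediction`: `per_augmentation_predictions`
#'   (length `n_tta`), `p_tta` (their mean), and `provenance`.
#' @export
predict_tta <- function(fit, slice, n_tta = 20L, seed = 1L,
                        identity_augment = FALSE) {
  if (n_tta < 1) stop("n_tta must be >= 1", call. = FALSE)
  prov <- NULL
  if (inherits(slice, "preprocessed_slice")) {
    prov <- slice$provenance
    slice <- slice$image
  }
  mode <- fit$spec$input_mode
  preds <- with_seed(seed, {
    xs <- lapply(seq_len(n_tta), function(t) {
      if (identity_augment) slice
      else augment_slice(slice, augment_draw(
        if (length(dim(slice)) == 3) dim(slice)[2:3] else dim(slice),
        fit$config$shift_frac %||% 0.2))
    })
    net_predict(fit$net, xs, mode)
  })
  structure(list(per_augmentation_predictions = preds, p_tta = mean(preds),
                 n_tta = n_tta, provenance = prov),
            class = "slice_prediction")
}

#' TTA predictions for a whole dataset
#'
#' One RNG stream per slice, derived from the master seed and the slice's
#' provenance, so results do not depend on evaluation order.
#'
#' @param fit A `brainage_fit`.
#' @param dataset A `brainage_dataset`.
#' @param n_tta Augmentations per slice.
#' @param seed Master seed.
#' @return Data frame with `subject_id`, `stack_id`, `slice_index`, `plane`,
#'   `ga_weeks`, `n_tta`, `p_tta`; the per-augmentation matrix is attached as
#'   attribute `"per_augmentation"`.
#' @export
predict_tta_dataset <- function(fit, dataset, n_tta = 20L, seed = 1L) {
  n <- length(dataset$x)
  p <- numeric(n)
  per <- matrix(NA_real_, n, n_tta)
  for (i in seq_len(n)) {
    tag <- paste(dataset$subject_id[i], dataset$stack_id[i],
                 dataset$slice_index[i], sep = "|")
    sp <- predict_tta(fit, dataset$x[[i]], n_tta = n_tta,
                      seed = derive_seed(seed, tag))
    p[i] <- sp$p_tta
    per[i, ] <- sp$per_augmentation_predictions
  }
  out <- data.frame(subject_id = dataset$subject_id,
                    stack_id = dataset$stack_id,
                    slice_index = dataset$slice_index,
                    plane = dataset$plane, ga_weeks = dataset$ga,
                    n_tta = n_tta, p_tta = p, stringsAsFactors = FALSE)
  attr(out, "per_augmentation") <- per
  out
}

#' MAE as a function of the number of augmentations
#'
#' Re-uses one set of augmented predictions per slice, truncating it to each
#' requested count, and reports the slice-level MAE per count.
#'
#' @param fit A `brainage_fit`.
#' @param dataset A `brainage_dataset` with ground-truth ages.
#' @param n_values Augmentation counts to evaluate.
#' @param seed Master seed.
#' @return Data frame with columns `n_tta` and `mae`.
#' @export
sweep_tta <- function(fit, dataset, n_values = c(1, 5, 10, 15, 20, 25, 30),
                      seed = 1L) {
  nmax <- max(n_values)
  preds <- predict_tta_dataset(fit, dataset, n_tta = nmax, seed = seed)
  per <- attr(preds, "per_augmentation")
  mae <- vapply(n_values, function(n) {
    p <- rowMeans(per[, seq_len(n), drop = FALSE])
    mean(abs(dataset$ga - p))
  }, numeric(1))
  data.frame(n_tta = n_values, mae = mae)
}
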