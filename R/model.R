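# Regression networks and training harness.
#
# The primary regressor is a 2D single-channel pre-activation residual CNN:
# convolutional trunk downsampling the canonical input 32-fold per axis
# (138 x 176 -> 5 x 6 under ceiling division), global average pooling,
# dropout, and a single linear output (age in weeks). Variants: a 2D
# multi-channel network (the four center slices of a stack as channels) and
# a volumetric network (3D convolutions over the stack), used for the
# input-strategy comparison experiments.

#' Model specification
#'
#' @param input_mode `"single_channel_2d"` (per-slice prediction, the primary
#'   method), `"multi_channel_2d"` (k slices as channels, one prediction per
#'   stack), or `"volumetric_3d"` (3D convolutions, one prediction per stack).
#' @param input_shape Canonical slice shape (rows, cols).
#' @param depth_profile `"desk"` (small residual stack, trainable on one CPU)
#'   or `"paper"` (full 101-layer bottleneck profile).
#' @param dropout_rate Dropout before the dense head.
#' @param channels Channels / depth for the multi-channel and 3D modes.
#' @return A list of class `brainage_spec`.
#' @export
model_spec <- function(input_mode = c("single_channel_2d", "multi_channel_2d",
                                      "volumetric_3d"),
                       input_shape = c(64L, 64L),
                       depth_profile = c("desk", "paper"),
                       dropout_rate = 0.3, channels = 4L) {
  input_mode <- match.arg(input_mode)
  depth_profile <- match.arg(depth_profile)
  if (length(input_shape) != 2 || any(input_shape < 32))
    stop("input_shape must be two dimensions of at least 32 pixels", call. = FALSE)
  if (input_mode != "single_channel_2d" && channels < 2)
    stop("multi-channel/3D modes need channels >= 2", call. = FALSE)
  structure(list(input_mode = input_mode, input_shape = as.integer(input_shape),
                 depth_profile = depth_profile, dropout_rate = dropout_rate,
                 channels = as.integer(channels)),
            class = "brainage_spec")
}

#' Build an untrained age regressor
#'
#' The desk profile uses a small residual stack (stem stride-2 convolution
#' plus four stride-2 pre-activation residual blocks: the same 32-fold
#' spatial reduction as the full model at under 5% of its parameters). The
#' paper profile reproduces the 101-layer bottleneck trunk (7x7/2 stem,
#' 3x3/2 max pool, stages of 3/4/23/3 bottleneck blocks, 2048 features).
#'
#' @param spec A [model_spec()].
#' @param seed Seed for weight initialization (He).
#' @return A list of class `brainage_net` with the layer stack and spec.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "brainage_spec"))
  c_in <- if (spec$input_mode == "multi_channel_2d") spec$channels else 1L
  layers <- with_seed(seed, {
    if (spec$input_mode == "volumetric_3d") {
      list(nn_conv3d(1L, 8L, k = 3L, stride = c(1L, 2L, 2L)),
           nn_resblock3d(8L, 16L, stride = c(2L, 2L, 2L)),
           nn_resblock3d(16L, 24L, stride = c(2L, 2L, 2L)),
           nn_resblock3d(24L, 32L, stride = c(1L, 2L, 2L)),
           nn_resblock3d(32L, 48L, stride = c(1L, 2L, 2L)),
           nn_bn(48L), nn_relu(), nn_gap(),
           nn_dropout(spec$dropout_rate), nn_dense(48L, 1L))
    } else if (spec$depth_profile == "desk") {
      list(nn_conv2d(c_in, 8L, k = 3L, stride = 2L),
           nn_resblock2d(8L, 16L, stride = 2L),
           nn_resblock2d(16L, 24L, stride = 2L),
           nn_resblock2d(24L, 32L, stride = 2L),
           nn_resblock2d(32L, 48L, stride = 2L),
           nn_bn(48L), nn_relu(), nn_gap(),
           nn_dropout(spec$dropout_rate), nn_dense(48L, 1L))
    } else {
      stages <- list(c(3L, 256L, 1L), c(4L, 512L, 2L),
                     c(23L, 1024L, 2L), c(3L, 2048L, 2L))
      ls <- list(nn_conv2d(c_in, 64L, k = 7L, stride = 2L),
                 nn_maxpool2d(3L, 2L))
      cprev <- 64L
      for (st in stages) {
        for (b in seq_len(st[1])) {
          stride <- if (b == 1L) st[3] else 1L
          ls[[length(ls) + 1L]] <- nn_resblock2d(cprev, st[2], stride = stride,
                                                 bottleneck = TRUE)
          cprev <- st[2]
        }
      }
      c(ls, list(nn_bn(cprev), nn_relu(), nn_gap(),
                 nn_dropout(spec$dropout_rate), nn_dense(cprev, 1L)))
    }
  })
  structure(list(layers = layers, spec = spec), class = "brainage_net")
}

#' Huber loss
#'
#' `0.5 (y - f)^2` for residuals below `delta`, `delta |y - f| - 0.5 delta^2`
#' otherwise; continuous and once-differentiable at the switch.
#'
#' @param y Observed ages (weeks).
#' @param f Predicted ages (weeks).
#' @param delta Quadratic-to-linear switch point (> 0).
#' @return Elementwise loss values.
#' @export
huber_loss <- function(y, f, delta = 1) {
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  assert_finite(y, "y"); assert_finite(f, "f")
  r <- abs(y - f)
  ifelse(r < delta, 0.5 * r^2, delta * r - 0.5 * delta^2)
}

huber_grad <- function(y, f, delta = 1) {
  r <- f - y
  ifelse(abs(r) < delta, r, delta * sign(r))
}

#' Random augmentation draw
#'
#' Draws the shared augmentation family: vertical flip (p = 0.5), horizontal
#' flip (p = 0.5), translations uniform in +/- `shift_frac` of each
#' dimension, rotation uniform in [0, 360) degrees, and a multiplicative
#' intensity factor uniform in [0.5, 1.0].
#'
#' @param shape Slice shape the shifts are scaled by.
#' @param shift_frac Shift range as a fraction of each dimension.
#' @return A list of draws consumable by [augment_slice()].
#' @export
augment_draw <- function(shape, shift_frac = 0.2) {
  list(vflip = stats::runif(1) < 0.5,
       hflip = stats::runif(1) < 0.5,
       shift = stats::runif(2, -shift_frac, shift_frac) * shape,
       angle = stats::runif(1, 0, 360),
       gain = stats::runif(1, 0.5, 1.0))
}

identity_draw <- function() {
  list(vflip = FALSE, hflip = FALSE, shift = c(0, 0), angle = 0, gain = 1)
}

#' Augment a slice (or multi-slice sample)
#'
#' Applies flips, an in-plane rigid rotation/translation (bilinear, zero
#' fill) and an intensity gain. For matrices the full family applies; for 3D
#' arrays (multi-channel or volumetric samples) the same in-plane transform
#' is applied to every slice, keeping inter-slice geometry intact.
#'
#' @param x Matrix (H x W) or array (D x H x W).
#' @param draw Augmentation draws from [augment_draw()]; when `NULL`, fresh
#'   draws are taken from the current RNG stream.
#' @return The augmented input, same shape.
#' @export
augment_slice <- function(x, draw = NULL) {
  is3d <- length(dim(x)) == 3
  shape <- if (is3d) dim(x)[2:3] else dim(x)
  if (is.null(draw)) draw <- augment_draw(shape)
  ap <- function(m) {
    if (draw$vflip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (draw$hflip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (draw$angle != 0 || any(draw$shift != 0))
      m <- warp_rigid(m, draw$angle, draw$shift)
    m * draw$gain
  }
  if (is3d) {
    out <- x
    for (s in seq_len(dim(x)[1])) out[s, , ] <- ap(x[s, , ])
    out
  } else ap(x)
}

#' Training configuration
#'
#' The `desk` profile is sized so a small cohort trains on one CPU in
#' minutes; the `paper` profile carries the full-scale hyperparameters
#' (batch 80, Adam at learning rate 0.1 with inverse-time decay 0.001,
#' patience 150), which are impractical without accelerators and kept as a
#' configuration surface.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param batch_size,learning_rate,decay,delta,epochs_max,patience,folds,
#'   val_fraction,augment,shift_frac,n_bins Overrides of the profile values.
#' @return A list of class `brainage_config`.
#' @export
train_config <- function(profile = c("desk", "paper"), batch_size = NULL,
                         learning_rate = NULL, decay = NULL, delta = 1,
                         epochs_max = NULL, patience = NULL, folds = NULL,
                         val_fraction = 0.1, augment = TRUE, shift_frac = 0.2,
                         n_bins = 9L) {
  profile <- match.arg(profile)
  def <- if (profile == "desk") {
    list(batch_size = 32L, learning_rate = 1e-3, decay = 0,
         epochs_max = 40L, patience = 8L, folds = 10L)
  } else {
    list(batch_size = 80L, learning_rate = 0.1, decay = 0.001,
         epochs_max = 2000L, patience = 150L, folds = 10L)
  }
  cfg <- list(profile = profile,
              batch_size = batch_size %||% def$batch_size,
              learning_rate = learning_rate %||% def$learning_rate,
              decay = decay %||% def$decay, delta = delta,
              epochs_max = epochs_max %||% def$epochs_max,
              patience = patience %||% def$patience,
              folds = folds %||% def$folds,
              val_fraction = val_fraction, augment = augment,
              shift_frac = shift_frac, n_bins = as.integer(n_bins))
  if (cfg$folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (cfg$patience < 1) stop("patience must be >= 1", call. = FALSE)
  if (cfg$delta <= 0) stop("delta must be > 0", call. = FALSE)
  structure(cfg, class = "brainage_config")
}

#' Assemble a training dataset from a preprocessed cohort
#'
#' For `single_channel_2d`, one sample per selected slice; for the stack
#' modes, one sample per stack (the k selected slices as channels/depth).
#'
#' @param pp A `preprocessed_cohort`.
#' @param input_mode As in [model_spec()].
#' @return A list of class `brainage_dataset`: `x` (list of matrices or
#'   D x H x W arrays), `ga`, `subject_id`, `stack_id`, `slice_index`,
#'   `plane`.
#' @export
assemble_dataset <- function(pp, input_mode = "single_channel_2d") {
  x <- list(); ga <- c(); sid <- c(); stid <- c(); sli <- c(); pl <- c()
  for (subj in pp$subjects) {
    for (stk in subj$stacks) {
      sel <- stk$slices[stk$selected]
      sel <- sel[!vapply(sel, is.null, logical(1))]
      if (!length(sel)) next
      if (input_mode == "single_channel_2d") {
        for (s in sel) {
          x[[length(x) + 1]] <- s$image
          ga <- c(ga, subj$ga_weeks); sid <- c(sid, subj$subject_id)
          stid <- c(stid, s$provenance$stack_id)
          sli <- c(sli, s$provenance$slice_index)
          pl <- c(pl, s$provenance$plane)
        }
      } else {
        arr <- array(0, c(length(sel), dim(sel[[1]]$image)))
        for (i in seq_along(sel)) arr[i, , ] <- sel[[i]]$image
        x[[length(x) + 1]] <- arr
        ga <- c(ga, subj$ga_weeks); sid <- c(sid, subj$subject_id)
        stid <- c(stid, sel[[1]]$provenance$stack_id)
        sli <- c(sli, NA); pl <- c(pl, sel[[1]]$provenance$plane)
      }
    }
  }
  structure(list(x = x, ga = ga, subject_id = sid, stack_id = stid,
                 slice_index = sli, plane = pl),
            class = "brainage_dataset")
}

# Gestational-age bins shared across stratification and oversampling: the
# nine cohort age groups (under 23 weeks, then 2-week periods).
ga_bin <- function(ga) vapply(ga, age_group_label, integer(1))

# Oversample subjects so GA-bin occupancy is near uniform (each bin is
# duplicated up to the count of the fullest bin).
oversample_subjects <- function(subjects, ga_by_subject) {
  bins <- ga_bin(ga_by_subject)
  tab <- table(bins)
  target <- max(tab)
  out <- c()
  for (b in names(tab)) {
    members <- subjects[bins == as.integer(b)]
    reps <- ceiling(target / length(members))
    out <- c(out, rep(members, reps)[seq_len(target)])
  }
  out
}

batch_array <- function(xs, mode) {
  if (mode == "volumetric_3d" || mode == "multi_channel_2d") {
    d <- dim(xs[[1]])
    arr <- array(0, c(length(xs), d))
    for (i in seq_along(xs)) arr[i, , , ] <- xs[[i]]
    if (mode == "multi_channel_2d") aperm(arr, c(1, 3, 4, 2))  # channels last
    else { dim(arr) <- c(dim(arr), 1L); arr }                  # (N,D,H,W,1)
  } else {
    d <- dim(xs[[1]])
    arr <- array(0, c(length(xs), d, 1L))
    for (i in seq_along(xs)) arr[i, , , 1L] <- xs[[i]]
    arr
  }
}

net_predict <- function(net, xs, mode) {
  out <- numeric(length(xs))
  bs <- 64L
  i <- 1L
  while (i <= length(xs)) {
    j <- min(i + bs - 1L, length(xs))
    xb <- batch_array(xs[i:j], mode)
    out[i:j] <- nn_forward(net, xb, training = FALSE)$out[, 1]
    i <- j + 1L
  }
  out
}

#' Fit a brain-age regressor
#'
#' Trains one network on the given samples with augmentation, Huber loss,
#' Adam, and early stopping on validation MAE. Subjects listed in
#' `val_subjects` form the validation set; otherwise a stratified
#' `val_fraction` of subjects is held out. The best-validation-MAE weights
#' are kept.
#'
#' @param dataset A `brainage_dataset`.
#' @param spec A [model_spec()]; its `input_mode` must match the dataset.
#' @param config A [train_config()].
#' @param seed Master seed (weights, shuffling, augmentation).
#' @param val_subjects Optional explicit validation subject ids.
#' @param oversample Balance GA-bin occupancy by duplicating subjects.
#' @param verbose Print a line per epoch.
#' @return An object of class `brainage_fit` with elements `net`, `spec`,
#'   `config`, `log` (per-epoch data frame), `best_epoch`, `val_mae`,
#'   `val_subjects`.
#' @export
fit_brainage <- function(dataset, spec = model_spec(), config = train_config(),
                         seed = 1L, val_subjects = NULL, oversample = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(dataset, "brainage_dataset"))
  mode <- spec$input_mode
  subj <- unique(dataset$subject_id)
  ga_subj <- dataset$ga[match(subj, dataset$subject_id)]
  with_seed(derive_seed(seed, "fit"), {
    if (is.null(val_subjects)) {
      val_subjects <- stratified_take(subj, ga_subj, config$val_fraction)
    }
    train_subj <- setdiff(subj, val_subjects)
    if (oversample) {
      ga_tr <- ga_subj[match(train_subj, subj)]
      train_subj_os <- oversample_subjects(train_subj, ga_tr)
    } else train_subj_os <- train_subj

    tr_idx_by_subj <- split(seq_along(dataset$x), dataset$subject_id)
    tr_idx <- unlist(tr_idx_by_subj[train_subj_os], use.names = FALSE)
    va_idx <- unlist(tr_idx_by_subj[val_subjects], use.names = FALSE)

    net <- build_model(spec, seed = derive_seed(seed, "init"))
    # start the output at the training-set mean age: with a bounded-gradient
    # loss the output bias otherwise crawls toward the data range
    net$layers[[length(net$layers)]]$params$b[] <- mean(dataset$ga[tr_idx])
    state <- nn_adam_init()
    best <- list(mae = Inf, layers = net$layers, epoch = 0L)
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_mae = numeric())
    n_tr <- length(tr_idx)
    for (epoch in seq_len(config$epochs_max)) {
      ord <- sample(tr_idx)
      tot_loss <- 0; nb <- 0L
      i <- 1L
      while (i <= n_tr) {
        j <- min(i + config$batch_size - 1L, n_tr)
        ids <- ord[i:j]
        xs <- dataset$x[ids]
        if (config$augment)
          xs <- lapply(xs, function(m) augment_slice(m))
        xb <- batch_array(xs, mode)
        fw <- nn_forward(net, xb, training = TRUE)
        net <- fw$net
        yb <- dataset$ga[ids]
        pred <- fw$out[, 1]
        tot_loss <- tot_loss + mean(huber_loss(yb, pred, config$delta))
        nb <- nb + 1L
        dout <- matrix(huber_grad(yb, pred, config$delta) / length(ids), ncol = 1)
        bk <- nn_backward(net, fw$caches, dout)
        up <- nn_adam_update(net, bk$grads, state, lr = config$learning_rate,
                             decay = config$decay)
        net <- up$net; state <- up$state
        i <- j + 1L
      }
      val_pred <- net_predict(net, dataset$x[va_idx], mode)
      vmae <- mean(abs(dataset$ga[va_idx] - val_pred))
      log <- rbind(log, data.frame(epoch = epoch, train_loss = tot_loss / nb,
                                   val_mae = vmae))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val MAE %.3f", epoch,
                        tot_loss / nb, vmae))
      if (vmae < best$mae)
        best <- list(mae = vmae, layers = net$layers, epoch = epoch)
      if (epoch - best$epoch >= config$patience) break
    }
    net$layers <- best$layers
    structure(list(net = net, spec = spec, config = config, log = log,
                   best_epoch = best$epoch, val_mae = best$mae,
                   val_subjects = val_subjects, seed = seed),
              class = "brainage_fit")
  })
}

# Stratified draw of ~fraction of ids, at least one, balanced over GA bins.
stratified_take <- function(ids, ga, fraction) {
  bins <- ga_bin(ga)
  take <- c()
  for (b in unique(bins)) {
    members <- ids[bins == b]
    n <- max(0L, round(length(members) * fraction))
    if (n > 0) take <- c(take, sample(members, n))
  }
  if (!length(take)) take <- sample(ids, max(1L, round(length(ids) * fraction)))
  take
}

#' Subject-level stratified cross-validation folds
#'
#' Subjects (never slices) are assigned to folds, stratified over the nine
#' GA groups so each fold spans the age range.
#'
#' @param subject_id,ga Parallel vectors (one entry per subject).
#' @param folds Number of folds.
#' @param seed Seed for the shuffled assignment.
#' @return Integer fold label per subject.
#' @export
make_folds <- function(subject_id, ga, folds = 10L, seed = 1L) {
  stopifnot(length(subject_id) == length(ga), !anyDuplicated(subject_id))
  bins <- ga_bin(ga)
  fold <- integer(length(subject_id))
  with_seed(derive_seed(seed, "folds"), {
    for (b in unique(bins)) {
      members <- which(bins == b)
      if (length(members) < 1)
        stop("empty GA stratum; reduce folds or widen bins", call. = FALSE)
      fold[members] <- sample(rep_len(seq_len(folds), length(members)))
    }
  })
  fold
}

#' Cross-validated training
#'
#' For each requested fold: its subjects are the held-out test set, a
#' stratified 10% of the remaining subjects the validation set, and the rest
#' (oversampled to near-uniform GA-bin occupancy) the training set.
#'
#' @param dataset A `brainage_dataset`.
#' @param spec,config,seed As in [fit_brainage()].
#' @param folds_to_run Integer subset of folds to actually train (all by
#'   default); training every fold of a 10-fold split is rarely needed at
#'   desk scale.
#' @param verbose Passed through.
#' @return An object of class `brainage_cv`: `fits` (by fold), `fold`
#'   (subject assignment), `test_subjects` per fold.
#' @export
fit_brainage_cv <- function(dataset, spec = model_spec(),
                            config = train_config(), seed = 1L,
                            folds_to_run = NULL, verbose = FALSE) {
  subj <- unique(dataset$subject_id)
  ga_subj <- dataset$ga[match(subj, dataset$subject_id)]
  fold <- make_folds(subj, ga_subj, folds = config$folds, seed = seed)
  if (is.null(folds_to_run)) folds_to_run <- seq_len(config$folds)
  fits <- list()
  for (f in folds_to_run) {
    test_subj <- subj[fold == f]
    keep <- !(dataset$subject_id %in% test_subj)
    sub_ds <- structure(lapply(dataset, function(v)
      if (is.list(v)) v[keep] else v[keep]), class = "brainage_dataset")
    fits[[as.character(f)]] <- fit_brainage(sub_ds, spec, config,
                                            seed = derive_seed(seed, paste0("fold", f)),
                                            verbose = verbose)
  }
  structure(list(fits = fits, fold = stats::setNames(fold, subj),
                 test_subjects = split(subj, fold), spec = spec,
                 config = config, seed = seed),
            class = "brainage_cv")
}

#' @export
print.brainage_fit <- function(x, ...) {
  cat("Brain-age regressor (", x$spec$input_mode, ", ",
      x$spec$depth_profile, " profile)\n", sep = "")
  cat(sprintf("  parameters: %d\n", nn_count_params(x$net)))
  cat(sprintf("  trained %d epochs; best epoch %d, validation MAE %.3f weeks\n",
              nrow(x$log), x$best_epoch, x$val_mae))
  invisible(x)
}

#' @export
summary.brainage_fit <- function(object, ...) {
  print(object)
  cat("  validation subjects:", length(object$val_subjects), "\n")
  cat("  input shape:", paste(object$spec$input_shape, collapse = " x "), "\n")
  invisible(object)
}

#' Predict ages for new samples
#'
#' @param object A `brainage_fit`.
#' @param newdata A `brainage_dataset` or list of matrices/arrays shaped like
#'   the training input.
#' @param n_tta Number of test-time augmentations; 0 (default) gives the
#'   plain deterministic forward pass.
#' @param seed Seed for the TTA augmentation draws.
#' @param ... Unused.
#' @return Numeric vector of predicted ages (weeks).
#' @export
predict.brainage_fit <- function(object, newdata, n_tta = 0L, seed = 1L, ...) {
  xs <- if (inherits(newdata, "brainage_dataset")) newdata$x else newdata
  if (n_tta <= 0) return(net_predict(object$net, xs, object$spec$input_mode))
  vapply(seq_along(xs), function(i) {
    predict_tta(object, xs[[i]], n_tta = n_tta,
                seed = derive_seed(seed, i))$p_tta
  }, numeric(1))
}

#' @export
residuals.brainage_fit <- function(object, dataset, ...) {
  dataset$ga - predict.brainage_fit(object, dataset)
}

#' @export
plot.brainage_fit <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$val_mae, type = "l", xlab = "epoch",
                 ylab = "validation MAE (weeks)",
                 main = "Training curve", ...)
  graphics::lines(x$log$epoch, x$log$train_loss, lty = 2, col = "grey40")
  graphics::legend("topright", legend = c("val MAE", "train loss"),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(x)
}
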