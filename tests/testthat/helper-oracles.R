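# Independent oracles and shared fixtures for the test suite.

# Literal grouped-mode oracle: explicit histogram over 0-anchored classes and
# the interpolation formula, written independently of the package routine.
oracle_grouped_mode <- function(v, i) {
  b <- floor(v / i + 1e-8)
  ids <- seq(min(b), max(b))
  f <- vapply(ids, function(k) sum(b == k), numeric(1))
  top <- which(f == max(f))
  if (length(top) > 1) return(3 * stats::median(v) - 2 * mean(v))
  f1 <- f[top]
  f0 <- if (top > 1) f[top - 1] else 0
  f2 <- if (top < length(f)) f[top + 1] else 0
  L <- ids[top] * i
  den <- 2 * f1 - f0 - f2
  if (den == 0) return(L + i / 2)
  L + i * (f1 - f0) / den
}

# Small, fast phantom pieces used across files (young brain, small grid).
quick_params <- function(ga = 24, ...) fetalage::phantom_params(ga, ...)

clean_params <- function(ga = 24, ...) {
  fetalage::phantom_params(ga, noise_sigma = 0, bias_strength = 0,
                           motion_jitter_mm = 0, motion_jitter_deg = 0, ...)
}

quick_stack <- function(ga = 24, seed = 7, params = quick_params(ga),
                        plane = "axial", n_vox = 48L) {
  vol <- fetalage::generate_volume(params, seed = seed, n_vox = n_vox)
  fetalage::acquire_stack(vol, plane, params, seed = seed + 1)
}

# An untrained single-channel model: enough for interface/determinism
# contracts that do not depend on prediction quality.
stub_fit <- function(shape = c(64L, 64L), mode = "single_channel_2d",
                     seed = 5L) {
  spec <- fetalage::model_spec(mode, input_shape = shape)
  structure(list(net = fetalage::build_model(spec, seed = seed), spec = spec,
                 config = fetalage::train_config("desk"),
                 log = data.frame(), best_epoch = 0L, val_mae = NA_real_,
                 val_subjects = character(), seed = seed),
            class = "brainage_fit")
}

# The end-to-end study fixture shared by the acceptance tests: trained once
# per test run and cached.
.study_cache <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (is.null(.study_cache$exp)) {
    .study_cache$exp <- fetalage::desk_experiment(
      seed = 42L, n_train = 120L, n_test = 15L, n_tta = 20L)
  }
  .study_cache$exp
}
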