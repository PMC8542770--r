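# Shared internal helpers.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed (< 2^31) from a master seed and a string tag, so that
# per-slice / per-stack RNG streams are reproducible regardless of ordering.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Rigid in-plane transform of a 2D image: rotation (degrees, about the image
# center) followed by a translation in pixels; bilinear, zero fill.
# EBImage convention: pixel i has coordinate i - 0.5; matrix rows are t(A), t.
warp_rigid <- function(img, angle_deg = 0, shift = c(0, 0), output_dim = dim(img)) {
  th <- angle_deg * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cc <- dim(img) / 2
  tr <- output_dim / 2 - A %*% cc + shift
  m <- rbind(t(A), as.vector(tr))
  out <- EBImage::affine(EBImage::Image(img), m,
                         output.dim = output_dim, bg.col = 0)
  matrix(EBImage::imageData(out), output_dim[1], output_dim[2])
}

# Isotropic scaling about an arbitrary fixed point (pixel coords), zero fill.
warp_scale <- function(img, scale, center = dim(img) / 2) {
  A <- diag(2) * scale
  tr <- center - A %*% center
  m <- rbind(t(A), as.vector(tr))
  out <- EBImage::affine(EBImage::Image(img), m,
                         output.dim = dim(img), bg.col = 0)
  matrix(EBImage::imageData(out), dim(img)[1], dim(img)[2])
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}
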