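# The network engine: analytic gradients must match finite differences, and
# the trunk geometry must reproduce the canonical 32-fold reduction.

numeric_grad_check <- function(net, x, y, get, set, ganal, n_probe = 4L,
                               eps = 1e-6, tol = 1e-4) {
  loss <- function(net, x) {
    f <- fetalage:::nn_forward(net, x, training = TRUE)
    0.5 * sum((f$out[, 1] - y)^2)
  }
  p <- get(net)
  for (j in sample(length(p), min(n_probe, length(p)))) {
    p1 <- p; p1[j] <- p[j] + eps
    p2 <- p; p2[j] <- p[j] - eps
    gnum <- (loss(set(net, p1), x) - loss(set(net, p2), x)) / (2 * eps)
    expect_lt(abs(gnum - ganal[j]), tol * (1 + abs(gnum)))
  }
}

test_that("backpropagation matches finite differences through a residual stack", {
  set.seed(11)
  net <- list(layers = list(
    fetalage:::nn_conv2d(1, 3, k = 3, stride = 2),
    fetalage:::nn_resblock2d(3, 4, stride = 2),
    fetalage:::nn_bn(4), fetalage:::nn_relu(), fetalage:::nn_gap(),
    fetalage:::nn_dense(4, 1)))
  x <- array(rnorm(2 * 9 * 10), c(2, 9, 10, 1))
  y <- c(1.5, -0.3)
  f <- fetalage:::nn_forward(net, x, training = TRUE)
  dout <- matrix(f$out[, 1] - y, ncol = 1)
  bk <- fetalage:::nn_backward(net, f$caches, dout)

  numeric_grad_check(net, x, y,
    function(n) n$layers[[1]]$params$W,
    function(n, p) { n$layers[[1]]$params$W[] <- p; n }, bk$grads[[1]]$W)
  numeric_grad_check(net, x, y,
    function(n) n$layers[[2]]$sub$conv1$params$W,
    function(n, p) { n$layers[[2]]$sub$conv1$params$W[] <- p; n },
    bk$grads[[2]]$conv1$W)
  numeric_grad_check(net, x, y,
    function(n) n$layers[[2]]$sub$bn1$params$gamma,
    function(n, p) { n$layers[[2]]$sub$bn1$params$gamma[] <- p; n },
    bk$grads[[2]]$bn1$gamma)
  numeric_grad_check(net, x, y,
    function(n) n$layers[[6]]$params$W,
    function(n, p) { n$layers[[6]]$params$W[] <- p; n }, bk$grads[[6]]$W)

  # input gradient (what saliency uses)
  loss <- function(x_) {
    f <- fetalage:::nn_forward(net, x_, training = TRUE)
    0.5 * sum((f$out[, 1] - y)^2)
  }
  eps <- 1e-6
  for (j in sample(length(x), 4)) {
    x1 <- x; x1[j] <- x[j] + eps
    x2 <- x; x2[j] <- x[j] - eps
    gnum <- (loss(x1) - loss(x2)) / (2 * eps)
    expect_lt(abs(gnum - bk$dx[j]), 1e-4 * (1 + abs(gnum)))
  }
})

test_that("volumetric convolution gradients match finite differences", {
  set.seed(12)
  net <- list(layers = list(
    fetalage:::nn_conv3d(1, 2, k = 3, stride = c(1, 2, 2)),
    fetalage:::nn_resblock3d(2, 3, stride = c(1, 2, 2)),
    fetalage:::nn_gap(), fetalage:::nn_dense(3, 1)))
  x <- array(rnorm(2 * 4 * 9 * 10), c(2, 4, 9, 10, 1))
  y <- c(1, -1)
  f <- fetalage:::nn_forward(net, x, training = TRUE)
  bk <- fetalage:::nn_backward(net, f$caches, matrix(f$out[, 1] - y, ncol = 1))
  numeric_grad_check(net, x, y,
    function(n) n$layers[[1]]$params$W,
    function(n, p) { n$layers[[1]]$params$W[] <- p; n }, bk$grads[[1]]$W)
})

test_that("stride-2 stages use ceiling division so 138 x 176 reaches 5 x 6", {
  # five halvings: 138 -> 69 -> 35 -> 18 -> 9 -> 5 and 176 -> ... -> 6
  net <- list(layers = list(
    fetalage:::nn_conv2d(1, 2, k = 7, stride = 2),
    fetalage:::nn_maxpool2d(3, 2),
    fetalage:::nn_conv2d(2, 2, k = 3, stride = 2),
    fetalage:::nn_conv2d(2, 2, k = 3, stride = 2),
    fetalage:::nn_conv2d(2, 2, k = 3, stride = 2)))
  x <- array(rnorm(138 * 176), c(1, 138, 176, 1))
  out <- fetalage:::nn_forward(net, x, training = FALSE)$out
  expect_identical(dim(out)[2:3], c(5L, 6L))
})

test_that("batch normalization switches between batch and running statistics", {
  set.seed(3)
  l <- fetalage:::nn_bn(2)
  x <- array(rnorm(40, mean = 5, sd = 3), c(10, 2, 1, 2))
  tr <- fetalage:::nn_layer_forward(l, x, training = TRUE)
  m <- matrix(tr$out, ncol = 2)
  expect_equal(colMeans(m), c(0, 0), tolerance = 1e-8)
  expect_equal(apply(m, 2, stats::sd), c(1, 1), tolerance = 0.1)
  # inference path uses the stored running stats, not the batch
  ev <- fetalage:::nn_layer_forward(tr$layer, x[1:2, , , , drop = FALSE],
                                    training = FALSE)
  expect_false(isTRUE(all.equal(colMeans(matrix(ev$out, ncol = 2)), c(0, 0))))
})
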