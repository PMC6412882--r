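test_that("conv1d forward matches the naive loop oracle", {
  set.seed(31)
  for (rep in 1:5) {
    B <- sample(1:3, 1); L <- sample(8:15, 1); Cin <- sample(1:4, 1)
    k <- sample(2:4, 1); Cout <- sample(1:5, 1)
    X <- array(rnorm(B * L * Cin), c(B, L, Cin))
    p <- rehabrec:::conv1d_init(k, Cin, Cout)
    got <- rehabrec:::conv1d_fwd(X, p)$out
    expect_equal(got, oracle_conv1d(X, p$W, p$b, k), tolerance = 1e-12)
  }
  # [TRIVIAL] kernel longer than the input errors
  p <- rehabrec:::conv1d_init(5L, 1L, 1L)
  expect_error(rehabrec:::conv1d_fwd(array(0, c(1, 3, 1)), p), "shorter")
})

test_that("conv1d backward matches finite differences of a scalar readout", {
  set.seed(32)
  X <- array(rnorm(2 * 9 * 2), c(2, 9, 2))
  p <- rehabrec:::conv1d_init(3L, 2L, 3L)
  R <- array(rnorm(2 * 7 * 3), c(2, 7, 3))  # fixed readout weights
  f <- rehabrec:::conv1d_fwd(X, p)
  g <- rehabrec:::conv1d_bwd(R, f, p)
  eps <- 1e-6
  # [DERIVED] loss = sum(Y * R); check a sample of W, b and X coordinates
  for (i in sample(length(p$W), 5)) {
    p2 <- p; p2$W[i] <- p2$W[i] + eps
    l1 <- sum(rehabrec:::conv1d_fwd(X, p2)$out * R)
    p2$W[i] <- p2$W[i] - 2 * eps
    l2 <- sum(rehabrec:::conv1d_fwd(X, p2)$out * R)
    expect_equal(g$dW[i], (l1 - l2) / (2 * eps), tolerance = 1e-5)
  }
  for (i in seq_along(p$b)) {
    p2 <- p; p2$b[i] <- p2$b[i] + eps
    l1 <- sum(rehabrec:::conv1d_fwd(X, p2)$out * R)
    p2$b[i] <- p2$b[i] - 2 * eps
    l2 <- sum(rehabrec:::conv1d_fwd(X, p2)$out * R)
    expect_equal(g$db[i], (l1 - l2) / (2 * eps), tolerance = 1e-5)
  }
  for (i in sample(length(X), 5)) {
    X2 <- X; X2[i] <- X2[i] + eps
    l1 <- sum(rehabrec:::conv1d_fwd(X2, p)$out * R)
    X2[i] <- X2[i] - 2 * eps
    l2 <- sum(rehabrec:::conv1d_fwd(X2, p)$out * R)
    expect_equal(g$dX[i], (l1 - l2) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("max pooling halves the length and routes gradients to the max", {
  X <- array(0, c(1, 5, 1))
  X[1, , 1] <- c(3, 1, 2, 5, 9)  # odd trailing sample dropped
  f <- rehabrec:::pool2_fwd(X)
  # [DERIVED] pairs (3,1), (2,5) -> 3, 5; the trailing 9 is dropped
  expect_equal(as.numeric(f$out), c(3, 5))
  dY <- array(1, c(1, 2, 1))
  dX <- rehabrec:::pool2_bwd(dY, f)
  expect_equal(as.numeric(dX), c(1, 0, 0, 1, 0))
  # [TRIVIAL] length-1 input passes through unpooled
  X1 <- array(7, c(1, 1, 1))
  f1 <- rehabrec:::pool2_fwd(X1)
  expect_true(f1$pass)
  expect_equal(f1$out, X1)
  expect_equal(rehabrec:::pool2_bwd(X1 * 2, f1), X1 * 2)
})

test_that("enc_out_len matches the actual encoder output length", {
  spec <- list(k1 = 5L, k2 = 3L, maps = c(2L, 3L))
  p <- rehabrec:::with_seed(33L, rehabrec:::enc_init(1L, spec))
  for (L in c(10L, 12L, 15L, 20L, 21L, 80L)) {
    X <- array(rnorm(L), c(1, L, 1))
    got <- dim(rehabrec:::enc_fwd(X, p)$out)[2]
    expect_identical(rehabrec:::enc_out_len(L, spec), got)
  }
})

test_that("softmax cross-entropy value and gradient are correct", {
  set.seed(34)
  Z <- matrix(rnorm(12), 3, 4)
  y <- c(2L, 4L, 1L)
  l <- rehabrec:::softmax_ce(Z, y)
  # [DERIVED] direct computation of -mean log softmax
  P <- exp(Z - apply(Z, 1, max)); P <- P / rowSums(P)
  expect_equal(l$loss, -mean(log(P[cbind(1:3, y)])), tolerance = 1e-12)
  expect_equal(rowSums(l$probs), rep(1, 3), tolerance = 1e-12)
  eps <- 1e-6
  for (i in sample(length(Z), 6)) {
    Z2 <- Z; Z2[i] <- Z2[i] + eps
    l1 <- rehabrec:::softmax_ce(Z2, y)$loss
    Z2[i] <- Z2[i] - 2 * eps
    l2 <- rehabrec:::softmax_ce(Z2, y)$loss
    expect_equal(l$dlogits[i], (l1 - l2) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("mse loss sums over outputs and averages over the batch", {
  Yh <- matrix(c(1, 2, 3, 4), 2, 2)
  Y <- matrix(c(0, 2, 5, 4), 2, 2)
  l <- rehabrec:::mse_loss(Yh, Y)
  # [DERIVED] ((1)^2 + (−2)^2) / 2 batch rows
  expect_equal(l$loss, (1 + 4) / 2)
  expect_equal(l$dY, 2 * (Yh - Y) / 2)
})

test_that("grad_clip rescales to the ceiling and is a no-op below it", {
  g <- list(a = list(W = matrix(3, 2, 2), b = c(4, 0)),
            b = matrix(1, 1, 2))
  norm0 <- sqrt(sum(unlist(g)^2))
  gc <- rehabrec:::grad_clip(g, 1)
  # [DERIVED] global L2 norm after clipping equals the ceiling
  expect_equal(sqrt(sum(unlist(gc)^2)), 1, tolerance = 1e-12)
  expect_equal(gc$a$W, g$a$W / norm0, tolerance = 1e-12)
  expect_identical(rehabrec:::grad_clip(g, norm0 + 1), g)
})

test_that("sgd with momentum follows the hand-computed update", {
  p <- list(w = c(1, 2))
  g <- list(w = c(0.5, -1))
  v <- rehabrec:::sgd_state(p)
  s1 <- rehabrec:::sgd_step(p, g, v, lr = 0.1, momentum = 0.9,
                            weight_decay = 0)
  # [DERIVED] v1 = -lr*g, p1 = p + v1
  expect_equal(s1$p$w, c(1, 2) - 0.1 * c(0.5, -1))
  s2 <- rehabrec:::sgd_step(s1$p, g, s1$v, lr = 0.1, momentum = 0.9,
                            weight_decay = 0)
  # [DERIVED] v2 = 0.9*v1 - lr*g
  v1 <- -0.1 * c(0.5, -1)
  expect_equal(s2$p$w, s1$p$w + 0.9 * v1 - 0.1 * c(0.5, -1),
               tolerance = 1e-12)
  # [DERIVED] weight decay adds wd*p to the gradient
  s3 <- rehabrec:::sgd_step(p, g, v, lr = 0.1, momentum = 0,
                            weight_decay = 0.5)
  expect_equal(s3$p$w, p$w - 0.1 * (g$w + 0.5 * p$w), tolerance = 1e-12)
})

test_that("training is bit-reproducible under the same seed", {
  set.seed(35)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(0:1, each = 20)
  cfg <- train_config(epochs = 3L, batch_size = 8L, seed = 7L)
  n1 <- train_net(build_mlp(6L, 8L, 2L, seed = 5L), list(x = X), y, cfg)
  n2 <- train_net(build_mlp(6L, 8L, 2L, seed = 5L), list(x = X), y, cfg)
  expect_identical(n1$params, n2$params)
  n3 <- train_net(build_mlp(6L, 8L, 2L, seed = 5L), list(x = X), y,
                  train_config(epochs = 3L, batch_size = 8L, seed = 8L))
  expect_false(identical(n1$params, n3$params))
})
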