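# small shared geometry for fast model tests
tiny_spec <- function(top_type = "gb", fusion_depth = 1L, input_len = 40L) {
  network_spec(n_classes = 3L, input_len = input_len, maps = c(3L, 4L),
               hidden = c(10L, 8L), n_parts = 4L, state_dim = 3L,
               fusion_depth = fusion_depth, top_type = top_type)
}

tiny_inputs <- function(B = 4L, spec = tiny_spec(), seed = 41L) {
  set.seed(seed)
  L <- spec$input_len
  seg <- ceiling(L / spec$n_parts)
  list(gravity = array(rnorm(B * L * 3), c(B, L, 3)),
       body = array(rnorm(B * L * 3), c(B, L, 3)),
       x = array(rnorm(B * L * 3), c(B, L, 3)),
       d_gravity = array(rnorm(B * seg * spec$n_parts * 3),
                         c(B, seg * spec$n_parts, 3)),
       d_body = array(rnorm(B * seg * spec$n_parts * 3),
                      c(B, seg * spec$n_parts, 3)))
}

test_that("builders produce consistent output shapes", {
  spec <- tiny_spec()
  ins <- tiny_inputs(4L, spec)
  gb <- build_gbcnn(spec, seed = 1L)
  expect_equal(dim(rehabrec:::net_forward(gb, ins)$out), c(4L, 3L))
  sc <- build_scnn(spec, seed = 1L)
  # [TRIVIAL] S-CNN output is the flattened n x n transition matrix
  expect_equal(dim(rehabrec:::net_forward(sc, ins)$out), c(4L, 9L))
  dc <- build_dcnn(spec, seed = 1L)
  expect_length(dc$params$encs, 8L)  # 2 features x 4 parts
  expect_equal(dim(rehabrec:::net_forward(
    dc, list(gravity = ins$d_gravity, body = ins$d_body))$out), c(4L, 3L))
  for (tt in c("gb", "d")) {
    mp <- build_mpcnn(tiny_spec(tt), seed = 1L)
    expect_equal(dim(rehabrec:::net_forward(mp, ins)$out), c(4L, 3L))
  }
  expect_error(build_scnn(network_spec(3L, input_len = 20L)), "state_dim")
})

test_that("MP-CNN fusion geometry concatenates maps correctly", {
  # [DERIVED] gb top: same pooled length as the S-CNN bottom -> channel
  # concat (mode 3) with doubled channels
  gg <- rehabrec:::mp_fusion_geom(tiny_spec("gb"))
  len <- rehabrec:::enc_out_len(40L, tiny_spec("gb"))
  expect_identical(gg$mode, 3L)
  expect_identical(gg$len, len)
  expect_identical(gg$ch, 8L)
  # [DERIVED] d top at input_len 48: path map length 8 * enc_out_len(12)
  # differs from the bottom's enc_out_len(48) -> time concat (mode 2)
  sd48 <- tiny_spec("d", input_len = 48L)
  gd <- rehabrec:::mp_fusion_geom(sd48)
  seg_len <- rehabrec:::enc_out_len(ceiling(48L / 4L), sd48)
  len48 <- rehabrec:::enc_out_len(48L, sd48)
  expect_true(8L * seg_len != len48)
  expect_identical(gd$mode, 2L)
  expect_identical(gd$len, 8L * seg_len + len48)
  expect_identical(gd$ch, 4L)
})

test_that("backpropagation matches finite differences on every variant", {
  spec <- tiny_spec()
  ins <- tiny_inputs(3L, spec)
  y <- c(1L, 3L, 2L)
  check_net <- function(net, inputs) {
    set.seed(42)
    net$params <- jitter_params(net$params)
    loss_of <- function(params) {
      net$params <- params
      f <- rehabrec:::net_forward(net, inputs)
      rehabrec:::softmax_ce(f$out, y)$loss
    }
    fwd <- rehabrec:::net_forward(net, ins)
    l <- rehabrec:::softmax_ce(fwd$out, y)
    grads <- rehabrec:::net_backward(net, fwd$cache, l$dlogits)
    gradcheck_worst(net$params, grads, loss_of, n_check = 4L)
  }
  # [DERIVED] analytic gradients agree with central differences
  expect_lt(check_net(build_gbcnn(spec, 2L), ins), 1e-4)
  expect_lt(check_net(build_dcnn(spec, 2L), ins), 1e-4)
  for (tt in c("gb", "d")) for (fd in 0:1)
    expect_lt(check_net(build_mpcnn(tiny_spec(tt, fd), 2L), ins), 1e-4)
  # S-CNN regression gradient
  sc <- build_scnn(spec, 2L)
  set.seed(43)
  sc$params <- jitter_params(sc$params)
  Yt <- matrix(runif(3 * 9), 3, 9)
  loss_of <- function(params) {
    sc$params <- params
    rehabrec:::mse_loss(rehabrec:::net_forward(sc, ins)$out, Yt)$loss
  }
  fwd <- rehabrec:::net_forward(sc, ins)
  l <- rehabrec:::mse_loss(fwd$out, Yt)
  grads <- rehabrec:::net_backward(sc, fwd$cache, l$dY)
  expect_lt(gradcheck_worst(sc$params, grads, loss_of, n_check = 4L), 1e-4)
})

test_that("pretrained sub-networks initialize the matching MP-CNN branches", {
  spec <- tiny_spec("gb")
  mp <- build_mpcnn(spec, seed = 1L)
  top <- build_gbcnn(spec, seed = 9L)
  bot <- build_scnn(spec, seed = 10L)
  ins <- tiny_inputs(4L, spec)
  out <- train_net(mp, ins, c(0L, 1L, 2L, 0L),
                   train_config(epochs = 0L),
                   pretrained = list(top = top, bot = bot))
  # [DERIVED] with zero epochs the copied branches are returned verbatim
  expect_identical(out$params$top, top$params)
  expect_identical(out$params$bot, bot$params)
  expect_identical(out$params$f1, mp$params$f1)
})

test_that("training reduces the loss on separable data", {
  set.seed(44)
  n <- 60
  y <- rep(0:2, each = n / 3)
  X <- matrix(rnorm(n * 4, mean = rep(y * 3, 4)), n, 4)
  net <- train_net(build_mlp(4L, 16L, 3L, seed = 3L), list(x = X), y,
                   train_config(lr = 0.05, epochs = 30L, seed = 3L))
  expect_lt(tail(net$history$loss, 1), head(net$history$loss, 1))
  expect_gt(net_accuracy(net, list(x = X), y), 0.9)
  # [TRIVIAL] predict types
  P <- predict(net, list(x = X), type = "prob")
  expect_equal(rowSums(P), rep(1, n), tolerance = 1e-12)
  cl <- predict(net, list(x = X), type = "class")
  expect_true(all(cl %in% 0:2))
  expect_equal(dim(predict(net, list(x = X), type = "raw")), c(n, 3L))
})
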