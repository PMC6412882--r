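# Minimal CPU neural-network primitives.
#
# Tensors are base arrays: conv inputs are (batch, length, channels), dense
# inputs are (batch, features). Every layer is a pure forward function with a
# matching hand-derived backward; SGD with momentum and weight decay drives
# training. All randomness goes through set.seed, so training is
# bit-reproducible on one CPU.

init_mat <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# ---- conv1d (valid, stride 1) ----------------------------------------------
# W is a (k*Cin) x Cout matrix; column block layout: (channel-major, then
# kernel offset), matching the im2col construction below.

conv1d_init <- function(k, cin, cout) {
  list(W = init_mat(k * cin, cout, k * cin), b = numeric(cout), k = k,
       cin = cin, cout = cout)
}

im2col <- function(X, k) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  Lo <- L - k + 1L
  Xc <- matrix(0, B * Lo, k * C)
  for (c2 in seq_len(C)) for (dk in 0:(k - 1L)) {
    Xc[, (c2 - 1L) * k + dk + 1L] <- X[, (1L + dk):(Lo + dk), c2]
  }
  Xc
}

conv1d_fwd <- function(X, p) {
  d <- dim(X); B <- d[1]; L <- d[2]
  Lo <- L - p$k + 1L
  if (Lo < 1) stop("conv1d: input length ", L, " shorter than kernel ", p$k)
  Xc <- im2col(X, p$k)
  Y <- Xc %*% p$W
  Y <- sweep(Y, 2, p$b, "+")
  dim(Y) <- c(B, Lo, p$cout)
  list(out = Y, Xc = Xc, in_dim = d)
}

conv1d_bwd <- function(dY, cache, p) {
  d <- cache$in_dim; B <- d[1]; L <- d[2]; C <- d[3]
  Lo <- L - p$k + 1L
  dY2 <- dY; dim(dY2) <- c(B * Lo, p$cout)
  dW <- crossprod(cache$Xc, dY2)
  db <- colSums(dY2)
  dXc <- tcrossprod(dY2, p$W)
  dX <- array(0, d)
  for (c2 in seq_len(C)) for (dk in 0:(p$k - 1L)) {
    dX[, (1L + dk):(Lo + dk), c2] <- dX[, (1L + dk):(Lo + dk), c2] +
      matrix(dXc[, (c2 - 1L) * p$k + dk + 1L], B, Lo)
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- max pooling (size 2, stride 2; odd trailing sample dropped) -----------

pool2_fwd <- function(X) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  Lp <- L %/% 2L
  if (Lp < 1) return(list(out = X, pass = TRUE, in_dim = d))
  a <- X[, seq(1L, 2L * Lp, 2L), , drop = FALSE]
  b <- X[, seq(2L, 2L * Lp, 2L), , drop = FALSE]
  mask <- a >= b
  list(out = a * mask + b * !mask, mask = mask, pass = FALSE, in_dim = d)
}

pool2_bwd <- function(dY, cache) {
  if (isTRUE(cache$pass)) return(dY)
  d <- cache$in_dim
  Lp <- d[2] %/% 2L
  dX <- array(0, d)
  dX[, seq(1L, 2L * Lp, 2L), ] <- dY * cache$mask
  dX[, seq(2L, 2L * Lp, 2L), ] <- dY * !cache$mask
  dX
}

# ---- elementwise / dense ----------------------------------------------------

relu_fwd <- function(X) list(out = X * (X > 0), mask = X > 0)
relu_bwd <- function(dY, cache) dY * cache$mask

flatten_fwd <- function(X) {
  d <- dim(X)
  Y <- X; dim(Y) <- c(d[1], prod(d[-1]))
  list(out = Y, in_dim = d)
}
flatten_bwd <- function(dY, cache) { dim(dY) <- cache$in_dim; dY }

dense_init <- function(nin, nout, bias = TRUE, scale = 1) {
  list(W = init_mat(nin, nout, nin) * scale,
       b = if (bias) numeric(nout) else NULL)
}

dense_fwd <- function(X, p) {
  Y <- X %*% p$W
  if (!is.null(p$b)) Y <- sweep(Y, 2, p$b, "+")
  list(out = Y, X = X)
}

dense_bwd <- function(dY, cache, p) {
  list(dX = tcrossprod(dY, p$W), dW = crossprod(cache$X, dY),
       db = if (is.null(p$b)) NULL else colSums(dY))
}

# ---- losses -----------------------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# y is 1-based class index; returns loss and dlogits
softmax_ce <- function(logits, y) {
  P <- softmax_rows(logits)
  B <- nrow(P)
  py <- pmax(P[cbind(seq_len(B), y)], 1e-12)
  d <- P
  d[cbind(seq_len(B), y)] <- d[cbind(seq_len(B), y)] - 1
  list(loss = -mean(log(py)), dlogits = d / B, probs = P)
}

# squared error summed over output dimensions, averaged over the batch:
# keeps the gradient scale comparable to the cross-entropy loss regardless
# of the output width
mse_loss <- function(Yhat, Y) {
  d <- Yhat - Y
  list(loss = sum(d^2) / nrow(d), dY = 2 * d / nrow(d))
}

# ---- SGD with momentum + weight decay --------------------------------------

sgd_state <- function(params) rapply(params, function(x) x * 0, how = "replace")

sgd_step <- function(params, grads, vel, lr, momentum, weight_decay) {
  upd <- function(p, g, v) {
    if (is.null(p) || is.null(g)) return(list(p = p, v = v))
    g <- g + weight_decay * p
    v <- momentum * v - lr * g
    list(p = p + v, v = v)
  }
  walk <- function(pp, gg, vv) {
    for (nm in names(pp)) {
      if (is.list(pp[[nm]]) && !is.null(names(pp[[nm]]))) {
        r <- walk(pp[[nm]], gg[[nm]], vv[[nm]])
        pp[[nm]] <- r$p; vv[[nm]] <- r$v
      } else if (is.numeric(pp[[nm]])) {
        r <- upd(pp[[nm]], gg[[nm]], vv[[nm]])
        pp[[nm]] <- r$p; vv[[nm]] <- r$v
      }
    }
    list(p = pp, v = vv)
  }
  walk(params, grads, vel)
}

# rescale a nested gradient list so its global L2 norm is at most max_norm
grad_clip <- function(grads, max_norm) {
  total <- sqrt(sum(unlist(lapply(grads, function(g)
    if (is.list(g)) sum(unlist(g)^2) else sum(g^2)))))
  if (!is.finite(total) || total <= max_norm) return(grads)
  scale_rec <- function(g) {
    if (is.null(g)) return(NULL)
    if (is.numeric(g)) return(g * (max_norm / total))
    lapply(g, scale_rec)
  }
  scale_rec(grads)
}

# elementwise sum of two (possibly nested, possibly NULL) gradient lists
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  for (nm in names(b)) a[[nm]] <- grad_add(a[[nm]], b[[nm]])
  a
}

zero_like <- function(x) rapply(x, function(v) v * 0, how = "replace")

# ---- two-stage conv encoder (conv-relu-pool twice) --------------------------

enc_init <- function(cin, spec) {
  list(c1 = conv1d_init(spec$k1, cin, spec$maps[1]),
       c2 = conv1d_init(spec$k2, spec$maps[1], spec$maps[2]))
}

enc_fwd <- function(X, p) {
  f1 <- conv1d_fwd(X, p$c1); r1 <- relu_fwd(f1$out); p1 <- pool2_fwd(r1$out)
  f2 <- conv1d_fwd(p1$out, p$c2); r2 <- relu_fwd(f2$out); p2 <- pool2_fwd(r2$out)
  list(out = p2$out, cache = list(f1 = f1, r1 = r1, p1 = p1,
                                  f2 = f2, r2 = r2, p2 = p2))
}

enc_bwd <- function(dOut, cache, p) {
  d <- pool2_bwd(dOut, cache$p2)
  d <- relu_bwd(d, cache$r2)
  b2 <- conv1d_bwd(d, cache$f2, p$c2)
  d <- pool2_bwd(b2$dX, cache$p1)
  d <- relu_bwd(d, cache$r1)
  b1 <- conv1d_bwd(d, cache$f1, p$c1)
  list(dX = b1$dX,
       grads = list(c1 = list(W = b1$dW, b = b1$db),
                    c2 = list(W = b2$dW, b = b2$db)))
}

# output length/width of the encoder for an input of length L
enc_out_len <- function(L, spec) {
  # mirrors pool2_fwd: lengths below 2 pass through unpooled
  l1 <- L - spec$k1 + 1L
  if (l1 >= 2L) l1 <- l1 %/% 2L
  l2 <- l1 - spec$k2 + 1L
  if (l2 >= 2L) l2 <- l2 %/% 2L
  l2
}

# concat a list of (B, L, C) arrays along dim 2 (time) or 3 (channels)
concat_arrays <- function(lst, along) {
  d1 <- dim(lst[[1]])
  if (along == 3) {
    out <- array(0, c(d1[1], d1[2], sum(vapply(lst, function(a) dim(a)[3], 1))))
    off <- 0L
    for (a in lst) {
      out[, , (off + 1):(off + dim(a)[3])] <- a
      off <- off + dim(a)[3]
    }
  } else {
    out <- array(0, c(d1[1], sum(vapply(lst, function(a) dim(a)[2], 1)), d1[3]))
    off <- 0L
    for (a in lst) {
      out[, (off + 1):(off + dim(a)[2]), ] <- a
      off <- off + dim(a)[2]
    }
  }
  out
}

split_array <- function(X, sizes, along) {
  out <- vector("list", length(sizes))
  off <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- if (along == 3) X[, , (off + 1):(off + sizes[i]), drop = FALSE]
    else X[, (off + 1):(off + sizes[i]), , drop = FALSE]
    off <- off + sizes[i]
  }
  out
}
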