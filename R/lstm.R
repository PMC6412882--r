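# LSTM layers with full backpropagation through time, used by the
# evaluation classifier. Same array conventions as nn.R: (batch, time, dim).

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(nin, nh) {
  list(Wx = init_mat(nin, 4L * nh, nin),
       Wh = init_mat(nh, 4L * nh, nh),
       # forget-gate bias starts at 1 (standard trick for gradient flow)
       b = c(rep(0, nh), rep(1, nh), rep(0, 2L * nh)),
       nh = nh)
}

lstm_fwd <- function(X, p) {
  d <- dim(X); B <- d[1]; Tn <- d[2]; nin <- d[3]
  nh <- p$nh
  H <- array(0, c(B, Tn, nh))
  h <- matrix(0, B, nh); cc <- matrix(0, B, nh)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], B, nin)
    z <- xt %*% p$Wx + h %*% p$Wh
    z <- sweep(z, 2, p$b, "+")
    ig <- sigmoid(z[, 1:nh, drop = FALSE])
    fg <- sigmoid(z[, (nh + 1):(2 * nh), drop = FALSE])
    gg <- tanh(z[, (2 * nh + 1):(3 * nh), drop = FALSE])
    og <- sigmoid(z[, (3 * nh + 1):(4 * nh), drop = FALSE])
    c_prev <- cc
    cc <- fg * c_prev + ig * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- og * tc
    H[, t, ] <- h
    steps[[t]] <- list(xt = xt, i = ig, f = fg, g = gg, o = og,
                       c = cc, c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(out = H, steps = steps, in_dim = d)
}

lstm_bwd <- function(dH, cache, p) {
  d <- cache$in_dim; B <- d[1]; Tn <- d[2]; nin <- d[3]
  nh <- p$nh
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dX <- array(0, d)
  dh_rec <- matrix(0, B, nh); dc_rec <- matrix(0, B, nh)
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    dh <- matrix(dH[, t, ], B, nh) + dh_rec
    do_ <- dh * s$tc
    dc <- dc_rec + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_ * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- tcrossprod(dz, p$Wx)
    dh_rec <- tcrossprod(dz, p$Wh)
    dc_rec <- dc * s$f
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

#' Build the LSTM evaluation classifier
#'
#' A three-layer LSTM over the resized signal, followed by two hidden dense
#' layers and a final bias-free linear layer whose weight matrix is the
#' classifier `C` of the evaluation framework; a softmax over the
#' `P = n_actions * n_levels` joint classes gives the prediction. The input
#' to the final layer is the feature compared against the learned general
#' features.
#'
#' @param input_len resized signal length (samples).
#' @param n_axes input channels (3 for triaxial acceleration).
#' @param dims widths of the three LSTM layers (default `c(224, 224, 196)`).
#' @param fc widths of the two dense layers before the classifier
#'   (default `c(128, 64)`; the second is the feature dimension N_f).
#' @param n_actions,n_levels class grid (defaults 4 and 3, P = 12).
#' @param seed seed for weight initialization.
#' @return an `rr_net` of type `"lstm_eval"`.
#' @export
build_lstm_classifier <- function(input_len, n_axes = 3L,
                                  dims = c(224L, 224L, 196L),
                                  fc = c(128L, 64L),
                                  n_actions = 4L, n_levels = 3L, seed = 1L) {
  P <- n_actions * n_levels
  params <- with_seed(seed, list(
    l1 = lstm_init(n_axes, dims[1]),
    l2 = lstm_init(dims[1], dims[2]),
    l3 = lstm_init(dims[2], dims[3]),
    d1 = dense_init(dims[3], fc[1]),
    d2 = dense_init(fc[1], fc[2]),
    C = dense_init(fc[2], P, bias = FALSE)))
  spec <- list(input_len = as.integer(input_len), dims = dims, fc = fc,
               n_actions = as.integer(n_actions),
               n_levels = as.integer(n_levels), P = P, n_feat = fc[2])
  new_net("lstm_eval", params, spec)
}

lstm_eval_fwd <- function(params, X) {
  B <- dim(X)[1]
  a <- lstm_fwd(X, params$l1)
  b <- lstm_fwd(a$out, params$l2)
  c3 <- lstm_fwd(b$out, params$l3)
  Tn <- dim(X)[2]
  f0 <- matrix(c3$out[, Tn, ], B, params$l3$nh)
  d1 <- dense_fwd(f0, params$d1); r1 <- relu_fwd(d1$out)
  d2 <- dense_fwd(r1$out, params$d2); r2 <- relu_fwd(d2$out)
  o <- dense_fwd(r2$out, params$C)
  list(logits = o$out, feature = r2$out,
       cache = list(a = a, b = b, c3 = c3, d1 = d1, r1 = r1, d2 = d2,
                    r2 = r2, o = o, Tn = Tn, B = B))
}

# dlogits: gradient at the classifier logits; dfeat: external gradient on the
# feature (from the evaluation loss); dC_extra: extra gradient on C (from the
# condition loss)
lstm_eval_bwd <- function(params, cache, dlogits, dfeat = NULL,
                          dC_extra = NULL) {
  grads <- list()
  bo <- dense_bwd(dlogits, cache$o, params$C)
  gW <- bo$dW
  if (!is.null(dC_extra)) gW <- gW + dC_extra
  grads$C <- list(W = gW, b = NULL)
  dr2 <- bo$dX
  if (!is.null(dfeat)) dr2 <- dr2 + dfeat
  dd2 <- relu_bwd(dr2, cache$r2)
  b2 <- dense_bwd(dd2, cache$d2, params$d2)
  grads$d2 <- list(W = b2$dW, b = b2$db)
  dd1 <- relu_bwd(b2$dX, cache$r1)
  b1 <- dense_bwd(dd1, cache$d1, params$d1)
  grads$d1 <- list(W = b1$dW, b = b1$db)
  dH3 <- array(0, dim(cache$c3$out))
  dH3[, cache$Tn, ] <- b1$dX
  l3b <- lstm_bwd(dH3, cache$c3, params$l3)
  grads$l3 <- l3b$grads
  l2b <- lstm_bwd(l3b$dX, cache$b, params$l2)
  grads$l2 <- l2b$grads
  l1b <- lstm_bwd(l2b$dX, cache$a, params$l1)
  grads$l1 <- l1b$grads
  grads
}

#' Resize a signal to a fixed length by linear interpolation
#'
#' Each axis of the T x 3 signal is interpolated onto `length_out` evenly
#' spaced points, so all evaluation samples share one input length.
#'
#' @param acc T x k signal matrix.
#' @param length_out output length (default 128).
#' @return length_out x k matrix.
#' @export
resize_signal <- function(acc, length_out = 128L) {
  T_in <- nrow(acc)
  if (T_in < 2) stop("need at least 2 samples to resize")
  xo <- seq(1, T_in, length.out = length_out)
  apply(acc, 2, function(col) stats::approx(seq_len(T_in), col, xo)$y)
}
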