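#' Architecture hyperparameters for the CNN family
#'
#' @param n_classes number of action classes (softmax width of the
#'   classifier heads).
#' @param input_len window length in samples (default 80).
#' @param k1,k2 kernel sizes of the two convolution stages (defaults 5, 3).
#' @param maps output feature maps of the two stages (default `c(16, 32)`).
#' @param hidden widths of the two hidden (fully connected) layers
#'   (default `c(1024, 512)`).
#' @param n_parts number of D-CNN channels per feature (default 4).
#' @param fusion_depth conv+pool stages in the MP-CNN middle path, 0-3
#'   (default 1, i.e. the "(3)" variants: one convolution on the second
#'   pooling outputs).
#' @param state_dim number of PFSA dictionary states n; the S-CNN output is
#'   n^2. Required for S-CNN / MP-CNN.
#' @param top_type MP-CNN top sub-network: `"gb"` (gravity/body CNN;
#'   MP-CNN-1) or `"d"` (dynamic CNN; MP-CNN-2).
#' @return list of class `network_spec`.
#' @export
network_spec <- function(n_classes, input_len = 80L, k1 = 5L, k2 = 3L,
                         maps = c(16L, 32L), hidden = c(1024L, 512L),
                         n_parts = 4L, fusion_depth = 1L, state_dim = NULL,
                         top_type = c("gb", "d")) {
  stopifnot(n_classes >= 2, input_len >= k1 + k2, fusion_depth %in% 0:3)
  structure(list(n_classes = as.integer(n_classes),
                 input_len = as.integer(input_len),
                 k1 = as.integer(k1), k2 = as.integer(k2),
                 maps = as.integer(maps), hidden = as.integer(hidden),
                 n_parts = as.integer(n_parts),
                 fusion_depth = as.integer(fusion_depth),
                 state_dim = state_dim, top_type = match.arg(top_type)),
            class = "network_spec")
}

#' Optimizer settings
#'
#' Defaults follow the standard SGD recipe for these models: learning rate
#' 0.01, momentum 0.9, weight decay 0.0005.
#'
#' @param lr learning rate (> 0).
#' @param momentum momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param epochs training epochs.
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed controlling shuffling (and any re-init).
#' @param clip global L2 gradient-norm ceiling (default `Inf`, no clipping;
#'   recurrent models train reliably with `clip = 1`).
#' @param verbose print per-epoch progress.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 5e-4,
                         epochs = 30L, batch_size = 32L, seed = 1L,
                         clip = Inf, verbose = FALSE) {
  stopifnot(lr > 0, clip > 0)
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 clip = clip, verbose = isTRUE(verbose)),
            class = "train_config")
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  expr
}

new_net <- function(type, params, spec) {
  structure(list(type = type, params = params, spec = spec),
            class = c(type, "rr_net"))
}

# ---- GB-CNN -----------------------------------------------------------------

#' Build the gravity/body CNN (GB-CNN)
#'
#' Gravity and body windows are combined channel-wise, passed through two
#' convolution+pooling stages, then two hidden layers and a softmax over the
#' action classes.
#'
#' @param spec a [network_spec()].
#' @param seed seed for weight initialization.
#' @return an `rr_net` of type `"gbcnn"`.
#' @export
build_gbcnn <- function(spec, seed = 1L) {
  flat <- enc_out_len(spec$input_len, spec) * spec$maps[2]
  params <- with_seed(seed, list(
    enc = enc_init(6L, spec),
    h1 = dense_init(flat, spec$hidden[1]),
    h2 = dense_init(spec$hidden[1], spec$hidden[2]),
    out = dense_init(spec$hidden[2], spec$n_classes)))
  new_net("gbcnn", params, spec)
}

gbcnn_fwd <- function(params, inputs) {
  X <- concat_arrays(list(inputs$gravity, inputs$body), along = 3)
  e <- enc_fwd(X, params$enc)
  fl <- flatten_fwd(e$out)
  d1 <- dense_fwd(fl$out, params$h1); r1 <- relu_fwd(d1$out)
  d2 <- dense_fwd(r1$out, params$h2); r2 <- relu_fwd(d2$out)
  o <- dense_fwd(r2$out, params$out)
  list(out = o$out,
       feats = list(pool2 = e$out, h2 = r2$out),
       cache = list(e = e, fl = fl, d1 = d1, r1 = r1, d2 = d2, r2 = r2, o = o))
}

# dlogits may be NULL (when used as MP-CNN top); dpool2/dh2 are external
# gradients arriving at the fusion taps
gbcnn_bwd <- function(params, cache, dlogits = NULL, dpool2 = NULL, dh2 = NULL) {
  grads <- list()
  dr2 <- NULL
  if (!is.null(dlogits)) {
    bo <- dense_bwd(dlogits, cache$o, params$out)
    grads$out <- list(W = bo$dW, b = bo$db)
    dr2 <- bo$dX
  } else {
    grads$out <- list(W = params$out$W * 0, b = params$out$b * 0)
  }
  dr2 <- grad_add(dr2, dh2)
  dd2 <- relu_bwd(dr2, cache$r2)
  b2 <- dense_bwd(dd2, cache$d2, params$h2)
  grads$h2 <- list(W = b2$dW, b = b2$db)
  dd1 <- relu_bwd(b2$dX, cache$r1)
  b1 <- dense_bwd(dd1, cache$d1, params$h1)
  grads$h1 <- list(W = b1$dW, b = b1$db)
  denc <- flatten_bwd(b1$dX, cache$fl)
  denc <- grad_add(denc, dpool2)
  be <- enc_bwd(denc, cache$e$cache, params$enc)
  grads$enc <- be$grads
  grads
}

# ---- S-CNN ------------------------------------------------------------------

#' Build the state-transition probability CNN (S-CNN)
#'
#' Maps a raw normalized window to the flattened PFSA transition matrix
#' (length `state_dim^2`) through two convolution+pooling stages and one
#' hidden layer; trained as a regression with mean-squared error.
#'
#' @inheritParams build_gbcnn
#' @return an `rr_net` of type `"scnn"`.
#' @export
build_scnn <- function(spec, seed = 1L) {
  if (is.null(spec$state_dim)) stop("spec$state_dim required for the S-CNN")
  flat <- enc_out_len(spec$input_len, spec) * spec$maps[2]
  n2 <- spec$state_dim^2
  params <- with_seed(seed, list(
    enc = enc_init(3L, spec),
    h1 = dense_init(flat, spec$hidden[1]),
    # small-scale output init: regression targets are probabilities, so a
    # full-scale random head would start with outputs far outside [0, 1]
    # and its error transient can kill the trunk ReLUs
    out = dense_init(spec$hidden[1], n2, scale = 0.05)))
  new_net("scnn", params, spec)
}

scnn_fwd <- function(params, inputs) {
  e <- enc_fwd(inputs$x, params$enc)
  fl <- flatten_fwd(e$out)
  d1 <- dense_fwd(fl$out, params$h1); r1 <- relu_fwd(d1$out)
  o <- dense_fwd(r1$out, params$out)
  list(out = o$out, feats = list(pool2 = e$out, sout = o$out),
       cache = list(e = e, fl = fl, d1 = d1, r1 = r1, o = o))
}

scnn_bwd <- function(params, cache, dout = NULL, dpool2 = NULL) {
  grads <- list()
  dr1 <- NULL
  if (!is.null(dout)) {
    bo <- dense_bwd(dout, cache$o, params$out)
    grads$out <- list(W = bo$dW, b = bo$db)
    dr1 <- bo$dX
  } else {
    grads$out <- list(W = params$out$W * 0, b = params$out$b * 0)
  }
  dd1 <- relu_bwd(dr1, cache$r1)
  b1 <- dense_bwd(dd1, cache$d1, params$h1)
  grads$h1 <- list(W = b1$dW, b = b1$db)
  denc <- flatten_bwd(b1$dX, cache$fl)
  denc <- grad_add(denc, dpool2)
  be <- enc_bwd(denc, cache$e$cache, params$enc)
  grads$enc <- be$grads
  grads
}

# ---- D-CNN ------------------------------------------------------------------

#' Build the dynamic CNN (D-CNN)
#'
#' Consumes channel-fitted gravity and body windows (see
#' [assign_window()]): each of the `n_parts` segments per feature runs
#' through its own convolution+pooling path, the path outputs are
#' concatenated along time into a feature map, then two hidden layers and a
#' softmax classify the action.
#'
#' @inheritParams build_gbcnn
#' @return an `rr_net` of type `"dcnn"`.
#' @export
build_dcnn <- function(spec, seed = 1L) {
  N <- spec$n_parts
  seg <- ceiling(spec$input_len / N)
  ls <- enc_out_len(seg, spec)
  if (ls < 1) stop("segments too short for the encoder kernels")
  flat <- 2L * N * ls * spec$maps[2]
  params <- with_seed(seed, {
    encs <- lapply(seq_len(2L * N), function(i) enc_init(3L, spec))
    names(encs) <- c(paste0("g", seq_len(N)), paste0("b", seq_len(N)))
    list(encs = encs,
         h1 = dense_init(flat, spec$hidden[1]),
         h2 = dense_init(spec$hidden[1], spec$hidden[2]),
         out = dense_init(spec$hidden[2], spec$n_classes))
  })
  net <- new_net("dcnn", params, spec)
  net$seg_len <- seg
  net
}

dcnn_paths <- function(params, inputs, spec) {
  N <- spec$n_parts
  seg <- ceiling(spec$input_len / N)
  outs <- vector("list", 2L * N)
  caches <- vector("list", 2L * N)
  feats <- list(inputs$gravity, inputs$body)
  for (f in 1:2) for (i in seq_len(N)) {
    j <- (f - 1L) * N + i
    Xs <- feats[[f]][, ((i - 1L) * seg + 1L):(i * seg), , drop = FALSE]
    e <- enc_fwd(Xs, params$encs[[j]])
    outs[[j]] <- e$out
    caches[[j]] <- e$cache
  }
  list(Z = concat_arrays(outs, along = 2), caches = caches,
       sizes = vapply(outs, function(a) dim(a)[2], numeric(1)))
}

dcnn_fwd <- function(params, inputs, spec) {
  p <- dcnn_paths(params, inputs, spec)
  fl <- flatten_fwd(p$Z)
  d1 <- dense_fwd(fl$out, params$h1); r1 <- relu_fwd(d1$out)
  d2 <- dense_fwd(r1$out, params$h2); r2 <- relu_fwd(d2$out)
  o <- dense_fwd(r2$out, params$out)
  list(out = o$out, feats = list(zmap = p$Z, h2 = r2$out),
       cache = list(p = p, fl = fl, d1 = d1, r1 = r1, d2 = d2, r2 = r2, o = o))
}

dcnn_bwd <- function(params, cache, spec, dlogits = NULL, dzmap = NULL,
                     dh2 = NULL) {
  grads <- list()
  dr2 <- NULL
  if (!is.null(dlogits)) {
    bo <- dense_bwd(dlogits, cache$o, params$out)
    grads$out <- list(W = bo$dW, b = bo$db)
    dr2 <- bo$dX
  } else {
    grads$out <- list(W = params$out$W * 0, b = params$out$b * 0)
  }
  dr2 <- grad_add(dr2, dh2)
  dd2 <- relu_bwd(dr2, cache$r2)
  b2 <- dense_bwd(dd2, cache$d2, params$h2)
  grads$h2 <- list(W = b2$dW, b = b2$db)
  dd1 <- relu_bwd(b2$dX, cache$r1)
  b1 <- dense_bwd(dd1, cache$d1, params$h1)
  grads$h1 <- list(W = b1$dW, b = b1$db)
  dZ <- flatten_bwd(b1$dX, cache$fl)
  dZ <- grad_add(dZ, dzmap)
  parts <- split_array(dZ, cache$p$sizes, along = 2)
  grads$encs <- vector("list", length(parts))
  names(grads$encs) <- names(params$encs)
  for (j in seq_along(parts)) {
    be <- enc_bwd(parts[[j]], cache$p$caches[[j]], params$encs[[j]])
    grads$encs[[j]] <- be$grads
  }
  grads
}

# ---- MLP (baseline / feature-classifier head) -------------------------------

#' Build a small dense softmax classifier
#'
#' Used as the classification head over S-CNN features and as a plain NN
#' baseline.
#'
#' @param n_in input feature dimension.
#' @param hidden integer vector of hidden widths (may be empty for a linear
#'   softmax model).
#' @param n_classes number of classes.
#' @param seed seed for weight initialization.
#' @return an `rr_net` of type `"mlp"`.
#' @export
build_mlp <- function(n_in, hidden, n_classes, seed = 1L) {
  dims <- c(n_in, hidden, n_classes)
  params <- with_seed(seed, lapply(seq_len(length(dims) - 1L), function(i)
    dense_init(dims[i], dims[i + 1L])))
  names(params) <- paste0("l", seq_along(params))
  net <- new_net("mlp", params, list(dims = dims, n_classes = n_classes))
  net
}

mlp_fwd <- function(params, inputs) {
  X <- inputs$x
  n <- length(params)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dense_fwd(X, params[[i]])
    r <- if (i < n) relu_fwd(d$out) else NULL
    caches[[i]] <- list(d = d, r = r)
    X <- if (i < n) r$out else d$out
  }
  list(out = X, feats = list(), cache = caches)
}

mlp_bwd <- function(params, cache, dlogits) {
  n <- length(params)
  grads <- vector("list", n)
  names(grads) <- names(params)
  dY <- dlogits
  for (i in rev(seq_len(n))) {
    if (i < n) dY <- relu_bwd(dY, cache[[i]]$r)
    b <- dense_bwd(dY, cache[[i]]$d, params[[i]])
    grads[[i]] <- list(W = b$dW, b = b$db)
    dY <- b$dX
  }
  grads
}

# ---- MP-CNN -----------------------------------------------------------------

mp_fusion_geom <- function(spec) {
  len_bot <- enc_out_len(spec$input_len, spec)
  if (spec$top_type == "gb") {
    len_top <- len_bot
  } else {
    seg <- ceiling(spec$input_len / spec$n_parts)
    len_top <- 2L * spec$n_parts * enc_out_len(seg, spec)
  }
  if (len_top == len_bot) {
    list(mode = 3L, len = len_top, ch = 2L * spec$maps[2],
         sizes = c(spec$maps[2], spec$maps[2]))
  } else {
    list(mode = 2L, len = len_top + len_bot, ch = spec$maps[2],
         sizes = c(len_top, len_bot))
  }
}

#' Build the multipath CNN (MP-CNN)
#'
#' Fuses a top sub-network (GB-CNN for MP-CNN-1, D-CNN for MP-CNN-2) with
#' the S-CNN: the second pooling outputs of both are combined and passed
#' through `fusion_depth` extra convolution+pooling stages (the middle
#' path); the middle-path output, the top network's second hidden layer and
#' the S-CNN output layer are concatenated and classified through two hidden
#' layers and a softmax. With `fusion_depth = 0` the middle path is absent.
#'
#' @inheritParams build_gbcnn
#' @return an `rr_net` of type `"mpcnn"`.
#' @export
build_mpcnn <- function(spec, seed = 1L) {
  if (is.null(spec$state_dim)) stop("spec$state_dim required for the MP-CNN")
  geom <- mp_fusion_geom(spec)
  len <- geom$len; ch <- geom$ch
  mids <- list()
  for (d in seq_len(spec$fusion_depth)) {
    if (len < 3L)
      stop("fusion depth ", spec$fusion_depth,
           " incompatible with fusion map length ", geom$len)
    mids[[d]] <- list(k = 3L, cin = ch, cout = spec$maps[2])
    len <- len - 2L
    if (len >= 2L) len <- len %/% 2L
    ch <- spec$maps[2]
  }
  mid_flat <- if (spec$fusion_depth > 0) len * ch else 0L
  n2 <- spec$state_dim^2
  f_in <- mid_flat + spec$hidden[2] + n2
  params <- with_seed(seed, {
    top <- if (spec$top_type == "gb") build_gbcnn(spec, seed)$params
    else build_dcnn(spec, seed)$params
    bot <- build_scnn(spec, seed + 1L)$params
    mid <- lapply(mids, function(m) conv1d_init(m$k, m$cin, m$cout))
    if (length(mid)) names(mid) <- paste0("m", seq_along(mid))
    list(top = top, bot = bot, mid = mid,
         f1 = dense_init(f_in, spec$hidden[1]),
         f2 = dense_init(spec$hidden[1], spec$hidden[2]),
         out = dense_init(spec$hidden[2], spec$n_classes))
  })
  net <- new_net("mpcnn", params, spec)
  net$geom <- geom
  net
}

mpcnn_fwd <- function(params, inputs, spec, geom) {
  topf <- if (spec$top_type == "gb")
    gbcnn_fwd(params$top, inputs)
  else dcnn_fwd(params$top, list(gravity = inputs$d_gravity,
                                 body = inputs$d_body), spec)
  botf <- scnn_fwd(params$bot, inputs)
  top_map <- if (spec$top_type == "gb") topf$feats$pool2 else topf$feats$zmap
  Z <- concat_arrays(list(top_map, botf$feats$pool2), along = geom$mode)
  mid_caches <- list()
  M <- Z
  for (d in seq_along(params$mid)) {
    f <- conv1d_fwd(M, params$mid[[d]])
    r <- relu_fwd(f$out)
    p <- pool2_fwd(r$out)
    mid_caches[[d]] <- list(f = f, r = r, p = p)
    M <- p$out
  }
  parts <- list()
  if (length(params$mid)) {
    mfl <- flatten_fwd(M)
    parts$mid <- mfl
    Fmat <- cbind(mfl$out, topf$feats$h2, botf$out)
  } else {
    mfl <- NULL
    Fmat <- cbind(topf$feats$h2, botf$out)
  }
  d1 <- dense_fwd(Fmat, params$f1); r1 <- relu_fwd(d1$out)
  d2 <- dense_fwd(r1$out, params$f2); r2 <- relu_fwd(d2$out)
  o <- dense_fwd(r2$out, params$out)
  list(out = o$out, feats = list(),
       cache = list(topf = topf, botf = botf, mid = mid_caches, mfl = mfl,
                    d1 = d1, r1 = r1, d2 = d2, r2 = r2, o = o,
                    dims = list(mid_flat = if (is.null(mfl)) 0L else
                      ncol(mfl$out),
                      h2 = ncol(topf$feats$h2), n2 = ncol(botf$out))))
}

mpcnn_bwd <- function(params, cache, spec, geom, dlogits) {
  grads <- list()
  bo <- dense_bwd(dlogits, cache$o, params$out)
  grads$out <- list(W = bo$dW, b = bo$db)
  dd2 <- relu_bwd(bo$dX, cache$r2)
  b2 <- dense_bwd(dd2, cache$d2, params$f2)
  grads$f2 <- list(W = b2$dW, b = b2$db)
  dd1 <- relu_bwd(b2$dX, cache$r1)
  b1 <- dense_bwd(dd1, cache$d1, params$f1)
  grads$f1 <- list(W = b1$dW, b = b1$db)
  dims <- cache$dims
  dF <- b1$dX
  off <- 0L
  dmid <- NULL
  if (dims$mid_flat > 0) {
    dmid <- dF[, 1:dims$mid_flat, drop = FALSE]
    off <- dims$mid_flat
  }
  dh2 <- dF[, (off + 1):(off + dims$h2), drop = FALSE]
  dsout <- dF[, (off + dims$h2 + 1):(off + dims$h2 + dims$n2), drop = FALSE]
  # middle path backward
  dZ <- NULL
  if (!is.null(dmid)) {
    dM <- flatten_bwd(dmid, cache$mfl)
    grads$mid <- vector("list", length(params$mid))
    names(grads$mid) <- names(params$mid)
    for (d in rev(seq_along(params$mid))) {
      mc <- cache$mid[[d]]
      dM <- pool2_bwd(dM, mc$p)
      dM <- relu_bwd(dM, mc$r)
      bc <- conv1d_bwd(dM, mc$f, params$mid[[d]])
      grads$mid[[d]] <- list(W = bc$dW, b = bc$db)
      dM <- bc$dX
    }
    dZ <- dM
  }
  if (!is.null(dZ)) {
    sp <- split_array(dZ, geom$sizes, along = geom$mode)
    dtop_map <- sp[[1]]; dbot_p2 <- sp[[2]]
  } else {
    dtop_map <- NULL; dbot_p2 <- NULL
  }
  grads$top <- if (spec$top_type == "gb")
    gbcnn_bwd(params$top, cache$topf$cache, dlogits = NULL,
              dpool2 = dtop_map, dh2 = dh2)
  else dcnn_bwd(params$top, cache$topf$cache, spec, dlogits = NULL,
                dzmap = dtop_map, dh2 = dh2)
  grads$bot <- scnn_bwd(params$bot, cache$botf$cache, dout = dsout,
                        dpool2 = dbot_p2)
  grads
}

# ---- generic forward / training ---------------------------------------------

net_forward <- function(net, inputs) {
  switch(net$type,
         gbcnn = gbcnn_fwd(net$params, inputs),
         scnn = scnn_fwd(net$params, inputs),
         dcnn = dcnn_fwd(net$params, inputs, net$spec),
         mpcnn = mpcnn_fwd(net$params, inputs, net$spec, net$geom),
         mlp = mlp_fwd(net$params, inputs),
         stop("unknown network type ", net$type))
}

net_backward <- function(net, cache, dout) {
  switch(net$type,
         gbcnn = gbcnn_bwd(net$params, cache, dlogits = dout),
         scnn = scnn_bwd(net$params, cache, dout = dout),
         dcnn = dcnn_bwd(net$params, cache, net$spec, dlogits = dout),
         mpcnn = mpcnn_bwd(net$params, cache, net$spec, net$geom, dout),
         mlp = mlp_bwd(net$params, cache, dout),
         stop("unknown network type ", net$type))
}

slice_inputs <- function(inputs, idx) {
  lapply(inputs, function(a) {
    if (length(dim(a)) == 3) a[idx, , , drop = FALSE]
    else a[idx, , drop = FALSE]
  })
}

#' Train a network with SGD
#'
#' Stochastic gradient descent with momentum and weight decay. Classifiers
#' (`loss = "ce"`) take 0-based integer labels in `y`; the S-CNN regression
#' (`loss = "mse"`) takes a target matrix. When `pretrained` sub-networks are
#' supplied (MP-CNN), their weights initialize the matching branches before
#' joint training.
#'
#' @param net an `rr_net` from one of the builders.
#' @param inputs named list of input arrays, first dimension = samples.
#'   Keys by model: GB-CNN/MP-CNN `gravity`, `body`; S-CNN/MP-CNN `x`;
#'   D-CNN/MP-CNN-2 (d_)gravity/(d_)body channel-fitted windows; MLP `x`.
#' @param y 0-based class labels (ce) or target matrix (mse).
#' @param cfg a [train_config()].
#' @param loss `"ce"` or `"mse"`.
#' @param pretrained optional named list of trained sub-networks, e.g.
#'   `list(top = gb_net, bot = s_net)`.
#' @return the network with trained parameters and a `history` data frame
#'   (epoch, loss, accuracy for ce).
#' @export
train_net <- function(net, inputs, y, cfg = train_config(),
                      loss = c("ce", "mse"), pretrained = NULL) {
  loss <- match.arg(loss)
  if (!is.null(pretrained)) {
    for (nm in names(pretrained)) {
      net$params[[nm]] <- pretrained[[nm]]$params
    }
  }
  n <- if (is.matrix(y)) nrow(y) else length(y)
  y1 <- if (loss == "ce") as.integer(y) + 1L else y
  vel <- sgd_state(net$params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      tot <- 0; correct <- 0
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        bi <- idx[b0:min(b0 + cfg$batch_size - 1L, n)]
        xin <- slice_inputs(inputs, bi)
        fwd <- net_forward(net, xin)
        if (loss == "ce") {
          l <- softmax_ce(fwd$out, y1[bi])
          correct <- correct + sum(max.col(fwd$out, ties.method = "first") ==
                                     y1[bi])
          dout <- l$dlogits
        } else {
          l <- mse_loss(fwd$out, y1[bi, , drop = FALSE])
          dout <- l$dY
        }
        if (!is.finite(l$loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        tot <- tot + l$loss * length(bi)
        grads <- net_backward(net, fwd$cache, dout)
        if (!is.null(cfg$clip) && is.finite(cfg$clip))
          grads <- grad_clip(grads, cfg$clip)
        st <- sgd_step(net$params, grads, vel, cfg$lr, cfg$momentum,
                       cfg$weight_decay)
        net$params <- st$p
        vel <- st$v
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, loss = tot / n,
        accuracy = if (loss == "ce") correct / n else NA_real_))
      if (cfg$verbose)
        message(sprintf("epoch %d: loss %.5f acc %.3f", ep, tot / n,
                        correct / n))
    }
  })
  net$history <- hist
  net
}

#' Predict from a trained network
#'
#' @param object an `rr_net`.
#' @param inputs named list of input arrays (see [train_net()]).
#' @param type `"prob"` (softmax posteriors), `"class"` (0-based labels) or
#'   `"raw"` (network output, e.g. the S-CNN transition-probability vector).
#' @param ... unused.
#' @return matrix of probabilities, integer labels, or raw outputs.
#' @export
predict.rr_net <- function(object, inputs, type = c("prob", "class", "raw"),
                           ...) {
  type <- match.arg(type)
  out <- net_forward(object, inputs)$out
  switch(type,
         raw = out,
         prob = softmax_rows(out),
         class = max.col(out, ties.method = "first") - 1L)
}

#' Classification accuracy of a network on labelled inputs
#'
#' @param net an `rr_net` classifier.
#' @param inputs named list of input arrays.
#' @param y 0-based true labels.
#' @return fraction correct.
#' @export
net_accuracy <- function(net, inputs, y) {
  mean(predict(net, inputs, type = "class") == as.integer(y))
}
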