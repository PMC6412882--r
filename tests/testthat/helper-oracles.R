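# Shared test utilities: independent oracle implementations and a
# finite-difference gradient checker. Everything here is written from the
# definitions, not by calling package internals.

# ---- finite-difference gradient checking ------------------------------------

flat_grad_names <- function(p, prefix = "") {
  out <- character(0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (is.list(v)) out <- c(out, flat_grad_names(v, paste0(prefix, nm, "$")))
    else if (is.numeric(v) && length(v) > 1) out <- c(out, paste0(prefix, nm))
  }
  out
}

get_path <- function(p, path) {
  for (k in path) p <- p[[k]]
  p
}

set_path <- function(p, path, val) {
  if (length(path) == 1) {
    p[[path]] <- val
    return(p)
  }
  p[[path[1]]] <- set_path(p[[path[1]]], path[-1], val)
  p
}

# worst relative error between analytic grads and central differences of
# loss_fn over a random sample of coordinates per parameter tensor
gradcheck_worst <- function(params, grads, loss_fn, n_check = 8L,
                            eps = 1e-5, seed = 99L) {
  worst <- 0
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  for (nm in flat_grad_names(grads)) {
    path <- strsplit(nm, "$", fixed = TRUE)[[1]]
    g <- get_path(grads, path)
    idx <- sample(length(g), min(n_check, length(g)))
    for (i in idx) {
      v <- get_path(params, path)
      v[i] <- v[i] + eps
      l1 <- loss_fn(set_path(params, path, v))
      v[i] <- v[i] - 2 * eps
      l2 <- loss_fn(set_path(params, path, v))
      num <- (l1 - l2) / (2 * eps)
      rel <- abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i]))
      if (rel > worst) worst <- rel
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  worst
}

# shift every weight/bias away from exact-zero pre-activations (ReLU kinks
# break central differences even when the analytic gradient is right)
jitter_params <- function(p, sd = 0.05) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (is.list(v)) p[[nm]] <- jitter_params(v, sd)
    else if (is.numeric(v) && length(v) > 1)
      p[[nm]] <- v + stats::rnorm(length(v), 0, sd)
  }
  p
}

# ---- independent oracles -----------------------------------------------------

# naive valid 1-D convolution: X (B,L,Cin), W (k*Cin)xCout laid out with
# column index (cin-1)*k + dk, b length Cout
oracle_conv1d <- function(X, W, b, k) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; Cin <- d[3]
  Lout <- L - k + 1
  Cout <- ncol(W)
  out <- array(0, c(B, Lout, Cout))
  for (bb in seq_len(B)) for (t in seq_len(Lout)) for (co in seq_len(Cout)) {
    acc <- b[co]
    for (ci in seq_len(Cin)) for (dk in seq_len(k))
      acc <- acc + X[bb, t + dk - 1, ci] * W[(ci - 1) * k + dk, co]
    out[bb, t, co] <- acc
  }
  out
}

# plain quadratic form (x-mu)' Sigma^{-1} (x-mu)
oracle_mahalanobis <- function(x, mu, Sigma) {
  d <- x - mu
  as.numeric(t(d) %*% solve(Sigma) %*% d)
}

# token-level Levenshtein by dynamic programming over token vectors
oracle_levenshtein <- function(a, b) {
  na <- length(a); nb <- length(b)
  D <- matrix(0, na + 1, nb + 1)
  D[, 1] <- 0:na; D[1, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb))
    D[i + 1, j + 1] <- min(D[i, j + 1] + 1, D[i + 1, j] + 1,
                           D[i, j] + (a[i] != b[j]))
  D[na + 1, nb + 1]
}

# random SPD matrix
random_spd <- function(d) {
  A <- matrix(stats::rnorm(d * d), d, d)
  crossprod(A) + diag(d) * (0.1 + stats::runif(1))
}

# tiny deterministic recording for preprocessing tests: sinusoid bursts
toy_recording <- function(T_len = 200L, fs = 32) {
  t <- seq(0, by = 1 / fs, length.out = T_len)
  acc <- cbind(sin(2 * pi * 2 * t), cos(2 * pi * 3 * t), 0.5 * sin(2 * pi * t))
  structure(list(t = t, acc = acc, action = 0L, level = 0L, subject = 0L,
                 id = 1L, rep_lengths = rep(T_len / 10, 10)),
            class = "signal_recording")
}
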