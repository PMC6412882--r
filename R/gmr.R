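#' Fit a joint time-acceleration Gaussian mixture (GMM-GMR model)
#'
#' Fits a `K_g`-component full-covariance Gaussian mixture by EM to 4-D
#' points `(t, ax, ay, az)` pooled across the windows of one class and one
#' feature (gravity or body). Covariances are regularized with `+ eps * I`.
#' For large point sets a seeded subsample is used for fitting. Fitting is
#' deterministic given `seed`.
#'
#' @param points n x 4 matrix, first column the (normalized) time index.
#' @param K_g number of mixture components (>= 1).
#' @param seed integer seed (controls subsampling / re-initialization).
#' @param eps covariance ridge (default 1e-6).
#' @param max_points subsample cap for EM (default 2000).
#' @return list of class `gmm_gmr`: `K`, `weights`, `means` (K x 4),
#'   `covs` (list of 4 x 4 matrices).
#' @export
fit_gmm_gmr <- function(points, K_g = 5L, seed = 1L, eps = 1e-6,
                        max_points = 2000L) {
  if (K_g < 1) stop("K_g must be >= 1")
  points <- as.matrix(points)
  if (nrow(points) < K_g * 10)
    stop("need at least 10*K_g points to fit the mixture")
  for (attempt in 0:2) {
    idx <- seq_len(nrow(points))
    if (length(idx) > max_points) {
      old <- .Random.seed_get(); set.seed(seed + attempt)
      idx <- sample(idx, max_points)
      .Random.seed_set(old)
    }
    fit <- tryCatch({
      dat <- points[idx, , drop = FALSE]
      bic <- mclust::mclustBIC(dat, G = K_g, modelNames = "VVV",
                               verbose = FALSE)
      mclust::Mclust(dat, G = K_g, modelNames = "VVV", x = bic,
                     verbose = FALSE)
    }, error = function(e) NULL)
    if (!is.null(fit) && !anyNA(fit$parameters$mean)) {
      p <- fit$parameters
      covs <- lapply(seq_len(K_g), function(k) {
        s <- if (K_g == 1) p$variance$sigma[, , 1] else p$variance$sigma[, , k]
        s <- (s + t(s)) / 2 + diag(eps, ncol(points))
        unname(s)
      })
      w <- if (is.null(p$pro)) rep(1, K_g) else p$pro
      return(structure(list(K = as.integer(K_g), weights = w / sum(w),
                            means = unname(t(p$mean)), covs = covs),
                       class = "gmm_gmr"))
    }
  }
  stop("EM failed to fit a non-degenerate ", K_g, "-component mixture")
}

#' Condition the mixture on a time index (Gaussian mixture regression)
#'
#' For each component k, the conditional acceleration mean and covariance at
#' time t are
#' \deqn{\hat\mu_k^a = \mu_k^a + \Sigma_k^{at}(\Sigma_k^{tt})^{-1}(t-\mu_k^t), \quad
#'       \hat\Sigma_k^{aa} = \Sigma_k^{aa} - \Sigma_k^{at}(\Sigma_k^{tt})^{-1}\Sigma_k^{ta},}
#' mixed by responsibilities \eqn{\beta_k(t) \propto \pi_k N(t; \mu_k^t,
#' \Sigma_k^{tt})} (computed in log-space) into
#' \eqn{\mu^a(t) = \sum_k \beta_k \hat\mu_k^a} and
#' \eqn{\Sigma^{aa}(t) = \sum_k \beta_k^2 \hat\Sigma_k^{aa}}.
#'
#' @param model a `gmm_gmr`.
#' @param t numeric vector of time indices.
#' @return list: `mean` (length(t) x 3), `cov` (3 x 3 x length(t)),
#'   `beta` (length(t) x K, rows sum to 1).
#' @export
condition_on_time <- function(model, t) {
  stopifnot(inherits(model, "gmm_gmr"))
  K <- model$K
  nt <- length(t)
  logd <- matrix(0, nt, K)
  mu_hat <- array(0, c(nt, 3, K))
  sig_hat <- vector("list", K)
  for (k in seq_len(K)) {
    mu <- model$means[k, ]
    S <- model$covs[[k]]
    stt <- S[1, 1]
    sat <- S[2:4, 1]            # Sigma^{at}, 3 x 1
    saa <- S[2:4, 2:4]
    logd[, k] <- log(model$weights[k]) +
      stats::dnorm(t, mu[1], sqrt(stt), log = TRUE)
    mu_hat[, , k] <- matrix(mu[2:4], nt, 3, byrow = TRUE) +
      outer(t - mu[1], sat / stt)
    sig_hat[[k]] <- saa - tcrossprod(sat) / stt
  }
  m <- apply(logd, 1, max)
  beta <- exp(logd - m)
  beta <- beta / rowSums(beta)
  mean_t <- matrix(0, nt, 3)
  cov_t <- array(0, c(3, 3, nt))
  for (k in seq_len(K)) {
    mean_t <- mean_t + beta[, k] * mu_hat[, , k]
    for (i in seq_len(nt))
      cov_t[, , i] <- cov_t[, , i] + beta[i, k]^2 * sig_hat[[k]]
  }
  list(mean = mean_t, cov = cov_t, beta = beta)
}

#' Squared Mahalanobis distance
#'
#' The quadratic form \eqn{(x-\mu)^\top \Sigma^{-1} (x-\mu)} (no square
#' root; monotone-equivalent for ranking segment-to-channel matches).
#'
#' @param x,mu numeric vectors of equal length.
#' @param Sigma covariance matrix (invertible).
#' @return non-negative scalar.
#' @export
mahalanobis_distance <- function(x, mu, Sigma) {
  d <- x - mu
  sol <- tryCatch(solve(Sigma, d), error = function(e)
    solve(Sigma + diag(1e-8, length(d)), d))
  as.numeric(crossprod(d, sol))
}

#' Mean Mahalanobis distance between a feature segment and a model slice
#'
#' @param segment n x 3 matrix of feature samples.
#' @param model_part list with `mean` (n x 3) and either `cov` (3 x 3 x n)
#'   or precomputed `inv` (3 x 3 x n).
#' @return mean of per-sample squared Mahalanobis distances.
#' @export
segment_distance <- function(segment, model_part) {
  n <- nrow(segment)
  if (n != nrow(model_part$mean))
    stop("segment and model part have different lengths")
  inv <- model_part$inv
  if (is.null(inv)) {
    tot <- 0
    for (i in seq_len(n)) {
      tot <- tot + mahalanobis_distance(segment[i, ], model_part$mean[i, ],
                                        model_part$cov[, , i])
    }
    return(tot / n)
  }
  # vectorized symmetric quadratic form over the time axis
  D <- segment - model_part$mean
  dt <- inv[1, 1, ] * D[, 1]^2 + inv[2, 2, ] * D[, 2]^2 +
    inv[3, 3, ] * D[, 3]^2 +
    2 * (inv[1, 2, ] * D[, 1] * D[, 2] + inv[1, 3, ] * D[, 1] * D[, 3] +
           inv[2, 3, ] * D[, 2] * D[, 3])
  mean(dt)
}

# conditional trajectory on a length-W grid with precomputed inverses
gmr_trajectory <- function(model, W) {
  t <- if (W > 1) (seq_len(W) - 1) / (W - 1) else 0
  traj <- condition_on_time(model, t)
  inv <- array(0, c(3, 3, W))
  for (i in seq_len(W)) {
    s <- traj$cov[, , i]
    inv[, , i] <- tryCatch(solve(s), error = function(e)
      solve(s + diag(1e-8, 3)))
  }
  traj$inv <- inv
  traj
}

part_indices <- function(W, N_p) {
  base <- W %/% N_p
  pad <- W %% N_p
  # pad by edge replication so parts are equal-length
  idx <- c(seq_len(W), rep(W, (N_p - pad) %% N_p))
  split(idx, rep(seq_len(N_p), each = length(idx) / N_p))
}

#' Dynamically assign feature segments to CNN channels
#'
#' Splits the feature window and the class trajectory model into `N_p` equal
#' contiguous parts, computes the `N_p` x `N_p` matrix of mean Mahalanobis
#' costs, and assigns segments to channels by the minimum-total-cost
#' one-to-one matching (exhaustive over permutations for `N_p <= 8`). Ties
#' resolve toward the identity mapping.
#'
#' @param features W x 3 feature matrix (gravity or body component).
#' @param model a `gmm_gmr` for the candidate class.
#' @param N_p number of parts/channels (default 4).
#' @param traj optional precomputed [gmr_trajectory()] for speed.
#' @return list of class `channel_assignment`: `mapping` (integer vector,
#'   `mapping[i]` = channel of segment i), `distances` (cost matrix),
#'   `total_cost`.
#' @export
dynamic_assign <- function(features, model, N_p = 4L, traj = NULL) {
  W <- nrow(features)
  if (is.null(traj)) traj <- gmr_trajectory(model, W)
  parts <- part_indices(W, N_p)
  cost <- matrix(0, N_p, N_p)
  for (i in seq_len(N_p)) {
    seg <- features[pmin(parts[[i]], W), , drop = FALSE]
    for (j in seq_len(N_p)) {
      jj <- parts[[j]]
      cost[i, j] <- segment_distance(seg, list(
        mean = traj$mean[jj, , drop = FALSE],
        inv = traj$inv[, , jj, drop = FALSE]))
    }
  }
  if (N_p == 1) {
    best <- matrix(1L, 1, 1)[1, ]
  } else if (N_p <= 8) {
    pm <- pracma::perms(seq_len(N_p))
    pm <- rbind(seq_len(N_p), pm)  # identity first so ties keep identity
    tot <- apply(pm, 1, function(p) sum(cost[cbind(seq_len(N_p), p)]))
    best <- pm[which.min(tot), ]
  } else {
    stop("N_p > 8 not supported by exhaustive matching")
  }
  structure(list(mapping = as.integer(best), distances = cost,
                 total_cost = sum(cost[cbind(seq_len(N_p), best)])),
            class = "channel_assignment")
}

#' Reorder a window so each channel receives its assigned segment
#'
#' @param values W x 3 matrix.
#' @param mapping integer vector from [dynamic_assign()] (`mapping[i]` =
#'   channel of segment i).
#' @return W' x 3 matrix (W' = padded length divisible by `N_p`) with
#'   segments placed in channel order.
#' @export
apply_assignment <- function(values, mapping) {
  N_p <- length(mapping)
  W <- nrow(values)
  parts <- part_indices(W, N_p)
  out <- vector("list", N_p)
  for (ch in seq_len(N_p)) {
    seg_i <- which(mapping == ch)
    out[[ch]] <- values[pmin(parts[[seg_i]], W), , drop = FALSE]
  }
  do.call(rbind, out)
}

#' Fit per-class gravity/body GMM-GMR models
#'
#' @param pairs list of `gravity_body_pair` windows (training set).
#' @param n_classes number of action classes.
#' @param K_g mixture components per model (default 5).
#' @param seed integer seed.
#' @return nested list: `models[[class + 1]]$gravity` / `$body` `gmm_gmr`
#'   models fitted on pooled `(t, x, y, z)` points of that class.
#' @export
fit_class_models <- function(pairs, n_classes, K_g = 5L, seed = 1L) {
  lapply(seq_len(n_classes) - 1L, function(cl) {
    sel <- Filter(function(p) p$action == cl, pairs)
    if (!length(sel)) stop("no windows for class ", cl)
    mk_points <- function(field) {
      do.call(rbind, lapply(sel, function(p) {
        W <- nrow(p[[field]])
        cbind(if (W > 1) (seq_len(W) - 1) / (W - 1) else 0, p[[field]])
      }))
    }
    list(gravity = fit_gmm_gmr(mk_points("gravity"), K_g, seed = seed),
         body = fit_gmm_gmr(mk_points("body"), K_g, seed = seed + 1L))
  })
}

#' Assign a window against every class model and keep the cheapest
#'
#' Test-time rule when the class is unknown: the assignment from the class
#' model with the lowest total cost is used.
#'
#' @param pair a `gravity_body_pair`.
#' @param models output of [fit_class_models()].
#' @param N_p number of parts (default 4).
#' @param trajs optional precomputed trajectories (same nesting as `models`).
#' @return list: `gravity`, `body` (reordered matrices), `class` (0-based
#'   best class), `assignments` (per-feature `channel_assignment`).
#' @export
assign_window <- function(pair, models, N_p = 4L, trajs = NULL) {
  W <- nrow(pair$gravity)
  best <- NULL
  for (cl in seq_along(models)) {
    tg <- if (is.null(trajs)) NULL else trajs[[cl]]$gravity
    tb <- if (is.null(trajs)) NULL else trajs[[cl]]$body
    ag <- dynamic_assign(pair$gravity, models[[cl]]$gravity, N_p, traj = tg)
    ab <- dynamic_assign(pair$body, models[[cl]]$body, N_p, traj = tb)
    tot <- ag$total_cost + ab$total_cost
    if (is.null(best) || tot < best$total) {
      best <- list(total = tot, cl = cl - 1L, ag = ag, ab = ab)
    }
  }
  list(gravity = apply_assignment(pair$gravity, best$ag$mapping),
       body = apply_assignment(pair$body, best$ab$mapping),
       class = best$cl,
       assignments = list(gravity = best$ag, body = best$ab))
}

#' Serialize GMM-GMR class models to JSON
#'
#' @param models output of [fit_class_models()].
#' @param path JSON file path.
#' @return invisibly, the path.
#' @export
gmr_to_json <- function(models, path) {
  obj <- lapply(models, function(m) lapply(m, function(g)
    list(K = g$K, weights = g$weights, means = g$means, covs = g$covs)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gmr_to_json
#' @export
gmr_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(obj, function(m) lapply(m, function(g) {
    covs <- g$covs
    if (is.array(covs) && length(dim(covs)) == 3)
      covs <- lapply(seq_len(dim(covs)[1]), function(k) covs[k, , ])
    covs <- lapply(covs, function(s) matrix(as.numeric(as.matrix(s)), 4, 4))
    structure(list(K = as.integer(g$K), weights = as.numeric(g$weights),
                   means = as.matrix(g$means),
                   covs = covs), class = "gmm_gmr")
  }))
}
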