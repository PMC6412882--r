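test_that("fit_gmm_gmr recovers the parameters of a known mixture", {
  g <- generate_known_gmm(dim = 4L, K_g = 2L, seed = 21L, n = 1500L,
                          separation = 10)
  fit <- fit_gmm_gmr(g$x, K_g = 2L, seed = 21L)
  # [DERIVED] match fitted components to truth by nearest mean
  true_means <- do.call(rbind, g$params$means)
  ord <- apply(fit$means, 1, function(m)
    which.min(colSums((t(true_means) - m)^2)))
  expect_identical(sort(ord), 1:2)
  for (k in 1:2) {
    expect_lt(sqrt(sum((fit$means[k, ] - true_means[ord[k], ])^2)), 0.5)
    expect_lt(abs(fit$weights[k] - g$params$weights[ord[k]]), 0.1)
    expect_lt(max(abs(fit$covs[[k]] - g$params$covs[[ord[k]]])), 0.5)
  }
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  # [TRIVIAL] argument validation
  expect_error(fit_gmm_gmr(matrix(rnorm(20), 5, 4), K_g = 2L), "at least")
  expect_error(fit_gmm_gmr(matrix(rnorm(400), 100, 4), K_g = 0L))
})

test_that("condition_on_time matches the single-Gaussian closed form", {
  # [DERIVED] for one joint Gaussian the conditional is the standard
  # formula mu_a + S_at (x - mu_t)/S_tt, S_aa - S_at S_ta / S_tt
  set.seed(22)
  S <- random_spd(4)
  mu <- rnorm(4)
  model <- structure(list(K = 1L, weights = 1, means = matrix(mu, 1),
                          covs = list(S)), class = "gmm_gmr")
  tq <- runif(25)
  out <- condition_on_time(model, tq)
  sat <- S[2:4, 1]; stt <- S[1, 1]; saa <- S[2:4, 2:4]
  want_mean <- t(vapply(tq, function(t0)
    mu[2:4] + sat * (t0 - mu[1]) / stt, numeric(3)))
  want_cov <- saa - tcrossprod(sat) / stt
  expect_equal(out$mean, want_mean, tolerance = 1e-10)
  for (i in seq_along(tq))
    expect_equal(out$cov[, , i], want_cov, tolerance = 1e-10)
  # [TRIVIAL] responsibilities of a 1-component mixture are identically 1
  expect_equal(as.numeric(out$beta), rep(1, 25))
})

test_that("responsibilities sum to one for a multi-component mixture", {
  g <- generate_known_gmm(dim = 4L, K_g = 3L, seed = 23L, n = 600L)
  fit <- fit_gmm_gmr(g$x, K_g = 3L, seed = 23L)
  tq <- runif(100, min(g$x[, 1]), max(g$x[, 1]))
  out <- condition_on_time(fit, tq)
  # [DERIVED] beta rows are normalized posteriors: sum exactly 1
  expect_equal(rowSums(out$beta), rep(1, 100), tolerance = 1e-12)
  expect_true(all(out$beta >= 0))
})

test_that("mahalanobis_distance matches the brute-force quadratic form", {
  set.seed(24)
  for (rep in 1:50) {
    d <- sample(2:6, 1)
    S <- random_spd(d)
    x <- rnorm(d); mu <- rnorm(d)
    expect_equal(mahalanobis_distance(x, mu, S),
                 oracle_mahalanobis(x, mu, S), tolerance = 1e-9)
  }
  # [TRIVIAL] zero at the mean
  expect_equal(mahalanobis_distance(1:3, 1:3, diag(3)), 0)
})

test_that("segment_distance averages per-sample quadratic forms", {
  set.seed(25)
  n <- 12
  seg <- matrix(rnorm(n * 3), n, 3)
  mean_t <- matrix(rnorm(n * 3), n, 3)
  covs <- array(0, c(3, 3, n)); invs <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    covs[, , i] <- random_spd(3)
    invs[, , i] <- solve(covs[, , i])
  }
  want <- mean(vapply(seq_len(n), function(i)
    oracle_mahalanobis(seg[i, ], mean_t[i, ], covs[, , i]), numeric(1)))
  # [DERIVED] both the loop path (cov) and vectorized path (inv) match
  expect_equal(segment_distance(seg, list(mean = mean_t, cov = covs)),
               want, tolerance = 1e-9)
  expect_equal(segment_distance(seg, list(mean = mean_t, inv = invs)),
               want, tolerance = 1e-9)
})

test_that("part_indices pads by edge replication to equal parts", {
  p <- rehabrec:::part_indices(10L, 4L)
  # [DERIVED] 10 = 4*2 + 2 -> pad to 12, parts of 3
  expect_length(p, 4L)
  expect_true(all(lengths(p) == 3L))
  expect_identical(unname(p[[4]]), c(10L, 10L, 10L))
  expect_identical(unname(unlist(p))[1:10], 1:10)
  q <- rehabrec:::part_indices(8L, 4L)
  expect_identical(unname(unlist(q)), 1:8)
})

test_that("dynamic_assign is identity on matching data and undoes a swap", {
  set.seed(26)
  W <- 40L; N_p <- 4L
  base <- cbind(sin(seq(0, 3, length.out = W)),
                cos(seq(0, 5, length.out = W)),
                seq(-1, 1, length.out = W))
  traj <- list(mean = base,
               inv = array(rep(diag(3), W), c(3, 3, W)))
  feats <- base + matrix(rnorm(W * 3, 0, 1e-3), W, 3)
  a <- dynamic_assign(feats, model = NULL, N_p = N_p, traj = traj)
  # [DERIVED] near-identical features: identity mapping, near-zero cost
  expect_identical(a$mapping, 1:4)
  expect_lt(a$total_cost, 1e-4)
  # [DERIVED] swapping segments 2 and 3 of the signal must be detected:
  # segment 2 now holds part-3 content, so it maps to channel 3
  sw <- feats
  sw[11:20, ] <- feats[21:30, ]
  sw[21:30, ] <- feats[11:20, ]
  a2 <- dynamic_assign(sw, model = NULL, N_p = N_p, traj = traj)
  expect_identical(a2$mapping, c(1L, 3L, 2L, 4L))
  # [DERIVED] applying the assignment restores channel order
  expect_equal(apply_assignment(sw, a2$mapping), feats, tolerance = 1e-12)
})

test_that("gmr models survive a JSON round trip", {
  g <- generate_known_gmm(dim = 4L, K_g = 2L, seed = 27L, n = 400L)
  m <- fit_gmm_gmr(g$x, K_g = 2L, seed = 27L)
  models <- list(list(gravity = m, body = m))
  path <- tempfile(fileext = ".json")
  gmr_to_json(models, path)
  back <- gmr_from_json(path)
  expect_equal(back[[1]]$gravity$means, m$means, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back[[1]]$body$covs[[2]], m$covs[[2]], tolerance = 1e-8)
  expect_equal(back[[1]]$gravity$weights, m$weights, tolerance = 1e-12)
  # [DERIVED] conditional trajectories agree after the round trip
  t0 <- c(0.2, 0.7)
  expect_equal(condition_on_time(back[[1]]$gravity, t0)$mean,
               condition_on_time(m, t0)$mean, tolerance = 1e-8)
  unlink(path)
})
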