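#' Cross-entropy prediction loss
#'
#' @param posterior probability vector (or matrix, one row per sample) over
#'   the P joint action-by-level classes.
#' @param y 0-based true class (vector for matrix input).
#' @return mean cross-entropy; probabilities are clamped at 1e-12 so the
#'   loss is always finite.
#' @export
prediction_loss <- function(posterior, y) {
  if (is.matrix(posterior)) {
    p <- posterior[cbind(seq_len(nrow(posterior)), as.integer(y) + 1L)]
  } else {
    p <- posterior[as.integer(y) + 1L]
  }
  mean(-log(pmax(p, 1e-12)))
}

#' Build the evaluation score matrix S
#'
#' A P x P matrix (P = M * L) with a single 1 on the diagonal entry of each
#' joint class t = m * L + l: the training signal of action m at level l
#' should score highest in its own entry.
#'
#' @param M number of actions.
#' @param L number of levels.
#' @return P x P matrix (the identity).
#' @export
build_score_matrix <- function(M, L) {
  stopifnot(M >= 1, L >= 1)
  P <- M * L
  S <- matrix(0, P, P)
  for (m in 0:(M - 1)) for (l in 0:(L - 1)) {
    t <- m * L + l
    S[t + 1L, t + 1L] <- 1
  }
  S
}

#' Condition loss
#'
#' Squared Frobenius norm of `G %*% C - S`: the objective whose minimizer
#' over G defines the general (best) features.
#'
#' @param G P x N_f general-feature matrix (one feature per row).
#' @param C N_f x P classifier matrix.
#' @param S P x P score matrix.
#' @return scalar loss.
#' @export
condition_loss <- function(G, C, S) {
  if (ncol(G) != nrow(C) || nrow(G) != nrow(S) || ncol(C) != ncol(S))
    stop("incompatible shapes: G is PxN_f, C is N_fxP, S is PxP")
  sum((G %*% C - S)^2)
}

#' Learn the general features G given a fixed classifier
#'
#' Solves `min_G ||G C - S||^2` in closed form via the Moore-Penrose
#' pseudo-inverse, `G = S C^+`; with C square orthonormal this is `C^T`.
#' Each row of G is the feature the classifier scores maximally for one
#' action-level class.
#'
#' @param C N_f x P classifier matrix.
#' @param S P x P score matrix.
#' @return P x N_f matrix G.
#' @export
learn_general_features <- function(C, S) {
  S %*% MASS::ginv(C)
}

#' Bounded cosine similarity score
#'
#' `score = -arccos(cos(feat, gen)) / pi + 1`: 1 for identical directions,
#' 0.5 for orthogonal, 0 for antipodal; scale-invariant in both arguments.
#'
#' @param feat,gen non-zero numeric vectors of equal length.
#' @return score in `[0, 1]`.
#' @export
cosine_score <- function(feat, gen) {
  nf <- sqrt(sum(feat^2)); ng <- sqrt(sum(gen^2))
  if (nf == 0 || ng == 0) stop("cosine score undefined for a zero vector")
  rho <- max(-1, min(1, sum(feat * gen) / (nf * ng)))
  -acos(rho) / pi + 1
}

#' Map an evaluation score to a quality level label
#'
#' Piecewise-constant ranges on the 0-100 scale: `[0, 33)` is bad (0),
#' `[33, 66)` average (1), `[66, 100]` good (2).
#'
#' @param evaluation score in `[0, 100]`.
#' @return integer label 0, 1 or 2.
#' @export
score_to_label <- function(evaluation) {
  if (evaluation < 0 || evaluation > 100)
    stop("evaluation must lie in [0, 100]")
  if (evaluation < 33) 0L else if (evaluation < 66) 1L else 2L
}

#' Score one extracted feature against its class's general features
#'
#' The feature is compared with the `L` general features of the predicted
#' action; the maximum cosine score times `interval` is the evaluation, and
#' the level label follows the 0-100 ranges.
#'
#' @param feat N_f feature vector.
#' @param heads list with `G` (P x N_f), `n_levels`.
#' @param m predicted action (0-based).
#' @param interval scaling of the top score (default 100).
#' @return list of class `quality_score`: `cosine_score` (winning score in
#'   `[0,1]`), `per_level` scores, `evaluation` in `[0, interval]`,
#'   `level_label`.
#' @export
evaluate_sample <- function(feat, heads, m, interval = 100) {
  L <- heads$n_levels
  scores <- vapply(0:(L - 1), function(l)
    cosine_score(feat, heads$G[m * L + l + 1L, ]), numeric(1))
  ev <- max(scores) * interval
  structure(list(cosine_score = max(scores), per_level = scores,
                 evaluation = ev,
                 level_label = score_to_label(ev / interval * 100)),
            class = "quality_score")
}

# soft relaxation of the Eq-15 level ranges: a squared-exponential kernel
# around each range center makes the range membership differentiable in the
# evaluation score
soft_level_probs <- function(evaluation, sigma = 8) {
  centers <- c(16.5, 49.5, 83)
  u <- -(evaluation - centers)^2 / (2 * sigma^2)
  u <- u - max(u)
  e <- exp(u)
  e / sum(e)
}

#' Evaluation loss (soft-label relaxation)
#'
#' Cross-entropy between the true level and a differentiable soft
#' distribution over the three score ranges (a squared-exponential kernel
#' around each range center); hard labels for reporting always use
#' [score_to_label()]. Returns the gradient with respect to the evaluation
#' score so the loss can train the feature extractor.
#'
#' @param evaluation numeric vector of evaluation scores on the 0-100 scale.
#' @param y_true 0-based true score-range labels (2 = highest range; note
#'   that dataset level 0, the best performance, targets range label 2).
#' @param sigma kernel width in score points (default 8; smaller is a more
#'   confident relaxation).
#' @return list: `loss` (mean cross-entropy), `deval` (gradient per sample).
#' @export
evaluation_loss <- function(evaluation, y_true, sigma = 8) {
  n <- length(evaluation)
  loss <- 0
  deval <- numeric(n)
  centers <- c(16.5, 49.5, 83)
  for (i in seq_len(n)) {
    p <- soft_level_probs(evaluation[i], sigma)
    yi <- as.integer(y_true[i]) + 1L
    loss <- loss - log(max(p[yi], 1e-12))
    du <- -(evaluation[i] - centers) / sigma^2
    ind <- numeric(3); ind[yi] <- 1
    deval[i] <- sum((p - ind) * du)
  }
  list(loss = loss / n, deval = deval / n)
}

#' Weighted total loss
#'
#' @param L_p,L_c,L_e the three loss terms.
#' @param weights list or vector `(alpha, beta, gamma)`, non-negative with
#'   at least one positive.
#' @return `alpha * L_p + beta * L_c + gamma * L_e`.
#' @export
total_loss <- function(L_p, L_c, L_e, weights = c(1, 1, 1)) {
  w <- as.numeric(unlist(weights))
  if (any(w < 0) || !any(w > 0))
    stop("weights must be non-negative with at least one positive")
  w[1] * L_p + w[2] * L_c + w[3] * L_e
}

# per-batch evaluation-loss forward/backward through the cosine scores
eval_loss_batch <- function(feats, logits, G, level_true, L, interval = 100,
                            sigma = 8) {
  B <- nrow(feats)
  m_pred <- (max.col(logits, ties.method = "first") - 1L) %/% L
  nf <- sqrt(rowSums(feats^2))
  score <- matrix(0, B, L)
  rho_all <- matrix(0, B, L)
  gnorm <- matrix(0, B, L)
  for (l in 0:(L - 1)) {
    Gm <- G[m_pred * L + l + 1L, , drop = FALSE]
    ng <- sqrt(rowSums(Gm^2))
    rho <- rowSums(feats * Gm) / pmax(nf * ng, 1e-12)
    rho <- pmax(-1, pmin(1, rho))
    rho_all[, l + 1L] <- rho
    gnorm[, l + 1L] <- ng
    score[, l + 1L] <- -acos(rho) / pi + 1
  }
  win <- max.col(score, ties.method = "first")
  s_max <- score[cbind(seq_len(B), win)]
  evaluation <- s_max * interval
  # dataset level 0 is the best performance, so it targets the highest
  # score range (range label L-1), and the worst level targets the lowest
  el <- evaluation_loss(evaluation, L - 1L - as.integer(level_true), sigma)
  dfeat <- matrix(0, B, ncol(feats))
  ok <- nf > 1e-8
  for (i in which(ok)) {
    l <- win[i]
    rho <- max(-0.999, min(0.999, rho_all[i, l]))
    Grow <- G[m_pred[i] * L + l, ]  # win is 1-based: row index m*L + (l-1) + 1
    ng <- gnorm[i, l]
    if (ng < 1e-12) next
    ds_drho <- 1 / (pi * sqrt(1 - rho^2))
    drho_df <- Grow / (nf[i] * ng) - rho * feats[i, ] / nf[i]^2
    dfeat[i, ] <- el$deval[i] * interval * ds_drho * drho_df
  }
  list(loss = el$loss, dfeat = dfeat, evaluation = evaluation,
       m_pred = m_pred, hard_label = vapply(
         pmin(pmax(evaluation / interval * 100, 0), 100), score_to_label,
         integer(1)))
}

#' Train the evaluation model (LSTM classifier + heads)
#'
#' Alternating scheme: within each epoch the LSTM and its heads are updated
#' by SGD on the weighted total of prediction loss (cross-entropy over the
#' P joint classes), condition loss (through the classifier matrix C, the
#' final layer's weights) and evaluation loss (through the extracted
#' features via the cosine scores); at the end of each epoch the general
#' features G are re-solved in closed form with C and S fixed.
#'
#' @param x array (N, T, 3) of resized signals (see [resize_signal()]).
#' @param action,level 0-based labels.
#' @param cfg a [train_config()].
#' @param net optional prebuilt [build_lstm_classifier()] (built from data
#'   dimensions otherwise).
#' @param weights loss weights `(alpha, beta, gamma)`, default `c(1, 1, 1)`.
#' @param interval evaluation scale (default 100).
#' @param sigma evaluation-loss relaxation width (default 8).
#' @param dims,fc architecture sizes forwarded to
#'   [build_lstm_classifier()] when `net` is NULL.
#' @param restarts number of independent training runs (seeds derived from
#'   `cfg$seed`); the run with the lowest final training loss is kept.
#'   Recurrent training is sensitive to initialization, and the selection
#'   uses training data only.
#' @return list of class `eval_model`: `net`, `heads` (C, G, S, n_actions,
#'   n_levels, interval), `history`.
#' @export
train_evaluation_model <- function(x, action, level, cfg = train_config(),
                                   net = NULL, weights = c(1, 1, 1),
                                   interval = 100, sigma = 8,
                                   dims = c(224L, 224L, 196L),
                                   fc = c(128L, 64L), restarts = 1L) {
  restarts <- max(1L, as.integer(restarts))
  best <- NULL
  errs <- character(0)
  for (r in seq_len(restarts)) {
    cfg_r <- cfg
    cfg_r$seed <- (cfg$seed + 10007L * (r - 1L)) %% 2147483647L
    m <- tryCatch(
      train_evaluation_once(x, action, level, cfg_r, net, weights, interval,
                            sigma, dims, fc),
      error = function(e) e)
    if (inherits(m, "error")) { errs <- c(errs, conditionMessage(m)); next }
    loss_r <- m$history$loss[nrow(m$history)]
    if (is.null(best) || loss_r < best$loss) best <- list(model = m,
                                                          loss = loss_r)
  }
  if (is.null(best))
    stop("all evaluation training restarts failed: ",
         paste(unique(errs), collapse = "; "))
  best$model
}

train_evaluation_once <- function(x, action, level, cfg, net, weights,
                                  interval, sigma, dims, fc) {
  M <- max(action) + 1L
  L <- max(level) + 1L
  N <- dim(x)[1]
  y <- as.integer(action) * L + as.integer(level)
  if (is.null(net))
    net <- build_lstm_classifier(dim(x)[2], dim(x)[3], dims = dims, fc = fc,
                                 n_actions = M, n_levels = L, seed = cfg$seed)
  S <- build_score_matrix(M, L)
  G <- learn_general_features(net$params$C$W, S)
  w <- as.numeric(unlist(weights))
  vel <- sgd_state(net$params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0), lp = numeric(0),
                     lc = numeric(0), le = numeric(0), accuracy = numeric(0))
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(N)
      tots <- c(lp = 0, lc = 0, le = 0); correct <- 0
      for (b0 in seq(1L, N, by = cfg$batch_size)) {
        bi <- idx[b0:min(b0 + cfg$batch_size - 1L, N)]
        xb <- x[bi, , , drop = FALSE]
        fwd <- lstm_eval_fwd(net$params, xb)
        ce <- softmax_ce(fwd$logits, y[bi] + 1L)
        correct <- correct + sum(max.col(fwd$logits, ties.method = "first") ==
                                   y[bi] + 1L)
        C <- net$params$C$W
        lc <- condition_loss(G, C, S)
        dC_extra <- w[2] * 2 * crossprod(G, G %*% C - S)
        eb <- eval_loss_batch(fwd$feature, fwd$logits, G, level[bi], L,
                              interval, sigma)
        lt <- w[1] * ce$loss + w[2] * lc + w[3] * eb$loss
        if (!is.finite(lt)) stop("evaluation training diverged at epoch ", ep)
        grads <- lstm_eval_bwd(net$params, fwd$cache,
                               dlogits = w[1] * ce$dlogits,
                               dfeat = w[3] * eb$dfeat,
                               dC_extra = dC_extra)
        if (!is.null(cfg$clip) && is.finite(cfg$clip))
          grads <- grad_clip(grads, cfg$clip)
        st <- sgd_step(net$params, grads, vel, cfg$lr, cfg$momentum,
                       cfg$weight_decay)
        net$params <- st$p
        vel <- st$v
        tots <- tots + c(ce$loss, lc, eb$loss) * length(bi)
      }
      G <- learn_general_features(net$params$C$W, S)
      hist <- rbind(hist, data.frame(
        epoch = ep, loss = sum(w * tots / N), lp = tots[1] / N,
        lc = tots[2] / N, le = tots[3] / N, accuracy = correct / N))
      if (cfg$verbose)
        message(sprintf("epoch %d: Lp %.4f Lc %.4f Le %.4f acc %.3f", ep,
                        tots[1] / N, tots[2] / N, tots[3] / N, correct / N))
    }
  })
  heads <- list(C = net$params$C$W, G = G, S = S, n_actions = M,
                n_levels = L, n_feat = ncol(G), interval = interval)
  structure(list(net = net, heads = heads, history = hist),
            class = "eval_model")
}

#' Predict and score a batch with a trained evaluation model
#'
#' @param model an `eval_model` from [train_evaluation_model()].
#' @param x array (N, T, 3) of resized signals.
#' @return data frame: `class_pred` (0-based joint class), `action_pred`,
#'   `level_pred` (classifier's level), `evaluation` (0-interval score),
#'   `level_label` (score-derived level from the 0-100 ranges).
#' @export
evaluate_batch <- function(model, x) {
  fwd <- lstm_eval_fwd(model$net$params, x)
  L <- model$heads$n_levels
  cls <- max.col(fwd$logits, ties.method = "first") - 1L
  m <- cls %/% L
  n <- dim(x)[1]
  ev <- numeric(n); lab <- integer(n)
  for (i in seq_len(n)) {
    f <- fwd$feature[i, ]
    if (sqrt(sum(f^2)) < 1e-12) { ev[i] <- 0; lab[i] <- 0L; next }
    qs <- evaluate_sample(f, model$heads, m[i], model$heads$interval)
    ev[i] <- qs$evaluation; lab[i] <- qs$level_label
  }
  data.frame(class_pred = cls, action_pred = m, level_pred = cls %% L,
             evaluation = ev, level_label = lab)
}
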