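#' Pipeline configuration
#'
#' Bundles every stage's settings with their standard defaults: sliding
#' window 80 samples at 50% overlap, size-3 median filter, 0.3 Hz
#' gravity/body cutoff, 10 quantization levels, 6 dictionary states per
#' class, 5 GMR mixture components, 4 D-CNN parts, and the common SGD recipe
#' (lr 0.01, momentum 0.9, weight decay 0.0005).
#'
#' @param synth a [synth_config()] for generated data.
#' @param window_size,window_overlap sliding-window settings.
#' @param median_size median filter length.
#' @param lowpass_cutoff,lowpass_order gravity low-pass settings (Hz).
#' @param K_q quantization levels per axis.
#' @param C_states dictionary states per class.
#' @param K_g GMR mixture components.
#' @param N_p D-CNN parts per feature.
#' @param fusion_depth MP-CNN middle-path depth.
#' @param top_type MP-CNN top sub-network ("gb" = MP-CNN-1, "d" = MP-CNN-2).
#' @param maps,hidden CNN feature maps and hidden widths.
#' @param epochs,batch_size,lr,momentum,weight_decay SGD settings.
#' @param train_frac fraction of subjects used for training.
#' @param eval_len resized signal length for the evaluation model.
#' @param eval_dims,eval_fc LSTM and dense widths of the evaluation model.
#' @param eval_epochs evaluation-model epochs.
#' @param eval_lr,eval_clip evaluation-model learning rate and gradient-norm
#'   ceiling (recurrent training needs a lower rate plus clipping).
#' @param eval_restarts evaluation-model training restarts; the run with the
#'   lowest final training loss is kept (recurrent training is sensitive to
#'   initialization).
#' @param seed master seed.
#' @return list of class `rr_config`.
#' @export
rr_config <- function(synth = synth_config(),
                      window_size = 80L, window_overlap = 0.5,
                      median_size = 3L, lowpass_cutoff = 0.3,
                      lowpass_order = 3L, K_q = 10L, C_states = 6L,
                      K_g = 5L, N_p = 4L, fusion_depth = 1L,
                      top_type = "d", maps = c(16L, 32L),
                      hidden = c(1024L, 512L), epochs = 30L,
                      batch_size = 32L, lr = 0.01, momentum = 0.9,
                      weight_decay = 5e-4, train_frac = 0.7,
                      eval_len = 128L, eval_dims = c(224L, 224L, 196L),
                      eval_fc = c(128L, 64L), eval_epochs = 30L,
                      eval_lr = 0.02, eval_clip = 1, eval_restarts = 3L,
                      seed = 1L) {
  structure(as.list(environment()), class = "rr_config")
}

#' Prepare model-ready data from a dataset
#'
#' Runs the preprocessing and symbolic stages once: sliding windows,
#' median-filter + normalization, gravity/body separation, PFSA transition
#' targets (quantizers and state dictionary fitted on training subjects
#' only), per-class GMM-GMR models, and dynamic channel assignment for every
#' window. The subject-wise train/test split is seeded and recorded.
#'
#' @param ds a `rehab_dataset`.
#' @param config an [rr_config()].
#' @return list of class `rr_bundle` with input arrays (`x`, `gravity`,
#'   `body`, `d_gravity`, `d_body`), labels (`action`, `level`, `subject`),
#'   `train_idx`/`test_idx`, `pfsa` (targets, dictionary, quantizers),
#'   `gmr_models`, and the config.
#' @export
prepare_experiment <- function(ds, config = rr_config()) {
  recs <- ds$recordings
  fs <- if (!is.null(ds$config)) ds$config$fs else 1 / median(diff(recs[[1]]$t))
  wins <- list(); pairs <- list()
  for (r in recs) {
    for (w in sliding_windows(r, config$window_size, config$window_overlap)) {
      wn <- denoise_normalize(w, config$median_size)
      wins[[length(wins) + 1L]] <- wn
      pairs[[length(pairs) + 1L]] <-
        gravity_body_split(wn, config$lowpass_cutoff, config$lowpass_order, fs)
    }
  }
  N <- length(wins)
  W <- config$window_size
  action <- vapply(wins, `[[`, integer(1), "action")
  level <- vapply(wins, `[[`, integer(1), "level")
  subject <- vapply(wins, `[[`, integer(1), "subject")
  subs <- sort(unique(subject))
  tr_subs <- with_seed(config$seed,
                       sort(sample(subs, ceiling(config$train_frac * length(subs)))))
  train_idx <- which(subject %in% tr_subs)
  test_idx <- which(!subject %in% tr_subs)
  if (!length(test_idx))
    stop("train_frac = ", config$train_frac, " leaves no held-out subjects ",
         "(", length(subs), " subjects total)")
  to_arr <- function(get) {
    a <- array(0, c(N, W, 3))
    for (i in seq_len(N)) a[i, , ] <- get(i)
    a
  }
  x <- to_arr(function(i) wins[[i]]$values)
  g <- to_arr(function(i) pairs[[i]]$gravity)
  b <- to_arr(function(i) pairs[[i]]$body)
  pf <- scnn_targets(lapply(wins, `[[`, "values"), action, train_idx,
                     config$K_q, config$C_states)
  models <- fit_class_models(pairs[train_idx], max(action) + 1L,
                             config$K_g, seed = config$seed)
  trajs <- lapply(models, function(m)
    list(gravity = gmr_trajectory(m$gravity, W),
         body = gmr_trajectory(m$body, W)))
  Wp <- ceiling(W / config$N_p) * config$N_p
  dg <- array(0, c(N, Wp, 3)); db <- array(0, c(N, Wp, 3))
  for (i in seq_len(N)) {
    aw <- assign_window(pairs[[i]], models, config$N_p, trajs)
    dg[i, , ] <- aw$gravity
    db[i, , ] <- aw$body
  }
  structure(list(x = x, gravity = g, body = b, d_gravity = dg, d_body = db,
                 action = action, level = level, subject = subject,
                 train_idx = train_idx, test_idx = test_idx,
                 train_subjects = tr_subs, pfsa = pf, gmr_models = models,
                 n_classes = max(action) + 1L, config = config),
            class = "rr_bundle")
}

#' Train the recognition model family on a prepared bundle
#'
#' Trains the S-CNN (transition-probability regression plus a softmax head
#' over its predicted features), the GB-CNN, the D-CNN, and the MP-CNN
#' initialized from the pre-trained sub-networks, and reports subject-held-out
#' test accuracy for each.
#'
#' @param bundle an `rr_bundle` from [prepare_experiment()].
#' @param seed training seed (weight init and shuffling).
#' @param epochs SGD epochs (defaults to the bundle config).
#' @return list: `accuracy` (named vector: gbcnn, scnn, dcnn, mpcnn),
#'   `nets`, `history` per net.
#' @export
train_recognition_models <- function(bundle, seed = NULL, epochs = NULL) {
  cfgc <- bundle$config
  if (is.null(seed)) seed <- cfgc$seed
  if (is.null(epochs)) epochs <- cfgc$epochs
  tr <- bundle$train_idx; te <- bundle$test_idx
  cfg <- train_config(lr = cfgc$lr, momentum = cfgc$momentum,
                      weight_decay = cfgc$weight_decay, epochs = epochs,
                      batch_size = cfgc$batch_size, seed = seed)
  spec <- network_spec(bundle$n_classes, input_len = cfgc$window_size,
                       maps = cfgc$maps, hidden = cfgc$hidden,
                       n_parts = cfgc$N_p, fusion_depth = cfgc$fusion_depth,
                       state_dim = bundle$pfsa$n_states,
                       top_type = cfgc$top_type)
  sl <- function(a, i) a[i, , , drop = FALSE]
  y_tr <- bundle$action[tr]; y_te <- bundle$action[te]

  # Task 1: S-CNN regression to the PFSA transition probabilities
  scnn <- build_scnn(spec, seed)
  scnn <- train_net(scnn, list(x = sl(bundle$x, tr)),
                    bundle$pfsa$targets[tr, , drop = FALSE], cfg, loss = "mse")
  feats_tr <- predict(scnn, list(x = sl(bundle$x, tr)), type = "raw")
  feats_te <- predict(scnn, list(x = sl(bundle$x, te)), type = "raw")
  shead <- build_mlp(ncol(feats_tr), 32L, bundle$n_classes, seed)
  shead <- train_net(shead, list(x = feats_tr), y_tr, cfg, loss = "ce")
  acc_s <- net_accuracy(shead, list(x = feats_te), y_te)

  # Task 2: D-CNN on channel-fitted features
  dspec <- spec
  dcnn <- build_dcnn(dspec, seed)
  dcnn <- train_net(dcnn, list(gravity = sl(bundle$d_gravity, tr),
                               body = sl(bundle$d_body, tr)), y_tr, cfg)
  acc_d <- net_accuracy(dcnn, list(gravity = sl(bundle$d_gravity, te),
                                   body = sl(bundle$d_body, te)), y_te)

  # GB-CNN
  gb <- build_gbcnn(spec, seed)
  gb <- train_net(gb, list(gravity = sl(bundle$gravity, tr),
                           body = sl(bundle$body, tr)), y_tr, cfg)
  acc_gb <- net_accuracy(gb, list(gravity = sl(bundle$gravity, te),
                                  body = sl(bundle$body, te)), y_te)

  # Task 3: MP-CNN with pre-trained sub-networks
  mp <- build_mpcnn(spec, seed)
  top_net <- if (spec$top_type == "gb") gb else dcnn
  mp_inputs_tr <- list(gravity = sl(bundle$gravity, tr),
                       body = sl(bundle$body, tr),
                       d_gravity = sl(bundle$d_gravity, tr),
                       d_body = sl(bundle$d_body, tr),
                       x = sl(bundle$x, tr))
  mp_inputs_te <- list(gravity = sl(bundle$gravity, te),
                       body = sl(bundle$body, te),
                       d_gravity = sl(bundle$d_gravity, te),
                       d_body = sl(bundle$d_body, te),
                       x = sl(bundle$x, te))
  mp <- train_net(mp, mp_inputs_tr, y_tr, cfg,
                  pretrained = list(top = top_net, bot = scnn))
  acc_mp <- net_accuracy(mp, mp_inputs_te, y_te)

  list(accuracy = c(gbcnn = acc_gb, scnn = acc_s, dcnn = acc_d,
                    mpcnn = acc_mp),
       nets = list(gbcnn = gb, scnn = scnn, scnn_head = shead, dcnn = dcnn,
                   mpcnn = mp))
}

#' Build the evaluation dataset: one resized sample per repetition
#'
#' Segments every recording into its repetitions and resizes each raw
#' segment to a fixed length. Recordings whose segmentation fails are
#' skipped with a warning.
#'
#' @param ds a `rehab_dataset`.
#' @param n_reps repetitions per recording.
#' @param length_out resized length.
#' @return list: `x` (N, length_out, 3), `action`, `level`, `subject`.
#' @export
make_eval_dataset <- function(ds, n_reps = 10L, length_out = 128L) {
  xs <- list(); action <- integer(0); level <- integer(0)
  subject <- integer(0)
  for (r in ds$recordings) {
    seg <- tryCatch(segment_repetitions(r, n_reps), error = function(e) NULL)
    if (is.null(seg)) {
      warning("skipping recording ", r$id, ": segmentation failed")
      next
    }
    for (s in seg$segments) {
      xs[[length(xs) + 1L]] <- resize_signal(s$acc, length_out)
      action <- c(action, r$action); level <- c(level, r$level)
      subject <- c(subject, r$subject)
    }
  }
  x <- array(0, c(length(xs), length_out, 3))
  for (i in seq_along(xs)) x[i, , ] <- xs[[i]]
  list(x = x, action = action, level = level, subject = subject)
}

#' Reduced-size configuration for CPU benchmarking
#'
#' The study conditions of the synthetic benchmark: the default generator
#' (4 actions x 3 levels x 20 subjects), but smaller networks and fewer
#' epochs than the full-size defaults so the whole run fits a single-CPU
#' budget. Only network/optimizer sizes differ from [rr_config()]; the data
#' generator is untouched.
#'
#' @param seed master seed.
#' @return an `rr_config`.
#' @export
benchmark_config <- function(seed = 1L) {
  rr_config(maps = c(8L, 12L), hidden = c(96L, 48L), epochs = 8L,
            eval_len = 64L, eval_dims = c(40L, 32L, 24L),
            eval_fc = c(32L, 24L), eval_epochs = 30L, seed = seed)
}

#' Run the multi-seed synthetic benchmark
#'
#' Prepares the dataset once, trains the recognition family under each
#' training seed, reports per-seed and median test accuracies, then trains
#' the evaluation model once and reports its per-action median scores by
#' quality level on held-out subjects.
#'
#' @param config an [rr_config()] (default [benchmark_config()]).
#' @param train_seeds integer vector of training seeds (weight init and
#'   shuffling); the dataset and split come from `config`.
#' @return list of class `rr_benchmark`: `accuracy` (seeds x models matrix),
#'   `median_accuracy`, `evaluation` (accuracy, `median_scores` data frame),
#'   `config`.
#' @export
run_benchmark <- function(config = benchmark_config(),
                          train_seeds = c(101L, 202L, 303L, 404L, 505L)) {
  ds <- generate_dataset(config$synth)
  bundle <- prepare_experiment(ds, config)
  acc <- t(vapply(train_seeds, function(s)
    train_recognition_models(bundle, seed = s)$accuracy, numeric(4)))
  rownames(acc) <- train_seeds
  med <- apply(acc, 2, median)
  ev <- make_eval_dataset(ds, config$synth$reps_per_recording,
                          config$eval_len)
  tr <- ev$subject %in% bundle$train_subjects
  cfg <- train_config(lr = config$eval_lr, momentum = config$momentum,
                      weight_decay = config$weight_decay,
                      epochs = config$eval_epochs,
                      batch_size = config$batch_size, seed = config$seed,
                      clip = config$eval_clip)
  model <- train_evaluation_model(
    ev$x[tr, , , drop = FALSE], ev$action[tr], ev$level[tr], cfg,
    dims = config$eval_dims, fc = config$eval_fc,
    restarts = config$eval_restarts)
  res <- evaluate_batch(model, ev$x[!tr, , , drop = FALSE])
  y12 <- ev$action[!tr] * model$heads$n_levels + ev$level[!tr]
  scores <- data.frame(action = ev$action[!tr], level = ev$level[!tr],
                       evaluation = res$evaluation)
  med_scores <- stats::aggregate(evaluation ~ action + level, scores, median)
  structure(list(accuracy = acc, median_accuracy = med,
                 evaluation = list(accuracy = mean(res$class_pred == y12),
                                   median_scores = med_scores,
                                   model = model),
                 config = config),
            class = "rr_benchmark")
}

#' Run the full pipeline on synthetic data
#'
#' Executes the three recognition tasks in order (S-CNN targets and
#' training; GMM-GMR fitting, dynamic assignment and D-CNN training; MP-CNN
#' training from pre-trained weights), then optionally the evaluation-model
#' training on segmented repetitions, and returns all metrics plus a run
#' manifest.
#'
#' @param config an [rr_config()].
#' @param ds optional pre-generated `rehab_dataset` (generated from
#'   `config$synth` otherwise).
#' @param run_eval train the evaluation model too (default TRUE).
#' @param out optional directory: writes `manifest.json` and metrics there.
#' @return list of class `rr_run`: `recognition` (accuracies + nets),
#'   `evaluation` (model, test metrics, score table), `manifest`.
#' @export
run_pipeline <- function(config = rr_config(), ds = NULL, run_eval = TRUE,
                         out = NULL) {
  if (is.null(ds)) ds <- generate_dataset(config$synth)
  bundle <- prepare_experiment(ds, config)
  recog <- train_recognition_models(bundle)
  evalr <- NULL
  if (run_eval) {
    ev <- make_eval_dataset(ds, config$synth$reps_per_recording,
                            config$eval_len)
    tr <- ev$subject %in% bundle$train_subjects
    cfg <- train_config(lr = config$eval_lr, momentum = config$momentum,
                        weight_decay = config$weight_decay,
                        epochs = config$eval_epochs,
                        batch_size = config$batch_size, seed = config$seed,
                        clip = config$eval_clip)
    model <- train_evaluation_model(
      ev$x[tr, , , drop = FALSE], ev$action[tr], ev$level[tr], cfg,
      dims = config$eval_dims, fc = config$eval_fc,
      restarts = config$eval_restarts)
    res <- evaluate_batch(model, ev$x[!tr, , , drop = FALSE])
    y12 <- ev$action[!tr] * model$heads$n_levels + ev$level[!tr]
    acc12 <- mean(res$class_pred == y12)
    scores <- data.frame(action = ev$action[!tr], level = ev$level[!tr],
                         evaluation = res$evaluation,
                         level_label = res$level_label)
    med <- stats::aggregate(evaluation ~ action + level, scores, median)
    evalr <- list(model = model, accuracy = acc12, scores = scores,
                  median_scores = med)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("rehabrec")),
    r_version = R.version.string,
    seed = config$seed,
    n_recordings = length(ds$recordings),
    n_windows = dim(bundle$x)[1],
    n_states = bundle$pfsa$n_states,
    config = config[setdiff(names(config), "synth")],
    synth = unclass(config$synth),
    recognition_accuracy = as.list(recog$accuracy),
    evaluation_accuracy = if (is.null(evalr)) NULL else evalr$accuracy)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(list(bundle = bundle, recognition = recog, evaluation = evalr,
                 manifest = manifest), class = "rr_run")
}
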