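#' Configuration for the synthetic rehabilitation-exercise generator
#'
#' Defines the study conditions emulated by [generate_dataset()]: four
#' exercise actions, each performed at three quality levels (good, average,
#' bad), ten repetitions in a row per recording, with per-subject speed and
#' amplitude variation and additive sensor noise.
#'
#' @param n_actions number of distinct exercises (M). Default 4.
#' @param n_levels number of quality levels (L), ordered good > average > bad.
#'   Default 3.
#' @param n_subjects number of simulated subjects. Default 20.
#' @param reps_per_recording repetitions performed in a row per recording.
#'   Default 10.
#' @param fs sampling rate in Hz. Default 32.
#' @param seed integer seed; the dataset is a pure function of the config.
#' @param noise_sd additive white accelerometer noise, in g. Default 0.03.
#' @param level_amp per-level amplitude multipliers, strictly decreasing from
#'   good to bad. Default `c(1.0, 0.7, 0.4)`.
#' @param level_shape per-level shape-completion factors (scales the later
#'   movement components; a sloppy performance truncates the secondary part
#'   of the motion). Default `c(1.0, 0.8, 0.55)`.
#' @param level_tremor per-level tremor amplitude in g (high-frequency wobble
#'   superimposed on degraded performances). Default `c(0, 0.04, 0.08)`.
#' @param rep_jitter per-repetition duration jitter (uniform, relative).
#'   Default 0.05 (+/-5%).
#' @param subject_warp per-subject global time-warp range (uniform,
#'   relative). Default 0.10.
#' @param subject_gain per-subject global gain range (uniform, relative).
#'   Default 0.15.
#'
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_actions = 4L, n_levels = 3L, n_subjects = 20L,
                         reps_per_recording = 10L, fs = 32, seed = 1L,
                         noise_sd = 0.03,
                         level_amp = c(1.0, 0.7, 0.4),
                         level_shape = c(1.0, 0.8, 0.55),
                         level_tremor = c(0, 0.04, 0.08),
                         rep_jitter = 0.05, subject_warp = 0.10,
                         subject_gain = 0.15) {
  stopifnot(n_actions >= 1, n_levels >= 1, n_subjects >= 1,
            reps_per_recording >= 1, fs > 0, noise_sd >= 0)
  if (length(level_amp) != n_levels || any(diff(level_amp) >= 0))
    stop("level_amp must have one strictly decreasing entry per level")
  structure(list(n_actions = as.integer(n_actions),
                 n_levels = as.integer(n_levels),
                 n_subjects = as.integer(n_subjects),
                 reps_per_recording = as.integer(reps_per_recording),
                 fs = fs, seed = as.integer(seed), noise_sd = noise_sd,
                 level_amp = level_amp, level_shape = level_shape,
                 level_tremor = level_tremor, rep_jitter = rep_jitter,
                 subject_warp = subject_warp, subject_gain = subject_gain),
            class = "synth_config")
}

# Fixed per-action movement templates. Parameters are drawn once from an RNG
# keyed only by the action index, so templates are stable across datasets and
# seeds: what varies between recordings is level, subject and noise.
action_template <- function(action) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(7000L + as.integer(action))
  n_bumps <- sample(2:3, 1)
  list(
    duration = c(2.0, 2.25, 1.75, 2.5, 2.1, 1.9)[(action %% 6) + 1],
    bump_center = matrix(runif(3 * n_bumps, 0.15, 0.85), nrow = 3),
    bump_width = matrix(runif(3 * n_bumps, 0.05, 0.12), nrow = 3),
    bump_amp = matrix(runif(3 * n_bumps, -1, 1), nrow = 3),
    sine_freq = sample(2:5, 3, replace = TRUE),
    sine_phase = runif(3, 0, 2 * pi),
    sine_amp = runif(3, 0.15, 0.35)
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

# Body acceleration of one repetition on a normalized time grid tau in [0,1).
# The sin^2 envelope brings the movement to rest at repetition boundaries,
# which is what makes autocorrelation-based repetition segmentation feasible.
rep_body <- function(tau, tmpl, shape_factor) {
  n <- length(tau)
  env <- sin(pi * tau)^2
  out <- matrix(0, n, 3)
  n_bumps <- ncol(tmpl$bump_center)
  for (ax in 1:3) {
    s <- tmpl$sine_amp[ax] * sin(2 * pi * tmpl$sine_freq[ax] * tau +
                                   tmpl$sine_phase[ax])
    b <- 0
    for (j in seq_len(n_bumps)) {
      comp <- tmpl$bump_amp[ax, j] *
        exp(-(tau - tmpl$bump_center[ax, j])^2 /
              (2 * tmpl$bump_width[ax, j]^2))
      # later movement components degrade with quality level
      if (j > 1) comp <- comp * shape_factor
      b <- b + comp
    }
    out[, ax] <- env * (b + shape_factor * s)
  }
  out
}

#' Generate a labelled synthetic rehabilitation dataset
#'
#' Each recording is one subject performing one action at one quality level,
#' ten repetitions in a row. Actions have distinct per-axis templates (sums
#' of Gaussian bumps plus a sinusoid under a rest-to-rest envelope); quality
#' levels scale amplitude (1.0 / 0.7 / 0.4 by default), truncate secondary
#' movement components and add tremor; subjects carry a random global
#' time-warp, gain, and gravity-vector tilt; repetitions jitter in duration;
#' white noise is added. Fully determined by `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return a list of class `rehab_dataset`: element `recordings` is a list of
#'   `signal_recording` objects (fields `t`, `acc` (T x 3 matrix, g-units),
#'   `action`, `level`, `subject`, `id`; actions/levels 0-based), element
#'   `config` the generating config.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(n_subjects = 2, seed = 1))
#' length(ds$recordings)  # 4 actions x 3 levels x 2 subjects
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  tmpls <- lapply(seq_len(cfg$n_actions) - 1L, action_template)
  recs <- list()
  id <- 0L
  for (subj in seq_len(cfg$n_subjects) - 1L) {
    warp <- runif(1, 1 - cfg$subject_warp, 1 + cfg$subject_warp)
    gain <- runif(1, 1 - cfg$subject_gain, 1 + cfg$subject_gain)
    tilt <- rnorm(2, 0, 3 * pi / 180)  # small deviation from vertical
    grav <- c(sin(tilt[1]), sin(tilt[2]) * cos(tilt[1]),
              cos(tilt[2]) * cos(tilt[1]))
    for (action in seq_len(cfg$n_actions) - 1L) {
      for (level in seq_len(cfg$n_levels) - 1L) {
        tmpl <- tmpls[[action + 1L]]
        segs <- vector("list", cfg$reps_per_recording)
        for (r in seq_len(cfg$reps_per_recording)) {
          dj <- runif(1, 1 - cfg$rep_jitter, 1 + cfg$rep_jitter)
          n <- max(8L, round(tmpl$duration * cfg$fs * warp * dj))
          tau <- (seq_len(n) - 1) / n
          body <- rep_body(tau, tmpl, cfg$level_shape[level + 1L])
          aj <- runif(1, 0.95, 1.05)  # per-repetition amplitude jitter
          body <- body * cfg$level_amp[level + 1L] * gain * aj
          if (cfg$level_tremor[level + 1L] > 0) {
            ph <- runif(3, 0, 2 * pi)
            trem <- sapply(1:3, function(ax)
              sin(2 * pi * 8 * tau * tmpl$duration + ph[ax]))
            body <- body + cfg$level_tremor[level + 1L] *
              trem * sin(pi * tau)^2
          }
          segs[[r]] <- body
        }
        acc <- do.call(rbind, segs)
        acc <- acc + matrix(grav, nrow(acc), 3, byrow = TRUE)
        acc <- acc + matrix(rnorm(length(acc), 0, cfg$noise_sd), nrow(acc), 3)
        colnames(acc) <- c("ax", "ay", "az")
        rec <- structure(list(
          t = (seq_len(nrow(acc)) - 1) / cfg$fs,
          acc = acc,
          action = action, level = level, subject = subj, id = id,
          rep_lengths = vapply(segs, nrow, integer(1))
        ), class = "signal_recording")
        recs[[length(recs) + 1L]] <- rec
        id <- id + 1L
      }
    }
  }
  structure(list(recordings = recs, config = cfg), class = "rehab_dataset")
}

#' @export
print.rehab_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "rehab_dataset: %d recordings (%d actions x %d levels x %d subjects), fs = %g Hz\n",
    length(x$recordings), cfg$n_actions, cfg$n_levels, cfg$n_subjects, cfg$fs))
  invisible(x)
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf(
    "signal_recording #%s: %d samples, action %d, level %d, subject %d\n",
    x$id, nrow(x$acc), x$action, x$level, x$subject))
  invisible(x)
}

#' Sample from a known Gaussian mixture (oracle for GMR tests)
#'
#' Draws points from a randomly constructed but fully known mixture of
#' `K_g` Gaussians in `dim` dimensions, returning both the sample and the
#' ground-truth parameters for parameter-recovery tests.
#'
#' @param dim dimensionality (4 for the joint time-acceleration space).
#' @param K_g number of mixture components.
#' @param seed integer seed.
#' @param n number of samples.
#' @param separation distance between consecutive component means.
#' @return list with `x` (n x dim matrix), `z` (component labels) and
#'   `params` (`weights`, `means` list, `covs` list).
#' @export
generate_known_gmm <- function(dim = 4L, K_g = 1L, seed = 1L, n = 500L,
                               separation = 6) {
  stopifnot(K_g >= 1, dim >= 1, n >= K_g)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  w <- runif(K_g, 0.8, 1.2); w <- w / sum(w)
  means <- lapply(seq_len(K_g), function(k)
    rnorm(dim, 0, 1) + (k - 1) * separation)
  covs <- lapply(seq_len(K_g), function(k) {
    A <- matrix(rnorm(dim * dim, 0, 0.4), dim, dim)
    crossprod(A) + diag(dim) * 0.5
  })
  z <- sample.int(K_g, n, replace = TRUE, prob = w)
  x <- t(vapply(z, function(k) {
    L <- chol(covs[[k]])
    means[[k]] + as.vector(t(L) %*% rnorm(dim))
  }, numeric(dim)))
  list(x = x, z = z, params = list(weights = w, means = means, covs = covs))
}
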