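#' Slice a recording into fixed-size sliding windows
#'
#' Windows of `size` samples with fractional `overlap` tile the recording;
#' the stride is `round(size * (1 - overlap))` and a trailing partial window
#' is dropped. Defaults follow the standard accelerometer HAR setting
#' (size 80, 50% overlap).
#'
#' @param rec a `signal_recording` (or any list with a T x 3 `acc` matrix).
#' @param size window length in samples (>= 2).
#' @param overlap fraction in `[0, 1)`.
#' @return list of `sensor_window` objects with fields `values` (size x 3),
#'   `start` (1-based start index), `recording_id`, `action`, `level`,
#'   `subject`.
#' @export
sliding_windows <- function(rec, size = 80L, overlap = 0.5) {
  stopifnot(size >= 2, overlap >= 0, overlap < 1)
  T_len <- nrow(rec$acc)
  if (T_len < size)
    stop("recording too short: ", T_len, " samples < window size ", size)
  stride <- max(1L, round(size * (1 - overlap)))
  starts <- seq.int(1L, T_len - size + 1L, by = stride)
  lapply(starts, function(s) {
    structure(list(values = rec$acc[s:(s + size - 1L), , drop = FALSE],
                   start = s, recording_id = rec$id,
                   action = rec$action, level = rec$level,
                   subject = rec$subject),
              class = "sensor_window")
  })
}

# running median with edge-replicated borders
median_filter <- function(x, k) {
  if (k <= 1) return(x)
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  if (k == 3) {
    a <- xp[1:(length(xp) - 2)]; b <- xp[2:(length(xp) - 1)]
    c2 <- xp[3:length(xp)]
    pmax(pmin(a, b), pmin(pmax(a, b), c2))
  } else {
    as.numeric(stats::runmed(xp, k, endrule = "keep"))[(h + 1):(h + length(x))]
  }
}

#' Median-filter and min-max normalize a window
#'
#' Applies a per-axis running median (edge-replicated borders) to remove
#' spike noise, then maps each axis onto `[0, 1]` by its own min and max.
#' A constant axis maps to 0.5 everywhere.
#'
#' @param win a `sensor_window`.
#' @param median_size odd filter length (default 3).
#' @return the window with filtered, normalized `values`.
#' @export
denoise_normalize <- function(win, median_size = 3L) {
  stopifnot(median_size %% 2 == 1)
  v <- win$values
  for (ax in seq_len(ncol(v))) {
    x <- median_filter(v[, ax], median_size)
    r <- range(x)
    v[, ax] <- if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else
      rep(0.5, length(x))
  }
  win$values <- v
  win
}

# zero-phase Butterworth low-pass; the mean is removed before filtering and
# restored after, so a constant signal passes through exactly and edge
# transients act only on the zero-mean residual. No extra padding: at a
# cutoff far below Nyquist the filter settling length can exceed a window,
# and any pad whose level differs from the signal mean bleeds across the
# whole window, while forward-backward filtering of the zero-mean residual
# starts its transients from zero.
lowpass_zerophase <- function(x, cutoff, fs, order = 3L) {
  if (!(cutoff > 0 && cutoff < fs / 2))
    stop("cutoff must satisfy 0 < cutoff < fs/2 (Nyquist)")
  m <- mean(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x - m)) + m
}

#' Split a window into gravity and body acceleration
#'
#' Gravity is the zero-phase low-pass component of each axis (3rd-order
#' Butterworth, forward-backward); body acceleration is the residual, so
#' `gravity + body` reconstructs the input exactly.
#'
#' @param win a `sensor_window`.
#' @param cutoff low-pass cutoff in Hz (default 0.3, the usual
#'   gravity/body separation cutoff for wearable accelerometry).
#' @param order Butterworth order (default 3).
#' @param fs sampling rate in Hz.
#' @return list of class `gravity_body_pair` with `gravity` and `body`
#'   (both W x 3) plus the window's labels.
#' @export
gravity_body_split <- function(win, cutoff = 0.3, order = 3L, fs = 32) {
  v <- win$values
  g <- v
  for (ax in seq_len(ncol(v))) g[, ax] <- lowpass_zerophase(v[, ax], cutoff, fs, order)
  structure(list(gravity = g, body = v - g,
                 recording_id = win$recording_id, start = win$start,
                 action = win$action, level = win$level,
                 subject = win$subject),
            class = "gravity_body_pair")
}

#' Autocorrelation of a series at a given lag
#'
#' The biased, variance-normalized sample autocorrelation
#' \deqn{r(k) = \frac{\sum_t (X_t-\bar X)(X_{t+k}-\bar X)}{\sum_t (X_t-\bar X)^2},}
#' with the mean taken over the full series; `r(0) = 1` exactly. Computed via
#' [stats::acf()].
#'
#' @param x numeric series (non-constant).
#' @param k lag, `0 <= k < length(x)`.
#' @return autocorrelation value.
#' @export
autocorrelation <- function(x, k) {
  stopifnot(k >= 0, k < length(x))
  if (var(x) == 0) stop("autocorrelation undefined for a zero-variance series")
  as.numeric(stats::acf(x, lag.max = k, plot = FALSE, demean = TRUE)$acf)[k + 1]
}

# prominence-filtered local maxima (indices) of a series
find_prominent_peaks <- function(r, min_prom_frac = 0.05) {
  n <- length(r)
  if (n < 3) return(integer(0))
  idx <- which(r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  rng <- diff(range(r))
  if (rng == 0) return(integer(0))
  prom <- vapply(idx, function(i) {
    # valley floors between this peak and the nearest higher ground each side
    left <- r[1:i]; right <- r[i:n]
    hl <- which(left > r[i]); hr <- which(right > r[i])
    lo_l <- if (length(hl)) min(left[max(hl):i]) else min(left)
    lo_r <- if (length(hr)) min(right[1:min(hr)]) else min(right)
    r[i] - max(lo_l, lo_r)
  }, numeric(1))
  idx[prom >= min_prom_frac * rng]
}

#' Segment a recording into its repetitions
#'
#' Repetition period structure is read off the autocorrelation of the
#' acceleration magnitude: its prominent peaks (plus lag 0) are cut-point
#' candidates. Since the recording holds `n_reps` repetitions, the expected
#' cut positions lie on the grid `i * T / n_reps`; each grid point draws its
#' nearby candidates (within 30% of the period), and the combination
#' minimizing the variance of consecutive gaps (including the final gap to
#' the end of the recording) is selected. A grid point with no nearby
#' candidate peak falls back to the grid position itself, which bridges
#' autocorrelation peaks suppressed by noise. Each selected cut is then
#' snapped to the nearest local minimum of the smoothed activity envelope
#' within 20% of the mean gap, which absorbs the cumulative drift caused by
#' repetition-duration jitter.
#'
#' @param rec a `signal_recording`.
#' @param n_reps expected number of repetitions (default 10).
#' @param min_prom_frac peak prominence threshold as a fraction of the
#'   autocorrelation range (default 0.05).
#' @return list of class `segmentation_result`: `cut_points` (`n_reps`
#'   1-based start indices), `peaks` (candidate lags), `segments` (list of
#'   `signal_recording` pieces).
#' @export
segment_repetitions <- function(rec, n_reps = 10L, min_prom_frac = 0.05) {
  mag <- sqrt(rowSums(rec$acc^2))
  T_len <- length(mag)
  if (var(mag) == 0) stop("cannot segment a constant signal: no peaks")
  r <- as.numeric(stats::acf(mag, lag.max = T_len - 1, plot = FALSE,
                             demean = TRUE)$acf)
  pk <- find_prominent_peaks(r, min_prom_frac) - 1L  # lags
  cand <- sort(unique(c(0L, pk)))
  p0 <- T_len / n_reps
  tol <- 0.3 * p0
  hit <- vapply(0:(n_reps - 1L), function(i) any(abs(cand - i * p0) <= tol),
                logical(1))
  if (sum(hit) < ceiling(n_reps / 2))
    stop("only ", sum(hit), " of ", n_reps, " expected cut positions have a ",
         "nearby autocorrelation peak; the signal may lack periodic structure")
  opts <- lapply(0:(n_reps - 1L), function(i) {
    g <- i * p0
    near <- cand[abs(cand - g) <= tol]
    if (!length(near)) as.integer(round(g)) else as.integer(sort(near))
  })
  cuts <- select_cuts_min_var(opts, T_len)
  gap <- mean(diff(cuts))
  # snap to activity valleys to absorb cumulative repetition jitter
  env <- smooth_envelope(mag, max(3L, round(gap / 4)))
  w <- max(1L, round(0.2 * gap))
  snapped <- vapply(cuts, function(cp) {
    lo <- max(0L, cp - w); hi <- min(T_len - 1L, cp + w)
    seg <- env[(lo + 1L):(hi + 1L)]
    lo + which.min(seg) - 1L
  }, numeric(1))
  snapped[1] <- min(snapped[1], cuts[1])  # never push the first cut right of lag 0 peak
  snapped <- as.integer(snapped)
  if (any(diff(snapped) <= 0))
    stop("segmentation produced non-increasing cut points")
  ends <- c(snapped[-1], min(T_len, snapped[n_reps] + round(gap)))
  segments <- lapply(seq_len(n_reps), function(i) {
    idx <- (snapped[i] + 1L):ends[i]
    structure(list(t = rec$t[idx], acc = rec$acc[idx, , drop = FALSE],
                   action = rec$action, level = rec$level,
                   subject = rec$subject, id = rec$id, rep_index = i - 1L),
              class = "signal_recording")
  })
  structure(list(cut_points = snapped, peaks = cand, segments = segments),
            class = "segmentation_result")
}

# choose one cut per grid-point option set, minimizing the variance of
# consecutive gaps (the final gap runs to the end of the recording);
# exhaustive over the option product when small, nearest-per-grid otherwise
select_cuts_min_var <- function(opts, T_len) {
  n <- length(opts)
  nopt <- prod(lengths(opts))
  if (nopt > 1) {
    if (nopt <= 2e4) {
      combos <- as.matrix(expand.grid(opts, KEEP.OUT.ATTRS = FALSE))
      vars <- apply(combos, 1, function(cc) {
        if (any(diff(cc) <= 0)) return(Inf)
        var(diff(c(cc, T_len)))
      })
      return(as.integer(combos[which.min(vars), ]))
    }
    # too many combinations: take the option nearest to its grid position
    p0 <- T_len / n
    cuts <- vapply(seq_len(n), function(i) {
      o <- opts[[i]]
      o[which.min(abs(o - (i - 1) * p0))]
    }, integer(1))
    if (any(diff(cuts) <= 0)) stop("could not select ", n,
                                   " increasing cut points")
    return(cuts)
  }
  cuts <- as.integer(unlist(opts))
  if (any(diff(cuts) <= 0)) stop("could not select ", n,
                                 " increasing cut points")
  cuts
}

smooth_envelope <- function(mag, k) {
  # activity = deviation from the quiescent baseline; a low quantile of the
  # magnitude tracks the rest level (repetition boundaries), whereas the
  # median sits mid-motion and would place valleys at median crossings
  e <- abs(mag - stats::quantile(mag, 0.1, names = FALSE))
  kk <- max(3L, as.integer(k) + (as.integer(k) %% 2 == 0))  # odd
  as.numeric(stats::filter(c(rep(e[1], kk), e, rep(e[length(e)], kk)),
                           rep(1 / kk, kk), sides = 2))[(kk + 1):(kk + length(e))]
}

#' Write / read recordings as delimited text
#'
#' One CSV per recording with header `t,ax,ay,az`, plus a `labels.csv`
#' sidecar (`recording_id,action,level,subject`).
#'
#' @param ds a `rehab_dataset` (or list of `signal_recording`).
#' @param dir output directory (created if missing).
#' @return `write_recordings`: invisibly, the directory.
#' @export
write_recordings <- function(ds, dir) {
  recs <- if (inherits(ds, "rehab_dataset")) ds$recordings else ds
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- do.call(rbind, lapply(recs, function(r)
    data.frame(recording_id = r$id, action = r$action, level = r$level,
               subject = r$subject)))
  for (r in recs) {
    df <- data.frame(t = r$t, ax = r$acc[, 1], ay = r$acc[, 2],
                     az = r$acc[, 3])
    write.csv(df, file.path(dir, sprintf("rec_%05d.csv", r$id)),
              row.names = FALSE)
  }
  write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_recordings
#' @return `read_recordings`: a `rehab_dataset`-like list with `recordings`.
#' @export
read_recordings <- function(dir) {
  lab <- read.csv(file.path(dir, "labels.csv"))
  recs <- lapply(seq_len(nrow(lab)), function(i) {
    df <- read.csv(file.path(dir, sprintf("rec_%05d.csv", lab$recording_id[i])))
    acc <- as.matrix(df[, c("ax", "ay", "az")])
    if (nrow(acc) < 2 || any(diff(df$t) <= 0))
      stop("invalid recording ", lab$recording_id[i])
    structure(list(t = df$t, acc = acc, action = lab$action[i],
                   level = lab$level[i], subject = lab$subject[i],
                   id = lab$recording_id[i]),
              class = "signal_recording")
  })
  structure(list(recordings = recs, config = NULL), class = "rehab_dataset")
}
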