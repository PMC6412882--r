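#' Fit a level quantizer by equal-count splitting
#'
#' All training values are concatenated and sorted; the sorted vector is
#' divided into `K_q` equal-count parts and the part boundaries become the
#' level boundaries. A value equal to a boundary belongs to the lower level.
#'
#' @param training_signals numeric vector or list of numeric vectors.
#' @param K_q number of quantization levels (>= 2).
#' @return list of class `level_quantizer` with `n_levels` and `boundaries`
#'   (`K_q - 1` non-decreasing thresholds).
#' @export
fit_quantizer <- function(training_signals, K_q = 10L) {
  if (K_q < 2) stop("K_q must be >= 2")
  v <- sort(unlist(training_signals, use.names = FALSE))
  n <- length(v)
  if (n < K_q) stop("need at least K_q samples to fit the quantizer")
  if (v[1] == v[n]) stop("degenerate data: all training values identical")
  b <- v[ceiling(seq_len(K_q - 1) * n / K_q)]
  structure(list(n_levels = as.integer(K_q), boundaries = as.numeric(b)),
            class = "level_quantizer")
}

#' Map a series to level indices
#'
#' Each sample becomes the index (0-based) of the quantizer level it falls
#' in; ties at a boundary go to the lower level.
#'
#' @param q a `level_quantizer`.
#' @param series numeric vector.
#' @return integer vector of levels in `[0, K_q)`.
#' @export
symbolize <- function(q, series) {
  stopifnot(inherits(q, "level_quantizer"))
  as.integer(findInterval(series, q$boundaries, left.open = TRUE))
}

tok_key <- function(tokens) paste(tokens, collapse = ",")

#' Build the LZW table of a symbol sequence (first pass)
#'
#' The table is seeded with every single token present, then grown by the
#' classic LZW rule: read the next token C; if P+C is known set P = P+C,
#' otherwise add P+C and set P = C.
#'
#' @param seq integer vector of tokens.
#' @return list of class `lzw_table`: `entries` (keys in insertion order,
#'   tokens comma-joined) and a lookup environment.
#' @export
lzw_build_table <- function(seq) {
  if (!length(seq)) stop("cannot build an LZW table from an empty sequence")
  env <- new.env(parent = emptyenv(), hash = TRUE)
  entries <- character(0)
  for (s in unique(seq)) {
    k <- as.character(s)
    assign(k, TRUE, envir = env)
    entries <- c(entries, k)
  }
  p <- as.character(seq[1])
  n <- length(seq)
  if (n >= 2) for (i in 2:n) {
    cc <- as.character(seq[i])
    pc <- paste0(p, ",", cc)
    if (exists(pc, envir = env, inherits = FALSE)) {
      p <- pc
    } else {
      assign(pc, TRUE, envir = env)
      entries <- c(entries, pc)
      p <- cc
    }
  }
  structure(list(entries = entries, env = env), class = "lzw_table")
}

#' Encode a symbol sequence with a fixed LZW table (second pass)
#'
#' Greedy longest-match parse: the table does not grow during encoding.
#' Each emitted code is the key of the matched table entry; the trailing
#' prefix is emitted at the end.
#'
#' @param seq integer vector of tokens.
#' @param table an `lzw_table` built over the same alphabet.
#' @return character vector of emitted state keys.
#' @export
lzw_encode <- function(seq, table) {
  if (!length(seq)) stop("cannot encode an empty sequence")
  env <- table$env
  p <- as.character(seq[1])
  if (!exists(p, envir = env, inherits = FALSE))
    stop("token ", p, " absent from the LZW table")
  out <- character(0)
  n <- length(seq)
  if (n >= 2) for (i in 2:n) {
    cc <- as.character(seq[i])
    if (!exists(cc, envir = env, inherits = FALSE))
      stop("token ", cc, " absent from the LZW table")
    pc <- paste0(p, ",", cc)
    if (exists(pc, envir = env, inherits = FALSE)) {
      p <- pc
    } else {
      out <- c(out, p)
      p <- cc
    }
  }
  c(out, p)
}

# token-level Levenshtein distance between two keys
token_levenshtein <- function(a, b) {
  ta <- strsplit(a, ",", fixed = TRUE)[[1]]
  tb <- strsplit(b, ",", fixed = TRUE)[[1]]
  na <- length(ta); nb <- length(tb)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1)
    cur[1] <- i
    for (j in seq_len(nb)) {
      cost <- if (ta[i] == tb[j]) 0 else 1
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1, prev[j] + cost)
    }
    prev <- cur
  }
  prev[nb + 1]
}

#' Build the state dictionary from per-class encoded states
#'
#' Per class, the `C_states` most frequently emitted LZW states are taken
#' (frequency ties broken by longer state first, then lexicographically);
#' the per-class lists are concatenated in class order and deduplicated.
#'
#' @param encoded_per_class named list: class -> character vector of emitted
#'   state keys (pooled over that class's windows).
#' @param C_states states kept per class (default 6).
#' @return list of class `state_dictionary` with `states` (keys) and
#'   `per_class_count`.
#' @export
build_state_dictionary <- function(encoded_per_class, C_states = 6L) {
  if (!length(encoded_per_class) || any(!lengths(encoded_per_class)))
    stop("every class must contribute at least one encoded state")
  pick <- function(states) {
    tab <- table(states)
    keys <- names(tab)
    len <- lengths(strsplit(keys, ",", fixed = TRUE))
    ord <- order(-as.numeric(tab), -len, keys)
    keys <- keys[ord]
    if (length(keys) < C_states)
      warning("class has only ", length(keys), " distinct states (< C_states)")
    utils::head(keys, C_states)
  }
  states <- unlist(lapply(encoded_per_class, pick), use.names = FALSE)
  states <- states[!duplicated(states)]
  structure(list(states = states, per_class_count = as.integer(C_states)),
            class = "state_dictionary")
}

#' Map a state onto the dictionary by token-level Levenshtein distance
#'
#' Returns the dictionary state with minimal edit distance to `s_u`
#' (distance 0, i.e. `s_u` itself, when it is in the dictionary); distance
#' ties go to the earlier dictionary state.
#'
#' @param s_u state key (tokens comma-joined).
#' @param D a `state_dictionary`.
#' @return a state key in `D$states`.
#' @export
map_state <- function(s_u, D) {
  stopifnot(length(D$states) > 0)
  if (s_u %in% D$states) return(s_u)
  d <- vapply(D$states, token_levenshtein, numeric(1), a = s_u)
  D$states[which.min(d)]
}

#' State-transition probability matrix over the dictionary
#'
#' Counts consecutive transitions in a mapped state sequence and
#' row-normalizes; states with no outgoing transition get a uniform row so
#' the matrix stays row-stochastic.
#'
#' @param states character vector (length >= 2) of mapped state keys, all in
#'   `D$states`.
#' @param D a `state_dictionary`.
#' @return an n x n row-stochastic matrix (n = number of dictionary states)
#'   with the states as dimnames.
#' @export
transition_matrix <- function(states, D) {
  if (length(states) < 2) stop("need at least 2 states to count transitions")
  n <- length(D$states)
  idx <- match(states, D$states)
  if (anyNA(idx)) stop("all states must be in the dictionary")
  m <- length(idx)
  counts <- matrix(0, n, n, dimnames = list(D$states, D$states))
  tab <- table(factor(idx[-m], levels = seq_len(n)),
               factor(idx[-1], levels = seq_len(n)))
  counts[] <- as.numeric(tab)
  rs <- rowSums(counts)
  pi_mat <- counts
  zero <- rs == 0
  pi_mat[!zero, ] <- counts[!zero, , drop = FALSE] / rs[!zero]
  pi_mat[zero, ] <- 1 / n
  pi_mat
}

# transition matrix of one normalized window: per-axis symbolize -> two-pass
# LZW -> dictionary mapping -> counts; the three per-axis matrices are
# averaged so the regression target keeps size n^2
window_transition_matrix <- function(values, quantizers, D, map_cache = NULL) {
  n_ax <- ncol(values)
  acc <- 0
  for (ax in seq_len(n_ax)) {
    sym <- symbolize(quantizers[[ax]], values[, ax])
    tab <- lzw_build_table(sym)
    enc <- lzw_encode(sym, tab)
    mapped <- map_states_cached(enc, D, map_cache)
    acc <- acc + transition_matrix(mapped, D)
  }
  acc / n_ax
}

map_states_cached <- function(states, D, cache = NULL) {
  if (is.null(cache)) return(vapply(states, map_state, character(1), D = D))
  vapply(states, function(s) {
    hit <- cache[[s]]
    if (is.null(hit)) {
      hit <- map_state(s, D)
      cache[[s]] <- hit
    }
    hit
  }, character(1))
}

#' Compute S-CNN regression targets for a window set
#'
#' Fits one equal-count quantizer per axis on the training windows, encodes
#' every window axis with its own two-pass LZW table, builds the state
#' dictionary from the training windows of each action class, and returns
#' one flattened (row-major) transition-probability matrix per window,
#' averaged over the three axes.
#'
#' @param values_list list of W x 3 normalized window matrices.
#' @param actions integer action label (0-based) per window.
#' @param train_idx indices of windows used to fit quantizers and dictionary.
#' @param K_q quantization levels per axis (default 10).
#' @param C_states dictionary states per class (default 6).
#' @return list: `targets` (N x n^2 matrix), `dictionary`, `quantizers`,
#'   `n_states`.
#' @export
scnn_targets <- function(values_list, actions, train_idx = seq_along(values_list),
                         K_q = 10L, C_states = 6L) {
  stopifnot(length(values_list) == length(actions))
  n_ax <- ncol(values_list[[1]])
  quantizers <- lapply(seq_len(n_ax), function(ax)
    fit_quantizer(lapply(values_list[train_idx], function(v) v[, ax]), K_q))
  # encode training windows once to build the dictionary
  enc_by_class <- list()
  enc_cache <- vector("list", length(values_list))
  for (i in train_idx) {
    v <- values_list[[i]]
    enc_ax <- lapply(seq_len(n_ax), function(ax) {
      sym <- symbolize(quantizers[[ax]], v[, ax])
      lzw_encode(sym, lzw_build_table(sym))
    })
    enc_cache[[i]] <- enc_ax
    key <- as.character(actions[i])
    enc_by_class[[key]] <- c(enc_by_class[[key]], unlist(enc_ax))
  }
  D <- build_state_dictionary(enc_by_class, C_states)
  n <- length(D$states)
  map_cache <- new.env(parent = emptyenv(), hash = TRUE)
  targets <- matrix(0, length(values_list), n * n)
  for (i in seq_along(values_list)) {
    v <- values_list[[i]]
    pim <- 0
    for (ax in seq_len(n_ax)) {
      enc <- if (!is.null(enc_cache[[i]])) enc_cache[[i]][[ax]] else {
        sym <- symbolize(quantizers[[ax]], v[, ax])
        lzw_encode(sym, lzw_build_table(sym))
      }
      mapped <- map_states_cached(enc, D, map_cache)
      pim <- pim + transition_matrix(mapped, D)
    }
    targets[i, ] <- as.vector(t(pim / n_ax))  # row-major flatten
  }
  list(targets = targets, dictionary = D, quantizers = quantizers,
       n_states = n)
}

#' Serialize / restore quantizers and dictionary as JSON
#'
#' @param quantizers list of `level_quantizer` (one per axis).
#' @param dictionary a `state_dictionary`.
#' @param path JSON file path.
#' @return `pfsa_to_json`: invisibly, the path.
#' @export
pfsa_to_json <- function(quantizers, dictionary, path) {
  obj <- list(
    quantizers = lapply(quantizers, function(q)
      list(n_levels = q$n_levels, boundaries = q$boundaries)),
    dictionary = list(states = lapply(strsplit(dictionary$states, ",", fixed = TRUE),
                                      as.integer),
                      per_class_count = dictionary$per_class_count))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pfsa_to_json
#' @export
pfsa_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  quantizers <- lapply(obj$quantizers, function(q)
    structure(list(n_levels = as.integer(q$n_levels),
                   boundaries = as.numeric(unlist(q$boundaries))),
              class = "level_quantizer"))
  states <- vapply(obj$dictionary$states, function(s)
    paste(unlist(s), collapse = ","), character(1))
  D <- structure(list(states = unname(states),
                      per_class_count = as.integer(obj$dictionary$per_class_count)),
                 class = "state_dictionary")
  list(quantizers = quantizers, dictionary = D)
}
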