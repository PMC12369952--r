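# Fixed-length numeric encodings of process cases.
#
# The GAN consumes (a) padded one-hot activity matrices, (b) timestamp
# differential sequences scaled by case duration (first position 0,
# zero-padded), (c) min-max normalized case durations, and (d) pairwise
# time-interval matrices built from the cumulative differentials.

#' Min-max normalize a case duration
#'
#' @param t_real Non-negative duration.
#' @param bounds Numeric `(T_min, T_max)`.
#' @param clamp If `TRUE`, out-of-bounds durations are clipped into the
#'   bounds instead of raising an error.
#' @return `(t_real - T_min) / (T_max - T_min)` in `[0, 1]`; 0 when
#'   `T_min == T_max`.
#' @export
normalize_duration <- function(t_real, bounds, clamp = FALSE) {
  lo <- bounds[1L]; hi <- bounds[2L]
  if (any(t_real < lo) || any(t_real > hi)) {
    if (!clamp) stop("duration out of bounds [", lo, ", ", hi, "]")
    t_real <- pmin(pmax(t_real, lo), hi)
  }
  if (hi == lo) return(rep(0, length(t_real)))
  (t_real - lo) / (hi - lo)
}

#' Timestamp differentials of a case
#'
#' Position 1 gets 0; position `i` gets `(ts_i - ts_{i-1}) / T_real`, then
#' the sequence is zero-padded to length `max_len`.  Non-pad differentials
#' of an authentic case sum to 1 (telescoping).  A case whose timestamps
#' are all equal encodes as all zeros with a warning.
#'
#' @param case A `process_case`.
#' @param max_len Maximum sequence length `l`.
#' @return Numeric vector of length `max_len`.
#' @export
compute_differentials <- function(case, max_len) {
  n <- length(case$timestamps)
  if (n > max_len) stop("case longer than max_len")
  dur <- case_duration(case)
  out <- numeric(max_len)
  if (dur <= 0) {
    if (n > 1L) warning("zero-duration case '", case$case_id,
                        "' encoded as all-zero differentials")
    return(out)
  }
  if (n > 1L) out[2:n] <- diff(case$timestamps) / dur
  out
}

#' Pad a case and one-hot encode its activities
#'
#' Rows `1..n` are the case's activities, rows `n+1..max_len` the pad
#' token.
#'
#' @param case A `process_case`.
#' @param max_len Maximum sequence length.
#' @param vocab An activity vocabulary (see [activity_vocabulary()]).
#' @return A `max_len x N_v` binary matrix (`N_v` includes the pad label).
#' @export
pad_and_onehot <- function(case, max_len, vocab) {
  n <- length(case$activities)
  if (n > max_len) stop("case longer than max_len")
  idx <- match(case$activities, vocab$labels)
  if (anyNA(idx)) {
    stop("unknown activity label(s): ",
         paste(unique(case$activities[is.na(idx)]), collapse = ", "))
  }
  idx <- c(idx, rep(vocab$pad_index, max_len - n))
  out <- matrix(0, max_len, length(vocab$labels))
  out[cbind(seq_len(max_len), idx)] <- 1
  out
}

#' Pairwise time-interval matrix
#'
#' The scaled timestamp sequence is restored by cumulative summation of the
#' differentials (`ts'_i = sum_{r<=i} t_r`) and `M[i, j] = ts'_i - ts'_j`.
#' `M` is antisymmetric with a zero diagonal by construction.
#'
#' @param differentials Numeric vector of non-negative differentials.
#' @return A square antisymmetric matrix.
#' @export
build_time_interval_matrix <- function(differentials) {
  tsp <- cumsum(differentials)
  outer(tsp, tsp, "-")
}

#' Encode one case for the networks
#'
#' @param case A `process_case`.
#' @param max_len Maximum sequence length.
#' @param vocab Activity vocabulary.
#' @param bounds Duration bounds of the log.
#' @return A list with `activity_onehot`, `activity_idx`, `differentials`,
#'   `duration_norm`, `duration_real`, `length`, and the case id.
#' @export
encode_case <- function(case, max_len, vocab, bounds) {
  dur <- case_duration(case)
  list(case_id = case$case_id,
       activity_onehot = pad_and_onehot(case, max_len, vocab),
       activity_idx = c(match(case$activities, vocab$labels),
                        rep(vocab$pad_index,
                            max_len - length(case$activities))),
       differentials = compute_differentials(case, max_len),
       duration_norm = normalize_duration(dur, bounds, clamp = TRUE),
       duration_real = dur,
       length = length(case$activities))
}

#' Encode a whole log into stacked arrays
#'
#' @param log An `event_log`.
#' @param max_len Maximum sequence length; defaults to the longest case.
#' @return A list with `onehot` (`N*l x N_v` stacked matrix), `idx`
#'   (`N x l`), `diffs` (`N x l`), `dur_norm`, `dur_real`, `lengths`,
#'   `max_len`, and the vocabulary.
#' @export
encode_log <- function(log, max_len = NULL) {
  if (is.null(max_len)) max_len <- max(case_lengths(log))
  vocab <- log$vocabulary
  n <- length(log$cases)
  nv <- length(vocab$labels)
  onehot <- matrix(0, n * max_len, nv)
  idx <- matrix(0L, n, max_len)
  diffs <- matrix(0, n, max_len)
  dur_real <- numeric(n)
  lens <- integer(n)
  for (i in seq_len(n)) {
    enc <- suppressWarnings(encode_case(log$cases[[i]], max_len, vocab,
                                        log$duration_bounds))
    rows <- ((i - 1L) * max_len + 1L):(i * max_len)
    onehot[rows, ] <- enc$activity_onehot
    idx[i, ] <- enc$activity_idx
    diffs[i, ] <- enc$differentials
    dur_real[i] <- enc$duration_real
    lens[i] <- enc$length
  }
  list(onehot = onehot, idx = idx, diffs = diffs,
       dur_norm = normalize_duration(dur_real, log$duration_bounds,
                                     clamp = TRUE),
       dur_real = dur_real, lengths = lens,
       max_len = max_len, vocab = vocab,
       bounds = log$duration_bounds)
}
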