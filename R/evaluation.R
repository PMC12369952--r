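# Three-part assessment of synthetic logs: statistical measures (lengths,
# pairwise-edit-distance diversity, activity occurrence and timestamp
# errors), a negative-sampling supervised realism scorer reporting a false
# positive rate, and a consensus-workflow summary via star alignment.

#' Levenshtein distance between two label sequences
#'
#' Unit-cost insert/delete/substitute edit distance, computed with a
#' row-vectorized dynamic program (the inner running minimum is folded into
#' a cumulative minimum, so cost grows with the shorter sequence only).
#'
#' @param a,b Character (or integer) vectors.
#' @return Non-negative integer distance.
#' @export
levenshtein <- function(a, b) {
  m <- length(a); n <- length(b)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  js <- 0:n
  prev <- js
  for (i in seq_len(m)) {
    cost <- as.numeric(a[i] != b)
    base <- c(i, pmin(prev[1:n] + cost, prev[2:(n + 1L)] + 1))
    prev <- js + cummin(base - js)
  }
  as.integer(prev[n + 1L])
}

activity_sequences <- function(log) lapply(log$cases, `[[`, "activities")

# all-pairs Levenshtein distance matrix over a list of sequences
levenshtein_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- levenshtein(seqs[[i]], seqs[[j]])
    }
  }
  d
}

#' Mean and standard deviation of case lengths
#'
#' @param log An `event_log`.
#' @return Named numeric `c(mean, sd)`; the sample (n-1) convention, with
#'   `sd = 0` (and a warning) for a single case.
#' @export
length_stats <- function(log) {
  lens <- case_lengths(log)
  s <- if (length(lens) > 1L) stats::sd(lens) else {
    warning("single-case log: standard deviation reported as 0")
    0
  }
  c(mean = mean(lens), sd = s)
}

#' Sequence diversity: sum of pairwise normalized edit distances
#'
#' `SPE = (1/N^2) * sum_{i<j} ED(s_i, s_j) / (len(s_i) + len(s_j))` over
#' the activity sequences of a sample.  The `1/N^2` normalization is used
#' as printed (not `2/(N(N-1))`).
#'
#' @param log An `event_log` with at least 2 cases.
#' @return Non-negative scalar; 0 for identical sequences.
#' @export
spe <- function(log) {
  seqs <- activity_sequences(log)
  n <- length(seqs)
  stopifnot(n >= 2L)
  lens <- lengths(seqs)
  d <- levenshtein_matrix(seqs)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    tot <- tot + sum(d[i, js] / (lens[i] + lens[js]))
  }
  tot / n^2
}

token_frequencies <- function(log, labels) {
  acts <- unlist(activity_sequences(log))
  tab <- table(factor(acts, levels = labels))
  as.numeric(tab) / length(acts)
}

#' Activity type occurrence error
#'
#' L1 distance between the per-activity token proportions of two logs,
#' summed over the union of their activity types.  Bounded by 2 (disjoint
#' supports).
#'
#' @param authentic,synthetic `event_log`s.
#' @return Scalar in `[0, 2]`.
#' @export
activity_occurrence_error <- function(authentic, synthetic) {
  labels <- sort(union(unlist(activity_sequences(authentic)),
                       unlist(activity_sequences(synthetic))))
  sum(abs(token_frequencies(authentic, labels) -
            token_frequencies(synthetic, labels)))
}

# per-activity statistic of cumulative scaled timestamps (fraction of case
# duration), x100
activity_time_stats <- function(log, labels, statistic) {
  vals <- stats::setNames(vector("list", length(labels)), labels)
  for (cs in log$cases) {
    dur <- case_duration(cs)
    if (dur <= 0) next
    scaled <- (cs$timestamps - cs$timestamps[1L]) / dur
    for (k in seq_along(cs$activities)) {
      a <- cs$activities[k]
      vals[[a]] <- c(vals[[a]], scaled[k])
    }
  }
  vapply(labels, function(a) {
    v <- vals[[a]]
    if (is.null(v)) return(NA_real_)
    100 * switch(statistic,
                 mean = mean(v),
                 p90 = as.numeric(stats::quantile(v, 0.9, type = 7)))
  }, numeric(1))
}

#' Activity timestamp error
#'
#' Per activity type, the chosen statistic (mean or 90th percentile, linear
#' interpolation) of its scaled timestamps -- fraction of case duration,
#' scale x100 -- is computed in each log; the error is the sum of absolute
#' differences over the union of activity types.  Activities absent from
#' one log compare against 0 with a warning.
#'
#' @param authentic,synthetic `event_log`s.
#' @param statistic `"mean"` or `"p90"`.
#' @return Non-negative scalar; 0 on identical logs.
#' @export
timestamp_error <- function(authentic, synthetic,
                            statistic = c("mean", "p90")) {
  statistic <- match.arg(statistic)
  labels <- sort(union(unlist(activity_sequences(authentic)),
                       unlist(activity_sequences(synthetic))))
  a <- activity_time_stats(authentic, labels, statistic)
  s <- activity_time_stats(synthetic, labels, statistic)
  if (anyNA(a) || anyNA(s)) {
    warning("activities absent from one log compare against 0: ",
            paste(labels[is.na(a) | is.na(s)], collapse = ", "))
  }
  a[is.na(a)] <- 0; s[is.na(s)] <- 0
  sum(abs(a - s))
}

#' Corrupt a log into negative samples
#'
#' Per case, a `noise_ratio` fraction of tokens is perturbed by operations
#' drawn uniformly from add / delete / switch: add inserts a random real
#' activity at an interior slot with a uniform timestamp between its
#' neighbors, delete removes an activity with its timestamp, switch swaps
#' two activities keeping the timestamps in place.  After any perturbation
#' the case's timestamps are re-scaled into `[0, 1]`.  Cases shorter than
#' 2 tokens skip switch/delete (add is used instead).
#'
#' @param log An `event_log`.
#' @param noise_ratio Fraction in `[0, 1]`; 0 returns an identical copy.
#' @param seed Integer seed.
#' @param id_suffix Suffix appended to corrupted case ids.
#' @return An `event_log` of corrupted cases.
#' @export
make_negative_samples <- function(log, noise_ratio, seed = 1L,
                                  id_suffix = "neg") {
  stopifnot(noise_ratio >= 0, noise_ratio <= 1)
  set.seed(seed)
  real_labels <- log$vocabulary$labels[seq_len(log$vocabulary$n_real)]
  cases <- lapply(log$cases, function(cs) {
    acts <- cs$activities; ts <- cs$timestamps
    n_ops <- if (noise_ratio > 0) max(1L, round(noise_ratio * length(acts)))
             else 0L
    for (op in seq_len(n_ops)) {
      kind <- sample(c("add", "delete", "switch"), 1L)
      if (length(acts) < 2L && kind != "add") kind <- "add"
      if (kind == "add" && length(acts) >= 2L) {
        j <- sample.int(length(acts) - 1L, 1L)
        new_ts <- stats::runif(1L, ts[j], ts[j + 1L])
        acts <- append(acts, sample(real_labels, 1L), after = j)
        ts <- append(ts, new_ts, after = j)
      } else if (kind == "add") {
        acts <- c(acts, sample(real_labels, 1L))
        ts <- c(ts, ts[length(ts)])
      } else if (kind == "delete") {
        j <- sample.int(length(acts), 1L)
        acts <- acts[-j]; ts <- ts[-j]
      } else {
        jj <- sample.int(length(acts), 2L)
        acts[jj] <- acts[rev(jj)]
      }
    }
    if (n_ops > 0L) {
      rng <- max(ts) - min(ts)
      ts <- if (rng > 0) (ts - min(ts)) / rng else ts * 0
    }
    process_case(paste0(cs$case_id, "_", id_suffix), acts, ts)
  })
  event_log(cases, time_unit = log$time_unit)
}

#' Train the "off-the-shelf" realism scorer
#'
#' A transformer-encoder binary classifier over activity + timestamp
#' sequences: the pooled sequence embedding is concatenated with the
#' activity frequency distribution and the sequence length, then passed
#' through two dense layers.  Negatives are noise-corrupted copies of the
#' authentic cases at `negatives_multiple` times the positive count; class
#' weights rebalance the loss.  Trained on a stratified 80/20 split; the
#' held-out weighted F1 gates use of the scorer (reliable above 0.8).
#'
#' @param log Authentic `event_log` (>= 20 cases).
#' @param noise_ratio Corruption ratio for the negatives.
#' @param negatives_multiple Negatives per positive (default 5).
#' @param epochs,batch_size,lr Training protocol.
#' @param hidden_size,n_layers,n_heads Encoder shape.
#' @param seed Integer seed.
#' @return List with the `model` (class `offshelf_classifier`), held-out
#'   weighted `f1`, and `reliable` (`f1 > 0.8`); warns when unreliable.
#' @export
train_offshelf_classifier <- function(log, noise_ratio = 0.2,
                                      negatives_multiple = 5L,
                                      epochs = 30L, batch_size = 32L,
                                      lr = 1e-3, hidden_size = 32L,
                                      n_layers = 2L, n_heads = 2L,
                                      seed = 1L) {
  stopifnot(length(log$cases) >= 20L)
  set.seed(seed)
  negs <- lapply(seq_len(negatives_multiple), function(k) {
    make_negative_samples(log, noise_ratio, seed = seed + k,
                          id_suffix = paste0("neg", k))
  })
  all_cases <- c(log$cases, unlist(lapply(negs, `[[`, "cases"),
                                   recursive = FALSE))
  y <- c(rep(1L, length(log$cases)),
         rep(0L, sum(vapply(negs, function(x) length(x$cases), integer(1)))))
  vocab <- log$vocabulary
  max_len <- max(vapply(all_cases, function(cs) length(cs$activities),
                        integer(1)))
  N <- length(all_cases)
  idx <- matrix(vocab$pad_index, N, max_len)
  diffs <- matrix(0, N, max_len)
  lens <- integer(N)
  for (i in seq_len(N)) {
    cs <- all_cases[[i]]
    ii <- match(cs$activities, vocab$labels)
    lens[i] <- length(ii)
    idx[i, seq_len(lens[i])] <- ii
    diffs[i, ] <- suppressWarnings(compute_differentials(cs, max_len))
  }

  # stratified 80/20 split
  te <- c(sample(which(y == 1L), round(0.2 * sum(y == 1L))),
          sample(which(y == 0L), round(0.2 * sum(y == 0L))))
  tr <- setdiff(seq_len(N), te)

  cfg <- seq_encoder_config(length(vocab$labels), max_len,
                            hidden_size = hidden_size, n_heads = n_heads,
                            n_layers = n_layers)
  encd <- init_seq_encoder(cfg)
  h2 <- 16L
  feat_dim <- cfg$hidden_size + vocab$n_real + 1L
  head <- list(w1 = ad_param(glorot(feat_dim, h2)),
               b1 = ad_param(zeros_row(h2)),
               w2 = ad_param(glorot(h2, 1L)), b2 = ad_param(zeros_row(1L)))
  model <- structure(list(encoder = encd, head = head, vocab = vocab,
                          max_len = max_len, cfg = cfg),
                     class = "offshelf_classifier")
  params <- model_params(model)
  opt <- adam_init(params, lr = lr)
  w_pos <- negatives_multiple  # rebalance 5x negatives

  forward <- function(rows, training) {
    pooled <- seq_encoder_forward(encd, idx[rows, , drop = FALSE],
                                  diffs[rows, , drop = FALSE], training)
    side <- trace_side_features(idx[rows, , drop = FALSE], lens[rows],
                                vocab$n_real, max_len)
    f <- ad_cbind_const(pooled, side)
    f <- ad_relu(ad_add_rowvec(ad_matmul(f, head$w1), head$b1))
    ad_sigmoid(ad_add_rowvec(ad_matmul(f, head$w2), head$b2))
  }

  for (ep in seq_len(epochs)) {
    perm <- sample(tr)
    for (st in seq(1L, length(perm), by = batch_size)) {
      rows <- perm[st:min(st + batch_size - 1L, length(perm))]
      p <- forward(rows, training = TRUE)
      yy <- y[rows]
      wts <- ifelse(yy == 1L, w_pos, 1)
      wts <- matrix(wts / sum(wts), ncol = 1L)
      # weighted binary cross-entropy
      loss <- ad_scale(ad_sum(ad_mul(ad_const(wts * yy),
                                     ad_log(p, eps = LOG_EPS))), -1)
      loss <- ad_sub(loss, ad_sum(ad_mul(
        ad_const(wts * (1 - yy)),
        ad_log(ad_sub(ad_const(matrix(1, length(rows), 1L)), p),
               eps = LOG_EPS))))
      ad_zero_grad(params)
      ad_backward(loss)
      adam_step(opt)
    }
  }

  pred <- with_no_grad(list(model), as.numeric(forward(te, FALSE)$value))
  f1 <- unname(weighted_prf(y[te], as.integer(pred > 0.5))["f1"])
  reliable <- f1 > 0.8
  if (!reliable) {
    warning(sprintf("held-out weighted F1 = %.3f <= 0.8; scorer unreliable",
                    f1))
  }
  list(model = model, f1 = f1, reliable = reliable)
}

classifier_scores <- function(model, log) {
  vocab <- model$vocab
  max_len <- model$max_len
  N <- length(log$cases)
  idx <- matrix(vocab$pad_index, N, max_len)
  diffs <- matrix(0, N, max_len)
  lens <- integer(N)
  for (i in seq_len(N)) {
    cs <- log$cases[[i]]
    ii <- match(cs$activities, vocab$labels)
    if (anyNA(ii)) stop("vocabulary mismatch: unknown activity in case ",
                        cs$case_id)
    if (length(ii) > max_len) {
      warning("case ", cs$case_id, " truncated to classifier max length")
      ii <- ii[seq_len(max_len)]
      cs <- process_case(cs$case_id, cs$activities[seq_len(max_len)],
                         cs$timestamps[seq_len(max_len)])
    }
    lens[i] <- length(ii)
    idx[i, seq_len(lens[i])] <- ii
    diffs[i, ] <- suppressWarnings(compute_differentials(cs, max_len))
  }
  with_no_grad(list(model), {
    pooled <- seq_encoder_forward(model$encoder, idx, diffs, FALSE)
    side <- trace_side_features(idx, lens, vocab$n_real, max_len)
    f <- ad_cbind_const(pooled, side)
    f <- ad_relu(ad_add_rowvec(ad_matmul(f, model$head$w1), model$head$b1))
    as.numeric(ad_sigmoid(ad_add_rowvec(ad_matmul(f, model$head$w2),
                                        model$head$b2))$value)
  })
}

#' Score a synthetic log with the trained realism classifier
#'
#' The false positive rate: the fraction of synthetic cases the
#' authentic-vs-noise classifier labels authentic.  Higher means the
#' synthetic data tricks the scorer more often.
#'
#' @param classifier Result of [train_offshelf_classifier()] (or its
#'   `$model`).
#' @param synthetic A synthetic `event_log` over the same vocabulary.
#' @return FPR in `[0, 1]`.
#' @export
supervised_score <- function(classifier, synthetic) {
  model <- if (inherits(classifier, "offshelf_classifier")) classifier
           else classifier$model
  mean(classifier_scores(model, synthetic) > 0.5)
}

# Needleman-Wunsch style alignment of a sequence onto a reference with unit
# edit costs; returns, per reference position, the aligned symbol or NA
# (deletion), plus the inserted symbols.
align_to_reference <- function(seq, ref) {
  m <- length(seq); n <- length(ref)
  D <- matrix(0, m + 1L, n + 1L)
  D[, 1L] <- 0:m; D[1L, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + (seq[i] != ref[j]),
                               D[i, j + 1L] + 1, D[i + 1L, j] + 1)
    }
  }
  cols <- rep(NA_character_, n)
  inserted <- character(0)
  i <- m; j <- n
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        D[i + 1L, j + 1L] == D[i, j] + (seq[i] != ref[j])) {
      cols[j] <- seq[i]; i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1) {
      inserted <- c(inserted, seq[i]); i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(cols = cols, inserted = inserted)
}

#' Consensus workflow summary of a log
#'
#' A simplified star alignment ("summary view", not a faithful
#' reimplementation of published trace-alignment algorithms): every trace
#' is aligned to the medoid trace (minimum total Levenshtein distance to
#' all others; earliest on ties), the consensus keeps, per medoid column,
#' the most frequent aligned symbol when it is present in more than 50% of
#' traces, and activities outside the consensus backbone are reported as
#' branch activities with their total occurrence counts.
#'
#' @param log An `event_log`.
#' @return List with `consensus` (character vector), `branches` (named
#'   counts), and `medoid` (the medoid activity sequence).
#' @export
consensus_workflow <- function(log) {
  seqs <- activity_sequences(log)
  n <- length(seqs)
  if (n == 1L) {
    return(list(consensus = seqs[[1L]],
                branches = stats::setNames(integer(0), character(0)),
                medoid = seqs[[1L]]))
  }
  d <- levenshtein_matrix(seqs)
  medoid <- seqs[[which.min(rowSums(d))]]
  cols <- matrix(NA_character_, n, length(medoid))
  for (i in seq_len(n)) {
    cols[i, ] <- align_to_reference(seqs[[i]], medoid)$cols
  }
  consensus <- character(0)
  for (j in seq_along(medoid)) {
    tab <- table(cols[, j])
    if (length(tab) && max(tab) > n / 2) {
      consensus <- c(consensus, names(tab)[which.max(tab)])
    }
  }
  acts <- unlist(seqs)
  branch_tab <- table(acts[!(acts %in% consensus)])
  list(consensus = consensus,
       branches = stats::setNames(as.integer(branch_tab),
                                  names(branch_tab)),
       medoid = medoid)
}

#' Full evaluation report for a synthetic log
#'
#' Assembles the statistical measures, optionally the supervised realism
#' score, and the consensus workflows of both logs.
#'
#' @param authentic,synthetic `event_log`s over a shared vocabulary.
#' @param classifier Optional result of [train_offshelf_classifier()]; when
#'   supplied, its held-out F1 and the synthetic FPR are included.
#' @return An `evaluation_report` list.
#' @export
evaluate_logs <- function(authentic, synthetic, classifier = NULL) {
  rep <- list(
    length_authentic = length_stats(authentic),
    length_synthetic = length_stats(synthetic),
    spe_authentic = spe(authentic),
    spe_synthetic = spe(synthetic),
    act_error = activity_occurrence_error(authentic, synthetic),
    time_error_mean = timestamp_error(authentic, synthetic, "mean"),
    time_error_p90 = timestamp_error(authentic, synthetic, "p90"),
    consensus_authentic = consensus_workflow(authentic),
    consensus_synthetic = consensus_workflow(synthetic)
  )
  if (!is.null(classifier)) {
    rep$classifier_f1 <- classifier$f1
    rep$fpr <- supervised_score(classifier, synthetic)
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation report\n")
  cat(sprintf("  length  authentic %.2f+/-%.2f   synthetic %.2f+/-%.2f\n",
              x$length_authentic["mean"], x$length_authentic["sd"],
              x$length_synthetic["mean"], x$length_synthetic["sd"]))
  cat(sprintf("  SPE     authentic %.3f   synthetic %.3f\n",
              x$spe_authentic, x$spe_synthetic))
  cat(sprintf("  ActError %.3f   TimeError(mean) %.2f   TimeError(p90) %.2f\n",
              x$act_error, x$time_error_mean, x$time_error_p90))
  if (!is.null(x$classifier_f1)) {
    cat(sprintf("  classifier F1 %.3f   FPR %.3f\n", x$classifier_f1,
                x$fpr))
  }
  cat("  consensus (synthetic):",
      paste(x$consensus_synthetic$consensus, collapse = " -> "), "\n")
  invisible(x)
}
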