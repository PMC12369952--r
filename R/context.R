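# Multi-task context generator.
#
# Learns trace -> context associations on authentic data (shared
# transformer encoder, one two-dense-layer head per context task) and
# infers contexts for synthetic traces.  Task losses -- cross-entropy for
# categorical contexts, squared error for numerical ones -- are combined
# with homoscedastic-uncertainty weighting: each task owns a learnable
# log-variance s_i and contributes exp(-s_i) * L_i + s_i, so noisier tasks
# are automatically down-weighted.

#' Define a context schema
#'
#' @param tasks List of task descriptors
#'   `list(name =, kind = "categorical"|"numerical", levels = )`
#'   (levels required for categorical tasks, >= 2).
#' @return A `context_schema`.
#' @export
context_schema <- function(tasks) {
  stopifnot(length(tasks) >= 1L)
  for (tk in tasks) {
    stopifnot(!is.null(tk$name), tk$kind %in% c("categorical", "numerical"))
    if (tk$kind == "categorical") stopifnot(length(tk$levels) >= 2L)
  }
  structure(list(tasks = tasks), class = "context_schema")
}

#' Context model configuration
#'
#' Training protocol defaults: batch 16, initial learning rate 1e-2 with a
#' step decay (halved every 10 epochs), Adam momentum pair (0.5, 0.99),
#' early stopping after 20 epochs without validation improvement, 5 folds.
#'
#' @param encoder A `seq_encoder_config` for the shared encoder.
#' @param head_size Width of the first dense layer of each task head.
#' @param batch_size,lr,lr_decay_every,lr_decay_factor,betas,patience,max_epochs,folds
#'   Training protocol.
#' @param seed Integer seed.
#' @return A `context_model_config`.
#' @export
context_model_config <- function(encoder, head_size = 16L,
                                 batch_size = 16L, lr = 1e-2,
                                 lr_decay_every = 10L,
                                 lr_decay_factor = 0.5,
                                 betas = c(0.5, 0.99),
                                 patience = 20L, max_epochs = 60L,
                                 folds = 5L, seed = 1L) {
  stopifnot(folds >= 2L)
  structure(list(encoder = encoder, head_size = as.integer(head_size),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor, betas = betas,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "context_model_config")
}

#' Uncertainty-weighted multi-task loss
#'
#' `sum_i exp(-log_sigma2_i) * L_i + log_sigma2_i`.  With `log_sigma2 = 0`
#' this is the plain sum; for a single task with loss `L` the optimum over
#' `log_sigma2` is `log(L)`, giving `1 + log(L)`.
#'
#' @param losses Numeric vector of per-task losses (>= 0).
#' @param log_sigma2 Numeric vector of per-task log-variances.
#' @return Scalar combined loss.
#' @export
uncertainty_weighted_loss <- function(losses, log_sigma2) {
  stopifnot(length(losses) == length(log_sigma2))
  sum(exp(-log_sigma2) * losses + log_sigma2)
}

init_context_model <- function(schema, cfg) {
  encd <- init_seq_encoder(cfg$encoder)
  feat_dim <- cfg$encoder$hidden_size +
    (cfg$encoder$vocab_size - 1L) + 1L   # pooled + freq over real + length
  heads <- lapply(schema$tasks, function(tk) {
    k_out <- if (tk$kind == "categorical") length(tk$levels) else 1L
    list(w1 = ad_param(glorot(feat_dim, cfg$head_size)),
         b1 = ad_param(zeros_row(cfg$head_size)),
         w2 = ad_param(glorot(cfg$head_size, k_out)),
         b2 = ad_param(zeros_row(k_out)),
         log_sigma2 = ad_param(matrix(0, 1L, 1L)))
  })
  structure(list(encoder = encd, heads = heads, schema = schema,
                 cfg = cfg),
            class = "context_model")
}

#' Featurize a batch of traces with the shared encoder
#'
#' The pooled transformer embedding concatenated with the within-case
#' activity frequency distribution (over real labels, sums to 1) and the
#' scaled sequence length; feature width = pooled width + `N_v` + 1.
#'
#' @param model A `context_model`.
#' @param idx `B x l` activity index matrix (pad-padded).
#' @param diffs `B x l` differential matrix.
#' @param lengths Integer vector of case lengths.
#' @param training Dropout switch.
#' @return A feature node (`B x feat_dim`); numeric values in `$value`.
#' @export
featurize_trace <- function(model, idx, diffs, lengths, training = FALSE) {
  pooled <- seq_encoder_forward(model$encoder, idx, diffs, training)
  n_real <- model$cfg$encoder$vocab_size - 1L
  side <- trace_side_features(idx, lengths, n_real,
                              model$cfg$encoder$max_len)
  ad_cbind_const(pooled, side)
}

#' Per-task predictions from trace features
#'
#' Categorical heads emit probability rows (softmax); numerical heads a
#' real value.
#'
#' @param model A `context_model`.
#' @param features Feature node or matrix from [featurize_trace()].
#' @return Named list of per-task nodes.
#' @export
context_forward <- function(model, features) {
  f <- if (is_ad_node(features)) features else ad_const(features)
  out <- list()
  for (i in seq_along(model$schema$tasks)) {
    tk <- model$schema$tasks[[i]]
    hd <- model$heads[[i]]
    z <- ad_relu(ad_add_rowvec(ad_matmul(f, hd$w1), hd$b1))
    z <- ad_add_rowvec(ad_matmul(z, hd$w2), hd$b2)
    out[[tk$name]] <- if (tk$kind == "categorical") ad_softmax_rows(z)
                      else z
  }
  out
}

encode_for_context <- function(log, vocab, max_len) {
  N <- length(log$cases)
  idx <- matrix(vocab$pad_index, N, max_len)
  diffs <- matrix(0, N, max_len)
  lens <- integer(N)
  for (i in seq_len(N)) {
    cs <- log$cases[[i]]
    ii <- match(cs$activities, vocab$labels)
    if (anyNA(ii)) stop("vocabulary mismatch in case ", cs$case_id)
    lens[i] <- length(ii)
    idx[i, seq_len(lens[i])] <- ii
    diffs[i, ] <- suppressWarnings(compute_differentials(cs, max_len))
  }
  list(idx = idx, diffs = diffs, lens = lens)
}

context_targets <- function(log, schema) {
  lapply(schema$tasks, function(tk) {
    vals <- lapply(log$cases, function(cs) {
      v <- cs$contexts[[tk$name]]
      if (is.null(v) || is.na(v)) {
        stop("case ", cs$case_id, " is missing context '", tk$name, "'")
      }
      v
    })
    if (tk$kind == "categorical") {
      m <- match(unlist(vals), tk$levels)
      if (anyNA(m)) stop("unknown level for context '", tk$name, "'")
      m
    } else {
      as.numeric(unlist(vals))
    }
  })
}

# one epoch pass over `rows`; returns mean combined loss, updates if opt
context_pass <- function(model, data, targets, rows, batch_size,
                         opt = NULL, lr = NULL) {
  total <- 0; nb <- 0L
  params <- if (!is.null(opt)) opt$params else NULL
  for (st in seq(1L, length(rows), by = batch_size)) {
    bi <- rows[st:min(st + batch_size - 1L, length(rows))]
    feats <- featurize_trace(model, data$idx[bi, , drop = FALSE],
                             data$diffs[bi, , drop = FALSE],
                             data$lens[bi], training = !is.null(opt))
    preds <- context_forward(model, feats)
    loss <- NULL
    for (i in seq_along(model$schema$tasks)) {
      tk <- model$schema$tasks[[i]]
      hd <- model$heads[[i]]
      p <- preds[[tk$name]]
      li <- if (tk$kind == "categorical") {
        onehot <- matrix(0, length(bi), length(tk$levels))
        onehot[cbind(seq_along(bi), targets[[i]][bi])] <- 1
        ad_scale(ad_sum(ad_mul(ad_const(onehot),
                               ad_log(p, eps = LOG_EPS))),
                 -1 / length(bi))
      } else {
        gap <- ad_sub(p, ad_const(matrix(targets[[i]][bi], ncol = 1L)))
        ad_scale(ad_sum(ad_mul(gap, gap)), 1 / length(bi))
      }
      # exp(-s) * L_i + s with learnable s
      s <- hd$log_sigma2
      wli <- ad_add(ad_mul(ad_op(exp(-s$value), list(s), function(g) {
        list(-g * exp(-s$value))
      }), li), s)
      loss <- if (is.null(loss)) wli else ad_add(loss, wli)
    }
    if (!is.null(opt)) {
      ad_zero_grad(params)
      ad_backward(loss)
      adam_step(opt, lr = lr)
    }
    total <- total + as.numeric(loss$value); nb <- nb + 1L
  }
  total / nb
}

context_predict <- function(model, data, rows) {
  with_no_grad(list(model), {
    feats <- featurize_trace(model, data$idx[rows, , drop = FALSE],
                             data$diffs[rows, , drop = FALSE],
                             data$lens[rows], training = FALSE)
    preds <- context_forward(model, feats)
    lapply(seq_along(model$schema$tasks), function(i) {
      tk <- model$schema$tasks[[i]]
      v <- preds[[tk$name]]$value
      if (tk$kind == "categorical") max.col(v, ties.method = "first")
      else as.numeric(v)
    })
  })
}

fit_context_once <- function(schema, cfg, data, targets, tr, va) {
  model <- init_context_model(schema, cfg)
  opt <- adam_init(model_params(model), lr = cfg$lr,
                   beta1 = cfg$betas[1L], beta2 = cfg$betas[2L])
  best <- Inf; best_w <- snapshot_weights(model); stall <- 0L
  for (ep in seq_len(cfg$max_epochs)) {
    lr <- cfg$lr * cfg$lr_decay_factor^((ep - 1L) %/% cfg$lr_decay_every)
    context_pass(model, data, targets, sample(tr), cfg$batch_size,
                 opt = opt, lr = lr)
    va_loss <- with_no_grad(list(model), {
      context_pass(model, data, targets, va, cfg$batch_size)
    })
    if (va_loss < best - 1e-6) {
      best <- va_loss; best_w <- snapshot_weights(model); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  restore_weights(model, best_w)
  model
}

#' Train the multi-task context generator
#'
#' K-fold cross-validation (default 5): for each fold a fresh model is
#' trained on the remaining folds with early stopping on the fold's
#' validation loss, and per-task metrics (weighted precision/recall/F1 for
#' categorical tasks, RMSE for numerical ones) are computed on the held-out
#' fold.  A final model is then trained on all cases (with an internal 20%
#' early-stop split) and returned for inference.
#'
#' @param log Authentic `event_log` whose every case carries all schema
#'   contexts.
#' @param schema A `context_schema`.
#' @param cfg A `context_model_config`; when `NULL` a default encoder is
#'   derived from the log.
#' @return List with the final `model`, `metrics` (per fold x task), and
#'   `summary` (per-task means over folds).
#' @export
train_context_generator <- function(log, schema, cfg = NULL) {
  if (is.null(cfg)) {
    max_len <- max(case_lengths(log))
    cfg <- context_model_config(
      seq_encoder_config(length(log$vocabulary$labels), max_len))
  }
  set.seed(cfg$seed)
  data <- encode_for_context(log, log$vocabulary, cfg$encoder$max_len)
  targets <- context_targets(log, schema)
  N <- length(log$cases)
  fold_id <- sample(rep_len(seq_len(cfg$folds), N))

  metrics <- list()
  for (fold in seq_len(cfg$folds)) {
    va <- which(fold_id == fold); tr <- which(fold_id != fold)
    model <- fit_context_once(schema, cfg, data, targets, tr, va)
    preds <- context_predict(model, data, va)
    for (i in seq_along(schema$tasks)) {
      tk <- schema$tasks[[i]]
      row <- if (tk$kind == "categorical") {
        truth <- tk$levels[targets[[i]][va]]
        pred <- tk$levels[preds[[i]]]
        as.list(weighted_prf(truth, pred))
      } else {
        list(rmse = sqrt(mean((targets[[i]][va] - preds[[i]])^2)))
      }
      metrics[[length(metrics) + 1L]] <-
        c(list(fold = fold, task = tk$name, kind = tk$kind), row)
    }
  }
  mdf <- do.call(rbind, lapply(metrics, function(m) {
    as.data.frame(m, stringsAsFactors = FALSE)
  }))

  # final model on all data with an internal early-stop split
  va <- sample.int(N, max(2L, round(0.2 * N)))
  tr <- setdiff(seq_len(N), va)
  final <- fit_context_once(schema, cfg, data, targets, tr, va)
  final$vocab <- log$vocabulary

  summ <- stats::aggregate(mdf[, setdiff(names(mdf),
                                         c("fold", "task", "kind")),
                               drop = FALSE],
                           by = list(task = mdf$task), FUN = mean)
  list(model = final, metrics = mdf, summary = summ)
}

#' Infer contexts for a synthetic log
#'
#' Attaches the argmax level (categorical) or predicted value (numerical)
#' of every schema task to every case, and reports the aggregate predicted
#' level distribution per task.
#'
#' @param fit Result of [train_context_generator()] (or a `context_model`).
#' @param synthetic A synthetic `event_log` over the same vocabulary.
#' @return List with `log` (contexts attached) and `distributions` (named
#'   list of per-task level proportions).
#' @export
infer_contexts <- function(fit, synthetic) {
  model <- if (inherits(fit, "context_model")) fit else fit$model
  schema <- model$schema
  data <- encode_for_context(synthetic, model$vocab,
                             model$cfg$encoder$max_len)
  preds <- context_predict(model, data, seq_along(synthetic$cases))
  cases <- synthetic$cases
  for (i in seq_along(cases)) {
    ctx <- as.list(cases[[i]]$contexts)
    for (t in seq_along(schema$tasks)) {
      tk <- schema$tasks[[t]]
      ctx[[tk$name]] <- if (tk$kind == "categorical")
        tk$levels[preds[[t]][i]] else preds[[t]][i]
    }
    cases[[i]]$contexts <- ctx
  }
  dists <- stats::setNames(lapply(seq_along(schema$tasks), function(t) {
    tk <- schema$tasks[[t]]
    if (tk$kind == "categorical") {
      tab <- table(factor(tk$levels[preds[[t]]], levels = tk$levels))
      as.numeric(tab) / sum(tab)
    } else {
      c(mean = mean(preds[[t]]), sd = stats::sd(preds[[t]]))
    }
  }), vapply(schema$tasks, `[[`, "", "name"))
  out <- synthetic
  out$cases <- cases
  list(log = out, distributions = dists)
}

#' ZeroR baseline: always predict the majority class
#'
#' @param truth_train,truth_test Label vectors.
#' @return Weighted precision/recall/F1 on the test labels.
#' @export
baseline_zeror <- function(truth_train, truth_test) {
  maj <- names(sort(table(truth_train), decreasing = TRUE))[1L]
  weighted_prf(truth_test, rep(maj, length(truth_test)))
}

#' Uniform-random baseline
#'
#' @param levels Candidate levels.
#' @param truth_test Label vector.
#' @param seed Integer seed.
#' @return Weighted precision/recall/F1.
#' @export
baseline_random <- function(levels, truth_test, seed = 1L) {
  set.seed(seed)
  weighted_prf(truth_test, sample(levels, length(truth_test),
                                  replace = TRUE))
}
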