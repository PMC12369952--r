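# Shared transformer sequence encoder.
#
# Both the supervised realism scorer and the multi-task context generator
# embed a trace the same way: per-position activity embedding with the
# timestamp differential appended, projected to the encoder width, plus
# sinusoidal positions, through standard self-attention blocks, then
# mean-pooled over positions.  The pooled embedding is concatenated with
# the within-case activity frequency distribution and the (scaled)
# sequence length.

#' Sequence encoder configuration
#'
#' @param vocab_size Vocabulary size including pad.
#' @param max_len Maximum sequence length.
#' @param embedding_size Activity embedding width.
#' @param hidden_size Encoder width; divisible by `n_heads`.
#' @param n_heads,n_layers Attention shape.
#' @param dropout Dropout rate.
#' @return A `seq_encoder_config`.
#' @export
seq_encoder_config <- function(vocab_size, max_len, embedding_size = 8L,
                               hidden_size = 32L, n_heads = 2L,
                               n_layers = 1L, dropout = 0.1) {
  stopifnot(hidden_size %% n_heads == 0L)
  structure(list(vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len),
                 embedding_size = as.integer(embedding_size),
                 hidden_size = as.integer(hidden_size),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 dropout = dropout),
            class = "seq_encoder_config")
}

init_seq_encoder <- function(cfg) {
  h <- cfg$hidden_size
  layers <- lapply(seq_len(cfg$n_layers), function(i) {
    list(wq = ad_param(glorot(h, h)), wk = ad_param(glorot(h, h)),
         wv = ad_param(glorot(h, h)), wo = ad_param(glorot(h, h)),
         bo = ad_param(zeros_row(h)),
         ln1_g = ad_param(matrix(1, 1L, h)), ln1_b = ad_param(zeros_row(h)),
         w1 = ad_param(glorot(h, h)), b1 = ad_param(zeros_row(h)),
         w2 = ad_param(glorot(h, h)), b2 = ad_param(zeros_row(h)),
         ln2_g = ad_param(matrix(1, 1L, h)), ln2_b = ad_param(zeros_row(h)))
  })
  list(cfg = cfg,
       emb = ad_param(glorot(cfg$vocab_size, cfg$embedding_size)),
       w_in = ad_param(glorot(cfg$embedding_size + 1L, h)),
       b_in = ad_param(zeros_row(h)),
       pos = sinusoidal_pe(cfg$max_len, h),
       layers = layers)
}

# pooled embedding node (B x hidden) from index + differential matrices
seq_encoder_forward <- function(encd, idx, diffs, training = FALSE) {
  cfg <- encd$cfg
  B <- nrow(idx); l <- cfg$max_len
  x <- ad_embed(encd$emb, as.integer(t(idx)))
  x <- ad_cbind_const(x, matrix(as.numeric(t(diffs)), ncol = 1L))
  x <- ad_add_rowvec(ad_matmul(x, encd$w_in), encd$b_in)
  x <- ad_add(x, ad_const(encd$pos[rep(seq_len(l), B), , drop = FALSE]))
  for (ly in encd$layers) {
    a <- ad_mha(x, ly$wq, ly$wk, ly$wv, B, l, cfg$n_heads)
    a <- ad_add_rowvec(ad_matmul(a, ly$wo), ly$bo)
    a <- ad_dropout(a, cfg$dropout, training)
    x <- ad_layernorm_rows(ad_add(x, a), ly$ln1_g, ly$ln1_b)
    f <- ad_add_rowvec(ad_matmul(x, ly$w1), ly$b1)
    f <- ad_add_rowvec(ad_matmul(ad_relu(f), ly$w2), ly$b2)
    f <- ad_dropout(f, cfg$dropout, training)
    x <- ad_layernorm_rows(ad_add(x, f), ly$ln2_g, ly$ln2_b)
  }
  ad_pool_mean(x, B, l)
}

# activity frequency distribution (over real labels, rows sum to 1) plus
# scaled sequence length, per case
trace_side_features <- function(idx, lengths, n_real, max_len) {
  B <- nrow(idx)
  freq <- matrix(0, B, n_real)
  for (i in seq_len(B)) {
    tab <- tabulate(idx[i, seq_len(lengths[i])], nbins = n_real)
    freq[i, ] <- tab / lengths[i]
  }
  cbind(freq, lengths / max_len)
}

#' Weighted precision, recall and F1
#'
#' Per-class scores weighted by class support in the truth (the convention
#' for imbalanced labels); undefined per-class values count as 0.
#'
#' @param truth,pred Vectors of class labels.
#' @return Named numeric `c(precision, recall, f1)`.
#' @export
weighted_prf <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(truth))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  prec <- rec <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  w <- support / sum(support)
  c(precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1))
}
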