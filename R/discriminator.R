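# Time-aware multi-head self-attention discriminator.
#
# Scores an encoded case as authentic vs synthetic from the interactions
# among activities, timestamp differentials, and the pairwise time-interval
# matrix.  Each scalar timestamp value and interval is mapped through its
# own learned linear map into the attention key/value spaces; the
# compatibility is
#   e_ij = (a_i W^Q) . (a_j W^K + dt^k_ij + ts^k_j) / sqrt(d_h)
# and the feature f_i = sum_j alpha_ij (a_j W^V + dt^v_ij + ts^v_j),
# computed per head on d/n_heads-dimensional slices and concatenated.
# Each attention layer is followed by the block
#   FFN1(ReLU(f)) + Dropout(FFN2(LayerNorm(f)))
# as printed (two separate feed-forward parameter sets).  The final
# features are mean-pooled over positions, passed through a feed-forward
# layer and a logistic link.
#
# With `time_aware = FALSE` the time projections and interval attention are
# dropped entirely and the differentials plus interval-matrix rows are
# concatenated onto the activity one-hots, feeding a vanilla
# transformer-encoder discriminator (the "w/o attention" ablation).

#' Discriminator configuration
#'
#' @param vocab_size Vocabulary size including pad.
#' @param max_len Maximum sequence length.
#' @param hidden_size Attention width `d`; divisible by `n_heads`.
#' @param n_heads Attention heads.
#' @param n_layers Attention + block stacks.
#' @param dropout Dropout rate.
#' @param time_aware If `FALSE`, use the concatenated-feature ablation.
#' @return A `discriminator_config`.
#' @export
discriminator_config <- function(vocab_size, max_len,
                                 hidden_size = 8L, n_heads = 2L,
                                 n_layers = 2L, dropout = 0.5,
                                 time_aware = TRUE) {
  stopifnot(hidden_size %% n_heads == 0L, dropout >= 0, dropout < 1)
  structure(list(vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len),
                 hidden_size = as.integer(hidden_size),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 dropout = dropout, time_aware = isTRUE(time_aware)),
            class = "discriminator_config")
}

#' Initialize discriminator weights
#'
#' @param cfg A `discriminator_config`.
#' @param seed Integer seed.
#' @return A `discriminator` object.
#' @export
init_discriminator <- function(cfg, seed = 1L) {
  set.seed(seed)
  d <- cfg$hidden_size
  d_in1 <- if (cfg$time_aware) cfg$vocab_size else
    cfg$vocab_size + 1L + cfg$max_len
  layers <- lapply(seq_len(cfg$n_layers), function(i) {
    din <- if (i == 1L) d_in1 else d
    ly <- list(wq = ad_param(glorot(din, d)), wk = ad_param(glorot(din, d)),
               wv = ad_param(glorot(din, d)),
               wf1 = ad_param(glorot(d, d)), bf1 = ad_param(zeros_row(d)),
               wf2 = ad_param(glorot(d, d)), bf2 = ad_param(zeros_row(d)),
               ln_g = ad_param(matrix(1, 1L, d)),
               ln_b = ad_param(zeros_row(d)))
    if (cfg$time_aware) {
      ly <- c(ly, list(
        w_tsk = ad_param(glorot(1L, d)), b_tsk = ad_param(zeros_row(d)),
        w_tsv = ad_param(glorot(1L, d)), b_tsv = ad_param(zeros_row(d)),
        w_mk = ad_param(glorot(1L, d)), b_mk = ad_param(zeros_row(d)),
        w_mv = ad_param(glorot(1L, d)), b_mv = ad_param(zeros_row(d))))
    }
    ly
  })
  disc <- list(cfg = cfg, layers = layers,
               w_out = ad_param(glorot(d, 1L)),
               b_out = ad_param(zeros_row(1L)))
  class(disc) <- "discriminator"
  disc
}

#' Project scalar time features into attention key/value space
#'
#' Maps each timestamp differential and each pairwise interval through its
#' own learned linear map (scalar to d-vector), four independent parameter
#' sets in total.
#'
#' @param differentials Length-`l` differential sequence.
#' @param M `l x l` time-interval matrix.
#' @param params Named list with `w_tsk`, `b_tsk`, `w_tsv`, `b_tsv`,
#'   `w_mk`, `b_mk`, `w_mv`, `b_mv` (numeric `1 x d` each).
#' @return List with `ts_k`, `ts_v` (`l x d`) and `M_k`, `M_v`
#'   (`l x l x d` arrays).
#' @export
project_time_features <- function(differentials, M, params) {
  p <- lapply(params, ad_value)
  l <- length(differentials)
  d <- ncol(p$w_tsk)
  lin_vec <- function(x, w, b) sweep(outer(x, as.numeric(w)), 2L,
                                     as.numeric(b), "+")
  lin_mat <- function(Mm, w, b) {
    out <- array(0, c(l, l, d))
    for (k in seq_len(d)) out[, , k] <- Mm * as.numeric(w)[k] +
        as.numeric(b)[k]
    out
  }
  list(ts_k = lin_vec(differentials, p$w_tsk, p$b_tsk),
       ts_v = lin_vec(differentials, p$w_tsv, p$b_tsv),
       M_k = lin_mat(M, p$w_mk, p$b_mk),
       M_v = lin_mat(M, p$w_mv, p$b_mv))
}

#' Time-aware self-attention over one encoded case
#'
#' Evaluation-mode forward of a single attention layer; mainly useful for
#' inspection and for verifying the reduction to plain scaled dot-product
#' attention when all time projections are zero.
#'
#' @param activity_onehot `l x N_v` one-hot matrix (or feature matrix).
#' @param differentials Length-`l` differential sequence.
#' @param params Layer parameter list (`wq`, `wk`, `wv` plus the eight time
#'   projections), numeric matrices or nodes.
#' @param n_heads Number of heads.
#' @return The `l x d` time-aware feature matrix `F`.
#' @export
time_aware_attention <- function(activity_onehot, differentials, params,
                                 n_heads = 1L) {
  p <- lapply(params, function(x) ad_const(ad_value(x)))
  out <- ad_time_mha(ad_const(activity_onehot),
                     ad_const(matrix(differentials, nrow = 1L)),
                     p$wq, p$wk, p$wv,
                     p$w_tsk, p$b_tsk, p$w_tsv, p$b_tsv,
                     p$w_mk, p$b_mk, p$w_mv, p$b_mv,
                     n_case = 1L, len = nrow(activity_onehot),
                     n_heads = n_heads)
  out$value
}

# one attention + block stack (autodiff path); x and diffs may be nodes
disc_layer_forward <- function(ly, x, diffs, n_case, len, n_heads,
                               dropout, training, time_aware) {
  att <- if (time_aware) {
    ad_time_mha(x, diffs, ly$wq, ly$wk, ly$wv,
                ly$w_tsk, ly$b_tsk, ly$w_tsv, ly$b_tsv,
                ly$w_mk, ly$b_mk, ly$w_mv, ly$b_mv,
                n_case, len, n_heads)
  } else {
    ad_mha(x, ly$wq, ly$wk, ly$wv, n_case, len, n_heads)
  }
  h1 <- ad_add_rowvec(ad_matmul(ad_relu(att), ly$wf1), ly$bf1)
  h2 <- ad_layernorm_rows(att, ly$ln_g, ly$ln_b)
  h2 <- ad_add_rowvec(ad_matmul(h2, ly$wf2), ly$bf2)
  h2 <- ad_dropout(h2, dropout, training)
  ad_add(h1, h2)
}

#' Discriminator block applied to a feature matrix
#'
#' Evaluation-mode forward of the post-attention composition
#' `FFN1(ReLU(F)) + FFN2(LayerNorm(F))` (dropout disabled).
#'
#' @param f `l x d` feature matrix.
#' @param params Layer parameter list (`wf1`, `bf1`, `wf2`, `bf2`, `ln_g`,
#'   `ln_b`).
#' @return Matrix of the same shape.
#' @export
discriminator_block <- function(f, params) {
  p <- lapply(params, function(x) ad_const(ad_value(x)))
  h1 <- ad_add_rowvec(ad_matmul(ad_relu(ad_const(f)), p$wf1), p$bf1)
  h2 <- ad_layernorm_rows(ad_const(f), p$ln_g, p$ln_b)
  h2 <- ad_add_rowvec(ad_matmul(h2, p$wf2), p$bf2)
  (ad_add(h1, h2))$value
}

#' Discriminator forward pass
#'
#' @param disc A `discriminator`.
#' @param onehot Stacked `B*l x N_v` one-hot matrix (or node).
#' @param diffs `B x l` differential matrix (or node).
#' @param n_case Number of cases `B`.
#' @param training If `TRUE`, dropout is active.
#' @return A `B x 1` node of authenticity probabilities in (0, 1); the
#'   numeric scores are in `$value`.
#' @export
discriminator_forward <- function(disc, onehot, diffs, n_case,
                                  training = FALSE) {
  cfg <- disc$cfg
  l <- cfg$max_len
  x <- if (is_ad_node(onehot)) onehot else ad_const(onehot)
  dnode <- if (is_ad_node(diffs)) diffs else ad_const(diffs)
  if (!cfg$time_aware) {
    x <- ad_cbind2(x, ad_time_features(dnode, n_case, l))
  }
  for (ly in disc$layers) {
    x <- disc_layer_forward(ly, x, dnode, n_case, l, cfg$n_heads,
                            cfg$dropout, training, cfg$time_aware)
  }
  pooled <- ad_pool_mean(x, n_case, l)
  ad_sigmoid(ad_add_rowvec(ad_matmul(pooled, disc$w_out), disc$b_out))
}

#' Numeric discriminator scores for an encoded batch
#'
#' Convenience evaluation-mode wrapper returning a plain numeric vector.
#'
#' @inheritParams discriminator_forward
#' @return Numeric vector of length `n_case`.
#' @export
discriminator_score <- function(disc, onehot, diffs, n_case) {
  with_no_grad(list(disc), {
    as.numeric(discriminator_forward(disc, ad_value(onehot),
                                     ad_value(diffs), n_case,
                                     training = FALSE)$value)
  })
}
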