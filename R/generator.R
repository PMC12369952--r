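# Conditional transformer-encoder generator.
#
# Input: a random activity index sequence Z (uniform over the real
# vocabulary) and a conditional case duration T in [0, 1] sampled from the
# authentic durations.  The scalar T is concatenated onto every position's
# activity embedding, projected to the encoder width, combined with a fixed
# sinusoidal positional encoding, and run through standard multi-head
# self-attention blocks.  Two decoder heads emit (a) per-position activity
# probability rows over the vocabulary (pad included -- pad positions
# define the generated length) and (b) a timestamp differential per
# position, ReLU-activated and min-max rescaled into [0, 1] per sequence
# with position 1 pinned at 0.

#' Generator configuration
#'
#' @param vocab_size Vocabulary size including the pad token.
#' @param max_len Maximum sequence length `l`.
#' @param embedding_size Activity embedding width (`N_emb`).
#' @param hidden_size Encoder width; must be divisible by `n_heads`.
#' @param n_heads Attention heads.
#' @param n_layers Encoder layers.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param temperature Gumbel-softmax temperature (> 0).
#' @param sum_to_one After the ReLU + per-sequence min-max rescale, L1
#'   normalize the differential row so it sums to 1, matching the
#'   telescoping-sum convention of authentic differentials (otherwise the
#'   min-max alone plants an exact 1.0 in every synthetic sequence, a
#'   trivially separable artifact; see the methods vignette).
#' @return A `generator_config`.
#' @export
generator_config <- function(vocab_size, max_len,
                             embedding_size = 4L, hidden_size = 64L,
                             n_heads = 4L, n_layers = 3L,
                             dropout = 0.1, temperature = 1,
                             sum_to_one = TRUE) {
  stopifnot(hidden_size %% n_heads == 0L, temperature > 0,
            dropout >= 0, dropout < 1, embedding_size >= 1L,
            n_layers >= 1L, max_len >= 1L, vocab_size >= 2L)
  structure(list(vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len),
                 embedding_size = as.integer(embedding_size),
                 hidden_size = as.integer(hidden_size),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 dropout = dropout, temperature = temperature,
                 sum_to_one = isTRUE(sum_to_one)),
            class = "generator_config")
}

sinusoidal_pe <- function(max_len, d) {
  pe <- matrix(0, max_len, d)
  pos <- seq_len(max_len) - 1L
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pe[, 2L * i - 1L] <- sin(pos * freq)
    if (2L * i <= d) pe[, 2L * i] <- cos(pos * freq)
  }
  pe
}

#' Initialize generator weights
#'
#' @param cfg A `generator_config`.
#' @param seed Integer seed for the Glorot-uniform initialization.
#' @return A `generator` object holding parameter nodes.
#' @export
init_generator <- function(cfg, seed = 1L) {
  set.seed(seed)
  h <- cfg$hidden_size; e <- cfg$embedding_size; nv <- cfg$vocab_size
  layers <- lapply(seq_len(cfg$n_layers), function(i) {
    list(wq = ad_param(glorot(h, h)), wk = ad_param(glorot(h, h)),
         wv = ad_param(glorot(h, h)), wo = ad_param(glorot(h, h)),
         bo = ad_param(zeros_row(h)),
         ln1_g = ad_param(matrix(1, 1L, h)), ln1_b = ad_param(zeros_row(h)),
         w1 = ad_param(glorot(h, h)), b1 = ad_param(zeros_row(h)),
         w2 = ad_param(glorot(h, h)), b2 = ad_param(zeros_row(h)),
         ln2_g = ad_param(matrix(1, 1L, h)), ln2_b = ad_param(zeros_row(h)))
  })
  gen <- list(cfg = cfg,
              emb = ad_param(glorot(nv, e)),
              w_in = ad_param(glorot(e + 1L, h)),
              b_in = ad_param(zeros_row(h)),
              pos = sinusoidal_pe(cfg$max_len, h),
              layers = layers,
              w_act = ad_param(glorot(h, nv)),
              b_act = ad_param(zeros_row(nv)),
              w_time = ad_param(glorot(h, 1L)),
              # positive bias keeps the ReLU of the time head alive at the
              # start of training (a dead head emits all-zero differentials
              # and receives no gradient through the flat min-max)
              b_time = ad_param(matrix(0.5, 1L, 1L)))
  class(gen) <- "generator"
  gen
}

#' Flat list of a model's parameter nodes
#' @param model A `generator`, `discriminator`, or similar parameter tree.
#' @return List of `ad_node` parameters.
#' @export
model_params <- function(model) {
  out <- list()
  walk <- function(x) {
    if (is_ad_node(x)) {
      if (x$requires_grad) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(model)
  out
}

# temporarily disable gradient tracking on a model's parameters
with_no_grad <- function(models, expr) {
  ps <- unlist(lapply(models, model_params), recursive = FALSE)
  for (p in ps) p$requires_grad <- FALSE
  on.exit(for (p in ps) p$requires_grad <- TRUE)
  force(expr)
}

#' Sample random generator input sequences
#'
#' Indices are drawn i.i.d. uniformly from the real (non-pad) labels.
#'
#' @param vocab Activity vocabulary.
#' @param max_len Sequence length.
#' @param n Number of sequences.
#' @return An `n x max_len` integer matrix.
#' @export
sample_random_input <- function(vocab, max_len, n = 1L) {
  matrix(sample.int(vocab$n_real, n * max_len, replace = TRUE),
         n, max_len)
}

#' Sample conditional durations from a log
#'
#' Draws authentic case durations uniformly with replacement.
#'
#' @param log An `event_log`.
#' @param n Number of draws.
#' @return List with `duration_norm` and `duration_real` vectors.
#' @export
sample_conditional_duration <- function(log, n = 1L) {
  durs <- case_durations(log)
  pick <- durs[sample.int(length(durs), n, replace = TRUE)]
  list(duration_norm = normalize_duration(pick, log$duration_bounds),
       duration_real = pick)
}

#' Generator forward pass
#'
#' @param gen A `generator`.
#' @param z `B x l` integer matrix of input indices.
#' @param t_norm Length-`B` vector of normalized conditional durations.
#' @param training If `TRUE`, dropout is active (stochastic via the global
#'   RNG); evaluation mode is deterministic.
#' @return List with `logits` (`B*l x N_v` node), `activity_probs`
#'   (numeric, rows on the simplex), `diffs` (`B x l` node of differentials
#'   in `[0, 1]`, position 1 = 0), and `duration_norm` echoed back.
#' @export
generator_forward <- function(gen, z, t_norm, training = FALSE) {
  cfg <- gen$cfg
  B <- nrow(z); l <- cfg$max_len
  stopifnot(ncol(z) == l, length(t_norm) == B,
            all(t_norm >= 0), all(t_norm <= 1))
  x <- ad_embed(gen$emb, as.integer(t(z)))
  x <- ad_cbind_const(x, matrix(rep(t_norm, each = l), ncol = 1L))
  x <- ad_add_rowvec(ad_matmul(x, gen$w_in), gen$b_in)
  x <- ad_add(x, ad_const(gen$pos[rep(seq_len(l), B), , drop = FALSE]))
  for (ly in gen$layers) {
    a <- ad_mha(x, ly$wq, ly$wk, ly$wv, B, l, cfg$n_heads)
    a <- ad_add_rowvec(ad_matmul(a, ly$wo), ly$bo)
    a <- ad_dropout(a, cfg$dropout, training)
    x <- ad_layernorm_rows(ad_add(x, a), ly$ln1_g, ly$ln1_b)
    f <- ad_add_rowvec(ad_matmul(x, ly$w1), ly$b1)
    f <- ad_add_rowvec(ad_matmul(ad_relu(f), ly$w2), ly$b2)
    f <- ad_dropout(f, cfg$dropout, training)
    x <- ad_layernorm_rows(ad_add(x, f), ly$ln2_g, ly$ln2_b)
  }
  logits <- ad_add_rowvec(ad_matmul(x, gen$w_act), gen$b_act)
  tcol <- ad_add_rowvec(ad_matmul(x, gen$w_time), gen$b_time)
  diffs <- ad_minmax_rows(ad_relu(ad_stack_to_rows(tcol, B, l)),
                          force_first_zero = TRUE)
  if (isTRUE(cfg$sum_to_one)) diffs <- ad_rownorm(diffs)
  probs <- {
    v <- logits$value
    v <- v - apply(v, 1L, max)
    ev <- exp(v); ev / rowSums(ev)
  }
  list(logits = logits, activity_probs = probs, diffs = diffs,
       duration_norm = t_norm, n_case = B)
}

#' Straight-through Gumbel-softmax sampling
#'
#' Forward value is the exact one-hot of `argmax(logits + gumbel)`; inside
#' the training graph the gradient of downstream losses with respect to the
#' logits is that of the temperature-softmax relaxation at the same
#' perturbed logits (the straight-through contract).
#'
#' @param logits Numeric matrix of per-row logits (or an `ad_node`).
#' @param temperature Softmax temperature (> 0).
#' @param gumbel Optional pre-drawn Gumbel noise matrix (for
#'   reproducibility); defaults to fresh draws from the global RNG.
#' @return For numeric input, the one-hot matrix; for node input, a node.
#' @export
gumbel_straight_through <- function(logits, temperature = 1, gumbel = NULL) {
  stopifnot(temperature > 0)
  v <- ad_value(logits)
  if (is.null(gumbel)) {
    gumbel <- matrix(-log(-log(stats::runif(length(v)))), nrow(v), ncol(v))
  }
  node <- ad_gumbel_st(if (is_ad_node(logits)) logits else ad_const(v),
                       gumbel, temperature)
  if (is_ad_node(logits)) node else node$value
}
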