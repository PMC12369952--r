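rand_time_params <- function(din, d, seed = 1L, zero_time = FALSE) {
  set.seed(seed)
  tp <- function() if (zero_time) matrix(0, 1, d) else
    matrix(rnorm(d) * 0.5, 1, d)
  list(wq = matrix(rnorm(din * d) * 0.5, din, d),
       wk = matrix(rnorm(din * d) * 0.5, din, d),
       wv = matrix(rnorm(din * d) * 0.5, din, d),
       w_tsk = tp(), b_tsk = tp(), w_tsv = tp(), b_tsv = tp(),
       w_mk = tp(), b_mk = tp(), w_mv = tp(), b_mv = tp())
}

test_that("time projections are linear in their scalar inputs", {
  d <- 6L; l <- 4L
  pars <- rand_time_params(3L, d, seed = 2L)
  zero_bias <- pars
  for (nm in c("b_tsk", "b_tsv", "b_mk", "b_mv")) {
    zero_bias[[nm]] <- matrix(0, 1, d)
  }
  diffs <- c(0, 0.2, 0.3, 0.5)
  M <- build_time_interval_matrix(diffs)
  # zero inputs with zero bias give zero projections
  pz <- project_time_features(rep(0, l), matrix(0, l, l), zero_bias)
  expect_equal(pz$ts_k, matrix(0, l, d))
  expect_true(all(pz$M_v == 0))
  # antisymmetry of M carries through zero-bias projections
  pm <- project_time_features(diffs, M, zero_bias)
  for (k in seq_len(d)) {
    expect_equal(pm$M_k[, , k], -t(pm$M_k[, , k]))
  }
  # homogeneity: doubling inputs doubles zero-bias projections
  p2 <- project_time_features(2 * diffs, 2 * M, zero_bias)
  expect_equal(p2$ts_v, 2 * pm$ts_v)
  expect_equal(p2$M_k, 2 * pm$M_k)
})

test_that("single-position attention collapses to its only summand", {
  d <- 4L
  pars <- rand_time_params(3L, d, seed = 3L)
  a1 <- c(1, 0, 0)
  f <- time_aware_attention(matrix(a1, 1), 0, pars, n_heads = 1L)
  tsv <- as.numeric(pars$w_tsv) * 0 + as.numeric(pars$b_tsv)
  mv <- as.numeric(pars$w_mv) * 0 + as.numeric(pars$b_mv)
  expect_equal(as.numeric(f),
               as.numeric(a1 %*% pars$wv) + tsv + mv,
               tolerance = 1e-12)
})

test_that("zeroed time projections reduce to plain attention (100 instances)", {
  set.seed(44)
  for (trial in 1:100) {
    l <- sample(2:8, 1)
    nv <- sample(3:6, 1)
    d <- 4L
    pars <- rand_time_params(nv, d, seed = 1000L + trial, zero_time = TRUE)
    onehot <- diag(nv)[sample.int(nv, l, replace = TRUE), , drop = FALSE]
    diffs <- c(0, runif(l - 1, 0, 0.5))[seq_len(l)]
    f <- time_aware_attention(onehot, diffs, pars, n_heads = 2L)
    oracle <- plain_attention_oracle(onehot, pars$wq, pars$wk, pars$wv, 2L)
    expect_lt(max(abs(f - oracle)), 1e-6)
  }
})

test_that("zero query weights give uniform attention", {
  l <- 5L; d <- 4L
  pars <- rand_time_params(3L, d, seed = 5L)
  pars$wq <- matrix(0, 3L, d)   # e rows constant when q = 0
  pars$w_mv <- matrix(0, 1, d)  # drop the i-dependent interval value term
  onehot <- diag(3)[c(1, 2, 3, 1, 2), ]
  diffs <- c(0, 0.1, 0.2, 0.3, 0.4)
  f <- time_aware_attention(onehot, diffs, pars, n_heads = 1L)
  # uniform alpha: f_i identical for all i
  expect_lt(max(abs(sweep(f, 2, f[1, ]))), 1e-10)
})

test_that("discriminator block composes FFN(ReLU) + FFN(LayerNorm)", {
  d <- 4L
  set.seed(6)
  f <- matrix(rnorm(12), 3, d)
  pars <- list(wf1 = diag(d), bf1 = matrix(0, 1, d),
               wf2 = diag(d), bf2 = matrix(0, 1, d),
               ln_g = matrix(1, 1, d), ln_b = matrix(0, 1, d))
  out <- discriminator_block(f, pars)
  mu <- rowMeans(f); xc <- f - mu
  ln <- xc / sqrt(rowMeans(xc^2) + 1e-5)
  expect_equal(out, pmax(f, 0) + ln, tolerance = 1e-12)
  expect_equal(dim(out), dim(f))
  expect_identical(out, discriminator_block(f, pars))
})

test_that("discriminator scores are probabilities, ~0.5 for random weights", {
  vocab_size <- 5L; l <- 6L
  set.seed(7)
  scores <- numeric(0)
  for (rep in 1:20) {
    disc <- init_discriminator(
      discriminator_config(vocab_size, l, hidden_size = 6L, n_heads = 2L,
                           n_layers = 2L), seed = 200L + rep)
    n <- 25L
    onehot <- diag(vocab_size)[sample.int(vocab_size, n * l,
                                          replace = TRUE), ]
    diffs <- matrix(runif(n * l, 0, 0.3), n, l); diffs[, 1] <- 0
    sc <- discriminator_score(disc, onehot, diffs, n)
    expect_true(all(sc > 0 & sc < 1))
    # deterministic in evaluation mode
    expect_identical(sc, discriminator_score(disc, onehot, diffs, n))
    scores <- c(scores, sc)
  }
  expect_lt(abs(mean(scores) - 0.5), 0.1)  # 500 random cases, 20 inits
})

test_that("the ablation discriminator consumes concatenated time features", {
  disc <- init_discriminator(
    discriminator_config(4L, 5L, hidden_size = 4L, n_heads = 2L,
                         n_layers = 1L, time_aware = FALSE), seed = 9L)
  onehot <- diag(4)[sample.int(4, 10, replace = TRUE), ]
  diffs <- matrix(runif(10, 0, 0.2), 2, 5); diffs[, 1] <- 0
  sc <- discriminator_score(disc, onehot, diffs, 2L)
  expect_length(sc, 2L)
  expect_true(all(sc > 0 & sc < 1))
  # timestamps now reach the score through the concatenated features
  diffs2 <- diffs * 0.5
  expect_false(isTRUE(all.equal(sc,
                                discriminator_score(disc, onehot, diffs2,
                                                    2L))))
})

test_that("the discriminator learns a trivially separable timing signal", {
  # authentic: evenly increasing differentials; fakes: same activities with
  # shuffled (non-monotone cumulative) timing mass at position 2
  set.seed(12)
  l <- 6L; nv <- 4L; n <- 24L
  onehot_seq <- function() diag(nv)[sample.int(nv - 1L, l, replace = TRUE), ]
  auth_d <- function() { d <- c(0, sort(runif(l - 1, 0, 1))); d / sum(d) }
  fake_d <- function() { d <- c(0, sort(runif(l - 1, 0, 1),
                                        decreasing = TRUE)); d / sum(d) }
  oh <- do.call(rbind, replicate(2 * n, onehot_seq(), simplify = FALSE))
  diffs <- rbind(t(replicate(n, auth_d())), t(replicate(n, fake_d())))
  y <- rep(c(1, 0), each = n)
  disc <- init_discriminator(
    discriminator_config(nv, l, hidden_size = 8L, n_heads = 2L,
                         n_layers = 1L, dropout = 0), seed = 13L)
  params <- model_params(disc)
  opt <- tracegan:::adam_init(params, lr = 5e-3)
  for (step in 1:200) {
    sc <- discriminator_forward(disc, oh, diffs, 2L * n, training = TRUE)
    ll <- tracegan:::ad_sub(
      tracegan:::ad_scale(tracegan:::ad_sum(tracegan:::ad_mul(
        tracegan:::ad_const(matrix(y / n, ncol = 1)),
        tracegan:::ad_log(sc, eps = 1e-8))), -0.5),
      tracegan:::ad_scale(tracegan:::ad_sum(tracegan:::ad_mul(
        tracegan:::ad_const(matrix((1 - y) / n, ncol = 1)),
        tracegan:::ad_log(tracegan:::ad_sub(
          tracegan:::ad_const(matrix(1, 2 * n, 1)), sc), eps = 1e-8))),
        0.5))
    tracegan:::ad_zero_grad(params)
    tracegan:::ad_backward(ll)
    tracegan:::adam_step(opt)
  }
  acc <- mean((discriminator_score(disc, oh, diffs, 2L * n) > 0.5) ==
                (y == 1))
  expect_gte(acc, 0.95)
})
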