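# Finite-difference checks of the autodiff engine.  Every op the networks
# rely on is exercised through a composite scalar loss; analytic gradients
# must match central differences to ~1e-6.

ad <- function(name) get(name, envir = asNamespace("tracegan"))

grad_check <- function(make_loss, numeric_loss, x0, tol = 1e-6) {
  p <- ad("ad_param")(x0)
  loss <- make_loss(p)
  ad("ad_backward")(loss)
  expect_lt(max(abs(p$grad - num_grad(numeric_loss, x0))), tol)
}

test_that("elementary op gradients match finite differences", {
  set.seed(1)
  x0 <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(12), 3, 4)
  co <- ad("ad_const")

  grad_check(
    function(p) ad("ad_mean")(ad("ad_log")(ad("ad_softmax_rows")(p),
                                           eps = 1e-9)),
    function(x) {
      y <- exp(x - apply(x, 1, max)); y <- y / rowSums(y)
      mean(log(y + 1e-9))
    }, x0)

  grad_check(
    function(p) ad("ad_sum")(ad("ad_mul")(
      ad("ad_layernorm_rows")(p, co(matrix(1.3, 1, 4)),
                              co(matrix(0.2, 1, 4))), co(W))),
    function(x) {
      mu <- rowMeans(x); xc <- x - mu
      v <- rowMeans(xc^2); xh <- xc / sqrt(v + 1e-5)
      sum((1.3 * xh + 0.2) * W)
    }, x0)

  grad_check(
    function(p) ad("ad_sum")(ad("ad_mul")(ad("ad_cumsum_rows")(p), co(W))),
    function(x) sum(t(apply(x, 1, cumsum)) * W), x0)

  grad_check(
    function(p) ad("ad_sum")(ad("ad_sigmoid")(ad("ad_matmul")(p, co(t(W))))),
    function(x) sum(1 / (1 + exp(-(x %*% t(W))))), x0)

  x1 <- matrix(runif(12), 3, 4)
  grad_check(
    function(p) ad("ad_sum")(ad("ad_mul")(ad("ad_minmax_rows")(p), co(W))),
    function(x) {
      lo <- apply(x, 1, min); hi <- apply(x, 1, max)
      y <- (x - lo) / (hi - lo); y[, 1] <- 0
      sum(y * W)
    }, x1)
})

test_that("attention op gradients match finite differences", {
  set.seed(21)
  B <- 2L; l <- 4L; d <- 6L; h <- 2L
  x0 <- matrix(rnorm(B * l * d), B * l, d)
  wq <- matrix(rnorm(d * d) * 0.5, d, d)
  wk <- matrix(rnorm(d * d) * 0.5, d, d)
  wv <- matrix(rnorm(d * d) * 0.5, d, d)
  W <- matrix(rnorm(B * l * d), B * l, d)
  co <- ad("ad_const")
  # cases attend only within themselves: apply the oracle per case block
  oracle_mat <- function(x, wq2) {
    rbind(plain_attention_oracle(x[1:l, ], wq2, wk, wv, h),
          plain_attention_oracle(x[(l + 1):(2 * l), ], wq2, wk, wv, h))
  }
  oracle <- function(x) sum(oracle_mat(x, wq) * W)
  grad_check(
    function(p) ad("ad_sum")(ad("ad_mul")(
      ad("ad_mha")(p, co(wq), co(wk), co(wv), B, l, h), co(W))),
    oracle, x0, tol = 1e-5)
  # weight gradient through the same op
  grad_check(
    function(p) ad("ad_sum")(ad("ad_mul")(
      ad("ad_mha")(co(x0), p, co(wk), co(wv), B, l, h), co(W))),
    function(wq2) sum(oracle_mat(x0, wq2) * W),
    wq, tol = 1e-5)
})

test_that("time-aware attention gradients reach diffs and all projections", {
  set.seed(33)
  B <- 2L; l <- 4L; din <- 5L; d <- 4L; h <- 2L
  xm <- matrix(rnorm(B * l * din), B * l, din)
  diffs <- matrix(runif(B * l) * 0.4, B, l); diffs[, 1] <- 0
  P <- list(wq = matrix(rnorm(din * d) * .5, din, d),
            wk = matrix(rnorm(din * d) * .5, din, d),
            wv = matrix(rnorm(din * d) * .5, din, d),
            w_tsk = matrix(rnorm(d) * .5, 1), b_tsk = matrix(rnorm(d) * .3, 1),
            w_tsv = matrix(rnorm(d) * .5, 1), b_tsv = matrix(rnorm(d) * .3, 1),
            w_mk = matrix(rnorm(d) * .5, 1), b_mk = matrix(rnorm(d) * .3, 1),
            w_mv = matrix(rnorm(d) * .5, 1), b_mv = matrix(rnorm(d) * .3, 1))
  W <- matrix(rnorm(B * l * d), B * l, d)
  co <- ad("ad_const")
  # single-case reference via the exported evaluation wrapper
  num <- function(xm_, diffs_, P_) {
    out <- rbind(
      time_aware_attention(xm_[1:l, ], diffs_[1, ], P_, h),
      time_aware_attention(xm_[(l + 1):(2 * l), ], diffs_[2, ], P_, h))
    sum(out * W)
  }
  run <- function(nodes) {
    o <- ad("ad_time_mha")(nodes$x, nodes$diffs, nodes$wq, nodes$wk,
                           nodes$wv, nodes$w_tsk, nodes$b_tsk, nodes$w_tsv,
                           nodes$b_tsv, nodes$w_mk, nodes$b_mk, nodes$w_mv,
                           nodes$b_mv, B, l, h)
    ad("ad_sum")(ad("ad_mul")(o, co(W)))
  }
  for (tgt in c("diffs", "w_tsk", "w_mk", "w_mv", "wq")) {
    nodes <- c(list(x = co(xm), diffs = co(diffs)), lapply(P, co))
    base <- if (tgt == "diffs") diffs else P[[tgt]]
    nodes[[tgt]] <- ad("ad_param")(base)
    loss <- run(nodes)
    ad("ad_backward")(loss)
    fn <- function(z) {
      if (tgt == "diffs") return(num(xm, z, P))
      PP <- P; PP[[tgt]] <- z
      num(xm, diffs, PP)
    }
    expect_lt(max(abs(nodes[[tgt]]$grad - num_grad(fn, base))), 1e-5)
  }
})

test_that("straight-through Gumbel output is hard, gradient is relaxed", {
  set.seed(5)
  logits <- matrix(rnorm(12), 3, 4)
  gum <- matrix(-log(-log(runif(12))), 3, 4)
  tau <- 0.7
  p <- ad("ad_param")(logits)
  y <- ad("ad_gumbel_st")(p, gum, tau)
  # forward: exact one-hot at argmax of the perturbed logits
  expect_true(all(rowSums(y$value) == 1))
  expect_true(all(y$value %in% c(0, 1)))
  expect_equal(max.col(logits + gum), max.col(y$value))
  # backward: jacobian of softmax((logits+g)/tau)
  W <- matrix(rnorm(12), 3, 4)
  loss <- ad("ad_sum")(ad("ad_mul")(y, ad("ad_const")(W)))
  ad("ad_backward")(loss)
  soft_loss <- function(x) {
    z <- (x + gum) / tau
    s <- exp(z - apply(z, 1, max)); s <- s / rowSums(s)
    sum(s * W)
  }
  expect_lt(max(abs(p$grad - num_grad(soft_loss, logits))), 1e-6)
})

test_that("gradients accumulate across repeated use of a node", {
  x0 <- matrix(2, 1, 1)
  p <- ad("ad_param")(x0)
  loss <- ad("ad_add")(ad("ad_mul")(p, p), ad("ad_scale")(p, 3))
  ad("ad_backward")(loss)
  expect_equal(as.numeric(p$grad), 2 * 2 + 3)  # d(x^2 + 3x)/dx at x = 2
})

test_that("evaluation-mode forwards do not grow the tape", {
  co <- ad("ad_const")
  out <- ad("ad_matmul")(co(matrix(1, 2, 2)), co(matrix(1, 2, 2)))
  expect_null(out$backward)
  expect_length(out$parents, 0L)
})
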