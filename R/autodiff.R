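# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value in the graph is a plain numeric matrix wrapped in an
# environment ("ad node") holding the value, an accumulated gradient, the
# parent nodes, and a backward closure mapping the output gradient to
# parent gradients.  Ops whose inputs carry no gradient short-circuit to a
# constant node, so evaluation-mode forwards pay almost nothing for the
# tape.  The engine is deliberately small: it supports exactly the ops the
# package's networks need, and each op's backward pass is checked against
# finite differences in the test suite.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

ad_next_id <- function() {
  .ad_env$counter <- .ad_env$counter + 1L
  .ad_env$counter
}


# fast row-wise max (C-level max.col instead of apply)
row_max <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

# upper-triangular ones matrix: x %*% upper_tri_ones(l) is a row cumsum
upper_tri_ones <- function(l) {
  m <- matrix(0, l, l)
  m[upper.tri(m, diag = TRUE)] <- 1
  m
}

# Linear indices (a plain integer vector, column-major for an (B*l) x l
# target) of the B diagonal l x l blocks of an (B*l) x (B*l) matrix:
# position (r, j) addresses full[(r, case-local column j)].  Attention over
# a batch of equal-length sequences is block diagonal, so one big BLAS
# product plus this gather/scatter replaces the per-case loop.  A vector
# (not a matrix) so subsetting is always linear indexing.  Cached per
# (B, l).
block_diag_idx <- function(n_case, len) {
  key <- paste0("bd_", n_case, "_", len)
  hit <- .ad_env[[key]]
  if (!is.null(hit)) return(hit)
  n <- n_case * len
  r <- seq_len(n)
  case_of <- rep(seq_len(n_case) - 1L, each = len)
  idx <- matrix(0L, n, len)
  for (j in seq_len(len)) {
    idx[, j] <- (case_of * len + j - 1L) * n + r
  }
  idx <- as.integer(idx)
  .ad_env[[key]] <- idx
  idx
}

#' Create an autodiff node
#'
#' @param value Numeric matrix (vectors are promoted to 1-column matrices).
#' @param parents List of parent nodes the value was computed from.
#' @param backward Function mapping the gradient at this node to a list of
#'   gradients, one per parent (`NULL` entries are skipped).
#' @param requires_grad Whether gradients should be accumulated here.
#' @return An object of class `ad_node`.
#' @keywords internal
ad_node <- function(value, parents = list(), backward = NULL,
                    requires_grad = FALSE) {
  if (!is.matrix(value)) value <- matrix(value, ncol = 1L)
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$requires_grad <- requires_grad
  node$id <- ad_next_id()
  class(node) <- "ad_node"
  node
}

#' @keywords internal
ad_param <- function(value) ad_node(value, requires_grad = TRUE)

#' @keywords internal
ad_const <- function(value) ad_node(value)

is_ad_node <- function(x) inherits(x, "ad_node")

ad_wrap <- function(x) if (is_ad_node(x)) x else ad_const(x)

# TRUE when at least one input participates in gradient computation.
ad_track <- function(...) {
  for (p in list(...)) {
    if (is_ad_node(p) && (p$requires_grad || !is.null(p$backward))) return(TRUE)
  }
  FALSE
}

ad_value <- function(x) if (is_ad_node(x)) x$value else x

# Build an op node; if no parent needs gradients the tape is not extended.
ad_op <- function(value, parents, backward) {
  need <- FALSE
  for (p in parents) if (p$requires_grad || !is.null(p$backward)) { need <- TRUE; break }
  if (!need) return(ad_const(value))
  ad_node(value, parents = parents, backward = backward)
}

#' Run the backward pass from a scalar root node
#'
#' Accumulates gradients into every reachable node with `requires_grad` or a
#' backward closure. Gradients add across multiple uses of a node.
#' @param root Scalar (1x1) `ad_node`.
#' @keywords internal
ad_backward <- function(root) {
  stopifnot(is_ad_node(root), length(root$value) == 1L)
  # collect reachable subgraph
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ids <- vapply(nodes, function(n) n$id, integer(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  root$grad <- matrix(1, 1L, 1L)
  for (nd in nodes) {
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (i in seq_along(ps)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- ps[[i]]
      if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
    }
  }
  invisible(root)
}

#' @keywords internal
ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- elementary ops -------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  av <- a$value; bv <- b$value
  ad_op(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

ad_add <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  ad_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

# a (n x d) plus a 1 x d bias row broadcast over rows
ad_add_rowvec <- function(a, v) {
  a <- ad_wrap(a); v <- ad_wrap(v)
  av <- a$value
  vv <- as.numeric(v$value)
  ad_op(av + matrix(vv, nrow(av), ncol(av), byrow = TRUE), list(a, v),
        function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ad_mul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  av <- a$value; bv <- b$value
  ad_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, s) {
  a <- ad_wrap(a)
  ad_op(a$value * s, list(a), function(g) list(g * s))
}

ad_relu <- function(a) {
  a <- ad_wrap(a)
  mask <- a$value > 0
  ad_op(a$value * mask, list(a), function(g) list(g * mask))
}

ad_sigmoid <- function(a) {
  a <- ad_wrap(a)
  y <- 1 / (1 + exp(-a$value))
  ad_op(y, list(a), function(g) list(g * y * (1 - y)))
}

ad_log <- function(a, eps = 0) {
  a <- ad_wrap(a)
  v <- a$value + eps
  ad_op(log(v), list(a), function(g) list(g / v))
}

ad_softmax_rows <- function(a) {
  a <- ad_wrap(a)
  x <- a$value
  x <- x - row_max(x)
  e <- exp(x)
  y <- e / rowSums(e)
  ad_op(y, list(a), function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

ad_mean <- function(a) {
  a <- ad_wrap(a)
  n <- length(a$value)
  dims <- dim(a$value)
  ad_op(matrix(mean(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g) / n, dims[1L], dims[2L]))
  })
}

ad_sum <- function(a) {
  a <- ad_wrap(a)
  dims <- dim(a$value)
  ad_op(matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g), dims[1L], dims[2L]))
  })
}

# select rows of an embedding table; duplicated indices accumulate gradient
ad_embed <- function(table, idx) {
  table <- ad_wrap(table)
  tv <- table$value
  idx <- as.integer(idx)
  ad_op(tv[idx, , drop = FALSE], list(table), function(g) {
    acc <- rowsum(g, group = idx)
    out <- matrix(0, nrow(tv), ncol(tv))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# concatenate a constant matrix of extra columns on the right
ad_cbind_const <- function(a, const) {
  a <- ad_wrap(a)
  na <- ncol(a$value)
  ad_op(cbind(a$value, const), list(a), function(g) {
    list(g[, seq_len(na), drop = FALSE])
  })
}

ad_dropout <- function(a, p, training = TRUE) {
  a <- ad_wrap(a)
  if (!training || p <= 0) return(a)
  keep <- matrix(stats::runif(length(a$value)) >= p,
                 nrow(a$value), ncol(a$value)) / (1 - p)
  ad_op(a$value * keep, list(a), function(g) list(g * keep))
}

# row-wise layer normalization with learned 1 x d gain/bias
ad_layernorm_rows <- function(a, gamma, beta, eps = 1e-5) {
  a <- ad_wrap(a); gamma <- ad_wrap(gamma); beta <- ad_wrap(beta)
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$value)
  y <- sweep(xhat, 2L, gv, "*")
  y <- sweep(y, 2L, as.numeric(beta$value), "+")
  ad_op(y, list(a, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

# mean-pool a stacked (B*l x d) matrix into B x d (each case has l rows)
ad_pool_mean <- function(a, n_case, len) {
  a <- ad_wrap(a)
  grp <- rep(seq_len(n_case), each = len)
  p <- matrix(0, n_case, n_case * len)
  p[cbind(grp, seq_len(n_case * len))] <- 1 / len
  ad_op(p %*% a$value, list(a), function(g) {
    list(crossprod(p, g))
  })
}

# row-wise cumulative sum over a B x l matrix (each row one sequence)
ad_cumsum_rows <- function(a) {
  a <- ad_wrap(a)
  u <- upper_tri_ones(ncol(a$value))
  ad_op(a$value %*% u, list(a), function(g) {
    list(g %*% t(u))
  })
}

# Per-row min-max rescale into [0,1]; constant rows map to 0.  Used by the
# generator's time head.  `force_first_zero` pins column 1 at 0 so synthetic
# differentials share the authentic convention that the first gap is 0.
ad_minmax_rows <- function(a, force_first_zero = TRUE, eps = 1e-12) {
  a <- ad_wrap(a)
  x <- a$value
  l <- ncol(x)
  i_hi <- max.col(x, ties.method = "first")
  i_lo <- max.col(-x, ties.method = "first")
  n_row <- nrow(x)
  hi <- x[cbind(seq_len(n_row), i_hi)]
  lo <- x[cbind(seq_len(n_row), i_lo)]
  rng <- hi - lo
  flat <- rng <= eps
  y <- (x - lo) / ifelse(flat, 1, rng)
  y[flat, ] <- 0
  if (force_first_zero) y[, 1L] <- 0
  ad_op(y, list(a), function(g) {
    if (force_first_zero) g[, 1L] <- 0
    dx <- g / ifelse(flat, 1, rng)
    dx[flat, ] <- 0
    # gradient w.r.t. the row min and max (subgradient at the arg positions):
    # d y_j / d lo = (y_j - 1)/rng ; d y_j / d hi = -y_j/rng
    gsum <- rowSums(g)
    gy <- rowSums(g * y)
    d_lo <- (-gsum + gy) / ifelse(flat, 1, rng)
    d_hi <- -gy / ifelse(flat, 1, rng)
    d_lo[flat] <- 0; d_hi[flat] <- 0
    for (i in seq_len(nrow(dx))) {
      if (flat[i]) next
      dx[i, i_lo[i]] <- dx[i, i_lo[i]] + d_lo[i]
      dx[i, i_hi[i]] <- dx[i, i_hi[i]] + d_hi[i]
    }
    list(dx)
  })
}

# reshape a stacked (B*l x 1) column into a B x l matrix (row-major)
ad_stack_to_rows <- function(a, n_case, len) {
  a <- ad_wrap(a)
  v <- matrix(as.numeric(a$value), n_case, len, byrow = TRUE)
  ad_op(v, list(a), function(g) {
    list(matrix(as.numeric(t(g)), ncol = 1L))
  })
}

# concatenate two nodes column-wise
ad_cbind2 <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  na <- ncol(a$value)
  ad_op(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

# subset columns
ad_cols <- function(a, cols) {
  a <- ad_wrap(a)
  dims <- dim(a$value)
  ad_op(a$value[, cols, drop = FALSE], list(a), function(g) {
    out <- matrix(0, dims[1L], dims[2L])
    out[, cols] <- g
    list(out)
  })
}

# Stacked per-position time features [t_i | M_i,.] (B*l x (1+l)) built from
# the differential matrix; used by the no-time-attention ablation where
# timestamps and the interval matrix are concatenated onto the activity
# one-hots instead of entering the attention equations.
ad_time_features <- function(diffs, n_case, len) {
  diffs <- ad_wrap(diffs)
  dv <- diffs$value
  out <- matrix(0, n_case * len, 1L + len)
  for (c in seq_len(n_case)) {
    rows <- ((c - 1L) * len + 1L):(c * len)
    tsp <- cumsum(dv[c, ])
    out[rows, 1L] <- dv[c, ]
    out[rows, -1L] <- tsp - matrix(tsp, len, len, byrow = TRUE)
  }
  ad_op(out, list(diffs), function(g) {
    dd <- matrix(0, n_case, len)
    for (c in seq_len(n_case)) {
      rows <- ((c - 1L) * len + 1L):(c * len)
      dM <- g[rows, -1L, drop = FALSE]
      dtsp <- rowSums(dM) - colSums(dM)
      dd[c, ] <- g[rows, 1L] + rev(cumsum(rev(dtsp)))
    }
    list(dd)
  })
}

# L1-normalize each row to sum to 1 (rows summing to ~0 stay zero); the
# synthetic differential convention matches the authentic telescoping sum
ad_rownorm <- function(a, eps = 1e-8) {
  a <- ad_wrap(a)
  x <- a$value
  rs <- rowSums(x)
  live <- rs > eps
  y <- x / ifelse(live, rs, 1)
  y[!live, ] <- 0
  ad_op(y, list(a), function(g) {
    dx <- (g - rowSums(g * y)) / ifelse(live, rs, 1)
    dx[!live, ] <- 0
    list(dx)
  })
}

## ---- attention ops --------------------------------------------------------

# Standard multi-head scaled dot-product self-attention over a stacked
# (B*l x d) input.  Returns the concatenated head outputs (no output
# projection; compose with ad_matmul for that).
ad_mha <- function(x, wq, wk, wv, n_case, len, n_heads) {
  x <- ad_wrap(x); wq <- ad_wrap(wq); wk <- ad_wrap(wk); wv <- ad_wrap(wv)
  xv <- x$value
  d <- ncol(wq$value)
  dh <- d %/% n_heads
  n <- n_case * len
  bd <- block_diag_idx(n_case, len)
  q_all <- xv %*% wq$value
  k_all <- xv %*% wk$value
  v_all <- xv %*% wv$value
  out <- matrix(0, n, d)
  alphas <- vector("list", n_heads)
  abigs <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- q_all[, cols, drop = FALSE]
    kh <- k_all[, cols, drop = FALSE]
    e <- matrix(tcrossprod(qh, kh)[bd], n, len) / sqrt(dh)
    e <- e - row_max(e)
    a <- exp(e); a <- a / rowSums(a)
    abig <- matrix(0, n, n); abig[bd] <- a
    out[, cols] <- abig %*% v_all[, cols, drop = FALSE]
    alphas[[h]] <- a; abigs[[h]] <- abig
  }
  ad_op(out, list(x, wq, wk, wv), function(g) {
    dq <- matrix(0, n, d); dk <- dq; dv <- dq
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      a <- alphas[[h]]
      gh <- g[, cols, drop = FALSE]
      vh <- v_all[, cols, drop = FALSE]
      dv[, cols] <- crossprod(abigs[[h]], gh)
      da <- matrix(tcrossprod(gh, vh)[bd], n, len)
      de <- a * (da - rowSums(da * a)) / sqrt(dh)
      debig <- matrix(0, n, n); debig[bd] <- de
      dq[, cols] <- debig %*% k_all[, cols, drop = FALSE]
      dk[, cols] <- crossprod(debig, q_all[, cols, drop = FALSE])
    }
    dx <- dq %*% t(wq$value) + dk %*% t(wk$value) + dv %*% t(wv$value)
    list(dx,
         crossprod(xv, dq),
         crossprod(xv, dk),
         crossprod(xv, dv))
  })
}

# Time-aware multi-head self-attention.
#
# Inputs: stacked activity/feature matrix x (B*l x din), the timestamp
# differential matrix `diffs` (B x l, one row per case, may be a node so
# gradients reach the generator's time head), and parameters:
#   wq, wk, wv : din x d          activity query/key/value
#   w_tsk,b_tsk, w_tsv,b_tsv : 1 x d   timestamp (differential) projections
#   w_mk,b_mk,  w_mv,b_mv  : 1 x d    time-interval projections
# The pairwise interval matrix M is built internally from the cumulative
# differentials (M_ij = ts'_i - ts'_j), so its gradient flows back into
# `diffs`.  Compatibility per head:
#   e_ij = q_i . (k_j + tsk_j + M_ij*wmk + bmk) / sqrt(dh)
# and the feature:
#   f_i = sum_j alpha_ij (v_j + tsv_j + M_ij*wmv + bmv).
# Because the time projections are linear in the scalar inputs, every term
# reduces to dense matrix algebra on the stacked batch; the block-diagonal
# gather/scatter of block_diag_idx() keeps cases independent.
ad_time_mha <- function(x, diffs, wq, wk, wv,
                        w_tsk, b_tsk, w_tsv, b_tsv,
                        w_mk, b_mk, w_mv, b_mv,
                        n_case, len, n_heads) {
  x <- ad_wrap(x); diffs <- ad_wrap(diffs)
  wq <- ad_wrap(wq); wk <- ad_wrap(wk); wv <- ad_wrap(wv)
  w_tsk <- ad_wrap(w_tsk); b_tsk <- ad_wrap(b_tsk)
  w_tsv <- ad_wrap(w_tsv); b_tsv <- ad_wrap(b_tsv)
  w_mk <- ad_wrap(w_mk); b_mk <- ad_wrap(b_mk)
  w_mv <- ad_wrap(w_mv); b_mv <- ad_wrap(b_mv)

  xv <- x$value; dv_mat <- diffs$value
  d <- ncol(wq$value)
  dh <- d %/% n_heads
  n <- n_case * len
  bd <- block_diag_idx(n_case, len)
  ut <- upper_tri_ones(len)
  q_all <- xv %*% wq$value
  k_all <- xv %*% wk$value
  v_all <- xv %*% wv$value
  wtsk <- as.numeric(w_tsk$value); btsk <- as.numeric(b_tsk$value)
  wtsv <- as.numeric(w_tsv$value); btsv <- as.numeric(b_tsv$value)
  wmk <- as.numeric(w_mk$value);  bmk <- as.numeric(b_mk$value)
  wmv <- as.numeric(w_mv$value);  bmv <- as.numeric(b_mv$value)

  tvec_flat <- as.numeric(t(dv_mat))
  tsp <- dv_mat %*% ut
  tsp_flat <- as.numeric(t(tsp))
  M_st <- tsp_flat - tsp[rep(seq_len(n_case), each = len), , drop = FALSE]
  kp <- k_all + outer(tvec_flat, wtsk)
  kp <- kp + matrix(btsk, n, d, byrow = TRUE)
  vp <- v_all + outer(tvec_flat, wtsv)
  vp <- vp + matrix(btsv, n, d, byrow = TRUE)

  out <- matrix(0, n, d)
  alphas <- vector("list", n_heads)
  abigs <- vector("list", n_heads)
  svecs <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- q_all[, cols, drop = FALSE]
    qm <- as.numeric(qh %*% wmk[cols])
    qb <- as.numeric(qh %*% bmk[cols])
    e <- (matrix(tcrossprod(qh, kp[, cols, drop = FALSE])[bd], n, len) +
            qm * M_st + qb) / sqrt(dh)
    e <- e - row_max(e)
    a <- exp(e); a <- a / rowSums(a)
    s <- rowSums(a * M_st)
    abig <- matrix(0, n, n); abig[bd] <- a
    out[, cols] <- abig %*% vp[, cols, drop = FALSE] +
      outer(s, wmv[cols]) + matrix(bmv[cols], n, dh, byrow = TRUE)
    alphas[[h]] <- a; abigs[[h]] <- abig; svecs[[h]] <- s
  }

  parents <- list(x, diffs, wq, wk, wv, w_tsk, b_tsk, w_tsv, b_tsv,
                  w_mk, b_mk, w_mv, b_mv)
  ad_op(out, parents, function(g) {
    dq <- matrix(0, n, d); dkp <- dq; dvp <- dq
    dM <- matrix(0, n, len)
    d_wmk <- numeric(d); d_bmk <- numeric(d)
    d_wmv <- numeric(d); d_bmv <- numeric(d)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      a <- alphas[[h]]; s <- svecs[[h]]
      gh <- g[, cols, drop = FALSE]
      qh <- q_all[, cols, drop = FALSE]
      qm <- as.numeric(qh %*% wmk[cols])
      dvp[, cols] <- dvp[, cols] + crossprod(abigs[[h]], gh)
      ds <- as.numeric(gh %*% wmv[cols])
      d_wmv[cols] <- d_wmv[cols] + colSums(gh * s)
      d_bmv[cols] <- d_bmv[cols] + colSums(gh)
      da <- matrix(tcrossprod(gh, vp[, cols, drop = FALSE])[bd], n, len) +
        ds * M_st
      dM <- dM + a * ds
      de <- a * (da - rowSums(da * a)) / sqrt(dh)
      debig <- matrix(0, n, n); debig[bd] <- de
      rs_dem <- rowSums(de * M_st); rs_de <- rowSums(de)
      dq[, cols] <- debig %*% kp[, cols, drop = FALSE] +
        outer(rs_dem, wmk[cols]) + outer(rs_de, bmk[cols])
      dkp[, cols] <- dkp[, cols] + crossprod(debig, qh)
      dM <- dM + de * qm
      d_wmk[cols] <- d_wmk[cols] + colSums(qh * rs_dem)
      d_bmk[cols] <- d_bmk[cols] + colSums(qh * rs_de)
    }
    d_wtsk <- colSums(dkp * tvec_flat); d_btsk <- colSums(dkp)
    d_wtsv <- colSums(dvp * tvec_flat); d_btsv <- colSums(dvp)
    dt_direct <- as.numeric(dkp %*% t(w_tsk$value)) +
      as.numeric(dvp %*% t(w_tsv$value))
    # M_st[r, j] = ts'_flat[r] - ts'[case(r), j]
    grp <- rep(seq_len(n_case), each = len)
    dtsp <- matrix(rowSums(dM), n_case, len, byrow = TRUE) -
      rowsum(dM, grp)
    dd <- dtsp %*% t(ut) + matrix(dt_direct, n_case, len, byrow = TRUE)
    dx <- dq %*% t(wq$value) + dkp %*% t(wk$value) + dvp %*% t(wv$value)
    list(dx, dd,
         crossprod(xv, dq), crossprod(xv, dkp), crossprod(xv, dvp),
         matrix(d_wtsk, 1L), matrix(d_btsk, 1L),
         matrix(d_wtsv, 1L), matrix(d_btsv, 1L),
         matrix(d_wmk, 1L), matrix(d_bmk, 1L),
         matrix(d_wmv, 1L), matrix(d_bmv, 1L))
  })
}

## ---- discrete sampling ----------------------------------------------------

# Straight-through Gumbel-softmax.  Forward value is the exact one-hot of
# argmax(logits + gumbel); the backward pass routes the output gradient
# through the temperature-softmax relaxation at the same perturbed logits.
ad_gumbel_st <- function(logits, gumbel, temperature = 1) {
  logits <- ad_wrap(logits)
  z <- logits$value + gumbel
  hard <- matrix(0, nrow(z), ncol(z))
  idx <- max.col(z, ties.method = "first")
  hard[cbind(seq_len(nrow(z)), idx)] <- 1
  zs <- z / temperature
  zs <- zs - row_max(zs)
  e <- exp(zs)
  soft <- e / rowSums(e)
  ad_op(hard, list(logits), function(g) {
    list(soft * (g - rowSums(g * soft)) / temperature)
  })
}

## ---- optimizer ------------------------------------------------------------

#' Adam optimizer state for a flat list of parameter nodes
#' @keywords internal
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st
}

#' @keywords internal
adam_step <- function(st, lr = NULL) {
  if (is.null(lr)) lr <- st$lr
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    mhat <- st$m[[i]] / corr1
    vhat <- st$v[[i]] / corr2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + st$eps)
  }
  invisible(st)
}

## ---- init helpers ---------------------------------------------------------

# Glorot-uniform initialization
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

zeros_row <- function(d) matrix(0, 1L, d)
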