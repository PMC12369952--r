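# Adversarial losses, auxiliary-weight calibration, the alternating
# training schedule, equilibrium checkpoint selection, and decoding of
# trained-generator output back into an event log.

LOG_EPS <- 1e-8

#' Training configuration
#'
#' @param epochs Total training epochs (required; the budget is
#'   data-dependent).
#' @param batch_size Minibatch size `m`.
#' @param k Generator-to-discriminator ratio: the discriminator is updated
#'   on epochs divisible by `k` (default 2), the generator every epoch.
#' @param lr_g,lr_d Adam learning rates.
#' @param betas Adam momentum pair, shared by both optimizers.
#' @param checkpoint_interval Record a checkpoint every this many epochs.
#' @param calibration_epochs Forward-only epochs used to set the auxiliary
#'   weights when `aux_weights = "auto"`.
#' @param aux_weights Either `"auto"` or a numeric `c(w_a, w_t)`.
#' @param aux_weight_cap Upper bound for auto-calibrated weights when an
#'   auxiliary expectation is ~0.
#' @param use_act_loss,use_time_loss Toggles for the two auxiliary losses
#'   (the "w/o" ablations).
#' @param holdout_frac Fraction of authentic cases held out for the
#'   equilibrium discriminator-accuracy monitor.
#' @param renormalize_differentials After dropping pad positions at
#'   decode time, rescale the remaining differentials to sum to 1 so the
#'   last timestamp equals the conditional duration.
#' @param seed Integer seed controlling all randomness of a run.
#' @return A `training_config`.
#' @export
training_config <- function(epochs, batch_size = 32L, k = 2L,
                            lr_g = 1e-3, lr_d = 1e-3,
                            betas = c(0.9, 0.999),
                            checkpoint_interval = 50L,
                            calibration_epochs = 3L,
                            aux_weights = "auto",
                            aux_weight_cap = 1e6,
                            use_act_loss = TRUE, use_time_loss = TRUE,
                            holdout_frac = 0.2,
                            renormalize_differentials = TRUE,
                            seed = 1L) {
  stopifnot(k >= 1L, checkpoint_interval >= 1L, epochs >= 1L,
            calibration_epochs >= 1L)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), k = as.integer(k),
                 lr_g = lr_g, lr_d = lr_d, betas = betas,
                 checkpoint_interval = as.integer(checkpoint_interval),
                 calibration_epochs = as.integer(calibration_epochs),
                 aux_weights = aux_weights,
                 aux_weight_cap = aux_weight_cap,
                 use_act_loss = isTRUE(use_act_loss),
                 use_time_loss = isTRUE(use_time_loss),
                 holdout_frac = holdout_frac,
                 renormalize_differentials = isTRUE(renormalize_differentials),
                 seed = as.integer(seed)),
            class = "training_config")
}

## ---- losses (plain numeric; the autodiff twins are checked against these) --

#' Generator adversarial loss
#'
#' `-mean(log D(G(Z|T)))` with scores clamped at `1e-8`.
#'
#' @param d_scores_on_synthetic Discriminator scores in (0, 1).
#' @return Scalar loss.
#' @export
generator_adversarial_loss <- function(d_scores_on_synthetic) {
  -mean(log(pmax(d_scores_on_synthetic, LOG_EPS)))
}

#' Discriminator loss
#'
#' `-mean(log D(X)) - mean(log(1 - D(G(Z|T))))`.
#'
#' @param d_authentic,d_synthetic Score batches in (0, 1).
#' @return Scalar loss.
#' @export
discriminator_loss <- function(d_authentic, d_synthetic) {
  -mean(log(pmax(d_authentic, LOG_EPS))) -
    mean(log(pmax(1 - d_synthetic, LOG_EPS)))
}

batch_activity_freq <- function(onehot) {
  colSums(ad_value(onehot)) / nrow(ad_value(onehot))
}

# per-activity mean cumulative scaled timestamp over a batch; activities
# absent from the batch get 0
batch_time_means <- function(onehot, diffs) {
  onehot <- ad_value(onehot); diffs <- ad_value(diffs)
  tsp <- diffs %*% upper_tri_ones(ncol(diffs))
  v <- as.numeric(t(tsp))
  cnt <- colSums(onehot)
  s <- colSums(onehot * v)
  ifelse(cnt > 0, s / pmax(cnt, 1), 0)
}

#' Activity distribution divergence (auxiliary generator loss)
#'
#' MSE between the within-batch activity frequency distributions of an
#' authentic and a synthetic batch:
#' `(1/(m*N_v)) * sum_a (X'_a(a) - S'_a(a))^2` over the `N_v` real
#' activity types.  Frequencies are proportions over all `m*l` positions
#' (pad included in the denominator, excluded from the sum).
#'
#' @param auth_onehot,syn_onehot Stacked `m*l x (N_v+1)` one-hot matrices.
#' @param m Batch size.
#' @param n_real Number of real (non-pad) activity types `N_v`.
#' @return Scalar loss.
#' @export
activity_divergence_loss <- function(auth_onehot, syn_onehot, m, n_real) {
  fa <- batch_activity_freq(auth_onehot)[seq_len(n_real)]
  fs <- batch_activity_freq(syn_onehot)[seq_len(n_real)]
  sum((fa - fs)^2) / (m * n_real)
}

#' Timestamp distribution divergence (auxiliary generator loss)
#'
#' MSE of the per-activity mean cumulative scaled timestamps (fraction of
#' case duration) between an authentic and a synthetic batch:
#' `(1/(m*N_v)) * sum_a (X'_ts(a) - S'_ts(a))^2`.  Activities absent from a
#' batch contribute their present-side mean against 0; absent from both, 0.
#'
#' @param auth,syn Lists with `onehot` (stacked) and `diffs` (`m x l`).
#' @param m Batch size.
#' @param n_real Number of real activity types.
#' @return Scalar loss.
#' @export
timestamp_divergence_loss <- function(auth, syn, m, n_real) {
  ma <- batch_time_means(auth$onehot, auth$diffs)[seq_len(n_real)]
  ms <- batch_time_means(syn$onehot, syn$diffs)[seq_len(n_real)]
  sum((ma - ms)^2) / (m * n_real)
}

## ---- autodiff twins of the auxiliary losses --------------------------------

ad_act_divergence <- function(onehot_node, auth_freq, m, n_real) {
  o <- onehot_node
  nr <- nrow(o$value)
  freq <- ad_matmul(ad_const(matrix(1 / nr, 1L, nr)), o)    # 1 x (Nv+1)
  gap <- ad_sub(ad_cols(freq, seq_len(n_real)),
                ad_const(matrix(auth_freq[seq_len(n_real)], 1L)))
  ad_scale(ad_sum(ad_mul(gap, gap)), 1 / (m * n_real))
}

# custom op: MSE of per-activity mean cumulative timestamps, with exact
# zero-count handling and gradients into both the one-hots (straight-through
# bridge) and the differentials (generator time head)
ad_time_divergence <- function(onehot_node, diffs_node, auth_means,
                               m, n_real, len) {
  o <- onehot_node; dn <- diffs_node
  ov <- o$value; dv <- dn$value
  n_case <- nrow(dv)
  ut <- upper_tri_ones(ncol(dv))
  tsp <- dv %*% ut
  v <- as.numeric(t(tsp))
  cnt <- colSums(ov)
  s <- colSums(ov * v)
  sm <- ifelse(cnt > 0, s / pmax(cnt, 1), 0)
  am <- auth_means
  gaps <- am[seq_len(n_real)] - sm[seq_len(n_real)]
  val <- sum(gaps^2) / (m * n_real)
  ad_op(matrix(val, 1L, 1L), list(o, dn), function(g) {
    gs <- as.numeric(g)
    coef <- numeric(length(cnt))
    coef[seq_len(n_real)] <- gs * 2 * (sm[seq_len(n_real)] -
                                         am[seq_len(n_real)]) / (m * n_real)
    coef[cnt == 0] <- 0
    safe_cnt <- pmax(cnt, 1)
    dO <- sweep(outer(v, sm, function(a, b) a) -
                  matrix(sm, nrow(ov), ncol(ov), byrow = TRUE),
                2L, coef / safe_cnt, "*")
    dO[, cnt == 0] <- 0
    dvflat <- rowSums(sweep(ov, 2L, coef / safe_cnt, "*"))
    dtsp <- matrix(dvflat, n_case, len, byrow = TRUE)
    dd <- dtsp %*% t(ut)
    list(dO, dd)
  })
}

## ---- calibration -----------------------------------------------------------

#' Calibrate the auxiliary loss weights
#'
#' Runs `e` forward-only epochs (no optimizer steps, evaluation mode),
#' accumulates the adversarial and the two auxiliary generator losses, and
#' returns `w_a = E[L_G]/E[L_Ga]`, `w_t = E[L_G]/E[L_Gt]`, placing the
#' three loss terms on a similar scale at the calibration point.
#'
#' @param gen,disc Initialized models.
#' @param log Authentic `event_log`.
#' @param e Number of calibration epochs.
#' @param batch_size Batch size.
#' @param cap Weight cap when an auxiliary expectation is ~0.
#' @param seed Integer seed.
#' @return Named vector `c(w_a =, w_t =)` with the raw expectations in
#'   attribute `"expectations"`.
#' @export
calibrate_aux_weights <- function(gen, disc, log, e = 3L,
                                  batch_size = 32L, cap = 1e6,
                                  seed = 1L) {
  set.seed(seed)
  enc <- encode_log(log, max_len = gen$cfg$max_len)
  n <- nrow(enc$diffs)
  vocab <- enc$vocab
  l <- gen$cfg$max_len
  acc <- c(lg = 0, lga = 0, lgt = 0); nb <- 0L
  with_no_grad(list(gen, disc), {
    for (ep in seq_len(e)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (st in starts) {
        idx <- perm[st:min(st + batch_size - 1L, n)]
        m <- length(idx)
        z <- sample_random_input(vocab, l, m)
        gout <- generator_forward(gen, z, enc$dur_norm[idx],
                                  training = FALSE)
        oh_s <- gumbel_straight_through(gout$logits, gen$cfg$temperature)
        oh_a <- gather_rows(enc$onehot, idx, l)
        df_a <- enc$diffs[idx, , drop = FALSE]
        sc <- discriminator_score(disc, oh_s, gout$diffs, m)
        acc["lg"] <- acc["lg"] + generator_adversarial_loss(sc)
        acc["lga"] <- acc["lga"] +
          activity_divergence_loss(oh_a, ad_value(oh_s), m, vocab$n_real)
        acc["lgt"] <- acc["lgt"] +
          timestamp_divergence_loss(list(onehot = oh_a, diffs = df_a),
                                    list(onehot = ad_value(oh_s),
                                         diffs = ad_value(gout$diffs)),
                                    m, vocab$n_real)
        nb <- nb + 1L
      }
    }
  })
  ex <- acc / nb
  safe_div <- function(a, b) {
    if (b <= .Machine$double.eps) {
      warning("auxiliary loss expectation ~0; weight capped at ", cap)
      cap
    } else min(a / b, cap)
  }
  out <- c(w_a = safe_div(ex["lg"], ex["lga"]),
           w_t = safe_div(ex["lg"], ex["lgt"]))
  names(out) <- c("w_a", "w_t")
  attr(out, "expectations") <- ex
  out
}

## ---- timestamp decoding ----------------------------------------------------

#' Map timestamp differentials to absolute timestamps
#'
#' `T_real = duration_norm * (T_max - T_min) + T_min`;
#' `ts_i = T_real * sum_{r<=i} t_r`.  Timestamps are non-decreasing for
#' non-negative differentials.
#'
#' @param differentials Differential sequence in `[0, 1]`.
#' @param duration_norm Normalized conditional duration.
#' @param bounds Duration bounds `(T_min, T_max)`.
#' @return Numeric timestamp sequence starting near 0.
#' @export
map_timestamps <- function(differentials, duration_norm, bounds) {
  t_real <- duration_norm * (bounds[2L] - bounds[1L]) + bounds[1L]
  t_real * cumsum(differentials)
}

## ---- training loop ---------------------------------------------------------

gather_rows <- function(mat, idx, l) {
  rows <- rep((idx - 1L) * l, each = l) + seq_len(l)
  mat[rows, , drop = FALSE]
}

# discriminator accuracy on held-out authentic cases + an equal generated
# sample (evaluation mode, gradient-free)
holdout_accuracy <- function(gen, disc, enc, ho_idx) {
  l <- gen$cfg$max_len
  m <- length(ho_idx)
  with_no_grad(list(gen, disc), {
    z <- sample_random_input(enc$vocab, l, m)
    gout <- generator_forward(gen, z, enc$dur_norm[ho_idx],
                              training = FALSE)
    oh_s <- gumbel_straight_through(gout$logits, gen$cfg$temperature)
    sc_s <- discriminator_score(disc, oh_s, gout$diffs, m)
    sc_a <- discriminator_score(disc, gather_rows(enc$onehot, ho_idx, l),
                                enc$diffs[ho_idx, , drop = FALSE], m)
    mean(c(sc_a > 0.5, sc_s <= 0.5))
  })
}

snapshot_weights <- function(model) {
  lapply(model_params(model), function(p) p$value)
}

restore_weights <- function(model, weights) {
  ps <- model_params(model)
  stopifnot(length(ps) == length(weights))
  for (i in seq_along(ps)) ps[[i]]$value <- weights[[i]]
  invisible(model)
}

#' Adversarial training of the generator and discriminator
#'
#' Alternates generator updates every epoch with discriminator updates on
#' epochs divisible by `k`.  The generator objective is
#' `L_G + w_a L_Ga + w_t L_Gt` through the straight-through Gumbel-softmax
#' bridge; conditional durations are matched to the authentic batch.  A
#' checkpoint (weight snapshots, held-out discriminator accuracy, a small
#' generated sample) is recorded every `checkpoint_interval` epochs.  Runs
#' are fully reproducible from `cfg$seed`.
#'
#' @param gen,disc Initialized models (modified in place).
#' @param log Authentic `event_log`.
#' @param cfg A `training_config`.
#' @return A list with `checkpoints`, the per-epoch `losses` data frame
#'   (`epoch`, `loss_g`, `loss_d`, `loss_ga`, `loss_gt`, `d_accuracy`,
#'   `d_updated`),
#'   the calibrated `aux_weights`, and the trained models.
#' @export
train_gan <- function(gen, disc, log, cfg) {
  set.seed(cfg$seed)
  l <- gen$cfg$max_len
  enc <- encode_log(log, max_len = l)
  n <- nrow(enc$diffs)
  vocab <- enc$vocab
  n_ho <- max(2L, round(cfg$holdout_frac * n))
  ho_idx <- sample.int(n, n_ho)
  tr_idx <- setdiff(seq_len(n), ho_idx)

  if (identical(cfg$aux_weights, "auto")) {
    w <- calibrate_aux_weights(gen, disc, log, e = cfg$calibration_epochs,
                               batch_size = cfg$batch_size,
                               cap = cfg$aux_weight_cap,
                               seed = cfg$seed + 1L)
  } else {
    w <- c(w_a = cfg$aux_weights[1L], w_t = cfg$aux_weights[2L])
  }
  w_a <- if (cfg$use_act_loss) unname(w["w_a"]) else 0
  w_t <- if (cfg$use_time_loss) unname(w["w_t"]) else 0

  adam_g <- adam_init(model_params(gen), lr = cfg$lr_g,
                      beta1 = cfg$betas[1L], beta2 = cfg$betas[2L])
  adam_d <- adam_init(model_params(disc), lr = cfg$lr_d,
                      beta1 = cfg$betas[1L], beta2 = cfg$betas[2L])

  losses <- data.frame(epoch = seq_len(cfg$epochs), loss_g = NA_real_,
                       loss_d = NA_real_, loss_ga = NA_real_,
                       loss_gt = NA_real_, d_accuracy = NA_real_,
                       d_updated = FALSE)
  checkpoints <- list()
  last_ld <- NA_real_

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample(tr_idx)
    starts <- seq(1L, length(perm), by = cfg$batch_size)
    ep_lg <- ep_lga <- ep_lgt <- 0; nb <- 0L
    ep_ld <- 0; nd <- 0L
    d_epoch <- (epoch %% cfg$k) == 0L

    for (st in starts) {
      idx <- perm[st:min(st + cfg$batch_size - 1L, length(perm))]
      m <- length(idx)
      oh_a <- gather_rows(enc$onehot, idx, l)
      df_a <- enc$diffs[idx, , drop = FALSE]

      # ---- generator update
      z <- sample_random_input(vocab, l, m)
      gout <- generator_forward(gen, z, enc$dur_norm[idx], training = TRUE)
      oh_s <- gumbel_straight_through(gout$logits, gen$cfg$temperature)
      sc_s <- discriminator_forward(disc, oh_s, gout$diffs, m,
                                    training = TRUE)
      lg <- ad_scale(ad_mean(ad_log(sc_s, eps = LOG_EPS)), -1)
      total <- lg
      lga_v <- lgt_v <- 0
      if (w_a > 0) {
        lga <- ad_act_divergence(oh_s, batch_activity_freq(oh_a), m,
                                 vocab$n_real)
        lga_v <- as.numeric(lga$value)
        total <- ad_add(total, ad_scale(lga, w_a))
      }
      if (w_t > 0) {
        am <- batch_time_means(oh_a, df_a)
        lgt <- ad_time_divergence(oh_s, gout$diffs, am, m, vocab$n_real, l)
        lgt_v <- as.numeric(lgt$value)
        total <- ad_add(total, ad_scale(lgt, w_t))
      }
      if (!is.finite(total$value)) {
        stop("non-finite generator loss at epoch ", epoch)
      }
      ad_zero_grad(adam_g$params); ad_zero_grad(adam_d$params)
      ad_backward(total)
      adam_step(adam_g)
      ep_lg <- ep_lg + as.numeric(lg$value)
      ep_lga <- ep_lga + lga_v; ep_lgt <- ep_lgt + lgt_v; nb <- nb + 1L

      # ---- discriminator update (epochs divisible by k)
      if (d_epoch) {
        syn <- with_no_grad(list(gen), {
          z2 <- sample_random_input(vocab, l, m)
          g2 <- generator_forward(gen, z2, enc$dur_norm[idx],
                                  training = FALSE)
          list(onehot = ad_value(gumbel_straight_through(
                 g2$logits, gen$cfg$temperature)),
               diffs = ad_value(g2$diffs))
        })
        sc_a <- discriminator_forward(disc, oh_a, df_a, m, training = TRUE)
        sc_f <- discriminator_forward(disc, syn$onehot, syn$diffs, m,
                                      training = TRUE)
        ld <- ad_sub(ad_scale(ad_mean(ad_log(sc_a, eps = LOG_EPS)), -1),
                     ad_mean(ad_log(ad_sub(ad_const(
                       matrix(1, m, 1L)), sc_f), eps = LOG_EPS)))
        if (!is.finite(ld$value)) {
          stop("non-finite discriminator loss at epoch ", epoch)
        }
        ad_zero_grad(adam_d$params); ad_zero_grad(adam_g$params)
        ad_backward(ld)
        adam_step(adam_d)
        ep_ld <- ep_ld + as.numeric(ld$value); nd <- nd + 1L
      }
    }

    acc <- holdout_accuracy(gen, disc, enc, ho_idx)
    if (nd > 0L) last_ld <- ep_ld / nd
    losses[epoch, 2:6] <- c(ep_lg / nb, last_ld, ep_lga / nb,
                            ep_lgt / nb, acc)
    losses$d_updated[epoch] <- d_epoch

    if (epoch %% cfg$checkpoint_interval == 0L || epoch == cfg$epochs) {
      sample_log <- generate_log(gen, min(32L, n), log,
                                 seed = cfg$seed + 1000L + epoch,
                                 renormalize = cfg$renormalize_differentials)
      checkpoints[[length(checkpoints) + 1L]] <-
        list(epoch = epoch,
             gen_weights = snapshot_weights(gen),
             disc_weights = snapshot_weights(disc),
             d_accuracy = acc,
             sample = as.data.frame(sample_log),
             loss_g = ep_lg / nb, loss_d = last_ld)
    }
  }

  list(checkpoints = checkpoints, losses = losses,
       aux_weights = c(w_a = w_a, w_t = w_t),
       generator = gen, discriminator = disc,
       holdout_idx = ho_idx)
}

#' Select the equilibrium checkpoint
#'
#' Returns the checkpoint whose held-out discriminator accuracy is nearest
#' 0.5 (the generator is fooling the discriminator); ties break toward the
#' later epoch.
#'
#' @param checkpoints List of checkpoints from [train_gan()].
#' @return The chosen checkpoint.
#' @export
select_equilibrium_checkpoint <- function(checkpoints) {
  stopifnot(length(checkpoints) >= 1L)
  # distances rounded so floating-point noise cannot decide a tie
  dist <- round(vapply(checkpoints, function(ck) abs(ck$d_accuracy - 0.5),
                       numeric(1)), 9L)
  epochs <- vapply(checkpoints, function(ck) ck$epoch, numeric(1))
  best <- which(dist == min(dist))
  checkpoints[[best[which.max(epochs[best])]]]
}

#' Generate a synthetic event log from a trained generator
#'
#' For each case a random input sequence and a conditional duration (drawn
#' from the authentic durations) are fed through the generator; positions
#' decode to the most probable activity, pad positions are dropped (with
#' their differentials), the remaining differentials are optionally
#' rescaled to sum to 1, and timestamps are mapped by cumulative summation
#' times the conditional duration.  Cases decoding to all-pad are retried
#' with a fresh input (bounded), falling back to the most confident
#' non-pad position.
#'
#' @param gen A trained `generator`.
#' @param n_cases Number of synthetic cases.
#' @param log Authentic `event_log` supplying the conditional durations,
#'   bounds, and vocabulary.
#' @param seed Integer seed.
#' @param renormalize Rescale kept differentials to sum to 1.
#' @param max_retries Retries for all-pad decodes.
#' @return A synthetic `event_log`.
#' @export
generate_log <- function(gen, n_cases, log, seed = 1L,
                         renormalize = TRUE, max_retries = 10L) {
  set.seed(seed)
  vocab <- log$vocabulary
  l <- gen$cfg$max_len
  bounds <- log$duration_bounds
  width <- max(4L, nchar(as.character(n_cases)))
  cases <- vector("list", n_cases)
  with_no_grad(list(gen), {
    for (i in seq_len(n_cases)) {
      cond <- sample_conditional_duration(log, 1L)
      for (try in seq_len(max_retries + 1L)) {
        z <- sample_random_input(vocab, l, 1L)
        gout <- generator_forward(gen, z, cond$duration_norm,
                                  training = FALSE)
        probs <- gout$activity_probs
        pick <- max.col(probs, ties.method = "first")
        keep <- which(pick != vocab$pad_index)
        if (length(keep)) break
      }
      if (!length(keep)) {
        # fall back: most confident real-activity position
        real_probs <- probs[, -vocab$pad_index, drop = FALSE]
        pos <- which.max(apply(real_probs, 1L, max))
        keep <- pos
        pick[pos] <- which.max(real_probs[pos, ])
      }
      d <- ad_value(gout$diffs)[1L, keep]
      if (renormalize && sum(d) > 0) d <- d / sum(d)
      ts <- map_timestamps(d, cond$duration_norm, bounds)
      cases[[i]] <- process_case(
        sprintf(paste0("synth_%0", width, "d"), i),
        vocab$labels[pick[keep]], ts)
    }
  })
  out <- event_log(cases, time_unit = log$time_unit)
  out
}

## ---- checkpoint serialization ---------------------------------------------

#' Save a generator (or checkpoint weights) to disk
#'
#' Writes an RDS with the config, weights, and the RNG state, plus a JSON
#' sidecar carrying the config and its MD5 hash.
#'
#' @param gen A `generator`.
#' @param path Output path (`.rds`).
#' @return Invisibly, `path`.
#' @export
save_generator <- function(gen, path) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize the RNG state
  }
  obj <- list(cfg = unclass(gen$cfg),
              weights = snapshot_weights(gen),
              rng_state = get(".Random.seed", envir = globalenv(),
                              inherits = FALSE))
  saveRDS(obj, path)
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj$cfg, auto_unbox = TRUE), tmp)
  sidecar <- list(config = obj$cfg,
                  config_md5 = unname(tools::md5sum(tmp)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a generator saved by [save_generator()]
#'
#' @param path RDS path.
#' @param restore_rng Restore the RNG state stored with the checkpoint so
#'   generation resumes bit-identically.
#' @return A `generator`.
#' @export
load_generator <- function(path, restore_rng = FALSE) {
  obj <- readRDS(path)
  cfg <- do.call(generator_config, obj$cfg[setdiff(names(obj$cfg), NULL)])
  gen <- init_generator(cfg, seed = 1L)
  restore_weights(gen, obj$weights)
  if (restore_rng) {
    assign(".Random.seed", obj$rng_state, envir = globalenv())
  }
  gen
}
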