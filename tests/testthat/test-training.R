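test_that("adversarial loss identities match hand arithmetic", {
  expect_equal(generator_adversarial_loss(c(1, 1, 1)), 0)
  expect_equal(generator_adversarial_loss(rep(exp(-1), 4)), 1)
  expect_equal(generator_adversarial_loss(c(0.5, 0.25)),
               (log(2) + log(4)) / 2, tolerance = 1e-9)
  expect_equal(discriminator_loss(c(1, 1), c(0, 0)), 0, tolerance = 1e-6)
  expect_equal(discriminator_loss(rep(0.5, 3), rep(0.5, 3)), 2 * log(2),
               tolerance = 1e-9)
  # symmetric under swapping an authentic score s with a synthetic 1 - s
  s <- c(0.3, 0.8)
  expect_equal(discriminator_loss(s, c(0.4, 0.9)),
               discriminator_loss(c(0.6, 0.1), 1 - s), tolerance = 1e-12)
})

toy_onehot <- function(idx, nv) diag(nv)[idx, , drop = FALSE]

test_that("activity divergence follows the frequency MSE definition", {
  nv <- 3L  # 2 real + pad
  a <- toy_onehot(c(1, 1), nv)   # m = 1, l = 2, all activity 1
  s <- toy_onehot(c(2, 2), nv)   # all activity 2
  expect_equal(activity_divergence_loss(a, a, 1L, 2L), 0)
  expect_equal(activity_divergence_loss(a, s, 1L, 2L), 1)  # (1+1)/(1*2)
  expect_equal(activity_divergence_loss(a, s, 1L, 2L),
               activity_divergence_loss(s, a, 1L, 2L))
})

test_that("timestamp divergence compares per-activity mean cumulative times", {
  nv <- 3L
  a <- list(onehot = toy_onehot(c(1, 2), nv),
            diffs = matrix(c(0, 0.5), 1))
  s <- list(onehot = toy_onehot(c(1, 2), nv),
            diffs = matrix(c(0, 0.4), 1))
  expect_equal(timestamp_divergence_loss(a, a, 1L, 2L), 0)
  # per-activity mean gaps (0, 0.1) -> 0.01 / 2
  expect_equal(timestamp_divergence_loss(a, s, 1L, 2L), 0.005,
               tolerance = 1e-12)
  expect_equal(timestamp_divergence_loss(a, s, 1L, 2L),
               timestamp_divergence_loss(s, a, 1L, 2L))
})

test_that("autodiff twins agree with the numeric losses and differentiate", {
  set.seed(19)
  nv <- 4L; m <- 3L; l <- 5L
  oh_s <- diag(nv)[sample.int(nv, m * l, replace = TRUE), ]
  oh_a <- diag(nv)[sample.int(nv, m * l, replace = TRUE), ]
  d_s <- matrix(runif(m * l, 0, 0.4), m, l); d_s[, 1] <- 0
  d_a <- matrix(runif(m * l, 0, 0.4), m, l); d_a[, 1] <- 0
  n_real <- nv - 1L
  af <- tracegan:::batch_activity_freq(oh_a)
  node <- tracegan:::ad_param(oh_s)
  lga <- tracegan:::ad_act_divergence(node, af, m, n_real)
  expect_equal(as.numeric(lga$value),
               activity_divergence_loss(oh_a, oh_s, m, n_real),
               tolerance = 1e-12)
  am <- tracegan:::batch_time_means(oh_a, d_a)
  on <- tracegan:::ad_param(oh_s); dn <- tracegan:::ad_param(d_s)
  lgt <- tracegan:::ad_time_divergence(on, dn, am, m, n_real, l)
  expect_equal(as.numeric(lgt$value),
               timestamp_divergence_loss(list(onehot = oh_a, diffs = d_a),
                                         list(onehot = oh_s, diffs = d_s),
                                         m, n_real), tolerance = 1e-12)
  # gradient of the timestamp divergence w.r.t. the differentials
  tracegan:::ad_backward(lgt)
  fn <- function(z) {
    timestamp_divergence_loss(list(onehot = oh_a, diffs = d_a),
                              list(onehot = oh_s, diffs = z), m, n_real)
  }
  expect_lt(max(abs(dn$grad - num_grad(fn, d_s))), 1e-6)
})

test_that("calibration puts the three losses on one scale", {
  log <- fixture_small
  l <- max(case_lengths(log))
  nv <- length(log$vocabulary$labels)
  gen <- init_generator(generator_config(nv, l, hidden_size = 16L,
                                         n_layers = 1L), seed = 2L)
  disc <- init_discriminator(discriminator_config(nv, l, n_layers = 1L),
                             seed = 3L)
  w <- calibrate_aux_weights(gen, disc, log, e = 2L, seed = 5L)
  ex <- attr(w, "expectations")
  expect_equal(unname(w["w_a"] * ex["lga"]), unname(ex["lg"]),
               tolerance = 1e-9)
  expect_equal(unname(w["w_t"] * ex["lgt"]), unname(ex["lg"]),
               tolerance = 1e-9)
  # total generator objective at the calibration point ~ 3 E[L_G]
  expect_equal(unname(ex["lg"] + w["w_a"] * ex["lga"] + w["w_t"] * ex["lgt"]),
               unname(3 * ex["lg"]), tolerance = 1e-9)
})

small_fit <- function(epochs = 6L, seed = 21L, n_cases = 30L) {
  log <- simulate_log(clinic_small_spec(n_cases = n_cases, seed = 17L))
  l <- max(case_lengths(log))
  nv <- length(log$vocabulary$labels)
  gen <- init_generator(generator_config(nv, l, hidden_size = 16L,
                                         n_heads = 2L, n_layers = 1L),
                        seed = seed)
  disc <- init_discriminator(discriminator_config(nv, l, n_layers = 1L),
                             seed = seed + 1L)
  cfg <- training_config(epochs = epochs, batch_size = 16L, seed = seed,
                         checkpoint_interval = 3L, calibration_epochs = 1L)
  list(fit = train_gan(gen, disc, log, cfg), log = log, gen = gen)
}

test_that("the alternating schedule updates D on epochs divisible by k", {
  res <- small_fit(epochs = 10L)
  expect_equal(sum(res$fit$losses$d_updated), 5L)  # k = 2 over 10 epochs
  expect_equal(which(res$fit$losses$d_updated), seq(2L, 10L, by = 2L))
  expect_true(all(is.finite(res$fit$losses$loss_g)))
})

test_that("identical seeds give identical loss reports", {
  a <- small_fit(epochs = 4L, seed = 31L)
  b <- small_fit(epochs = 4L, seed = 31L)
  expect_identical(a$fit$losses, b$fit$losses)
})

test_that("equilibrium selection picks accuracy nearest 0.5, later on ties", {
  cks <- list(list(epoch = 50, d_accuracy = 0.9),
              list(epoch = 100, d_accuracy = 0.55),
              list(epoch = 150, d_accuracy = 0.45))
  # 0.55 and 0.45 are an exact tie in |acc - 0.5|: the later epoch wins
  expect_equal(select_equilibrium_checkpoint(cks)$epoch, 150)
  expect_equal(select_equilibrium_checkpoint(
    list(list(epoch = 50, d_accuracy = 0.9),
         list(epoch = 100, d_accuracy = 0.52),
         list(epoch = 150, d_accuracy = 0.45)))$epoch, 100)
  expect_equal(select_equilibrium_checkpoint(cks[1])$epoch, 50)
  tie <- list(list(epoch = 50, d_accuracy = 0.6),
              list(epoch = 100, d_accuracy = 0.4))
  expect_equal(select_equilibrium_checkpoint(tie)$epoch, 100)
})

test_that("map_timestamps scales cumulative differentials by the duration", {
  expect_equal(map_timestamps(c(0, 0.25, 0.75), 1, c(0, 100)),
               c(0, 25, 100))
  expect_equal(map_timestamps(rep(0, 4), 0.5, c(0, 100)), rep(0, 4))
  set.seed(23)
  for (i in 1:20) {
    d <- runif(6, 0, 0.5)
    ts <- map_timestamps(d, runif(1), c(10, 500))
    expect_true(all(diff(ts) >= 0))
  }
})

test_that("generated logs are valid event logs over the real vocabulary", {
  res <- small_fit(epochs = 2L)
  synth <- generate_log(res$gen, 15L, res$log, seed = 5L)
  expect_length(synth$cases, 15L)
  real <- res$log$vocabulary$labels[seq_len(res$log$vocabulary$n_real)]
  for (cs in synth$cases) {
    expect_true(all(diff(cs$timestamps) >= 0))
    expect_true(all(cs$activities %in% real))
  }
})

test_that("checkpoint save/load round trip regenerates bit-identically", {
  res <- small_fit(epochs = 2L)
  path <- tempfile(fileext = ".rds")
  set.seed(99)  # RNG state stored with the checkpoint
  save_generator(res$gen, path)
  s1 <- generate_log(res$gen, 5L, res$log, seed = 7L)
  gen2 <- load_generator(path, restore_rng = TRUE)
  s2 <- generate_log(gen2, 5L, res$log, seed = 7L)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$config$max_len, res$gen$cfg$max_len)
})

test_that("ablation toggles disable the auxiliary losses", {
  log <- simulate_log(clinic_small_spec(n_cases = 20L, seed = 17L))
  l <- max(case_lengths(log))
  nv <- length(log$vocabulary$labels)
  gen <- init_generator(generator_config(nv, l, hidden_size = 8L,
                                         n_heads = 2L, n_layers = 1L),
                        seed = 1L)
  disc <- init_discriminator(discriminator_config(nv, l, n_layers = 1L),
                             seed = 2L)
  cfg <- training_config(epochs = 2L, batch_size = 10L, seed = 3L,
                         use_act_loss = FALSE, use_time_loss = FALSE,
                         calibration_epochs = 1L)
  fit <- train_gan(gen, disc, log, cfg)
  expect_equal(unname(fit$aux_weights), c(0, 0))
  expect_equal(fit$losses$loss_ga, rep(0, 2))
})
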