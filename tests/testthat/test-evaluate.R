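test_that("classification accuracy is the exact percentage of correct labels", {
  expect_equal(classification_accuracy(c("a", "b"), c("a", "b")), 100)
  expect_equal(classification_accuracy(c("a", "b", "a", "a"),
                                       c("a", "b", "b", "a")), 75)
  expect_equal(classification_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_error(classification_accuracy(character(0), character(0)), "empty")
  expect_error(classification_accuracy("a", c("a", "b")), "length")
})

test_that("repetition folds are contiguous blocks of balanced size", {
  blocks <- rscmotion:::fold_blocks(30, 4)
  expect_equal(lengths(blocks), c(8L, 8L, 7L, 7L))
  expect_equal(unlist(blocks), 1:30)
  expect_equal(lengths(rscmotion:::fold_blocks(8, 4)), rep(2L, 4))
})

test_that("folds partition repetitions disjointly and windows follow them", {
  session <- small_session(seed = 2, n_repetitions = 6)
  ds <- segment_windows(concatenate_recordings(session), 300, 100)
  fold <- rscmotion:::window_folds(ds$labels, ds$rep_of_window, 4)
  expect_true(all(fold %in% 1:4))
  # each (class, repetition) pair maps to exactly one fold
  key <- paste(ds$labels, ds$rep_of_window)
  expect_true(all(tapply(fold, key, function(f) length(unique(f))) == 1))
})

test_that("cross-validation reports are internally consistent", {
  session <- small_session(seed = 1, n_repetitions = 6)
  ds <- segment_windows(concatenate_recordings(session), 300, 100)
  rep <- cross_validate(ds, c("RMS", "WL"), classifier_spec("KNN"), 4)

  expect_s3_class(rep, "rsc_eval")
  expect_true(rep$ca_pct >= 0 && rep$ca_pct <= 100)
  # confusion rows sum to 100
  expect_equal(unname(rowSums(rep$confusion_pct)), rep(100, 6),
               tolerance = 1e-9)
  # overall CA equals the label-frequency-weighted mean of per-class CAs
  w <- rowSums(rep$confusion_counts) / sum(rep$confusion_counts)
  expect_equal(rep$ca_pct, sum(w * rep$per_class_ca_pct), tolerance = 1e-9)
  # per-class CA is the diagonal of the row-normalised confusion matrix
  expect_equal(rep$per_class_ca_pct, diag(rep$confusion_pct))
  expect_length(rep$folds, 4)
  expect_error(cross_validate(ds, c("RMS"), classifier_spec("KNN"), 8),
               "repetitions")
})

test_that("cross-validation is deterministic given fixed config and seeds", {
  session <- small_session(seed = 4, n_repetitions = 5)
  ds <- segment_windows(concatenate_recordings(session), 300, 100)
  r1 <- cross_validate(ds, c("RMS", "WL"), classifier_spec("SVM"), 4)
  r2 <- cross_validate(ds, c("RMS", "WL"), classifier_spec("SVM"), 4)
  expect_identical(r1, r2)
})

test_that("SFS grows the set greedily one feature at a time", {
  session <- small_session(seed = 3, n_repetitions = 5)
  ds <- segment_windows(concatenate_recordings(session), 300, 100)
  spec <- classifier_spec("KNN")
  res <- sfs_select(ds, spec, max_features = 3, n_folds = 4,
                    candidate_ids = c("MAV", "RMS", "WL", "KURT"))
  expect_s3_class(res, "rsc_sfs")
  expect_length(res$steps, 3)
  sets <- lapply(res$steps, function(s) s$set)
  expect_equal(lengths(sets), 1:3)
  for (k in 2:3) expect_true(all(sets[[k - 1]] %in% sets[[k]]))
  # step-1 winner is the argmax over single-feature evaluations
  singles <- vapply(c("MAV", "RMS", "WL", "KURT"), function(f)
    cross_validate(ds, f, spec, 4)$ca_pct, numeric(1))
  expect_equal(res$steps[[1]]$added, names(singles)[which.max(singles)])
  # one-step boundary case
  res1 <- sfs_select(ds, spec, max_features = 1,
                     candidate_ids = c("RMS", "WL"))
  expect_length(res1$steps, 1)
  expect_error(sfs_select(ds, spec, max_features = 20), "max_features")
})

test_that("SFS finds the single informative feature in a constructed problem", {
  # windows drawn so only RMS (scale) separates classes: same-shape noise
  # at class-specific amplitudes; KURT and the like carry nothing
  set.seed(12)
  n_rep <- 8
  recs <- list()
  for (cl in c("low", "mid", "high")) {
    amp <- switch(cl, low = 1, mid = 4, high = 16)
    for (r in seq_len(n_rep)) {
      recs[[length(recs) + 1]] <-
        new_recording(matrix(rnorm(400, sd = amp), ncol = 2), 100, cl, r)
    }
  }
  ds <- segment_windows(concatenate_recordings(recs), 300, 100)
  res <- sfs_select(ds, classifier_spec("KNN"), max_features = 2,
                    n_folds = 4, candidate_ids = c("RMS", "KURT"))
  expect_equal(res$steps[[1]]$added, "RMS")
  expect_gt(res$steps[[1]]$ca_pct, 80)
  # accuracy plateaus: adding KURT gains little
  expect_lt(abs(res$steps[[2]]$ca_pct - res$steps[[1]]$ca_pct), 10)
  expect_equal(res$best_set, "RMS")
})

test_that("window sweep evaluates each unique length once", {
  session <- small_session(seed = 6, n_repetitions = 5)
  tab <- suppressWarnings(
    window_sweep(session, c(100, 300), ids = c("RMS", "WL")))
  expect_equal(tab$window_ms, c(100, 300))
  expect_true(all(tab$ca_pct >= 0 & tab$ca_pct <= 100))
  expect_warning(
    tab2 <- window_sweep(session, c(300, 300), ids = c("RMS", "WL"),
                         notch_hz = NA),
    "duplicated")
  expect_equal(nrow(tab2), 1)
})

test_that("the zero-noise sweep row reproduces the clean pipeline exactly", {
  session <- small_session(seed = 8, n_repetitions = 5)
  clean <- quiet_evaluate(session, ids = c("RMS", "WL"))
  tab <- suppressWarnings(
    noise_sweep(session, ratios_pct = c(0, 60), ids = c("RMS", "WL"),
                seeds = 1:2))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$ca_mean_pct[1], clean$ca_pct)
  expect_equal(tab$ca_sd_pct[1], 0)
  expect_error(noise_sweep(session, ratios_pct = -10), "ratios")
})

test_that("evaluate_session composes the modules end to end", {
  session <- small_session(seed = 10, n_repetitions = 5)
  rep <- quiet_evaluate(session, ids = c("RMS", "WL"),
                        spec = classifier_spec("KNN"))
  expect_s3_class(rep, "rsc_eval")
  expect_equal(sort(rownames(rep$confusion_pct)), sort(motion_classes()))
  # leak-free strict mode also runs
  rep_strict <- quiet_evaluate(session, ids = c("RMS", "WL"),
                               straddle = FALSE)
  expect_s3_class(rep_strict, "rsc_eval")
})
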