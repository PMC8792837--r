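test_that("hand-computed example values are reproduced", {
  x <- c(1, -1, 2, -2)
  expect_equal(compute_feature("MAV", x), 1.5)
  expect_equal(compute_feature("WL", x), 9)     # 2 + 3 + 4
  expect_equal(compute_feature("AAC", x), 2.25) # 9 / 4
  ones <- rep(1, 5)
  expect_equal(compute_feature("SSI", ones), 5)
  expect_equal(compute_feature("RMS", ones), 1)
  expect_equal(compute_feature("TM3", ones), 1)
  expect_equal(compute_feature("TM4", ones), 1)
  expect_equal(compute_feature("TM5", ones), 1)
  expect_equal(compute_feature("LOGD", ones), 1, tolerance = 1e-12)
})

test_that("constant and degenerate windows take their defined values", {
  c0 <- rep(3.2, 10)
  for (id in c("WL", "AAC", "VAR", "STD", "DASDV"))
    expect_equal(compute_feature(id, c0), 0, info = id)
  expect_equal(compute_feature("MAV", c0), 3.2)
  expect_equal(compute_feature("RMS", c0), 3.2)
  expect_equal(compute_feature("LOGD", c0), 3.2, tolerance = 1e-12)
  # all-zero window: KURT is defined as 0, LOGD stays finite
  z <- rep(0, 8)
  expect_equal(compute_feature("KURT", z), 0)
  expect_true(is.finite(compute_feature("LOGD", z)))
  expect_error(compute_feature("MAV", 1), "N >= 2")
  expect_error(compute_feature("MAV", c(1, NA)), "finite")
  expect_error(compute_feature("XYZ", 1:5))
})

test_that("all 13 features agree with the literal-formula oracle", {
  set.seed(101)
  for (i in 1:200) {
    x <- random_window(sample(2:100, 1))
    for (id in feature_ids()) {
      got <- compute_feature(id, x)
      want <- oracle_feature(id, x)
      expect_equal(got, want, tolerance = 1e-10, info = id)
    }
  }
})

test_that("algebraic identities hold on random windows", {
  set.seed(7)
  for (i in 1:100) {
    x <- random_window(sample(2:80, 1))
    n <- length(x)
    expect_equal(compute_feature("STD", x), sqrt(compute_feature("VAR", x)),
                 tolerance = 1e-10)
    expect_equal(compute_feature("SSI", x), n * compute_feature("RMS", x)^2,
                 tolerance = 1e-10)
    expect_equal(n * compute_feature("AAC", x), compute_feature("WL", x),
                 tolerance = 1e-10)
    expect_equal(compute_feature("DASDV", x)^2 * (n - 1), sum(diff(x)^2),
                 tolerance = 1e-10)
    # power-mean inequality
    expect_lte(compute_feature("MAV", x), compute_feature("RMS", x))
  }
})

test_that("features scale with the documented homogeneity degrees", {
  degrees <- c(MAV = 1, WL = 1, AAC = 1, SSI = 2, RMS = 1, VAR = 2, STD = 1,
               DASDV = 1, TM3 = 3, TM4 = 4, TM5 = 5, KURT = -6, LOGD = 1)
  set.seed(21)
  for (i in 1:20) {
    x <- random_window(30)
    for (a in c(0.5, 2, 10)) {
      for (id in names(degrees)) {
        expect_equal(compute_feature(id, a * x),
                     a^degrees[[id]] * compute_feature(id, x),
                     tolerance = 1e-9, info = paste(id, a))
      }
    }
  }
})

test_that("features other than KURT are invariant to sign flips of the window", {
  # KURT as printed centres |x| on the *signed* mean, so it is the one
  # feature that changes under x -> -x; the other twelve are even.
  set.seed(33)
  for (i in 1:30) {
    x <- random_window(25)
    for (id in setdiff(feature_ids(), "KURT"))
      expect_equal(compute_feature(id, -x), compute_feature(id, x),
                   tolerance = 1e-12, info = id)
    expect_equal(compute_feature("KURT", -x), oracle_feature("KURT", -x),
                 tolerance = 1e-10)
  }
})

test_that("the standard-kurtosis option computes the conventional moment ratio", {
  set.seed(5)
  x <- rnorm(500)
  m <- mean(x)
  want <- mean((x - m)^4) / mean((x - m)^2)^2
  expect_equal(compute_feature("KURT", x, kurt_standard = TRUE), want)
  # the as-printed form differs from the conventional one
  expect_false(isTRUE(all.equal(compute_feature("KURT", x), want)))
})

test_that("extraction assembles channel-major matrices consistent with compute_feature", {
  session <- small_session(seed = 3, n_repetitions = 4)
  ds <- segment_windows(concatenate_recordings(session), 300, 100)
  n_ch <- dim(ds$windows)[3]

  # columns are channel-major with features in canonical feature_ids()
  # order (WL precedes RMS) regardless of the order requested
  fm2 <- extract_features(ds, c("RMS", "WL"))
  expect_equal(ncol(fm2$values), 2 * n_ch)
  expect_equal(colnames(fm2$values)[1:2], c("ch1_WL", "ch1_RMS"))

  fm13 <- extract_features(ds)
  expect_equal(ncol(fm13$values), 13 * n_ch)
  expect_true(all(is.finite(fm13$values)))
  expect_identical(fm13$labels, ds$labels)
  expect_identical(fm13$rep_of_window, ds$rep_of_window)

  # single window row matches direct calls
  for (ch in seq_len(n_ch)) {
    for (id in c("MAV", "KURT", "LOGD")) {
      expect_equal(fm13$values[5, paste0("ch", ch, "_", id)],
                   compute_feature(id, ds$windows[5, , ch]),
                   ignore_attr = TRUE)
    }
  }
  expect_error(extract_features(ds, character(0)), "non-empty")
  expect_error(extract_features(ds, c("RMS", "RMS")), "distinct")
})

test_that("feature matrices round-trip through TSV", {
  session <- small_session(seed = 6, n_repetitions = 4)
  ds <- segment_windows(concatenate_recordings(session), 300, 100)
  fm <- extract_features(ds, c("RMS", "WL", "MAV"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(fm, path)
  back <- read_features(path)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_equal(as.character(back$labels), as.character(fm$labels))
  expect_equal(back$rep_of_window, fm$rep_of_window)
})
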