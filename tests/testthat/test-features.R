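# Tilt angles, statistical moments and the z-scored feature matrix.

test_that("tilt angle reproduces the analytic reference directions", {
  g <- 9.81
  expect_equal(tilt_angle(0, 0, g), 0)
  expect_equal(tilt_angle(g, 0, 0), 90)
  expect_equal(tilt_angle(0, 0, -g), 180)
  expect_equal(tilt_angle(0, g, 0), 90)
  expect_true(is.na(tilt_angle(0, 0, 0)))
})

test_that("tilt angle is scale invariant and bounded", {
  set.seed(8)
  a <- matrix(rnorm(300), ncol = 3)
  phi <- tilt_angle(a[, 1], a[, 2], a[, 3])
  for (c_scale in c(0.01, 1, 250)) {
    expect_equal(tilt_angle(c_scale * a[, 1], c_scale * a[, 2],
                            c_scale * a[, 3]), phi, tolerance = 1e-9)
  }
  expect_true(all(phi >= 0 & phi <= 180))
})

test_that("max tilt delta follows the signed difference", {
  expect_equal(max_delta_tilt(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(max_delta_tilt(c(11, 12), c(1, 2)), 10)
  expect_equal(max_delta_tilt(c(0, 30, 10), c(0, 10, 20)), 20)
  # anti-symmetric in its arguments only up to max vs min
  expect_equal(max_delta_tilt(c(0, 10, 20), c(0, 30, 10)), 10)
  expect_error(max_delta_tilt(1:3, 1:4), "equal length")
})

test_that("statistical moments match hand computations and e1071", {
  st <- stat_features(c(3, 4))
  expect_equal(st$aRMS, sqrt(12.5))
  expect_equal(st$variance, 0.25)
  expect_equal(st$max, 4)

  st2 <- stat_features(c(-1, 1))
  expect_equal(st2$kurtosis, 1)
  expect_equal(st2$skewness, 0)

  # symmetric series: odd central moment vanishes
  expect_equal(stat_features(c(-3, -1, 1, 3))$skewness, 0)

  skip_if_not_installed("e1071")
  set.seed(11)
  x <- rnorm(500)
  st3 <- stat_features(x)
  expect_equal(st3$skewness, e1071::skewness(x, type = 1),
               tolerance = 1e-12)
  expect_equal(st3$kurtosis, e1071::kurtosis(x, type = 1) + 3,
               tolerance = 1e-12)
  expect_equal(st3$variance, mean((x - mean(x))^2), tolerance = 1e-12)
})

test_that("constant series yields zero skewness/kurtosis with a warning", {
  expect_warning(st <- stat_features(rep(2, 10)), "constant")
  expect_equal(st$skewness, 0)
  expect_equal(st$kurtosis, 0)
  expect_equal(st$variance, 0)
})

test_that("the feature vocabulary has 50 and 16 names", {
  full <- feature_names("all_sensors")
  expect_length(full, 50)
  expect_false(anyDuplicated(full) > 0)
  expect_true(all(c("var_Y2", "aRMS_Z3", "maxdphi_1_2", "phiRMS_1") %in%
                    full))
  for (s in 1:3) {
    single <- feature_names("single_sensor", s)
    expect_length(single, 16)
    expect_true(all(grepl(paste0(s, "$|_", s, "$"), single)))
  }
  expect_error(feature_names("single_sensor"), "sensor")
})

test_that("feature matrices have the study dimensions and exact z-scores", {
  fm <- small_feature_matrix()
  expect_equal(nrow(fm), 18)
  expect_length(feature_columns(fm), 50)
  z <- as.matrix(fm[feature_columns(fm)])
  expect_lt(max(abs(colMeans(z))), 1e-9)
  sd_pop <- sqrt(colMeans(sweep(z, 2, colMeans(z))^2))
  expect_lt(max(abs(sd_pop - 1)), 1e-9)

  fm2 <- small_feature_matrix(mode = "single_sensor", sensor = 2)
  expect_length(feature_columns(fm2), 16)
})

test_that("kurtosis dominates squared skewness on every computed row", {
  raw <- attr(small_feature_matrix(), "raw_features")
  for (s in 1:3) for (a in c("X", "Y", "Z")) {
    k <- raw[, paste0("kurt_", a, s)]
    sk <- raw[, paste0("skew_", a, s)]
    expect_true(all(k >= sk^2 + 1 - 1e-9))
  }
})

test_that("identical raw rows stay identical after z-scoring", {
  sets <- preprocess_cohort(small_cohort())[c(1, 1, 2, 3, 4, 5)]
  fm <- build_feature_matrix(sets, "all_sensors")
  z <- as.matrix(fm[feature_columns(fm)])
  expect_equal(z[1, ], z[2, ], tolerance = 1e-12)
})

test_that("mixed exercises are rejected and empty input errors", {
  a <- preprocess_cohort(small_cohort("prone_rocking"))[1:2]
  b <- preprocess_cohort(small_cohort("rowing", seed = 102))[1:2]
  expect_error(build_feature_matrix(c(a, b)), "mixed exercises")
  expect_error(build_feature_matrix(list()), "empty")
})

test_that("feature matrices round-trip through CSV to 12 significant digits", {
  fm <- small_feature_matrix()
  path <- file.path(tempdir(), "fm_roundtrip.csv")
  write_feature_matrix_csv(fm, path)
  back <- read_feature_matrix_csv(path)
  expect_equal(back$subject_id, fm$subject_id)
  expect_equal(back$category, fm$category)
  z0 <- as.matrix(fm[feature_columns(fm)])
  z1 <- as.matrix(back[feature_columns(back)])
  expect_equal(z1, z0, tolerance = 1e-12)
  raw1 <- attr(back, "raw_features")
  expect_equal(raw1, attr(fm, "raw_features"), tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(c(path, paste0(path, ".json")))
})
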