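# Synthetic data generator: determinism, marker structure, gravity
# projection and quantization.

test_that("static aligned sensor reads +g on Z and recovers zero tilt", {
  spec <- exercise_spec("prone_rocking", 3, 0,
                        tilt_waveforms = rep(list(list(baseline = 0,
                                                       amplitude = 0)), 3))
  seg <- simulate_repetition(spec, "CPE", 1, noiseless_model(), rng_seed = 1)
  for (s in 1:3) {
    az <- seg[, paste0("s", s, "_az")]
    expect_true(all(abs(az - 9.81) < 0.01))  # quantizer step ~0.019
    phi <- tilt_angle(seg[, paste0("s", s, "_ax")],
                      seg[, paste0("s", s, "_ay")], az)
    expect_true(all(abs(phi) < 0.5))
  }
})

test_that("a 90-degree baseline puts gravity on X and zero on Z", {
  wf <- list(list(baseline = 0, amplitude = 0),
             list(baseline = 90, amplitude = 0),
             list(baseline = 0, amplitude = 0))
  spec <- exercise_spec("prone_rocking", 3, 0, tilt_waveforms = wf)
  seg <- simulate_repetition(spec, "CPE", 1, noiseless_model(), rng_seed = 1)
  expect_true(all(abs(seg[, "s2_az"]) < 0.01))
  expect_true(all(abs(seg[, "s2_ax"] - 9.81) < 0.01))
  phi <- tilt_angle(seg[, "s2_ax"], seg[, "s2_ay"], seg[, "s2_az"])
  expect_true(all(abs(phi - 90) < 0.5))
})

test_that("recovered tilt matches the generating trajectory within quantization", {
  spec <- default_exercises()$prone_rocking
  model <- noiseless_model()
  n <- 600
  seg <- simulate_repetition(spec, "CPE", n / model$sampling_rate, model,
                             rng_seed = 3)
  u <- (seq_len(nrow(seg)) - 1) / nrow(seg)
  for (s in 1:3) {
    w <- spec$tilt_waveforms[[s]]
    truth <- w$baseline + w$amplitude * 0.5 * (1 - cos(2 * pi * u))
    phi <- tilt_angle(seg[, paste0("s", s, "_ax")],
                      seg[, paste0("s", s, "_ay")],
                      seg[, paste0("s", s, "_az")])
    # one quantizer step on a component maps to < 0.3 degree here
    expect_lt(max(abs(phi - truth)), 0.3)
  }
})

test_that("zero-amplitude TCM effects make the categories bit-identical", {
  spec <- default_exercises()$bird_dog
  spec$tcm_effects <- lapply(spec$tcm_effects, function(ef) {
    ef$amplitude <- 0
    ef
  })
  a <- simulate_repetition(spec, "CPE", 2, rng_seed = 9)
  b <- simulate_repetition(spec, "TCM", 2, rng_seed = 9)
  expect_identical(a, b)
  s1 <- generate_session("S01", spec, "CPE", 1, rng_seed = 9)
  s2 <- generate_session("S01", spec, "TCM", 1, rng_seed = 9)
  expect_identical(s1$channels, s2$channels)
})

test_that("simulation is deterministic given the seed", {
  spec <- default_exercises()$rowing
  expect_identical(simulate_repetition(spec, "TCM", 2.5, rng_seed = 77),
                   simulate_repetition(spec, "TCM", 2.5, rng_seed = 77))
  r1 <- generate_session("S01", spec, "TCM", 2, rng_seed = 13)
  r2 <- generate_session("S01", spec, "TCM", 2, rng_seed = 13)
  expect_identical(r1, r2)
  expect_false(identical(
    simulate_repetition(spec, "TCM", 2.5, rng_seed = 77),
    simulate_repetition(spec, "TCM", 2.5, rng_seed = 78)))
})

test_that("sessions carry 7 markers bounding 6 repetitions", {
  spec <- default_exercises()$prone_rocking
  rec <- generate_session("S01", spec, "CPE", 1, rng_seed = 4)
  expect_length(rec$markers, 7)
  expect_true(all(diff(rec$markers) > 0))
  expect_lte(max(rec$markers), nrow(rec$channels) + 1)
  segs <- segment_repetitions(rec)
  expect_length(segs, 6)
})

test_that("zero duration variation gives equal-length repetitions", {
  spec <- default_exercises()$prone_rocking
  spec$rep_duration_cv <- 0
  rec <- generate_session("S01", spec, "CPE", 1, rng_seed = 4)
  lens <- diff(rec$markers)
  expect_true(all(lens == lens[1]))
})

test_that("quantizer clips to full scale and uses a finite level grid", {
  m <- sensor_model(resolution_bits = 4, full_scale = 8, noise_sd = 0)
  x <- seq(-20, 20, by = 0.01)
  q <- quantize(x, m)
  expect_true(all(q >= -8 & q <= 8))
  expect_lte(length(unique(q)), 2^4)
  # idempotent on its own output
  expect_equal(quantize(q, m), q)
})

test_that("cohort cardinalities follow the recording plan", {
  coh <- small_cohort()
  m <- coh$manifest
  expect_equal(nrow(m), 3 * 2 * 3)  # subjects x categories x sets
  expect_equal(length(coh$recordings), nrow(m))
  expect_equal(as.integer(table(m$category)), c(9L, 9L))
  # both Bird-Dog sides appear when requested
  coh4 <- generate_cohort(n_subjects = 1,
                          exercises = c("prone_rocking", "bird_dog",
                                        "rowing"),
                          master_seed = 3, bird_dog_sides = TRUE)
  expect_equal(nrow(coh4$manifest), 24)
  expect_setequal(unique(coh4$manifest$side[coh4$manifest$exercise ==
                                              "bird_dog"]),
                  c("left", "right"))
})

test_that("unknown exercises and empty lists are rejected", {
  expect_error(generate_cohort(2, exercises = "jumping_jack"),
               "unknown exercise")
  expect_error(generate_cohort(2, exercises = list()), "empty exercise")
  expect_error(simulate_repetition(default_exercises()$rowing, "CPE", -1),
               "positive")
})

test_that("cohort generation is reproducible from the master seed", {
  a <- generate_cohort(2, "rowing", master_seed = 55)
  b <- generate_cohort(2, "rowing", master_seed = 55)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$recordings[[5]]$channels, b$recordings[[5]]$channels)
})
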