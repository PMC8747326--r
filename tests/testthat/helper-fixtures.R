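# Shared small fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Small cohort: 3 subjects, one exercise, default effects.
small_cohort <- function(exercise = "prone_rocking", effect_scale = 1,
                         seed = 101) {
  key <- paste(exercise, effect_scale, seed, sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_cohort(
      n_subjects = 3, exercises = exercise, effect_scale = effect_scale,
      master_seed = seed)
  }
  .fixture_cache[[key]]
}

small_feature_matrix <- function(exercise = "prone_rocking",
                                 effect_scale = 1, seed = 101,
                                 mode = "all_sensors", sensor = NULL) {
  key <- paste("fm", exercise, effect_scale, seed, mode, sensor, sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    sets <- preprocess_cohort(small_cohort(exercise, effect_scale, seed))
    .fixture_cache[[key]] <- build_feature_matrix(sets, mode, sensor)
  }
  .fixture_cache[[key]]
}

# A noise-free sensor model for analytic checks.
noiseless_model <- function() sensor_model(noise_sd = 0)

# Hand-built feature matrix with a single perfectly separating feature
# plus pure-noise columns; subjects get 2 rows each.
separable_matrix <- function(n_subjects = 6, seed = 5) {
  set.seed(seed)
  rows <- n_subjects * 2
  category <- rep(c("CPE", "TCM"), n_subjects)
  good <- ifelse(category == "TCM", 1, -1) + rnorm(rows, 0, 0.1)
  fm <- data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), each = 2),
    category = category,
    set_index = 1L,
    alpha_noise = rnorm(rows),
    good_feature = good,
    zeta_noise = rnorm(rows),
    stringsAsFactors = FALSE)
  raw <- as.matrix(fm[c("alpha_noise", "good_feature", "zeta_noise")])
  attr(fm, "raw_features") <- raw
  attr(fm, "mode") <- "all_sensors"
  attr(fm, "exercise") <- "prone_rocking"
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}
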