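# Synthetic accelerometer recordings: repetitions, sessions, cohorts.

# Raised-cosine pulse on normalized time: 0 at u = 0 and u = 1, 1 at
# u = 0.5. Used as the canonical within-repetition movement shape.
raised_cosine <- function(u) 0.5 * (1 - cos(2 * pi * u))

# Deterministic (noise-free, unquantized) 9-channel acceleration for one
# repetition on normalized time u. Gravity projection with pitch = tilt
# angle phi about the lateral axis and a fixed mounting roll:
#   A_X = g sin(phi), A_Y = -g cos(phi) sin(roll), A_Z = g cos(phi) cos(roll)
# so that for roll = 0 the tilt is exactly recoverable as
# acos(A_Z / |A|).
deterministic_acc <- function(spec, category, u) {
  n <- length(u)
  acc <- matrix(0, n, 9, dimnames = list(NULL, CHANNEL_NAMES))
  for (s in 1:3) {
    w <- spec$tilt_waveforms[[s]]
    phi <- w$baseline + w$amplitude * raised_cosine(u - w$phase)
    if (category == "TCM") {
      for (ef in spec$tcm_effects) {
        if (ef$sensor != s) next
        if (ef$type == "tilt_offset") phi <- phi + ef$amplitude
        if (ef$type == "tilt_pulse")
          phi <- phi + ef$amplitude * raised_cosine(ef$cycles * (u - ef$phase))
      }
    }
    pr <- phi * pi / 180
    rr <- w$roll * pi / 180
    acc[, channel_index(s, "x")] <- GRAVITY * sin(pr)
    acc[, channel_index(s, "y")] <- -GRAVITY * cos(pr) * sin(rr)
    acc[, channel_index(s, "z")] <- GRAVITY * cos(pr) * cos(rr)
  }
  if (category == "TCM") {
    for (ef in spec$tcm_effects) {
      if (!ef$type %in% c("acc_osc", "acc_dip")) next
      j <- channel_index(ef$sensor, ef$axis)
      wave <- if (ef$type == "acc_osc") {
        ef$amplitude * sin(2 * pi * (ef$cycles * u + ef$phase))
      } else {
        -ef$amplitude * raised_cosine(ef$cycles * (u - ef$phase))
      }
      acc[, j] <- acc[, j] + wave
    }
  }
  if (spec$mirror) {
    for (s in 1:3) {
      j <- channel_index(s, "y")
      acc[, j] <- -acc[, j]
    }
  }
  acc
}

add_noise_and_quantize <- function(acc, model, rng_seed) {
  if (model$noise_sd > 0) {
    noise <- with_seed(rng_seed,
                       matrix(stats::rnorm(length(acc), 0, model$noise_sd),
                              nrow(acc), ncol(acc)))
    acc <- acc + noise
  }
  quantize(acc, model)
}

#' Simulate one exercise repetition
#'
#' Produces the 9-channel acceleration segment of a single repetition: a
#' per-sensor tilt trajectory (plus the exercise's TCM effects when
#' `category = "TCM"`) is projected onto the gravity vector, then Gaussian
#' sensor noise and ADC quantization are applied. Deterministic given
#' `rng_seed`.
#'
#' @param spec An [exercise_spec()].
#' @param category `"CPE"` or `"TCM"`.
#' @param duration Repetition duration in seconds (> 0).
#' @param model A [sensor_model()].
#' @param rng_seed Integer seed for the noise stream.
#' @return Numeric matrix `n_samples x 9` with columns `s1_ax` .. `s3_az`.
#' @examples
#' spec <- default_exercises()$prone_rocking
#' seg <- simulate_repetition(spec, "CPE", duration = 3, rng_seed = 1)
#' dim(seg)
#' @export
simulate_repetition <- function(spec, category, duration,
                                model = sensor_model(), rng_seed = 1) {
  stopifnot(inherits(spec, "exercise_spec"))
  category <- match.arg(category, CATEGORIES)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  n <- max(2L, as.integer(round(duration * model$sampling_rate)))
  u <- (seq_len(n) - 1) / n
  acc <- deterministic_acc(spec, category, u)
  add_noise_and_quantize(acc, model, rng_seed)
}

# Static posture segment (lead-in before the first push-button press and
# tail after the last): the subject holds the repetition start posture.
static_segment <- function(spec, category, n, model, rng_seed) {
  acc <- deterministic_acc(spec, category, rep(0, n))
  add_noise_and_quantize(acc, model, rng_seed)
}

#' Simulate one recording session (one set)
#'
#' One set of six repetitions with log-normal repetition durations,
#' concatenated, with a short static lead-in and tail, and push-button
#' markers at the set start and after every repetition (7 marker events).
#'
#' @param subject_id Subject identifier.
#' @param spec An [exercise_spec()].
#' @param category `"CPE"` or `"TCM"`.
#' @param set_index Set number, 1..3.
#' @param model A [sensor_model()].
#' @param rng_seed Integer seed; the session is deterministic given it.
#' @param n_repetitions Repetitions per set.
#' @param rest_s Static lead-in/tail duration, seconds.
#' @return An object of class `session_recording`: list with `channels`
#'   (`n x 9` matrix), `markers` (sample indices, strictly increasing),
#'   `sampling_rate` and the identifying metadata.
#' @export
generate_session <- function(subject_id, spec, category, set_index,
                             model = sensor_model(), rng_seed = 1,
                             n_repetitions = 6L, rest_s = 0.25) {
  stopifnot(set_index %in% 1:3)
  category <- match.arg(category, CATEGORIES)
  cv <- spec$rep_duration_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(spec$rep_duration_mean) - sdlog^2 / 2
  durations <- with_seed(derive_seed(rng_seed, 0),
                         stats::rlnorm(n_repetitions, meanlog, sdlog))
  n_rest <- max(1L, as.integer(round(rest_s * model$sampling_rate)))
  lead <- static_segment(spec, category, n_rest, model,
                         derive_seed(rng_seed, 100))
  tail_seg <- static_segment(spec, category, n_rest, model,
                             derive_seed(rng_seed, 101))
  reps <- lapply(seq_len(n_repetitions), function(i) {
    simulate_repetition(spec, category, durations[i], model,
                        derive_seed(rng_seed, i))
  })
  rep_lengths <- vapply(reps, nrow, integer(1))
  channels <- do.call(rbind, c(list(lead), reps, list(tail_seg)))
  markers <- as.integer(n_rest + 1 + c(0, cumsum(rep_lengths)))
  structure(list(subject_id = subject_id,
                 exercise = spec$name,
                 category = category,
                 set_index = as.integer(set_index),
                 side = NA_character_,
                 channels = channels,
                 markers = markers,
                 sampling_rate = model$sampling_rate),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> subject %s, %s, %s, set %d: %d samples @ %g Hz, %d markers\n",
    x$subject_id, x$exercise, x$category, x$set_index, nrow(x$channels),
    x$sampling_rate, length(x$markers)))
  invisible(x)
}

#' Between-subject variability model
#'
#' Random per-subject offsets applied to the exercise specifications when
#' a cohort is generated: a whole-body lean added to every sensor's tilt
#' baseline, small per-sensor mounting pitch offsets, per-sensor mounting
#' roll (the sensor axes are only roughly aligned with the body axes when
#' taped to the skin), and a log-normal movement speed factor.
#'
#' @param lean_sd SD of the shared baseline tilt offset, degrees.
#' @param pitch_sd SD of per-sensor baseline pitch offsets, degrees.
#' @param roll_sd SD of per-sensor mounting roll, degrees.
#' @param speed_cv CV of the per-subject repetition-duration factor.
#' @param noise_cv CV of the per-subject sensor-noise factor (log-normal,
#'   mean 1); attachment quality and soft tissue make the effective noise
#'   level differ between individuals.
#' @return An object of class `subject_variability`.
#' @export
subject_variability <- function(lean_sd = 8, pitch_sd = 2, roll_sd = 8,
                                speed_cv = 0.10, noise_cv = 0.40) {
  stopifnot(lean_sd >= 0, pitch_sd >= 0, roll_sd >= 0, speed_cv >= 0,
            noise_cv >= 0)
  structure(list(lean_sd = lean_sd, pitch_sd = pitch_sd, roll_sd = roll_sd,
                 speed_cv = speed_cv, noise_cv = noise_cv),
            class = "subject_variability")
}

# Draw one subject's offsets and return a function that personalises an
# exercise_spec.
draw_subject_offsets <- function(variability, rng_seed) {
  with_seed(rng_seed, {
    lean <- stats::rnorm(1, 0, variability$lean_sd)
    pitch <- stats::rnorm(3, 0, variability$pitch_sd)
    roll <- stats::rnorm(3, 0, variability$roll_sd)
    sl <- sqrt(log(1 + variability$speed_cv^2))
    speed <- stats::rlnorm(1, -sl^2 / 2, sl)
    nl <- sqrt(log(1 + variability$noise_cv^2))
    noise_factor <- stats::rlnorm(1, -nl^2 / 2, nl)
    list(lean = lean, pitch = pitch, roll = roll, speed = speed,
         noise_factor = noise_factor)
  })
}

personalise_spec <- function(spec, offsets) {
  for (s in 1:3) {
    spec$tilt_waveforms[[s]]$baseline <-
      spec$tilt_waveforms[[s]]$baseline + offsets$lean + offsets$pitch[s]
    spec$tilt_waveforms[[s]]$roll <-
      spec$tilt_waveforms[[s]]$roll + offsets$roll[s]
  }
  spec$rep_duration_mean <- spec$rep_duration_mean * offsets$speed
  spec
}

#' Generate a labelled synthetic cohort
#'
#' Simulates the full study recording plan: `n_subjects` subjects each
#' performing every exercise in both categories (CPE and TCM) for 3 sets
#' of 6 repetitions, with per-subject random offsets (baseline lean,
#' mounting pitch/roll, movement speed) inducing between-subject
#' variability. With the default exercise list this yields
#' `n_subjects x 2 x 3` recordings per exercise, i.e. 180 analysis sets
#' per exercise for 30 subjects.
#'
#' With `bird_dog_sides = TRUE` the Bird-Dog exercise is performed on both
#' sides (the mirrored side flips the lateral channels), reproducing the
#' protocol's bookkeeping of 24 sets per subject
#' (2 categories x 4 counted exercises x 3 sets). The default keeps one
#' pooled Bird-Dog stream, matching the study's per-exercise analysis
#' cardinality of 180 sets.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param exercises Named list of [exercise_spec()] objects, or a character
#'   vector of names resolved through [default_exercises()].
#' @param model A [sensor_model()].
#' @param effect_scale Non-negative multiplier on every TCM effect
#'   amplitude; 0 makes the two categories generatively identical.
#' @param master_seed Integer master seed; all randomness derives from it.
#' @param variability A [subject_variability()].
#' @param bird_dog_sides Simulate Bird-Dog separately on both sides.
#' @return An object of class `cohort`: list with `recordings` (list of
#'   `session_recording`) and `manifest` (data frame with one row per
#'   recording: subject, exercise, side, category, set_index, n_samples,
#'   seed).
#' @export
generate_cohort <- function(n_subjects = 30L,
                            exercises = default_exercises(),
                            model = sensor_model(),
                            effect_scale = 1,
                            master_seed = 1L,
                            variability = subject_variability(),
                            bird_dog_sides = FALSE) {
  stopifnot(n_subjects >= 1, effect_scale >= 0)
  if (is.character(exercises)) {
    pool <- default_exercises()
    missing <- setdiff(exercises, names(pool))
    if (length(missing))
      stop("unknown exercise(s): ", paste(missing, collapse = ", "))
    exercises <- pool[exercises]
  }
  if (length(exercises) == 0) stop("empty exercise list")
  stopifnot(all(vapply(exercises, inherits, logical(1), "exercise_spec")))

  # Expand to exercise instances: (spec, label, side).
  instances <- list()
  for (nm in names(exercises)) {
    spec <- scale_tcm_effects(exercises[[nm]], effect_scale)
    if (identical(spec$name, "bird_dog") && bird_dog_sides) {
      left <- spec; left$mirror <- !spec$mirror
      instances[[length(instances) + 1]] <-
        list(spec = spec, label = nm, side = "right")
      instances[[length(instances) + 1]] <-
        list(spec = left, label = nm, side = "left")
    } else {
      instances[[length(instances) + 1]] <-
        list(spec = spec, label = nm, side = NA_character_)
    }
  }

  recordings <- list()
  rows <- list()
  for (subj in seq_len(n_subjects)) {
    subject_id <- sprintf("S%02d", subj)
    offsets <- draw_subject_offsets(variability, derive_seed(master_seed, subj))
    model_subj <- model
    model_subj$noise_sd <- model$noise_sd * offsets$noise_factor
    for (ii in seq_along(instances)) {
      inst <- instances[[ii]]
      spec_subj <- personalise_spec(inst$spec, offsets)
      for (ci in seq_along(CATEGORIES)) {
        for (set_index in 1:3) {
          seed <- derive_seed(master_seed, subj, ii, ci, set_index)
          rec <- generate_session(subject_id, spec_subj, CATEGORIES[ci],
                                  set_index, model_subj, seed)
          rec$side <- inst$side
          recordings[[length(recordings) + 1]] <- rec
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = subject_id, exercise = inst$label,
            side = inst$side, category = CATEGORIES[ci],
            set_index = set_index, n_samples = nrow(rec$channels),
            seed = seed, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(recordings = recordings, manifest = manifest),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<cohort> %d recordings: %d subjects, exercises: %s\n",
              nrow(m), length(unique(m$subject_id)),
              paste(unique(m$exercise), collapse = ", ")))
  invisible(x)
}
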