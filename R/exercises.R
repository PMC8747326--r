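#' Parametric description of one rehabilitation exercise
#'
#' An exercise is described by the tilt-angle trajectory of each of the
#' three spine-mounted sensors over one repetition (normalized time
#' 0..1), plus the additive signal effects that distinguish the typical
#' compensatory movement (TCM) from the clinically prescribed execution
#' (CPE). The kinematics are deliberately simple raised-cosine pulses: the
#' downstream pipeline consumes accelerations only, so a parametric tilt
#' trajectory is sufficient to emulate the recordings.
#'
#' @param name Exercise identifier, one of `"prone_rocking"`,
#'   `"bird_dog"`, `"rowing"`.
#' @param rep_duration_mean Mean repetition duration, seconds (> 0).
#' @param rep_duration_cv Coefficient of variation of repetition durations
#'   (>= 0); durations are log-normal.
#' @param tilt_waveforms List of three per-sensor waveforms, each a list
#'   with elements `baseline` (deg), `amplitude` (deg), `phase` (fraction
#'   of the repetition) and `roll` (mounting roll about the body's
#'   longitudinal axis, deg).
#' @param tcm_effects List of [tcm_effect()] objects applied only when a
#'   repetition is simulated in the TCM category. With all amplitudes 0
#'   the two categories are generatively identical.
#' @param mirror Logical; if `TRUE` the lateral (Y) channels are sign
#'   flipped, used for the mirrored Bird-Dog side.
#' @return An object of class `exercise_spec`.
#' @seealso [default_exercises()] for the three study exercises.
#' @export
exercise_spec <- function(name, rep_duration_mean, rep_duration_cv,
                          tilt_waveforms, tcm_effects = list(),
                          mirror = FALSE) {
  name <- match.arg(name, c("prone_rocking", "bird_dog", "rowing"))
  stopifnot(rep_duration_mean > 0, rep_duration_cv >= 0,
            length(tilt_waveforms) == 3)
  tilt_waveforms <- lapply(tilt_waveforms, function(w) {
    w <- utils::modifyList(list(baseline = 0, amplitude = 0, phase = 0,
                                roll = 0), w)
    stopifnot(is.numeric(w$baseline), is.numeric(w$amplitude))
    w
  })
  structure(list(name = name,
                 rep_duration_mean = rep_duration_mean,
                 rep_duration_cv = rep_duration_cv,
                 tilt_waveforms = tilt_waveforms,
                 tcm_effects = tcm_effects,
                 mirror = isTRUE(mirror)),
            class = "exercise_spec")
}

#' Additive TCM signal effect
#'
#' One component of a typical compensatory movement signature. Tilt-type
#' effects act on a sensor's tilt trajectory (degrees); acceleration-type
#' effects act directly on one acceleration channel (m/s^2) after gravity
#' projection, representing motion acceleration.
#'
#' @param sensor Sensor index 1..3 (1 = L5/S1, 2 = Th1/C7, 3 = head).
#' @param type `"tilt_offset"` (constant tilt shift), `"tilt_pulse"`
#'   (raised-cosine tilt excursion), `"acc_osc"` (sinusoidal acceleration
#'   oscillation) or `"acc_dip"` (negative raised-cosine acceleration
#'   excursion).
#' @param amplitude Effect amplitude, degrees for tilt types and m/s^2 for
#'   acceleration types.
#' @param axis Channel axis `"X"`, `"Y"` or `"Z"` (acceleration types only).
#' @param cycles Number of effect cycles per repetition.
#' @param phase Phase offset (fraction of a cycle for `acc_osc`, of the
#'   repetition otherwise).
#' @return An object of class `tcm_effect`.
#' @export
tcm_effect <- function(sensor, type, amplitude, axis = NULL, cycles = 2,
                       phase = 0) {
  type <- match.arg(type, c("tilt_offset", "tilt_pulse", "acc_osc",
                            "acc_dip"))
  stopifnot(sensor %in% 1:3, is.numeric(amplitude), amplitude >= 0)
  if (type %in% c("acc_osc", "acc_dip") && is.null(axis))
    stop("acceleration effects need an axis")
  structure(list(sensor = as.integer(sensor), type = type,
                 amplitude = amplitude, axis = axis, cycles = cycles,
                 phase = phase),
            class = "tcm_effect")
}

#' Default exercise specifications
#'
#' The three low back pain exercises of the study protocol with their
#' per-sensor tilt trajectories and TCM signatures:
#'
#' * **Prone-Rocking** — rocking back onto the heels from quadruped; large
#'   sagittal tilt excursions at all three sensors. TCM: twisting around
#'   the longitudinal spine axis, emulated as a lateral acceleration
#'   oscillation at the upper-back sensor (raises the Y2 variance).
#' * **Bird-Dog** — quadruped with contralateral arm/leg lift; small tilt
#'   excursions. TCM: head tilt-up with lumbar extension, emulated as a
#'   downward excursion of the head sensor's Z channel (the head tilting
#'   away from gravity lowers its Z projection, raising the Z3 variance)
#'   plus a constant tilt offset of the lumbar sensor (shifting its tilt
#'   RMS).
#' * **Rowing** — standing bent-over rowing; large static tilt, small
#'   excursions. TCM: rounding of the lower back by posterior pelvic tilt,
#'   emulated as a constant tilt offset of the lumbar sensor that makes
#'   its tilt diverge from the upper-back sensor, plus a dropped-head
#'   posture as a tilt offset of the head sensor (shifting its Z-channel
#'   level and RMS).
#'
#' @return Named list of [exercise_spec()] objects.
#' @export
default_exercises <- function() {
  list(
    prone_rocking = exercise_spec(
      "prone_rocking", rep_duration_mean = 3, rep_duration_cv = 0.15,
      tilt_waveforms = list(list(baseline = 10, amplitude = 45),
                            list(baseline = 15, amplitude = 35),
                            list(baseline = 20, amplitude = 30)),
      tcm_effects = list(tcm_effect(2, "acc_osc", amplitude = 1.5,
                                    axis = "Y", cycles = 2))),
    bird_dog = exercise_spec(
      "bird_dog", rep_duration_mean = 4, rep_duration_cv = 0.15,
      tilt_waveforms = list(list(baseline = 5, amplitude = 8),
                            list(baseline = 8, amplitude = 8),
                            list(baseline = 10, amplitude = 12)),
      tcm_effects = list(tcm_effect(3, "acc_dip", amplitude = 1.2,
                                    axis = "Z", cycles = 1),
                         tcm_effect(1, "tilt_offset", amplitude = 12))),
    rowing = exercise_spec(
      "rowing", rep_duration_mean = 3, rep_duration_cv = 0.15,
      tilt_waveforms = list(list(baseline = 40, amplitude = 12),
                            list(baseline = 45, amplitude = 10),
                            list(baseline = 50, amplitude = 10)),
      tcm_effects = list(tcm_effect(1, "tilt_offset", amplitude = 18),
                         tcm_effect(3, "tilt_offset", amplitude = 10)))
  )
}

# Multiply every TCM effect amplitude by a scale factor.
scale_tcm_effects <- function(spec, effect_scale) {
  stopifnot(effect_scale >= 0)
  spec$tcm_effects <- lapply(spec$tcm_effects, function(ef) {
    ef$amplitude <- ef$amplitude * effect_scale
    ef
  })
  spec
}
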