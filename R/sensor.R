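#' Accelerometer sensor model
#'
#' Describes the measurement chain of one tri-axial MEMS accelerometer:
#' sampling rate, ADC resolution, full-scale range and additive sensor
#' noise. Defaults emulate a body-worn 200 Hz, 12-bit accelerometer
#' configured for a +/- 4 g range.
#'
#' @param sampling_rate Samples per second (Hz).
#' @param resolution_bits ADC resolution; the quantizer maps every in-range
#'   value to one of `2^resolution_bits` levels.
#' @param full_scale Half range of the sensor in m/s^2; readings are
#'   clipped to `[-full_scale, full_scale]`.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise,
#'   m/s^2, applied before quantization.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(sampling_rate = 200, resolution_bits = 12L,
                         full_scale = 4 * GRAVITY, noise_sd = 0.25) {
  stopifnot(sampling_rate > 0, resolution_bits >= 1, full_scale > 0,
            noise_sd >= 0)
  structure(list(sampling_rate = sampling_rate,
                 resolution_bits = as.integer(resolution_bits),
                 full_scale = full_scale,
                 noise_sd = noise_sd),
            class = "sensor_model")
}

#' Quantize acceleration readings
#'
#' Uniform quantizer over `[-full_scale, full_scale]` with
#' `2^resolution_bits` levels; out-of-range values clip to full scale.
#'
#' @param a Numeric vector or matrix of accelerations, m/s^2.
#' @param model A [sensor_model()].
#' @return `a` with every element mapped to the nearest quantizer level.
#' @export
quantize <- function(a, model) {
  stopifnot(inherits(model, "sensor_model"))
  fs <- model$full_scale
  n_levels <- 2^model$resolution_bits
  step <- 2 * fs / (n_levels - 1)
  clipped <- pmin(pmax(a, -fs), fs)
  out <- -fs + round((clipped + fs) / step) * step
  if (is.matrix(a)) dim(out) <- dim(a)
  dimnames(out) <- dimnames(a)
  out
}
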