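# Tilt-angle estimation and statistical feature extraction.

#' Tilt angle from gravity projection
#'
#' The tilt angle phi between a sensor's Z axis and the gravity vector,
#' recovered from the three acceleration components as
#' `phi = acos(A_Z / sqrt(A_X^2 + A_Y^2 + A_Z^2))`, in degrees. Applied
#' element-wise to series. The angle is scale invariant: scaling all three
#' components by a positive constant leaves it unchanged. Zero-norm
#' samples have no defined direction and yield `NA`.
#'
#' @param ax,ay,az Acceleration components, m/s^2 (vectors of equal
#'   length).
#' @return Numeric vector of angles in `[0, 180]` degrees, `NA` for
#'   zero-norm samples.
#' @examples
#' tilt_angle(0, 0, 9.81)   # 0 degrees
#' tilt_angle(9.81, 0, 0)   # 90 degrees
#' tilt_angle(0, 0, -9.81)  # 180 degrees
#' @export
tilt_angle <- function(ax, ay, az) {
  stopifnot(length(ax) == length(ay), length(ay) == length(az))
  nrm <- sqrt(ax^2 + ay^2 + az^2)
  out <- acos(pmin(pmax(az / nrm, -1), 1)) * 180 / pi
  out[nrm == 0] <- NA_real_
  out
}

# Tilt series of one sensor from an averaged set; the set is rejected if
# more than 1% of its samples have no defined direction.
tilt_series <- function(set, sensor, max_invalid = 0.01) {
  ch <- set$channels
  phi <- tilt_angle(ch[, channel_index(sensor, "x")],
                    ch[, channel_index(sensor, "y")],
                    ch[, channel_index(sensor, "z")])
  frac <- mean(is.na(phi))
  if (frac > max_invalid)
    stop(sprintf("set rejected: %.1f%% invalid (zero-norm) samples on sensor %d",
                 100 * frac, sensor))
  phi
}

#' Maximum signed tilt difference between two sensors
#'
#' The signed difference `phi_a - phi_b` is formed sample-wise and its
#' maximum over time returned. In the study pipeline only the pairs
#' (1,2) and (2,3) are used.
#'
#' @param phi_a,phi_b Tilt-angle series of equal length, degrees.
#' @return Scalar maximum of the signed difference.
#' @export
max_delta_tilt <- function(phi_a, phi_b) {
  if (length(phi_a) != length(phi_b))
    stop("tilt series must have equal length")
  max(phi_a - phi_b, na.rm = TRUE)
}

#' Statistical features of one series
#'
#' Population (divide-by-N) moments throughout: root mean square, maximum,
#' variance, skewness and raw (non-excess) kurtosis, so a normal series
#' has kurtosis near 3. A constant series has undefined skewness and
#' kurtosis; both are set to 0 with a warning so degenerate inputs keep
#' the feature matrix complete.
#'
#' @param x Numeric series (length >= 2; `NA`s are dropped).
#' @return Named list with `aRMS`, `max`, `skewness`, `kurtosis`,
#'   `variance`.
#' @examples
#' stat_features(c(3, 4))  # aRMS = sqrt(12.5), variance = 0.25
#' @export
stat_features <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("series must have at least 2 valid samples")
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n
  if (v == 0) {
    warning("constant series: skewness/kurtosis undefined, set to 0")
    skew <- 0
    kurt <- 0
  } else {
    sdev <- sqrt(v)
    skew <- mean((x - m)^3) / sdev^3
    kurt <- mean((x - m)^4) / sdev^4
  }
  list(aRMS = sqrt(mean(x^2)), max = max(x), skewness = skew,
       kurtosis = kurt, variance = v)
}

STAT_NAMES <- c("aRMS", "max", "skew", "kurt", "var")
AXIS_LABELS <- c("X", "Y", "Z")

#' Feature vocabulary
#'
#' Canonical ordered feature names: in `all_sensors` mode the 45
#' axis-signal features (5 statistics x 9 channels) plus `maxdphi_1_2`,
#' `maxdphi_2_3` and `phiRMS_1..3` (50 total); in `single_sensor` mode the
#' 15 axis-signal features of that sensor plus its `phiRMS` (16 total).
#'
#' @param mode `"all_sensors"` or `"single_sensor"`.
#' @param sensor Sensor index 1..3, required for `single_sensor`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(mode = c("all_sensors", "single_sensor"),
                          sensor = NULL) {
  mode <- match.arg(mode)
  axis_feats <- function(s) {
    as.vector(vapply(AXIS_LABELS, function(a)
      paste0(STAT_NAMES, "_", a, s), character(length(STAT_NAMES))))
  }
  if (mode == "all_sensors") {
    c(unlist(lapply(1:3, axis_feats)),
      "maxdphi_1_2", "maxdphi_2_3",
      paste0("phiRMS_", 1:3))
  } else {
    if (is.null(sensor) || !sensor %in% 1:3)
      stop("single_sensor mode needs sensor in 1..3")
    c(axis_feats(sensor), paste0("phiRMS_", sensor))
  }
}

# Raw (unscaled) feature vector of one averaged set.
set_feature_vector <- function(set, mode, sensor = NULL) {
  sensors <- if (mode == "all_sensors") 1:3 else sensor
  vals <- c()
  for (s in sensors) {
    for (a in AXIS_LABELS) {
      st <- stat_features(set$channels[, channel_index(s, a)])
      v <- c(st$aRMS, st$max, st$skewness, st$kurtosis, st$variance)
      names(v) <- paste0(STAT_NAMES, "_", a, s)
      vals <- c(vals, v)
    }
  }
  phi <- lapply(sensors, function(s) tilt_series(set, s))
  names(phi) <- as.character(sensors)
  if (mode == "all_sensors") {
    vals <- c(vals,
              maxdphi_1_2 = max_delta_tilt(phi[["1"]], phi[["2"]]),
              maxdphi_2_3 = max_delta_tilt(phi[["2"]], phi[["3"]]))
  }
  for (s in sensors) {
    v <- sqrt(mean(phi[[as.character(s)]]^2, na.rm = TRUE))
    names(v) <- paste0("phiRMS_", s)
    vals <- c(vals, v)
  }
  vals[feature_names(mode, sensor)]
}

#' Build the z-scored feature matrix
#'
#' Computes every feature of the vocabulary on each averaged set and
#' z-scores each column over all rows (`z = (n - mean) / sd` with the
#' population standard deviation). One row per (subject, category, set).
#' The raw values and the per-column scaling are kept as attributes
#' (`raw_features`, `scaling`) so train-only rescaling and lossless
#' round-trips remain possible.
#'
#' @param sets List of `averaged_set` objects from one exercise.
#' @param mode `"all_sensors"` (50 features) or `"single_sensor"`
#'   (16 features).
#' @param sensor Sensor index for `single_sensor` mode.
#' @return A `feature_matrix`: data frame with columns `subject_id`,
#'   `category`, `set_index` and the z-scored feature columns.
#' @export
build_feature_matrix <- function(sets, mode = c("all_sensors",
                                                "single_sensor"),
                                 sensor = NULL) {
  mode <- match.arg(mode)
  if (length(sets) == 0) stop("empty set list")
  exercises <- unique(vapply(sets, function(s) s$exercise %||% NA_character_,
                             character(1)))
  if (length(exercises) > 1)
    stop("mixed exercises in one feature matrix: ",
         paste(exercises, collapse = ", "))
  feats <- feature_names(mode, sensor)
  raw <- t(vapply(sets, set_feature_vector, numeric(length(feats)),
                  mode = mode, sensor = sensor))
  colnames(raw) <- feats
  meta <- data.frame(
    subject_id = vapply(sets, function(s) as.character(s$subject_id %||% NA),
                        character(1)),
    category = vapply(sets, function(s) as.character(s$category %||% NA),
                      character(1)),
    set_index = vapply(sets, function(s) as.integer(s$set_index %||% NA),
                       integer(1)),
    stringsAsFactors = FALSE)
  mu <- colMeans(raw)
  sd_pop <- sqrt(colMeans(sweep(raw, 2, mu)^2))
  z <- sweep(raw, 2, mu)
  nz <- sd_pop > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sd_pop[nz], "/")
  if (any(!nz))
    warning("constant feature column(s) left at 0 after centering: ",
            paste(feats[!nz], collapse = ", "))
  fm <- cbind(meta, as.data.frame(z))
  attr(fm, "raw_features") <- raw
  attr(fm, "scaling") <- data.frame(feature = feats, mean = mu, sd = sd_pop,
                                    row.names = NULL)
  attr(fm, "mode") <- mode
  attr(fm, "sensor") <- sensor
  attr(fm, "exercise") <- exercises
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Feature column names of a feature matrix
#' @param fm A `feature_matrix`.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(fm) {
  setdiff(colnames(fm), c("subject_id", "category", "set_index"))
}
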