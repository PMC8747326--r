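# Marker-based repetition segmentation, duration normalization and
# per-set averaging.

#' Split a session into repetition segments
#'
#' Uses the push-button marker events to cut the recording into
#' repetitions. With `m` markers the result is `m - 1` segments; segment
#' `i` spans the half-open sample interval `[marker_i, marker_{i+1})`, so
#' boundary samples are never double counted.
#'
#' @param rec A `session_recording`.
#' @return List of `repetition_segment` objects, each with `channels`
#'   (`n x 9` matrix), `repetition_index` and `n_samples`.
#' @export
segment_repetitions <- function(rec) {
  stopifnot(inherits(rec, "session_recording"))
  m <- rec$markers
  if (length(m) < 2) stop("need at least 2 markers to segment")
  if (any(diff(m) <= 0)) stop("markers must be strictly increasing")
  n <- nrow(rec$channels)
  if (m[1] < 1 || m[length(m)] > n + 1)
    stop("marker outside signal range")
  lapply(seq_len(length(m) - 1), function(i) {
    idx <- m[i]:(m[i + 1] - 1)
    seg <- rec$channels[idx, , drop = FALSE]
    if (nrow(seg) < 2) stop("repetition segment with fewer than 2 samples")
    structure(list(channels = seg, repetition_index = i,
                   n_samples = nrow(seg)),
              class = "repetition_segment")
  })
}

#' Normalize repetition durations and average them into one set trace
#'
#' The longest repetition of the set defines the reference grid (100%
#' duration); every repetition is linearly interpolated onto that grid in
#' normalized time, and the channels are then averaged sample-wise across
#' repetitions, making fast and slow repetitions comparable and damping
#' outliers.
#'
#' @param segments List of `repetition_segment` objects (>= 1).
#' @param meta Optional named list of identifying metadata (subject_id,
#'   exercise, category, set_index) carried into the result.
#' @return An object of class `averaged_set` with `channels`
#'   (`grid_length x 9` matrix on the normalized time grid 0..100%),
#'   `grid_length`, and the metadata.
#' @export
normalize_and_average <- function(segments, meta = list()) {
  if (length(segments) == 0) stop("need at least one segment")
  lens <- vapply(segments, function(s) nrow(s$channels), integer(1))
  if (any(lens < 2)) stop("segments must have at least 2 samples")
  grid_length <- max(lens)
  grid <- seq(0, 1, length.out = grid_length)
  resampled <- lapply(segments, function(s) {
    n <- nrow(s$channels)
    x <- seq(0, 1, length.out = n)
    apply(s$channels, 2, function(col) {
      stats::approx(x, col, xout = grid)$y
    })
  })
  channels <- Reduce(`+`, resampled) / length(resampled)
  colnames(channels) <- CHANNEL_NAMES
  structure(c(list(channels = channels, grid_length = grid_length),
              meta[c("subject_id", "exercise", "category", "set_index",
                     "side")[c("subject_id", "exercise", "category",
                               "set_index", "side") %in% names(meta)]]),
            class = "averaged_set")
}

#' Preprocess one session into its averaged set
#'
#' Convenience wrapper: [segment_repetitions()] followed by
#' [normalize_and_average()], carrying the session metadata.
#'
#' @param rec A `session_recording`.
#' @return An `averaged_set`.
#' @export
preprocess_session <- function(rec) {
  segments <- segment_repetitions(rec)
  normalize_and_average(segments,
                        meta = rec[c("subject_id", "exercise", "category",
                                     "set_index", "side")])
}

#' Preprocess every recording of a cohort
#'
#' @param cohort A `cohort` object (or a bare list of
#'   `session_recording`s).
#' @return List of `averaged_set` objects, one per recording.
#' @export
preprocess_cohort <- function(cohort) {
  recs <- if (inherits(cohort, "cohort")) cohort$recordings else cohort
  lapply(recs, preprocess_session)
}

#' @export
print.averaged_set <- function(x, ...) {
  cat(sprintf("<averaged_set> %s %s %s set %s: grid length %d\n",
              x$subject_id %||% "?", x$exercise %||% "?",
              x$category %||% "?", x$set_index %||% "?", x$grid_length))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
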