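# Readers and writers for session, averaged-set, feature-matrix and model
# artifacts. Every writer is paired with a reader that reconstructs the
# in-memory object to full double precision.

#' Write a session recording to CSV
#'
#' Columns `time_s`, the nine channels `s1_ax` .. `s3_az` and a 0/1
#' `marker` impulse column with a 1 on every push-button sample.
#'
#' @param rec A `session_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(rec, path) {
  stopifnot(inherits(rec, "session_recording"))
  n <- nrow(rec$channels)
  marker <- integer(n)
  marker[rec$markers] <- 1L
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sampling_rate,
                   rec$channels, marker = marker, check.names = FALSE)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session recording from CSV
#'
#' Inverse of [write_session_csv()]; identifying metadata is not stored
#' in the CSV and is supplied by the caller (normally from the manifest).
#'
#' @param path CSV file path.
#' @param subject_id,exercise,category,set_index,side Metadata to attach.
#' @return A `session_recording`.
#' @export
read_session_csv <- function(path, subject_id = NA, exercise = NA,
                             category = NA, set_index = NA, side = NA) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("time_s", CHANNEL_NAMES, "marker") %in% colnames(df)))
  channels <- as.matrix(df[CHANNEL_NAMES])
  dt <- diff(df$time_s[1:2])
  structure(list(subject_id = subject_id, exercise = exercise,
                 category = category,
                 set_index = if (is.na(set_index)) NA_integer_
                             else as.integer(set_index),
                 side = side, channels = channels,
                 markers = which(df$marker == 1),
                 sampling_rate = round(1 / dt)),
            class = "session_recording")
}

#' Write an averaged set to CSV
#'
#' Columns `norm_time_pct` (0..100% of repetition duration) plus the nine
#' channel columns.
#'
#' @param set An `averaged_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_averaged_set_csv <- function(set, path) {
  stopifnot(inherits(set, "averaged_set"))
  df <- data.frame(
    norm_time_pct = seq(0, 100, length.out = set$grid_length),
    set$channels, check.names = FALSE)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature matrix to CSV with a JSON scaling sidecar
#'
#' The CSV holds the z-scored values with identifier columns; the sidecar
#' (`<path>.json`) records per-column raw mean and population SD so the
#' raw values can be reconstructed.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm)
  num <- vapply(df, is.numeric, logical(1)) & colnames(df) != "set_index"
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(mode = attr(fm, "mode"),
                  sensor = attr(fm, "sensor"),
                  exercise = attr(fm, "exercise"),
                  scaling = attr(fm, "scaling"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix_csv()]
#'
#' @param path CSV path (the `.json` sidecar must sit next to it).
#' @return A `feature_matrix` with reconstructed raw values and scaling
#'   attributes.
#' @export
read_feature_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  feats <- sidecar$scaling$feature
  z <- as.matrix(df[feats])
  raw <- sweep(sweep(z, 2, sidecar$scaling$sd, "*"), 2,
               sidecar$scaling$mean, "+")
  fm <- df
  attr(fm, "raw_features") <- raw
  attr(fm, "scaling") <- sidecar$scaling
  attr(fm, "mode") <- sidecar$mode
  attr(fm, "sensor") <- sidecar$sensor
  attr(fm, "exercise") <- sidecar$exercise
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

# Flatten a cart_tree node into plain lists for JSON.
node_to_list <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", class = node$class,
         counts = as.list(node$counts), gini = node$gini)
  } else {
    list(type = "split", feature = node$feature,
         split_value = node$split_value, counts = as.list(node$counts),
         gini = node$gini, left = node_to_list(node$left),
         right = node_to_list(node$right))
  }
}

list_to_node <- function(lst) {
  counts <- unlist(lst$counts)
  if (identical(lst$type, "leaf")) {
    list(type = "leaf", class = lst$class, counts = counts,
         gini = lst$gini)
  } else {
    list(type = "split", feature = lst$feature,
         split_value = lst$split_value, counts = counts, gini = lst$gini,
         left = list_to_node(lst$left), right = list_to_node(lst$right))
  }
}

#' Serialize a decision tree to JSON
#'
#' @param tree A `cart_tree`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(tree, path) {
  stopifnot(inherits(tree, "cart_tree"))
  jsonlite::write_json(
    list(features = tree$features, one_use = tree$one_use,
         n_train = tree$n_train, root = node_to_list(tree$root)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a decision tree serialized by [write_model_json()]
#'
#' @param path JSON path.
#' @return A `cart_tree`.
#' @export
read_model_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(root = list_to_node(lst$root),
                 features = unlist(lst$features),
                 one_use = lst$one_use,
                 n_train = lst$n_train),
            class = "cart_tree")
}
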