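# Shared internal helpers: constants, seeding, channel bookkeeping.

# Standard gravity used for the gravity-projection kinematics, m/s^2.
GRAVITY <- 9.81

# Column order of the nine acceleration channels (sensor-major, X/Y/Z).
CHANNEL_NAMES <- as.vector(t(outer(paste0("s", 1:3), c("ax", "ay", "az"),
                                   paste, sep = "_")))

CATEGORIES <- c("CPE", "TCM")

channel_index <- function(sensor, axis) {
  ai <- match(tolower(axis), c("x", "y", "z"))
  if (is.na(ai)) stop("unknown axis: ", axis)
  (sensor - 1L) * 3L + ai
}

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with a sequence of integer keys (subject index,
#' category index, set index, ...) so that every simulated unit gets its own
#' deterministic random stream. The result is always a positive integer
#' below 2^31.
#'
#' @param seed Master seed (integer).
#' @param ... Integer keys identifying the unit.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629  # prime < 2^31; keeps products exact in doubles
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s * 69069 + as.numeric(k) + 1) %% m
  }
  as.integer(s)
}

with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
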