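# Named random substreams derived from one master seed.
#
# Every source of randomness in the package flows through a stream created
# here: one substream per station, one for arrivals, one each for routing,
# bed disposition and length of stay, suffixed with the replication index.
# Identical (master_seed, stream_id) always reproduces the same variates,
# and scenarios that share a master seed share streams (common random
# numbers).

# Deterministic 31-bit hash of a label; stable across platforms/sessions.
.hash_label <- function(label) {
  codes <- utf8ToInt(enc2utf8(as.character(label)))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

#' Create a named random substream
#'
#' @param master_seed Integer master seed (all package randomness derives
#'   from it).
#' @param stream_id Character label, e.g. `"service:decision_to_admit/rep3"`.
#' @return An object of class `rng_stream` holding its own RNG state.
#' @examples
#' s <- rng_stream(1L, "arrivals")
#' stream_runif(s, 3)
#' @export
rng_stream <- function(master_seed, stream_id) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  master_seed <- as.integer(master_seed %% 2147483647)
  seed <- as.integer((as.double(master_seed) * 48271 +
                      as.double(.hash_label(stream_id))) %% 2147483647)
  e <- new.env(parent = emptyenv())
  e$seed <- seed
  e$stream_id <- as.character(stream_id)
  e$state <- NULL  # lazily initialised .Random.seed
  class(e) <- "rng_stream"
  e
}

# Run `fn()` with the stream's RNG state active; save the advanced state.
with_stream <- function(stream, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (is.null(stream$state)) {
    set.seed(stream$seed, kind = "Mersenne-Twister")
  } else {
    assign(".Random.seed", stream$state, envir = globalenv())
  }
  res <- fn()
  stream$state <- get(".Random.seed", globalenv())
  res
}

#' Draw from a named stream
#'
#' `stream_runif` / `stream_rexp` draw uniform / exponential variates from
#' the stream, advancing its private state; the global RNG state is left
#' untouched.
#'
#' @param stream An [rng_stream()].
#' @param n Number of draws.
#' @param mean Mean of the exponential (minutes).
#' @return Numeric vector of length `n`.
#' @export
stream_runif <- function(stream, n) with_stream(stream, function() stats::runif(n))

#' @rdname stream_runif
#' @export
stream_rexp <- function(stream, n, mean = 1) {
  with_stream(stream, function() stats::rexp(n, rate = 1 / mean))
}

#' Sample service durations from a triangular distribution
#'
#' @param dist A [triangular_dist()].
#' @param stream An [rng_stream()].
#' @param n Number of variates (>= 1).
#' @return `n` triangular variates, all inside `[lower, upper]`;
#'   reproducible under a fixed stream.
#' @export
sample_duration <- function(dist, stream, n) {
  stopifnot(inherits(dist, "triangular_dist"), n >= 1)
  qtri(stream_runif(stream, n), dist)
}

#' Sample inter-arrival times from an exponential arrival process
#'
#' @param arr An [exponential_arrival()].
#' @param stream An [rng_stream()].
#' @param n Number of variates (>= 1).
#' @return `n` exponential inter-arrival times (minutes, all > 0).
#' @export
sample_interarrivals <- function(arr, stream, n) {
  stopifnot(inherits(arr, "exponential_arrival"), n >= 1)
  stream_rexp(stream, n, mean = arr$mean_interarrival)
}
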