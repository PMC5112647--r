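#' Reproducible purpose-keyed random number streams
#'
#' The paired-arm design requires that both reversal arms see *identical*
#' random inputs (common random numbers) and that every modelled source of
#' randomness (procedure durations, turnovers, cancellations, verification,
#' clinical events, ...) is independent of the others. `or_streams` supports
#' this with deterministic substreams: every `(purpose, replication, day)`
#' triple is hashed together with the master seed into a substream seed, so
#' the same key always yields the same uniforms, regardless of the order in
#' which substreams are consumed.
#'
#' @param master_seed a single integer seed.
#' @return an object of class `or_streams`.
#' @examples
#' s <- or_streams(7)
#' stream_uniforms(s, "turnover", 3, replication = 1, day = 2)
#' @export
or_streams <- function(master_seed) {
  if (length(master_seed) != 1L || is.na(master_seed) ||
      master_seed != trunc(master_seed))
    stop("master_seed must be a single integer", call. = FALSE)
  structure(list(master_seed = as.double(master_seed) %% 2147483629),
            class = "or_streams")
}

#' @export
print.or_streams <- function(x, ...) {
  cat("<or_streams> master seed", format(x$master_seed), "\n")
  invisible(x)
}

# Deterministic hash of (master seed, purpose, replication, day) onto
# [1, 2^31). Mixing is done modulo a prime below 2^31 with multipliers small
# enough that every intermediate product stays below 2^53 (exact in doubles);
# the Mersenne-Twister seeding then scrambles the result so that nearby keys
# give effectively independent sequences.
substream_seed <- function(master_seed, purpose, replication = 0L, day = 0L) {
  M <- 2147483629
  h <- 0
  for (ch in utf8ToInt(as.character(purpose))) h <- (h * 131 + ch) %% M
  x <- as.double(master_seed) %% M
  x <- (x * 599479 + h) %% M
  x <- (x * 900001 + as.double(replication) %% M) %% M
  x <- (x * 701147 + as.double(day) %% M) %% M
  as.integer(x + 1)
}

#' Draw uniforms from a named substream
#'
#' Returns `n` uniforms on `(0, 1)` from the substream identified by
#' `(purpose, replication, day)`. Identical keys and master seed always give
#' identical values; different purposes give independent sequences. The
#' global RNG state is saved and restored, so stream draws never perturb
#' user-level randomness.
#'
#' @param streams an [or_streams()] object.
#' @param purpose character key naming the source of randomness.
#' @param n number of uniforms.
#' @param replication,day integer indices identifying the simulated month
#'   and day.
#' @return numeric vector of `n` uniforms.
#' @export
stream_uniforms <- function(streams, purpose, n, replication = 0L, day = 0L) {
  stopifnot(inherits(streams, "or_streams"))
  if (n == 0L) return(numeric(0))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(streams$master_seed, purpose, replication, day))
  stats::runif(n)
}
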