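#' Reproducible per-process random-number streams
#'
#' The simulator gives every (patient, process) pair its own random-number
#' stream so that the four policies share random numbers for every process a
#' policy change does not touch (common random numbers). A stream is a small
#' environment holding a saved R RNG state; draws temporarily swap that state
#' into the session RNG, run the requested sampling call, and swap the
#' previous session state back, so streams never disturb user-level
#' reproducibility.
#'
#' @param seed Integer seed (0 <= seed < 2^31) initialising the stream.
#' @return An object of class `rng_stream`.
#' @examples
#' s <- rng_stream(42)
#' a <- stream_eval(s, function() rexp(3))
#' b <- stream_eval(s, function() rexp(3))   # continues the stream
#' identical(a, stream_eval(rng_stream(42), function() rexp(3)))
#' @export
rng_stream <- function(seed) {
  s <- new.env(parent = emptyenv())
  s$seed <- as.numeric(seed)
  s$state <- NULL
  class(s) <- "rng_stream"
  s
}

#' Evaluate a sampling function on a stream
#'
#' @param stream An [rng_stream()].
#' @param fn A zero-argument function performing RNG draws.
#' @return The value of `fn()`.
#' @export
stream_eval <- function(stream, fn) {
  genv <- globalenv()
  old <- get0(".Random.seed", envir = genv, inherits = FALSE)
  if (is.null(stream$state)) {
    set.seed(stream$seed %% 2147483647)
  } else {
    assign(".Random.seed", stream$state, envir = genv)
  }
  out <- fn()
  stream$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = genv)
  } else {
    assign(".Random.seed", old, envir = genv)
  }
  out
}

# Deterministic seed for a (master seed, patient id, process index) triple.
# Mixing is done in doubles (exact below 2^53) and reduced mod a prime < 2^31
# so derived seeds are always valid 32-bit R seeds.
derive_seed <- function(master, patient_id, process) {
  m <- 2147483629
  ((as.numeric(master) %% m) * 48271 +
     as.numeric(patient_id) * 30269 +
     as.numeric(process) * 9973) %% m
}

# Named stream set for one patient. Process indices are fixed so streams stay
# aligned across policies.
PROCESSES <- c(onset = 1L, episode = 2L, contacts = 3L, review = 4L,
               treatment = 5L, diabetes = 6L, misc = 7L)

patient_streams <- function(master, patient_id) {
  out <- lapply(PROCESSES, function(p) rng_stream(derive_seed(master, patient_id, p)))
  names(out) <- names(PROCESSES)
  out
}

# Run fn() with the session RNG seeded locally; previous RNG state restored.
with_local_seed <- function(seed, fn) {
  s <- rng_stream(seed)
  stream_eval(s, fn)
}
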