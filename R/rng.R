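# Reproducible per-simulation random-number substreams.
#
# A single master seed spawns L'Ecuyer-CMRG substreams by counter, so that
# simulation l of a Monte-Carlo run can be reproduced in isolation and runs
# are bit-identical for identical (design, seed).

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Derive `n` independent RNG substreams from a master seed without
# perturbing the caller's RNG state.
make_streams <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  suppressWarnings(set.seed(as.integer(seed %% .Machine$integer.max),
                            kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", envir = globalenv())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  out
}

# Activate one substream (the kind is encoded in the seed vector itself).
use_stream <- function(stream) {
  assign(".Random.seed", stream, envir = globalenv())
  invisible(NULL)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stopf("'%s' must be >= 0 (got %g)", name, x)
  if (integer && abs(x - round(x)) > 1e-8)
    stopf("'%s' must be an integer (got %g)", name, x)
  invisible(x)
}

check_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  check_scalar(x, name)
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok)
    stopf("'%s' must lie in %s0, 1%s (got %g)", name,
          if (open_left) "(" else "[", if (open_right) ")" else "]", x)
  invisible(x)
}
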