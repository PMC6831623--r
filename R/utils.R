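# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage seed from a global seed and labels
#'
#' One global seed deterministically derives every stage/session seed via a
#' small FNV-style string hash, so a whole run is reproducible from its
#' configuration alone. Derived seeds stay below 2^31 - 1.
#'
#' @param seed integer global seed
#' @param ... labels (coerced to character) naming the consumer
#' @return a single integer seed
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(as.integer(seed)), vapply(list(...), format, "")),
               collapse = "/")
  h <- 216613626
  for (cc in utf8ToInt(key)) {
    # polynomial rolling hash in double precision, modulus < 2^31 keeps
    # every intermediate exactly representable
    h <- (h * 131 + cc) %% 2147483629
  }
  as.integer(h) + 1L
}

# evaluate `expr` under a given RNG seed, restoring global RNG state after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", name)
  invisible(x)
}

# package-local cache (coarse dipole grids etc.)
.eegtrack_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, compute) {
  if (!exists(key, envir = .eegtrack_cache, inherits = FALSE)) {
    assign(key, compute(), envir = .eegtrack_cache)
  }
  get(key, envir = .eegtrack_cache, inherits = FALSE)
}
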