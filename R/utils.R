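#' Run code with a locally set RNG seed
#'
#' Sets the RNG seed for the duration of the calling function and restores the
#' previous global RNG state on exit, so that seeded package functions do not
#' clobber the caller's random stream. A `NULL` seed leaves the current stream
#' untouched (draws then consume from it).
#'
#' @param seed integer seed or `NULL`.
#' @param envir frame whose exit triggers restoration.
#' @keywords internal
#' @noRd
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    expr <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    expr <- quote(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Derive a reproducible child seed from a base seed and an index/label
#'
#' Deterministic 31-bit mixing so that independent stochastic components
#' (participants, bootstrap iterations, optimizer starts) get distinct,
#' reproducible streams from one global seed.
#'
#' @param seed base integer seed.
#' @param index non-negative integer distinguishing the component.
#' @param label optional character tag mixed into the hash.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, index = 0L, label = "") {
  h <- as.double(seed %% 2147483647)
  for (k in c(as.double(index), as.double(utf8ToInt(label)))) {
    h <- (h * 48271 + k + 1) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Reflect values into [0, 1] by iterated folding at both boundaries.
fold_reflect <- function(x) {
  while (any(x < 0 | x > 1)) {
    x <- ifelse(x < 0, -x, x)
    x <- ifelse(x > 1, 2 - x, x)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
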