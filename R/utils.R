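#' Derive a child seed from a master seed and a stream label
#'
#' Hierarchical seeding: every stochastic stage (ensemble member, module
#' stream) gets its own reproducible stream derived from one master seed, so
#' runs are bit-identical under a fixed master seed while streams stay
#' decorrelated. The hash is a small multiplicative mix kept below 2^31.
#'
#' @param master integer master seed
#' @param ... further labels (character or integer) identifying the stream
#' @return an integer in [1, 2^31 - 2] usable with [set.seed()]
#' @export
derive_seed <- function(master, ...) {
  labels <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(master) %% 2147483647
  for (lab in labels) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h %% 2147483645 + 1)
}

# evaluate expr with a local RNG state (restores caller's state)
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
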