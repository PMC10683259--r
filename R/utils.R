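# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so that seeded generators never disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a base seed; keeps results
# reproducible when one user-facing seed drives several generators.
# Double arithmetic: the product stays below 2^53, so the modulus is
# exact and the result fits in a 32-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483562)
}

stop_methrisk <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "methrisk_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Column-wise mode, breaking ties by first level order.
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA)
  tab <- table(x)
  names(tab)[which.max(tab)]
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
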