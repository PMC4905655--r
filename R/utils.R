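# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the ambient RNG stream" (no save/restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-stream seed from a master seed and labels
#'
#' Deterministically maps a master seed plus an arbitrary tuple of labels
#' (numbers or strings, e.g. `("power", n_cells, n_loci, replicate)`) to an
#' integer seed in `[0, 2^31)`.  Distinct label tuples map to distinct seeds
#' with high probability, so every replicate of every analysis can run on
#' its own independent, reproducible stream.
#'
#' Two independent polynomial hashes over small primes are combined; all
#' arithmetic stays below 2^53 so the result is exact in double precision.
#'
#' @param master_seed Integer master seed.
#' @param ... Labels identifying the sub-stream (coerced to character).
#' @return A single integer in `[0, 2^31 - 1]`.
#' @examples
#' derive_seed(1, "power", 50, 5000, 7)
#' @export
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  labels <- vapply(list(...), function(x) paste(format(x, digits = 15), collapse = ","),
                   character(1))
  bytes <- utf8ToInt(paste(c(format(master_seed, digits = 15), labels),
                           collapse = "\x1f"))
  m1 <- 94906231; m2 <- 94906249   # primes < 2^26.6: products with <2^27 stay < 2^53
  h1 <- 17; h2 <- 29
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% m1
    h2 <- (h2 * 137 + b) %% m2
  }
  as.integer((h1 * 22695477 + h2) %% 2147483647)
}

# stop() with a condition class so callers can distinguish failure modes
stop_with <- function(class, msg, call = sys.call(-1)) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = call)))
}
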