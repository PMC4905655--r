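#' Mutation model for STR or SNV loci
#'
#' Defines how a panel of loci mutates at each cell division.
#'
#' STR (microsatellite) loci follow the stepwise (single-step) mutation
#' model: at every division each locus independently gains one repeat unit
#' with probability `rate/2`, loses one with probability `rate/2`, and is
#' otherwise unchanged.  Repeat counts are stored as signed integer offsets
#' from the root value (root = 0 at every locus) and are unbounded.
#'
#' SNV loci are categorical with four states (0 = reference, 1..3 =
#' alternative bases).  At every division each locus is independently
#' replaced, with probability `rate`, by one of the other three states
#' chosen uniformly; back-mutation to the reference is therefore possible.
#'
#' Typical per-division rates: STR `1e-3`-`1e-5` per locus (the high end
#' corresponding to microsatellite-unstable cancer cells), SNV `1e-7`-`1e-9`
#' per base.
#'
#' @param kind `"STR"` or `"SNV"`.
#' @param rate Mutation probability per locus (STR) or per base (SNV) per
#'   cell division, in `[0, 1]`.
#' @param n_loci Number of loci in the panel (>= 1).
#' @return An object of class `mutation_model`.
#' @examples
#' mutation_model("STR", rate = 1e-4, n_loci = 5000)
#' @export
mutation_model <- function(kind = c("STR", "SNV"), rate, n_loci) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (rate < 0 || rate > 1) stop_with("invalid_rate", "`rate` must lie in [0, 1]")
  n_loci <- as.integer(n_loci)
  stopifnot(length(n_loci) == 1L, !is.na(n_loci), n_loci >= 1L)
  structure(list(kind = kind, rate = rate, n_loci = n_loci,
                 snv_states = 4L),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("<mutation_model> %s, rate %g per %s per division, %d loci\n",
              x$kind, x$rate, if (x$kind == "STR") "locus" else "base", x$n_loci))
  invisible(x)
}

#' Root genotype of a mutation model
#'
#' The unmutated founder state: all-zero offsets (STR) or all-reference
#' categories (SNV).
#'
#' @param model A [mutation_model()].
#' @return Integer vector of length `model$n_loci`.
#' @export
root_genotype <- function(model) {
  stopifnot(inherits(model, "mutation_model"))
  integer(model$n_loci)
}

check_genotype <- function(genotype, model) {
  if (!is.numeric(genotype) || length(genotype) != model$n_loci ||
      anyNA(genotype) || any(genotype != round(genotype))) {
    stop_with("invalid_genotype",
              "genotype must be an integer vector of length n_loci with no NAs")
  }
  if (model$kind == "SNV" && (any(genotype < 0) || any(genotype > 3)))
    stop_with("invalid_genotype", "SNV genotype entries must lie in 0..3")
  invisible(TRUE)
}

#' Apply one cell division of mutation to a genotype
#'
#' @param genotype Integer vector of per-locus states (STR offsets or SNV
#'   categories) consistent with `model`.
#' @param model A [mutation_model()].
#' @param seed Optional integer seed; identical seeds give identical output
#'   and the ambient RNG state is left untouched.
#' @return A new genotype vector; the input is not modified.
#' @examples
#' m <- mutation_model("STR", 0.5, 10)
#' mutate_one_division(root_genotype(m), m, seed = 1)
#' @export
mutate_one_division <- function(genotype, model, seed = NULL) {
  stopifnot(inherits(model, "mutation_model"))
  check_genotype(genotype, model)
  with_seed(seed, {
    n <- model$n_loci
    if (model$kind == "STR") {
      u <- stats::runif(n)
      step <- integer(n)
      step[u < model$rate / 2] <- 1L
      step[u >= model$rate / 2 & u < model$rate] <- -1L
      as.integer(genotype + step)
    } else {
      hit <- stats::runif(n) < model$rate
      out <- as.integer(genotype)
      if (any(hit)) {
        # uniform over the 3 states other than the current one
        shift <- sample.int(3L, sum(hit), replace = TRUE)
        out[hit] <- (out[hit] + shift[seq_len(sum(hit))]) %% 4L
      }
      out
    }
  })
}

#' Propagate a genotype through k cell divisions
#'
#' Distributionally equivalent to `k` successive calls of
#' [mutate_one_division()], computed in closed form per locus:
#'
#' * STR: the number of mutated divisions is Binomial(`k`, `rate`) and each
#'   mutation is an independent fair +/-1 step, so the offset increment is
#'   a sum of `n_mut` signed unit steps.
#' * SNV: the 4-state symmetric chain is iterated via its `k`-step
#'   transition probability `P(unchanged) = 1/4 + 3/4 (1 - 4 rate/3)^k`;
#'   by symmetry a changed locus is uniform over the other three states.
#'
#' @inheritParams mutate_one_division
#' @param k Number of divisions (>= 0); `k = 0` returns the input.
#' @param method `"fast"` (closed form, default) or `"stepwise"` (literal
#'   k-fold loop; used for cross-validation of the fast path).
#' @return A new genotype vector.
#' @export
propagate <- function(genotype, k, model, seed = NULL,
                      method = c("fast", "stepwise")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "mutation_model"))
  check_genotype(genotype, model)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L)
    stop_with("invalid_divisions", "`k` must be a single integer >= 0")
  if (k == 0L) return(as.integer(genotype))
  if (method == "stepwise") {
    return(with_seed(seed, {
      g <- genotype
      for (i in seq_len(k)) g <- mutate_one_division(g, model)
      g
    }))
  }
  with_seed(seed, {
    n <- model$n_loci
    if (model$kind == "STR") {
      n_mut <- stats::rbinom(n, k, model$rate)
      up <- stats::rbinom(n, n_mut, 0.5)
      as.integer(genotype + 2L * up - n_mut)
    } else {
      p_same <- 0.25 + 0.75 * (1 - 4 * model$rate / 3)^k
      hit <- stats::runif(n) >= p_same
      out <- as.integer(genotype)
      if (any(hit)) {
        shift <- sample.int(3L, sum(hit), replace = TRUE)
        out[hit] <- (out[hit] + shift) %% 4L
      }
      out
    }
  })
}
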