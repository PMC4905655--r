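# Maximum-likelihood calibration of the dropout model from a binary
# signal table, by simulated annealing with multiple restarts.
#
# The likelihood depends on (P, Q) only through the products p_i q_j, so
# the parameters are identifiable only up to a scalar: after optimization
# the fit is put in a canonical scale with max_j q_j = 1.

#' Simulated-annealing configuration for dropout calibration
#'
#' Coordinate-wise Gaussian random-walk proposals (reflected into
#' `[0, 1]`) with geometric cooling.  Several restarts from independent
#' random starting points guard against local optima; the best restart is
#' returned and restart-to-restart agreement of the fitted product matrix
#' is recorded.
#'
#' @param t_init Initial temperature (> 0).
#' @param cooling Geometric cooling factor in (0, 1), applied per iteration.
#' @param iterations Proposals per restart.
#' @param step_sd Standard deviation of the Gaussian proposal.
#' @param restarts Number of independent restarts (>= 2).
#' @param start_range Range of the Uniform starting values.
#' @param seed Optional integer seed.
#' @return An object of class `annealing_config`.
#' @export
annealing_config <- function(t_init = 1, cooling = 0.995, iterations = 2e4,
                             step_sd = 0.05, restarts = 5,
                             start_range = c(0.2, 0.9), seed = NULL) {
  stopifnot(t_init > 0, cooling > 0, cooling < 1, iterations >= 1,
            step_sd > 0, restarts >= 2, length(start_range) == 2L)
  structure(list(t_init = t_init, cooling = cooling,
                 iterations = as.integer(iterations), step_sd = step_sd,
                 restarts = as.integer(restarts), start_range = start_range,
                 seed = seed),
            class = "annealing_config")
}

# log-likelihood contribution of one sample row (or, transposed, one locus
# column): sum_j log(x pq + (1-x)(1-pq)), clamped
slice_loglik <- function(x_slice, pq_slice) {
  # x*pq + (1-x)*(1-pq), written branch-free
  sum(log(pmax(1 - pq_slice + x_slice * (2 * pq_slice - 1), 1e-12)))
}

anneal_once <- function(x, config) {
  M <- nrow(x); N <- ncol(x)
  p <- stats::runif(M, config$start_range[1], config$start_range[2])
  q <- stats::runif(N, config$start_range[1], config$start_range[2])
  ll <- dropout_log_likelihood(p, q, x)
  temp <- config$t_init
  idx <- sample.int(M + N, config$iterations, replace = TRUE)
  steps <- stats::rnorm(config$iterations, 0, config$step_sd)
  acc_u <- stats::runif(config$iterations)
  for (it in seq_len(config$iterations)) {
    i <- idx[it]
    if (i <= M) {
      old <- p[i]
      new <- reflect01(old + steps[it])
      delta <- slice_loglik(x[i, ], new * q) - slice_loglik(x[i, ], old * q)
      if (delta > 0 || acc_u[it] < exp(delta / temp)) { p[i] <- new; ll <- ll + delta }
    } else {
      j <- i - M
      old <- q[j]
      new <- reflect01(old + steps[it])
      delta <- slice_loglik(x[, j], p * new) - slice_loglik(x[, j], p * old)
      if (delta > 0 || acc_u[it] < exp(delta / temp)) { q[j] <- new; ll <- ll + delta }
    }
    temp <- temp * config$cooling
  }
  list(p = p, q = q, loglik = ll)
}

# reflect a proposal into [0, 1]
reflect01 <- function(v) {
  v <- abs(v)
  if (v > 1) v <- 2 - v
  min(max(v, 0), 1)
}

#' Fit the dropout model to a binary signal table by maximum likelihood
#'
#' Maximizes the dropout log-likelihood (see [dropout_log_likelihood()])
#' over the per-sample probabilities P and per-locus probabilities Q by
#' simulated annealing, repeated from `config$restarts` random starting
#' points; the best restart is returned.  Because only the products
#' `p_i q_j` are identifiable, the result is rescaled so that
#' `max(q) == 1`.
#'
#' @param x M x N binary signal table (M, N >= 2).
#' @param config An [annealing_config()].
#' @return A [dropout_model()] with attributes `loglik` (achieved
#'   log-likelihood), `restart_logliks`, and `product_spread` (maximum
#'   absolute restart-to-restart difference of fitted products, a
#'   convergence diagnostic).
#' @examples
#' fx <- generate_calibration_fixture(20, 50, seed = 1)
#' fit <- fit_dropout_ml(fx$signal, annealing_config(iterations = 2000, seed = 1))
#' @export
fit_dropout_ml <- function(x, config = annealing_config()) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 2L,
            all(x %in% c(0L, 1L)), inherits(config, "annealing_config"))
  if (all(x == 0)) {
    warning("signal table is all-zero: dropout products are 0 and P, Q are unidentifiable")
    out <- dropout_model(rep(0, nrow(x)), rep(0, ncol(x)))
    attr(out, "loglik") <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  with_seed(config$seed, {
    fits <- lapply(seq_len(config$restarts), function(r) anneal_once(x, config))
    lls <- vapply(fits, `[[`, numeric(1), "loglik")
    best <- fits[[which.max(lls)]]
    # restart agreement on the identifiable scale (the product matrix)
    prods <- lapply(fits, function(f) outer(f$p, f$q))
    spread <- max(vapply(prods, function(pr)
      max(abs(pr - prods[[which.max(lls)]])), numeric(1)))
    scale <- max(best$q)
    out <- dropout_model(pmin(1, best$p * scale), best$q / scale)
    attr(out, "loglik") <- best$loglik
    attr(out, "restart_logliks") <- lls
    attr(out, "product_spread") <- spread
    out
  })
}
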