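# Observed-signal modeling: mutation tables with missing entries, the
# per-sample x per-locus allele-dropout model, genotyping noise, and the
# synthetic calibration fixtures that stand in for real amplified
# single-cell panels.

#' Mutation table of observed single-cell genotypes
#'
#' An M samples x N loci matrix of genotype calls: STR repeat-count offsets
#' (signed integers) or SNV categories (0..3).  `NA` marks allele dropout
#' (no signal at that sample/locus).  The binary signal table is derived
#' via [signal_table()].
#'
#' @param values Numeric matrix (samples in rows, loci in columns); `NA`
#'   for missing entries.
#' @param kind `"STR"` or `"SNV"`.
#' @param validate Check entry integrity (skipped on internal rewraps of
#'   already-validated tables).
#' @return The matrix with class `mutation_table` and a `kind` attribute.
#' @export
mutation_table <- function(values, kind = c("STR", "SNV"), validate = TRUE) {
  kind <- match.arg(kind)
  if (validate) {
    stopifnot(is.matrix(values), is.numeric(values))
    if (any(values[!is.na(values)] != round(values[!is.na(values)])))
      stop_with("invalid_table", "mutation table entries must be integers")
    if (kind == "SNV" && any(values < 0 | values > 3, na.rm = TRUE))
      stop_with("invalid_table", "SNV entries must lie in 0..3")
  }
  structure(values, class = unique(c("mutation_table", class(values))),
            kind = kind)
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf("<mutation_table> %s, %d samples x %d loci, %.1f%% missing\n",
              attr(x, "kind"), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

table_kind <- function(table) {
  k <- attr(table, "kind")
  if (is.null(k)) "STR" else k
}

# subsetting keeps class and kind
#' @export
`[.mutation_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) out <- mutation_table(out, kind = table_kind(x), validate = FALSE)
  out
}

#' Binary signal table of a mutation table
#'
#' @param table A [mutation_table()] (or any matrix with `NA` = dropout).
#' @return A 0/1 matrix: 0 where the entry is missing, 1 where a signal
#'   was observed.
#' @export
signal_table <- function(table) {
  out <- matrix(as.integer(!is.na(table)), nrow(table), ncol(table),
                dimnames = dimnames(table))
  out
}

#' Allele-dropout model with per-sample and per-locus signal probabilities
#'
#' Entry (i, j) of a mutation table is observed with probability
#' `p[i] * q[j]` and dropped otherwise: `p` captures per-cell amplification
#' quality, `q` captures per-locus amplification bias.
#'
#' @param p Length-M vector of per-sample signal probabilities in `[0, 1]`.
#' @param q Length-N vector of per-locus signal probabilities in `[0, 1]`.
#' @return An object of class `dropout_model`.
#' @export
dropout_model <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) >= 1, length(q) >= 1)
  if (anyNA(p) || anyNA(q) || any(p < 0 | p > 1) || any(q < 0 | q > 1))
    stop_with("invalid_probability", "all entries of p and q must lie in [0, 1]")
  structure(list(p = as.numeric(p), q = as.numeric(q)), class = "dropout_model")
}

#' @export
print.dropout_model <- function(x, ...) {
  cat(sprintf("<dropout_model> %d samples (mean p %.3f), %d loci (mean q %.3f)\n",
              length(x$p), mean(x$p), length(x$q), mean(x$q)))
  invisible(x)
}

#' Beta priors for drawing dropout probabilities
#'
#' Describes the population of per-sample and per-locus signal
#' probabilities rather than fixed vectors: each simulated experiment draws
#' `p[i] ~ Beta(p_shape)` per cell and `q[j] ~ Beta(q_shape)` per locus.
#' The defaults, Beta(8, 2) for samples (mean 0.8, broad) and Beta(5, 5)
#' for loci (mean 0.5), emulate the wide quality spread seen across
#' whole-genome-amplified single cells and targeted loci.  `boost`
#' multiplies every draw (capped at 1) and encodes projected signal
#' improvements.
#'
#' @param p_shape,q_shape Length-2 Beta shape parameters.
#' @param boost Multiplier applied to every draw, capped at 1.
#' @return An object of class `dropout_prior`.
#' @export
dropout_prior <- function(p_shape = c(8, 2), q_shape = c(5, 5), boost = 1) {
  stopifnot(length(p_shape) == 2L, length(q_shape) == 2L,
            all(p_shape > 0), all(q_shape > 0), boost > 0)
  structure(list(p_shape = as.numeric(p_shape), q_shape = as.numeric(q_shape),
                 boost = boost), class = "dropout_prior")
}

#' Draw a concrete dropout model from a prior
#'
#' @param prior A [dropout_prior()].
#' @param M,N Numbers of samples and loci.
#' @param seed Optional integer seed.
#' @return A [dropout_model()].
#' @export
draw_dropout <- function(prior, M, N, seed = NULL) {
  stopifnot(inherits(prior, "dropout_prior"))
  with_seed(seed, {
    p <- pmin(1, prior$boost * stats::rbeta(M, prior$p_shape[1], prior$p_shape[2]))
    q <- pmin(1, prior$boost * stats::rbeta(N, prior$q_shape[1], prior$q_shape[2]))
    dropout_model(p, q)
  })
}

#' Apply allele dropout to a mutation table
#'
#' Each entry (i, j) is independently retained with probability
#' `p[i] * q[j]` and set to `NA` otherwise.  Retained values are never
#' altered.
#'
#' @param table A [mutation_table()].
#' @param model A [dropout_model()] with dimensions matching `table`.
#' @param seed Optional integer seed.
#' @return A [mutation_table()] with dropouts applied.
#' @export
apply_dropout <- function(table, model, seed = NULL) {
  stopifnot(inherits(model, "dropout_model"))
  if (length(model$p) != nrow(table) || length(model$q) != ncol(table))
    stop_with("dimension_mismatch",
              "dropout model dimensions must match the table")
  with_seed(seed, {
    keep_prob <- outer(model$p, model$q)
    drop <- matrix(stats::runif(length(table)), nrow(table)) >= keep_prob
    out <- unclass(table)
    out[drop] <- NA
    mutation_table(out, kind = table_kind(table), validate = FALSE)
  })
}

#' Genotyping-noise model
#'
#' Per-observed-entry measurement error: an observed STR locus shifts by
#' one repeat unit (directions equiprobable) with probability
#' `str_shift_prob`; an observed SNV base is miscalled as a uniformly
#' chosen other category with probability `snv_error_prob`.  The STR
#' default 0.005 is a plausible duplicate-inconsistency scale for
#' amplified single cells (see [estimate_str_noise()]); the SNV default
#' 1e-4 matches single-cell variant-calling error estimates.
#'
#' @param str_shift_prob Per-observed-locus one-repeat shift probability.
#' @param snv_error_prob Per-observed-base miscall probability.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(str_shift_prob = 0.005, snv_error_prob = 1e-4) {
  v <- c(str_shift_prob, snv_error_prob)
  if (anyNA(v) || any(v < 0 | v > 1))
    stop_with("invalid_probability", "noise probabilities must lie in [0, 1]")
  structure(list(str_shift_prob = str_shift_prob, snv_error_prob = snv_error_prob),
            class = "noise_model")
}

#' Apply genotyping noise to a mutation table
#'
#' Only observed entries are perturbed; missing entries are never
#' resurrected.
#'
#' @param table A [mutation_table()].
#' @param model A [noise_model()].
#' @param kind Table kind; defaults to the table's own `kind` attribute.
#' @param seed Optional integer seed.
#' @return A [mutation_table()].
#' @export
apply_noise <- function(table, model, kind = NULL, seed = NULL) {
  stopifnot(inherits(model, "noise_model"))
  if (is.null(kind)) kind <- table_kind(table)
  kind <- match.arg(kind, c("STR", "SNV"))
  with_seed(seed, {
    out <- unclass(table)
    obs <- which(!is.na(out))
    if (kind == "STR") {
      u <- stats::runif(length(obs))
      s <- model$str_shift_prob
      up <- obs[u < s / 2]
      dn <- obs[u >= s / 2 & u < s]
      out[up] <- out[up] + 1L
      out[dn] <- out[dn] - 1L
    } else {
      hit <- obs[stats::runif(length(obs)) < model$snv_error_prob]
      if (length(hit))
        out[hit] <- (out[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4
    }
    mutation_table(out, kind = kind, validate = FALSE)
  })
}

#' Distort a true genotype table with dropout then noise
#'
#' The composition used throughout the power analyses: allele dropout is
#' applied first, then genotyping noise on the surviving entries.  If
#' `dropout` is a [dropout_prior()], a fresh dropout model is drawn for the
#' table's dimensions (one draw per simulated experiment).
#'
#' @param table A [mutation_table()] of true genotypes.
#' @param dropout A [dropout_model()] or [dropout_prior()] (or `NULL` to skip).
#' @param noise A [noise_model()] (or `NULL` to skip).
#' @param seed Optional integer seed.
#' @return A distorted [mutation_table()].
#' @export
distort_table <- function(table, dropout = dropout_prior(),
                          noise = noise_model(), seed = NULL) {
  with_seed(seed, {
    if (inherits(dropout, "dropout_prior"))
      dropout <- draw_dropout(dropout, nrow(table), ncol(table))
    out <- table
    if (!is.null(dropout)) out <- apply_dropout(out, dropout)
    if (!is.null(noise)) out <- apply_noise(out, noise)
    out
  })
}

#' Log-likelihood of a binary signal table under the dropout model
#'
#' `sum over (i, j) of log(x_ij p_i q_j + (1 - x_ij)(1 - p_i q_j))`.
#' Terms are clamped to `>= 1e-12` before the log so boundary parameter
#' values keep the result finite during optimization.  The likelihood
#' depends on `p` and `q` only through the products `p_i q_j`, so it is
#' invariant under the rescaling `(c p, q / c)`.
#'
#' @param p,q Probability vectors (lengths M and N).
#' @param x M x N binary signal table (see [signal_table()]).
#' @return The log-likelihood (a single number).
#' @export
dropout_log_likelihood <- function(p, q, x) {
  stopifnot(is.matrix(x), length(p) == nrow(x), length(q) == ncol(x))
  if (any(p < 0 | p > 1) || any(q < 0 | q > 1))
    stop_with("invalid_probability", "p and q must lie in [0, 1]")
  pq <- outer(as.numeric(p), as.numeric(q))
  term <- ifelse(x == 1, pq, 1 - pq)
  sum(log(pmax(term, 1e-12)))
}

#' Project future signal enhancements onto dropout and noise models
#'
#' Signal probabilities are increased by 25% relative (capped at 1) and
#' noise probabilities are halved, projecting anticipated improvements in
#' single-cell amplification and genotyping.
#'
#' @param dropout A [dropout_model()] or [dropout_prior()].
#' @param noise A [noise_model()].
#' @return A list with the enhanced `dropout` and `noise` objects.
#' @examples
#' enhance_future(dropout_model(0.4, 0.9), noise_model(0.005, 1e-4))
#' @export
enhance_future <- function(dropout, noise) {
  noise2 <- noise_model(noise$str_shift_prob / 2, noise$snv_error_prob / 2)
  if (inherits(dropout, "dropout_prior")) {
    dropout2 <- dropout_prior(dropout$p_shape, dropout$q_shape,
                              boost = dropout$boost * 1.25)
  } else {
    stopifnot(inherits(dropout, "dropout_model"))
    dropout2 <- dropout_model(pmin(1, 1.25 * dropout$p), pmin(1, 1.25 * dropout$q))
  }
  list(dropout = dropout2, noise = noise2)
}

#' Generate a synthetic dropout-calibration fixture
#'
#' Builds a binary signal table mimicking a panel of amplified single
#' cells: `p_i ~ Beta(p_shape)` per sample, `q_j ~ Beta(q_shape)` per
#' locus, and `x_ij ~ Bernoulli(p_i q_j)`.  The generating model is
#' returned so parameter-recovery tests can score the fit.  The default
#' size (167 samples) matches the scale of a typical ex-vivo single-cell
#' calibration panel.
#'
#' @param M,N Numbers of samples and loci.
#' @param p_shape,q_shape Beta shape parameters for samples and loci.
#' @param seed Optional integer seed.
#' @return A list: `signal` (M x N 0/1 matrix), `truth` (the generating
#'   [dropout_model()]).
#' @export
generate_calibration_fixture <- function(M = 167, N = 1000,
                                         p_shape = c(8, 2), q_shape = c(5, 5),
                                         seed = NULL) {
  with_seed(seed, {
    truth <- draw_dropout(dropout_prior(p_shape, q_shape), M, N)
    pq <- outer(truth$p, truth$q)
    x <- matrix(as.integer(stats::runif(M * N) < pq), M, N)
    dimnames(x) <- list(paste0("cell", seq_len(M)), paste0("L", seq_len(N)))
    list(signal = x, truth = truth)
  })
}

#' Estimate the STR noise rate from duplicate measurements
#'
#' Given two mutation tables measured from identical genomes (duplicate
#' amplifications of the same cells), returns the inconsistency rate: the
#' fraction of entries observed in both tables whose calls differ.  This is
#' the empirical scale used to set `str_shift_prob` in [noise_model()];
#' note that both duplicates carry noise, so for a small per-measurement
#' shift probability s the expected inconsistency rate is about 2s.
#'
#' @param table1,table2 Two [mutation_table()]s of identical shape.
#' @return The inconsistency rate (fraction in `[0, 1]`).
#' @export
estimate_str_noise <- function(table1, table2) {
  if (!all(dim(table1) == dim(table2)))
    stop_with("dimension_mismatch", "duplicate tables must have identical shape")
  both <- !is.na(table1) & !is.na(table2)
  if (!any(both))
    stop_with("undefined_distance", "no locus observed in both duplicates")
  mean(table1[both] != table2[both])
}
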