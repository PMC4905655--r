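# Monte-Carlo power and accuracy estimation over (cells x loci) designs,
# 95%-power contour extraction, and linear-cost experimental-design
# optimization.

# replace panel size / group sizes in a scenario spec for grid sweeps;
# n_cells is the TOTAL number of analyzed cells, split as evenly as
# possible between the two groups
scenario_with_cells <- function(spec, n_cells) {
  if (is.null(n_cells)) return(spec)
  n_cells <- as.integer(n_cells)
  stopifnot(n_cells >= 4L)
  nA <- n_cells %/% 2L
  nB <- n_cells - nA
  spec$nA <- nA
  spec$nB <- nB
  spec
}

# One simulated experiment -> 0/1 detection outcome, per scenario class.
run_replicate <- function(spec, model, dropout, noise, alpha, cap) {
  UseMethod("run_replicate")
}

# root distances of every cell with at least one observed locus
safe_root_distances <- function(table) {
  ok <- rowSums(!is.na(table)) > 0
  stats::setNames(root_distances(table[ok, , drop = FALSE]), rownames(table)[ok])
}

#' @export
run_replicate.depth_groups_spec <- function(spec, model, dropout, noise, alpha, cap) {
  sim <- simulate_depth_groups(spec, model, cap = cap)
  tab <- distort_table(sim$table, dropout, noise)
  rd <- safe_root_distances(tab)
  grp <- sim$labels[match(names(rd), rownames(tab))]
  res <- depth_test(rd[grp == "A"], rd[grp == "B"], alpha)
  # a detection only counts if the deeper group is the one flagged deeper
  as.integer(res$indicator == 1L && res$mean_B > res$mean_A)
}

#' @export
run_replicate.equal_depth_null_spec <- function(spec, model, dropout, noise, alpha, cap) {
  sim <- simulate_equal_depth_null(spec, model, cap = cap)
  tab <- distort_table(sim$table, dropout, noise)
  rd <- safe_root_distances(tab)
  grp <- sim$labels[match(names(rd), rownames(tab))]
  depth_test(rd[grp == "A"], rd[grp == "B"], alpha)$indicator
}

#' @export
run_replicate.subclone_spec <- function(spec, model, dropout, noise, alpha, cap) {
  sim <- simulate_subclones(spec, model, cap = cap)
  tab <- distort_table(sim$table, dropout, noise)
  clustering_test(tab, sim$labels, alpha)$indicator
}

#' @export
run_replicate.mixed_clone_null_spec <- function(spec, model, dropout, noise, alpha, cap) {
  sim <- simulate_mixed_clone_null(spec, model, cap = cap)
  tab <- distort_table(sim$table, dropout, noise)
  clustering_test(tab, sim$labels, alpha)$indicator
}

#' Monte-Carlo detection probability of a lineage scenario
#'
#' Repeatedly simulates a scenario, distorts the mutational signal with
#' the dropout and noise models, applies the scenario's classifier, and
#' returns the fraction of replicates with a correct detection.  For the
#' depth scenario a detection additionally requires the deeper group to
#' show the larger mean root distance; for the null scenarios the returned
#' proportion is the empirical type I error rate.
#'
#' @param spec A scenario spec (see [scenario_specs]).
#' @param n_cells Total analyzed cells, split evenly between the two
#'   groups (`NULL`: use the spec's own group sizes).
#' @param n_loci Number of loci analyzed (`NULL`: use `model$n_loci`).
#' @param model A [mutation_model()] (its `n_loci` is overridden by
#'   `n_loci` when given).
#' @param dropout A [dropout_model()] or [dropout_prior()]; `NULL` disables
#'   dropout.
#' @param noise A [noise_model()]; `NULL` disables noise.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param alpha Classifier significance threshold.
#' @param cap Genealogy population cap.
#' @param seed Optional master seed; each replicate runs on a derived
#'   sub-stream, so results are reproducible and independent of `n_reps`
#'   batching.
#' @return The detection proportion, with attribute `n_reps`.
#' @export
estimate_power <- function(spec, n_cells = NULL, n_loci = NULL, model,
                           dropout = dropout_prior(), noise = noise_model(),
                           n_reps = 1000, alpha = 0.05, cap = 2^20,
                           seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(model, "mutation_model"),
            n_reps >= 1)
  spec <- scenario_with_cells(spec, n_cells)
  if (!is.null(n_loci)) model <- mutation_model(model$kind, model$rate, n_loci)
  hits <- vapply(seq_len(n_reps), function(r) {
    rseed <- if (is.null(seed)) NULL else
      derive_seed(seed, class(spec)[1], spec$nA, spec$nB, model$n_loci, r)
    with_seed(rseed, run_replicate(spec, model, dropout, noise, alpha, cap))
  }, integer(1))
  structure(mean(hits), n_reps = n_reps)
}

#' Monte-Carlo triplet reconstruction accuracy
#'
#' Fraction of simulated triplets whose reconstructed cherry matches the
#' truth.  With an uninformative signal all three distances tie and the
#' random tie-break yields the 1/3 baseline of random topology choice.
#'
#' @inheritParams estimate_power
#' @param spec A [triplet_spec()].
#' @return The accuracy proportion, with attribute `n_reps`.
#' @export
triplet_accuracy <- function(spec, n_loci = NULL, model,
                             dropout = dropout_prior(), noise = noise_model(),
                             n_reps = 1000, cap = 2^20, seed = NULL) {
  stopifnot(inherits(spec, "triplet_spec"), inherits(model, "mutation_model"),
            n_reps >= 1)
  if (!is.null(n_loci)) model <- mutation_model(model$kind, model$rate, n_loci)
  hits <- vapply(seq_len(n_reps), function(r) {
    rseed <- if (is.null(seed)) NULL else
      derive_seed(seed, "triplet", spec$X, model$n_loci, r)
    with_seed(rseed, {
      sim <- simulate_triplet(spec, model)
      tab <- distort_table(sim$table, dropout, noise)
      as.integer(reconstruct_triplet(tab)$cherry == sim$cherry)
    })
  }, integer(1))
  structure(mean(hits), n_reps = n_reps)
}

#' Monte-Carlo power grid over (cells x loci) designs
#'
#' Estimates the detection probability of a scenario at every combination
#' of the `cells` and `loci` axes.
#'
#' @inheritParams estimate_power
#' @param cells Strictly increasing integer vector of total cell counts.
#' @param loci Strictly increasing integer vector of locus counts.
#' @return An object of class `power_grid`: `power` (loci x cells matrix),
#'   `cells`, `loci`, `n_reps`.
#' @export
power_grid <- function(spec, cells, loci, model,
                       dropout = dropout_prior(), noise = noise_model(),
                       n_reps = 1000, alpha = 0.05, cap = 2^20, seed = NULL) {
  stopifnot(all(diff(cells) > 0), all(diff(loci) > 0), length(cells) >= 1,
            length(loci) >= 1)
  power <- matrix(NA_real_, length(loci), length(cells),
                  dimnames = list(loci = loci, cells = cells))
  for (ci in seq_along(cells)) {
    for (li in seq_along(loci)) {
      gseed <- if (is.null(seed)) NULL else
        derive_seed(seed, "grid", cells[ci], loci[li])
      power[li, ci] <- estimate_power(spec, n_cells = cells[ci],
                                      n_loci = loci[li], model = model,
                                      dropout = dropout, noise = noise,
                                      n_reps = n_reps, alpha = alpha,
                                      cap = cap, seed = gseed)
    }
  }
  structure(list(power = power, cells = as.integer(cells),
                 loci = as.integer(loci), n_reps = n_reps),
            class = "power_grid")
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf("<power_grid> %d loci values x %d cell values, %d reps/cell\n",
              length(x$loci), length(x$cells), x$n_reps))
  print(round(x$power, 3))
  invisible(x)
}

#' Extract the iso-power contour from a power grid
#'
#' For each cell count, the minimal number of loci achieving the given
#' power level.  Monte-Carlo noise makes raw grids non-monotone, so the
#' grid is first smoothed by isotonic regression along the loci axis
#' (power nondecreasing in loci) and then along the cells axis (power
#' nondecreasing in cells); the crossing is located by linear
#' interpolation between adjacent loci values.
#'
#' @param grid A [power_grid()].
#' @param level Target power (default 0.95).
#' @return A data frame with columns `n_cells` and `n_loci`, one row per
#'   cell count where the level is attainable (zero rows, with a warning,
#'   if it is attainable nowhere).
#' @export
extract_contour <- function(grid, level = 0.95) {
  stopifnot(inherits(grid, "power_grid"), level > 0, level < 1)
  pw <- grid$power
  if (length(grid$loci) > 1)
    pw <- apply(pw, 2, function(col) stats::isoreg(grid$loci, col)$yf)
  pw <- matrix(pw, length(grid$loci), length(grid$cells))
  if (length(grid$cells) > 1)
    pw <- t(apply(pw, 1, function(row) stats::isoreg(grid$cells, row)$yf))
  res <- lapply(seq_along(grid$cells), function(ci) {
    col <- pw[, ci]
    if (max(col) < level) return(NULL)
    k <- which(col >= level)[1]
    loci_at <- if (k == 1L) grid$loci[1] else {
      x0 <- grid$loci[k - 1]; x1 <- grid$loci[k]
      y0 <- col[k - 1]; y1 <- col[k]
      x0 + (level - y0) / (y1 - y0) * (x1 - x0)
    }
    data.frame(n_cells = grid$cells[ci], n_loci = loci_at)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    warning(sprintf("power level %g is not attained anywhere on the grid", level))
    out <- data.frame(n_cells = integer(0), n_loci = numeric(0))
  }
  out
}

#' Linear cost model of a single-cell lineage experiment
#'
#' Total cost = `cost_per_locus * n_loci + cost_per_cell * n_cells`.
#' Defaults encode rough current costs: 10$ fixed overhead per analyzed
#' cell, 0.01$ per STR locus and 0.0001$ per sequenced base (SNV) — a
#' 1:1000 cell:STR-locus cost ratio.
#'
#' @param kind `"STR"` or `"SNV"` (sets the default per-locus cost).
#' @param cost_per_locus Dollars per locus (overrides the kind default).
#' @param cost_per_cell Dollars per analyzed cell.
#' @return An object of class `cost_model`.
#' @examples
#' total_cost(cost_model("STR"), n_loci = 65000, n_cells = 90)  # 1550
#' @export
cost_model <- function(kind = c("STR", "SNV"), cost_per_locus = NULL,
                       cost_per_cell = 10) {
  kind <- match.arg(kind)
  if (is.null(cost_per_locus))
    cost_per_locus <- if (kind == "STR") 0.01 else 1e-4
  stopifnot(cost_per_locus >= 0, cost_per_cell >= 0)
  structure(list(cost_per_locus = cost_per_locus, cost_per_cell = cost_per_cell),
            class = "cost_model")
}

#' Total cost of an experimental design
#'
#' @param cost A [cost_model()].
#' @param n_loci,n_cells Design size (vectorized).
#' @return Cost in dollars.
#' @export
total_cost <- function(cost, n_loci, n_cells) {
  stopifnot(inherits(cost, "cost_model"))
  cost$cost_per_locus * n_loci + cost$cost_per_cell * n_cells
}

#' Cost-minimizing design on an iso-power contour
#'
#' Evaluates the linear cost at every contour point and returns the
#' cheapest design; exact ties are resolved in favor of fewer cells.
#'
#' @param contour A data frame from [extract_contour()].
#' @param cost A [cost_model()].
#' @return A list: `n_cells`, `n_loci`, `cost`.
#' @export
optimize_cost <- function(contour, cost) {
  stopifnot(is.data.frame(contour))
  if (nrow(contour) == 0L)
    stop_with("empty_contour", "cannot optimize cost on an empty contour")
  costs <- total_cost(cost, contour$n_loci, contour$n_cells)
  best <- order(costs, contour$n_cells)[1]
  list(n_cells = contour$n_cells[best], n_loci = contour$n_loci[best],
       cost = costs[best])
}

#' Plot a power grid with its iso-power contour and cost curve
#'
#' Heatmap of detection probability over (cells, loci) with the contour
#' overlaid in white and, on a secondary axis, the cost along the contour
#' in black.
#'
#' @param grid A [power_grid()].
#' @param level Contour power level.
#' @param cost A [cost_model()] (or `NULL` to omit the cost curve).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the contour data frame.
#' @export
plot_power_grid <- function(grid, level = 0.95, cost = cost_model("STR"), ...) {
  stopifnot(inherits(grid, "power_grid"))
  graphics::image(grid$cells, grid$loci, t(grid$power),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "number of cells", ylab = "number of loci",
                  main = sprintf("detection power (%d reps)", grid$n_reps), ...)
  ct <- tryCatch(extract_contour(grid, level), warning = function(w) NULL)
  if (!is.null(ct) && nrow(ct)) {
    graphics::lines(ct$n_cells, ct$n_loci, col = "white", lwd = 2)
    if (!is.null(cost)) {
      cc <- total_cost(cost, ct$n_loci, ct$n_cells)
      scale <- max(grid$loci) / max(cc)
      graphics::lines(ct$n_cells, cc * scale, col = "black", lwd = 2)
      graphics::axis(4, at = pretty(cc) * scale, labels = pretty(cc))
      graphics::mtext("cost ($)", side = 4, line = 2)
    }
  }
  invisible(ct)
}
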