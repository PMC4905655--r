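# File formats: TSV mutation/signal tables (empty cell = dropout), CSV
# result records, JSON calibration output, YAML/JSON run configs.

#' Read a mutation table from TSV
#'
#' Expects a header row of locus ids and a first column of sample ids.
#' Empty cells (and `"NA"`) are read as missing.
#'
#' @param path TSV file path.
#' @param kind `"STR"` or `"SNV"`.
#' @return A [mutation_table()].
#' @export
read_mutation_table <- function(path, kind = c("STR", "SNV")) {
  kind <- match.arg(kind)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                      colClasses = "character"),
    error = function(e) stop_with("invalid_file",
                                  sprintf("cannot parse '%s': %s", path,
                                          conditionMessage(e))))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop_with("invalid_file", "mutation table needs sample ids and >= 1 locus")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- !is.na(vals) & is.na(num)
  if (any(bad))
    stop_with("invalid_file", "non-numeric genotype entries found")
  if (any(num[!is.na(num)] != round(num[!is.na(num)])))
    stop_with("invalid_file", "non-integer genotype entries found")
  storage.mode(num) <- "integer"
  mutation_table(num, kind = kind)
}

#' Write a mutation table to TSV
#'
#' Canonical format: sample ids in the first column (`sample`), one column
#' per locus, missing entries written as empty cells.  Round-trips with
#' [read_mutation_table()].
#'
#' @param table A [mutation_table()] (or signal matrix).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mutation_table <- function(table, path) {
  vals <- unclass(table)
  colnames(vals) <- colnames(vals) %||% paste0("L", seq_len(ncol(vals)))
  df <- data.frame(sample = rownames(vals) %||% paste0("s", seq_len(nrow(vals))),
                   vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write analysis result records to CSV
#'
#' Records are written with a fixed, deterministic column order (the
#' union of fields in first-appearance order); an empty record list
#' produces a header-only file when the fields are supplied.
#'
#' @param records A data frame or list of named lists/rows.
#' @param path Output path.
#' @param fields Optional explicit column order.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path, fields = NULL) {
  if (is.data.frame(records)) {
    df <- records
  } else if (length(records) == 0L) {
    if (is.null(fields))
      stop_with("invalid_records", "empty record list needs explicit `fields`")
    df <- stats::setNames(data.frame(matrix(nrow = 0, ncol = length(fields))),
                          fields)
  } else {
    df <- do.call(rbind, lapply(records, function(r) as.data.frame(r)))
  }
  if (!is.null(fields)) df <- df[, fields, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fitted dropout calibration to JSON
#'
#' Stores P, Q, the scale-fixing convention and the achieved
#' log-likelihood.
#'
#' @param fit A [dropout_model()] from [fit_dropout_ml()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calibration <- function(fit, path) {
  stopifnot(inherits(fit, "dropout_model"))
  jsonlite::write_json(list(p = fit$p, q = fit$q,
                            convention = "max(q) == 1",
                            loglik = attr(fit, "loglik"),
                            restart_logliks = attr(fit, "restart_logliks"),
                            product_spread = attr(fit, "product_spread")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' A run config bundles the scenario, mutation model, dropout/noise
#' parameters, grid axes, cost model and master seed of one analysis.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
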