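# JSON serialization for metric reports and CSV round-trips for latent
# tables.

#' Write / read a metric report as JSON
#'
#' Schema-versioned; [read_report()] rejects files with a different schema
#' version or missing required keys. Floats survive at full double
#' precision.
#'
#' @param report a [metric_report()].
#' @param path file path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   restored `metric_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("schema_version", "scores", "seed", "n_samples")
  missing <- setdiff(required, names(obj))
  if (length(missing) > 0) {
    stop("metric report missing required keys: ", paste(missing, collapse = ", "))
  }
  if (!identical(as.integer(obj$schema_version), 1L)) {
    stop(
      "unsupported metric-report schema version ", obj$schema_version,
      " (this build reads version 1)"
    )
  }
  metric_report(
    scores = as.list(obj$scores),
    seed = obj$seed,
    n_samples = obj$n_samples,
    config = as.list(obj$config),
    warnings = as.character(obj$warnings %||% character(0))
  )
}

#' Dump / read a latent table as CSV
#'
#' One row per particle; learned columns keep their `learned_` labels and
#' factors their `factor_` labels. Values are written with 17 significant
#' digits so the round trip is exact in double precision. Rows containing
#' NaN are rejected with their row index.
#'
#' @param table a `latent_table`.
#' @param path file path.
#' @return `dump_latents()` returns `path` invisibly; `read_latents()` the
#'   restored `latent_table`.
#' @export
dump_latents <- function(table, path) {
  stopifnot(inherits(table, "latent_table"))
  all_mat <- cbind(table$learned, table$factors)
  bad <- which(!stats::complete.cases(all_mat))
  if (length(bad) > 0) {
    stop("NaN in latent table at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  txt <- apply(all_mat, 2, function(col) sprintf("%.17g", col))
  if (nrow(all_mat) == 1) txt <- matrix(txt, nrow = 1)
  writeLines(
    c(
      paste(colnames(all_mat), collapse = ","),
      apply(txt, 1, paste, collapse = ",")
    ),
    path
  )
  invisible(path)
}

#' @rdname dump_latents
#' @export
read_latents <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  is_learned <- startsWith(nm, "learned_")
  is_factor <- startsWith(nm, "factor_")
  if (!all(is_learned | is_factor) || !any(is_learned) || !any(is_factor)) {
    stop(
      "latent CSV header must consist of learned_* followed by factor_* ",
      "columns; got: ", paste(nm, collapse = ", ")
    )
  }
  new_latent_table(
    as.matrix(df[, is_learned, drop = FALSE]),
    as.matrix(df[, is_factor, drop = FALSE])
  )
}
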