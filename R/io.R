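#' Persist time series and results as plain text
#'
#' A `binary_series` or `expression_matrix` is written as a headered CSV
#' (columns `G1..Gn`, one row per kept time step) plus a JSON sidecar
#' `<path>.json` holding the run metadata (steps, burn-in, perturbation,
#' seed). Results tables are plain CSVs.
#'
#' @param series a `binary_series` from [simulate_discrete()] or
#'   [discretize_median()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return the path, invisibly (readers return the reconstructed object).
#' @export
write_binary_series <- function(series, path) {
  stopifnot(inherits(series, "binary_series"))
  write.csv(series$samples, path, row.names = FALSE)
  jsonlite::write_json(series_meta_(series), paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

series_meta_ <- function(x) {
  meta <- x$meta
  meta$pert <- if (!is.null(meta$pert)) unclass(meta$pert) else NULL
  meta$params <- if (!is.null(meta$params)) unclass(meta$params) else NULL
  list(steps = x$steps, burn_in = x$burn_in, meta = meta)
}

#' @rdname write_binary_series
#' @export
read_binary_series <- function(path) {
  mat <- as.matrix(read.csv(path, check.names = FALSE))
  storage.mode(mat) <- "integer"
  side <- paste0(path, ".json")
  info <- if (file.exists(side)) jsonlite::read_json(side) else
    list(steps = nrow(mat), burn_in = 0L, meta = list())
  new_binary_series(mat, info$steps, info$burn_in, meta = info$meta)
}

#' @rdname write_binary_series
#' @param expr an `expression_matrix` from [simulate_sde()].
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  write.csv(expr$values, path, row.names = FALSE)
  jsonlite::write_json(series_meta_(expr), paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_binary_series
#' @param results a [run_grid()] table.
#' @export
write_results <- function(results, path) {
  write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binary_series
#' @export
read_results <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if (!"error" %in% names(out)) out$error <- NA_character_
  out$error <- as.character(out$error)
  class(out) <- c("degeneracy_results", class(out))
  out
}

#' Build an experiment configuration from a JSON document
#'
#' The JSON mirrors [experiment_config()] field for field; absent fields
#' take the defaults. A `kinetics` object, when present, is passed to
#' [kinetic_params()].
#'
#' @param path JSON file path.
#' @return an [experiment_config()].
#' @export
experiment_config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$kinetics)) {
    raw$kinetics <- do.call(kinetic_params, as.list(raw$kinetics))
  }
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config fields: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(experiment_config, raw)
}
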