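## Small output helpers: TSV tables and run manifests.

#' Write a pairwise-competition table as TSV
#'
#' @param grid A data.frame from [invasion_grid()] or [invasion_column()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_invasion_tsv <- function(grid, path) {
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a stationary distribution as TSV
#'
#' @param x A `stationary_dist`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stationary_tsv <- function(x, path) {
  stopifnot(inherits(x, "stationary_dist"))
  write.table(
    data.frame(rate = x$bin, mass = x$mass, count = x$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Run manifest
#'
#' Collects parameters, seed and session information for reproducibility;
#' written as JSON when the jsonlite package is available, otherwise as
#' `dput` text.
#'
#' @param params Named list of run parameters.
#' @param seed RNG seed used.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(params, seed, path) {
  manifest <- list(
    package = "recstorage",
    version = as.character(utils::packageVersion("recstorage")),
    seed = seed,
    parameters = params,
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    dput(manifest, file = path)
  }
  invisible(path)
}
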