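#' Read and write numeric samples
#'
#' Samples are stored as single-column plain text (CSV or
#' whitespace-delimited), one observation per line; a single non-numeric
#' first line is treated as a header and skipped.
#'
#' @param path file path.
#' @param x numeric vector to write.
#' @param header optional column name to write (default none).
#' @return `read_sample` returns a numeric vector; `write_sample` returns
#'   `path` invisibly.
#' @export
read_sample <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty sample file.")
  first <- suppressWarnings(as.numeric(strsplit(lines[1], "[,\\s]+")[[1]][1]))
  if (is.na(first)) lines <- lines[-1]
  vals <- suppressWarnings(as.numeric(vapply(
    strsplit(lines, "[,\\s]+"), `[[`, character(1), 1)))
  if (any(is.na(vals))) abort("non-numeric values in sample file.")
  vals
}

#' @rdname read_sample
#' @export
write_sample <- function(x, path, header = NULL) {
  lines <- format(x, digits = 17, trim = TRUE, scientific = FALSE)
  if (!is.null(header)) lines <- c(header, lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write a chain to CSV
#'
#' Columns: `iteration` plus one column per parameter — the interchange
#' format standard MCMC diagnostic tools read directly.
#'
#' @param chain a `bmb_chain`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(chain, path) {
  stopifnot(inherits(chain, "bmb_chain"))
  utils::write.csv(chain$draws, path, row.names = FALSE)
  invisible(path)
}

#' Serialize normalizing constants or a run manifest as JSON
#'
#' @param x a `norm_constants` object, or any list of run metadata
#'   (family, k, seeds, hyperparameters, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_json_manifest <- function(x, path) {
  if (inherits(x, "norm_constants")) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
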