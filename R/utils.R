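#' @keywords internal
"_PACKAGE"

## Shared helpers: TSV dialect, logging, assertions.
## TSV dialect throughout the package: tab-delimited, header row, UTF-8,
## '.' decimal separator, no quoting unless needed, no row names.

#' Read a tab-separated table
#'
#' @param path File path.
#' @param ... Passed to [utils::read.delim()].
#' @return A `data.frame`.
#' @keywords internal
read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

#' Write a tab-separated table
#' @keywords internal
write_tsv_strict <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Structured per-stage log line
#'
#' Messages are emitted with a timestamp and stage tag so pipeline runs can
#' be audited; silenced via `options(feedomics.verbose = FALSE)`.
#' @keywords internal
log_stage <- function(stage, ...) {
  if (isFALSE(getOption("feedomics.verbose", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
  invisible(NULL)
}

#' Stop unless a condition holds
#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
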