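#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

xdg_version <- function() {
  tryCatch(as.character(utils::packageVersion("xdosage")), error = function(e) "dev")
}

#' Format the commented parameter header written at the top of output tables
#' @noRd
param_header <- function(params = list()) {
  kv <- if (length(params)) {
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(p) paste(format(p), collapse = ","), "")),
          collapse = " ")
  } else ""
  sprintf("# xdosage %s %s", xdg_version(), kv)
}

#' Write a table as TSV with a commented header line recording parameters
#'
#' All on-disk outputs of the package go through this writer so that every
#' file carries the tool version and the parameters (including the run
#' configuration hash) that produced it.
#'
#' @param df data.frame to write
#' @param path output path
#' @param params named list recorded in the comment header
#' @return the path, invisibly
#' @export
write_xdg_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(param_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_xdg_tsv()] (comment lines are skipped)
#' @param path file path
#' @param ... passed to [utils::read.delim()]
#' @return data.frame
#' @export
read_xdg_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# First comment line of an output file; used to recover the config hash.
read_xdg_header <- function(path) {
  readLines(path, n = 1L)
}

#' Short stable hash of a run configuration
#'
#' Polynomial rolling hash over the deparsed object; used to stamp output
#' files so that a report never mixes artifacts from different runs.
#' @param x any serialisable R object
#' @return 8-character hex string
#' @export
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
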