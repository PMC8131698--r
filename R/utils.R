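# internal validation helpers ------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, allow_na = FALSE) {
  if (allow_na && all(is.na(x))) return(invisible(x))
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_field(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}

check_positive <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && !anyNA(x) && all(if (strict) x > 0 else x >= 0)
  if (!ok) stop_field(field, if (strict) "must be > 0" else "must be >= 0")
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= min && x == as.integer(x)
  if (!ok) stop_field(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a comment header carried by every serialized table
clonarch_header <- function(seed) {
  sprintf("# clonarch %s seed=%s", as.character(utils::packageVersion("clonarch")),
          format(seed))
}

#' Write a table with a tool/seed comment header
#'
#' All tables emitted by the pipeline carry a single `#`-prefixed header line
#' recording the package version and the master seed, so a file is traceable
#' to the run that produced it.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param seed seed recorded in the header line.
#' @return `path`, invisibly.
#' @export
write_clonarch_tsv <- function(x, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(clonarch_header(seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_clonarch_tsv()]
#'
#' @param path file path.
#' @return data.frame (the comment header is skipped).
#' @export
read_clonarch_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
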