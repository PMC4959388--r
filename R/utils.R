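# Internal helpers shared across modules.

#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

#' Run an expression under a fixed RNG seed
#'
#' All stochastic code in the package funnels through this wrapper so that no
#' function touches the global RNG state of the caller.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Strict TSV reader: the column header must match `cols` exactly.
#' @noRd
read_tsv_strict <- function(path, cols, optional = character()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = "character", check.names = FALSE,
                   stringsAsFactors = FALSE)
  have <- names(df)
  required <- setdiff(cols, optional)
  if (!all(required %in% have) || !all(have %in% cols)) {
    stop(sprintf("%s: expected TSV columns {%s}, found {%s}", path,
                 paste(cols, collapse = ", "), paste(have, collapse = ", ")),
         call. = FALSE)
  }
  df[intersect(cols, have)]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Canonical key for an unordered concept pair ("small|large").
#' @noRd
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Turn two cui vectors into a lexicographically sorted unordered-pair frame.
#' @noRd
pair_frame <- function(a, b) {
  df <- data.frame(cui_a = pmin(a, b), cui_b = pmax(a, b),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df[order(df$cui_a, df$cui_b), , drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
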