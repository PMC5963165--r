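# Shared sentinels and small internal helpers.

#' Sentinel strings used throughout the package
#'
#' Fixed strings that mark missing information without dropping rows:
#' `unknown_organism` / `unknown_function` for reference headers that lack a
#' bracketed organism or a function name, `NO LEVEL` for empty intermediate
#' hierarchy categories, and `NO HIERARCHY` for functions absent from the
#' hierarchy table.
#'
#' @format A named character vector with elements `organism`, `function_name`,
#'   `no_level`, `no_hierarchy`.
#' @export
SENTINELS <- c(
  organism      = "unknown_organism",
  function_name = "unknown_function",
  no_level      = "NO LEVEL",
  no_hierarchy  = "NO HIERARCHY"
)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Read a "stream" argument: an existing file path, or literal text
# (a single string with newlines, or a character vector of lines).
read_stream_lines <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

is_count <- function(x, min = 0) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= min && x == trunc(x)
}

# genus = first whitespace token of the organism name; sentinel-aware
genus_of <- function(organism) {
  out <- sub("\\s.*$", "", organism)
  out[organism == SENTINELS[["organism"]]] <- "unknown"
  out
}

# deterministic child seed for module i under a user seed (kept below 2^31)
derive_seed <- function(seed, i) {
  (as.integer(seed) * 7919L + as.integer(i) * 104729L) %% 2147483587L
}
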