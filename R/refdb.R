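# Protein reference databases and the functional-hierarchy table.
#
# Reference FASTA headers follow the convention
#   ><ref_id> <function name> [<organism>]
# i.e. an internal identifier, a free-text function name, and the source
# organism in the LAST balanced bracket group (function names themselves may
# contain brackets). The hierarchy table maps each specific function to a
# four-level classification (level1 = broadest category, level4 = the
# function itself).

#' Split a reference FASTA title into id, function name and organism
#'
#' The first whitespace-delimited token is the reference id. The organism is
#' the content of the *last* balanced `[...]` group in the remainder; the
#' function name is whatever lies between the id and that group. Degenerate
#' titles fall back to sentinels rather than erroring: no bracket group gives
#' organism `"unknown_organism"`, an id-only title gives function
#' `"unknown_function"`.
#'
#' @param title Character vector of FASTA title lines (without the leading
#'   `>`).
#' @return A data.frame with columns `ref_id`, `function_name`, `organism`.
#' @examples
#' parse_header("REF_9 beta-galactosidase [Bacteroides fragilis NCTC 9343]")
#' @export
parse_header <- function(title) {
  stopifnot(is.character(title), all(nzchar(trimws(title))))
  out <- lapply(title, parse_header_one)
  data.frame(
    ref_id        = vapply(out, `[[`, "", "ref_id"),
    function_name = vapply(out, `[[`, "", "function_name"),
    organism      = vapply(out, `[[`, "", "organism"),
    stringsAsFactors = FALSE
  )
}

parse_header_one <- function(title) {
  title <- trimws(title)
  ref_id <- sub("\\s.*$", "", title)
  rest <- trimws(substring(title, nchar(ref_id) + 1))
  if (!nzchar(rest)) {
    return(list(ref_id = ref_id,
                function_name = SENTINELS[["function_name"]],
                organism = SENTINELS[["organism"]]))
  }
  grp <- last_balanced_group(rest)
  if (is.null(grp)) {
    return(list(ref_id = ref_id, function_name = rest,
                organism = SENTINELS[["organism"]]))
  }
  fn <- trimws(substring(rest, 1, grp$start - 1))
  if (!nzchar(fn)) fn <- SENTINELS[["function_name"]]
  org <- trimws(substring(rest, grp$start + 1, grp$end - 1))
  if (!nzchar(org)) org <- SENTINELS[["organism"]]
  list(ref_id = ref_id, function_name = fn, organism = org)
}

# Last top-level balanced [...] group: single left-to-right scan tracking
# nesting depth; unbalanced trailing opens are ignored.
last_balanced_group <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  open_at <- NA_integer_
  grp <- NULL
  for (i in seq_along(chars)) {
    if (chars[i] == "[") {
      if (depth == 0L) open_at <- i
      depth <- depth + 1L
    } else if (chars[i] == "]") {
      if (depth > 0L) {
        depth <- depth - 1L
        if (depth == 0L) grp <- list(start = open_at, end = i)
      }
    }
  }
  grp
}

#' Parse a protein reference database from FASTA
#'
#' Reads a protein FASTA file (or literal FASTA text) whose headers follow
#' the id / function / `[organism]` convention and returns one record per
#' sequence. Sequences are uppercased with whitespace removed; the genus is
#' derived as the first whitespace token of the organism name.
#'
#' @param stream Path to a FASTA file, or FASTA text.
#' @return A data.frame of class `reference_db` with columns `ref_id`,
#'   `function_name`, `organism`, `genus`, `sequence`.
#' @seealso [parse_header()], [write_reference_fasta()]
#' @export
parse_reference_fasta <- function(stream) {
  lines <- read_stream_lines(stream)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(empty_reference_db())
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("not FASTA: line ", nonblank[1], " is not a '>' title line")
  }
  tf <- tempfile(fileext = ".faa")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  aa <- Biostrings::readAAStringSet(tf)
  titles <- names(aa)
  seqs <- toupper(gsub("\\s", "", as.character(aa)))
  if (any(!nzchar(seqs))) {
    bad <- titles[!nzchar(seqs)][1]
    stop("empty sequence for record '", sub("\\s.*$", "", bad), "'")
  }
  hdr <- parse_header(titles)
  dup <- hdr$ref_id[duplicated(hdr$ref_id)]
  if (length(dup) > 0) {
    stop("duplicate ref_id in reference database: ",
         paste(unique(dup), collapse = ", "))
  }
  db <- data.frame(
    ref_id = hdr$ref_id,
    function_name = hdr$function_name,
    organism = hdr$organism,
    genus = genus_of(hdr$organism),
    sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
  class(db) <- c("reference_db", "data.frame")
  db
}

empty_reference_db <- function() {
  db <- data.frame(ref_id = character(), function_name = character(),
                   organism = character(), genus = character(),
                   sequence = character(), stringsAsFactors = FALSE)
  class(db) <- c("reference_db", "data.frame")
  db
}

#' Write a reference database back to FASTA
#'
#' Headers are reconstructed as `ref_id function_name [organism]`, so a
#' parse/write/parse round trip reproduces the records whenever the organism
#' itself contains no brackets.
#'
#' @param db A `reference_db` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, path) {
  aa <- Biostrings::AAStringSet(db$sequence)
  names(aa) <- sprintf("%s %s [%s]", db$ref_id, db$function_name, db$organism)
  Biostrings::writeXStringSet(aa, path, width = 70)
  invisible(path)
}

#' Write the plain-text sidecar index for a parsed reference database
#'
#' A three-column TSV (`ref_id`, `function_name`, `organism`) written next to
#' a parsed database so downstream joins never need the sequences. This
#' plain, inspectable index is what the package's aligner consumes instead of
#' a binary aligner database.
#'
#' @param db A `reference_db`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_refdb_index <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("ref_id\tfunction_name\torganism", con)
  if (nrow(db) > 0) {
    writeLines(sprintf("%s\t%s\t%s", db$ref_id, db$function_name, db$organism),
               con)
  }
  invisible(path)
}

#' Load a four-level functional-hierarchy table
#'
#' The on-disk dialect is a 5-column TSV: `function_key`, `level4`, `level3`,
#' `level2`, `level1`, with `#` comment lines. Keys are case-folded and
#' trimmed; empty `level2`/`level3` cells become the `"NO LEVEL"` sentinel.
#' The same key listed twice with an identical path is tolerated; conflicting
#' paths are an error (a function may not sit under two different branches).
#'
#' Real hierarchical-ontology flat files come in several layouts; this
#' package standardises on the 5-column dialect above and leaves conversion
#' from other layouts to the caller.
#'
#' @param stream Path to a TSV file, or TSV text.
#' @return An object of class `hierarchy_map`.
#' @export
load_hierarchy <- function(stream) {
  lines <- read_stream_lines(stream)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5)) {
    bad <- which(nf != 5)[1]
    stop("hierarchy row at line ", rows[bad], " has ", nf[bad],
         " tab-separated fields (expected 5)")
  }
  m <- if (length(parts) > 0) do.call(rbind, parts) else
    matrix(character(), ncol = 5)
  key <- tolower(trimws(m[, 1]))
  path <- data.frame(
    level1 = trimws(m[, 5]),
    level2 = trimws(m[, 4]),
    level3 = trimws(m[, 3]),
    level4 = trimws(m[, 2]),
    stringsAsFactors = FALSE
  )
  path$level2[!nzchar(path$level2)] <- SENTINELS[["no_level"]]
  path$level3[!nzchar(path$level3)] <- SENTINELS[["no_level"]]
  if (any(!nzchar(path$level1)) || any(!nzchar(path$level4))) {
    stop("hierarchy rows must have non-empty level1 and level4 entries")
  }
  # duplicates: identical full path -> drop; conflicting -> error
  sig <- paste(path$level1, path$level2, path$level3, path$level4, sep = "\r")
  first <- !duplicated(key)
  conflict <- !first & sig != sig[match(key, key)]
  if (any(conflict)) {
    stop("conflicting hierarchy paths for key '", key[which(conflict)[1]], "'")
  }
  map <- list(key = key[first], path = path[first, , drop = FALSE])
  rownames(map$path) <- NULL
  class(map) <- "hierarchy_map"
  map
}

#' Look up the hierarchy path for a function
#'
#' Case-folded exact matching after whitespace trimming. A miss returns
#' `NULL` (single key) or an `NA` row (vectorised form), never an error.
#'
#' @param map A `hierarchy_map` from [load_hierarchy()].
#' @param function_key Function name(s) to look up.
#' @return For a single key: a list with `level1..level4`, or `NULL` on a
#'   miss. For several keys: a data.frame with one row per key (`NA`s on
#'   misses).
#' @export
lookup_hierarchy <- function(map, function_key) {
  stopifnot(inherits(map, "hierarchy_map"))
  idx <- match(tolower(trimws(function_key)), map$key)
  if (length(function_key) == 1) {
    if (is.na(idx)) return(NULL)
    return(as.list(map$path[idx, , drop = FALSE]))
  }
  out <- map$path[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vectorised lookup that always returns one row per key (NAs on misses)
hierarchy_rows <- function(map, function_keys) {
  idx <- match(tolower(trimws(function_keys)), map$key)
  out <- map$path[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a hierarchy map back to the 5-column TSV dialect
#'
#' Inverse of [load_hierarchy()]; `"NO LEVEL"` sentinels are written back
#' as empty cells.
#'
#' @param map A `hierarchy_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(map, path) {
  stopifnot(inherits(map, "hierarchy_map"))
  p <- map$path
  blank <- function(x) ifelse(x == SENTINELS[["no_level"]], "", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# function_key\tlevel4\tlevel3\tlevel2\tlevel1", con)
  if (length(map$key) > 0) {
    writeLines(sprintf("%s\t%s\t%s\t%s\t%s", p$level4, p$level4,
                       blank(p$level3), blank(p$level2), p$level1), con)
  }
  invisible(path)
}

#' @export
print.hierarchy_map <- function(x, ...) {
  cat("<hierarchy_map> ", length(x$key), " function keys, ",
      length(unique(x$path$level1)), " level-1 categories\n", sep = "")
  invisible(x)
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db> ", nrow(x), " records, ",
      length(unique(x$organism)), " organisms\n", sep = "")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x)[, 1:4], 5))
  invisible(x)
}
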