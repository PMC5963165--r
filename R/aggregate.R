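# Sorted abundance counts and data slicing.
#
# An abundance table condenses a sample's per-read annotations into
# (name, count, percent) rows for one key kind: organism, genus, function,
# or one of the four hierarchy levels. Percentages use annotated reads as
# denominator (raw read totals live in the run log, not here); counts are
# the authoritative values and percents are always re-derivable from them.

KEY_KINDS <- c("organism", "genus", "function", "level1", "level2",
               "level3", "level4")

key_column <- function(key_kind) {
  switch(key_kind, "function" = "function_name", key_kind)
}

new_abundance_table <- function(names_vec, counts, sample_id, key_kind) {
  names_vec <- as.character(names_vec)
  counts <- as.integer(counts)
  total <- sum(counts)
  ord <- order(-counts, names_vec, method = "radix")
  rows <- data.frame(
    name = names_vec[ord],
    count = as.integer(counts[ord]),
    percent = if (total > 0) 100 * counts[ord] / total else numeric(length(ord)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(sample_id = sample_id, key_kind = key_kind,
                 total = as.integer(total), rows = rows),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> sample=", x$sample_id, " key=", x$key_kind,
      " total=", x$total, "\n", sep = "")
  print(utils::head(transform(x$rows, percent = round(percent, 2)), 10))
  if (nrow(x$rows) > 10) cat("... ", nrow(x$rows) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Condense per-read annotations into a sorted abundance count
#'
#' Counts distinct values of the chosen key over all annotations; percent is
#' `100 * count / total annotations`. Rows are sorted by count descending,
#' then name ascending, so identical annotation sets always produce
#' identical tables regardless of input order.
#'
#' @param annotations Annotation data.frame (see [annotate_reads()]).
#' @param key_kind One of `"organism"`, `"genus"`, `"function"`, `"level1"`
#'   .. `"level4"`.
#' @param sample_id Sample label stored in the table (default `"sample"`).
#' @return An `abundance_table`.
#' @export
aggregate_annotations <- function(annotations, key_kind = "organism",
                                  sample_id = "sample") {
  key_kind <- match.arg(key_kind, KEY_KINDS)
  vals <- annotations[[key_column(key_kind)]]
  tab <- table(vals)
  new_abundance_table(names(tab), as.integer(tab), sample_id, key_kind)
}

#' Roll annotations up to one hierarchy level
#'
#' Counts the level-`level` category of each annotation; reads whose
#' function has no hierarchy entry are counted under the `"NO HIERARCHY"`
#' row rather than dropped, so every rollup totals the full annotation set.
#'
#' @param annotations Annotation data.frame.
#' @param level Hierarchy level, 1 (broadest) to 4 (the specific function).
#' @param sample_id Sample label.
#' @return An `abundance_table` with `key_kind = "level<level>"`.
#' @export
rollup_hierarchy <- function(annotations, level, sample_id = "sample") {
  stopifnot(level %in% 1:4)
  aggregate_annotations(annotations, paste0("level", level), sample_id)
}

#' Functional profile of one organism or genus
#'
#' Restricts the annotations to those whose organism (or genus) equals
#' `pattern` after case-folding, and aggregates their functions. The number
#' of selected reads is the table's total; slicing over all organisms tiles
#' the global function table exactly.
#'
#' @param annotations Annotation data.frame.
#' @param pattern Organism or genus name (case-insensitive exact match).
#' @param match_level `"organism"` or `"genus"`.
#' @param sample_id Sample label.
#' @return An `abundance_table` of functions within the selection.
#' @export
slice_by_organism <- function(annotations, pattern,
                              match_level = c("organism", "genus"),
                              sample_id = "sample") {
  stopifnot(nzchar(pattern))
  match_level <- match.arg(match_level)
  sel <- tolower(annotations[[match_level]]) == tolower(pattern)
  if (!any(sel)) {
    warning("no annotations match ", match_level, " '", pattern, "'")
  }
  aggregate_annotations(annotations[sel, , drop = FALSE], "function", sample_id)
}

#' Organism profile of one function or functional category
#'
#' The mirror image of [slice_by_organism()]: restricts annotations to one
#' function (or one hierarchy category at the chosen scope) and aggregates
#' the organisms producing those transcripts.
#'
#' @param annotations Annotation data.frame.
#' @param pattern Function name or category (case-insensitive exact match).
#' @param scope `"function"` or `"level1"` .. `"level4"`.
#' @param sample_id Sample label.
#' @return An `abundance_table` of organisms within the selection.
#' @export
slice_by_function <- function(annotations, pattern,
                              scope = c("function", "level1", "level2",
                                        "level3", "level4"),
                              sample_id = "sample") {
  stopifnot(nzchar(pattern))
  scope <- match.arg(scope)
  sel <- tolower(annotations[[key_column(scope)]]) == tolower(pattern)
  if (!any(sel)) {
    warning("no annotations match ", scope, " '", pattern, "'")
  }
  aggregate_annotations(annotations[sel, , drop = FALSE], "organism", sample_id)
}

#' Write / read a sorted abundance count file
#'
#' Plain TSV: three `#` header lines (`sample`, `key_kind`, `total`)
#' followed by `count<TAB>percent<TAB>name` rows, percent printed with two
#' decimals. On read, counts are authoritative and percents are re-derived
#' from them, so write/read/write is byte-identical.
#'
#' @param table An `abundance_table`.
#' @param path File path.
#' @return `write_abundance`: `path`, invisibly. `read_abundance`: an
#'   `abundance_table`.
#' @export
write_abundance <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sample=", table$sample_id),
               paste0("# key_kind=", table$key_kind),
               paste0("# total=", table$total)), con)
  if (nrow(table$rows) > 0) {
    writeLines(sprintf("%d\t%.2f\t%s", table$rows$count,
                       table$rows$percent, table$rows$name), con)
  }
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header_val <- function(i, field) {
    prefix <- paste0("# ", field, "=")
    if (length(lines) < i || !startsWith(lines[i], prefix)) {
      stop("abundance file ", path, ": line ", i,
           " is not the expected '", prefix, "' header")
    }
    substring(lines[i], nchar(prefix) + 1)
  }
  sample_id <- header_val(1, "sample")
  key_kind <- header_val(2, "key_kind")
  total <- as.integer(header_val(3, "total"))
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  counts <- integer(0); names_vec <- character(0)
  if (length(body) > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 3)) {
      bad <- which(nf != 3)[1]
      stop("abundance file ", path, ": line ", bad + 3,
           " has ", nf[bad], " fields (expected 3)")
    }
    m <- do.call(rbind, parts)
    counts <- suppressWarnings(as.integer(m[, 1]))
    if (anyNA(counts) || any(counts <= 0)) {
      bad <- which(is.na(counts) | counts <= 0)[1]
      stop("abundance file ", path, ": line ", bad + 3,
           ": count must be a positive integer")
    }
    names_vec <- m[, 3]
  }
  if (sum(counts) != total) {
    stop("abundance file ", path, ": row counts sum to ", sum(counts),
         " but header total is ", total)
  }
  new_abundance_table(names_vec, counts, sample_id, key_kind)
}
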