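# BLAST tabular (outfmt 6 / "m8") I/O, best-hit selection, and the join of
# hits with the reference database into per-read annotations.

M8_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")
M8_NUMERIC <- M8_COLUMNS[3:12]

#' Read 12-column BLAST tabular alignment output
#'
#' One `HitRecord` per non-empty line, in file order. Rows with a field
#' count other than 12, unparsable numeric fields, `pident` outside
#' \[0, 100\] or negative e-values are errors naming the offending line.
#'
#' @param stream Path to an m8 file, or m8 text.
#' @return A data.frame with the 12 standard columns `qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`.
#' @export
read_m8 <- function(stream) {
  lines <- read_stream_lines(stream)
  rows <- which(nzchar(lines))
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop("m8 line ", rows[bad], " has ", nf[bad], " fields (expected 12)")
  }
  if (length(parts) == 0) return(empty_m8())
  m <- do.call(rbind, parts)
  hits <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                     stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("m8 line ", rows[bad], ": cannot parse '", m[bad, j],
           "' in column ", M8_COLUMNS[j])
    }
    hits[[M8_COLUMNS[j]]] <- v
  }
  for (j in c("length", "mismatch", "gapopen", "qstart", "qend",
              "sstart", "send")) {
    hits[[j]] <- as.integer(hits[[j]])
  }
  if (any(hits$pident < 0 | hits$pident > 100)) {
    bad <- which(hits$pident < 0 | hits$pident > 100)[1]
    stop("m8 line ", rows[bad], ": pident out of [0, 100]")
  }
  if (any(hits$evalue < 0)) {
    bad <- which(hits$evalue < 0)[1]
    stop("m8 line ", rows[bad], ": negative evalue")
  }
  hits
}

empty_m8 <- function() {
  hits <- data.frame(qseqid = character(), sseqid = character(),
                     stringsAsFactors = FALSE)
  for (j in M8_NUMERIC) hits[[j]] <- numeric()
  for (j in c("length", "mismatch", "gapopen", "qstart", "qend",
              "sstart", "send")) hits[[j]] <- integer()
  hits
}

#' Write hits in m8 format
#'
#' Numeric fields are serialised with R's default `as.character` formatting,
#' which parses back to the identical double, so write/read/write round
#' trips are byte-exact.
#'
#' @param hits An m8 data.frame (see [read_m8()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_m8 <- function(hits, path) {
  cols <- lapply(M8_COLUMNS, function(j) as.character(hits[[j]]))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Select the single best hit per query read
#'
#' Aligners may report several hits per read; aggregation needs exactly one.
#' For each `qseqid` the retained hit maximises bitscore, with ties broken by
#' minimal e-value, then lexicographically smallest `sseqid`, then first
#' occurrence in the input. Up to the first-occurrence rule the result is
#' independent of input row order.
#'
#' @param hits An m8 data.frame.
#' @param evalue_max Optional e-value ceiling applied before selection
#'   (default `NULL`: keep all hits, cutoffs are the aligner's business).
#' @return An m8 data.frame with one row per distinct `qseqid`, in order of
#'   first appearance of each query.
#' @export
best_hit_per_query <- function(hits, evalue_max = NULL) {
  if (!is.null(evalue_max)) hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  ord <- order(-hits$bitscore, hits$evalue, hits$sseqid,
               seq_len(nrow(hits)), method = "radix")
  ranked <- hits[ord, , drop = FALSE]
  best <- ranked[!duplicated(ranked$qseqid), , drop = FALSE]
  # stable query order: first appearance in the original input
  best <- best[order(match(best$qseqid, hits$qseqid)), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Join best hits with the reference database into per-read annotations
#'
#' Each best hit is joined to its subject's organism, genus and function;
#' the functional hierarchy is attached by case-folded function-name lookup
#' (a miss fills all four levels with `"NO HIERARCHY"`). Hits whose subject
#' is missing from the database — e.g. an m8 file produced against a newer
#' database copy — are counted and reported via a warning, never silently
#' dropped and never fatal.
#'
#' @param best_hits One hit per read, from [best_hit_per_query()].
#' @param db A `reference_db`.
#' @param hierarchy Optional `hierarchy_map`; `NULL` marks every read as
#'   hierarchy-miss.
#' @return A list with `annotations` (data.frame: `read_id`, `ref_id`,
#'   `organism`, `genus`, `function_name`, `level1`..`level4`),
#'   `unmatched_count` and `unmatched_ids`.
#' @export
annotate_reads <- function(best_hits, db, hierarchy = NULL) {
  idx <- match(best_hits$sseqid, db$ref_id)
  missing <- is.na(idx)
  unmatched_ids <- unique(best_hits$sseqid[missing])
  if (any(missing)) {
    warning(sum(missing), " hit(s) reference subjects absent from the database: ",
            paste(utils::head(unmatched_ids, 5), collapse = ", "),
            if (length(unmatched_ids) > 5) ", ..." else "")
  }
  keep <- which(!missing)
  ann <- data.frame(
    read_id = best_hits$qseqid[keep],
    ref_id = db$ref_id[idx[keep]],
    organism = db$organism[idx[keep]],
    genus = db$genus[idx[keep]],
    function_name = db$function_name[idx[keep]],
    stringsAsFactors = FALSE
  )
  nh <- SENTINELS[["no_hierarchy"]]
  ann$level1 <- ann$level2 <- ann$level3 <- ann$level4 <- rep(nh, nrow(ann))
  if (!is.null(hierarchy) && nrow(ann) > 0) {
    path <- hierarchy_rows(hierarchy, ann$function_name)
    hit <- !is.na(path$level1)
    for (lv in c("level1", "level2", "level3", "level4")) {
      ann[[lv]][hit] <- path[[lv]][hit]
    }
  }
  ann <- ann[, c("read_id", "ref_id", "organism", "genus", "function_name",
                 "level1", "level2", "level3", "level4")]
  list(annotations = ann,
       unmatched_count = sum(missing),
       unmatched_ids = unmatched_ids)
}

ANNOTATION_COLUMNS <- c("read_id", "ref_id", "organism", "genus",
                        "function_name", "level1", "level2", "level3", "level4")

#' Write / read the per-read annotation checkpoint file
#'
#' The checkpoint is the pivot of the workflow: annotation (the expensive
#' step) runs once per database, and every aggregation, slice or statistic
#' can be recomputed from this file alone. Plain TSV with a header row; the
#' round trip is byte-exact.
#'
#' @param annotations Annotation data.frame (see [annotate_reads()]).
#' @param path File path.
#' @return `write_annotations`: `path`, invisibly. `read_annotations`: the
#'   annotation data.frame.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(ANNOTATION_COLUMNS %in% names(annotations)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ANNOTATION_COLUMNS, collapse = "\t"), con)
  if (nrow(annotations) > 0) {
    cols <- lapply(ANNOTATION_COLUMNS, function(j) annotations[[j]])
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != paste(ANNOTATION_COLUMNS, collapse = "\t")) {
    stop("annotation checkpoint ", path, ": line 1 is not the expected header")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    ann <- as.data.frame(stats::setNames(
      replicate(length(ANNOTATION_COLUMNS), character(), simplify = FALSE),
      ANNOTATION_COLUMNS), stringsAsFactors = FALSE)
    return(ann)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(ANNOTATION_COLUMNS))) {
    bad <- which(nf != length(ANNOTATION_COLUMNS))[1]
    stop("annotation checkpoint ", path, ": line ", bad + 1,
         " has ", nf[bad], " fields (expected ", length(ANNOTATION_COLUMNS), ")")
  }
  m <- do.call(rbind, parts)
  colnames(m) <- ANNOTATION_COLUMNS
  as.data.frame(m, stringsAsFactors = FALSE)
}
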