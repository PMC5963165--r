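# FASTQ handling and simplified preprocessing: paired-read merging, sliding
# window quality trimming, and a k-mer rRNA screen. These are deliberately
# simple, fully specified stand-ins for the dedicated preprocessing tools a
# production run would use (see the pipeline module's external mode); every
# step partitions its input so no read is ever silently lost.

#' Read / write FASTQ
#'
#' Reads are represented as a plain data.frame with columns `read_id`,
#' `sequence`, `quality` (Phred+33). The round trip is byte-exact for
#' standard 4-line FASTQ.
#'
#' @param path FASTQ file path (gzip transparently supported on read).
#' @param reads FASTQ data.frame to write.
#' @return `read_fastq`: the data.frame. `write_fastq`: `path`, invisibly.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    read_id = names(x),
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)),
            all(nchar(reads$sequence) == nchar(reads$quality)))
  if (nrow(reads) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$sequence, "+", reads$quality))
  writeLines(lines, path)
  invisible(path)
}

revcomp <- function(sequences) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequences)))
}

reverse_string <- function(s) {
  vapply(strsplit(s, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Merge overlapping paired-end reads
#'
#' For each pair the reverse read is reverse-complemented and every
#' suffix-of-forward / prefix-of-reverse overlap of length at least
#' `min_overlap` is scanned, longest first; the first overlap whose mismatch
#' fraction is at most `max_mismatch_rate` is accepted. Disagreeing overlap
#' bases are resolved in favour of the higher quality call. Pairs with no
#' acceptable overlap are passed through unchanged to the two `notCombined`
#' outputs, so `merged` plus `notCombined` partition the input pairs.
#'
#' @param fwd,rev FASTQ data.frames, paired in order.
#' @param min_overlap Minimum overlap length in bases (default 10).
#' @param max_mismatch_rate Maximum fraction of mismatching bases tolerated
#'   inside the overlap (default 0.1).
#' @return A list with FASTQ data.frames `merged`, `notCombined_fwd`,
#'   `notCombined_rev`.
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 10, max_mismatch_rate = 0.1) {
  if (nrow(fwd) != nrow(rev)) {
    stop("forward and reverse files have different read counts (",
         nrow(fwd), " vs ", nrow(rev), ")")
  }
  if (!is_count(min_overlap, min = 1)) stop("min_overlap must be >= 1")
  if (nrow(fwd) == 0) {
    return(list(merged = fwd, notCombined_fwd = fwd, notCombined_rev = rev))
  }
  rc_seq <- revcomp(rev$sequence)
  rc_qual <- reverse_string(rev$quality)
  merged_rows <- vector("list", nrow(fwd))
  ok <- logical(nrow(fwd))
  for (i in seq_len(nrow(fwd))) {
    m <- merge_one_pair(fwd$sequence[i], fwd$quality[i],
                        rc_seq[i], rc_qual[i],
                        min_overlap, max_mismatch_rate)
    if (!is.null(m)) {
      ok[i] <- TRUE
      merged_rows[[i]] <- data.frame(read_id = fwd$read_id[i],
                                     sequence = m$sequence,
                                     quality = m$quality,
                                     stringsAsFactors = FALSE)
    }
  }
  merged <- if (any(ok)) do.call(rbind, merged_rows[ok]) else fwd[0, ]
  rownames(merged) <- NULL
  list(merged = merged,
       notCombined_fwd = fwd[!ok, , drop = FALSE],
       notCombined_rev = rev[!ok, , drop = FALSE])
}

merge_one_pair <- function(fs, fq, rs, rq, min_overlap, max_mismatch_rate) {
  lf <- nchar(fs); lr <- nchar(rs)
  if (min(lf, lr) < min_overlap) return(NULL)
  f_chr <- utf8ToInt(fs); r_chr <- utf8ToInt(rs)
  f_q <- utf8ToInt(fq);  r_q <- utf8ToInt(rq)
  for (o in seq(min(lf, lr), min_overlap)) {
    fi <- (lf - o + 1L):lf
    ri <- 1L:o
    mm <- f_chr[fi] != r_chr[ri]
    if (sum(mm) / o <= max_mismatch_rate) {
      seq_ov <- ifelse(f_q[fi] >= r_q[ri], f_chr[fi], r_chr[ri])
      qual_ov <- pmax(f_q[fi], r_q[ri])
      merged_seq <- c(f_chr[seq_len(lf - o)], seq_ov,
                      r_chr[seq(o + 1L, length.out = lr - o)])
      merged_qual <- c(f_q[seq_len(lf - o)], qual_ov,
                       r_q[seq(o + 1L, length.out = lr - o)])
      return(list(sequence = intToUtf8(merged_seq),
                  quality = intToUtf8(merged_qual)))
    }
  }
  NULL
}

#' Sliding-window 3' quality trimming
#'
#' Scans windows of `window` bases from the 5' end and clips the read at the
#' start of the first window whose mean Phred quality falls below `mean_q`;
#' optional adapters are removed beforehand by exact prefix match. Reads
#' shorter than `min_len` after clipping are dropped (but returned, so kept
#' plus dropped partition the input).
#'
#' @param reads FASTQ data.frame.
#' @param window Window width in bases (default 4).
#' @param mean_q Minimum mean Phred quality per window (default 15).
#' @param min_len Minimum retained read length (default 70).
#' @param adapters Optional character vector of adapter sequences clipped by
#'   exact prefix match (default none).
#' @return A list with FASTQ data.frames `reads` (trimmed survivors) and
#'   `dropped` (original reads that fell below `min_len`).
#' @export
quality_trim <- function(reads, window = 4, mean_q = 15, min_len = 70,
                         adapters = character()) {
  if (!is_count(window, min = 1)) stop("window must be >= 1")
  original <- reads
  for (ad in adapters) {
    pre <- startsWith(reads$sequence, ad)
    n <- nchar(ad)
    reads$sequence[pre] <- substring(reads$sequence[pre], n + 1L)
    reads$quality[pre] <- substring(reads$quality[pre], n + 1L)
  }
  keep_len <- integer(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    q <- utf8ToInt(reads$quality[i]) - 33L
    L <- length(q)
    cut <- L
    if (L >= window) {
      wm <- (cumsum(q)[window:L] -
               c(0, cumsum(q))[1:(L - window + 1L)]) / window
      fail <- which(wm < mean_q)
      if (length(fail) > 0) cut <- fail[1] - 1L
    }
    keep_len[i] <- cut
  }
  reads$sequence <- substring(reads$sequence, 1L, keep_len)
  reads$quality <- substring(reads$quality, 1L, keep_len)
  keep <- keep_len >= min_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, dropped = original[!keep, , drop = FALSE])
}

#' Partition reads into ribosomal and other by a k-mer screen
#'
#' A read is flagged ribosomal when at least `hit_fraction` of its
#' nucleotide k-mers (either strand) occur in the rRNA reference k-mer set.
#' The non-ribosomal partition is what proceeds to annotation; both
#' partitions are returned so nothing is lost.
#'
#' @param reads FASTQ data.frame.
#' @param rrna_reference A `reference_db`-like data.frame with a `sequence`
#'   column of rRNA nucleotide sequences, or a FASTA path.
#' @param k Nucleotide k-mer length (default 21).
#' @param hit_fraction Minimum fraction of a read's k-mers found in the
#'   reference set to call it ribosomal (default 0.10).
#' @return A list with FASTQ data.frames `ribosomal` and `other`.
#' @export
rrna_filter <- function(reads, rrna_reference, k = 21, hit_fraction = 0.10) {
  if (is.character(rrna_reference)) {
    x <- Biostrings::readDNAStringSet(rrna_reference)
    rrna_reference <- data.frame(sequence = as.character(x),
                                 stringsAsFactors = FALSE)
  }
  if (nrow(rrna_reference) == 0) stop("rRNA reference is empty")
  ref_kmers <- unique(unlist(lapply(toupper(rrna_reference$sequence), function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character())
    substring(s, 1:n, k:(n + k - 1L))
  }), use.names = FALSE))
  is_ribo <- vapply(toupper(reads$sequence), function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(FALSE)
    km <- substring(s, 1:n, k:(n + k - 1L))
    km_rc <- revcomp(km)
    hits <- sum(km %in% ref_kmers | km_rc %in% ref_kmers)
    hits / n >= hit_fraction
  }, logical(1), USE.NAMES = FALSE)
  list(ribosomal = reads[is_ribo, , drop = FALSE],
       other = reads[!is_ribo, , drop = FALSE])
}
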