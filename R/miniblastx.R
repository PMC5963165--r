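# A small translated-search aligner: nucleotide reads against a protein
# database through a peptide k-mer index, emitting standard m8 rows.
#
# This is a transparent test harness for the annotation workflow, not a
# replacement for a production translated aligner: seeding is exact k-mer
# matching, extension is ungapped, and the reported "evalue" is a monotone
# surrogate (2^-score), NOT a statistical expectation value.

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames `+1..+3` read the sequence at offsets 0..2; frames `-1..-3` read
#' the reverse complement the same way. Standard genetic code; stop codons
#' become `*`; codons containing `N` become `X`; trailing partial codons are
#' dropped.
#'
#' @param dna A nucleotide string over `A,C,G,T,N` of length >= 3.
#' @return Named character vector of 6 peptides (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @export
translate_six_frames <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1)
  if (nchar(dna) < 3) stop("sequence shorter than one codon")
  translate_frames_batch(dna)[1, ]
}

# Batch six-frame translation: rows = reads, columns = frames.
translate_frames_batch <- function(sequences) {
  x <- Biostrings::DNAStringSet(sequences)
  rc <- Biostrings::reverseComplement(x)
  frame_of <- function(set, shift) {
    w <- Biostrings::width(set)
    start <- pmin(shift + 1L, w + 1L)
    len <- pmax(w - shift, 0L)
    len <- len - (len %% 3L)
    sub <- Biostrings::subseq(set, start = start, width = len)
    as.character(suppressWarnings(
      Biostrings::translate(sub, if.fuzzy.codon = "X", no.init.codon = TRUE)))
  }
  out <- cbind(
    `+1` = frame_of(x, 0L), `+2` = frame_of(x, 1L), `+3` = frame_of(x, 2L),
    `-1` = frame_of(rc, 0L), `-2` = frame_of(rc, 1L), `-3` = frame_of(rc, 2L)
  )
  rownames(out) <- NULL
  out
}

#' Build a peptide k-mer index over a reference database
#'
#' Postings map each amino-acid k-mer to the `(ref_id, offset)` pairs where
#' it occurs. K-mers containing `*` or `X` are excluded.
#'
#' @param db A `reference_db`.
#' @param k K-mer length in amino acids (default 5; must be >= 3).
#' @return A `peptide_kmer_index` object.
#' @export
build_peptide_index <- function(db, k = 5) {
  if (!is_count(k, min = 3)) stop("k must be an integer >= 3")
  k <- as.integer(k)
  tabs <- lapply(seq_len(nrow(db)), function(i) {
    s <- db$sequence[i]
    n <- nchar(s) - k + 1L
    if (n < 1L) return(NULL)
    km <- substring(s, 1:n, k:(n + k - 1L))
    keep <- !grepl("[*X]", km)
    if (!any(keep)) return(NULL)
    data.table::data.table(kmer = km[keep], ref_id = db$ref_id[i],
                           offset = which(keep))
  })
  postings <- data.table::rbindlist(tabs)
  if (nrow(postings) == 0) {
    postings <- data.table::data.table(kmer = character(),
                                       ref_id = character(),
                                       offset = integer())
  }
  data.table::setkey(postings, kmer)
  idx <- list(k = k, postings = postings,
              sequences = stats::setNames(db$sequence, db$ref_id))
  class(idx) <- "peptide_kmer_index"
  idx
}

#' @export
print.peptide_kmer_index <- function(x, ...) {
  cat("<peptide_kmer_index> k=", x$k, ", ",
      nrow(x$postings), " postings over ", length(x$sequences),
      " reference sequences\n", sep = "")
  invisible(x)
}

#' Search nucleotide reads against a peptide k-mer index
#'
#' For each read, every frame's k-mers are looked up in the index; a
#' candidate reference's score is the maximum (over frames) number of
#' distinct query k-mer positions it seeds. References scoring at least
#' `min_seeds` are reported as m8 rows: coordinates and percent identity
#' come from an ungapped extension around the densest seed diagonal of the
#' best frame, the e-value surrogate is `2^-score` and the bitscore is the
#' score itself. Rows are ordered by read, then score descending, then
#' `ref_id` ascending, so identical inputs give byte-identical output.
#'
#' Query coordinates are 1-based nucleotide positions on the read as
#' sequenced; minus-frame alignments have `qstart > qend`. Subject
#' coordinates are 1-based amino-acid positions.
#'
#' @param reads A data.frame with columns `read_id` and `sequence` (a FASTQ
#'   data.frame from [read_fastq()] works as-is).
#' @param index A `peptide_kmer_index` from [build_peptide_index()].
#' @param min_seeds Minimum shared-k-mer score to report a candidate
#'   (default 2).
#' @return An m8 data.frame (possibly 0 rows), valid input to [read_m8()]
#'   semantics and [best_hit_per_query()].
#' @export
miniblastx_search <- function(reads, index, min_seeds = 2) {
  stopifnot(inherits(index, "peptide_kmer_index"))
  if (!is_count(min_seeds, min = 1)) stop("min_seeds must be a positive integer")
  if (nrow(reads) == 0) return(empty_m8())
  k <- index$k
  pep <- translate_frames_batch(reads$sequence)

  # long table of query k-mers: (read index, frame, aa position, kmer)
  qparts <- vector("list", 6L)
  for (f in 1:6) {
    p <- pep[, f]
    n <- nchar(p) - k + 1L
    ridx <- rep.int(seq_along(p), pmax(n, 0L))
    starts <- unlist(lapply(n, function(m) if (m >= 1L) seq_len(m) else integer()),
                     use.names = FALSE)
    if (length(ridx) == 0) next
    km <- substring(p[ridx], starts, starts + k - 1L)
    keep <- !grepl("[*X]", km)
    qparts[[f]] <- data.table::data.table(
      ridx = ridx[keep], frame = f, qpos = starts[keep], kmer = km[keep])
  }
  qtab <- data.table::rbindlist(qparts)
  if (nrow(qtab) == 0) return(empty_m8())

  seeds <- index$postings[qtab, on = "kmer", nomatch = NULL,
                          allow.cartesian = TRUE]
  if (nrow(seeds) == 0) return(empty_m8())

  # score per (read, frame, ref) = distinct seeded query positions
  qpos <- ridx <- frame <- ref_id <- score <- NULL # R CMD check NSE
  fr_scores <- seeds[, list(score = length(unique(qpos))),
                     by = list(ridx, frame, ref_id)]
  data.table::setorder(fr_scores, ridx, ref_id, -score, frame)
  cand <- fr_scores[!duplicated(fr_scores[, list(ridx, ref_id)])]
  cand <- cand[cand$score >= min_seeds]
  if (nrow(cand) == 0) return(empty_m8())
  data.table::setorder(cand, ridx, -score, ref_id)

  read_len <- nchar(reads$sequence)
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ci <- cand[i]
    sd <- seeds[seeds$ridx == ci$ridx & seeds$frame == ci$frame &
                  seeds$ref_id == ci$ref_id]
    rows[[i]] <- extend_candidate(
      qseqid = reads$read_id[ci$ridx],
      query_pep = pep[ci$ridx, ci$frame],
      subject_pep = index$sequences[[ci$ref_id]],
      sseqid = ci$ref_id,
      qpos = sd$qpos, spos = sd$offset,
      k = k, frame = ci$frame, read_len = read_len[ci$ridx],
      score = ci$score)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Ungapped extension around the densest seed diagonal; returns one m8 row.
extend_candidate <- function(qseqid, query_pep, subject_pep, sseqid,
                             qpos, spos, k, frame, read_len, score) {
  diag <- qpos - spos
  dens <- table(diag)
  best_diag <- as.integer(names(dens)[order(-as.integer(dens),
                                            as.integer(names(dens)))][1])
  on_diag <- diag == best_diag
  qa <- min(qpos[on_diag]); qb <- max(qpos[on_diag]) + k - 1L
  sa <- qa - best_diag;     sb <- qb - best_diag
  qc <- utf8ToInt(query_pep)
  sc <- utf8ToInt(subject_pep)
  while (qa > 1L && sa > 1L && qc[qa - 1L] == sc[sa - 1L]) {
    qa <- qa - 1L; sa <- sa - 1L
  }
  nq <- length(qc); ns <- length(sc)
  while (qb < nq && sb < ns && qc[qb + 1L] == sc[sb + 1L]) {
    qb <- qb + 1L; sb <- sb + 1L
  }
  alen <- qb - qa + 1L
  matches <- sum(qc[qa:qb] == sc[sa:sb])
  # aa -> nt coordinates on the read as sequenced
  shift <- (frame - 1L) %% 3L
  nt_a <- shift + 3L * (qa - 1L) + 1L
  nt_b <- shift + 3L * qb
  if (frame <= 3L) {
    qstart <- nt_a; qend <- nt_b
  } else {
    qstart <- read_len - nt_a + 1L
    qend <- read_len - nt_b + 1L
  }
  data.frame(
    qseqid = qseqid, sseqid = sseqid,
    pident = round(100 * matches / alen, 2),
    length = alen, mismatch = alen - matches, gapopen = 0L,
    qstart = qstart, qend = qend, sstart = sa, send = sb,
    evalue = 2^(-score), bitscore = as.numeric(score),
    stringsAsFactors = FALSE
  )
}

#' Align reads and write m8 output (convenience wrapper)
#'
#' @param reads FASTQ data.frame (`read_id`, `sequence`, `quality`).
#' @param db A `reference_db`.
#' @param path Output m8 path, or `NULL` to return the data.frame only.
#' @param k,min_seeds Index and scoring parameters, see
#'   [build_peptide_index()] and [miniblastx_search()].
#' @return The m8 data.frame, invisibly when `path` is given.
#' @export
miniblastx_align <- function(reads, db, path = NULL, k = 5, min_seeds = 2) {
  idx <- build_peptide_index(db, k = k)
  hits <- miniblastx_search(reads, idx, min_seeds = min_seeds)
  if (!is.null(path)) {
    write_m8(hits, path)
    return(invisible(hits))
  }
  hits
}
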