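# Seed-deterministic synthetic data: mock protein reference databases with
# a four-level hierarchy, provenance-tracked simulated reads, directly
# fabricated m8 files with controlled miscall rates, and the accuracy
# evaluator that compares predicted annotations against read provenance.
#
# The error model is substitution-only and the peptides are uniform random
# over the 20 amino acids: enough to exercise seeding, ranking degradation
# and the full aggregation/statistics path, with none of the compositional
# structure, homology or indel behaviour of real sequencing data.

CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  # third codon position varies fastest, matching the code string below
  codons <- paste0(rep(bases, each = 16), rep(rep(bases, each = 4), 4),
                   rep(bases, 16))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  split(codons, aa)[setdiff(unique(aa), "*")]
})

#' Generate a mock protein reference database with hierarchy and coding DNA
#'
#' Peptides are uniform random over the 20 amino acids, each back-translated
#' through random synonymous codons into a coding DNA sequence. Organisms
#' are named `Genus_<i> species_<i>` (two whitespace tokens, so genus
#' extraction is always well defined); every gene gets a unique function
#' name assigned to a hierarchy path drawn from a grid of
#' `hierarchy_shape[1]` level-1 categories, each with `hierarchy_shape[2]`
#' level-2 and `hierarchy_shape[3]` level-3 subcategories. Fully
#' deterministic given `seed`.
#'
#' @param n_organisms Number of organisms (one genus each).
#' @param genes_per_organism Genes per organism.
#' @param peptide_len Peptide length in amino acids (default 120).
#' @param hierarchy_shape Integer vector of length 3: level-1 categories,
#'   level-2 per level-1, level-3 per level-2 (default `c(3, 2, 2)`).
#' @param seed Integer seed (required).
#' @return A list: `db` (a `reference_db`), `hierarchy` (a
#'   `hierarchy_map`), `dna` (named character vector of coding sequences,
#'   one per gene).
#' @export
generate_reference_db <- function(n_organisms, genes_per_organism,
                                  peptide_len = 120,
                                  hierarchy_shape = c(3, 2, 2),
                                  seed) {
  stopifnot(is_count(n_organisms, 1), is_count(genes_per_organism, 1),
            is_count(peptide_len, 1), length(hierarchy_shape) == 3,
            all(hierarchy_shape >= 1))
  if (missing(seed)) stop("seed is required")
  withr::with_seed(as.integer(seed), {
    n_genes <- n_organisms * genes_per_organism
    aa20 <- setdiff(c("A","R","N","D","C","Q","E","G","H","I","L","K",
                      "M","F","P","S","T","W","Y","V"), NULL)
    peptides <- vapply(seq_len(n_genes), function(i)
      paste(sample(aa20, peptide_len, replace = TRUE), collapse = ""), "")
    dna <- vapply(peptides, back_translate, "", USE.NAMES = FALSE)
    org_idx <- rep(seq_len(n_organisms), each = genes_per_organism)
    organisms <- sprintf("Genus_%02d species_%02d", org_idx, org_idx)
    functions <- sprintf("enzyme_activity_%04d", seq_len(n_genes))
    ref_ids <- sprintf("REF_%04d", seq_len(n_genes))

    # hierarchy grid: leaves = level1 x level2 x level3; functions assigned
    # round-robin so every branch is populated
    leaves <- expand.grid(l3 = seq_len(hierarchy_shape[3]),
                          l2 = seq_len(hierarchy_shape[2]),
                          l1 = seq_len(hierarchy_shape[1]))
    leaf <- leaves[((seq_len(n_genes) - 1) %% nrow(leaves)) + 1, ]
    path <- data.frame(
      level1 = sprintf("Category_%02d", leaf$l1),
      level2 = sprintf("Subcategory_%02d_%02d", leaf$l1, leaf$l2),
      level3 = sprintf("Subsystem_%02d_%02d_%02d", leaf$l1, leaf$l2, leaf$l3),
      level4 = functions, stringsAsFactors = FALSE
    )
    db <- data.frame(ref_id = ref_ids, function_name = functions,
                     organism = organisms, genus = genus_of(organisms),
                     sequence = peptides, stringsAsFactors = FALSE)
    class(db) <- c("reference_db", "data.frame")
    hier <- list(key = tolower(functions), path = path)
    class(hier) <- "hierarchy_map"
    list(db = db, hierarchy = hier, dna = stats::setNames(dna, ref_ids))
  })
}

back_translate <- function(peptide) {
  aas <- strsplit(peptide, "", fixed = TRUE)[[1]]
  paste(vapply(aas, function(a) {
    cods <- CODON_TABLE[[a]]
    cods[sample.int(length(cods), 1)]
  }, "", USE.NAMES = FALSE), collapse = "")
}

#' Simulate provenance-tracked reads from a mock database
#'
#' Genes are sampled per the abundance model (`"uniform"`, or
#' `"lognormal"` weights with sdlog 1); each read is a substring of the
#' gene's coding DNA at a uniform offset, on either strand, with every base
#' substituted independently with probability `error_rate`. Phred qualities
#' are set consistently with the error rate
#' (`Q = -10 log10(max(error_rate, 1e-4))`).
#'
#' @param ref A list from [generate_reference_db()] (needs `db` and `dna`),
#'   optionally with `hierarchy` for truth paths.
#' @param n_reads Number of reads.
#' @param read_len Read length in nucleotides (default 150; must not exceed
#'   the shortest gene).
#' @param error_rate Per-base substitution probability in \[0, 1).
#' @param abundance_model `"uniform"` or `"lognormal"`.
#' @param seed Integer seed (required).
#' @return A list: `reads` (FASTQ data.frame) and `truth` (data.frame
#'   `read_id`, `source_ref_id`, `organism`, `genus`, `function_name`,
#'   `level1`..`level4`, `strand`, `offset`).
#' @export
simulate_reads <- function(ref, n_reads, read_len = 150, error_rate = 0,
                           abundance_model = c("uniform", "lognormal"),
                           seed) {
  abundance_model <- match.arg(abundance_model)
  if (missing(seed)) stop("seed is required")
  stopifnot(is_count(n_reads, 1), error_rate >= 0, error_rate < 1)
  dna <- ref$dna
  gene_len <- nchar(dna)
  if (read_len > min(gene_len)) {
    stop("read_len ", read_len, " exceeds the shortest gene (",
         min(gene_len), " nt)")
  }
  db <- ref$db
  withr::with_seed(as.integer(seed), {
    w <- switch(abundance_model,
                uniform = rep(1, length(dna)),
                lognormal = stats::rlnorm(length(dna), sdlog = 1))
    gi <- sample.int(length(dna), n_reads, replace = TRUE, prob = w)
    offset <- vapply(gene_len[gi] - read_len + 1L,
                     function(m) sample.int(m, 1), 1L)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(dna[gi], offset, offset + read_len - 1L)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    if (error_rate > 0) {
      seqs <- add_substitutions(seqs, error_rate)
    }
    q <- as.integer(round(-10 * log10(max(error_rate, 1e-4))))
    qual <- strrep(intToUtf8(min(q, 40L) + 33L), read_len)
    read_id <- sprintf("read_%06d", seq_len(n_reads))
    hier_path <- if (!is.null(ref$hierarchy)) {
      hierarchy_rows(ref$hierarchy, db$function_name[gi])
    } else {
      nh <- SENTINELS[["no_hierarchy"]]
      data.frame(level1 = rep(nh, n_reads), level2 = nh,
                 level3 = nh, level4 = nh)
    }
    truth <- data.frame(
      read_id = read_id,
      source_ref_id = db$ref_id[gi],
      organism = db$organism[gi],
      genus = db$genus[gi],
      function_name = db$function_name[gi],
      stringsAsFactors = FALSE
    )
    truth <- cbind(truth, hier_path,
                   data.frame(strand = strand, offset = offset))
    list(reads = data.frame(read_id = read_id, sequence = seqs,
                            quality = qual, stringsAsFactors = FALSE),
         truth = truth)
  })
}

add_substitutions <- function(seqs, error_rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < error_rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1)
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Fabricate an m8 file with a controlled miscall rate
#'
#' Bypasses alignment entirely: each truth read gets exactly one m8 row
#' whose subject is its true source with probability `1 - miscall_rate`,
#' or a uniformly random *other* reference otherwise. Filler alignment
#' columns are plausible constants. This lets aggregation, slicing and
#' statistics be tested with a known annotation error rate and no aligner.
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param db A `reference_db` (the pool of decoy subjects).
#' @param miscall_rate Probability of a wrong subject, in \[0, 1\].
#' @param seed Integer seed (required).
#' @return An m8 data.frame (one row per truth read).
#' @export
fabricate_m8 <- function(truth, db, miscall_rate = 0, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(miscall_rate >= 0, miscall_rate <= 1, nrow(db) >= 2)
  withr::with_seed(as.integer(seed), {
    n <- nrow(truth)
    sseqid <- truth$source_ref_id
    flip <- stats::runif(n) < miscall_rate
    for (i in which(flip)) {
      sseqid[i] <- sample(setdiff(db$ref_id, truth$source_ref_id[i]), 1)
    }
    data.frame(
      qseqid = truth$read_id, sseqid = sseqid,
      pident = 97.5, length = 50L, mismatch = 1L, gapopen = 0L,
      qstart = 1L, qend = 150L, sstart = 1L, send = 50L,
      evalue = 1e-20, bitscore = 100,
      stringsAsFactors = FALSE
    )
  })
}

ACCURACY_LEVELS <- c("species", "genus", "function",
                     "level1", "level2", "level3")

#' Evaluate annotation accuracy against read provenance
#'
#' Compares each read's predicted organism/function/hierarchy against the
#' truth record of the read it was simulated from. Species correctness is
#' case-folded equality of the full organism string, genus of the genus
#' token, function of the function string, and level-k of the hierarchy
#' category at that level. Reads with no annotation are excluded from the
#' denominator by default and reported separately (set
#' `include_unannotated = TRUE` to count them as evaluated-and-incorrect).
#'
#' @param annotations Annotation data.frame (see [annotate_reads()]).
#' @param truth Truth data.frame from [simulate_reads()].
#' @param include_unannotated Count unannotated reads as incorrect
#'   (default `FALSE`: exclude and report).
#' @return A data.frame of class `accuracy_report`: one row per level
#'   (`species`, `genus`, `function`, `level1`..`level3`) with
#'   `n_evaluated`, `n_correct`, `accuracy`; the number of unannotated
#'   reads is in `attr(, "unannotated")`.
#' @export
evaluate_accuracy <- function(annotations, truth, include_unannotated = FALSE) {
  idx <- match(truth$read_id, annotations$read_id)
  annotated <- !is.na(idx)
  if (!any(annotated)) {
    stop("no truth read has an annotation (empty read-id intersection)")
  }
  n_unannotated <- sum(!annotated)
  fold <- function(x) tolower(trimws(x))
  correct_of <- function(level) {
    tcol <- switch(level, species = "organism", genus = "genus",
                   "function" = "function_name", level)
    ok <- fold(annotations[[tcol]][idx]) == fold(truth[[tcol]])
    ok[!annotated] <- FALSE
    ok
  }
  rows <- lapply(ACCURACY_LEVELS, function(level) {
    ok <- correct_of(level)
    n_eval <- if (include_unannotated) nrow(truth) else sum(annotated)
    n_corr <- sum(ok)
    data.frame(level = level, n_evaluated = n_eval, n_correct = n_corr,
               accuracy = n_corr / n_eval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "unannotated") <- n_unannotated
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> (", attr(x, "unannotated"),
      " unannotated reads)\n", sep = "")
  print.data.frame(transform(as.data.frame(x),
                             accuracy = round(accuracy, 4)))
  invisible(x)
}

#' Write simulated outputs with parameter headers
#'
#' Truth tables are TSVs with `# seed=` / `# params=` comment headers so a
#' simulation's provenance travels with its files.
#'
#' @param truth Truth data.frame.
#' @param path Output path.
#' @param seed,params Values recorded in the header.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, seed = NA, params = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# seed=", seed), paste0("# params=", params)), con)
  cols <- c("read_id", "source_ref_id", "organism", "genus", "function_name",
            "level1", "level2", "level3", "level4")
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(do.call(paste, c(truth[cols], sep = "\t")), con)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  parts <- strsplit(body[-1], "\t", fixed = TRUE)
  m <- do.call(rbind, parts)
  colnames(m) <- cols
  as.data.frame(m, stringsAsFactors = FALSE)
}
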