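# Fixture builders and independent oracles shared across test files.
# Oracles deliberately re-derive results by brute force / first principles,
# independent of the implementation paths they check.

`%+%` <- function(a, b) paste0(a, b)

# --- fixtures ---------------------------------------------------------------

fixture_fasta <- function() {
  paste(
    ">REF_001 DNA polymerase III subunit beta [Escherichia coli]",
    "MKLV",
    ">REF_9 beta-galactosidase [Bacteroides fragilis NCTC 9343]",
    "MSNALAVTLR",
    ">REF_7 hypothetical protein",
    "MAAAK",
    sep = "\n")
}

fixture_hierarchy <- function() {
  paste(
    "# function_key\tlevel4\tlevel3\tlevel2\tlevel1",
    "BGAL\tbeta-galactosidase\tLactose utilization\tDi- and oligosaccharides\tCarbohydrates",
    "beta-galactosidase\tbeta-galactosidase\tLactose utilization\tDi- and oligosaccharides\tCarbohydrates",
    "cytochrome oxidase\tcytochrome oxidase\t\t\tRespiration",
    sep = "\n")
}

# three annotated reads: 2x E. coli (Carbohydrates), 1x B. fragilis (Respiration)
fixture_annotations <- function() {
  data.frame(
    read_id = c("r1", "r2", "r3"),
    ref_id = c("REF_A", "REF_A", "REF_B"),
    organism = c("Escherichia coli", "Escherichia coli", "Bacteroides fragilis"),
    genus = c("Escherichia", "Escherichia", "Bacteroides"),
    function_name = c("beta-galactosidase", "beta-galactosidase",
                      "cytochrome oxidase"),
    level1 = c("Carbohydrates", "Carbohydrates", "Respiration"),
    level2 = c("Di- and oligosaccharides", "Di- and oligosaccharides", "NO LEVEL"),
    level3 = c("Lactose utilization", "Lactose utilization", "NO LEVEL"),
    level4 = c("beta-galactosidase", "beta-galactosidase", "cytochrome oxidase"),
    stringsAsFactors = FALSE
  )
}

fixture_fastq <- function(n = 4, len = 20, q = "I", seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      read_id = sprintf("fx_%03d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), ""),
      quality = strrep(q, len),
      stringsAsFactors = FALSE
    )
  })
}

random_m8 <- function(n_queries, n_hits, seed) {
  withr::with_seed(seed, {
    q <- sample(sprintf("q%02d", seq_len(n_queries)), n_hits, replace = TRUE)
    data.frame(
      qseqid = q,
      sseqid = sample(sprintf("S%02d", 1:8), n_hits, replace = TRUE),
      pident = round(stats::runif(n_hits, 50, 100), 1),
      length = sample(30:60, n_hits, replace = TRUE),
      mismatch = sample(0:5, n_hits, replace = TRUE),
      gapopen = 0L,
      qstart = 1L, qend = 150L,
      sstart = 1L, send = 50L,
      # coarse grids so bitscore/evalue ties actually occur
      evalue = sample(c(1e-30, 1e-20, 1e-10, 1e-5), n_hits, replace = TRUE),
      bitscore = sample(c(40, 60, 80, 100), n_hits, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

abundance_from_counts <- function(counts, sample_id, key_kind = "organism") {
  ann <- data.frame(
    read_id = sprintf("%s_r%04d", sample_id, seq_len(sum(counts))),
    organism = rep(names(counts), counts),
    stringsAsFactors = FALSE
  )
  ann$ref_id <- ann$genus <- ann$function_name <- ann$organism
  ann$level1 <- ann$level2 <- ann$level3 <- ann$level4 <- "NO HIERARCHY"
  aggregate_annotations(ann, key_kind, sample_id)
}

# --- independent oracles ----------------------------------------------------

# last balanced top-level bracket pair by exhaustive pair enumeration
oracle_last_bracket <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  best <- NULL
  for (i in seq_along(ch)) {
    if (ch[i] != "[") next
    # effective depth before i, with unmatched closers ignored (floor at 0)
    depth_before <- 0L
    for (t in seq_len(i - 1)) {
      if (ch[t] == "[") depth_before <- depth_before + 1L
      if (ch[t] == "]" && depth_before > 0L) depth_before <- depth_before - 1L
    }
    if (depth_before != 0L) next
    depth <- 0L
    for (j in i:length(ch)) {
      if (ch[j] == "[") depth <- depth + 1L
      if (ch[j] == "]") depth <- depth - 1L
      if (depth == 0L) {
        if (is.null(best) || i > best$start) best <- list(start = i, end = j)
        break
      }
    }
  }
  best
}

# best hit by exhaustive scan under the full tie-break chain
oracle_best_hits <- function(hits) {
  out <- list()
  for (q in unique(hits$qseqid)) {
    rows <- which(hits$qseqid == q)
    best <- rows[1]
    for (r in rows[-1]) {
      b <- hits[best, ]; c <- hits[r, ]
      better <- FALSE
      if (c$bitscore > b$bitscore) better <- TRUE
      else if (c$bitscore == b$bitscore) {
        if (c$evalue < b$evalue) better <- TRUE
        else if (c$evalue == b$evalue && c$sseqid < b$sseqid) better <- TRUE
        # equal on all keys: first occurrence wins, i.e. keep `best`
      }
      if (better) best <- r
    }
    out[[q]] <- hits[best, ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# BH step-up from its definition: q_(i) = min_{j>=i} m p_(j)/j, capped at 1
oracle_bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# 3'-clip position by brute-force window scan over Phred values
oracle_trim_cut <- function(qual, window, mean_q) {
  q <- utf8ToInt(qual) - 33L
  L <- length(q)
  if (L < window) return(L)
  for (i in 1:(L - window + 1)) {
    if (mean(q[i:(i + window - 1)]) < mean_q) return(i - 1L)
  }
  L
}

# codon-by-codon translation from the genetic-code table (no Biostrings
# translate call): independent check of frame translation
oracle_translate <- function(dna) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(dna) %/% 3
  if (n == 0) return("")
  cods <- substring(dna, 3 * (1:n) - 2, 3 * (1:n))
  aa <- vapply(cods, function(cd) {
    if (grepl("N", cd)) "X" else unname(gc[cd])
  }, "", USE.NAMES = FALSE)
  paste(aa, collapse = "")
}

oracle_revcomp <- function(dna) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# full-sensitivity check: which references contain any read frame peptide
# (>= min_aa residues) as an exact substring
oracle_matching_refs <- function(read_seq, db, min_aa = 10) {
  frames <- c(
    vapply(0:2, function(s) oracle_translate(substring(read_seq, s + 1)), ""),
    vapply(0:2, function(s)
      oracle_translate(substring(oracle_revcomp(read_seq), s + 1)), ""))
  frames <- frames[nchar(frames) >= min_aa]
  db$ref_id[vapply(db$sequence, function(ref)
    any(vapply(frames, function(f) grepl(f, ref, fixed = TRUE), TRUE)),
    TRUE, USE.NAMES = FALSE)]
}

expect_tables_equal <- function(a, b) {
  expect_equal(a$key_kind, b$key_kind)
  expect_equal(a$total, b$total)
  expect_equal(a$rows$name, b$rows$name)
  expect_equal(a$rows$count, b$rows$count)
  expect_equal(a$rows$percent, b$rows$percent, tolerance = 1e-12)
}
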