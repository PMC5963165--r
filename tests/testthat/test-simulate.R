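test_that("reference generation is deterministic, counted and well-formed", {
  r1 <- generate_reference_db(5, 10, seed = 91)
  r2 <- generate_reference_db(5, 10, seed = 91)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$db), 50)
  expect_equal(length(r1$hierarchy$key), 50)
  expect_equal(length(r1$dna), 50)
  # organism names have exactly two whitespace tokens -> genus well defined
  expect_true(all(lengths(strsplit(r1$db$organism, "\\s+")) == 2))
  expect_equal(r1$db$genus, sub("\\s.*", "", r1$db$organism))
  # coding DNA translates back to the stored peptide
  p <- as.character(Biostrings::translate(Biostrings::DNAStringSet(r1$dna),
                                          no.init.codon = TRUE))
  expect_equal(unname(p), r1$db$sequence)
  # different seed, different content
  expect_false(identical(generate_reference_db(5, 10, seed = 92)$db$sequence,
                         r1$db$sequence))
})

test_that("back-translation codon table is the standard genetic code", {
  gc <- Biostrings::GENETIC_CODE
  for (aa in names(metatx:::CODON_TABLE)) {
    expect_true(all(gc[metatx:::CODON_TABLE[[aa]]] == aa), info = aa)
  }
  expect_setequal(names(metatx:::CODON_TABLE), setdiff(unique(gc), "*"))
})

test_that("simulated reads carry exact provenance at error rate zero", {
  ref <- generate_reference_db(4, 3, peptide_len = 80, seed = 101)
  sim <- simulate_reads(ref, n_reads = 50, read_len = 100, error_rate = 0,
                        seed = 102)
  expect_equal(nrow(sim$reads), 50)
  expect_true(all(nchar(sim$reads$sequence) == 100))
  for (i in seq_len(50)) {
    src <- ref$dna[[sim$truth$source_ref_id[i]]]
    seq <- sim$reads$sequence[i]
    if (sim$truth$strand[i] == "-") seq <- oracle_revcomp(seq)
    expect_true(grepl(seq, src, fixed = TRUE))
  }
  # determinism
  sim2 <- simulate_reads(ref, n_reads = 50, read_len = 100, error_rate = 0,
                         seed = 102)
  expect_identical(sim, sim2)
  expect_error(simulate_reads(ref, 10, read_len = 10000, seed = 1),
               "exceeds the shortest gene")
})

test_that("substitution rate matches the binomial oracle", {
  ref <- generate_reference_db(2, 2, peptide_len = 200, seed = 111)
  er <- 0.02
  sim <- simulate_reads(ref, n_reads = 400, read_len = 250, error_rate = er,
                        seed = 112)
  mismatches <- 0L; total <- 0L
  for (i in seq_len(nrow(sim$reads))) {
    src <- ref$dna[[sim$truth$source_ref_id[i]]]
    frag <- substring(src, sim$truth$offset[i], sim$truth$offset[i] + 249)
    seq <- sim$reads$sequence[i]
    if (sim$truth$strand[i] == "-") seq <- oracle_revcomp(seq)
    mismatches <- mismatches +
      sum(utf8ToInt(frag) != utf8ToInt(seq))
    total <- total + 250L
  }
  se <- sqrt(er * (1 - er) / total)
  expect_lt(abs(mismatches / total - er), 3 * se + 1e-9)
})

test_that("fabricated m8 hits miscall at the requested rate", {
  ref <- generate_reference_db(6, 4, peptide_len = 50, seed = 121)
  sim <- simulate_reads(ref, n_reads = 2000, read_len = 90, error_rate = 0,
                        seed = 122)
  m8 <- fabricate_m8(sim$truth, ref$db, miscall_rate = 0.2, seed = 123)
  expect_equal(nrow(m8), 2000)
  frac <- mean(m8$sseqid != sim$truth$source_ref_id)
  se <- sqrt(0.2 * 0.8 / 2000)
  expect_lt(abs(frac - 0.2), 3 * se)
  # rate 0: all correct; downstream species accuracy 1
  m0 <- fabricate_m8(sim$truth, ref$db, miscall_rate = 0, seed = 123)
  ann <- annotate_reads(best_hit_per_query(m0), ref$db, ref$hierarchy)$annotations
  acc <- evaluate_accuracy(ann, sim$truth)
  expect_equal(acc$accuracy[acc$level == "species"], 1)
  # fabricated output parses as m8 after writing
  tf <- withr::local_tempfile()
  write_m8(m8, tf)
  expect_equal(nrow(read_m8(tf)), 2000)
})

test_that("accuracy evaluation counts matches per level under both denominators", {
  truth <- data.frame(
    read_id = sprintf("r%d", 1:10),
    source_ref_id = "R", organism = "Genus_01 species_01",
    genus = "Genus_01", function_name = "fn_a",
    level1 = "Cat", level2 = "Sub", level3 = "Sys", level4 = "fn_a",
    strand = "+", offset = 1L, stringsAsFactors = FALSE)
  ann <- data.frame(
    read_id = sprintf("r%d", 1:9),
    ref_id = "R", organism = "Genus_01 species_01", genus = "Genus_01",
    function_name = "fn_a", level1 = "Cat", level2 = "Sub", level3 = "Sys",
    level4 = "fn_a", stringsAsFactors = FALSE)
  # default: unannotated read excluded, reported separately
  acc <- evaluate_accuracy(ann, truth)
  expect_equal(acc$n_evaluated[acc$level == "species"], 9)
  expect_equal(acc$accuracy[acc$level == "species"], 1)
  expect_equal(attr(acc, "unannotated"), 1L)
  # flag: counted as evaluated-and-incorrect
  acc2 <- evaluate_accuracy(ann, truth, include_unannotated = TRUE)
  expect_equal(acc2$n_evaluated[acc2$level == "species"], 10)
  expect_equal(acc2$accuracy[acc2$level == "species"], 0.9)

  # same genus, different species epithet: genus correct, species not
  ann_g <- ann
  ann_g$organism <- "Genus_01 species_99"
  accg <- evaluate_accuracy(ann_g, truth)
  expect_equal(accg$accuracy[accg$level == "species"], 0)
  expect_equal(accg$accuracy[accg$level == "genus"], 1)

  # exact function implies correctness at levels 1-3
  accf <- evaluate_accuracy(ann, truth)
  fn_acc <- accf$accuracy[accf$level == "function"]
  for (lv in c("level1", "level2", "level3")) {
    expect_gte(accf$accuracy[accf$level == lv], fn_acc)
  }
  expect_error(evaluate_accuracy(ann[0, ], truth), "intersection")
})

test_that("accuracy ordering invariants hold across fabricated miscall rates", {
  ref <- generate_reference_db(5, 4, peptide_len = 60, seed = 131)
  sim <- simulate_reads(ref, n_reads = 500, read_len = 100, error_rate = 0,
                        seed = 132)
  for (rate in c(0, 0.3, 0.8)) {
    m8 <- fabricate_m8(sim$truth, ref$db, miscall_rate = rate, seed = 133)
    ann <- annotate_reads(best_hit_per_query(m8), ref$db,
                          ref$hierarchy)$annotations
    acc <- evaluate_accuracy(ann, sim$truth)
    a <- stats::setNames(acc$accuracy, acc$level)
    expect_gte(a[["genus"]], a[["species"]])
    for (lv in c("level1", "level2", "level3")) {
      expect_gte(a[[lv]], a[["function"]])
    }
  }
})

test_that("truth tables round-trip with their provenance headers", {
  ref <- generate_reference_db(3, 2, peptide_len = 60, seed = 141)
  sim <- simulate_reads(ref, n_reads = 20, read_len = 90, error_rate = 0,
                        seed = 142)
  tf <- withr::local_tempfile()
  write_truth(sim$truth, tf, seed = 142, params = "n_reads=20")
  lines <- readLines(tf)
  expect_equal(lines[1], "# seed=142")
  expect_equal(lines[2], "# params=n_reads=20")
  back <- read_truth(tf)
  expect_equal(back$read_id, sim$truth$read_id)
  expect_equal(back$source_ref_id, sim$truth$source_ref_id)
  expect_equal(back$level1, sim$truth$level1)
})
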