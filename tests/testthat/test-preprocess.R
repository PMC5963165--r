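test_that("FASTQ round trip is byte-exact", {
  reads <- fixture_fastq(n = 6, len = 30, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f1)
  write_fastq(read_fastq(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(read_fastq(f1), reads)
})

test_that("paired reads merge on their overlap with length arithmetic", {
  # fwd AAAACCCC + rev CCCCGGGG (revcomp CCCCGGGG) overlap 4 -> 12-mer
  fwd <- data.frame(read_id = "p1", sequence = "AAAACCCC",
                    quality = "IIIIIIII", stringsAsFactors = FALSE)
  rev <- data.frame(read_id = "p1", sequence = "CCCCGGGG",
                    quality = "IIIIIIII", stringsAsFactors = FALSE)
  m <- merge_pairs(fwd, rev, min_overlap = 4, max_mismatch_rate = 0)
  expect_equal(nrow(m$merged), 1)
  expect_equal(m$merged$sequence, "AAAACCCCGGGG")
  expect_equal(nchar(m$merged$sequence), 8 + 8 - 4)

  # non-overlapping pair goes to both notCombined outputs unchanged
  rev2 <- data.frame(read_id = "p2", sequence = "TTTTTTTT",
                     quality = "IIIIIIII", stringsAsFactors = FALSE)
  m2 <- merge_pairs(fwd, rev2, min_overlap = 4, max_mismatch_rate = 0)
  expect_equal(nrow(m2$merged), 0)
  expect_equal(m2$notCombined_fwd$sequence, fwd$sequence)
  expect_equal(m2$notCombined_rev$sequence, rev2$sequence)

  expect_error(merge_pairs(fwd, rbind(rev, rev2)), "different read counts")
})

test_that("disagreeing overlap bases resolve by higher quality", {
  # fwd ends ...CCCA, revcomp(rev) begins CCCC; the disagreeing base has
  # higher quality on the reverse read
  fwd <- data.frame(read_id = "p", sequence = "AAAACCCA",
                    quality = "IIIIIII#", stringsAsFactors = FALSE)
  rev <- data.frame(read_id = "p", sequence = "CCCCGGGG",
                    quality = "IIIIIIII", stringsAsFactors = FALSE)
  m <- merge_pairs(fwd, rev, min_overlap = 4, max_mismatch_rate = 0.25)
  expect_equal(m$merged$sequence, "AAAACCCCGGGG")
})

test_that("merging partitions pairs and trimming partitions reads", {
  withr::with_seed(21, {
    n <- 30
    fwd <- fixture_fastq(n, len = 40, seed = 22)
    frag_tail <- substring(fwd$sequence, 21, 40)
    rev_seq <- vapply(seq_len(n), function(i) {
      if (i %% 3 == 0) {
        # unrelated read: no overlap
        paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
      } else {
        oracle_revcomp(paste0(frag_tail[i],
                              paste(sample(c("A", "C", "G", "T"), 20,
                                           replace = TRUE), collapse = "")))
      }
    }, "")
    rev <- data.frame(read_id = fwd$read_id, sequence = rev_seq,
                      quality = strrep("I", 40), stringsAsFactors = FALSE)
    m <- merge_pairs(fwd, rev, min_overlap = 10, max_mismatch_rate = 0.1)
    expect_equal(nrow(m$merged) + nrow(m$notCombined_fwd), n)
    expect_equal(nrow(m$notCombined_fwd), nrow(m$notCombined_rev))

    tr <- quality_trim(fwd, window = 4, mean_q = 15, min_len = 20)
    expect_equal(nrow(tr$reads) + nrow(tr$dropped), n)
  })
})

test_that("quality trimming clips at the first failing window (oracle check)", {
  high <- fixture_fastq(1, len = 50, q = "I", seed = 31)
  expect_equal(quality_trim(high, min_len = 10)$reads$sequence, high$sequence)

  # quality collapses to Phred 2 ('#') halfway: clip where the oracle says
  mixed <- high
  mixed$quality <- paste0(strrep("I", 25), strrep("#", 25))
  cut <- oracle_trim_cut(mixed$quality, window = 4, mean_q = 15)
  tr <- quality_trim(mixed, window = 4, mean_q = 15, min_len = 10)
  expect_equal(nchar(tr$reads$sequence), cut)
  expect_equal(tr$reads$sequence, substring(mixed$sequence, 1, cut))

  # randomized qualities agree with the brute-force window scan
  withr::with_seed(32, {
    for (rep in 1:20) {
      qual <- intToUtf8(33 + sample(0:40, 60, replace = TRUE), multiple = FALSE)
      rd <- data.frame(read_id = "r", sequence = strrep("A", 60),
                       quality = qual, stringsAsFactors = FALSE)
      cut <- oracle_trim_cut(qual, window = 5, mean_q = 20)
      tr <- quality_trim(rd, window = 5, mean_q = 20, min_len = 0)
      got_len <- if (nrow(tr$reads) > 0) nchar(tr$reads$sequence) else
        nchar(tr$dropped$sequence) * 0
      expect_equal(got_len, cut)
    }
  })

  # all-low-quality read is dropped entirely
  low <- high
  low$quality <- strrep("#", 50)
  tr <- quality_trim(low, min_len = 10)
  expect_equal(nrow(tr$reads), 0)
  expect_equal(nrow(tr$dropped), 1)
})

test_that("adapter prefixes are clipped by exact match", {
  rd <- data.frame(read_id = "r", sequence = "ACGTACGTAAAAACCCCC",
                   quality = strrep("I", 18), stringsAsFactors = FALSE)
  tr <- quality_trim(rd, min_len = 5, adapters = "ACGTACGT")
  expect_equal(tr$reads$sequence, "AAAAACCCCC")
})

test_that("rRNA k-mer screen partitions reads by reference membership", {
  withr::with_seed(41, {
    rrna <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                  collapse = "")
    ref <- data.frame(sequence = rrna, stringsAsFactors = FALSE)
    ribo_read <- data.frame(read_id = "ribo", sequence = substring(rrna, 10, 80),
                            quality = strrep("I", 71), stringsAsFactors = FALSE)
    ribo_rc <- data.frame(read_id = "ribo_rc",
                          sequence = oracle_revcomp(substring(rrna, 10, 80)),
                          quality = strrep("I", 71), stringsAsFactors = FALSE)
    other_read <- fixture_fastq(1, len = 71, seed = 42)
    reads <- rbind(ribo_read, ribo_rc, other_read)
    out <- rrna_filter(reads, ref, k = 21, hit_fraction = 0.10)
    expect_setequal(out$ribosomal$read_id, c("ribo", "ribo_rc"))
    expect_equal(out$other$read_id, other_read$read_id)
    expect_equal(nrow(out$ribosomal) + nrow(out$other), nrow(reads))
    expect_error(rrna_filter(reads, ref[0, , drop = FALSE]), "empty")
  })
})
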