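make_matrix <- function(counts, groups) {
  # counts: named list sample -> named count vector
  tables <- lapply(names(counts), function(s)
    abundance_from_counts(counts[[s]], s))
  build_count_matrix(tables, groups)
}

test_that("count matrices assemble with zero fill, filters and validation", {
  cm <- make_matrix(
    list(s1 = c(A = 5), s2 = c(B = 7)),
    c(s1 = "control", s2 = "experimental"))
  expect_equal(dim(cm$counts), c(2, 2))
  expect_equal(cm$counts["A", "s2"], 0L)
  expect_equal(cm$counts["B", "s1"], 0L)
  # column sums equal the source table totals
  expect_equal(unname(colSums(cm$counts)), c(5, 7))
  # min_total filter excludes from testing but not from the raw matrix
  cm2 <- make_matrix(
    list(s1 = c(A = 2, B = 50), s2 = c(A = 2, B = 60)),
    c(s1 = "control", s2 = "experimental"))
  expect_false("A" %in% cm2$test_features)
  expect_true("A" %in% rownames(cm2$counts))

  t1 <- abundance_from_counts(c(A = 1), "s1")
  expect_error(build_count_matrix(list(t1, t1), c(s1 = "g")), "duplicate sample")
  expect_error(build_count_matrix(list(t1), c(zz = "g")), "without a group")
})

test_that("median-of-ratios size factors recover library-size ratios", {
  withr::with_seed(51, {
    base <- stats::rpois(30, 50) + 1
    names(base) <- sprintf("f%02d", 1:30)
    cm <- make_matrix(list(a = base, b = base * 2L),
                      c(a = "control", b = "experimental"))
    nz <- normalize_counts(cm)
    expect_equal(nz$method, "median_of_ratios")
    expect_equal(nz$size_factors[["b"]] / nz$size_factors[["a"]], 2)
    expect_equal(nz$normalized[, "a"], nz$normalized[, "b"])
    # identical samples -> unit size factors
    cmi <- make_matrix(list(a = base, b = base),
                       c(a = "control", b = "experimental"))
    expect_equal(unname(normalize_counts(cmi)$size_factors), c(1, 1))
    # cross-check against the reference implementation of the same estimator
    sf_ref <- DESeq2::estimateSizeFactorsForMatrix(cm$counts)
    expect_equal(unname(nz$size_factors), unname(sf_ref), tolerance = 1e-8)
  })
})

test_that("too few shared features triggers the total-count fallback", {
  cm <- make_matrix(list(a = c(X = 10, Y = 5), b = c(X = 20, Z = 10)),
                    c(a = "control", b = "experimental"))
  expect_message(nz <- normalize_counts(cm), "total-count")
  expect_equal(nz$method, "total_count")
  expect_equal(nz$size_factors[["b"]] / nz$size_factors[["a"]], 2)
})

test_that("diversity indices match their closed forms", {
  m <- cbind(u = c(25, 25, 25, 25), two = c(50, 50, 0, 0),
             one = c(100, 0, 0, 0), zero = c(0, 0, 0, 0))
  rownames(m) <- paste0("f", 1:4)
  d <- sample_diversity(m)
  expect_equal(d$richness, c(4L, 2L, 1L, 0L))
  expect_equal(d$shannon, c(log(4), log(2), 0, 0))
  expect_equal(d$simpson, c(0.75, 0.5, 0, 0))
  expect_true(all(d$shannon <= log(pmax(d$richness, 1)) + 1e-12))
})

test_that("PCA coordinates preserve sample distances (eigen oracle)", {
  withr::with_seed(61, {
    counts <- matrix(stats::rpois(40 * 4, 60) + 1, nrow = 40,
                     dimnames = list(sprintf("f%02d", 1:40), paste0("s", 1:4)))
    counts[, 2] <- counts[, 1] # byte-identical pair
    cm <- structure(list(counts = counts,
                         groups = stats::setNames(rep(c("a", "b"), 2),
                                                  colnames(counts)),
                         key_kind = "organism", min_total = 5,
                         test_features = rownames(counts)),
                    class = "count_matrix")
    pc <- pca_coordinates(cm)
    # identical samples land on the same point in every component
    expect_equal(unname(pc$coordinates["s1", ]), unname(pc$coordinates["s2", ]))
    # variance fractions are non-increasing and sum to <= 1
    expect_true(all(diff(pc$variance_fraction) <= 1e-12))
    expect_lte(sum(pc$variance_fraction), 1 + 1e-12)
    # distances in coordinate space equal distances of the transformed data
    x <- log2(normalize_counts(cm)$normalized + 1)
    x <- x - rowMeans(x)
    expect_equal(unname(as.matrix(stats::dist(pc$coordinates))),
                 unname(as.matrix(stats::dist(t(x)))), tolerance = 1e-8)
    # duplicating every sample leaves pairwise distances unchanged
    counts2 <- cbind(counts, counts)
    colnames(counts2) <- c(colnames(counts), paste0(colnames(counts), "_dup"))
    cm2 <- cm; cm2$counts <- counts2
    cm2$groups <- stats::setNames(rep(cm$groups, 2), colnames(counts2))
    pc2 <- pca_coordinates(cm2)
    d1 <- as.matrix(stats::dist(pc$coordinates))[1:4, 1:4]
    d2 <- as.matrix(stats::dist(pc2$coordinates))[1:4, 1:4]
    expect_equal(unname(d2), unname(d1), tolerance = 1e-8)
    expect_error(pca_coordinates(cm$counts[, 1, drop = FALSE]), "2 samples")
  })
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(71, {
    for (rep in 1:50) {
      p <- stats::runif(sample(1:40, 1))
      expect_equal(bh_adjust(p), oracle_bh_stepup(p))
    }
  })
})

test_that("a spiked feature dominates differential results (formula oracle)", {
  nullc <- stats::setNames(rep(20L, 19), sprintf("null%02d", 1:19))
  ctrl <- list(c1 = c(nullc, spike = 10L), c2 = c(nullc, spike = 12L),
               c3 = c(nullc, spike = 11L), c4 = c(nullc, spike = 9L))
  expc <- list(e1 = c(nullc, spike = 80L), e2 = c(nullc, spike = 95L),
               e3 = c(nullc, spike = 88L), e4 = c(nullc, spike = 102L))
  groups <- stats::setNames(rep(c("control", "experimental"), each = 4),
                            c(names(ctrl), names(expc)))
  cm <- make_matrix(c(ctrl, expc), groups)
  res <- differential_activity(cm)
  expect_equal(res$feature[1], "spike")
  expect_equal(res$q_value[1], min(res$q_value))

  # oracle: size factors are 1 by construction (19 identical null features),
  # so recompute Welch t and log2fc from first principles
  a <- log2(c(10, 12, 11, 9) + 1)
  b <- log2(c(80, 95, 88, 102) + 1)
  se <- sqrt(stats::var(a) / 4 + stats::var(b) / 4)
  tstat <- (mean(b) - mean(a)) / se
  df <- se^4 / ((stats::var(a) / 4)^2 / 3 + (stats::var(b) / 4)^2 / 3)
  p_oracle <- 2 * stats::pt(-abs(tstat), df)
  spike_row <- res[res$feature == "spike", ]
  expect_equal(spike_row$log2fc, mean(b) - mean(a), tolerance = 1e-10)
  expect_equal(spike_row$log2fc, 3.1, tolerance = 0.05)
  expect_equal(spike_row$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(spike_row$base_mean_control, mean(c(10, 12, 11, 9)))

  # constant features get p = 1; q >= p and BH-monotone ordering hold
  expect_true(all(res$p_value[res$feature != "spike"] == 1))
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  # permuting sample order changes no p-value
  perm <- c(ctrl, expc)[c(3, 1, 4, 2, 7, 5, 8, 6)]
  res_p <- differential_activity(make_matrix(perm, groups))
  expect_equal(res_p$p_value[match(res$feature, res_p$feature)], res$p_value)

  # a group with < 2 samples refuses with guidance
  small <- make_matrix(c(ctrl[1], expc), groups)
  expect_error(differential_activity(small), "2 samples")
})

test_that("summary tables: stacked-bar, distances and pie fractions", {
  withr::with_seed(81, {
    counts <- matrix(stats::rpois(12 * 4, 40) + 1, nrow = 12,
                     dimnames = list(sprintf("f%02d", 1:12), paste0("s", 1:4)))
    cm <- structure(list(counts = counts,
                         groups = stats::setNames(rep(c("a", "b"), 2),
                                                  colnames(counts)),
                         key_kind = "genus", min_total = 5,
                         test_features = rownames(counts)),
                    class = "count_matrix")
    st <- summary_tables(cm, n = 5)
    expect_equal(nrow(st$top_relative), 6) # 5 + other
    expect_equal(unname(colSums(st$top_relative)), rep(100, 4),
                 tolerance = 0.01)
    expect_equal(unname(colSums(st$top_absolute)),
                 unname(colSums(counts)))
    expect_true(isSymmetric(st$distances))
    expect_equal(unname(diag(st$distances)), rep(0, 4))
    # n >= #features -> all-zero other row
    st_all <- summary_tables(cm, n = 20)
    expect_equal(unname(st_all$top_absolute["other", ]), rep(0, 4))
    expect_equal(unname(colSums(st$pie_fractions)), rep(100, 4),
                 tolerance = 0.01)
  })
})

test_that("count matrix TSV round-trips byte-exactly", {
  cm <- make_matrix(
    list(s1 = c(A = 5, B = 9), s2 = c(B = 7, C = 3)),
    c(s1 = "control", s2 = "experimental"))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_count_matrix(cm, f1)
  back <- read_count_matrix(f1)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$groups, cm$groups)
  write_count_matrix(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})
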