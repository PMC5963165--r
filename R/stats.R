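# Cross-sample statistics: count matrices, median-of-ratios normalization,
# diversity indices, PCA coordinates, and two-group differential activity
# with Benjamini-Hochberg FDR control.
#
# The differential test is a deliberately simple, fully specified
# procedure: per-feature Welch t-test on log2(normalized count + 1), BH
# adjusted. It is not intended to reproduce negative-binomial shrinkage
# estimators numerically; the count matrix interchange TSV lets users hand
# the same counts to any external differential framework.

#' Assemble per-sample abundance tables into a count matrix
#'
#' Features are the union of names across tables; absent cells are 0. A
#' low-count filter marks features whose total count is below `min_total`
#' as excluded from testing (they stay in the raw matrix).
#'
#' @param tables List of `abundance_table`s, one per sample, sharing a
#'   `key_kind`; sample ids are taken from the tables.
#' @param groups Named character vector mapping every sample id to a group
#'   label (two groups, e.g. control / experimental, for differential use).
#' @param min_total Minimum feature total to enter the test set (default 5).
#' @return A `count_matrix` object: integer matrix `counts`
#'   (features x samples), `groups`, `key_kind`, and `test_features`.
#' @export
build_count_matrix <- function(tables, groups, min_total = 5) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "abundance_table")))
  kinds <- unique(vapply(tables, `[[`, "", "key_kind"))
  if (length(kinds) != 1) {
    stop("all tables must share one key_kind; found: ",
         paste(kinds, collapse = ", "))
  }
  samples <- vapply(tables, `[[`, "", "sample_id")
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ", samples[duplicated(samples)][1])
  }
  if (!all(samples %in% names(groups))) {
    stop("samples without a group label: ",
         paste(setdiff(samples, names(groups)), collapse = ", "))
  }
  features <- sort(unique(unlist(lapply(tables, function(t) t$rows$name))),
                   method = "radix")
  counts <- matrix(0L, nrow = length(features), ncol = length(samples),
                   dimnames = list(features, samples))
  for (j in seq_along(tables)) {
    r <- tables[[j]]$rows
    counts[match(r$name, features), j] <- r$count
  }
  structure(list(counts = counts,
                 groups = groups[samples],
                 key_kind = kinds,
                 min_total = min_total,
                 test_features = features[rowSums(counts) >= min_total]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " ", x$key_kind, " features x ",
      ncol(x$counts), " samples (", length(x$test_features),
      " pass the min_total=", x$min_total, " filter)\n", sep = "")
  invisible(x)
}

#' Median-of-ratios library-size normalization
#'
#' Size factors are per-sample medians of count ratios to a geometric-mean
#' reference built over features nonzero in every sample. When fewer than
#' 10 such shared features exist the reference is unstable, and the method
#' falls back to total-count scaling (factors proportional to column sums,
#' geometric mean 1); the fallback is reported in the returned `method`.
#'
#' @param matrix A `count_matrix`, or a bare numeric matrix.
#' @return A list: `normalized` (counts / size factor, per column),
#'   `size_factors`, `method` (`"median_of_ratios"` or `"total_count"`).
#' @export
normalize_counts <- function(matrix) {
  counts <- if (inherits(matrix, "count_matrix")) matrix$counts else matrix
  shared <- rowSums(counts == 0) == 0
  if (sum(shared) >= 10) {
    logc <- log(counts[shared, , drop = FALSE])
    ref <- exp(rowMeans(logc))
    sf <- apply(counts[shared, , drop = FALSE], 2, function(col)
      stats::median(col / ref))
    method <- "median_of_ratios"
  } else {
    libs <- colSums(counts)
    if (any(libs == 0)) libs[libs == 0] <- 1
    sf <- libs / exp(mean(log(libs)))
    method <- "total_count"
    message("fewer than 10 features nonzero in all samples; ",
            "falling back to total-count size factors")
  }
  list(normalized = sweep(counts, 2, sf, "/"),
       size_factors = sf, method = method)
}

#' Per-sample diversity statistics
#'
#' Richness (number of nonzero features), Shannon entropy (natural log) and
#' the Gini-Simpson index `1 - sum(p^2)`, computed on each sample's count
#' proportions. All-zero samples get zeros throughout.
#'
#' @param matrix A `count_matrix` or numeric matrix (features x samples).
#' @return A data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `simpson`.
#' @export
sample_diversity <- function(matrix) {
  counts <- if (inherits(matrix, "count_matrix")) matrix$counts else matrix
  res <- lapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    if (sum(x) == 0) {
      return(data.frame(richness = 0L, shannon = 0, simpson = 0))
    }
    data.frame(richness = sum(x > 0),
               shannon = unname(vegan::diversity(x, index = "shannon")),
               simpson = unname(vegan::diversity(x, index = "simpson")))
  })
  cbind(data.frame(sample_id = colnames(counts), stringsAsFactors = FALSE),
        do.call(rbind, res))
}

log_norm <- function(matrix) {
  log2(normalize_counts(matrix)$normalized + 1)
}

#' PCA coordinates of samples
#'
#' Samples are projected by singular value decomposition of the
#' feature-centered `log2(normalized + 1)` matrix; the transformation is
#' distance-preserving, so sample-to-sample Euclidean distances in full
#' coordinate space equal those of the transformed data.
#'
#' @param matrix A `count_matrix` (>= 2 samples).
#' @param n_components Number of components to return (default: all).
#' @return A list: `coordinates` (samples x components) and
#'   `variance_fraction` (non-increasing, sums to <= 1).
#' @export
pca_coordinates <- function(matrix, n_components = NULL) {
  counts <- if (inherits(matrix, "count_matrix")) matrix$counts else matrix
  if (ncol(counts) < 2) stop("PCA needs at least 2 samples")
  x <- log_norm(counts)
  x <- x - rowMeans(x)
  pr <- stats::prcomp(t(x), center = FALSE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  var_frac <- if (total_var > 0) pr$sdev^2 / total_var else
    rep(0, length(pr$sdev))
  k <- min(n_components %||% length(var_frac), ncol(pr$x))
  list(coordinates = pr$x[, seq_len(k), drop = FALSE],
       variance_fraction = var_frac[seq_len(k)])
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j>=i) m p_(j) / j`, capped at 1,
#' returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group differential activity
#'
#' Per feature (after the low-count filter), a two-sided Welch t-test on
#' `log2(normalized count + 1)` compares the experimental against the
#' control group; `log2fc` is the difference of group means on that scale,
#' and q-values come from [bh_adjust()]. Features that are constant across
#' all samples get p = 1; the degenerate case of two zero-variance groups
#' with different means gets p = 0. Results are sorted by (q, p, feature)
#' for deterministic output files.
#'
#' @param matrix A `count_matrix` with two group labels and >= 2 samples in
#'   each group.
#' @param control,experimental Group labels; by default the first label in
#'   sorted order is control and the second experimental.
#' @return A data.frame: `feature`, `base_mean_control`,
#'   `base_mean_experimental` (normalized-scale means), `log2fc`,
#'   `p_value`, `q_value`.
#' @export
differential_activity <- function(matrix, control = NULL, experimental = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  labels <- sort(unique(unname(matrix$groups)))
  if (length(labels) != 2) {
    stop("differential testing needs exactly 2 group labels; found ",
         length(labels))
  }
  control <- control %||% labels[1]
  experimental <- experimental %||% labels[2]
  ctrl <- names(matrix$groups)[matrix$groups == control]
  expr <- names(matrix$groups)[matrix$groups == experimental]
  if (length(ctrl) < 2 || length(expr) < 2) {
    stop("each group needs >= 2 samples for testing; ",
         "use descriptive output (abundance tables, summaries) instead")
  }
  norm <- normalize_counts(matrix)$normalized
  x <- log2(norm + 1)
  feats <- matrix$test_features
  res <- lapply(feats, function(f) {
    a <- x[f, ctrl]; b <- x[f, expr]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      p <- stats::t.test(b, a, var.equal = FALSE)$p.value
    }
    data.frame(feature = f,
               base_mean_control = mean(norm[f, ctrl]),
               base_mean_experimental = mean(norm[f, expr]),
               log2fc = mean(b) - mean(a),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$q_value, out$p_value, out$feature, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Summary tables backing the standard figures
#'
#' Produces the data behind the usual presentation graphics: a top-`n`
#' stacked-bar table (relative percentages per sample summing to 100, and
#' absolute counts) with an `"other"` remainder row, a sample-by-sample
#' Euclidean distance matrix on `log2(normalized + 1)` for heatmaps, and
#' per-sample fractions (pie data) over all features.
#'
#' @param matrix A `count_matrix`.
#' @param n Number of top features, ranked by mean normalized abundance.
#' @return A list: `top_relative`, `top_absolute`, `distances`,
#'   `pie_fractions`.
#' @export
summary_tables <- function(matrix, n = 10) {
  stopifnot(inherits(matrix, "count_matrix"), is_count(n, min = 1))
  counts <- matrix$counts
  norm <- normalize_counts(matrix)$normalized
  top <- names(sort(rowMeans(norm), decreasing = TRUE))[seq_len(min(n, nrow(norm)))]
  rest <- setdiff(rownames(counts), top)
  rel_all <- sweep(norm, 2, pmax(colSums(norm), .Machine$double.eps), "/") * 100
  stack_rows <- function(m) {
    rbind(m[top, , drop = FALSE],
          other = if (length(rest) > 0) colSums(m[rest, , drop = FALSE])
                  else rep(0, ncol(m)))
  }
  list(top_relative = stack_rows(rel_all),
       top_absolute = stack_rows(counts),
       distances = as.matrix(stats::dist(t(log2(norm + 1)))),
       pie_fractions = rel_all)
}

#' Write / read the count-matrix interchange TSV
#'
#' `# group:<sample>=<label>` header lines, then a `feature` + sample-id
#' header row and integer count rows. Byte-exact round trip; the
#' `min_total` filter setting is carried in a `# min_total=` line.
#'
#' @param matrix A `count_matrix`.
#' @param path File path.
#' @return `write_count_matrix`: `path`, invisibly. `read_count_matrix`: a
#'   `count_matrix`.
#' @export
write_count_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# group:%s=%s", names(matrix$groups),
                     unname(matrix$groups)), con)
  writeLines(paste0("# min_total=", matrix$min_total), con)
  writeLines(paste(c("feature", colnames(matrix$counts)), collapse = "\t"), con)
  if (nrow(matrix$counts) > 0) {
    body <- apply(matrix$counts, 1, paste, collapse = "\t")
    writeLines(paste(rownames(matrix$counts), body, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grp_lines <- grep("^# group:", lines, value = TRUE)
  kv <- sub("^# group:", "", grp_lines)
  groups <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  mt_line <- grep("^# min_total=", lines, value = TRUE)
  min_total <- if (length(mt_line) > 0) as.numeric(sub("^# min_total=", "", mt_line[1])) else 5
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0) stop("count matrix file ", path, ": no header row")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  feats <- vapply(rows, `[[`, "", 1)
  counts <- matrix(0L, nrow = length(feats), ncol = length(samples),
                   dimnames = list(feats, samples))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.integer(rows[[i]][-1]))
    if (length(v) != length(samples) || anyNA(v)) {
      stop("count matrix file ", path, ": malformed row for feature '",
           feats[i], "'")
    }
    counts[i, ] <- v
  }
  structure(list(counts = counts, groups = groups[samples],
                 key_kind = "unknown", min_total = min_total,
                 test_features = feats[rowSums(counts) >= min_total]),
            class = "count_matrix")
}
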