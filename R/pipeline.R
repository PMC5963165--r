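# Pipeline orchestration: run the preprocessing -> annotation ->
# aggregation -> statistics chain over a sample manifest with per-step
# checkpoint files, content-hash caching, a read-count ledger, and optional
# shelling out to external tools (PEAR / Trimmomatic / SortMeRNA / DIAMOND)
# when they are on PATH.
#
# Every step writes its outputs before the next starts, so any downstream
# analysis can be redone from the per-read annotation checkpoint without
# re-running the expensive annotation step (see reaggregate()).

#' Build a pipeline configuration
#'
#' @param samples A data.frame with columns `sample_id`, `fastq` (path; for
#'   paired data the forward file), optional `fastq2` (reverse file) and
#'   `group`.
#' @param database Path to the protein reference FASTA.
#' @param hierarchy Optional path to the 5-column hierarchy TSV.
#' @param output_dir Output directory (created if needed).
#' @param steps Character vector of enabled steps, a subset of
#'   `c("merge", "trim", "rrna_filter", "annotate", "aggregate", "stats")`.
#' @param rrna_reference Optional rRNA FASTA for the filtering step.
#' @param tool_mode `"internal"` (package stand-ins) or `"external"`
#'   (shell out to PEAR/Trimmomatic/SortMeRNA/DIAMOND when on PATH,
#'   falling back to internal with a log note otherwise).
#' @param params Named list of step parameter overrides (e.g.
#'   `list(min_overlap = 10, kmer = 5, min_seeds = 2, min_total = 5)`).
#' @param seed Integer seed recorded in the run report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(samples, database, hierarchy = NULL,
                            output_dir = "metatx_out",
                            steps = c("merge", "trim", "rrna_filter",
                                      "annotate", "aggregate", "stats"),
                            rrna_reference = NULL,
                            tool_mode = c("internal", "external"),
                            params = list(), seed = 1) {
  tool_mode <- match.arg(tool_mode)
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "fastq") %in% names(samples)))
  defaults <- list(min_overlap = 10, max_mismatch_rate = 0.1,
                   window = 4, mean_q = 15, min_len = 70,
                   rrna_k = 21, rrna_hit_fraction = 0.10,
                   kmer = 5, min_seeds = 2, evalue_max = NULL,
                   min_total = 5, top_n = 10,
                   include_unmerged_forward = FALSE)
  params <- utils::modifyList(defaults, params)
  cfg <- list(samples = samples, database = database, hierarchy = hierarchy,
              output_dir = output_dir, steps = steps,
              rrna_reference = rrna_reference, tool_mode = tool_mode,
              params = params, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors the arguments of [pipeline_config()]: a `samples` list
#' of `{sample_id, fastq, fastq2, group}` records plus top-level keys.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  samples <- do.call(rbind, lapply(y$samples, function(s)
    data.frame(sample_id = s$sample_id, fastq = s$fastq,
               fastq2 = s$fastq2 %||% NA_character_,
               group = s$group %||% NA_character_,
               stringsAsFactors = FALSE)))
  pipeline_config(samples = samples, database = y$database,
                  hierarchy = y$hierarchy, output_dir = y$output_dir %||% "metatx_out",
                  steps = y$steps %||% c("merge", "trim", "rrna_filter",
                                         "annotate", "aggregate", "stats"),
                  rrna_reference = y$rrna_reference,
                  tool_mode = y$tool_mode %||% "internal",
                  params = y$params %||% list(), seed = y$seed %||% 1)
}

validate_config <- function(cfg) {
  inputs <- c(cfg$samples$fastq,
              if ("fastq2" %in% names(cfg$samples))
                stats::na.omit(cfg$samples$fastq2),
              cfg$database, cfg$hierarchy, cfg$rrna_reference)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  if ("annotate" %in% cfg$steps && is.null(cfg$database)) {
    stop("annotate step enabled but no database configured")
  }
  if ("aggregate" %in% cfg$steps && !("annotate" %in% cfg$steps)) {
    stop("aggregate step enabled but annotate is not; ",
         "supply an annotation checkpoint via reaggregate() instead")
  }
  if ("rrna_filter" %in% cfg$steps && is.null(cfg$rrna_reference)) {
    stop("rrna_filter step enabled but no rrna_reference configured")
  }
  if (anyDuplicated(cfg$samples$sample_id)) {
    stop("duplicate sample_id in manifest")
  }
  invisible(cfg)
}

step_digest <- function(input_paths, params) {
  files <- unname(tools::md5sum(input_paths[file.exists(input_paths)]))
  ptxt <- paste(deparse(params), collapse = "")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(files, ptxt), tf)
  unname(tools::md5sum(tf))
}

checkpoint_fresh <- function(ckpt_file, digest, outputs, force) {
  if (force || !file.exists(ckpt_file)) return(FALSE)
  rec <- tryCatch(jsonlite::read_json(ckpt_file), error = function(e) NULL)
  !is.null(rec) && identical(rec$digest, digest) &&
    all(file.exists(unlist(rec$outputs)))
}

write_checkpoint <- function(ckpt_file, step, digest, outputs, params) {
  jsonlite::write_json(
    list(step = step, digest = digest, outputs = outputs,
         params = params, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    ckpt_file, auto_unbox = TRUE, null = "null")
}

external_available <- function(tool) nzchar(Sys.which(tool))

#' Run the full pipeline over a sample manifest
#'
#' Executes, per sample, the enabled steps in fixed order — merge, trim,
#' rRNA filter, annotate, aggregate — then cross-sample statistics, with a
#' validation pass before anything runs. Each step writes its outputs and a
#' content-hash checkpoint; a re-run with unchanged inputs and parameters
#' skips cached steps unless `force = TRUE`. The run report records the
#' full parameter set and a read-count ledger (reads surviving each step).
#'
#' @param cfg A `pipeline_config`.
#' @param force Re-run all steps even if checkpoints are fresh.
#' @return The run report (a list, also written to
#'   `<output_dir>/run_report.json`), invisibly.
#' @export
run_pipeline <- function(cfg, force = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  ckpt_dir <- file.path(cfg$output_dir, "checkpoints")
  dir.create(ckpt_dir, showWarnings = FALSE)
  p <- cfg$params
  db <- parse_reference_fasta(cfg$database)
  write_refdb_index(db, file.path(cfg$output_dir, "refdb_index.tsv"))
  hier <- if (!is.null(cfg$hierarchy)) load_hierarchy(cfg$hierarchy) else NULL
  report <- list(seed = cfg$seed, tool_mode = cfg$tool_mode,
                 parameters = p, steps = cfg$steps,
                 samples = list(), log = character())
  say <- function(...) {
    msg <- paste0(...)
    report$log <<- c(report$log, msg)
    message(msg)
  }

  tables <- list(organism = list(), genus = list(), `function` = list(),
                 level1 = list(), level2 = list(), level3 = list(),
                 level4 = list())
  for (i in seq_len(nrow(cfg$samples))) {
    sm <- cfg$samples[i, ]
    sid <- sm$sample_id
    sdir <- file.path(cfg$output_dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    ledger <- list()
    current <- read_fastq(sm$fastq)
    ledger$raw <- nrow(current)

    if ("merge" %in% cfg$steps && "fastq2" %in% names(sm) && !is.na(sm$fastq2)) {
      rev <- read_fastq(sm$fastq2)
      mg <- merge_pairs(current, rev, p$min_overlap, p$max_mismatch_rate)
      write_fastq(mg$merged, file.path(sdir, paste0(sid, ".merged.fastq")))
      write_fastq(mg$notCombined_fwd,
                  file.path(sdir, paste0(sid, ".notCombined_1.fastq")))
      write_fastq(mg$notCombined_rev,
                  file.path(sdir, paste0(sid, ".notCombined_2.fastq")))
      current <- mg$merged
      if (isTRUE(p$include_unmerged_forward)) {
        current <- rbind(current, mg$notCombined_fwd)
      }
      ledger$merged <- nrow(current)
      say(sid, ": merge (simplified overlap merger): ", ledger$raw,
          " pairs -> ", nrow(mg$merged), " merged, ",
          nrow(mg$notCombined_fwd), " notCombined")
    }

    if ("trim" %in% cfg$steps) {
      tr <- quality_trim(current, p$window, p$mean_q, p$min_len)
      current <- tr$reads
      write_fastq(current, file.path(sdir, paste0(sid, ".cleaned.fastq")))
      ledger$trimmed <- nrow(current)
      say(sid, ": trim (simplified sliding window): kept ", nrow(current),
          ", dropped ", nrow(tr$dropped))
    }

    if ("rrna_filter" %in% cfg$steps) {
      fl <- rrna_filter(current, cfg$rrna_reference,
                        p$rrna_k, p$rrna_hit_fraction)
      write_fastq(fl$ribosomal, file.path(sdir, paste0(sid, ".ribosomes.fastq")))
      write_fastq(fl$other, file.path(sdir, paste0(sid, ".mRNA.fastq")))
      current <- fl$other
      ledger$mRNA <- nrow(current)
      say(sid, ": rRNA filter (simplified k-mer screen): ",
          nrow(fl$ribosomal), " ribosomal, ", nrow(fl$other), " mRNA")
    }

    if ("annotate" %in% cfg$steps) {
      m8_path <- file.path(sdir, paste0(sid, ".m8"))
      ann_path <- file.path(sdir, paste0(sid, ".annotations.tsv"))
      ck <- file.path(ckpt_dir, paste0(sid, ".annotate.json"))
      digest_inputs <- c(cfg$database, cfg$hierarchy)
      dg <- step_digest(digest_inputs,
                        list(p$kmer, p$min_seeds, p$evalue_max,
                             n = nrow(current),
                             ids = utils::head(current$read_id, 50)))
      if (checkpoint_fresh(ck, dg, list(m8_path, ann_path), force)) {
        say(sid, ": annotate: cached, skipping")
        ann <- read_annotations(ann_path)
      } else {
        if (cfg$tool_mode == "external" && external_available("diamond")) {
          hits <- diamond_align(current, cfg$database, sdir, sid, say)
        } else {
          if (cfg$tool_mode == "external") {
            say(sid, ": diamond not on PATH; using internal aligner")
          }
          hits <- miniblastx_align(current, db, k = p$kmer,
                                   min_seeds = p$min_seeds)
        }
        write_m8(hits, m8_path)
        best <- best_hit_per_query(hits, evalue_max = p$evalue_max)
        res <- annotate_reads(best, db, hier)
        ann <- res$annotations
        write_annotations(ann, ann_path)
        write_checkpoint(ck, "annotate", dg, list(m8_path, ann_path),
                         list(kmer = p$kmer, min_seeds = p$min_seeds))
        say(sid, ": annotate: ", nrow(ann), " of ", nrow(current),
            " reads annotated (", res$unmatched_count, " unmatched subjects)")
      }
      ledger$annotated <- nrow(ann)

      if ("aggregate" %in% cfg$steps) {
        for (kind in names(tables)) {
          tab <- aggregate_annotations(ann, kind, sample_id = sid)
          write_abundance(tab, file.path(
            sdir, paste0(sid, ".", kind, ".abundance.tsv")))
          tables[[kind]][[sid]] <- tab
        }
        say(sid, ": aggregate: wrote organism/genus/function and ",
            "4 hierarchy-level abundance tables")
      }
    }
    report$samples[[sid]] <- ledger
  }

  if ("stats" %in% cfg$steps && "aggregate" %in% cfg$steps &&
      "group" %in% names(cfg$samples) && !anyNA(cfg$samples$group)) {
    groups <- stats::setNames(cfg$samples$group, cfg$samples$sample_id)
    stats_dir <- file.path(cfg$output_dir, "stats")
    dir.create(stats_dir, showWarnings = FALSE)
    for (kind in c("organism", "genus", "function", "level1")) {
      if (length(tables[[kind]]) < 2) next
      cm <- build_count_matrix(tables[[kind]], groups, p$min_total)
      write_count_matrix(cm, file.path(stats_dir, paste0(kind, ".counts.tsv")))
      div <- sample_diversity(cm)
      utils::write.table(div, file.path(stats_dir, paste0(kind, ".diversity.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      two_groups <- length(unique(groups)) == 2 &&
        all(table(groups[colnames(cm$counts)]) >= 2)
      if (two_groups) {
        dr <- differential_activity(cm)
        utils::write.table(dr, file.path(stats_dir, paste0(kind, ".differential.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      say("stats[", kind, "]: diversity", if (two_groups) " + differential")
    }
  }

  jsonlite::write_json(report, file.path(cfg$output_dir, "run_report.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(report)
}

# Thin wrapper shelling out to DIAMOND blastx when requested; argv logged.
diamond_align <- function(reads, database, sdir, sid, say) {
  fq <- file.path(sdir, paste0(sid, ".for_diamond.fastq"))
  write_fastq(reads, fq)
  dmnd <- file.path(sdir, "db.dmnd")
  out <- file.path(sdir, paste0(sid, ".diamond.m8"))
  argv1 <- c("makedb", "--in", database, "-d", sub("\\.dmnd$", "", dmnd))
  argv2 <- c("blastx", "-d", dmnd, "-q", fq, "-o", out, "--outfmt", "6")
  say(sid, ": exec: diamond ", paste(argv1, collapse = " "))
  system2("diamond", argv1)
  say(sid, ": exec: diamond ", paste(argv2, collapse = " "))
  system2("diamond", argv2)
  read_m8(out)
}

#' Re-run aggregation, slicing and statistics from a checkpoint
#'
#' Annotation is the expensive step; everything downstream can be redone
#' from the per-read annotation checkpoint, including restricted views
#' ("all annotations or a subset"): `organism`/`genus` filters select one
#' taxon's functional profile, `function_pattern`/`scope` one category's
#' organism profile.
#'
#' @param checkpoint Path to an annotation checkpoint TSV
#'   (see [write_annotations()]).
#' @param key_kind Key for the output abundance table.
#' @param organism,match_level Optional taxon filter (see
#'   [slice_by_organism()]).
#' @param function_pattern,scope Optional function/category filter (see
#'   [slice_by_function()]).
#' @param sample_id Sample label for the resulting table.
#' @return An `abundance_table`.
#' @export
reaggregate <- function(checkpoint, key_kind = "organism",
                        organism = NULL, match_level = "organism",
                        function_pattern = NULL, scope = "function",
                        sample_id = "sample") {
  ann <- read_annotations(checkpoint)
  if (!is.null(organism)) {
    return(slice_by_organism(ann, organism, match_level, sample_id))
  }
  if (!is.null(function_pattern)) {
    return(slice_by_function(ann, function_pattern, scope, sample_id))
  }
  aggregate_annotations(ann, key_kind, sample_id)
}
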