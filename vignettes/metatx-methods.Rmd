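---
title: "metatx: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metatx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metatx)
```

# The analysis problem

A metatranscriptome is the pooled RNA of a mixed microbial community,
sequenced in bulk. Two questions dominate its analysis: *who* is
transcriptionally active (organism profile) and *what* they are doing
(functional profile). The standard read-based strategy answers both at
once: align each mRNA read against a protein reference database whose
entries carry an organism and a function in their FASTA headers, keep one
best alignment per read, and count. Because a single sample can hit
hundreds of thousands of distinct specific functions, functions are also
rolled up through a four-level hierarchical ontology (level 1 the broadest
category, level 4 the specific function), where community-scale shifts
become visible even when no single function moves significantly.

`metatx` implements this whole chain at desk scale: reference-database
parsing, BLAST-tabular best-hit selection, per-read annotation with
hierarchy attachment, sorted abundance counts with organism/function data
slicing, cross-sample statistics, and — so the chain can be tested without
any external aligner or database download — a small translated-search
aligner and a seed-deterministic read simulator with a ground-truth
accuracy evaluator.

# Reference databases and the hierarchy table

Reference headers follow the `<id> <function name> [<organism>]`
convention. Two parsing rules are deliberately strict and documented
because real headers are messy:

* **Organism = last balanced bracket group.** Function names themselves may
  contain brackets (`chaperone [with internal] note [Escherichia coli]`),
  so the organism is taken from the *last* balanced `[...]` group and the
  function is everything between the id and that group. Unmatched brackets
  are ignored. Degenerate titles never error; they fall back to the
  sentinels `unknown_organism` / `unknown_function`.
* **Genus = first whitespace token of the organism.** Genus-level
  evaluation needs a genus, and the first token is the only extraction that
  needs no taxonomy service (`Escherichia coli O157` → `Escherichia`).

The hierarchy table is a 5-column TSV (`function_key`, `level4`, `level3`,
`level2`, `level1`, `#` comments allowed). Real hierarchical-ontology flat
files come in several layouts; this package standardises on one explicit
dialect and treats converters as out of scope. Keys are matched
case-insensitively after trimming — no fuzzy matching, because a silent
wrong match is worse than a reported miss. Empty intermediate levels
become `NO LEVEL`; a function absent from the table annotates as
`NO HIERARCHY` at all four levels and stays in every table as a real row.
A key listed under two different level-1 branches is rejected at load:
rollups would otherwise be ambiguous.

# Best hits and per-read annotation

Aligners may emit several hits per read; aggregation needs exactly one.
The retained hit maximises bitscore, with ties broken by minimal e-value,
then lexicographically smallest subject id, then first occurrence. The
chain matters: it makes annotation independent of input row order, so
re-running a pipeline reproduces files byte for byte. An optional e-value
ceiling can be applied before selection but is off by default — alignment
cutoffs belong to the aligner.

Hits whose subject id is missing from the database copy (a plausible
version skew between an m8 file and the FASTA it was made from) are
counted, reported via a warning, and excluded — never silently dropped and
never fatal. The per-read annotation checkpoint TSV (`read_id`, `ref_id`,
organism, genus, function, levels 1–4) is the pivot of the design: the
expensive annotation step runs once per database, and every aggregation,
slice or statistic can be recomputed from the checkpoint alone
(`reaggregate()`).

The hierarchy join key is the function *name*, not the reference id,
because the hierarchy table is keyed by function and one function string
may be shared by many database entries.

# The toy translated aligner

`miniblastx_search()` exists so the pipeline runs end to end with no
external binary. It is a transparent test harness, not a production
aligner:

* all six reading frames are translated (standard code, stops as `*`,
  `N`-containing codons as `X`, partial codons dropped);
* candidate references are found through exact peptide k-mer seeding
  (default `k = 5` amino acids); a candidate's score is the maximum over
  frames of the number of distinct seeded query positions, and candidates
  below `min_seeds = 2` are discarded;
* coordinates and percent identity come from an ungapped extension around
  the densest seed diagonal;
* the reported e-value is the surrogate `2^-score` — monotone in score and
  type-correct for m8, but **not** a statistical expectation value — and
  the bitscore is the seed score itself.

The defaults are tuned to the simulator's regime: a 150-nt read contributes
about 46 query 5-mers in its correct frame, so error-free reads score far
above `min_seeds`, while random peptides of unrelated genes essentially
never share two 5-mers. With substitution errors each amino-acid change
destroys up to *k* seeds, which produces the monotone score degradation the
tests assert. There is no gapped alignment, no reduced alphabet, no
frameshift handling.

# Preprocessing stand-ins

The merge / trim / rRNA-filter steps are simplified, fully specified
stand-ins for the dedicated tools a production run would use; the pipeline
can shell out to those tools instead (`tool_mode = "external"`) and logs
the exact argv when it does. The stand-ins are labelled "simplified" in
their log lines. Parameters, with units and defaults:

| step | parameter | default | meaning |
|---|---|---|---|
| merge | `min_overlap` | 10 nt | shortest acceptable overlap |
| merge | `max_mismatch_rate` | 0.1 | mismatch fraction tolerated in overlap |
| trim | `window` | 4 nt | sliding window width |
| trim | `mean_q` | 15 | minimum mean Phred quality per window |
| trim | `min_len` | 70 nt | shortest retained read |
| rRNA | `k` | 21 nt | screen k-mer length |
| rRNA | `hit_fraction` | 0.10 | k-mer hit fraction that flags ribosomal |

Merging scans overlaps longest-first and resolves disagreeing bases by
higher quality; trimming clips at the *start* of the first failing window;
the rRNA screen checks both strands of each read k-mer. Every step
partitions its input — merged ∪ notCombined, kept ∪ dropped, ribosomal ∪
other — and the pipeline's read-count ledger asserts the resulting
monotone chain raw ≥ merged ≥ trimmed ≥ mRNA ≥ annotated.

# Abundance tables and slicing

An abundance table is a per-sample sorted count: rows `(name, count,
percent)` ordered by count descending then name ascending. Counts are
authoritative; percents are always re-derived from counts (files print two
decimals, memory keeps full precision). The percent denominator is the
number of *annotated* reads in the sample, not raw reads — the tables
derive from aligner output only, and raw totals live in the run log.
Slicing is exact partitioning: the function tables of all organisms tile
the global function table, and the organism tables of all level-k
categories (including `NO HIERARCHY`) tile the global organism table. No
length normalisation (RPKM/TPM) is applied anywhere: these are read
counts.

# Cross-sample statistics

`build_count_matrix()` assembles per-sample tables of one key kind into a
features × samples integer matrix (absent cells 0). Features with total
count below `min_total = 5` are excluded from testing but stay in the raw
matrix.

The differential procedure is a deliberately simple, fully specified
substitute for negative-binomial shrinkage frameworks:

1. **Median-of-ratios size factors.** Reference = geometric mean across
   samples over features nonzero in every sample; size factor = median
   ratio to the reference. With fewer than 10 such shared features the
   reference is unstable and the method falls back to total-count scaling
   (reported in the return value and the log).
2. **`log2(normalized + 1)` transform.** Zero-safe, standard, stated.
3. **Per-feature two-sided Welch t-test**, experimental vs control;
   `log2fc` is the difference of group means on the transformed scale.
4. **Benjamini–Hochberg q-values**, results sorted by `(q, p, feature)`
   for deterministic files.

Degenerate inputs: a feature constant across all samples gets p = 1; the
(practically unreachable) case of two zero-variance groups with different
means gets p = 0. Groups with fewer than 2 samples are refused with a
pointer to descriptive output. Users wanting a shrinkage estimator can
export the interchange TSV and run their framework of choice on identical
counts.

Diversity per sample: richness (nonzero features), Shannon entropy
(natural log, so the uniform S-feature sample gives exactly `ln S`) and
Gini–Simpson `1 − Σp²`. These three were chosen as the standard
descriptive trio; all-zero samples get zeros. PCA coordinates come from
the SVD of the feature-centred transformed matrix; the projection is
distance-preserving, variance fractions are non-increasing and defined as
zero for a degenerate zero-variance matrix. Heatmap distances are
Euclidean on the same transform.

# The simulator and what passing tests mean

`generate_reference_db()` draws peptides uniformly over the 20 amino acids
and back-translates them through random synonymous codons; organisms are
`Genus_i species_i` (two tokens, one organism per genus), each gene gets a
unique function attached to a path in a level grid (default 3 × 2 × 2).
`simulate_reads()` samples genes (uniform or log-normal weights), takes a
substring at a uniform offset on either strand, and substitutes each base
independently with probability `error_rate`; qualities are set consistently
with that rate. `fabricate_m8()` bypasses alignment entirely with a
controlled miscall rate, so aggregation and statistics can be tested with
a known annotation error rate. Everything is seed-deterministic and
parameters travel in file headers.

What this emulates: provenance-tracked reads with tunable substitution
noise and a discriminative reference. What it does *not* emulate:
compositional structure, homology between database entries, indels,
quality-dependent error profiles, chimeras, or real ontology ambiguity.
Passing recovery tests therefore demonstrate that the pipeline's plumbing
is correct and loss-free — not that real-data accuracy will match the
simulated numbers, which depend entirely on the reference database and
read length in use.

Accuracy is evaluated per level (species, genus, function, hierarchy
levels 1–3) by case-folded string equality against the truth record.
Unannotated reads are excluded from the denominator by default and
reported separately (`include_unannotated = TRUE` counts them as wrong
instead); both denominators are defensible and the flag makes the choice
explicit. Two orderings hold by construction and are asserted on every
run: genus accuracy ≥ species accuracy, and level-k accuracy ≥
exact-function accuracy.

# Study conditions used by the test suite

The shipped tests and `scripts/acceptance.R` run at sizes chosen as
realistic-but-small study conditions:

* end-to-end recovery: 10 genera × 5 genes (120-aa peptides), 2,000
  error-free 150-nt reads — species and function accuracy are expected to
  be exactly 1.0 because the random-peptide database is discriminative at
  `k = 5`;
* degradation ordering: substitution rates {0, 0.01, 0.02, 0.05}, 10 seeds
  × 400 reads per rate;
* differential recovery: 4 vs 4 samples, 200 null features drawn from a
  shared negative binomial with mean 400 and dispersion 0.01, one feature
  spiked 8-fold. The mean/dispersion emulate well-measured category-level
  counts at recommended sequencing depth; this matters because with n = 4
  per group the Welch test has 3–6 degrees of freedom, and its heavy tails
  make an 8-fold spike on *low*-abundance features (mean ≲ 50)
  undetectable at BH q < 0.05 across 200 features in any reliable fraction
  of runs. The recovery design is a statement about well-measured
  features, and the simulation says so explicitly.

# Known limitations

* The toy aligner's e-value surrogate makes its m8 output unsuitable for
  tools that interpret e-values statistically.
* The preprocessing stand-ins approximate, but do not reproduce, the
  behaviour of dedicated merge/trim/rRNA tools; external mode exists for
  faithful runs.
* Genus extraction by first token misparses non-binomial organism strings
  (e.g. "Candidatus X"); the sentinel fallbacks keep such records visible
  rather than correct.
* The differential test is per-feature Welch on transformed counts; it
  does not share dispersion information across features and will be less
  powerful than shrinkage estimators on small counts.
* Checkpoint caching covers the annotation step (the expensive one);
  preprocessing steps are cheap and deterministically recomputed on
  re-runs.
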