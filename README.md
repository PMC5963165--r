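# metatx

Desk-scale metatranscriptome functional annotation and analysis for R.

A metatranscriptome — the bulk-sequenced RNA of a mixed microbial
community — answers two questions at once: which organisms are
transcriptionally active, and what functions they are expressing. The
read-based strategy implemented here aligns each mRNA read against a
protein reference database whose FASTA headers carry an internal id, a
function name and the organism in brackets, keeps one best hit per read,
joins it to organism/function/hierarchy annotations, and condenses the
result into sorted abundance counts that feed diversity, ordination and
differential-activity statistics.

`metatx` covers that whole chain for researchers who want an inspectable,
fully local workflow they can validate end to end:

* **refdb** — parse protein reference FASTA (`<id> <function> [<organism>]`
  headers; organism = last balanced bracket group, genus = its first
  token) and a 5-column functional-hierarchy TSV mapping each function to
  four levels of classification;
* **alignment I/O** — read/write 12-column BLAST tabular (m8), select best
  hits (bitscore, then e-value, then subject id, then first occurrence),
  join to per-read annotations with a byte-exact checkpoint file;
* **miniblastx** — a small translated-search aligner (six-frame
  translation + peptide k-mer seeding + ungapped extension) so the
  pipeline runs with no external binary;
* **preprocess** — simplified paired-read merging, sliding-window quality
  trimming and a k-mer rRNA screen, each partitioning its input, with
  optional shelling out to the dedicated external tools;
* **aggregate** — sorted abundance counts per organism / genus / function /
  hierarchy level, plus exact data slicing (one organism's functional
  profile; one category's organism profile);
* **stats** — median-of-ratios size factors, per-sample richness /
  Shannon (−Σ pᵢ ln pᵢ) / Gini–Simpson (1 − Σ pᵢ²), PCA coordinates, and
  two-group differential activity: per-feature two-sided Welch t on
  log2(normalized + 1) with Benjamini–Hochberg q-values;
* **simulate** — seed-deterministic mock databases, provenance-tracked
  reads with substitution errors, fabricated m8 with a controlled miscall
  rate, and an accuracy evaluator (species / genus / function / hierarchy
  levels) against the ground truth;
* **pipeline** — orchestration over a sample manifest with per-step
  checkpoint files, a read-count ledger and annotation caching, plus a
  thin CLI (`inst/scripts/metatx-cli.R`).

## Worked example

Simulate a small community, annotate its reads with the built-in aligner,
and inspect the profiles:

```r
library(metatx)

ref <- generate_reference_db(n_organisms = 10, genes_per_organism = 5, seed = 421)
sim <- simulate_reads(ref, n_reads = 2000, read_len = 150,
                      error_rate = 0.01, seed = 422)
hits <- miniblastx_align(sim$reads, ref$db)
best <- best_hit_per_query(hits)
ann  <- annotate_reads(best, ref$db, ref$hierarchy)$annotations

aggregate_annotations(ann, "genus", "demo")
#> <abundance_table> sample=demo key=genus total=2000
#>        name count percent
#> 1  Genus_05   211   10.55
#> 2  Genus_08   211   10.55
#> 3  Genus_01   205   10.25
#> ...

rollup_hierarchy(ann, 1, "demo")
#> <abundance_table> sample=demo key=level1 total=2000
#>          name count percent
#> 1 Category_01   726   36.30
#> 2 Category_03   651   32.55
#> 3 Category_02   623   31.15

evaluate_accuracy(ann, sim$truth)
#> <accuracy_report> (0 unannotated reads)
#>      level n_evaluated n_correct accuracy
#> 1  species        2000      2000        1
#> 2    genus        2000      2000        1
#> 3 function        2000      2000        1
#> ...
```

The genus table says each of the ten simulated genera captured ~10% of the
2,000 annotated reads (uniform abundance model); the level-1 rollup
redistributes the same 2,000 reads over the three top-level functional
categories; and the accuracy report confirms every read was annotated back
to its true source species and function — at a 1% substitution error rate
the discriminative toy database still resolves every read.

All randomness is seed-controlled: the same seeds reproduce these tables
byte for byte.

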