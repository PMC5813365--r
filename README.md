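# srnacascade

Small RNA sequencing (sRNA-seq) reads are short (15–32 nt), highly
redundant, and come from a mixture of sources: annotated small RNAs,
unannotated genomic loci (candidate novel miRNAs), microbial contamination
or infection, and conserved miRNAs of other species. `srnacascade`
implements a complete, scriptable analysis engine for such data, for
bioinformaticians who want the behavior of an sRNA web pipeline as plain R
functions with deterministic, machine-readable outputs:

* **Preprocessing** — leftmost-match 3' adapter trimming, symmetric
  `barcode_n` clipping (default 0), 15–32 nt length filter.
* **A four-tier alignment cascade** with strict precedence: (1) known
  target-organism transcripts, (2) target genome, (3) pathogen genomes,
  (4) cross-species miRNA precursors. Reads of 15–19 nt align with 0
  mismatches, 20–32 nt with ≤ 1 (Hamming); each read is consumed by exactly
  one tier, so tier counts always partition the sample.
* **Novel miRNA prediction** — read clustering on the genome (≤ 5 loci per
  read), 110-nt precursor window excision, Nussinov folding (Watson–Crick +
  GU), an explicit 5-term hairpin score, and the three-criterion quality
  filter: score > 10 (strict), no shared 20-mer with tRNA/rRNA decoys, and
  dinucleotide-shuffle structure p ≤ 0.05 (Altschul–Erickson shuffles,
  `p = (1 + #{pairs(shuffle) ≥ pairs(orig)})/(n+1)`). Survivors enter a
  named GFF3+TSV catalog.
* **Pathogen screen** — canonical 18-mer database over a genome panel with
  LCA collapsing, Kraken-style maximal root-to-leaf path classification, a
  ranked top-5 species report, and a precision/recall/F evaluation harness.
* **Biomarker module** — balanced random forests (each tree bootstraps m
  samples per class, m = minority size), out-of-bag error, stratified
  cross-validated rank AUC, and backward feature pruning over geometrically
  shrinking top-importance subsets, reporting the full and the best model.
* **Synthetic data** — a deterministic generator for every input (host
  genome with planted hairpins, transcript/decoy/cross-species references,
  pathogen panel + taxonomy, reads with per-read provenance, classification
  count tables), used by the whole test suite.

See `vignettes/srnacascade-methods.Rmd` for the model details and design
choices.

## Worked example

Simulate an infected sample with known provenance, run the full pipeline,
and fit the biomarker module on a synthetic 6-vs-6 count table:

```r
library(srnacascade)

spec  <- fixture_spec(seed = 1, read_error_rate = 0)
host  <- make_host(spec)                      # genome + 5 planted hairpins
panel <- make_pathogen_panel(spec)            # 12 genomes, 4-level taxonomy
db    <- build_kmer_db(panel$genomes, panel$taxonomy)   # k = 18
sim   <- simulate_sample(host, panel, spec)

res <- run_pipeline(default_config(
  adapter3 = spec$sample$adapter3, seed = 1,
  refs = list(reads = sim$reads, transcripts = host$transcripts,
              genome = host$genome, nto = host$nto, decoys = host$decoys,
              kmer_db = db, taxonomy = panel$taxonomy)))

str(res$cascade$summary)
#> List of 5
#>  $ TIER1_TRANSCRIPT: int 300
#>  $ TIER2_GENOME    : int 144
#>  $ TIER3_PATHOGEN  : int 200
#>  $ TIER4_NTO       : int 100
#>  $ UNALIGNED       : int 200
```

Every simulated read landed on its provenance tier (error rate 0): 300
transcript reads, 144 genomic hairpin/decoy-cluster reads, 200 reads from
the planted infection, 100 cross-species reads, 200 random reads unaligned.

```r
res$pathogen_report
#> Top-5 pathogen species report
#>   taxon_id       name read_count
#> 1       s1 species_01        181
#> above-species: 19, unclassified: 0
```

The planted infection (`s1`) tops the report; 19 of its reads fell in
genomic blocks shared between sibling species and were classified at the
genus (above-species) level.

```r
res$prediction$catalog[, c("name", "strand", "pre_start", "score", "randfold_p")]
#>              name strand pre_start    score randfold_p
#> 1 syn-oasis-mir-1      -       848 20.25107       0.01
#> 2 syn-oasis-mir-2      -      2230 25.40088       0.01
#> 3 syn-oasis-mir-3      +     10989 24.17493       0.01
#> 4 syn-oasis-mir-4      -     12512 24.31985       0.01
#> 5 syn-oasis-mir-5      -     16467 23.40088       0.01
```

All five planted hairpins — and none of the five planted non-hairpin decoy
clusters — pass the three-criterion filter (score > 10, no decoy 20-mer,
shuffle p ≤ 0.05; 0.01 is the p floor at 99 shuffles).

```r
ds  <- make_classification_dataset(fixture_spec(seed = 1), seed = 1)
tab <- normalize_counts(ds$counts, ds$sheet)
prune_features(tab, n_trees = 1000, seed = 1)
#> Balanced random-forest classifier with feature pruning
#>   full model: 301 features, OOB error 0.167, CV AUC 0.722
#>   best model: 1 features, OOB error 0.083, CV AUC 1.000
```

With one perfectly separating feature among ~300 uninformative ones, the
full model is mediocre (CV AUC 0.72) while pruning recovers a one-feature
model with CV AUC 1.0 — the failure mode the pruning routine exists for.

A thin command-line front end with `detect` / `simulate` / `classify`
subcommands is installed at `inst/scripts/srna-cascade`.

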