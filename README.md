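# panpep

Minimal surrogate-peptide panels covering bacterial panallelomes.

## The problem

Bacterial proteins accumulate mutations fast, so a single "reference"
sequence rarely represents all circulating alleles of a virulence factor or
resistance protein. Targeted proteomics quantifies a protein through a few
surrogate tryptic peptides; if those peptides sit on polymorphic positions,
entire allelic variants become invisible to the assay. The same problem
affects motif-based protein detection in genomic data.

`panpep` addresses this end to end. Given a directory of proteome FAA files
(one per genome, translated coding sequences) and a reference protein, it:

1. **Screens genomes** — removes genomes containing ambiguous residues
   (B, Z, J, X, `-`) or whose protein count deviates >15% from the median.
2. **Digests and flags multi-copy peptides** — simulates trypsin cleavage
   (cut after K or R unless followed by P) and records every peptide
   occurring ≥2 times within a single genome; such peptides cannot
   quantify a single protein.
3. **Compacts the panallelome** — exact deduplication (100% identity and
   coverage = string equality) into a nonredundant database: one
   representative per distinct sequence plus the full list of identical
   members, processed in length-partitioned chunks so memory stays bounded.
4. **Selects allelic variants** — Smith–Waterman search of the reference
   against the representatives (k-mer prefiltered, ≥60% identity and query
   coverage), best hit per genome, a divergence filter
   `|pct_length − pct_identity|` on the global alignment, iterative
   greedy clustering with the reference (70% identity, +0.5% per round)
   to resolve within-genome ambiguity, and a frequency filter retaining
   variants that together account for ≥98% of observations.
5. **Picks the minimum peptide list** — builds the peptide × variant
   presence/absence matrix (multi-copy and user-excluded peptides removed),
   then greedily selects peptides until every variant is covered by ≥3
   selected peptides (configurable), each round rescuing the
   peptide-poorest under-covered variants first.
6. **Validates specificity** — exact substring scan of every selected
   peptide against the whole database with a cleavage-context check (an
   occurrence only counts if trypsin could actually release it there), and
   a per-protein report of peptide counts and global identity to the
   reference, separating allelic variants from off-target proteins.

The greedy selection step works on the boolean matrix `M[p, v]` ("peptide
`p` is a digestion product of variant `v`"): while any variant has coverage
below the target `t`, take the under-covered variants with minimal
coverage (a), the remaining peptides they contain (b), those covering the
most under-covered variants (c), and among these pick the peptide whose
worst-off variant has the fewest remaining peptides (d–e), breaking ties by
peptide sequence. Each selected peptide leaves the matrix; the loop
terminates in at most `nrow(M)` rounds.

A deterministic synthetic-proteome generator (`make_panel()`) plants a
variant family, decoy paralogs, duplicated loci and spurious genomes with
full ground truth, so every stage is testable without downloading genomes.

## Worked example

```r
library(panpep)

# a synthetic panel: 12 genomes, planted variant family at 80-95% identity,
# decoy paralogs at 40-65%, one ambiguous genome, one count outlier
pan <- make_panel(seed = 42, n_genomes = 12, reference_length = 200,
                  n_background_shared = 6, n_background_unique = 6)

run <- run_pipeline(pipeline_config(seed = 42),
                    proteins = pan$proteins, reference = pan$reference)
run
#> <pipeline_run>
#>   genomes passing QC : 10 (2 removed)
#>   nonredundant db    : 81 representatives / 137 proteins
#>   multi-copy peptides: 49
#>   allelic variants   : 10
#>   minimum peptides   : 7 (0 variant(s) uncoverable)
#>   off-target proteins: 0
```

The two removed genomes are exactly the planted spurious ones; the 10
retained allelic variants are exactly the planted family. The minimum list
and what each peptide buys:

```r
tidy(run$selection)
#> # A tibble: 7 × 5
#>    rank peptide source length n_variants_covered
#>   <int> <chr>   <chr>   <int>              <int>
#> 1     1 STR     greedy      3                  7
#> 2     2 VYHGR   greedy      5                  7
#> 3     3 EK      greedy      2                  7
#> 4     4 SLTFNK  greedy      6                  6
#> 5     5 LHK     greedy      3                  7
#> 6     6 ADR     greedy      3                  4
#> 7     7 ACR     greedy      3                  2

glance(run$variants)
#> # A tibble: 1 × 4
#>   n_variants total_observations retained_fraction mean_identity
#>        <int>              <int>             <dbl>         <dbl>
#> 1         10                 10                 1          87.6
```

Seven peptides give every one of the 10 variants at least 3 covering
peptides (`n_variants_covered` is how many variants contain each peptide);
the validation scan finds no off-target protein carrying any of them with a
valid cleavage context. `autoplot()` methods visualize the database
compaction, the variant set and the per-variant coverage; on-disk runs
(`pipeline_config(input_dir=, reference_faa=, out_dir=)`) write the QC
report, multi-copy FAA, representative FAA + cluster TSV, variant FAA/TSV,
minimum-peptide FAA, validation TSV and a run-summary JSON.

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "panpep.R", package = "panpep"))')
Rscript $CLI synth --out_dir panel --seed 5 --n_genomes 12
Rscript $CLI run --input_dir panel --reference_faa reference.faa \
                 --out_dir results --seed 5
Rscript $CLI resume --db_dir results --reference_faa other_ref.faa
```

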