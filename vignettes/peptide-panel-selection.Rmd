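---
title: "Selecting minimal peptide panels over a bacterial panallelome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting minimal peptide panels over a bacterial panallelome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

`panpep` solves a coverage problem: given the observed allelic diversity of
a bacterial protein across many genomes, find a small set of tryptic
peptides such that every allelic variant contains at least a target number
of them. Such a set can be monitored by targeted mass spectrometry (each
peptide a surrogate for the protein) or used as sequence motifs for
protein detection in assemblies. The pipeline has three parts — database
preparation, variant selection, peptide selection — followed by a
specificity validation, and every step is deterministic given its inputs.

### Database preparation

Per-genome FAA files are screened twice. The *alphabet screen* rejects a
genome if any protein contains a character outside the 20 standard
one-letter residues: ambiguity codes (B, Z, J), placeholders (X, `-`) and
internal stops all indicate annotation or assembly problems. The decision
is made per genome, not per protein, because a proteome that contains such
residues is generally untrustworthy as a whole. Selenocysteine (U) and
pyrrolysine (O) are treated as failures by default — they are vanishingly
rare in bacterial annotation sets and more often signal translation-table
errors — but can be whitelisted via `valid_alphabet`. The *count screen*
rejects genomes whose protein count deviates from the median by more than
`max_dev` (default 0.15, i.e. 15%): heavily fragmented or contaminated
assemblies inflate or deflate the count. The median is computed after the
alphabet screen so that corrupted genomes cannot distort it; the screen is
scale-invariant. Both screens are optional (`qc_enabled = FALSE`), in which
case diagnostics are still reported.

Digestion follows the two-rule trypsin model: cleave after lysine (K) or
arginine (R) unless the next residue is proline (P). No missed cleavages
are simulated — the panel is meant to work under complete digestion, and a
missed-cleavage variant of a covered peptide still contains it. A peptide
whose occurrence count *within one genome* reaches two (across proteins, or
repeated inside one protein) is flagged multi-copy: its MS signal cannot be
attributed to a single protein copy. We deliberately do not flag peptides
merely shared *between* genomes — cross-genome conservation is exactly what
makes a peptide useful, and blacklisting conserved peptides would make
coverage impossible.

Compaction to the nonredundant database uses the fact that clustering at
100% identity *and* 100% coverage admits only exact string equality, so the
"clustering" is hashing. Proteins are processed in chunks of at most
`chunk_size` (default $10^7$) and partitioned by length inside each chunk —
two sequences of different lengths can never be identical — which bounds
the working set on large inputs. The result is provably independent of
chunk size and input order; the test suite checks this against a naive
single-pass hash dedup for chunk sizes 1, 17, 1000 and "everything".
Member identifiers are genome-qualified (`genome|protein`) so clusters can
be expanded back to genomes later. The representative description is the
modal description over the whole final member list (chunk-local modes are
never used, so merging cannot change the answer); ties fall back to byte
order of the description, then the byte-smallest id bearing it. The
byte-order tie-break is our choice — only the description rule is inherent
to the method — made so that output never depends on locale.

### Variant selection

The reference is compared against every representative by Smith–Waterman
local alignment (BLOSUM62, gap open 11, extend 1), preceded by a shared
4-mer prefilter that discards sequences with no exact 4-mer in common with
the reference. The prefilter is a pure speedup with a small theoretical
risk of missing extremely diverged true hits; it can be disabled
(`prefilter = FALSE`), and the hit tables with and without it are identical
on the test panels. Hits require ≥60% identity and ≥60% coverage; coverage
is measured on the *reference* side, since the goal is to cover the
reference protein (the subject-side choice would admit short fragments).
Hits are expanded to genomes through cluster membership and only the
highest-scoring hit per genome survives ("best" = local alignment score,
ties by subject id).

Each candidate is then globally aligned to the reference
(Needleman–Wunsch, BLOSUM62, gap open 10, extend 0.5; end gaps are
penalized; a gap of length $L$ costs $\mathrm{open} + L\cdot\mathrm{ext}$).
Percent identity counts identical pairs over *all* alignment columns, gaps
included. The divergence metric is

$$d = |\,\mathrm{pct\_length} - \mathrm{pct\_identity}\,|,$$

with $\mathrm{pct\_length} = 100\cdot\min(l_a,l_b)/\max(l_a,l_b)$ on the
raw sequence lengths. We read "percentage length" as the raw length ratio
(not an aligned-length ratio) because the metric is meant to be directly
comparable to percent identity. For a length-conserved variant of identity
$I$, $d \approx 100 - I$; for a truncated but otherwise conserved variant,
both terms drop together and $d$ stays near zero, so the filter tolerates
honest truncations while rejecting same-length paralogs. The threshold
`max_divergence` has no canonical value; the default of 25 percentage
points keeps length-conserved variants down to roughly 75% identity while
removing paralogs at ≤65% identity (divergence ≥35), which separates the
two populations by a comfortable margin for typical core-genome proteins.
It is the one knob a user should actively think about, and it is recorded
prominently in every run summary.

If any genome still contributes more than one retained sequence, the
retained set plus the reference is clustered greedily in the style of
incremental identity clustering (longest first, join the first cluster
whose representative matches at or above the threshold; identity here is
identical pairs over the *shorter* sequence, the convention of such
clusterers). The threshold starts at 70% and rises by 0.5 points per round;
after each round only the reference's cluster survives. The loop ends when
every genome is unambiguous. Two degenerate endings are defined explicitly
because the procedure itself does not define them: if the threshold passes
100, or if an entire round would separate *all* remaining candidates from
the reference at once (equidistant duplicate loci), the current set is kept
and a warning names the affected genomes.

Finally the frequency filter sorts candidates by observation count (their
cluster sizes) and keeps the shortest prefix whose cumulative share of
observations reaches `keep_fraction` (default 0.98). We apply the 98% to
observation mass, not to the count of distinct variants: rare singleton
alleles are exactly what the filter exists to drop, and a count-based
reading would remove a fixed 2% of variants regardless of how common they
are. A candidate identical to the reference is never dropped, whatever its
rank.

### Peptide selection

The retained variants are digested and a boolean matrix $M[p,v]$ records
which peptides are products of which variants; multi-copy and user-excluded
peptides never enter the matrix. Optional `min_pep_length` /
`max_pep_length` bounds can restrict the pool to MS-friendly lengths; they
are off by default because the coverage problem itself has no length
constraint. A user-supplied include list seeds the selection (peptides not
present in the matrix are reported and skipped).

Selection then loops while any variant has fewer than `target_coverage`
(default 3) selected peptides: (a) the under-covered variants at minimal
coverage; (b) the remaining peptides occurring in them; (c) of these, the
peptides contained in the most under-covered variants — all under-covered
variants, not only those of (a), per the literal reading of the procedure;
(d) each candidate's under-covered variants; (e) each such variant's count
of remaining potential peptides. The candidate whose minimum over (e) is
smallest wins: among the peptides that help the most variants, prefer the
one whose neediest variant has the fewest options left. Coverage counts
*selected* peptides per variant (so it starts at zero, or at the seeded
counts), which is the only initialization consistent with the loop's own
stopping rule. Ties at step (e) break by byte order of the peptide
sequence. Selected peptides leave the matrix but keep counting toward
coverage; a variant whose remaining peptide count hits zero below target is
moved to an explicit `uncoverable` set with its achieved coverage. Every
round removes one matrix row, so the loop terminates. Greedy set cover is a
heuristic — the test suite compares its size against an exhaustive optimum
on small random instances and records the ratio rather than asserting
optimality.

### Specificity validation

Every selected peptide is located in every representative by exact
substring search (all occurrences, overlaps included). Short-peptide
alignment filtered to zero mismatches and zero gaps is equivalent to exact
search, which is why no aligner is involved; an optional diagnostic mode
also reports single-substitution near-matches, which are never counted as
valid. An occurrence is *context-valid* only if trypsin could actually
release it there: the site before the match is cleavable (or the match
starts the protein) and the site after the last residue is cleavable (or
the match ends the protein), with the proline block applied on both sides.
Because digestion peptides contain no internal cleavage site, a
context-valid occurrence of a selected peptide is exactly a digestion
product of the containing protein. Positions are 0-based and half-open.
The per-protein report counts distinct peptides and global identity to the
reference and flags membership in the variant set; proteins outside it are
off-target, and their peptide counts are what a user consults when setting
a detection threshold (an accessory protein sharing one peptide of ten is
not a variant). A multiple alignment and tree over the hit proteins would
carry the same signal; the pairwise identity table was chosen to keep the
package self-contained.

## The synthetic study panel

`make_panel()` generates the ground-truth panels used throughout the tests:
per genome, a shared core of identical background proteins (making the
compaction non-trivial), genome-specific random background proteins with
bacterial residue frequencies (K+R ≈ 11%, so tryptic peptide lengths are
realistic, mean ≈ 9), one planted variant of the reference (substitutions
only, identity uniform in 0.80–0.95), and optionally: a decoy paralog
(identity 0.40–0.65) in 40% of genomes, a duplicated locus in 20% (its
peptides become expected multi-copy truth), one genome corrupted with an
ambiguous residue and one with a 30% inflated protein count. The default
of 50 genomes with ~30 proteins each (~1500 proteins) is the study
condition for the end-to-end properties; the dedup-equivalence property
uses 200 genomes at ~100 proteins each (~20 000 proteins), and alignment
and set-cover oracles run on 500 pairs (length ≤ 30) and 1000 random
matrices (≤ 12 peptides × ≤ 10 variants) respectively — sizes at which the
exhaustive oracles are exact yet fast.

One property is *built in*: every non-family protein is scrubbed of any
tryptic peptide shared with the reference or any planted variant (one
substitution inside each shared peptide, never creating new cleavage
sites). This makes peptide uniqueness a planted truth, so the validation
stage has an exact expectation: zero off-target proteins. Real proteomes
offer no such guarantee — paralogs genuinely share peptides with their
homologs — so passing this check demonstrates that the scan and context
logic are sound, not that real off-target hits cannot occur. Other
realism gaps are deliberate: substitution-only variants (no indels, so
recovering truncated alleles is exercised only by the divergence-filter
unit tests), no phylogenetic correlation between genomes, and uniform
background composition.

## Numerical and degenerate-input choices

* All id and peptide tie-breaks use byte order (`sort(method = "radix")`),
  never locale collation; two runs with the same seed are byte-identical.
* Alignment scores are floating point; the DP oracle comparison uses a
  $10^{-9}$ tolerance, everything else is exact.
* A single terminal `*` is stripped on FASTA input (ubiquitous in
  translated CDS files); internal `*` is left for QC to flag. Duplicate ids
  within a file, sequence-less headers and empty files are errors, as are
  two files mapping to the same genome id.
* `digest("")` is an error; a genome set in which *all* genomes fail QC is
  an error carrying the full report; a reference with no hit above the
  search thresholds is an error ("reference not found in database").
* A variant left with no matrix peptides keeps its empty column, is
  reported, and ends in `uncoverable` — it is never silently dropped.
* Resuming from a previous run's database directory reproduces the
  downstream results exactly; the loader re-validates every database
  invariant and names the violated one on failure.

## Limitations

Peptide detectability (hydrophobicity, flyability, length windows) is not
modeled; the optional length bounds are the only MS-practicality knob.
The local search is exhaustive over representatives apart from the k-mer
prefilter — appropriate up to a few hundred thousand representatives, not
for metagenome-scale databases. Orthology is not assigned: a paralog more
similar to the reference than 60/60 and length-matched within the
divergence threshold would be treated as a variant; the validation report
is where such cases surface. Only exact (100/100) deduplication is
performed at the database stage by design; near-identical alleles are kept
distinct, which is precisely what makes variant frequencies meaningful.
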