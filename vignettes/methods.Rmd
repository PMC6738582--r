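---
title: "Methods: building a healthy gut baseline at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a healthy gut baseline at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutbaseline)
```

## Overview

gutbaseline implements a whole-metagenome workflow for characterising the
bacterial composition of healthy human stool samples and comparing an
individual sample against a cohort baseline. The chain is: build a
blacklist-filtered nucleotide reference; quality-filter reads; estimate
the taxonomic composition by subsampling census; curate the census into a
versioned organism knowledgebase; map all reads best-match against the
knowledgebase organisms to obtain relative abundances; roll abundances up
the taxonomy; collect unmappable reads as "dark matter" contigs; correlate
abundances with nutrient features; and render a standardized three-domain
report with cohort reference ranges.

Every stochastic step takes an explicit seed, and every stage is a pure
function of its inputs, so runs are reproducible byte-for-byte.

## Reference filtering

Public nucleotide collections contain many entries whose taxonomic
placement carries no biological information for profiling (unclassified,
unidentified, uncultured, unspecified, unknown, vectors, environmental
samples, artificial and other sequences). `build_blacklist()` marks a
taxon when its own scientific name **or any ancestor's name** contains one
of these terms, then closes the set under descendants;
`filter_reference()` drops the corresponding sequences.

Design choices worth noting:

* **Substring, case-insensitive matching** over scientific names. The
  substring rule catches singular/plural and embedded variants
  ("environmental samples", "uncultured bacterium"); matching is
  restricted to the scientific-name class — synonyms and other name
  classes are not scanned, since they frequently contain incidental
  occurrences of common words.
* **Unmapped accessions are removed**, not retained, and counted in a
  separate `unmapped_sequences` bucket: a sequence without a resolvable
  lineage cannot support a taxonomic claim. The bookkeeping identity
  `initial = retained + removed + unmapped` is enforced by construction
  in `filter_stats()`.
* Filtering preserves input order and header text, so it is idempotent
  and diff-stable.

## Read quality control

`read_stats()` tabulates base composition, per-cycle mean Phred quality,
read-length and mean-quality histograms. `filter_reads()` discards reads
whose **mean Phred quality is 20 or less** — the threshold is inclusive,
so a read at exactly Q20 is discarded. Phred+33 encoding is assumed and
the offset is configurable. File-level checks are warnings, never
filters: a positional warning when any cycle's mean quality drops below
20, and a base-skew warning when any A/C/G/T frequency deviates from 0.25
by more than 0.15. The skew tolerance is pragmatic plumbing for flagging
"unusual" composition; there is no principled universal value, and real
libraries with extreme GC content would trip it without being faulty.
Paired-end mates are judged independently; `filter_read_pairs()`
optionally (and by default) drops both mates when either fails, so
mate files stay synchronized.

## Read mapping and best-match assignment

The package defines an aligner contract — reads in, per-organism match
scores out — and ships a k-mer seed-count aligner behind it. The index
stores every k-mer of every reference sequence on both strands (default
k = 15); a read's score against an organism is the total number of
matching seeds summed over the organism's accessions, which makes scores
orientation-invariant and keeps multi-replicon genomes (many gut
organisms carry several chromosomes/plasmids) from being penalized.
Alignments below `min_seeds = 2` matching seeds are suppressed as noise.

`best_match_assign()` gives each read to the single organism with the
greatest score. Ties break deterministically to the lexicographically
smallest organism identifier: determinism was prioritised over unbiased
tie splitting because downstream knowledgebase versioning and report
rendering must be reproducible; the rule is configurable in principle
(seeded-random or fractional splitting would be drop-in alternatives,
at the cost of bit-stability or integer counts).

"Number of matches" is deliberately defined as *seed count*, not aligned
bases: the downstream pipeline consumes only relative per-organism
scores, which seed counts preserve at desk scale. The aligner is
ungapped and substitution-tolerant only through seed redundancy — a
documented limitation matched by the substitution-only read simulator.

## Subsampling census and curation

`run_census()` estimates composition from small random subsamples instead
of mapping the whole file: by default 5 iterations of 2,500 reads each
(a 12,500-read alignment budget). Draws are without replacement within an
iteration and independent across iterations (iteration *i* uses
`seed + i - 1`). Match counts accumulate over all iterations, and
`aligned + unaligned = sampled` is maintained on every run.

`curate()` encodes the organism-acceptance rules applied before an
organism enters the knowledgebase:

1. **Match count ≥ 5** over the whole census — fewer alignments are too
   thin to appraise authenticity.
2. **Resolvable lineage** — hits whose taxid cannot be placed in the
   taxonomy are rejected (`NO_LINEAGE`).
3. **Pathogen rule** — organisms on a user-supplied watch list are
   accepted only at ≥ 1% of sampled reads, because close homology among
   related taxa makes low-abundance pathogen calls unreliable. The
   fraction used is the census fraction of sampled reads, since curation
   happens before full mapping.

Every rejection carries a machine-readable reason. The completeness
concern — partial sequences skewing abundance — is handled structurally:
accessions map to organisms in the reference index, so partial entries
cannot become independent abundance bins. No convergence-based early
stop is implemented; the iteration count is fixed and configurable.

## Abundance profiles and roll-ups

`profile_sample()` turns full-file assignments into percentages **over
aligned reads**; the unaligned fraction of all reads is reported
alongside and never mixed into the 100%. This keeps organism percentages
comparable across samples with very different mappability. `rollup()`
replaces organism columns by their ancestors at a target rank and sums;
row sums are preserved exactly (tested at 1e-9), and taxa without an
ancestor at the target rank group under `"unranked"` rather than being
dropped. No renormalization is performed after roll-up.

`cohort_stats()` computes presence (percent of samples with nonzero
abundance, over **all** samples) and mean/sd/min/max/median **excluding
zero-abundance samples**, so the moments describe the organism where it
occurs. `sd` uses the n−1 denominator. Percentages are held at full
precision and rounded only at serialization (2 decimals).

## The organism knowledgebase

A knowledgebase is a single TSV — one row per organism, multi-valued
cells comma-joined, the version in a `# kb_version=N` header — chosen to
be diff-able and version-controllable. `add_organism()` is idempotent
(re-adding an identical record changes nothing) and increments the
version exactly when the record set changes; conflicting re-adds are
errors, not silent updates. Records carry accessions, lineage, optional
proteome/assembly cross-references, cohort presence/abundance, and opaque
annotation text; no live database retrieval is performed.

`expand_rpg()` widens the organism set through representative proteome
group clusters: every cluster containing a knowledgebase proteome
contributes all members; unclustered members pass through unchanged (a
real situation — some organisms lack a reference proteome). Taxids are
optional on records (validated positive when present) because curated
species tables are commonly published without them; rank summaries
(`kb_rank_counts()`) are always computed from lineages, never
hard-coded.

The package ships a packaged baseline of 109 healthy-gut species with
cohort presence and mean-abundance annotations (`baseline_species()`,
`baseline_kb()`), used as a worked reference table and test fixture.

## Dark matter

Reads that map to no reference organism are collected
(`collect_unaligned()`), assembled externally (any FASTQ→FASTA assembler
satisfies the contract; a pass-through stub and a quadratic greedy
exact-overlap joiner are provided for tests), and filtered at a
**10,000 nt inclusive** minimum contig length. Retained contigs are
sorted long-to-short and their headers rewritten as
`sampleID|rank|length|gender|age|ethnicity` with `NA` for missing
fields. The length threshold trades recall for confidence in biological
origin: `coverage_fraction()` quantifies the rationale — against the
largest baseline genome (6.17 Mb) a single 10 kb contig still covers
0.16% of the genome, or 0.19% of its coding region at the average 87%
bacterial protein-coding density. The threshold is stated inclusively
("10,000 or higher") and implemented that way; it is configurable.

## Nutrient–abundance correlation

Before correlation, abundance and feature matrices are zero-centered and
variance-scaled per column (`standardize()`; constant columns become
zeros with a warning instead of NaNs), and categorical features are
encoded lexicographic-ordinal (`encode_categorical()`), making the
encoding invariant to row order; one-hot encoding can be layered on by
the caller.

The correlation statistic for organism *j* and feature *k* is the sum
product over samples of the standardized abundance and feature values.
As a literal sum this quantity is unbounded; interpreted on a cosine
scale (strong correlation near 1, strong anti-correlation near −1, 0.7
as the marginal evidence threshold) it must be normalized. The default
therefore divides by the product of the two column norms — the true
cosine similarity, bounded in [−1, 1] with unit self-similarity — and
`normalize = FALSE` reproduces the literal raw sum. No p-values or
multiplicity control are attached; the threshold is a screening device,
not a test. Correlation runs over per-sample rows; when hosts
contribute repeated samples, average replicates into one row per host
before standardizing — the sum-product form makes that a plain
`dplyr::summarise` upstream, so no separate flag is built in.

`variability_ratio()` summarises measurement stability: intra-host
variability is the standard deviation of a host's repeated measurements
averaged over hosts (single-replicate hosts contribute sd 0 by default,
configurable to be dropped); inter-host variability is the standard
deviation of per-host means; the ratio is undefined (NA) when the
inter-host sd is 0.

## The report

`render_report()` produces a three-domain document. The Result domain
reports the organisms that **cumulatively cover** the top 50% of the
sample's abundance (coverage reading, not "top half of the organism
count"; the organism crossing the threshold is included, and the
threshold is user-settable). Each row carries the sample abundance, the
cohort reference range, a WITHIN/ABOVE/BELOW flag, and the organism's
knowledgebase annotation verbatim (`"not in KB"` as placeholder). Range
boundaries are inclusive: a value at the observed cohort minimum was, by
definition, observed in healthy samples. `family_overview()` is exactly
the composition `rollup` ∘ `cohort_stats` at family rank. No phenotype
interpretation is generated; that is deliberately left to the
requesting clinician.

## Synthetic data: what it does and does not emulate

The generators (`make_taxonomy()`, `make_genomes()`, `make_reads()`,
`make_features()`) produce: taxonomies with exact rank shapes; uniform
i.i.d. genomes, optionally with pairwise-disjoint k-mer sets (via
rejection resampling) so that error-free reads identify their source
organism unambiguously; reads drawn multinomially from a stated profile
with uniform position and strand and substitution-only errors; a planted
"dark matter" genome with the same base composition as the references,
so unalignability stems from sequence identity rather than composition;
and feature tables with planted linear organism–feature relationships
plus pure-noise features and one categorical column.

Passing tests on these fixtures demonstrates the *bookkeeping and
estimation machinery* — conservation identities, multinomial recovery
within sampling error, threshold boundary behaviour, determinism. They
do not demonstrate robustness to properties of real gut metagenomes the
generators deliberately omit: homologous regions shared between related
genomes, indels and quality-correlated errors, GC bias, uneven coverage,
and adapter content. The substitution-only error model matches the
ungapped aligner's contract.

## Problem sizes and numerical choices

The shipped test suite runs census fixtures at 300–6,000 reads on 1.2–2
kb toy genomes, profile-recovery checks at 10,000 reads (L1 error below
0.02 against the generating profile), and property loops of 20–100
random cases per invariant — sizes chosen so the full suite completes in
a few minutes on one CPU while keeping every statistical check at ≥3
standard errors of slack. Tolerances: row-sum conservation at 1e-9
absolute; standardization at 1e-12; sampling checks at 3 SEs plus a
small constant guard. Roll-up uses exact summation (`rowsum`), and
cumulative coverage uses plain `cumsum` — both stable at these scales.

## Known limitations

* The built-in aligner is a seed counter: no gapped alignment, no
  base-level scores, no mapping qualities; organisms sharing long exact
  regions are separated only by their unique k-mer content.
* The greedy joiner is quadratic and exists for tests; real assemblies
  should come from a dedicated assembler through the contract.
* Blacklist matching scans scientific names only.
* Merged/deleted-taxid side tables are not consulted; the
  accession→taxid mapping is taken as authoritative.
* Cohort statistics assume columns are comparable percentages; no
  compositional-data transformations are applied.
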