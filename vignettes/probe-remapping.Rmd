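---
title: "Transcript-level probe remapping and Splicing-Index analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript-level probe remapping and Splicing-Index analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remapkit)
```

## The problem

3' expression arrays (the Affymetrix Zebrafish Genome Array is the
motivating platform) measure transcript abundance with probe sets of 11-20
25-mer probes.  These probe sets were designed from EST collections that
predate current genome assemblies; a substantial fraction of probes no
longer matches the genome at all, matches it in several places, or sits in
what is now known to be intronic or intergenic sequence.  Summarizing such
probes together mixes signals from different genes — or from nothing.

`remapkit` rebuilds probe sets from current annotation in three stages:

1. **Annotation integration** (`parse_genepred()`, `parse_psl()`,
   `filter_transcript_alignments()`, `integrate_collections()`): transcript
   structures from several databases are read, alignment-filtered, and
   merged into one collection.
2. **Gene definition** (`cluster_transcripts()`, `cluster_by_xref()`):
   transcripts are clustered into gene loci as the connected components of
   a pairwise linkage relation.
3. **Probe remapping** (`match_probes()`, `rescue_junction_probes()`,
   `classify_and_group()`): each probe is placed on the genome, classified
   into one of seven mutually exclusive categories, and the retained probes
   are regrouped by *transcript signature* — the exact set of transcripts
   whose exons fully contain the probe.

Probe sets defined by signature report transcript-level expression, which
in turn lets the **Splicing Index** (`splice_calls()`) flag alternative
splicing between two conditions.

## Annotation model and filters

Coordinates are 0-based half-open throughout, the native convention of the
genePred and PSL dialects the package reads; every output file states this
in its header.  A transcript is a chromosome, a strand, ordered disjoint
exons, and a CDS interval; `cds_start == cds_end` encodes a non-coding
transcript.

Alignment filtering keeps placements with base identity of at least 0.96
(the `min_identity` argument; identity is computed as
`matches / (matches + misMatches + repMatches)`, with a configurable
convention that may include query gap openings in the denominator — PSL
producers differ and the choice is recorded in the output metadata).  When
a transcript aligns in several places, placements within a per-database
*near-best window* of the transcript's best identity are retained: 0.001
for RefSeq, 0.005 for GenBank, 0 (single best) otherwise.  Collections
supplied as genePred (e.g. Ensembl structures, which come pre-aligned) are
exempt from the identity filter unless alignments are given.

## The four gene definitions

Two transcripts are linked when they

* `exlink` — overlap by at least one base in their *coding* exon intervals
  (exons intersected with the CDS); this is the default.  Non-coding
  transcripts have no coding exons and therefore form singletons.
* `overlap_0` — overlap by at least one base in any exon, UTRs included.
* `exbd` — share both boundaries of at least one exon (an identical
  `(start, end)` pair); the most stringent rule.
* `itbd` — share at least one intron boundary.

Genes are the connected components of the linkage graph (transitive
closure).  Three design points were genuinely open:

* **Strand handling.** Opposite-strand transcripts are never linked.
  Overlapping antisense genes are biologically distinct, and the probe
  classifier depends on a well-defined strand per gene to separate sense
  from reverse-complementary probe sets.
* **What counts as a shared intron boundary.** `itbd` matches a boundary
  by coordinate *and side*: an intron start only matches an intron start,
  an intron end only an intron end.  Matching bare coordinates would link
  a transcript whose exon *ends* at position x to one whose exon *begins*
  there — two transcripts whose exons do not overlap at all — and would
  break the expected coarseness ordering in which `overlap_0` never
  produces more genes than the stricter rules (each same-side shared
  boundary implies the two flanking exons overlap).  The
  one-fully-shared-intron reading is available by construction (a shared
  intron shares both sides) but single-boundary sharing is the default,
  the literal reading of the rule.  Single-exon transcripts have no intron
  boundaries and are always `itbd` singletons.
* **Gene identifiers.** Components are sorted by (chromosome, span start,
  span end, smallest member transcript ID) and numbered `g000001`, ... —
  memberships and IDs are invariant under permutations of the input.

Two clustering algorithms are provided: the default links transcripts
through shared feature keys (merged overlap blocks from an interval-sorted
sweep, or exact exon / boundary keys) in near-linear time; `algorithm =
"naive"` evaluates all same-locus pairs and exists as an independent
cross-check.  The test suite verifies their equivalence on hundreds of
random collections.

## Probe classification

Each probe is assigned exactly one of seven categories, in a fixed
precedence order:

1. `MULTI_GENOME` — two or more perfect genomic matches (probe or reverse
   complement).  Tested before junction rescue.
2. `NO_GENOME` — no genomic match and no spliced-transcript match.
   Probes with non-ACGT characters end up here too.
3. `MULTI_GENE` — the signature spans two or more genes, e.g. probes in
   the overlapping UTRs of adjacent genes.  Mixed-sense signatures also
   land here: with strand-restricted linkage, opposite-strand transcripts
   are different genes by construction.
4. `INTRONIC` — empty signature, but the footprint lies within some gene
   span (either strand of the same locus).
5. `INTERGENIC` — empty signature elsewhere.
6. `UNDERPOPULATED_SET` — the probe's (gene, signature, sense) group has
   fewer than `min_probes` members.  The default threshold keeps sets with
   at least 3 probes, and is exposed as a parameter.
7. `GOOD` — everything else; each group becomes a probe set
   `"{gene}_{k}"`, numbered by the genomic start of the group's leftmost
   probe, with reverse-complementary sets suffixed `_RC`.

Containment is all-25-bases: a probe straddling an exon edge does not
interrogate the transcript and gets no signature.  Probes with no genomic
match are re-matched against each transcript's spliced (exon-concatenated)
sequence; an exact match there identifies an exon-junction probe, whose
signature is the set of matched transcripts.  Reverse-complementary probe
sets are retained and flagged — such probes target the opposite strand of
the transcript and usually yield weaker signal, so downstream analysis may
drop them (`keep_antisense = FALSE`, in which case those placements fall
through to the intronic/intergenic rules rather than breaking the
seven-category accounting).

The accounting table always sums to the number of input probes — this
conservation property holds for every published count column shipped in
`inst/extdata/` and is asserted for every simulated configuration.  When
two remappings are compared (`compare_remappings()`), genes are paired by
shared good probes; a one-to-one pair is *same* only if both genes carry
identical member-probe partitions, label differences ignored.  Rare
many-to-many pairings are counted as *diff*, `max(nA, nB)` genes per
component, since every gene involved has a changed annotation.

## The Splicing Index

For a gene with probe sets $i$ and two conditions $x \in \{1, 2\}$, with
replicate intensities averaged per condition first,

$$NI_{i,x} = \frac{P_{i,x}}{G_x}, \qquad
  G_x = \frac{1}{n}\sum_i P_{i,x}, \qquad
  SI_i = \log_2 \frac{NI_{i,1}}{NI_{i,2}}.$$

A gene is called alternatively spliced when any $|SI_i| \ge 0.5$.  The
gene signal $G_x$ is the unweighted mean over probe sets — weighting by
probe-set size was considered and rejected, as the gene-level signal is
defined as the average of probe-set expressions.  Intensities are linear
scale at the interface (the index is a ratio); `log2_input = TRUE`
exponentiates first, since upstream summarization tools usually emit log2
values.  Useful identities, all asserted in tests: the mean of $NI_{i,x}$
over a gene's sets is 1; swapping condition labels negates every $SI$;
rescaling all of one condition's signals leaves every $SI$ unchanged —
which is why the index tolerates the strong 3'-position signal bias of
oligo-dT-amplified arrays better than ANOVA-style probe models.
Single-set genes are skipped with a reason (their $NI \equiv 1$ carries no
splicing information) and reported with gene-level expression only.

Differential expression is consumed, not computed: `select_de()` applies
the conventional cutoffs (adjusted p strictly below 0.05, fold change at
least 2 or at most 0.5) to externally computed statistics, and
`bh_adjust()` provides the Benjamini-Hochberg step-up via
`stats::p.adjust`.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions used throughout the
tests:

* **Layout** — 8 genes of 3 × 200-base exons separated by 200-base
  introns, 1000-base intergenic gaps, alternating strands; each gene has a
  full-length isoform and a cassette-exon skip isoform sharing the CDS.  A
  single-exon decoy gene pair overlaps only in UTR sequence, which
  separates `exlink` from `overlap_0` by exactly one gene.
* **Planted probes** — exact per-category counts (default 5 per filter
  category, 15 good probes in sets of 3, 3 junction probes) are
  *constructed*, never rejection-sampled: duplicated 25-mers are copied
  between two reserved scratch regions, intergenic probes come from a
  reserved zone, orphan groups are planted in cassette exons whose
  signature differs from the good groups'.  A verification pass re-matches
  every probe and errors on the (astronomically unlikely) random
  collision, so truth counts are exact by construction.  The planted
  categories refer to the default coding-exon-overlap gene definition.
* **Expression** — 200 genes with 2 probe sets each, 3 replicates per
  condition, per-gene log-normal baselines (meanlog `log(500)`, sdlog 1),
  balanced probe-set abundance within a gene, a 4-fold isoform switch
  planted in half the genes, and multiplicative log-normal noise with
  natural-log sd 0.1 — matching a typical well-powered two-condition
  array comparison.  With balanced sets the planted fold `f` gives a
  closed-form index: $\log_2((1+f)/2)$ on the unaffected set and
  $\log_2((1+f)/(2f))$ on the affected one, i.e. ±1.32/−0.68 at `f = 4`,
  comfortably beyond the 0.5 threshold.

Within-gene baselines are balanced deliberately: the index of a `f`-fold
switch shrinks toward zero as the affected isoform's share of the gene
signal shrinks, so an unbalanced generator would conflate detection power
with abundance composition.  Real data are messier in exactly the ways the
generator omits: probe-specific affinity and GC effects, 3'-positional
bias within probe sets, correlated (not i.i.d.) replicate noise,
cross-hybridization below exact-match stringency, and genome sequence that
is anything but uniformly random.  Passing tests therefore demonstrate
correctness of the algorithms under their stated assumptions, not
performance on any particular array experiment.

All generator randomness flows from one integer seed through R's default
generator, seeded once per generator call (`seed`, `seed + 1`, `seed + 2`
for annotation, probes, expression); identical seeds give byte-identical
outputs.

## Numerical and degenerate-input choices

* Percentages and summary ratios are reported to three decimals, matching
  the precision of the published tables the accounting reproduces.
* Probe-set numbering ties (two groups with equal leftmost start) break on
  signature then sense, keeping file output byte-stable across runs and
  input orderings; provenance headers carry no timestamps for the same
  reason.
* Degenerate inputs: empty collections and empty probe tables flow through
  every stage; a transcript referencing a chromosome absent from the
  genome is skipped with a warning during junction rescue; zero or
  negative intensities are an error (the index is undefined), as are
  p-values outside [0, 1].
* `cluster_by_xref()` splits an external gene whose transcripts occupy
  several (chromosome, strand) loci into per-locus models, because the
  probe classifier requires single-locus genes; transcripts missing from
  the cross-reference become logged singletons.

## Problem sizes used in the checks

The shipped test and acceptance runs use 200-transcript random collections
over 100 seeds for the clustering cross-check, 150-transcript collections
for the coarseness ordering, the default planted fixture (about 50 probes
over a 20 kb genome) for end-to-end truth recovery, and 200 simulated
genes for Splicing-Index recovery — sizes at which the naive quadratic
oracle remains an exact, independently computed reference.

## Known limitations

* Only exact 25-mer matching is implemented; near-matches that would
  cross-hybridize on a real array are out of scope.
* Binary chip-description containers are not produced; probe-set
  definitions are plain TSV.
* GTF/GFF3 ingestion is not provided (genePred and PSL only).
* The moderated t-statistics feeding `select_de()` must be computed
  upstream (e.g. with limma); the package deliberately does not refit
  them.
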