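---
title: "txome: object model, iterators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{txome: object model, iterators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model behind `txome`, the conventions it fixes,
the places where the design was genuinely open and what was decided there,
and what the synthetic test data does and does not demonstrate.

## The object model

`txome` separates three things that are often conflated:

1. **Locations** — immutable genomic intervals (chromosome, 1-based
   inclusive start/stop, strand). Interval sets are tibbles, so equality is
   value-based and `gi_key()` gives a canonical string key; nothing ever
   mutates a location in place.
2. **Order** — a reference dictionary (RefDict), the ordered
   chromosome → length map every dataset carries. All sorting, merging and
   joining is defined relative to a RefDict, and operations that combine
   datasets first check that their RefDicts agree.
3. **Data** — mutable payloads and annotations attached *next to* the
   frozen locations: iterator items pair a location with a format-specific
   payload; the Transcriptome keeps an external annotation store keyed by
   feature identity.

A Transcriptome is the parsed gene → transcript → exon/intron/CDS/UTR
hierarchy from a GTF/GFF3 file, with every feature frozen after
construction, children sorted in genomic order, and parent/child
containment verified at build time (violations are build errors, not
warnings).

## Coordinate and strand conventions

Internally everything is **1-based, fully closed**; the length of an
interval is `end - start + 1`. This matches GFF/GTF/VCF/SAM, the primary
inputs. The BED and bedGraph adapters convert at the boundary (`start + 1`
on read, `start - 1` on write), and the BED round-trip is bit-exact — a
tested invariant, because silent off-by-one shifts are the single most
common integration bug in this space.

Strand is three-valued (`+`, `-`, `.`); `.` and missing values mean
unstranded. Overlap tests ignore strand unless asked
(`strand_specific = TRUE`), in which case an unstranded side matches both
strands. Most overlap joins in transcriptomics practice are strand-agnostic
(reads from unstranded libraries, variant tracks), which is why
strand-agnostic is the default and strand-specificity is an opt-in on the
join, not a property of the data.

Two smaller conventions worth stating explicitly:

- `gi_merge()` coalesces **book-ended** intervals (`stop + 1 == next
  start`). This makes merge output identical to the per-base union, which
  is the oracle the tests use. Callers that want touching-but-separate
  intervals must pre-filter.
- Sorting orders by (RefDict chromosome index, start, stop), so shorter
  intervals precede longer ones at equal starts. Features with fully equal
  coordinates additionally order by type rank
  (gene < transcript < exon < intron < CDS < UTRs) and then ID, making
  iteration order fully deterministic: parsing the same file twice yields
  the same sequence, byte for byte.

## RefDict compatibility

Two dictionaries are incompatible when a shared chromosome differs in
length, or when shared chromosomes appear in contradictory relative order —
the latter because a sorted k-way merge over such streams would silently
interleave wrongly; order conflicts are therefore hard errors at the few
places that escalate (sequence loading tolerates pure order differences,
stream merging does not). Chromosome name normalisation is **never**
automatic: `"1"` and `"chr1"` are different chromosomes unless the caller
passes an alias table. Silent renaming is exactly the class of bug the
check exists to catch, so the two dictionaries simply come out as disjoint
but compatible, which downstream code can then notice.

## Parsing: dialects, flavors, synthesized parents

The GTF vs GFF3 dialect is detected from the attribute column
(`key "value";` vs `key=value`) and can be forced per flavor. Flavor tables
map each provider's feature-type vocabulary and attribute keys onto the
canonical model; rows with unmapped types (e.g. `chromosome`,
`biological_region`, `start_codon`) are skipped with a *counted* warning —
real files carry many auxiliary types and failing on them would make the
parser useless. The gene-type attribute key is provider-specific
(`gene_type` for GENCODE-style files, `biotype` for Ensembl GFF3); the
generic flavor uses `gene_type`, and both the key and the type map can be
overridden for custom formats.

GTF dialects that omit gene and/or transcript rows (UCSC-style exports,
microRNA annotations) get those parents synthesized as the span of their
children, so the hierarchy is uniform downstream. Transcripts without exon
rows get one synthetic exon spanning the transcript, which keeps the
spliced-sequence logic free of special cases. In the GFF3 dialect a
`Parent` that does not resolve is an error naming the orphan ID — there is
no attribute from which to synthesize it.

Introns are inferred per transcript from the gaps between consecutive
exons; book-ended exon pairs produce none. Transcripts that share intron
coordinates get **separate** intron features, each parented to its own
transcript: parentage stays a tree, IDs stay deterministic
(`<transcript>_intron<k>`, numbered in genomic order), and the annotation
store can hold per-transcript intron annotations without aliasing
surprises. The cost — a few duplicate coordinate rows — is negligible at
annotation scale.

Filters (region, feature IDs, gene types) compose as AND and are applied
while parsing, so excluded features are never instantiated. Region
filtering keeps a gene iff it *overlaps* the region, matching the typical
"load chr21 only" usage where boundary-straddling genes should load.

## Sequences: gene-level storage, lazy slicing, translation

Sequences are cached at **gene level only**, always as the plus-strand
genomic sequence. Any descendant's sequence is sliced from its gene on
request: `genomic` is the raw slice, `oriented` reverse-complements on the
minus strand, `spliced` concatenates exon sequences in transcript (5'→3')
order, and `translated` concatenates CDS segments 5'→3' before translating.
The same slicing applies to per-base (*positional*) annotations attached to
genes, so a coverage vector stored once per gene is readable, correctly
oriented, on any exon or intron.

Translation follows the GFF3 phase definition: the phase of the *first* CDS
segment in 5'→3' order (the last genomic segment on the minus strand) is
skipped, trailing bases short of a codon are dropped, stop codons render as
`*`, and codons containing ambiguous bases render as `X`. Annotation
sources disagree on whether phases are populated; a missing phase is taken
as 0, the common case for complete CDSs.

## Iterators: sorted streams and the single-pass join

Every adapter yields items strictly in sort order and verifies it as items
are pulled: an item starting before its predecessor, or returning to an
earlier chromosome, raises an unsorted-input error naming the record.
Sortedness is checked on (chromosome, start) — not on stop — because
coordinate-sorted BAMs guarantee nothing about end positions at equal
starts, and rejecting `samtools sort` output would be absurd.

Region-restricted access goes through the file's index (tabix for bgzipped
text, `.bai` for BAM); asking for a region on an unindexed file is a
capability error rather than a silent full scan. An alignment's location is
its full reference span from the CIGAR — matches, deletions *and* splices —
so overlap semantics agree with what index queries return; per-base
operations (the mismatch profiler) walk the aligned pairs instead. A VCF
record spans its REF allele (`POS .. POS + len(REF) - 1`); symbolic
alleles carry no reference length beyond that and fall back to the
single-base span with a warning.

`annotation_iterator()` implements the overlap join as a single pass with
one sliding buffer per source: items are buffered while they may still
overlap a future anchor and evicted once their end falls before the current
anchor's start. Correctness relies only on anchors being sorted by start —
a stated precondition, enforced by the stream machinery, not an assumption.
Because anchors may themselves overlap, buffered items are re-checked
against each anchor, so one item can (correctly) appear in several bundles.
Every configured source label is present in every bundle, even when empty;
an instrumented counter in the tests verifies each source record is parsed
exactly once per join.

Quantitative tracks are served by the bedGraph adapter; BigWig, a purely
binary format, is not read — converting with standard tooling
(`bigWigToBedGraph`) is the supported path. This keeps the package and its
test suite free of binary-format dependencies.

## Export

`write_gff3()` reproduces the hierarchy exactly — `ID`/`Parent`
attributes, percent-encoded values, `##sequence-region` pragmas from the
RefDict — and re-parsing its output yields identical coordinates, types,
IDs and parentage (a tested round trip). Inferred introns are written only
on request, since most consumers re-infer them and round-trip fidelity to
the input's explicit feature set is the safer default. Scalar annotations
can be serialized as extra attributes; anything non-scalar is an error
naming the label, never a silent `toString()`. Numbers render with `.` as
the decimal separator regardless of locale.

## The tools

The mismatch profiler reports counts in **read orientation**: bases of
minus-strand reads are complement-adjusted, so a T→C conversion counts as
T→C whichever strand the read maps to — the convention under which
metabolic-labelling chemistry (T→C from 4sU) is interpreted. Defaults
follow common practice and are all exposed as flags, since no single
standard exists: exclude unmapped/secondary/supplementary/duplicate reads,
mapping quality ≥ 0, base quality ≥ 10. Bases over reference N are
excluded. Overlapping mate pairs would be double-counted; the fixture reads
are single-end and mate de-duplication is out of scope.

`annotate_conversions()` drives the same per-base counter through the
overlap-join loop, memoising per-read conversion counts so reads spanning
several transcripts are inspected once, and always emits a row per
transcript (zeros, not missing, when nothing overlaps).

## The fixture generator

The generator emulates exactly what the tests need to have known truth:
random uniform genomes (≤ 100 kb per chromosome, so per-base brute-force
oracles stay sub-second), non-overlapping genes on both strands with
sampled transcript/exon structures (exon gaps ≥ 2 bases so intron inference
is exercised, one lncRNA gene so type filtering has a victim), ungapped
perfectly-placed reads with independent per-base errors, and T→C
conversions applied per template T at a configured rate with the applied
count recorded in each read's `nc:i` tag. Every file is a pure function of
the seed — regeneration is byte-identical — and each artifact ships a
manifest of the truths tests assert against.

What it deliberately does **not** emulate: spliced (N-CIGAR) alignments,
indels, quality-score variation, mate pairs, GC bias, or realistic error
models. Passing tests therefore demonstrate the correctness of the
*machinery* — coordinate handling, joins, counting, round trips — on
idealized data, not robustness to the full messiness of real libraries.
Default simulation sizes (two chromosomes of 10 kb/6 kb, six genes,
coverage 10, 50 bp reads; ~20k template Ts in the conversion fixture) were
chosen so binomial checks on the 10% conversion rate have tight expected
error (3σ ≈ 0.6%) while the whole suite runs in about a minute.

## Verification sizes and known limitations

The property checks run at these sizes: 1 000 random range queries against
a linear-scan oracle; an overlap join of 400 anchors against three sources
of 2 000 random intervals each, against the all-pairs oracle; per-base
tiling/merge checks on chromosomes ≤ 10 kb; and full round trips of every
fixture file. The gene range index is a per-chromosome binary search on
sorted starts with an end filter; an independent cross-check against
`GenomicRanges::findOverlaps` runs in the test suite.

Known limitations: no liftover or assembly remapping; no CRAM; no BigWig;
no remote annotation services (the join accepts any stream, which is the
extension point); no haplotype-aware transcriptomes; GFF3 feature types
outside the canonical seven are skipped, not modelled; streams are
single-use (reopen to iterate again), and text-format streams materialize
the file's lines before lazily parsing records, which favours correctness
and simplicity over constant-memory scanning of very large uncompressed
files — indexed access is the intended route for those.
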