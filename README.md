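# txome

Transcriptomics analyses constantly re-solve the same plumbing problems:
associating gene features (transcript isoforms, introns, UTRs) with the
relevant subsections of large genomics datasets across many file formats,
querying those data by genomic location and annotation attributes, and doing
all of it without falling into the classic traps — 0-based vs 1-based
coordinates, unsorted files, contradictory chromosome orders. `txome` is an R
toolkit for building such analyses. It provides:

- **Genomic intervals** — immutable 1-based, fully closed locations
  (`chrom`, `start`, `end`, `strand`) held in tidy tibbles, with a complete
  interval algebra: overlap, envelopment, distance, merging (book-ended
  intervals coalesce), sorting and tiling. Any component may be unset, so an
  interval can reference a whole chromosome or "the first 100 kb of any
  chromosome", and `gi_key()` renders a value-based key for use in mapping
  structures.
- **Reference dictionaries (RefDicts)** — ordered chromosome → length maps
  built automatically from `.fai` files, SAM/BAM headers or tabix indices.
  They define the global sort order and power a compatibility check that
  refuses to integrate datasets whose shared chromosomes conflict in length
  or relative order. Chromosome renaming (`"1"` vs `"chr1"`) is never
  silent; you pass an explicit alias table.
- **A Transcriptome container** — GTF/GFF3 parsed (Ensembl, GENCODE, UCSC,
  FlyBase, WormBase, CHESS, MirGeneDB or custom attribute mappings) into a
  frozen gene → transcript → exon/intron/CDS/UTR hierarchy with inferred
  introns, indexed lookups by ID, name (with aliasing) and range, filters by
  region / IDs / gene type applied during parsing, and an external
  annotation store. Sequences load from an indexed FASTA **at gene level
  only**; spliced and translated transcript sequences (and any per-base
  annotation on a gene) are sliced and orientation-adjusted on request.
- **Sorted genomic iterators** — one `open_iterator()` over BED, bedGraph,
  GFF3/GTF, VCF, SAM/BAM and FASTA windows, converting every format to the
  internal coordinate convention, verifying sortedness as items are pulled,
  and using tabix/BAM indices for region-restricted access without a full
  scan. Streams can be grouped by overlap, tiled, merged (k-way, stable),
  and joined with the single-pass `annotation_iterator()`, which hands every
  anchor its overlapping items from any number of labelled sources.
- **Exporters** — BED6 and round-trip-faithful GFF3 writers plus
  `to_table()` with user-defined column specifications.
- **Tools** — `mismatch_profile()` (per-base reference/read nucleotide
  tallies from alignments, reported in read orientation and split by
  strand) and `annotate_conversions()` (per-transcript T→C conversion
  counts, as produced by metabolic RNA-labelling chemistry), both with
  `tidy()`/`glance()`/`autoplot()` methods, also exposed as a command-line
  script (`inst/cli/txome-tools.R`).
- **A deterministic fixture generator** — seeded synthetic genome,
  annotation, tracks, variants and reads (with known conversion/error
  rates, truth recorded in manifests and `nc:i` tags) used by the whole
  test suite; no download needed.

## Worked example

```r
library(txome)

cfg <- fixture_config(seed = 42, conversion_rate = 0.1)
fx  <- make_fixture_suite(cfg, file.path(tempdir(), "demo"))

tx <- read_transcriptome(fx$annotation$gff3)
tx
#> Transcriptome <.../demo/annotation.gff3> (flavor: generic)
#>   gene: 6, transcript: 8, exon: 14, intron: 6, CDS: 13, five_prime_UTR: 0, three_prime_UTR: 0
#>   chromosomes: chr1, chr2

tx_load_sequences(tx, fx$genome$fasta)        # gene-level cache only
tx_sequence(tx, "g4.t1", "spliced")           # mature RNA, 5'->3'

mp <- mismatch_profile(fx$reads$sam, fx$genome$fasta)
glance(mp)
#>   n_reads n_bases n_mismatches mismatch_rate tc_rate
#> 1    1217   60850         1509        0.0248   0.101

annotate_conversions(fx$reads$sam, fx$genome$fasta, fx$annotation$gff3)
#>   transcript_id n_reads n_converted frac_converted
#> 1 g4.t1             239         172          0.720
#> 2 g6.t1             322         221          0.686
#> ...

to_table(tx_query(tx, "chr1:1-10000", "gene"),
         column_spec(chrom = "chrom", start = "start", stop = "end",
                     name = attr_col("gene_name"), type = attr_col("gene_type")))
#>   chrom start  stop name  type
#> 1 chr1      9  1204 GENE4 protein_coding
#> 2 chr1   3144  3946 GENE6 protein_coding
#> 3 chr1   7557  8512 GENE3 protein_coding
#> 4 chr1   9400  9760 GENE2 lncRNA
```

The numbers read as follows: the simulated library converts each template T
to C with probability 0.1, and the mismatch profiler recovers `tc_rate =
0.101` — the T→C fraction among aligned T positions in read orientation —
while the overall `mismatch_rate` also includes the conversions themselves.
`annotate_conversions()` counts, per transcript, overlapping reads and reads
carrying at least one T→C mismatch; with ~50 Ts per read and a 10%
per-T conversion rate, roughly 70% of reads carry one or more conversions,
matching `frac_converted`.

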