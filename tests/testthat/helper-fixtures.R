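# Session-cached fixture suites (built once, reused across test files) and a
# hand-built micro transcriptome with fully known coordinates and sequence.

.fixture_cache <- new.env()

get_fixture <- function(name = c("base", "conversion", "errors")) {
  name <- match.arg(name)
  hit <- .fixture_cache[[name]]
  if (!is.null(hit)) return(hit)
  cfg <- switch(name,
    base = fixture_config(seed = 101L),
    conversion = fixture_config(seed = 202L, conversion_rate = 0.1),
    errors = fixture_config(seed = 303L, base_error_rate = 0.01))
  dir <- file.path(tempdir(), paste0("txome-fx-", name))
  fx <- make_fixture_suite(cfg, dir, bam = (name == "base"))
  out <- list(cfg = cfg, fx = fx, dir = dir)
  .fixture_cache[[name]] <- out
  out
}

# micro transcriptome: 2 genes / 3 transcripts / 7 exons (=> 4 inferred
# introns), one lncRNA gene, one minus-strand gene, a CDS translating to MK*
micro_fasta <- function(dir = tempdir()) {
  # chrM, 100 bp; positions 1-9 spell ATGAAATAG so tA1's CDS translates MK*
  seq <- substr(paste0("ATGAAATAG", strrep("ACGT", 25)), 1, 100)
  path <- file.path(dir, "micro.fa")
  writeLines(c(">chrM", substr(seq, 1, 60), substr(seq, 61, 100)), path)
  writeLines(sprintf("chrM\t100\t%d\t60\t61", nchar(">chrM") + 1L),
             paste0(path, ".fai"))
  list(fasta = path, seq = seq)
}

micro_gff3 <- function(dir = tempdir()) {
  path <- file.path(dir, "micro.gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chrM 1 100",
    "chrM\ttest\tgene\t1\t40\t.\t+\t.\tID=geneA;gene_name=AAA;gene_type=protein_coding",
    "chrM\ttest\ttranscript\t1\t40\t.\t+\t.\tID=tA1;Parent=geneA",
    "chrM\ttest\texon\t1\t10\t.\t+\t.\tParent=tA1",
    "chrM\ttest\texon\t21\t30\t.\t+\t.\tParent=tA1",
    "chrM\ttest\tCDS\t1\t9\t.\t+\t0\tParent=tA1",
    "chrM\ttest\ttranscript\t1\t40\t.\t+\t.\tID=tA2;Parent=geneA",
    "chrM\ttest\texon\t1\t12\t.\t+\t.\tParent=tA2",
    "chrM\ttest\texon\t21\t40\t.\t+\t.\tParent=tA2",
    "chrM\ttest\tgene\t51\t90\t.\t-\t.\tID=geneB;gene_name=BBB;gene_type=lncRNA",
    "chrM\ttest\ttranscript\t51\t90\t.\t-\t.\tID=tB1;Parent=geneB",
    "chrM\ttest\texon\t51\t60\t.\t-\t.\tParent=tB1",
    "chrM\ttest\texon\t67\t72\t.\t-\t.\tParent=tB1",
    "chrM\ttest\texon\t81\t90\t.\t-\t.\tParent=tB1"
  ), path)
  path
}

micro_transcriptome <- function(dir = tempdir()) {
  read_transcriptome(micro_gff3(dir))
}

# brute-force overlap oracle over two interval tibbles: list (per row of a)
# of indices of b overlapping it
oracle_overlaps <- function(a, b, strand_specific = FALSE) {
  lapply(seq_len(nrow(a)), function(i) {
    which(gi_overlaps(b, a[i, , drop = FALSE],
                      strand_specific = strand_specific))
  })
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L,
                             max_len = 60L) {
  start <- sample(seq_len(max_pos), n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = pmin(start + sample(0:max_len, n, replace = TRUE), max_pos + max_len),
    strand = sample(c("+", "-", "."), n, replace = TRUE))
}

sorted_memory_stream <- function(df, rd) {
  k <- gi_sort_key(as_gi(df), rd)
  memory_stream(df[order(k$cidx, k$start, k$end), , drop = FALSE],
                refdict = rd)
}
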