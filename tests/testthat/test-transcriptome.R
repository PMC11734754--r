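test_that("the micro annotation builds the exact hierarchy with inferred introns", {
  tx <- micro_transcriptome()
  cnt <- table(tx$features$feature_type)
  expect_equal(as.integer(cnt[["gene"]]), 2L)
  expect_equal(as.integer(cnt[["transcript"]]), 3L)
  expect_equal(as.integer(cnt[["exon"]]), 7L)
  expect_equal(as.integer(cnt[["intron"]]), 4L)
  # intron coordinates are exactly the exon gaps
  introns <- tx_children(tx, "tA1", "intron")
  expect_equal(c(introns$start, introns$end), c(11L, 20L))
  expect_equal(introns$feature_id, "tA1_intron1")
  iB <- tx_children(tx, "tB1", "intron")
  expect_equal(iB$start, c(61L, 73L))
  expect_equal(iB$end, c(66L, 80L))
  expect_equal(iB$feature_id, c("tB1_intron1", "tB1_intron2"))
})

test_that("intron inference handles gaps, single exons and book-ended exons", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "introns.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t20\t.\t+\t.\tID=g1",
    "chr1\tt\ttranscript\t1\t9\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tt\texon\t1\t3\t.\t+\t.\tParent=t1",
    "chr1\tt\texon\t7\t9\t.\t+\t.\tParent=t1",
    "chr1\tt\ttranscript\t1\t6\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\tt\texon\t1\t6\t.\t+\t.\tParent=t2",
    "chr1\tt\ttranscript\t1\t6\t.\t+\t.\tID=t3;Parent=g1",
    "chr1\tt\texon\t1\t3\t.\t+\t.\tParent=t3",
    "chr1\tt\texon\t4\t6\t.\t+\t.\tParent=t3"), p)
  tx <- read_transcriptome(p)
  i1 <- tx_children(tx, "t1", "intron")
  expect_equal(c(i1$start, i1$end), c(4L, 6L))
  expect_equal(nrow(tx_children(tx, "t2", "intron")), 0L)  # single exon
  expect_equal(nrow(tx_children(tx, "t3", "intron")), 0L)  # book-ended
  expect_equal(nrow(infer_introns(tx, "t2")), 0L)
  expect_equal(infer_introns(tx, "t1")$start, 4L)
})

test_that("fixture manifest counts match the parsed transcriptome exactly", {
  fixt <- get_fixture("base")
  tx <- read_transcriptome(fixt$fx$annotation$gff3)
  man <- fixt$fx$annotation$manifest
  cnt <- table(factor(tx$features$feature_type,
                      levels = c("gene", "transcript", "exon", "intron",
                                 "CDS")))
  expect_equal(as.integer(cnt[["gene"]]), man$n_genes)
  expect_equal(as.integer(cnt[["transcript"]]), man$n_transcripts)
  expect_equal(as.integer(cnt[["exon"]]), man$n_exons)
  expect_equal(as.integer(cnt[["intron"]]), man$n_introns)
  expect_equal(as.integer(cnt[["CDS"]]), man$n_cds)
  # every reachable feature is indexed exactly once
  expect_equal(length(tx$id_index), nrow(tx$features))
  expect_false(anyDuplicated(names(tx$id_index)) > 0L)
})

test_that("gene-type, region and ID filters compose during parsing", {
  tx <- read_transcriptome(micro_gff3(), gene_types = "protein_coding")
  expect_equal(tx_features(tx, "gene")$feature_id, "geneA")
  tx2 <- read_transcriptome(micro_gff3(), gene_types = "lncRNA")
  expect_equal(tx_features(tx2, "gene")$feature_id, "geneB")
  tx3 <- read_transcriptome(micro_gff3(), feature_ids = "tA1")
  expect_equal(tx_features(tx3, "transcript")$feature_id, "tA1")
  expect_equal(tx_features(tx3, "gene")$feature_id, "geneA")

  fixt <- get_fixture("base")
  bgz <- index_annotation(fixt$fx$annotation$gff3)
  full <- read_transcriptome(fixt$fx$annotation$gff3)
  chr2_genes <- tx_features(full, "gene")
  chr2_genes <- chr2_genes[chr2_genes$chrom == "chr2", ]
  restricted <- read_transcriptome(bgz, region = "chr2")
  expect_setequal(tx_features(restricted, "gene")$feature_id,
                  chr2_genes$feature_id)
})

test_that("build errors name orphan parents and containment violations", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "orphan.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t20\t.\t+\t.\tID=g1",
    "chr1\tt\ttranscript\t1\t20\t.\t+\t.\tID=t1;Parent=gMISSING"), p)
  expect_error(read_transcriptome(p), "gMISSING")

  p2 <- file.path(dir, "contain.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t10\t20\t.\t+\t.\tID=g1",
    "chr1\tt\ttranscript\t10\t25\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tt\texon\t10\t25\t.\t+\t.\tParent=t1"), p2)
  expect_error(read_transcriptome(p2), "extends outside")

  p3 <- file.path(dir, "overlap-exons.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t20\t.\t+\t.\tID=g1",
    "chr1\tt\ttranscript\t1\t20\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tt\texon\t1\t10\t.\t+\t.\tParent=t1",
    "chr1\tt\texon\t8\t20\t.\t+\t.\tParent=t1"), p3)
  expect_error(read_transcriptome(p3), "overlapping exon")
})

test_that("ID and name lookup distinguish misses from errors and support aliases", {
  tx <- micro_transcriptome()
  expect_equal(tx_feature(tx, "tA1")$feature_type, "transcript")
  expect_null(tx_feature(tx, "absent"))
  expect_equal(tx_gene_by_name(tx, "AAA")$feature_id, "geneA")
  expect_null(tx_gene_by_name(tx, "absent"))
  expect_equal(tx_gene_by_name(tx, "OldName",
                               aliases = c(OldName = "BBB"))$feature_id,
               "geneB")
  # ambiguity is an error listing candidates
  dir <- withr::local_tempdir()
  p <- file.path(dir, "dupname.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t10\t.\t+\t.\tID=g1;gene_name=SAME",
    "chr1\tt\tgene\t30\t40\t.\t+\t.\tID=g2;gene_name=SAME"), p)
  txd <- read_transcriptome(p)
  expect_error(tx_gene_by_name(txd, "SAME"), "ambiguous.*g1.*g2")
})

test_that("range queries equal a brute-force scan of the feature table", {
  fixt <- get_fixture("base")
  tx <- read_transcriptome(fixt$fx$annotation$gff3)
  set.seed(41)
  rd <- tx$refdict
  for (i in 1:200) {
    chrom <- sample(rd$chrom, 1L)
    s <- sample(seq_len(rd$length[match(chrom, rd$chrom)]), 1L)
    e <- min(s + sample(0:3000, 1L), rd$length[match(chrom, rd$chrom)])
    region <- gi(chrom, s, e)
    ftype <- sample(c("gene", "transcript", "exon", "intron"), 1L)
    got <- tx_query(tx, region, ftype)
    all_f <- tx_features(tx, ftype)
    want <- all_f[gi_overlaps(all_f, region), ]
    expect_identical(got$feature_id, want$feature_id)
    gotE <- tx_query(tx, region, ftype, envelop_only = TRUE)
    wantE <- all_f[gi_envelops(region, all_f), ]
    expect_identical(gotE$feature_id, wantE$feature_id)
  }
  expect_error(tx_query(tx, gi("chrZZ", 1, 10)), "chrZZ")
  # independent cross-check of the gene index against GenomicRanges
  genes <- tx_features(tx, "gene")
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  for (i in 1:50) {
    chrom <- sample(rd$chrom, 1L)
    s <- sample(seq_len(rd$length[match(chrom, rd$chrom)]), 1L)
    region <- gi(chrom, s, s + 2500L)
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + 2500L)), gr)
    want_ids <- sort(genes$feature_id[S4Vectors::subjectHits(hits)])
    expect_equal(sort(tx_query(tx, region, "gene")$feature_id), want_ids)
  }
  # a region strictly inside an intron contains no exon
  tx_m <- micro_transcriptome()
  expect_equal(nrow(tx_query(tx_m, gi("chrM", 14, 18), "exon")), 0L)
  # whole-chromosome region returns every gene on it
  expect_equal(nrow(tx_query(tx_m, gi("chrM"), "gene")), 2L)
})

test_that("hierarchy closure: every non-gene feature is enveloped by its parent", {
  for (tx in list(micro_transcriptome(),
                  read_transcriptome(get_fixture("base")$fx$annotation$gff3))) {
    f <- tx$features
    nong <- f[!is.na(f$parent_id), ]
    parents <- f[match(nong$parent_id, f$feature_id), ]
    expect_true(all(gi_envelops(parents, nong)))
    # parent/child links are mutual
    for (i in sample(nrow(nong), min(25, nrow(nong)))) {
      kids <- tx_children(tx, nong$parent_id[i])
      expect_true(nong$feature_id[i] %in% kids$feature_id)
      expect_equal(tx_parent(tx, nong$feature_id[i])$feature_id,
                   nong$parent_id[i])
    }
    # children are sorted in genomic order
    expect_false(is.unsorted(tx_children(tx, f$feature_id[1L])$start))
  }
})

test_that("building the same file twice is fully deterministic", {
  fixt <- get_fixture("base")
  tx1 <- read_transcriptome(fixt$fx$annotation$gff3)
  tx2 <- read_transcriptome(fixt$fx$annotation$gff3)
  expect_identical(tx1$features$feature_id, tx2$features$feature_id)
  expect_identical(as.data.frame(tx1$features[1:6]),
                   as.data.frame(tx2$features[1:6]))
})

test_that("GTF dialect parses and synthesizes missing parent rows", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ucsc.gtf")
  writeLines(c(
    paste0("chr1\tt\texon\t1\t10\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tt\texon\t21\t30\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tt\tCDS\t1\t9\t.\t+\t0\t",
           'gene_id "g1"; transcript_id "t1";')), p)
  tx <- read_transcriptome(p, flavor = "ucsc")
  expect_equal(tx_features(tx, "gene")$feature_id, "g1")
  t1 <- tx_feature(tx, "t1")
  expect_equal(c(t1$start, t1$end), c(1L, 30L))
  expect_equal(nrow(tx_children(tx, "t1", "exon")), 2L)
  expect_equal(nrow(tx_children(tx, "t1", "intron")), 1L)
})

test_that("unmapped feature types are skipped with a counted warning", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "aux.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tchromosome\t1\t1000\t.\t.\t.\tID=chr1",
    "chr1\tt\tgene\t1\t20\t.\t+\t.\tID=g1",
    "chr1\tt\tbiological_region\t5\t6\t.\t+\t.\tID=b1"), p)
  expect_warning(tx <- read_transcriptome(p), "skipped 2")
  expect_equal(sum(tx$skipped_types), 2L)
  expect_equal(nrow(tx$features), 1L)
})
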