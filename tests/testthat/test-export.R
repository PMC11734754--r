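test_that("BED export inverts the coordinate convention and round-trips", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "one.bed")
  write_bed(as_gi(data.frame(chrom = "chr1", start = 1L, end = 10L,
                             strand = "+")), out)
  expect_equal(readLines(out), "chr1\t0\t10\t.\t0\t+")
  # empty input -> empty file, no header
  write_bed(as_gi(data.frame(chrom = character(), start = integer(),
                             end = integer())), file.path(dir, "empty.bed"))
  expect_length(readLines(file.path(dir, "empty.bed")), 0L)
  # fixture stream round-trip preserves the location sequence exactly
  fixt <- get_fixture("base")
  src <- stream_collect(open_iterator(fixt$fx$tracks$bed, "bed"))
  rt <- file.path(dir, "rt.bed")
  write_bed(open_iterator(fixt$fx$tracks$bed, "bed"), rt,
            name_from = "name", score_from = "score")
  back <- stream_collect(open_iterator(rt, "bed"))
  expect_equal(back$chrom, src$chrom)
  expect_equal(back$start, src$start)
  expect_equal(back$end, src$end)
  expect_equal(back$strand, src$strand)
  # scores are clamped to 0..1000
  write_bed(as_gi(data.frame(chrom = "chr1", start = 1L, end = 2L,
                             score = 5000)), file.path(dir, "clamp.bed"),
            score_from = "score")
  expect_match(readLines(file.path(dir, "clamp.bed")), "\t1000\t")
})

test_that("GFF3 export round-trips through a second parse and build", {
  dir <- withr::local_tempdir()
  for (src in list(micro_transcriptome(dir),
                   read_transcriptome(get_fixture("base")$fx$annotation$gff3))) {
    out <- file.path(dir, "rt.gff3")
    write_gff3(src, out)
    lines <- readLines(out)
    expect_equal(lines[1L], "##gff-version 3")
    expect_true(any(startsWith(lines, "##sequence-region")))
    back <- read_transcriptome(out)
    cols <- c("chrom", "start", "end", "strand", "feature_id",
              "feature_type", "parent_id")
    expect_identical(as.data.frame(src$features[cols]),
                     as.data.frame(back$features[cols]))
    # structural validity: unique IDs, resolvable Parents, sorted rows
    dat <- lines[!startsWith(lines, "#")]
    ids <- sub(".*ID=([^;]+).*", "\\1", dat)
    expect_false(anyDuplicated(ids) > 0L)
    parents <- sub(".*Parent=([^;]+).*", "\\1", dat[grepl("Parent=", dat)])
    expect_true(all(parents %in% ids))
  }
})

test_that("introns are exported only on request", {
  dir <- withr::local_tempdir()
  tx <- micro_transcriptome(dir)
  write_gff3(tx, file.path(dir, "no-introns.gff3"))
  expect_false(any(grepl("\tintron\t", readLines(file.path(dir, "no-introns.gff3")))))
  write_gff3(tx, file.path(dir, "with-introns.gff3"), include_introns = TRUE)
  back <- read_transcriptome(file.path(dir, "with-introns.gff3"))
  expect_equal(nrow(tx_features(back, "intron")), 4L)
})

test_that("attribute values are percent-encoded and annotations serialized", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "esc.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t10\t.\t+\t.\tID=g1;note=a%3Bb%3Dc"), p)
  tx <- read_transcriptome(p)
  expect_equal(unname(tx$features$attrs[[1L]]["note"]), "a;b=c")
  out <- file.path(dir, "esc-out.gff3")
  tx_set_annotation(tx, "g1", "score", 4.25)
  write_gff3(tx, out, include_annotations = "score")
  line <- grep("\tgene\t", readLines(out), value = TRUE)
  expect_match(line, "note=a%3Bb%3Dc", fixed = TRUE)
  expect_match(line, "score=4.25", fixed = TRUE)
  back <- read_transcriptome(out)
  expect_equal(unname(back$features$attrs[[1L]]["note"]), "a;b=c")
  # non-scalar annotations are a serialization error naming the label
  tx_set_annotation(tx, "g1", "vec", 1:3)
  expect_error(write_gff3(tx, out, include_annotations = "vec"),
               "'vec'.*not scalar")
})

test_that("to_table flattens features with explicit missing markers", {
  tx <- micro_transcriptome()
  spec <- column_spec(chrom = "chrom", start = "start", stop = "end",
                      gene_name = attr_col("gene_name"))
  genes <- tx_features(tx, "gene")
  tab <- to_table(genes, spec)
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab), c("chrom", "start", "stop", "gene_name"))
  expect_setequal(tab$gene_name, c("AAA", "BBB"))
  # annotation columns; absent annotations yield NA, never a blank
  tx_set_annotation(tx, genes$feature_id[1L], "expr", 1.5)
  tab2 <- to_table(genes, column_spec(id = "feature_id",
                                      expr = ann_col("expr")), tx = tx)
  expect_equal(sum(is.na(tab2$expr)), 1L)
  expect_equal(tab2$expr[!is.na(tab2$expr)], 1.5)
  # record count equals stream length on an arbitrary stream
  fixt <- get_fixture("base")
  n <- length(readLines(fixt$fx$tracks$bed))
  tab3 <- to_table(open_iterator(fixt$fx$tracks$bed, "bed"),
                   column_spec(chrom = "chrom", start = "start",
                               stop = "end"))
  expect_equal(nrow(tab3), n)
  # invalid specs are rejected at construction
  expect_error(column_spec(a = "chrom", a = "start"), "duplicate")
  expect_error(column_spec(a = "nonsense"), "unknown extractor")
  expect_error(column_spec(1, 2), "named")
})
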