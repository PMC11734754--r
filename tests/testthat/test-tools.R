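test_that("a zero-error fixture gives a purely diagonal mismatch profile", {
  fixt <- get_fixture("base")
  mp <- mismatch_profile(fixt$fx$reads$sam, fixt$fx$genome$fasta)
  both <- mp$counts[, , 1L] + mp$counts[, , 2L]
  expect_gt(sum(diag(both)), 0L)
  expect_equal(sum(both) - sum(diag(both)), 0L)
  g <- glance(mp)
  expect_equal(g$n_mismatches, 0L)
  expect_equal(sum(both), g$n_bases)
  # tidy() exposes the full 4x4x2 tally
  td <- tidy(mp)
  expect_equal(nrow(td), 32L)
  expect_equal(sum(td$count), sum(mp$counts))
})

test_that("the conversion fixture recovers T->C at its simulated rate", {
  fixt <- get_fixture("conversion")
  mp <- mismatch_profile(fixt$fx$reads$sam, fixt$fx$genome$fasta)
  both <- mp$counts[, , 1L] + mp$counts[, , 2L]
  tc <- both["T", "C"]; tt <- both["T", "T"]
  p <- fixt$cfg$conversion_rate
  sigma <- sqrt(p * (1 - p) / (tc + tt))
  expect_lt(abs(tc / (tc + tt) - p), 3 * sigma)
  # conversions are the only mismatch class in this fixture
  off <- sum(both) - sum(diag(both))
  expect_equal(off, unname(both["T", "C"]))
  # minus-strand reads exist, so the complement adjustment is exercised
  expect_gt(sum(mp$counts[, , "-"]), 0L)
  expect_gt(mp$counts["T", "C", "-"], 0L)
})

test_that("base-quality and mapping-quality filters empty the profile", {
  fixt <- get_fixture("base")
  mp <- mismatch_profile(fixt$fx$reads$sam, fixt$fx$genome$fasta,
                         min_base_quality = 99L)
  expect_equal(sum(mp$counts), 0L)
  mp2 <- mismatch_profile(fixt$fx$reads$sam, fixt$fx$genome$fasta,
                          min_mapping_quality = 99L)
  expect_equal(sum(mp2$counts), 0L)
})

test_that("profiles are additive over disjoint regions", {
  fixt <- get_fixture("base")
  bam <- fixt$fx$reads$bam
  man <- fixt$fx$annotation$manifest
  g1 <- man$genes[[1L]]; g3 <- man$genes[[3L]]
  r1 <- gi(g1$chrom, g1$start, g1$end)
  r2 <- gi(g3$chrom, g3$start, g3$end)
  expect_false(gi_overlaps(r1, r2))  # generator places genes disjointly
  p1 <- mismatch_profile(bam, fixt$fx$genome$fasta, region = r1)
  p2 <- mismatch_profile(bam, fixt$fx$genome$fasta, region = r2)
  reads <- stream_collect(open_iterator(bam, "bam_reads"))
  in_either <- gi_overlaps(reads, r1) | gi_overlaps(reads, r2)
  expect_equal(p1$n_reads + p2$n_reads, sum(in_either))
  # per-read recount oracle: total aligned bases = reads x read length
  expect_equal(sum(p1$counts), p1$n_reads * fixt$cfg$read_length)
})

test_that("converted-read counts match the nc-tag ground truth exactly", {
  fixt <- get_fixture("conversion")
  res <- annotate_conversions(fixt$fx$reads$sam, fixt$fx$genome$fasta,
                              fixt$fx$annotation$gff3, min_conversions = 1L)
  reads <- stream_collect(open_iterator(fixt$fx$reads$sam, "bam_reads",
                                        tags = "nc"))
  nc <- vapply(reads$payload, function(p) {
    v <- p$tags$nc
    if (is.null(v) || is.na(v)) 0 else v
  }, 1)
  txs <- tx_features(read_transcriptome(fixt$fx$annotation$gff3),
                     "transcript")
  for (i in seq_len(nrow(res))) {
    t <- txs[txs$feature_id == res$transcript_id[i], ]
    ov <- gi_overlaps(reads, t)
    expect_equal(res$n_reads[i], sum(ov))
    expect_equal(res$n_converted[i], sum(ov & nc >= 1))
  }
})

test_that("an impossible conversion threshold zeroes every transcript", {
  fixt <- get_fixture("conversion")
  res <- annotate_conversions(fixt$fx$reads$sam, fixt$fx$genome$fasta,
                              fixt$fx$annotation$gff3,
                              min_conversions = 1000L)
  expect_true(all(res$n_converted == 0L))
  expect_true(all(res$n_reads > 0L))
})

test_that("transcripts without overlapping reads get explicit zero rows", {
  dir <- withr::local_tempdir()
  fa <- micro_fasta(dir)
  gff <- micro_gff3(dir)
  sam <- file.path(dir, "one.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrM\tLN:100",
    sprintf("r1\t0\tchrM\t1\t60\t9M\t*\t0\t0\t%s\t%s",
            substr(fa$seq, 1, 9), strrep("I", 9))), sam)
  res <- annotate_conversions(sam, fa$fasta, gff)
  expect_equal(nrow(res), 3L)
  b <- res[res$transcript_id == "tB1", ]
  expect_equal(b$n_reads, 0L)
  expect_equal(b$n_converted, 0L)
  expect_equal(b$frac_converted, 0)
})

test_that("the autoplot method renders a faceted mismatch heatmap", {
  fixt <- get_fixture("base")
  mp <- mismatch_profile(fixt$fx$reads$sam, fixt$fx$genome$fasta)
  p <- ggplot2::autoplot(mp)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(length(built$data), 0L)
})

test_that("the command-line front end writes its outputs", {
  skip_if_not_installed("optparse")
  fixt <- get_fixture("base")
  cli <- system.file("cli", "txome-tools.R", package = "txome")
  skip_if(cli == "", "CLI script not installed")
  out <- tempfile(fileext = ".tsv")
  status <- system2("Rscript", c(
    cli, "mismatch-profile", "--reads", fixt$fx$reads$sam,
    "--fasta", fixt$fx$genome$fasta, "--out", out),
    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  tab <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(nrow(tab), 32L)
})
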