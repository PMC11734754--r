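test_that("format adapters convert coordinates to the 1-based closed convention", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "x.bed")
  writeLines("chr1\t0\t10\tx", bed)
  it <- stream_next(open_iterator(bed, "bed"))
  expect_equal(c(it$start, it$end), c(1L, 10L))
  expect_equal(it$payload$name, "x")

  bg <- file.path(dir, "x.bedgraph")
  writeLines("chr1\t0\t10\t2.5", bg)
  itb <- stream_next(open_iterator(bg, "bedgraph"))
  expect_equal(c(itb$start, itb$end, itb$payload$value), c(1, 10, 2.5))

  vcf <- file.path(dir, "x.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tACGT\tA\t.\tPASS\t."), vcf)
  itv <- stream_next(open_iterator(vcf, "vcf"))
  expect_equal(c(itv$start, itv$end), c(100L, 103L))  # POS + len(REF) - 1
  expect_equal(itv$payload$ref, "ACGT")

  gff <- file.path(dir, "x.gff3")
  writeLines("chr1\tt\tgene\t5\t20\t.\t-\t.\tID=g1;Name=a%3Bb", gff)
  itg <- stream_next(open_iterator(gff, "gff"))
  expect_equal(c(itg$start, itg$end), c(5L, 20L))
  expect_equal(unname(itg$payload$attrs["Name"]), "a;b")
})

test_that("unsorted inputs and unknown contigs are rejected with named records", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "unsorted.bed")
  writeLines(c("chr1\t49\t55", "chr1\t9\t15"), bed)
  expect_error(stream_collect(open_iterator(bed, "bed")),
               "unsorted input.*record 2")
  # returning to an earlier chromosome is unsorted too
  bed2 <- file.path(dir, "chromswap.bed")
  writeLines(c("chr1\t0\t5", "chr2\t0\t5", "chr1\t10\t15"), bed2)
  expect_error(stream_collect(open_iterator(bed2, "bed")), "unsorted")
  # contig missing from an explicit RefDict
  bed3 <- file.path(dir, "badcontig.bed")
  writeLines("chrX\t0\t5", bed3)
  expect_error(
    stream_collect(open_iterator(bed3, "bed", refdict = refdict("chr1", 100L))),
    "contig 'chrX'")
})

test_that("region-restricted iteration uses the index and equals filtered full scans", {
  fixt <- get_fixture("base")
  # text format through tabix
  bed <- fixt$fx$tracks$bed
  bgz <- Rsamtools::bgzip(bed, paste0(bed, ".gz"), overwrite = TRUE)
  Rsamtools::indexTabix(bgz, format = "bed")
  man <- fixt$fx$annotation$manifest
  g <- man$genes[[1L]]
  region <- gi(g$chrom, g$start, g$end)
  got <- stream_collect(open_iterator(bgz, "bed", region = region))
  full <- stream_collect(open_iterator(bed, "bed"))
  want <- full[gi_overlaps(full, region), ]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  # an unindexed file cannot serve regions
  expect_error(open_iterator(bed, "bed", region = region), "unindexed")
  # BAM through its .bai
  bam <- fixt$fx$reads$bam
  gotb <- stream_collect(open_iterator(bam, "bam_reads", region = region))
  fullb <- stream_collect(open_iterator(bam, "bam_reads"))
  wantb <- fullb[gi_overlaps(fullb, region), ]
  expect_equal(gotb$start, wantb$start)
  expect_equal(nrow(gotb), nrow(wantb))
  # SAM text and BAM agree on the full scan
  fulls <- stream_collect(open_iterator(fixt$fx$reads$sam, "bam_reads"))
  expect_equal(fulls$start, fullb$start)
  expect_equal(fulls$chrom, fullb$chrom)
})

test_that("a known-count region query returns exactly the inside records", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "six.bed")
  writeLines(sprintf("chr1\t%d\t%d", c(0, 10, 120, 300, 400, 500),
                     c(5, 20, 180, 310, 410, 510)), bed)
  bgz <- Rsamtools::bgzip(bed, overwrite = TRUE)
  Rsamtools::indexTabix(bgz, format = "bed")
  got <- stream_collect(open_iterator(bgz, "bed", region = "chr1:100-200"))
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 121L)
})

test_that("fasta_windows yields every base once with its sequence", {
  dir <- withr::local_tempdir()
  fa <- micro_fasta(dir)
  s <- open_iterator(fa$fasta, "fasta_windows", win_size = 30L)
  tb <- stream_collect(s)
  expect_equal(nrow(tb), 4L)
  expect_equal(sum(gi_width(tb)), 100L)
  joined <- paste(vapply(tb$payload, `[[`, "", "seq"), collapse = "")
  expect_equal(joined, fa$seq)
})

test_that("group_by_overlap forms transitive overlap groups covering the source", {
  s <- memory_stream(data.frame(chrom = "chr1", start = c(1, 3, 20),
                                end = c(5, 8, 25)))
  g <- stream_collect(group_by_overlap(s))
  expect_equal(nrow(g), 2L)
  expect_equal(c(g$start, g$end), c(1L, 20L, 8L, 25L))
  expect_equal(lengths(lapply(g$payload, `[[`, "items")), c(2L, 1L))
  # non-overlapping items give singleton groups
  s2 <- memory_stream(data.frame(chrom = "chr1", start = c(1, 10),
                                 end = c(5, 15)))
  expect_equal(nrow(stream_collect(group_by_overlap(s2))), 2L)
  # random case: groups equal connected components of sorted adjacency, and
  # concatenating members reproduces the source
  set.seed(51)
  rd <- refdict("chr1", 2000L)
  x <- random_intervals(120, chroms = "chr1", max_pos = 1800L, max_len = 40L)
  xs <- gi_sort(as_gi(x), rd)
  groups <- stream_collect(group_by_overlap(memory_stream(xs, refdict = rd)))
  members <- unlist(lapply(groups$payload, function(p)
    vapply(p$items, `[[`, 1L, "start")))
  expect_equal(members, xs$start)
  # oracle: a new component starts where an item clears the running max end
  comp_new <- c(TRUE, xs$start[-1L] > cummax(xs$end)[-nrow(xs)])
  expect_equal(nrow(groups), sum(comp_new))
})

test_that("tile_stream assigns every item to every tile it overlaps", {
  rd <- refdict("chr1", 10L)
  s <- memory_stream(data.frame(chrom = "chr1", start = 3, end = 6),
                     refdict = rd)
  tt <- stream_collect(tile_stream(s, 4L))
  expect_equal(nrow(tt), 3L)
  counts <- lengths(lapply(tt$payload, `[[`, "items"))
  expect_equal(counts, c(1L, 1L, 0L))  # item 3-6 spans tiles 1-4 and 5-8
  # empty source still yields every tile
  s0 <- memory_stream(data.frame(chrom = character(), start = integer(),
                                 end = integer()), refdict = rd)
  expect_equal(nrow(stream_collect(tile_stream(s0, 4L))), 3L)
  # counting oracle: occurrences summed over tiles equal tiles-overlapped
  # summed over items
  set.seed(61)
  rd2 <- refdict(c("cA", "cB"), c(1000L, 700L))
  x <- random_intervals(150, chroms = rd2$chrom, max_pos = 600L, max_len = 90L)
  xs <- gi_sort(as_gi(x), rd2)
  tiles <- stream_collect(tile_stream(memory_stream(xs, refdict = rd2), 64L))
  occurrences <- sum(lengths(lapply(tiles$payload, `[[`, "items")))
  tile_tbl <- gi_tile(rd2, 64L)
  per_item <- sum(vapply(seq_len(nrow(xs)), function(i)
    sum(gi_overlaps(tile_tbl, xs[i, , drop = FALSE])), 1L))
  expect_equal(occurrences, per_item)
})

test_that("merge_streams is a stable sorted k-way merge with pre-flight checks", {
  rd <- refdict("chr1", 100L)
  m <- merge_streams(list(
    memory_stream(data.frame(chrom = "chr1", start = 5, end = 6), rd),
    memory_stream(data.frame(chrom = "chr1", start = 3, end = 4), rd)))
  tb <- stream_collect(m)
  expect_equal(tb$start, c(3L, 5L))
  expect_equal(tb$source, c(2L, 1L))
  # contradictory chromosome orders abort before yielding
  r1 <- refdict(c("chr1", "chr2"), c(100L, 100L))
  r2 <- refdict(c("chr2", "chr1"), c(100L, 100L))
  expect_error(merge_streams(list(
    memory_stream(data.frame(chrom = "chr1", start = 1, end = 2), r1),
    memory_stream(data.frame(chrom = "chr1", start = 1, end = 2), r2))),
    "contradictory relative order")
  # merge of n random streams equals the sort of their concatenation
  set.seed(71)
  rd3 <- refdict(c("chr1", "chr2"), c(1000L, 1000L))
  parts <- lapply(1:4, function(i)
    random_intervals(40, chroms = rd3$chrom, max_pos = 900L))
  streams <- lapply(parts, sorted_memory_stream, rd = rd3)
  merged <- stream_collect(merge_streams(streams))
  all_sorted <- gi_sort(as_gi(dplyr::bind_rows(parts)), rd3)
  expect_equal(merged$chrom, all_sorted$chrom)
  expect_equal(merged$start, all_sorted$start)
  expect_equal(merged$end, all_sorted$end)
})

test_that("the overlap join equals the all-pairs oracle and re-uses items", {
  rd <- refdict("chr1", 500L)
  anchors <- memory_stream(data.frame(chrom = "chr1", start = c(1, 20),
                                      end = c(10, 30)), rd)
  src <- memory_stream(data.frame(chrom = "chr1", start = c(5, 25, 100),
                                  end = c(6, 40, 200)), rd)
  out <- stream_collect(annotation_iterator(anchors, list(v = src)))
  expect_equal(lengths(lapply(out$payload, function(p) p$data$v)), c(1L, 1L))
  expect_equal(out$payload[[1L]]$data$v[[1L]]$start, 5L)
  expect_equal(out$payload[[2L]]$data$v[[1L]]$start, 25L)
  # an item overlapping two anchors appears in both bundles
  anchors2 <- memory_stream(data.frame(chrom = "chr1", start = c(1, 5),
                                       end = c(10, 15)), rd)
  src2 <- memory_stream(data.frame(chrom = "chr1", start = 7, end = 8), rd)
  out2 <- stream_collect(annotation_iterator(anchors2, list(v = src2)))
  expect_equal(lengths(lapply(out2$payload, function(p) p$data$v)), c(1L, 1L))
  # labels are present even when empty
  expect_named(out2$payload[[1L]]$data, "v")

  # random fixtures, 3 sources, vs the brute-force all-pairs oracle
  set.seed(81)
  rd2 <- refdict(c("chr1", "chr2"), c(1000L, 800L))
  anch_df <- random_intervals(60, chroms = rd2$chrom, max_pos = 700L)
  k <- gi_sort_key(as_gi(anch_df), rd2)
  anch_df <- anch_df[order(k$cidx, k$start, k$end), ]
  src_dfs <- lapply(1:3, function(i)
    random_intervals(200, chroms = rd2$chrom, max_pos = 700L))
  it <- annotation_iterator(
    memory_stream(anch_df, rd2),
    list(a = sorted_memory_stream(src_dfs[[1L]], rd2),
         b = sorted_memory_stream(src_dfs[[2L]], rd2),
         c = sorted_memory_stream(src_dfs[[3L]], rd2)))
  bundles <- stream_collect(it)
  expect_equal(nrow(bundles), nrow(anch_df))
  for (lab in c("a", "b", "c")) {
    j <- match(lab, c("a", "b", "c"))
    src_sorted <- gi_sort(as_gi(src_dfs[[j]]), rd2)
    want <- oracle_overlaps(as_gi(anch_df), src_sorted)
    got <- lapply(bundles$payload, function(p)
      sort(vapply(p$data[[lab]], function(x) paste(x$chrom, x$start, x$end),
                  "")))
    want_str <- lapply(want, function(ix)
      sort(paste(src_sorted$chrom[ix], src_sorted$start[ix],
                 src_sorted$end[ix])))
    expect_equal(got, want_str)
  }
})

test_that("strand-specific joins drop opposite-strand hits but keep unstranded", {
  rd <- refdict("chr1", 100L)
  anchors <- memory_stream(data.frame(chrom = "chr1", start = 1, end = 10,
                                      strand = "+"), rd)
  src <- memory_stream(data.frame(chrom = "chr1", start = c(2, 4, 6),
                                  end = c(3, 5, 7),
                                  strand = c("+", "-", ".")), rd)
  out <- stream_collect(annotation_iterator(anchors, list(v = src),
                                            strand_specific = TRUE))
  hits <- vapply(out$payload[[1L]]$data$v, `[[`, "", "strand")
  expect_setequal(hits, c("+", "."))
})

test_that("every source record is parsed exactly once per join (single pass)", {
  fixt <- get_fixture("base")
  bed_stream <- open_iterator(fixt$fx$tracks$bed, "bed")
  vcf_stream <- open_iterator(fixt$fx$tracks$vcf, "vcf")
  tx <- read_transcriptome(fixt$fx$annotation$gff3)
  anchors <- features_stream(tx, "transcript")
  out <- stream_collect(annotation_iterator(
    anchors, list(exons = bed_stream, vars = vcf_stream)))
  expect_equal(nrow(out), nrow(tx_features(tx, "transcript")))
  n_bed <- length(readLines(fixt$fx$tracks$bed))
  vcf_lines <- readLines(fixt$fx$tracks$vcf)
  n_vcf <- sum(!startsWith(vcf_lines, "#"))
  expect_equal(stream_records_parsed(bed_stream), n_bed)
  expect_equal(stream_records_parsed(vcf_stream), n_vcf)
})

test_that("emitted streams stay sorted under their RefDict", {
  fixt <- get_fixture("base")
  rd <- fixt$fx$genome$refdict
  check_sorted <- function(tb, rd) {
    k <- gi_sort_key(tb, rd)
    expect_true(all(diff(k$cidx) >= 0))
    same <- diff(k$cidx) == 0
    expect_true(all(diff(k$start)[same] >= 0))
  }
  check_sorted(stream_collect(open_iterator(fixt$fx$tracks$bed, "bed")), rd)
  check_sorted(stream_collect(open_iterator(fixt$fx$reads$sam, "bam_reads")),
               rd)
  s <- open_iterator(fixt$fx$tracks$bedgraph, "bedgraph")
  check_sorted(stream_collect(group_by_overlap(s)), rd)
})
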