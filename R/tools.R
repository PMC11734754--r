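COMP <- function(x) chartr("ACGTN", "TGCAN", x)

# walk an alignment's CIGAR and return aligned (ref_pos, read_pos) runs for
# M/=/X ops; insertions and clips advance the read, deletions and splices
# advance the reference
aligned_runs <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  lens <- as.integer(sub(".$", "", ops))
  kind <- substring(ops, nchar(ops))
  ref <- pos; rd <- 1L
  runs <- list()
  for (i in seq_along(ops)) {
    k <- kind[i]; l <- lens[i]
    if (k %in% c("M", "=", "X")) {
      runs[[length(runs) + 1L]] <- c(ref, rd, l)
      ref <- ref + l; rd <- rd + l
    } else if (k %in% c("I", "S")) {
      rd <- rd + l
    } else if (k %in% c("D", "N")) {
      ref <- ref + l
    }
  }
  runs
}

# per-chromosome reference cache backed by an indexed FASTA
chrom_seq_cache <- function(fasta_path) {
  rd <- refdict_from_fai(fasta_path)
  cache <- new.env(parent = emptyenv())
  list(refdict = rd, get = function(chrom) {
    s <- get0(chrom, envir = cache, ifnotfound = NULL)
    if (is.null(s)) {
      fa <- Rsamtools::FaFile(fasta_path)
      len <- rd$length[match(chrom, rd$chrom)]
      if (is.na(len)) stop("chromosome not in FASTA: ", chrom, call. = FALSE)
      s <- as.character(Rsamtools::scanFa(
        fa, GenomicRanges::GRanges(chrom, IRanges::IRanges(1L, len))))
      assign(chrom, s, envir = cache)
    }
    s
  })
}

# count (ref base, read base) pairs for one alignment item, in read
# orientation: minus-strand reads have both bases complemented, so a T->C
# conversion on a minus-strand read still counts as T->C
count_read_bases <- function(item, chromseq, min_base_quality,
                             tally = NULL, tc_only = FALSE) {
  p <- item$payload
  runs <- aligned_runs(item$start, p$cigar)
  minus <- item$strand == "-"
  tc <- 0L
  for (r in runs) {
    ref_s <- r[1L]; rd_s <- r[2L]; l <- r[3L]
    refb <- strsplit(substr(chromseq, ref_s, ref_s + l - 1L), "")[[1L]]
    readb <- strsplit(substr(p$seq, rd_s, rd_s + l - 1L), "")[[1L]]
    q <- utf8ToInt(substr(p$qual, rd_s, rd_s + l - 1L)) - 33L
    if (minus) { refb <- COMP(refb); readb <- COMP(readb) }
    ok <- q >= min_base_quality & refb %in% BASES & readb %in% BASES
    if (!any(ok)) next
    refb <- refb[ok]; readb <- readb[ok]
    if (tc_only) {
      tc <- tc + sum(refb == "T" & readb == "C")
    } else {
      si <- if (minus) 2L else 1L
      for (j in seq_along(refb)) {
        ri <- match(refb[j], BASES); ci <- match(readb[j], BASES)
        tally[ri, ci, si] <- tally[ri, ci, si] + 1L
      }
    }
  }
  if (tc_only) tc else tally
}

#' Nucleotide mismatch profile from alignments
#'
#' Tallies every aligned (non-clipped, non-deleted) read base against its
#' reference base into a 4x4 count matrix over \{A, C, G, T\}, split by read
#' strand and reported in read orientation: minus-strand reads are
#' complement-adjusted, so a T-to-C conversion counts as T->C regardless of
#' the strand the read maps to. Bases below the base-quality threshold and
#' positions with reference N are excluded. Alignments are iterated through
#' [open_iterator()], inheriting its flag and mapping-quality filters; the
#' default filters exclude unmapped, secondary, supplementary and duplicate
#' reads. Counts are additive over disjoint regions.
#'
#' @param reads_path SAM or BAM file (BAM must be indexed when `region` is
#'   given).
#' @param fasta_path Indexed reference FASTA; its RefDict must be compatible
#'   with the alignment header's.
#' @param region Optional region restricting the profile.
#' @param min_base_quality Minimum Phred base quality for a base to count.
#' @param min_mapping_quality Minimum mapping quality.
#' @param keep_secondary,keep_supplementary,keep_duplicates Flag filters.
#' @return An object of class `txome_mismatch_profile`: a list with the
#'   `counts` array (`ref x read x strand`), `n_reads`, and the filter
#'   `settings`. Has [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
mismatch_profile <- function(reads_path, fasta_path, region = NULL,
                             min_base_quality = 10L,
                             min_mapping_quality = 0L,
                             keep_secondary = FALSE,
                             keep_supplementary = FALSE,
                             keep_duplicates = FALSE) {
  ref <- chrom_seq_cache(fasta_path)
  reads <- open_iterator(reads_path, "bam_reads", region = region,
                         min_mapq = min_mapping_quality,
                         keep_secondary = keep_secondary,
                         keep_supplementary = keep_supplementary,
                         keep_duplicates = keep_duplicates)
  assert_refdict_compatible(stream_refdict(reads), ref$refdict,
                            what = "alignments vs reference")
  counts <- array(0L, dim = c(4L, 4L, 2L),
                  dimnames = list(ref = BASES, read = BASES,
                                  strand = c("+", "-")))
  n_reads <- 0L
  repeat {
    it <- stream_next(reads)
    if (is.null(it)) break
    n_reads <- n_reads + 1L
    counts <- count_read_bases(it, ref$get(it$chrom), min_base_quality,
                               tally = counts)
  }
  structure(list(counts = counts, n_reads = n_reads,
                 settings = list(min_base_quality = min_base_quality,
                                 min_mapping_quality = min_mapping_quality,
                                 region = if (is.null(region)) NULL else
                                   gi_format(if (is.character(region))
                                     gi_parse(region) else region))),
            class = "txome_mismatch_profile")
}

#' @export
print.txome_mismatch_profile <- function(x, ...) {
  cat("Mismatch profile over", x$n_reads, "reads,",
      sum(x$counts), "aligned bases\n")
  both <- x$counts[, , 1L] + x$counts[, , 2L]
  print(both)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.txome_mismatch_profile <- function(x, ...) {
  grid <- expand.grid(ref = BASES, read = BASES, strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  tibble::tibble(ref = grid$ref, read = grid$read, strand = grid$strand,
                 count = as.integer(x$counts[cbind(
                   match(grid$ref, BASES), match(grid$read, BASES),
                   match(grid$strand, c("+", "-")))])) |>
    dplyr::arrange(.data$strand, .data$ref, .data$read)
}

#' @importFrom generics glance
#' @export
glance.txome_mismatch_profile <- function(x, ...) {
  both <- x$counts[, , 1L] + x$counts[, , 2L]
  total <- sum(both)
  matches <- sum(diag(both))
  tc <- both["T", "C"]
  tt <- both["T", "T"]
  tibble::tibble(
    n_reads = x$n_reads,
    n_bases = total,
    n_mismatches = total - matches,
    mismatch_rate = if (total > 0L) (total - matches) / total else NA_real_,
    tc_rate = if (tc + tt > 0L) tc / (tc + tt) else NA_real_)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.txome_mismatch_profile <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::group_by(d, .data$strand) |>
    dplyr::mutate(frac = .data$count / pmax(1, sum(.data$count))) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$read, y = .data$ref,
                                  fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::facet_wrap(~ strand, labeller = ggplot2::label_both) +
    ggplot2::scale_y_discrete(limits = rev(BASES)) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "read base (read orientation)", y = "reference base",
                  fill = "fraction", title = "Nucleotide mismatch profile")
}

#' Annotate transcripts with T->C conversion counts
#'
#' For every transcript, reports the total number of overlapping reads, the
#' number of reads carrying at least `min_conversions` T->C mismatches in
#' read orientation, and their ratio. Reads are joined to transcripts with
#' the single-pass overlap annotation loop ([tx_annotate()]); per-read
#' conversion counts are computed against the reference once and memoised,
#' so reads overlapping several transcripts are only inspected once.
#' Transcripts without overlapping reads get a zero row, never a missing
#' one.
#'
#' @inheritParams mismatch_profile
#' @param annotation_path GTF/GFF3 annotation parsed with
#'   [read_transcriptome()].
#' @param out_path Optional TSV destination.
#' @param min_conversions Minimum observed T->C mismatches for a read to
#'   count as converted.
#' @param flavor Annotation flavor.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `n_reads`, `n_converted`, `frac_converted`.
#' @export
annotate_conversions <- function(reads_path, fasta_path, annotation_path,
                                 out_path = NULL, min_conversions = 1L,
                                 min_base_quality = 10L,
                                 min_mapping_quality = 0L,
                                 flavor = "generic") {
  ref <- chrom_seq_cache(fasta_path)
  tx <- read_transcriptome(annotation_path, flavor = flavor)
  assert_refdict_compatible(tx$refdict, ref$refdict,
                            what = "annotation vs reference",
                            allow_order_mismatch = TRUE)
  reads <- open_iterator(reads_path, "bam_reads",
                         min_mapq = min_mapping_quality)
  memo <- new.env(parent = emptyenv())
  conv_count <- function(item) {
    key <- paste(item$payload$qname, item$start, sep = "\r")
    v <- get0(key, envir = memo, ifnotfound = NULL)
    if (is.null(v)) {
      v <- count_read_bases(item, ref$get(item$chrom), min_base_quality,
                            tc_only = TRUE)
      assign(key, v, envir = memo)
    }
    v
  }
  rows <- new.env(parent = emptyenv()); rows$acc <- list()
  tx_annotate(tx, list(reads = reads), feature_type = "transcript",
              fun = function(feature, bundle, tx) {
    items <- bundle$reads
    n <- nrow(items)
    n_conv <- if (n > 0L) {
      sum(vapply(seq_len(n), function(i)
        conv_count(list(chrom = items$chrom[i], start = items$start[i],
                        end = items$end[i], strand = items$strand[i],
                        payload = items$payload[[i]])) >= min_conversions,
        TRUE))
    } else 0L
    rows$acc[[feature$feature_id]] <- tibble::tibble(
      transcript_id = feature$feature_id, gene_id = feature$gene_id,
      chrom = feature$chrom, start = feature$start, end = feature$end,
      strand = feature$strand, n_reads = n, n_converted = n_conv,
      frac_converted = if (n > 0L) n_conv / n else 0)
    tx_set_annotation(tx, feature, "n_reads", n)
    tx_set_annotation(tx, feature, "n_converted", n_conv)
  })
  out <- dplyr::bind_rows(rows$acc)
  if (!is.null(out_path)) readr::write_tsv(out, out_path)
  out
}
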