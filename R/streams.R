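# Sorted genomic streams.
#
# A stream is a pull-based iterator over LocationItems: lists with fields
# chrom / start / end / strand (the location, always in the internal 1-based
# closed convention) and payload (the format-specific record, which never
# carries a second copy of the coordinates). Streams expose their RefDict,
# check sortedness as items are yielded, and support one-item lookahead,
# which is what the combinators (grouping, tiling, merging, overlap join)
# build on.

new_stream <- function(refdict, gen, label = "stream", counter = NULL) {
  s <- new.env(parent = emptyenv())
  s$rd <- refdict
  s$gen <- gen
  s$label <- label
  s$seen <- character()    # observed chromosome order when rd is NULL
  s$last_cidx <- -Inf
  s$last_start <- -Inf
  s$n <- 0L
  s$peeked <- NULL
  s$counter <- counter
  class(s) <- "txome_stream"
  s
}

#' Streams: pull items, peek, collect
#'
#' `stream_next()` returns the next LocationItem (a list with `chrom`,
#' `start`, `end`, `strand`, `payload`) or `NULL` when exhausted;
#' `stream_peek()` looks one item ahead without consuming it;
#' `stream_collect()` drains the stream into a tibble with one row per item
#' and the payload in a list-column; `stream_refdict()` returns the stream's
#' reference dictionary (`NULL` when the stream infers chromosome order from
#' the data). Sortedness is verified on every yield: an item starting before
#' its predecessor, or returning to an earlier chromosome, raises an
#' unsorted-input error naming the offending record.
#'
#' @param s A `txome_stream`.
#' @return See above.
#' @export
stream_next <- function(s) {
  if (!is.null(s$peeked)) {
    item <- s$peeked
    s$peeked <- NULL
    return(item)
  }
  item <- s$gen()
  if (is.null(item)) return(NULL)
  s$n <- s$n + 1L
  # chromosome resolution / compatibility
  if (!is.null(s$rd)) {
    cidx <- match(item$chrom, s$rd$chrom)
    if (is.na(cidx)) {
      stop("contig '", item$chrom, "' in ", s$label,
           " is absent from its reference dictionary '",
           refdict_name(s$rd), "'", call. = FALSE)
    }
  } else {
    cidx <- match(item$chrom, s$seen)
    if (is.na(cidx)) {
      s$seen <- c(s$seen, item$chrom)
      cidx <- length(s$seen)
    }
  }
  if (cidx < s$last_cidx ||
      (cidx == s$last_cidx && item$start < s$last_start)) {
    stop("unsorted input in ", s$label, ": record ", s$n, " (", item$chrom,
         ":", item$start, "-", item$end, ") starts before its predecessor",
         call. = FALSE)
  }
  s$last_cidx <- cidx
  s$last_start <- item$start
  item
}

#' @rdname stream_next
#' @export
stream_peek <- function(s) {
  if (is.null(s$peeked)) s$peeked <- stream_next(s)
  s$peeked
}

#' @rdname stream_next
#' @export
stream_refdict <- function(s) s$rd

#' @rdname stream_next
#' @export
stream_records_parsed <- function(s) {
  if (is.null(s$counter)) NA_integer_ else s$counter$n
}

#' @rdname stream_next
#' @export
stream_collect <- function(s) {
  items <- list()
  repeat {
    it <- stream_next(s)
    if (is.null(it)) break
    items[[length(items) + 1L]] <- it
  }
  items_to_tibble(items)
}

items_to_tibble <- function(items) {
  if (length(items) == 0L) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          payload = list())
    return(new_gi(out))
  }
  out <- tibble::tibble(
    chrom = vapply(items, `[[`, "", "chrom"),
    start = vapply(items, `[[`, 1L, "start"),
    end = vapply(items, `[[`, 1L, "end"),
    strand = vapply(items, `[[`, "", "strand"),
    payload = lapply(items, `[[`, "payload"))
  src <- lapply(items, function(x) x$source)
  if (!all(vapply(src, is.null, TRUE))) {
    out$source <- vapply(src, function(x) x %||% NA_integer_, 1L)
  }
  new_gi(out)
}

# -- open_iterator ------------------------------------------------------------

#' Open a sorted iterator over a genomics file
#'
#' Uniform entry point for sorted iteration over the common formats. All
#' adapters convert coordinates to the internal 1-based, fully closed
#' convention at the boundary (BED and bedGraph inputs are 0-based
#' half-open; GFF/GTF/VCF/SAM are 1-based). When `region` is given, records
#' are fetched through the file's index (tabix `.tbi` for text formats,
#' `.bai` for BAM) without a full scan; asking for a region on an unindexed
#' file is a capability error. Each stream carries a RefDict taken from, in
#' order of preference, the `refdict` argument, the file's index or header,
#' or (for plain text files) the observed contig order.
#'
#' @param path Input file. Plain text or bgzip-compressed for the text
#'   formats; `.sam` or `.bam` for `format = "bam_reads"`; an indexed FASTA
#'   for `format = "fasta_windows"`.
#' @param format One of `"bed"`, `"bedgraph"`, `"gff"`, `"gtf"`, `"vcf"`,
#'   `"bam_reads"`, `"fasta_windows"`, or `"auto"` (by file extension).
#' @param region Optional region (string or one-row `txome_gi`) restricting
#'   iteration to overlapping records.
#' @param refdict Optional [refdict()] overriding the stream's dictionary;
#'   contigs found in the file but absent from it raise an incompatibility
#'   error.
#' @param min_mapq,keep_secondary,keep_supplementary,keep_duplicates,keep_unmapped
#'   Alignment filters for `bam_reads` (defaults exclude unmapped,
#'   secondary, supplementary and duplicate reads).
#' @param tags Auxiliary tag names to load into alignment payloads.
#' @param win_size Window width for `fasta_windows`.
#' @return A `txome_stream`. Alignment payloads carry `qname`, `flag`,
#'   `mapq`, `cigar`, `seq`, `qual` and requested `tags`; the location of an
#'   alignment is its full reference span from the CIGAR (matches, deletions
#'   and splices included).
#' @export
open_iterator <- function(path, format = c("auto", "bed", "bedgraph", "gff",
                                           "gtf", "vcf", "bam_reads",
                                           "fasta_windows"),
                          region = NULL, refdict = NULL,
                          min_mapq = 0L, keep_secondary = FALSE,
                          keep_supplementary = FALSE, keep_duplicates = FALSE,
                          keep_unmapped = FALSE, tags = character(),
                          win_size = 1000L) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (is.character(region)) region <- gi_parse(region)
  switch(format,
         bed = text_stream(path, region, refdict, parse_bed, "BED"),
         bedgraph = text_stream(path, region, refdict, parse_bedgraph,
                                "bedGraph"),
         gff = text_stream(path, region, refdict, parse_gxf_factory("gff3"),
                           "GFF3"),
         gtf = text_stream(path, region, refdict, parse_gxf_factory("gtf"),
                           "GTF"),
         vcf = text_stream(path, region, refdict, parse_vcf, "VCF"),
         bam_reads = reads_stream(path, region, refdict, min_mapq,
                                  keep_secondary, keep_supplementary,
                                  keep_duplicates, keep_unmapped, tags),
         fasta_windows = fasta_window_stream(path, region, refdict, win_size))
}

guess_format <- function(path) {
  base <- sub("\\.(gz|bgz)$", "", path)
  ext <- tolower(sub(".*\\.", "", base))
  switch(ext,
         bed = "bed", bedgraph = "bedgraph", bg = "bedgraph",
         gff = "gff", gff3 = "gff", gtf = "gtf", vcf = "vcf",
         bam = "bam_reads", sam = "bam_reads",
         fa = "fasta_windows", fasta = "fasta_windows", fna = "fasta_windows",
         stop("cannot guess format from extension: ", path, call. = FALSE))
}

#' Wrap an in-memory interval table as a sorted stream
#'
#' @param x A data frame with `chrom`, `start`, `end` (and optionally
#'   `strand`) columns; remaining columns become the item payload.
#' @param refdict Optional [refdict()] fixing chromosome order.
#' @param region Optional region; only overlapping rows are yielded.
#' @return A `txome_stream`.
#' @export
memory_stream <- function(x, refdict = NULL, region = NULL) {
  x <- as_gi(x)
  if (is.character(region)) region <- gi_parse(region)
  if (!is.null(region)) x <- x[gi_overlaps(x, region), , drop = FALSE]
  extra <- setdiff(names(x), c("chrom", "start", "end", "strand"))
  i <- 0L
  new_stream(refdict, function() {
    i <<- i + 1L
    if (i > nrow(x)) return(NULL)
    list(chrom = x$chrom[i], start = x$start[i], end = x$end[i],
         strand = x$strand[i],
         payload = as.list(x[i, extra, drop = FALSE]))
  }, label = "memory")
}

# read data lines for a text format, via tabix when a region is requested
text_source_lines <- function(path, region, label) {
  if (!file.exists(path)) stop(label, " file not found: ", path, call. = FALSE)
  if (!is.null(region)) {
    if (!file.exists(paste0(path, ".tbi"))) {
      stop("region-restricted access to an unindexed ", label, " file: ",
           path, " (no .tbi index)", call. = FALSE)
    }
    tf <- Rsamtools::TabixFile(path)
    open(tf); on.exit(close(tf))
    contigs <- Rsamtools::seqnamesTabix(tf)
    qchrom <- region$chrom[1L]
    if (!is.na(qchrom) && !qchrom %in% contigs) return(character())
    gr <- GenomicRanges::GRanges(
      qchrom, IRanges::IRanges(
        ifelse(is.na(region$start[1L]), 1L, region$start[1L]),
        ifelse(is.na(region$end[1L]), 536870912L, region$end[1L])))
    return(unname(unlist(Rsamtools::scanTabix(tf, param = gr))))
  }
  con <- if (grepl("\\.(gz|bgz)$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

text_stream <- function(path, region, refdict, parse_line, label) {
  lines <- text_source_lines(path, region, label)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") &
                   !startsWith(lines, "browser")]
  rd <- refdict
  if (is.null(rd) && file.exists(paste0(path, ".tbi"))) {
    rd <- refdict_from_tabix(path)
  }
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  i <- 0L
  s <- new_stream(rd, function() {
    repeat {
      i <<- i + 1L
      if (i > length(lines)) return(NULL)
      counter$n <- counter$n + 1L
      item <- parse_line(lines[[i]], i)
      if (!is.null(item)) return(item)
    }
  }, label = paste0(label, " ", path), counter = counter)
  s
}

parse_bed <- function(line, i) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 3L) stop("malformed BED line ", i, call. = FALSE)
  strand <- if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "."
  list(chrom = f[1L], start = as.integer(f[2L]) + 1L, end = as.integer(f[3L]),
       strand = strand,
       payload = list(name = if (length(f) >= 4L) f[4L] else NA_character_,
                      score = if (length(f) >= 5L)
                        suppressWarnings(as.numeric(f[5L])) else NA_real_,
                      fields = f))
}

parse_bedgraph <- function(line, i) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 4L) stop("malformed bedGraph line ", i, call. = FALSE)
  list(chrom = f[1L], start = as.integer(f[2L]) + 1L, end = as.integer(f[3L]),
       strand = ".", payload = list(value = as.numeric(f[4L])))
}

parse_gxf_factory <- function(dialect) {
  force(dialect)
  function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) stop("malformed annotation line ", i, call. = FALSE)
    attrs <- if (length(f) >= 9L) {
      if (dialect == "gtf") parse_attrs_gtf(f[9L])[[1L]] else
        parse_attrs_gff3(f[9L])[[1L]]
    } else character()
    strand <- if (f[7L] %in% c("+", "-")) f[7L] else "."
    list(chrom = f[1L], start = as.integer(f[4L]), end = as.integer(f[5L]),
         strand = strand,
         payload = list(source = f[2L], type = f[3L], score = f[6L],
                        phase = suppressWarnings(as.integer(f[8L])),
                        attrs = attrs))
  }
}

parse_vcf <- function(line, i) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 8L) stop("malformed VCF line ", i, call. = FALSE)
  pos <- as.integer(f[2L])
  ref <- f[4L]; alt <- f[5L]
  # span covers the reference allele; symbolic ALTs carry no length on the
  # reference beyond REF, fall back to the single-base span with a warning
  if (grepl("^<.*>$", alt) && nchar(ref) == 1L) {
    warning("symbolic allele without explicit length at ", f[1L], ":", pos,
            "; using single-base span", call. = FALSE)
  }
  list(chrom = f[1L], start = pos, end = pos + nchar(ref) - 1L, strand = ".",
       payload = list(id = f[3L], ref = ref, alt = alt, qual = f[6L],
                      filter = f[7L], info = f[8L]))
}

# -- alignments ---------------------------------------------------------------

cigar_ref_span <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(NA_integer_)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  kind <- sub("^[0-9]+", "", ops)
  sum(lens[kind %in% c("M", "D", "N", "=", "X")])
}

sam_flag_keep <- function(flag, keep_secondary, keep_supplementary,
                          keep_duplicates, keep_unmapped) {
  ok <- rep(TRUE, length(flag))
  if (!keep_unmapped) ok <- ok & bitwAnd(flag, 4L) == 0L
  if (!keep_secondary) ok <- ok & bitwAnd(flag, 256L) == 0L
  if (!keep_duplicates) ok <- ok & bitwAnd(flag, 1024L) == 0L
  if (!keep_supplementary) ok <- ok & bitwAnd(flag, 2048L) == 0L
  ok
}

reads_stream <- function(path, region, refdict, min_mapq, keep_secondary,
                         keep_supplementary, keep_duplicates, keep_unmapped,
                         tags) {
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  rd <- refdict %||% refdict_from_sam_header(path)
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  if (is_bam) {
    if (!is.null(region) && !file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path))) {
      stop("region-restricted access to an unindexed BAM file: ", path,
           call. = FALSE)
    }
    flag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = if (keep_unmapped) NA else FALSE,
      isSecondaryAlignment = if (keep_secondary) NA else FALSE,
      isSupplementaryAlignment = if (keep_supplementary) NA else FALSE,
      isDuplicate = if (keep_duplicates) NA else FALSE)
    what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
    param <- if (is.null(region)) {
      Rsamtools::ScanBamParam(what = what, tag = tags, flag = flag,
                              mapqFilter = min_mapq)
    } else {
      gr <- GenomicRanges::GRanges(
        region$chrom[1L],
        IRanges::IRanges(ifelse(is.na(region$start[1L]), 1L, region$start[1L]),
                         ifelse(is.na(region$end[1L]), 536870912L,
                                region$end[1L])))
      Rsamtools::ScanBamParam(what = what, tag = tags, flag = flag,
                              mapqFilter = min_mapq, which = gr)
    }
    res <- Rsamtools::scanBam(path, param = param)
    recs <- do.call(rbind_bam_chunks, res)
  } else {
    recs <- parse_sam_text(path, tags)
    keep <- sam_flag_keep(recs$flag, keep_secondary, keep_supplementary,
                          keep_duplicates, keep_unmapped) &
      recs$mapq >= min_mapq
    recs <- lapply(recs, function(col) col[keep])
    if (!is.null(region)) {
      span <- vapply(recs$cigar, cigar_ref_span, 1L, USE.NAMES = FALSE)
      ends <- recs$pos + span - 1L
      qs <- ifelse(is.na(region$start[1L]), 1L, region$start[1L])
      qe <- ifelse(is.na(region$end[1L]), .Machine$integer.max, region$end[1L])
      keep <- (is.na(region$chrom[1L]) | recs$rname == region$chrom[1L]) &
        recs$pos <= qe & ends >= qs
      recs <- lapply(recs, function(col) col[keep])
    }
  }
  n_rec <- length(recs$pos)
  i <- 0L
  new_stream(rd, function() {
    i <<- i + 1L
    if (i > n_rec) return(NULL)
    counter$n <- counter$n + 1L
    span <- cigar_ref_span(recs$cigar[[i]])
    tag_vals <- if (length(tags)) {
      stats::setNames(lapply(tags, function(t) {
        v <- recs$tag[[t]]
        if (is.null(v) || length(v) < i) NA else v[[i]]
      }), tags)
    } else list()
    list(chrom = as.character(recs$rname[[i]]), start = recs$pos[[i]],
         end = recs$pos[[i]] + (span %|NA|% 1L) - 1L,
         strand = if (bitwAnd(recs$flag[[i]], 16L) > 0L) "-" else "+",
         payload = list(qname = recs$qname[[i]], flag = recs$flag[[i]],
                        mapq = recs$mapq[[i]], cigar = recs$cigar[[i]],
                        seq = as.character(recs$seq[[i]]),
                        qual = as.character(recs$qual[[i]]),
                        tags = tag_vals))
  }, label = paste0("reads ", path), counter = counter)
}

rbind_bam_chunks <- function(...) {
  chunks <- list(...)
  out <- list(
    qname = unlist(lapply(chunks, `[[`, "qname")),
    flag = unlist(lapply(chunks, `[[`, "flag")),
    rname = unlist(lapply(chunks, function(c) as.character(c$rname))),
    pos = unlist(lapply(chunks, `[[`, "pos")),
    mapq = unlist(lapply(chunks, `[[`, "mapq")),
    cigar = unlist(lapply(chunks, `[[`, "cigar")),
    seq = unlist(lapply(chunks, function(c) as.character(c$seq))),
    qual = unlist(lapply(chunks, function(c) as.character(c$qual))))
  tag_names <- unique(unlist(lapply(chunks, function(c) names(c$tag))))
  out$tag <- stats::setNames(lapply(tag_names, function(t)
    unlist(lapply(chunks, function(c) c$tag[[t]]))), tag_names)
  out
}

parse_sam_text <- function(path, tags) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get_tag <- function(f, tag) {
    opt <- f[-seq_len(11L)]
    hit <- opt[startsWith(opt, paste0(tag, ":"))]
    if (!length(hit)) return(NA)
    parts <- strsplit(hit[[1L]], ":", fixed = TRUE)[[1L]]
    val <- paste(parts[-(1:2)], collapse = ":")
    if (parts[2L] %in% c("i", "f")) as.numeric(val) else val
  }
  list(
    qname = vapply(fields, `[[`, "", 1L),
    flag = as.integer(vapply(fields, `[[`, "", 2L)),
    rname = vapply(fields, `[[`, "", 3L),
    pos = as.integer(vapply(fields, `[[`, "", 4L)),
    mapq = as.integer(vapply(fields, `[[`, "", 5L)),
    cigar = vapply(fields, `[[`, "", 6L),
    seq = vapply(fields, `[[`, "", 10L),
    qual = vapply(fields, `[[`, "", 11L),
    tag = stats::setNames(lapply(tags, function(t)
      lapply(fields, get_tag, tag = t)), tags))
}

fasta_window_stream <- function(path, region, refdict, win_size) {
  rd <- refdict %||% refdict_from_fai(path)
  tiles <- gi_tile(rd, win_size)
  if (!is.null(region)) tiles <- tiles[gi_overlaps(tiles, region), ,
                                       drop = FALSE]
  fa <- Rsamtools::FaFile(path)
  cur_chrom <- ""; cur_seq <- ""
  i <- 0L
  new_stream(rd, function() {
    i <<- i + 1L
    if (i > nrow(tiles)) return(NULL)
    if (tiles$chrom[i] != cur_chrom) {
      cur_chrom <<- tiles$chrom[i]
      cur_seq <<- as.character(Rsamtools::scanFa(
        fa, GenomicRanges::GRanges(cur_chrom, IRanges::IRanges(
          1L, rd$length[match(cur_chrom, rd$chrom)]))))
    }
    list(chrom = tiles$chrom[i], start = tiles$start[i], end = tiles$end[i],
         strand = ".",
         payload = list(seq = substr(cur_seq, tiles$start[i], tiles$end[i])))
  }, label = paste0("fasta ", path))
}

# -- combinators --------------------------------------------------------------

#' Group a sorted stream by location overlap
#'
#' Consecutive, transitively overlapping items form one group; the group's
#' location is the merged envelope of its members. Concatenating the groups'
#' member lists reproduces the source sequence exactly.
#'
#' @param s A sorted `txome_stream`.
#' @return A `txome_stream` whose items carry `payload$items`, the list of
#'   member LocationItems.
#' @export
group_by_overlap <- function(s) {
  new_stream(stream_refdict(s), function() {
    first <- stream_next(s)
    if (is.null(first)) return(NULL)
    members <- list(first)
    env_end <- first$end
    repeat {
      nxt <- stream_peek(s)
      if (is.null(nxt) || nxt$chrom != first$chrom || nxt$start > env_end) break
      members[[length(members) + 1L]] <- stream_next(s)
      env_end <- max(env_end, nxt$end)
    }
    list(chrom = first$chrom, start = first$start, end = env_end,
         strand = ".", payload = list(items = members))
  }, label = "group_by_overlap")
}

#' Tile a sorted stream over fixed-size windows
#'
#' Yields every tile of [gi_tile()] in order, together with all source items
#' overlapping it. An item spanning a tile boundary appears in every tile it
#' overlaps (documented duplication).
#'
#' @param s A sorted `txome_stream`.
#' @param tile_size Tile width in bases.
#' @param refdict RefDict with known lengths defining the tiles (defaults to
#'   the stream's own).
#' @return A `txome_stream` whose items are tiles with `payload$items`.
#' @export
tile_stream <- function(s, tile_size, refdict = stream_refdict(s)) {
  if (is.null(refdict)) {
    stop("tile_stream() needs a reference dictionary with known lengths",
         call. = FALSE)
  }
  tiles <- gi_tile(refdict, tile_size)
  buffer <- list()
  ti <- 0L
  cidx_of <- function(chrom) match(chrom, refdict$chrom)
  new_stream(refdict, function() {
    ti <<- ti + 1L
    if (ti > nrow(tiles)) return(NULL)
    tc <- tiles$chrom[ti]; ts <- tiles$start[ti]; te <- tiles$end[ti]
    tci <- cidx_of(tc)
    buffer <<- Filter(function(it) it$chrom == tc && it$end >= ts, buffer)
    repeat {
      nxt <- stream_peek(s)
      if (is.null(nxt)) break
      nci <- cidx_of(nxt$chrom)
      if (is.na(nci)) {
        stop("contig '", nxt$chrom, "' absent from tiling RefDict",
             call. = FALSE)
      }
      if (nci < tci) { stream_next(s); next }       # chromosome already tiled
      if (nci == tci && nxt$start <= te) {
        it <- stream_next(s)
        if (it$end >= ts) buffer[[length(buffer) + 1L]] <<- it
        next
      }
      break
    }
    list(chrom = tc, start = ts, end = te, strand = ".",
         payload = list(items = buffer))
  }, label = "tile_stream")
}

#' Merge several sorted streams into one
#'
#' A stable k-way merge: output is globally sorted under the merged RefDict;
#' ties break by source order, then by interval sort order. The RefDicts of
#' all sources must be pairwise compatible — shared chromosomes in
#' contradictory relative order abort before anything is yielded.
#'
#' @param streams List of sorted `txome_stream`s.
#' @return A `txome_stream`; each yielded item carries `$source`, the
#'   1-based index of the stream it came from.
#' @export
merge_streams <- function(streams) {
  stopifnot(length(streams) >= 1L)
  rds <- lapply(streams, stream_refdict)
  known <- Filter(Negate(is.null), rds)
  rd <- if (length(known)) refdict_merge(known) else NULL
  cidx_of <- function(chrom) {
    if (is.null(rd)) return(0L)
    i <- match(chrom, rd$chrom)
    if (is.na(i)) stop("contig '", chrom, "' absent from merged RefDict",
                       call. = FALSE)
    i
  }
  new_stream(rd, function() {
    best <- NULL; best_key <- NULL
    for (k in seq_along(streams)) {
      it <- stream_peek(streams[[k]])
      if (is.null(it)) next
      key <- c(cidx_of(it$chrom), it$start, it$end, k)
      if (is.null(best) || key_less(key, best_key)) {
        best <- k; best_key <- key
      }
    }
    if (is.null(best)) return(NULL)
    item <- stream_next(streams[[best]])
    item$source <- best
    item
  }, label = "merge_streams")
}

key_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Single-pass overlap join over sorted streams
#'
#' For each item of the anchor stream, in anchor order, collects all items
#' of every labelled source stream whose location overlaps the anchor. Each
#' source is read exactly once, with a sliding buffer per source: items are
#' buffered while they may still overlap a future anchor and evicted once
#' their end falls before the current anchor's start — anchors sorted by
#' start make this safe. Overlap is strand-agnostic unless
#' `strand_specific = TRUE` (strands must match or either side be
#' unstranded).
#'
#' @param anchors A sorted `txome_stream` of anchor locations.
#' @param sources Named list of sorted `txome_stream`s.
#' @param strand_specific Restrict to strand-compatible overlaps.
#' @return A `txome_stream` of bundles: each item has the anchor's location
#'   and `payload = list(anchor = <anchor item>, data = <named list of
#'   overlapping items per label>)`; every configured label is present even
#'   when its list is empty.
#' @export
annotation_iterator <- function(anchors, sources = list(),
                                strand_specific = FALSE) {
  if (length(sources) && (is.null(names(sources)) ||
                          any(!nzchar(names(sources))))) {
    stop("sources must be a named list of streams", call. = FALSE)
  }
  rds <- Filter(Negate(is.null),
                c(list(stream_refdict(anchors)),
                  lapply(sources, stream_refdict)))
  rd <- if (length(rds)) refdict_merge(rds, what = "overlap-join streams")
  else NULL
  cidx_of <- function(chrom) {
    if (is.null(rd)) return(0L)
    i <- match(chrom, rd$chrom)
    if (is.na(i)) stop("contig '", chrom, "' absent from joined RefDict",
                       call. = FALSE)
    i
  }
  buffers <- replicate(length(sources), list(), simplify = FALSE)
  strands_ok <- function(a, b) {
    !strand_specific || a == "." || b == "." || a == b
  }
  new_stream(stream_refdict(anchors), function() {
    a <- stream_next(anchors)
    if (is.null(a)) return(NULL)
    aci <- cidx_of(a$chrom)
    data <- vector("list", length(sources))
    names(data) <- names(sources)
    for (k in seq_along(sources)) {
      src <- sources[[k]]
      # evict items that can no longer overlap this or any future anchor
      buffers[[k]] <<- Filter(function(it)
        it$.cidx > aci || (it$.cidx == aci && it$end >= a$start),
        buffers[[k]])
      repeat {
        nxt <- stream_peek(src)
        if (is.null(nxt)) break
        nci <- cidx_of(nxt$chrom)
        if (nci < aci) { stream_next(src); next }   # behind all future anchors
        if (nci == aci && nxt$start <= a$end) {
          it <- stream_next(src)
          it$.cidx <- nci
          if (it$end >= a$start) buffers[[k]][[length(buffers[[k]]) + 1L]] <<- it
          next
        }
        break
      }
      hits <- Filter(function(it)
        it$.cidx == aci && it$start <= a$end && it$end >= a$start &&
          strands_ok(a$strand, it$strand),
        buffers[[k]])
      data[[k]] <- lapply(hits, function(it) { it$.cidx <- NULL; it })
    }
    list(chrom = a$chrom, start = a$start, end = a$end, strand = a$strand,
         payload = list(anchor = a, data = data))
  }, label = "annotation_iterator")
}
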