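#' Genomic intervals
#'
#' A genomic interval (GI) is an immutable reference to a genomic location:
#' chromosome, 1-based inclusive start and stop coordinate, and strand.
#' Interval sets are represented as tibbles with one interval per row and
#' columns `chrom`, `start`, `end`, `strand`, carrying class `txome_gi` so the
#' usual dplyr verbs work on them unchanged. Any coordinate component may be
#' unset (`NA`): an unset chromosome matches any chromosome, an unset start
#' means "from the first base", an unset end means "to the end of the
#' chromosome". Because a row is a plain value, equality is value-based and
#' [gi_key()] renders a canonical string usable as a key in named lists and
#' environments.
#'
#' @param chrom Character vector of chromosome names (`NA` = any chromosome).
#' @param start,end Integer vectors of 1-based inclusive coordinates
#'   (`NA` = unbounded). Both ends are inclusive, so the length of a bounded
#'   interval is `end - start + 1`.
#' @param strand Character vector using `"+"`, `"-"` or `"."` (unstranded);
#'   `NA` is mapped to `"."`.
#'
#' @return A tibble of class `txome_gi` with columns `chrom`, `start`, `end`,
#'   `strand`.
#' @examples
#' gi("chr1", 1, 10, "+")
#' gi_parse("chr2:100-200:-")
#' @export
gi <- function(chrom = NA_character_, start = NA_integer_, end = NA_integer_,
               strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  if (n == 0L) {
    return(new_gi(tibble::tibble(chrom = character(), start = integer(),
                                 end = integer(), strand = character())))
  }
  chrom <- as.character(rep_len(chrom, n))
  start <- as.integer(rep_len(start, n))
  end <- as.integer(rep_len(end, n))
  strand <- as.character(rep_len(strand, n))
  strand[is.na(strand) | strand == ""] <- "."
  bad_strand <- !strand %in% c("+", "-", ".")
  if (any(bad_strand)) {
    stop("invalid strand value(s): ",
         paste(unique(strand[bad_strand]), collapse = ", "), call. = FALSE)
  }
  bad_start <- !is.na(start) & start < 1L
  if (any(bad_start)) {
    stop("invalid start coordinate(s) < 1: ",
         paste(utils::head(start[bad_start], 3L), collapse = ", "),
         call. = FALSE)
  }
  bad_order <- !is.na(start) & !is.na(end) & end < start
  if (any(bad_order)) {
    i <- which(bad_order)[1L]
    stop(sprintf("invalid interval: stop (%d) < start (%d)", end[i], start[i]),
         call. = FALSE)
  }
  new_gi(tibble::tibble(chrom = chrom, start = start, end = end,
                        strand = strand))
}

new_gi <- function(df) {
  class(df) <- unique(c("txome_gi", class(tibble::as_tibble(df))))
  df
}

#' Coerce a data frame to a genomic-interval tibble
#'
#' Accepts any data frame with `chrom`, `start`, `end` (and optionally
#' `strand`) columns and validates it through [gi()]. Extra columns are kept.
#'
#' @param x A data frame.
#' @return A `txome_gi` tibble.
#' @export
as_gi <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    stop("as_gi() needs columns chrom, start, end", call. = FALSE)
  }
  if (!"strand" %in% names(x)) x[["strand"]] <- rep(".", nrow(x))
  core <- gi(x$chrom, x$start, x$end, x$strand)
  extra <- x[setdiff(names(x), c("chrom", "start", "end", "strand"))]
  new_gi(tibble::as_tibble(cbind(core, extra)))
}

#' Parse region strings into genomic intervals
#'
#' Region strings use the syntax `"chrom[:start-stop][:strand]"`, e.g.
#' `"chr1"`, `"chr1:100-200"`, `"chr1:100-200:-"`. Thousands separators
#' (`,`) are tolerated in coordinates on input but never emitted by
#' [gi_format()]. A parsed string re-rendered with [gi_format()] round-trips.
#'
#' @param spec Character vector of region strings.
#' @return A `txome_gi` tibble.
#' @export
gi_parse <- function(spec) {
  spec <- as.character(spec)
  parse1 <- function(s) {
    s0 <- trimws(s)
    strand <- "."
    m <- regmatches(s0, regexec("^(.*):([+.-])$", s0))[[1]]
    if (length(m) == 3L && grepl("[:0-9]", m[2])) {
      # strand suffix only if a coordinate part (or colon) precedes it,
      # so bare names like "chr-" stay chromosome names
      strand <- m[3]
      s0 <- m[2]
    }
    if (!grepl(":", s0, fixed = TRUE)) {
      if (!nzchar(s0)) stop("unparsable region string: '", s, "'", call. = FALSE)
      return(list(chrom = s0, start = NA_integer_, end = NA_integer_,
                  strand = strand))
    }
    mm <- regmatches(s0, regexec("^(.+):([0-9,]+)-([0-9,]*)$", s0))[[1]]
    if (length(mm) != 4L) {
      stop("unparsable region string: '", s, "' (expected chrom[:start-stop][:strand])",
           call. = FALSE)
    }
    num <- function(v) if (nzchar(v)) as.integer(gsub(",", "", v, fixed = TRUE))
      else NA_integer_  # open end: to end of chromosome
    list(chrom = mm[2], start = num(mm[3]), end = num(mm[4]),
         strand = strand)
  }
  parts <- lapply(spec, parse1)
  gi(chrom = vapply(parts, `[[`, "", "chrom"),
     start = vapply(parts, `[[`, 1L, "start"),
     end = vapply(parts, `[[`, 1L, "end"),
     strand = vapply(parts, `[[`, "", "strand"))
}

#' Render genomic intervals as region strings
#'
#' @param x A `txome_gi` tibble (or data frame with the same columns).
#' @return Character vector of canonical region strings that [gi_parse()]
#'   parses back to the same intervals.
#' @export
gi_format <- function(x) {
  out <- ifelse(is.na(x$chrom), "*", x$chrom)
  has_coords <- !is.na(x$start) | !is.na(x$end)
  s <- ifelse(is.na(x$start), 1L, x$start)
  e <- ifelse(is.na(x$end), x$end, x$end)
  coord <- paste0(s, "-", ifelse(is.na(e), "", e))
  out <- ifelse(has_coords, paste0(out, ":", coord), out)
  ifelse(x$strand == ".", out, paste0(out, ":", x$strand))
}

#' Canonical value-based key for intervals
#'
#' Two intervals with identical fields produce identical keys, so intervals
#' can reliably index named lists, environments, and other mapping structures.
#'
#' @inheritParams gi_format
#' @return Character vector of keys.
#' @export
gi_key <- function(x) {
  paste(ifelse(is.na(x$chrom), "*", x$chrom),
        ifelse(is.na(x$start), "NA", x$start),
        ifelse(is.na(x$end), "NA", x$end),
        x$strand, sep = "\r")
}

#' Interval length in bases
#'
#' @inheritParams gi_format
#' @return Integer vector (`NA` for unbounded intervals).
#' @export
gi_width <- function(x) {
  as.integer(x$end - ifelse(is.na(x$start), 1L, x$start) + 1L)
}

#' Pairwise overlap test
#'
#' True where the two intervals share at least one base. Chromosomes must be
#' equal, but an unset chromosome matches any chromosome; unset start/end act
#' as unbounded range ends. Strand is ignored unless `strand_specific = TRUE`,
#' in which case strands must be equal or either interval unstranded.
#'
#' @param a,b `txome_gi` tibbles, recycled to common length.
#' @param strand_specific Require strand agreement as described above.
#' @return Logical vector.
#' @export
gi_overlaps <- function(a, b, strand_specific = FALSE) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  chrom_ok <- is.na(a$chrom[ai]) | is.na(b$chrom[bi]) |
    a$chrom[ai] == b$chrom[bi]
  as_ <- ifelse(is.na(a$start[ai]), 1L, a$start[ai])
  bs_ <- ifelse(is.na(b$start[bi]), 1L, b$start[bi])
  ae_ <- ifelse(is.na(a$end[ai]), Inf, a$end[ai])
  be_ <- ifelse(is.na(b$end[bi]), Inf, b$end[bi])
  range_ok <- as_ <= be_ & bs_ <= ae_
  ok <- chrom_ok & range_ok
  if (strand_specific) {
    sa <- a$strand[ai]; sb <- b$strand[bi]
    ok <- ok & (sa == "." | sb == "." | sa == sb)
  }
  ok
}

#' Pairwise envelopment test
#'
#' True where `outer` fully contains `inner` (same chromosome,
#' `outer$start <= inner$start` and `inner$end <= outer$end`). Every interval
#' envelops itself.
#'
#' @param outer,inner `txome_gi` tibbles, recycled to common length.
#' @return Logical vector.
#' @export
gi_envelops <- function(outer, inner) {
  n <- max(nrow(outer), nrow(inner))
  oi <- rep_len(seq_len(nrow(outer)), n)
  ii <- rep_len(seq_len(nrow(inner)), n)
  chrom_ok <- is.na(outer$chrom[oi]) | outer$chrom[oi] == inner$chrom[ii]
  os <- ifelse(is.na(outer$start[oi]), 1L, outer$start[oi])
  is_ <- ifelse(is.na(inner$start[ii]), 1L, inner$start[ii])
  oe <- ifelse(is.na(outer$end[oi]), Inf, outer$end[oi])
  ie <- ifelse(is.na(inner$end[ii]), Inf, inner$end[ii])
  chrom_ok & os <= is_ & ie <= oe
}

#' Pairwise gap distance
#'
#' 0 for overlapping intervals, otherwise the number of bases strictly between
#' them; `NA` when the chromosomes differ (distance is undefined across
#' chromosomes).
#'
#' @param a,b `txome_gi` tibbles with set coordinates, recycled.
#' @return Integer vector.
#' @export
gi_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  # gap = bases strictly between the intervals; adjacent intervals gap 0
  d <- pmax(pmax(a$start[ai] - b$end[bi], b$start[bi] - a$end[ai]) - 1L, 0L)
  d[!is.na(a$chrom[ai]) & !is.na(b$chrom[bi]) &
      a$chrom[ai] != b$chrom[bi]] <- NA_integer_
  as.integer(d)
}

#' Merge an interval set into its union
#'
#' Returns the minimal set of maximal intervals covering exactly the union of
#' the input. Overlapping *and* book-ended intervals (stop + 1 == next start)
#' coalesce; callers that want touching-but-separate intervals kept apart
#' should pre-filter. Strand is preserved when every member of a merged run
#' agrees, otherwise the run is unstranded. The output is sorted by
#' (chromosome name, start, end); use [gi_sort()] for RefDict order.
#'
#' @param x A `txome_gi` tibble with set chromosome/start/end on every row.
#' @return A `txome_gi` tibble of disjoint, non-book-ended intervals.
#' @export
gi_merge <- function(x) {
  if (nrow(x) == 0L) return(gi(character(), integer(), integer(), character()))
  stopifnot(!anyNA(x$chrom), !anyNA(x$start), !anyNA(x$end))
  o <- order(x$chrom, x$start, x$end)
  chrom <- x$chrom[o]; start <- x$start[o]; end <- x$end[o]
  strand <- x$strand[o]
  # run id increments when a new cluster starts: different chromosome or a
  # gap of >= 1 base after the running maximum end (book-ended => same run)
  run_end <- cummax_by(end, chrom)
  new_run <- c(TRUE, chrom[-1L] != chrom[-length(chrom)] |
                 start[-1L] > run_end[-length(run_end)] + 1L)
  run <- cumsum(new_run)
  out <- tibble::tibble(chrom = chrom, start = start, end = end,
                        strand = strand, run = run) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(chrom = .data$chrom[1L],
                     start = min(.data$start),
                     end = max(.data$end),
                     strand = if (length(unique(.data$strand)) == 1L)
                       .data$strand[1L] else ".",
                     .groups = "drop") |>
    dplyr::select(!"run")
  new_gi(out)
}

# running maximum restarted at each chromosome change
cummax_by <- function(x, group) {
  out <- x
  r <- rle(group)
  idx <- c(0L, cumsum(r$lengths))
  for (k in seq_along(r$lengths)) {
    sel <- (idx[k] + 1L):idx[k + 1L]
    out[sel] <- cummax(x[sel])
  }
  out
}

#' Sort keys and sorting under a reference dictionary
#'
#' `gi_sort_key()` returns a data frame of orderable components
#' (chromosome index in `rd`, start, end) implementing the global sort order:
#' chromosome order is taken from the RefDict, ties break by start, then stop
#' (shorter interval first). An unset chromosome sorts before all set ones; an
#' unset start is treated as 1; an unset stop sorts after all set stops.
#' `gi_sort()` returns `x` reordered accordingly; equal-coordinate rows keep
#' their input order (stable).
#'
#' @param x A `txome_gi` tibble.
#' @param rd A [refdict()]. Every set chromosome in `x` must be listed in it.
#' @return `gi_sort_key()`: a data frame with columns `cidx`, `start`, `end`;
#'   `gi_sort()`: the reordered tibble.
#' @export
gi_sort_key <- function(x, rd) {
  cidx <- match(x$chrom, rd$chrom)
  missing <- !is.na(x$chrom) & is.na(cidx)
  if (any(missing)) {
    stop("chromosome(s) not in reference dictionary '", refdict_name(rd),
         "': ", paste(unique(x$chrom[missing]), collapse = ", "),
         call. = FALSE)
  }
  cidx[is.na(x$chrom)] <- 0L
  data.frame(cidx = cidx,
             start = ifelse(is.na(x$start), 1L, x$start),
             end = ifelse(is.na(x$end), Inf, as.numeric(x$end)))
}

#' @rdname gi_sort_key
#' @export
gi_sort <- function(x, rd) {
  k <- gi_sort_key(x, rd)
  x[order(k$cidx, k$start, k$end), , drop = FALSE]
}
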