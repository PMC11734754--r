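#' Reference dictionaries
#'
#' A RefDict is an ordered chromosome -> length map. Entry order is
#' significant: it defines the global sort order of genomic intervals, and it
#' is what the compatibility check compares when deciding whether two
#' datasets may be merged. Lengths may be unknown (`NA`), e.g. when the
#' dictionary was derived from a tabix index, which records contig names but
#' not lengths.
#'
#' @param chrom Character vector of unique chromosome names, in order.
#' @param length Integer vector of chromosome lengths (`NA` = unknown).
#' @param name Label recording where the dictionary came from (typically the
#'   source file path).
#' @return A tibble of class `txome_refdict` with columns `chrom`, `length`.
#' @examples
#' refdict(c("chr1", "chr2"), c(1000L, 500L))
#' @export
refdict <- function(chrom, length = NA_integer_, name = "refdict") {
  chrom <- as.character(chrom)
  length <- as.integer(rep_len(length, base::length(chrom)))
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome name(s) in reference dictionary: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(length) & length <= 0L)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  out <- tibble::tibble(chrom = chrom, length = length)
  class(out) <- unique(c("txome_refdict", class(out)))
  attr(out, "refdict_name") <- name
  out
}

#' @rdname refdict
#' @param rd A `txome_refdict`.
#' @export
refdict_name <- function(rd) attr(rd, "refdict_name") %||% "refdict"

#' Build a RefDict from a FASTA index (.fai)
#'
#' Reads the first two columns (contig name, length) of a `samtools faidx`
#' style index, preserving file order.
#'
#' @param path Path to a `.fai` file, or to a FASTA file whose sibling
#'   `<path>.fai` exists.
#' @return A [refdict()].
#' @export
refdict_from_fai <- function(path) {
  fai <- if (grepl("\\.fai$", path)) path else paste0(path, ".fai")
  if (!file.exists(fai)) stop("FASTA index not found: ", fai, call. = FALSE)
  lines <- readLines(fai, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("malformed .fai file: ", fai, call. = FALSE)
  }
  refdict(vapply(fields, `[[`, "", 1L),
          as.integer(vapply(fields, `[[`, "", 2L)),
          name = fai)
}

#' Build a RefDict from SAM/BAM @SQ header lines
#'
#' @param path Path to a BAM file (read via its header) or a SAM text file.
#' @return A [refdict()].
#' @export
refdict_from_sam_header <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    hdr <- Rsamtools::scanBamHeader(path)[[1L]]$targets
    if (anyDuplicated(names(hdr))) {
      stop("duplicate @SQ contig in BAM header: ", path, call. = FALSE)
    }
    return(refdict(names(hdr), as.integer(hdr), name = path))
  }
  con <- file(path, "r")
  on.exit(close(con))
  chroms <- character(); lens <- integer()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L || !startsWith(line, "@")) break
    if (startsWith(line, "@SQ")) {
      sn <- sub(".*\tSN:([^\t]+).*", "\\1", line)
      ln <- suppressWarnings(as.integer(sub(".*\tLN:([0-9]+).*", "\\1", line)))
      chroms <- c(chroms, sn); lens <- c(lens, ln)
    }
  }
  if (length(chroms) == 0L) {
    stop("no @SQ header lines found in ", path, call. = FALSE)
  }
  refdict(chroms, lens, name = path)
}

#' Build a RefDict from a tabix index
#'
#' Tabix indices record contig names and order but not lengths, so all
#' lengths are unknown.
#'
#' @param path Path to a bgzip-compressed, tabix-indexed file (the `.tbi`
#'   must sit next to it).
#' @return A [refdict()] with `NA` lengths.
#' @export
refdict_from_tabix <- function(path) {
  if (!file.exists(paste0(path, ".tbi"))) {
    stop("tabix index not found: ", paste0(path, ".tbi"), call. = FALSE)
  }
  tf <- Rsamtools::TabixFile(path)
  open(tf); on.exit(close(tf))
  chroms <- Rsamtools::seqnamesTabix(tf)
  refdict(chroms, NA_integer_, name = path)
}

#' Check compatibility of two reference dictionaries
#'
#' Two dictionaries are *identical* when they list the same chromosomes in
#' the same order with the same (known) lengths; *compatible* when every
#' shared chromosome agrees in relative order and in length wherever both
#' lengths are known; *incompatible* on a length conflict or when shared
#' chromosomes appear in contradictory relative order (sorted merging would
#' silently interleave wrongly — an explicit `allow_order_mismatch` downgrade
#' is available at the call sites that escalate). Chromosome name
#' normalisation is never automatic; pass `aliases` to map names in `b` onto
#' the vocabulary of `a` (e.g. `c("1" = "chr1")`).
#'
#' @param a,b [refdict()]s.
#' @param aliases Named character vector mapping alternative chromosome names
#'   to canonical ones, applied to both sides before comparison.
#' @return A list of class `txome_refdict_compat` with elements `verdict`
#'   (`"identical"`, `"compatible"` or `"incompatible"`), `only_a`, `only_b`,
#'   `length_conflicts` (tibble), and `order_conflict` (logical). The verdict
#'   is symmetric in `a` and `b`.
#' @export
refdict_compat <- function(a, b, aliases = NULL) {
  canon <- function(x) {
    if (!is.null(aliases)) {
      hit <- x %in% names(aliases)
      x[hit] <- unname(aliases[x[hit]])
    }
    x
  }
  ca <- canon(a$chrom); cb <- canon(b$chrom)
  shared <- intersect(ca, cb)
  only_a <- setdiff(ca, cb); only_b <- setdiff(cb, ca)
  la <- a$length[match(shared, ca)]
  lb <- b$length[match(shared, cb)]
  conflict <- !is.na(la) & !is.na(lb) & la != lb
  length_conflicts <- tibble::tibble(chrom = shared[conflict],
                                     length_a = la[conflict],
                                     length_b = lb[conflict])
  order_conflict <- length(shared) > 1L &&
    is.unsorted(match(shared[order(match(shared, ca))], cb), strictly = TRUE)
  verdict <- if (nrow(length_conflicts) > 0L || order_conflict) {
    "incompatible"
  } else if (identical(ca, cb) && identical(a$length, b$length)) {
    "identical"
  } else {
    "compatible"
  }
  structure(list(verdict = verdict, only_a = only_a, only_b = only_b,
                 length_conflicts = length_conflicts,
                 order_conflict = order_conflict),
            class = "txome_refdict_compat")
}

#' @export
print.txome_refdict_compat <- function(x, ...) {
  cat("RefDict compatibility:", x$verdict, "\n")
  if (length(x$only_a)) cat("  only in a:", paste(x$only_a, collapse = ", "), "\n")
  if (length(x$only_b)) cat("  only in b:", paste(x$only_b, collapse = ", "), "\n")
  if (nrow(x$length_conflicts)) {
    cat("  length conflicts:",
        paste(x$length_conflicts$chrom, collapse = ", "), "\n")
  }
  if (x$order_conflict) cat("  shared chromosomes in contradictory order\n")
  invisible(x)
}

# escalate an incompatible report to an error (or warning for pure order
# conflicts when the caller opts in)
assert_refdict_compatible <- function(a, b, aliases = NULL,
                                      allow_order_mismatch = FALSE,
                                      what = "datasets") {
  rep <- refdict_compat(a, b, aliases = aliases)
  if (rep$verdict != "incompatible") return(invisible(rep))
  if (nrow(rep$length_conflicts) > 0L) {
    stop("incompatible reference dictionaries for ", what,
         ": length conflict on ",
         paste(rep$length_conflicts$chrom, collapse = ", "),
         " (", refdict_name(a), " vs ", refdict_name(b), ")", call. = FALSE)
  }
  if (rep$order_conflict && allow_order_mismatch) {
    warning("reference dictionaries for ", what,
            " list shared chromosomes in different order", call. = FALSE)
    return(invisible(rep))
  }
  stop("incompatible reference dictionaries for ", what,
       ": shared chromosomes in contradictory relative order (",
       refdict_name(a), " vs ", refdict_name(b), ")", call. = FALSE)
}

# union of pairwise-compatible refdicts, preserving a consistent order;
# lengths filled from whichever side knows them
refdict_merge <- function(rds, aliases = NULL, what = "streams") {
  stopifnot(length(rds) >= 1L)
  if (length(rds) > 1L) {
    for (i in seq_len(length(rds) - 1L)) {
      for (j in seq(i + 1L, length(rds))) {
        assert_refdict_compatible(rds[[i]], rds[[j]], aliases = aliases,
                                  what = what)
      }
    }
  }
  out_chrom <- character(); out_len <- integer()
  for (rd in rds) {
    for (k in seq_len(nrow(rd))) {
      i <- match(rd$chrom[k], out_chrom)
      if (is.na(i)) {
        # insert after the last already-placed chromosome that precedes it
        prev <- rd$chrom[seq_len(k - 1L)]
        pos <- max(c(0L, match(prev, out_chrom)), na.rm = TRUE)
        out_chrom <- append(out_chrom, rd$chrom[k], after = pos)
        out_len <- append(out_len, rd$length[k], after = pos)
      } else if (is.na(out_len[i])) {
        out_len[i] <- rd$length[k]
      }
    }
  }
  refdict(out_chrom, out_len, name = "merged")
}

#' Tile a reference dictionary into fixed-size windows
#'
#' Produces, per chromosome, the consecutive intervals `[1..t]`, `[t+1..2t]`,
#' ..., truncating the final tile at the chromosome length. The tiles are
#' disjoint, emitted in RefDict sort order, and their union covers every base
#' of every chromosome exactly once.
#'
#' @param rd A [refdict()] with all lengths known.
#' @param tile_size Tile width in bases (positive integer).
#' @return A `txome_gi` tibble of tiles.
#' @export
gi_tile <- function(rd, tile_size) {
  stopifnot(is.numeric(tile_size), tile_size >= 1)
  tile_size <- as.integer(tile_size)
  if (anyNA(rd$length)) {
    stop("cannot tile chromosome(s) of unknown length: ",
         paste(rd$chrom[is.na(rd$length)], collapse = ", "), call. = FALSE)
  }
  pieces <- lapply(seq_len(nrow(rd)), function(i) {
    starts <- seq.int(1L, rd$length[i], by = tile_size)
    tibble::tibble(chrom = rd$chrom[i], start = starts,
                   end = pmin(starts + tile_size - 1L, rd$length[i]),
                   strand = ".")
  })
  new_gi(dplyr::bind_rows(pieces))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
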