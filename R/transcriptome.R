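#' Build a Transcriptome from a GTF/GFF3 annotation file
#'
#' Parses a gene annotation file into a hierarchical, queryable Transcriptome:
#' genes contain transcripts, transcripts contain exons, inferred introns,
#' CDS segments and UTRs. Features are frozen at build time; mutable state
#' (sequences, user annotations) lives in an external store keyed by feature
#' identity, so distinct features at identical coordinates hold independent
#' annotations. Feature rows are themselves genomic intervals (`txome_gi`)
#' and are accepted anywhere an interval is.
#'
#' Filters compose as AND and are applied while parsing, so excluded features
#' are never instantiated: `region` keeps a gene iff it overlaps the region;
#' `feature_ids` keeps listed genes (all their transcripts) and listed
#' transcripts (with their gene); `gene_types` filters on the flavor's gene
#' type attribute (e.g. `gene_biotype` for Ensembl-style files).
#'
#' Transcripts lacking exon rows receive a single synthetic exon spanning the
#' transcript, keeping spliced-sequence logic uniform. Introns are inferred
#' per transcript from the gaps between consecutive exons (see
#' [infer_introns()]); transcripts sharing intron coordinates get separate
#' intron features, each parented to its own transcript.
#'
#' @param path GTF or GFF3 file (plain text or bgzip-compressed; a sibling
#'   `.tbi` index enables region-restricted parsing without a full scan).
#' @param flavor Provider profile name, see [annotation_flavor()].
#' @param type_map Named character vector overriding the flavor's mapping
#'   from source feature-type strings to canonical types.
#' @param attr_map Named list overriding attribute keys, entries
#'   `gene_name` and/or `gene_type`.
#' @param region A `txome_gi` row or region string restricting parsing.
#' @param feature_ids Character vector of gene/transcript IDs to keep.
#' @param gene_types Character vector of gene types (biotypes) to keep.
#' @param keep_attrs Character vector naming the attributes to retain on
#'   features (`NULL` = all).
#' @param name Label for the transcriptome's RefDict.
#' @param compute_introns Infer introns for transcripts that have none
#'   (default `TRUE`).
#' @return An object of class `txome_transcriptome`.
#' @examples
#' \dontrun{
#' tx <- read_transcriptome("gencode.v44.gtf.gz", flavor = "gencode",
#'                          region = "chr21")
#' }
#' @export
read_transcriptome <- function(path, flavor = "generic", type_map = NULL,
                               attr_map = NULL, region = NULL,
                               feature_ids = NULL, gene_types = NULL,
                               keep_attrs = NULL, name = path,
                               compute_introns = TRUE) {
  fl <- annotation_flavor(flavor)
  if (!is.null(type_map)) fl$type_map <- type_map
  if (!is.null(attr_map)) {
    if (!is.null(attr_map$gene_name)) fl$gene_name_key <- attr_map$gene_name
    if (!is.null(attr_map$gene_type)) fl$gene_type_key <- attr_map$gene_type
  }
  if (is.character(region)) region <- gi_parse(region)

  src <- read_annotation_lines(path, region)
  rows <- parse_annotation_rows(src$lines, fl, keep_attrs)
  rd <- annotation_refdict(path, src$seqregions, rows, name)
  if (!is.null(region) && !is.na(region$chrom[1L]) &&
      !region$chrom[1L] %in% rd$chrom) {
    stop("region chromosome not in annotation: ", region$chrom[1L],
         call. = FALSE)
  }

  feats <- assemble_hierarchy(rows, fl, dialect = rows$dialect[1L] %||% "gff3",
                              region = region, feature_ids = feature_ids,
                              gene_types = gene_types,
                              compute_introns = compute_introns)
  feats <- sort_features(feats, rd)

  if (anyDuplicated(feats$feature_id)) {
    stop("duplicate feature IDs in annotation: ",
         paste(utils::head(unique(
           feats$feature_id[duplicated(feats$feature_id)]), 5L),
           collapse = ", "), call. = FALSE)
  }

  tx <- structure(list(
    refdict = rd,
    features = feats,
    flavor = fl,
    source = path,
    skipped_types = attr(rows, "skipped_types"),
    store = new.env(parent = emptyenv())
  ), class = "txome_transcriptome")
  tx$store$ann <- new.env(parent = emptyenv())
  tx$store$seq <- new.env(parent = emptyenv())
  tx$id_index <- stats::setNames(seq_len(nrow(feats)), feats$feature_id)
  tx$gene_tree <- gene_interval_tree(feats)
  tx$name_index <- gene_name_index(feats, fl$gene_name_key)
  tx
}

# -- file reading -------------------------------------------------------------

read_annotation_lines <- function(path, region = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  has_tbi <- file.exists(paste0(path, ".tbi"))
  if (!is.null(region)) {
    if (!has_tbi) {
      stop("region-restricted parsing requires a tabix index next to ", path,
           call. = FALSE)
    }
    tf <- Rsamtools::TabixFile(path)
    open(tf); on.exit(close(tf), add = TRUE)
    hdr <- Rsamtools::headerTabix(tf)$header
    contigs <- Rsamtools::seqnamesTabix(tf)
    qchrom <- region$chrom[1L]
    if (!is.na(qchrom) && !qchrom %in% contigs) {
      lines <- character()
    } else {
      gr <- GenomicRanges::GRanges(
        qchrom,
        IRanges::IRanges(ifelse(is.na(region$start[1L]), 1L, region$start[1L]),
                         ifelse(is.na(region$end[1L]), 536870912L,
                                region$end[1L])))
      lines <- Rsamtools::scanTabix(tf, param = gr)[[1L]]
    }
    all_lines <- c(hdr, lines)
  } else {
    con <- if (grepl("\\.(gz|bgz)$", path)) gzfile(path, "r") else file(path, "r")
    on.exit(close(con), add = TRUE)
    all_lines <- readLines(con, warn = FALSE)
  }
  seqreg <- all_lines[startsWith(all_lines, "##sequence-region")]
  seqregions <- NULL
  if (length(seqreg)) {
    parts <- strsplit(trimws(seqreg), "\\s+")
    ok <- lengths(parts) >= 4L
    seqregions <- tibble::tibble(
      chrom = vapply(parts[ok], `[[`, "", 2L),
      length = as.integer(vapply(parts[ok], `[[`, "", 4L)))
  }
  data_lines <- all_lines[!startsWith(all_lines, "#") & nzchar(all_lines)]
  list(lines = data_lines, seqregions = seqregions)
}

parse_annotation_rows <- function(lines, fl, keep_attrs = NULL) {
  if (length(lines) == 0L) {
    out <- tibble::tibble(chrom = character(), source = character(),
                          src_type = character(), type = character(),
                          start = integer(), end = integer(),
                          score = character(), strand = character(),
                          phase = integer(), attrs = list(),
                          dialect = character())
    attr(out, "skipped_types") <- integer()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 8L)) {
    bad <- which(lengths(fields) < 8L)[1L]
    stop("malformed annotation line ", bad, ": fewer than 8 columns",
         call. = FALSE)
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else ".", "")
  attr_col <- col(9L)
  dialect <- if (fl$dialect == "auto") detect_dialect(attr_col) else fl$dialect
  attrs <- if (dialect == "gtf") parse_attrs_gtf(attr_col) else
    parse_attrs_gff3(attr_col)
  src_type <- col(3L)
  type <- unname(fl$type_map[src_type])
  skipped <- table(src_type[is.na(type)])
  skipped_types <- stats::setNames(as.integer(skipped), names(skipped))
  if (length(skipped_types)) {
    warning("skipped ", sum(skipped_types), " annotation row(s) with unmapped ",
            "feature type(s): ", paste(names(skipped_types), collapse = ", "),
            call. = FALSE)
  }
  keep <- !is.na(type)
  strand <- col(7L)
  strand[!strand %in% c("+", "-")] <- "."
  out <- tibble::tibble(
    chrom = col(1L)[keep],
    source = col(2L)[keep],
    src_type = src_type[keep],
    type = type[keep],
    start = as.integer(col(4L))[keep],
    end = as.integer(col(5L))[keep],
    score = col(6L)[keep],
    strand = strand[keep],
    phase = suppressWarnings(as.integer(col(8L)))[keep],
    attrs = attrs[keep],
    dialect = dialect
  )
  if (!is.null(keep_attrs)) {
    out$attrs <- lapply(out$attrs, function(a) a[names(a) %in% keep_attrs])
  }
  attr(out, "skipped_types") <- skipped_types
  out
}

annotation_refdict <- function(path, seqregions, rows, name) {
  lens <- integer(); lnames <- character()
  if (!is.null(seqregions)) {
    lnames <- seqregions$chrom; lens <- seqregions$length
  }
  if (file.exists(paste0(path, ".tbi"))) {
    rd <- refdict_from_tabix(path)
    rd$length <- lens[match(rd$chrom, lnames)]
    attr(rd, "refdict_name") <- name
    return(rd)
  }
  observed <- unique(rows$chrom)
  if (length(lnames) && all(observed %in% lnames)) {
    return(refdict(lnames, lens, name = name))
  }
  refdict(observed, lens[match(observed, lnames)], name = name)
}

# -- hierarchy assembly -------------------------------------------------------

attr1 <- function(attrs, key) {
  v <- if (is.list(attrs)) attrs[[key]] else unname(attrs[key])
  if (is.null(v) || length(v) != 1L || is.na(v)) return(NA_character_)
  v <- as.character(v)
  if (!nzchar(v)) NA_character_ else v
}

assemble_hierarchy <- function(rows, fl, dialect, region = NULL,
                               feature_ids = NULL, gene_types = NULL,
                               compute_introns = TRUE) {
  n <- nrow(rows)
  if (n == 0L) return(empty_features())
  id <- character(n); parent <- vector("list", n)
  if (dialect == "gtf") {
    for (i in seq_len(n)) {
      a <- rows$attrs[[i]]
      id[i] <- switch(rows$type[i],
                      gene = attr1(a, "gene_id"),
                      transcript = attr1(a, "transcript_id"),
                      attr1(a, "ID"))
      parent[[i]] <- switch(rows$type[i],
                            gene = character(),
                            transcript = attr1(a, "gene_id"),
                            attr1(a, "transcript_id"))
    }
  } else {
    for (i in seq_len(n)) {
      a <- rows$attrs[[i]]
      id[i] <- attr1(a, "ID")
      p <- attr1(a, "Parent")
      parent[[i]] <- if (is.na(p)) character() else
        strsplit(p, ",", fixed = TRUE)[[1L]]
    }
  }
  rows$feature_id <- id
  rows$parents <- parent

  genes <- rows[rows$type == "gene", ]
  txs <- rows[rows$type == "transcript", ]
  subs <- rows[!rows$type %in% c("gene", "transcript"), ]
  # one record per parent for multi-parent sub-features (GFF3 shared exons)
  if (nrow(subs)) {
    sub_parents <- subs$parents
    np <- lengths(sub_parents)
    if (any(np == 0L)) {
      stop("sub-feature row(s) without a parent reference (",
           paste(utils::head(unique(subs$src_type[np == 0L]), 3L),
                 collapse = ", "), ")", call. = FALSE)
    }
    subs <- subs[rep(seq_len(nrow(subs)), np), ]
    subs$parent_id <- unlist(sub_parents, use.names = FALSE)
  } else {
    subs$parent_id <- character()
  }
  txs$parent_id <- vapply(txs$parents, function(p)
    if (length(p)) p[[1L]] else NA_character_, "")

  if (anyNA(genes$feature_id)) {
    stop("gene row(s) without an ID", call. = FALSE)
  }
  if (anyNA(txs$feature_id)) {
    stop("transcript row(s) without an ID", call. = FALSE)
  }

  # GTF dialects may omit transcript and/or gene rows: synthesize them from
  # their children so the hierarchy is uniform (UCSC-style files)
  if (dialect == "gtf" && nrow(subs)) {
    missing_tx <- setdiff(unique(subs$parent_id), txs$feature_id)
    if (length(missing_tx)) {
      synth <- synthesize_parents(subs[subs$parent_id %in% missing_tx, ],
                                  missing_tx, "transcript")
      synth$parent_id <- vapply(missing_tx, function(t) {
        a <- subs$attrs[[which(subs$parent_id == t)[1L]]]
        attr1(a, "gene_id")
      }, "")
      if (anyNA(synth$parent_id)) {
        stop("cannot synthesize transcript(s) without gene_id attribute",
             call. = FALSE)
      }
      txs <- dplyr::bind_rows(txs, synth)
    }
  }
  if (dialect == "gtf" && nrow(txs)) {
    missing_g <- setdiff(unique(txs$parent_id), genes$feature_id)
    missing_g <- missing_g[!is.na(missing_g)]
    if (length(missing_g)) {
      synth <- synthesize_parents(txs[txs$parent_id %in% missing_g, ],
                                  missing_g, "gene")
      synth$parent_id <- NA_character_
      genes <- dplyr::bind_rows(genes, synth)
    }
  }

  orphan_tx <- setdiff(txs$parent_id[!is.na(txs$parent_id)], genes$feature_id)
  orphan_sub <- setdiff(subs$parent_id, txs$feature_id)
  if (length(c(orphan_tx, orphan_sub))) {
    stop("parent ID(s) not found in annotation: ",
         paste(utils::head(unique(c(orphan_tx, orphan_sub)), 10L),
               collapse = ", "), call. = FALSE)
  }

  gene_of_tx <- stats::setNames(txs$parent_id, txs$feature_id)

  # gene-level filters (AND): region overlap, gene type, ID lists
  keep_gene <- rep(TRUE, nrow(genes))
  if (!is.null(region)) {
    keep_gene <- keep_gene & gi_overlaps(
      gi(genes$chrom, genes$start, genes$end, genes$strand), region)
  }
  if (!is.null(gene_types)) {
    gt <- vapply(genes$attrs, attr1, "", key = fl$gene_type_key)
    keep_gene <- keep_gene & !is.na(gt) & gt %in% gene_types
  }
  keep_tx <- rep(TRUE, nrow(txs))
  if (!is.null(feature_ids)) {
    listed_gene <- genes$feature_id %in% feature_ids
    tx_gene_listed <- unname(gene_of_tx[txs$feature_id]) %in%
      genes$feature_id[listed_gene]
    listed_tx <- txs$feature_id %in% feature_ids
    keep_gene <- keep_gene &
      (listed_gene | genes$feature_id %in% gene_of_tx[listed_tx])
    keep_tx <- tx_gene_listed | listed_tx
  }
  genes <- genes[keep_gene, ]
  txs <- txs[keep_tx & txs$parent_id %in% genes$feature_id, ]
  subs <- subs[subs$parent_id %in% txs$feature_id, ]

  # containment validation
  check_containment(txs, genes, "transcript", "gene")
  check_containment(subs, txs, "sub-feature", "transcript")

  build_feature_rows(genes, txs, subs, compute_introns)
}

synthesize_parents <- function(children, parent_ids, ptype) {
  sp <- split(seq_len(nrow(children)), children$parent_id)[parent_ids]
  tibble::tibble(
    chrom = unname(vapply(sp, function(ix) children$chrom[ix[1L]], "")),
    source = "txome",
    src_type = ptype,
    type = ptype,
    start = unname(vapply(sp, function(ix) min(children$start[ix]), 1L)),
    end = unname(vapply(sp, function(ix) max(children$end[ix]), 1L)),
    score = ".",
    strand = unname(vapply(sp, function(ix) children$strand[ix[1L]], "")),
    phase = NA_integer_,
    attrs = lapply(sp, function(ix) children$attrs[[ix[1L]]]),
    dialect = children$dialect[1L],
    feature_id = parent_ids,
    parents = replicate(length(parent_ids), character(), simplify = FALSE)
  )
}

check_containment <- function(children, parents, cl, pl) {
  if (nrow(children) == 0L) return(invisible())
  pi <- match(children$parent_id, parents$feature_id)
  bad <- children$chrom != parents$chrom[pi] |
    children$start < parents$start[pi] |
    children$end > parents$end[pi]
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(cl, " '", children$feature_id[i] %|NA|% "(unnamed)",
         "' (", children$chrom[i], ":", children$start[i], "-", children$end[i],
         ") extends outside its ", pl, " '", children$parent_id[i], "' (",
         parents$chrom[pi[i]], ":", parents$start[pi[i]], "-",
         parents$end[pi[i]], ")", call. = FALSE)
  }
  invisible()
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

empty_features <- function() {
  new_gi(tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), feature_id = character(), feature_type = character(),
    parent_id = character(), gene_id = character(),
    transcript_id = character(), phase = integer(), attrs = list()))
}

build_feature_rows <- function(genes, txs, subs, compute_introns) {
  frow <- function(df, type, parent_id, gene_id, transcript_id) {
    tibble::tibble(
      chrom = df$chrom, start = df$start, end = df$end, strand = df$strand,
      feature_id = df$feature_id, feature_type = type,
      parent_id = parent_id, gene_id = gene_id, transcript_id = transcript_id,
      phase = df$phase, attrs = df$attrs)
  }
  gene_of_tx <- stats::setNames(txs$parent_id, txs$feature_id)
  out <- list(
    frow(genes, "gene", NA_character_, genes$feature_id, NA_character_),
    frow(txs, "transcript", txs$parent_id, unname(gene_of_tx[txs$feature_id]),
         txs$feature_id)
  )

  # per-transcript sub-feature processing: deterministic IDs, synthetic exon
  # when none present, intron inference
  sub_by_tx <- split(seq_len(nrow(subs)), factor(subs$parent_id,
                                                 levels = txs$feature_id))
  for (ti in seq_len(nrow(txs))) {
    tid <- txs$feature_id[ti]
    gid <- unname(gene_of_tx[tid])
    ix <- sub_by_tx[[tid]]
    s <- subs[ix, ]
    pieces <- list()
    for (tp in c("exon", "intron", "CDS", "five_prime_UTR",
                 "three_prime_UTR")) {
      p <- s[s$type == tp, ]
      if (tp == "exon" && nrow(p) == 0L) {
        # synthetic exon spanning the transcript
        p <- tibble::tibble(chrom = txs$chrom[ti], start = txs$start[ti],
                            end = txs$end[ti], strand = txs$strand[ti],
                            feature_id = NA_character_, phase = NA_integer_,
                            attrs = list(character()))
      }
      if (nrow(p) == 0L) next
      p <- p[order(p$start, p$end), ]
      if (tp %in% c("exon", "CDS") && nrow(p) > 1L &&
          any(p$start[-1L] <= p$end[-nrow(p)])) {
        stop("overlapping ", tp, " segments in transcript '", tid, "'",
             call. = FALSE)
      }
      suffix <- c(exon = "exon", intron = "intron", CDS = "CDS",
                  five_prime_UTR = "five_prime_UTR",
                  three_prime_UTR = "three_prime_UTR")[[tp]]
      auto_id <- paste0(tid, "_", suffix, seq_len(nrow(p)))
      fid <- if ("feature_id" %in% names(p)) p$feature_id else
        rep(NA_character_, nrow(p))
      fid[is.na(fid)] <- auto_id[is.na(fid)]
      if (anyDuplicated(fid)) fid <- auto_id  # shared GFF3 CDS IDs
      pieces[[tp]] <- tibble::tibble(
        chrom = p$chrom, start = p$start, end = p$end, strand = p$strand,
        feature_id = fid, feature_type = tp, parent_id = tid, gene_id = gid,
        transcript_id = tid, phase = p$phase,
        attrs = if ("attrs" %in% names(p)) p$attrs else
          replicate(nrow(p), character(), simplify = FALSE))
    }
    if (compute_introns && is.null(pieces[["intron"]]) &&
        !is.null(pieces[["exon"]])) {
      intr <- infer_introns_from_exons(pieces[["exon"]], tid, gid)
      if (nrow(intr)) pieces[["intron"]] <- intr
    }
    out <- c(out, pieces)
  }
  feats <- dplyr::bind_rows(out)
  new_gi(feats)
}

infer_introns_from_exons <- function(exons, tid, gid) {
  e <- exons[order(exons$start), ]
  n <- nrow(e)
  if (n < 2L) return(empty_features()[0L, ])
  istart <- e$end[-n] + 1L
  iend <- e$start[-1L] - 1L
  keep <- iend >= istart  # book-ended exon pairs produce no intron
  istart <- istart[keep]; iend <- iend[keep]
  if (!length(istart)) return(empty_features()[0L, ])
  tibble::tibble(
    chrom = e$chrom[1L], start = istart, end = iend, strand = e$strand[1L],
    feature_id = paste0(tid, "_intron", seq_along(istart)),
    feature_type = "intron", parent_id = tid, gene_id = gid,
    transcript_id = tid, phase = NA_integer_,
    attrs = replicate(length(istart), character(), simplify = FALSE))
}

#' Infer introns from a transcript's exons
#'
#' Returns one intron per gap between consecutive exons of a transcript:
#' `[prev_exon.end + 1, next_exon.start - 1]`. Book-ended exon pairs (no gap)
#' produce no intron. Intron IDs are deterministic,
#' `"<transcript_id>_intron<k>"` numbered 1..n in genomic order; strand,
#' chromosome and parentage are inherited from the transcript.
#'
#' @param tx A `txome_transcriptome`.
#' @param transcript_id ID of a transcript in `tx`.
#' @return A `txome_gi` feature tibble of introns (possibly empty).
#' @export
infer_introns <- function(tx, transcript_id) {
  t <- tx_feature(tx, transcript_id)
  if (is.null(t) || t$feature_type != "transcript") {
    stop("not a transcript ID: ", transcript_id, call. = FALSE)
  }
  exons <- tx_children(tx, transcript_id, "exon")
  if (nrow(exons) == 0L) {
    stop("transcript '", transcript_id, "' has no exons", call. = FALSE)
  }
  infer_introns_from_exons(exons, transcript_id, t$gene_id)
}

sort_features <- function(feats, rd) {
  if (nrow(feats) == 0L) return(feats)
  k <- gi_sort_key(feats, rd)
  feats[order(k$cidx, k$start, k$end, type_rank(feats$feature_type),
              feats$feature_id), , drop = FALSE]
}

# per-chromosome gene lookup index: genes sorted by start, queried with a
# binary search on starts (findInterval) plus an end filter over the prefix
gene_interval_tree <- function(feats) {
  g <- feats[feats$feature_type == "gene", ]
  idx <- split(seq_len(nrow(g)), g$chrom)
  lapply(idx, function(ix) {
    o <- ix[order(g$start[ix], g$end[ix])]
    list(start = g$start[o], end = g$end[o], gene_id = g$feature_id[o])
  })
}

query_gene_index <- function(tree, chrom, qs, qe) {
  node <- tree[[chrom]]
  if (is.null(node)) return(character())
  i_max <- findInterval(qe, node$start)  # genes starting at or before qe
  if (i_max < 1L) return(character())
  pre <- seq_len(i_max)
  node$gene_id[pre[node$end[pre] >= qs]]
}

gene_name_index <- function(feats, gene_name_key) {
  g <- feats[feats$feature_type == "gene", ]
  nm <- vapply(g$attrs, attr1, "", key = gene_name_key)
  ok <- !is.na(nm)
  split(g$feature_id[ok], nm[ok])
}

# -- accessors ----------------------------------------------------------------

#' Access features of a Transcriptome
#'
#' `tx_features()` returns the (sorted, frozen) feature table, optionally
#' restricted to one canonical feature type. `tx_feature()` looks up a single
#' feature by ID, returning `NULL` (a not-found marker, not an error) on a
#' miss. `tx_children()` returns the ordered children of a feature;
#' `tx_parent()` its parent row.
#'
#' @param tx A `txome_transcriptome`.
#' @param feature_type Optional canonical type
#'   (`"gene"`, `"transcript"`, `"exon"`, `"intron"`, `"CDS"`,
#'   `"five_prime_UTR"`, `"three_prime_UTR"`).
#' @return A `txome_gi` feature tibble (one row for `tx_feature()`, or
#'   `NULL` when the ID is absent).
#' @export
tx_features <- function(tx, feature_type = NULL) {
  f <- tx$features
  if (!is.null(feature_type)) {
    stopifnot(all(feature_type %in% canonical_types))
    f <- f[f$feature_type %in% feature_type, , drop = FALSE]
  }
  f
}

#' @rdname tx_features
#' @param feature_id A feature ID.
#' @export
tx_feature <- function(tx, feature_id) {
  i <- unname(tx$id_index[feature_id])
  if (length(i) != 1L || is.na(i)) return(NULL)
  tx$features[i, , drop = FALSE]
}

#' @rdname tx_features
#' @export
tx_children <- function(tx, feature_id, feature_type = NULL) {
  f <- tx$features[!is.na(tx$features$parent_id) &
                     tx$features$parent_id == feature_id, , drop = FALSE]
  if (!is.null(feature_type)) f <- f[f$feature_type %in% feature_type, ,
                                     drop = FALSE]
  f
}

#' @rdname tx_features
#' @export
tx_parent <- function(tx, feature_id) {
  f <- tx_feature(tx, feature_id)
  if (is.null(f) || is.na(f$parent_id)) return(NULL)
  tx_feature(tx, f$parent_id)
}

#' Look up a gene by name
#'
#' Exact-match lookup on the flavor's gene-name attribute. When the direct
#' name misses, the alias table (obsolete -> current symbol) is consulted.
#' A miss returns `NULL`; a name shared by several genes is an error listing
#' the candidates.
#'
#' @param tx A `txome_transcriptome`.
#' @param name Gene symbol.
#' @param aliases Named character vector mapping obsolete to current symbols.
#' @return A one-row feature tibble, or `NULL` if not found.
#' @export
tx_gene_by_name <- function(tx, name, aliases = NULL) {
  ids <- tx$name_index[[name]]
  if (is.null(ids) && !is.null(aliases) && name %in% names(aliases)) {
    ids <- tx$name_index[[unname(aliases[[name]])]]
  }
  if (is.null(ids)) return(NULL)
  if (length(ids) > 1L) {
    stop("ambiguous gene name '", name, "': ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  tx_feature(tx, ids)
}

#' Range query over a Transcriptome
#'
#' Finds all features of a type overlapping (or, with `envelop_only`, fully
#' contained in) a region. Gene-level candidates come from the per-chromosome
#' interval tree; sub-features are found by descending into the candidate
#' genes, so the result is identical to a brute-force scan of the feature
#' table (a tested property) but touches only the relevant genes.
#'
#' @param tx A `txome_transcriptome`.
#' @param region A one-row `txome_gi` or region string; its chromosome must
#'   be known to the transcriptome's RefDict.
#' @param feature_type Canonical feature type to return (default all types).
#' @param envelop_only Return only features fully inside `region`.
#' @return A sorted `txome_gi` feature tibble.
#' @export
tx_query <- function(tx, region, feature_type = NULL, envelop_only = FALSE) {
  if (is.character(region)) region <- gi_parse(region)
  stopifnot(nrow(region) == 1L)
  if (!is.na(region$chrom[1L]) && !region$chrom[1L] %in% tx$refdict$chrom) {
    stop("chromosome(s) not in reference dictionary '",
         refdict_name(tx$refdict), "': ", region$chrom[1L], call. = FALSE)
  }
  qs <- ifelse(is.na(region$start[1L]), 1L, region$start[1L])
  qe <- ifelse(is.na(region$end[1L]), 536870912L, region$end[1L])
  chroms <- if (is.na(region$chrom[1L])) tx$refdict$chrom else region$chrom[1L]
  gene_ids <- unlist(lapply(chroms, function(ch)
    query_gene_index(tx$gene_tree, ch, qs, qe)), use.names = FALSE)
  f <- tx$features
  keep <- f$gene_id %in% gene_ids
  if (!is.null(feature_type)) keep <- keep & f$feature_type %in% feature_type
  qchrom <- region$chrom[1L]
  if (envelop_only) {
    keep <- keep & (is.na(qchrom) | f$chrom == qchrom) &
      f$start >= qs & f$end <= qe
  } else {
    keep <- keep & (is.na(qchrom) | f$chrom == qchrom) &
      f$start <= qe & f$end >= qs
  }
  f[keep, , drop = FALSE]
}

#' @export
print.txome_transcriptome <- function(x, ...) {
  cnt <- table(factor(x$features$feature_type, levels = canonical_types))
  cat("Transcriptome <", x$source, "> (flavor: ", x$flavor$name, ")\n",
      sep = "")
  cat("  ", paste(sprintf("%s: %d", names(cnt), as.integer(cnt)),
                  collapse = ", "), "\n", sep = "")
  cat("  chromosomes: ", paste(utils::head(x$refdict$chrom, 6L),
                               collapse = ", "),
      if (nrow(x$refdict) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}
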