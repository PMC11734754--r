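#' Write a sorted stream (or interval tibble) as BED6
#'
#' Coordinates are converted from the internal 1-based closed convention to
#' BED's 0-based half-open one (`start - 1`, `end`); strand renders as
#' `+` / `-` / `.`. Scores are clamped to 0-1000 and missing scores render
#' as 0. Writing a stream and reading it back with
#' `open_iterator(format = "bed")` yields the identical location sequence.
#'
#' @param x A `txome_stream` or a data frame with interval columns.
#' @param path Output file.
#' @param name_from,score_from Either a column/payload field name or a
#'   `function(payload)` extracting the BED name/score per item; `NULL`
#'   writes `"."` names and 0 scores.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name_from = NULL, score_from = NULL) {
  tbl <- if (inherits(x, "txome_stream")) stream_collect(x) else
    as_gi(tibble::as_tibble(x))
  extract <- function(from, i) {
    if (is.null(from)) return(NA)
    p <- if ("payload" %in% names(tbl)) tbl$payload[[i]] else
      as.list(tbl[i, , drop = FALSE])
    if (is.function(from)) from(p) else p[[from]] %||% NA
  }
  n <- nrow(tbl)
  name <- vapply(seq_len(n), function(i) {
    v <- extract(name_from, i)
    if (is.null(v) || is.na(v)) "." else as.character(v)
  }, "")
  score <- vapply(seq_len(n), function(i) {
    v <- extract(score_from, i)
    v <- suppressWarnings(as.numeric(v))
    if (is.null(v) || length(v) == 0L || is.na(v)) 0 else
      max(0, min(1000, v))
  }, 1)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   tbl$chrom, tbl$start - 1L, tbl$end, name,
                   format_num(score), tbl$strand)
  con <- file(path, "w")
  on.exit(close(con))
  if (n > 0L) writeLines(lines, con)
  invisible(path)
}

# shortest round-trip decimal rendering; '.' decimal separator always
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.numeric(v) && v == round(v) && abs(v) < 1e15) {
      return(format(as.integer(v), scientific = FALSE))
    }
    format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, "")
}

#' Export a Transcriptome as GFF3
#'
#' Emits a `##gff-version 3` header, `##sequence-region` pragmas for every
#' RefDict chromosome of known length, and all features in sort order with
#' `ID`/`Parent` attributes reconstructing the exact hierarchy. Attribute
#' values are percent-encoded per the GFF3 rules and decoded again on
#' re-parse, so re-reading the file with the `generic` flavor reproduces
#' identical feature coordinates, types, IDs and parentage. Inferred introns
#' are written only on request, since most consumers re-infer them; the
#' default mirrors the annotation's explicit feature set.
#'
#' @param tx A `txome_transcriptome`.
#' @param path Output file.
#' @param include_annotations Character vector of annotation labels to
#'   serialize as extra attributes; every value must be scalar text or
#'   number (anything else is a serialization error naming the label).
#' @param include_introns Also write inferred introns (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(tx, path, include_annotations = character(),
                       include_introns = FALSE) {
  f <- tx$features
  if (!include_introns) f <- f[f$feature_type != "intron", , drop = FALSE]
  rd <- tx$refdict
  hdr <- "##gff-version 3"
  known <- !is.na(rd$length)
  if (any(known)) {
    hdr <- c(hdr, sprintf("##sequence-region %s 1 %d",
                          rd$chrom[known], rd$length[known]))
  }
  lines <- vapply(seq_len(nrow(f)), function(i) {
    attrs <- c(ID = f$feature_id[i])
    if (!is.na(f$parent_id[i])) attrs <- c(attrs, Parent = f$parent_id[i])
    pa <- f$attrs[[i]]
    pa <- pa[!names(pa) %in% c("ID", "Parent")]
    attrs <- c(attrs, pa)
    for (lab in include_annotations) {
      v <- tx_get_annotation(tx, f[i, , drop = FALSE], lab)
      if (is.null(v)) next
      if (length(v) != 1L || !(is.character(v) || is.numeric(v))) {
        stop("annotation '", lab, "' on feature '", f$feature_id[i],
             "' is not scalar text/number; cannot serialize to GFF3",
             call. = FALSE)
      }
      attrs <- c(attrs, stats::setNames(
        if (is.numeric(v)) format_num(v) else as.character(v), lab))
    }
    attr_str <- paste(paste0(percent_encode_gff3(names(attrs)), "=",
                             percent_encode_gff3(unname(attrs))),
                      collapse = ";")
    sprintf("%s\ttxome\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            f$chrom[i], f$feature_type[i], f$start[i], f$end[i],
            f$strand[i],
            if (is.na(f$phase[i])) "." else as.character(f$phase[i]),
            attr_str)
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Column specifications for tabular export
#'
#' A ColumnSpec is an ordered list of named extractors turning features or
#' stream items into uniform records. Extractors are either a coordinate
#' component name (`"chrom"`, `"start"`, `"end"`, `"strand"`,
#' `"feature_id"`, `"feature_type"`, `"parent_id"`, `"width"`), an
#' [attr_col()] (a key from the source file's attribute column), or an
#' [ann_col()] (a label from the annotation store). Unknown descriptors are
#' rejected at construction; duplicate column names too.
#'
#' @param ... Named extractor descriptors.
#' @return A `txome_column_spec`.
#' @examples
#' column_spec(chrom = "chrom", start = "start", stop = "end",
#'             name = attr_col("gene_name"), expr = ann_col("expression"))
#' @export
column_spec <- function(...) {
  cols <- list(...)
  if (length(cols) == 0L || is.null(names(cols)) || any(!nzchar(names(cols)))) {
    stop("column_spec() needs named columns", call. = FALSE)
  }
  if (anyDuplicated(names(cols))) {
    stop("duplicate column name(s): ",
         paste(unique(names(cols)[duplicated(names(cols))]), collapse = ", "),
         call. = FALSE)
  }
  coord_fields <- c("chrom", "start", "end", "strand", "feature_id",
                    "feature_type", "parent_id", "gene_id", "transcript_id",
                    "width")
  for (nm in names(cols)) {
    d <- cols[[nm]]
    ok <- inherits(d, "txome_extractor") ||
      (is.character(d) && length(d) == 1L && d %in% coord_fields)
    if (!ok) {
      stop("unknown extractor descriptor for column '", nm,
           "': use a coordinate component name, attr_col() or ann_col()",
           call. = FALSE)
    }
  }
  structure(cols, class = "txome_column_spec")
}

#' @rdname column_spec
#' @param key Attribute key to extract.
#' @export
attr_col <- function(key) {
  structure(list(kind = "attr", key = key), class = "txome_extractor")
}

#' @rdname column_spec
#' @param label Annotation-store label to extract.
#' @export
ann_col <- function(label) {
  structure(list(kind = "ann", key = label), class = "txome_extractor")
}

#' Flatten features or stream items into a tidy table
#'
#' Produces one record per feature/item with columns in ColumnSpec order.
#' Missing attributes or annotations yield an explicit `NA`, never a silent
#' blank; the record count always equals the input count.
#'
#' @param x A feature tibble (from [tx_features()], [tx_query()], ...) or a
#'   `txome_stream`.
#' @param spec A [column_spec()].
#' @param tx The `txome_transcriptome` owning `x`; required for [ann_col()]
#'   extractors.
#' @return A tibble.
#' @export
to_table <- function(x, spec, tx = NULL) {
  stopifnot(inherits(spec, "txome_column_spec"))
  tbl <- if (inherits(x, "txome_stream")) stream_collect(x) else
    tibble::as_tibble(x)
  n <- nrow(tbl)
  out <- lapply(names(spec), function(nm) {
    d <- spec[[nm]]
    if (is.character(d)) {
      if (d == "width") return(tbl$end - tbl$start + 1L)
      return(if (d %in% names(tbl)) tbl[[d]] else rep(NA, n))
    }
    if (d$kind == "attr") {
      src <- if ("attrs" %in% names(tbl)) tbl$attrs else tbl$payload
      return(vapply(seq_len(n), function(i) {
        a <- src[[i]]
        if (is.list(a) && !is.null(a$attrs)) a <- a$attrs  # stream payloads
        attr1(a, d$key)
      }, ""))
    }
    # annotation extractor
    if (is.null(tx)) {
      stop("ann_col('", d$key, "') requires the owning transcriptome (tx =)",
           call. = FALSE)
    }
    lapply(seq_len(n), function(i)
      tx_get_annotation(tx, tbl[i, , drop = FALSE], d$key)) |>
      simplify_col()
  })
  names(out) <- names(spec)
  tibble::as_tibble(out)
}

simplify_col <- function(vals) {
  vals <- lapply(vals, function(v) if (is.null(v)) NA else v)
  if (all(lengths(vals) == 1L) &&
      all(vapply(vals, function(v) is.atomic(v), TRUE))) {
    return(unlist(vals, use.names = FALSE))
  }
  vals
}
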