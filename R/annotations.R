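#' Attach and retrieve feature annotations
#'
#' The annotation store associates arbitrary values with `(feature, label)`
#' pairs. Values live outside the frozen feature table, keyed by feature
#' identity, so two distinct features at identical coordinates hold
#' independent annotations. The store is an environment, so updates made
#' inside annotation callbacks are visible without reassigning the
#' transcriptome object; both functions also return `tx` (invisibly for the
#' setter) so calls chain with the pipe.
#'
#' A value declared `positional` must be attached at gene level and supply
#' exactly one element per base of the gene (in plus-strand order, like the
#' stored gene sequence). Reading a positional label on a descendant feature
#' returns the enveloped slice, reversed for minus-strand features —
#' orientation-adjusted exactly like sequences.
#'
#' @param tx A `txome_transcriptome`.
#' @param feature A feature ID or one-row feature tibble.
#' @param label Annotation label (single string).
#' @param value Any R value; for `positional = TRUE`, a vector with one
#'   element per gene base.
#' @param positional Declare the value per-base (gene-level features only).
#' @return `tx_set_annotation()`: `tx`, invisibly. `tx_get_annotation()`:
#'   the stored value, a positional slice, or `default` when the label is
#'   absent.
#' @export
tx_set_annotation <- function(tx, feature, label, value, positional = FALSE) {
  f <- if (is.character(feature)) tx_feature(tx, feature) else feature
  if (is.null(f)) stop("feature not found: ", feature, call. = FALSE)
  if (is.null(tx$id_index[[f$feature_id]])) {
    stop("feature '", f$feature_id, "' does not belong to this transcriptome",
         call. = FALSE)
  }
  if (positional) {
    if (f$feature_type != "gene") {
      stop("positional annotations attach at gene level; '", f$feature_id,
           "' is a ", f$feature_type, call. = FALSE)
    }
    glen <- f$end - f$start + 1L
    if (length(value) != glen) {
      stop("positional annotation '", label, "' has length ", length(value),
           " but gene '", f$feature_id, "' spans ", glen, " bases",
           call. = FALSE)
    }
  }
  assign(paste(f$feature_id, label, sep = "\r"),
         list(value = value, positional = positional),
         envir = tx$store$ann)
  invisible(tx)
}

#' @rdname tx_set_annotation
#' @param default Value returned when no annotation is found.
#' @export
tx_get_annotation <- function(tx, feature, label, default = NULL) {
  f <- if (is.character(feature)) tx_feature(tx, feature) else feature
  if (is.null(f)) stop("feature not found: ", feature, call. = FALSE)
  hit <- get0(paste(f$feature_id, label, sep = "\r"), envir = tx$store$ann,
              ifnotfound = NULL)
  if (!is.null(hit)) {
    if (!hit$positional || f$feature_type == "gene") return(hit$value)
  }
  # fall back to a positional annotation on the feature's gene and slice it
  if (!is.na(f$gene_id)) {
    ghit <- get0(paste(f$gene_id, label, sep = "\r"), envir = tx$store$ann,
                 ifnotfound = NULL)
    if (!is.null(ghit) && ghit$positional) {
      gene <- tx_feature(tx, f$gene_id)
      idx <- (f$start - gene$start + 1L):(f$end - gene$start + 1L)
      if (f$strand == "-") idx <- rev(idx)
      return(ghit$value[idx])
    }
  }
  default
}

#' @rdname tx_set_annotation
#' @export
tx_annotation_labels <- function(tx) {
  keys <- ls(tx$store$ann)
  unique(vapply(strsplit(keys, "\r", fixed = TRUE), `[[`, "", 2L))
}

#' Annotate transcriptome features from overlapping data sources
#'
#' Runs the single-pass overlap join ([annotation_iterator()]) with the
#' transcriptome's features of one type as anchors and an arbitrary set of
#' labelled sorted streams as sources, applying a user function to every
#' feature. The function receives the feature row, an overlap bundle (one
#' tibble of overlapping items per source label, present even when empty)
#' and the transcriptome; it typically stores results with
#' [tx_set_annotation()]. Every source is read in a single pass; RefDict
#' compatibility of all sources with the transcriptome is verified before
#' iteration starts.
#'
#' @param tx A `txome_transcriptome`.
#' @param sources Named list of `txome_stream` objects (names become bundle
#'   labels); may be empty, in which case `fun` is still called once per
#'   feature with an empty bundle.
#' @param fun `function(feature, bundle, tx)`; `bundle` is a named list of
#'   item tibbles. Errors raised in `fun` are re-thrown with the current
#'   feature's ID attached.
#' @param feature_type Which features to anchor on (default transcripts).
#' @param strand_specific Restrict overlaps to compatible strands.
#' @return `tx`, invisibly.
#' @export
tx_annotate <- function(tx, sources = list(), fun,
                        feature_type = "transcript",
                        strand_specific = FALSE) {
  stopifnot(is.function(fun))
  if (length(sources)) {
    if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
      stop("sources must be a named list of streams", call. = FALSE)
    }
    for (lab in names(sources)) {
      assert_refdict_compatible(tx$refdict, stream_refdict(sources[[lab]]),
                                what = paste0("source '", lab, "'"))
    }
  }
  anchors <- features_stream(tx, feature_type)
  it <- annotation_iterator(anchors, sources, strand_specific = strand_specific)
  repeat {
    b <- stream_next(it)
    if (is.null(b)) break
    fid <- b$payload$anchor$payload$feature_id
    feature <- tx_feature(tx, fid)
    bundle <- lapply(b$payload$data, items_to_tibble)
    tryCatch(fun(feature, bundle, tx), error = function(e) {
      stop("annotation function failed at feature '", fid, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  invisible(tx)
}

#' A sorted stream over transcriptome features
#'
#' Exposes the features of a transcriptome as a `txome_stream` (items carry
#' the feature row as payload), so features can anchor the overlap join or
#' be mixed with file-based streams. [tx_annotate()] uses this internally;
#' it is exported so the same code path can be driven directly.
#'
#' @param tx A `txome_transcriptome`.
#' @param feature_type Canonical feature type(s) to yield (default all).
#' @return A `txome_stream`.
#' @export
features_stream <- function(tx, feature_type = NULL) {
  f <- tx_features(tx, feature_type)
  i <- 0L
  new_stream(tx$refdict, function() {
    i <<- i + 1L
    if (i > nrow(f)) return(NULL)
    row <- f[i, , drop = FALSE]
    list(chrom = row$chrom, start = row$start, end = row$end,
         strand = row$strand, payload = row)
  }, label = "features")
}
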