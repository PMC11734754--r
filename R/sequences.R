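#' Load gene sequences from an indexed reference FASTA
#'
#' Reads, for every gene, the genomic (plus-strand) sequence of its interval
#' from an indexed FASTA and caches it in the transcriptome's store. To avoid
#' storing redundant information, sequences are held at gene level only;
#' sequences of descendant features are sliced from the gene sequence on
#' request by [tx_sequence()]. RefDict compatibility between the annotation
#' and the FASTA index is verified before any sequence is read: a chromosome
#' length conflict aborts with the store untouched.
#'
#' @param tx A `txome_transcriptome`.
#' @param fasta_path FASTA file with a sibling `.fai` index covering every
#'   chromosome used by a gene.
#' @return `tx`, invisibly (the sequence store is updated in place).
#' @export
tx_load_sequences <- function(tx, fasta_path) {
  rd_fa <- refdict_from_fai(fasta_path)
  assert_refdict_compatible(tx$refdict, rd_fa, what = "annotation vs FASTA",
                            allow_order_mismatch = TRUE)
  genes <- tx_features(tx, "gene")
  missing <- setdiff(unique(genes$chrom), rd_fa$chrom)
  if (length(missing)) {
    stop("chromosome(s) used by genes missing from FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(genes) == 0L) return(invisible(tx))
  fa <- Rsamtools::FaFile(fasta_path)
  open(fa); on.exit(close(fa))
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  seqs <- as.character(Rsamtools::scanFa(fa, gr))
  for (i in seq_len(nrow(genes))) {
    assign(genes$feature_id[i], seqs[[i]], envir = tx$store$seq)
  }
  invisible(tx)
}

#' @rdname tx_load_sequences
#' @export
tx_has_sequences <- function(tx) length(ls(tx$store$seq)) > 0L

revcomp <- function(s) {
  vapply(s, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    "", USE.NAMES = FALSE)
}

#' Extract feature sequences
#'
#' Slices sequences for any feature from its gene's cached sequence:
#' \describe{
#'   \item{`genomic`}{the plus-strand slice of the feature's interval.}
#'   \item{`oriented`}{`genomic`, reverse-complemented for minus-strand
#'     features (5'->3' of the feature).}
#'   \item{`spliced`}{for transcripts: the 5'->3' concatenation of the exon
#'     `oriented` sequences in transcript order (genomic order reversed on
#'     the minus strand) — the mature RNA sequence.}
#'   \item{`translated`}{for transcripts with CDS children: the CDS segments
#'     concatenated 5'->3', the phase of the first CDS segment (in 5'->3'
#'     order) skipped, trailing incomplete codons dropped, translated with
#'     the standard nuclear code; stop codons render as `"*"`, codons with
#'     ambiguous bases as `"X"`.}
#' }
#'
#' @param tx A `txome_transcriptome` with sequences loaded
#'   ([tx_load_sequences()]).
#' @param feature A feature ID or one-row feature tibble from `tx`.
#' @param mode One of `"genomic"`, `"oriented"`, `"spliced"`, `"translated"`.
#' @return A single character string (nucleotides, or amino acids for
#'   `"translated"`).
#' @export
tx_sequence <- function(tx, feature,
                        mode = c("genomic", "oriented", "spliced",
                                 "translated")) {
  mode <- match.arg(mode)
  f <- if (is.character(feature)) tx_feature(tx, feature) else feature
  if (is.null(f)) stop("feature not found: ", feature, call. = FALSE)
  if (!tx_has_sequences(tx)) {
    stop("no sequences loaded; call tx_load_sequences() first", call. = FALSE)
  }
  gid <- if (f$feature_type == "gene") f$feature_id else f$gene_id
  gseq <- get0(gid, envir = tx$store$seq, ifnotfound = NULL)
  if (is.null(gseq)) {
    stop("no sequence stored for gene '", gid, "'", call. = FALSE)
  }
  gene <- tx_feature(tx, gid)
  slice <- function(s, e) substr(gseq, s - gene$start + 1L, e - gene$start + 1L)

  if (mode == "genomic") return(slice(f$start, f$end))
  if (mode == "oriented") {
    s <- slice(f$start, f$end)
    return(if (f$strand == "-") revcomp(s) else s)
  }
  if (f$feature_type != "transcript") {
    stop("mode '", mode, "' requires a transcript feature, got '",
         f$feature_type, "'", call. = FALSE)
  }
  if (mode == "spliced") {
    exons <- tx_children(tx, f$feature_id, "exon")
    parts <- vapply(seq_len(nrow(exons)),
                    function(i) slice(exons$start[i], exons$end[i]), "")
    joined <- paste(parts, collapse = "")
    return(if (f$strand == "-") revcomp(joined) else joined)
  }
  # translated
  cds <- tx_children(tx, f$feature_id, "CDS")
  if (nrow(cds) == 0L) {
    stop("transcript '", f$feature_id, "' has no CDS; cannot translate",
         call. = FALSE)
  }
  parts <- vapply(seq_len(nrow(cds)),
                  function(i) slice(cds$start[i], cds$end[i]), "")
  nt <- paste(parts, collapse = "")
  if (f$strand == "-") nt <- revcomp(nt)
  # phase of the first CDS segment in 5'->3' order (last genomic segment on
  # the minus strand); unreported phase is taken as 0
  first_i <- if (f$strand == "-") nrow(cds) else 1L
  phase <- cds$phase[first_i]
  if (is.na(phase)) phase <- 0L
  nt <- substr(nt, phase + 1L, nchar(nt))
  nt <- substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)  # drop incomplete codon
  if (!nzchar(nt)) return("")
  translate_nt(nt)
}

translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "solve",
                                     no.init.codon = TRUE))
}
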