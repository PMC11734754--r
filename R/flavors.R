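# Annotation-provider flavor tables.
#
# A flavor maps a provider's feature-type vocabulary and attribute keys onto
# the canonical model (gene / transcript / exon / intron / CDS /
# five_prime_UTR / three_prime_UTR). Rows whose type is not mapped are
# skipped with a counted warning, because real annotation files carry many
# auxiliary types (chromosome, start_codon, Selenocysteine, ...).

canonical_types <- c("gene", "transcript", "exon", "intron", "CDS",
                     "five_prime_UTR", "three_prime_UTR")

type_rank <- function(type) {
  match(type, c("gene", "transcript", "exon", "intron", "CDS",
                "five_prime_UTR", "three_prime_UTR"))
}

base_type_map <- c(
  gene = "gene", transcript = "transcript", mRNA = "transcript",
  exon = "exon", intron = "intron", CDS = "CDS",
  five_prime_UTR = "five_prime_UTR", three_prime_UTR = "three_prime_UTR"
)

ncrna_tx_types <- c("lnc_RNA", "ncRNA", "miRNA", "rRNA", "snRNA", "snoRNA",
                    "tRNA", "scRNA", "pre_miRNA", "pseudogenic_transcript")

#' Annotation flavors
#'
#' Provider-specific parsing profiles for [read_transcriptome()]. A flavor
#' fixes the GTF/GFF3 dialect (or leaves it auto-detected), the mapping from
#' the provider's feature-type strings to the canonical model, and the
#' attribute keys holding the gene symbol and the gene type (biotype). The
#' `generic` flavor understands canonical type names directly and is what
#' [write_gff3()] output is read back with; pass `type_map` / `attr_map`
#' overrides to [read_transcriptome()] for fully custom formats.
#'
#' @param name One of `"generic"`, `"ensembl"`, `"gencode"`, `"ucsc"`,
#'   `"flybase"`, `"wormbase"`, `"chess"`, `"mirgenedb"`.
#' @return A list with elements `dialect`, `type_map`, `gene_name_key`,
#'   `gene_type_key`.
#' @export
annotation_flavor <- function(name = c("generic", "ensembl", "gencode",
                                       "ucsc", "flybase", "wormbase",
                                       "chess", "mirgenedb")) {
  name <- match.arg(name)
  fl <- switch(
    name,
    generic = list(
      dialect = "auto",
      type_map = base_type_map,
      gene_name_key = "gene_name",
      gene_type_key = "gene_type"
    ),
    ensembl = list(
      dialect = "gff3",
      type_map = c(base_type_map,
                   ncRNA_gene = "gene", pseudogene = "gene",
                   stats::setNames(rep("transcript", length(ncrna_tx_types)),
                                   ncrna_tx_types)),
      gene_name_key = "Name",
      gene_type_key = "biotype"
    ),
    gencode = list(
      dialect = "gtf",
      type_map = base_type_map,
      gene_name_key = "gene_name",
      gene_type_key = "gene_type"
    ),
    ucsc = list(
      dialect = "gtf",
      type_map = base_type_map,
      gene_name_key = "gene_name",
      gene_type_key = "gene_type"
    ),
    flybase = list(
      dialect = "gff3",
      type_map = c(base_type_map,
                   stats::setNames(rep("transcript", length(ncrna_tx_types)),
                                   ncrna_tx_types)),
      gene_name_key = "Name",
      gene_type_key = "gene_type"
    ),
    wormbase = list(
      dialect = "gff3",
      type_map = c(base_type_map,
                   stats::setNames(rep("transcript", length(ncrna_tx_types)),
                                   ncrna_tx_types)),
      gene_name_key = "Name",
      gene_type_key = "biotype"
    ),
    chess = list(
      dialect = "gff3",
      type_map = base_type_map,
      gene_name_key = "gene_name",
      gene_type_key = "gene_type"
    ),
    mirgenedb = list(
      dialect = "gff3",
      type_map = c(pre_miRNA = "gene", miRNA = "transcript"),
      gene_name_key = "Name",
      gene_type_key = "gene_type"
    )
  )
  fl$name <- name
  fl
}

# -- attribute-column parsing -------------------------------------------------

percent_decode <- function(x) {
  need <- grepl("%", x, fixed = TRUE)
  x[need] <- vapply(x[need], utils::URLdecode, "", USE.NAMES = FALSE)
  x
}

percent_encode_gff3 <- function(x) {
  # GFF3 column 9 reserved characters; encode '%' first
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x
}

parse_attrs_gff3 <- function(attr_col) {
  lapply(attr_col, function(s) {
    if (is.na(s) || s == "." || !nzchar(s)) return(character())
    parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    eq <- regexpr("=", parts, fixed = TRUE)
    keys <- percent_decode(substr(parts, 1L, eq - 1L))
    vals <- percent_decode(substr(parts, eq + 1L, nchar(parts)))
    stats::setNames(vals, keys)
  })
}

parse_attrs_gtf <- function(attr_col) {
  lapply(attr_col, function(s) {
    if (is.na(s) || s == "." || !nzchar(s)) return(character())
    m <- gregexpr('([A-Za-z0-9_]+)\\s+(("([^"]*)")|([^";]+))\\s*;?', s)[[1L]]
    if (m[1L] == -1L) return(character())
    pieces <- regmatches(s, gregexpr(
      '([A-Za-z0-9_]+)\\s+(("[^"]*")|([^";]+))\\s*(;|$)', s))[[1L]]
    keys <- sub('^([A-Za-z0-9_]+)\\s+.*$', "\\1", pieces)
    vals <- sub('^[A-Za-z0-9_]+\\s+("?)(.*?)\\1\\s*(;|)$', "\\2", pieces)
    stats::setNames(trimws(vals), keys)
  })
}

detect_dialect <- function(attr_col) {
  probe <- attr_col[!is.na(attr_col) & nzchar(attr_col) & attr_col != "."]
  probe <- utils::head(probe, 25L)
  gtf_hits <- sum(grepl('\\w+\\s+"', probe))
  gff3_hits <- sum(grepl("\\w+=", probe))
  if (gtf_hits > gff3_hits) "gtf" else "gff3"
}
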