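#' Configuration for the synthetic fixture generator
#'
#' The generator produces the small genome, annotation, track, variant and
#' alignment files the test suite consumes — fully seeded, so the same
#' configuration always yields byte-identical files. Chromosome lengths are
#' capped at 100 kb to keep per-base brute-force oracles fast.
#'
#' @param seed Integer seed driving all sampling.
#' @param chromosomes Named integer vector of chromosome lengths.
#' @param n_genes Number of non-overlapping genes to place.
#' @param transcripts_per_gene,exons_per_transcript Inclusive integer ranges
#'   (length-2 vectors) sampled per gene / per transcript.
#' @param read_length Simulated read length in bases.
#' @param coverage Target depth over transcript spans; each transcript gets
#'   `round(coverage * span / read_length)` reads.
#' @param base_error_rate Per-base sequencing error probability.
#' @param conversion_rate Probability that a template T (read orientation) is
#'   converted to C, emulating metabolic-labelling chemistry.
#' @return A list of class `txome_fixture_config`.
#' @export
fixture_config <- function(seed = 42L,
                           chromosomes = c(chr1 = 10000L, chr2 = 6000L),
                           n_genes = 6L,
                           transcripts_per_gene = c(1L, 3L),
                           exons_per_transcript = c(1L, 4L),
                           read_length = 50L,
                           coverage = 10,
                           base_error_rate = 0,
                           conversion_rate = 0) {
  stopifnot(length(chromosomes) >= 1L, !is.null(names(chromosomes)),
            all(chromosomes >= 1L), all(chromosomes <= 100000L),
            n_genes >= 1L, length(transcripts_per_gene) == 2L,
            length(exons_per_transcript) == 2L, read_length >= 10L,
            coverage > 0, base_error_rate >= 0, base_error_rate < 1,
            conversion_rate >= 0, conversion_rate <= 1)
  structure(list(seed = as.integer(seed),
                 chromosomes = as.integer(chromosomes) |>
                   stats::setNames(names(chromosomes)),
                 n_genes = as.integer(n_genes),
                 transcripts_per_gene = as.integer(transcripts_per_gene),
                 exons_per_transcript = as.integer(exons_per_transcript),
                 read_length = as.integer(read_length),
                 coverage = coverage,
                 base_error_rate = base_error_rate,
                 conversion_rate = conversion_rate),
            class = "txome_fixture_config")
}

BASES <- c("A", "C", "G", "T")

#' Generate the fixture genome (FASTA + .fai)
#'
#' Random A/C/G/T sequences of the configured lengths, wrapped at 60
#' columns, with a consistent `samtools faidx`-style index written next to
#' the FASTA.
#'
#' @param cfg A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return A list with `fasta`, `fai`, `refdict`, `seqs` (named character)
#'   and `manifest`.
#' @export
make_genome <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 1L)
  seqs <- vapply(cfg$chromosomes, function(len)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), "")
  fasta <- file.path(dir, "genome.fa")
  con <- file(fasta, "wb")  # binary mode: fixed \n line endings everywhere
  offsets <- integer(length(seqs))
  pos <- 0L
  for (i in seq_along(seqs)) {
    hdr <- paste0(">", names(seqs)[i], "\n")
    writeChar(hdr, con, eos = NULL)
    pos <- pos + nchar(hdr)
    offsets[i] <- pos
    len <- nchar(seqs[[i]])
    starts <- seq.int(1L, len, by = 60L)
    body <- paste0(paste(substring(seqs[[i]], starts,
                                   pmin(starts + 59L, len)),
                         collapse = "\n"), "\n")
    writeChar(body, con, eos = NULL)
    pos <- pos + nchar(body)
  }
  close(con)
  fai <- paste0(fasta, ".fai")
  writeLines(sprintf("%s\t%d\t%d\t60\t61", names(seqs),
                     unname(cfg$chromosomes), offsets), fai)
  manifest <- list(chromosomes = as.list(cfg$chromosomes))
  jsonlite::write_json(manifest, file.path(dir, "genome.manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(fasta = fasta, fai = fai,
       refdict = refdict_from_fai(fai),
       seqs = seqs, manifest = manifest)
}

# split `total` into n_parts with given minimums, randomly distributing the
# surplus (deterministic under the caller's seed)
random_composition <- function(total, mins) {
  extra <- total - sum(mins)
  stopifnot(extra >= 0L)
  if (extra == 0L || length(mins) == 1L) {
    if (length(mins) == 1L) return(total)
    add <- rep(0L, length(mins))
  } else {
    draw <- stats::rmultinom(1L, extra, rep(1, length(mins)))[, 1L]
    add <- as.integer(draw)
  }
  mins + add
}

#' Generate the fixture gene annotation (GFF3 + manifest)
#'
#' Places non-overlapping genes uniformly over the genome, on both strands,
#' each with sampled transcript and exon counts. Exons within a transcript
#' are non-overlapping with gaps of at least 2 bases, so intron inference is
#' exercised; the first and last exon touch the transcript ends. CDS rows
#' covering all exons (with GFF3 phases) are written for protein-coding
#' genes; one gene is flagged `lncRNA` so gene-type filtering has something
#' to drop. All counts and coordinates are recorded in a manifest so tests
#' can assert exact numbers.
#'
#' @param cfg A [fixture_config()].
#' @param dir Output directory.
#' @return A list with `gff3`, `manifest` (and the manifest JSON on disk).
#' @export
make_annotation <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 2L)
  chroms <- names(cfg$chromosomes)
  placed <- list()
  genes <- list()
  min_gene <- 300L
  for (g in seq_len(cfg$n_genes)) {
    ok <- FALSE
    for (try in 1:2000) {
      chrom <- sample(chroms, 1L, prob = as.numeric(cfg$chromosomes))
      clen <- cfg$chromosomes[[chrom]]
      glen <- sample(min_gene:min(1200L, clen - 2L), 1L)
      gstart <- sample(seq_len(clen - glen + 1L), 1L)
      gend <- gstart + glen - 1L
      clash <- any(vapply(placed, function(p)
        p$chrom == chrom && gstart <= p$end + 10L && p$start <= gend + 10L,
        TRUE))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("genome too small to place ", cfg$n_genes,
                  " non-overlapping genes", call. = FALSE)
    placed[[g]] <- list(chrom = chrom, start = gstart, end = gend)
    genes[[g]] <- list(
      gene_id = paste0("g", g), chrom = chrom, start = gstart, end = gend,
      strand = if (g %% 2L == 0L) "-" else "+",
      gene_name = paste0("GENE", g),
      gene_type = if (g == 2L && cfg$n_genes >= 2L) "lncRNA" else
        "protein_coding")
  }

  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", chroms,
                     unname(cfg$chromosomes)))
  manifest_tx <- list(); manifest_exons <- list()
  n_tx <- 0L; n_exon <- 0L; n_cds <- 0L; n_intron <- 0L
  a <- function(...) paste(..., sep = ";")
  for (gn in genes) {
    lines <- c(lines, sprintf(
      "%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_name=%s;gene_type=%s",
      gn$chrom, gn$start, gn$end, gn$strand, gn$gene_id, gn$gene_name,
      gn$gene_type))
    k_tx <- sample(cfg$transcripts_per_gene[1L]:cfg$transcripts_per_gene[2L],
                   1L)
    for (t in seq_len(k_tx)) {
      n_tx <- n_tx + 1L
      tid <- paste0(gn$gene_id, ".t", t)
      span <- gn$end - gn$start + 1L
      k_ex <- sample(cfg$exons_per_transcript[1L]:cfg$exons_per_transcript[2L],
                     1L)
      # shrink exon count if the span cannot host it
      while (k_ex > 1L && span < k_ex * 20L + (k_ex - 1L) * 2L) {
        k_ex <- k_ex - 1L
      }
      mins <- c(rbind(rep(20L, k_ex), rep(2L, k_ex)))[seq_len(2L * k_ex - 1L)]
      parts <- random_composition(span, mins)
      exon_len <- parts[seq(1L, 2L * k_ex - 1L, by = 2L)]
      gap_len <- if (k_ex > 1L) parts[seq(2L, 2L * k_ex - 2L, by = 2L)] else
        integer()
      starts <- gn$start + cumsum(c(0L, utils::head(
        exon_len, -1L) + gap_len))
      ends <- starts + exon_len - 1L
      lines <- c(lines, sprintf(
        "%s\tfixture\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        gn$chrom, gn$start, gn$end, gn$strand, tid, gn$gene_id))
      lines <- c(lines, sprintf(
        "%s\tfixture\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        gn$chrom, starts, ends, gn$strand, tid))
      n_exon <- n_exon + k_ex
      n_intron <- n_intron + (k_ex - 1L)
      if (gn$gene_type == "protein_coding") {
        # CDS over all exons; phase per GFF3, assigned in 5'->3' order
        lens53 <- if (gn$strand == "-") rev(exon_len) else exon_len
        cum_prev <- c(0L, cumsum(utils::head(lens53, -1L)))
        phase53 <- (3L - (cum_prev %% 3L)) %% 3L
        phase <- if (gn$strand == "-") rev(phase53) else phase53
        lines <- c(lines, sprintf(
          "%s\tfixture\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
          gn$chrom, starts, ends, gn$strand, phase, tid))
        n_cds <- n_cds + k_ex
      }
      manifest_tx[[tid]] <- list(transcript_id = tid, gene_id = gn$gene_id,
                                 chrom = gn$chrom, start = gn$start,
                                 end = gn$end, strand = gn$strand,
                                 n_exons = k_ex)
      manifest_exons[[tid]] <- list(start = as.integer(starts),
                                    end = as.integer(ends))
    }
  }
  gff3 <- file.path(dir, "annotation.gff3")
  writeLines(lines, gff3)
  manifest <- list(
    n_genes = length(genes), n_transcripts = n_tx, n_exons = n_exon,
    n_cds = n_cds, n_introns = n_intron,
    genes = genes, transcripts = manifest_tx, exons = manifest_exons)
  jsonlite::write_json(manifest, file.path(dir, "annotation.manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(gff3 = gff3, manifest = manifest)
}

#' Compress and tabix-index a fixture annotation
#'
#' @param gff3 Path to a plain-text, position-sorted GFF3 file.
#' @return Path to the bgzip-compressed file (with `.tbi` next to it).
#' @export
index_annotation <- function(gff3) {
  # GFF3 rows must be position-sorted for tabix; fixture rows are grouped by
  # gene, so re-sort
  lines <- readLines(gff3, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  dat <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(dat, "\t", fixed = TRUE)
  dat <- dat[order(vapply(f, `[[`, "", 1L),
                   as.integer(vapply(f, `[[`, "", 4L)))]
  sorted <- sub("\\.gff3$", ".sorted.gff3", gff3)
  writeLines(c(hdr, dat), sorted)
  bgz <- Rsamtools::bgzip(sorted, overwrite = TRUE)
  Rsamtools::indexTabix(bgz, format = "gff")
  bgz
}

read_fasta_simple <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(lines, ">"))
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), "")
  names(seqs) <- sub("^>", "", sub("\\s.*", "", lines[hdr]))
  seqs
}

#' Simulate reads over the fixture transcripts (SAM, optionally BAM)
#'
#' Reads are sampled uniformly from each transcript's genomic span at the
#' configured depth and aligned ungapped at their true position (CIGAR all
#' match), so mismatch counting has exact ground truth. Per-base sequencing
#' errors are applied at `base_error_rate`; additionally each template T (in
#' read orientation, i.e. the transcript strand) is converted to C with
#' probability `conversion_rate`. The number of conversions actually applied
#' to a read is recorded in its `nc:i:` tag, so conversion truth is fully
#' recoverable from the alignments themselves; aggregate truths are also
#' written to the manifest.
#'
#' @param cfg A [fixture_config()].
#' @param dir Output directory.
#' @param genome Result of [make_genome()] (or a path to the fixture FASTA).
#' @param annotation Result of [make_annotation()] (or the manifest list).
#' @param bam Also produce a sorted, indexed BAM next to the SAM.
#' @return A list with `sam`, optionally `bam`, and `manifest`.
#' @export
make_reads <- function(cfg, dir, genome, annotation, bam = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 3L)
  seqs <- if (is.character(genome)) read_fasta_simple(genome) else genome$seqs
  man <- if (!is.null(annotation$manifest)) annotation$manifest else annotation
  L <- cfg$read_length
  recs <- list()
  total_T <- 0L; total_conv <- 0L
  for (txm in man$transcripts) {
    span <- txm$end - txm$start + 1L
    if (span < L) next
    n_reads <- max(1L, round(cfg$coverage * span / L))
    starts <- sample(txm$start:(txm$end - L + 1L), n_reads, replace = TRUE)
    for (k in seq_len(n_reads)) {
      s <- starts[k]
      ref <- substr(seqs[[txm$chrom]], s, s + L - 1L)
      oriented <- if (txm$strand == "-") revcomp(ref) else ref
      b <- strsplit(oriented, "", fixed = TRUE)[[1L]]
      is_T <- b == "T"
      total_T <- total_T + sum(is_T)
      nc <- 0L
      if (cfg$conversion_rate > 0 && any(is_T)) {
        conv <- is_T & stats::runif(L) < cfg$conversion_rate
        b[conv] <- "C"
        nc <- sum(conv)
        total_conv <- total_conv + nc
      }
      if (cfg$base_error_rate > 0) {
        err <- stats::runif(L) < cfg$base_error_rate
        if (any(err)) {
          b[err] <- vapply(b[err], function(x)
            sample(setdiff(BASES, x), 1L), "")
        }
      }
      read_seq <- paste(b, collapse = "")
      seq_plus <- if (txm$strand == "-") revcomp(read_seq) else read_seq
      recs[[length(recs) + 1L]] <- list(
        qname = sprintf("r_%s_%d", txm$transcript_id, k),
        flag = if (txm$strand == "-") 16L else 0L,
        chrom = txm$chrom, pos = s, seq = seq_plus, nc = nc)
    }
  }
  rd <- refdict(names(seqs), vapply(seqs, nchar, 1L), name = "fixture genome")
  cidx <- vapply(recs, function(r) match(r$chrom, rd$chrom), 1L)
  pos <- vapply(recs, `[[`, 1L, "pos")
  recs <- recs[order(cidx, pos)]
  qual <- paste(rep("I", L), collapse = "")  # constant Q40
  sam_lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", rd$chrom, rd$length),
    vapply(recs, function(r) sprintf(
      "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tnc:i:%d",
      r$qname, r$flag, r$chrom, r$pos, L, r$seq, qual, r$nc), ""))
  sam <- file.path(dir, "reads.sam")
  writeLines(sam_lines, sam)
  manifest <- list(n_reads = length(recs), read_length = L,
                   n_template_T = total_T, n_conversions = total_conv,
                   base_error_rate = cfg$base_error_rate,
                   conversion_rate = cfg$conversion_rate)
  jsonlite::write_json(manifest, file.path(dir, "reads.manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- list(sam = sam, manifest = manifest)
  if (bam) {
    bam_path <- Rsamtools::asBam(sam, file.path(dir, "reads"),
                                 overwrite = TRUE, indexDestination = TRUE)
    out$bam <- bam_path
  }
  out
}

#' Generate fixture interval tracks (BED, bedGraph, VCF)
#'
#' Writes a BED6 file of all exon intervals, a bedGraph assigning each exon
#' its rank within its transcript, and a VCF planting SNVs at recorded
#' positions inside the first gene and in intergenic space. All truths
#' (positions, values, counts) are returned in the manifest.
#'
#' @param cfg A [fixture_config()].
#' @param dir Output directory.
#' @param genome Result of [make_genome()] (or FASTA path).
#' @param annotation Result of [make_annotation()].
#' @param n_variants_inside,n_variants_outside SNV counts to plant.
#' @return A list with `bed`, `bedgraph`, `vcf`, `manifest`.
#' @export
make_tracks <- function(cfg, dir, genome, annotation,
                        n_variants_inside = 5L, n_variants_outside = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 4L)
  seqs <- if (is.character(genome)) read_fasta_simple(genome) else genome$seqs
  man <- if (!is.null(annotation$manifest)) annotation$manifest else annotation
  rd <- refdict(names(seqs), vapply(seqs, nchar, 1L))

  exon_rows <- list()
  for (tid in names(man$exons)) {
    ex <- man$exons[[tid]]
    txm <- man$transcripts[[tid]]
    for (i in seq_along(ex$start)) {
      exon_rows[[length(exon_rows) + 1L]] <- list(
        chrom = txm$chrom, start = ex$start[i], end = ex$end[i],
        strand = txm$strand, name = paste0(tid, "_exon", i), rank = i)
    }
  }
  cidx <- vapply(exon_rows, function(r) match(r$chrom, rd$chrom), 1L)
  st <- vapply(exon_rows, `[[`, 1L, "start")
  en <- vapply(exon_rows, `[[`, 1L, "end")
  exon_rows <- exon_rows[order(cidx, st, en)]

  bed <- file.path(dir, "exons.bed")
  writeLines(vapply(exon_rows, function(r) sprintf(
    "%s\t%d\t%d\t%s\t0\t%s", r$chrom, r$start - 1L, r$end, r$name, r$strand),
    ""), bed)
  bedgraph <- file.path(dir, "exon_rank.bedgraph")
  writeLines(vapply(exon_rows, function(r) sprintf(
    "%s\t%d\t%d\t%d", r$chrom, r$start - 1L, r$end, r$rank), ""), bedgraph)

  g1 <- man$genes[[1L]]
  inside <- sort(sample(g1$start:g1$end, n_variants_inside))
  # intergenic candidates on g1's chromosome
  covered <- rep(FALSE, rd$length[match(g1$chrom, rd$chrom)])
  for (gn in man$genes) {
    if (gn$chrom == g1$chrom) covered[gn$start:gn$end] <- TRUE
  }
  free <- which(!covered)
  outside <- sort(sample(free, n_variants_outside))
  all_pos <- sort(c(inside, outside))
  refb <- substring(seqs[[g1$chrom]], all_pos, all_pos)
  altb <- vapply(refb, function(x) sample(setdiff(BASES, x), 1L), "")
  vcf <- file.path(dir, "variants.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", rd$chrom, rd$length),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\tv%d\t%s\t%s\t.\tPASS\t.", g1$chrom, all_pos,
            seq_along(all_pos), refb, altb)), vcf)
  manifest <- list(
    n_exon_rows = length(exon_rows),
    variant_positions_inside_gene1 = inside,
    variant_positions_outside_genes = outside,
    gene1 = g1)
  jsonlite::write_json(manifest, file.path(dir, "tracks.manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(bed = bed, bedgraph = bedgraph, vcf = vcf, manifest = manifest)
}

#' Generate the full fixture suite
#'
#' Runs [make_genome()], [make_annotation()], [make_reads()] and
#' [make_tracks()] into one directory. The whole suite is a pure function of
#' the configuration: regenerating it from the same config is byte-identical.
#'
#' @param cfg A [fixture_config()].
#' @param dir Output directory.
#' @param bam Also produce the sorted, indexed BAM.
#' @return A named list with the four component results.
#' @export
make_fixture_suite <- function(cfg, dir, bam = FALSE) {
  genome <- make_genome(cfg, dir)
  annotation <- make_annotation(cfg, dir)
  reads <- make_reads(cfg, dir, genome, annotation, bam = bam)
  tracks <- make_tracks(cfg, dir, genome, annotation)
  list(genome = genome, annotation = annotation, reads = reads,
       tracks = tracks)
}
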