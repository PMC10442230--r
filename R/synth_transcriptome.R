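# Synthetic transcriptome: one canonical single-exon transcript per gene,
# GGACH motifs planted at chromosome-class-specific Poisson densities into a
# background that cannot spell GGACH by accident (no G ever follows G outside
# planted motifs), so that truth-by-construction equals truth-by-scan.

BASES <- c("A", "C", "G", "T")
H_BASES <- c("A", "C", "T")

# i.i.d. ACGT background with second G of any GG run replaced by a non-G
# letter; the result contains no "GG" and therefore no GGACH.
sample_background <- function(n) {
  if (n <= 0) return(character(0))
  x <- sample(BASES, n, replace = TRUE)
  is_g <- x == "G"
  bad <- is_g & c(FALSE, is_g[-n])
  if (any(bad)) x[bad] <- sample(H_BASES, sum(bad), replace = TRUE)
  x
}

# n motif start offsets (0-based) in [1, len - 5] with pairwise gap >= 6
# (room for the motif plus a non-G guard base on the left).
sample_motif_starts <- function(n, len) {
  hi <- len - 5L
  if (n == 0L || hi < 1L) return(integer(0))
  span <- hi - 6L * (n - 1L)
  while (span < 1L && n > 0L) {   # region too crowded: plant what fits
    n <- n - 1L
    span <- hi - 6L * (n - 1L)
  }
  if (n == 0L) return(integer(0))
  z <- sort(sample.int(span, n))
  as.integer(z + 6L * (seq_len(n) - 1L))
}

region_order <- c("utr5", "cds", "utr3")

#' Generate a synthetic transcriptome with planted GGACH motifs
#'
#' Draws region lengths, plants GGACH motifs per region at the configured
#' per-kb Poisson rates (3'UTR density differs between autosomes and the X;
#' CDS scales with it; 5'UTR density is class-independent), assembles spliced
#' transcript and genome sequences, and rescans every transcript so that the
#' returned motif table and ground truth always equal what a motif scan of
#' the sequences reports.
#'
#' @param config a [synth_config()].
#' @return list with elements `models` (a `transcript_models` object),
#'   `tx_seq` (named [Biostrings::DNAStringSet] of spliced sense-strand
#'   transcripts), `genome` ([Biostrings::DNAStringSet] of chromosomes),
#'   `motifs` (data.frame of GGACH occurrences: gene_id, region, tx_start,
#'   genomic start/end, chromosome, strand) and `truth` (ground-truth
#'   skeleton with per-region motif counts and base half-lives).
#' @export
gen_transcriptome <- function(config) {
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, "transcriptome"))
  chroms <- synth_chromosomes(config)
  n_genes <- config$n_chromosomes * config$genes_per_chromosome

  gene_chrom <- rep(chroms, each = config$genes_per_chromosome)
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  transcript_id <- sprintf("T%04d.1", seq_len(n_genes))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  is_x <- gene_chrom == "chrX"

  rl <- config$region_length_params
  draw_len <- function(p, min_len) {
    pmax(min_len, round(stats::rlnorm(n_genes, p[["meanlog"]], p[["sdlog"]])))
  }
  utr5_len <- as.integer(draw_len(rl$utr5, 20))
  cds_len <- as.integer(draw_len(rl$cds, 90))
  cds_len <- cds_len - cds_len %% 3L            # whole codons
  utr3_len <- as.integer(draw_len(rl$utr3, 50))
  tx_len <- utr5_len + cds_len + utr3_len

  dens_utr3 <- ifelse(is_x, config$ggach_density_X,
                      config$ggach_density_autosome)
  dens_cds <- dens_utr3 * config$ggach_density_cds_scale
  dens_utr5 <- rep(config$ggach_density_utr5, n_genes)

  tx_seq <- character(n_genes)
  for (i in seq_len(n_genes)) {
    seq_chars <- sample_background(tx_len[i])
    offsets <- c(utr5 = 0L, cds = utr5_len[i],
                 utr3 = utr5_len[i] + cds_len[i])
    lens <- c(utr5 = utr5_len[i], cds = cds_len[i], utr3 = utr3_len[i])
    dens <- c(utr5 = dens_utr5[i], cds = dens_cds[i], utr3 = dens_utr3[i])
    for (r in region_order) {
      n_mot <- stats::rpois(1L, dens[[r]] * lens[[r]] / 1000)
      starts <- sample_motif_starts(n_mot, lens[[r]])
      for (s in starts) {
        pos <- offsets[[r]] + s
        seq_chars[pos] <- "G"; seq_chars[pos + 1L] <- "G"
        seq_chars[pos + 2L] <- "A"; seq_chars[pos + 3L] <- "C"
        seq_chars[pos + 4L] <- sample(H_BASES, 1L)
        if (pos > 1L && seq_chars[pos - 1L] == "G")
          seq_chars[pos - 1L] <- sample(H_BASES, 1L)
      }
    }
    # stop codon occupies the last CDS codon
    stop_at <- utr5_len[i] + cds_len[i] - 2L
    seq_chars[stop_at:(stop_at + 2L)] <- c("T", "A", "A")
    tx_seq[i] <- paste(seq_chars, collapse = "")
  }

  # genome assembly: genes in order along each chromosome, 100-nt spacers
  spacer <- 100L
  genome <- character(length(chroms))
  names(genome) <- chroms
  tx_start <- integer(n_genes)
  for (ci in seq_along(chroms)) {
    idx <- which(gene_chrom == chroms[ci])
    pieces <- character(2L * length(idx) + 1L)
    pieces[1L] <- paste(sample_background(spacer), collapse = "")
    at <- spacer
    for (j in seq_along(idx)) {
      g <- idx[j]
      gseq <- tx_seq[g]
      if (strand[g] == "-")
        gseq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(gseq)))
      pieces[2L * j] <- gseq
      tx_start[g] <- at
      at <- at + tx_len[g]
      pieces[2L * j + 1L] <- paste(sample_background(spacer), collapse = "")
      at <- at + spacer
    }
    genome[ci] <- paste(pieces, collapse = "")
  }

  transcripts <- data.frame(
    gene_id = gene_id, transcript_id = transcript_id,
    chromosome = gene_chrom, strand = strand,
    ccds_present = TRUE, transcript_support_level = 1L, level = 1L,
    utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
    spliced_length = tx_len,
    stop_codon_tx = utr5_len + cds_len - 3L,
    tx_start = tx_start, tx_end = tx_start + tx_len,
    stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = transcript_id, chromosome = gene_chrom, strand = strand,
    start = tx_start, end = tx_start + tx_len, exon_rank = 1L,
    stringsAsFactors = FALSE)
  models <- new_transcript_models(transcripts, exons)

  tx_set <- Biostrings::DNAStringSet(tx_seq)
  names(tx_set) <- transcript_id
  genome_set <- Biostrings::DNAStringSet(genome)

  motifs <- scan_transcript_motifs(models, tx_set, pattern = "GGACH")

  cnt <- table(factor(motifs$gene_id, levels = gene_id),
               factor(motifs$region, levels = region_order))
  truth <- data.frame(
    gene_id = gene_id, transcript_id = transcript_id,
    chromosome = gene_chrom,
    class = as.character(chromosome_class(gene_chrom)),
    strand = strand,
    utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
    n_ggach_utr5 = as.integer(cnt[, "utr5"]),
    n_ggach_cds = as.integer(cnt[, "cds"]),
    n_ggach_utr3 = as.integer(cnt[, "utr3"]),
    t_half_base = stats::rlnorm(n_genes,
                                config$halflife_base[["meanlog"]],
                                config$halflife_base[["sdlog"]]),
    is_spikein = FALSE,
    stringsAsFactors = FALSE)

  list(models = models, tx_seq = tx_set, genome = genome_set,
       motifs = motifs, truth = truth)
}

#' Scan spliced transcripts for motif occurrences
#'
#' IUPAC-aware scan of the sense-strand spliced sequences; overlapping
#' matches are counted and each occurrence is assigned to the region
#' (5'UTR/CDS/3'UTR) containing its first base and mapped back to genomic
#' coordinates through the exon structure.
#'
#' @param models a `transcript_models` object.
#' @param tx_seq `DNAStringSet` named by transcript_id.
#' @param pattern IUPAC pattern, default `"GGACH"`.
#' @return data.frame: gene_id, transcript_id, chromosome, strand, region,
#'   tx_start (0-based transcript coordinate), genomic start/end (0-based
#'   half-open, position of the motif's first genomic base on + strand).
#' @export
scan_transcript_motifs <- function(models, tx_seq, pattern = "GGACH") {
  tr <- models$transcripts
  stopifnot(all(tr$transcript_id %in% names(tx_seq)))
  plen <- nchar(pattern)
  hits <- Biostrings::vmatchPattern(pattern, tx_seq[tr$transcript_id],
                                    fixed = "subject")
  starts <- lapply(hits, function(h) BiocGenerics::start(h) - 1L)
  n_per <- lengths(starts)
  idx <- rep(seq_len(nrow(tr)), n_per)
  tx_pos <- unlist(starts, use.names = FALSE)
  if (length(tx_pos) == 0L) {
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      chromosome = character(0), strand = character(0),
                      region = character(0), tx_start = integer(0),
                      gstart = integer(0), gend = integer(0),
                      stringsAsFactors = FALSE))
  }
  region <- ifelse(tx_pos < tr$utr5_len[idx], "utr5",
            ifelse(tx_pos < tr$utr5_len[idx] + tr$cds_len[idx],
                   "cds", "utr3"))
  gpos <- tx_to_genomic(models, tr$transcript_id[idx], tx_pos)
  # genomic start of the motif's first base span on the + strand
  gstart <- ifelse(tr$strand[idx] == "+", gpos, gpos - (plen - 1L))
  data.frame(gene_id = tr$gene_id[idx],
             transcript_id = tr$transcript_id[idx],
             chromosome = tr$chromosome[idx],
             strand = tr$strand[idx],
             region = region,
             tx_start = tx_pos,
             gstart = as.integer(gstart),
             gend = as.integer(gstart + plen),
             stringsAsFactors = FALSE)
}
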