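# Internal transcript representation. Coordinates are 0-based half-open
# everywhere inside the package; GTF (1-based inclusive) is converted at the
# I/O boundary. A `transcript_models` object bundles one row per transcript
# with its exon table; exon_rank 1 is the 5'-most exon in transcript
# orientation.

#' Construct a transcript_models object
#'
#' @param transcripts data.frame with columns gene_id, transcript_id,
#'   chromosome, strand, ccds_present, transcript_support_level, level,
#'   utr5_len, cds_len, utr3_len, spliced_length, stop_codon_tx (0-based
#'   transcript coordinate of the stop codon's first base).
#' @param exons data.frame with columns transcript_id, chromosome, strand,
#'   start, end (0-based half-open), exon_rank.
#' @return object of class `transcript_models`.
#' @export
new_transcript_models <- function(transcripts, exons) {
  need_tr <- c("gene_id", "transcript_id", "chromosome", "strand",
               "utr5_len", "cds_len", "utr3_len", "spliced_length",
               "stop_codon_tx")
  miss <- setdiff(need_tr, names(transcripts))
  if (length(miss)) abort("transcripts table missing columns: %s",
                          paste(miss, collapse = ", "))
  need_ex <- c("transcript_id", "chromosome", "strand", "start", "end",
               "exon_rank")
  miss <- setdiff(need_ex, names(exons))
  if (length(miss)) abort("exon table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(exons$end <= exons$start)) abort("exon with non-positive length")
  ex_len <- tapply(exons$end - exons$start, exons$transcript_id, sum)
  sl <- transcripts$spliced_length
  names(sl) <- transcripts$transcript_id
  bad <- names(ex_len)[ex_len != sl[names(ex_len)]]
  if (length(bad)) abort("spliced_length != sum of exon lengths for %s",
                         bad[1])
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d transcripts / %d genes on %d chromosomes\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              length(unique(x$transcripts$chromosome))))
  invisible(x)
}

# per-transcript exon table sorted by rank, as a named list (cached lookup)
exon_index <- function(models) {
  ex <- models$exons
  ex <- ex[order(ex$transcript_id, ex$exon_rank), ]
  split(ex[c("start", "end", "strand")], ex$transcript_id)
}

#' Map transcript coordinates to genomic coordinates
#'
#' @param models a `transcript_models` object.
#' @param transcript_id character vector (recycled against `tx_pos`).
#' @param tx_pos 0-based transcript coordinates.
#' @return 0-based genomic position of each queried base.
#' @export
tx_to_genomic <- function(models, transcript_id, tx_pos) {
  idx <- exon_index(models)
  out <- integer(length(tx_pos))
  for (i in seq_along(tx_pos)) {
    ex <- idx[[transcript_id[i]]]
    if (is.null(ex)) abort("unknown transcript %s", transcript_id[i])
    w <- ex$end - ex$start
    cum <- cumsum(c(0L, w))
    j <- findInterval(tx_pos[i], cum, rightmost.closed = FALSE)
    if (j < 1L || tx_pos[i] >= cum[length(cum)])
      abort("transcript coordinate %d out of range for %s",
            tx_pos[i], transcript_id[i])
    off <- tx_pos[i] - cum[j]
    out[i] <- if (ex$strand[1] == "+") ex$start[j] + off
              else ex$end[j] - 1L - off
  }
  out
}

#' Map genomic positions to transcript coordinates
#'
#' @param models a `transcript_models` object.
#' @param transcript_id character vector (recycled against `gpos`).
#' @param gpos 0-based genomic positions.
#' @return 0-based transcript coordinates; `NA` for positions outside the
#'   transcript's exons (intronic or flanking).
#' @export
genomic_to_tx <- function(models, transcript_id, gpos) {
  idx <- exon_index(models)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_along(gpos)) {
    ex <- idx[[transcript_id[i]]]
    if (is.null(ex)) next
    w <- ex$end - ex$start
    cum <- cumsum(c(0L, w))
    for (j in seq_len(nrow(ex))) {
      if (gpos[i] >= ex$start[j] && gpos[i] < ex$end[j]) {
        off <- if (ex$strand[1] == "+") gpos[i] - ex$start[j]
               else ex$end[j] - 1L - gpos[i]
        out[i] <- cum[j] + off
        break
      }
    }
  }
  out
}

#' Extract spliced sense-strand transcript sequences from a genome
#'
#' @param models a `transcript_models` object.
#' @param genome named [Biostrings::DNAStringSet] of chromosome sequences.
#' @return named `DNAStringSet` of spliced transcripts (5'->3' sense).
#' @export
extract_transcript_seq <- function(models, genome) {
  idx <- exon_index(models)
  tr <- models$transcripts
  seqs <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    ex <- idx[[tr$transcript_id[i]]]
    ex <- ex[order(ex$start), ]        # genomic order for extraction
    chrom_seq <- genome[[tr$chromosome[i]]]
    parts <- Biostrings::DNAStringSet(chrom_seq,
                                      start = ex$start + 1L, end = ex$end)
    s <- Biostrings::DNAStringSet(paste(as.character(parts), collapse = ""))
    if (tr$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- tr$transcript_id
  out
}
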