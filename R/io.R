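# Readers and writers for the standard formats. Internal coordinates are
# 0-based half-open everywhere; GTF (1-based inclusive) and BED (0-based
# half-open) are converted exactly at this boundary. GTF/BED writing is done
# with plain formatting for exact attribute control; reading goes through
# rtracklayer, which doubles as an independent check on the writers.

#' Write transcript models as GTF
#'
#' Emits transcript, exon, CDS, five_prime_utr and three_prime_utr rows with
#' attributes gene_id, transcript_id, ccdsid (when present), level and
#' transcript_support_level; 1-based inclusive coordinates.
#'
#' @param models a `transcript_models` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  tr <- models$transcripts
  idx <- exon_index(models)
  lines <- vector("list", nrow(tr))
  attr_str <- function(i) {
    s <- sprintf('gene_id "%s"; transcript_id "%s";', tr$gene_id[i],
                 tr$transcript_id[i])
    if (isTRUE(tr$ccds_present[i]))
      s <- paste0(s, sprintf(' ccdsid "CCDS%s";', sub("^G", "", tr$gene_id[i])))
    paste0(s, sprintf(' level %s; transcript_support_level "%s";',
                      tr$level[i], tr$transcript_support_level[i]))
  }
  fmt <- function(chrom, feat, start0, end0, strand, attrs) {
    sprintf("%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, start0 + 1L, end0, strand, attrs)
  }
  for (i in seq_len(nrow(tr))) {
    at <- attr_str(i)
    ex <- idx[[tr$transcript_id[i]]]
    out <- c(fmt(tr$chromosome[i], "transcript", min(ex$start), max(ex$end),
                 tr$strand[i], at),
             fmt(tr$chromosome[i], "exon", ex$start, ex$end, tr$strand[i], at))
    # region rows in transcript coordinates mapped back to genomic spans
    spans <- list(five_prime_utr = c(0L, tr$utr5_len[i]),
                  CDS = c(tr$utr5_len[i], tr$utr5_len[i] + tr$cds_len[i]),
                  three_prime_utr = c(tr$utr5_len[i] + tr$cds_len[i],
                                      tr$spliced_length[i]))
    for (feat in names(spans)) {
      sp <- spans[[feat]]
      if (sp[2] <= sp[1]) next
      segs <- tx_span_to_genomic(models, tr$transcript_id[i], sp[1], sp[2],
                                 idx = idx)
      out <- c(out, fmt(tr$chromosome[i], feat, segs$start, segs$end,
                        tr$strand[i], at))
    }
    lines[[i]] <- out
  }
  writeLines(unlist(lines), path)
  invisible(path)
}

# genomic segments ([start,end) rows) covered by transcript span [a, b)
tx_span_to_genomic <- function(models, transcript_id, a, b,
                               idx = exon_index(models)) {
  ex <- idx[[transcript_id]]
  w <- ex$end - ex$start
  cum <- cumsum(c(0L, w))
  segs <- list()
  for (j in seq_len(nrow(ex))) {
    lo <- max(a, cum[j]); hi <- min(b, cum[j + 1])
    if (hi <= lo) next
    if (ex$strand[1] == "+") {
      segs[[length(segs) + 1L]] <- c(ex$start[j] + (lo - cum[j]),
                                     ex$start[j] + (hi - cum[j]))
    } else {
      segs[[length(segs) + 1L]] <- c(ex$end[j] - (hi - cum[j]),
                                     ex$end[j] - (lo - cum[j]))
    }
  }
  out <- do.call(rbind, segs)
  data.frame(start = out[, 1], end = out[, 2])
}

#' Read a GTF annotation into transcript models
#'
#' Accepts GENCODE-style GTF with gene_id/transcript_id/ccdsid/level/
#' transcript_support_level attributes. Coordinates convert exactly to the
#' internal 0-based half-open convention; region lengths are summed from
#' five_prime_utr/CDS/three_prime_utr rows. Transcripts missing a mandatory
#' attribute are skipped and counted.
#'
#' @param path GTF file.
#' @return list with `models` (a `transcript_models`) and `n_skipped`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1L          # to 0-based half-open
  df$end0 <- df$end
  need <- c("gene_id", "transcript_id")
  miss_attr <- !stats::complete.cases(df[need])
  n_skipped_rows <- sum(miss_attr)
  if (n_skipped_rows) {
    warning(sprintf("%d GTF records missing gene_id/transcript_id skipped",
                    n_skipped_rows))
    df <- df[!miss_attr, , drop = FALSE]
  }
  ex <- df[df$type == "exon", , drop = FALSE]
  if (!nrow(ex)) abort("GTF contains no exon records")
  region_len <- function(feat) {
    r <- df[df$type == feat, , drop = FALSE]
    if (!nrow(r)) return(stats::setNames(numeric(0), character(0)))
    tapply(r$end0 - r$start0, r$transcript_id, sum)
  }
  l5 <- region_len("five_prime_utr")
  lc <- region_len("CDS")
  l3 <- region_len("three_prime_utr")
  getlen <- function(tab, id) {
    v <- as.integer(tab[id])
    v[is.na(v)] <- 0L
    v
  }

  ord <- order(ex$transcript_id, ex$start0)
  ex <- ex[ord, , drop = FALSE]
  first <- !duplicated(ex$transcript_id)
  tx_ids <- ex$transcript_id[first]
  tr <- data.frame(
    transcript_id = tx_ids,
    gene_id = ex$gene_id[first],
    chromosome = as.character(ex$seqnames[first]),
    strand = as.character(ex$strand[first]),
    stringsAsFactors = FALSE)
  tsl_raw <- if ("transcript_support_level" %in% names(df))
    stats::setNames(df$transcript_support_level,
                    df$transcript_id)[tx_ids] else rep(NA, length(tx_ids))
  lvl_raw <- if ("level" %in% names(df))
    stats::setNames(df$level, df$transcript_id)[tx_ids]
    else rep(NA, length(tx_ids))
  ccds <- if ("ccdsid" %in% names(df)) {
    cc <- stats::setNames(df$ccdsid, df$transcript_id)[tx_ids]
    !is.na(cc) & nzchar(as.character(cc))
  } else rep(FALSE, length(tx_ids))
  tr$ccds_present <- unname(ccds)
  tr$transcript_support_level <-
    suppressWarnings(as.numeric(as.character(tsl_raw)))
  tr$level <- suppressWarnings(as.numeric(as.character(lvl_raw)))
  tr$utr5_len <- getlen(l5, tx_ids)
  tr$cds_len <- getlen(lc, tx_ids)
  tr$utr3_len <- getlen(l3, tx_ids)
  sp_len <- tapply(ex$end0 - ex$start0, ex$transcript_id, sum)
  tr$spliced_length <- as.integer(sp_len[tx_ids])
  tr$stop_codon_tx <- tr$utr5_len + tr$cds_len - 3L

  # exon rank: 5'-most first in transcript orientation
  exon_rows <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(e) {
    e <- e[order(e$start0, decreasing = e$strand[1] == "-"), , drop = FALSE]
    data.frame(transcript_id = e$transcript_id,
               chromosome = as.character(e$seqnames),
               strand = as.character(e$strand),
               start = e$start0, end = e$end0,
               exon_rank = seq_len(nrow(e)), stringsAsFactors = FALSE)
  }))
  rownames(exon_rows) <- NULL
  list(models = new_transcript_models(tr[order(tr$transcript_id), ],
                                      exon_rows),
       n_skipped = n_skipped_rows)
}

#' Write single-nucleotide sites (or peaks) as BED6
#'
#' @param sites data.frame with chromosome, start, end (0-based half-open),
#'   strand and optionally gene_id (used as name).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  name <- if ("gene_id" %in% names(sites)) sites$gene_id else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", sites$chromosome, sites$start,
                   sites$end, name, sites$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read single-nucleotide m6A sites from BED6 and assign genes
#'
#' Sites are validated to be single-nucleotide and within chromosome bounds
#' (when lengths are supplied), then assigned to genes by strand-matched
#' exonic overlap against the provided models. Sites overlapping no gene on
#' the matching strand (including antisense-only overlaps) go to the orphan
#' ledger; rejected records (width != 1) are counted.
#'
#' @param path BED6 file.
#' @param models a `transcript_models` object for gene assignment (NULL to
#'   skip assignment).
#' @param chromosome_lengths optional named vector for bounds checking.
#' @return list with `sites` (chromosome, start, end, strand, gene_id),
#'   `orphans`, `n_rejected`.
#' @export
read_sites <- function(path, models = NULL, chromosome_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  d <- data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
                  start = BiocGenerics::start(gr) - 1L,
                  end = BiocGenerics::end(gr),
                  strand = as.character(BiocGenerics::strand(gr)),
                  stringsAsFactors = FALSE)
  bad <- (d$end - d$start) != 1L
  if (!is.null(chromosome_lengths)) {
    len <- chromosome_lengths[d$chromosome]
    bad <- bad | is.na(len) | d$start < 0 | d$end > len
  }
  n_rejected <- sum(bad)
  d <- d[!bad, , drop = FALSE]
  if (is.null(models)) {
    d$gene_id <- NA_character_
    return(list(sites = d, orphans = d[0, ], n_rejected = n_rejected))
  }
  ex <- models$exons
  tr <- models$transcripts
  gene_of <- stats::setNames(tr$gene_id, tr$transcript_id)
  ex_gr <- GenomicRanges::GRanges(
    ex$chromosome,
    IRanges::IRanges(ex$start + 1L, ex$end),
    strand = ex$strand)
  site_gr <- GenomicRanges::GRanges(
    d$chromosome, IRanges::IRanges(d$start + 1L, d$end), strand = d$strand)
  ov <- GenomicRanges::findOverlaps(site_gr, ex_gr, ignore.strand = FALSE)
  gene_hit <- tapply(gene_of[ex$transcript_id[S4Vectors::subjectHits(ov)]],
                     S4Vectors::queryHits(ov),
                     function(g) unique(g)[1])
  d$gene_id <- NA_character_
  d$gene_id[as.integer(names(gene_hit))] <- unname(gene_hit)
  orphans <- d[is.na(d$gene_id), , drop = FALSE]
  list(sites = d[!is.na(d$gene_id), , drop = FALSE], orphans = orphans,
       n_rejected = n_rejected)
}

#' Read and validate a TSV table
#'
#' Schema-checked readers for the tables the pipeline consumes. Duplicate
#' keys are an error; conversion rows with `tc_count > t_coverage` are
#' rejected (counted in attribute `n_rejected`); numeric parsing is
#' locale-independent.
#'
#' @param path TSV file with header.
#' @param kind one of `"counts"`, `"tpm"`, `"conversions"`, `"orthologs"`.
#' @return validated data.frame (counts/tpm: gene_id column plus numeric
#'   sample columns).
#' @export
read_tables <- function(path, kind = c("counts", "tpm", "conversions",
                                       "orthologs")) {
  kind <- match.arg(kind)
  old <- Sys.getlocale("LC_NUMERIC")
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_cols <- function(need) {
    miss <- setdiff(need, names(d))
    if (length(miss))
      abort("%s table missing column(s): %s", kind,
            paste(miss, collapse = ", "))
  }
  if (kind %in% c("counts", "tpm")) {
    check_cols("gene_id")
    if (anyDuplicated(d$gene_id))
      abort("duplicate gene_id '%s' in %s table",
            d$gene_id[duplicated(d$gene_id)][1], kind)
    val <- d[setdiff(names(d), "gene_id")]
    if (!all(vapply(val, is.numeric, TRUE)))
      abort("%s table has non-numeric sample columns", kind)
  } else if (kind == "conversions") {
    check_cols(c("utr_id", "time_h", "condition", "replicate",
                 "t_coverage", "tc_count"))
    bad <- d$tc_count > d$t_coverage | d$tc_count < 0 | d$t_coverage < 0
    if (any(bad)) {
      warning(sprintf("%d conversion rows with tc_count > t_coverage rejected",
                      sum(bad)))
      d <- d[!bad, , drop = FALSE]
      attr(d, "n_rejected") <- sum(bad)
    }
  } else if (kind == "orthologs") {
    check_cols(c("mouse_gene", "species", "ortholog_gene"))
  }
  d
}

#' Write a data.frame as TSV
#' @param d data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits annotation.gtf, genome.fa, transcripts.fa, sites.bed,
#' conversions_labeled.tsv, conversions_unlabeled.tsv, counts_ctrl.tsv,
#' counts_trt.tsv, tpm.tsv, rpkm.tsv and truth.json. Output bytes are a
#' pure function of the config (including its seed).
#'
#' @param sim result of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(outdir, x)
  write_gtf(sim$models, fp("annotation.gtf"))
  Biostrings::writeXStringSet(sim$genome, fp("genome.fa"))
  Biostrings::writeXStringSet(sim$tx_seq, fp("transcripts.fa"))
  write_bed(sim$sites, fp("sites.bed"))
  write_tsv(sim$slam$labeled, fp("conversions_labeled.tsv"))
  write_tsv(sim$slam$unlabeled, fp("conversions_unlabeled.tsv"))
  mat_tsv <- function(m, path) {
    d <- data.frame(gene_id = rownames(m), m, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(d, path)
  }
  mat_tsv(sim$counts$counts_ctrl, fp("counts_ctrl.tsv"))
  mat_tsv(sim$counts$counts_trt, fp("counts_trt.tsv"))
  mat_tsv(sim$expression$tpm, fp("tpm.tsv"))
  mat_tsv(sim$expression$rpkm, fp("rpkm.tsv"))
  jsonlite::write_json(sim$truth, fp("truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(outdir)
}
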