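# Expression-binned quantification of single-nucleotide m6A sites and
# chromosome-stratified fold changes. Site detection depends on transcript
# abundance, so all chromosome comparisons are made within expression bins.

#' Assign transcripts to expression bins
#'
#' Replicate TPM values are averaged and log10-transformed; transcripts are
#' stratified into 12 equal-width bins of step 0.25 in log10(TPM), with all
#' transcripts below 0.5 or above 3.0 collected into the outer bins. A
#' minimum of TPM > 1 is required; transcripts at or below that floor stay
#' unassigned (bin `NA`).
#'
#' @param tpm matrix (genes x replicates) or data.frame with a `gene_id`
#'   column and replicate columns, or a named vector of TPM values.
#' @return data.frame: gene_id, tpm_mean, log10_tpm, bin (integer 1..12 or
#'   NA).
#' @export
assign_bins <- function(tpm) {
  if (is.data.frame(tpm)) {
    ids <- tpm$gene_id
    m <- as.matrix(tpm[setdiff(names(tpm), "gene_id")])
  } else if (is.matrix(tpm)) {
    ids <- rownames(tpm)
    m <- tpm
  } else {
    ids <- names(tpm)
    m <- matrix(tpm, ncol = 1)
  }
  if (is.null(ids)) abort("TPM input must carry gene identifiers")
  avg <- rowMeans(m)
  lt <- ifelse(avg > 0, log10(avg), NA_real_)
  edges <- c(0, seq(0.5, 3, by = 0.25))      # 12 left edges, last bin open
  bin <- rep(NA_integer_, length(avg))
  assigned <- avg > 1
  bin[assigned] <- findInterval(lt[assigned], edges)
  data.frame(gene_id = ids, tpm_mean = avg, log10_tpm = lt, bin = bin,
             stringsAsFactors = FALSE)
}

#' Count m6A sites per transcript
#'
#' Sites must already carry gene assignments. With
#' `region_filter = "stop_window"` only sites whose spliced-transcript
#' offset from the stop codon's first base lies in `[-50, +150]` (201
#' positions, where most m6A accumulates) are counted — the transcript-length
#' control.
#'
#' @param sites SiteSet data.frame (gene_id and, for the stop window, either
#'   `tx_pos` or genomic `start` to be mapped through `models`).
#' @param models a `transcript_models` object (defines the transcript
#'   universe and stop-codon anchors).
#' @param region_filter `"none"` or `"stop_window"`.
#' @param window `c(upstream, downstream)` offsets, inclusive.
#' @return data.frame gene_id, n_sites (zero for genes with no sites), with
#'   attribute `orphans`: rows whose gene is absent from the annotation.
#' @export
count_sites_per_transcript <- function(sites, models,
                                       region_filter = c("none", "stop_window"),
                                       window = c(-50, 150)) {
  region_filter <- match.arg(region_filter)
  tr <- models$transcripts
  known <- sites$gene_id %in% tr$gene_id
  orphans <- sites[!known, , drop = FALSE]
  sites <- sites[known, , drop = FALSE]

  if (region_filter == "stop_window" && nrow(sites)) {
    tx_of_gene <- stats::setNames(tr$transcript_id, tr$gene_id)
    stop_tx <- stats::setNames(tr$stop_codon_tx, tr$gene_id)
    if ("tx_pos" %in% names(sites)) {
      pos <- sites$tx_pos
    } else {
      pos <- genomic_to_tx(models, tx_of_gene[sites$gene_id], sites$start)
    }
    off <- pos - stop_tx[sites$gene_id]
    keep <- !is.na(off) & off >= window[1] & off <= window[2]
    sites <- sites[keep, , drop = FALSE]
  }
  n <- table(factor(sites$gene_id, levels = tr$gene_id))
  out <- data.frame(gene_id = tr$gene_id, n_sites = as.integer(n),
                    stringsAsFactors = FALSE)
  attr(out, "orphans") <- orphans
  out
}

#' Mean m6A sites per transcript in each expression bin
#'
#' Mean with a normal-approximation 95% confidence interval
#' (mean +- 1.96 SEM) per bin, optionally stratified by chromosome. Bins
#' with fewer than 2 transcripts report no CI; empty bins are omitted.
#'
#' @param counts data.frame from [count_sites_per_transcript()].
#' @param bins data.frame from [assign_bins()].
#' @param chromosome_map optional named vector gene -> chromosome; when
#'   given, per-chromosome profiles are returned in addition to the pooled
#'   one (`chromosome = "all"`).
#' @return data.frame: chromosome, bin, n, mean_sites, ci_lo, ci_hi.
#' @export
bin_profile <- function(counts, bins, chromosome_map = NULL) {
  d <- merge(counts, bins[c("gene_id", "bin")], by = "gene_id")
  d <- d[!is.na(d$bin), ]
  strata <- list(all = d)
  if (!is.null(chromosome_map)) {
    d$chromosome <- chromosome_map[d$gene_id]
    strata <- c(strata, split(d, d$chromosome))
  }
  out <- do.call(rbind, lapply(names(strata), function(nm) {
    s <- strata[[nm]]
    if (!nrow(s)) return(NULL)
    agg <- do.call(rbind, lapply(split(s$n_sites, s$bin), function(x) {
      m <- mean(x)
      sem <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
      c(n = length(x), mean_sites = m,
        ci_lo = m - 1.96 * sem, ci_hi = m + 1.96 * sem)
    }))
    data.frame(chromosome = nm, bin = as.integer(rownames(agg)), agg,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# per-bin chromosome/all means for the fold-change machinery
.bin_chrom_means <- function(d, bin_range) {
  d <- d[!is.na(d$bin) & d$bin %in% bin_range, ]
  all_mean <- tapply(d$n_sites, d$bin, mean)
  list(d = d, all_mean = all_mean)
}

#' Per-chromosome m6A fold change across expression bins
#'
#' Within each used expression bin, the mean number of m6A sites on a
#' chromosome's transcripts is divided by the mean over transcripts of all
#' chromosomes; the chromosome summary is the arithmetic mean of per-bin
#' log2 fold changes. The autosome-versus-X class difference is tested by a
#' two-tailed Wald test on the class coefficient of a negative-binomial GLM
#' with bin as categorical covariate. Per-chromosome bootstrap confidence
#' intervals on the summary resample transcripts within chromosome x bin.
#'
#' @param counts data.frame from [count_sites_per_transcript()].
#' @param bins data.frame from [assign_bins()].
#' @param chromosome_map named vector gene -> chromosome.
#' @param bin_range bins used (default 3:8, the intermediate-expression
#'   bins).
#' @param n_boot bootstrap replicates for the summary CI (0 disables).
#' @param conf_level confidence level of the bootstrap interval.
#' @param seed RNG seed for the bootstrap.
#' @param x_aliases chromosome names treated as X.
#' @return list with `per_bin` (chromosome, bin, n, fc, log2fc), `summary`
#'   (chromosome, n_bins, summary_log2fc, ci_lo, ci_hi), `skipped`
#'   (chromosome/bin combinations with no transcripts) and `class_test`
#'   (NB-GLM Wald estimate and p for X vs autosomes).
#' @export
chrom_fold_change <- function(counts, bins, chromosome_map, bin_range = 3:8,
                              n_boot = 200, conf_level = 0.95, seed = 1,
                              x_aliases = c("X", "chrX")) {
  d <- merge(counts, bins[c("gene_id", "bin")], by = "gene_id")
  d$chromosome <- chromosome_map[d$gene_id]
  d <- d[!is.na(d$chromosome), ]
  bm <- .bin_chrom_means(d, bin_range)
  d <- bm$d
  if (!nrow(d)) abort("no transcripts in the requested bins")

  summarize <- function(dd, all_mean) {
    cm <- tapply(dd$n_sites, list(dd$chromosome, dd$bin), mean)
    nn <- table(dd$chromosome, dd$bin)
    fc <- sweep(cm, 2, all_mean[colnames(cm)], "/")
    per_bin <- data.frame(
      chromosome = rep(rownames(fc), ncol(fc)),
      bin = rep(as.integer(colnames(fc)), each = nrow(fc)),
      n = as.integer(nn), fc = as.numeric(fc),
      log2fc = as.numeric(log2(fc)), stringsAsFactors = FALSE)
    summ <- tapply(per_bin$log2fc, per_bin$chromosome,
                   function(x) mean(x[is.finite(x)]))
    list(per_bin = per_bin, summary = summ)
  }
  full <- summarize(d, bm$all_mean)
  per_bin <- full$per_bin[!is.na(full$per_bin$fc), ]
  skipped <- full$per_bin[is.na(full$per_bin$fc),
                          c("chromosome", "bin"), drop = FALSE]

  chroms <- sort(unique(d$chromosome))
  ci <- matrix(NA_real_, length(chroms), 2,
               dimnames = list(chroms, c("lo", "hi")))
  if (n_boot > 0) {
    set.seed(derive_seed(seed, "chrom_fc_boot"))
    strata <- split(seq_len(nrow(d)), list(d$chromosome, d$bin), drop = TRUE)
    boots <- matrix(NA_real_, n_boot, length(chroms),
                    dimnames = list(NULL, chroms))
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(strata, function(ix)
        ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
      db <- d[idx, ]
      am <- tapply(db$n_sites, db$bin, mean)
      sb <- summarize(db, am)$summary
      boots[b, names(sb)] <- sb
    }
    a <- (1 - conf_level) / 2
    ci <- t(apply(boots, 2, stats::quantile, probs = c(a, 1 - a),
                  na.rm = TRUE))
  }
  summary_df <- data.frame(
    chromosome = chroms,
    n_bins = as.integer(table(per_bin$chromosome)[chroms]),
    summary_log2fc = as.numeric(full$summary[chroms]),
    ci_lo = ci[chroms, 1], ci_hi = ci[chroms, 2],
    row.names = NULL, stringsAsFactors = FALSE)

  klass <- chromosome_class(d$chromosome, x_aliases)
  class_test <- tryCatch({
    fit <- suppressWarnings(
      MASS::glm.nb(n_sites ~ factor(bin) + klass,
                   data = data.frame(n_sites = d$n_sites, bin = d$bin,
                                     klass = klass)))
    co <- summary(fit)$coefficients
    data.frame(term = "classX", estimate = unname(co["klassX", "Estimate"]),
               z = unname(co["klassX", "z value"]),
               p = unname(co["klassX", "Pr(>|z|)"]),
               stringsAsFactors = FALSE)
  }, error = function(e)
    data.frame(term = "classX", estimate = NA_real_, z = NA_real_,
               p = NA_real_, stringsAsFactors = FALSE))

  list(per_bin = per_bin, summary = summary_df, skipped = skipped,
       class_test = class_test)
}

#' Subsampled per-chromosome m6A fold change
#'
#' To control for unequal transcript numbers per chromosome, `n_per_bin`
#' genes are drawn (without replacement) per chromosome and used bin, the
#' per-chromosome fold-change summary is computed on the subsample, and the
#' procedure is repeated `reps` times. Chromosomes with fewer than
#' `n_per_bin` transcripts in a bin contribute all they have and are
#' flagged.
#'
#' @param counts,bins,chromosome_map as in [chrom_fold_change()].
#' @param n_per_bin genes sampled per chromosome per bin.
#' @param bin_range bins used (default 3:5).
#' @param reps number of repetitions.
#' @param seed RNG seed.
#' @return list with `distribution` (chromosome, median, q25, q75 of the
#'   summary log2 fold change over reps), `samples` (reps x chromosome
#'   matrix) and `short` (chromosome/bin strata smaller than `n_per_bin`).
#' @export
subsample_fold_change <- function(counts, bins, chromosome_map,
                                  n_per_bin = 30, bin_range = 3:5,
                                  reps = 100, seed = 1) {
  d <- merge(counts, bins[c("gene_id", "bin")], by = "gene_id")
  d$chromosome <- chromosome_map[d$gene_id]
  d <- d[!is.na(d$chromosome) & !is.na(d$bin) & d$bin %in% bin_range, ]
  strata <- split(seq_len(nrow(d)), list(d$chromosome, d$bin), drop = TRUE)
  sizes <- lengths(strata)
  short <- data.frame(stratum = names(sizes)[sizes < n_per_bin],
                      n_available = as.integer(sizes[sizes < n_per_bin]),
                      stringsAsFactors = FALSE)
  chroms <- sort(unique(d$chromosome))
  set.seed(derive_seed(seed, "subsample_fc"))
  samples <- matrix(NA_real_, reps, length(chroms),
                    dimnames = list(NULL, chroms))
  for (r in seq_len(reps)) {
    idx <- unlist(lapply(strata, function(ix)
      ix[sample.int(length(ix), min(n_per_bin, length(ix)))]),
      use.names = FALSE)
    db <- d[idx, ]
    am <- tapply(db$n_sites, db$bin, mean)
    cm <- tapply(db$n_sites, list(db$chromosome, db$bin), mean)
    fc <- log2(sweep(cm, 2, am[colnames(cm)], "/"))
    summ <- apply(fc, 1, function(x) mean(x[is.finite(x)]))
    samples[r, names(summ)] <- summ
  }
  qs <- t(apply(samples, 2, stats::quantile,
                probs = c(0.5, 0.25, 0.75), na.rm = TRUE))
  distribution <- data.frame(chromosome = rownames(qs),
                             median = qs[, 1], q25 = qs[, 2], q75 = qs[, 3],
                             row.names = NULL, stringsAsFactors = FALSE)
  list(distribution = distribution, samples = samples, short = short)
}

#' Fraction of GGACH motifs carrying a methylation site, per chromosome
#'
#' Among expressed transcripts, the number of motif occurrences overlapped
#' by an observed m6A site divided by the number of motif occurrences, per
#' chromosome. A site overlaps a motif when it falls within the motif's
#' 5-nt genomic span on the same gene.
#'
#' @param sites observed SiteSet data.frame (gene_id, start).
#' @param motif_positions motif table (gene_id, chromosome, gstart, gend) as
#'   from [scan_transcript_motifs()].
#' @param expressed_set gene ids considered expressed.
#' @return data.frame: chromosome, n_motifs, n_methylated, fraction (NA
#'   with flag where a chromosome has no motifs).
#' @export
fraction_motifs_methylated <- function(sites, motif_positions, expressed_set) {
  mot <- motif_positions[motif_positions$gene_id %in% expressed_set, ]
  st <- sites[sites$gene_id %in% expressed_set, ]
  key_hit <- paste(st$gene_id, st$start)
  hit <- logical(nrow(mot))
  if (nrow(mot)) {
    for (off in 0:4) {
      hit <- hit | (paste(mot$gene_id, mot$gstart + off) %in% key_hit)
    }
  }
  chroms <- sort(unique(mot$chromosome))
  n_mot <- table(factor(mot$chromosome, levels = chroms))
  n_met <- tapply(hit, factor(mot$chromosome, levels = chroms), sum)
  n_met[is.na(n_met)] <- 0
  data.frame(chromosome = chroms, n_motifs = as.integer(n_mot),
             n_methylated = as.integer(n_met),
             fraction = ifelse(n_mot > 0, as.numeric(n_met / n_mot),
                               NA_real_),
             undefined = as.integer(n_mot) == 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Length-normalized peak density ratio per chromosome
#'
#' Peak counts are divided by chromosome length and then by the median
#' length-normalized peak number over all chromosomes.
#'
#' @param peaks data.frame with a `chromosome` column (one row per peak).
#' @param chromosome_lengths named vector of chromosome lengths (> 0).
#' @return data.frame: chromosome, n_peaks, density, ratio.
#' @export
peak_density_ratio <- function(peaks, chromosome_lengths) {
  if (any(chromosome_lengths <= 0)) abort("chromosome lengths must be > 0")
  chroms <- names(chromosome_lengths)
  n <- table(factor(peaks$chromosome, levels = chroms))
  dens <- as.numeric(n) / chromosome_lengths
  data.frame(chromosome = chroms, n_peaks = as.integer(n),
             density = dens, ratio = dens / stats::median(dens),
             row.names = NULL, stringsAsFactors = FALSE)
}
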