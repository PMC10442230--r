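# Expression response to m6A depletion, stratified by chromosome:
# reference-gene normalization, per-gene log2 fold changes, per-chromosome
# summaries with a median-shift/IQR effect size, and X-to-autosome
# expression ratios with gene-level bootstrap inference.

#' Pick reference genes for normalization
#'
#' A seeded uniform sample of `n` genes that carry no m6A site but show
#' noticeable expression (RPKM above `min_rpkm`) — the alternative to
#' spike-in normalization.
#'
#' @param counts count matrix (defines the gene universe; rownames used).
#' @param site_counts named vector of m6A sites per gene (genes absent are
#'   treated as unmethylated only if present in the vector's names; missing
#'   genes are excluded from eligibility).
#' @param rpkm matrix or named vector of RPKM values (replicates averaged).
#' @param n number of reference genes.
#' @param min_rpkm expression floor for eligibility.
#' @param seed RNG seed.
#' @return character vector of `n` gene ids.
#' @export
pick_reference_genes <- function(counts, site_counts, rpkm, n = 100,
                                 min_rpkm = 10, seed = 1) {
  genes <- rownames(counts)
  if (is.matrix(rpkm)) rpkm <- rowMeans(rpkm)
  eligible <- genes[genes %in% names(site_counts) &
                      site_counts[genes] == 0 &
                      genes %in% names(rpkm) & rpkm[genes] > min_rpkm]
  if (length(eligible) < n)
    abort("only %d genes eligible as references (need %d): zero m6A sites and RPKM > %g",
          length(eligible), n, min_rpkm)
  set.seed(derive_seed(seed, "reference_genes"))
  sort(sample(eligible, n))
}

#' Median-of-ratios size factors on a reference gene set
#'
#' For each sample, the median over reference genes of the count divided by
#' that gene's geometric mean across samples (the DESeq-style estimator
#' restricted to the reference set). Genes with a zero geometric mean are
#' ignored.
#'
#' @param counts count matrix (genes x samples).
#' @param reference_genes gene ids to use.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts, reference_genes) {
  m <- counts[reference_genes, , drop = FALSE]
  gm <- apply(m, 1, geom_mean)
  use <- gm > 0
  if (!any(use)) abort("all reference genes have zero geometric mean")
  ratios <- sweep(m[use, , drop = FALSE], 1, gm[use], "/")
  sf <- apply(ratios, 2, stats::median)
  if (any(sf <= 0))
    abort("sample %s has a non-positive size factor (reference genes all zero?)",
          colnames(counts)[which(sf <= 0)[1]])
  sf
}

#' Per-gene log2 fold change between conditions
#'
#' Counts are divided by their size factors, averaged over replicates per
#' condition, and contrasted as
#' `log2((mean_trt + pseudocount) / (mean_ctrl + pseudocount))`.
#'
#' @param counts_ctrl,counts_trt count matrices with identical rownames.
#' @param factors_ctrl,factors_trt per-sample size factors.
#' @param pseudocount added to both normalized means.
#' @return data.frame: gene_id, mean_ctrl, mean_trt, log2fc.
#' @export
gene_log2fc <- function(counts_ctrl, counts_trt, factors_ctrl, factors_trt,
                        pseudocount = 0.5) {
  if (!identical(rownames(counts_ctrl), rownames(counts_trt)))
    abort("count matrices must share an identical gene set")
  if (any(factors_ctrl <= 0) || any(factors_trt <= 0))
    abort("size factors must be positive")
  norm_c <- sweep(counts_ctrl, 2, factors_ctrl, "/")
  norm_t <- sweep(counts_trt, 2, factors_trt, "/")
  mc <- rowMeans(norm_c)
  mt <- rowMeans(norm_t)
  data.frame(gene_id = rownames(counts_ctrl), mean_ctrl = mc, mean_trt = mt,
             log2fc = log2((mt + pseudocount) / (mc + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Median-shift effect size as percent of the average IQR
#'
#' `100 * (median(a) - median(b)) / ((IQR(a) + IQR(b)) / 2)`; antisymmetric
#' under swapping the groups and zero iff the medians are equal.
#'
#' @param a,b numeric vectors (conventionally autosomal and X log2 fold
#'   changes).
#' @return scalar percent effect size.
#' @export
effect_size_iqr <- function(a, b) {
  100 * (stats::median(a) - stats::median(b)) /
    ((stats::IQR(a) + stats::IQR(b)) / 2)
}

#' Chromosome-stratified response to m6A depletion
#'
#' Per-chromosome median log2 fold changes, empirical cumulative curves,
#' the autosome-minus-X effect size in percent of the average IQR, and a
#' two-tailed Wilcoxon rank-sum test X versus autosomes. Genes may be
#' excluded from the summaries by an expression floor (`min_rpkm` on
#' `rpkm`), matching the RPKM > 1 restriction used for chromosome-level
#' comparisons.
#'
#' @param log2fc data.frame from [gene_log2fc()] (gene_id, log2fc).
#' @param chromosome_map named vector gene -> chromosome.
#' @param rpkm optional matrix or named vector of RPKM values; with
#'   `min_rpkm`, genes at or below the floor are dropped (counted).
#' @param min_rpkm expression floor (default 1).
#' @param x_aliases chromosome names treated as X.
#' @return list with `per_gene`, `chromosome` (n and median log2fc per
#'   chromosome), `effect_size_pct`, `p_ranksum`, `n_dropped_floor`,
#'   `n_dropped_unmapped`, and `curves` (per-chromosome ecdf functions).
#' @export
chromosome_response <- function(log2fc, chromosome_map, rpkm = NULL,
                                min_rpkm = 1, x_aliases = c("X", "chrX")) {
  d <- log2fc
  d$chromosome <- chromosome_map[d$gene_id]
  n_unmapped <- sum(is.na(d$chromosome))
  d <- d[!is.na(d$chromosome), ]
  n_floor <- 0L
  if (!is.null(rpkm)) {
    if (is.matrix(rpkm)) rpkm <- rowMeans(rpkm)
    keep <- d$gene_id %in% names(rpkm) & rpkm[d$gene_id] > min_rpkm
    n_floor <- sum(!keep)
    d <- d[keep, ]
  }
  d$class <- chromosome_class(d$chromosome, x_aliases)
  if (any(table(d$class) < 2)) abort("need >= 2 genes in each class")

  chrom <- stats::aggregate(list(median_log2fc = d$log2fc),
                            by = list(chromosome = d$chromosome),
                            stats::median)
  chrom$n <- as.integer(table(d$chromosome)[chrom$chromosome])
  a <- d$log2fc[d$class == "autosome"]
  x <- d$log2fc[d$class == "X"]
  curves <- lapply(split(d$log2fc, d$chromosome), stats::ecdf)
  list(per_gene = d, chromosome = chrom,
       effect_size_pct = effect_size_iqr(a, x),
       p_ranksum = suppressWarnings(stats::wilcox.test(x, a))$p.value,
       n_dropped_floor = n_floor, n_dropped_unmapped = n_unmapped,
       curves = curves)
}

#' X-to-autosome expression ratio with bootstrap CI
#'
#' `rho = median(X-gene expression) / median(autosomal expression)` over
#' genes above `min_expr`, with a percentile bootstrap CI from resampling
#' genes within each group. Scale-invariant: rescaling all expression
#' values leaves rho unchanged.
#'
#' @param expression named vector of normalized expression values.
#' @param chromosome_map named vector gene -> chromosome.
#' @param min_expr expression floor applied to both groups.
#' @param n_boot bootstrap replicates.
#' @param conf_level CI level.
#' @param seed RNG seed.
#' @param x_aliases chromosome names treated as X.
#' @return list: rho, ci (length-2), n_x, n_autosome, boot (replicates).
#' @export
xa_expression_ratio <- function(expression, chromosome_map, min_expr = 1,
                                n_boot = 1000, conf_level = 0.95, seed = 1,
                                x_aliases = c("X", "chrX")) {
  genes <- names(expression)
  chrom <- chromosome_map[genes]
  keep <- !is.na(chrom) & expression > min_expr
  if (!any(keep)) abort("no genes above the expression floor")
  klass <- chromosome_class(chrom[keep], x_aliases)
  x <- expression[keep][klass == "X"]
  a <- expression[keep][klass == "autosome"]
  if (!length(x) || !length(a))
    abort("a chromosome class is empty after filtering")
  rho <- stats::median(x) / stats::median(a)
  set.seed(derive_seed(seed, "xa_ratio"))
  boot <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(x, replace = TRUE)) /
      stats::median(sample(a, replace = TRUE))
  }, 0)
  alpha <- (1 - conf_level) / 2
  list(rho = rho,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       n_x = length(x), n_autosome = length(a), boot = boot)
}

#' Compare X:A ratios between two conditions (paired bootstrap)
#'
#' The two conditions measure the same genes, so the bootstrap resamples
#' gene indices once per replicate and applies them to both conditions;
#' gene-level abundance variation then cancels from `delta = rho_trt -
#' rho_ctrl`, and only between-condition changes contribute. The two-sided
#' p-value is the tail mass of the paired bootstrap distribution on the
#' other side of zero.
#'
#' @param expr_ctrl,expr_trt named expression vectors on a common gene set.
#' @param chromosome_map named vector gene -> chromosome.
#' @param min_expr expression floor; a gene is kept if it exceeds the floor
#'   in the control condition (one common universe for both conditions).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @param x_aliases chromosome names treated as X.
#' @return list: rho_ctrl, rho_trt, delta, p_boot, ci_delta, n_x,
#'   n_autosome.
#' @export
xa_ratio_compare <- function(expr_ctrl, expr_trt, chromosome_map,
                             min_expr = 1, n_boot = 1000, seed = 1,
                             x_aliases = c("X", "chrX")) {
  genes <- intersect(names(expr_ctrl), names(expr_trt))
  chrom <- chromosome_map[genes]
  keep <- !is.na(chrom) & expr_ctrl[genes] > min_expr
  genes <- genes[keep]
  klass <- chromosome_class(chrom[keep], x_aliases)
  xg <- genes[klass == "X"]
  ag <- genes[klass == "autosome"]
  if (!length(xg) || !length(ag))
    abort("a chromosome class is empty after filtering")
  rho_of <- function(g_x, g_a, expr)
    stats::median(expr[g_x]) / stats::median(expr[g_a])
  rho_c <- rho_of(xg, ag, expr_ctrl)
  rho_t <- rho_of(xg, ag, expr_trt)
  delta <- rho_t - rho_c
  set.seed(derive_seed(seed, "xa_compare"))
  boot <- vapply(seq_len(n_boot), function(i) {
    bx <- sample(xg, replace = TRUE)
    ba <- sample(ag, replace = TRUE)
    rho_of(bx, ba, expr_trt) - rho_of(bx, ba, expr_ctrl)
  }, 0)
  p <- 2 * min(mean(boot >= 0), mean(boot <= 0))
  p <- min(max(p, 1 / n_boot), 1)
  list(rho_ctrl = rho_c, rho_trt = rho_t, delta = delta, p_boot = p,
       ci_delta = unname(stats::quantile(boot, c(0.025, 0.975))),
       n_x = length(xg), n_autosome = length(ag))
}

#' Median fold change by m6A burden bin
#'
#' Genes are grouped by their number of m6A sites into the bins 0, 1, 2 and
#' >= 3 (configurable) and the median log2 fold change reported per bin.
#'
#' @param log2fc data.frame from [gene_log2fc()].
#' @param m6a_counts named vector of sites per gene.
#' @param breaks upper-open burden bin starts (default `c(0, 1, 2, 3)`:
#'   bins 0, 1, 2, >= 3).
#' @return data.frame: burden (label), n, median_log2fc; empty bins are
#'   omitted with attribute `empty_bins`.
#' @export
fc_vs_m6a_burden <- function(log2fc, m6a_counts, breaks = c(0, 1, 2, 3)) {
  genes <- intersect(log2fc$gene_id, names(m6a_counts))
  fc <- stats::setNames(log2fc$log2fc, log2fc$gene_id)[genes]
  cnt <- m6a_counts[genes]
  labels <- c(as.character(breaks[-length(breaks)]),
              paste0(">=", breaks[length(breaks)]))
  bin <- findInterval(cnt, breaks)          # 1..length(breaks)
  bin[cnt < breaks[1]] <- NA
  tab <- table(factor(bin, levels = seq_along(labels)))
  med <- tapply(fc, factor(bin, levels = seq_along(labels)), stats::median)
  out <- data.frame(burden = labels, n = as.integer(tab),
                    median_log2fc = as.numeric(med),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "empty_bins") <- labels[out$n == 0]
  out[out$n > 0, ]
}

#' Per-chromosome fold-change trajectories over a depletion time course
#'
#' Applies [chromosome_response()] at every time point and reports the
#' earliest time at which the X median leaves the autosomal min-max band.
#'
#' @param fc_tables named list (by time label, coercible to numeric hours)
#'   of [gene_log2fc()] outputs.
#' @param chromosome_map named vector gene -> chromosome.
#' @param ... passed to [chromosome_response()].
#' @return list with `trajectory` (time_h, chromosome, median_log2fc, n),
#'   `x_separated` (logical per time point), `first_separation_h` (NA if
#'   never), and `missing` (time points whose table lacked a chromosome).
#' @export
timecourse_response <- function(fc_tables, chromosome_map, ...) {
  if (length(fc_tables) < 2) abort("need >= 2 time points")
  times <- as.numeric(names(fc_tables))
  if (any(is.na(times))) abort("fc_tables names must be numeric hours")
  all_chroms <- sort(unique(chromosome_map))
  rows <- list()
  sep <- stats::setNames(logical(length(times)), names(fc_tables))
  missing <- list()
  for (i in seq_along(fc_tables)) {
    cr <- chromosome_response(fc_tables[[i]], chromosome_map, ...)
    ch <- cr$chromosome
    ch$time_h <- times[i]
    rows[[i]] <- ch
    absent <- setdiff(all_chroms, ch$chromosome)
    if (length(absent))
      missing[[names(fc_tables)[i]]] <- absent
    x_med <- ch$median_log2fc[chromosome_class(ch$chromosome) == "X"]
    a_med <- ch$median_log2fc[chromosome_class(ch$chromosome) == "autosome"]
    sep[i] <- length(x_med) == 1 &&
      (x_med < min(a_med) || x_med > max(a_med))
  }
  trajectory <- do.call(rbind, rows)
  first <- if (any(sep)) times[which(sep)[1]] else NA_real_
  list(trajectory = trajectory, x_separated = sep,
       first_separation_h = first, missing = missing)
}
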