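#' Generate expression tables for the synthetic transcriptome
#'
#' True per-gene abundances are lognormal TPM; per-replicate counts are
#' negative-binomial with mean proportional to TPM x transcript length (kb)
#' x sequencing depth, and TPM/RPKM tables are recomputed from the counts so
#' the three tables are mutually consistent, as they would be for real data.
#'
#' @param transcriptome result of [gen_transcriptome()].
#' @param config a [synth_config()].
#' @param n_replicates number of replicates (default `config$n_replicates`).
#' @return list with `true_tpm` (named vector), `counts`, `tpm`, `rpkm`
#'   (gene x replicate matrices) and `length_kb` (named vector).
#' @export
gen_expression <- function(transcriptome, config,
                           n_replicates = config$n_replicates) {
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, "expression"))
  tr <- transcriptome$models$transcripts
  n <- nrow(tr)
  true_tpm <- stats::rlnorm(n, config$expression_params[["meanlog"]],
                            config$expression_params[["sdlog"]])
  names(true_tpm) <- tr$gene_id
  len_kb <- tr$spliced_length / 1000
  names(len_kb) <- tr$gene_id
  mu <- true_tpm * len_kb * config$library_scale
  size <- 1 / config$nb_dispersion
  counts <- matrix(stats::rnbinom(n * n_replicates, mu = rep(mu, n_replicates),
                                  size = size),
                   nrow = n, ncol = n_replicates,
                   dimnames = list(tr$gene_id,
                                   paste0("rep", seq_len(n_replicates))))
  # the mini-genome carries only `transcriptome_fraction` of a full
  # library's reads; scale so TPM/RPKM sit on the usual per-million scale
  frac <- config$transcriptome_fraction
  lib <- colSums(counts) / frac
  rate <- counts / len_kb                       # reads per kb
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6 * frac
  rpkm <- sweep(rate, 2, lib / 1e6, "/")
  list(true_tpm = true_tpm, counts = counts, tpm = tpm, rpkm = rpkm,
       length_kb = len_kb)
}

#' Place observed m6A sites on planted GGACH motifs
#'
#' Each GGACH motif is methylated independently with `methylation_prob`
#' (scaled by `x_methylation_scale` on the X); methylated motifs are then
#' *observed* with a probability that depends on the gene's expression bin,
#' emulating the abundance dependence of site detection in single-nucleotide
#' m6A mapping. The reported site position is the methylated adenosine (the
#' third base of GGACH).
#'
#' @param transcriptome result of [gen_transcriptome()].
#' @param expression result of [gen_expression()] (supplies TPM for bins).
#' @param config a [synth_config()].
#' @return list with `sites` (observed SiteSet data.frame: chromosome,
#'   start, end, strand, gene_id, tx_pos), `methylated` (all truly
#'   methylated motifs, same layout) and `truth` columns `n_meth_true`,
#'   `n_sites_observed` (named vectors by gene).
#' @export
gen_m6a_sites <- function(transcriptome, expression, config) {
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, "m6a_sites"))
  mot <- transcriptome$motifs
  tr <- transcriptome$models$transcripts
  gene_ids <- tr$gene_id

  p <- rep(config$methylation_prob, nrow(mot))
  p[mot$chromosome == "chrX"] <- p[mot$chromosome == "chrX"] *
    config$x_methylation_scale
  meth <- stats::runif(nrow(mot)) < p

  bins <- assign_bins(expression$tpm)
  bin_of <- bins$bin
  names(bin_of) <- bins$gene_id
  bin_idx <- bin_of[mot$gene_id]
  bin_idx[is.na(bin_idx)] <- 1L              # sub-floor expression: outer bin
  det_p <- config$detection_curve[bin_idx]
  observed <- meth & (stats::runif(nrow(mot)) < det_p)

  site_frame <- function(keep) {
    m <- mot[keep, , drop = FALSE]
    a_tx <- m$tx_start + 2L                  # the A of GGACH
    gpos <- tx_to_genomic(transcriptome$models, m$transcript_id, a_tx)
    data.frame(chromosome = m$chromosome, start = as.integer(gpos),
               end = as.integer(gpos + 1L), strand = m$strand,
               gene_id = m$gene_id, tx_pos = a_tx,
               stringsAsFactors = FALSE)
  }
  n_meth <- tapply(meth, factor(mot$gene_id, levels = gene_ids), sum)
  n_obs <- tapply(observed, factor(mot$gene_id, levels = gene_ids), sum)
  n_meth[is.na(n_meth)] <- 0L
  n_obs[is.na(n_obs)] <- 0L
  list(sites = site_frame(observed), methylated = site_frame(meth),
       n_meth_true = as.integer(n_meth), n_sites_observed = as.integer(n_obs))
}
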