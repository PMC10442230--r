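#' Run the full synthetic-data analysis pipeline
#'
#' Generates a synthetic dataset and runs every analysis stage over it in
#' dependency order (synth, then half-life fitting, m6A landscape, dosage
#' response and motif analyses), collecting per-stage summaries, filter
#' ledgers and the config echo into one report. All thresholds default to
#' the published values (T-coverage > 100, half-life bounds 0.67-18 h,
#' residual s.e. <= 0.3, TPM bins 3-8, 100 reference genes at RPKM > 10,
#' RPKM > 1 summary floor). A stage failure aborts before any downstream
#' stage runs.
#'
#' @param config a [synth_config()]; its seed drives every stage.
#' @param stages subset of `c("slamfit", "m6amap", "dosage", "motifs")`.
#' @param outdir optional directory; when given, the synthetic dataset and
#'   the JSON report are written there.
#' @param n_boot bootstrap replicates used by the m6amap/dosage stages.
#' @return report list (config echo, per-stage summaries); invisibly also
#'   the full objects in attribute `"objects"`.
#' @export
run_pipeline <- function(config = synth_config(),
                         stages = c("slamfit", "m6amap", "dosage", "motifs"),
                         outdir = NULL, n_boot = 200) {
  stages <- match.arg(stages, several.ok = TRUE)
  sim <- simulate_dataset(config)
  chrom_map <- stats::setNames(sim$truth$chromosome, sim$truth$gene_id)
  site_counts <- count_sites_per_transcript(sim$sites, sim$models)
  m6a_vec <- stats::setNames(site_counts$n_sites, site_counts$gene_id)
  report <- list(config = unclass(config), seed = config$seed,
                 package_version = as.character(utils::packageVersion("m6Adosage")),
                 n_genes = nrow(sim$truth))
  objects <- list(sim = sim)

  if ("slamfit" %in% stages) {
    norm <- correct_and_normalize(sim$slam$labeled, sim$slam$unlabeled)
    fits <- fit_decay(norm$series)
    filt <- filter_fits(fits)
    kept <- split(filt$kept, filt$kept$condition)
    contrast <- halflife_contrast(kept$ctrl, kept$trt, m6a_vec, chrom_map)
    report$slamfit <- list(
      n_series = nrow(fits), ledger = as.list(filt$ledger),
      n_excluded_normalization = nrow(norm$excluded),
      median_t_half_ctrl = stats::median(kept$ctrl$t_half),
      median_t_half_trt = stats::median(kept$trt$t_half),
      groups = contrast$groups, tests = contrast$tests)
    objects$slamfit <- list(norm = norm, fits = fits, filt = filt,
                            contrast = contrast)
  }
  if ("m6amap" %in% stages) {
    bins <- assign_bins(sim$expression$tpm)
    profile <- bin_profile(site_counts, bins, chrom_map)
    fc <- chrom_fold_change(site_counts, bins, chrom_map,
                            n_boot = n_boot, seed = config$seed)
    sub <- subsample_fold_change(site_counts, bins, chrom_map,
                                 seed = config$seed)
    frac <- fraction_motifs_methylated(
      sim$sites, sim$motifs,
      expressed_set = bins$gene_id[!is.na(bins$bin)])
    report$m6amap <- list(
      n_binned = sum(!is.na(bins$bin)), profile = profile,
      chrom_summary = fc$summary, class_test = fc$class_test,
      subsample = sub$distribution, fraction_methylated = frac)
    objects$m6amap <- list(bins = bins, fc = fc, sub = sub, frac = frac)
  }
  if ("dosage" %in% stages) {
    cc <- sim$counts
    refs <- pick_reference_genes(cc$counts_ctrl, m6a_vec,
                                 sim$expression$rpkm, seed = config$seed)
    sf_c <- size_factors(cc$counts_ctrl, refs)
    sf_t <- size_factors(cc$counts_trt, refs)
    fc <- gene_log2fc(cc$counts_ctrl, cc$counts_trt, sf_c, sf_t)
    gene_rows <- fc$gene_id %in% sim$truth$gene_id
    resp <- chromosome_response(fc[gene_rows, ], chrom_map,
                                rpkm = sim$expression$rpkm)
    norm_c <- rowMeans(sweep(cc$counts_ctrl, 2, sf_c, "/"))
    norm_t <- rowMeans(sweep(cc$counts_trt, 2, sf_t, "/"))
    xa <- xa_ratio_compare(norm_c[sim$truth$gene_id],
                           norm_t[sim$truth$gene_id], chrom_map,
                           n_boot = max(n_boot, 1000), seed = config$seed)
    burden <- fc_vs_m6a_burden(fc[gene_rows, ], m6a_vec)
    report$dosage <- list(
      reference_genes = refs, size_factors_ctrl = sf_c,
      size_factors_trt = sf_t,
      chromosome = resp$chromosome, effect_size_pct = resp$effect_size_pct,
      p_ranksum = resp$p_ranksum,
      xa = xa[c("rho_ctrl", "rho_trt", "delta", "p_boot")],
      burden = burden)
    objects$dosage <- list(fc = fc, resp = resp, xa = xa, burden = burden)
  }
  if ("motifs" %in% stages) {
    canon <- select_canonical_isoforms(sim$models)
    dens3 <- region_density(canon$models, sim$tx_seq, "GGACH", "utr3")
    klass <- chromosome_class(dens3$chromosome)
    ok <- !is.na(dens3$density_per_kb)
    report$motifs <- list(
      n_genes_dropped = canon$n_genes_dropped,
      mean_density_autosome =
        mean(dens3$density_per_kb[ok & klass == "autosome"]),
      mean_density_X = mean(dens3$density_per_kb[ok & klass == "X"]))
    objects$motifs <- list(canon = canon, dens3 = dens3)
  }
  if (!is.null(outdir)) {
    write_dataset(sim, outdir)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
  }
  attr(report, "objects") <- objects
  report
}
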