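#' Configuration for the synthetic mini-transcriptome generator
#'
#' Builds and validates the parameter set that drives every synthetic-data
#' generator in the package. The defaults describe a "mini-mouse": 19
#' autosomes plus one X chromosome, lognormal expression, negative-binomial
#' counts, GGACH motifs planted at 3.1 per kb of 3'UTR on autosomes and 1.7
#' per kb on the X (the observed mouse densities), per-motif methylation with
#' expression-dependent site detection, first-order decay SLAM-seq conversion
#' time courses with an s4U incorporation rate of 1.36e-2 at chase onset over
#' a background of 1e-3, and a treatment (m6A depletion) that up-regulates
#' autosomal genes in proportion to their m6A burden while leaving the X and
#' spike-ins untouched.
#'
#' @param n_chromosomes number of chromosomes; the last one is labeled "chrX".
#' @param genes_per_chromosome genes simulated on each chromosome.
#' @param region_length_params named list of `c(meanlog, sdlog)` lognormal
#'   parameters (nt) for regions `utr5`, `cds`, `utr3`.
#' @param ggach_density_autosome GGACH motifs per kb of 3'UTR on autosomes.
#' @param ggach_density_X GGACH motifs per kb of 3'UTR on the X chromosome.
#' @param ggach_density_cds_scale CDS planting density relative to the 3'UTR
#'   density of the same chromosome class (X depletion applies to CDS too).
#' @param ggach_density_utr5 motifs per kb planted in 5'UTRs on every
#'   chromosome (no X depletion; 5'UTR densities do not differ in mouse).
#' @param methylation_prob probability that a planted GGACH is methylated.
#' @param x_methylation_scale multiplier on `methylation_prob` for X genes
#'   (default 1: the X deficit arises from motif density, as in mouse).
#' @param detection_curve length-12 vector of per-expression-bin detection
#'   probabilities for methylated sites (bins as in [assign_bins()]).
#' @param halflife_base `c(meanlog, sdlog)` lognormal parameters of the
#'   unmethylated half-life in hours.
#' @param destabilization_per_site multiplicative half-life factor per
#'   methylated site in the control condition (< 1 destabilizes).
#' @param destabilization_cap maximum number of sites contributing to
#'   destabilization (and to the treatment response).
#' @param background_conversion T-to-C conversion rate without s4U labeling.
#' @param t0_conversion conversion rate at chase onset after 24 h labeling.
#' @param chase_timepoints hours of uridine chase; strictly increasing,
#'   starting at 0.
#' @param coverage_params `c(mu, size)` negative-binomial parameters of the
#'   per-UTR, per-time-point T coverage.
#' @param expression_params `c(meanlog, sdlog)` lognormal TPM parameters.
#' @param transcriptome_fraction fraction of the sequencing library carried
#'   by the simulated genes: the mini-genome stands in for a slice of a
#'   full (~10x larger) transcriptome, so recomputed TPM/RPKM are scaled by
#'   this factor to keep them on the usual per-million scale.
#' @param nb_dispersion count-model dispersion for genes.
#' @param spikein_dispersion count-model dispersion for spike-ins (technical
#'   only, hence smaller).
#' @param library_scale expected counts per (TPM x kb) unit.
#' @param beta_treatment log2 fold change per (capped) m6A site under
#'   depletion, applied on autosomes.
#' @param treatment_on_X apply the burden effect on X genes too (default
#'   FALSE, matching the observed autosome-restricted response).
#' @param treated_halflife_ratio optional fixed treated/control half-life
#'   ratio for truly methylated transcripts; overrides the per-site
#'   destabilization-removal model when not `NULL` (used for controlled
#'   injection experiments).
#' @param n_spikeins number of spike-in species in count tables.
#' @param n_replicates RNA-seq replicates per condition.
#' @param slam_replicates labeled SLAM-seq replicates per condition.
#' @param seed master integer seed; identical configs produce byte-identical
#'   outputs.
#' @return object of class `synth_config` (a validated named list).
#' @export
synth_config <- function(n_chromosomes = 20,
                         genes_per_chromosome = 100,
                         region_length_params = list(
                           utr5 = c(meanlog = log(150), sdlog = 0.35),
                           cds = c(meanlog = log(1200), sdlog = 0.40),
                           utr3 = c(meanlog = log(1000), sdlog = 0.50)),
                         ggach_density_autosome = 3.1,
                         ggach_density_X = 1.7,
                         ggach_density_cds_scale = 0.6,
                         ggach_density_utr5 = 1.0,
                         methylation_prob = 0.25,
                         x_methylation_scale = 1,
                         detection_curve = c(0.05, 0.15, 0.30, 0.50, 0.70,
                                             0.80, 0.85, 0.90, 0.90, 0.90,
                                             0.90, 0.90),
                         halflife_base = c(meanlog = log(3.5), sdlog = 0.45),
                         destabilization_per_site = 1 / 1.08,
                         destabilization_cap = 5,
                         background_conversion = 1e-3,
                         t0_conversion = 1.36e-2,
                         chase_timepoints = c(0, 0.5 * 1.5^(0:7), 12),
                         coverage_params = c(mu = 10000, size = 20),
                         expression_params = c(meanlog = log(20), sdlog = 1.3),
                         transcriptome_fraction = 0.1,
                         nb_dispersion = 0.02,
                         spikein_dispersion = 0.005,
                         library_scale = 5,
                         beta_treatment = 0.1,
                         treatment_on_X = FALSE,
                         treated_halflife_ratio = NULL,
                         n_spikeins = 92,
                         n_replicates = 3,
                         slam_replicates = 3,
                         seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    region_length_params = region_length_params,
    ggach_density_autosome = ggach_density_autosome,
    ggach_density_X = ggach_density_X,
    ggach_density_cds_scale = ggach_density_cds_scale,
    ggach_density_utr5 = ggach_density_utr5,
    methylation_prob = methylation_prob,
    x_methylation_scale = x_methylation_scale,
    detection_curve = detection_curve,
    halflife_base = halflife_base,
    destabilization_per_site = destabilization_per_site,
    destabilization_cap = as.integer(destabilization_cap),
    background_conversion = background_conversion,
    t0_conversion = t0_conversion,
    chase_timepoints = chase_timepoints,
    coverage_params = coverage_params,
    expression_params = expression_params,
    transcriptome_fraction = transcriptome_fraction,
    nb_dispersion = nb_dispersion,
    spikein_dispersion = spikein_dispersion,
    library_scale = library_scale,
    beta_treatment = beta_treatment,
    treatment_on_X = isTRUE(treatment_on_X),
    treated_halflife_ratio = treated_halflife_ratio,
    n_spikeins = as.integer(n_spikeins),
    n_replicates = as.integer(n_replicates),
    slam_replicates = as.integer(slam_replicates),
    seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Validate a synth_config
#'
#' @param cfg a `synth_config`.
#' @return the config, invisibly; errors on any violated invariant.
#' @export
validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_chromosomes < 2) abort("need at least 1 autosome plus X")
  if (cfg$genes_per_chromosome < 1) abort("genes_per_chromosome must be >= 1")
  for (r in c("utr5", "cds", "utr3")) {
    p <- cfg$region_length_params[[r]]
    if (is.null(p) || !all(is.finite(p)))
      abort("region_length_params$%s missing or non-finite", r)
    if (exp(p[["meanlog"]]) < 1)
      abort("zero-length region requested for %s", r)
  }
  dens <- c(cfg$ggach_density_autosome, cfg$ggach_density_X,
            cfg$ggach_density_utr5)
  if (any(dens < 0)) abort("motif densities must be >= 0")
  probs <- c(cfg$methylation_prob, cfg$detection_curve)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0,1]")
  if (length(cfg$detection_curve) != 12)
    abort("detection_curve must have one entry per expression bin (12)")
  rates <- c(cfg$background_conversion, cfg$t0_conversion)
  if (any(rates <= 0 | rates >= 1)) abort("conversion rates must be in (0,1)")
  tp <- cfg$chase_timepoints
  if (length(tp) < 2 || tp[1] != 0 || any(diff(tp) <= 0))
    abort("chase_timepoints must start at 0 and increase strictly")
  if (cfg$transcriptome_fraction <= 0 || cfg$transcriptome_fraction > 1)
    abort("transcriptome_fraction must lie in (0,1]")
  if (cfg$x_methylation_scale < 0 || cfg$x_methylation_scale > 1)
    abort("x_methylation_scale must lie in [0,1]")
  if (!is.null(cfg$treated_halflife_ratio) &&
      cfg$treated_halflife_ratio <= 0)
    abort("treated_halflife_ratio must be positive")
  invisible(cfg)
}

#' Chromosome names of a synth_config
#' @param cfg a `synth_config`.
#' @return character vector, `chr1 ... chr<k-1>, chrX`.
#' @export
synth_chromosomes <- function(cfg) {
  c(paste0("chr", seq_len(cfg$n_chromosomes - 1L)), "chrX")
}
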