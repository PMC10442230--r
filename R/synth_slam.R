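#' Assign true half-lives under control and m6A-depleted conditions
#'
#' In the control condition each truly methylated site shortens the base
#' half-life multiplicatively (`destabilization_per_site`, capped at
#' `destabilization_cap` sites); m6A depletion removes that destabilization,
#' so treated half-lives revert to the base value. When
#' `config$treated_halflife_ratio` is set, the treated half-life of
#' methylated transcripts is instead exactly `ratio x control` (controlled
#' injection for recovery experiments).
#'
#' @param truth ground-truth skeleton from [gen_transcriptome()].
#' @param n_meth_true integer vector of truly methylated sites per gene,
#'   aligned with `truth`.
#' @param config a [synth_config()].
#' @return `truth` with columns `n_meth_true`, `t_half_ctrl`, `t_half_trt`,
#'   `k_ctrl`, `k_trt` appended.
#' @export
assign_halflives <- function(truth, n_meth_true, config) {
  stopifnot(length(n_meth_true) == nrow(truth))
  m <- pmin(n_meth_true, config$destabilization_cap)
  t_ctrl <- truth$t_half_base * config$destabilization_per_site^m
  if (is.null(config$treated_halflife_ratio)) {
    t_trt <- truth$t_half_base
  } else {
    t_trt <- ifelse(n_meth_true > 0,
                    t_ctrl * config$treated_halflife_ratio, t_ctrl)
  }
  truth$n_meth_true <- as.integer(n_meth_true)
  truth$t_half_ctrl <- t_ctrl
  truth$t_half_trt <- t_trt
  truth$k_ctrl <- log(2) / t_ctrl
  truth$k_trt <- log(2) / t_trt
  truth
}

#' Simulate SLAM-seq conversion time courses
#'
#' For every 3'UTR (one per gene), condition, replicate and chase time point,
#' T coverage is drawn negative-binomially and the T-to-C conversion count
#' binomially with success rate
#' `background + (t0_conversion - background) * 2^(-t / t_half)`.
#' Unlabeled control profiles (no s4U) convert at the background rate only.
#'
#' @param transcriptome result of [gen_transcriptome()].
#' @param truth truth table carrying `t_half_ctrl` / `t_half_trt` (see
#'   [assign_halflives()]).
#' @param config a [synth_config()].
#' @param conditions condition labels; each uses the matching
#'   `t_half_<condition>` truth column.
#' @return list with `labeled` and `unlabeled` conversion tables (columns
#'   utr_id, condition, replicate, time_h, t_coverage, tc_count).
#' @export
gen_slam_profiles <- function(transcriptome, truth, config,
                              conditions = c("ctrl", "trt")) {
  validate_synth_config(config)
  if (length(config$chase_timepoints) == 0)
    abort("chase_timepoints must not be empty")
  set.seed(derive_seed(config$seed, "slam"))
  tp <- config$chase_timepoints
  bg <- config$background_conversion
  r0 <- config$t0_conversion
  mu <- config$coverage_params[["mu"]]
  size <- config$coverage_params[["size"]]
  reps <- seq_len(config$slam_replicates)

  one_block <- function(cond, rate_fun) {
    grid <- expand.grid(utr_id = truth$gene_id, replicate = reps,
                        time_h = tp, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    t_half <- truth[[paste0("t_half_", cond)]]
    names(t_half) <- truth$gene_id
    rate <- rate_fun(t_half[grid$utr_id], grid$time_h)
    cov <- stats::rnbinom(nrow(grid), mu = mu, size = size)
    tc <- stats::rbinom(nrow(grid), cov, rate)
    data.frame(utr_id = grid$utr_id, condition = cond,
               replicate = grid$replicate, time_h = grid$time_h,
               t_coverage = cov, tc_count = tc, stringsAsFactors = FALSE)
  }
  labeled <- do.call(rbind, lapply(conditions, function(cond)
    one_block(cond, function(th, t) bg + (r0 - bg) * 2^(-t / th))))
  unlabeled <- do.call(rbind, lapply(conditions, function(cond)
    one_block(cond, function(th, t) rep(bg, length(t)))))
  rownames(labeled) <- rownames(unlabeled) <- NULL
  list(labeled = labeled, unlabeled = unlabeled)
}

#' Simulate paired control / m6A-depleted RNA-seq count matrices
#'
#' Depleted-condition expected counts are multiplied by
#' `2^(beta_treatment * min(m6A count, cap))` for autosomal genes (and X
#' genes too when `treatment_on_X`); spike-in rows share identical expected
#' counts in both conditions with technical-scale dispersion.
#'
#' @param expression result of [gen_expression()].
#' @param truth truth table carrying `n_meth_true` (see
#'   [assign_halflives()]).
#' @param config a [synth_config()].
#' @return list with `counts_ctrl`, `counts_trt` (gene+spike-in x replicate
#'   matrices), `true_log2fc` (named vector incl. spike-ins, exactly 0 for
#'   spike-ins), `spikein_ids`, and `rpkm_ctrl` for reference-gene picking.
#' @export
gen_treatment_counts <- function(expression, truth, config) {
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, "treatment"))
  n <- nrow(truth)
  reps <- config$n_replicates
  mu_ctrl <- expression$true_tpm[truth$gene_id] *
    expression$length_kb[truth$gene_id] * config$library_scale
  burden <- pmin(truth$n_meth_true, config$destabilization_cap)
  affected <- truth$class == "autosome" | config$treatment_on_X
  log2fc <- ifelse(affected, config$beta_treatment * burden, 0)
  mu_trt <- mu_ctrl * 2^log2fc

  draw <- function(mu, size, nrep, ids) {
    m <- matrix(stats::rnbinom(length(mu) * nrep, mu = rep(mu, nrep),
                               size = size),
                nrow = length(mu), ncol = nrep,
                dimnames = list(ids, paste0("rep", seq_len(nrep))))
    m
  }
  size_g <- 1 / config$nb_dispersion
  counts_ctrl <- draw(mu_ctrl, size_g, reps, truth$gene_id)
  counts_trt <- draw(mu_trt, size_g, reps, truth$gene_id)

  spike_ids <- sprintf("spike_%03d", seq_len(config$n_spikeins))
  if (config$n_spikeins > 0) {
    mu_sp <- stats::rlnorm(config$n_spikeins, log(500), 1)
    size_sp <- 1 / config$spikein_dispersion
    sp_ctrl <- draw(mu_sp, size_sp, reps, spike_ids)
    sp_trt <- draw(mu_sp, size_sp, reps, spike_ids)
    counts_ctrl <- rbind(counts_ctrl, sp_ctrl)
    counts_trt <- rbind(counts_trt, sp_trt)
  }
  true_log2fc <- c(stats::setNames(log2fc, truth$gene_id),
                   stats::setNames(rep(0, config$n_spikeins), spike_ids))
  list(counts_ctrl = counts_ctrl, counts_trt = counts_trt,
       true_log2fc = true_log2fc, spikein_ids = spike_ids,
       rpkm_ctrl = expression$rpkm)
}

#' Run the full synthetic generator
#'
#' Chains transcriptome, expression, m6A-site, half-life, SLAM-seq and
#' treatment-count generation under a single config, returning all tables
#' plus the completed ground truth. Identical configs (including seed) give
#' identical outputs.
#'
#' @param config a [synth_config()].
#' @param slam generate the SLAM-seq conversion tables (skippable for
#'   expression-only studies at large gene counts).
#' @param treatment generate the paired treatment count matrices.
#' @return list: `config`, `models`, `tx_seq`, `genome`, `motifs`, `sites`
#'   (observed), `methylated` (true sites), `expression`, `slam`
#'   (labeled/unlabeled; NULL when skipped), `counts` (treatment
#'   experiment; NULL when skipped), `truth`.
#' @export
simulate_dataset <- function(config = synth_config(), slam = TRUE,
                             treatment = TRUE) {
  txome <- gen_transcriptome(config)
  expression <- gen_expression(txome, config)
  sites <- gen_m6a_sites(txome, expression, config)
  truth <- assign_halflives(txome$truth, sites$n_meth_true, config)
  truth$n_sites_observed <- sites$n_sites_observed
  slam_tabs <- if (slam) gen_slam_profiles(txome, truth, config) else NULL
  counts <- NULL
  if (treatment) {
    counts <- gen_treatment_counts(expression, truth, config)
    truth$true_log2fc <- counts$true_log2fc[truth$gene_id]
  }
  list(config = config, models = txome$models, tx_seq = txome$tx_seq,
       genome = txome$genome, motifs = txome$motifs,
       sites = sites$sites, methylated = sites$methylated,
       expression = expression, slam = slam_tabs, counts = counts,
       truth = truth)
}
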