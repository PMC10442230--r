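# Synthetic-data generator: determinism, configured-rate recovery,
# truth-equals-scan bookkeeping.

test_that("config validation rejects invalid parameter sets", {
  expect_error(synth_config(chase_timepoints = c(1, 2)), "start at 0")
  expect_error(synth_config(chase_timepoints = c(0, 2, 2)), "strictly")
  expect_error(synth_config(methylation_prob = 1.5), "probabilities")
  expect_error(synth_config(t0_conversion = 0), "rates")
  expect_error(synth_config(region_length_params = list(
    utr5 = c(meanlog = log(0.1), sdlog = 0.1),
    cds = c(meanlog = log(1200), sdlog = 0.4),
    utr3 = c(meanlog = log(1000), sdlog = 0.5))), "zero-length")
  expect_error(synth_config(detection_curve = c(0.5, 0.5)), "12")
})

test_that("identical config gives byte-identical serialized outputs", {
  cfg <- synth_config(genes_per_chromosome = 5, seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("ground truth motif counts equal an independent scan of the sequences", {
  sim <- small_sim()
  idx <- sample(nrow(sim$truth), 25)
  for (i in idx) {
    tr <- sim$models$transcripts[i, ]
    s <- as.character(sim$tx_seq[[tr$transcript_id]])
    u3 <- substr(s, tr$utr5_len + tr$cds_len + 1, tr$spliced_length)
    expect_equal(sim$truth$n_ggach_utr3[i], oracle_count(u3, "GGACH"))
  }
  # gene-set conservation across truth, annotation and count tables
  expect_setequal(sim$truth$gene_id, sim$models$transcripts$gene_id)
  expect_setequal(c(sim$truth$gene_id, sim$counts$spikein_ids),
                  rownames(sim$counts$counts_ctrl))
})

test_that("equalized densities remove the chromosome motif contrast", {
  cfg <- synth_config(genes_per_chromosome = 25, ggach_density_X = 3.1,
                      seed = 5)
  tx <- gen_transcriptome(cfg)
  d <- region_density(tx$models, tx$tx_seq, "GGACH", "utr3")
  kl <- chromosome_class(d$chromosome)
  dens <- function(sel) 1000 * sum(d$count[sel]) / sum(d$length_nt[sel])
  expect_lt(abs(log2(dens(kl == "X") / dens(kl == "autosome"))), 0.25)
})

test_that("m6A site generation respects methylation and detection settings", {
  sim <- small_sim()
  cfg0 <- synth_config(genes_per_chromosome = 5, methylation_prob = 0,
                       seed = 3)
  tx <- gen_transcriptome(cfg0)
  expr <- gen_expression(tx, cfg0)
  s0 <- gen_m6a_sites(tx, expr, cfg0)
  expect_equal(nrow(s0$sites), 0)
  expect_true(all(s0$n_meth_true == 0))

  cfg1 <- synth_config(genes_per_chromosome = 5,
                       detection_curve = rep(1, 12), seed = 3)
  tx1 <- gen_transcriptome(cfg1)
  ex1 <- gen_expression(tx1, cfg1)
  s1 <- gen_m6a_sites(tx1, ex1, cfg1)
  expect_identical(s1$n_sites_observed, s1$n_meth_true)
  expect_identical(nrow(s1$sites), nrow(s1$methylated))
})

test_that("count model matches the configured NB moments", {
  cfg <- synth_config(genes_per_chromosome = 10, nb_dispersion = 0.1,
                      seed = 8)
  tx <- gen_transcriptome(cfg)
  ex <- gen_expression(tx, cfg, n_replicates = 50)
  mu <- ex$true_tpm * (tx$models$transcripts$spliced_length / 1000) *
    cfg$library_scale
  v <- apply(ex$counts, 1, stats::var)
  m <- rowMeans(ex$counts)
  # var ~ mu + mu^2 * disp, checked on the aggregate regression slope
  disp_hat <- sum((v - m) * mu^2) / sum(mu^4)
  expect_lt(abs(disp_hat - 0.1), 0.03)

  # near-Poisson limit
  cfgp <- synth_config(genes_per_chromosome = 10, nb_dispersion = 1e-6,
                       seed = 8)
  txp <- gen_transcriptome(cfgp)
  exp_ <- gen_expression(txp, cfgp, n_replicates = 50)
  ratio <- apply(exp_$counts, 1, stats::var) / rowMeans(exp_$counts)
  expect_lt(abs(mean(ratio) - 1), 0.15)
})

test_that("doubling depth doubles counts but leaves TPM calibrated", {
  cfg1 <- synth_config(genes_per_chromosome = 10, seed = 4)
  cfg2 <- synth_config(genes_per_chromosome = 10, library_scale = 10,
                       seed = 4)
  tx <- gen_transcriptome(cfg1)
  e1 <- gen_expression(tx, cfg1)
  e2 <- gen_expression(tx, cfg2)
  expect_lt(abs(sum(e2$counts) / sum(e1$counts) - 2), 0.05)
  expect_lt(abs(stats::median(rowMeans(e2$tpm)) /
                  stats::median(rowMeans(e1$tpm)) - 1), 0.05)
})

test_that("conversion rates follow the first-order decay construction", {
  sim <- small_sim()
  ir <- incorporation_rate(sim$slam$labeled,
                           group_keys = c("condition", "time_h"))
  r0 <- ir$rate[ir$time_h == 0]
  expect_true(all(abs(r0 - 1.36e-2) < 1e-3))  # chase-onset incorporation
  # unlabeled stays at background at every time point
  iru <- incorporation_rate(sim$slam$unlabeled, group_keys = "time_h")
  expect_true(all(abs(iru$rate - 1e-3) < 3e-4))

  # binomial sampling check at t = t_half: rate = bg + (r0-bg)/2
  cfg <- synth_config(genes_per_chromosome = 5,
                      coverage_params = c(mu = 1e4, size = 1e6),
                      chase_timepoints = c(0, 3), seed = 10)
  tx <- gen_transcriptome(cfg)
  truth <- tx$truth
  truth$n_meth_true <- 0L
  truth$t_half_ctrl <- truth$t_half_trt <- 3
  pro <- gen_slam_profiles(tx, truth, cfg, conditions = "ctrl")
  at3 <- pro$labeled[pro$labeled$time_h == 3, ]
  expected <- 1e-3 + (1.36e-2 - 1e-3) / 2
  pooled <- sum(at3$tc_count) / sum(at3$t_coverage)
  se <- sqrt(expected * (1 - expected) / sum(at3$t_coverage))
  expect_lt(abs(pooled - expected), 3 * se)

  # zero decay: constant conversion over the chase
  truth$t_half_ctrl <- Inf
  pro0 <- gen_slam_profiles(tx, truth, cfg, conditions = "ctrl")
  ir0 <- incorporation_rate(pro0$labeled, group_keys = "time_h")
  expect_lt(abs(ir0$rate[1] - ir0$rate[2]), 3e-3)
})

test_that("treatment counts encode the burden effect and spare spike-ins", {
  sim <- small_sim()
  cc <- sim$counts
  expect_true(all(sim$truth$true_log2fc[sim$truth$chromosome == "chrX"] == 0))
  sp <- cc$true_log2fc[cc$spikein_ids]
  expect_true(all(sp == 0))
  ratio <- rowMeans(cc$counts_trt[cc$spikein_ids, ]) /
    rowMeans(cc$counts_ctrl[cc$spikein_ids, ])
  expect_lt(abs(mean(ratio) - 1), 0.05)

  cfg0 <- synth_config(genes_per_chromosome = 10, beta_treatment = 0,
                       seed = 6)
  sim0 <- simulate_dataset(cfg0, slam = FALSE)
  fc0 <- log2(rowMeans(sim0$counts$counts_trt[sim0$truth$gene_id, ]) /
                rowMeans(sim0$counts$counts_ctrl[sim0$truth$gene_id, ]))
  expect_lt(abs(stats::median(fc0)), 0.05)
})
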