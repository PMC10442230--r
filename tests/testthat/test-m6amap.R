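# Expression binning, site counting with the stop-codon window control,
# per-bin profiles and chromosome fold changes.

test_that("expression bins follow the 0.25-step log10(TPM) scheme", {
  tpm <- stats::setNames(c(0.5, 1.5, 10, 1000.0001, 3.17, 1.0),
                         paste0("g", 1:6))
  b <- assign_bins(tpm)
  expect_true(is.na(b$bin[1]))                # at/below the TPM > 1 floor
  expect_equal(b$bin[2], 1L)                  # log10(1.5) ~ 0.176
  expect_equal(b$bin[3], 4L)                  # log10(10) = 1.0
  expect_equal(b$bin[4], 12L)                 # above 3.0: outer bin
  expect_equal(b$bin[5], 2L)                  # log10(3.17) ~ 0.501: bin 2
  expect_true(is.na(b$bin[6]))                # TPM must exceed 1

  # partition property against an edge-enumeration oracle
  set.seed(2)
  v <- stats::setNames(10^runif(500, -0.5, 3.5), paste0("r", 1:500))
  bb <- assign_bins(v)
  edges <- c(0, seq(0.5, 3, 0.25), Inf)
  for (i in seq_along(v)) {
    if (v[i] <= 1) {
      expect_true(is.na(bb$bin[i]))
    } else {
      lt <- log10(v[i])
      oracle <- which(lt >= edges[-length(edges)] & lt < edges[-1])
      expect_equal(bb$bin[i], oracle)
    }
  }
})

test_that("replicate TPM values are averaged before binning", {
  m <- matrix(c(0.5, 40, 3, 10), nrow = 2,
              dimnames = list(c("g1", "g2"), c("r1", "r2")))
  b <- assign_bins(m)
  expect_equal(b$tpm_mean, c(1.75, 25))
  expect_equal(b$bin, c(1L, 5L))              # log10(25) ~ 1.398 -> bin 5
})

test_that("stop-codon window counts use inclusive -50..+150 offsets", {
  tr <- data.frame(gene_id = "G1", transcript_id = "T1", chromosome = "chr1",
                   strand = "+", ccds_present = TRUE,
                   transcript_support_level = 1, level = 1,
                   utr5_len = 100L, cds_len = 300L, utr3_len = 400L,
                   spliced_length = 800L, stop_codon_tx = 397L,
                   stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = "T1", chromosome = "chr1", strand = "+",
                   start = 0L, end = 800L, exon_rank = 1L,
                   stringsAsFactors = FALSE)
  models <- new_transcript_models(tr, ex)
  offs <- c(-51, -50, 0, 150, 151)
  sites <- data.frame(gene_id = "G1", chromosome = "chr1",
                      tx_pos = 397L + offs, start = 397L + offs,
                      strand = "+", stringsAsFactors = FALSE)
  all_counts <- count_sites_per_transcript(sites, models)
  expect_equal(all_counts$n_sites, 5L)
  win <- count_sites_per_transcript(sites, models,
                                    region_filter = "stop_window")
  expect_equal(win$n_sites, 3L)               # -50, 0, +150 kept

  orphan <- rbind(sites, data.frame(gene_id = "GX", chromosome = "chr1",
                                    tx_pos = 1L, start = 1L, strand = "+"))
  oc <- count_sites_per_transcript(orphan, models)
  expect_equal(nrow(attr(oc, "orphans")), 1L)
})

test_that("bin profiles report mean and normal 95% CI", {
  counts <- data.frame(gene_id = paste0("g", 1:6),
                       n_sites = c(1, 1, 1, 0, 2, 4))
  bins <- data.frame(gene_id = paste0("g", 1:6),
                     bin = c(3L, 3L, 3L, 5L, 5L, 5L))
  pr <- bin_profile(counts, bins)
  b3 <- pr[pr$bin == 3, ]
  expect_equal(b3$mean_sites, 1)
  expect_equal(b3$ci_hi - b3$ci_lo, 0)
  b5 <- pr[pr$bin == 5, ]
  expect_equal(b5$mean_sites, 2)
  expect_equal(b5$ci_hi, 2 + 1.96 * 2 / sqrt(3), tolerance = 1e-12)

  # per-chromosome means aggregate back to the pooled mean
  cm <- stats::setNames(rep(c("chr1", "chrX"), 3), paste0("g", 1:6))
  prc <- bin_profile(counts, bins, cm)
  for (b in c(3, 5)) {
    sub <- prc[prc$bin == b & prc$chromosome != "all", ]
    pooled <- prc[prc$bin == b & prc$chromosome == "all", ]
    expect_equal(sum(sub$mean_sites * sub$n) / sum(sub$n),
                 pooled$mean_sites)
  }
})

test_that("chromosome fold change matches hand arithmetic and conserves", {
  counts <- data.frame(gene_id = paste0("g", 1:4),
                       n_sites = c(2, 2, 1, 1))
  bins <- data.frame(gene_id = paste0("g", 1:4), bin = 3L)
  cm <- stats::setNames(c("chr1", "chr1", "chrX", "chrX"), paste0("g", 1:4))
  fc <- suppressWarnings(
    chrom_fold_change(counts, bins, cm, bin_range = 3, n_boot = 0))
  pb <- fc$per_bin
  expect_equal(pb$fc[pb$chromosome == "chr1"], 4 / 3, tolerance = 1e-12)
  expect_equal(pb$fc[pb$chromosome == "chrX"], 2 / 3, tolerance = 1e-12)
  expect_equal(sum(pb$n * pb$fc) / sum(pb$n), 1, tolerance = 1e-12)

  # identical count distributions: all fold changes 1, summaries 0
  counts2 <- data.frame(gene_id = paste0("g", 1:4), n_sites = 2)
  fc2 <- suppressWarnings(
    chrom_fold_change(counts2, bins, cm, bin_range = 3, n_boot = 0))
  expect_true(all(fc2$per_bin$fc == 1))
  expect_true(all(fc2$summary$summary_log2fc == 0))
})

test_that("per-bin weighted conservation holds on simulated data", {
  sim <- small_sim()
  counts <- count_sites_per_transcript(sim$sites, sim$models)
  bins <- assign_bins(sim$expression$tpm)
  fc <- suppressWarnings(
    chrom_fold_change(counts, bins, chrom_map_of(sim), n_boot = 0))
  # holds per bin regardless of chromosomes absent from the bin: their
  # transcript weight is zero
  for (b in unique(fc$per_bin$bin)) {
    pb <- fc$per_bin[fc$per_bin$bin == b, ]
    expect_equal(sum(pb$n * pb$fc) / sum(pb$n), 1, tolerance = 1e-12)
  }
})

test_that("subsampled fold changes are deterministic and centered when null", {
  set.seed(3)
  n <- 400
  counts <- data.frame(gene_id = paste0("g", 1:n),
                       n_sites = rpois(n, 2))
  bins <- data.frame(gene_id = paste0("g", 1:n),
                     bin = sample(3:5, n, replace = TRUE))
  cm <- stats::setNames(sample(c("chr1", "chr2", "chrX"), n, replace = TRUE),
                        paste0("g", 1:n))
  s1 <- subsample_fold_change(counts, bins, cm, n_per_bin = 20, reps = 30,
                              seed = 5)
  s2 <- subsample_fold_change(counts, bins, cm, n_per_bin = 20, reps = 30,
                              seed = 5)
  expect_identical(s1$samples, s2$samples)
  expect_true(all(abs(s1$distribution$median) < 0.25))
})

test_that("methylated-motif fractions count overlapped motif positions", {
  mot <- data.frame(gene_id = rep("g1", 10), chromosome = "chr1",
                    gstart = seq(0, 90, 10), gend = seq(5, 95, 10))
  sites <- data.frame(gene_id = "g1", chromosome = "chr1",
                      start = c(2, 12, 34))   # motifs 1, 2 and 4
  fr <- fraction_motifs_methylated(sites, mot, expressed_set = "g1")
  expect_equal(fr$fraction, 0.3)
  fr0 <- fraction_motifs_methylated(sites[0, ], mot, "g1")
  expect_equal(fr0$fraction, 0)
  all_sites <- data.frame(gene_id = "g1", chromosome = "chr1",
                          start = seq(2, 92, 10))
  expect_equal(fraction_motifs_methylated(all_sites, mot, "g1")$fraction, 1)
})

test_that("peak density ratios normalize by length and median", {
  lens <- c(chr1 = 1000, chr2 = 2000, chr3 = 1000)
  peaks <- data.frame(chromosome = c(rep("chr1", 10), rep("chr2", 20),
                                     rep("chr3", 20)))
  pr <- peak_density_ratio(peaks, lens)
  expect_equal(pr$ratio, c(1, 1, 2))          # chr3 at double density
  none <- peak_density_ratio(peaks[peaks$chromosome != "chr3", ,
                                   drop = FALSE], lens)
  expect_equal(none$ratio[none$chromosome == "chr3"], 0)
})
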