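# Half-life estimation: incorporation rates, normalization arithmetic,
# decay fitting (exactness, oracle equivalence), filters and contrasts.

make_profile <- function(utr, time, cov, tc, condition = "ctrl", rep = 1) {
  data.frame(utr_id = utr, condition = condition, replicate = rep,
             time_h = time, t_coverage = cov, tc_count = tc,
             stringsAsFactors = FALSE)
}

test_that("incorporation rate is total conversions over total coverage", {
  p <- make_profile("u1", c(0, 1), c(200, 300), c(2, 3))
  r <- incorporation_rate(p, group_keys = "utr_id")
  expect_equal(r$rate, 5 / 500)
  r0 <- incorporation_rate(make_profile("u1", 0, 500, 0),
                           group_keys = "utr_id")
  expect_equal(r0$rate, 0)
  rz <- incorporation_rate(make_profile("u1", 0, 0, 0),
                           group_keys = "utr_id")
  expect_true(rz$undefined)
  expect_true(is.na(rz$rate))
})

test_that("pooled rate equals the coverage-weighted mean of per-UTR rates", {
  set.seed(1)
  p <- data.frame(utr_id = sample(paste0("u", 1:20), 200, replace = TRUE),
                  condition = "ctrl", replicate = 1,
                  time_h = sample(c(0, 1, 3), 200, replace = TRUE),
                  t_coverage = sample(50:500, 200, replace = TRUE))
  p$tc_count <- rbinom(200, p$t_coverage, 0.01)
  pooled <- incorporation_rate(p, group_keys = "condition")
  per_utr <- incorporation_rate(p, group_keys = "utr_id")
  oracle <- sum(per_utr$rate * per_utr$t_coverage) / sum(per_utr$t_coverage)
  expect_equal(pooled$rate, oracle, tolerance = 1e-12)
  expect_equal(pooled$rate, sum(p$tc_count) / sum(p$t_coverage))
})

test_that("background subtraction and T0 normalization match hand arithmetic", {
  cov <- 1e5
  lab <- make_profile("u1", c(0, 3, 6), cov,
                      c(0.0136, 0.0073, 0.00415) * cov)
  unl <- make_profile("u1", c(0, 3, 6), cov, 0.001 * cov)
  out <- correct_and_normalize(lab, unl)
  expect_equal(out$series$norm_value, c(1, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(nrow(out$excluded), 0)

  # degenerate: labeled rate equals background everywhere -> excluded
  lab0 <- make_profile("u2", c(0, 3, 6), cov, 0.001 * cov)
  unl0 <- make_profile("u2", c(0, 3, 6), cov, 0.001 * cov)
  out0 <- correct_and_normalize(lab0, unl0)
  expect_equal(out0$excluded$reason, "nonpositive_t0")
  expect_equal(nrow(out0$series), 0)

  # zero background: normalization by the raw T0 rate, output[0] = 1
  unlz <- make_profile("u1", c(0, 3, 6), cov, 0)
  outz <- correct_and_normalize(lab, unlz)
  expect_equal(outz$series$norm_value[outz$series$time_h == 0], 1)
  expect_equal(outz$series$norm_value[outz$series$time_h == 3],
               0.0073 / 0.0136, tolerance = 1e-12)
})

test_that("noise-free exponential series are recovered exactly", {
  s <- data.frame(utr_id = "u1", condition = "ctrl",
                  time_h = c(0, 3, 6, 12),
                  norm_value = c(1, 0.5, 0.25, 0.0625))
  f <- fit_decay(s)
  expect_equal(f$k, log(2) / 3, tolerance = 1e-12)
  expect_equal(f$t_half, 3, tolerance = 1e-9)
  expect_equal(f$residual_se, 0, tolerance = 1e-9)
  expect_equal(f$t_half * f$k, log(2), tolerance = 1e-12)

  const <- data.frame(utr_id = "u2", condition = "ctrl",
                      time_h = c(0, 3, 6), norm_value = c(1, 1, 1))
  fc <- fit_decay(const)
  expect_true(!is.finite(fc$t_half) || fc$t_half > 18)
  verdict <- filter_fits(fc, require_both_conditions = FALSE)
  expect_equal(verdict$fits$reason, "t_half_high")
})

test_that("estimator equals an independent numerical least-squares oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    t <- sort(c(0, runif(n - 1, 0.3, 12)))
    k_true <- runif(1, 0.05, 1.5)
    y <- -k_true * t + rnorm(n, 0, 0.15)
    y[1] <- 0
    s <- data.frame(utr_id = "u", condition = "c", time_h = t,
                    norm_value = exp(y))
    f <- fit_decay(s)
    expect_equal(f$k, oracle_fit_k(t, y), tolerance = 1e-6)
  }
})

test_that("every emitted fit satisfies t_half * k = ln 2", {
  sim <- small_sim()
  f <- fit_decay(correct_and_normalize(sim$slam$labeled,
                                       sim$slam$unlabeled)$series)
  ok <- is.finite(f$t_half) & f$k > 0
  expect_true(any(ok))
  expect_true(all(abs(f$t_half[ok] * f$k[ok] - log(2)) < 1e-12))
})

test_that("recovery error shrinks monotonically with coverage", {
  meds <- vapply(c(1e2, 1e3, 1e4), function(mu) {
    cfg <- synth_config(genes_per_chromosome = 8,
                        coverage_params = c(mu = mu, size = 20), seed = 13)
    sim <- simulate_dataset(cfg, treatment = FALSE)
    f <- fit_decay(correct_and_normalize(sim$slam$labeled,
                                         sim$slam$unlabeled)$series)
    f <- f[f$condition == "ctrl" & is.finite(f$t_half), ]
    tru <- stats::setNames(sim$truth$t_half_ctrl, sim$truth$gene_id)
    stats::median(abs(f$t_half - tru[f$utr_id]) / tru[f$utr_id])
  }, 0)
  expect_true(all(diff(meds) < 0))
})

test_that("quality filters apply the published thresholds with a conserving ledger", {
  fits <- data.frame(
    utr_id = rep(sprintf("u%d", 1:5), each = 2),
    condition = rep(c("ctrl", "trt"), 5),
    k = log(2) / c(3, 3,   20, 3,  0.5, 3,  3, 3,    3, 3),
    t_half = c(3, 3,  20, 3,  0.5, 3,  3, 3,  3, 3),
    residual_se = c(.1, .1, .1, .1, .1, .1, .4, .1, .1, .1),
    n_timepoints = 10, n_dropped = 0,
    t_coverage_min = c(900, 900, 900, 900, 900, 900, 900, 900, 50, 900),
    stringsAsFactors = FALSE)
  out <- filter_fits(fits)
  lg <- out$ledger
  expect_equal(unname(lg["kept"]), 2L)           # u1 passes both conditions
  expect_equal(unname(lg["t_half_high"]), 1L)    # 20 h > 18 h
  expect_equal(unname(lg["t_half_low"]), 1L)     # 0.5 h < 0.67 h
  expect_equal(unname(lg["poor_fit"]), 1L)       # rse 0.4 > 0.3
  expect_equal(unname(lg["low_coverage"]), 1L)   # 50 <= 100
  expect_equal(unname(lg["other_condition"]), 4L)
  expect_equal(sum(lg), nrow(fits))  # kept + all rejections = input rows
  expect_setequal(out$kept$utr_id, "u1")

  # relaxing the residual threshold never shrinks the kept set
  relaxed <- filter_fits(fits, max_rse = 0.5)
  expect_true(all(out$kept$utr_id %in% relaxed$kept$utr_id))
})

test_that("half-life contrast reproduces hand-computed group summaries", {
  mk <- function(cond, th) {
    data.frame(utr_id = paste0("g", 1:6), condition = cond,
               k = log(2) / th, t_half = th, residual_se = 0.1,
               n_timepoints = 10, t_coverage_min = 1e3,
               stringsAsFactors = FALSE)
  }
  th_c <- c(2, 4, 3, 5, 2, 4)
  th_t <- c(2.2, 4.4, 3, 5, 2, 4.4)
  cm <- stats::setNames(rep(c("chr1", "chrX"), each = 3), paste0("g", 1:6))
  m6a <- stats::setNames(c(1, 2, 0, 0, 0, 3), paste0("g", 1:6))
  ctr <- suppressWarnings(suppressMessages(
    halflife_contrast(mk("ctrl", th_c), mk("trt", th_t), m6a, cm)))
  per_chrom <- stats::setNames(ctr$chromosome$median_log2fc,
                               ctr$chromosome$chromosome)
  expect_equal(unname(per_chrom["chr1"]),
               stats::median(log2(th_t[1:3] / th_c[1:3])))
  expect_equal(unname(per_chrom["chrX"]),
               stats::median(log2(th_t[4:6] / th_c[4:6])))
  g <- ctr$groups
  expect_equal(g$pct_median_change[g$group == "methylated"], 10,
               tolerance = 1e-9)
  expect_equal(g$pct_median_change[g$group == "unmethylated"], 0,
               tolerance = 1e-9)

  # identical fits in both conditions: all fold changes exactly zero
  ctr0 <- suppressWarnings(suppressMessages(
    halflife_contrast(mk("ctrl", th_c), mk("trt", th_c), m6a, cm)))
  expect_true(all(ctr0$per_transcript$log2fc == 0))
  expect_equal(ctr0$groups$pct_median_change,
               rep(0, 4), tolerance = 1e-12)
})
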