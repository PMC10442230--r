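# mRNA half-life estimation from SLAM-seq T-to-C conversion time courses.
# The model is first-order decay of the labeled fraction: after background
# subtraction and normalization to the chase-onset (T0) rate, log conversion
# falls linearly with time at slope -k, and t1/2 = ln(2)/k.

#' s4U incorporation rate per group
#'
#' Pooled T-to-C conversion rate: total conversions divided by total T
#' coverage within each group (equivalently the coverage-weighted mean of
#' per-profile rates).
#'
#' @param profiles conversion table (utr_id, condition, replicate, time_h,
#'   t_coverage, tc_count).
#' @param group_keys columns to aggregate over.
#' @return data.frame with the group keys, `t_coverage`, `tc_count`, `rate`
#'   (NA with `undefined = TRUE` where total coverage is zero).
#' @export
incorporation_rate <- function(profiles,
                               group_keys = c("condition", "time_h")) {
  miss <- setdiff(c(group_keys, "t_coverage", "tc_count"), names(profiles))
  if (length(miss)) abort("missing columns: %s", paste(miss, collapse = ", "))
  key <- interaction(profiles[group_keys], drop = TRUE, lex.order = TRUE)
  agg <- stats::aggregate(profiles[c("t_coverage", "tc_count")],
                          by = profiles[group_keys], FUN = sum)
  agg <- agg[do.call(order, agg[group_keys]), , drop = FALSE]
  agg$rate <- ifelse(agg$t_coverage > 0, agg$tc_count / agg$t_coverage, NA_real_)
  agg$undefined <- agg$t_coverage == 0
  rownames(agg) <- NULL
  agg
}

#' Background-correct and T0-normalize conversion series
#'
#' Per 3'UTR and condition, replicate-pooled conversion rates are computed at
#' every chase time point, the unlabeled background rate is subtracted
#' (clamped below at `floor`), and the series is divided by its corrected
#' chase-onset (t = 0) value, so the normalized series starts at exactly 1.
#' Background is the pooled unlabeled rate per UTR where unlabeled coverage
#' exists, otherwise the global pooled unlabeled rate.
#'
#' @param labeled labeled conversion table.
#' @param unlabeled no-s4U conversion table (same layout).
#' @param floor lower clamp for the background-subtracted rate; clamped
#'   points are flagged `floored` and excluded from decay fits.
#' @return list with `series` (utr_id, condition, time_h, rate, norm_value,
#'   t_coverage, floored) and `excluded` (utr_id, condition, reason) for
#'   series whose corrected T0 rate is non-positive.
#' @export
correct_and_normalize <- function(labeled, unlabeled, floor = 1e-6) {
  pooled <- incorporation_rate(labeled,
                               group_keys = c("utr_id", "condition", "time_h"))
  bg_utr <- incorporation_rate(unlabeled, group_keys = "utr_id")
  bg_global <- sum(unlabeled$tc_count) / sum(unlabeled$t_coverage)
  bg <- stats::setNames(bg_utr$rate, bg_utr$utr_id)
  bgv <- bg[pooled$utr_id]
  bgv[is.na(bgv)] <- bg_global

  raw_corr <- pooled$rate - bgv
  corr <- pmax(raw_corr, floor)
  floored <- raw_corr < floor

  key <- paste(pooled$utr_id, pooled$condition, sep = "\r")
  is_t0 <- pooled$time_h == 0
  t0 <- stats::setNames(raw_corr[is_t0], key[is_t0])
  t0v <- t0[key]

  ok <- !is.na(t0v) & t0v > floor
  excluded_keys <- unique(key[!ok])
  excluded <- if (length(excluded_keys)) {
    parts <- strsplit(excluded_keys, "\r", fixed = TRUE)
    data.frame(utr_id = vapply(parts, `[`, "", 1),
               condition = vapply(parts, `[`, "", 2),
               reason = "nonpositive_t0", stringsAsFactors = FALSE)
  } else {
    data.frame(utr_id = character(0), condition = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  series <- data.frame(utr_id = pooled$utr_id, condition = pooled$condition,
                       time_h = pooled$time_h, rate = pooled$rate,
                       norm_value = corr / t0v,
                       t_coverage = pooled$t_coverage,
                       floored = floored, stringsAsFactors = FALSE)[ok, ]
  series$norm_value[series$time_h == 0] <- 1   # exact by construction
  series$floored[series$time_h == 0] <- FALSE
  rownames(series) <- NULL
  list(series = series, excluded = excluded)
}

#' Fit first-order decay to normalized conversion series
#'
#' Least-squares line through `log(norm_value)` versus time with the
#' intercept fixed at zero (normalization pins the t = 0 value to 1); the
#' slope is -k and t1/2 = ln(2)/k. The residual standard error is on the log
#' scale with one estimated parameter. Floored or non-positive points are
#' dropped before taking logs and counted per series.
#'
#' @param series data.frame from [correct_and_normalize()] (or with columns
#'   utr_id, condition, time_h, norm_value and optionally floored,
#'   t_coverage).
#' @return data.frame of fits: utr_id, condition, k (per hour), t_half (h,
#'   `Inf` when k <= 0), residual_se, n_timepoints (points used),
#'   n_dropped, t_coverage_min.
#' @export
fit_decay <- function(series) {
  if (!"floored" %in% names(series)) series$floored <- FALSE
  if (!"t_coverage" %in% names(series)) series$t_coverage <- NA_integer_
  key <- paste(series$utr_id, series$condition, sep = "\r")
  usable <- !series$floored & is.finite(series$norm_value) &
    series$norm_value > 0
  ukey <- unique(key)
  g <- factor(key, levels = ukey)

  cov_min <- tapply(series$t_coverage, g, function(x)
    if (all(is.na(x))) NA_integer_ else min(x, na.rm = TRUE))
  n_all <- tabulate(g, nbins = length(ukey))
  gu <- g[usable]
  t <- series$time_h[usable]
  y <- log(series$norm_value[usable])
  n_use <- tabulate(gu, nbins = length(ukey))

  st2 <- tapply(t * t, gu, sum, default = 0)
  sty <- tapply(t * y, gu, sum, default = 0)
  st2[is.na(st2)] <- 0; sty[is.na(sty)] <- 0
  slope <- ifelse(st2 > 0, sty / st2, NA_real_)
  resid <- y - slope[as.integer(gu)] * t
  rss <- tapply(resid^2, gu, sum, default = 0)
  rss[is.na(rss)] <- 0
  sigma <- ifelse(n_use > 1, sqrt(rss / pmax(n_use - 1, 1)), NA_real_)

  k <- -slope
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  data.frame(
    utr_id = vapply(parts, `[`, "", 1),
    condition = vapply(parts, `[`, "", 2),
    k = as.numeric(k),
    t_half = ifelse(!is.na(k) & k > 0, log(2) / k, Inf),
    residual_se = as.numeric(sigma),
    n_timepoints = n_use,
    n_dropped = n_all - n_use,
    t_coverage_min = as.integer(cov_min),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the half-life quality filters
#'
#' Verdicts follow the published thresholds: minimum T coverage above
#' `min_t_cov`, half-life inside `bounds` hours, residual standard error at
#' most `max_rse`, and at least 3 usable time points; optionally a
#' transcript must pass in every condition present. Reason codes are
#' assigned in the order low_coverage, poor_fit, t_half_high, t_half_low.
#'
#' @param fits data.frame from [fit_decay()].
#' @param min_t_cov keep only series whose minimum T coverage exceeds this.
#' @param bounds `c(low, high)` admissible half-life range in hours.
#' @param max_rse maximum residual standard error (log scale).
#' @param require_both_conditions transcript kept only if it passes in every
#'   condition it was fit in.
#' @return list with `fits` (verdict and reason columns added), `kept`
#'   (surviving rows) and `ledger` (named counts per reason; includes
#'   `other_condition` for fits dropped solely because a partner condition
#'   failed; kept + rejections = input rows).
#' @export
filter_fits <- function(fits, min_t_cov = 100, bounds = c(0.67, 18),
                        max_rse = 0.3, require_both_conditions = TRUE) {
  reason <- rep(NA_character_, nrow(fits))
  bad_cov <- !is.na(fits$t_coverage_min) & fits$t_coverage_min <= min_t_cov
  bad_fit <- fits$n_timepoints < 3 | !is.finite(fits$k) |
    (!is.na(fits$residual_se) & fits$residual_se > max_rse)
  high <- !is.finite(fits$t_half) | fits$t_half > bounds[2]
  low <- is.finite(fits$t_half) & fits$t_half < bounds[1]
  reason[low] <- "t_half_low"
  reason[high] <- "t_half_high"
  reason[bad_fit] <- "poor_fit"
  reason[bad_cov] <- "low_coverage"
  fits$verdict <- ifelse(is.na(reason), "pass", "fail")
  fits$reason <- reason

  if (require_both_conditions) {
    pass_by <- tapply(fits$verdict == "pass", fits$utr_id, all)
    partner_bad <- fits$verdict == "pass" & !pass_by[fits$utr_id]
    fits$verdict[partner_bad] <- "fail"
    fits$reason[partner_bad] <- "other_condition"
  }
  kept <- fits[fits$verdict == "pass", , drop = FALSE]
  reasons <- c("low_coverage", "t_half_high", "t_half_low", "poor_fit",
               "other_condition")
  ledger <- c(kept = nrow(kept),
              stats::setNames(vapply(reasons, function(r)
                sum(fits$reason == r, na.rm = TRUE), 0L), reasons))
  list(fits = fits, kept = kept, ledger = ledger)
}

#' Contrast half-lives between conditions, by methylation and chromosome
#'
#' Per transcript, the half-life response to m6A depletion is
#' `log2(t_half_treated / t_half_control)`. Summaries: median percent change
#' for methylated (>= 1 site) versus unmethylated transcripts and for
#' autosomal versus X transcripts, with paired Wilcoxon signed-rank tests
#' within groups; per-chromosome median log2 fold change; an unpaired
#' rank-sum test X versus autosomes; and a mixed model with chromosome-class
#' fixed effect and per-chromosome random intercept. P-values within each
#' reported family are Benjamini-Hochberg adjusted.
#'
#' @param fits_ctrl,fits_trt passing fits for the two conditions (must share
#'   `utr_id`s; typically `filter_fits(...)$kept` split by condition).
#' @param m6a_counts named vector of m6A sites per transcript.
#' @param chromosome_map named vector transcript -> chromosome.
#' @param x_aliases chromosome names treated as X.
#' @return list with `per_transcript`, `groups` (per-group n, median log2fc,
#'   percent median change, signed-rank p and BH-adjusted p), `chromosome`
#'   (per-chromosome n and median log2fc), `tests` (rank-sum and mixed-model
#'   class contrast with estimate and p).
#' @export
halflife_contrast <- function(fits_ctrl, fits_trt, m6a_counts,
                              chromosome_map, x_aliases = c("X", "chrX")) {
  common <- intersect(fits_ctrl$utr_id, fits_trt$utr_id)
  if (!length(common)) abort("no transcripts shared between conditions")
  tc <- stats::setNames(fits_ctrl$t_half, fits_ctrl$utr_id)[common]
  tt <- stats::setNames(fits_trt$t_half, fits_trt$utr_id)[common]
  ratio <- tt / tc
  l2 <- log2(ratio)
  chrom <- chromosome_map[common]
  klass <- chromosome_class(chrom, x_aliases)
  meth <- m6a_counts[common] > 0
  meth[is.na(meth)] <- FALSE

  per_transcript <- data.frame(utr_id = common, t_half_ctrl = tc,
                               t_half_trt = tt, log2fc = l2,
                               chromosome = chrom, class = klass,
                               methylated = meth, row.names = NULL,
                               stringsAsFactors = FALSE)

  group_summary <- function(sel, label) {
    if (!any(sel)) {
      return(data.frame(group = label, n = 0L, median_log2fc = NA_real_,
                        pct_median_change = NA_real_, p_signed_rank = NA_real_,
                        stringsAsFactors = FALSE))
    }
    p <- tryCatch(suppressWarnings(stats::wilcox.test(l2[sel], mu = 0))$p.value,
                  error = function(e) NA_real_)
    data.frame(group = label, n = sum(sel),
               median_log2fc = stats::median(l2[sel]),
               pct_median_change = 100 * (stats::median(ratio[sel]) - 1),
               p_signed_rank = p, stringsAsFactors = FALSE)
  }
  groups <- rbind(group_summary(meth, "methylated"),
                  group_summary(!meth, "unmethylated"),
                  group_summary(klass == "autosome", "autosome"),
                  group_summary(klass == "X", "X"))
  groups$p_adj <- adjust_bh(groups$p_signed_rank)

  chrom_med <- stats::aggregate(list(median_log2fc = l2),
                                by = list(chromosome = chrom), stats::median)
  chrom_med$n <- as.integer(table(chrom)[chrom_med$chromosome])

  p_ranksum <- if (nlevels(droplevels(klass)) == 2)
    suppressWarnings(stats::wilcox.test(l2 ~ klass))$p.value else NA_real_
  mixed <- tryCatch({
    d <- data.frame(l2 = l2, klass = klass, chromosome = chrom)
    fit <- lmerTest::lmer(l2 ~ klass + (1 | chromosome), data = d)
    co <- summary(fit)$coefficients
    list(estimate = unname(co["klassX", "Estimate"]),
         p = unname(co["klassX", "Pr(>|t|)"]))
  }, error = function(e) list(estimate = NA_real_, p = NA_real_))

  tests <- data.frame(
    test = c("ranksum_X_vs_autosome", "mixed_model_class"),
    estimate = c(stats::median(l2[klass == "X"]) -
                   stats::median(l2[klass == "autosome"]), mixed$estimate),
    p = c(p_ranksum, mixed$p), stringsAsFactors = FALSE)
  tests$p_adj <- adjust_bh(tests$p)

  list(per_transcript = per_transcript, groups = groups,
       chromosome = chrom_med, tests = tests)
}
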