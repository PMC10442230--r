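# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

# 200-gene dataset with all tables; small enough for every unit test
small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- synth_config(genes_per_chromosome = 10, seed = 42)
    .fixture_env$small <- simulate_dataset(cfg)
  }
  .fixture_env$small
}

chrom_map_of <- function(sim) {
  stats::setNames(sim$truth$chromosome, sim$truth$gene_id)
}

site_counts_of <- function(sim) {
  sc <- count_sites_per_transcript(sim$sites, sim$models)
  stats::setNames(sc$n_sites, sc$gene_id)
}

# hand-built annotation with decoy isoforms for isoform-selection tests:
# gene GA: three isoforms (one fails CCDS, two qualify with a length tie),
# gene GB: one qualifying isoform, gene GC: none qualify.
decoy_models <- function() {
  tr <- data.frame(
    gene_id = c("GA", "GA", "GA", "GB", "GC"),
    transcript_id = c("TA1", "TA2", "TA9", "TB1", "TC1"),
    chromosome = "chr1", strand = "+",
    ccds_present = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    transcript_support_level = c(1, 2, 1, 3, 5),
    level = c(1, 2, 1, 2, 1),
    utr5_len = 10L, cds_len = c(60L, 60L, 90L, 30L, 30L),
    utr3_len = c(30L, 30L, 40L, 20L, 20L),
    spliced_length = c(100L, 100L, 140L, 60L, 60L),
    stop_codon_tx = c(67L, 67L, 97L, 37L, 37L),
    stringsAsFactors = FALSE)
  ex <- data.frame(
    transcript_id = tr$transcript_id, chromosome = "chr1", strand = "+",
    start = c(0L, 200L, 400L, 600L, 800L),
    end = c(0L, 200L, 400L, 600L, 800L) + tr$spliced_length,
    exon_rank = 1L, stringsAsFactors = FALSE)
  new_transcript_models(tr, ex)
}

# brute-force IUPAC motif counter: position-by-position sliding window
oracle_count <- function(seq, pattern) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  n <- 0L
  if (length(s) < length(p)) return(0L)
  for (i in seq_len(length(s) - length(p) + 1L)) {
    ok <- TRUE
    for (j in seq_along(p)) {
      if (!(s[i + j - 1L] %in% iupac[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) n <- n + 1L
  }
  n
}

# independent least-squares oracle: minimize RSS(k) of log-values vs -k*t
# by 1-d numerical optimization (no closed form shared with fit_decay)
oracle_fit_k <- function(t, y, interval = c(-5, 20)) {
  rss <- function(k) sum((y + k * t)^2)
  stats::optimize(rss, interval = interval, tol = 1e-12)$minimum
}
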