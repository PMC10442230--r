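# Motif counting, canonical isoform selection, densities, ortholog and
# gene-set comparisons.

test_that("IUPAC counting handles H degeneracy and overlaps", {
  expect_equal(count_motifs("GGACA", "GGACH"), 1L)
  expect_equal(count_motifs("GGACG", "GGACH"), 0L)
  expect_equal(count_motifs("GGACTGGACC", "GGACH"), 2L)
  expect_equal(count_motifs("GGACUGGACU", "GGACH"), 2L)  # U == T
  expect_equal(count_motifs("GGGACT", "GGACH"), 1L)
  expect_equal(count_motifs("GGNCT", "GGACH"), 0L)       # N never matches
  expect_equal(count_motifs("AAAA", "GGACH"), 0L)
})

test_that("counting equals the sliding-window oracle on random sequences", {
  set.seed(9)
  seqs <- vapply(seq_len(1000), function(i)
    paste(sample(c("A", "C", "G", "T"), sample(20:120, 1), replace = TRUE),
          collapse = ""), "")
  got <- count_motifs(seqs, "GGACH")
  want <- vapply(seqs, oracle_count, 0L, pattern = "GGACH")
  expect_identical(got, unname(want))
  got_d <- count_motifs(seqs[1:200], "DRACH")
  want_d <- vapply(seqs[1:200], oracle_count, 0L, pattern = "DRACH")
  expect_identical(got_d, unname(want_d))
})

test_that("density is additive over concatenated fragments", {
  set.seed(10)
  a <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ca <- count_motifs(a, "GGACH"); cb <- count_motifs(b, "GGACH")
  joint <- count_motifs(paste0(a, b), "GGACH")
  # concatenation can create at most 4 junction-spanning matches
  expect_gte(joint, ca + cb)
  expect_lte(joint - (ca + cb), 4)
  # the stated arithmetic: 2 motifs over 600 + 400 nt is 2 per kb
  expect_equal(1000 * 2 / (600 + 400), 2)
})

test_that("canonical isoform selection applies flags, length and tie-break", {
  sel <- select_canonical_isoforms(decoy_models())
  picked <- sel$models$transcripts
  # GA: TA9 is longest but lacks CCDS; TA1/TA2 tie at 100 nt -> TA1
  expect_equal(picked$transcript_id[picked$gene_id == "GA"], "TA1")
  expect_equal(picked$transcript_id[picked$gene_id == "GB"], "TB1")
  expect_false("GC" %in% picked$gene_id)      # TSL 5 fails
  expect_equal(sel$n_genes_dropped, 1L)

  # order independence
  m <- decoy_models()
  perm <- new_transcript_models(m$transcripts[c(4, 2, 5, 1, 3), ], m$exons)
  sel2 <- select_canonical_isoforms(perm)
  expect_setequal(sel2$models$transcripts$transcript_id,
                  picked$transcript_id)
})

test_that("region densities use spliced sense-strand sequence", {
  sim <- small_sim()
  d <- region_density(sim$models, sim$tx_seq, "GGACH", "utr3")
  tr <- sim$models$transcripts
  i <- match(d$gene_id, tr$gene_id)
  expect_equal(d$length_nt, tr$utr3_len[i])
  expect_equal(d$density_per_kb, 1000 * d$count / d$length_nt)
  # spot-check counts against the oracle on a minus-strand gene
  minus <- which(tr$strand == "-")[1:5]
  for (j in minus) {
    s <- as.character(sim$tx_seq[[tr$transcript_id[j]]])
    u3 <- substr(s, tr$utr5_len[j] + tr$cds_len[j] + 1, tr$spliced_length[j])
    expect_equal(d$count[d$gene_id == tr$gene_id[j]],
                 oracle_count(u3, "GGACH"))
  }
})

test_that("strong/weak DRACH subsets are disjoint and tested separately", {
  sim <- small_sim()
  expect_length(drach_motifs(), 18)
  expect_error(
    drach_subset_density(sim$models, sim$tx_seq,
                         strong_set = c("GGACA", "GGACT"),
                         weak_set = c("GGACT", "AGACT")),
    "overlap")
  cfg <- synth_config(genes_per_chromosome = 25, seed = 18)
  tx <- gen_transcriptome(cfg)
  out <- drach_subset_density(tx$models, tx$tx_seq)
  expect_setequal(out$tests$subset, c("strong", "weak"))
  # strong motifs are GGACH: depleted on X by construction; weak are not
  dens <- out$densities
  med <- function(sub, cls) {
    d <- dens[dens$subset == sub & !is.na(dens$density_per_kb), ]
    stats::median(d$density_per_kb[chromosome_class(d$chromosome) == cls])
  }
  expect_lt(med("strong", "X"), med("strong", "autosome"))
  expect_lt(out$tests$p_adj[out$tests$subset == "strong"], 0.05)
  expect_gt(out$tests$p_adj[out$tests$subset == "weak"], 0.05)
})

test_that("ortholog comparison finds the contrast only in the depleted species", {
  cfg_m <- synth_config(genes_per_chromosome = 25, seed = 14)
  cfg_o <- synth_config(genes_per_chromosome = 25, ggach_density_X = 3.1,
                        seed = 15)
  txm <- gen_transcriptome(cfg_m)
  txo <- gen_transcriptome(cfg_o)
  dm <- region_density(txm$models, txm$tx_seq, "GGACH", "exons")
  do <- region_density(txo$models, txo$tx_seq, "GGACH", "exons")
  do$gene_id <- sub("^G", "O", do$gene_id)
  genes <- dm$gene_id
  map <- data.frame(mouse_gene = genes, species = "outgroup",
                    ortholog_gene = sub("^G", "O", genes))
  klass <- stats::setNames(txm$truth$class, txm$truth$gene_id)
  res <- ortholog_group_compare(list(mouse = dm, outgroup = do), map, klass)
  p <- stats::setNames(res$per_species$p, res$per_species$species)
  expect_lt(p[["mouse"]], 0.01)
  expect_gt(p[["outgroup"]], 0.05)
  expect_equal(res$n_groups, length(genes))

  # many-to-many rows are dropped and counted
  map2 <- rbind(map, data.frame(mouse_gene = genes[1], species = "outgroup",
                                ortholog_gene = "O9999"))
  res2 <- ortholog_group_compare(list(mouse = dm, outgroup = do), map2,
                                 klass)
  expect_equal(res2$n_dropped_many_to_many, 2L)
  expect_equal(res2$n_groups, length(genes) - 1L)
})

test_that("permuted class labels give non-extreme ortholog p-values", {
  cfg <- synth_config(genes_per_chromosome = 25, ggach_density_X = 3.1,
                      seed = 16)
  tx <- gen_transcriptome(cfg)
  d <- region_density(tx$models, tx$tx_seq, "GGACH", "exons")
  set.seed(17)
  ps <- vapply(1:20, function(i) {
    klass <- stats::setNames(sample(tx$truth$class), tx$truth$gene_id)
    res <- ortholog_group_compare(
      list(mouse = d),
      data.frame(mouse_gene = character(0), species = character(0),
                 ortholog_gene = character(0)),
      klass)
    res$per_species$p
  }, 0)
  expect_gt(mean(ps > 0.05), 0.7)
  expect_gt(min(ps), 1e-4)
})

test_that("gene-set comparison tests against class-matched complement", {
  sim <- small_sim()
  dens <- region_density(sim$models, sim$tx_seq, "GGACH", "utr3")
  x_genes <- dens$gene_id[chromosome_class(dens$chromosome) == "X"]
  sets <- list(first_half_X = sort(x_genes)[1:5],
               absent = c("nope1", "nope2"))
  out <- geneset_density_compare(dens, sets, k = 50)
  t1 <- out$tests[out$tests$set == "first_half_X", ]
  expect_false(t1$empty)
  expect_equal(t1$n_set + t1$n_complement, length(x_genes))
  expect_gt(t1$p, 0.001)                      # arbitrary split: no signal
  expect_true(out$tests$empty[out$tests$set == "absent"])
  # ranked low-density list is deterministic with gene_id tie-break
  out2 <- geneset_density_compare(dens, sets, k = 50)
  expect_identical(out$lowest_density, out2$lowest_density)
  expect_equal(nrow(out$lowest_density), 50)
})
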