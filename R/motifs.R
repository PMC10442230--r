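# GGACH/DRACH motif analyses on canonical isoforms: isoform selection by
# annotation quality flags, IUPAC motif counting on spliced sense-strand
# sequence, per-region densities, and ortholog / gene-set comparisons.

#' Select one canonical isoform per gene
#'
#' Isoforms are filtered to transcript support level <= 3, annotation level
#' <= 2 and the presence of a CCDS ID; among survivors the longest spliced
#' transcript wins, ties broken by lexicographically smallest
#' transcript_id. An `NA` support level fails the filter (conservative
#' reading). Genes with no surviving isoform are excluded and counted.
#'
#' @param models a `transcript_models` object (possibly several isoforms
#'   per gene).
#' @param max_tsl,max_level,require_ccds the three filter thresholds.
#' @return list with `models` (filtered to one transcript per gene) and
#'   `n_genes_dropped`.
#' @export
select_canonical_isoforms <- function(models, max_tsl = 3, max_level = 2,
                                      require_ccds = TRUE) {
  tr <- models$transcripts
  tsl <- suppressWarnings(as.numeric(tr$transcript_support_level))
  lvl <- suppressWarnings(as.numeric(tr$level))
  ok <- !is.na(tsl) & tsl <= max_tsl & !is.na(lvl) & lvl <= max_level
  if (require_ccds) ok <- ok & tr$ccds_present
  surv <- tr[ok, , drop = FALSE]
  n_all <- length(unique(tr$gene_id))
  if (!nrow(surv))
    return(list(models = NULL, n_genes_dropped = n_all))
  # longest spliced transcript; ties -> smallest transcript_id
  surv <- surv[order(surv$gene_id, -surv$spliced_length, surv$transcript_id), ]
  pick <- surv[!duplicated(surv$gene_id), , drop = FALSE]
  ex <- models$exons[models$exons$transcript_id %in% pick$transcript_id, ,
                     drop = FALSE]
  list(models = new_transcript_models(pick[order(pick$gene_id), ], ex),
       n_genes_dropped = n_all - nrow(pick))
}

#' Count IUPAC motif matches in a sequence
#'
#' Overlapping matches are counted; IUPAC codes in the pattern (H = A/C/T,
#' D = A/G/T, R = A/G, ...) are expanded while subject letters are taken
#' literally, so an N in the sequence never matches. U is treated as T.
#'
#' @param sequence character vector of sequences (or a
#'   [Biostrings::DNAStringSet]).
#' @param pattern IUPAC pattern string.
#' @return integer vector of match counts.
#' @export
count_motifs <- function(sequence, pattern) {
  if (is.character(sequence))
    sequence <- Biostrings::DNAStringSet(chartr("Uu", "Tt", sequence))
  as.integer(Biostrings::vcountPattern(pattern, sequence,
                                       fixed = "subject"))
}

# transcript-coordinate region boundaries as [start, end) per region class
region_bounds <- function(tr, region_class) {
  switch(region_class,
         utr5 = cbind(0L, tr$utr5_len),
         cds = cbind(tr$utr5_len, tr$utr5_len + tr$cds_len),
         utr3 = cbind(tr$utr5_len + tr$cds_len, tr$spliced_length),
         exons = cbind(0L, tr$spliced_length),
         abort("unknown region class '%s'", region_class))
}

#' Per-gene motif density in a transcript region
#'
#' The motif count over the region's spliced sense-strand sequence divided
#' by the region length, reported per kb. Genes whose region has zero
#' length are flagged with `NA` density.
#'
#' @param models a `transcript_models` object (canonical isoforms).
#' @param tx_seq named `DNAStringSet` of spliced transcripts.
#' @param pattern IUPAC pattern (default `"GGACH"`).
#' @param region_class one of `"utr5"`, `"cds"`, `"utr3"`, `"exons"`.
#' @return data.frame: gene_id, chromosome, region, count, length_nt,
#'   density_per_kb.
#' @export
region_density <- function(models, tx_seq, pattern = "GGACH",
                           region_class = "utr3") {
  tr <- models$transcripts
  b <- region_bounds(tr, region_class)
  len <- b[, 2] - b[, 1]
  seqs <- tx_seq[tr$transcript_id]
  cnt <- integer(nrow(tr))
  nonzero <- len > 0
  if (any(nonzero)) {
    sub <- Biostrings::subseq(seqs[nonzero], start = b[nonzero, 1] + 1L,
                              end = b[nonzero, 2])
    cnt[nonzero] <- count_motifs(sub, pattern)
  }
  data.frame(gene_id = tr$gene_id, chromosome = tr$chromosome,
             region = region_class, count = cnt, length_nt = as.integer(len),
             density_per_kb = ifelse(len > 0, 1000 * cnt / len, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' All 18 DRACH 5-mers
#' @return character vector of DRACH motifs (D = A/G/T, R = A/G, H = A/C/T).
#' @export
drach_motifs <- function() {
  out <- as.character(outer(c("A", "G", "T"), c("A", "G"), paste0))
  out <- as.character(outer(out, "AC", paste0))
  sort(as.character(outer(out, c("A", "C", "T"), paste0)))
}

#' Densities of strong versus weak DRACH subsets
#'
#' Region densities are computed for the union of each 5-mer subset
#' (summing counts over member motifs) and the X-versus-autosome difference
#' is rank-sum tested per subset with Benjamini-Hochberg adjustment across
#' the two subsets. The default partition takes the GGACH family as strong
#' and the remaining DRACH 5-mers as weak.
#'
#' @param models a `transcript_models` object.
#' @param tx_seq named `DNAStringSet`.
#' @param strong_set,weak_set disjoint character vectors of 5-mers.
#' @param region_class region to scan (default `"utr3"`).
#' @param x_aliases chromosome names treated as X.
#' @return list with `densities` (gene_id, chromosome, subset,
#'   density_per_kb) and `tests` (subset, p, p_adj).
#' @export
drach_subset_density <- function(models, tx_seq,
                                 strong_set = c("GGACA", "GGACC", "GGACT"),
                                 weak_set = setdiff(drach_motifs(),
                                                    c("GGACA", "GGACC",
                                                      "GGACT")),
                                 region_class = "utr3",
                                 x_aliases = c("X", "chrX")) {
  if (length(intersect(strong_set, weak_set)))
    abort("strong and weak motif sets overlap")
  subset_density <- function(motifs, label) {
    if (!length(motifs)) return(NULL)
    parts <- lapply(motifs, function(m)
      region_density(models, tx_seq, m, region_class))
    cnt <- Reduce(`+`, lapply(parts, `[[`, "count"))
    base <- parts[[1]]
    base$count <- cnt
    base$density_per_kb <- ifelse(base$length_nt > 0,
                                  1000 * cnt / base$length_nt, NA_real_)
    base$subset <- label
    base
  }
  dens <- rbind(subset_density(strong_set, "strong"),
                subset_density(weak_set, "weak"))
  tests <- do.call(rbind, lapply(unique(dens$subset), function(s) {
    d <- dens[dens$subset == s & !is.na(dens$density_per_kb), ]
    kl <- chromosome_class(d$chromosome, x_aliases)
    p <- if (nlevels(droplevels(kl)) == 2)
      suppressWarnings(stats::wilcox.test(d$density_per_kb ~ kl))$p.value else NA_real_
    data.frame(subset = s, p = p, stringsAsFactors = FALSE)
  }))
  tests$p_adj <- adjust_bh(tests$p)
  list(densities = dens, tests = tests)
}

#' Compare motif densities of ortholog groups across species
#'
#' Genes are restricted to one-to-one orthologs present in every species;
#' within each species, exonic motif densities are grouped by the *mouse*
#' chromosome class of the ortholog group and rank-sum tested, with
#' Benjamini-Hochberg adjustment across species.
#'
#' @param densities_by_species named list (species -> data.frame with
#'   gene_id, density_per_kb); must include the reference species named
#'   `reference_species`.
#' @param ortholog_map data.frame (mouse_gene, species, ortholog_gene);
#'   many-to-many rows are dropped and counted.
#' @param mouse_chromosome_class named vector mouse_gene ->
#'   `"autosome"`/`"X"` (or chromosome names, converted).
#' @param reference_species name of the reference species in
#'   `densities_by_species` (its gene ids are the `mouse_gene` ids).
#' @return list with `per_species` (species, n per class, median densities,
#'   p, p_adj), `n_dropped_many_to_many`, `n_groups`.
#' @export
ortholog_group_compare <- function(densities_by_species, ortholog_map,
                                   mouse_chromosome_class,
                                   reference_species = "mouse") {
  if (!reference_species %in% names(densities_by_species))
    abort("densities_by_species must include '%s'", reference_species)
  om <- ortholog_map
  # one-to-one within species: a mouse gene (or target gene) appearing twice
  # for the same species is ambiguous
  key_m <- paste(om$species, om$mouse_gene)
  key_o <- paste(om$species, om$ortholog_gene)
  bad <- key_m %in% key_m[duplicated(key_m)] |
    key_o %in% key_o[duplicated(key_o)]
  n_dropped <- sum(bad)
  om <- om[!bad, , drop = FALSE]
  other_species <- setdiff(names(densities_by_species), reference_species)
  per_sp_map <- split(om, om$species)
  complete <- Reduce(intersect, c(
    list(densities_by_species[[reference_species]]$gene_id),
    lapply(other_species, function(s) per_sp_map[[s]]$mouse_gene)))
  if (!length(complete)) abort("no ortholog groups span all species")

  if (!all(mouse_chromosome_class %in% c("autosome", "X")))
    mouse_chromosome_class <- stats::setNames(
      as.character(chromosome_class(mouse_chromosome_class)),
      names(mouse_chromosome_class))
  klass <- factor(mouse_chromosome_class[complete],
                  levels = c("autosome", "X"))

  rows <- lapply(c(reference_species, other_species), function(sp) {
    d <- densities_by_species[[sp]]
    dens <- stats::setNames(d$density_per_kb, d$gene_id)
    if (sp == reference_species) {
      v <- dens[complete]
    } else {
      m <- per_sp_map[[sp]]
      map <- stats::setNames(m$ortholog_gene, m$mouse_gene)
      v <- dens[map[complete]]
    }
    ok <- !is.na(v)
    p <- if (nlevels(droplevels(klass[ok])) == 2)
      suppressWarnings(stats::wilcox.test(v[ok] ~ klass[ok]))$p.value else NA_real_
    data.frame(species = sp,
               n_autosome = sum(klass[ok] == "autosome"),
               n_x = sum(klass[ok] == "X"),
               median_autosome = stats::median(v[ok][klass[ok] == "autosome"]),
               median_x = stats::median(v[ok][klass[ok] == "X"]),
               p = p, stringsAsFactors = FALSE)
  })
  per_species <- do.call(rbind, rows)
  per_species$p_adj <- adjust_bh(per_species$p)
  list(per_species = per_species, n_dropped_many_to_many = n_dropped,
       n_groups = length(complete))
}

#' Compare motif densities between gene sets and their class-matched
#' complement
#'
#' Each named gene set is tested (rank-sum) against the non-member genes of
#' the same chromosome class(es), with Benjamini-Hochberg adjustment across
#' sets; also reports the `k` lowest-density genes for downstream
#' enrichment tools (ties broken by gene_id, so the list is deterministic).
#'
#' @param densities data.frame (gene_id, chromosome, density_per_kb).
#' @param gene_sets named list of gene id vectors.
#' @param k number of lowest-density genes to report.
#' @param x_aliases chromosome names treated as X.
#' @return list with `tests` (set, n_set, n_complement, median_set,
#'   median_complement, p, p_adj, flag for empty intersections) and
#'   `lowest_density` (gene_id, density_per_kb).
#' @export
geneset_density_compare <- function(densities, gene_sets, k = 200,
                                    x_aliases = c("X", "chrX")) {
  d <- densities[!is.na(densities$density_per_kb), ]
  d$class <- as.character(chromosome_class(d$chromosome, x_aliases))
  rows <- lapply(names(gene_sets), function(nm) {
    members <- d$gene_id %in% gene_sets[[nm]]
    if (!any(members))
      return(data.frame(set = nm, n_set = 0L, n_complement = 0L,
                        median_set = NA_real_, median_complement = NA_real_,
                        p = NA_real_, empty = TRUE, stringsAsFactors = FALSE))
    classes <- unique(d$class[members])
    comp <- !members & d$class %in% classes
    p <- if (any(comp))
      suppressWarnings(stats::wilcox.test(
        d$density_per_kb[members], d$density_per_kb[comp]))$p.value
      else NA_real_
    data.frame(set = nm, n_set = sum(members), n_complement = sum(comp),
               median_set = stats::median(d$density_per_kb[members]),
               median_complement = stats::median(d$density_per_kb[comp]),
               p = p, empty = FALSE, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$p_adj <- adjust_bh(tests$p)
  ord <- order(d$density_per_kb, d$gene_id)
  lowest <- d[ord, c("gene_id", "density_per_kb")][seq_len(min(k, nrow(d))), ]
  rownames(lowest) <- NULL
  list(tests = tests, lowest_density = lowest)
}
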