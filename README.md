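# m6Adosage

Chromosome-stratified epitranscriptomics in R: mRNA half-lives from
SLAM-seq metabolic labeling, single-nucleotide m6A site quantification
across expression bins, the expression response to m6A depletion, and
GGACH/DRACH motif densities — the complete computational chain behind the
observation that X-chromosomal transcripts carry fewer m6A sites, live
longer, and are therefore spared when m6A is depleted, perturbing
X-to-autosome dosage compensation.

The package is written for computational biologists who want to run these
analyses on their own tables (conversion counts, site lists, count
matrices, GTF/FASTA annotations) or to study the estimators themselves: a
fully parameterized synthetic transcriptome generator with known ground
truth makes every stage verifiable by parameter recovery.

## The models in brief

* **Half-life.** For each 3'UTR the T→C conversion rate r(t) over a
  uridine chase follows first-order decay. After subtracting the no-label
  background and normalizing to chase onset,
  `log r(t) = −k t` and `t½ = ln 2 / k`; k is estimated by zero-intercept
  least squares on the log scale. Fits are filtered by T-coverage > 100,
  0.67 h ≤ t½ ≤ 18 h, residual s.e. ≤ 0.3, and validity in both
  conditions.
* **m6A landscape.** Transcripts are stratified into 12 expression bins
  (log10 TPM, step 0.25, TPM > 1). Per bin, a chromosome's mean site count
  over the all-chromosome mean gives a fold change; a chromosome's summary
  is the mean per-bin log2 FC (bins 3–8), with a negative-binomial GLM
  Wald test for the X-versus-autosome class.
* **Dosage response.** Counts are normalized by median-of-ratios factors
  on 100 reference genes (zero m6A sites, RPKM > 10; validated against
  spike-ins). Per-chromosome medians of per-gene log2 fold changes, an
  effect size in percent of the average IQR, and the X:A expression ratio
  ρ = median(X) / median(autosomes) with gene-level (paired, between
  conditions) bootstrap.
* **Motifs.** Canonical isoforms (TSL ≤ 3, level ≤ 2, CCDS; longest),
  overlap-counting IUPAC scans of spliced sense-strand sequence, densities
  per kb of 5'UTR/CDS/3'UTR, strong vs weak DRACH subsets, ortholog-group
  and gene-set comparisons.

## Worked example

The `analysis/` directory holds numbered drivers that run each stage on
the default synthetic dataset (2,000 genes; 19 autosomes + X) and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      --seed 1
Rscript analysis/02_halflife.R      --seed 1
Rscript analysis/03_m6a_landscape.R --seed 1
Rscript analysis/04_dosage.R        --seed 1
Rscript analysis/05_motifs.R        --seed 1
```

With seed 1 the drivers print, among other lines:

```
Planted GGACH densities (3'UTR): autosomes 3.11/kb, X 1.75/kb (configured 3.1 vs 1.7).
Fitted 4000 series; kept 3548 (low_coverage 0, t_half_high 2, t_half_low 1, poor_fit 256, other_condition 193).
Median half-life: control 3.34 h, depleted 3.75 h.
X vs autosome half-life response (mixed model): -0.054 log2 (p = 0.0148).
Median log2FC upon depletion: autosomes 0.132, X -0.008; effect size 49% of average IQR (rank-sum p = 1e-07).
Median log2FC by m6A burden: 0: 0.053, 1: 0.140, 2: 0.214, >=3: 0.358
X:A expression ratio: control 1.040 -> depleted 0.944 (delta -0.096, paired bootstrap p = 0.054).
utr3  GGACH/kb: autosomes 3.11, X 1.75 (adj. p = 3.4e-15)
```

Read: the generator planted the mouse 3'UTR motif densities and the
analysis recovered them; ~89% of conversion series passed the published
quality filters; m6A depletion lengthened half-lives and up-regulated
autosomal transcripts in proportion to their m6A burden while X
transcripts (no burden effect) stood still, so the X:A expression ratio
dropped — the dosage-compensation perturbation, here at desk scale where
the ratio test is direction-stable but borderline for significance (the
vignette discusses power versus gene count).

The methods vignette (`vignettes/methods.Rmd`) documents every model,
default and numerical choice, what the generator emulates, and what
passing tests do and do not show about real data.

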