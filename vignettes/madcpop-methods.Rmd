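---
title: "Methods: from microhaplotype read counts to population genetics"
author: "madcpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from microhaplotype read counts to population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madcpop)
```

# The data model

Targeted amplicon genotyping panels (DArTag-style) assay a fixed set of
~3,000 marker loci with short amplicons (54–81 bp) designed around known
SNPs. Sequencing a sample returns, for every locus, read counts over the
distinct amplicon sequences observed there — the *microhaplotypes*, each a
combination of the designed target SNP allele and any off-target variants
inside the amplicon, which are in near-complete linkage at these lengths.
The per-sample table of microhaplotype read counts is the MADC ("missing
allele discovery counts") report; it is the raw input of this package,
represented as a `MadcExperiment` (a `SummarizedExperiment` whose rows are
microhaplotype records and whose columns are samples), alongside a
`MadcPanel` (a `GRanges` carrying the reference amplicon and the 0-based
target-SNP offset per locus; genomic positions are 1-based).

When such a panel designed for one species is applied to relatives, a locus
only yields reads if its primer sites still match: the more diverged the
species, the more loci drop out. The package's analyses quantify exactly
this transferability, then use the loci that do amplify for diversity,
structure, phylogeny and label verification in germplasm collections of
predominantly self-pollinating diploids sampled as three single-plant
replicates plus one bulked (7-plant) sample per accession.

# Processing pipeline

`runPipeline()` executes the stages in a fixed order; every stage logs
in/out counts that are reconciled in the JSON run report.

1. **Singleton zeroing** (`zeroSingletons`): a read depth of exactly 1 for a
   microhaplotype is treated as sequencing error and set to 0. The rule is
   idempotent and is re-applied after pooling replicates
   (`consolidateSingles`), so pooled pseudo-samples face the same error
   model as real samples.
2. **Presence filtering** (`presenceMatrix`): a locus is present in a
   sample when its total read count is *strictly* greater than 10; loci
   present in >5% of samples are retained. All presence thresholds in the
   package are strict inequalities, so a locus seen in exactly 5% of
   samples is excluded at the 5% threshold.
3. **Diversity accounting** (`compareSingleVsBulk`, `lowessTrend`,
   `perMarkerHapProportion`, `replicateCorrelations`): microhaplotype
   counts per sample, the median over the three singles against the bulk,
   a LOWESS trend (f = 2/3, 3 robustness iterations — the classical
   defaults; the method itself prescribes none), and Pearson correlations
   of per-locus read-count totals among the four replicates.
4. **SNP extraction** (`extractSnps`): every observed microhaplotype is
   globally aligned to its locus's reference amplicon (match +1, mismatch
   −1, gap open −4, gap extend −1). Equal-length pairs within Hamming
   distance 5 skip the aligner: under this scoring any gapped alignment of
   equal-length sequences scores at least 11 below a perfect match, so the
   column-by-column comparison is provably optimal there. Each polymorphic
   aligned column becomes a SNP (the target column is always emitted and
   flagged), and read counts collapse into per-allele depths. Haplotypes
   aligning below 50% identity are flagged as putative paralogs and
   excluded from depths rather than silently dropped. InDels are aligned
   across but not emitted; a deleted column simply contributes no reads.
   The VCF writer emits `DP:RA:AD` genotype fields, encodes zero-depth
   calls as missing, and deliberately writes no file date so identical
   runs are byte-identical.
5. **Hind/HE filtering** (`hindHe`, `filterByHindHe`): per SNP and sample,
   Hind is the probability that two reads drawn without replacement carry
   distinct alleles, `(n² − Σc²)/(n(n−1))`; HE is `1 − Σp̂²` from pooled
   read fractions. For diploid outcrossers at equilibrium E[Hind/HE] = 1/2;
   paralog collapse pushes it above 1, inbreeding and allele-specific
   artifacts toward 0. SNPs with ratio in [0.1, 1.0] are retained.
6. **Dosage calling** (`callDosage`): maximum-likelihood diploid dosage
   under binomial read sampling with alternate-allele fractions
   {ε, ½, 1−ε} (ε = 0.01), minimum depth 10, ties resolved to the
   heterozygote, multiallelic SNPs collapsed to the most-read alternate.
   This deliberately simple, deterministic caller replaces hierarchical
   Bayesian machinery; for structure-level analyses on high-depth amplicon
   data the difference is immaterial and testability is better.
7. **Structure** (`genotypePca`, `weirFst`, `fstMatrix`): PCA uses SNP-wise
   mean imputation, column centering and SVD, with the sign convention
   that each component's largest-magnitude loading is positive.
   FST is the Weir–Cockerham method-of-moments decomposition (a, b, c) with
   weighted mean Σa/Σ(a+b+c); one single-plant replicate per accession
   (highest mean depth) enters these analyses.
8. **Phylogeny** (`sampleSequences`, `tamuraNeiDistance`, `njTree`,
   `bootstrapSupport`): per-sample SNP base strings (dosage 0 → ref,
   2 → alt, heterozygote → read-majority allele with ties to ref,
   missing → N) feed Tamura–Nei (TN93) distances and neighbor-joining.
   Read-majority resolution keeps sequences on the A/C/G/T alphabet the
   distance is defined on; in highly selfed material heterozygotes are
   rare, so the approximation is mild. Saturated distances (a log argument
   ≤ 0) raise an error rather than returning a number; bootstrap
   replicates that saturate are skipped and support is normalized by the
   completed count. Negative NJ branch lengths are clamped to zero.
9. **Mislabel flagging** (`flagOutliers`): for each sample, the k = 5
   nearest neighbours (excluding its own accession) vote; if ≥ 80% of them
   belong to a single *other* species (with ≥ 2 accessions), the accession
   is flagged with that species as the proposed assignment. An explicit
   rule stands in for what is usually done by eye on a PCA or tree; ties
   and near-even votes yield no flag, which deliberately silences the
   statistic between genuinely indistinguishable sister species.

Welch's ANOVA (`stats::oneway.test`), Levene's test (`car::leveneTest`,
mean-centered) and a Games–Howell post hoc (own implementation: pairwise
Welch t statistics referred to the studentized range with q = t√2, plus an
insert-and-absorb compact letter display) compare missing-locus counts
among species.

# The synthetic-data generator

`simulateMadc()` generates MADC datasets with the statistical structure the
analyses assume, plus a complete ground-truth sidecar. Defaults describe
the study conditions the package is aimed at: a 3,000-locus panel on 8
chromosomes (per-chromosome weights of a real 3K panel), 81-bp amplicons,
10 species at divergences 0.15–1.10 from the design species, 192 accessions
(102 "Collection" + 90 "Genebank"), 3 singles + 1 bulk of 7 per accession
(768 samples).

- **Dropout**: a locus amplifies in a species with probability
  `plogis(0.55 − 1.2·d)`; coefficients were calibrated so per-species
  missing-locus fractions span roughly 40–70% across the divergence grid.
  A conserved core (15% of loci) amplifies in every species: without it,
  presence-in-all-species would be a product of 10 independent
  probabilities and the ">95% of samples" marker set would be empty,
  whereas panels in practice retain a sizeable cross-species core (the
  full-scale defaults give ~2,900 loci present in >5% of samples and
  ~375 in >95%, with per-species mean missing loci 1,220–1,880 of 3,000).
- **Differentiation**: Balding–Nichols Beta draws around ancestral
  frequencies p0 ~ U(0.05, 0.95), θ_between = 0.30 among species and
  θ_within = 0.05 between sources. Balding–Nichols is used precisely
  because its θ *is* the FST a correct Weir–Cockerham implementation must
  recover, giving the estimator an exact recovery oracle.
- **Selfing**: with probability F = 0.90 a plant's second amplicon
  haplotype is a copy of the first, giving the textbook inbred genotype
  frequencies; haplotypes are drawn with complete linkage within the
  amplicon and linkage equilibrium between loci.
- **Read depths**: negative binomial per sample × locus (mean 60, size 30)
  scaled by a per-locus lognormal amplification efficiency (median 1,
  sdlog 1.2). The locus effect is essential, not cosmetic: with i.i.d.
  depths, replicate read-count correlations are ~0, while locus-specific
  amplification bias — the dominant, highly reproducible feature of real
  amplicon data — produces the high replicate R² that the reproducibility
  analyses measure. The defaults follow from the closed form
  r ≈ c/(c + (1+c)/size) for the between-replicate correlation, where c is
  the squared coefficient of variation of the locus effect.
- **Errors**: with probability 0.05 per amplified sample × locus, one
  spurious microhaplotype (reference sequence mutated at a non-SNP
  position, drawn from a two-sequence per-locus pool) receives exactly one
  read; singleton zeroing removes these by construction.
- **Mislabels**: requested swaps change only the metadata label, never the
  generating genotypes, so detection can be scored against truth.

What the generator does *not* emulate: linkage maps and recombination,
InDels, per-read base-call errors inside retained haplotypes, ascertainment
bias of the panel's SNP selection, and accession-level family structure
(plants are drawn from their source population, so accessions are more
diverse than true single-collection seed lots). Passing tests therefore
demonstrate correctness of the estimators and the internal consistency of
the pipeline under this model — not field performance on any particular
real panel.

# Numerical and design choices

- **Hind/HE sample set.** Singles-only Hind/HE under strong selfing has
  expectation (1−F)/2 ≈ 0.05, *below* the fixed 0.1 retention bound — the
  filter would discard ~98% of honest SNPs. The pipeline therefore
  computes Hind/HE over all replicates by default (bulks pool 14 allele
  copies and carry the accession-level heterozygosity), which restores the
  statistic's discriminating range; `filters$hindhe_exclude_bulks = TRUE`
  restores the singles-only reading.
- **Degenerate inputs.** Monomorphic SNPs have HE = 0 and an undefined
  ratio (dropped by the filter with a logged count); zero-variance
  replicate vectors yield NA correlations; an empty common-locus set is a
  warning, not an error; group tests refuse degenerate groups.
- **Tie-breaks.** Dosage likelihood ties go to the heterozygote; base
  majority ties at heterozygous sites go to the reference; NJ ties follow
  the agglomeration order of `ape::nj`.
- **Determinism.** A single integer seed drives panel, truth, reads,
  bootstrap and swaps; reruns with the same config are byte-identical
  (outputs carry no timestamps).
- **Problem sizes.** The test suite runs the generator mostly at 60–300
  loci with 3–4 species, sizes at which every stage is statistically
  well-posed; the single-vs-bulk and transferability checks run at the
  full default scale (3,000 loci, 768 samples). The estimator-recovery
  checks use 2,000 SNPs and 20+20 diploids per the Balding–Nichols
  oracle's design.

# Known limitations

Multiallelic SNPs are collapsed to the most-read alternate for dosage and
FST; paralog handling flags rather than deconvolves; the TN93 distance
errors on saturation instead of falling back to a cruder distance, so
extremely sparse SNP overlap between samples is a hard failure by design;
and the mislabel rule is intentionally conservative — it reports only
unambiguous majority votes and stays silent between species whose
between-FST is comparable to their within-FST.
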