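# Shared fixtures: small simulation configs and hand-built MADC tables.

suppressPackageStartupMessages({
  library(S4Vectors)
  library(SummarizedExperiment)
})

# A small, moderately diverged multi-species config that keeps every
# pipeline stage well-posed at test scale.
smallSimConfig <- function(seed = 1L, n_loci = 60L, mislabel_swaps = 0L,
                           ...) {
  simulationConfig(
    n_loci = n_loci,
    species = data.frame(
      name = c("spA", "spB", "spC"),
      divergence = c(0.2, 0.5, 0.9),
      n_collection = c(3L, 3L, 3L),
      n_genebank = c(2L, 2L, 2L)),
    mislabel_swaps = mislabel_swaps,
    seed = seed, ...)
}

# Hand-built two-locus MADC table: L1 (2 haps) and L2 (1 hap), 2 samples.
toyMadc <- function() {
  pan <- madcPanel(c("L1", "L2"), c("chr1.1", "chr2.1"), c(100L, 200L),
                   c("ACGTACGT", "TTGGCCAA"), c(3L, 0L))
  counts <- rbind(c(5L, 0L), c(3L, 8L), c(4L, 9L))
  colnames(counts) <- c("S1", "S2")
  MadcExperiment(counts,
                 locus_id = c("L1", "L1", "L2"),
                 hap_id = c("Ref", "Alt", "Ref"),
                 sequence = c("ACGTACGT", "ACGAACGT", "TTGGCCAA"),
                 panel = pan)
}

# Metadata for a set of accessions with 3 singles + 1 bulk each.
toyMetadata <- function(accessions, species = "spA", source = "Collection") {
  do.call(rbind, lapply(seq_along(accessions), function(i)
    data.frame(
      sample_id = paste0(accessions[i], c("_P1", "_P2", "_P3", "_B")),
      accession_id = accessions[i],
      species_label = rep(species, length.out = length(accessions))[i],
      source = source,
      role = c("single", "single", "single", "bulk"),
      plant_count = c(1L, 1L, 1L, 7L),
      stringsAsFactors = FALSE)))
}
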