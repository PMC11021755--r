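test_that("panel apportionment conserves locus counts and covers chromosomes", {
  cfg <- smallSimConfig(n_loci = 3000L)
  set.seed(1); pan <- simulatePanel(cfg)
  counts <- table(as.character(GenomicRanges::seqnames(pan)))
  expect_equal(sum(counts), 3000L)
  expect_true(all(counts >= 210 & counts <= 426))
  # n_loci = 8: exactly one locus per chromosome
  cfg8 <- smallSimConfig(n_loci = 8L)
  set.seed(1); pan8 <- simulatePanel(cfg8)
  expect_equal(as.integer(table(as.character(
    GenomicRanges::seqnames(pan8)))), rep(1L, 8))
  # determinism: same seed, byte-identical panel
  set.seed(9); p1 <- simulatePanel(cfg8)
  set.seed(9); p2 <- simulatePanel(cfg8)
  expect_identical(mcols(p1), mcols(p2))
  expect_error(simulationConfig(chromosomes = c("chr1", "chr2")),
               "8 chromosomes")
})

test_that("dropout follows the logistic model and is monotone in divergence", {
  cfg <- smallSimConfig(n_loci = 60L, dropout_a = 0.5, dropout_b = 1.5)
  set.seed(2); pan <- simulatePanel(cfg)
  # sigmoid(0) boundary: a = b*d means amplification probability 1/2
  cfg0 <- smallSimConfig(n_loci = 60L, dropout_a = 1e-9, dropout_b = 1)
  set.seed(3)
  flags <- replicate(400, simulateDropout(pan, 0, cfg0))
  expect_equal(mean(flags), 0.5, tolerance = 0.02)
  # Monte-Carlo means match the closed form and preserve ordering
  set.seed(4)
  for (d in c(0.1, 0.6, 1.4)) {
    p_hat <- mean(replicate(200, mean(simulateDropout(pan, d, cfg))))
    expect_equal(p_hat, plogis(0.5 - 1.5 * d), tolerance = 0.02)
  }
  set.seed(5)
  miss1 <- mean(!replicate(200, simulateDropout(pan, 0.3, cfg)))
  miss2 <- mean(!replicate(200, simulateDropout(pan, 1.0, cfg)))
  expect_lt(miss1, miss2)
})

test_that("Balding-Nichols frequencies have the stated degenerate and moment behavior", {
  sp <- data.frame(name = c("A", "B"), divergence = c(0, 0),
                   n_collection = c(1L, 1L), n_genebank = c(1L, 1L))
  set.seed(6)
  f0 <- simulateFrequencies(500, sp, theta_between = 0, theta_within = 0)
  expect_identical(f0$species_freq[, "A"], f0$p0)
  expect_identical(f0$group_freq[, "A:Genebank"], f0$p0)
  # theta = 1 is rejected
  expect_error(simulateFrequencies(10, sp, theta_between = 1), "theta")
  # moment check: Var(p_s | p0) = theta * p0 (1 - p0)
  set.seed(7)
  reps <- replicate(4000, {
    k <- (1 - 0.5) / 0.5
    rbeta(1, 0.5 * k, 0.5 * k)
  })
  expect_lt(abs(var(reps) - 0.5 * 0.5 * 0.5), 0.01)
  set.seed(8)
  f <- simulateFrequencies(4000, sp, theta_between = 0.5)
  # p0 varies per SNP; standardized deviations should have variance theta
  z <- (f$species_freq[, "A"] - f$p0)^2 / (f$p0 * (1 - f$p0))
  expect_equal(mean(z), 0.5, tolerance = 0.03)
})

test_that("genotype draws respect the inbreeding coefficient and sampling design", {
  sp <- data.frame(name = "A", divergence = 0, n_collection = 40L,
                   n_genebank = 0L)
  cfg1 <- simulationConfig(n_loci = 8L, species = sp, selfing_F = 1)
  set.seed(9)
  pan <- simulatePanel(cfg1)
  vars <- simulateLocusVariants(pan, cfg1)
  fr <- simulateFrequencies(nrow(vars), sp, 0.1, 0)
  g1 <- simulateAccessions(fr, vars, cfg1)
  # F = 1: the two haplotype copies are always identical
  expect_true(all(g1$copies[, 1, ] == g1$copies[, 2, ]))
  # F = 0 at p = 0.5: per-SNP heterozygote fraction near 1/2
  cfg0 <- simulationConfig(n_loci = 8L, species = sp, selfing_F = 0)
  fr$group_freq[] <- 0.5
  set.seed(10)
  g0 <- simulateAccessions(fr, vars, cfg0)
  # single-SNP loci: haplotype index 1/2 maps directly to the allele
  single <- which(g1$n_snps == 1L)
  het <- mean(vapply(single, function(l)
    mean(g0$copies[, 1, l] != g0$copies[, 2, l]), numeric(1)))
  n_draws <- dim(g0$copies)[1] * length(single)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / n_draws) + 0.01)
  # sample sheet: 3 singles + 1 bulk of n_plants - 3 per accession
  gen <- simulateMadc(smallSimConfig())
  tab <- table(gen$metadata$accession_id, gen$metadata$role)
  expect_true(all(tab[, "single"] == 3L & tab[, "bulk"] == 1L))
  expect_true(all(gen$metadata$plant_count[gen$metadata$role == "bulk"] == 7L))
})

test_that("read generation conserves depth and respects the truth set", {
  # error_rate = 0: per sample x locus counts are a multinomial over the
  # sample's true haplotypes; homozygous singles put all reads on one hap
  sp <- data.frame(name = "A", divergence = 0, n_collection = 4L,
                   n_genebank = 0L)
  cfg <- simulationConfig(n_loci = 10L, species = sp, selfing_F = 1,
                          error_rate = 0, dropout_a = 50, seed = 11)
  gen <- simulateMadc(cfg)
  cts <- madcCounts(gen$madc)
  singles <- gen$metadata$sample_id[gen$metadata$role == "single"]
  locus <- rowData(gen$madc)$locus_id
  for (s in singles) {
    per_locus_nonzero <- tapply(cts[, s] > 0, locus, sum)
    expect_true(all(per_locus_nonzero <= 1))   # fully homozygous plants
  }
  # error_rate = 1: every amplified locus gains at least one depth-1 hap
  cfg_e <- simulationConfig(n_loci = 10L, species = sp, selfing_F = 1,
                            error_rate = 1, dropout_a = 50, seed = 12)
  gen_e <- simulateMadc(cfg_e)
  cts_e <- madcCounts(gen_e$madc)
  rd_e <- rowData(gen_e$madc)
  err_rows <- grepl("^Other", rd_e$hap_id)
  per_sample_err <- rowsum((cts_e[err_rows, , drop = FALSE] == 1L) + 0L,
                           rd_e$locus_id[err_rows])
  expect_true(all(per_sample_err >= 1L))
  # bulk read split tracks the 14-copy dosage fraction (Monte-Carlo)
  cfg_b <- simulationConfig(n_loci = 8L, species = sp, selfing_F = 0,
                            error_rate = 0, dropout_a = 50,
                            depth_mean = 200, theta_between = 0.01,
                            seed = 13)
  gen_b <- simulateMadc(cfg_b)
  truth <- gen_b$truth
  bulks <- gen_b$metadata$sample_id[gen_b$metadata$role == "bulk"]
  cts_b <- madcCounts(gen_b$madc)
  rd_b <- rowData(gen_b$madc)
  plants <- truth$genotypes$plants
  for (b in bulks) {
    acc <- gen_b$metadata$accession_id[gen_b$metadata$sample_id == b]
    rows <- which(plants$accession_id == acc & plants$plant > 3L)
    for (l in seq_along(truth$panel)) {
      lid <- S4Vectors::mcols(truth$panel)$locus_id[l]
      dose <- table(factor(c(truth$genotypes$copies[rows, 1, l],
                             truth$genotypes$copies[rows, 2, l]),
                           levels = 1:64))
      obs <- cts_b[rd_b$locus_id == lid, b]
      tot <- sum(obs)
      if (tot < 50) next
      # compare observed fractions of the most common haplotype
      top <- which.max(dose)
      if (dose[top] == 14L) next     # monomorphic in the bulk: nothing to split
      seq_top <- madcpop:::.hap_sequence(
        S4Vectors::mcols(truth$panel)$ref_amplicon[l],
        truth$variants[truth$variants$locus_id == lid, ], as.integer(top))
      obs_top <- obs[rd_b$sequence[rd_b$locus_id == lid] == seq_top]
      p <- dose[top] / 14
      expect_lt(abs(obs_top / tot - p), 4 * sqrt(p * (1 - p) / tot))
    }
  }
  # conservation: nonzero counts only at amplified loci
  amp <- truth$amplification[, "A"]
  lid_all <- S4Vectors::mcols(truth$panel)$locus_id
  zero_loci <- lid_all[!amp]
  if (length(zero_loci))
    expect_true(all(cts_b[rd_b$locus_id %in% zero_loci, ] == 0L))
})

test_that("same seed gives byte-identical MADC and truth files", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  t1 <- withr::local_tempfile(fileext = ".json")
  t2 <- withr::local_tempfile(fileext = ".json")
  g1 <- simulateMadc(smallSimConfig(seed = 42))
  g2 <- simulateMadc(smallSimConfig(seed = 42))
  writeMadc(g1$madc, f1); writeMadc(g2$madc, f2)
  writeTruth(g1$truth, t1); writeTruth(g2$truth, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("truth sidecar round-trips", {
  gen <- simulateMadc(smallSimConfig(seed = 5, n_loci = 12L,
                                     mislabel_swaps = 2L))
  f <- withr::local_tempfile(fileext = ".json")
  writeTruth(gen$truth, f)
  back <- readTruth(f)
  expect_identical(back$genotypes$copies, gen$truth$genotypes$copies)
  expect_equal(back$frequencies$group_freq, gen$truth$frequencies$group_freq)
  expect_equal(back$mislabels, gen$truth$mislabels, ignore_attr = TRUE)
  expect_identical(back$amplification, gen$truth$amplification)
  # empty mislabel set round-trips as empty
  gen0 <- simulateMadc(smallSimConfig(seed = 5, n_loci = 12L))
  writeTruth(gen0$truth, f)
  expect_equal(nrow(readTruth(f)$mislabels), 0L)
})
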