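# Exhaustive oracle for the read-pair heterozygosity: enumerate every
# unordered pair of reads and count pairs carrying distinct alleles.
.hind_oracle <- function(ad) {
  reads <- rep(seq_along(ad), ad)
  n <- length(reads)
  if (n < 2) return(NA_real_)
  pairs <- combn(n, 2)
  mean(reads[pairs[1, ]] != reads[pairs[2, ]])
}

.mk_presence_experiment <- function(counts_by_locus) {
  n_l <- nrow(counts_by_locus)
  MadcExperiment(counts_by_locus, locus_id = sprintf("L%03d", seq_len(n_l)),
                 hap_id = rep("Ref", n_l),
                 sequence = rep("ACGT", n_l))
}

test_that("presence is strict: totals of 10 are absent, 11 present", {
  cts <- matrix(c(11L, 10L, 0L), 1, 3,
                dimnames = list(NULL, c("S1", "S2", "S3")))
  x <- .mk_presence_experiment(cts)
  pm <- presenceMatrix(x)
  expect_identical(as.vector(pm), c(TRUE, FALSE, FALSE))
  # threshold 0 reduces to any-read presence
  pm0 <- presenceMatrix(x, 0L)
  expect_identical(as.vector(pm0), c(TRUE, TRUE, FALSE))
  # totals are per locus, summed over microhaplotypes
  cts2 <- rbind(c(6L, 5L), c(5L, 5L))
  colnames(cts2) <- c("S1", "S2")
  x2 <- MadcExperiment(cts2, locus_id = c("L1", "L1"), hap_id = c("A", "B"),
                       sequence = c("AC", "AG"))
  expect_identical(as.vector(presenceMatrix(x2)), c(TRUE, FALSE))
})

test_that("presence curve is monotone non-increasing with strict thresholds", {
  set.seed(3)
  cts <- matrix(sample(c(0L, 50L), 40 * 20, TRUE, prob = c(0.4, 0.6)), 40, 20)
  colnames(cts) <- paste0("S", 1:20)
  pm <- presenceMatrix(.mk_presence_experiment(cts))
  cv <- presenceCurve(pm)
  expect_true(all(diff(cv$loci) <= 0))
  # locus in all samples is counted at every threshold below 100
  cts1 <- matrix(50L, 1, 20, dimnames = list(NULL, paste0("S", 1:20)))
  cv1 <- presenceCurve(presenceMatrix(.mk_presence_experiment(cts1)))
  expect_true(all(cv1$loci[cv1$percent < 100] == 1L))
  expect_equal(cv1$loci[cv1$percent == 100], 0L)   # strict >100% impossible
  # locus in 1 of 20 samples (5%) is excluded at t = 5 by strictness
  cts5 <- matrix(c(50L, rep(0L, 19)), 1, 20,
                 dimnames = list(NULL, paste0("S", 1:20)))
  cv5 <- presenceCurve(presenceMatrix(.mk_presence_experiment(cts5)))
  expect_equal(cv5$loci[cv5$percent == 5], 0L)
})

test_that("common-locus selection nests and reconciles per chromosome", {
  gen <- simulateMadc(smallSimConfig(seed = 41, n_loci = 60L))
  x <- zeroSingletons(gen$madc)
  pm <- presenceMatrix(x)
  s95 <- selectCommonLoci(pm, panel(x), 95)
  s5 <- selectCommonLoci(pm, panel(x), 5)
  expect_true(all(s95$loci %in% s5$loci))
  tot <- s5$by_chromosome
  expect_equal(tot$selected[tot$chromosome == "Total"],
               sum(tot$selected[tot$chromosome != "Total"]))
  expect_equal(tot$selected[tot$chromosome == "Total"], length(s5$loci))
  # constructed truth: loci forced present everywhere are always selected
  cts <- rbind(matrix(50L, 5, 20), matrix(0L, 5, 20))
  colnames(cts) <- paste0("S", 1:20)
  pm2 <- presenceMatrix(.mk_presence_experiment(cts))
  pan2 <- madcPanel(sprintf("L%03d", 1:10), rep("chr1.1", 10), 1:10,
                    rep("ACGT", 10), 0L)
  expect_setequal(selectCommonLoci(pm2, pan2, 95)$loci,
                  sprintf("L%03d", 1:5))
})

test_that("Hind matches the exhaustive read-pair oracle for all depth vectors up to 8 reads", {
  # all compositions of n <= 8 reads over up to 4 alleles
  for (n in 2:8) {
    comps <- expand.grid(rep(list(0:n), 4))
    comps <- comps[rowSums(comps) == n, ]
    for (r in seq_len(nrow(comps))) {
      ad <- as.integer(comps[r, ])
      expect_equal(madcpop:::.hind_one(ad), .hind_oracle(ad))
    }
  }
})

test_that("Hind/HE reproduces hand-computed values", {
  # single sample AD (3,3): Hind = 0.6, HE = 0.5, ratio 1.2
  gr <- GenomicRanges::GRanges("chr1.1", IRanges::IRanges(1, 1))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locus_id = "L1", ref = "A",
    alt = IRanges::CharacterList(list("C")), is_target = TRUE)
  mk_vs <- function(ad_list) {
    n <- length(ad_list)
    AD <- matrix(ad_list, 1, n)
    DP <- matrix(vapply(ad_list, sum, numeric(1)), 1, n)
    RA <- matrix(vapply(ad_list, `[`, numeric(1), 1), 1, n)
    storage.mode(DP) <- "integer"; storage.mode(RA) <- "integer"
    dimnames(DP) <- dimnames(RA) <- dimnames(AD) <-
      list("v1", paste0("S", seq_len(n)))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(DP = DP, RA = RA, AD = AD), rowRanges = gr)
    new("VariantSet", se)
  }
  r <- hindHe(mk_vs(list(c(3L, 3L))))
  expect_equal(r$hind, 0.6)
  expect_equal(r$he, 0.5)
  expect_equal(r$ratio, 1.2)
  # AD (6,0): all reads identical, Hind = 0 and HE = 0 so no ratio
  r2 <- hindHe(mk_vs(list(c(6L, 0L))))
  expect_equal(r2$hind, 0)
  expect_true(is.na(r2$ratio))
  # a 1-read sample does not contribute
  r3 <- hindHe(mk_vs(list(c(3L, 3L), c(1L, 0L))))
  expect_equal(r3$n_samples, 1L)
  expect_equal(r3$hind, 0.6)
})

test_that("Hind/HE has the diploid HWE expectation and drops under selfing", {
  sim_ratio <- function(F, seed) {
    set.seed(seed)
    n_snp <- 150; n_ind <- 80; depth <- 40
    ratios <- numeric(n_snp)
    for (k in seq_len(n_snp)) {
      p <- runif(1, 0.2, 0.8)
      probs <- c(p^2 + F * p * (1 - p), 2 * p * (1 - p) * (1 - F),
                 (1 - p)^2 + F * p * (1 - p))
      g <- sample(0:2, n_ind, TRUE, prob = probs)
      alt <- rbinom(n_ind, depth, g / 2)
      ad <- cbind(depth - alt, alt)
      hind <- mean((depth^2 - (ad[, 1]^2 + ad[, 2]^2)) /
                     (depth * (depth - 1)))
      q <- sum(ad[, 2]) / sum(ad)
      he <- 1 - q^2 - (1 - q)^2
      ratios[k] <- hind / he
    }
    mean(ratios)
  }
  expect_lt(abs(sim_ratio(0, 7) - 0.5), 0.03)
  expect_lt(sim_ratio(0.9, 8), 0.35)
  # package statistic agrees with the direct simulation route above:
  # mean ratio from hindHe on simulated HWE outcrossers is also ~0.5
  set.seed(9)
  sp <- data.frame(name = "A", divergence = 0, n_collection = 20L,
                   n_genebank = 0L)
  cfg <- simulationConfig(n_loci = 40L, species = sp, selfing_F = 0,
                          depth_mean = 60, depth_locus_sdlog = 0,
                          error_rate = 0, dropout_a = 50, seed = 10)
  gen <- simulateMadc(cfg)
  vs <- extractSnps(zeroSingletons(gen$madc))
  singles <- gen$metadata$sample_id[gen$metadata$role == "single"]
  hh <- hindHe(vs, samples = singles)
  poly <- !is.na(hh$ratio) & hh$he > 0.1
  expect_lt(abs(mean(hh$ratio[poly]) - 0.5), 0.05)
})

test_that("Hind/HE filter applies the inclusive 0.1-1.0 window", {
  res <- data.frame(variant_id = paste0("v", 1:5),
                    hind = 1, he = 1,
                    ratio = c(0.05, 1.2, 0.5, 0.1, NA))
  keep <- suppressMessages(filterByHindHe(res))
  expect_setequal(keep, c("v3", "v4"))
})

test_that("species shared-SNP intersections match hand enumeration", {
  md <- data.frame(sample_id = paste0("S", 1:6),
                   accession_id = paste0("A", 1:6),
                   species_label = rep(c("sp1", "sp2", "sp3"), each = 2),
                   source = "Collection", role = "single", plant_count = 1L)
  dm <- rbind(
    c(0L, 1L, 0L, NA, 0L, 0L),   # v1: poly in sp1 only
    c(0L, 1L, 0L, 2L, 0L, 0L),   # v2: poly in sp1 and sp2
    c(0L, 0L, 1L, 2L, 1L, 0L),   # v3: poly in sp2 and sp3
    c(0L, 0L, 0L, 0L, 0L, 0L))   # v4: monomorphic everywhere
  dm <- t(dm)
  rownames(dm) <- md$sample_id; colnames(dm) <- paste0("v", 1:4)
  sh <- speciesSharedSnps(dm, md)
  expect_equal(unname(sh$totals[c("sp1", "sp2", "sp3")]), c(2L, 2L, 1L))
  expect_equal(unname(sh$unique_counts[c("sp1", "sp2", "sp3")]),
               c(1L, 0L, 0L))
  expect_equal(sh$pairwise["sp1", "sp2"], 1L)
  expect_equal(sh$pairwise["sp1", "sp3"], 0L)
  expect_equal(sh$pairwise["sp2", "sp3"], 1L)
  # a species duplicated under two labels intersects fully
  md2 <- md; md2$species_label <- rep(c("x", "y"), 3)
  dm2 <- dm[, 1:3]
  dm2[] <- rep(c(0L, 1L), each = 3)
  sh2 <- speciesSharedSnps(dm2, md2)
  expect_equal(unname(sh2$pairwise["x", "y"]), 3L)
})

test_that("missingness counts complement presence", {
  cts <- rbind(c(50L, 0L), c(50L, 50L))
  colnames(cts) <- c("S1", "S2")
  pm <- presenceMatrix(.mk_presence_experiment(cts))
  expect_equal(unname(missingnessBySample(pm, 10L)), c(8L, 9L))
  expect_error(missingnessBySample(pm, 1L), "smaller")
  # divergent species miss more loci on synthetic data
  gen <- simulateMadc(smallSimConfig(seed = 43, n_loci = 100L))
  pm2 <- presenceMatrix(zeroSingletons(gen$madc))
  miss <- missingnessBySample(pm2, 100L)
  by_sp <- tapply(miss[gen$metadata$sample_id],
                  gen$metadata$species_label, mean)
  expect_lt(by_sp["spA"], by_sp["spC"])
})
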