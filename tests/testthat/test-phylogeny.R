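# TN93 oracle: ape's dist.dna implementation of the same model serves as an
# independent reference for the distance values.
.tn93_ape <- function(a, b) {
  m <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
  rownames(m) <- c("a", "b")
  as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "TN93",
                           pairwise.deletion = TRUE))
}

test_that("per-sample SNP bases follow dosage and read majority", {
  gr <- GenomicRanges::GRanges("chr1.1", IRanges::IRanges(1:2, 1:2))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locus_id = c("L1", "L2"), ref = c("A", "G"),
    alt = IRanges::CharacterList(list("C", "T")), is_target = TRUE)
  names(gr) <- c("v1", "v2")
  AD <- matrix(list(c(9L, 0L), c(2L, 9L), c(0L, 0L), c(5L, 5L)), 2, 2,
               byrow = TRUE)
  DP <- matrix(vapply(AD, sum, numeric(1)), 2, 2)
  RA <- matrix(vapply(AD, `[`, numeric(1), 1), 2, 2)
  storage.mode(DP) <- "integer"; storage.mode(RA) <- "integer"
  dimnames(DP) <- dimnames(RA) <- dimnames(AD) <-
    list(c("v1", "v2"), c("S1", "S2"))
  vs <- new("VariantSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(DP = DP, RA = RA, AD = AD), rowRanges = gr))
  dm <- matrix(c(0L, 1L, NA, 1L), 2, 2,
               dimnames = list(c("S1", "S2"), c("v1", "v2")))
  bm <- sampleSequences(dm, vs)
  expect_identical(bm["S1", ], c(v1 = "A", v2 = "N"))
  # het with AD (2,9): majority alternate; AD (5,5): tie resolves to ref
  expect_identical(bm["S2", ], c(v1 = "C", v2 = "G"))
})

test_that("TN93 distance matches an independent implementation to 1e-10", {
  expect_equal(tamuraNeiDistance("ACGTACGT", "ACGTACGT"), 0)
  set.seed(51)
  for (i in 1:20) {
    n <- 1000
    a <- paste(sample(c("A", "C", "G", "T"), n, TRUE,
                      prob = c(0.3, 0.2, 0.3, 0.2)), collapse = "")
    bc <- strsplit(a, "")[[1]]
    idx <- sample(n, 60)
    for (p in idx) bc[p] <- sample(setdiff(c("A", "C", "G", "T"), bc[p]), 1)
    b <- paste(bc, collapse = "")
    expect_equal(tamuraNeiDistance(a, b), .tn93_ape(a, b),
                 tolerance = 1e-10)
  }
  # N columns are excluded pairwise
  expect_equal(tamuraNeiDistance("ACGTN", "ACGTA"),
               tamuraNeiDistance("ACGT", "ACGT"))
  expect_error(tamuraNeiDistance("NNNN", "ACGT"), "comparable")
})

test_that("TN93 errors on saturation instead of returning a number", {
  # all transversions at half of all sites: log argument goes non-positive
  a <- strrep("A", 50)
  b <- paste(rep(c("C", "A"), 25), collapse = "")
  expect_error(tamuraNeiDistance(a, b), "saturated")
})

test_that("TN93 reduces to Jukes-Cantor under equal frequencies and balanced changes", {
  # 24 sites engineered so both sequences have equal base composition,
  # P1 = P2 = 1/12 and Q = 1/6 (= 2 * P1), the JC-symmetric configuration
  a <- c("A","G", "C","T", "A","C", "G","T", "A","T", "C","G",
         "A","C","G","T","A","C","G","T","A","C","G","T")
  b <- c("G","A", "T","C", "C","A", "T","G", "T","A", "G","C",
         "A","C","G","T","A","C","G","T","A","C","G","T")
  a <- paste(a, collapse = ""); b <- paste(b, collapse = "")
  p <- 12 / 24   # total proportion of differing sites
  jc <- -3 / 4 * log(1 - 4 / 3 * p)
  expect_equal(tamuraNeiDistance(a, b), jc, tolerance = 1e-8)
})

test_that("NJ recovers additive trees exactly", {
  # ((A:1,B:2):1,(C:3,D:4)) gives the additive matrix below
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- njTree(d)
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(d),
                                                           colnames(d)]),
               unname(d), tolerance = 1e-12)
  # random additive trees, 4-8 taxa: path lengths reconstructed < 1e-9
  set.seed(52)
  for (n in 4:8) {
    src <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    dd <- as.matrix(ape::cophenetic.phylo(src))
    tr2 <- njTree(dd)
    d2 <- as.matrix(ape::cophenetic.phylo(tr2))[rownames(dd), colnames(dd)]
    expect_lt(max(abs(d2 - dd)), 1e-9)
  }
  # 3 taxa: closed-form star lengths from the three-point equations
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- njTree(d3)
  e <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(e[["x"]], (2 + 3 - 4) / 2)
  expect_equal(e[["y"]], (2 + 4 - 3) / 2)
  expect_equal(e[["z"]], (3 + 4 - 2) / 2)
  d_bad <- d3; d_bad[1, 2] <- 5
  expect_error(njTree(d_bad), "symmetric")
})

test_that("bootstrap support is reproducible and tracks differentiation", {
  mk <- function(theta, seed) {
    set.seed(seed)
    sp <- data.frame(name = c("A", "B"), divergence = c(0, 0),
                     n_collection = c(1L, 1L), n_genebank = c(0L, 0L))
    fr <- simulateFrequencies(200, sp, theta)
    g <- rbind(t(replicate(6, rbinom(200, 2, fr$species_freq[, 1]))),
               t(replicate(6, rbinom(200, 2, fr$species_freq[, 2]))))
    rownames(g) <- paste0("S", 1:12); colnames(g) <- paste0("v", 1:200)
    ref <- rep("A", 200); alt <- rep("G", 200)
    gr <- GenomicRanges::GRanges("chr1.1", IRanges::IRanges(1:200, 1:200))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      locus_id = paste0("L", 1:200), ref = ref,
      alt = IRanges::CharacterList(as.list(alt)), is_target = TRUE)
    names(gr) <- paste0("v", 1:200)
    AD <- matrix(list(), 200, 12)
    for (k in 1:200) for (j in 1:12)
      AD[[k, j]] <- c(30L - 15L * g[j, k], 15L * g[j, k])
    DP <- matrix(30L, 200, 12); RA <- matrix(vapply(AD, `[`, numeric(1), 1),
                                             200, 12)
    storage.mode(RA) <- "integer"
    dimnames(DP) <- dimnames(RA) <- dimnames(AD) <-
      list(paste0("v", 1:200), paste0("S", 1:12))
    vs <- new("VariantSet", SummarizedExperiment::SummarizedExperiment(
      assays = list(DP = DP, RA = RA, AD = AD), rowRanges = gr))
    list(dm = g, vs = vs)
  }
  hi <- mk(0.48, 61)
  b1 <- bootstrapSupport(hi$dm, hi$vs, n_reps = 30, seed = 1)
  b2 <- bootstrapSupport(hi$dm, hi$vs, n_reps = 30, seed = 1)
  expect_identical(b1$support, b2$support)
  expect_null(bootstrapSupport(hi$dm, hi$vs, n_reps = 0)$support)
  # support for the species split at theta 0.48 exceeds theta 0.10
  split_support <- function(b, tips) {
    tr <- b$tree
    node <- ape::getMRCA(tr, tips)
    b$support[node - ape::Ntip(tr)]
  }
  lo <- mk(0.10, 61)
  b_lo <- bootstrapSupport(lo$dm, lo$vs, n_reps = 30, seed = 2)
  s_hi <- split_support(b1, paste0("S", 1:6))
  s_lo <- split_support(b_lo, paste0("S", 1:6))
  expect_gte(s_hi, s_lo)
  expect_gte(s_hi, 95)
})

test_that("FST species tree pairs the close species and roots on the outgroup", {
  fst <- matrix(c(0, 0.1, 0.4,
                  0.1, 0, 0.4,
                  0.4, 0.4, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- fstSpeciesTree(fst, "C")
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  root_children <- tr$edge[tr$edge[, 1] == ape::Ntip(tr) + 1, 2]
  expect_true(match("C", tr$tip.label) %in% root_children)
  fst_na <- fst; fst_na[1, 3] <- fst_na[3, 1] <- NA
  expect_error(fstSpeciesTree(fst_na, "C"), "A-C")
})

test_that("nearest-neighbour voting flags injected swaps and only those", {
  gen <- simulateMadc(smallSimConfig(
    seed = 71, n_loci = 150L,
    mislabel_swaps = data.frame(accession_id = "ACC002",
                                wrong_species = "spB")))
  x <- zeroSingletons(gen$madc)
  pm <- presenceMatrix(x)
  keep <- rownames(pm)[rowMeans(pm) > 0.05]
  vs <- extractSnps(x[rowData(x)$locus_id %in% keep, ],
                    panel(x)[mcols(panel(x))$locus_id %in% keep])
  dm <- callDosage(vs)
  md <- gen$metadata
  reps <- md$sample_id[md$role == "single" & grepl("_P1$", md$sample_id)]
  d <- tn93DistanceMatrix(sampleSequences(dm[reps, ], vs))
  flags <- suppressMessages(flagOutliers(d, md, k = 5, majority = 0.8))
  expect_equal(flags$accession_id, "ACC002")
  expect_equal(flags$labeled_species, "spB")
  expect_equal(flags$assigned_species, "spA")
  # without swaps nothing is flagged
  gen0 <- simulateMadc(smallSimConfig(seed = 71, n_loci = 150L))
  x0 <- zeroSingletons(gen0$madc)
  vs0 <- extractSnps(x0[rowData(x0)$locus_id %in% keep, ],
                     panel(x0)[mcols(panel(x0))$locus_id %in% keep])
  d0 <- tn93DistanceMatrix(sampleSequences(callDosage(vs0)[reps, ], vs0))
  expect_equal(nrow(suppressMessages(flagOutliers(d0, gen0$metadata))), 0L)
})

test_that("indistinguishable sister species do not trigger flags", {
  # two labels over one panmictic population: majority vote cannot settle
  set.seed(81)
  sp <- data.frame(name = "A", divergence = 0.1, n_collection = 10L,
                   n_genebank = 0L)
  cfg <- simulationConfig(n_loci = 100L, species = sp, seed = 81)
  gen <- simulateMadc(cfg)
  md <- gen$metadata
  md$species_label <- ifelse(md$accession_id %in%
                               sprintf("ACC%03d", 1:5), "sisterX", "sisterY")
  x <- zeroSingletons(gen$madc)
  vs <- extractSnps(x)
  dm <- callDosage(vs)
  reps <- md$sample_id[md$role == "single" & grepl("_P1$", md$sample_id)]
  d <- tn93DistanceMatrix(sampleSequences(dm[reps, ], vs))
  flags <- suppressMessages(flagOutliers(d, md, k = 5, majority = 0.8))
  # neighbours split ~evenly between the two labels: the 80% majority is
  # essentially unreachable for every sample
  expect_lte(nrow(flags), 1L)
})
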