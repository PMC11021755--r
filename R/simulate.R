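# Synthetic MADC generator. Emulates the statistical structure of a
# cross-species targeted amplicon (DArTag-style) experiment: a fixed panel
# designed on one species, genotyped across related species whose divergence
# from the design species drives locus dropout; Balding-Nichols allele
# frequency differentiation among species and between sources within a
# species; high selfing; 3 single-plant + 1 bulked (7-plant) sample per
# accession; negative-binomial read depths; and depth-1 error
# microhaplotypes. Ground truth is returned alongside the count table.

# Per-chromosome locus weights of a 3K panel (8 chromosomes).
.PANEL_CHROM_WEIGHTS <- c(414, 364, 419, 426, 390, 210, 367, 410)

#' Default species table for the synthetic generator
#'
#' Ten diploid species at increasing divergence from the (ungenotyped) panel
#' design species, each sampled from two sources ("Collection", a targeted
#' collecting mission, and "Genebank", a reference subset), 192 accessions in
#' total. Divergences span the range over which the default dropout model
#' yields roughly 40-70\% missing loci per species.
#'
#' @return data.frame with columns \code{name, divergence, n_collection,
#'   n_genebank}.
#' @export
defaultSpeciesTable <- function() {
  data.frame(
    name = sprintf("species%02d", 1:10),
    divergence = seq(0.15, 1.10, length.out = 10),
    n_collection = c(11L, 10L, 10L, 10L, 10L, 10L, 10L, 10L, 10L, 11L),
    n_genebank = rep(9L, 10),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic MADC generator
#'
#' @param n_loci number of panel loci (>= number of chromosomes).
#' @param chromosomes chromosome names; the panel model assumes 8.
#' @param amplicon_len amplicon length in bases.
#' @param species data.frame as \code{\link{defaultSpeciesTable}}.
#' @param theta_between Balding-Nichols differentiation among species, in
#'   [0, 1).
#' @param theta_within differentiation between sources within a species.
#' @param selfing_F inbreeding coefficient in [0, 1].
#' @param depth_mean,depth_dispersion negative-binomial read-depth mean and
#'   size (dispersion) per sample x locus, conditional on the locus's
#'   amplification efficiency.
#' @param depth_locus_sdlog spread (log scale) of the per-locus lognormal
#'   amplification efficiency, median-normalized to 1. Locus-specific
#'   amplification bias is what makes amplicon read counts reproducible
#'   across replicates of the same DNA; 0 disables it.
#' @param dropout_a,dropout_b logistic locus-amplification coefficients:
#'   a locus amplifies in a species with probability
#'   \code{plogis(dropout_a - dropout_b * divergence)}; \code{dropout_b > 0}.
#' @param conserved_fraction fraction of loci whose primer sites are
#'   conserved across the genus: these amplify in every species regardless
#'   of divergence, giving the panel a core of near-universal markers.
#' @param error_rate per sample x locus probability of one spurious depth-1
#'   microhaplotype.
#' @param n_offtarget_max maximum off-target SNPs per amplicon; the count is
#'   Poisson(1) capped at this value.
#' @param n_plants plants grown per accession; plants 1-3 are the single
#'   samples and the remainder form the bulk.
#' @param mislabel_swaps either an integer number of accessions to relabel
#'   with a wrong species, or a data.frame with columns \code{accession_id,
#'   wrong_species}.
#' @param seed integer seed; fully determines the generated dataset.
#' @return validated configuration list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(n_loci = 3000L,
                             chromosomes = paste0("chr", 1:8, ".1"),
                             amplicon_len = 81L,
                             species = defaultSpeciesTable(),
                             theta_between = 0.30,
                             theta_within = 0.05,
                             selfing_F = 0.90,
                             depth_mean = 60,
                             depth_dispersion = 30,
                             depth_locus_sdlog = 1.2,
                             dropout_a = 0.55,
                             dropout_b = 1.2,
                             conserved_fraction = 0.15,
                             error_rate = 0.05,
                             n_offtarget_max = 3L,
                             n_plants = 10L,
                             mislabel_swaps = 0L,
                             seed = 1L) {
  if (length(chromosomes) != 8L)
    .stopf("configuration error: exactly 8 chromosomes expected (got %d)",
           length(chromosomes))
  n_loci <- .check_count(n_loci, "n_loci", min = length(chromosomes))
  amplicon_len <- .check_count(amplicon_len, "amplicon_len", min = 2L)
  stopifnot(is.data.frame(species),
            all(c("name", "divergence", "n_collection", "n_genebank") %in%
                  colnames(species)))
  if (any(species$divergence < 0)) .stopf("divergences must be >= 0")
  .check_range(theta_between, "theta_between", 0, 1, hi_open = TRUE)
  .check_range(theta_within, "theta_within", 0, 1, hi_open = TRUE)
  .check_range(selfing_F, "selfing_F", 0, 1)
  .check_range(error_rate, "error_rate", 0, 1)
  .check_range(depth_mean, "depth_mean", 0, Inf, lo_open = TRUE)
  .check_range(depth_dispersion, "depth_dispersion", 0, Inf, lo_open = TRUE)
  .check_range(depth_locus_sdlog, "depth_locus_sdlog", 0, Inf)
  if (dropout_b <= 0) .stopf("configuration error: dropout_b must be > 0")
  .check_range(conserved_fraction, "conserved_fraction", 0, 1)
  n_plants <- .check_count(n_plants, "n_plants", min = 4L)
  n_offtarget_max <- .check_count(n_offtarget_max, "n_offtarget_max")
  structure(list(n_loci = n_loci, chromosomes = chromosomes,
                 amplicon_len = amplicon_len, species = species,
                 theta_between = theta_between, theta_within = theta_within,
                 selfing_F = selfing_F, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 depth_locus_sdlog = depth_locus_sdlog,
                 dropout_a = dropout_a,
                 conserved_fraction = conserved_fraction,
                 dropout_b = dropout_b, error_rate = error_rate,
                 n_offtarget_max = n_offtarget_max, n_plants = n_plants,
                 mislabel_swaps = mislabel_swaps, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a panel definition
#'
#' Assigns loci to the 8 chromosomes by largest-remainder apportionment of
#' the canonical 3K per-chromosome weights, draws sorted target-SNP
#' positions, a random reference amplicon per locus and a target-SNP offset
#' within it. Uses the current RNG stream.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A \linkS4class{MadcPanel}.
#' @export
simulatePanel <- function(config) {
  n_chr <- .apportion(config$n_loci, .PANEL_CHROM_WEIGHTS)
  chrom <- rep(config$chromosomes, n_chr)
  pos <- unlist(lapply(n_chr, function(k)
    sort(sample.int(5e7L, k))), use.names = FALSE)
  locus_id <- sprintf("L%04d", seq_len(config$n_loci))
  amp <- .random_dna(config$n_loci, config$amplicon_len)
  off <- sample.int(config$amplicon_len, config$n_loci, replace = TRUE) - 1L
  madcPanel(locus_id, chrom, pos, amp, off)
}

#' Simulate per-locus SNP definitions
#'
#' Each locus carries its target SNP plus \code{min(Poisson(1),
#' n_offtarget_max)} off-target SNPs at distinct offsets within the amplicon.
#' The target SNP is listed first for each locus.
#'
#' @param panel a \linkS4class{MadcPanel}.
#' @param config a \code{\link{simulationConfig}}.
#' @return data.frame: \code{locus_id, offset} (0-based), \code{ref, alt,
#'   is_target}.
#' @export
simulateLocusVariants <- function(panel, config) {
  m <- mcols(panel)
  n <- length(panel)
  len <- nchar(m$ref_amplicon)
  n_off <- pmin(stats::rpois(n, 1), config$n_offtarget_max)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    offs <- m$target_offset[i]
    if (n_off[i] > 0) {
      cand <- setdiff(seq_len(len[i]) - 1L, offs)
      offs <- c(offs, sort(sample(cand, n_off[i])))
    }
    ref <- substring(m$ref_amplicon[i], offs + 1L, offs + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(.DNA, b), 1L), character(1),
                  USE.NAMES = FALSE)
    out[[i]] <- data.frame(locus_id = m$locus_id[i], offset = offs,
                           ref = ref, alt = alt,
                           is_target = offs == m$target_offset[i],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate divergence-dependent locus dropout
#'
#' Each locus amplifies in a species with probability
#' \code{plogis(dropout_a - dropout_b * divergence)}, so the expected number
#' of missing loci is non-decreasing in divergence.
#'
#' @param panel a \linkS4class{MadcPanel}.
#' @param divergence non-negative divergence of the species from the panel's
#'   design species.
#' @param config a \code{\link{simulationConfig}}.
#' @return logical vector of per-locus amplification flags.
#' @export
simulateDropout <- function(panel, divergence, config) {
  stopifnot(divergence >= 0)
  p <- stats::plogis(config$dropout_a - config$dropout_b * divergence)
  stats::runif(length(panel)) < p
}

# Balding-Nichols draw: Beta(p(1-t)/t, (1-p)(1-t)/t) around p; t = 0 returns
# p exactly.
.bn_draw <- function(p, theta) {
  if (theta == 0) return(p)
  if (theta >= 1) .stopf("configuration error: theta must be < 1")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  k <- (1 - theta) / theta
  stats::rbeta(length(p), p * k, (1 - p) * k)
}

#' Simulate allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies p0 ~ Uniform(0.05, 0.95) per SNP; per-species
#' frequencies are Balding-Nichols draws around p0 with
#' \code{theta_between}; per-source frequencies are drawn the same way
#' around the species frequency with \code{theta_within}. Uses the current
#' RNG stream.
#'
#' @param n_snps number of SNPs.
#' @param species species table (see \code{\link{defaultSpeciesTable}}).
#' @param theta_between,theta_within differentiation parameters in [0, 1).
#' @return list: \code{p0} (vector), \code{species_freq} (n_snps x species),
#'   \code{group_freq} (n_snps x group, group = species:source),
#'   \code{groups} (data.frame species/source per group).
#' @export
simulateFrequencies <- function(n_snps, species, theta_between,
                                theta_within = 0) {
  p0 <- stats::runif(n_snps, 0.05, 0.95)
  sp_freq <- vapply(seq_len(nrow(species)), function(s)
    .bn_draw(p0, theta_between), numeric(n_snps))
  if (is.null(dim(sp_freq))) sp_freq <- matrix(sp_freq, nrow = n_snps)
  colnames(sp_freq) <- species$name
  groups <- data.frame(
    species = rep(species$name, each = 2L),
    source = rep(c("Collection", "Genebank"), nrow(species)),
    stringsAsFactors = FALSE)
  groups$n_accessions <- as.integer(t(as.matrix(
    species[, c("n_collection", "n_genebank")])))
  grp_freq <- vapply(seq_len(nrow(groups)), function(g)
    .bn_draw(sp_freq[, groups$species[g]], theta_within), numeric(n_snps))
  if (is.null(dim(grp_freq))) grp_freq <- matrix(grp_freq, nrow = n_snps)
  colnames(grp_freq) <- paste(groups$species, groups$source, sep = ":")
  list(p0 = p0, species_freq = sp_freq, group_freq = grp_freq,
       groups = groups)
}

#' Simulate accession and plant genotypes
#'
#' Grows \code{n_plants} plants per accession. Each plant's two amplicon
#' haplotypes at a locus are drawn from its source-group allele frequencies
#' with complete linkage within the amplicon; with probability
#' \code{selfing_F} the second haplotype is an identical copy of the first
#' (giving per-SNP genotype frequencies p^2 + Fpq, 2pq(1-F), q^2 + Fpq).
#' Plants 1-3 become the single samples; the remaining plants form the bulk.
#'
#' @param freqs output of \code{\link{simulateFrequencies}}.
#' @param variants output of \code{\link{simulateLocusVariants}}.
#' @param config a \code{\link{simulationConfig}}.
#' @return list: \code{accessions} (data.frame), \code{plants} (data.frame),
#'   \code{copies} (integer array [plant, 2, locus] of haplotype indices;
#'   index = 1 + sum over SNPs of allele * 2^snp_rank, target SNP first),
#'   \code{n_snps} per locus.
#' @export
simulateAccessions <- function(freqs, variants, config) {
  species <- config$species
  groups <- freqs$groups
  acc <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g)
    if (groups$n_accessions[g] > 0)
      data.frame(species_true = groups$species[g], source = groups$source[g],
                 group = g, stringsAsFactors = FALSE)[
                   rep(1L, groups$n_accessions[g]), ]))
  rownames(acc) <- NULL
  acc$accession_id <- sprintf("ACC%03d", seq_len(nrow(acc)))
  n_plants <- config$n_plants
  plants <- data.frame(
    accession_id = rep(acc$accession_id, each = n_plants),
    plant = rep(seq_len(n_plants), nrow(acc)),
    group = rep(acc$group, each = n_plants))
  locus_ids <- unique(variants$locus_id)
  n_loci <- length(locus_ids)
  snp_of_locus <- split(seq_len(nrow(variants)),
                        factor(variants$locus_id, levels = locus_ids))
  n_snps <- lengths(snp_of_locus)
  np <- nrow(plants)
  copies <- array(1L, dim = c(np, 2L, n_loci))
  plant_rows_by_group <- split(seq_len(np), plants$group)
  grp_ids <- as.integer(names(plant_rows_by_group))
  Fself <- config$selfing_F
  for (l in seq_len(n_loci)) {
    rows <- snp_of_locus[[l]]
    S <- length(rows)
    pw2 <- 2^(seq_len(S) - 1L)
    for (gi in seq_along(grp_ids)) {
      pr <- plant_rows_by_group[[gi]]
      npg <- length(pr)
      p <- freqs$group_freq[rows, grp_ids[gi]]
      a1 <- matrix(stats::rbinom(npg * S, 1L, rep(p, each = npg)), npg, S)
      h1 <- 1L + as.integer(a1 %*% pw2)
      dup <- stats::runif(npg) < Fself
      a2 <- matrix(stats::rbinom(npg * S, 1L, rep(p, each = npg)), npg, S)
      h2 <- 1L + as.integer(a2 %*% pw2)
      h2[dup] <- h1[dup]
      copies[pr, 1L, l] <- h1
      copies[pr, 2L, l] <- h2
    }
  }
  list(accessions = acc[, c("accession_id", "species_true", "source", "group")],
       plants = plants, copies = copies, n_snps = n_snps,
       locus_ids = locus_ids)
}

# Build the haplotype sequence for hap index h (1-based) of a locus.
.hap_sequence <- function(ref_amplicon, snp_tab, h) {
  s <- strsplit(ref_amplicon, "")[[1]]
  bits <- bitwAnd(h - 1L, 2^(seq_len(nrow(snp_tab)) - 1L)) > 0
  s[snp_tab$offset[bits] + 1L] <- snp_tab$alt[bits]
  paste(s, collapse = "")
}

#' Simulate MADC read counts from a truth set
#'
#' Per sample x locus, total depth is negative-binomial
#' (\code{depth_mean}, \code{depth_dispersion}); reads are allocated
#' multinomially over the sample's true haplotype copies (2 for singles,
#' 2 x bulk plants for bulks). Loci that did not amplify in a sample's (true)
#' species produce no reads. With probability \code{error_rate}, one
#' spurious microhaplotype receives exactly one read.
#'
#' @param truth a truth set as assembled by \code{\link{simulateMadc}}
#'   (needs \code{panel, variants, amplification, genotypes, samples}).
#' @param config a \code{\link{simulationConfig}}.
#' @return A \linkS4class{MadcExperiment}.
#' @export
simulateReads <- function(truth, config) {
  panel <- truth$panel
  samples <- truth$samples
  plants <- truth$genotypes$plants
  copies <- truth$genotypes$copies
  n_s <- nrow(samples)
  n_loci <- length(panel)
  # copy -> sample assignment (fixed: plants 1-3 are singles, rest the bulk)
  plant_sample <- integer(nrow(plants))
  for (j in seq_len(n_s)) {
    pr <- which(plants$accession_id == samples$accession_id[j] &
                  (if (samples$role[j] == "single")
                     plants$plant == samples$plant[j]
                   else plants$plant > 3L))
    plant_sample[pr] <- j
  }
  copy_sample <- c(plant_sample, plant_sample)   # column-major [,1] then [,2]
  sp_idx <- match(truth$species_of_accession[samples$accession_id],
                  colnames(truth$amplification))
  m_tab <- mcols(panel)
  snp_split <- split(truth$variants, factor(truth$variants$locus_id,
                                            levels = m_tab$locus_id))
  rows_info <- vector("list", n_loci)
  rows_counts <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    snp_tab <- snp_split[[l]]
    n_hap <- 2L^nrow(snp_tab)
    amp <- truth$amplification[l, sp_idx]
    eff <- if (is.null(truth$locus_efficiency)) 1
           else truth$locus_efficiency[l]
    depth <- stats::rnbinom(n_s, mu = config$depth_mean * eff,
                            size = config$depth_dispersion)
    depth[!amp] <- 0L
    h <- c(copies[, 1L, l], copies[, 2L, l])
    dos <- matrix(tabulate(h + n_hap * (copy_sample - 1L),
                           nbins = n_hap * n_s), n_hap, n_s)
    cnt <- matrix(0L, n_hap, n_s)
    rem <- as.integer(depth)
    mrem <- colSums(dos)
    for (k in seq_len(n_hap)) {
      pk <- ifelse(mrem > 0, dos[k, ] / mrem, 0)
      ck <- stats::rbinom(n_s, rem, pk)
      cnt[k, ] <- ck
      rem <- rem - ck
      mrem <- mrem - dos[k, ]
    }
    err <- stats::runif(n_s) < config$error_rate & amp
    keep <- which(rowSums(cnt) > 0L)
    info <- NULL
    counts <- NULL
    if (length(keep)) {
      seqs <- vapply(keep, function(k)
        .hap_sequence(m_tab$ref_amplicon[l], snp_tab, k), character(1))
      hap_id <- character(length(keep))
      hap_id[keep == 1L] <- "Ref"
      hap_id[keep == 2L] <- "Alt"
      other <- !keep %in% c(1L, 2L)
      hap_id[other] <- sprintf("AltMatch_%d", seq_len(sum(other)) + 1L)
      info <- data.frame(locus_id = m_tab$locus_id[l], hap_id = hap_id,
                         sequence = seqs, stringsAsFactors = FALSE)
      counts <- cnt[keep, , drop = FALSE]
    }
    if (any(err)) {
      # spurious depth-1 haplotypes drawn from a small per-locus pool of
      # sequences mutated at a non-SNP position
      pool_n <- 2L
      cand <- setdiff(seq_len(nchar(m_tab$ref_amplicon[l])) - 1L,
                      snp_tab$offset)
      pool_pos <- sample(cand, pool_n)
      pool_seq <- vapply(pool_pos, function(po) {
        s <- strsplit(m_tab$ref_amplicon[l], "")[[1]]
        s[po + 1L] <- sample(setdiff(.DNA, s[po + 1L]), 1L)
        paste(s, collapse = "")
      }, character(1))
      pick <- sample.int(pool_n, n_s, replace = TRUE)
      ecnt <- matrix(0L, pool_n, n_s)
      ecnt[cbind(pick, seq_len(n_s))] <- as.integer(err)
      ekeep <- rowSums(ecnt) > 0L
      einfo <- data.frame(locus_id = m_tab$locus_id[l],
                          hap_id = sprintf("Other_%d", which(ekeep)),
                          sequence = pool_seq[ekeep],
                          stringsAsFactors = FALSE)
      info <- rbind(info, einfo)
      counts <- rbind(counts, ecnt[ekeep, , drop = FALSE])
    }
    rows_info[[l]] <- info
    rows_counts[[l]] <- counts
  }
  info <- do.call(rbind, rows_info)
  counts <- do.call(rbind, rows_counts)
  colnames(counts) <- samples$sample_id
  MadcExperiment(counts, locus_id = info$locus_id, hap_id = info$hap_id,
                 sequence = info$sequence, panel = panel,
                 colData = DataFrame(samples, row.names = samples$sample_id))
}

#' Generate a complete synthetic MADC dataset with ground truth
#'
#' Runs the full generative model: panel, per-locus SNPs, per-species
#' dropout, Balding-Nichols frequencies, selfed diploid genotypes,
#' replicate/bulk sampling, negative-binomial read depths and error
#' haplotypes, plus optional species-label swaps. The seed in \code{config}
#' fully determines the output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list: \code{madc} (\linkS4class{MadcExperiment}),
#'   \code{metadata} (sample data.frame, with any injected wrong labels),
#'   \code{truth} (ground-truth list: panel, variants, frequencies,
#'   amplification flags, genotypes, sample table, mislabels).
#' @export
simulateMadc <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  panel <- simulatePanel(config)
  variants <- simulateLocusVariants(panel, config)
  # a conserved core of loci amplifies in every species; the rest follow
  # the divergence-dependent logistic dropout
  conserved <- stats::runif(length(panel)) < config$conserved_fraction
  amp <- vapply(seq_len(nrow(config$species)), function(s)
    conserved | simulateDropout(panel, config$species$divergence[s], config),
    logical(length(panel)))
  colnames(amp) <- config$species$name
  rownames(amp) <- mcols(panel)$locus_id
  freqs <- simulateFrequencies(nrow(variants), config$species,
                               config$theta_between, config$theta_within)
  # per-locus amplification efficiency (median 1): the reproducible
  # locus-specific depth bias of amplicon assays
  locus_eff <- stats::rlnorm(config$n_loci, 0, config$depth_locus_sdlog)
  geno <- simulateAccessions(freqs, variants, config)
  acc <- geno$accessions
  # sample sheet: three singles (plants 1-3) and one bulk per accession
  samples <- do.call(rbind, lapply(seq_len(nrow(acc)), function(i)
    data.frame(
      sample_id = paste0(acc$accession_id[i], c("_P1", "_P2", "_P3", "_B")),
      accession_id = acc$accession_id[i],
      species_true = acc$species_true[i],
      source = acc$source[i],
      role = c("single", "single", "single", "bulk"),
      plant = c(1L, 2L, 3L, NA_integer_),
      plant_count = c(1L, 1L, 1L, config$n_plants - 3L),
      stringsAsFactors = FALSE)))
  rownames(samples) <- NULL
  # mislabel injection: labels lie, genotypes keep the true species
  acc$species_label <- acc$species_true
  swaps <- config$mislabel_swaps
  if (is.numeric(swaps) && length(swaps) == 1L && swaps > 0) {
    pick <- sample(acc$accession_id, swaps)
    swaps <- data.frame(
      accession_id = pick,
      wrong_species = vapply(pick, function(a) {
        sample(setdiff(unique(acc$species_true),
                       acc$species_true[acc$accession_id == a]), 1L)
      }, character(1), USE.NAMES = FALSE), stringsAsFactors = FALSE)
  } else if (!is.data.frame(swaps)) {
    swaps <- data.frame(accession_id = character(0),
                        wrong_species = character(0))
  }
  if (nrow(swaps)) {
    i <- match(swaps$accession_id, acc$accession_id)
    if (anyNA(i)) .stopf("mislabel_swaps names unknown accession")
    acc$species_label[i] <- swaps$wrong_species
  }
  samples$species_label <- acc$species_label[match(samples$accession_id,
                                                   acc$accession_id)]
  species_of_accession <- stats::setNames(acc$species_true, acc$accession_id)
  truth <- list(panel = panel, variants = variants, frequencies = freqs,
                amplification = amp, conserved = conserved,
                locus_efficiency = locus_eff,
                genotypes = geno, samples = samples,
                species_of_accession = species_of_accession,
                accessions = acc,
                mislabels = swaps, config = config)
  class(truth) <- "MadcTruth"
  madc <- simulateReads(truth, config)
  metadata <- samples[, c("sample_id", "accession_id", "species_label",
                          "source", "role", "plant_count")]
  list(madc = madc, metadata = validateMetadata(metadata), truth = truth)
}

#' Write / read a truth set sidecar (JSON)
#'
#' Lossless round-trip of the simulator's ground truth.
#'
#' @param truth an \code{MadcTruth} list from \code{\link{simulateMadc}}.
#' @param path output JSON path.
#' @export
writeTruth <- function(truth, path) {
  g <- truth$genotypes
  obj <- list(
    panel = list(locus_id = mcols(truth$panel)$locus_id,
                 chromosome = as.character(
                   GenomicRanges::seqnames(truth$panel)),
                 position = GenomicRanges::start(truth$panel),
                 ref_amplicon = mcols(truth$panel)$ref_amplicon,
                 target_offset = mcols(truth$panel)$target_offset),
    variants = truth$variants,
    p0 = truth$frequencies$p0,
    species_freq = list(dim = dim(truth$frequencies$species_freq),
                        colnames = colnames(truth$frequencies$species_freq),
                        data = as.vector(truth$frequencies$species_freq)),
    group_freq = list(dim = dim(truth$frequencies$group_freq),
                      colnames = colnames(truth$frequencies$group_freq),
                      data = as.vector(truth$frequencies$group_freq)),
    groups = truth$frequencies$groups,
    amplification = list(dim = dim(truth$amplification),
                         colnames = colnames(truth$amplification),
                         rownames = rownames(truth$amplification),
                         data = as.vector(truth$amplification)),
    locus_efficiency = truth$locus_efficiency,
    conserved = truth$conserved,
    accessions = truth$accessions,
    plants = g$plants,
    copies = list(dim = dim(g$copies), data = as.vector(g$copies)),
    n_snps = as.integer(g$n_snps),
    locus_ids = g$locus_ids,
    samples = truth$samples,
    mislabels = truth$mislabels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @return \code{readTruth}: the truth set (class \code{MadcTruth}); the
#'   generator config is not stored and comes back NULL.
#' @export
readTruth <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  panel <- madcPanel(o$panel$locus_id, o$panel$chromosome, o$panel$position,
                     o$panel$ref_amplicon, o$panel$target_offset)
  mk_mat <- function(x) {
    m <- matrix(x$data, x$dim[1], x$dim[2])
    colnames(m) <- x$colnames
    if (!is.null(x$rownames)) rownames(m) <- x$rownames
    m
  }
  freqs <- list(p0 = o$p0, species_freq = mk_mat(o$species_freq),
                group_freq = mk_mat(o$group_freq), groups = o$groups)
  copies <- array(as.integer(o$copies$data), dim = o$copies$dim)
  geno <- list(accessions = o$accessions, plants = o$plants, copies = copies,
               n_snps = stats::setNames(as.integer(o$n_snps), o$locus_ids),
               locus_ids = o$locus_ids)
  mis <- as.data.frame(o$mislabels, stringsAsFactors = FALSE)
  if (!nrow(mis)) mis <- data.frame(accession_id = character(0),
                                    wrong_species = character(0))
  truth <- list(panel = panel, variants = o$variants, frequencies = freqs,
                amplification = mk_mat(o$amplification) > 0,
                locus_efficiency = o$locus_efficiency,
                conserved = o$conserved,
                genotypes = geno, samples = o$samples,
                species_of_accession = stats::setNames(
                  o$accessions$species_true, o$accessions$accession_id),
                accessions = o$accessions, mislabels = mis, config = NULL)
  class(truth) <- "MadcTruth"
  truth
}
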