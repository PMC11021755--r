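# Presence/missingness filters, presence curves, common-locus selection,
# Hind/HE computation and filtering, and per-species SNP intersections.
# All presence thresholds are strict (">").

#' Locus presence matrix
#'
#' A locus is "present" in a sample when its total read count (summed over
#' microhaplotypes) is strictly greater than \code{min_reads}: totals of 10
#' are absent, 11 present, under the default.
#'
#' @param x a \linkS4class{MadcExperiment}.
#' @param min_reads presence threshold (default 10, strict).
#' @return logical matrix loci x samples with attribute
#'   \code{"min_reads"}.
#' @export
presenceMatrix <- function(x, min_reads = 10L) {
  locus <- factor(rowData(x)$locus_id, levels = unique(rowData(x)$locus_id))
  tot <- rowsum(madcCounts(x), locus)
  pm <- tot > min_reads
  attr(pm, "min_reads") <- min_reads
  pm
}

#' Presence curve over sample-percentage thresholds
#'
#' For each threshold t, the number of loci present in strictly more than
#' t\% of samples; non-increasing in t.
#'
#' @param pm a \code{\link{presenceMatrix}}.
#' @param thresholds percentages (default 5 to 100 by 5).
#' @return data.frame \code{percent, loci}.
#' @export
presenceCurve <- function(pm, thresholds = seq(5L, 100L, 5L)) {
  if (ncol(pm) < 1L) .stopf("presence matrix has no samples")
  frac <- rowMeans(pm) * 100
  data.frame(percent = thresholds,
             loci = vapply(thresholds, function(t) sum(frac > t), integer(1)))
}

#' Select loci common to most samples
#'
#' Loci present (strictly) in more than \code{percent}\% of samples, with a
#' per-chromosome summary against the full panel.
#'
#' @param pm a \code{\link{presenceMatrix}}.
#' @param panel a \linkS4class{MadcPanel}.
#' @param percent presence percentage (default 95, strict).
#' @return list: \code{loci} (character vector), \code{by_chromosome}
#'   (data.frame \code{chromosome, selected, panel, ratio} plus a Total
#'   row).
#' @export
selectCommonLoci <- function(pm, panel, percent = 95) {
  frac <- rowMeans(pm) * 100
  loci <- rownames(pm)[frac > percent]
  if (!length(loci)) warning("no loci pass the ", percent, "% presence filter")
  pm_meta <- mcols(panel)
  chrom <- as.character(GenomicRanges::seqnames(panel))
  chroms <- unique(chrom)
  sel_chrom <- chrom[match(loci, pm_meta$locus_id)]
  tab <- data.frame(
    chromosome = chroms,
    selected = vapply(chroms, function(c) sum(sel_chrom == c, na.rm = TRUE),
                      integer(1)),
    panel = vapply(chroms, function(c) sum(chrom == c), integer(1)))
  tab <- rbind(tab, data.frame(chromosome = "Total",
                               selected = sum(tab$selected),
                               panel = sum(tab$panel)))
  tab$ratio <- round(tab$selected / tab$panel, 3)
  rownames(tab) <- NULL
  list(loci = loci, by_chromosome = tab)
}

# Within-sample read-pair heterozygosity for one AD vector: probability that
# two reads sampled without replacement carry distinct alleles.
.hind_one <- function(ad) {
  n <- sum(ad)
  if (n < 2L) return(NA_real_)
  (n^2 - sum(ad^2)) / (n * (n - 1))
}

#' Hind/HE statistic per SNP
#'
#' Hind is the mean over samples of the probability that two reads sampled
#' (without replacement) from that sample carry distinct alleles; HE is the
#' expected heterozygosity 1 - sum(p^2) from pooled read-fraction allele
#' frequencies. For diploid outcrossers at Hardy-Weinberg equilibrium the
#' ratio has expectation (ploidy-1)/ploidy = 0.5; values near 1 or above
#' suggest paralog collapse, values near 0 inbreeding or allele-specific
#' error. Samples with fewer than 2 reads at a SNP do not contribute to
#' Hind. Bulked samples pool many allele copies, so their within-sample
#' read heterozygosity approaches the accession-level expectation rather
#' than the individual one; use \code{samples} to restrict the statistic
#' to single-plant replicates when that reading is intended.
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param samples sample ids to use (default all).
#' @return data.frame \code{variant_id, hind, he, ratio, n_samples}; ratio
#'   is NA for monomorphic SNPs (HE = 0).
#' @export
hindHe <- function(vs, samples = colnames(vs)) {
  AD <- assay(vs, "AD")[, samples, drop = FALSE]
  DP <- assay(vs, "DP")[, samples, drop = FALSE]
  n_r <- nrow(AD); n_c <- ncol(AD)
  # flatten the allele-depth lists once: per-element row, allele rank and
  # flat cell index
  lens <- lengths(AD)
  flat <- as.numeric(unlist(AD, use.names = FALSE))
  el_cell <- rep.int(seq_len(n_r * n_c), lens)
  el_row <- rep.int(rep(seq_len(n_r), n_c), lens)
  el_allele <- sequence(lens)
  S2 <- matrix(0, n_r, n_c)
  s2 <- rowsum(flat^2, el_cell, reorder = FALSE)
  S2[as.integer(rownames(s2))] <- s2
  H <- (DP^2 - S2) / (DP * (DP - 1))
  H[DP < 2L] <- NA
  contrib <- !is.na(H)
  hind <- rowMeans(H, na.rm = TRUE)
  hind[rowSums(contrib) == 0L] <- NA
  # pooled read-fraction allele frequencies over contributing samples
  el_keep <- contrib[el_cell]
  he <- rep(NA_real_, n_r)
  if (any(el_keep)) {
    key <- el_row[el_keep] + n_r * (el_allele[el_keep] - 1)
    pooled <- rowsum(flat[el_keep], key, reorder = FALSE)
    prow <- ((as.integer(rownames(pooled)) - 1L) %% n_r) + 1L
    tot <- rowsum(pooled, prow)
    sq <- rowsum(pooled^2, prow)
    rowi <- as.integer(rownames(tot))
    he[rowi] <- 1 - sq[, 1] / tot[, 1]^2
  }
  ratio <- ifelse(!is.na(he) & he > 0, hind / he, NA_real_)
  data.frame(variant_id = rownames(vs), hind = hind, he = he,
             ratio = ratio, n_samples = rowSums(contrib),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter SNPs by Hind/HE ratio
#'
#' Keeps SNPs with \code{low <= ratio <= high}; undefined ratios
#' (monomorphic SNPs) are dropped. Counts are reported via message.
#'
#' @param res output of \code{\link{hindHe}}.
#' @param low,high retention bounds (defaults 0.1 and 1.0).
#' @return character vector of retained variant ids.
#' @export
filterByHindHe <- function(res, low = 0.1, high = 1.0) {
  keep <- !is.na(res$ratio) & res$ratio >= low & res$ratio <= high
  .msg("Hind/HE filter: %d of %d SNPs retained (%d undefined, %d out of [%g, %g])",
       sum(keep), nrow(res), sum(is.na(res$ratio)),
       sum(!keep) - sum(is.na(res$ratio)), low, high)
  res$variant_id[keep]
}

#' Per-species polymorphic SNP sets and their intersections
#'
#' A SNP is polymorphic within a species when at least two dosage classes
#' are observed among that species' genotyped samples. Species with fewer
#' than 2 accessions are skipped.
#'
#' @param dm dosage matrix (samples x SNPs; see \code{\link{callDosage}}).
#' @param metadata sample metadata for the dosage-matrix rows.
#' @return list: \code{per_species} (named list of SNP id vectors),
#'   \code{totals}, \code{unique_counts} (SNPs found in exactly one
#'   species), and \code{pairwise} (symmetric intersection-count matrix).
#' @export
speciesSharedSnps <- function(dm, metadata) {
  md <- metadata[match(rownames(dm), metadata$sample_id), ]
  sets <- list()
  for (sp in unique(md$species_label)) {
    rows <- which(md$species_label == sp)
    if (length(unique(md$accession_id[rows])) < 2L) {
      .msg("species '%s' skipped (<2 accessions)", sp)
      next
    }
    sub <- dm[rows, , drop = FALSE]
    n_classes <- apply(sub, 2, function(g) length(unique(g[!is.na(g)])))
    sets[[sp]] <- colnames(dm)[n_classes >= 2L]
  }
  if (!length(sets)) .stopf("no species with >= 2 accessions")
  all_snps <- unlist(sets, use.names = FALSE)
  uniq <- vapply(names(sets), function(sp)
    sum(!sets[[sp]] %in% unlist(sets[setdiff(names(sets), sp)],
                                use.names = FALSE)), integer(1))
  k <- length(sets)
  pw <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  list(per_species = sets, totals = lengths(sets), unique_counts = uniq,
       pairwise = pw)
}

#' Missing-locus count per sample
#'
#' @param pm a \code{\link{presenceMatrix}}.
#' @param panel_size total panel size (>= number of observed loci).
#' @return named integer vector: panel_size minus present loci, per sample.
#' @export
missingnessBySample <- function(pm, panel_size) {
  if (panel_size < nrow(pm))
    .stopf("panel_size (%d) smaller than observed loci (%d)", panel_size,
           nrow(pm))
  panel_size - colSums(pm)
}
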