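# Microhaplotype-level cleaning and the single-plant vs bulked-sample
# diversity accounting.

#' Zero out depth-1 microhaplotype counts
#'
#' A read depth of one for a single microhaplotype is treated as a
#' sequencing error and set to zero; all other counts are unchanged. The
#' operation is idempotent.
#'
#' @param x a \linkS4class{MadcExperiment}.
#' @return the experiment with singleton counts zeroed.
#' @export
zeroSingletons <- function(x) {
  cts <- madcCounts(x)
  cts[cts == 1L] <- 0L
  SummarizedExperiment::assay(x, "counts") <- cts
  x
}

#' Count detected microhaplotypes per sample
#'
#' Number of microhaplotype records with a positive read count for the given
#' sample(s). Apply \code{\link{zeroSingletons}} first so depth-1 errors do
#' not inflate the count.
#'
#' @param x a \linkS4class{MadcExperiment}.
#' @param sample_id sample id(s); default all samples.
#' @return named integer vector.
#' @export
countMicrohaplotypes <- function(x, sample_id = colnames(x)) {
  bad <- setdiff(sample_id, colnames(x))
  if (length(bad)) .stopf("unknown sample(s): %s", paste(bad, collapse = ", "))
  colSums(madcCounts(x)[, sample_id, drop = FALSE] > 0L)
}

#' Pool an accession's single-plant samples into one pseudo-sample
#'
#' Per-microhaplotype counts are summed over the accession's single-plant
#' samples, then singleton zeroing is re-applied to the pooled counts so the
#' consolidated sample faces the same error model as real samples.
#'
#' @param x a \linkS4class{MadcExperiment}.
#' @param metadata sample metadata (see \code{\link{readMetadata}}).
#' @param accession accession id.
#' @return named integer vector of pooled counts (one per record).
#' @export
consolidateSingles <- function(x, metadata, accession) {
  ids <- metadata$sample_id[metadata$accession_id == accession &
                              metadata$role == "single"]
  ids <- intersect(ids, colnames(x))
  if (length(ids) < 2L)
    .stopf("accession '%s' has <2 single-plant samples", accession)
  pooled <- rowSums(madcCounts(x)[, ids, drop = FALSE])
  pooled[pooled == 1L] <- 0L
  stats::setNames(as.integer(pooled), rownames(x))
}

#' Compare microhaplotype diversity in single vs bulked samples
#'
#' For every accession with exactly three single-plant samples and one bulk,
#' reports the median microhaplotype count over the singles, the bulk count,
#' the consolidated (pooled singles) count and the bulk - median difference.
#' Other accessions are skipped with a message.
#'
#' @param x a singleton-zeroed \linkS4class{MadcExperiment}.
#' @param metadata sample metadata.
#' @return data.frame with one row per eligible accession: columns
#'   \code{accession_id, median_single_count, bulk_count,
#'   consolidated_count, delta}.
#' @export
compareSingleVsBulk <- function(x, metadata) {
  metadata <- metadata[metadata$sample_id %in% colnames(x), ]
  counts <- countMicrohaplotypes(x)
  res <- lapply(split(metadata, metadata$accession_id), function(m) {
    singles <- m$sample_id[m$role == "single"]
    bulk <- m$sample_id[m$role == "bulk"]
    if (length(singles) != 3L || length(bulk) != 1L) return(NULL)
    med <- stats::median(counts[singles])
    cons <- sum(consolidateSingles(x, m, m$accession_id[1]) > 0L)
    data.frame(accession_id = m$accession_id[1],
               median_single_count = med,
               bulk_count = unname(counts[bulk]),
               consolidated_count = cons,
               delta = unname(counts[bulk]) - med,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped) .msg("%d accession(s) without 3 singles + 1 bulk skipped",
                    skipped)
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' LOWESS trend of single-plant microhaplotype counts
#'
#' Orders accessions by their bulked-sample microhaplotype number and fits a
#' locally weighted regression (tricube weights, local linear fits) to the
#' single-plant median counts along that ordering.
#'
#' @param records output of \code{\link{compareSingleVsBulk}}.
#' @param f smoothing fraction (default 2/3).
#' @param iter robustness iterations (default 3).
#' @return the records ordered by \code{bulk_count}, with an added
#'   \code{smoothed} column of the same length.
#' @export
lowessTrend <- function(records, f = 2/3, iter = 3L) {
  if (nrow(records) < 5L) .stopf("need >= 5 accessions for a LOWESS trend")
  ord <- order(records$bulk_count, records$accession_id)
  records <- records[ord, ]
  fit <- stats::lowess(records$bulk_count, records$median_single_count,
                       f = f, iter = iter)
  # lowess() returns sorted-by-x values; x order already sorted here
  records$smoothed <- fit$y
  rownames(records) <- NULL
  records
}

#' Per-marker corrected microhaplotype proportion
#'
#' For each locus, the mean observed microhaplotype count over the chosen
#' sample group divided by the total number of distinct microhaplotypes at
#' that locus across all samples, scaling values to [0, 1]. Loci with no
#' microhaplotype detected anywhere are excluded with a message.
#'
#' @param x a singleton-zeroed \linkS4class{MadcExperiment}.
#' @param metadata sample metadata.
#' @param group \code{"singles"} or \code{"bulks"}.
#' @return named numeric vector (per locus) in [0, 1].
#' @export
perMarkerHapProportion <- function(x, metadata,
                                   group = c("singles", "bulks")) {
  group <- match.arg(group)
  role <- if (group == "singles") "single" else "bulk"
  ids <- intersect(metadata$sample_id[metadata$role == role], colnames(x))
  if (!length(ids)) .stopf("no %s samples present", group)
  cts <- madcCounts(x)
  locus <- factor(rowData(x)$locus_id,
                  levels = unique(rowData(x)$locus_id))
  detected_any <- rowSums(cts > 0L) > 0L
  total_haps <- as.vector(rowsum(as.integer(detected_any), locus))
  per_sample <- rowsum((cts[, ids, drop = FALSE] > 0L) + 0L, locus)
  mean_obs <- rowMeans(per_sample)
  drop <- total_haps == 0L
  if (any(drop)) .msg("%d locus/loci with no detected microhaplotypes excluded",
                      sum(drop))
  stats::setNames(mean_obs[!drop] / total_haps[!drop],
                  levels(locus)[!drop])
}

#' Pairwise Pearson correlations among an accession's replicates
#'
#' Per-sample vectors are total read counts per marker locus (summed over
#' its microhaplotypes), restricted to loci where at least one of the
#' accession's samples has reads. Zero-variance vectors yield NA entries.
#'
#' @param x a \linkS4class{MadcExperiment}.
#' @param metadata sample metadata.
#' @param accession accession id.
#' @return symmetric correlation matrix (typically 4 x 4: three singles and
#'   the bulk), diagonal 1.
#' @export
replicateCorrelations <- function(x, metadata, accession) {
  ids <- intersect(metadata$sample_id[metadata$accession_id == accession],
                   colnames(x))
  if (length(ids) < 2L)
    .stopf("accession '%s' has <2 genotyped samples", accession)
  locus <- factor(rowData(x)$locus_id, levels = unique(rowData(x)$locus_id))
  per_locus <- rowsum(madcCounts(x)[, ids, drop = FALSE], locus)
  keep <- rowSums(per_locus) > 0L
  per_locus <- per_locus[keep, , drop = FALSE]
  sds <- apply(per_locus, 2, stats::sd)
  if (any(sds == 0))
    .msg("zero-variance read-count vector(s) for %s: correlations undefined",
         paste(ids[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(per_locus))
  diag(r) <- 1
  r
}
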