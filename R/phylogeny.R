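# Distance-based phylogeny: per-sample SNP base strings, Tamura-Nei (TN93)
# distances, neighbor-joining with bootstrap support, an FST-based species
# tree, and nearest-neighbour taxonomic mislabel flagging.

.BASES <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)

#' Concatenated SNP base strings per sample
#'
#' One base per SNP per sample: dosage 0 gives the reference allele, 2 the
#' alternate, heterozygotes resolve to the allele with the higher read
#' count (ties to the reference) and missing dosages give N. Read-majority
#' resolution (rather than IUPAC ambiguity codes) keeps sequences on the
#' A/C/G/T alphabet that the nucleotide distance is defined on; for highly
#' selfing species heterozygotes are rare, so the impact is minor.
#'
#' @param dm dosage matrix from \code{\link{callDosage}} (carries the
#'   ref/alt alleles as attributes).
#' @param vs the \linkS4class{VariantSet} the dosages were called from
#'   (for read counts at heterozygous calls).
#' @return character matrix samples x SNPs of single bases; use
#'   \code{\link{tn93DistanceMatrix}} downstream.
#' @export
sampleSequences <- function(dm, vs) {
  m <- mcols(rowRanges(vs))
  ref <- stats::setNames(m$ref, rownames(vs))[colnames(dm)]
  # dosage is called against the most-read alternate, listed first
  alt <- stats::setNames(vapply(as.list(m$alt), function(a)
    if (length(a)) a[1] else NA_character_, character(1)),
    rownames(vs))[colnames(dm)]
  alt[is.na(alt)] <- ref[is.na(alt)]
  AD <- assay(vs, "AD")[colnames(dm), rownames(dm), drop = FALSE]
  out <- matrix("N", nrow(dm), ncol(dm), dimnames = dimnames(dm))
  for (k in seq_len(ncol(dm))) {
    d <- dm[, k]
    out[, k] <- ifelse(is.na(d), "N", ifelse(d == 0L, ref[k], alt[k]))
    het <- which(!is.na(d) & d == 1L)
    if (length(het)) {
      maj_alt <- vapply(AD[k, het], function(ad)
        length(ad) > 1L && ad[2] > ad[1], logical(1))
      out[het, k] <- ifelse(maj_alt, alt[k], ref[k])
    }
  }
  out
}

.encode_bases <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(x, "")[[1]]
  v <- unname(.BASES[x])
  v[is.na(v)] <- 0L
  v
}

# One TN93 term: -coef * log(arg); zero when the matching substitution
# proportion is zero, a saturation error when the log argument is <= 0.
.tn93_term <- function(coef, arg, prop) {
  if (!is.finite(coef) || coef == 0) {
    if (prop > 0) .stopf("Tamura-Nei distance undefined (saturated)")
    return(0)
  }
  if (arg <= 0) .stopf("Tamura-Nei distance undefined (saturated)")
  -coef * log(arg)
}

#' Tamura-Nei (TN93) nucleotide distance
#'
#' Distance between two equal-length sequences under the Tamura-Nei model
#' (distinct purine and pyrimidine transition rates, unequal base
#' frequencies estimated by averaging over both sequences). Sites where
#' either sequence has N (or a gap) are excluded pairwise.
#'
#' @param seq_a,seq_b sequences: single strings or character vectors over
#'   A/C/G/T/N.
#' @return the distance (substitutions per site). Errors when no site is
#'   comparable or the model saturates (a log argument <= 0).
#' @export
tamuraNeiDistance <- function(seq_a, seq_b) {
  a <- .encode_bases(seq_a)
  b <- .encode_bases(seq_b)
  if (length(a) != length(b)) .stopf("sequences must have equal length")
  use <- a > 0L & b > 0L
  if (!any(use)) .stopf("no comparable (non-N) sites")
  .tn93_core(a[use], b[use])
}

.tn93_core <- function(a, b) {
  n <- length(a)
  g <- (tabulate(a, 4L) + tabulate(b, 4L)) / (2 * n)   # A C G T
  gA <- g[1]; gC <- g[2]; gG <- g[3]; gT <- g[4]
  gR <- gA + gG; gY <- gC + gT
  diff <- a != b
  purA <- (a == 1L & b == 3L) | (a == 3L & b == 1L)
  pyrC <- (a == 2L & b == 4L) | (a == 4L & b == 2L)
  P1 <- mean(purA); P2 <- mean(pyrC)
  Q <- mean(diff & !purA & !pyrC)
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  .tn93_term(k1, 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR), P1) +
    .tn93_term(k2, 1 - gY * P2 / (2 * gC * gT) - Q / (2 * gY), P2) +
    .tn93_term(k3, 1 - Q / (2 * gR * gY), Q)
}

#' Pairwise TN93 distance matrix
#'
#' @param base_mat character matrix samples x sites (from
#'   \code{\link{sampleSequences}}); rows that are entirely N are dropped
#'   with a message.
#' @return symmetric distance matrix.
#' @export
tn93DistanceMatrix <- function(base_mat) {
  codes <- matrix(unname(.BASES[base_mat]), nrow(base_mat), ncol(base_mat))
  codes[is.na(codes)] <- 0L
  empty <- rowSums(codes > 0L) == 0L
  if (any(empty)) {
    .msg("%d all-missing sample(s) excluded from distances: %s", sum(empty),
         paste(rownames(base_mat)[empty], collapse = ", "))
    codes <- codes[!empty, , drop = FALSE]
    base_mat <- base_mat[!empty, , drop = FALSE]
  }
  n <- nrow(codes)
  d <- matrix(0, n, n, dimnames = list(rownames(base_mat),
                                       rownames(base_mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- codes[i, ] > 0L & codes[j, ] > 0L
    if (!any(use)) .stopf("samples %s and %s share no comparable sites",
                          rownames(base_mat)[i], rownames(base_mat)[j])
    d[i, j] <- d[j, i] <- .tn93_core(codes[i, use], codes[j, use])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \code{\link[ape]{nj}}); negative branch
#' lengths are clamped to zero with a message. Exact on additive distances.
#'
#' @param d symmetric distance matrix with zero diagonal, n >= 3.
#' @return an \code{ape} \code{phylo} tree.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) .stopf("need >= 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) .stopf("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) .stopf("distance matrix diagonal must be 0")
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    .msg("%d negative NJ branch length(s) clamped to 0", sum(neg))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Neighbor-joining tree with SNP bootstrap support
#'
#' Builds the point-estimate tree from all SNP columns, then resamples SNP
#' columns with replacement \code{n_reps} times, rebuilding
#' sequences-distances-NJ per replicate; support is the percentage of
#' completed replicates containing each internal bipartition of the point
#' tree. Replicates whose distances saturate are skipped with a message.
#'
#' @param dm dosage matrix (see \code{\link{callDosage}}).
#' @param vs the corresponding \linkS4class{VariantSet}.
#' @param n_reps bootstrap replicates (default 100).
#' @param seed optional seed for the resampling.
#' @return list: \code{tree} (phylo; \code{node.label} holds support, NA at
#'   the root), \code{support} (numeric, per internal node), \code{n_done}.
#' @export
bootstrapSupport <- function(dm, vs, n_reps = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base_mat <- sampleSequences(dm, vs)
  d0 <- tn93DistanceMatrix(base_mat)
  tree <- njTree(d0)
  if (n_reps == 0L)
    return(list(tree = tree, support = NULL, n_done = 0L))
  boot <- vector("list", n_reps)
  done <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncol(base_mat), replace = TRUE)
    tr <- tryCatch(njTree(tn93DistanceMatrix(
      base_mat[, idx, drop = FALSE])), error = function(e) NULL)
    if (is.null(tr)) next
    done <- done + 1L
    boot[[done]] <- tr
  }
  if (done < n_reps)
    .msg("%d bootstrap replicate(s) skipped (saturated distances)",
         n_reps - done)
  if (done == 0L) .stopf("all bootstrap replicates failed")
  cnt <- ape::prop.clades(tree, boot[seq_len(done)], rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  support <- 100 * cnt / done
  tree$node.label <- round(support, 1)
  list(tree = tree, support = support, n_done = done)
}

#' Species tree from a pairwise FST matrix
#'
#' Neighbor-joining on the FST matrix, rooted on the branch leading to
#' \code{root_species}.
#'
#' @param fst complete symmetric FST matrix over species.
#' @param root_species species to root on (must be a row of \code{fst}).
#' @return rooted \code{phylo} tree.
#' @export
fstSpeciesTree <- function(fst, root_species) {
  fst <- as.matrix(fst)
  miss <- which(is.na(fst) & upper.tri(fst), arr.ind = TRUE)
  if (nrow(miss))
    .stopf("FST matrix incomplete for pair(s): %s",
           paste(rownames(fst)[miss[, 1]], colnames(fst)[miss[, 2]],
                 sep = "-", collapse = ", "))
  if (!root_species %in% rownames(fst))
    .stopf("root species '%s' not in the matrix", root_species)
  tr <- njTree(fst)
  ape::root(tr, outgroup = root_species, resolve.root = TRUE)
}

#' Flag putative species mislabels by nearest-neighbour voting
#'
#' For each sample, takes its k nearest neighbours in the distance matrix
#' (excluding samples of the same accession); if a single species other
#' than the sample's label holds at least \code{majority} of the
#' neighbours, the sample's accession is flagged with that species as the
#' proposed assignment. Species represented by fewer than 2 accessions are
#' not eligible assignment targets.
#'
#' @param d distance matrix; row/col names are sample ids.
#' @param metadata sample metadata (needs \code{sample_id, accession_id,
#'   species_label}).
#' @param k neighbours to inspect (default 5).
#' @param majority fraction of neighbours required (default 0.8).
#' @return data.frame \code{accession_id, labeled_species,
#'   assigned_species} (zero rows when nothing is flagged).
#' @export
flagOutliers <- function(d, metadata, k = 5L, majority = 0.8) {
  d <- as.matrix(d)
  if (nrow(d) < k + 1L) .stopf("need more than k samples")
  md <- metadata[match(rownames(d), metadata$sample_id), ]
  acc_count <- table(unique(md[, c("accession_id", "species_label")])$species_label)
  eligible <- names(acc_count)[acc_count >= 2L]
  if (length(setdiff(names(acc_count), eligible)))
    .msg("species with <2 accessions not eligible as assignments: %s",
         paste(setdiff(names(acc_count), eligible), collapse = ", "))
  flags <- list()
  for (i in seq_len(nrow(d))) {
    others <- which(md$accession_id != md$accession_id[i])
    nb <- others[order(d[i, others])][seq_len(min(k, length(others)))]
    votes <- table(md$species_label[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) != 1L) next               # ambiguous: no flag
    if (top == md$species_label[i]) next
    if (!top %in% eligible) next
    if (votes[top] >= majority * k)
      flags[[length(flags) + 1L]] <- data.frame(
        accession_id = md$accession_id[i],
        labeled_species = md$species_label[i],
        assigned_species = top, stringsAsFactors = FALSE)
  }
  if (!length(flags))
    return(data.frame(accession_id = character(0),
                      labeled_species = character(0),
                      assigned_species = character(0)))
  out <- unique(do.call(rbind, flags))
  rownames(out) <- NULL
  out
}
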