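# Dosage calling, genotype and phenotype PCA, and Weir-Cockerham FST.

#' Call diploid allele dosage from read depths
#'
#' Maximum-likelihood diploid genotype under binomial read sampling with a
#' per-read error rate: alternate-read counts are compared against
#' alternate-allele fractions \code{epsilon}, 0.5 and \code{1 - epsilon}
#' for dosages 0, 1 and 2. Likelihood ties resolve to the heterozygote.
#' Multiallelic SNPs are collapsed to the most-read alternate allele versus
#' the rest. Samples with \code{DP < min_depth} are missing (NA).
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param min_depth minimum depth for a call (default 10).
#' @param error_rate per-read error rate epsilon (default 0.01).
#' @return integer matrix samples x SNPs of alternate-allele dosages
#'   0/1/2 or NA, with attributes \code{"alt_allele"} and
#'   \code{"ref_allele"} (per SNP) and the caller parameters.
#' @export
callDosage <- function(vs, min_depth = 10L, error_rate = 0.01) {
  AD <- assay(vs, "AD")
  DP <- assay(vs, "DP")
  m <- mcols(rowRanges(vs))
  n_v <- nrow(vs); n_s <- ncol(vs)
  alt_used <- character(n_v)
  a_cnt <- matrix(0L, n_v, n_s)   # reads on the chosen alternate
  for (k in seq_len(n_v)) {
    alts <- m$alt[[k]]
    if (!length(alts)) { alt_used[k] <- NA_character_; next }
    # alternates are depth-ordered by extractSnps; the first is most-read
    alt_used[k] <- alts[1]
    a_cnt[k, ] <- vapply(AD[k, ], function(ad) ad[2], numeric(1))
  }
  eps <- error_rate
  ll <- function(a, n, f) a * log(f) + (n - a) * log(1 - f)
  L0 <- ll(a_cnt, DP, eps)
  L1 <- ll(a_cnt, DP, 0.5)
  L2 <- ll(a_cnt, DP, 1 - eps)
  dos <- ifelse(L1 >= L0 & L1 >= L2, 1L, ifelse(L0 > L2, 0L,
                ifelse(L2 > L0, 2L, 1L)))
  dos[DP < min_depth] <- NA_integer_
  dos[is.na(alt_used), ] <- ifelse(DP[is.na(alt_used), , drop = FALSE] >=
                                     min_depth, 0L, NA_integer_)
  out <- t(dos)
  dimnames(out) <- list(colnames(vs), rownames(vs))
  attr(out, "ref_allele") <- stats::setNames(m$ref, rownames(vs))
  attr(out, "alt_allele") <- stats::setNames(alt_used, rownames(vs))
  attr(out, "min_depth") <- min_depth
  attr(out, "error_rate") <- error_rate
  out
}

#' PCA of a dosage matrix
#'
#' SNP-wise mean imputation of missing dosages, column centering and SVD.
#' All-missing and zero-variance SNPs are dropped. Sign convention: within
#' each component the largest-magnitude SNP loading is positive.
#'
#' @param dm dosage matrix, samples x SNPs.
#' @param n_components number of PCs to return.
#' @return list: \code{scores} (samples x PCs), \code{loadings},
#'   \code{variance} (fraction of total variance per PC),
#'   \code{imputed_fraction}.
#' @export
genotypePca <- function(dm, n_components = 10L) {
  storage.mode(dm) <- "double"
  all_na <- colSums(!is.na(dm)) == 0L
  if (any(all_na)) .msg("%d all-missing SNP(s) dropped", sum(all_na))
  dm <- dm[, !all_na, drop = FALSE]
  imp_frac <- mean(is.na(dm))
  mu <- colMeans(dm, na.rm = TRUE)
  for (j in which(colSums(is.na(dm)) > 0L)) dm[is.na(dm[, j]), j] <- mu[j]
  x <- sweep(dm, 2, colMeans(dm))
  keep <- colSums(x != 0) > 0L
  x <- x[, keep, drop = FALSE]
  if (nrow(x) < 2L || ncol(x) < 2L)
    .stopf("need >= 2 samples and >= 2 variable SNPs for PCA")
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]; sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  loadings <- sweep(sv$v, 2, flip, `*`)
  dimnames(scores) <- list(rownames(dm), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  list(scores = scores, loadings = loadings,
       variance = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
       imputed_fraction = imp_frac)
}

#' PCA of mixed phenotype descriptors
#'
#' Character/factor traits are expanded to full one-hot indicator columns,
#' all columns are standardized to unit variance (zero-variance columns
#' dropped with a message), and PCA is performed as in
#' \code{\link{genotypePca}}. Rows with any missing trait are dropped when
#' \code{complete_cases_only}.
#'
#' @param traits data.frame of descriptors, rownames = accessions.
#' @param complete_cases_only drop rows with any missing value
#'   (default TRUE).
#' @param n_components number of PCs.
#' @return as \code{\link{genotypePca}}, plus \code{n_used}.
#' @export
phenotypePca <- function(traits, complete_cases_only = TRUE,
                         n_components = 10L) {
  if (complete_cases_only) {
    cc <- stats::complete.cases(traits)
    if (!all(cc)) .msg("%d incomplete accession(s) dropped", sum(!cc))
    traits <- traits[cc, , drop = FALSE]
  }
  cols <- lapply(colnames(traits), function(nm) {
    v <- traits[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      v <- as.factor(v)
      m <- vapply(levels(v), function(l) as.numeric(v == l),
                  numeric(length(v)))
      if (is.null(dim(m))) m <- matrix(m, nrow = length(v))
      colnames(m) <- paste(nm, levels(v), sep = ".")
    }
    m
  })
  x <- do.call(cbind, cols)
  rownames(x) <- rownames(traits)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    .msg("%d zero-variance column(s) dropped: %s", sum(sds == 0),
         paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  x <- scale(x)
  res <- genotypePca(x, n_components)
  res$n_used <- nrow(x)
  res
}

# Weir & Cockerham (1984) per-SNP variance components a (among
# populations), b (among individuals within populations) and c (within
# individuals), for diploid dosage data over r >= 2 populations.
.wc_components <- function(dm, pops) {
  pops <- droplevels(as.factor(pops))
  r <- nlevels(pops)
  idx <- split(seq_len(nrow(dm)), pops)
  n_v <- ncol(dm)
  a <- b <- cc <- rep(NA_real_, n_v)
  n_i <- vapply(idx, function(rs) colSums(!is.na(dm[rs, , drop = FALSE])),
                numeric(n_v))
  p_i <- vapply(idx, function(rs)
    colMeans(dm[rs, , drop = FALSE], na.rm = TRUE) / 2, numeric(n_v))
  h_i <- vapply(idx, function(rs)
    colMeans(dm[rs, , drop = FALSE] == 1L, na.rm = TRUE), numeric(n_v))
  if (n_v == 1L) {
    n_i <- matrix(n_i, 1); p_i <- matrix(p_i, 1); h_i <- matrix(h_i, 1)
  }
  ok <- rowSums(n_i >= 2L) == r
  n_tot <- rowSums(n_i)
  nbar <- n_tot / r
  nc <- (n_tot - rowSums(n_i^2) / n_tot) / (r - 1)
  pbar <- rowSums(n_i * p_i) / n_tot
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / n_tot
  a_v <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b_v <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c_v <- hbar / 2
  a[ok] <- a_v[ok]; b[ok] <- b_v[ok]; cc[ok] <- c_v[ok]
  data.frame(variant_id = colnames(dm), a = a, b = b, c = cc)
}

#' Weir-Cockerham FST between two populations
#'
#' Per-SNP variance components of the Weir & Cockerham (1984)
#' method-of-moments decomposition (a: among populations, b: among
#' individuals within populations, c: within individuals), computed from
#' diploid dosage calls, and the weighted mean estimate
#' sum(a) / sum(a + b + c) over SNPs with a defined denominator.
#'
#' @param dm dosage matrix, samples x SNPs.
#' @param metadata sample metadata for the rows of \code{dm}.
#' @param pop_a,pop_b species (or group) labels to compare; with
#'   \code{by = "source"} the labels are sources within \code{species}.
#' @param by grouping column of \code{metadata} (default
#'   \code{"species_label"}).
#' @return list: \code{components} (per-SNP a, b, c), \code{fst}
#'   (weighted mean), \code{n_snps} (SNPs contributing).
#' @export
weirFst <- function(dm, metadata, pop_a, pop_b, by = "species_label") {
  md <- metadata[match(rownames(dm), metadata$sample_id), ]
  rows <- md[[by]] %in% c(pop_a, pop_b)
  if (sum(md[[by]] == pop_a, na.rm = TRUE) < 2L ||
      sum(md[[by]] == pop_b, na.rm = TRUE) < 2L)
    .stopf("both populations need >= 2 genotyped samples")
  comp <- .wc_components(dm[rows, , drop = FALSE], md[[by]][rows])
  denom <- comp$a + comp$b + comp$c
  use <- !is.na(denom) & denom > 0
  list(components = comp, fst = sum(comp$a[use]) / sum(denom[use]),
       n_snps = sum(use))
}

#' Pairwise weighted FST matrix
#'
#' All pairwise Weir-Cockerham weighted FST values among species (or among
#' sources within each species). Pairs lacking two genotyped samples on
#' either side are reported as NA.
#'
#' @param dm dosage matrix, samples x SNPs.
#' @param metadata sample metadata.
#' @param level \code{"species"} (pairs of species) or \code{"source"}
#'   (Collection vs Genebank within each species).
#' @return for \code{"species"}: a symmetric matrix with zero diagonal; for
#'   \code{"source"}: a data.frame \code{species, fst, n_snps} with NA for
#'   unavailable pairs.
#' @export
fstMatrix <- function(dm, metadata, level = c("species", "source")) {
  level <- match.arg(level)
  md <- metadata[match(rownames(dm), metadata$sample_id), ]
  if (level == "species") {
    sps <- sort(unique(md$species_label))
    k <- length(sps)
    if (k < 2L) .stopf("need >= 2 species")
    m <- matrix(0, k, k, dimnames = list(sps, sps))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      f <- tryCatch(
        weirFst(dm, md, sps[i], sps[j])$fst,
        error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- f
    }
    m
  } else {
    sps <- sort(unique(md$species_label))
    res <- lapply(sps, function(sp) {
      rows <- md$species_label == sp
      f <- tryCatch({
        r <- weirFst(dm[rows, , drop = FALSE], md[rows, ],
                     "Collection", "Genebank", by = "source")
        data.frame(species = sp, fst = r$fst, n_snps = r$n_snps)
      }, error = function(e)
        data.frame(species = sp, fst = NA_real_, n_snps = 0L))
      f
    })
    do.call(rbind, res)
  }
}

#' Rank agreement between per-species missingness and FST to a reference
#'
#' Orders species by their FST to a reference species and reports the
#' Spearman rank correlation with mean missing-locus counts; a positive
#' correlation reproduces the expected transferability decay (more distant
#' species miss more panel loci).
#'
#' @param missing_by_species named numeric vector (mean missing loci).
#' @param fst_to_reference named numeric vector (same species keys).
#' @return list: \code{table} (ordered data.frame), \code{spearman}.
#' @export
missingnessVsFst <- function(missing_by_species, fst_to_reference) {
  if (!setequal(names(missing_by_species), names(fst_to_reference)))
    .stopf("species keys of the two inputs differ")
  if (length(missing_by_species) < 2L)
    .stopf("need >= 2 species for a rank correlation")
  fst <- fst_to_reference[names(missing_by_species)]
  ord <- order(fst)
  tab <- data.frame(species = names(missing_by_species)[ord],
                    fst = unname(fst[ord]),
                    mean_missing = unname(missing_by_species[ord]))
  list(table = tab,
       spearman = stats::cor(tab$fst, tab$mean_missing, method = "spearman"))
}
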