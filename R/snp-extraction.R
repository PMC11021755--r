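# Alignment-based SNP extraction: align each observed microhaplotype to its
# locus's reference amplicon, collect target and off-target substitution
# columns, collapse read counts per allele, and emit VCF.

# scoring fixed: match +1, mismatch -1, gap open -4, gap extend -1
.ALN_MATCH <- 1; .ALN_MISMATCH <- -1; .ALN_GAP_OPEN <- 4; .ALN_GAP_EXT <- 1

.aln_submat <- local({
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(.ALN_MISMATCH, 5, 5, dimnames = list(letters, letters))
  diag(m) <- .ALN_MATCH
  m["N", ] <- 0; m[, "N"] <- 0
  m
})

#' Globally align a microhaplotype to its reference amplicon
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -4,
#' gap extend -1; N scores 0 against anything). Substitutions are reported
#' at 0-based reference (amplicon) offsets; gap and N columns are never
#' reported as substitutions. Equal-length pairs within Hamming distance 5
#' take a direct column-comparison fast path (provably optimal under this
#' scoring, since any gapped alignment of equal-length sequences scores at
#' least 11 below the perfect match).
#'
#' @param ref_amplicon reference amplicon sequence (A/C/G/T/N).
#' @param hap_sequence observed microhaplotype sequence.
#' @return list: \code{aligned_ref}, \code{aligned_hap} (gapped strings of
#'   equal length), \code{substitutions} (data.frame \code{offset, ref,
#'   alt}), \code{identity} (matching columns / alignment length).
#' @export
alignToReference <- function(ref_amplicon, hap_sequence) {
  if (!nzchar(ref_amplicon) || !nzchar(hap_sequence))
    .stopf("empty sequence passed to alignToReference")
  ref_amplicon <- toupper(ref_amplicon)
  hap_sequence <- toupper(hap_sequence)
  if (grepl("[^ACGTN]", ref_amplicon) || grepl("[^ACGTN]", hap_sequence))
    .stopf("sequences must be over A/C/G/T/N")
  rc <- strsplit(ref_amplicon, "")[[1]]
  hc <- strsplit(hap_sequence, "")[[1]]
  if (length(rc) == length(hc)) {
    diff <- rc != hc
    if (sum(diff) <= 5L) {
      sub <- diff & rc != "N" & hc != "N"
      return(list(aligned_ref = ref_amplicon, aligned_hap = hap_sequence,
                  substitutions = data.frame(
                    offset = which(sub) - 1L, ref = rc[sub], alt = hc[sub],
                    stringsAsFactors = FALSE),
                  identity = mean(!diff)))
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = ref_amplicon, subject = hap_sequence, type = "global",
    substitutionMatrix = .aln_submat,
    gapOpening = .ALN_GAP_OPEN, gapExtension = .ALN_GAP_EXT)
  ar <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ah <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  is_sub <- ar != ah & ar != "-" & ah != "-" & ar != "N" & ah != "N"
  offset <- cumsum(ar != "-") - 1L
  list(aligned_ref = paste(ar, collapse = ""),
       aligned_hap = paste(ah, collapse = ""),
       substitutions = data.frame(offset = offset[is_sub],
                                  ref = ar[is_sub], alt = ah[is_sub],
                                  stringsAsFactors = FALSE),
       identity = mean(ar == ah))
}

# Per-reference-offset base map of an aligned haplotype ("-" at deletions,
# insertions dropped).
.hap_base_map <- function(aln) {
  ar <- strsplit(aln$aligned_ref, "")[[1]]
  ah <- strsplit(aln$aligned_hap, "")[[1]]
  ah[ar != "-"]
}

#' Extract target and off-target SNPs from microhaplotype counts
#'
#' For each panel locus, aligns every observed microhaplotype to the
#' reference amplicon, emits one variant per polymorphic aligned column
#' (plus the target column, always, flagged \code{is_target}), and collapses
#' per-sample microhaplotype read counts into per-allele depths (AD).
#' Haplotypes aligning below \code{min_identity} are flagged as putative
#' paralogs and excluded from AD; their ids are recorded in
#' \code{metadata(result)$excluded_haplotypes}. InDels are aligned over but
#' not emitted as variants; a haplotype deleted at a column contributes no
#' reads there.
#'
#' @param x a singleton-zeroed \linkS4class{MadcExperiment} (typically
#'   restricted to presence-filtered loci).
#' @param panel a \linkS4class{MadcPanel}; defaults to the panel attached to
#'   \code{x}.
#' @param min_identity alignment identity below which a haplotype is treated
#'   as a putative paralog (default 0.5).
#' @return A \linkS4class{VariantSet} sorted by chromosome and position.
#' @export
extractSnps <- function(x, panel = NULL, min_identity = 0.5) {
  if (is.null(panel)) panel <- panel(x)
  if (is.null(panel)) .stopf("no panel attached or supplied")
  cts <- madcCounts(x)
  rd <- rowData(x)
  pm <- mcols(panel)
  n_s <- ncol(x)
  off_panel <- setdiff(unique(rd$locus_id), pm$locus_id)
  if (length(off_panel))
    .msg("%d locus/loci absent from the panel skipped in SNP extraction",
         length(off_panel))
  excluded <- list()
  recs <- list()
  for (i in seq_along(panel)) {
    lid <- pm$locus_id[i]
    rows <- which(rd$locus_id == lid)
    rows <- rows[rowSums(cts[rows, , drop = FALSE]) > 0L]
    if (!length(rows)) next          # locus with no read support at all
    ref <- pm$ref_amplicon[i]
    t_off <- pm$target_offset[i]
    ref_chars <- strsplit(ref, "")[[1]]
    maps <- list(); used <- integer(0)
    for (r in rows) {
      if (rd$sequence[r] == ref) {
        maps[[length(maps) + 1L]] <- ref_chars
        used <- c(used, r)
        next
      }
      aln <- alignToReference(ref, rd$sequence[r])
      if (aln$identity < min_identity) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          locus_id = lid, hap_id = rd$hap_id[r], identity = aln$identity,
          stringsAsFactors = FALSE)
        next
      }
      maps[[length(maps) + 1L]] <- .hap_base_map(aln)
      used <- c(used, r)
    }
    base_mat <- if (length(maps)) do.call(rbind, maps)
                else matrix(character(0), 0, nchar(ref))
    # polymorphic columns: any included haplotype carries a real base
    # different from the reference there
    poly <- which(vapply(seq_len(nchar(ref)), function(o) {
      b <- base_mat[, o]
      any(b != ref_chars[o] & b != "-" & b != "N")
    }, logical(1)))
    emit <- sort(union(poly, t_off + 1L)) - 1L   # 0-based
    for (o in emit) {
      b <- if (nrow(base_mat)) base_mat[, o + 1L] else character(0)
      ref_base <- ref_chars[o + 1L]
      cand <- setdiff(unique(b), c(ref_base, "-", "N"))
      allele_rows <- c(list(used[b == ref_base]),
                       lapply(cand, function(a) used[b == a]))
      ad <- vapply(allele_rows, function(rr)
        if (length(rr)) colSums(cts[rr, , drop = FALSE]) else integer(n_s),
        numeric(n_s))
      if (is.null(dim(ad))) ad <- matrix(ad, nrow = n_s)
      # order alternates by total depth (desc), ties alphabetical
      if (length(cand)) {
        tot <- colSums(ad)[-1]
        ord <- order(-tot, cand)
        ad <- cbind(ad[, 1, drop = FALSE], ad[, 1 + ord, drop = FALSE])
        cand <- cand[ord]
      }
      storage.mode(ad) <- "integer"
      recs[[length(recs) + 1L]] <- list(
        chrom = as.character(GenomicRanges::seqnames(panel))[i],
        pos = GenomicRanges::start(panel)[i] + (o - t_off),
        id = sprintf("%s_%02d", lid, o), locus_id = lid,
        ref = ref_base, alt = cand, is_target = o == t_off, ad = ad)
    }
  }
  if (!length(recs)) .stopf("no variants extracted")
  chrom <- vapply(recs, `[[`, character(1), "chrom")
  pos <- vapply(recs, `[[`, numeric(1), "pos")
  ord <- order(chrom, pos, vapply(recs, `[[`, character(1), "id"),
               method = "radix")
  recs <- recs[ord]
  gr <- GRanges(vapply(recs, `[[`, character(1), "chrom"),
                IRanges(vapply(recs, `[[`, numeric(1), "pos"), width = 1L))
  names(gr) <- vapply(recs, `[[`, character(1), "id")
  mcols(gr) <- DataFrame(
    locus_id = vapply(recs, `[[`, character(1), "locus_id"),
    ref = vapply(recs, `[[`, character(1), "ref"),
    alt = IRanges::CharacterList(lapply(recs, `[[`, "alt")),
    is_target = vapply(recs, `[[`, logical(1), "is_target"))
  DP <- matrix(unlist(lapply(recs, function(r) rowSums(r$ad))),
               nrow = length(recs), ncol = n_s, byrow = TRUE)
  RA <- matrix(unlist(lapply(recs, function(r) r$ad[, 1])),
               nrow = length(recs), ncol = n_s, byrow = TRUE)
  storage.mode(DP) <- "integer"; storage.mode(RA) <- "integer"
  AD <- matrix(vector("list", length(recs) * n_s), length(recs), n_s)
  for (k in seq_along(recs))
    AD[k, ] <- lapply(seq_len(n_s), function(j) recs[[k]]$ad[j, ])
  dimnames(DP) <- dimnames(RA) <- dimnames(AD) <-
    list(names(gr), colnames(x))
  se <- SummarizedExperiment(
    assays = list(DP = DP, RA = RA, AD = AD), rowRanges = gr,
    colData = colData(x))
  metadata(se)$excluded_haplotypes <-
    if (length(excluded)) do.call(rbind, excluded)
    else data.frame(locus_id = character(0), hap_id = character(0),
                    identity = numeric(0))
  if (length(excluded))
    .msg("%d putative paralogous haplotype(s) excluded (identity < %.2f)",
         length(excluded), min_identity)
  vs <- new("VariantSet", se)
  vs
}

#' Write a VariantSet to VCF 4.2
#'
#' FORMAT is \code{DP:RA:AD} (total depth, reference-allele depth,
#' per-allele depths, reference first). Samples with zero depth at a site
#' are written as missing (\code{.}). INFO carries the locus id
#' (\code{LID}) and a \code{TARGET} flag for designed target SNPs. Input
#' must be sorted by chromosome and position; duplicated (chrom, pos) pairs
#' are allowed and disambiguated by the locus-derived ID column.
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param path output path.
#' @export
emitVcf <- function(vs, path) {
  gr <- rowRanges(vs)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)
  o <- order(chrom, pos, method = "radix")
  if (!identical(o, seq_along(o)))
    .stopf("variants must be sorted by chromosome then position")
  dup <- duplicated(paste(chrom, pos))
  if (any(dup))
    .msg("%d duplicated (chrom, pos) record(s); disambiguated by ID",
         sum(dup))
  m <- mcols(gr)
  DP <- assay(vs, "DP"); AD <- assay(vs, "AD")
  alt_str <- vapply(as.list(m$alt), function(a)
    if (length(a)) paste(a, collapse = ",") else ".", character(1))
  info <- paste0("LID=", m$locus_id,
                 ifelse(m$is_target, ";TARGET", ""))
  body <- vapply(seq_len(nrow(vs)), function(k) {
    cells <- vapply(seq_len(ncol(vs)), function(j) {
      if (DP[k, j] == 0L) return(".")
      ad <- AD[[k, j]]
      sprintf("%d:%d:%s", DP[k, j], ad[1], paste(ad, collapse = ","))
    }, character(1))
    paste(c(chrom[k], pos[k], names(gr)[k], m$ref[k], alt_str[k], ".", ".",
            info[k], "DP:RA:AD", cells), collapse = "\t")
  }, character(1))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=madcpop",
    paste0("##contig=<ID=", unique(chrom), ">"),
    "##INFO=<ID=LID,Number=1,Type=String,Description=\"Marker locus id\">",
    "##INFO=<ID=TARGET,Number=0,Type=Flag,Description=\"Designed target SNP\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=RA,Number=1,Type=Integer,Description=\"Reference allele read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth for each allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vs)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
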