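#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData rowRanges
NULL

#' Marker panel definition for a targeted amplicon assay
#'
#' A \code{MadcPanel} is a \link[GenomicRanges]{GRanges} whose ranges are the
#' 1-based genomic positions of each locus's target SNP, carrying the panel
#' design as metadata columns: \code{locus_id} (unique), \code{ref_amplicon}
#' (the reference microhaplotype sequence over A/C/G/T) and
#' \code{target_offset} (0-based offset of the target SNP within the
#' amplicon).
#'
#' @aliases MadcPanel-class
#' @exportClass MadcPanel
setClass("MadcPanel", contains = "GRanges")

setValidity("MadcPanel", function(object) {
  m <- mcols(object)
  need <- c("locus_id", "ref_amplicon", "target_offset")
  if (!all(need %in% colnames(m)))
    return(paste("missing metadata columns:",
                 paste(setdiff(need, colnames(m)), collapse = ", ")))
  if (anyDuplicated(m$locus_id))
    return("locus_id values must be unique")
  len <- nchar(m$ref_amplicon)
  if (any(m$target_offset < 0L | m$target_offset >= len))
    return("target_offset must satisfy 0 <= target_offset < nchar(ref_amplicon)")
  if (any(grepl("[^ACGTN]", m$ref_amplicon)))
    return("ref_amplicon must be over the alphabet A/C/G/T/N")
  TRUE
})

#' Construct a MadcPanel
#'
#' @param locus_id character vector of unique locus identifiers.
#' @param chromosome chromosome name per locus.
#' @param position 1-based genomic coordinate of the target SNP.
#' @param ref_amplicon reference microhaplotype (amplicon) sequence.
#' @param target_offset 0-based offset of the target SNP within the amplicon.
#' @return A \linkS4class{MadcPanel}.
#' @examples
#' madcPanel("L1", "chr1.1", 1000L, "ACGTACGT", 3L)
#' @export
madcPanel <- function(locus_id, chromosome, position, ref_amplicon,
                      target_offset) {
  gr <- GRanges(seqnames = chromosome,
                ranges = IRanges(start = as.integer(position), width = 1L))
  mcols(gr) <- DataFrame(locus_id = as.character(locus_id),
                         ref_amplicon = toupper(as.character(ref_amplicon)),
                         target_offset = as.integer(target_offset))
  names(gr) <- locus_id
  new("MadcPanel", gr)
}

#' Microhaplotype read-count experiment (MADC table)
#'
#' A \code{MadcExperiment} extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: rows are microhaplotype
#' records (one observed amplicon sequence under one marker locus), columns
#' are samples, and the \code{"counts"} assay holds per-sample read counts.
#' Row metadata carries \code{locus_id}, \code{hap_id}, \code{sequence} and
#' \code{in_panel} (whether the locus is described by the attached panel).
#' The panel itself, when known, is stored in
#' \code{metadata(x)$panel}.
#'
#' @aliases MadcExperiment-class
#' @exportClass MadcExperiment
setClass("MadcExperiment", contains = "SummarizedExperiment")

setValidity("MadcExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  rd <- rowData(object)
  need <- c("locus_id", "hap_id", "sequence")
  if (!all(need %in% colnames(rd)))
    return(paste("missing rowData columns:",
                 paste(setdiff(need, colnames(rd)), collapse = ", ")))
  cts <- assay(object, "counts")
  if (any(cts < 0, na.rm = TRUE)) return("counts must be non-negative")
  key <- paste(rd$locus_id, rd$hap_id, sep = "|")
  if (anyDuplicated(key))
    return("hap_id must be unique within each locus")
  TRUE
})

#' Construct a MadcExperiment
#'
#' @param counts integer matrix of read counts, one row per microhaplotype
#'   record, one column per sample.
#' @param locus_id,hap_id,sequence row annotation vectors (recycled checks
#'   apply): the marker locus, the microhaplotype identifier within the
#'   locus, and the amplicon sequence.
#' @param panel optional \linkS4class{MadcPanel}; loci absent from the panel
#'   are kept and flagged \code{in_panel = FALSE}.
#' @param colData optional \link[S4Vectors]{DataFrame} of sample metadata.
#' @return A \linkS4class{MadcExperiment}.
#' @export
MadcExperiment <- function(counts, locus_id, hap_id, sequence, panel = NULL,
                           colData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  in_panel <- if (is.null(panel)) rep(NA, length(locus_id))
              else locus_id %in% mcols(panel)$locus_id
  rd <- DataFrame(locus_id = as.character(locus_id),
                  hap_id = as.character(hap_id),
                  sequence = as.character(sequence),
                  in_panel = in_panel)
  rownames(counts) <- paste(rd$locus_id, rd$hap_id, sep = "|")
  if (is.null(colData)) colData <- DataFrame(row.names = colnames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts), rowData = rd,
                             colData = colData)
  metadata(se)$panel <- panel
  new("MadcExperiment", se)
}

#' Per-SNP variant set with read-depth assays
#'
#' A \code{VariantSet} extends
#' \link[SummarizedExperiment]{RangedSummarizedExperiment}: rows are SNPs
#' (GRanges with \code{locus_id}, \code{ref}, \code{alt} - a CharacterList of
#' alternate alleles - and \code{is_target}), columns are samples. Assays:
#' \code{DP} (total read depth, integer), \code{RA} (reference-allele depth)
#' and \code{AD} (a list-matrix whose cells are integer vectors of per-allele
#' depths, reference first, in the order \code{c(ref, alt)}).
#'
#' @aliases VariantSet-class
#' @exportClass VariantSet
setClass("VariantSet", contains = "RangedSummarizedExperiment")

setValidity("VariantSet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("DP", "RA", "AD") %in% an))
    return("assays DP, RA and AD are required")
  m <- mcols(rowRanges(object))
  need <- c("locus_id", "ref", "alt", "is_target")
  if (!all(need %in% colnames(m)))
    return(paste("missing rowRanges columns:",
                 paste(setdiff(need, colnames(m)), collapse = ", ")))
  TRUE
})

# ---- generics & accessors ---------------------------------------------------

#' @rdname MadcExperiment
#' @param x a MadcExperiment.
#' @export
madcCounts <- function(x) assay(x, "counts")

#' @rdname MadcExperiment
#' @export
locusIds <- function(x) {
  if (is(x, "MadcExperiment")) rowData(x)$locus_id
  else if (is(x, "MadcPanel")) mcols(x)$locus_id
  else if (is(x, "VariantSet")) mcols(rowRanges(x))$locus_id
  else stop("no locus ids for this class")
}

#' @rdname MadcExperiment
#' @export
hapIds <- function(x) rowData(x)$hap_id

#' @rdname MadcExperiment
#' @export
hapSequences <- function(x) rowData(x)$sequence

#' Panel attached to a MadcExperiment
#' @param x a MadcExperiment.
#' @param value a MadcPanel or NULL.
#' @export
panel <- function(x) metadata(x)$panel

#' @rdname panel
#' @export
`panel<-` <- function(x, value) {
  metadata(x)$panel <- value
  validObject(x)
  x
}

setMethod("show", "MadcPanel", function(object) {
  cat(sprintf("MadcPanel with %d loci on %d sequence(s); amplicon lengths %s\n",
              length(object), length(unique(as.character(
                GenomicRanges::seqnames(object)))),
              paste(range(nchar(mcols(object)$ref_amplicon)), collapse = "-")))
  methods::callNextMethod()
})

setMethod("show", "MadcExperiment", function(object) {
  cat(sprintf("MadcExperiment: %d microhaplotype records over %d loci x %d samples\n",
              nrow(object), length(unique(rowData(object)$locus_id)),
              ncol(object)))
  if (!is.null(panel(object)))
    cat(sprintf("  panel: %d loci\n", length(panel(object))))
  invisible(NULL)
})

setMethod("show", "VariantSet", function(object) {
  tg <- sum(mcols(rowRanges(object))$is_target)
  cat(sprintf("VariantSet: %d SNPs (%d target, %d off-target) x %d samples\n",
              nrow(object), tg, nrow(object) - tg, ncol(object)))
  invisible(NULL)
})
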