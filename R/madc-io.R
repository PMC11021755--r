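# Reading and writing MADC count tables, panel definitions and sample
# metadata. The MADC dialect is fixed to three leading columns (AlleleID,
# CloneID, AlleleSequence) followed by one column per sample; any extra
# leading annotation columns before the first sample column are ignored with
# a message. AlleleID is "<locus_id>|<hap_id>".

.MADC_LEAD <- c("AlleleID", "CloneID", "AlleleSequence")

#' Read an MADC microhaplotype count table
#'
#' Parses a missing-allele-discovery-counts (MADC) style CSV: per-sample read
#' counts for every observed microhaplotype sequence, grouped under marker
#' loci. Loci present in the file but absent from \code{panel} are kept with
#' coordinates unset and flagged (\code{in_panel = FALSE}).
#'
#' @param path CSV file with header \code{AlleleID,CloneID,AlleleSequence}
#'   then one column per sample; \code{AlleleID} is
#'   \code{"<locus_id>|<hap_id>"}.
#' @param panel optional \linkS4class{MadcPanel}.
#' @return A \linkS4class{MadcExperiment}.
#' @export
readMadc <- function(path, panel = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(.MADC_LEAD %in% colnames(df)))
    .stopf("MADC format error: missing required columns %s",
           paste(setdiff(.MADC_LEAD, colnames(df)), collapse = ", "))
  lead_end <- max(match(.MADC_LEAD, colnames(df)))
  extra <- setdiff(colnames(df)[seq_len(lead_end)], .MADC_LEAD)
  if (length(extra))
    .msg("ignoring %d annotation column(s): %s", length(extra),
         paste(extra, collapse = ", "))
  sample_cols <- colnames(df)[-seq_len(lead_end)]
  if (!length(sample_cols)) .stopf("MADC format error: no sample columns")
  if (anyDuplicated(df$AlleleID))
    .stopf("MADC format error: duplicated AlleleID '%s'",
           df$AlleleID[anyDuplicated(df$AlleleID)])
  cts <- as.matrix(df[, sample_cols, drop = FALSE])
  suppressWarnings(storage.mode(cts) <- "double")
  if (anyNA(cts) || any(cts != floor(cts)))
    .stopf("MADC format error: non-integer read count found")
  storage.mode(cts) <- "integer"
  parts <- regmatches(df$AlleleID, regexpr("|", df$AlleleID, fixed = TRUE),
                      invert = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    .stopf("MADC format error: AlleleID without '|' separator: '%s'",
           df$AlleleID[bad][1])
  locus_id <- vapply(parts, `[`, character(1), 1L)
  hap_id <- vapply(parts, `[`, character(1), 2L)
  x <- MadcExperiment(cts, locus_id = locus_id, hap_id = hap_id,
                      sequence = df$AlleleSequence, panel = panel)
  if (!is.null(panel)) {
    n_off <- sum(!rowData(x)$in_panel)
    if (n_off) .msg("%d record(s) at loci absent from the panel (flagged)",
                    n_off)
  }
  .msg("read %d MADC records (%d input rows) for %d samples from %s",
       nrow(x), nrow(df), ncol(x), path)
  x
}

#' Write an MADC count table
#'
#' Canonical column order (\code{AlleleID,CloneID,AlleleSequence,<samples>})
#' and deterministic row order (locus, then hap id); round-trips through
#' \code{\link{readMadc}}.
#'
#' @param x a \linkS4class{MadcExperiment}.
#' @param path output CSV path.
#' @export
writeMadc <- function(x, path) {
  rd <- rowData(x)
  ord <- order(rd$locus_id, rd$hap_id, method = "radix")
  df <- data.frame(AlleleID = paste(rd$locus_id, rd$hap_id, sep = "|")[ord],
                   CloneID = rd$locus_id[ord],
                   AlleleSequence = rd$sequence[ord],
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(madcCounts(x)[ord, , drop = FALSE],
                                check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a panel definition CSV
#'
#' Columns: \code{locus_id, chromosome, position, ref_amplicon,
#' target_offset} (position 1-based, offset 0-based).
#' @param path CSV path.
#' @return \code{readPanel}: a \linkS4class{MadcPanel}.
#' @export
readPanel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "chromosome", "position", "ref_amplicon",
            "target_offset")
  if (!all(need %in% colnames(df)))
    .stopf("panel format error: missing columns %s",
           paste(setdiff(need, colnames(df)), collapse = ", "))
  madcPanel(df$locus_id, df$chromosome, df$position, df$ref_amplicon,
            df$target_offset)
}

#' @rdname readPanel
#' @param panel a \linkS4class{MadcPanel}.
#' @export
writePanel <- function(panel, path) {
  df <- data.frame(locus_id = mcols(panel)$locus_id,
                   chromosome = as.character(GenomicRanges::seqnames(panel)),
                   position = GenomicRanges::start(panel),
                   ref_amplicon = mcols(panel)$ref_amplicon,
                   target_offset = mcols(panel)$target_offset)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.SAMPLE_ROLES <- c("single", "bulk")

#' Read and validate sample metadata
#'
#' Expects a CSV with columns \code{sample_id, accession_id, species_label,
#' source, role, plant_count}; \code{role} is \code{"single"} (one plant) or
#' \code{"bulk"} (pooled plants). Each accession may have at most three
#' singles and one bulk.
#'
#' @param path CSV path.
#' @return data.frame of validated sample records.
#' @export
readMetadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateMetadata(df)
}

#' @rdname readMetadata
#' @param df a data.frame of sample records (validated and returned).
#' @export
validateMetadata <- function(df) {
  need <- c("sample_id", "accession_id", "species_label", "source", "role",
            "plant_count")
  if (!all(need %in% colnames(df)))
    .stopf("metadata error: missing columns %s",
           paste(setdiff(need, colnames(df)), collapse = ", "))
  if (anyDuplicated(df$sample_id))
    .stopf("metadata error: duplicated sample_id '%s'",
           df$sample_id[anyDuplicated(df$sample_id)])
  bad_role <- !df$role %in% .SAMPLE_ROLES
  if (any(bad_role))
    .stopf("metadata error: unknown role '%s' (sample '%s')",
           df$role[bad_role][1], df$sample_id[bad_role][1])
  if (any(df$role == "single" & df$plant_count != 1L))
    .stopf("metadata error: single samples must have plant_count 1")
  if (any(df$role == "bulk" & df$plant_count < 2L))
    .stopf("metadata error: bulk samples must pool >= 2 plants")
  n_single <- table(df$accession_id[df$role == "single"])
  if (any(n_single > 3L))
    .stopf("metadata error: accession '%s' has >3 single samples",
           names(n_single)[which(n_single > 3L)[1]])
  n_bulk <- table(df$accession_id[df$role == "bulk"])
  if (any(n_bulk > 1L))
    .stopf("metadata error: accession '%s' has >1 bulk sample",
           names(n_bulk)[which(n_bulk > 1L)[1]])
  df
}

#' @rdname readMetadata
#' @export
writeMetadata <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
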