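# End-to-end orchestration: simulate or ingest -> microhaplotype QC ->
# SNP extraction -> filtering -> dosage/structure -> phylogeny -> mislabel
# flags -> machine-readable run report. A fixed config + seed reproduces
# byte-identical outputs.

#' Default pipeline configuration
#'
#' @param seed integer seed.
#' @return nested list understood by \code{\link{runPipeline}}: a
#'   \code{simulation} block (passed to \code{\link{simulationConfig}}) or
#'   an \code{inputs} block (\code{madc}, \code{panel}, \code{metadata}
#'   paths), plus \code{filters}, \code{dosage}, \code{phylo} and
#'   \code{outliers} parameter blocks.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(seed = as.integer(seed),
       simulation = list(),
       filters = list(presence_min_reads = 10L, presence_percent = 5,
                      common_percent = 95, hindhe_low = 0.1,
                      hindhe_high = 1.0, hindhe_exclude_bulks = FALSE),
       dosage = list(min_depth = 10L, error_rate = 0.01),
       phylo = list(bootstrap_reps = 100L, support_threshold = 50,
                    root_species = NULL),
       outliers = list(k = 5L, majority = 0.8),
       write_truth = TRUE)
}

.merge_config <- function(user, default) {
  for (nm in names(default)) {
    if (is.null(user[[nm]])) user[nm] <- default[nm]
    else if (is.list(default[[nm]]) && is.list(user[[nm]]))
      user[[nm]] <- .merge_config(user[[nm]], default[[nm]])
  }
  user
}

.species_from_config <- function(sim) {
  if (is.null(sim$species)) return(defaultSpeciesTable())
  as.data.frame(lapply(sim$species, unlist), stringsAsFactors = FALSE)
}

#' Run the full MADC-to-population-genetics pipeline
#'
#' Stages, in fixed order: read or simulate inputs; singleton zeroing;
#' presence filtering; single-vs-bulk diversity accounting and replicate
#' correlations; SNP extraction and VCF export; Hind/HE filtering; dosage
#' calling; PCA, pairwise FST and missingness group tests; TN93
#' neighbor-joining phylogeny with bootstrap; FST species tree; mislabel
#' flagging; CSV tables and a JSON run report with per-stage
#' reconciliation counts. Rerunning with the same config and seed
#' reproduces byte-identical outputs.
#'
#' @param config a config list (see \code{\link{defaultPipelineConfig}})
#'   or the path of a YAML file holding one.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the run \code{report} and the main
#'   in-memory results.
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  config <- .merge_config(config, defaultPipelineConfig())
  counts <- list()
  input_md5 <- character(0)

  if (!is.null(config$inputs)) {
    for (f in unlist(config$inputs))
      if (!file.exists(f)) .stopf("input path does not exist: %s", f)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)

  # ---- stage: inputs -------------------------------------------------------
  set.seed(config$seed)
  truth <- NULL
  if (!is.null(config$inputs)) {
    input_md5 <- tools::md5sum(unlist(config$inputs))
    pan <- readPanel(config$inputs$panel)
    madc <- readMadc(config$inputs$madc, pan)
    metadata <- readMetadata(config$inputs$metadata)
  } else {
    sim <- config$simulation
    sim$species <- .species_from_config(sim)
    sim$seed <- config$seed
    scfg <- do.call(simulationConfig, sim)
    gen <- simulateMadc(scfg)
    madc <- gen$madc; metadata <- gen$metadata; truth <- gen$truth
    pan <- panel(madc)
    writeMadc(madc, pth("madc.csv"))
    writePanel(pan, pth("panel.csv"))
    writeMetadata(metadata, pth("metadata.csv"))
    if (isTRUE(config$write_truth)) writeTruth(truth, pth("truth.json"))
  }
  counts$samples <- ncol(madc)
  counts$accessions <- length(unique(metadata$accession_id))
  counts$madc_records <- nrow(madc)
  counts$panel_loci <- length(pan)

  # ---- stage: microhaplotype QC -------------------------------------------
  madc <- zeroSingletons(madc)
  pm <- presenceMatrix(madc, config$filters$presence_min_reads)
  curve <- presenceCurve(pm)
  utils::write.csv(curve, pth("presence_curve.csv"), row.names = FALSE)
  missing_by_sample <- missingnessBySample(pm, length(pan))
  common <- selectCommonLoci(pm, pan, config$filters$common_percent)
  utils::write.csv(common$by_chromosome, pth("loci_by_chromosome.csv"),
                   row.names = FALSE)
  retained_loci <- rownames(pm)[rowMeans(pm) * 100 >
                                  config$filters$presence_percent]
  counts$loci_retained_presence <- length(retained_loci)
  counts$loci_dropped_presence <- nrow(pm) - length(retained_loci)
  counts$loci_common <- length(common$loci)

  div <- compareSingleVsBulk(madc, metadata)
  if (!is.null(div) && nrow(div) >= 5L) div <- lowessTrend(div)
  utils::write.csv(div, pth("diversity.csv"), row.names = FALSE)
  counts$accessions_diversity <- if (is.null(div)) 0L else nrow(div)
  corr <- do.call(rbind, lapply(unique(metadata$accession_id), function(a) {
    r <- tryCatch(replicateCorrelations(madc, metadata, a),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    off <- r[upper.tri(r)]
    data.frame(accession_id = a, mean_r = mean(off, na.rm = TRUE),
               mean_r2 = mean(off^2, na.rm = TRUE))
  }))
  utils::write.csv(corr, pth("replicate_correlations.csv"),
                   row.names = FALSE)

  # ---- stage: SNP extraction ----------------------------------------------
  madc_kept <- madc[rowData(madc)$locus_id %in% retained_loci, ]
  pan_kept <- pan[mcols(pan)$locus_id %in% retained_loci]
  vs <- extractSnps(madc_kept, pan_kept)
  emitVcf(vs, pth("variants.vcf"))
  counts$snps_extracted <- nrow(vs)

  # ---- stage: Hind/HE filter ----------------------------------------------
  hh_ids <- if (isTRUE(config$filters$hindhe_exclude_bulks))
    intersect(metadata$sample_id[metadata$role == "single"], colnames(vs))
  else colnames(vs)
  hh <- hindHe(vs, samples = hh_ids)
  utils::write.csv(hh, pth("hindhe.csv"), row.names = FALSE)
  keep_snps <- filterByHindHe(hh, config$filters$hindhe_low,
                              config$filters$hindhe_high)
  vs_kept <- vs[rownames(vs) %in% keep_snps, ]
  counts$snps_retained_hindhe <- nrow(vs_kept)
  counts$snps_dropped_hindhe <- nrow(vs) - nrow(vs_kept)

  # ---- stage: dosage & structure ------------------------------------------
  dm_all <- callDosage(vs_kept, config$dosage$min_depth,
                       config$dosage$error_rate)
  # one single-plant replicate per accession: highest mean read depth
  DP <- assay(vs_kept, "DP")
  mean_dp <- colMeans(DP)
  rep_ids <- vapply(split(metadata, metadata$accession_id), function(m) {
    s <- intersect(m$sample_id[m$role == "single"], colnames(vs_kept))
    if (!length(s)) return(NA_character_)
    s[which.max(mean_dp[s])]
  }, character(1))
  rep_ids <- rep_ids[!is.na(rep_ids)]
  dm <- dm_all[rep_ids, , drop = FALSE]
  counts$structure_samples <- nrow(dm)

  pca <- tryCatch(genotypePca(dm), error = function(e) NULL)
  if (!is.null(pca)) {
    sc <- data.frame(sample_id = rownames(pca$scores), pca$scores)
    utils::write.csv(sc, pth("pca_scores.csv"), row.names = FALSE)
  }
  fst_sp <- tryCatch(fstMatrix(dm, metadata, "species"),
                     error = function(e) NULL)
  if (!is.null(fst_sp))
    utils::write.csv(data.frame(species = rownames(fst_sp), fst_sp,
                                check.names = FALSE),
                     pth("fst_species.csv"), row.names = FALSE)
  fst_src <- tryCatch(fstMatrix(dm, metadata, "source"),
                      error = function(e) NULL)
  if (!is.null(fst_src)) {
    tab3 <- data.frame(species = fst_src$species,
                       fst = ifelse(is.na(fst_src$fst), "-",
                                    format(round(fst_src$fst, 3),
                                           trim = TRUE)))
    utils::write.csv(tab3, pth("fst_source_within_species.csv"),
                     row.names = FALSE)
  }

  # missingness group tests over species labels (structure replicates)
  miss_rep <- missing_by_sample[rep_ids]
  sp_rep <- metadata$species_label[match(rep_ids, metadata$sample_id)]
  tests <- NULL
  if (length(unique(sp_rep)) >= 2L && all(table(sp_rep) >= 2L) &&
      all(tapply(miss_rep, sp_rep, stats::var) > 0)) {
    lev <- leveneVarTest(miss_rep, sp_rep)
    wel <- welchAnova(miss_rep, sp_rep)
    gh <- gamesHowell(miss_rep, sp_rep)
    tests <- list(levene = lev, welch = wel, games_howell = gh)
    utils::write.csv(gh$pairs, pth("games_howell.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(species = names(gh$letters), letters = unname(gh$letters),
                 mean_missing = as.vector(tapply(miss_rep, sp_rep,
                                                 mean)[names(gh$letters)])),
      pth("missingness_groups.csv"), row.names = FALSE)
  } else .msg("missingness group tests skipped (degenerate groups)")

  shared <- tryCatch(speciesSharedSnps(dm, metadata),
                     error = function(e) NULL)
  if (!is.null(shared))
    utils::write.csv(data.frame(species = rownames(shared$pairwise),
                                shared$pairwise, check.names = FALSE),
                     pth("species_shared_snps.csv"), row.names = FALSE)

  # ---- stage: phylogeny & mislabel flags ----------------------------------
  phylo <- NULL; flags <- NULL
  if (nrow(dm) >= 4L) {
    phylo <- bootstrapSupport(dm, vs_kept,
                              n_reps = config$phylo$bootstrap_reps)
    tr <- phylo$tree
    if (!is.null(tr$node.label))
      tr$node.label <- ifelse(
        phylo$support >= config$phylo$support_threshold,
        format(round(phylo$support, 1), trim = TRUE), "")
    ape::write.tree(tr, pth("nj_tree.nwk"))
    dmat <- tn93DistanceMatrix(sampleSequences(dm, vs_kept))
    flags <- flagOutliers(dmat, metadata, config$outliers$k,
                          config$outliers$majority)
    utils::write.csv(flags, pth("flagged_outliers.csv"), row.names = FALSE)
    if (!is.null(fst_sp) && !anyNA(fst_sp[upper.tri(fst_sp)]) &&
        nrow(fst_sp) >= 3L) {
      ftr <- if (!is.null(config$phylo$root_species) &&
                 config$phylo$root_species %in% rownames(fst_sp))
        fstSpeciesTree(fst_sp, config$phylo$root_species)
      else njTree(fst_sp)
      ape::write.tree(ftr, pth("fst_tree.nwk"))
    }
  } else .msg("phylogeny skipped (<4 structure samples)")
  counts$flagged_outliers <- if (is.null(flags)) 0L else nrow(flags)

  # ---- report --------------------------------------------------------------
  report <- list(
    package_version = as.character(utils::packageVersion("madcpop")),
    seed = config$seed,
    parameters = config[c("filters", "dosage", "phylo", "outliers")],
    input_checksums = as.list(input_md5),
    counts = counts,
    headline = list(
      presence_curve = curve,
      mean_replicate_r2 = if (!is.null(corr)) mean(corr$mean_r2) else NA,
      mean_bulk_minus_single_delta =
        if (!is.null(div)) mean(div$delta) else NA,
      flagged_outliers = if (is.null(flags)) list() else flags),
    outputs = list(fst_matrix = "fst_species.csv", tree = "nj_tree.nwk"))
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  .msg("pipeline complete: %d loci retained, %d SNPs, %d structure samples",
       counts$loci_retained_presence, counts$snps_retained_hindhe,
       counts$structure_samples)
  invisible(list(report = report, madc = madc, metadata = metadata,
                 panel = pan, variants = vs_kept, dosage = dm,
                 diversity = div, presence = pm, truth = truth,
                 fst_species = fst_sp, tests = tests, phylo = phylo,
                 flags = flags))
}

#' Write the headline CSV tables from a finished run
#'
#' Re-emits the presence-curve table, the per-chromosome common-locus
#' table and the per-species source-vs-source FST table (with "-" for
#' pairs that cannot be analysed) from a pipeline output directory into
#' \code{tables_dir}.
#'
#' @param out_dir a directory produced by \code{\link{runPipeline}}.
#' @param tables_dir destination (default \code{out_dir}).
#' @export
makeTables <- function(out_dir, tables_dir = out_dir) {
  dir.create(tables_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("presence_curve.csv", "loci_by_chromosome.csv",
              "fst_source_within_species.csv")) {
    src <- file.path(out_dir, f)
    if (!file.exists(src)) .stopf("missing pipeline output: %s", src)
    if (!identical(normalizePath(out_dir), normalizePath(tables_dir)))
      file.copy(src, file.path(tables_dir, f), overwrite = TRUE)
  }
  invisible(tables_dir)
}
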