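#' Default pipeline configuration
#'
#' Every stage threshold defaults to its published value: design filters
#' (MAF >= 0.05, GC 40--70\%, QUAL >= 30, 35-bp flanks), sample QC
#' (DQC >= 0.82, call rate >= 97\%), SNP QC cutoffs (97\% / 3.6 / -0.1 /
#' -0.3 / 0.6 / 0.3), map construction (1:1 chi-squared removal at
#' p < 0.01, rf <= 0.35, LOD >= 6, Kosambi) and ICIM (1000 permutations at
#' alpha 0.05, 1-cM walking step). The \code{simulate} block holds the
#' synthetic-data study conditions.
#'
#' @return nested named list
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_chrom = 8L, chrom_length = 200000L, gene_count = 40L,
      ssr_count = 20L, gc_target = 0.5,
      n_accessions = 50L, snp_rate = 1e-3, indel_rate = 5e-5,
      n_groups = 8L, markers_per_group = 25L, group_length_cm = 100,
      n_ril = 150L, residual_het_rate = 0.02, missing_rate = 0.002,
      separation = 8, dqc_low_fraction = 0.02,
      qtl = list(trait = "trait1", group = "LG01", pos_cm = 50,
                 effect = 1),
      residual_sd = 1,
      environments = list(location = c("L1", "L2"),
                          year = c(2005L, 2006L), shift = c(0, 0))),
    design = list(flank = 35L, maf_min = 0.05, gc_min = 0.40,
                  gc_max = 0.70, qual_min = 30),
    qc = list(dqc_min = 0.82, cr_min = 0.97, cr = 0.97, fld = 3.6,
              het_so = -0.1, het_so_otv = -0.3, hom_ro_1 = 0.6,
              hom_ro_2 = 0.3, hom_fld = 6.5, minor_hom = 2L,
              var_x = 0.8, var_y = 0.8, otv_min_frac = 0.05),
    map = list(alpha = 0.01, rf_max = 0.35, lod_min = 6,
               min_joint_coverage = 0.5),
    qtl = list(n_perm = 1000L, alpha = 0.05, step = 1, p_in = 0.001,
               p_out = 0.002, merge_cm = 5, coloc_cm = 10))
}

#' Check that the shipped defaults equal their published values
#'
#' @return TRUE (errors otherwise)
#' @export
configSelfTest <- function() {
  cfg <- defaultConfig()
  expect <- list(
    c(cfg$design$maf_min, 0.05), c(cfg$design$gc_min, 0.40),
    c(cfg$design$gc_max, 0.70), c(cfg$design$qual_min, 30),
    c(cfg$design$flank, 35), c(cfg$qc$dqc_min, 0.82),
    c(cfg$qc$cr_min, 0.97), c(cfg$qc$cr, 0.97), c(cfg$qc$fld, 3.6),
    c(cfg$qc$het_so, -0.1), c(cfg$qc$het_so_otv, -0.3),
    c(cfg$qc$hom_ro_1, 0.6), c(cfg$qc$hom_ro_2, 0.3),
    c(cfg$map$alpha, 0.01), c(cfg$map$rf_max, 0.35),
    c(cfg$map$lod_min, 6), c(cfg$qtl$n_perm, 1000),
    c(cfg$qtl$alpha, 0.05))
  ok <- vapply(expect, function(p) isTRUE(all.equal(p[1], p[2])),
               logical(1))
  stopIfNot(all(ok), "a shipped default deviates from its printed value")
  TRUE
}

#' Read and validate a pipeline configuration
#'
#' YAML values override \code{\link{defaultConfig}}; unknown keys at any
#' level are rejected before any work happens.
#'
#' @param path YAML file, or NULL for the defaults
#' @param overrides named list merged over the file (tests/automation)
#' @return validated nested config list
#' @export
readPipelineConfig <- function(path = NULL, overrides = NULL) {
  cfg <- defaultConfig()
  merge <- function(base, extra, where) {
    unknown <- setdiff(names(extra), names(base))
    if (length(unknown))
      stop("unknown config key", if (length(unknown) > 1) "s", " ",
           paste0(where, unknown, collapse = ", "), call. = FALSE)
    for (k in names(extra)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(extra[[k]]) &&
                       !is.null(names(base[[k]])))
        merge(base[[k]], extra[[k]], paste0(where, k, "$"))
      else extra[[k]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge(cfg, yaml::read_yaml(path), "")
  if (!is.null(overrides)) cfg <- merge(cfg, overrides, "")
  cfg
}

#' Run the full pipeline: simulate, design, QC, map, QTL
#'
#' Executes every stage on synthetic data with known ground truth and
#' writes all artifacts (FASTA/GFF3/VCF, probe sheet, attrition report,
#' per-SNP QC categories, map, scan profiles, QTL table) plus a run log
#' under \code{outDir}. Deterministic for a fixed config seed.
#'
#' @param config nested list from \code{\link{readPipelineConfig}}
#' @param outDir output directory (created if needed)
#' @return invisible list of in-memory stage results
#' @export
runPipeline <- function(config = readPipelineConfig(),
                        outDir = tempfile("pipeline")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  seed <- as.integer(config$seed)
  log <- c(paste("pipeline run, seed", seed),
           paste("package cicerArrayQTL",
                 as.character(utils::packageVersion("cicerArrayQTL"))))

  # --- simulate ---
  genome <- makeReference(seed, sim$n_chrom, sim$chrom_length,
                          sim$gene_count, sim$ssr_count, sim$gc_target)
  writeGenome(genome, file.path(outDir, "genome.fa"),
              file.path(outDir, "genes.gff3"))
  panel <- simulatePanel(genome, sim$n_accessions, sim$snp_rate,
                         sim$indel_rate, seed = seed + 1L)
  writePanelVcf(panel, file.path(outDir, "panel.vcf"))
  trueMap <- makeTrueMap(sim$n_groups, sim$markers_per_group,
                         sim$group_length_cm, seed = seed + 2L)
  calls <- simulateRil(c("P1", "P2"), trueMap, sim$n_ril,
                       sim$residual_het_rate, sim$missing_rate,
                       seed = seed + 3L)
  qtlSpec <- as.data.frame(sim$qtl)
  env <- as.data.frame(sim$environments)
  phen <- simulatePhenotypes(calls, trueMap, qtlSpec, sim$residual_sd,
                             env, seed = seed + 4L)
  sig <- simulateClusterSignals(calls[, -(1:2), drop = FALSE],
                                separation = sim$separation,
                                dqcLowFraction = sim$dqc_low_fraction,
                                seed = seed + 5L)
  writeGenotypes(calls, file.path(outDir, "genotypes.tsv"))
  writePhenotypes(phen, file.path(outDir, "phenotypes.tsv"))
  writeClusters(sig$clusters, file.path(outDir, "clusters.tsv"))
  writeSampleQc(sig$samples, file.path(outDir, "samples.tsv"))
  log <- c(log, paste("simulate:", nrow(panel), "panel variants,",
                      nrow(calls), "markers,", ncol(calls) - 2L, "RILs"))

  # --- design ---
  dcfg <- designConfig()
  dcfg$flank <- config$design$flank
  dcfg$maf_min <- config$design$maf_min
  dcfg$gc_min <- config$design$gc_min
  dcfg$gc_max <- config$design$gc_max
  dcfg$qual_min <- config$design$qual_min
  des <- applyDesignFilters(panel, genome, geneModels(genome), dcfg)
  write.table(des$candidates, file.path(outDir, "probe_sheet.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writePanelVcf(des$survivors[, c("chrom", "pos", "id", "ref", "alt",
                                  "qual", "ac", "an", "type", "planted")],
                file.path(outDir, "survivors.vcf"))
  att <- attritionTable(des$report)
  write.table(att, file.path(outDir, "attrition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log <- c(log, paste("design:", des$report@input, "candidates,",
                      des$report@survivors, "survivors"))

  # --- qc ---
  th <- qcThresholds()
  for (k in intersect(names(th), names(config$qc)))
    th[[k]] <- config$qc[[k]]
  sampQc <- sig$samples
  sampQc$call_rate <- colMeans(sig$calls != "U")
  sampFilt <- filterSamples(sampQc, config$qc$dqc_min, config$qc$cr_min)
  keepCols <- sampFilt$retained$sample
  qcRes <- classifySnps(sig$calls[, keepCols, drop = FALSE],
                        sig$clusters, th)
  qcSum <- qcSummary(qcRes$category)
  write.table(qcRes, file.path(outDir, "snp_qc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(qcSum, file.path(outDir, "qc_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log <- c(log, paste("qc:", length(sampFilt$removed_dqc), "samples out by DQC,",
                      length(sampFilt$removed_call_rate), "by call rate;",
                      attr(qcSum, "polymorphic_usable"),
                      "PolyHighResolution SNPs"))

  # --- map ---
  usable <- qcRes$snp[qcRes$category == "PolyHighResolution"]
  mapCalls <- calls[rownames(calls) %in% usable,
                    !colnames(calls) %in% c("P1", "P2"), drop = FALSE]
  mp <- buildGeneticMap(mapCalls, alpha = config$map$alpha,
                        rfMax = config$map$rf_max,
                        lodMin = config$map$lod_min,
                        minJointCoverage = config$map$min_joint_coverage,
                        anchor = setNames(seq_len(nrow(calls)),
                                          rownames(calls)))
  writeMap(mp$map, file.path(outDir, "map.tsv"))
  ms <- mapSummary(mp$map)
  write.table(ms$groups, file.path(outDir, "map_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log <- c(log, paste("map:", nMarkers(mp$map), "markers in",
                      length(unique(mapTable(mp$map)$group)), "groups,",
                      round(ms$totals$length_cm, 2), "cM"))

  # --- qtl ---
  qres <- mapQtls(phen, calls[mapTable(mp$map)$marker,
                              !colnames(calls) %in% c("P1", "P2"),
                              drop = FALSE],
                  mapTable(mp$map), nPerm = config$qtl$n_perm,
                  alpha = config$qtl$alpha, seed = seed + 6L,
                  step = config$qtl$step, colocCm = config$qtl$coloc_cm)
  write.table(qres$qtls, file.path(outDir, "qtls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log <- c(log, paste("qtl:", nrow(qres$qtls), "QTLs above threshold"))

  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(list(genome = genome, panel = panel, trueMap = trueMap,
                 calls = calls, phenotypes = phen, signals = sig,
                 design = des, sampleFilter = sampFilt, snpQc = qcRes,
                 qcSummary = qcSum, mapResult = mp, mapSummary = ms,
                 qtl = qres, outDir = outDir))
}

#' Attrition table of a DesignReport
#'
#' @param report a \code{\link{DesignReport}}
#' @return data.frame: stage, removed, remaining
#' @export
attritionTable <- function(report) {
  rem <- report@removed
  remaining <- report@input - cumsum(rem)
  data.frame(stage = c("input", names(rem)),
             removed = c(0L, unname(rem)),
             remaining = c(report@input, unname(remaining)))
}

#' Render the pipeline's human-readable summary tables
#'
#' Produces the attrition table, the QC category table (counts and
#' half-up percentages summing to 100), the map summary with Total and
#' Average rows, and the QTL table.
#'
#' @param results list returned by \code{\link{runPipeline}}
#' @return named list of data.frames
#' @export
renderReport <- function(results) {
  att <- attritionTable(results$design$report)
  cat_tb <- results$qcSummary
  ms <- results$mapSummary
  mapTab <- ms$groups
  mapTab$length_cm <- roundHalfUp(mapTab$length_cm, 2)
  totalRow <- data.frame(group = "Total",
                         n_markers = ms$totals$n_markers,
                         length_cm = roundHalfUp(ms$totals$length_cm, 2),
                         density = ms$totals$density)
  avgRow <- data.frame(group = "Average",
                       n_markers = ms$totals$avg_markers_per_group,
                       length_cm = ms$totals$avg_length_cm,
                       density = NA_real_)
  mapTab <- rbind(mapTab, totalRow, avgRow)
  qtlTab <- results$qtl$qtls
  list(attrition = att, categories = cat_tb, map = mapTab, qtls = qtlTab)
}
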