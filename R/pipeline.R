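#' Pipeline run configuration
#'
#' Bundles every tunable the two workflows use. Defaults mirror the study's
#' thresholds; `qc` can be overridden (e.g. a lower detected-gene floor for
#' shallow synthetic data).
#'
#' @param out_dir Output directory for all tables and the manifest.
#' @param seed Seed stamped into the manifest and used by seeded stages.
#' @param qc A [qcThresholds()] list.
#' @param de A [deThresholds()] list.
#' @param taxonomy A [taxonomyThresholds()] list.
#' @param roster Populations classified for smoking response (default: the
#'   eight main populations of [simConfig()]).
#' @param gmt Optional path to a GMT collection for the enrichment stage
#'   (skipped with a log line when `NULL`).
#' @param scale_total Normalization target total.
#' @param lineage_root,lineage_end Root/terminal populations of the lineage
#'   workflow.
#' @param anchors Anchor mucin pair for the program stage.
#' @param smooth_window Pseudotime smoothing window in cells.
#' @param n_top_pcs,n_top_genes Reduced-space parameters.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(out_dir, seed = 1L,
                      qc = qcThresholds(), de = deThresholds(),
                      taxonomy = taxonomyThresholds(),
                      roster = c("Basal.differentiating", "Basal.proliferating",
                                 "Basal.proteasomal", "KRT8.high", "Ciliated",
                                 "Secretory", "SMG.basal", "SMG.secretory"),
                      gmt = NULL, scale_total = 1e4,
                      lineage_populations = c("Basal.differentiating",
                                              "KRT8.high", "Secretory",
                                              "Secretory.mature"),
                      lineage_root = "Basal.differentiating",
                      lineage_end = "Secretory.mature",
                      anchors = c("MUC5AC", "MUC5B"),
                      smooth_window = 100L,
                      n_top_pcs = 10L, n_top_genes = 1000L) {
  cfg <- as.list(environment())
  if (cfg$seed < 0 || cfg$seed != floor(cfg$seed))
    stop("seed must be a non-negative integer")
  class(cfg) <- "RunConfig"
  cfg
}

.writeTSV <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.stage <- function(manifest, name, paths, rows) {
  manifest$stages[[name]] <- list(
    outputs = unname(paths),
    rows = unname(rows),
    md5 = unname(tools::md5sum(paths)))
  message("[", name, "] wrote ", length(paths), " file(s); rows: ",
          paste(rows, collapse = ", "))
  manifest
}

.initManifest <- function(config, workflow) {
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, paste0(workflow, "_config.json"))
  jsonlite::write_json(config[setdiff(names(config), "out_dir")], cfg_path,
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  list(workflow = workflow, seed = config$seed,
       config_hash = unname(tools::md5sum(cfg_path)), stages = list())
}

.preflight <- function(sce, config, need_pops) {
  cd <- colData(sce)
  miss <- setdiff(c("donor", "smoking", "population"), colnames(cd))
  if (length(miss))
    stop("annotations lack required column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(need_pops, unique(cd$population))
  if (length(bad))
    stop("population(s) absent from annotations: ", paste(bad, collapse = ", "))
  if (!all(c("never", "heavy") %in% cd$smoking))
    stop("need cells from both never- and heavy-smoker donors")
  invisible(TRUE)
}

.qcNormalize <- function(sce, config, manifest) {
  fc <- filterCells(sce, thresholds = config$qc)
  fg <- filterGenes(fc$sce, thresholds = config$qc)
  sce <- normalizeCounts(fg$sce, config$scale_total)
  qc_path <- file.path(config$out_dir, "qc_report.json")
  jsonlite::write_json(list(cells = unclass(fc$report),
                            genes = unclass(fg$report)),
                       qc_path, auto_unbox = TRUE, digits = NA)
  manifest <- .stage(manifest, "qc", qc_path,
                     sprintf("%d cells x %d genes kept", ncol(sce), nrow(sce)))
  list(sce = sce, manifest = manifest)
}

#' Run the smoking-response workflow
#'
#' QC -> normalization -> per-population smoker-vs-non-smoker differential
#' expression (Wilcoxon, gated) -> core/unique/semi-unique taxonomy ->
#' optional gene-set enrichment of the core responses -> donor-level
#' composition shifts. All tables are written under `config$out_dir`; any
#' stage failure aborts with the stage name.
#'
#' @param sce A `SingleCellExperiment` with counts and cell annotations
#'   (donor, smoking, population in `colData`).
#' @param config A [runConfig()] list.
#' @return A `PipelineManifest` list (also written as JSON).
#' @export
runSmokingWorkflow <- function(sce, config) {
  .preflight(sce, config, config$roster)
  manifest <- .initManifest(config, "smoking")
  qn <- .qcNormalize(sce, config, manifest)
  sce <- qn$sce
  manifest <- qn$manifest

  cd <- colData(sce)
  eligible <- !cd$excluded_flag & cd$smoking %in% c("never", "heavy")
  de_tables <- list()
  de_paths <- character()
  for (p in config$roster) {
    in_pop <- eligible & cd$population == p
    a <- which(in_pop & cd$smoking == "heavy")
    b <- which(in_pop & cd$smoking == "never")
    if (!length(a) || !length(b))
      stop("stage de: population ", p, " lacks cells in one smoking group")
    tab <- deContrast(sce, a, b, config$de, test = "wilcoxon")
    de_tables[[p]] <- tab
    de_paths[p] <- .writeTSV(tab, file.path(config$out_dir,
                                            paste0("de_", p, ".tsv")))
  }
  manifest <- .stage(manifest, "de", de_paths,
                     vapply(de_tables, function(t) sum(t$tested), 0L))

  taxo <- classifyResponse(de_tables, config$taxonomy, config$roster)
  taxo_paths <- c(
    .writeTSV(taxo$up, file.path(config$out_dir, "taxonomy_up.tsv")),
    .writeTSV(taxo$down, file.path(config$out_dir, "taxonomy_down.tsv")))
  manifest <- .stage(manifest, "taxonomy", taxo_paths,
                     c(nrow(taxo$up), nrow(taxo$down)))

  if (!is.null(config$gmt)) {
    collection <- readGMT(config$gmt)
    sets <- responseGeneSets(taxo)
    core <- sets[intersect(c("core_up", "core_down"), names(sets))]
    enr_paths <- character()
    for (nm in names(core)) {
      tab <- overrepresentation(core[[nm]], collection, rownames(sce),
                                alpha = config$taxonomy$alpha)
      enr_paths[nm] <- .writeTSV(tab, file.path(config$out_dir,
                                                paste0("enrichment_", nm, ".tsv")))
    }
    if (length(enr_paths))
      manifest <- .stage(manifest, "enrichment", enr_paths,
                         rep(length(collection), length(enr_paths)))
  } else {
    message("[enrichment] no GMT configured; stage skipped")
  }

  shifts <- proportionShift(cd)
  comp_paths <- c(
    .writeTSV(shifts$summary, file.path(config$out_dir, "composition_summary.tsv")),
    .writeTSV(shifts$per_donor, file.path(config$out_dir, "composition_per_donor.tsv")))
  manifest <- .stage(manifest, "composition", comp_paths,
                     c(nrow(shifts$summary), nrow(shifts$per_donor)))

  man_path <- file.path(config$out_dir, "smoking_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  manifest$path <- man_path
  class(manifest) <- "PipelineManifest"
  manifest
}

#' Run the lineage workflow
#'
#' QC -> normalization -> reduced-space centroid MST lineage and projection
#' pseudotime -> pseudotime-association testing (smoking covariate) ->
#' windowed smoothing of top associated genes -> Gaussian-mixture endpoint
#' isolation -> mucin co-expression programs and their smoking shift test on
#' the isolated mature secretory cells.
#'
#' @inheritParams runSmokingWorkflow
#' @return A `PipelineManifest` list (also written as JSON).
#' @export
runLineageWorkflow <- function(sce, config) {
  lineage_pops <- unique(c(config$lineage_populations, config$lineage_root,
                           config$lineage_end))
  .preflight(sce, config, lineage_pops)
  manifest <- .initManifest(config, "lineage")
  qn <- .qcNormalize(sce, config, manifest)
  manifest <- qn$manifest
  # the trajectory is built on the lineage populations only
  sce <- qn$sce[, colData(qn$sce)$population %in% lineage_pops]
  cd <- colData(sce)

  red <- reduceDimensions(sce, n_top = config$n_top_genes,
                          n_pcs = config$n_top_pcs)
  path <- buildLineage(red, cd$population, config$lineage_root,
                       config$lineage_end)
  pt <- path$pseudotime
  pt_path <- .writeTSV(
    data.frame(cell_id = names(pt), pseudotime = unname(pt)),
    file.path(config$out_dir, "pseudotime.tsv"))
  manifest <- .stage(manifest, "trajectory", pt_path, length(pt))

  smoking_cov <- setNames((cd[names(pt), "smoking"] == "heavy") * 1, names(pt))
  assoc <- pseudotimeAssociation(sce, pt, covariate = smoking_cov)
  assoc_path <- .writeTSV(assoc, file.path(config$out_dir,
                                           "pseudotime_association.tsv"))
  manifest <- .stage(manifest, "association", assoc_path, sum(assoc$flagged))

  top <- head(assoc$gene[order(assoc$q, assoc$p)], 10L)
  norm <- assay(sce, "lognorm")
  smooth_paths <- vapply(top, function(g) {
    sm <- smoothExpression(setNames(norm[g, names(pt)], names(pt)), pt,
                           window = min(config$smooth_window, length(pt)))
    .writeTSV(sm, file.path(config$out_dir, paste0("smoothed_", g, ".tsv")))
  }, "")
  manifest <- .stage(manifest, "smoothing", smooth_paths, rep(length(pt), length(top)))

  # mixture fit on the branch containing the endpoint (last two path states)
  branch_pops <- utils::tail(path$populations, 2L)
  branch <- pt[cd[names(pt), "population"] %in% branch_pops]
  fit <- fitGmm2(branch)
  mask <- isolateTerminal(pt, fit)
  gmm_path <- file.path(config$out_dir, "gmm_fit.json")
  jsonlite::write_json(list(weights = fit@weights, means = fit@means,
                            sds = fit@sds, logLik = fit@logLik,
                            iterations = fit@iterations,
                            converged = fit@converged,
                            n_terminal = sum(mask)),
                       gmm_path, auto_unbox = TRUE, digits = NA)
  term_path <- .writeTSV(
    data.frame(cell_id = names(pt), pseudotime = unname(pt), terminal = mask),
    file.path(config$out_dir, "terminal_mask.tsv"))
  manifest <- .stage(manifest, "endpoint", c(gmm_path, term_path),
                     c(1L, sum(mask)))

  terminal_cells <- names(pt)[mask]
  prog <- derivePrograms(sce, terminal_cells, anchors = config$anchors)
  prog_path <- .writeTSV(prog, file.path(config$out_dir, "mucin_programs.tsv"))
  elig <- attr(prog, "cells")
  sm_cells <- elig[cd[elig, "smoking"] == "heavy"]
  ns_cells <- elig[cd[elig, "smoking"] == "never"]
  shift <- list(
    A = programShiftTest(sce, prog, "A", sm_cells, ns_cells, "greater"),
    B = programShiftTest(sce, prog, "B", sm_cells, ns_cells, "less"))
  shift_path <- file.path(config$out_dir, "program_shift.json")
  jsonlite::write_json(list(p_A_greater = shift$A$p, p_B_less = shift$B$p,
                            n_smoker = length(sm_cells),
                            n_nonsmoker = length(ns_cells)),
                       shift_path, auto_unbox = TRUE, digits = NA)
  manifest <- .stage(manifest, "mucin", c(prog_path, shift_path),
                     c(nrow(prog), 2L))

  man_path <- file.path(config$out_dir, "lineage_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  manifest$path <- man_path
  class(manifest) <- "PipelineManifest"
  manifest
}
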