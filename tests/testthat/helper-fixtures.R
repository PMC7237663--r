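suppressPackageStartupMessages({
  library(SingleCellExperiment)
  library(Matrix)
})

# Expensive simulated datasets are built once per test session and shared.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# QC thresholds scaled to the simulator's sequencing depth (2000-gene panel,
# ~3000 UMI/cell): the detected-gene floor is proportionally lower than the
# paper-scale default.
qcSim <- function() qcThresholds(min_genes_per_cell = 150L)

qcNorm <- function(sce) {
  normalizeCounts(filterGenes(filterCells(sce, thresholds = qcSim())$sce,
                              thresholds = qcSim())$sce)
}

# the default study-structure dataset (all planted structure present)
defaultSim <- function() fixture("default_sim", function() {
  simulateDataset(simConfig(seed = 7L))
})

defaultNorm <- function() fixture("default_norm", function() {
  qcNorm(defaultSim())
})

# markers are the only population-discriminating structure
markersOnlyNorm <- function() fixture("markers_only_norm", function() {
  qcNorm(simulateDataset(simConfig(
    seed = 7L, core_logfc = 0, unique_logfc = 0, lineage_phase_logfc = 0,
    mucin_program_strength = 0, anchor_shift = 0)))
})

markersOnlyTruth <- function() fixture("markers_only_truth", function() {
  t <- newGroundTruth(simConfig(
    seed = 7L, core_logfc = 0, unique_logfc = 0, lineage_phase_logfc = 0,
    mucin_program_strength = 0, anchor_shift = 0))
  t$genes
})

# fully null configuration: no planted effects at all
nullSimConfig <- function(seed) {
  simConfig(
    seed = seed, marker_logfc = 0, core_logfc = 0, unique_logfc = 0,
    lineage_phase_logfc = 0, mucin_program_strength = 0, anchor_shift = 0,
    donor_effect_sd = 0,
    populations = setNames(rep(0.125, 8),
                           c("Basal.differentiating", "Basal.proliferating",
                             "Basal.proteasomal", "KRT8.high", "Ciliated",
                             "Secretory", "SMG.basal", "SMG.secretory")),
    lineage_populations = c("Basal.differentiating", "KRT8.high", "Secretory"),
    mucin_population = "Secretory")
}

nullNorm <- function() fixture("null_norm", function() {
  qcNorm(simulateDataset(nullSimConfig(101L)))
})

# mucin-focused dataset at the program stage's stated problem size
# (~2000 eligible mature secretory cells)
mucinSimConfig <- function(seed = 7L, ...) {
  simConfig(
    seed = seed, cells_per_donor = 600L,
    populations = c(Basal.differentiating = 0.09, Basal.proliferating = 0.04,
                    Basal.proteasomal = 0.035, KRT8.high = 0.105,
                    Ciliated = 0.12, Secretory = 0.05,
                    Secretory.mature = 0.50, SMG.basal = 0.03,
                    SMG.secretory = 0.026, Ionocyte = 0.0015, PNEC = 0.0015,
                    Tuft = 0.001), ...)
}

mucinNorm <- function() fixture("mucin_norm", function() {
  qcNorm(simulateDataset(mucinSimConfig()))
})

mucinTruthGenes <- function() fixture("mucin_truth", function() {
  newGroundTruth(mucinSimConfig())$genes
})

# downsampled pairwise marker table on the markers-only dataset
markersTable <- function() fixture("markers_table", function() {
  sce <- markersOnlyNorm()
  roster <- simConfig(seed = 7L)$roster
  keep <- colData(sce)$population %in% roster
  pairwiseMarkers(sce[, keep], seed = 7L)
})

# per-population smoker-vs-non-smoker DE on the default dataset
defaultDeTables <- function() fixture("default_de", function() {
  sce <- defaultNorm()
  cfg <- metadata(defaultSim())$config
  cd <- colData(sce)
  tabs <- list()
  for (p in cfg$roster) {
    a <- which(cd$population == p & cd$smoking == "heavy")
    b <- which(cd$population == p & cd$smoking == "never")
    tabs[[p]] <- deContrast(sce, a, b)
  }
  tabs
})

# small dataset + double pipeline run shared by integration/determinism tests
pipelineSim <- function() fixture("pipeline_sim", function() {
  simulateDataset(simConfig(seed = 11L, cells_per_donor = 250L,
                            n_genes = 1200L, markers_per_population = 15L))
})

pipelineRun <- function(which = c("first", "second")) {
  which <- match.arg(which)
  fixture(paste0("pipeline_", which), function() {
    out <- file.path(tempfile("pipe"), which)
    cfg <- runConfig(out_dir = out, seed = 11L, qc = qcSim())
    sce <- pipelineSim()
    list(smoking = runSmokingWorkflow(sce, cfg),
         lineage = suppressWarnings(runLineageWorkflow(sce, cfg)),
         dir = out)
  })
}

# marker-program membership at the reporting cut used for program figures
programCalls <- function(prog) {
  list(A = prog$gene[prog$class == "A_specific" & !is.na(prog$rho_A) &
                       prog$rho_A > 0.15],
       B = prog$gene[prog$class == "B_specific" & !is.na(prog$rho_B) &
                       prog$rho_B > 0.15])
}
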