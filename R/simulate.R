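#' Simulation configuration for a synthetic tracheal-epithelium dataset
#'
#' Builds the configuration of the gamma-Poisson (negative binomial) count
#' simulator. Defaults emulate the structure of the study design the package
#' targets: 6 never-smoker + 6 heavy-smoker donors, eight main epithelial
#' populations plus three rare types (composite rare frequency 0.008), a
#' basal-to-mature-secretory differentiation continuum, anchored MUC5AC/MUC5B
#' co-expression programs, donor batch effects, and planted marker, core and
#' population-unique smoking-response genes.
#'
#' All log fold-changes are on the natural-log scale. Smoking effects multiply
#' negative-binomial means in affected populations only; donor effects are
#' lognormal multiplicative per donor-gene pair; per-cell sequencing depth is
#' lognormal and enters as an exposure factor.
#'
#' @param n_donors_per_group Donors per smoking group (never / heavy).
#' @param n_light_donors Extra light-smoker donors whose cells carry
#'   `excluded_flag = TRUE` (analysis exclusions).
#' @param cells_per_donor Cells simulated per donor.
#' @param n_genes Number of genes.
#' @param populations Named numeric vector of population frequencies summing
#'   to 1; must contain the roster, lineage and mucin populations.
#' @param roster The main populations over which smoking responses are
#'   classified (default: the eight main epithelial populations).
#' @param markers_per_population,marker_logfc Planted marker block size and
#'   effect per population.
#' @param core_n_up,core_n_down Planted core response genes per direction.
#' @param core_n_affected Number of roster populations each core gene is
#'   affected in (must be >= 5 so planted genes meet the core definition).
#' @param core_logfc Core smoking effect size.
#' @param unique_n_up,unique_n_down,unique_logfc Population-unique smoking
#'   response genes per direction per roster population, and their effect.
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`).
#' @param depth_meanlog,depth_sdlog Lognormal per-cell depth parameters.
#' @param mito_gene_count,mito_beta_shape1,mito_beta_shape2 Number of
#'   mitochondrial (`MT-` prefixed) genes and the Beta parameters of the
#'   per-cell mitochondrial UMI fraction.
#' @param lineage_populations Populations forming the differentiation
#'   continuum, in order; the last is the terminal (mature) population.
#' @param lineage_phase_genes Genes per expression phase (three phases).
#' @param lineage_phase_logfc Peak amplitude (natural log) of phase bumps.
#' @param pseudotime_noise_sd Gaussian noise around non-terminal population
#'   pseudotime centers.
#' @param terminal_pt_mean,terminal_pt_sd The second (endpoint) Gaussian
#'   component of true pseudotime, separated from the rest of the lineage.
#' @param mucin_population Population in which mucin programs operate.
#' @param mucin_program_genes Program genes per anchor.
#' @param mucin_program_strength Coupling strength in `[0, 1]`: log-mean
#'   loading of a program gene on its anchor's latent activity.
#' @param anchor_shift Smoking shift of anchor latent activities (anchor A up,
#'   anchor B down in smokers).
#' @param donor_effect_sd SD of lognormal donor-gene batch effects.
#' @param seed Non-negative integer seed; identical seeds give bit-identical
#'   datasets.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(n_donors_per_group = 6L,
                      n_light_donors = 0L,
                      cells_per_donor = 420L,
                      n_genes = 2000L,
                      populations = c(
                        Basal.differentiating = 0.17,
                        Basal.proliferating   = 0.08,
                        Basal.proteasomal     = 0.07,
                        KRT8.high             = 0.21,
                        Ciliated              = 0.20,
                        Secretory             = 0.10,
                        Secretory.mature      = 0.05,
                        SMG.basal             = 0.06,
                        SMG.secretory         = 0.052,
                        Ionocyte              = 0.003,
                        PNEC                  = 0.003,
                        Tuft                  = 0.002),
                      roster = c("Basal.differentiating", "Basal.proliferating",
                                 "Basal.proteasomal", "KRT8.high", "Ciliated",
                                 "Secretory", "SMG.basal", "SMG.secretory"),
                      markers_per_population = 25L,
                      marker_logfc = 1.5,
                      core_n_up = 25L, core_n_down = 25L,
                      core_n_affected = 6L, core_logfc = 1.0,
                      unique_n_up = 10L, unique_n_down = 10L,
                      unique_logfc = 1.0,
                      nb_dispersion = 0.3,
                      depth_meanlog = log(3000), depth_sdlog = 0.3,
                      mito_gene_count = 10L,
                      mito_beta_shape1 = 2, mito_beta_shape2 = 18,
                      lineage_populations = c("Basal.differentiating",
                                              "KRT8.high", "Secretory",
                                              "Secretory.mature"),
                      lineage_phase_genes = 25L,
                      lineage_phase_logfc = 2.0,
                      pseudotime_noise_sd = 0.6,
                      terminal_pt_mean = 8, terminal_pt_sd = 0.5,
                      mucin_population = "Secretory.mature",
                      mucin_program_genes = 40L,
                      mucin_program_strength = 0.9,
                      anchor_shift = 0.8,
                      donor_effect_sd = 0.15,
                      seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' Validate a `SimConfig`
#' @param cfg A `SimConfig` list.
#' @return Invisibly `cfg`; stops on violation.
#' @export
validateSimConfig <- function(cfg) {
  p <- cfg$populations
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop("populations must be a named frequency vector")
  if (any(p <= 0) || any(p >= 1)) stop("population frequencies must be in (0,1)")
  if (abs(sum(p) - 1) > 1e-9) stop("population frequencies must sum to 1")
  if (!all(cfg$roster %in% names(p)))
    stop("roster contains unknown population(s)")
  if (!all(cfg$lineage_populations %in% names(p)))
    stop("lineage references unknown population(s)")
  if (!(cfg$mucin_population %in% names(p)))
    stop("mucin_population is not a simulated population")
  if (cfg$core_n_affected < 5L)
    stop("core_n_affected must be >= 5 (core-response definition)")
  if (cfg$core_n_affected > length(cfg$roster))
    stop("core_n_affected exceeds roster size")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$mucin_program_strength < 0 || cfg$mucin_program_strength > 1)
    stop("mucin_program_strength must be in [0, 1]")
  if (cfg$seed < 0 || cfg$seed != floor(cfg$seed))
    stop("seed must be a non-negative integer")
  counts <- c(cfg$n_donors_per_group, cfg$cells_per_donor, cfg$n_genes,
              cfg$markers_per_population, cfg$lineage_phase_genes,
              cfg$mucin_program_genes)
  if (any(counts <= 0)) stop("all size parameters must be positive")
  planted <- cfg$mito_gene_count + 2L +
    length(p) * cfg$markers_per_population +
    cfg$core_n_up + cfg$core_n_down +
    length(cfg$roster) * (cfg$unique_n_up + cfg$unique_n_down) +
    3L * cfg$lineage_phase_genes + 2L * cfg$mucin_program_genes
  if (planted > cfg$n_genes)
    stop("planted gene roles (", planted, ") exceed n_genes (", cfg$n_genes, ")")
  invisible(cfg)
}

# Allocate gene ids to planted roles. Deterministic given cfg (no RNG).
.layoutGenes <- function(cfg) {
  ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  ptr <- 0L
  take <- function(n) {
    out <- ids[(ptr + 1L):(ptr + n)]
    ptr <<- ptr + n
    out
  }
  mito <- sprintf("MT-SIM%02d", seq_len(cfg$mito_gene_count))
  ids[seq_len(cfg$mito_gene_count)] <- mito
  take(cfg$mito_gene_count)
  anchors <- c(A = "MUC5AC", B = "MUC5B")
  ids[(ptr + 1L):(ptr + 2L)] <- anchors
  take(2L)
  pops <- names(cfg$populations)
  markers <- lapply(pops, function(p) take(cfg$markers_per_population))
  names(markers) <- pops
  # field-familiar aliases for two planted markers
  if ("Ionocyte" %in% pops) {
    ids[ids == markers$Ionocyte[1]] <- "CFTR"
    markers$Ionocyte[1] <- "CFTR"
  }
  if ("Secretory.mature" %in% pops) {
    ids[ids == markers$Secretory.mature[1]] <- "SCGB1A1"
    markers$Secretory.mature[1] <- "SCGB1A1"
  }
  core_up <- take(cfg$core_n_up)
  core_down <- take(cfg$core_n_down)
  uniq_up <- lapply(cfg$roster, function(p) take(cfg$unique_n_up))
  names(uniq_up) <- cfg$roster
  uniq_down <- lapply(cfg$roster, function(p) take(cfg$unique_n_down))
  names(uniq_down) <- cfg$roster
  phase <- lapply(1:3, function(p) take(cfg$lineage_phase_genes))
  prog_A <- take(cfg$mucin_program_genes)
  prog_B <- take(cfg$mucin_program_genes)
  list(gene_ids = ids, mito = mito, anchors = anchors, markers = markers,
       core_up = core_up, core_down = core_down,
       unique_up = uniq_up, unique_down = uniq_down,
       phase = phase, program_A = prog_A, program_B = prog_B)
}

#' Initialize the planted ground truth (gene roles and cell assignments)
#'
#' Draws donor/smoking/population assignments per cell, per-cell depth and
#' mitochondrial fraction, gene base abundances, donor batch effects and the
#' roster subsets affected by each core gene. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A `SimConfig`.
#' @return A `GroundTruth` list with `genes` (role bookkeeping), `cells`
#'   (per-cell truth data.frame) and model parameters.
#' @export
newGroundTruth <- function(cfg) {
  validateSimConfig(cfg)
  set.seed(cfg$seed)
  lay <- .layoutGenes(cfg)
  ng <- cfg$n_genes
  pops <- names(cfg$populations)

  # donors: never, heavy, then optional light (excluded from contrasts)
  donors <- c(sprintf("N%02d", seq_len(cfg$n_donors_per_group)),
              sprintf("S%02d", seq_len(cfg$n_donors_per_group)),
              if (cfg$n_light_donors > 0)
                sprintf("L%02d", seq_len(cfg$n_light_donors)))
  smoking_of <- c(rep("never", cfg$n_donors_per_group),
                  rep("heavy", cfg$n_donors_per_group),
                  rep("light", cfg$n_light_donors))
  n_cells <- length(donors) * cfg$cells_per_donor
  donor <- rep(donors, each = cfg$cells_per_donor)
  smoking <- rep(smoking_of, each = cfg$cells_per_donor)
  population <- sample(pops, n_cells, replace = TRUE, prob = cfg$populations)
  cell_id <- sprintf("%s_C%04d", donor,
                     unlist(lapply(donors, function(d) seq_len(cfg$cells_per_donor)),
                            use.names = FALSE))
  depth <- rlnorm(n_cells, cfg$depth_meanlog, cfg$depth_sdlog)
  mito_frac <- rbeta(n_cells, cfg$mito_beta_shape1, cfg$mito_beta_shape2)

  # base relative abundances; anchors elevated so both are widely detected
  rho <- rlnorm(ng, meanlog = 0, sdlog = 1.2)
  names(rho) <- lay$gene_ids
  # planted-role genes must be expressed to carry their effect: floor their
  # base abundance at a detectable level
  planted <- unique(c(unlist(lay$markers, use.names = FALSE),
                      lay$core_up, lay$core_down,
                      unlist(lay$unique_up, use.names = FALSE),
                      unlist(lay$unique_down, use.names = FALSE),
                      unlist(lay$phase, use.names = FALSE),
                      lay$program_A, lay$program_B))
  rho[planted] <- pmax(rho[planted], quantile(rho, 0.35))
  rho[lay$anchors] <- quantile(rho, 0.85) * c(1, 1)
  mito_w <- rlnorm(cfg$mito_gene_count, 0, 0.5)
  mito_w <- mito_w / sum(mito_w)
  rho[lay$mito] <- 0            # mito genes handled by the mito fraction
  rho[setdiff(lay$gene_ids, lay$mito)] <-
    rho[setdiff(lay$gene_ids, lay$mito)] /
    sum(rho[setdiff(lay$gene_ids, lay$mito)])

  donor_log <- matrix(rnorm(ng * length(donors), 0, cfg$donor_effect_sd),
                      nrow = ng, dimnames = list(lay$gene_ids, donors))

  affected <- lapply(c(lay$core_up, lay$core_down), function(g)
    sort(sample(cfg$roster, cfg$core_n_affected)))
  names(affected) <- c(lay$core_up, lay$core_down)

  truth <- list(
    genes = lay, rho = rho, mito_w = mito_w, donor_log = donor_log,
    core_affected = affected,
    cells = data.frame(cell_id = cell_id, donor = donor, smoking = smoking,
                       population = population,
                       excluded_flag = smoking == "light",
                       depth = depth, mito_fraction = mito_frac,
                       true_pseudotime = NA_real_,
                       anchor_A_activity = NA_real_,
                       anchor_B_activity = NA_real_,
                       stringsAsFactors = FALSE))
  class(truth) <- "GroundTruth"
  truth
}

#' Planted phase-bump expression multiplier along pseudotime
#'
#' Mean multiplier (natural scale) applied to a phase gene at true pseudotime
#' `t`: a Gaussian bump in scaled pseudotime, so phase genes rise then fall
#' within their phase (secretory-preparation, club, and mucus phases).
#'
#' @param cfg A `SimConfig`.
#' @param phase Phase index 1..3.
#' @param t True pseudotime value(s).
#' @return Numeric multiplier(s) `exp(amplitude * bump)`.
#' @export
lineagePhaseMultiplier <- function(cfg, phase, t) {
  centers <- c(0.08, 0.35, 0.95)   # early bump, club-phase bump, mucus bump
  width <- 0.15
  s <- t / cfg$terminal_pt_mean
  exp(cfg$lineage_phase_logfc * exp(-(s - centers[phase])^2 / (2 * width^2)))
}

#' Plant the differentiation lineage into the ground truth
#'
#' Cells of the lineage populations receive true pseudotime increasing along
#' the configured order: non-terminal populations at evenly spaced centers in
#' the early range with Gaussian noise, the terminal population drawn from a
#' separated second Gaussian component (so endpoint isolation is testable).
#'
#' @param cfg A `SimConfig`.
#' @param truth A `GroundTruth` from [newGroundTruth()].
#' @return The updated `GroundTruth`.
#' @export
plantLineage <- function(cfg, truth) {
  if (!all(cfg$lineage_populations %in% names(cfg$populations)))
    stop("lineage references unknown population(s)")
  set.seed(cfg$seed + 1L)
  lp <- cfg$lineage_populations
  m <- length(lp)
  centers <- seq(0.8, 3.6, length.out = m - 1L)
  pt <- truth$cells$true_pseudotime
  for (j in seq_len(m - 1L)) {
    idx <- which(truth$cells$population == lp[j])
    pt[idx] <- pmax(0, rnorm(length(idx), centers[j], cfg$pseudotime_noise_sd))
  }
  idx <- which(truth$cells$population == lp[m])
  pt[idx] <- pmax(0, rnorm(length(idx), cfg$terminal_pt_mean, cfg$terminal_pt_sd))
  truth$cells$true_pseudotime <- pt
  truth
}

#' Plant mucin co-expression programs into the ground truth
#'
#' Within the mucin (mature secretory) population, each cell receives latent
#' activities for the two anchors; smoking shifts the anchor-A latent up and
#' the anchor-B latent down. Anchor genes load on their latent with weight 1;
#' each program gene loads on exactly one anchor's latent with the configured
#' strength.
#'
#' @param cfg A `SimConfig`.
#' @param truth A `GroundTruth`.
#' @return The updated `GroundTruth`.
#' @export
plantMucinPrograms <- function(cfg, truth) {
  if (cfg$mucin_program_strength < 0 || cfg$mucin_program_strength > 1)
    stop("mucin_program_strength must be in [0, 1]")
  set.seed(cfg$seed + 2L)
  idx <- which(truth$cells$population == cfg$mucin_population)
  smoker <- truth$cells$smoking[idx] == "heavy"
  truth$cells$anchor_A_activity[idx] <- rnorm(length(idx),
                                              ifelse(smoker, cfg$anchor_shift, 0), 1)
  truth$cells$anchor_B_activity[idx] <- rnorm(length(idx),
                                              ifelse(smoker, -cfg$anchor_shift, 0), 1)
  truth
}

#' Simulate a complete synthetic dataset
#'
#' Draws gamma-Poisson UMI counts with gene base means, lognormal donor
#' effects, population marker effects, smoking effects (multiplicative, in
#' affected populations only), lineage phase bumps, mucin program loadings and
#' lognormal per-cell depth. Identical seeds give bit-identical output.
#'
#' @param cfg A `SimConfig`.
#' @return A `SingleCellExperiment` with a sparse `counts` assay; per-cell
#'   truth in `colData` (donor, smoking, population, true_pseudotime,
#'   excluded_flag), gene roles in `rowData(sce)$role`, and the full
#'   `GroundTruth` in `metadata(sce)$truth` (config in `metadata(sce)$config`).
#' @export
simulateDataset <- function(cfg) {
  truth <- newGroundTruth(cfg)
  truth <- plantLineage(cfg, truth)
  truth <- plantMucinPrograms(cfg, truth)
  set.seed(cfg$seed + 3L)

  lay <- truth$genes
  genes <- lay$gene_ids
  ng <- length(genes)
  cells <- truth$cells
  nc <- nrow(cells)
  mito_idx <- match(lay$mito, genes)

  log_rho <- log(truth$rho)
  log_rho[mito_idx] <- log(truth$mito_w)   # weights within the mito share
  logmu <- matrix(log_rho, nrow = ng, ncol = nc)
  cell_off <- log(cells$depth) + log1p(-cells$mito_fraction)
  logmu <- sweep(logmu, 2, cell_off, `+`)
  logmu[mito_idx, ] <- sweep(logmu[mito_idx, , drop = FALSE], 2,
                             log(cells$depth * cells$mito_fraction) - cell_off, `+`)
  logmu <- logmu + truth$donor_log[, match(cells$donor, colnames(truth$donor_log))]

  # population markers
  for (p in names(lay$markers)) {
    j <- which(cells$population == p)
    if (length(j))
      logmu[match(lay$markers[[p]], genes), j] <-
        logmu[match(lay$markers[[p]], genes), j] + cfg$marker_logfc
  }
  # smoking response genes (heavy-smoker cells of affected populations only)
  smoker <- cells$smoking == "heavy"
  for (g in lay$core_up) {
    j <- which(smoker & cells$population %in% truth$core_affected[[g]])
    logmu[match(g, genes), j] <- logmu[match(g, genes), j] + cfg$core_logfc
  }
  for (g in lay$core_down) {
    j <- which(smoker & cells$population %in% truth$core_affected[[g]])
    logmu[match(g, genes), j] <- logmu[match(g, genes), j] - cfg$core_logfc
  }
  for (p in cfg$roster) {
    j <- which(smoker & cells$population == p)
    if (length(j)) {
      logmu[match(lay$unique_up[[p]], genes), j] <-
        logmu[match(lay$unique_up[[p]], genes), j] + cfg$unique_logfc
      logmu[match(lay$unique_down[[p]], genes), j] <-
        logmu[match(lay$unique_down[[p]], genes), j] - cfg$unique_logfc
    }
  }
  # lineage phase bumps
  lin <- which(!is.na(cells$true_pseudotime))
  if (length(lin)) {
    for (ph in 1:3) {
      bump <- log(lineagePhaseMultiplier(cfg, ph, cells$true_pseudotime[lin]))
      gi <- match(lay$phase[[ph]], genes)
      logmu[gi, lin] <- sweep(logmu[gi, lin, drop = FALSE], 2, bump, `+`)
    }
  }
  # mucin anchors and programs
  muc <- which(!is.na(cells$anchor_A_activity))
  if (length(muc)) {
    a <- cells$anchor_A_activity[muc]
    b <- cells$anchor_B_activity[muc]
    logmu[match(lay$anchors["A"], genes), muc] <-
      logmu[match(lay$anchors["A"], genes), muc] + a
    logmu[match(lay$anchors["B"], genes), muc] <-
      logmu[match(lay$anchors["B"], genes), muc] + b
    s <- cfg$mucin_program_strength
    gi <- match(lay$program_A, genes)
    logmu[gi, muc] <- sweep(logmu[gi, muc, drop = FALSE], 2, s * a, `+`)
    gi <- match(lay$program_B, genes)
    logmu[gi, muc] <- sweep(logmu[gi, muc, drop = FALSE], 2, s * b, `+`)
  }

  counts <- matrix(rnbinom(ng * nc, mu = exp(logmu), size = 1 / cfg$nb_dispersion),
                   nrow = ng, dimnames = list(genes, cells$cell_id))
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  role <- rep("background", ng)
  names(role) <- genes
  role[lay$mito] <- "mito"
  role[unlist(lay$markers, use.names = FALSE)] <- "marker"
  role[lay$core_up] <- "core_up"
  role[lay$core_down] <- "core_down"
  role[unlist(lay$unique_up, use.names = FALSE)] <- "unique_up"
  role[unlist(lay$unique_down, use.names = FALSE)] <- "unique_down"
  role[unlist(lay$phase, use.names = FALSE)] <- "lineage_phase"
  role[lay$program_A] <- "program_A"
  role[lay$program_B] <- "program_B"
  role[lay$anchors] <- "anchor"

  cd <- S4Vectors::DataFrame(cells[, c("cell_id", "donor", "smoking",
                                       "population", "true_pseudotime",
                                       "excluded_flag")],
                             row.names = cells$cell_id)
  sce <- SingleCellExperiment(assays = list(counts = counts), colData = cd)
  rowData(sce)$role <- unname(role)
  metadata(sce)$truth <- truth
  metadata(sce)$config <- cfg
  sce
}

#' Write a simulated dataset to disk
#'
#' Writes the MatrixMarket trio, the annotation TSV and a ground-truth JSON.
#'
#' @param sce Output of [simulateDataset()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
writeDataset <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeCountMatrix(sce, dir)
  writeAnnotations(as.data.frame(colData(sce)),
                   file.path(dir, "annotations.tsv"))
  truth <- metadata(sce)$truth
  if (!is.null(truth)) {
    tr <- truth$genes[c("mito", "anchors", "markers", "core_up", "core_down",
                        "unique_up", "unique_down", "phase",
                        "program_A", "program_B")]
    tr$core_affected <- truth$core_affected
    jsonlite::write_json(tr, file.path(dir, "ground_truth.json"),
                         auto_unbox = FALSE)
  }
  invisible(dir)
}
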