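# small but complete configuration for fast cases
smallCfg <- function(seed = 3L, ...) {
  simConfig(seed = seed, cells_per_donor = 40L, n_genes = 800L,
            markers_per_population = 10L, ...)
}

test_that("identical seeds give bit-identical datasets", {
  s1 <- simulateDataset(smallCfg(seed = 7L))
  s2 <- simulateDataset(smallCfg(seed = 7L))
  expect_identical(as.matrix(assay(s1, "counts")), as.matrix(assay(s2, "counts")))
  expect_identical(colData(s1), colData(s2))
  s3 <- simulateDataset(smallCfg(seed = 8L))
  expect_false(identical(as.matrix(assay(s1, "counts")),
                         as.matrix(assay(s3, "counts"))))
})

test_that("with zero effect sizes smoker and non-smoker means are equal", {
  cfg <- smallCfg(seed = 5L, marker_logfc = 0, core_logfc = 0,
                  unique_logfc = 0, lineage_phase_logfc = 0,
                  mucin_program_strength = 0, anchor_shift = 0,
                  donor_effect_sd = 0)
  sce <- simulateDataset(cfg)
  cnt <- as.matrix(assay(sce, "counts"))
  smoker <- colData(sce)$smoking == "heavy"
  m1 <- rowMeans(cnt[, smoker]); m2 <- rowMeans(cnt[, !smoker])
  v1 <- apply(cnt[, smoker], 1, var); v2 <- apply(cnt[, !smoker], 1, var)
  z <- (m1 - m2) / sqrt(v1 / sum(smoker) + v2 / sum(!smoker))
  expect_true(all(abs(z[is.finite(z)]) < 4))
})

test_that("marginal count means match the gamma-Poisson expectation", {
  cfg <- smallCfg(seed = 9L, marker_logfc = 0, core_logfc = 0,
                  unique_logfc = 0, lineage_phase_logfc = 0,
                  mucin_program_strength = 0, anchor_shift = 0,
                  donor_effect_sd = 0)
  sce <- simulateDataset(cfg)
  truth <- metadata(sce)$truth
  cnt <- as.matrix(assay(sce, "counts"))
  non_mito <- !startsWith(rownames(sce), "MT-")
  expected <- truth$rho[non_mito] *
    mean(truth$cells$depth * (1 - truth$cells$mito_fraction))
  observed <- rowMeans(cnt[non_mito, ])
  # aggregate over genes: total observed vs total expected within MC error
  expect_lt(abs(sum(observed) / sum(expected) - 1), 0.02)
  keep <- expected > 0.5
  expect_gt(cor(observed[keep], expected[keep]), 0.99)
})

test_that("realized rare-cell fraction matches the planted 0.8%", {
  cfg <- simConfig(seed = 13L, cells_per_donor = 2500L)   # 30,000 cells
  truth <- newGroundTruth(cfg)
  rare <- mean(truth$cells$population %in% c("Ionocyte", "PNEC", "Tuft"))
  ci <- qbinom(c(0.005, 0.995), 30000, 0.008) / 30000
  expect_gte(rare, ci[1])
  expect_lte(rare, ci[2])
})

test_that("planted lineage pseudotime is ordered and phase bumps peak in-phase", {
  # zero noise: pseudotime is a step function separating the populations
  cfg <- smallCfg(seed = 3L, pseudotime_noise_sd = 0, terminal_pt_sd = 0,
                  lineage_populations = c("KRT8.high", "Secretory.mature"))
  truth <- plantLineage(cfg, newGroundTruth(cfg))
  pt <- truth$cells$true_pseudotime
  pop <- truth$cells$population
  a <- pt[pop == "KRT8.high"]; b <- pt[pop == "Secretory.mature"]
  expect_equal(unique(a), 0.8)
  expect_equal(unique(b), cfg$terminal_pt_mean)
  expect_true(max(a) < min(b))

  # phase-2 mean multiplier at mid-pseudotime strictly exceeds both ends
  cfg2 <- simConfig(seed = 1L)
  grid <- seq(0, cfg2$terminal_pt_mean, length.out = 101)
  bump2 <- lineagePhaseMultiplier(cfg2, 2, grid)
  mid <- lineagePhaseMultiplier(cfg2, 2, cfg2$terminal_pt_mean / 2)
  expect_gt(mid, bump2[1])
  expect_gt(mid, bump2[101])
  # each phase's peak lies inside its own third of the continuum
  peaks <- vapply(1:3, function(p)
    grid[which.max(lineagePhaseMultiplier(cfg2, p, grid))], 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("terminal pseudotime forms a recoverable second component", {
  cfg <- simConfig(seed = 2L)
  truth <- plantLineage(cfg, newGroundTruth(cfg))
  pt <- truth$cells$true_pseudotime
  pop <- truth$cells$population
  lin <- !is.na(pt)
  expect_true(all(pt[lin & pop != "Secretory.mature"] < 6))
  fit <- fitGmm2(pt[lin & pop %in% c("Secretory", "Secretory.mature")])
  expect_true(gmmSeparated(fit))
  expect_lt(abs(fit@means[2] - cfg$terminal_pt_mean), 0.2)
})

test_that("anchor latents shift with smoking as constructed", {
  truth <- metadata(defaultSim())$truth
  cells <- truth$cells
  mat <- cells$population == "Secretory.mature"
  a_s <- mean(cells$anchor_A_activity[mat & cells$smoking == "heavy"])
  a_n <- mean(cells$anchor_A_activity[mat & cells$smoking == "never"])
  b_s <- mean(cells$anchor_B_activity[mat & cells$smoking == "heavy"])
  b_n <- mean(cells$anchor_B_activity[mat & cells$smoking == "never"])
  expect_gt(a_s, a_n)
  expect_lt(b_s, b_n)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(populations = c(A = 0.5, B = 0.4)), "sum to 1")
  expect_error(simConfig(core_n_affected = 4L), ">= 5")
  expect_error(simConfig(lineage_populations = c("Nope", "Secretory.mature")),
               "unknown population")
  expect_error(simConfig(n_genes = 100L), "exceed n_genes")
  expect_error(simConfig(mucin_program_strength = 1.2), "\\[0, 1\\]")
})

test_that("simulated datasets round-trip to disk with ground truth", {
  sce <- simulateDataset(smallCfg(seed = 4L))
  d <- withr::local_tempdir()
  writeDataset(sce, d)
  back <- readCountMatrix(file.path(d, "matrix.mtx"), file.path(d, "genes.tsv"),
                          file.path(d, "barcodes.tsv"))
  expect_identical(as.matrix(assay(back, "counts")),
                   as.matrix(assay(sce, "counts")))
  ann <- readAnnotations(file.path(d, "annotations.tsv"))
  expect_identical(ann$cell_id, colnames(sce))
  expect_true(file.exists(file.path(d, "ground_truth.json")))
})
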