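# Hand-built DE tables over a 4-gene universe and 8 populations.
mkTab <- function(logfc, p, fdr, tested) {
  data.frame(gene = paste0("g", seq_along(logfc)), logfc = logfc,
             pct_a = 0.5, pct_b = 0.5, p = p, fdr = fdr, tested = tested,
             stringsAsFactors = FALSE)
}

fixtureTables <- function() {
  pops <- paste0("P", 1:8)
  tabs <- list()
  for (i in seq_along(pops)) {
    # g1: up-significant in P1..P5 only
    g1 <- if (i <= 5) c(0.8, 1e-4, 1e-3) else c(0.05, NA, NA)
    # g2: up-significant only in P1; elsewhere tested with fdr 0.5
    g2 <- if (i == 1) c(1.0, 1e-5, 1e-4) else c(0.3, 0.4, 0.5)
    # g3: up-significant in P1 and P2; P3 shadow zone (logfc .3, fdr .1)
    g3 <- if (i <= 2) c(0.9, 1e-4, 1e-3)
          else if (i == 3) c(0.3, 0.05, 0.1) else c(0.1, 0.6, 0.7)
    # g4: nothing anywhere
    g4 <- c(0.02, 0.8, 0.9)
    m <- rbind(g1, g2, g3, g4)
    tested <- !is.na(m[, 2])
    tabs[[pops[i]]] <- mkTab(m[, 1], m[, 2], m[, 3], tested)
  }
  tabs
}

test_that("the response taxonomy applies core/unique/semi-unique rules", {
  tabs <- fixtureTables()
  taxo <- classifyResponse(tabs)
  up <- taxo$up
  expect_identical(up$class[up$gene == "g1"], "core")       # 5 of 8
  expect_identical(up$class[up$gene == "g2"], "unique")     # fdr > 0.2 elsewhere
  expect_identical(up$population[up$gene == "g2"], "P1")
  expect_identical(up$class[up$gene == "g3"], "semi_unique")
  expect_identical(up$class[up$gene == "g4"], "none")
  # nothing was planted downward
  expect_true(all(taxo$down$class == "none"))
})

test_that("classification is invariant to population order and validates input", {
  tabs <- fixtureTables()
  taxo1 <- classifyResponse(tabs)
  perm <- sample(names(tabs))
  taxo2 <- classifyResponse(tabs[perm], roster = names(tabs))
  expect_identical(taxo1$up$class, taxo2$up$class)
  expect_error(classifyResponse(tabs, roster = c(names(tabs), "P9")),
               "missing DE table")
  bad <- tabs
  bad$P2$gene <- rev(bad$P2$gene)
  expect_error(classifyResponse(bad), "gene universe")
  expect_error(classifyResponse(tabs, taxonomyThresholds(core_min = 9L)),
               "roster size")
})

test_that("a significant-in-one gene with a shadow zone elsewhere is semi-unique", {
  tabs <- fixtureTables()
  # make g2 fail the exclusion in P5: tested, logfc 0.4, fdr 0.1
  tabs$P5[tabs$P5$gene == "g2", c("logfc", "p", "fdr", "tested")] <-
    list(0.4, 0.05, 0.1, TRUE)
  taxo <- classifyResponse(tabs)
  expect_identical(taxo$up$class[taxo$up$gene == "g2"], "semi_unique")
})

test_that("marker-set enrichment flags true overlap and not disjoint sets", {
  universe <- paste0("g", 1:2000)
  markers <- list(M1 = universe[1:30], M2 = universe[101:130])
  response <- list(R_same = universe[1:30], R_disjoint = universe[1001:1030])
  em <- markerSetEnrichment(markers, response, universe)
  expect_lt(em$p["M1", "R_same"], 1e-30)
  expect_true(em$significant["M1", "R_same"])
  expect_equal(em$overlap["M2", "R_same"], 0)
  expect_equal(em$p["M2", "R_same"], 1)           # P(X >= 0) = 1
  expect_false(em$significant["M2", "R_disjoint"])
})

test_that("composition shifts are exact percent changes over non-smoker means", {
  ann <- data.frame(
    cell_id = sprintf("c%03d", 1:400),
    donor = rep(c("N1", "N2", "S1", "S2"), each = 100),
    smoking = rep(c("never", "never", "heavy", "heavy"), each = 100),
    population = c(rep(c("X", "Y"), c(10, 90)), rep(c("X", "Y"), c(10, 90)),
                   rep(c("X", "Y"), c(12, 88)), rep(c("X", "Y"), c(10, 90))),
    stringsAsFactors = FALSE)
  res <- proportionShift(ann)
  x <- res$per_donor[res$per_donor$population == "X", ]
  expect_equal(x$shift_pct[x$donor == "S1"], 20)    # 12% vs 10% baseline
  expect_equal(x$shift_pct[x$donor == "S2"], 0)
  expect_equal(res$summary$mean_shift_pct[res$summary$population == "X"], 10)
})

test_that("composition shifts center on zero under smoking-label permutation", {
  set.seed(9)
  donors <- paste0("D", 1:12)
  ann <- data.frame(
    cell_id = sprintf("c%04d", 1:2400),
    donor = rep(donors, each = 200),
    smoking = NA_character_,
    population = sample(c("X", "Y", "Z"), 2400, TRUE, prob = c(0.2, 0.5, 0.3)),
    stringsAsFactors = FALSE)
  shifts <- replicate(40, {
    lab <- sample(rep(c("never", "heavy"), each = 6))
    ann$smoking <- lab[match(ann$donor, donors)]
    res <- proportionShift(ann)
    res$summary$mean_shift_pct[res$summary$population == "X"]
  })
  expect_lt(abs(mean(shifts)), 2 * sd(shifts) / sqrt(length(shifts)) + 3)
})

test_that("transcript shares are conserved and folds match planted ratios", {
  # two populations, gene at mean 100 vs 200 per cell, equal totals
  n <- 50
  cnt <- rbind(GENE = c(rep(100L, n), rep(200L, n)),
               FILL = c(rep(900L, n), rep(800L, n)))
  colnames(cnt) <- paste0("c", 1:(2 * n))
  sce <- makeCountSCE(Matrix::Matrix(cnt, sparse = TRUE),
                      colData = data.frame(cell_id = colnames(cnt),
                                           population = rep(c("A", "B"), each = n)))
  sce <- normalizeCounts(sce, scale_total = 1000)
  ts <- transcriptShare(sce, "GENE")
  expect_equal(sum(ts$share), 1)
  expect_equal(unname(ts$share["B"]), 200 / 300)
  expect_lt(abs(ts$fold["B", "A"] - 2), 0.02)    # +1 stabilizer vanishes
  # single expressing population takes the whole share
  cnt2 <- rbind(GENE = c(rep(0L, n), rep(50L, n)), FILL = 1000L)
  colnames(cnt2) <- colnames(cnt)
  sce2 <- normalizeCounts(makeCountSCE(Matrix::Matrix(cnt2, sparse = TRUE),
                                       colData = colData(sce)), 1000)
  expect_equal(unname(transcriptShare(sce2, "GENE")$share), c(0, 1))
  expect_error(transcriptShare(sce2, "NOPE"), "not present")
})
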