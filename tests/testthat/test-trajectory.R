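test_that("pseudotime on collinear geometry reproduces coordinates exactly", {
  set.seed(2)
  x <- c(runif(30, 0, 1), runif(30, 2, 3), runif(30, 4, 5))
  red <- cbind(x, 0)
  rownames(red) <- paste0("c", 1:90)
  labels <- rep(c("A", "B", "C"), each = 30)
  path <- buildLineage(red, labels, root = "A")
  expect_identical(path$populations, c("A", "B", "C"))
  pt <- path$pseudotime[rownames(red)]
  # analytic projection on a line: arc length of x clamped to the
  # [root centroid, end centroid] interval
  cA <- mean(x[labels == "A"]); cC <- mean(x[labels == "C"])
  expect_equal(unname(pt), pmin(pmax(x, cA), cC) - cA, tolerance = 1e-10)
  # ordering equals coordinate ordering for cells between the end centroids
  inside <- x >= cA & x <= cC
  expect_identical(order(pt[inside]), order(x[inside]))
  # cells placed exactly at centroids get the cumulative arc-lengths
  cent <- path$centroids
  red2 <- rbind(red, cent)
  rownames(red2) <- c(rownames(red), paste0("cc", 1:3))
  labels2 <- c(labels, "A", "B", "C")
  path2 <- buildLineage(red2, labels2, root = "A", end = "C")
  expect_equal(unname(path2$pseudotime[paste0("cc", 1:3)]),
               unname(path2$arc_lengths), tolerance = 1e-8)
  # permuting cell order leaves pseudotime unchanged
  perm <- sample(90)
  path3 <- buildLineage(red[perm, ], labels[perm], root = "A")
  expect_equal(path3$pseudotime[rownames(red)], pt)
  expect_error(buildLineage(red, labels, root = "A", end = "A"), "differ")
  expect_error(buildLineage(red, labels, root = "Z"), "absent")
})

test_that("pseudotime association flags trends and respects the covariate", {
  set.seed(5)
  n <- 1000
  pt <- setNames(runif(n, 0, 10), paste0("c", 1:n))
  # smoking habit correlated with position along the trajectory, as in
  # tissue where exposure shifts lineage composition
  smoking <- setNames(rbinom(n, 1, plogis(pt - 5)), names(pt))
  norm <- rbind(
    TREND = 0.5 * pt + rnorm(n, sd = 0.5),
    FLAT = rep(1, n),
    SMOKE = 2 * smoking + rnorm(n, sd = 0.5))
  colnames(norm) <- names(pt)
  res <- pseudotimeAssociation(norm, pt, covariate = smoking)
  expect_true(res$flagged[res$gene == "TREND"])
  expect_lt(res$q[res$gene == "TREND"], 1e-10)
  expect_false(res$flagged[res$gene == "FLAT"])
  expect_false(res$flagged[res$gene == "SMOKE"])   # absorbed by covariate
  # ablation: without the covariate the smoking-only gene is (spuriously)
  # associated with pseudotime, demonstrating the covariate's role
  res2 <- pseudotimeAssociation(norm, pt)
  expect_true(res2$flagged[res2$gene == "SMOKE"])
  expect_lt(res2$p[res2$gene == "SMOKE"], 1e-10)
  expect_error(pseudotimeAssociation(norm, setNames(rep(1, n), names(pt))),
               "constant pseudotime")
  expect_error(pseudotimeAssociation(norm[, 1:10], pt[1:10]), "at least 20")
})

test_that("triangular smoothing is exact on constants and lines", {
  pt <- 1:200
  sm <- smoothExpression(rep(3, 200), pt, window = 50)
  expect_true(all(sm$smoothed == 3))
  lin <- smoothExpression(2 * pt + 1, pt, window = 51)
  # symmetric weights reproduce a line away from the ends
  interior <- 30:170
  expect_equal(sm$pseudotime, sort(pt))
  expect_equal(lin$smoothed[interior], (2 * pt + 1)[interior], tolerance = 1e-10)
  # convex combination: output range inside input range
  set.seed(1)
  v <- rnorm(300)
  sm2 <- smoothExpression(v, runif(300), window = 100)
  expect_gte(min(sm2$smoothed), min(v))
  expect_lte(max(sm2$smoothed), max(v))
  expect_error(smoothExpression(v, runif(300), window = 2), ">= 3")
  expect_error(smoothExpression(v[1:10], runif(10), window = 100), "fewer cells")
})

test_that("EM recovers a separated two-component mixture", {
  set.seed(6)
  x <- c(rnorm(1000, 2, 0.5), rnorm(1000, 8, 0.5))
  fit <- fitGmm2(x)
  expect_lt(abs(fit@means[1] - 2), 0.1)
  expect_lt(abs(fit@means[2] - 8), 0.1)
  expect_true(fit@converged)
  expect_true(gmmSeparated(fit))
  # EM property: log-likelihood never decreases
  expect_true(all(diff(fit@trace) > -1e-8))
  # a single tight cluster is flagged as unseparated
  y <- rnorm(500, 5, 0.3)
  fit1 <- fitGmm2(y)
  expect_false(gmmSeparated(fit1))
  expect_error(isolateTerminal(y, fit1), "not separated")
  expect_error(fitGmm2(rep(1:3, 10)), "distinct")
})

test_that("EM attains the likelihood of brute-force and reference fits", {
  set.seed(17)
  x <- c(rnorm(25, 1, 0.6), rnorm(25, 5, 0.8))
  fit <- fitGmm2(x)
  grid_ll <- gridGmmLoglik(x)
  expect_gte(fit@logLik, grid_ll - 0.01 * abs(grid_ll))
  # independent EM implementation agrees on the fitted log-likelihood
  suppressPackageStartupMessages(library(mclust))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(fit@logLik - mc$loglik), 0.01 * abs(mc$loglik))
  expect_lt(max(abs(sort(fit@means) - sort(mc$parameters$mean))), 0.15)
})

test_that("the 2-SD endpoint rule selects terminal cells", {
  fit <- new("MixtureFit", weights = c(0.5, 0.5), means = c(2, 8),
             sds = c(0.5, 1), logLik = 0, trace = 0, iterations = 1L,
             converged = TRUE)
  pt <- c(5.9, 6.01, 7, 10)
  expect_identical(isolateTerminal(pt, fit), c(FALSE, TRUE, TRUE, TRUE))
  # monotone: anything above a selected cell is selected
  set.seed(3)
  p2 <- runif(100, 0, 12)
  m <- isolateTerminal(p2, fit)
  expect_true(all(m[p2 > min(p2[m])]))
})

test_that("the full trajectory stage orders the planted lineage", {
  sce <- defaultNorm()
  cfg <- metadata(defaultSim())$config
  cd <- colData(sce)
  sub <- sce[, cd$population %in% cfg$lineage_populations]
  red <- reduceDimensions(sub)
  path <- buildLineage(red, colData(sub)$population,
                       "Basal.differentiating", "Secretory.mature")
  expect_identical(path$populations, cfg$lineage_populations)
  pt <- path$pseudotime
  truth_pt <- colData(sub)[names(pt), "true_pseudotime"]
  expect_gte(cor(pt, truth_pt, method = "spearman"), 0.9)
  # root population sits at the start of the path
  med <- tapply(pt, colData(sub)[names(pt), "population"], median)
  expect_identical(names(which.min(med)), "Basal.differentiating")
})
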