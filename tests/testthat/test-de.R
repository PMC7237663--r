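test_that("rank-sum p-values match enumeration and handle ties", {
  # fully separated 3 vs 3: 2 of the 20 assignments are as extreme
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(enumWilcoxonTwoSided(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # complete tie
  expect_equal(wilcoxonRankSum(5, 5), 1)
  # one-sided directions: complete separation of 3 vs 3 gives 1/20
  expect_equal(wilcoxonRankSum(c(4, 5, 6), c(1, 2, 3), "greater"), 1 / 20)
  expect_equal(wilcoxonRankSum(c(4, 5, 6), c(1, 2, 3), "less"), 1)
  expect_error(wilcoxonRankSum(numeric(0), 1), "empty")
})

test_that("approximate rank-sum path tracks the exact enumeration", {
  set.seed(42)
  vals <- sample(1000, 12)          # distinct values
  for (na in c(2, 4, 6, 10, 11)) {
    for (rep in 1:5) {
      idx <- sample(12, na)
      a <- vals[idx]; b <- vals[-idx]
      p_enum <- enumWilcoxonTwoSided(a, b)
      p_ours <- wilcoxonRankSum(a, b)
      tol <- if (na <= 10 && (12 - na) <= 10) 1e-12 else 0.01
      expect_lt(abs(p_ours - p_enum), tol + 1e-15)
    }
  }
  # tie-heavy data: approximation equals the reference implementation
  set.seed(7)
  for (rep in 1:10) {
    a <- rpois(60, 1.5); b <- rpois(80, 1.5)
    expect_equal(wilcoxonRankSum(a, b),
                 wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
})

test_that("logistic LR test behaves at its boundary cases", {
  set.seed(1)
  g <- rep(c(0, 1), each = 100)
  # constant expression carries no information
  expect_equal(lrTest(rep(2, 200), g), 1)
  # perfectly separating expression: penalized fallback, tiny p
  expr <- g + rnorm(200, sd = 1e-3)
  expect_lt(lrTest(expr, g), 1e-10)
  expect_error(lrTest(rnorm(10), rep(1, 10)), "both classes")
})

test_that("LR p-values are uniform when the covariate explains the signal", {
  set.seed(11)
  ps <- replicate(500, {
    z <- rnorm(200)
    grp <- rbinom(200, 1, plogis(z))
    expr <- z + rnorm(200, sd = 0.05)
    lrTest(expr, grp, covariates = cbind(z = z))
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("log fold-change follows the +1-stabilized mean convention", {
  a <- matrix(log1p(c(5, 5, 5)), nrow = 1)
  expect_equal(logFoldChange(a, a), 0)
  b <- matrix(log1p(c(2, 3, 4)), nrow = 1)
  expect_equal(logFoldChange(a, b), -logFoldChange(b, a))
  # group a at e x group b means converges to logFC 1 for large values
  m <- 5000
  a <- matrix(log1p(exp(1) * m), nrow = 1)
  b <- matrix(log1p(m), nrow = 1)
  expect_lt(abs(logFoldChange(a, b) - 1), 1e-3)
})

test_that("detection fractions are simple proportions", {
  expect_equal(pctExpressed(matrix(0, 2, 4)), c(0, 0))
  expect_equal(pctExpressed(matrix(1, 2, 4)), c(1, 1))
  expect_equal(pctExpressed(matrix(c(1, 0, 1, 0, 1, 0, 0, 0), nrow = 1)), 0.375)
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.3), 0.3)
  set.seed(3)
  p <- runif(50)
  expect_equal(bhFdr(p), bruteBH(p))
  ord <- sample(50)
  expect_equal(bhFdr(p)[ord], bhFdr(p[ord]))
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the logFC gate keeps separated-but-small genes untested", {
  # gene 1: perfectly separated but logFC = log(13/11) < 0.25
  cnt <- rbind(G1 = c(rep(12L, 50), rep(10L, 50)),
               FILL = c(rep(88L, 50), rep(90L, 50)))
  colnames(cnt) <- paste0("c", 1:100)
  sce <- normalizeCounts(makeCountSCE(Matrix::Matrix(cnt, sparse = TRUE)),
                         scale_total = 100)
  tab <- deContrast(sce, 1:50, 51:100)
  expect_false(tab$tested[tab$gene == "G1"])
  expect_true(is.na(tab$p[tab$gene == "G1"]))
})

test_that("contrasts recover planted smoking effects and respect symmetry", {
  sce <- defaultNorm()
  truth <- metadata(defaultSim())$truth
  cfg <- metadata(defaultSim())$config
  cd <- colData(sce)
  p <- "KRT8.high"
  a <- which(cd$population == p & cd$smoking == "heavy")
  b <- which(cd$population == p & cd$smoking == "never")
  tab <- defaultDeTables()[[p]]
  planted <- intersect(
    names(Filter(function(pp) p %in% pp,
                 truth$core_affected[truth$genes$core_up])), tab$gene)
  sig <- tab$tested & !is.na(tab$fdr) & tab$fdr < 0.05 & tab$logfc > 0
  expect_gte(mean(sig[match(planted, tab$gene)]), 0.9)

  # relabeling a<->b flips logFC and keeps p
  flip <- deContrast(sce, b, a)
  expect_equal(flip$logfc, -tab$logfc)
  expect_equal(flip$p, tab$p)
  # cell order within groups is irrelevant
  perm <- deContrast(sce, sample(a), sample(b))
  expect_equal(perm$p, tab$p)
  expect_error(deContrast(sce, a, c(b, a[1])), "overlap")
})
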