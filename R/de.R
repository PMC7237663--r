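#' Differential-expression thresholds
#'
#' The study's gates: a gene enters a comparison only with natural-log fold
#' change above 0.25 (in the favored direction) and detection in more than
#' 10% of cells in at least one group; significance is called at FDR < 0.05.
#'
#' @param min_logfc Minimum |log fold-change| (natural log).
#' @param min_pct Minimum detection fraction in at least one group.
#' @param alpha_fdr FDR significance level.
#' @return A validated list of class `DEThresholds`.
#' @export
deThresholds <- function(min_logfc = 0.25, min_pct = 0.10, alpha_fdr = 0.05) {
  if (min_logfc < 0) stop("min_logfc must be >= 0")
  if (min_pct <= 0 || min_pct >= 1) stop("min_pct must be in (0, 1)")
  if (alpha_fdr <= 0 || alpha_fdr >= 1) stop("alpha_fdr must be in (0, 1)")
  structure(list(min_logfc = min_logfc, min_pct = min_pct,
                 alpha_fdr = alpha_fdr), class = "DEThresholds")
}

# Normal-approximation rank-sum p with tie and continuity corrections.
# Matches stats::wilcox.test(exact = FALSE, correct = TRUE).
.rankSumApprox <- function(a, b, alternative) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- rle(sort(c(a, b)))$lengths
  sigma2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  sigma <- sqrt(sigma2)
  d <- U - mu
  p <- switch(alternative,
    two_sided = {
      corr <- sign(d) * 0.5
      z <- (d - corr) / sigma
      min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    },
    greater = pnorm((d - 0.5) / sigma, lower.tail = FALSE),
    less = pnorm((d + 0.5) / sigma))
  max(min(p, 1), .Machine$double.xmin)
}

#' Wilcoxon rank-sum test p-value
#'
#' Exact distribution when both groups have fewer than 50 observations and no
#' ties are present (the reference-implementation rule; the normal
#' approximation is too coarse for very unbalanced small splits); otherwise
#' the normal approximation with tie and continuity corrections.
#'
#' @param a,b Non-empty numeric vectors.
#' @param alternative One of `"two_sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @return A p-value in (0, 1].
#' @export
wilcoxonRankSum <- function(a, b,
                            alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L) stop("empty group in rank-sum test")
  no_ties <- !anyDuplicated(c(a, b))
  if (length(a) <= 49L && length(b) <= 49L && no_ties) {
    alt <- c(two_sided = "two.sided", greater = "greater", less = "less")
    return(stats::wilcox.test(a, b, alternative = alt[[alternative]],
                              exact = TRUE)$p.value)
  }
  .rankSumApprox(a, b, alternative)
}

.designMatrix <- function(n, covariates) {
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- apply(covariates, 2, function(v) length(unique(v)) > 1L)
    X <- cbind(X, covariates[, keep, drop = FALSE])
  }
  q <- qr(X)
  X[, q$pivot[seq_len(q$rank)], drop = FALSE]
}

.ridgeLogit <- function(X, y, lambda = 1e-2, maxit = 200L) {
  pen <- c(0, rep(lambda, ncol(X) - 1L))
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    H <- crossprod(X, X * w) + diag(pen, ncol(X))
    beta_new <- drop(solve(H, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(pmin(eta, 700))))
  ll - 0.5 * sum(pen * beta^2)
}

#' Likelihood-ratio logistic test with latent covariates
#'
#' Tests whether a gene's expression separates two cell groups beyond a set
#' of latent covariates (e.g. smoking habit, donor): logistic models
#' `group ~ covariates` versus `group ~ expression + covariates` are fit by
#' maximum likelihood and compared by a 1-df chi-square likelihood-ratio
#' statistic. Perfect separation is handled by a ridge-penalized refit of
#' both models (same penalty), a documented fallback rather than a failure.
#'
#' @param expr Numeric expression vector.
#' @param group Binary group vector (logical or 0/1); both classes required.
#' @param covariates Optional numeric matrix of covariates (constants and
#'   collinear columns are dropped).
#' @return A p-value.
#' @export
lrTest <- function(expr, group, covariates = NULL) {
  y <- as.numeric(group)
  if (length(unique(y)) != 2L) stop("group must contain both classes")
  X0 <- .designMatrix(length(y), covariates)
  X1 <- cbind(X0, expr = expr)
  fit0 <- suppressWarnings(glm.fit(X0, y, family = binomial()))
  fit1 <- suppressWarnings(glm.fit(X1, y, family = binomial()))
  separated <- !fit1$converged ||
    any(fit1$fitted.values < 1e-10 | fit1$fitted.values > 1 - 1e-10) ||
    max(abs(fit1$coefficients), na.rm = TRUE) > 15
  if (separated) {
    ll0 <- .ridgeLogit(X0, y)
    ll1 <- .ridgeLogit(X1, y)
    lr <- max(0, 2 * (ll1 - ll0))
  } else {
    lr <- max(0, fit0$deviance - fit1$deviance)
  }
  pchisq(lr, df = 1, lower.tail = FALSE)
}

#' Log fold-change between two groups of normalized expression
#'
#' Natural-log difference of the +1-stabilized group means of depth-normalized
#' counts: `log(mean(expm1(a)) + 1) - log(mean(expm1(b)) + 1)`, computed per
#' gene (rows). This is the droplet-ecosystem convention matching the +0.25
#' gate scale.
#'
#' @param norm_a,norm_b Log-normalized genes x cells matrices (or vectors for
#'   one gene).
#' @return Per-gene numeric vector of log fold-changes (a vs b).
#' @export
logFoldChange <- function(norm_a, norm_b) {
  if (is.null(dim(norm_a))) norm_a <- matrix(norm_a, nrow = 1)
  if (is.null(dim(norm_b))) norm_b <- matrix(norm_b, nrow = 1)
  log(matrixStats::rowMeans2(expm1(as.matrix(norm_a))) + 1) -
    log(matrixStats::rowMeans2(expm1(as.matrix(norm_b))) + 1)
}

#' Detection fraction per gene
#'
#' Fraction of cells with raw UMI count > 0, per gene (rows).
#'
#' @param counts Raw counts (genes x cells matrix, sparse allowed, or vector).
#' @return Per-gene numeric vector in `[0, 1]`.
#' @export
pctExpressed <- function(counts) {
  if (is.null(dim(counts))) return(mean(counts > 0))
  Matrix::rowSums(counts > 0) / ncol(counts)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, clipped at 1, order-invariant.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
bhFdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Gated two-group differential expression for one contrast
#'
#' Computes per-gene log fold-change and detection fractions, gates genes on
#' `|logFC| > min_logfc` and detection `> min_pct` in at least one group, and
#' tests only gated genes (Wilcoxon rank-sum for smoking contrasts, the
#' latent-covariate logistic LR test for population contrasts). FDR is
#' computed over tested genes only; untested genes carry `NA` p/FDR.
#'
#' @param sce `SingleCellExperiment` with `counts` and `lognorm` assays.
#' @param cells_a,cells_b Disjoint, non-empty cell selections (barcodes or
#'   indices); `logfc > 0` means higher in `cells_a`.
#' @param thresholds A [deThresholds()] list.
#' @param test `"wilcoxon"` or `"lr"`.
#' @param covariates Covariate matrix over `c(cells_a, cells_b)` (LR test
#'   only), e.g. smoking indicator and one-hot donors (first level dropped).
#' @return A `DETable` data.frame: gene, logfc, pct_a, pct_b, p, fdr, tested.
#' @export
deContrast <- function(sce, cells_a, cells_b, thresholds = deThresholds(),
                       test = c("wilcoxon", "lr"), covariates = NULL) {
  test <- match.arg(test)
  if (is.character(cells_a)) cells_a <- match(cells_a, colnames(sce))
  if (is.character(cells_b)) cells_b <- match(cells_b, colnames(sce))
  if (length(cells_a) == 0L || length(cells_b) == 0L)
    stop("both cell groups must be non-empty")
  if (length(intersect(cells_a, cells_b)))
    stop("cell groups overlap")
  norm <- .lognormMatrix(sce)
  counts <- .countsMatrix(sce)
  na <- length(cells_a)
  A <- norm[, cells_a, drop = FALSE]
  B <- norm[, cells_b, drop = FALSE]
  logfc <- logFoldChange(A, B)
  pct_a <- pctExpressed(counts[, cells_a, drop = FALSE])
  pct_b <- pctExpressed(counts[, cells_b, drop = FALSE])
  tested <- abs(logfc) > thresholds$min_logfc &
    (pct_a > thresholds$min_pct | pct_b > thresholds$min_pct)

  p <- rep(NA_real_, nrow(norm))
  idx <- which(tested)
  if (length(idx)) {
    if (test == "wilcoxon") {
      p[idx] <- vapply(idx, function(i)
        wilcoxonRankSum(A[i, ], B[i, ], "two_sided"), 0)
    } else {
      y <- rep(c(1, 0), c(na, length(cells_b)))
      X0 <- .designMatrix(length(y), covariates)
      fit0 <- suppressWarnings(glm.fit(X0, y, family = binomial()))
      p[idx] <- vapply(idx, function(i) {
        expr <- c(A[i, ], B[i, ])
        X1 <- cbind(X0, expr = expr)
        fit1 <- suppressWarnings(glm.fit(X1, y, family = binomial()))
        separated <- !fit1$converged ||
          any(fit1$fitted.values < 1e-10 | fit1$fitted.values > 1 - 1e-10) ||
          max(abs(fit1$coefficients), na.rm = TRUE) > 15
        lr <- if (separated) {
          max(0, 2 * (.ridgeLogit(X1, y) - .ridgeLogit(X0, y)))
        } else {
          max(0, fit0$deviance - fit1$deviance)
        }
        pchisq(lr, df = 1, lower.tail = FALSE)
      }, 0)
    }
  }
  fdr <- rep(NA_real_, length(p))
  if (length(idx)) fdr[idx] <- bhFdr(p[idx])
  out <- data.frame(gene = rownames(norm), logfc = logfc,
                    pct_a = pct_a, pct_b = pct_b,
                    p = p, fdr = fdr, tested = tested,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("DETable", "data.frame")
  out
}
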