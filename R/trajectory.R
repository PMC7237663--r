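#' Reduced-dimension space for trajectory geometry
#'
#' PCA (top components of the gene-scaled log-normalized matrix restricted to
#' the most dispersed genes) used for centroid geometry. Dispersion is the
#' variance-to-mean ratio of normalized counts, residualized on mean
#' expression by ranking within mean bins, so highly expressed genes do not
#' dominate.
#'
#' @param sce `SingleCellExperiment` with a `lognorm` assay (or the matrix).
#' @param n_top Number of most-dispersed genes (default 1000).
#' @param n_pcs Number of principal components (default 10).
#' @param n_bins Mean-expression bins for dispersion standardization.
#' @return Cells x components coordinate matrix.
#' @export
reduceDimensions <- function(sce, n_top = 1000L, n_pcs = 10L, n_bins = 20L) {
  norm <- .lognormMatrix(sce)
  nc_counts <- expm1(norm)
  m <- matrixStats::rowMeans2(nc_counts)
  v <- matrixStats::rowVars(nc_counts)
  ok <- m > 0 & v > 0
  disp <- log(v[ok] / m[ok])
  bins <- cut(rank(m[ok], ties.method = "first"), breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  top <- rownames(norm)[ok][order(-z)][seq_len(min(n_top, sum(ok)))]
  X <- norm[top, , drop = FALSE]
  X <- X[matrixStats::rowVars(X) > 0, , drop = FALSE]
  X <- (X - matrixStats::rowMeans2(X)) / sqrt(matrixStats::rowVars(X))
  pc <- prcomp(t(X), center = FALSE, scale. = FALSE, rank. = n_pcs)
  coords <- pc$x
  rownames(coords) <- colnames(norm)
  coords
}

#' Build a cluster-anchored lineage and projection pseudotime
#'
#' Fits a Euclidean minimum spanning tree over population centroids in the
#' reduced space; the root-to-end MST path (root to the farthest leaf when no
#' end is given) defines a piecewise-linear lineage through the centroids.
#' Each member cell's pseudotime is the arc-length coordinate of its
#' orthogonal projection onto the path (clamped to the path ends).
#' Deterministic.
#'
#' @param reduced Cells x dimensions coordinate matrix.
#' @param labels Population label per cell.
#' @param root Root population (differentiating basal analog).
#' @param end Optional terminal population.
#' @return A `LineagePath` list: `populations` (ordered along the path),
#'   `centroids`, cumulative `arc_lengths`, and named per-cell `pseudotime`
#'   for cells of the path populations.
#' @export
buildLineage <- function(reduced, labels, root, end = NULL) {
  labels <- as.character(labels)
  pops <- sort(unique(labels))
  if (length(pops) < 2L) stop("need at least two populations")
  if (!root %in% pops) stop("root population absent")
  if (!is.null(end)) {
    if (!end %in% pops) stop("end population absent")
    if (identical(root, end)) stop("root and end must differ")
  }
  cent <- t(vapply(pops, function(p)
    matrixStats::colMeans2(reduced[labels == p, , drop = FALSE]),
    numeric(ncol(reduced))))
  D <- as.matrix(dist(cent))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  if (is.null(end)) {
    dists <- igraph::distances(tree, v = root)
    end <- pops[which.max(dists)]
  }
  path_idx <- as.integer(igraph::shortest_paths(tree, from = root,
                                                to = end)$vpath[[1]])
  path_pops <- pops[path_idx]
  P <- cent[path_idx, , drop = FALSE]
  seg <- diff(P)
  seg_len <- sqrt(rowSums(seg^2))
  cum_len <- c(0, cumsum(seg_len))

  member <- which(labels %in% path_pops)
  X <- reduced[member, , drop = FALSE]
  best_d2 <- rep(Inf, nrow(X))
  pt <- rep(0, nrow(X))
  for (s in seq_len(nrow(seg))) {
    d <- seg[s, ]
    tproj <- pmin(pmax((sweep(X, 2, P[s, ]) %*% d) / sum(d^2), 0), 1)
    q <- outer(drop(tproj), d) + rep(P[s, ], each = nrow(X))
    d2 <- rowSums((X - q)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    pt[upd] <- cum_len[s] + tproj[upd] * seg_len[s]
  }
  names(pt) <- rownames(reduced)[member]
  out <- list(populations = path_pops, centroids = P,
              arc_lengths = cum_len, pseudotime = pt)
  class(out) <- "LineagePath"
  out
}

#' Test genes for association with pseudotime
#'
#' Per gene, a likelihood-ratio test of a linear model on a natural cubic
#' spline basis of pseudotime (3 df) plus covariate against the
#' covariate-only model; q-values by BH. Genes are flagged at
#' `q < q_threshold` (the study's cut for trajectory-correlated genes).
#'
#' @param sce `SingleCellExperiment` with a `lognorm` assay (or the matrix).
#' @param pseudotime Named per-cell pseudotime (cells outside are ignored).
#' @param covariate Optional per-cell covariate vector aligned to
#'   `pseudotime` (e.g. smoking indicator).
#' @param q_threshold Flagging threshold (default 1e-10).
#' @return An `AssociationResult` data.frame: gene, statistic, p, q, flagged.
#' @export
pseudotimeAssociation <- function(sce, pseudotime, covariate = NULL,
                                  q_threshold = 1e-10) {
  norm <- .lognormMatrix(sce)
  cells <- intersect(colnames(norm), names(pseudotime))
  if (length(cells) < 20L) stop("need at least 20 cells with pseudotime")
  pt <- pseudotime[cells]
  if (length(unique(pt)) < 2L) stop("constant pseudotime")
  Y <- t(norm[, cells, drop = FALSE])
  n <- nrow(Y)
  X0 <- cbind(rep(1, n))
  if (!is.null(covariate)) {
    cv <- covariate[match(cells, names(pseudotime))]
    if (length(unique(cv)) > 1L) X0 <- cbind(X0, cv)
  }
  S <- splines::ns(pt, df = 3)
  X1 <- cbind(X0, S)
  rss <- function(X) {
    q <- qr(X)
    matrixStats::colSums2(qr.resid(q, Y)^2)
  }
  rss0 <- rss(X0)
  rss1 <- rss(X1)
  stat <- n * log(pmax(rss0, .Machine$double.xmin) /
                    pmax(rss1, .Machine$double.xmin))
  stat[rss0 == 0 & rss1 == 0] <- 0     # constant genes
  stat <- pmax(stat, 0)
  p <- pchisq(stat, df = 3, lower.tail = FALSE)
  q <- bhFdr(p)
  out <- data.frame(gene = colnames(Y), statistic = stat, p = p, q = q,
                    flagged = q < q_threshold, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("AssociationResult", "data.frame")
  out
}

#' Smooth expression along pseudotime with a triangular window
#'
#' Sorts cells by pseudotime and applies a centered moving average with
#' triangular weights; the window is truncated symmetrically at the ends, so
#' the output is a convex combination of inputs (range preserved) and has
#' one value per cell.
#'
#' @param values Per-cell numeric vector.
#' @param pseudotime Per-cell pseudotime, same length.
#' @param window Window size in cells (default 100).
#' @return A data.frame sorted by pseudotime: `pseudotime`, `value`,
#'   `smoothed` (and `cell` when `values` is named).
#' @export
smoothExpression <- function(values, pseudotime, window = 100L) {
  n <- length(values)
  if (window < 3L) stop("window must be >= 3")
  if (n < window) stop("fewer cells (", n, ") than window (", window, ")")
  ord <- order(pseudotime)
  v <- values[ord]
  half <- floor(window / 2)
  sm <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    k <- (i - h):(i + h)
    w <- h + 1 - abs(k - i)
    sum(w * v[k]) / sum(w)
  }, 0)
  out <- data.frame(pseudotime = pseudotime[ord], value = v, smoothed = sm)
  if (!is.null(names(values))) out$cell <- names(values)[ord]
  out
}

#' Two-component 1-D Gaussian mixture fit
#'
#' @slot weights Component weights (sum to 1).
#' @slot means Component means, ordered `mu1 <= mu2`.
#' @slot sds Component standard deviations (floored at 1e-6 x data range).
#' @slot logLik Final log-likelihood.
#' @slot trace Per-iteration log-likelihood (non-decreasing, an EM property).
#' @slot iterations Iterations run.
#' @slot converged Whether the log-likelihood gain fell below tolerance.
#' @export
setClass("MixtureFit",
         representation(weights = "numeric", means = "numeric",
                        sds = "numeric", logLik = "numeric",
                        trace = "numeric", iterations = "integer",
                        converged = "logical"))

setValidity("MixtureFit", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  if (object@means[1] > object@means[2]) return("means must be ordered")
  if (any(object@sds <= 0)) return("sds must be positive")
  TRUE
})

#' @describeIn fitGmm2 Compact display of a mixture fit.
#' @param object A `MixtureFit`.
#' @export
setMethod("show", "MixtureFit", function(object) {
  cat("2-component Gaussian mixture fit\n")
  cat(sprintf("  component 1: w = %.3f, mu = %.4g, sd = %.4g\n",
              object@weights[1], object@means[1], object@sds[1]))
  cat(sprintf("  component 2: w = %.3f, mu = %.4g, sd = %.4g\n",
              object@weights[2], object@means[2], object@sds[2]))
  cat(sprintf("  logLik %.4f after %d iterations (%s)\n", object@logLik,
              object@iterations,
              if (object@converged) "converged" else "not converged"))
})

#' Fit a two-component Gaussian mixture to pseudotime by EM
#'
#' Models 1-D pseudotime as a two-component Gaussian mixture (branch cells
#' versus the denser endpoint), the basis for terminal-population isolation.
#' Initialization is deterministic (25th/75th percentile means, pooled SD,
#' equal weights); components are relabeled so `mu1 <= mu2`; SDs are floored
#' at 1e-6 of the data range to avoid collapse.
#'
#' @param values Numeric vector with at least 10 distinct values.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood gain (default 1e-8).
#' @return A [MixtureFit-class] object.
#' @export
fitGmm2 <- function(values, max_iter = 500L, tol = 1e-8) {
  x <- as.numeric(values)
  if (length(unique(x)) < 10L) stop("need at least 10 distinct values")
  n <- length(x)
  floor_sd <- 1e-6 * diff(range(x))
  mu <- unname(quantile(x, c(0.25, 0.75)))
  sdv <- rep(max(sd(x), floor_sd), 2)
  w <- c(0.5, 0.5)
  ll_of <- function(w, mu, sdv) {
    sum(log(w[1] * stats::dnorm(x, mu[1], sdv[1]) +
              w[2] * stats::dnorm(x, mu[2], sdv[2])))
  }
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sdv[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sdv[2])
    tot <- pmax(d1 + d2, .Machine$double.xmin)
    g <- d1 / tot
    n1 <- sum(g); n2 <- n - n1
    w <- c(n1, n2) / n
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sdv <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                  sum((1 - g) * (x - mu[2])^2) / n2))
    sdv <- pmax(sdv, floor_sd)
    ll <- ll_of(w, mu, sdv)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sdv <- rev(sdv); w <- rev(w)
  }
  new("MixtureFit", weights = w, means = mu, sds = sdv,
      logLik = trace[length(trace)], trace = trace,
      iterations = it, converged = converged)
}

#' Are the two mixture components separated?
#'
#' Diagnostic guarding endpoint isolation: components are considered
#' separated when `|mu2 - mu1| >= 2 * max(sd1, sd2)`.
#'
#' @param fit A `MixtureFit`.
#' @return Logical.
#' @export
gmmSeparated <- function(fit) {
  diff(fit@means) >= 2 * max(fit@sds)
}

#' Isolate the terminal (mature) population by the 2-SD rule
#'
#' Cells with pseudotime greater than two standard deviations to the left of
#' the second (endpoint) mixture component are called terminal:
#' `pseudotime > mu2 - 2 * sd2`.
#'
#' @param pseudotime Per-cell pseudotime vector.
#' @param fit A converged, separated `MixtureFit`.
#' @return Logical mask along `pseudotime` (monotone in pseudotime).
#' @export
isolateTerminal <- function(pseudotime, fit) {
  if (!gmmSeparated(fit))
    stop("mixture components are not separated; endpoint isolation is not ",
         "advisable on this fit")
  pseudotime > fit@means[2] - 2 * fit@sds[2]
}
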