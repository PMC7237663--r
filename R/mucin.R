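#' Mucin co-expression classes of secretory cells
#'
#' Classifies each cell of a secretory subset by raw-count positivity of the
#' two anchor mucins into `both`, `A_only`, `B_only` or `neither`, and
#' reports class proportions (summing to 1) plus an optional third-gene
#' positivity rate (e.g. an SCGB1A1 analog).
#'
#' @param sce `SingleCellExperiment` (or counts matrix).
#' @param cells Cell selection (barcodes or indices) for the secretory subset.
#' @param anchors Length-2 character vector `c(A, B)` (A = MUC5AC analog).
#' @param third Optional third gene whose positivity rate is reported.
#' @return A `CoexpressionProfile` list: `class` (per-cell factor),
#'   `proportions` (named, sums to 1), `third_positive_rate`.
#' @export
coexpressionClasses <- function(sce, cells = seq_len(ncol(sce)),
                                anchors = c("MUC5AC", "MUC5B"), third = NULL) {
  counts <- .countsMatrix(sce)
  if (!all(anchors %in% rownames(counts)))
    stop("anchor gene(s) absent: ",
         paste(setdiff(anchors, rownames(counts)), collapse = ", "))
  if (is.character(cells)) cells <- match(cells, colnames(counts))
  a <- as.numeric(counts[anchors[1], cells]) > 0
  b <- as.numeric(counts[anchors[2], cells]) > 0
  cls <- ifelse(a & b, "both", ifelse(a, "A_only", ifelse(b, "B_only", "neither")))
  cls <- factor(cls, levels = c("both", "A_only", "B_only", "neither"))
  prop <- as.numeric(table(cls)) / length(cls)
  names(prop) <- levels(cls)
  out <- list(class = cls, proportions = prop,
              third_positive_rate = if (!is.null(third)) {
                if (!third %in% rownames(counts)) stop("third gene absent")
                mean(as.numeric(counts[third, cells]) > 0)
              })
  class(out) <- "CoexpressionProfile"
  out
}

.rankRows <- function(M) {
  out <- t(apply(M, 1, rank))
  dimnames(out) <- dimnames(M)
  out
}

#' Partial Spearman correlation controlling for a confounder
#'
#' Rank-transforms `x`, `y` and `z` (average ranks for ties), residualizes
#' the ranked `x` and `y` on ranked `z` by least squares, and returns the
#' Pearson correlation of the residuals with a t-approximation p-value on
#' n - 3 degrees of freedom. A constant `z` falls back to plain Spearman
#' (n - 2 df) with a warning.
#'
#' @param x,y Numeric vectors (non-constant after ranking).
#' @param z Confounder vector (e.g. a smoking indicator).
#' @return List with `rho` and `p`.
#' @export
partialSpearman <- function(x, y, z) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("x and y must be non-constant")
  rx <- rank(x); ry <- rank(y)
  plain <- length(unique(z)) < 2L
  if (plain) {
    warning("constant confounder; falling back to plain Spearman")
    ex <- rx - mean(rx); ey <- ry - mean(ry)
    df <- n - 2L
  } else {
    rz <- rank(z)
    zc <- rz - mean(rz)
    ex <- rx - mean(rx) - sum((rx - mean(rx)) * zc) / sum(zc^2) * zc
    ey <- ry - mean(ry) - sum((ry - mean(ry)) * zc) / sum(zc^2) * zc
    df <- n - 3L
  }
  rho <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  rho <- max(min(rho, 1), -1)
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * pt(-abs(tstat), df))
}

#' Derive anchor-specific co-expression programs
#'
#' Within eligible cells (excluded-donor cells removed; cells not expressing
#' both anchors removed), computes for every gene the partial Spearman
#' correlation with each anchor's log-normalized expression, controlling for
#' smoking, BH-adjusts each anchor's p-vector, and assigns each gene to
#' `A_specific`, `B_specific`, `both` or `none`. Genes are flagged
#' `reportable` when the relevant |rho| exceeds `min_rho_report` (the
#' plotting cut used for the strongest correlations).
#'
#' @param sce `SingleCellExperiment` with `counts`/`lognorm` assays and
#'   `smoking` (+ optional `excluded_flag`) in `colData`.
#' @param cells Secretory-subset cell selection (barcodes or indices).
#' @param anchors Length-2 character vector `c(A, B)`.
#' @param min_rho_report Reporting cut on the partial correlation.
#' @param alpha FDR level for "significantly correlated".
#' @param exclusions Genes to leave out (anchors are always excluded).
#' @return A `ProgramAssignment` data.frame: gene, rho/p/fdr per anchor,
#'   class, reportable; eligible cell ids in attribute `"cells"`.
#' @export
derivePrograms <- function(sce, cells, anchors = c("MUC5AC", "MUC5B"),
                           min_rho_report = 0.15, alpha = 0.05,
                           exclusions = character()) {
  counts <- .countsMatrix(sce)
  norm <- .lognormMatrix(sce)
  if (is.character(cells)) cells <- match(cells, colnames(counts))
  cd <- colData(sce)
  if (!is.null(cd$excluded_flag)) cells <- cells[!cd$excluded_flag[cells]]
  both_pos <- as.numeric(counts[anchors[1], cells]) > 0 &
    as.numeric(counts[anchors[2], cells]) > 0
  cells <- cells[both_pos]
  if (length(cells) < 50L)
    stop("fewer than 50 eligible cells (", length(cells),
         "); rank correlation at this scale is unreliable")
  smoking <- (cd$smoking[cells] == "heavy") * 1

  genes <- setdiff(rownames(norm), c(anchors, exclusions))
  Y <- norm[genes, cells, drop = FALSE]
  keep <- matrixStats::rowVars(Y) > 0
  R <- .rankRows(Y[keep, , drop = FALSE])
  n <- length(cells)

  partial_vs <- function(anchor) {
    ra <- rank(norm[anchor, cells])
    if (length(unique(smoking)) < 2L) {
      ac <- ra - mean(ra)
      Rc <- R - rowMeans(R)
      df <- n - 2L
    } else {
      zc <- rank(smoking) - mean(rank(smoking))
      ac <- ra - mean(ra) - sum((ra - mean(ra)) * zc) / sum(zc^2) * zc
      Rc <- R - rowMeans(R)
      beta <- (Rc %*% zc) / sum(zc^2)
      Rc <- Rc - beta %*% t(zc)
      df <- n - 3L
    }
    rho <- drop(Rc %*% ac) / sqrt(matrixStats::rowSums2(Rc^2) * sum(ac^2))
    rho <- pmax(pmin(rho, 1), -1)
    tstat <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
    list(rho = rho, p = 2 * pt(-abs(tstat), df))
  }
  A <- partial_vs(anchors[1])
  B <- partial_vs(anchors[2])

  out <- data.frame(gene = genes, rho_A = NA_real_, p_A = NA_real_,
                    fdr_A = NA_real_, rho_B = NA_real_, p_B = NA_real_,
                    fdr_B = NA_real_, stringsAsFactors = FALSE)
  gk <- genes[keep]
  m <- match(gk, out$gene)
  out$rho_A[m] <- A$rho; out$p_A[m] <- A$p; out$fdr_A[m] <- bhFdr(A$p)
  out$rho_B[m] <- B$rho; out$p_B[m] <- B$p; out$fdr_B[m] <- bhFdr(B$p)
  sigA <- !is.na(out$fdr_A) & out$fdr_A < alpha
  sigB <- !is.na(out$fdr_B) & out$fdr_B < alpha
  out$class <- ifelse(sigA & sigB, "both",
                      ifelse(sigA, "A_specific",
                             ifelse(sigB, "B_specific", "none")))
  out$reportable <- (sigA & abs(out$rho_A) > min_rho_report) |
    (sigB & abs(out$rho_B) > min_rho_report)
  class(out) <- c("ProgramAssignment", "data.frame")
  attr(out, "cells") <- colnames(counts)[cells]
  out
}

#' Smoking shift of mucin-program scores
#'
#' Per cell, the mean log-normalized expression over the top program genes
#' (ranked by descending partial rho with their anchor); smoker and
#' non-smoker cell scores are compared by a one-sided Wilcoxon rank-sum test
#' whose direction must be stated by the caller (A program: smoker greater;
#' B program: smoker less), never inferred from the data.
#'
#' @param sce `SingleCellExperiment` with a `lognorm` assay.
#' @param program A `ProgramAssignment`.
#' @param which_anchor `"A"` or `"B"`: which anchor-specific program to score.
#' @param cells_smoker,cells_nonsmoker Cell selections.
#' @param direction `"greater"` if smokers are hypothesized higher, `"less"`
#'   otherwise.
#' @param top_n Number of top program genes (default 25).
#' @return List with `p`, the program `genes` used, and per-cell `scores`
#'   (named by cell, smokers then non-smokers).
#' @export
programShiftTest <- function(sce, program, which_anchor = c("A", "B"),
                             cells_smoker, cells_nonsmoker,
                             direction = c("greater", "less"), top_n = 25L) {
  which_anchor <- match.arg(which_anchor)
  direction <- match.arg(direction)
  cls <- paste0(which_anchor, "_specific")
  rho_col <- paste0("rho_", which_anchor)
  sub <- program[program$class == cls, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty ", cls, " program")
  genes <- sub$gene[order(-sub[[rho_col]])][seq_len(min(top_n, nrow(sub)))]
  norm <- .lognormMatrix(sce)
  if (is.character(cells_smoker)) cells_smoker <- match(cells_smoker, colnames(norm))
  if (is.character(cells_nonsmoker)) cells_nonsmoker <- match(cells_nonsmoker, colnames(norm))
  s_sm <- matrixStats::colMeans2(norm[genes, cells_smoker, drop = FALSE])
  s_ns <- matrixStats::colMeans2(norm[genes, cells_nonsmoker, drop = FALSE])
  p <- wilcoxonRankSum(s_sm, s_ns, alternative = direction)
  list(p = p, genes = genes,
       scores = setNames(c(s_sm, s_ns),
                         colnames(norm)[c(cells_smoker, cells_nonsmoker)]))
}
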