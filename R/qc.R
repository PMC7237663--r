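#' QC thresholds
#'
#' Defaults follow the study's filters: doublet guard at the 99th percentile
#' of detected-gene and total-UMI counts, a 1500 detected-gene minimum, a 40%
#' mitochondrial-fraction ceiling (30% is the stricter second-pass option),
#' removal of genes detected in fewer than 0.1% of cells and of
#' mitochondrial/ribosomal symbol prefixes.
#'
#' @param min_genes_per_cell Minimum detected genes per cell.
#' @param max_mito_fraction Maximum mitochondrial UMI fraction.
#' @param upper_percentile Doublet-guard percentile (applied to both detected
#'   gene count and total UMI count, linear interpolation).
#' @param min_cell_fraction_per_gene Minimum fraction of cells a gene must be
#'   detected in (raw count > 0).
#' @param excluded_gene_prefixes Symbol prefixes removed before analysis.
#' @return A validated list of class `QCThresholds`.
#' @export
qcThresholds <- function(min_genes_per_cell = 1500L,
                         max_mito_fraction = 0.40,
                         upper_percentile = 99,
                         min_cell_fraction_per_gene = 0.001,
                         excluded_gene_prefixes = c("MTAT", "MT-", "MTCO",
                                                    "MTCY", "MTERF", "MTND",
                                                    "MTRF", "MTRN", "MRPL",
                                                    "MRPS", "RPL", "RPS")) {
  t <- as.list(environment())
  if (t$max_mito_fraction <= 0 || t$max_mito_fraction > 1)
    stop("max_mito_fraction must be in (0, 1]")
  if (t$upper_percentile <= 50 || t$upper_percentile >= 100)
    stop("upper_percentile must be in (50, 100)")
  if (t$min_cell_fraction_per_gene < 0 || t$min_cell_fraction_per_gene >= 1)
    stop("min_cell_fraction_per_gene must be in [0, 1)")
  class(t) <- "QCThresholds"
  t
}

#' Filter cells by doublet guard, detected-gene floor and mito fraction
#'
#' Removes cells in a fixed attribution order: (1) doublet guard — detected
#' gene count or total UMI count above the configured percentile of the input
#' cells (thresholds computed once on the input, linear interpolation);
#' (2) detected genes below the minimum; (3) mitochondrial UMI fraction above
#' the ceiling. A cell failing several rules is attributed to the first.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param mito_mask Logical vector along genes marking mitochondrial genes;
#'   by default genes whose symbol starts with `"MT-"`.
#' @param thresholds A [qcThresholds()] list.
#' @return A list with `sce` (filtered) and `report` (a `QCReport` list with
#'   per-rule removal tallies, survivors and the frozen percentile cutoffs).
#' @export
filterCells <- function(sce, mito_mask = NULL, thresholds = qcThresholds()) {
  counts <- assay(sce, "counts")
  if (ncol(counts) == 0L || nrow(counts) == 0L) stop("empty count matrix")
  if (is.null(mito_mask)) mito_mask <- startsWith(rownames(counts), "MT-")
  if (length(mito_mask) != nrow(counts))
    stop("mito_mask length does not match gene count")
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito_frac <- if (any(mito_mask))
    Matrix::colSums(counts[mito_mask, , drop = FALSE]) / pmax(total, 1)
  else rep(0, ncol(counts))

  p <- thresholds$upper_percentile / 100
  cut_genes <- quantile(detected, p, type = 7, names = FALSE)
  cut_umi <- quantile(total, p, type = 7, names = FALSE)

  fail1 <- detected > cut_genes | total > cut_umi
  fail2 <- !fail1 & detected < thresholds$min_genes_per_cell
  fail3 <- !fail1 & !fail2 & mito_frac > thresholds$max_mito_fraction
  keep <- !(fail1 | fail2 | fail3)

  report <- list(
    input_cells = ncol(counts),
    removed_doublet_guard = sum(fail1),
    removed_min_genes = sum(fail2),
    removed_mito = sum(fail3),
    survivors = sum(keep),
    cutoff_detected_genes = cut_genes,
    cutoff_total_umi = cut_umi)
  class(report) <- "QCReport"
  stopifnot(report$input_cells ==
              report$removed_doublet_guard + report$removed_min_genes +
              report$removed_mito + report$survivors)
  list(sce = sce[, keep], report = report)
}

#' Filter genes by symbol prefix and detection fraction
#'
#' Removes genes whose symbol starts with an excluded prefix (exact
#' string-prefix match, case sensitive), then genes detected (raw count > 0)
#' in fewer than `min_cell_fraction_per_gene` of the remaining cells.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param thresholds A [qcThresholds()] list.
#' @return A list with `sce` (filtered) and `report` (`QCReport` tallies).
#' @export
filterGenes <- function(sce, thresholds = qcThresholds()) {
  counts <- assay(sce, "counts")
  genes <- rownames(counts)
  pref <- rep(FALSE, length(genes))
  for (px in thresholds$excluded_gene_prefixes)
    pref <- pref | startsWith(genes, px)
  frac <- Matrix::rowSums(counts > 0) / ncol(counts)
  low <- !pref & frac < thresholds$min_cell_fraction_per_gene
  keep <- !(pref | low)
  report <- list(
    input_genes = length(genes),
    removed_prefix = sum(pref),
    removed_min_fraction = sum(low),
    survivors = sum(keep))
  class(report) <- "QCReport"
  stopifnot(report$input_genes ==
              report$removed_prefix + report$removed_min_fraction +
              report$survivors)
  list(sce = sce[keep, ], report = report)
}

#' Depth-normalize and log-transform counts
#'
#' Scales each cell to a fixed total count and applies `log(x + 1)`. This is
#' the package's deliberate, deterministic replacement for regression-based
#' variance stabilization: every downstream stage is rank- or detection-based
#' and insensitive to that choice.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param scale_total Target total count per cell.
#' @return `sce` with an added dense `lognorm` assay.
#' @export
normalizeCounts <- function(sce, scale_total = 1e4) {
  counts <- assay(sce, "counts")
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("cell(s) with zero total count; run QC first")
  norm <- log1p(Matrix::t(Matrix::t(counts) * (scale_total / total)))
  assay(sce, "lognorm") <- as.matrix(norm)
  sce
}

#' Geometric-mean expression score over a gene panel
#'
#' Per cell, `exp(mean(log(x + 1))) - 1` over the listed genes, where `x` is
#' log-normalized expression. The +1 convention keeps all-zero cells at 0 and
#' damps outliers. Genes absent from the matrix are dropped with a warning.
#'
#' @param normalized Genes x cells matrix of log-normalized expression (the
#'   `lognorm` assay), or a `SingleCellExperiment` carrying one.
#' @param genes Character vector of gene symbols.
#' @return Named per-cell numeric vector.
#' @export
geometricMeanScore <- function(normalized, genes) {
  m <- .lognormMatrix(normalized)
  present <- intersect(genes, rownames(m))
  if (length(present) == 0L) stop("none of the listed genes are present")
  if (length(present) < length(genes))
    warning(length(genes) - length(present), " listed gene(s) absent; dropped")
  exp(colMeans(log1p(m[present, , drop = FALSE]))) - 1
}

#' Scale values to the unit interval
#'
#' `(x - min) / (max - min)`; invariant under affine transforms of the input.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Vector in `[0, 1]`.
#' @export
scaleUnit <- function(values) {
  r <- range(values)
  if (diff(r) == 0) stop("cannot unit-scale a constant vector")
  (values - r[1]) / (r[2] - r[1])
}

.lognormMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (!"lognorm" %in% assayNames(x))
      stop("no 'lognorm' assay; run normalizeCounts() first")
    assay(x, "lognorm")
  } else {
    as.matrix(x)
  }
}

.countsMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) assay(x, "counts") else x
}
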