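#' Cell characterization rule
#'
#' Percentile rule used to call cells as characteristic of a population: a
#' cell is labeled `P` iff its `P` marker score is at least at the
#' `own_percentile` of `P` scores across all cells while every other
#' population's score stays below that population's `other_percentile`.
#'
#' @param own_percentile Percentile a population's own score must reach.
#' @param other_percentile Percentile all other populations' scores must stay
#'   below.
#' @param top_n_markers Markers per population used for the score.
#' @param overrides Optional named vector of per-population percentile
#'   overrides (e.g. 95 for a transitional population needing stringency).
#' @return A list of class `CharacterizationRule`.
#' @export
characterizationRule <- function(own_percentile = 85, other_percentile = 85,
                                 top_n_markers = 100L, overrides = NULL) {
  if (own_percentile <= 50 || own_percentile >= 100 ||
      other_percentile <= 50 || other_percentile >= 100)
    stop("percentiles must be in (50, 100)")
  structure(list(own_percentile = own_percentile,
                 other_percentile = other_percentile,
                 top_n_markers = top_n_markers,
                 overrides = overrides), class = "CharacterizationRule")
}

.onehot <- function(f) {
  f <- factor(f)
  if (nlevels(f) < 2L) return(NULL)
  m <- outer(f, levels(f)[-1], `==`) * 1
  colnames(m) <- paste0("lvl_", levels(f)[-1])
  m
}

#' Derive population markers by downsampled pairwise differential expression
#'
#' For every population pair, clusters larger than the median cluster size
#' are downsampled (seeded, without replacement) to that size, and a gated DE
#' contrast is run. A gene is a marker of population `P` iff significantly
#' upregulated (FDR < alpha) in `P` against every other population. Each
#' marker's summary p is the largest p across `P`'s comparisons, re-adjusted
#' by BH within `P`; ranks are by ascending FDR, ties broken by descending
#' minimum log fold-change then gene name.
#'
#' @param sce `SingleCellExperiment` with `counts`/`lognorm` assays and a
#'   `population` column in `colData` (or pass `labels`).
#' @param labels Optional population label vector overriding `colData`.
#' @param thresholds A [deThresholds()] list.
#' @param test `"lr"` (latent smoking + donor covariates, the study's choice
#'   for population contrasts) or `"wilcoxon"`.
#' @param min_cells Populations with fewer cells are excluded with a warning.
#' @param seed Seed for the downsampling.
#' @return A `MarkerTable` data.frame: population, gene, max_p, fdr,
#'   min_logfc, rank.
#' @export
pairwiseMarkers <- function(sce, labels = NULL, thresholds = deThresholds(),
                            test = c("lr", "wilcoxon"), min_cells = 25L,
                            seed = 1L) {
  test <- match.arg(test)
  if (is.null(labels)) labels <- colData(sce)$population
  if (is.null(labels)) stop("no population labels available")
  labels <- as.character(labels)
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_cells]
  if (length(small))
    warning("excluding population(s) below ", min_cells, " cells: ",
            paste(small, collapse = ", "))
  pops <- setdiff(names(sizes), small)
  if (length(pops) < 2L) stop("need at least two populations")
  med <- median(sizes[pops])

  set.seed(seed)
  cells_of <- lapply(pops, function(p) {
    idx <- which(labels == p)
    if (length(idx) > med) sort(sample(idx, med)) else idx
  })
  names(cells_of) <- pops

  cd <- colData(sce)
  covs_for <- function(idx) {
    sm <- if (!is.null(cd$smoking)) (cd$smoking[idx] == "heavy") * 1 else NULL
    dn <- if (!is.null(cd$donor)) .onehot(cd$donor[idx]) else NULL
    cbind(smoking = sm, dn)
  }

  np <- length(pops)
  de <- vector("list", np * np)  # de[[i + np*(j-1)]]: contrast pops[i] vs pops[j]
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      idx <- c(cells_of[[i]], cells_of[[j]])
      tab <- deContrast(sce, cells_of[[i]], cells_of[[j]], thresholds,
                        test = test,
                        covariates = if (test == "lr") covs_for(idx))
      de[[i + np * (j - 1L)]] <- tab
      flip <- tab
      flip$logfc <- -tab$logfc
      flip$pct_a <- tab$pct_b
      flip$pct_b <- tab$pct_a
      de[[j + np * (i - 1L)]] <- flip
    }
  }

  rows <- list()
  for (i in seq_len(np)) {
    others <- setdiff(seq_len(np), i)
    ok <- rep(TRUE, nrow(sce))
    max_p <- rep(0, nrow(sce))
    min_lfc <- rep(Inf, nrow(sce))
    for (j in others) {
      tab <- de[[i + np * (j - 1L)]]
      pass <- tab$tested & !is.na(tab$fdr) & tab$fdr < thresholds$alpha_fdr &
        tab$logfc > thresholds$min_logfc
      ok <- ok & pass
      max_p <- pmax(max_p, ifelse(is.na(tab$p), 1, tab$p))
      min_lfc <- pmin(min_lfc, tab$logfc)
    }
    if (!any(ok)) next
    g <- which(ok)
    fdr <- bhFdr(max_p[g])
    ord <- order(fdr, -min_lfc[g], rownames(sce)[g])
    rows[[pops[i]]] <- data.frame(
      population = pops[i], gene = rownames(sce)[g][ord],
      max_p = max_p[g][ord], fdr = fdr[ord],
      min_logfc = min_lfc[g][ord], rank = seq_along(ord),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(population = character(), gene = character(),
                  max_p = numeric(), fdr = numeric(), min_logfc = numeric(),
                  rank = integer(), stringsAsFactors = FALSE)
  class(out) <- c("MarkerTable", "data.frame")
  out
}

#' Marker-signature score per cell
#'
#' Geometric mean of log-normalized expression over the top-ranked markers of
#' a population (all markers if fewer than `top_n` are available).
#'
#' @param normalized `lognorm` matrix or a `SingleCellExperiment`.
#' @param marker_table A `MarkerTable` from [pairwiseMarkers()].
#' @param population Population whose signature to score.
#' @param top_n Number of top markers (default 25).
#' @return Named per-cell numeric score vector.
#' @export
signatureScore <- function(normalized, marker_table, population, top_n = 25L) {
  sub <- marker_table[marker_table$population == population, , drop = FALSE]
  if (nrow(sub) == 0L) stop("population ", population, " absent from marker table")
  genes <- sub$gene[order(sub$rank)][seq_len(min(top_n, nrow(sub)))]
  geometricMeanScore(normalized, genes)
}

#' Characterize cells by the percentile rule
#'
#' Scores every cell for every population's marker signature and labels a
#' cell with a population only when its score reaches that population's own
#' percentile while all other populations' scores stay below their
#' percentiles (computed across all cells); otherwise the cell is unassigned.
#'
#' @param normalized `lognorm` matrix or a `SingleCellExperiment`.
#' @param marker_table A `MarkerTable`.
#' @param rule A [characterizationRule()].
#' @return Character vector of labels (`NA` for unassigned), one per cell.
#' @export
characterizeCells <- function(normalized, marker_table,
                              rule = characterizationRule()) {
  pops <- unique(marker_table$population)
  if (length(pops) < 2L) stop("need markers for at least two populations")
  m <- .lognormMatrix(normalized)
  scores <- vapply(pops, function(p)
    signatureScore(m, marker_table, p, rule$top_n_markers),
    numeric(ncol(m)))
  pct <- setNames(rep(rule$other_percentile, length(pops)), pops)
  if (!is.null(rule$overrides)) pct[names(rule$overrides)] <- rule$overrides
  own_cut <- vapply(pops, function(p)
    quantile(scores[, p], max(rule$own_percentile, pct[p]) / 100,
             names = FALSE), 0)
  other_cut <- vapply(pops, function(p)
    quantile(scores[, p], pct[p] / 100, names = FALSE), 0)
  passes_own <- sweep(scores, 2, own_cut, `>=`)
  below_other <- sweep(scores, 2, other_cut, `<`)
  labels <- rep(NA_character_, nrow(scores))
  for (k in seq_along(pops)) {
    others_ok <- rowSums(!below_other[, -k, drop = FALSE]) == 0L
    hit <- passes_own[, k] & others_ok
    labels[hit & is.na(labels)] <- pops[k]
    labels[hit & !is.na(labels) & labels != pops[k]] <- "ambiguous"
  }
  labels[labels %in% "ambiguous"] <- NA_character_
  names(labels) <- colnames(m)
  labels
}
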