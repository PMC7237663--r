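#' Smoking-response taxonomy thresholds
#'
#' @param core_min Minimum number of roster populations a gene must be
#'   significant in (same direction) to be core (default 5).
#' @param unique_logfc_max A unique gene must show |logFC| below this in all
#'   other roster populations (or...)
#' @param unique_fdr_min ...an FDR above this (inclusive-or, per population),
#'   or be untested there.
#' @param alpha Per-population FDR significance level.
#' @return A list of class `TaxonomyThresholds`.
#' @export
taxonomyThresholds <- function(core_min = 5L, unique_logfc_max = 0.25,
                               unique_fdr_min = 0.2, alpha = 0.05) {
  if (core_min < 1L) stop("core_min must be positive")
  if (unique_logfc_max <= 0 || unique_fdr_min <= 0 || alpha <= 0 || alpha >= 1)
    stop("thresholds must be positive (alpha in (0,1))")
  structure(list(core_min = core_min, unique_logfc_max = unique_logfc_max,
                 unique_fdr_min = unique_fdr_min, alpha = alpha),
            class = "TaxonomyThresholds")
}

.significanceMatrix <- function(de_tables, roster, alpha, direction) {
  genes <- de_tables[[roster[1]]]$gene
  sig <- vapply(roster, function(p) {
    tab <- de_tables[[p]]
    s <- tab$tested & !is.na(tab$fdr) & tab$fdr < alpha
    if (direction == "up") s & tab$logfc > 0 else s & tab$logfc < 0
  }, logical(length(genes)))
  rownames(sig) <- genes
  sig
}

#' Classify smoking-response genes into core / unique / semi-unique
#'
#' Runs separately per direction. A gene is *significant* in a population iff
#' FDR < alpha with log fold-change of that sign. It is **core** when
#' significant in at least `core_min` roster populations; **unique** to a
#' population when significant there and nowhere else while every other
#' roster population shows |logFC| below `unique_logfc_max` and/or FDR above
#' `unique_fdr_min` (untested genes count as not affected); significant
#' somewhere but neither core nor unique is **semi-unique**.
#'
#' @param de_tables Named list of `DETable`s (smoker vs non-smoker, one per
#'   roster population, shared gene universe).
#' @param thresholds A [taxonomyThresholds()] list.
#' @param roster Populations assessed (default: all table names).
#' @return A `ResponseTaxonomy` list with `up` and `down` data.frames
#'   (gene, class, population, n_significant) and the roster used.
#' @export
classifyResponse <- function(de_tables, thresholds = taxonomyThresholds(),
                             roster = names(de_tables)) {
  miss <- setdiff(roster, names(de_tables))
  if (length(miss)) stop("missing DE table(s) for roster population(s): ",
                         paste(miss, collapse = ", "))
  if (thresholds$core_min > length(roster))
    stop("core_min exceeds roster size")
  genes <- de_tables[[roster[1]]]$gene
  for (p in roster)
    if (!identical(de_tables[[p]]$gene, genes))
      stop("DE tables do not share a gene universe")

  classify_dir <- function(direction) {
    sig <- .significanceMatrix(de_tables, roster, thresholds$alpha, direction)
    n_sig <- rowSums(sig)
    cls <- rep("none", length(genes))
    pop <- rep(NA_character_, length(genes))
    cls[n_sig >= thresholds$core_min] <- "core"
    one <- which(n_sig == 1L)
    for (i in one) {
      p_sig <- roster[which(sig[i, ])]
      excl_ok <- vapply(setdiff(roster, p_sig), function(p) {
        tab <- de_tables[[p]]
        !tab$tested[i] ||
          abs(tab$logfc[i]) < thresholds$unique_logfc_max ||
          (!is.na(tab$fdr[i]) && tab$fdr[i] > thresholds$unique_fdr_min)
      }, TRUE)
      if (all(excl_ok)) {
        cls[i] <- "unique"
        pop[i] <- p_sig
      } else {
        cls[i] <- "semi_unique"
      }
    }
    cls[n_sig >= 2L & cls == "none"] <- "semi_unique"
    data.frame(gene = genes, class = cls, population = pop,
               n_significant = n_sig, row.names = NULL,
               stringsAsFactors = FALSE)
  }
  out <- list(up = classify_dir("up"), down = classify_dir("down"),
              roster = roster)
  class(out) <- "ResponseTaxonomy"
  out
}

#' Extract the gene sets of a response taxonomy
#'
#' @param taxonomy A `ResponseTaxonomy`.
#' @return Named list of gene sets: `core_up`, `core_down`,
#'   `unique_up.<pop>`, `unique_down.<pop>`, `semi_unique_up/down`.
#' @export
responseGeneSets <- function(taxonomy) {
  sets <- list(core_up = taxonomy$up$gene[taxonomy$up$class == "core"],
               core_down = taxonomy$down$gene[taxonomy$down$class == "core"],
               semi_unique_up = taxonomy$up$gene[taxonomy$up$class == "semi_unique"],
               semi_unique_down = taxonomy$down$gene[taxonomy$down$class == "semi_unique"])
  for (p in taxonomy$roster) {
    sets[[paste0("unique_up.", p)]] <-
      taxonomy$up$gene[taxonomy$up$class == "unique" &
                         !is.na(taxonomy$up$population) &
                         taxonomy$up$population == p]
    sets[[paste0("unique_down.", p)]] <-
      taxonomy$down$gene[taxonomy$down$class == "unique" &
                           !is.na(taxonomy$down$population) &
                           taxonomy$down$population == p]
  }
  sets[vapply(sets, length, 1L) > 0L]
}

#' Marker-set enrichment in response gene sets
#'
#' Upper-tail hypergeometric over-representation of each population's marker
#' set within each response gene set, BH-adjusted across the whole matrix.
#'
#' @param marker_sets Named list of marker gene sets, or a `MarkerTable`
#'   (all markers per population are used).
#' @param response_sets Named list of response gene sets (e.g.
#'   [responseGeneSets()] output) .
#' @param universe Character vector: the tested gene universe.
#' @param alpha Significance level on the adjusted values.
#' @return An `EnrichmentMatrix` list with matrices `neglog10_fdr`, `fdr`,
#'   `overlap` and `significant` (marker sets x response sets).
#' @export
markerSetEnrichment <- function(marker_sets, response_sets, universe,
                                alpha = 0.05) {
  if (length(universe) == 0L) stop("empty universe")
  if (methods::is(marker_sets, "data.frame"))
    marker_sets <- split(marker_sets$gene, marker_sets$population)
  marker_sets <- lapply(marker_sets, intersect, y = universe)
  response_sets <- lapply(response_sets, intersect, y = universe)
  N <- length(unique(universe))
  pm <- matrix(NA_real_, length(marker_sets), length(response_sets),
               dimnames = list(names(marker_sets), names(response_sets)))
  ov <- pm
  for (i in seq_along(marker_sets)) {
    for (j in seq_along(response_sets)) {
      k <- length(intersect(marker_sets[[i]], response_sets[[j]]))
      ov[i, j] <- k
      pm[i, j] <- hypergeomUpper(k, length(marker_sets[[i]]),
                                 length(response_sets[[j]]), N)
    }
  }
  fdr <- matrix(bhFdr(as.vector(pm)), nrow(pm), ncol(pm),
                dimnames = dimnames(pm))
  out <- list(neglog10_fdr = -log10(fdr), fdr = fdr, overlap = ov,
              significant = fdr < alpha, p = pm)
  class(out) <- "EnrichmentMatrix"
  out
}

#' Donor-level composition shift of population proportions
#'
#' Per donor, population proportions over that donor's cells; each smoker
#' donor's percent shift is measured relative to the mean proportion across
#' non-smoker donors, and summarized as mean and standard error across smoker
#' donors. Light-smoker/excluded cells are ignored.
#'
#' @param annotations Per-cell `DataFrame`/data.frame with `donor`, `smoking`,
#'   `population` (and optional `excluded_flag`).
#' @return A data.frame per population: non-smoker mean proportion, per-donor
#'   shifts (long format columns `donor`, `shift_pct`), and per-population
#'   summary columns `mean_shift_pct`, `se_shift_pct`, `defined`.
#' @export
proportionShift <- function(annotations) {
  a <- as.data.frame(annotations)
  if (!is.null(a$excluded_flag)) a <- a[!a$excluded_flag, , drop = FALSE]
  a <- a[a$smoking %in% c("never", "heavy") & !is.na(a$population), ,
         drop = FALSE]
  if (!any(a$smoking == "never") || !any(a$smoking == "heavy"))
    stop("need labeled cells from both never- and heavy-smoker donors")
  pops <- sort(unique(a$population))
  donors <- unique(a[, c("donor", "smoking")])
  prop_of <- function(d) {
    cells <- a[a$donor == d, ]
    tab <- table(factor(cells$population, levels = pops))
    as.numeric(tab) / nrow(cells)
  }
  props <- vapply(donors$donor, prop_of, numeric(length(pops)))
  rownames(props) <- pops
  ns_mean <- rowMeans(props[, donors$smoking == "never", drop = FALSE])
  sm <- props[, donors$smoking == "heavy", drop = FALSE]
  shifts <- 100 * sweep(sweep(sm, 1, ns_mean, `-`), 1, ns_mean, `/`)
  defined <- ns_mean > 0
  shifts[!defined, ] <- NA_real_
  summary <- data.frame(
    population = pops,
    nonsmoker_mean_proportion = ns_mean,
    mean_shift_pct = rowMeans(shifts),
    se_shift_pct = apply(shifts, 1, sd) / sqrt(ncol(shifts)),
    defined = defined,
    row.names = NULL, stringsAsFactors = FALSE)
  per_donor <- data.frame(
    population = rep(pops, ncol(shifts)),
    donor = rep(colnames(sm), each = length(pops)),
    shift_pct = as.vector(shifts),
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, per_donor = per_donor)
}

#' Per-population share of a gene's transcripts and per-cell fold differences
#'
#' The share is each population's summed raw UMIs for the gene over the total
#' (shares sum to 1 exactly); per-cell fold differences are ratios of
#' +1-stabilized population means of depth-normalized expression.
#'
#' @param sce `SingleCellExperiment` with `counts` and `lognorm` assays and
#'   population labels in `colData`.
#' @param gene Gene symbol.
#' @return A list with `share` (named vector) and `fold` (population x
#'   population matrix; entry `[a, b]` = fold of `a` over `b`).
#' @export
transcriptShare <- function(sce, gene) {
  if (!gene %in% rownames(sce)) stop("gene ", gene, " not present")
  pop <- colData(sce)$population
  if (is.null(pop)) stop("no population labels")
  cnt <- as.numeric(assay(sce, "counts")[gene, ])
  if (sum(cnt) == 0) stop("gene ", gene, " is unexpressed; shares undefined")
  norm <- .lognormMatrix(sce)[gene, ]
  pops <- sort(unique(pop))
  share <- vapply(pops, function(p) sum(cnt[pop == p]), 0) / sum(cnt)
  m <- vapply(pops, function(p) mean(expm1(norm[pop == p])), 0)
  fold <- outer(m + 1, m + 1, `/`)
  dimnames(fold) <- list(pops, pops)
  list(share = share, fold = fold)
}
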