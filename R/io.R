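#' Read a UMI count matrix from MatrixMarket + id files
#'
#' Reads the standard CellRanger-style trio: a MatrixMarket coordinate file of
#' UMI counts plus one-symbol-per-line gene and barcode files. On-disk
#' orientation is genes x cells by default; set `transpose = TRUE` for files
#' stored cells x genes.
#'
#' @param matrix_path Path to the `.mtx` file (coordinate integer format).
#' @param genes_path Path to the gene symbol file (one per line).
#' @param barcodes_path Path to the cell barcode file (one per line).
#' @param transpose Logical; `TRUE` if the file is stored cells x genes.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (sparse, genes x cells), gene symbols as rownames and barcodes as
#'   colnames.
#' @export
readCountMatrix <- function(matrix_path, genes_path, barcodes_path,
                            transpose = FALSE) {
  m <- Matrix::readMM(matrix_path)
  if (transpose) m <- Matrix::t(m)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  genes <- sub("\t.*$", "", genes)     # tolerate 10x two-column genes.tsv
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
    stop("count matrix is ", nrow(m), " x ", ncol(m), " but id files have ",
         length(genes), " genes and ", length(barcodes), " barcodes")
  }
  rownames(m) <- genes
  colnames(m) <- barcodes
  makeCountSCE(m)
}

#' Assemble and validate a count container
#'
#' Wraps a genes x cells matrix into a `SingleCellExperiment` after checking
#' the count-matrix invariants: unique ids, non-negative integral entries.
#'
#' @param counts Matrix or sparse Matrix with rownames (genes) and colnames
#'   (cell barcodes).
#' @param colData Optional per-cell annotation `DataFrame`/data.frame.
#' @return A `SingleCellExperiment`.
#' @export
makeCountSCE <- function(counts, colData = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell barcodes")
  x <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(x) && (min(x) < 0 || any(x != floor(x))))
    stop("counts must be non-negative integers")
  counts <- methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
  if (is.null(colData)) {
    SingleCellExperiment(assays = list(counts = counts))
  } else {
    colData <- S4Vectors::DataFrame(colData)
    if (!identical(rownames(colData), colnames(counts)) &&
        !is.null(colData$cell_id))
      rownames(colData) <- colData$cell_id
    if (!identical(rownames(colData), colnames(counts)))
      stop("colData rows do not match count matrix cells")
    SingleCellExperiment(assays = list(counts = counts), colData = colData)
  }
}

#' Write a count matrix as MatrixMarket + id files
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths written.
#' @export
writeCountMatrix <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- assay(sce, "counts")
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(m, paths[1])
  writeLines(rownames(m), paths[2])
  writeLines(colnames(m), paths[3])
  invisible(paths)
}

.smoking_levels <- c("never", "light", "heavy")

#' Read a per-cell annotation table
#'
#' Expects a TSV with header and at least `cell_id`, `donor` and `smoking`
#' columns; `population`, `pseudotime` and `excluded_flag` are optional.
#' Smoking must be one of `never`, `light`, `heavy`.
#'
#' @param path Path to the TSV.
#' @return A [S4Vectors::DataFrame] keyed by `cell_id`.
#' @export
readAnnotations <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateAnnotations(d)
}

#' Validate a per-cell annotation table
#' @param d data.frame with cell_id, donor, smoking columns.
#' @return A validated `DataFrame` keyed by cell_id.
#' @export
validateAnnotations <- function(d) {
  need <- c("cell_id", "donor", "smoking")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) stop("annotation table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(d$cell_id)) stop("duplicated cell_id in annotations")
  bad <- setdiff(unique(d$smoking), .smoking_levels)
  if (length(bad)) stop("unknown smoking level(s): ", paste(bad, collapse = ", "))
  if (!is.null(d$pseudotime)) {
    pt <- d$pseudotime[!is.na(d$pseudotime)]
    if (length(pt) && (!all(is.finite(pt)) || any(pt < 0)))
      stop("pseudotime must be finite and non-negative")
  }
  if (is.null(d$excluded_flag)) d$excluded_flag <- FALSE
  out <- S4Vectors::DataFrame(d)
  rownames(out) <- d$cell_id
  out
}

#' Write a per-cell annotation table to TSV
#' @param ann DataFrame/data.frame of annotations.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeAnnotations <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields `name`, `description`, then member
#' symbols, all tab-separated. Duplicate members within a set are dropped.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; the source path is kept in the
#'   `"source"` attribute.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  if (any(vapply(sets, length, 1L) == 0L)) stop("empty gene set in GMT")
  attr(sets, "source") <- path
  sets
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return Invisibly, `path`.
#' @export
writeGMT <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
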