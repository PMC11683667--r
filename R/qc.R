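#' Cell and gene inclusion thresholds
#'
#' The standard single-cell inclusion criteria: genes detected in more than
#' `min_cells_per_gene` cells; cells with more than `min_genes_per_cell`
#' detected genes, a detected-gene count inside `gene_count_range`, and a
#' mitochondrial count percentage below `max_mito_percent` (10 for human
#' tissue, 20 for mouse). All "more than"/"below" comparisons are strict.
#'
#' @param min_cells_per_gene Keep genes detected (count > 0) in strictly
#'   more than this many cells.
#' @param min_genes_per_cell Keep cells with strictly more detected genes.
#' @param gene_count_range Inclusive `[lower, upper]` window on the number
#'   of detected genes per cell.
#' @param max_mito_percent Cells at or above this mitochondrial percentage
#'   are removed.
#' @param species Convenience switch: `"mouse"` raises the default
#'   mitochondrial cutoff to 20.
#' @return A list of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_cells_per_gene = 3,
                          min_genes_per_cell = 300,
                          gene_count_range = c(200, 5000),
                          max_mito_percent = if (species == "mouse") 20 else 10,
                          species = c("human", "mouse")) {
  species <- match.arg(species)
  if (gene_count_range[1] > gene_count_range[2])
    stop("parameter error: gene_count_range lower bound exceeds upper bound")
  if (max_mito_percent < 0 || max_mito_percent > 100)
    stop("parameter error: max_mito_percent must be in [0,100]")
  structure(list(min_cells_per_gene = min_cells_per_gene,
                 min_genes_per_cell = min_genes_per_cell,
                 gene_count_range = gene_count_range,
                 max_mito_percent = max_mito_percent,
                 species = species),
            class = "QCThresholds")
}

#' Apply cell and gene quality filters
#'
#' The gene filter is applied first; the cell criteria (detected genes,
#' detected-gene window, mitochondrial percentage) are then evaluated on the
#' gene-filtered matrix. Surviving labels keep their input order. Removing
#' every cell is reported with a warning, not an error.
#'
#' @param counts An [expression_matrix()] in `raw_counts` mode.
#' @param thresholds A [qc_thresholds()].
#' @param mito_genes Character vector of mitochondrial gene symbols (used to
#'   compute the per-cell mitochondrial percentage; symbols absent from the
#'   matrix are ignored).
#' @return List with `counts` (filtered matrix) and `report` (a `QCReport`:
#'   totals in/out plus per-criterion removal counts; a cell failing several
#'   criteria appears in each per-criterion count but once in the totals).
#' @export
apply_qc <- function(counts, thresholds = qc_thresholds(),
                     mito_genes = character(0)) {
  assert_mode(counts, "raw_counts", "apply_qc")
  x <- counts$values
  detected <- x > 0
  keep_gene <- rowSums(detected) > thresholds$min_cells_per_gene
  x2 <- x[keep_gene, , drop = FALSE]

  ngenes_cell <- colSums(x2 > 0)
  mito_here <- intersect(mito_genes, rownames(x2))
  tot <- colSums(x2)
  mito_pct <- ifelse(tot > 0,
                     100 * colSums(x2[mito_here, , drop = FALSE]) / tot, 0)
  fail_min <- !(ngenes_cell > thresholds$min_genes_per_cell)
  fail_range <- ngenes_cell < thresholds$gene_count_range[1] |
    ngenes_cell > thresholds$gene_count_range[2]
  fail_mito <- !(mito_pct < thresholds$max_mito_percent)
  keep_cell <- !(fail_min | fail_range | fail_mito)

  if (!any(keep_cell))
    warning("apply_qc removed every cell; output matrix has zero columns")

  out <- expression_matrix(x2[, keep_cell, drop = FALSE],
                           counts$gene_ids[keep_gene],
                           counts$obs_ids[keep_cell], "raw_counts")
  report <- structure(list(
    n_genes_in = nrow(x), n_genes_out = nrow(out$values),
    n_cells_in = ncol(x), n_cells_out = ncol(out$values),
    genes_removed_low_detection = sum(!keep_gene),
    cells_removed_min_genes = sum(fail_min),
    cells_removed_gene_range = sum(fail_range),
    cells_removed_mito = sum(fail_mito)), class = "QCReport")
  list(counts = out, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QC: genes", x$n_genes_in, "->", x$n_genes_out,
      "| cells", x$n_cells_in, "->", x$n_cells_out, "\n")
  cat("  genes removed (low detection):", x$genes_removed_low_detection, "\n")
  cat("  cells failing min detected genes:", x$cells_removed_min_genes,
      "; gene-count window:", x$cells_removed_gene_range,
      "; mito percent:", x$cells_removed_mito, "\n")
  invisible(x)
}

#' Library-size normalization and log transform for single cells
#'
#' Scales each cell to a common library size `scale_factor` and applies
#' `log1p`, the standard single-cell log-normalization. Cells with zero
#' total counts are an error (run [apply_qc()] first).
#'
#' @param counts An [expression_matrix()] in `raw_counts` mode.
#' @param scale_factor Common library size (default 10,000).
#' @return An [expression_matrix()] in `log_normalized` mode.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  assert_mode(counts, "raw_counts", "lognormalize")
  tot <- colSums(counts$values)
  if (any(tot == 0))
    stop("lognormalize: ", sum(tot == 0),
         " cell(s) have zero total counts; apply QC first")
  vals <- log1p(sweep(counts$values, 2, tot / scale_factor, "/"))
  expression_matrix(vals, counts$gene_ids, counts$obs_ids, "log_normalized")
}

#' Median-of-ratios normalization for bulk counts
#'
#' Size factors are the per-sample median ratio to the geometric-mean
#' reference profile, computed over genes with all-positive counts; counts
#' are divided by the factor and transformed with `log2(x + 1)`. When no
#' gene has all-positive counts the factors fall back to relative library
#' sizes, with a warning.
#'
#' @param counts An [expression_matrix()] of raw counts over samples.
#' @return An [expression_matrix()] in `log_normalized` mode (log2 scale),
#'   with the size factors attached as attribute `size_factors`.
#' @export
normalize_bulk <- function(counts) {
  assert_mode(counts, "raw_counts", "normalize_bulk")
  x <- counts$values
  allpos <- rowSums(x > 0) == ncol(x)
  if (!any(allpos)) {
    warning("normalize_bulk: no gene with all-positive counts; ",
            "falling back to library-size factors")
    lib <- colSums(x)
    sf <- lib / exp(mean(log(lib)))
  } else {
    logx <- log(x[allpos, , drop = FALSE])
    ref <- rowMeans(logx)
    sf <- exp(apply(logx - ref, 2, stats::median))
  }
  vals <- log2(sweep(x, 2, sf, "/") + 1)
  out <- expression_matrix(vals, counts$gene_ids, counts$obs_ids,
                           "log_normalized")
  attr(out, "size_factors") <- setNames(sf, counts$obs_ids)
  out
}
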