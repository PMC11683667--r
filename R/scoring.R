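#' Binned-control module score
#'
#' The standard single-cell gene-set score: genes are ranked by their mean
#' expression across cells and cut into `n_bins` equal-frequency bins; for
#' each set gene, `n_ctrl` control genes are drawn (seeded; with replacement
#' when the bin is smaller than `n_ctrl`) from the same bin; a cell's score
#' is its mean expression over the set genes minus its mean expression over
#' all sampled control genes. Controls are expression-matched, so the score
#' is centered near zero for an uninformative set and is invariant to
#' adding a constant to one cell's expression vector.
#'
#' @param expr [expression_matrix()], `log_normalized`, over cells.
#' @param gene_set Character vector of set gene symbols.
#' @param n_bins Number of equal-frequency expression bins.
#' @param n_ctrl Control genes sampled per set gene.
#' @param seed Integer seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1) {
  assert_mode(expr, "log_normalized", "module_score")
  present <- intersect(gene_set, expr$gene_ids)
  if (!length(present))
    stop("no gene of the set is present in the matrix; missing: ",
         paste(utils::head(gene_set, 10), collapse = ", "))
  n_genes <- length(expr$gene_ids)
  if (n_bins > n_genes)
    stop("n_bins exceeds the number of genes")
  means <- rowMeans(expr$values)
  bin <- ceiling(rank(means, ties.method = "first") * n_bins / n_genes)
  names(bin) <- expr$gene_ids
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- expr$gene_ids[bin == bin[[g]]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }), use.names = FALSE)
  })
  set_mean <- colMeans(expr$values[present, , drop = FALSE])
  ctrl_mean <- colMeans(expr$values[ctrl, , drop = FALSE])
  set_mean - ctrl_mean
}

#' Single-sample GSEA score for one observation
#'
#' The rank-based integrated difference between the in-set and out-of-set
#' cumulative distributions: genes are ordered by decreasing expression
#' (ties broken by ascending gene symbol for determinism); the in-set
#' running weight at each position uses the absolute rank value raised to
#' `alpha`, normalized to 1 over the set; the out-of-set running weight is
#' uniform; the score is the sum over positions of their difference. With
#' `alpha = 0` the score depends on ranks only and is invariant under any
#' strictly monotone transform of the values.
#'
#' @param values Named numeric vector, one observation's expression.
#' @param gene_set Character vector of set genes.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param gene_ids Gene symbols aligned to `values` (defaults to
#'   `names(values)`).
#' @return A single numeric score.
#' @export
ssgsea_score <- function(values, gene_set, alpha = 0.25,
                         gene_ids = names(values)) {
  if (is.null(gene_ids)) stop("gene identifiers are required")
  inset <- gene_ids %in% gene_set
  m <- sum(inset)
  if (m == 0) stop("no gene of the set is present")
  N <- length(values)
  if (m == N) stop("every gene is in the set; the out-of-set ECDF is undefined")
  ord <- order(-values, gene_ids)
  inset <- inset[ord]
  z <- (N - seq_len(N) + 1)^alpha   # rank value: N for the top gene
  w_in <- ifelse(inset, z, 0)
  p_in <- cumsum(w_in) / sum(w_in)
  p_out <- cumsum(!inset) / (N - m)
  sum(p_in - p_out)
}

#' Pseudobulk aggregation of raw counts
#'
#' Per sample and gene, the sum of raw counts over the masked cells (for
#' the paper-style use, the tumor-called cells). Samples with no masked
#' cell are dropped with a warning.
#'
#' @param counts [expression_matrix()], `raw_counts`, over cells.
#' @param sample_of_cell Character vector, sample of each cell.
#' @param cell_mask Logical per cell (default: keep all).
#' @return [expression_matrix()] of raw counts over samples.
#' @export
pseudobulk <- function(counts, sample_of_cell, cell_mask = NULL) {
  assert_mode(counts, "raw_counts", "pseudobulk")
  stopifnot(length(sample_of_cell) == length(counts$obs_ids))
  if (is.null(cell_mask)) cell_mask <- rep(TRUE, length(counts$obs_ids))
  if (!any(cell_mask))
    stop("cell mask excludes every cell; nothing to aggregate")
  all_samples <- unique(sample_of_cell)
  kept <- sample_of_cell[cell_mask]
  dropped <- setdiff(all_samples, unique(kept))
  if (length(dropped))
    warning("samples with zero masked cells dropped: ",
            paste(dropped, collapse = ", "))
  agg <- t(rowsum(t(counts$values[, cell_mask, drop = FALSE]), group = kept))
  ord <- intersect(all_samples, colnames(agg))
  agg <- agg[, ord, drop = FALSE]
  expression_matrix(agg, counts$gene_ids, ord, "raw_counts")
}

#' Iterative ssGSEA refinement of a gene set
#'
#' Repeatedly scores every sample against the current set and removes set
#' genes whose Pearson correlation with the score vector (across samples)
#' falls strictly below `r_min`, until a pass removes nothing, a removal
#' would shrink the set below `min_set_size` (the current set is kept), or
#' `max_iter` passes have run. Correlations are recomputed against the
#' updated scores each pass. Intended for transferring a signature derived
#' in one system (mouse single cells) to another (human bulk cohorts).
#'
#' @param expr [expression_matrix()], `log_normalized`, over samples.
#' @param gene_set Starting gene set.
#' @param r_min Correlation threshold (default 0.5).
#' @param min_set_size Smallest admissible refined set.
#' @param max_iter Maximum refinement passes.
#' @param alpha ssGSEA exponent.
#' @return List: `set` (refined genes), `scores` (per-sample scores on the
#'   final set), `trace` (data.frame per iteration: iteration, n_retained,
#'   n_removed), `gene_correlations` (final-pass correlations).
#' @export
iterative_ssgsea <- function(expr, gene_set, r_min = 0.5,
                             min_set_size = 10, max_iter = 20,
                             alpha = 0.25) {
  assert_mode(expr, "log_normalized", "iterative_ssgsea")
  if (length(expr$obs_ids) < 3) stop("at least 3 samples are required")
  current <- intersect(gene_set, expr$gene_ids)
  if (length(current) < min_set_size)
    stop("only ", length(current), " set genes present; fewer than ",
         "min_set_size = ", min_set_size)
  trace <- list()
  score_set <- function(set) {
    vapply(expr$obs_ids, function(s)
      ssgsea_score(expr$values[, s], set, alpha = alpha,
                   gene_ids = expr$gene_ids), numeric(1))
  }
  scores <- score_set(current)
  rvec <- NULL
  for (it in seq_len(max_iter)) {
    rvec <- vapply(current, function(g) {
      gx <- expr$values[g, ]
      if (sd(gx) == 0 || sd(scores) == 0) return(-Inf)
      cor(gx, scores)
    }, numeric(1))
    drop <- current[rvec < r_min]
    keep <- setdiff(current, drop)
    if (!length(drop)) {
      trace[[it]] <- data.frame(iteration = it,
                                n_retained = length(current), n_removed = 0)
      break
    }
    if (length(keep) < min_set_size) {
      trace[[it]] <- data.frame(iteration = it,
                                n_retained = length(current), n_removed = 0)
      break
    }
    trace[[it]] <- data.frame(iteration = it, n_retained = length(keep),
                              n_removed = length(drop))
    current <- keep
    scores <- score_set(current)
  }
  list(set = current, scores = scores,
       trace = do.call(rbind, trace), gene_correlations = rvec)
}

#' Score a panel of gene sets
#'
#' Applies the chosen scorer to every set of a collection. Sets with no
#' gene in the matrix are skipped and listed in the `skipped` attribute
#' rather than failing the panel.
#'
#' @param expr [expression_matrix()], `log_normalized`.
#' @param collection Named list of gene sets ([read_gmt()] layout).
#' @param method `"module_score"` (per cell, binned controls) or
#'   `"ssgsea"` (per observation, rank-based).
#' @param ... Passed to the scorer ([module_score()] or [ssgsea_score()]).
#' @return data.frame of observations x sets with attributes `skipped` and
#'   `method`.
#' @export
score_panel <- function(expr, collection,
                        method = c("module_score", "ssgsea"), ...) {
  method <- match.arg(method)
  assert_mode(expr, "log_normalized", "score_panel")
  cols <- list(); skipped <- character(0)
  for (nm in names(collection)) {
    res <- tryCatch({
      if (method == "module_score")
        module_score(expr, collection[[nm]], ...)
      else
        vapply(expr$obs_ids, function(s)
          ssgsea_score(expr$values[, s], collection[[nm]],
                       gene_ids = expr$gene_ids, ...), numeric(1))
    }, error = function(e) e)
    if (inherits(res, "error")) skipped <- c(skipped, nm)
    else cols[[nm]] <- res
  }
  out <- as.data.frame(cols, row.names = expr$obs_ids, optional = TRUE)
  attr(out, "skipped") <- skipped
  attr(out, "method") <- method
  out
}
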