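#' Select the two tumor-cell populations compared for the signature
#'
#' Group A: tumor cells from the gain-of-function condition that express
#' Cd83 (raw count > 0) and lack CD45 (raw PTPRC count == 0). Group B:
#' tumor cells from the wild-type condition that express neither Cd83 nor
#' CD45. Positivity is defined on raw counts because it is a detection
#' statement, not a magnitude one.
#'
#' @param counts [expression_matrix()] in `raw_counts` mode.
#' @param tumor_calls Logical per cell, aligned to `counts$obs_ids`.
#' @param condition_labels Character per cell (e.g. `"GOF"`/`"WT"`).
#' @param gof_label,wt_label Labels naming the two conditions.
#' @param cd83_gene,cd45_gene Symbols of Cd83 and CD45 in the matrix.
#' @return List with `groupA` and `groupB` cell-id vectors.
#' @export
select_signature_populations <- function(counts, tumor_calls,
                                         condition_labels,
                                         gof_label = "GOF", wt_label = "WT",
                                         cd83_gene = "Cd83",
                                         cd45_gene = "Ptprc") {
  assert_mode(counts, "raw_counts", "select_signature_populations")
  stopifnot(length(tumor_calls) == length(counts$obs_ids),
            length(condition_labels) == length(counts$obs_ids))
  for (g in c(cd83_gene, cd45_gene))
    if (!g %in% counts$gene_ids)
      stop("gene ", g, " absent from count matrix")
  cd83 <- counts$values[cd83_gene, ]
  cd45 <- counts$values[cd45_gene, ]
  groupA <- counts$obs_ids[tumor_calls & condition_labels == gof_label &
                             cd83 > 0 & cd45 == 0]
  groupB <- counts$obs_ids[tumor_calls & condition_labels == wt_label &
                             cd83 == 0 & cd45 == 0]
  if (!length(groupA))
    stop("empty stratum: no ", gof_label, " tumor cells that are ",
         cd83_gene, "+ / ", cd45_gene, "-")
  if (!length(groupB))
    stop("empty stratum: no ", wt_label, " tumor cells that are ",
         cd83_gene, "- / ", cd45_gene, "-")
  list(groupA = groupA, groupB = groupB)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Mid-ranks for ties. The null distribution is exact (full enumeration)
#' when the smaller group has at most 8 observations and there are no ties;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used. The reported statistic is the rank sum of
#' the first sample.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param mode `"auto"` (default rule above), `"exact"`, or `"normal"`.
#' @return List with `statistic` (rank sum of `a`) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  W <- sum(r[seq_along(a)])
  ties <- anyDuplicated(c(a, b)) > 0
  if (diff(range(c(a, b))) == 0)
    return(list(statistic = W, p = 1))
  exact <- switch(mode,
                  exact = TRUE,
                  normal = FALSE,
                  auto = min(length(a), length(b)) <= 8 && !ties)
  if (exact && ties)
    stop("exact mode is not defined in the presence of ties")
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- ht$p.value
  if (is.na(p)) p <- 1
  list(statistic = W, p = min(p, 1))
}

#' Per-gene differential expression between two cell groups
#'
#' For each gene: log2 fold change of the group means in de-logged
#' (`expm1`) normalized space with a pseudocount, and a Wilcoxon rank-sum
#' p-value (normal approximation with tie-corrected variance and continuity
#' correction, vectorized over genes), Bonferroni-adjusted over all genes
#' tested. Genes with identical values in both groups get p = 1.
#'
#' @param expr [expression_matrix()], `log_normalized`.
#' @param groupA,groupB Cell-id vectors (disjoint).
#' @param pseudocount Added to both group means before the ratio.
#' @return data.frame: gene, logFC, statistic (rank sum of group A), p_raw,
#'   p_adj, direction.
#' @export
differential_expression <- function(expr, groupA, groupB,
                                    pseudocount = 1e-9) {
  assert_mode(expr, "log_normalized", "differential_expression")
  missing <- setdiff(c(groupA, groupB), expr$obs_ids)
  if (length(missing))
    stop("cells absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  xa <- expr$values[, groupA, drop = FALSE]
  xb <- expr$values[, groupB, drop = FALSE]
  ma <- rowMeans(expm1(xa)); mb <- rowMeans(expm1(xb))
  logfc <- log2((ma + pseudocount) / (mb + pseudocount))

  na <- length(groupA); nb <- length(groupB); N <- na + nb
  comb <- cbind(xa, xb)
  W <- numeric(nrow(comb)); p <- numeric(nrow(comb))
  for (i in seq_len(nrow(comb))) {
    r <- rank(comb[i, ])
    W[i] <- sum(r[seq_len(na)])
    tt <- rle(sort.int(comb[i, ], method = "quick"))$lengths
    tiesum <- sum(tt^3 - tt)
    v <- na * nb / 12 * ((N + 1) - tiesum / (N * (N - 1)))
    if (v <= 0) { p[i] <- 1; next }
    muW <- na * (N + 1) / 2
    d <- W[i] - muW
    z <- (d - sign(d) * 0.5) / sqrt(v)
    p[i] <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  data.frame(gene = expr$gene_ids, logFC = unname(logfc),
             statistic = W, p_raw = p,
             p_adj = stats::p.adjust(p, method = "bonferroni"),
             direction = sign(unname(logfc)),
             stringsAsFactors = FALSE)
}

#' Derive the up-regulated gene signature from a DE table
#'
#' Keeps genes with logFC strictly greater than `logfc_min` and adjusted
#' p strictly below `padj_max` — the up-regulated direction only, since the
#' signature characterizes genes enriched in the CD83-positive tumor cells.
#'
#' @param de DE table from [differential_expression()].
#' @param logfc_min Strict lower bound on log2 fold change (default 1).
#' @param padj_max Strict upper bound on adjusted p (default 0.05).
#' @return Character vector of gene symbols, in DE-table order.
#' @export
derive_signature <- function(de, logfc_min = 1, padj_max = 0.05) {
  keep <- de$logFC > logfc_min & de$p_adj < padj_max
  genes <- de$gene[keep]
  if (!length(genes))
    stop("empty signature: no gene passed logFC > ", logfc_min,
         " and adjusted p < ", padj_max)
  genes
}

#' Map mouse gene symbols to human counterparts
#'
#' Uses a supplied two-column ortholog table (`mouse`, `human`) when given,
#' dropping unmapped symbols; otherwise the standard case heuristic
#' (uppercase the mouse symbol). Duplicates after mapping are collapsed,
#' first occurrence kept.
#'
#' @param symbols Mouse gene symbols.
#' @param ortholog_table Optional data.frame with columns `mouse`, `human`.
#' @return Character vector of human symbols with attribute `unmapped`
#'   (symbols dropped by the table).
#' @export
map_mouse_to_human <- function(symbols, ortholog_table = NULL) {
  if (is.null(ortholog_table)) {
    out <- toupper(symbols)
    unmapped <- character(0)
  } else {
    stopifnot(all(c("mouse", "human") %in% names(ortholog_table)))
    idx <- match(symbols, ortholog_table$mouse)
    out <- ortholog_table$human[idx]
    unmapped <- symbols[is.na(idx)]
    out <- out[!is.na(idx)]
  }
  out <- out[!duplicated(out)]
  attr(out, "unmapped") <- unmapped
  out
}
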