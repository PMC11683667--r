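#' Expression matrix container
#'
#' A light container for a genes x observations expression matrix. Rows are
#' gene symbols, columns are cell barcodes or sample identifiers. `mode`
#' records whether the values are raw counts or log-normalized expression,
#' and every downstream operation checks it, so counts can never be scored
#' and normalized values can never be pseudobulked by accident.
#'
#' @param values Numeric matrix, genes in rows, observations in columns.
#' @param gene_ids Character vector of unique gene symbols, one per row.
#' @param obs_ids Character vector of unique observation identifiers, one per
#'   column.
#' @param mode `"raw_counts"` or `"log_normalized"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `obs_ids`, `mode`.
#' @export
expression_matrix <- function(values, gene_ids, obs_ids,
                              mode = c("raw_counts", "log_normalized")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (nrow(values) != length(gene_ids))
    stop("gene_ids length (", length(gene_ids),
         ") does not match number of rows (", nrow(values), ")")
  if (ncol(values) != length(obs_ids))
    stop("obs_ids length (", length(obs_ids),
         ") does not match number of columns (", ncol(values), ")")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids are not allowed")
  if (anyDuplicated(obs_ids))
    stop("duplicate obs_ids are not allowed")
  if (mode == "raw_counts") {
    if (any(!is.finite(values)) || any(values < 0))
      stop("raw_counts values must be finite and >= 0")
  }
  dimnames(values) <- list(gene_ids, obs_ids)
  structure(list(values = values,
                 gene_ids = as.character(gene_ids),
                 obs_ids = as.character(obs_ids),
                 mode = mode),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", length(x$gene_ids), "genes x",
      length(x$obs_ids), "observations [", x$mode, "]\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

is_expression_matrix <- function(x) inherits(x, "ExpressionMatrix")

assert_mode <- function(x, mode, what) {
  if (!is_expression_matrix(x))
    stop(what, " requires an ExpressionMatrix")
  if (x$mode != mode)
    stop(what, " requires mode '", mode, "', got '", x$mode, "'")
  invisible(x)
}
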