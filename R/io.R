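#' Read a sparse count matrix in 10x-style triplet form
#'
#' Reads a Matrix-Market coordinate file together with one-identifier-per-line
#' (or TSV, identifier in the first column) gene and barcode files, in the
#' layout CellRanger emits. Label files must agree with the matrix header;
#' a mismatch is an error naming the offending file. Duplicate gene symbols
#' are de-duplicated by suffixing an ordinal (`make.unique`).
#'
#' @param path_matrix Path to the `.mtx` coordinate file.
#' @param path_genes Path to the gene/feature file (one symbol per line, or
#'   TSV with the symbol in column 1).
#' @param path_obs Path to the barcode/sample file, same conventions.
#' @return An [expression_matrix()] in `raw_counts` mode, labels in file order.
#' @export
read_counts <- function(path_matrix, path_genes, path_obs) {
  m <- Matrix::readMM(path_matrix)
  genes <- read_id_column(path_genes)
  obs <- read_id_column(path_obs)
  if (nrow(m) != length(genes))
    stop("format error in '", path_genes, "': ", length(genes),
         " identifiers for a matrix with ", nrow(m), " rows")
  if (ncol(m) != length(obs))
    stop("format error in '", path_obs, "': ", length(obs),
         " identifiers for a matrix with ", ncol(m), " columns")
  genes <- make.unique(genes, sep = ".")
  expression_matrix(as.matrix(m), genes, obs, mode = "raw_counts")
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a count matrix in 10x-style triplet form
#'
#' Inverse of [read_counts()]: writes `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv` under `dir`.
#'
#' @param x An `ExpressionMatrix` in `raw_counts` mode.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three paths written.
#' @export
write_counts <- function(x, dir) {
  assert_mode(x, "raw_counts", "write_counts")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(x$values, sparse = TRUE),
                              "generalMatrix"), paths[1])
  writeLines(x$gene_ids, paths[2])
  writeLines(x$obs_ids, paths[3])
  invisible(paths)
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are dropped, first occurrence kept; file order of sets
#' is preserved. Lines with fewer than three fields are a format error
#' reported with the line number.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (class `GeneSetCollection`),
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("format error in '", path, "' line ", i,
           ": expected at least 3 tab-separated fields")
    nm <- fields[1]
    sets[[nm]] <- unique(fields[-(1:2)])
    descs[nm] <- fields[2]
  }
  structure(sets, descriptions = descs, class = "GeneSetCollection")
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors (optionally with a
#'   `descriptions` attribute, as returned by [read_gmt()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    nm <- names(sets)[i]
    d <- if (!is.null(descs) && !is.na(descs[nm])) descs[[nm]] else "na"
    paste(c(nm, d, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-cell variant-call table
#'
#' TSV with columns `cell_id`, `gene`, `variant_id`, `protein_change`,
#' `in_cosmic` (0/1) and `dbsnp_freq` (fraction, or NA when the variant is
#' absent from dbSNP; an unobserved frequency passes the downstream rarity
#' filter). Filtering happens in [snv_evidence()], not here.
#'
#' @param path Path to the TSV.
#' @return A typed `data.frame`, one row per variant call.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("cell_id", "gene", "variant_id", "protein_change",
                "in_cosmic", "dbsnp_freq")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("format error in '", path, "': missing required column(s) ",
         paste(missing, collapse = ", "))
  tab$in_cosmic <- as.integer(tab$in_cosmic)
  tab$dbsnp_freq <- as.numeric(tab$dbsnp_freq)
  bad <- !is.na(tab$dbsnp_freq) & (tab$dbsnp_freq < 0 | tab$dbsnp_freq > 1)
  if (any(bad))
    stop("format error in '", path, "': dbsnp_freq outside [0,1]")
  tab[required]
}

#' @rdname read_variant_table
#' @param tab Variant table to write.
#' @export
write_variant_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-chromosome-arm table
#'
#' TSV with columns `gene`, `chrom`, `arm`. Row order defines the positional
#' order of genes along each arm, as in a coordinate-sorted BED-like file.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `gene`, `chrom`, `arm`.
#' @export
read_gene_arm_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", "chrom", "arm"), names(tab))
  if (length(missing))
    stop("format error in '", path, "': missing required column(s) ",
         paste(missing, collapse = ", "))
  tab
}

#' Read a survival table
#'
#' TSV with columns `sample_id`, `time`, `event` (0/1).
#'
#' @param path Path to the TSV.
#' @return A typed `data.frame`.
#' @export
read_survival_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "time", "event"), names(tab))
  if (length(missing))
    stop("format error in '", path, "': missing required column(s) ",
         paste(missing, collapse = ", "))
  tab$time <- as.numeric(tab$time)
  tab$event <- as.integer(tab$event)
  if (any(tab$time < 0, na.rm = TRUE))
    stop("format error in '", path, "': negative survival times")
  tab
}

#' Run configuration
#'
#' Flat key/value configuration serialized as JSON. One global `seed` is the
#' only source of randomness; each pipeline stage derives its own substream
#' with [derive_seed()].
#'
#' @param path Path to a JSON config file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop("config error: 'seed' is required")
  cfg
}

#' @rdname read_run_config
#' @param config Named list to serialize.
#' @export
write_run_config <- function(config, path) {
  # I(17) = 17 significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Derive a stage-specific seed from the global seed
#'
#' Deterministic, stage-name-keyed substream derivation so that adding or
#' reordering stages never perturbs another stage's random numbers. Result
#' is kept in the 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 7919) %% 2147483647L)
}
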