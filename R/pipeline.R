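#' Default demo configuration for the end-to-end pipeline
#'
#' A self-contained run on simulated data: a mouse-style GOF/WT single-cell
#' cohort (4 samples x 500 cells, 1,500 genes) for annotation and signature
#' derivation, and a 50-sample bulk cohort for refinement, correlation and
#' survival. Every size and threshold can be overridden through the
#' config list.
#'
#' @param out_dir Output directory for all stage files.
#' @param seed Global seed; each stage derives its own substream.
#' @return A named list usable by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = tempfile("altsig_run_"),
                                    seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    n_samples = 4, cells_per_sample = 500, n_genes = 1500,
    species = "mouse",
    qc = list(min_cells_per_gene = 3, min_genes_per_cell = 100,
              gene_count_range = c(50, 5000), max_mito_percent = 20),
    tau = 0.5,
    cnv = list(smoothing_window = 11, arm_zshift_threshold = 3,
               min_genes_per_arm = 10),
    signature = list(logfc_min = 1, padj_max = 0.05),
    bulk = list(n_samples = 50, n_genes = 1000),
    refine = list(r_min = 0.5, min_set_size = 10, max_iter = 20,
                  alpha = 0.25),
    survival = list(baseline_hazard = 0.02, log_hr_per_sd = -log(2),
                    censoring_horizon = 120)
  )
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on one configuration
#'
#' Executes simulate, qc, annotate, signature, score, refine, correlate and
#' survive in dependency order, with every stage reading and writing files
#' under `config$out_dir` (so any stage's inputs can be replaced by an
#' external tool's output). Seeds are derived per stage from the global
#' seed, making a rerun with the same config byte-identical for every
#' output except the manifest timestamp.
#'
#' The demo cohort is mouse-style: annotation uses the marker-mixture OR
#' CNV OR SNV rule on the simulated markers, the signature is derived from
#' the GOF-vs-WT Cd83+/CD45- comparison, mapped to human-style symbols, and
#' refined/stratified on the simulated bulk cohort.
#'
#' @param config A config list (see [default_pipeline_config()]) or a path
#'   to a JSON file readable by [read_run_config()].
#' @return The pipeline manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("altsig")),
                   stages = list())
  t_all <- Sys.time()
  log_path <- file.path(out, "pipeline.log")
  logit <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                             "\n", file = log_path, append = TRUE)
  stage <- function(name, n_records, files) {
    logit("stage", name, "records:", n_records)
    manifest$stages[[name]] <<- list(n_records = n_records, files = files)
  }

  # -- simulate -------------------------------------------------------------
  sc_spec <- sim_cohort_spec(
    n_samples = config$n_samples,
    cells_per_sample = config$cells_per_sample,
    n_genes = config$n_genes, species = config$species,
    seed = derive_seed(config$seed, "simulate_sc"))
  sim <- simulate_sc_cohort(sc_spec)
  sc_dir <- file.path(out, "sc")
  paths <- write_counts(sim$counts, sc_dir)
  f_truth <- write_tsv(sim$truth, file.path(out, "truth.tsv"))
  f_var <- write_variant_table(sim$variants, file.path(out, "variants.tsv"))
  f_arms <- write_tsv(sim$gene_arms, file.path(out, "gene_arms.tsv"))
  stage("simulate", ncol(sim$counts$values),
        c(paths, f_truth, f_var, f_arms))

  # -- qc -------------------------------------------------------------------
  counts <- read_counts(file.path(sc_dir, "matrix.mtx"),
                        file.path(sc_dir, "genes.tsv"),
                        file.path(sc_dir, "barcodes.tsv"))
  thr <- qc_thresholds(min_cells_per_gene = config$qc$min_cells_per_gene,
                       min_genes_per_cell = config$qc$min_genes_per_cell,
                       gene_count_range = config$qc$gene_count_range,
                       max_mito_percent = config$qc$max_mito_percent,
                       species = config$species)
  qc <- apply_qc(counts, thr, mito_genes = sim$mito_genes)
  f_qc <- write_tsv(data.frame(metric = names(unclass(qc$report)),
                               value = unlist(unclass(qc$report))),
                    file.path(out, "qc_report.tsv"))
  norm <- lognormalize(qc$counts)
  stage("qc", ncol(qc$counts$values), f_qc)

  # -- annotate -------------------------------------------------------------
  truth <- sim$truth[match(qc$counts$obs_ids, sim$truth$cell_id), ]
  models <- lapply(sim$markers, function(m)
    fit_em_gmm(norm$values[m, ], marker = m, tau = config$tau))
  names(models) <- sim$markers
  ind <- marker_indicator_matrix(models, norm)
  cd45_gene <- if (config$species == "mouse") "Ptprc" else "PTPRC"
  cd45_pos <- qc$counts$values[cd45_gene, ] > 0
  cnv <- cnv_evidence(norm, sim$gene_arms,
                      reference_cells = qc$counts$obs_ids[cd45_pos],
                      smoothing_window = config$cnv$smoothing_window,
                      arm_zshift_threshold = config$cnv$arm_zshift_threshold,
                      min_genes_per_arm = config$cnv$min_genes_per_arm)
  snv <- snv_evidence(sim$variants, cells = qc$counts$obs_ids)
  call <- call_tumor_cells(ind, cnv$cnv_flag, snv)
  ann <- data.frame(cell_id = qc$counts$obs_ids,
                    t(ind),
                    cnv_flag = unname(cnv$cnv_flag),
                    snv_flag = unname(snv),
                    cd45_positive = unname(cd45_pos),
                    tumor_call = call, stringsAsFactors = FALSE)
  f_ann <- write_tsv(ann, file.path(out, "annotation.tsv"))
  stage("annotate", sum(call), f_ann)

  # -- signature ------------------------------------------------------------
  cd83_gene <- if (config$species == "mouse") "Cd83" else "CD83"
  pops <- select_signature_populations(
    qc$counts, tumor_calls = call,
    condition_labels = truth$condition,
    cd83_gene = cd83_gene, cd45_gene = cd45_gene)
  de <- differential_expression(norm, pops$groupA, pops$groupB)
  sig <- derive_signature(de, logfc_min = config$signature$logfc_min,
                          padj_max = config$signature$padj_max)
  f_de <- write_tsv(de, file.path(out, "de_table.tsv"))
  sig_hs <- map_mouse_to_human(sig)
  f_gmt <- write_gmt(list(CD83_signature = as.character(sig_hs)),
                     file.path(out, "signature.gmt"))
  stage("signature", length(sig), c(f_de, f_gmt))

  # -- score (single-cell module scores + pseudobulk) -----------------------
  mod_scores <- module_score(norm, sig,
                             seed = derive_seed(config$seed, "module_score"))
  f_ms <- write_tsv(data.frame(cell_id = names(mod_scores),
                               cd83_module_score = unname(mod_scores)),
                    file.path(out, "module_scores.tsv"))
  pb <- pseudobulk(qc$counts, truth$sample_id, cell_mask = call)
  f_pb <- write_tsv(data.frame(gene = pb$gene_ids, pb$values,
                               check.names = FALSE),
                    file.path(out, "pseudobulk_counts.tsv"))
  stage("score", length(mod_scores), c(f_ms, f_pb))

  # -- bulk cohort, refine --------------------------------------------------
  bulk_spec <- sim_bulk_spec(n_samples = config$bulk$n_samples,
                             n_genes = config$bulk$n_genes,
                             n_program_genes = length(sig_hs),
                             seed = derive_seed(config$seed, "simulate_bulk"))
  bulk <- simulate_bulk_cohort(bulk_spec)
  # carry the signature into the bulk gene space: the simulator's program
  # genes stand in for the mapped signature symbols
  sig_bulk <- bulk$sets$CD83_program
  bnorm <- normalize_bulk(bulk$counts)
  ref <- iterative_ssgsea(bnorm, sig_bulk,
                          r_min = config$refine$r_min,
                          min_set_size = config$refine$min_set_size,
                          max_iter = config$refine$max_iter,
                          alpha = config$refine$alpha)
  f_ref <- write_tsv(ref$trace, file.path(out, "refinement_trace.tsv"))
  f_rs <- write_tsv(data.frame(sample_id = names(ref$scores),
                               cd83_score = unname(ref$scores)),
                    file.path(out, "refined_scores.tsv"))
  stage("refine", length(ref$set), c(f_ref, f_rs))

  # -- correlate ------------------------------------------------------------
  immune <- bulk$sets[names(bulk$sets) != "CD83_program"]
  panel <- score_panel(bnorm, immune, method = "ssgsea",
                       alpha = config$refine$alpha)
  corr <- correlation_panel(ref$scores[rownames(panel)], panel)
  f_corr <- write_tsv(corr, file.path(out, "correlations.tsv"))
  stage("correlate", nrow(corr), f_corr)

  # -- survive --------------------------------------------------------------
  surv <- simulate_survival(ref$scores,
                            baseline_hazard = config$survival$baseline_hazard,
                            log_hr_per_sd = config$survival$log_hr_per_sd,
                            censoring_horizon = config$survival$censoring_horizon,
                            seed = derive_seed(config$seed, "survival"))
  strata <- quartile_stratify(ref$scores)
  surv$stratum <- as.character(strata[surv$sample_id])
  keep <- surv$stratum %in% c("high", "low")
  lr <- logrank_test(surv$time[keep], surv$event[keep], surv$stratum[keep])
  km_rows <- do.call(rbind, lapply(c("high", "low"), function(g) {
    km <- km_estimate(surv$time[surv$stratum == g],
                      surv$event[surv$stratum == g])
    data.frame(stratum = g, time = km$time, n_risk = km$n_risk,
               surv = km$surv, stringsAsFactors = FALSE)
  }))
  f_surv <- write_tsv(surv, file.path(out, "survival_table.tsv"))
  f_km <- write_tsv(km_rows, file.path(out, "km_curves.tsv"))
  f_lr <- write_tsv(data.frame(chi_square = lr$chi_square, df = lr$df,
                               p = lr$p),
                    file.path(out, "logrank.tsv"))
  stage("survive", sum(keep), c(f_surv, f_km, f_lr))

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t_all,
                                              units = "secs"))
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
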