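#' @importFrom stats rnbinom rnorm runif rexp quantile sd cor setNames
NULL

# Run code under a temporary RNG state so generators are reproducible given
# (spec, seed) without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic single-cell cohort
#'
#' Parameters of the generative model behind [simulate_sc_cohort()]: a
#' mixed tumor / immune / normal cohort with negative-binomial counts
#' (log-link), elevated tumor-marker expression in tumor cells, arm-level
#' copy-number shifts, rare driver variants captured in a fraction of tumor
#' cells, a mitochondrial-gene count fraction, and (in mouse mode) a
#' gain-of-function (GOF) vs wild-type (WT) condition that plants a
#' Cd83-centered expression program in GOF tumor cells plus a GFP pseudo-gene
#' restricted to the electroporated tumor lineage.
#'
#' Marker means are on the natural-log scale of the negative-binomial mean.
#' Copy-number and program effects are log2 fold changes, matching how such
#' effects are usually reported.
#'
#' @param n_samples Number of samples (patients/mice).
#' @param cells_per_sample Cells simulated per sample.
#' @param fraction_tumor,fraction_immune Cell-type fractions; the remainder
#'   are non-malignant "normal" cells.
#' @param n_genes Total genes including markers, mito and arm genes.
#' @param species `"human"` or `"mouse"`; controls symbol casing, the GFP
#'   pseudo-gene, and whether samples carry GOF/WT condition labels.
#' @param marker_params Named list (one entry per marker) of
#'   `list(normal_mean, tumor_mean, sd)` on the log scale.
#' @param cnv_arms Named numeric: log2 shift applied to each arm's genes in
#'   tumor cells (e.g. `c("7p" = 1, "10q" = -1)`, the classic glioma +7/-10).
#' @param genes_per_arm Genes placed on each simulated arm.
#' @param snv_params List: `capture_rate` (probability a tumor cell yields a
#'   driver variant record), `benign_rate` (probability any cell yields a
#'   common, non-pathogenic record).
#' @param mito_fraction_params List: `mean_normal`, `mean_stressed`,
#'   `stressed_fraction` — expected mitochondrial count fraction for typical
#'   and stressed cells.
#' @param program_params List: `n_genes` in the planted program,
#'   `log2fc` applied to program genes in carrier cells, `cd83_log2fc`
#'   applied to Cd83 itself (the paper-scale effect), `cd83_baseline_mu`.
#' @param dispersion Negative-binomial dispersion (1/size); > 0 gives
#'   variance mu + dispersion * mu^2, i.e. super-Poisson.
#' @param gof_fraction Fraction of samples assigned the GOF condition
#'   (mouse mode; human samples are all labelled WT).
#' @param seed Integer seed; all outputs are reproducible given the spec.
#' @return A list of class `SimCohortSpec`.
#' @export
sim_cohort_spec <- function(n_samples = 4,
                            cells_per_sample = 500,
                            fraction_tumor = 0.5,
                            fraction_immune = 0.25,
                            n_genes = 1500,
                            species = c("human", "mouse"),
                            marker_params = NULL,
                            cnv_arms = c("7p" = 1, "10q" = -1),
                            genes_per_arm = 80,
                            snv_params = list(capture_rate = 0.1,
                                              benign_rate = 0.03),
                            mito_fraction_params = list(mean_normal = 0.05,
                                                        mean_stressed = 0.3,
                                                        stressed_fraction = 0.03),
                            program_params = list(n_genes = 40,
                                                  log2fc = 2,
                                                  cd83_log2fc = 3,
                                                  cd83_baseline_mu = 0.2),
                            dispersion = 0.5,
                            gof_fraction = 0.5,
                            seed = 1) {
  species <- match.arg(species)
  if (fraction_tumor < 0 || fraction_immune < 0 ||
      fraction_tumor > 1 || fraction_immune > 1 ||
      fraction_tumor + fraction_immune > 1)
    stop("parameter error: cell-type fractions must lie in [0,1] and sum to <= 1")
  if (dispersion < 0) stop("parameter error: dispersion must be >= 0")
  if (!is.null(snv_params$capture_rate) &&
      (snv_params$capture_rate < 0 || snv_params$capture_rate > 1))
    stop("parameter error: capture_rate must be in [0,1]")
  if (is.null(marker_params)) {
    mk <- if (species == "human") c("SOX2", "EGFR", "PDGFRA")
          else c("Sox2", "Egfr", "Pdgfra")
    marker_params <- setNames(rep(list(
      list(normal_mean = -4, tumor_mean = 1, sd = 0.4)), 3), mk)
  }
  if (any(vapply(marker_params, function(p) p$sd <= 0, logical(1))))
    stop("parameter error: marker sd must be > 0")
  structure(list(n_samples = n_samples, cells_per_sample = cells_per_sample,
                 fraction_tumor = fraction_tumor,
                 fraction_immune = fraction_immune,
                 n_genes = n_genes, species = species,
                 marker_params = marker_params, cnv_arms = cnv_arms,
                 genes_per_arm = genes_per_arm, snv_params = snv_params,
                 mito_fraction_params = mito_fraction_params,
                 program_params = program_params, dispersion = dispersion,
                 gof_fraction = gof_fraction, seed = seed),
            class = "SimCohortSpec")
}

sim_symbols <- function(spec) {
  human <- spec$species == "human"
  list(
    markers = names(spec$marker_params),
    cd45 = if (human) "PTPRC" else "Ptprc",
    cd83 = if (human) "CD83" else "Cd83",
    mito_prefix = if (human) "MT-" else "mt-",
    gfp = "GFP",
    program = sprintf(if (human) "PROG%03d" else "Prog%03d",
                      seq_len(spec$program_params$n_genes))
  )
}

#' Simulate a single-cell cohort with known truth
#'
#' Draws a genes x cells count matrix from a negative-binomial model whose
#' log-mean is a per-gene baseline plus marker / program / copy-number
#' effects determined by each cell's ground-truth labels, together with the
#' companion files every downstream stage consumes: per-cell truth, a
#' per-cell variant-call table, and a gene-to-arm coordinate table.
#'
#' Immune cells have nonzero CD45 (PTPRC) counts by construction; tumor
#' cells carry the configured marker elevation, arm shifts, and driver
#' variants at `capture_rate`; mouse-mode GOF tumor cells carry the planted
#' Cd83 program and only tumor-lineage cells express the GFP pseudo-gene.
#'
#' @param spec A [sim_cohort_spec()].
#' @return List with elements `counts` ([expression_matrix()], raw counts),
#'   `truth` (data.frame: cell_id, sample_id, type, condition,
#'   carries_program, arms), `variants` (variant table), `gene_arms`
#'   (gene/chrom/arm table), `mito_genes`, `markers`.
#' @export
simulate_sc_cohort <- function(spec) {
  stopifnot(inherits(spec, "SimCohortSpec"))
  with_seed(spec$seed, simulate_sc_cohort_impl(spec))
}

simulate_sc_cohort_impl <- function(spec) {
  sym <- sim_symbols(spec)
  n_cells <- spec$n_samples * spec$cells_per_sample
  n_mito <- 13L
  arm_names <- names(spec$cnv_arms)
  n_arm_genes <- length(arm_names) * spec$genes_per_arm
  special <- c(sym$markers, sym$cd45, sym$cd83, sym$program)
  n_named <- length(special) + n_mito + n_arm_genes +
    (spec$species == "mouse")
  if (spec$n_genes <= n_named)
    stop("parameter error: n_genes too small for the configured named genes")
  n_filler <- spec$n_genes - n_named

  mito_genes <- paste0(sym$mito_prefix, sprintf("RNR%02d", seq_len(n_mito)))
  arm_genes <- lapply(arm_names, function(a)
    sprintf("A%s.%03d", gsub("[^0-9A-Za-z]", "", a), seq_len(spec$genes_per_arm)))
  names(arm_genes) <- arm_names
  filler <- sprintf(if (spec$species == "human") "GENE%04d" else "Gene%04d",
                    seq_len(n_filler))
  genes <- c(special, mito_genes, unlist(arm_genes, use.names = FALSE), filler)
  if (spec$species == "mouse") genes <- c(genes, sym$gfp)

  gene_arms <- data.frame(
    gene = unlist(arm_genes, use.names = FALSE),
    chrom = rep(sub("[pq]$", "", arm_names), each = spec$genes_per_arm),
    arm = rep(arm_names, each = spec$genes_per_arm),
    stringsAsFactors = FALSE)

  # -- truth labels ---------------------------------------------------------
  samples <- sprintf("S%02d", seq_len(spec$n_samples))
  n_gof <- if (spec$species == "mouse")
    round(spec$gof_fraction * spec$n_samples) else 0L
  condition <- setNames(rep("WT", spec$n_samples), samples)
  if (n_gof > 0) condition[seq_len(n_gof)] <- "GOF"

  if (n_cells == 0) {
    truth <- data.frame(cell_id = character(0), sample_id = character(0),
                        type = character(0), condition = character(0),
                        carries_program = logical(0), arms = character(0),
                        stringsAsFactors = FALSE)
    counts <- expression_matrix(
      matrix(0, length(genes), 0), genes, character(0), "raw_counts")
    variants <- empty_variant_table()
    return(list(counts = counts, truth = truth, variants = variants,
                gene_arms = gene_arms, mito_genes = mito_genes,
                markers = sym$markers))
  }

  sample_of_cell <- rep(samples, each = spec$cells_per_sample)
  cell_id <- sprintf("%s_c%04d", sample_of_cell,
                     unlist(lapply(seq_len(spec$n_samples),
                                   function(i) seq_len(spec$cells_per_sample))))
  n_tum <- round(spec$fraction_tumor * spec$cells_per_sample)
  n_imm <- round(spec$fraction_immune * spec$cells_per_sample)
  type_one <- c(rep("tumor", n_tum), rep("immune", n_imm),
                rep("normal", spec$cells_per_sample - n_tum - n_imm))
  type <- unlist(lapply(seq_len(spec$n_samples),
                        function(i) sample(type_one)))
  cond_of_cell <- condition[sample_of_cell]
  carries <- type == "tumor" & cond_of_cell == "GOF"
  is_tum <- type == "tumor"
  is_imm <- type == "immune"

  truth <- data.frame(cell_id = cell_id, sample_id = sample_of_cell,
                      type = type, condition = unname(cond_of_cell),
                      carries_program = carries,
                      arms = ifelse(is_tum,
                                    paste(arm_names, collapse = ";"), ""),
                      stringsAsFactors = FALSE)

  # -- negative-binomial means ---------------------------------------------
  mu <- matrix(0, length(genes), n_cells, dimnames = list(genes, NULL))
  base_filler <- exp(runif(n_filler, log(0.02), log(1)))
  mu[filler, ] <- base_filler
  for (a in arm_names) {
    base_a <- exp(runif(spec$genes_per_arm, log(0.5), log(3)))
    mu[arm_genes[[a]], ] <- base_a
    mu[arm_genes[[a]], is_tum] <-
      base_a * 2^spec$cnv_arms[[a]]
  }
  base_prog <- exp(runif(length(sym$program), log(0.2), log(2)))
  mu[sym$program, ] <- base_prog
  if (any(carries))
    mu[sym$program, carries] <- base_prog * 2^spec$program_params$log2fc

  pp <- spec$program_params
  mu[sym$cd83, ] <- pp$cd83_baseline_mu
  if (any(carries))
    mu[sym$cd83, carries] <- pp$cd83_baseline_mu * 2^pp$cd83_log2fc

  for (m in names(spec$marker_params)) {
    p <- spec$marker_params[[m]]
    lm <- ifelse(is_tum, p$tumor_mean, p$normal_mean)
    mu[m, ] <- exp(lm + rnorm(n_cells, 0, p$sd))
  }
  mu[sym$cd45, ] <- ifelse(is_imm, 3, 0)
  if (spec$species == "mouse") mu[sym$gfp, ] <- ifelse(is_tum, 2, 0)

  mp <- spec$mito_fraction_params
  other_tot <- mean(colSums(mu))
  frac <- rep(mp$mean_normal, n_cells)
  stressed <- runif(n_cells) < mp$stressed_fraction
  frac[stressed] <- mp$mean_stressed
  mu[mito_genes, ] <- matrix(rep(other_tot * frac / (1 - frac) / n_mito,
                                 each = n_mito), n_mito, n_cells)

  size <- if (spec$dispersion > 0) 1 / spec$dispersion else Inf
  counts_vals <- if (is.finite(size)) {
    matrix(rnbinom(length(mu), mu = mu, size = size), nrow(mu), ncol(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
  }
  rownames(counts_vals) <- genes
  counts_vals[sym$cd45, is_imm] <- pmax(counts_vals[sym$cd45, is_imm], 1)

  counts <- expression_matrix(counts_vals, genes, cell_id, "raw_counts")

  variants <- simulate_variants(spec, cell_id, is_tum)

  list(counts = counts, truth = truth, variants = variants,
       gene_arms = gene_arms, mito_genes = mito_genes, markers = sym$markers)
}

empty_variant_table <- function() {
  data.frame(cell_id = character(0), gene = character(0),
             variant_id = character(0), protein_change = character(0),
             in_cosmic = integer(0), dbsnp_freq = numeric(0),
             stringsAsFactors = FALSE)
}

simulate_variants <- function(spec, cell_id, is_tum) {
  sp <- spec$snv_params
  drivers <- data.frame(
    gene = c("IDH1", "IDH1", "EGFR"),
    variant_id = c("v_IDH1_R132H", "v_IDH1_R132C", "v_EGFR_A289V"),
    protein_change = c("R132H", "R132C", "A289V"),
    stringsAsFactors = FALSE)
  out <- list(empty_variant_table())
  cap <- if (is.null(sp$capture_rate)) 0 else sp$capture_rate
  hit <- is_tum & runif(length(cell_id)) < cap
  if (any(hit)) {
    idx <- sample(nrow(drivers), sum(hit), replace = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      cell_id = cell_id[hit], gene = drivers$gene[idx],
      variant_id = drivers$variant_id[idx],
      protein_change = drivers$protein_change[idx],
      in_cosmic = 1L, dbsnp_freq = 0, stringsAsFactors = FALSE)
  }
  ben <- if (is.null(sp$benign_rate)) 0 else sp$benign_rate
  bhit <- runif(length(cell_id)) < ben
  if (any(bhit)) {
    # common polymorphism: in dbSNP at 5%, not a driver
    out[[length(out) + 1L]] <- data.frame(
      cell_id = cell_id[bhit], gene = "TP53",
      variant_id = "v_TP53_common", protein_change = "P72R",
      in_cosmic = 1L, dbsnp_freq = 0.05, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Specification of a synthetic bulk cohort
#'
#' Parameters for [simulate_bulk_cohort()] and [simulate_gene_sets()]: a
#' genes x samples negative-binomial count matrix in which a latent
#' per-sample factor (the activity of the planted CD83-like program) drives
#' the program genes and, with configurable sign and magnitude, the member
#' genes of each planted immune-like gene set.
#'
#' @param n_samples Number of bulk samples.
#' @param n_genes Total gene count (program + immune-set + background genes).
#' @param n_program_genes Size of the planted program set.
#' @param program_coupling Log-units of expression per SD of the latent
#'   factor for program genes.
#' @param immune_couplings Named numeric; per planted immune set, signed
#'   log-units per SD of the latent factor (0 = uncoupled).
#' @param immune_set_size Genes per immune set.
#' @param dispersion NB dispersion (bulk libraries are deep, so small).
#' @param lib_sd SD of the log-normal per-sample library-size multiplier.
#' @param seed Integer seed.
#' @return A list of class `SimBulkSpec`.
#' @export
sim_bulk_spec <- function(n_samples = 50, n_genes = 1000,
                          n_program_genes = 40,
                          program_coupling = 1,
                          immune_couplings = c(immune_up = 1,
                                               immune_down = -1,
                                               immune_up_weak = 0.5,
                                               immune_down_weak = -0.5,
                                               immune_null = 0),
                          immune_set_size = 25,
                          dispersion = 0.1, lib_sd = 0.3, seed = 1) {
  if (length(immune_couplings) < 1)
    stop("parameter error: at least one immune set is required")
  if (dispersion < 0 || lib_sd < 0)
    stop("parameter error: dispersion and lib_sd must be >= 0")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_program_genes = n_program_genes,
                 program_coupling = program_coupling,
                 immune_couplings = immune_couplings,
                 immune_set_size = immune_set_size,
                 dispersion = dispersion, lib_sd = lib_sd, seed = seed),
            class = "SimBulkSpec")
}

bulk_gene_names <- function(spec) {
  prog <- sprintf("PROG%03d", seq_len(spec$n_program_genes))
  sets <- lapply(seq_along(spec$immune_couplings), function(k)
    sprintf("IS%d.G%02d", k, seq_len(spec$immune_set_size)))
  names(sets) <- names(spec$immune_couplings)
  n_used <- length(prog) + length(sets) * spec$immune_set_size
  if (spec$n_genes <= n_used)
    stop("parameter error: n_genes too small for the configured sets")
  bg <- sprintf("BG%04d", seq_len(spec$n_genes - n_used))
  list(program = prog, immune = sets, background = bg)
}

#' Planted gene-set collection for a synthetic bulk cohort
#'
#' Returns the planted program set verbatim plus the immune-like sets whose
#' member genes [simulate_bulk_cohort()] couples to the same latent sample
#' factor that drives the program. Deterministic given the spec.
#'
#' @param spec A [sim_bulk_spec()].
#' @return A named list of gene-symbol vectors (class `GeneSetCollection`).
#' @export
simulate_gene_sets <- function(spec) {
  stopifnot(inherits(spec, "SimBulkSpec"))
  nm <- bulk_gene_names(spec)
  sets <- c(list(CD83_program = nm$program), nm$immune)
  structure(sets,
            descriptions = setNames(
              c("planted program",
                sprintf("planted immune set, coupling %g",
                        spec$immune_couplings)),
              names(sets)),
            class = "GeneSetCollection")
}

#' Simulate a bulk expression cohort with a planted program
#'
#' @param spec A [sim_bulk_spec()].
#' @return List with `counts` (raw [expression_matrix()], genes x samples),
#'   `latent` (per-sample factor, named), `sets` (the
#'   [simulate_gene_sets()] collection), `couplings` (per-gene coupling),
#'   `lib_factors` (true library-size multipliers).
#' @export
simulate_bulk_cohort <- function(spec) {
  stopifnot(inherits(spec, "SimBulkSpec"))
  with_seed(spec$seed, {
    nm <- bulk_gene_names(spec)
    genes <- c(nm$program, unlist(nm$immune, use.names = FALSE),
               nm$background)
    coup <- setNames(numeric(length(genes)), genes)
    coup[nm$program] <- spec$program_coupling
    for (k in names(nm$immune))
      coup[nm$immune[[k]]] <- spec$immune_couplings[[k]]

    samples <- sprintf("B%03d", seq_len(spec$n_samples))
    latent <- setNames(rnorm(spec$n_samples), samples)
    lib <- exp(rnorm(spec$n_samples, 0, spec$lib_sd))
    base <- exp(runif(length(genes), log(20), log(200)))
    mu <- (base * exp(outer(coup, latent))) %*% diag(lib)
    size <- if (spec$dispersion > 0) 1 / spec$dispersion else Inf
    vals <- if (is.finite(size))
      matrix(rnbinom(length(mu), mu = mu, size = size), nrow(mu), ncol(mu))
    else matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    counts <- expression_matrix(vals, genes, samples, "raw_counts")
    list(counts = counts, latent = latent, sets = simulate_gene_sets(spec),
         couplings = coup, lib_factors = setNames(lib, samples))
  })
}

#' Simulate survival times driven by a per-sample score
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hr_per_sd * z)` where `z` is the standardized
#' score; censoring is uniform on `(0, censoring_horizon]`; the observed time
#' is the earlier of the two and `event = 1` iff failure precedes censoring.
#'
#' @param sample_scores Named numeric, one score per sample.
#' @param baseline_hazard Baseline hazard (events per time unit), > 0.
#' @param log_hr_per_sd Log hazard ratio per SD of the score. The default
#'   `-log(2)` makes a high score protective (halved hazard per SD), the
#'   direction reported for the CD83 program.
#' @param censoring_horizon Upper bound of the uniform censoring time, > 0.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(sample_scores, baseline_hazard = 0.02,
                              log_hr_per_sd = -log(2),
                              censoring_horizon = 120, seed = 1) {
  if (baseline_hazard <= 0)
    stop("parameter error: baseline_hazard must be > 0")
  if (censoring_horizon <= 0)
    stop("parameter error: censoring_horizon must be > 0")
  n <- length(sample_scores)
  ids <- names(sample_scores)
  if (is.null(ids)) ids <- sprintf("B%03d", seq_len(n))
  s <- sd(sample_scores)
  z <- if (is.na(s) || s == 0) rep(0, n)
       else (sample_scores - mean(sample_scores)) / s
  with_seed(seed, {
    t_event <- rexp(n, rate = baseline_hazard * exp(log_hr_per_sd * z))
    t_cens <- runif(n, 0, censoring_horizon)
    data.frame(sample_id = ids,
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })
}
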