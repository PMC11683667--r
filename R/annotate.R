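#' Fit a two-component Gaussian mixture to one marker's expression
#'
#' One-dimensional finite Gaussian mixture with G = 2 classes (normal vs
#' tumor), fitted by expectation-maximization on log-normalized expression
#' values. Two deterministic starts are used (median-split and
#' extreme-anchored) and the fit with the higher log-likelihood is kept, so
#' results are bit-reproducible without touching the RNG. Component
#' variances are floored rather than allowed to collapse; the log-likelihood
#' is non-decreasing across iterations by construction of EM and is recorded
#' in the returned trace.
#'
#' @param values Numeric vector of at least 10 finite log-normalized values.
#' @param G Number of components (only 2 is supported).
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations.
#' @param variance_floor Lower bound applied to both component variances.
#' @param marker Optional marker symbol stored in the model.
#' @param tau Posterior-probability cutoff used by
#'   [marker_indicator_matrix()]; a cell is marker-positive when its tumor
#'   class posterior strictly exceeds `tau`.
#' @return An object of class `MarkerMixtureModel`: weights, means,
#'   variances, `tumor_component` (higher-mean component until
#'   [assign_tumor_component()] overrides it), `tau`, `n_iter`,
#'   `loglik_trace`, `final_loglik`.
#' @export
fit_em_gmm <- function(values, G = 2, tol = 1e-8, max_iter = 500,
                       variance_floor = 1e-6, marker = NULL, tau = 0.5) {
  if (G != 2) stop("only G = 2 components are supported")
  values <- values[is.finite(values)]
  if (length(values) < 10)
    stop("fit_em_gmm requires at least 10 finite values")
  if (diff(range(values)) == 0)
    stop("degenerate data: all values identical, no 2-class structure")

  starts <- em_starts(values, variance_floor)
  fits <- lapply(starts, function(s)
    em_run(values, s, tol, max_iter, variance_floor))
  best <- fits[[which.max(vapply(fits, function(f) f$final_loglik,
                                 numeric(1)))]]
  best$marker <- marker
  best$tau <- tau
  best$tumor_component <- which.max(best$means)
  class(best) <- "MarkerMixtureModel"
  best
}

em_starts <- function(values, floor_var) {
  med <- stats::median(values)
  lo <- values[values <= med]; hi <- values[values > med]
  if (!length(hi)) { hi <- max(values); lo <- values[values < max(values)] }
  v <- function(x) max(stats::var(x), floor_var, na.rm = TRUE)
  list(
    list(pi = c(0.5, 0.5), mu = c(mean(lo), mean(hi)),
         s2 = c(v(lo), v(hi))),
    list(pi = c(0.5, 0.5), mu = range(values),
         s2 = rep(max(stats::var(values) / 4, floor_var), 2))
  )
}

em_run <- function(x, par, tol, max_iter, floor_var) {
  pi <- par$pi; mu <- par$mu; s2 <- pmax(par$s2, floor_var)
  n <- length(x)
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step (log-space for stability)
    lp <- cbind(log(pi[1]) + stats::dnorm(x, mu[1], sqrt(s2[1]), log = TRUE),
                log(pi[2]) + stats::dnorm(x, mu[2], sqrt(s2[2]), log = TRUE))
    m <- pmax(lp[, 1], lp[, 2])
    lse <- m + log(exp(lp[, 1] - m) + exp(lp[, 2] - m))
    ll <- sum(lse)
    trace <- c(trace, ll)
    r <- exp(lp - lse)
    # M-step
    nk <- colSums(r)
    pi <- nk / n
    mu <- colSums(r * x) / nk
    s2 <- pmax(colSums(r * (outer(x, mu, "-"))^2) / nk, floor_var)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weights = pi, means = mu, variances = s2, n_iter = it,
       loglik_trace = trace, final_loglik = trace[length(trace)])
}

#' @export
print.MarkerMixtureModel <- function(x, ...) {
  cat("MarkerMixtureModel", if (!is.null(x$marker)) paste0("[", x$marker, "]"),
      "\n  weights:", signif(x$weights, 4),
      "\n  means:  ", signif(x$means, 4),
      "\n  vars:   ", signif(x$variances, 4),
      "\n  tumor component:", x$tumor_component,
      " tau:", x$tau, " iterations:", x$n_iter, "\n")
  invisible(x)
}

#' Posterior probability of the tumor component
#'
#' @param model A `MarkerMixtureModel`.
#' @param x Expression values.
#' @return Posterior probability of `model$tumor_component` at each value.
#' @export
posterior_tumor <- function(model, x) {
  k <- model$tumor_component
  lp <- vapply(1:2, function(j)
    log(model$weights[j]) +
      stats::dnorm(x, model$means[j], sqrt(model$variances[j]), log = TRUE),
    numeric(length(x)))
  lp <- matrix(lp, ncol = 2)
  m <- pmax(lp[, 1], lp[, 2])
  den <- m + log(exp(lp[, 1] - m) + exp(lp[, 2] - m))
  exp(lp[, k] - den)
}

#' Assign the tumor component from a labeled reference
#'
#' Sets `tumor_component` to the component whose mean is nearer the mean of
#' tumor-labeled reference values (e.g. a brain-atlas normal compendium plus
#' tumor datasets). With no labels, or labels covering only one class, the
#' higher-mean component is used (with a warning in the one-class case).
#'
#' @param model A `MarkerMixtureModel`.
#' @param ref_values Reference expression values.
#' @param ref_labels Character labels `"normal"`/`"tumor"` aligned to
#'   `ref_values`.
#' @return The model with `tumor_component` set.
#' @export
assign_tumor_component <- function(model, ref_values = NULL,
                                   ref_labels = NULL) {
  if (is.null(ref_values) || is.null(ref_labels)) {
    model$tumor_component <- which.max(model$means)
    return(model)
  }
  if (length(unique(ref_labels)) < 2) {
    warning("labeled reference covers a single class; ",
            "falling back to the higher-mean component")
    model$tumor_component <- which.max(model$means)
    return(model)
  }
  tum_mean <- mean(ref_values[ref_labels == "tumor"])
  model$tumor_component <- which.min(abs(model$means - tum_mean))
  if (model$tumor_component != which.max(model$means))
    message("assign_tumor_component: tumor component is the lower-mean ",
            "component per the labeled reference")
  model
}

#' Marker-positivity indicator matrix
#'
#' For each marker model and each cell, the indicator is 1 iff the posterior
#' probability of the tumor component at that cell's expression value
#' strictly exceeds the model's `tau`.
#'
#' @param models Named list of `MarkerMixtureModel`s, one per marker.
#' @param expr An [expression_matrix()] in `log_normalized` mode.
#' @return Binary matrix, markers x cells.
#' @export
marker_indicator_matrix <- function(models, expr) {
  assert_mode(expr, "log_normalized", "marker_indicator_matrix")
  markers <- vapply(seq_along(models), function(i) {
    m <- models[[i]]$marker
    if (is.null(m)) names(models)[i] else m
  }, character(1))
  missing <- setdiff(markers, expr$gene_ids)
  if (length(missing))
    stop("markers absent from matrix: ", paste(missing, collapse = ", "))
  ind <- t(vapply(seq_along(models), function(i) {
    p <- posterior_tumor(models[[i]], expr$values[markers[i], ])
    as.integer(p > models[[i]]$tau)
  }, integer(length(expr$obs_ids))))
  dimnames(ind) <- list(markers, expr$obs_ids)
  ind
}

#' Arm-level copy-number evidence from smoothed expression
#'
#' A deliberately simple arm-level caller: per gene, expression is centered
#' on the reference-cell mean; per cell, genes are taken in positional order
#' along each arm and smoothed with a moving average; the arm score is the
#' mean smoothed value. An arm is called altered in a cell when its score
#' deviates from the reference mean arm score by more than
#' `arm_zshift_threshold` reference standard deviations, and the cell-level
#' flag is the OR over arms. Arms carrying fewer than `min_genes_per_arm`
#' mapped genes are skipped with a warning. Large-scale alteration of any
#' arm is treated downstream as sufficient evidence of malignancy.
#'
#' @param expr [expression_matrix()], `log_normalized`.
#' @param gene_arm_table data.frame with columns `gene`, `chrom`, `arm`;
#'   row order gives the positional order along each arm.
#' @param reference_cells Observation ids of presumed-diploid reference
#'   cells (e.g. CD45-positive immune cells).
#' @param smoothing_window Moving-average width (genes).
#' @param arm_zshift_threshold Deviation threshold in reference SD units.
#' @param min_genes_per_arm Minimum mapped genes for an arm to be scored.
#' @return List: `cnv_flag` (named logical per cell), `arm_scores`
#'   (cells x arms), `arm_calls` (cells x arms logical), `skipped_arms`.
#' @export
cnv_evidence <- function(expr, gene_arm_table, reference_cells,
                         smoothing_window = 11, arm_zshift_threshold = 3,
                         min_genes_per_arm = 10) {
  assert_mode(expr, "log_normalized", "cnv_evidence")
  if (!length(reference_cells))
    stop("cnv_evidence requires non-empty reference_cells")
  missing_ref <- setdiff(reference_cells, expr$obs_ids)
  if (length(missing_ref))
    stop("reference cells absent from matrix: ",
         paste(utils::head(missing_ref, 5), collapse = ", "))
  arms <- unique(gene_arm_table$arm)
  scores <- list(); calls <- list(); skipped <- character(0)
  for (a in arms) {
    genes <- gene_arm_table$gene[gene_arm_table$arm == a]
    genes <- genes[genes %in% expr$gene_ids]
    if (length(genes) < min_genes_per_arm) {
      warning("arm ", a, " has fewer than ", min_genes_per_arm,
              " mapped genes; skipped")
      skipped <- c(skipped, a)
      next
    }
    x <- expr$values[genes, , drop = FALSE]
    x <- x - rowMeans(x[, reference_cells, drop = FALSE])
    sm <- apply(x, 2, running_mean, w = smoothing_window)
    s <- colMeans(sm)
    ref_s <- s[reference_cells]
    mu0 <- mean(ref_s); sd0 <- sd(ref_s)
    scores[[a]] <- s
    calls[[a]] <- if (is.na(sd0) || sd0 == 0) rep(FALSE, length(s))
                  else abs(s - mu0) > arm_zshift_threshold * sd0
  }
  if (!length(scores)) {
    flag <- setNames(rep(FALSE, length(expr$obs_ids)), expr$obs_ids)
    return(list(cnv_flag = flag,
                arm_scores = matrix(numeric(0), length(expr$obs_ids), 0,
                                    dimnames = list(expr$obs_ids, NULL)),
                arm_calls = matrix(logical(0), length(expr$obs_ids), 0),
                skipped_arms = skipped))
  }
  arm_scores <- do.call(cbind, scores)
  arm_calls <- do.call(cbind, calls)
  rownames(arm_calls) <- rownames(arm_scores) <- expr$obs_ids
  flag <- setNames(rowSums(arm_calls) > 0, expr$obs_ids)
  list(cnv_flag = flag, arm_scores = arm_scores, arm_calls = arm_calls,
       skipped_arms = skipped)
}

# Centered moving average with edge shrinkage (window truncates at the ends,
# so the mean of the smoothed series stays close to the mean of the input).
running_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 1) return(x)
  half <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

default_driver_rules <- function() {
  data.frame(gene = c("IDH1", "IDH1", "IDH2", "IDH2", "EGFR"),
             protein_change = c("R132H", "R132C", "R132H", "R132C", NA),
             stringsAsFactors = FALSE)
}

#' Per-cell SNV evidence from a variant-call table
#'
#' A cell is flagged iff it carries at least one record that (i) is
#' COSMIC-documented (when `cosmic_required`), (ii) has a dbSNP population
#' frequency strictly below `max_dbsnp_freq` (a missing frequency counts as
#' unobserved and passes), and (iii) matches the driver rules: IDH1/IDH2
#' with protein change R132H or R132C, or any qualifying EGFR record.
#'
#' @param variants A variant table ([read_variant_table()] layout).
#' @param cells Observation ids defining the output universe.
#' @param cosmic_required Require `in_cosmic == 1`.
#' @param max_dbsnp_freq Strict upper bound on dbSNP frequency (default
#'   0.001, i.e. 0.1%).
#' @param driver_rules data.frame with columns `gene`, `protein_change`
#'   (NA = any change qualifies).
#' @return Named logical vector over `cells`.
#' @export
snv_evidence <- function(variants, cells, cosmic_required = TRUE,
                         max_dbsnp_freq = 0.001,
                         driver_rules = default_driver_rules()) {
  flag <- setNames(rep(FALSE, length(cells)), cells)
  if (!nrow(variants)) return(flag)
  pass <- rep(TRUE, nrow(variants))
  if (cosmic_required) pass <- pass & variants$in_cosmic == 1
  pass <- pass & (is.na(variants$dbsnp_freq) |
                    variants$dbsnp_freq < max_dbsnp_freq)
  rule_hit <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(driver_rules))) {
    g <- driver_rules$gene[i]; pc <- driver_rules$protein_change[i]
    rule_hit <- rule_hit | (variants$gene == g &
                              (is.na(pc) | variants$protein_change == pc))
  }
  hits <- unique(variants$cell_id[pass & rule_hit])
  flag[names(flag) %in% hits] <- TRUE
  flag
}

#' Integrate evidence channels into a tumor call
#'
#' A cell is called tumor when it meets one or more of the criteria: at
#' least one marker indicator is 1, the CNV flag is set, or the SNV flag is
#' set (logical OR).
#'
#' @param indicators Binary markers x cells matrix
#'   ([marker_indicator_matrix()]), or NULL for no marker channel.
#' @param cnv_flags,snv_flags Logical vectors per cell (or NULL).
#' @return Logical vector of tumor calls.
#' @export
call_tumor_cells <- function(indicators = NULL, cnv_flags = NULL,
                             snv_flags = NULL) {
  lens <- c(if (!is.null(indicators)) ncol(indicators),
            if (!is.null(cnv_flags)) length(cnv_flags),
            if (!is.null(snv_flags)) length(snv_flags))
  if (!length(lens)) stop("at least one evidence channel is required")
  if (length(unique(lens)) != 1)
    stop("evidence channels have mismatched lengths: ",
         paste(lens, collapse = ", "))
  n <- lens[1]
  call <- rep(FALSE, n)
  if (!is.null(indicators)) call <- call | colSums(indicators > 0) > 0
  if (!is.null(cnv_flags)) call <- call | as.logical(cnv_flags)
  if (!is.null(snv_flags)) call <- call | as.logical(snv_flags)
  call
}

#' Per-marker expression thresholds from a reference quantile
#'
#' The mouse-mode thresholds are the 99% quantile of each marker's
#' expression in a normal reference (linear-interpolation quantile
#' definition, R type 7).
#'
#' @param reference_expr [expression_matrix()] of reference cells, or a
#'   numeric matrix with gene rownames.
#' @param markers Marker symbols.
#' @param q Quantile (default 0.99).
#' @return Named numeric vector of thresholds.
#' @export
reference_quantile_thresholds <- function(reference_expr, markers, q = 0.99) {
  vals <- if (is_expression_matrix(reference_expr)) reference_expr$values
          else as.matrix(reference_expr)
  missing <- setdiff(markers, rownames(vals))
  if (length(missing))
    stop("markers absent from reference: ", paste(missing, collapse = ", "))
  vapply(markers, function(m)
    unname(quantile(vals[m, ], probs = q, type = 7)), numeric(1))
}

#' Threshold-based tumor annotation for mouse data
#'
#' A cell is called tumor when any marker's log-normalized expression
#' strictly exceeds its threshold (defaults are the published 99%-quantile
#' cutoffs Pdgfra > 2.64, Egfr > 2.04, Sox2 > 1.95) or when it expresses
#' GFP (raw count > 0), marking the electroporated tumor lineage. Marker
#' rows absent from the matrix are treated as all-zero with a warning.
#'
#' @param expr [expression_matrix()], `log_normalized`.
#' @param thresholds Named numeric marker thresholds.
#' @param gfp_counts Named numeric raw GFP counts per cell (optional).
#' @return Named logical vector of tumor calls.
#' @export
annotate_mouse_tumor <- function(expr,
                                 thresholds = c(Pdgfra = 2.64, Egfr = 2.04,
                                                Sox2 = 1.95),
                                 gfp_counts = NULL) {
  assert_mode(expr, "log_normalized", "annotate_mouse_tumor")
  call <- setNames(rep(FALSE, length(expr$obs_ids)), expr$obs_ids)
  for (m in names(thresholds)) {
    if (!m %in% expr$gene_ids) {
      warning("marker ", m, " absent from matrix; treated as all-zero")
      next
    }
    call <- call | expr$values[m, ] > thresholds[[m]]
  }
  if (!is.null(gfp_counts))
    call <- call | gfp_counts[expr$obs_ids] > 0
  call
}
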