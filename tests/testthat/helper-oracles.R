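# Shared fixtures and independent oracles used across test files.

# Quick ExpressionMatrix from a bare matrix, with generated labels.
em <- function(m, mode = "log_normalized", genes = NULL, obs = NULL) {
  m <- as.matrix(m)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(obs)) obs <- sprintf("c%03d", seq_len(ncol(m)))
  expression_matrix(m, genes, obs, mode = mode)
}

# Literal term-by-term evaluation of the ssGSEA running-sum definition,
# kept deliberately naive (explicit loop) as the oracle.
brute_ssgsea <- function(values, gene_ids, set, alpha) {
  N <- length(values)
  ord <- order(-values, gene_ids)
  ids <- gene_ids[ord]
  inset <- ids %in% set
  m <- sum(inset)
  denom <- 0
  for (i in seq_len(N)) if (inset[i]) denom <- denom + (N - i + 1)^alpha
  p_in <- 0; p_out <- 0; s <- 0
  for (i in seq_len(N)) {
    if (inset[i]) p_in <- p_in + (N - i + 1)^alpha / denom
    else p_out <- p_out + 1 / (N - m)
    s <- s + (p_in - p_out)
  }
  s
}

# Exact two-sided rank-sum p by full enumeration of group assignments
# (valid for untied values; uses the symmetry of the null distribution).
enum_wilcox_p <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals); na <- length(a)
  r <- rank(vals)
  W_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  combs <- utils::combn(n, na)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]))
  min(1, mean(abs(Ws - mu) >= abs(W_obs - mu)))
}

# Rank-based AUC of scores for the positive class.
auc_of <- function(scores, positive) {
  r <- rank(scores)
  na <- sum(positive); nb <- sum(!positive)
  (sum(r[positive]) - na * (na + 1) / 2) / (na * nb)
}

# Small mouse cohort reused by signature/scoring tests.
small_mouse_cohort <- function(seed = 101, cells = 300) {
  simulate_sc_cohort(sim_cohort_spec(species = "mouse",
                                     cells_per_sample = cells,
                                     n_genes = 800, seed = seed))
}
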