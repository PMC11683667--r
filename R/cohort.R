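#' Pearson correlation test
#'
#' Product-moment correlation with the two-sided t-test on
#' `t = r * sqrt((n - 2) / (1 - r^2))`, n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both nonconstant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("pearson_test requires n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input vector")
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p = ht$p.value, n = n)
}

#' Correlation panel of a signature score against a score table
#'
#' Pearson tests of the signature score against every gene-set score
#' column, optionally within groups (per-sample correlations across cells,
#' as in the single-cell analysis). Groups with fewer than 3 observations
#' or a constant vector are reported with missing r/p and a note rather
#' than dropped. A Benjamini-Hochberg column is added for convenience; the
#' per-set p-values themselves are unadjusted.
#'
#' @param sig_scores Numeric signature score per observation.
#' @param panel data.frame of observations x gene-set scores
#'   ([score_panel()] output).
#' @param group_by Optional grouping vector (e.g. sample of cell).
#' @return data.frame: group, gene_set, r, p, n, note, p_adj_bh.
#' @export
correlation_panel <- function(sig_scores, panel, group_by = NULL) {
  stopifnot(length(sig_scores) == nrow(panel))
  if (is.null(group_by)) group_by <- rep("all", length(sig_scores))
  rows <- list()
  for (g in unique(group_by)) {
    idx <- group_by == g
    for (set in names(panel)) {
      x <- sig_scores[idx]; y <- panel[[set]][idx]
      res <- tryCatch(pearson_test(x, y), error = function(e) e)
      if (inherits(res, "error"))
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, gene_set = set, r = NA_real_, p = NA_real_,
          n = sum(idx), note = conditionMessage(res),
          stringsAsFactors = FALSE)
      else
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, gene_set = set, r = res$r, p = res$p, n = res$n,
          note = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Quartile stratification of per-sample scores
#'
#' High stratum: score >= Q3; low stratum: score <= Q1 (linear-interpolation
#' quantiles, boundary ties included in the extreme groups); the middle
#' half is excluded. When every score is identical the strata are
#' meaningless and every sample is excluded, with a warning; fewer than 8
#' samples triggers a warning that strata may be tiny.
#'
#' @param scores Named numeric, one score per sample.
#' @return Factor over samples with levels `high`, `low`, `excluded`.
#' @export
quartile_stratify <- function(scores) {
  n <- length(scores)
  if (n < 8)
    warning("fewer than 8 samples; quartile strata may be tiny")
  if (n > 0 && diff(range(scores)) == 0) {
    warning("degenerate score distribution (all equal); no strata assigned")
    return(factor(setNames(rep("excluded", n), names(scores)),
                  levels = c("high", "low", "excluded")))
  }
  q <- quantile(scores, probs = c(0.25, 0.75), type = 7)
  stratum <- rep("excluded", n)
  stratum[scores >= q[2]] <- "high"
  stratum[scores <= q[1]] <- "low"
  both <- scores >= q[2] & scores <= q[1]
  stratum[both] <- "excluded"
  factor(setNames(stratum, names(scores)),
         levels = c("high", "low", "excluded"))
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival curve over the distinct event times; the median
#' is the first time at which the curve drops to 0.5 or below, undefined
#' (NA) when the curve never does.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return List of class `KMCurve`: `time`, `n_risk`, `n_event`, `surv`,
#'   `median`, `n`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty input")
  stopifnot(length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  s <- fit$surv
  med <- if (any(s <= 0.5)) fit$time[which(s <= 0.5)[1]] else NA_real_
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = s, median = med,
                 n = length(times)),
            class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", sum(x$n_event),
      ", median =", if (is.na(x$median)) "not reached" else x$median, "\n")
  invisible(x)
}

#' Log-rank test between survival groups
#'
#' The standard log-rank statistic: at each distinct event time, observed
#' versus hypergeometric-expected events per group, chi-square with k - 1
#' degrees of freedom for k groups (1 df for the usual two-stratum
#' comparison). A group with zero events is handled normally.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group labels (two or more non-empty groups).
#' @return List with `chi_square`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("at least two non-empty groups are required")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  list(chi_square = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df = df, lower.tail = FALSE))
}
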