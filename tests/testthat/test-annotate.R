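test_that("EM recovers a well-separated two-component mixture", {
  set.seed(1)
  x <- c(rnorm(3000, 0, 1), rnorm(2000, 3, 1))
  m <- fit_em_gmm(x)
  lo <- which.min(m$means); hi <- which.max(m$means)
  expect_lt(abs(m$means[lo] - 0), 0.1)
  expect_lt(abs(m$means[hi] - 3), 0.1)
  expect_lt(abs(m$weights[lo] - 0.6), 0.03)
  expect_equal(sum(m$weights), 1)
  # posteriors over components sum to one at any value
  p_t <- posterior_tumor(m, x[1:50])
  m2 <- m; m2$tumor_component <- setdiff(1:2, m$tumor_component)
  expect_equal(p_t + posterior_tumor(m2, x[1:50]), rep(1, 50))
})

test_that("EM agrees with the mclust fit on the same data", {
  withr::local_package("mclust")
  set.seed(2)
  x <- c(rnorm(1500, 0, 1), rnorm(1000, 3, 1))
  m <- fit_em_gmm(x)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(m$means) - sort(as.numeric(mc$parameters$mean)))),
            0.1)
  expect_lt(max(abs(sort(m$weights) - sort(mc$parameters$pro))), 0.03)
})

test_that("EM log-likelihood is non-decreasing on random datasets", {
  for (s in 1:100) {
    set.seed(s)
    shift <- runif(1, 0, 4)
    x <- rnorm(200, 0, runif(1, 0.5, 2)) +
      ifelse(runif(200) < runif(1, 0.2, 0.8), shift, 0)
    m <- fit_em_gmm(x)
    expect_true(all(diff(m$loglik_trace) >= -1e-8))
  }
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(fit_em_gmm(rep(2, 100)), "degenerate")
  expect_error(fit_em_gmm(rnorm(5)), "at least 10")
})

test_that("tumor component follows the labeled reference, else the higher mean", {
  set.seed(3)
  x <- c(rnorm(500, 0.1, 0.2), rnorm(500, 2.9, 0.2))
  m <- fit_em_gmm(x)
  hi <- which.max(m$means)

  ref_vals <- c(rnorm(50, 0.1, 0.1), rnorm(50, 3, 0.1))
  ref_lab <- rep(c("normal", "tumor"), each = 50)
  m1 <- assign_tumor_component(m, ref_vals, ref_lab)
  expect_equal(m1$tumor_component, hi)

  m2 <- assign_tumor_component(m)
  expect_equal(m2$tumor_component, hi)

  # adversarial labels: tumor reference sits at the low mode
  m3 <- suppressMessages(
    assign_tumor_component(m, ref_vals, rev(ref_lab)))
  expect_equal(m3$tumor_component, setdiff(1:2, hi))

  expect_warning(assign_tumor_component(m, ref_vals[1:50],
                                        rep("tumor", 50)), "single class")
})

test_that("marker indicators follow the closed-form posterior", {
  # equal variances and weights: posterior of the high component is the
  # logistic function 1/(1+exp(-3*(x - 1.5))), so the 0.5 crossing is at 1.5
  m <- structure(list(weights = c(0.5, 0.5), means = c(0, 3),
                      variances = c(1, 1), tumor_component = 2L,
                      tau = 0.5, marker = "SOX2"),
                 class = "MarkerMixtureModel")
  vals <- matrix(c(3, 0, 1.5, 2), nrow = 1,
                 dimnames = list("SOX2", NULL))
  x <- expression_matrix(vals, "SOX2", sprintf("c%d", 1:4), "log_normalized")
  ind <- marker_indicator_matrix(list(SOX2 = m), x)
  expect_equal(unname(ind["SOX2", ]), c(1L, 0L, 0L, 1L))  # 1.5 is strict
  expect_equal(posterior_tumor(m, 2), 1 / (1 + exp(-3 * (2 - 1.5))))

  # raising expression never flips 1 -> 0 when tumor is the high component
  grid <- seq(-2, 6, by = 0.1)
  p <- posterior_tumor(m, grid)
  expect_true(all(diff(p) >= 0))

  expect_error(marker_indicator_matrix(
    list(EGFR = structure(list(weights = c(0.5, 0.5), means = c(0, 1),
                               variances = c(1, 1), tumor_component = 2L,
                               tau = 0.5, marker = "EGFR"),
                          class = "MarkerMixtureModel")), x),
    "EGFR")
})

test_that("CNV evidence is silent on flat data and calibrated on references", {
  arms <- data.frame(gene = sprintf("g%03d", 1:40),
                     chrom = "7", arm = "7p")
  flat <- em(matrix(1, 40, 30))
  res <- cnv_evidence(flat, arms, reference_cells = flat$obs_ids[1:10])
  expect_false(any(res$cnv_flag))

  set.seed(5)
  x <- em(matrix(rnorm(40 * 200), 40, 200))
  null <- cnv_evidence(x, arms, reference_cells = x$obs_ids,
                       arm_zshift_threshold = 2)
  # nominal two-sided rate at z > 2 is ~4.6%; observed must stay below 2x
  expect_lt(mean(null$cnv_flag), 2 * 0.046)

  expect_warning(
    cnv_evidence(x, data.frame(gene = "g001", chrom = "1", arm = "1p"),
                 reference_cells = x$obs_ids[1:5]),
    "skipped")
  expect_error(cnv_evidence(x, arms, reference_cells = character(0)),
               "non-empty")
})

test_that("SNV evidence applies the COSMIC, rarity and driver-gene rules", {
  tab <- data.frame(
    cell_id = c("c1", "c2", "c3", "c4", "c5", "c6"),
    gene = c("IDH1", "TP53", "EGFR", "IDH1", "IDH2", "EGFR"),
    variant_id = sprintf("v%d", 1:6),
    protein_change = c("R132H", "R175H", "A289V", "R100Q", "R132C", "L858R"),
    in_cosmic = c(1L, 1L, 1L, 1L, 1L, 0L),
    dbsnp_freq = c(0, NA, NA, 0, 0.05, NA),
    stringsAsFactors = FALSE)
  flag <- snv_evidence(tab, cells = sprintf("c%d", 1:7))
  # c1: IDH1 R132H, rare, cosmic -> flagged
  # c2: TP53 not in the driver rules -> not flagged
  # c3: EGFR, any protein change qualifies -> flagged
  # c4: IDH1 but not R132H/R132C -> not flagged
  # c5: IDH2 R132C but dbSNP frequency 5% fails < 0.1% -> not flagged
  # c6: EGFR but not COSMIC-documented -> not flagged
  expect_equal(unname(flag), c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(any(snv_evidence(tab[0, ], cells = c("c1", "c2"))))
})

test_that("the tumor call is the OR over evidence channels, exhaustively", {
  combos <- expand.grid(marker = 0:1, cnv = 0:1, snv = 0:1)
  ind <- matrix(combos$marker, nrow = 1)
  call <- call_tumor_cells(ind, combos$cnv == 1, combos$snv == 1)
  brute <- apply(combos, 1, function(r) any(r == 1))
  expect_equal(call, unname(brute))
  expect_error(call_tumor_cells(ind, combos$cnv == 1, TRUE), "mismatch")
  expect_false(any(call_tumor_cells(matrix(0, 2, 4), rep(FALSE, 4),
                                    rep(FALSE, 4))))
})

test_that("reference quantile thresholds use linear interpolation", {
  ref <- em(matrix(1:100, nrow = 1, dimnames = list("Sox2", NULL)),
            genes = "Sox2", obs = sprintf("c%d", 1:100))
  expect_equal(unname(reference_quantile_thresholds(ref, "Sox2", 0.99)),
               99.01)
  expect_equal(unname(reference_quantile_thresholds(ref, "Sox2", 1)), 100)
  cst <- em(matrix(2, 1, 10, dimnames = list("Egfr", NULL)), genes = "Egfr")
  expect_equal(unname(reference_quantile_thresholds(cst, "Egfr", 0.99)), 2)
  expect_error(reference_quantile_thresholds(ref, "Pdgfra"), "Pdgfra")
})

test_that("mouse annotation applies the printed thresholds strictly plus GFP", {
  vals <- rbind(Sox2 = c(2.10, 1.95, 0, 1.96),
                Egfr = c(0, 0, 0, 0),
                Pdgfra = c(0, 0, 0, 0))
  x <- expression_matrix(vals, rownames(vals), sprintf("c%d", 1:4),
                         "log_normalized")
  gfp <- setNames(c(0, 0, 1, 0), x$obs_ids)
  call <- annotate_mouse_tumor(x, gfp_counts = gfp)
  expect_equal(unname(call), c(TRUE, FALSE, TRUE, TRUE))
  w <- capture_warnings(
    annotate_mouse_tumor(em(matrix(0, 1, 2, dimnames = list("Sox2", NULL)),
                            genes = "Sox2")))
  expect_match(w, "absent", all = TRUE)
  expect_length(w, 2)  # Pdgfra and Egfr rows are missing
})
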