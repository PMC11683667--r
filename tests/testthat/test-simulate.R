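test_that("degenerate cohort specs produce empty but well-formed outputs", {
  sim <- simulate_sc_cohort(sim_cohort_spec(cells_per_sample = 0, seed = 1))
  expect_equal(ncol(sim$counts$values), 0)
  expect_equal(nrow(sim$truth), 0)

  sim0 <- simulate_sc_cohort(sim_cohort_spec(
    snv_params = list(capture_rate = 0, benign_rate = 0),
    cells_per_sample = 50, seed = 1))
  expect_equal(nrow(sim0$variants), 0)

  expect_error(sim_cohort_spec(fraction_tumor = 0.8, fraction_immune = 0.5),
               "parameter error")
  expect_error(sim_cohort_spec(snv_params = list(capture_rate = 2)),
               "parameter error")
})

test_that("configured marker effects are recovered from simulated counts", {
  mk <- list(SOX2 = list(normal_mean = -1, tumor_mean = 2, sd = 0.3),
             EGFR = list(normal_mean = -4, tumor_mean = 1, sd = 0.4),
             PDGFRA = list(normal_mean = -4, tumor_mean = 1, sd = 0.4))
  sim <- simulate_sc_cohort(sim_cohort_spec(marker_params = mk, seed = 5))
  tum <- sim$truth$type == "tumor"
  norm_cells <- sim$truth$type == "normal"
  diff_log <- log(mean(sim$counts$values["SOX2", tum])) -
    log(mean(sim$counts$values["SOX2", norm_cells]))
  expect_lt(abs(diff_log - 3), 0.15)
})

test_that("generated cohorts are reproducible and carry the promised structure", {
  spec <- sim_cohort_spec(cells_per_sample = 100, n_genes = 600, seed = 9)
  a <- simulate_sc_cohort(spec)
  b <- simulate_sc_cohort(spec)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$variants, b$variants)

  # immune cells are CD45-positive by construction
  imm <- a$truth$type == "immune"
  expect_true(all(a$counts$values["PTPRC", imm] > 0))
  # non-immune cells do not express CD45
  expect_true(all(a$counts$values["PTPRC", !imm] == 0))

  # overdispersion: variance exceeds the mean for expressed genes
  v <- apply(a$counts$values, 1, var)
  m <- rowMeans(a$counts$values)
  hi <- m > 0.5
  expect_gt(mean(v[hi] > m[hi]), 0.9)
})

test_that("mouse mode plants GFP in tumor lineage and the Cd83 program in GOF", {
  sim <- small_mouse_cohort(seed = 3)
  tum <- sim$truth$type == "tumor"
  expect_true(all(sim$counts$values["GFP", !tum] == 0))
  expect_gt(mean(sim$counts$values["GFP", tum] > 0), 0.5)
  expect_true(all(sim$truth$carries_program ==
                    (tum & sim$truth$condition == "GOF")))
  # planted program effect: carrier mean expression elevated ~4-fold
  prog <- sprintf("Prog%03d", 1:40)
  carrier <- sim$truth$carries_program
  ratio <- mean(sim$counts$values[prog, carrier]) /
    mean(sim$counts$values[prog, tum & !carrier])
  expect_gt(ratio, 3); expect_lt(ratio, 5.5)
})

test_that("bulk generator couples planted sets to the program factor", {
  b <- simulate_bulk_cohort(sim_bulk_spec(seed = 21))
  bn <- normalize_bulk(b$counts)
  prog_mean <- colMeans(bn$values[b$sets$CD83_program, ])
  r_of <- function(set) cor(colMeans(bn$values[b$sets[[set]], ]), prog_mean)
  expect_gt(r_of("immune_up"), 0.5)
  expect_lt(r_of("immune_down"), -0.5)
  expect_lt(abs(r_of("immune_null")), 0.3)
  # planted program set is returned verbatim and deterministically
  expect_identical(b$sets$CD83_program, sprintf("PROG%03d", 1:40))
  expect_identical(simulate_gene_sets(sim_bulk_spec(seed = 21)),
                   simulate_gene_sets(sim_bulk_spec(seed = 99)))
  expect_error(sim_bulk_spec(immune_couplings = numeric(0)),
               "parameter error")
})

test_that("survival generator honors hazard parameters and limits", {
  expect_error(simulate_survival(rnorm(10), baseline_hazard = 0),
               "parameter error")
  tiny <- simulate_survival(rnorm(50), censoring_horizon = 1e-9, seed = 1)
  expect_true(all(tiny$event == 0))
  expect_true(all(tiny$time <= 1e-9))

  # beta = 0: quartile-contrast log-rank p behaves like a null p-value
  pv <- vapply(1:200, function(s) {
    set.seed(s)
    sc <- setNames(rnorm(80), sprintf("B%03d", 1:80))
    surv <- simulate_survival(sc, log_hr_per_sd = 0, seed = s)
    st <- quartile_stratify(sc)
    k <- st[surv$sample_id] %in% c("high", "low")
    logrank_test(surv$time[k], surv$event[k],
                 as.character(st[surv$sample_id][k]))$p
  }, numeric(1))
  expect_gt(mean(pv < 0.05), 0.01)
  expect_lt(mean(pv < 0.05), 0.12)

  # protective score: high quartile outlives low quartile most of the time
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    sc <- setNames(rnorm(200), sprintf("B%03d", 1:200))
    surv <- simulate_survival(sc, seed = s)
    st <- as.character(quartile_stratify(sc)[surv$sample_id])
    mh <- km_estimate(surv$time[st == "high"], surv$event[st == "high"])$median
    ml <- km_estimate(surv$time[st == "low"], surv$event[st == "low"])$median
    if (is.na(mh) && !is.na(ml)) TRUE
    else if (!is.na(mh) && !is.na(ml)) mh > ml
    else FALSE
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
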