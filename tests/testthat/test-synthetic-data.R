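test_that("generated betas are bounded, cell fractions sum to 1, seeds reproduce", {
  co <- small_cohort(seed = 11)
  expect_true(all(co$beta >= 0 & co$beta <= 1))
  cells <- as.matrix(co$clinical[, paste0("cell_", 1:5)])
  expect_equal(unname(rowSums(cells)), rep(1, nrow(cells)), tolerance = 1e-12)
  expect_equal(as.integer(table(co$truth$labels)[c("control", "G1", "G2")]),
               c(40L, 20L, 20L))

  co2 <- small_cohort(seed = 11)
  expect_identical(co$beta, co2$beta)
  expect_identical(co$clinical, co2$clinical)
  expect_identical(co$truth, co2$truth)

  co3 <- small_cohort(seed = 12)
  expect_false(identical(co$beta, co3$beta))
})

test_that("planted G2 shift lands within sampling error of the configured delta", {
  # coupling off: the example isolates the planted group shift
  cfg <- synth_config(n_control = 100, n_g1 = 50, n_g2 = 50, n_genes = 1500,
                      delta_g2 = 0.06, delta_g1 = -0.06,
                      methylation_factor_coupling = 0, seed = 21)
  co <- generate_cohort(cfg)
  # oracle: direct group means over the planted G2 signal genes
  probes <- co$annotation$probe_id[co$annotation$gene %in%
                                     co$truth$signal_genes_g2]
  vals <- rowMeans(co$beta[, probes, drop = FALSE])
  is_g2 <- co$truth$labels == "G2"
  is_ctrl <- co$truth$labels == "control"
  diff <- mean(vals[is_g2]) - mean(vals[is_ctrl])
  se <- sqrt(var(vals[is_g2]) / sum(is_g2) + var(vals[is_ctrl]) / sum(is_ctrl))
  expect_lt(abs(diff - 0.06), 2 * se + 1e-9)
})

test_that("within-gene probe correlation tracks the configured target", {
  mean_within_r <- function(target) {
    co <- generate_cohort(synth_config(n_control = 150, n_g1 = 0, n_g2 = 0,
                                       n_genes = 200, n_signal_genes_g1 = 0,
                                       n_signal_genes_g2 = 0,
                                       within_gene_corr = target, seed = 3))
    genes <- unique(co$annotation$gene[co$annotation$gene != ""])
    rs <- unlist(lapply(genes[1:80], function(g) {
      pr <- co$annotation$probe_id[co$annotation$gene == g]
      if (length(pr) < 2L) return(NULL)
      cm <- cor(co$beta[, pr])
      cm[upper.tri(cm)]
    }))
    mean(rs)
  }
  r_hi <- mean_within_r(0.8)
  r_lo <- mean_within_r(0.3)
  # near the target (the logit->beta map and covariate effects attenuate
  # slightly), and monotone in the configured value
  expect_lt(abs(r_hi - 0.8), 0.2)
  expect_lt(abs(r_lo - 0.3), 0.2)
  expect_gt(r_hi, r_lo)
})

test_that("a zero-effect cohort yields no excess DMG calls", {
  co <- generate_cohort(synth_config(n_control = 30, n_g1 = 15, n_g2 = 15,
                                     n_genes = 700, delta_g1 = 0, delta_g2 = 0,
                                     clinical_loading = 0,
                                     methylation_factor_coupling = 0,
                                     physical_coupling = 0,
                                     covariate_effects = list(age = 0, bmi = 0,
                                                              cell = 0,
                                                              ancestry = 0),
                                     seed = 9))
  probes <- co$annotation$probe_id[co$annotation$gene != ""][1:2000]
  is_case <- co$truth$labels != "control"
  dm <- moderated_ttest(co$beta[, probes], is_case)
  called <- call_dmg(dm, co$annotation, p_cut = 0.01, d_cut = 0)
  # <= 2x the nominal false-positive expectation at p < 0.01
  expect_lte(sum(called$table$dmp), 2 * 0.01 * length(probes))
})

test_that("recall pairs honour the target test-retest correlation", {
  cfg <- synth_config(n_control = 60, n_g1 = 0, n_g2 = 0, n_genes = 150,
                      n_signal_genes_g1 = 0, n_signal_genes_g2 = 0,
                      recall_corr = 0.9, seed = 5)
  rp <- generate_recall_pair(cfg, n_recall = 41)
  expect_identical(unname(rp$mapping), rownames(rp$original))
  expect_identical(rownames(rp$original), rownames(rp$recall))
  rs <- vapply(seq_len(ncol(rp$original)),
               function(j) cor(rp$original[, j], rp$recall[, j]), 1)
  expect_gt(mean(rs), 0.8)

  # identity limit: perfect recall correlation reproduces the original
  cfg1 <- synth_config(n_control = 20, n_g1 = 0, n_g2 = 0, n_genes = 50,
                       n_signal_genes_g1 = 0, n_signal_genes_g2 = 0,
                       recall_corr = 1, seed = 6)
  rp1 <- generate_recall_pair(cfg1, n_recall = 10)
  expect_identical(rp1$original, rp1$recall)
})

test_that("unstable recall regions fail the stability filter almost surely", {
  # Monte-Carlo over seeds: a gene redrawn independently at recall should be
  # dropped by the r >= 0.65 filter in >= 95% of draws at n = 41
  n_fail <- 0L
  n_seeds <- 60L
  for (s in seq_len(n_seeds)) {
    cfg <- synth_config(n_control = 41, n_g1 = 0, n_g2 = 0, n_genes = 30,
                        n_signal_genes_g1 = 0, n_signal_genes_g2 = 0,
                        n_physical_genes = 0,
                        recall_corr = 0.95, recall_unstable_frac = 0.2,
                        seed = 1000 + s)
    rp <- generate_recall_pair(cfg, n_recall = 41)
    ann <- rp$annotation
    keep <- ann$gene %in% rp$unstable_genes
    pr <- ann$probe_id[keep]
    pr <- intersect(pr, colnames(rp$original))
    rs <- vapply(pr, function(p) cor(rp$original[, p], rp$recall[, p]), 1)
    if (all(rs < 0.65)) n_fail <- n_fail + 1L
  }
  expect_gte(n_fail / n_seeds, 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_genes = 10, n_signal_genes_g1 = 8,
                            n_signal_genes_g2 = 8), "signal genes")
  expect_error(synth_config(delta_g2 = 0.5), "outside")
  expect_error(synth_config(within_gene_corr = 1.2), "within_gene_corr")
  expect_error(synth_config(recall_corr = -0.1), "recall_corr")
})

test_that("cohort writer round-trips through the plain-text readers", {
  co <- small_cohort(seed = 31)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  beta <- read_beta_matrix(paths[["beta"]])
  expect_equal(beta, co$beta, tolerance = 1e-12)
  ann <- read_annotation(paths[["annotation"]])
  expect_equal(ann, co$annotation)
  clin <- read_clinical(paths[["clinical"]])
  expect_equal(clin$caps_total, co$clinical$caps_total, tolerance = 1e-6)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(sort(truth$signal_genes_g2), sort(co$truth$signal_genes_g2))
})
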