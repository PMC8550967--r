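# Marker-panel selection: candidate rules, subset search, forward cutoff,
# pruning, refinement and ROC evaluation.

test_that("candidate probes require train thresholds plus cross-cohort sign", {
  set.seed(14)
  train <- panel_cohort_fixture(n_case = 40, n_control = 40, n_signal = 5,
                                n_null = 45, shift = 0.08, seed = 14)
  v1 <- panel_cohort_fixture(n_case = 25, n_control = 25, n_signal = 5,
                             n_null = 45, shift = 0.08, seed = 15)
  v2 <- panel_cohort_fixture(n_case = 25, n_control = 25, n_signal = 5,
                             n_null = 45, shift = 0.08, seed = 16)
  got <- candidate_dmps(train, list(v1, v2), p_cut = 0.1, d_cut = 0.02)
  # brute-force oracle: the three rules applied directly
  dm <- moderated_ttest(train$beta, train$is_case)
  md <- function(co) {
    apply(co$beta[co$is_case, ], 2, median) -
      apply(co$beta[!co$is_case, ], 2, median)
  }
  d0 <- md(train)
  keep <- dm$table$p < 0.1 & abs(d0) > 0.02 &
    sign(md(v1)) == sign(d0) & sign(md(v2)) == sign(d0)
  expect_setequal(got, colnames(train$beta)[keep])
  expect_true(all(sprintf("cg%07d", 1:5) %in% got))

  # sign flip in one validation cohort drops the probe
  v_flip <- v1
  v_flip$beta[v_flip$is_case, 1] <- v_flip$beta[v_flip$is_case, 1] - 0.3
  v_flip$beta <- pmin(pmax(v_flip$beta, 0.001), 0.999)
  got2 <- candidate_dmps(train, list(v_flip, v2))
  expect_false("cg0000001" %in% got2)
})

test_that("ROC metrics: perfect separation, null scores, concordance oracle", {
  perfect <- roc_metrics(c(1:10, 21:30), rep(c(FALSE, TRUE), each = 10))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  set.seed(18)
  null <- roc_metrics(rnorm(2000), rep(c(TRUE, FALSE), 1000))
  se <- sqrt(1 / 12 * (1 / 1000 + 1 / 1000))   # ~SE of a null AUC
  expect_lt(abs(null$auc - 0.5), 3 * se)

  # 30-sample fixture with ties: trapezoidal AUC equals Mann-Whitney
  # pairwise concordance (ties counted 1/2)
  set.seed(19)
  scores <- sample(rep(1:10, 3))
  labs <- rep(c(TRUE, FALSE), 15)
  m <- roc_metrics(scores, labs)
  pos <- scores[labs]; neg <- scores[!labs]
  conc <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(m$auc, conc, tolerance = 1e-12)

  # AUC is invariant to monotone transforms of the scores
  m2 <- roc_metrics(exp(scores / 3), labs)
  expect_equal(m2$auc, m$auc, tolerance = 1e-12)
  expect_error(roc_metrics(1:5, rep(TRUE, 5)), "single class")
})

test_that("subset search ranks a planted separator first and is seeded", {
  train <- panel_cohort_fixture(n_case = 25, n_control = 25, n_signal = 1,
                                n_null = 19, shift = 0.35, seed = 20)
  v1 <- panel_cohort_fixture(n_case = 20, n_control = 20, n_signal = 1,
                             n_null = 19, shift = 0.35, seed = 21)
  cands <- colnames(train$beta)
  pr <- random_subset_search(cands, train, list(v1), n_runs = 300,
                             subset_size = 5, auc_keep = 0.8, seed = 31)
  expect_identical(pr$ranking$probe[1], "cg0000001")
  expect_gt(pr$ranking$frequency[1], max(pr$ranking$frequency[-1]))
  pr2 <- random_subset_search(cands, train, list(v1), n_runs = 300,
                              subset_size = 5, auc_keep = 0.8, seed = 31)
  expect_identical(pr$ranking, pr2$ranking)

  # auc_keep = 0 retains every subset: frequencies near subset_size/K
  pr0 <- random_subset_search(cands, train, list(v1), n_runs = 400,
                              subset_size = 5, auc_keep = 0, seed = 32)
  expect_equal(pr0$n_retained, 400L)
  expo <- 5 / length(cands)
  binom_se <- sqrt(expo * (1 - expo) / 400)
  expect_true(all(abs(pr0$ranking$frequency - expo) < 5 * binom_se))
})

test_that("forward trajectory peaks early with planted probes; tol 0 is argmax", {
  train <- panel_cohort_fixture(n_case = 30, n_control = 30, n_signal = 3,
                                n_null = 12, shift = 0.3, seed = 22)
  v1 <- panel_cohort_fixture(n_case = 25, n_control = 25, n_signal = 3,
                             n_null = 12, shift = 0.3, seed = 23)
  ranking <- data.frame(probe = colnames(train$beta))  # planted first
  fw <- forward_auc_cutoff(ranking, train, list(v1), k_max = 10)
  expect_equal(nrow(fw$trajectory), 10L)
  expect_lte(fw$k, 5)
  fw0 <- forward_auc_cutoff(ranking, train, list(v1), k_max = 10,
                            tolerance = 0)
  expect_equal(fw0$k, which.max(fw0$trajectory$mean_auc))
})

test_that("collinearity pruning drops duplicates, keeps independent probes", {
  set.seed(24)
  n <- 40
  base <- matrix(plogis(rnorm(n * 4, sd = 0.4)), n)
  beta <- cbind(base[, 1], base[, 1] + rnorm(n, sd = 1e-4), base[, 2],
                base[, 3], base[, 3] * 0.98 + rnorm(n, sd = 1e-3), base[, 4])
  colnames(beta) <- paste0("p", 1:6)
  train <- list(beta = beta, is_case = rep(c(TRUE, FALSE), n / 2))
  got <- collinearity_prune(paste0("p", 1:6), train, prune_r = 0.8)
  # hand-worked greedy walk: p2 falls to p1, p5 falls to p4
  expect_identical(got, c("p1", "p3", "p4", "p6"))
  low <- collinearity_prune(paste0("p", c(1, 3, 4, 6)), train, prune_r = 0.8)
  expect_identical(low, c("p1", "p3", "p4", "p6"))
})

test_that("biotype refinement recovers per-biotype separators", {
  mk <- function(seed) {
    co <- panel_cohort_fixture(n_case = 30, n_control = 30, n_signal = 0,
                               n_null = 26, seed = seed)
    g1 <- which(co$is_case)[1:15]; g2 <- which(co$is_case)[16:30]
    co$biotype[g1] <- "G1"; co$biotype[g2] <- "G2"
    co$beta[g1, 1:3] <- pmin(co$beta[g1, 1:3] + 0.3, 0.999)
    co$beta[g2, 4:6] <- pmin(co$beta[g2, 4:6] + 0.3, 0.999)
    co
  }
  train <- mk(25); v1 <- mk(26)
  ref <- biotype_refine(colnames(train$beta)[1:12], train, list(v1))
  # separators for BOTH biotypes must be picked (neither AUC can exceed
  # chance otherwise), and nothing outside the planted six helps
  expect_gt(sum(sprintf("cg%07d", 1:3) %in% ref$probes), 0)
  expect_gt(sum(sprintf("cg%07d", 4:6) %in% ref$probes), 0)
  # stopping-rule guarantee: returned objective within tolerance of the
  # full-panel objective
  full_obj <- methylotype:::panel_mean_auc(colnames(train$beta)[1:12], train,
                                           list(v1), per_biotype = TRUE)
  expect_gte(ref$objective, full_obj - 0.005)

  v_missing <- v1; v_missing$biotype[v_missing$biotype == "G1"] <- "G2"
  expect_error(biotype_refine(colnames(train$beta)[1:6], train,
                              list(v_missing)), "absent")
})

test_that("panel evaluation supports biotype-restricted contrasts", {
  train <- panel_cohort_fixture(n_case = 30, n_control = 30, n_signal = 0,
                                n_null = 20, seed = 27)
  test_co <- panel_cohort_fixture(n_case = 30, n_control = 30, n_signal = 0,
                                  n_null = 20, seed = 28)
  # plant signal only in G2 cases of both cohorts
  for (nm in c("train", "test_co")) {
    co <- get(nm)
    g2 <- which(co$is_case & co$biotype == "G2")
    co$beta[g2, 1:5] <- pmin(co$beta[g2, 1:5] + 0.25, 0.999)
    assign(nm, co)
  }
  # keep the training signal G2-specific, so the classifier separates G2 only
  panel <- colnames(train$beta)[1:5]
  eg2 <- evaluate_panel(panel, train, test_co, group = "G2")
  eg1 <- evaluate_panel(panel, train, test_co, group = "G1")
  expect_gte(eg2$auc - eg1$auc, 0.2)
  expect_equal(eg2$n_case, 15)
  expect_equal(eg2$n_control, 30)
})
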