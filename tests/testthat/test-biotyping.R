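# LDA boundary geometry, the closed-form biotype score, assignment rules,
# and biotype-vs-clinical comparisons.

test_that("LDA normal matches the closed-form pooled-covariance solve", {
  set.seed(30)
  n <- 60
  lat0 <- cbind(x = rnorm(n, 0, 1), y = rnorm(n, 0, 2))
  lat1 <- cbind(x = rnorm(n, 3, 1), y = rnorm(n, 1, 2))
  lat <- rbind(lat0, lat1)
  is_case <- rep(c(FALSE, TRUE), each = n)
  bd <- fit_lda_boundary(lat, is_case)
  # oracle: explicit 2x2 solve of S_pooled^{-1} (mu1 - mu0)
  s0 <- cov(lat0); s1 <- cov(lat1)
  sp <- ((n - 1) * s0 + (n - 1) * s1) / (2 * n - 2)
  ref <- solve(sp, colMeans(lat0) - colMeans(lat1))
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(abs(sum(bd$normal * ref)), 1, tolerance = 1e-10)
  # orientation: control mean on the positive side
  expect_gt(sum(colMeans(lat0) * bd$normal) + bd$intercept, 0)
  # label swap flips the normal, |score| unchanged
  bd2 <- fit_lda_boundary(lat, !is_case)
  s_a <- drop(lat %*% bd$normal) + bd$intercept
  s_b <- drop(lat %*% bd2$normal) + bd2$intercept
  expect_equal(abs(s_a), abs(s_b), tolerance = 1e-10)
})

test_that("isotropic clusters give the perpendicular-bisector boundary", {
  set.seed(31)
  n <- 4000
  lat0 <- matrix(rnorm(n * 2), n)
  lat1 <- sweep(matrix(rnorm(n * 2), n), 2, c(2, 1), `+`)
  bd <- fit_lda_boundary(rbind(lat0, lat1), rep(c(FALSE, TRUE), each = n))
  dir <- c(2, 1) / sqrt(5)
  expect_equal(abs(sum(bd$normal * dir)), 1, tolerance = 0.05)
})

test_that("the closed-form score equals the explicit three-stage projection", {
  co <- small_cohort(seed = 37)
  fit <- suppressWarnings(fit_biotype(co$beta, co$annotation, co$clinical,
                                      config = pipeline_config(n_iter = 30,
                                                               top_k = 40)))
  m <- fit$model
  regs <- fit$regions$values[, m$regions]
  # explicit path: regions -> PCA -> CCA -> discriminant
  lat <- project_latent(m$correlates, regs)
  explicit <- drop(lat %*% m$boundary$normal) + m$boundary$intercept
  closed <- biotype_score(m, regs)
  expect_lt(max(abs(closed - explicit)), 1e-10)
  # linearity: doubling the centered regions doubles the centered score
  centered <- sweep(regs, 2, m$center)
  doubled <- sweep(2 * centered, 2, m$center, `+`)
  rownames(doubled) <- rownames(regs)
  expect_equal(biotype_score(m, doubled) - m$intercept,
               2 * (closed - m$intercept), tolerance = 1e-8)
  # a sample at the training mean sits at the latent origin
  mu <- matrix(m$center[m$regions], nrow = 1,
               dimnames = list("mu", m$regions))
  expect_equal(unname(drop(project_latent(m$correlates, mu))), c(0, 0),
               tolerance = 1e-8)
})

test_that("a zero score is labelled G1 (the tie falls on 'otherwise')", {
  # minimal hand-built model: one region, unit weight, zero intercept
  correlates <- structure(list(
    pca_gene = structure(list(center = c(r1 = 0.5), scale = NULL,
                              rotation = matrix(1, 1, 1,
                                                dimnames = list("r1", NULL)),
                              n_pcs = 1L), class = "pca_model"),
    cca = structure(list(xcoef = matrix(1, 1, 1), xcenter = 0, cor = 1),
                    class = "cca_model"),
    regions = "r1"), class = "correlate_model")
  boundary <- structure(list(normal = 1, intercept = 0),
                        class = "lda_boundary")
  m <- biotype_model(correlates, boundary)
  regs <- matrix(c(0.5, 0.4, 0.6), ncol = 1,
                 dimnames = list(c("tie", "below", "above"), "r1"))
  a <- assign_biotype(m, regs)
  expect_equal(a$score, c(0, -0.1, 0.1), tolerance = 1e-12)
  expect_identical(a$biotype, c("G1", "G2", "G1"))
})

test_that("assignment follows the sign rule and honours control flags", {
  co <- small_cohort(seed = 41)
  fit <- suppressWarnings(fit_biotype(co$beta, co$annotation, co$clinical,
                                      config = pipeline_config(n_iter = 30,
                                                               top_k = 40)))
  m <- fit$model
  regs <- fit$regions$values[, m$regions]
  is_case <- co$clinical$diagnosis == "PTSD"
  a <- assign_biotype(m, regs, is_case = is_case)
  expect_identical(a$biotype[a$is_case],
                   ifelse(a$score[a$is_case] < 0, "G2", "G1"))
  expect_true(all(is.na(a$biotype[!a$is_case])))
  ac <- assign_biotype(m, regs, is_case = is_case, include_controls = TRUE)
  expect_false(anyNA(ac$biotype))
  # column permutation of the region matrix does not change labels
  perm <- sample(ncol(regs))
  a2 <- assign_biotype(m, regs[, perm], is_case = is_case)
  expect_identical(a$biotype, a2$biotype)
})

test_that("clinical comparison matches direct group means when covariates are orthogonal", {
  set.seed(33)
  n <- 60
  assignment <- data.frame(sample_id = sprintf("S%03d", 1:n),
                           score = rnorm(n),
                           x = 0, y = 0, is_case = TRUE,
                           biotype = rep(c("G1", "G2"), each = n / 2),
                           stringsAsFactors = FALSE)
  g2 <- assignment$biotype == "G2"
  covs <- matrix(rnorm(n * 2), n)
  covs <- covs - outer(g2 - mean(g2), colSums(covs * (g2 - mean(g2))) /
                         sum((g2 - mean(g2))^2))   # orthogonal to biotype
  clin <- data.frame(feat_1 = rnorm(n) + 1.5 * g2,
                     feat_2 = rnorm(n),
                     const = rep(1, n),
                     bmi = covs[, 1] + 27, age = covs[, 2] + 40)
  rownames(clin) <- assignment$sample_id
  out <- compare_clinical_by_biotype(assignment, clin,
                                     features = c("feat_1", "feat_2", "const"))
  direct <- mean(clin$feat_1[g2]) - mean(clin$feat_1[!g2])
  expect_equal(out$estimate[out$feature == "feat_1"], direct,
               tolerance = 1e-8)
  expect_true(out$degenerate[out$feature == "const"])
  expect_equal(out$p[out$feature == "const"], 1)
  # BH adjustment equals the hand computation on the returned p-values
  expect_equal(out$fdr, p.adjust(out$p, "BH"))
})

test_that("Benjamini-Hochberg matches the hand-worked reference", {
  p <- c(0.001, 0.02, 0.04, 0.9)
  expect_equal(p.adjust(p, "BH"), c(0.004, 0.04, 0.04 * 4 / 3, 0.9),
               tolerance = 1e-12)
})

test_that("ternary coordinates normalize absolute subcategory correlations", {
  set.seed(34)
  n <- 200
  clin <- data.frame(caps_b = rnorm(n), caps_c = rnorm(n), caps_d = rnorm(n))
  clin$copy_d <- clin$caps_d
  clin$mix <- clin$caps_b + clin$caps_c
  clin$indep <- rnorm(n)
  tc <- ternary_coordinates(clin, c("copy_d", "mix", "indep"))
  expect_equal(unname(rowSums(tc)), rep(1, 3), tolerance = 1e-12)
  # exact copy of CAPS-D concentrates on the D corner
  expect_gt(tc["copy_d", "D"], 0.8)
  # brute-force oracle on every feature
  for (f in rownames(tc)) {
    r <- abs(sapply(c("caps_b", "caps_c", "caps_d"),
                    function(s) cor(clin[[f]], clin[[s]])))
    expect_equal(unname(tc[f, ]), unname(r / sum(r)), tolerance = 1e-12)
  }
})

test_that("the LDA direction agrees with the MASS reference implementation", {
  set.seed(35)
  n <- 50
  lat <- rbind(cbind(rnorm(n), rnorm(n, sd = 1.5)),
               cbind(rnorm(n, 2), rnorm(n, 1, 1.5)))
  colnames(lat) <- c("x", "y")
  grp <- rep(c("ctrl", "case"), each = n)
  bd <- fit_lda_boundary(lat, grp == "case")
  ref <- MASS::lda(lat, grouping = grp)$scaling[, 1]
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(abs(sum(bd$normal * ref)), 1, tolerance = 1e-8)
})
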