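# LDA biotype boundary, closed-form per-region biotype score, G1/G2
# assignment, and biotype-vs-clinical comparisons.
#
# The two-class LDA in latent (x, y) space separates the control cluster
# from the case cluster. Because the latent scores are themselves a linear
# map of the (centered) region values, the discriminant collapses to a
# single weighted sum over regions:
#
#   score(sample) = sum_i w_i * (region_i - training_mean_i) + intercept
#   w = P_gene %*% C_gene %*% normal
#
# where P_gene is the gene-block PCA loading matrix, C_gene the gene-side
# canonical coefficients, and `normal` the LDA normal vector in latent
# space. Cases with score < 0 are labelled G2 (control-distinct), otherwise
# G1 (control-like); the convention orients the normal so the control mean
# scores positive.

#' Fit a two-class LDA boundary in latent space
#'
#' Pooled within-class covariance, equal priors: the boundary passes through
#' the midpoint of the class means with normal vector
#' `solve(S_pooled, mu_case - mu_control)`. The normal is stored unit-norm
#' and oriented so the control class mean has a positive discriminant value.
#'
#' @param latent samples x 2 latent score matrix (columns x, y).
#' @param is_case logical vector: `TRUE` for cases.
#' @param ridge ridge added to a singular pooled covariance (with a message).
#' @param flip_sign flip the stored normal (and hence the score signs);
#'   exposed because the axis orientation is a convention.
#' @return list of class `lda_boundary`: `normal` (unit vector), `intercept`
#'   (so that discriminant = latent %*% normal + intercept), class means.
#' @export
fit_lda_boundary <- function(latent, is_case, ridge = 1e-8, flip_sign = FALSE) {
  latent <- as.matrix(latent)
  is_case <- as.logical(is_case)
  stopifnot(length(is_case) == nrow(latent))
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  mu0 <- colMeans(latent[!is_case, , drop = FALSE])
  mu1 <- colMeans(latent[is_case, , drop = FALSE])
  s0 <- stats::cov(latent[!is_case, , drop = FALSE])
  s1 <- stats::cov(latent[is_case, , drop = FALSE])
  n0 <- sum(!is_case); n1 <- sum(is_case)
  sp <- ((n0 - 1) * s0 + (n1 - 1) * s1) / (n0 + n1 - 2)
  normal <- tryCatch(solve(sp, mu0 - mu1), error = function(e) {
    message("singular pooled covariance; ridge-regularizing with epsilon ", ridge)
    solve(sp + diag(ridge, ncol(sp)), mu0 - mu1)
  })
  # orient: control mean on the positive side
  normal <- normal / sqrt(sum(normal^2))
  mid <- (mu0 + mu1) / 2
  if (sum((mu0 - mid) * normal) < 0) normal <- -normal
  if (flip_sign) normal <- -normal
  structure(list(normal = normal, intercept = -sum(mid * normal),
                 mu_control = mu0, mu_case = mu1, pooled_cov = sp),
            class = "lda_boundary")
}

#' Build a biotype model from a correlate model and an LDA boundary
#'
#' Folds the PCA loadings, canonical coefficients and LDA normal into the
#' closed-form per-region weight vector `w`.
#'
#' @param correlates a `correlate_model` fitted on the selected regions.
#' @param boundary an `lda_boundary` fitted on its latent scores.
#' @return object of class `biotype_model` with fields `regions`, `center`
#'   (training region means), `weights` (w), `intercept`, `boundary`,
#'   `correlates`.
#' @export
biotype_model <- function(correlates, boundary) {
  stopifnot(inherits(correlates, "correlate_model"),
            inherits(boundary, "lda_boundary"))
  p <- correlates$pca_gene$rotation              # regions x n_pcs
  cc <- correlates$cca$xcoef                     # n_pcs x n_pairs
  w <- drop(p %*% cc %*% boundary$normal)
  # centering: region means, folded with the CCA centering of the PC scores
  center <- correlates$pca_gene$center
  # latent = (pcs - xcenter) %*% xcoef; fold xcenter into the intercept
  intercept <- boundary$intercept -
    sum(correlates$cca$xcenter * drop(cc %*% boundary$normal))
  structure(list(regions = correlates$regions,
                 center = center, weights = stats::setNames(w, correlates$regions),
                 intercept = intercept, boundary = boundary,
                 correlates = correlates),
            class = "biotype_model")
}

#' Closed-form biotype score
#'
#' `score = sum_i w_i (region_i - center_i) + intercept`; identical (to
#' numerical precision) to projecting through PCA, CCA and the LDA
#' discriminant explicitly.
#'
#' @param model a `biotype_model`.
#' @param regions `region_matrix` or samples x regions matrix containing the
#'   model's regions.
#' @return named numeric vector of per-sample scores.
#' @export
biotype_score <- function(model, regions) {
  stopifnot(inherits(model, "biotype_model"))
  vals <- if (inherits(regions, "region_matrix")) regions$values else regions
  missing <- setdiff(model$regions, colnames(vals))
  if (length(missing) > 0L) {
    stop("missing regions: ", paste(utils::head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  vals <- vals[, model$regions, drop = FALSE]
  centered <- sweep(vals, 2L, model$center)
  drop(centered %*% model$weights) + model$intercept
}

#' Assign G1/G2 biotypes from biotype scores
#'
#' Cases with score < 0 are G2 (control-distinct); score >= 0 is G1
#' (control-like; a score of exactly 0 is G1). Controls receive scores but
#' are labelled only when `include_controls = TRUE`.
#'
#' @param model a `biotype_model`.
#' @param regions region values for the samples to assign.
#' @param is_case logical per sample; `NULL` treats all samples as cases.
#' @param include_controls also label non-case samples by the same rule.
#' @return data.frame: `sample_id`, `score`, `x`, `y`, `is_case`, `biotype`
#'   (`G1`/`G2`, `NA` for unlabelled controls).
#' @export
assign_biotype <- function(model, regions, is_case = NULL,
                           include_controls = FALSE) {
  vals <- if (inherits(regions, "region_matrix")) regions$values else regions
  score <- biotype_score(model, regions)
  latent <- project_latent(model$correlates, vals)
  n <- length(score)
  if (is.null(is_case)) is_case <- rep(TRUE, n)
  lab <- ifelse(score < 0, "G2", "G1")
  lab[!is_case & !include_controls] <- NA_character_
  data.frame(sample_id = rownames(vals) %||% seq_len(n),
             score = unname(score),
             x = unname(latent[, 1L]),
             y = unname(latent[, min(2L, ncol(latent))]),
             is_case = is_case,
             biotype = lab,
             stringsAsFactors = FALSE)
}

#' Compare clinical features between biotypes with covariate adjustment
#'
#' Per feature, fits `feature ~ biotype + covariates` by ordinary least
#' squares and reports the biotype coefficient, its two-sided p-value and
#' the Benjamini-Hochberg FDR across the feature family. Degenerate
#' (constant) features get coefficient 0 and p = 1, flagged.
#'
#' @param assignment output of [assign_biotype()] (cases labelled G1/G2).
#' @param clinical clinical table (rownames = sample ids).
#' @param features feature columns to compare (default: auto-detected).
#' @param covariates adjustment columns (default BMI and age).
#' @return data.frame: feature, estimate (G2 minus G1), p, fdr, degenerate.
#' @export
compare_clinical_by_biotype <- function(assignment, clinical, features = NULL,
                                        covariates = c("bmi", "age")) {
  features <- features %||% clinical_feature_columns(clinical)
  cases <- assignment[!is.na(assignment$biotype), ]
  if (min(table(cases$biotype)) < 3L) {
    stop("need at least 3 samples per biotype", call. = FALSE)
  }
  clin <- align_samples(clinical, cases$sample_id, "clinical table")
  g2 <- as.numeric(cases$biotype == "G2")
  covmat <- as.matrix(clin[, covariates, drop = FALSE])
  # drop collinear covariates
  X <- cbind(1, g2, covmat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_ix <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping collinear covariate(s): ",
            paste(colnames(X)[drop_ix], collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  res <- lapply(features, function(f) {
    yv <- clin[[f]]
    if (stats::sd(yv) == 0) {
      return(data.frame(feature = f, estimate = 0, p = 1, degenerate = TRUE))
    }
    fit <- stats::lm.fit(X, yv)
    cf <- fit$coefficients["g2"]
    rdf <- fit$df.residual
    sigma2 <- sum(fit$residuals^2) / rdf
    XtXinv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(sigma2 * XtXinv[2L, 2L])
    tval <- cf / se
    data.frame(feature = f, estimate = unname(cf),
               p = 2 * stats::pt(-abs(tval), rdf), degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[, c("feature", "estimate", "p", "fdr", "degenerate")]
}

#' Ternary similarity coordinates of clinical features
#'
#' Expresses each feature's relative similarity to three core symptom
#' subcategories (e.g. CAPS B/C/D) as normalized absolute correlations:
#' `coord_k = |r(feature, sub_k)| / sum_k |r(feature, sub_k)|`.
#'
#' @param clinical clinical table.
#' @param features feature columns to place.
#' @param caps_b,caps_c,caps_d names of the three subcategory columns.
#' @return matrix features x 3, rows summing to 1; features uncorrelated
#'   with all three subcategories get (1/3, 1/3, 1/3) and a warning.
#' @export
ternary_coordinates <- function(clinical, features, caps_b = "caps_b",
                                caps_c = "caps_c", caps_d = "caps_d") {
  subs <- c(caps_b, caps_c, caps_d)
  stopifnot(all(subs %in% colnames(clinical)))
  out <- t(vapply(features, function(f) {
    r <- abs(vapply(subs, function(s) safe_cor(clinical[[f]], clinical[[s]]),
                    numeric(1L)))
    if (sum(r) == 0) {
      warning("feature ", f, " uncorrelated with all three subcategories; ",
              "uniform coordinates")
      return(rep(1 / 3, 3L))
    }
    r / sum(r)
  }, numeric(3L)))
  colnames(out) <- c("B", "C", "D")
  out
}

## ---- the umbrella model ----

#' Fit the full epigenetic biotype model
#'
#' Runs the discovery pipeline end to end: probe filtering, region
#' collapsing (and optional recall-stability filtering), the resampled
#' clinical-association screen, PCA+CCA latent composites, and the LDA
#' biotype boundary with its closed-form per-region weights.
#'
#' @param beta samples x probes beta matrix.
#' @param annotation probe annotation (`probe_id`, `gene`, `region_class`).
#' @param clinical clinical table (rownames = sample ids) with a `diagnosis`
#'   column distinguishing cases from controls.
#' @param config a [pipeline_config()] list of thresholds and sizes.
#' @param recall optional recall assay: list with `beta` and
#'   `stable_sample_ids` (see [preprocess_beta()]).
#' @param case_label value of `diagnosis` identifying cases (default
#'   `"PTSD"`; anything else is control).
#' @return object of class `biotype_fit`: the `biotype_model` plus the
#'   intermediate `regions`, `screen`, and training `assignment`.
#' @examples
#' cohort <- generate_cohort(synth_config(n_control = 40, n_g1 = 20,
#'                                        n_g2 = 20, n_genes = 300, seed = 3))
#' fit <- fit_biotype(cohort$beta, cohort$annotation, cohort$clinical,
#'                    config = pipeline_config(n_iter = 20, top_k = 40))
#' table(fit$assignment$biotype, useNA = "ifany")
#' @export
fit_biotype <- function(beta, annotation, clinical,
                        config = pipeline_config(), recall = NULL,
                        case_label = "PTSD") {
  cfg <- config
  clinical <- align_samples(clinical, rownames(beta), "clinical table")
  regions <- preprocess_beta(beta, annotation,
                             sd_min = cfg$sd_min, mean_lo = cfg$mean_lo,
                             mean_hi = cfg$mean_hi, r_thresh = cfg$r_collapse,
                             scope = cfg$collapse_scope, recall = recall,
                             r_recall = cfg$r_recall)
  screen <- cv_frequency_ranking(regions, clinical,
                                 r_clin = cfg$r_clin, r_conf = cfg$r_conf,
                                 n_iter = cfg$n_iter, leave_out = cfg$leave_out,
                                 top_k = cfg$top_k,
                                 seed = sub_seed(cfg$seed, "screen"))
  sel <- regions$values[, screen$selected, drop = FALSE]
  correlates <- fit_correlates(sel, clinical,
                               n_pcs_gene = cfg$n_pcs_gene,
                               n_pcs_clin = cfg$n_pcs_clin,
                               n_pairs = cfg$n_cca_pairs,
                               alpha = cfg$wilks_alpha,
                               severity_col = cfg$severity_col)
  is_case <- clinical$diagnosis == case_label
  # the discriminant uses only the canonical pairs that pass the Wilks gate
  # (a non-significant pair is a noise direction the LDA would overfit);
  # the first pair is always kept
  use <- if (isTRUE(cfg$lda_significant_only)) {
    which(correlates$cca$significant | seq_along(correlates$cca$significant) == 1L)
  } else {
    seq_along(correlates$cca$significant)
  }
  # The boundary discriminates a control-like cluster from a distinct
  # cluster in latent space. Under "cluster" labels (default) the clusters
  # come from 2-means on the latent scores -- cases overlapping the control
  # cluster then sit on the control side, which is what makes them the
  # control-like biotype. Under "diagnosis" labels the LDA uses the
  # case/control flags directly.
  lda_labels <- if (identical(cfg$boundary_labels, "diagnosis")) {
    is_case
  } else {
    set.seed(sub_seed(cfg$seed, "boundary"))
    km <- stats::kmeans(correlates$latent[, use, drop = FALSE], centers = 2L,
                        nstart = 25L)
    ctrl_cluster <- as.integer(names(which.max(table(km$cluster[!is_case]))))
    km$cluster != ctrl_cluster
  }
  boundary <- fit_lda_boundary(correlates$latent[, use, drop = FALSE],
                               lda_labels, flip_sign = cfg$flip_sign)
  if (length(use) < ncol(correlates$latent)) {
    full <- numeric(ncol(correlates$latent))
    full[use] <- boundary$normal
    boundary$normal <- full
  }
  model <- biotype_model(correlates, boundary)
  assignment <- assign_biotype(model, sel, is_case = is_case)
  structure(list(model = model, regions = regions, screen = screen,
                 assignment = assignment, config = cfg),
            class = "biotype_fit")
}

#' @export
print.biotype_fit <- function(x, ...) {
  cat("Epigenetic biotype model\n")
  cat(sprintf("  regions after preprocessing: %d; selected: %d\n",
              ncol(x$regions$values), length(x$model$regions)))
  cat(sprintf("  canonical correlations: %s\n",
              paste(sprintf("%.3f", x$model$correlates$cca$cor), collapse = ", ")))
  nv <- x$model$boundary$normal
  cat(sprintf("  LDA boundary: %.3f x + %.3f y + %.3f = 0\n",
              nv[1L], nv[2L], x$model$boundary$intercept))
  tab <- table(x$assignment$biotype, useNA = "no")
  cat(sprintf("  training cases: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
summary.biotype_fit <- function(object, ...) {
  print(object)
  cat("\nWilks' lambda tests:\n")
  print(object$model$correlates$cca$wilks, row.names = FALSE)
  cat("\nTop selected regions:\n")
  print(utils::head(object$screen$ranking, 10L), row.names = FALSE)
  invisible(object)
}

#' Per-region biotype weights of a fitted model
#' @param object a `biotype_fit`.
#' @param ... unused.
#' @export
coef.biotype_fit <- function(object, ...) object$model$weights

#' Assign biotypes in a new cohort with a fitted model
#'
#' Collapses the new cohort's probes into the model's regions (using the
#' training membership map), projects with the training centering, and
#' applies the sign rule. No refitting takes place.
#'
#' @param object a `biotype_fit`.
#' @param beta new samples x probes beta matrix (must contain the member
#'   probes of the model's regions).
#' @param is_case optional logical; default labels every sample.
#' @param include_controls label non-cases too.
#' @param ... unused.
#' @return the [assign_biotype()] data.frame for the new samples.
#' @export
predict.biotype_fit <- function(object, beta, is_case = NULL,
                                include_controls = FALSE, ...) {
  vals <- regionize(beta, object$regions$membership[object$model$regions])
  assign_biotype(object$model, vals, is_case = is_case,
                 include_controls = include_controls)
}

# Average probe columns into the given regions (membership: region -> probes).
regionize <- function(beta, membership) {
  need <- unique(unlist(membership))
  missing <- setdiff(need, colnames(beta))
  if (length(missing) > 0L) {
    stop("new cohort missing probes: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  vals <- vapply(membership, function(pr) {
    rowMeans(beta[, pr, drop = FALSE])
  }, numeric(nrow(beta)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L,
                                         dimnames = list(rownames(beta), names(membership)))
  vals
}
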