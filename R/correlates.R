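# Latent gene-clinical composites: PCA on each block, then CCA on the PCs.
#
# The gene block (selected methylation regions, shared beta units) is
# centered but not scaled; the clinical block (heterogeneous instruments)
# is z-scored. Both blocks are reduced to a few PCs before CCA so the
# subject-to-feature ratio stays high enough to stabilize the canonical
# loadings.

#' Fit a PCA model that remembers its training centering
#'
#' @param x samples x features numeric matrix.
#' @param n_pcs number of components to keep.
#' @param standardize if `TRUE`, features are scaled to unit variance
#'   (training scales stored for later projection).
#' @return object of class `pca_model`: `center`, `scale` (or NULL),
#'   `rotation` (features x n_pcs, orthonormal columns), `ev_fraction`
#'   (explained-variance fractions, non-increasing).
#' @export
fit_pca <- function(x, n_pcs, standardize = FALSE) {
  x <- as.matrix(x)
  if (n_pcs > min(nrow(x) - 1L, ncol(x))) {
    stop("n_pcs exceeds min(n_samples - 1, n_features)", call. = FALSE)
  }
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance feature(s) with standardize = TRUE: ",
           paste(utils::head(colnames(x)[sds == 0], 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(center = pc$center,
                 scale = if (standardize) pc$scale else NULL,
                 rotation = pc$rotation[, seq_len(n_pcs), drop = FALSE],
                 ev_fraction = ev[seq_len(n_pcs)],
                 n_pcs = n_pcs),
            class = "pca_model")
}

#' Project data through a fitted PCA model
#' @param object a `pca_model`.
#' @param newdata samples x features matrix with the training features.
#' @param ... unused.
#' @return samples x n_pcs score matrix.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, rownames(object$rotation), drop = FALSE]
  x <- sweep(x, 2L, object$center)
  if (!is.null(object$scale)) x <- sweep(x, 2L, object$scale, `/`)
  x %*% object$rotation
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d features -> %d PCs (%.1f%% variance)\n",
              nrow(x$rotation), x$n_pcs, 100 * sum(x$ev_fraction)))
  invisible(x)
}

#' Canonical correlation analysis between two PC score blocks
#'
#' Fits CCA maximizing the correlation between linear combinations of the
#' two blocks under the usual orthogonality constraints, and tests the
#' number of significant canonical dimensions with Wilks' lambda (Bartlett's
#' chi-square approximation). Coefficients are scaled so each training
#' canonical variate has unit variance. Signs are arbitrary in CCA; when a
#' `severity` vector is given, each pair is flipped so its x-side variate
#' correlates positively with severity.
#'
#' @param x,y samples x p / samples x q score matrices (same samples).
#' @param n_pairs canonical pairs to retain (default 2).
#' @param alpha Wilks' lambda significance gate (default 1e-4); pairs
#'   failing it are retained but flagged.
#' @param severity optional per-sample severity score used to fix signs.
#' @return object of class `cca_model`: `xcoef` (p x n_pairs), `ycoef`
#'   (q x n_pairs), `xcenter`, `ycenter`, `cor` (canonical correlations),
#'   `wilks` (data.frame: lambda, chisq, df, p), `significant` flags.
#' @export
fit_cca <- function(x, y, n_pairs = 2L, alpha = 1e-4, severity = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  p <- ncol(x); q <- ncol(y); n <- nrow(x)
  if (n_pairs > min(p, q)) stop("n_pairs exceeds block ranks", call. = FALSE)
  if (qr(scale(x, scale = FALSE))$rank < p || qr(scale(y, scale = FALSE))$rank < q) {
    stop("rank-deficient block; reduce the number of PCs", call. = FALSE)
  }
  cc <- stats::cancor(x, y)

  d <- min(p, q)
  rho <- cc$cor[seq_len(d)]
  # Bartlett: chi2_k = -(n - 1 - (p+q+1)/2) * log prod_{i>=k} (1 - rho_i^2)
  lambda <- rev(cumprod(rev(1 - rho^2)))
  mult <- n - 1 - (p + q + 1) / 2
  chisq <- -mult * log(lambda)
  df <- (p - seq_len(d) + 1) * (q - seq_len(d) + 1)
  pval <- stats::pchisq(chisq, df, lower.tail = FALSE)
  wilks <- data.frame(pair = seq_len(d), lambda = lambda, chisq = chisq,
                      df = df, p = pval)

  keep <- seq_len(n_pairs)
  xcoef <- cc$xcoef[, keep, drop = FALSE]
  ycoef <- cc$ycoef[, keep, drop = FALSE]
  # rescale so training variates have unit variance
  u <- scale(x, center = cc$xcenter, scale = FALSE) %*% xcoef
  v <- scale(y, center = cc$ycenter, scale = FALSE) %*% ycoef
  xcoef <- sweep(xcoef, 2L, apply(u, 2L, stats::sd), `/`)
  ycoef <- sweep(ycoef, 2L, apply(v, 2L, stats::sd), `/`)

  if (!is.null(severity)) {
    v <- scale(y, center = cc$ycenter, scale = FALSE) %*% ycoef
    for (k in keep) {
      r <- safe_cor(v[, k], severity)
      if (r < 0) {
        xcoef[, k] <- -xcoef[, k]
        ycoef[, k] <- -ycoef[, k]
      }
    }
  }
  colnames(xcoef) <- colnames(ycoef) <- paste0("pair", keep)
  structure(list(xcoef = xcoef, ycoef = ycoef,
                 xcenter = cc$xcenter, ycenter = cc$ycenter,
                 cor = rho[keep], wilks = wilks,
                 significant = pval[keep] < alpha, alpha = alpha),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat("CCA model\n")
  for (k in seq_along(x$cor)) {
    cat(sprintf("  pair %d: r = %.3f, Wilks p = %.3g%s\n", k, x$cor[k],
                x$wilks$p[k], if (x$significant[k]) "" else " (not significant)"))
  }
  invisible(x)
}

#' Fit the gene-clinical correlate model (PCA blocks + CCA)
#'
#' Runs PCA on the selected methylation regions (centered, unscaled) and on
#' the clinical features (z-scored), then CCA on the two PC score blocks.
#' The first canonical pair is interpreted as the "Psychological" axis and
#' the second as the "Physical-Dissociative" axis; signs are fixed so the
#' gene-side variates correlate positively with the severity column.
#'
#' @param regions `region_matrix` or samples x regions matrix restricted to
#'   the screened regions.
#' @param clinical clinical table (rownames = sample ids).
#' @param features clinical feature columns (default: auto-detected).
#' @param n_pcs_gene,n_pcs_clin PCs per block (defaults 4 and 6).
#' @param n_pairs canonical pairs (default 2).
#' @param alpha Wilks' gate (default 1e-4).
#' @param severity_col clinical column used to orient signs
#'   (default `"caps_total"`; set NULL to skip).
#' @return object of class `correlate_model`: `pca_gene`, `pca_clin`, `cca`,
#'   `regions` (region ids used), plus the training `latent` scores.
#' @export
fit_correlates <- function(regions, clinical, features = NULL,
                           n_pcs_gene = 4L, n_pcs_clin = 6L, n_pairs = 2L,
                           alpha = 1e-4, severity_col = "caps_total") {
  vals <- if (inherits(regions, "region_matrix")) regions$values else regions
  features <- features %||% clinical_feature_columns(clinical)
  clin <- align_samples(clinical, rownames(vals), "clinical table")
  ratio <- nrow(vals) / (n_pcs_gene + n_pcs_clin)
  if (ratio < 20) {
    warning(sprintf("subject-to-feature ratio %.1f < 20; canonical loadings may be unstable",
                    ratio))
  }
  pca_gene <- fit_pca(vals, n_pcs_gene, standardize = FALSE)
  pca_clin <- fit_pca(as.matrix(clin[, features, drop = FALSE]), n_pcs_clin,
                      standardize = TRUE)
  gene_pcs <- predict(pca_gene, vals)
  clin_pcs <- predict(pca_clin, as.matrix(clin[, features, drop = FALSE]))
  severity <- if (!is.null(severity_col) && severity_col %in% colnames(clin)) {
    clin[[severity_col]]
  } else NULL
  cca <- fit_cca(gene_pcs, clin_pcs, n_pairs = n_pairs, alpha = alpha,
                 severity = severity)
  model <- structure(list(pca_gene = pca_gene, pca_clin = pca_clin, cca = cca,
                          regions = colnames(vals), features = features),
                     class = "correlate_model")
  model$latent <- project_latent(model, vals)
  model
}

#' Project samples into the latent DNAm composite space
#'
#' Computes the latent methylation scores x ("Psychological") and y
#' ("Physical-Dissociative"): centered region values through the gene-block
#' PCA loadings, then the gene-side canonical coefficients. New cohorts are
#' centered with the training means; there is no per-cohort re-centering.
#'
#' @param model a `correlate_model`.
#' @param regions `region_matrix` or samples x regions matrix containing the
#'   model's regions.
#' @return samples x n_pairs matrix of latent scores (columns `x`, `y` for
#'   the first two pairs).
#' @export
project_latent <- function(model, regions) {
  stopifnot(inherits(model, "correlate_model"))
  vals <- if (inherits(regions, "region_matrix")) regions$values else regions
  missing <- setdiff(model$regions, colnames(vals))
  if (length(missing) > 0L) {
    stop("missing regions: ", paste(utils::head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  vals <- vals[, model$regions, drop = FALSE]
  gene_pcs <- predict(model$pca_gene, vals)
  scores <- sweep(gene_pcs, 2L, model$cca$xcenter) %*% model$cca$xcoef
  cn <- c("x", "y", paste0("pair", seq_len(ncol(scores))))[seq_len(ncol(scores))]
  if (ncol(scores) >= 2L) cn[1:2] <- c("x", "y")
  colnames(scores) <- cn
  scores
}

#' Clinical-side composite scores for the training features
#'
#' @param model a `correlate_model`.
#' @param clinical clinical table covering the model's feature columns.
#' @return samples x n_pairs matrix of clinical composite scores.
#' @export
project_clinical <- function(model, clinical) {
  stopifnot(inherits(model, "correlate_model"))
  clin <- as.matrix(clinical[, model$features, drop = FALSE])
  pcs <- predict(model$pca_clin, clin)
  sweep(pcs, 2L, model$cca$ycenter) %*% model$cca$ycoef
}

#' @export
print.correlate_model <- function(x, ...) {
  cat(sprintf("Gene-clinical correlate model: %d regions, %d clinical features\n",
              length(x$regions), length(x$features)))
  cat(sprintf("  gene PCs: %d; clinical PCs: %d\n",
              x$pca_gene$n_pcs, x$pca_clin$n_pcs))
  print(x$cca)
  invisible(x)
}
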