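# Covariate-adjusted differential methylation with empirical-Bayes variance
# moderation, and gene-level DMG calling.
#
# Per probe, beta is regressed on a case indicator plus covariates by least
# squares. Residual variances are shrunk toward a pooled prior estimated by
# method of moments on the log residual variances (the scaled-F model):
#
#   s2_tilde = (d0 * s0^2 + d * s^2) / (d0 + d)
#   t_mod    = coef / (se_unit * s_tilde),  df = d0 + d
#
# where d is the residual df, and (d0, s0^2) are the prior df and variance.

#' Moderated t-tests for differential methylation
#'
#' @param beta samples x probes beta matrix.
#' @param is_case logical per sample: `TRUE` = case group of the contrast.
#' @param covariates optional samples x k numeric matrix/data.frame of
#'   adjustment covariates (e.g. cell fractions, ancestry PCs, age).
#' @param d0 optional prior degrees of freedom override: `0` gives ordinary
#'   t-tests (no shrinkage), `Inf` complete shrinkage to the pooled
#'   variance; `NULL` (default) estimates d0 from the data.
#' @return object of class `dm_result`: data.frame `table` (probe,
#'   delta_beta, t, t_mod, p, direction), plus `d0`, `s0_sq`, `df_residual`,
#'   `df_total`.
#' @export
moderated_ttest <- function(beta, is_case, covariates = NULL, d0 = NULL) {
  beta <- as.matrix(beta)
  is_case <- as.logical(is_case)
  stopifnot(length(is_case) == nrow(beta))
  X <- cbind(intercept = 1, case = as.numeric(is_case))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient (collinear covariates?)", call. = FALSE)
  }
  n <- nrow(X)
  df <- n - ncol(X)
  if (df < 2L) stop("need at least 2 residual degrees of freedom", call. = FALSE)

  coefs <- qr.coef(qrX, beta)           # p x probes
  resid <- beta - X %*% coefs
  s2 <- colSums(resid^2) / df
  v_case <- chol2inv(chol(crossprod(X)))[2L, 2L] # unit variance of the case coef
  b <- coefs["case", ]
  t_ord <- b / sqrt(s2 * v_case)

  if (is.null(d0)) {
    fit <- fit_f_dist(s2, df)
    d0 <- fit$d0
    s0_sq <- fit$s0_sq
    if (is.na(d0)) {
      warning("prior df estimation failed; falling back to ordinary t-tests")
      d0 <- 0
      s0_sq <- NA_real_
    }
  } else {
    s0_sq <- if (is.infinite(d0)) mean(s2) else mean(s2)
  }
  s2_tilde <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    if (d0 == 0) s2 else (d0 * s0_sq + df * s2) / (d0 + df)
  }
  df_total <- if (is.infinite(d0)) n - 1 else d0 + df  # cap at a finite df downstream
  t_mod <- b / sqrt(s2_tilde * v_case)
  p <- 2 * stats::pt(-abs(t_mod), df = min(df_total, 1e6))

  delta <- colMeans(beta[is_case, , drop = FALSE]) -
    colMeans(beta[!is_case, , drop = FALSE])
  tab <- data.frame(probe = colnames(beta),
                    delta_beta = unname(delta),
                    t = unname(t_ord), t_mod = unname(t_mod), p = unname(p),
                    direction = ifelse(delta > 0, "hyper", "hypo"),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, d0 = d0, s0_sq = s0_sq,
                 df_residual = df, df_total = df_total),
            class = "dm_result")
}

# Method-of-moments fit of the scaled-F model to residual variances:
# log s^2 has mean log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) +
# log(d0/2) and excess variance trigamma(d0/2) beyond trigamma(d/2).
fit_f_dist <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2L) return(list(d0 = NA_real_, s0_sq = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(ev)) return(list(d0 = NA_real_, s0_sq = NA_real_))
  if (ev <= 0) {
    # no dispersion beyond sampling noise: infinite prior df
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(ev)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(x) = y by Newton iteration on the decreasing convex map.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' @export
print.dm_result <- function(x, ...) {
  cat(sprintf("Differential methylation: %d probes, residual df = %d\n",
              nrow(x$table), x$df_residual))
  cat(sprintf("  prior df d0 = %s, prior variance s0^2 = %s\n",
              format(x$d0, digits = 4), format(x$s0_sq, digits = 4)))
  if (!is.null(x$genes)) {
    cat(sprintf("  DMPs: %d; DMGs: %d (%d hyper, %d hypo)\n",
                sum(x$table$dmp), nrow(x$genes[x$genes$dmg, ]),
                sum(x$genes$direction == "hyper" & x$genes$dmg),
                sum(x$genes$direction == "hypo" & x$genes$dmg)))
  }
  invisible(x)
}

#' Call differentially methylated probes and genes
#'
#' A probe is a DMP when `p < p_cut` and `|delta_beta| > d_cut`. A gene is a
#' DMG when at least one member probe is a DMP; its direction is that of
#' the member DMP with the largest `|delta_beta|` (or the majority
#' direction, with ties broken by the largest-effect probe).
#'
#' @param result a `dm_result`.
#' @param annotation probe annotation mapping probes to genes.
#' @param p_cut p-value cutoff (default 0.01).
#' @param d_cut absolute beta-difference cutoff (default 0.02).
#' @param direction_mode `"max_effect"` (default) or `"majority"`.
#' @return the `dm_result` with `dmp` flags added to `table` and a `genes`
#'   data.frame (gene, dmg, direction, n_dmp) plus a `counts` summary.
#' @export
call_dmg <- function(result, annotation, p_cut = 0.01, d_cut = 0.02,
                     direction_mode = c("max_effect", "majority")) {
  stopifnot(inherits(result, "dm_result"))
  direction_mode <- match.arg(direction_mode)
  tab <- result$table
  tab$dmp <- tab$p < p_cut & abs(tab$delta_beta) > d_cut
  tab$gene <- annotation$gene[match(tab$probe, annotation$probe_id)]
  tab$gene[is.na(tab$gene)] <- ""

  dmp_tab <- tab[tab$dmp & tab$gene != "", , drop = FALSE]
  genes <- unique(tab$gene[tab$gene != ""])
  gene_dir <- vapply(split(dmp_tab, dmp_tab$gene), function(d) {
    if (direction_mode == "majority") {
      nh <- sum(d$direction == "hyper")
      nl <- nrow(d) - nh
      if (nh != nl) return(if (nh > nl) "hyper" else "hypo")
    }
    d$direction[which.max(abs(d$delta_beta))]
  }, "")
  gene_n <- table(dmp_tab$gene)
  genes_df <- data.frame(gene = genes,
                         dmg = genes %in% names(gene_dir),
                         direction = gene_dir[genes],
                         n_dmp = as.integer(gene_n[genes]),
                         row.names = NULL, stringsAsFactors = FALSE)
  genes_df$direction[!genes_df$dmg] <- NA_character_
  genes_df$n_dmp[is.na(genes_df$n_dmp)] <- 0L

  result$table <- tab
  result$genes <- genes_df
  result$counts <- c(dmp = sum(tab$dmp),
                     dmg = sum(genes_df$dmg),
                     hyper = sum(genes_df$dmg & genes_df$direction == "hyper",
                                 na.rm = TRUE),
                     hypo = sum(genes_df$dmg & genes_df$direction == "hypo",
                                na.rm = TRUE))
  result$params <- list(p_cut = p_cut, d_cut = d_cut,
                        direction_mode = direction_mode)
  result
}

#' Write a differential-methylation table as TSV
#' @param result a `dm_result` (after [call_dmg()] for dmp/gene columns).
#' @param path output TSV.
#' @export
write_dm_result <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
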