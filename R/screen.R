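# Clinical-association screen with resampled frequency ranking.
#
# A region is clinically informative when it correlates modestly
# (|r| > r_clin) with at least one of the declared clinical features while
# staying unassociated (|r| <= r_conf) with every declared confounder
# (age, ancestry PCs, BMI, cell composition, smoking, alcohol, deployments).
# The choice is stabilized by a leave-k-out resampling scheme: the scan is
# re-run with a few samples removed, and regions are ranked by how often
# they pass.

#' Declared confounder columns of a clinical table
#'
#' @param clinical clinical table.
#' @return character vector of the confounder columns present.
#' @export
confounder_columns <- function(clinical) {
  cand <- c("age", "bmi", paste0("cell_", 1:5), paste0("ancestry_pc", 1:3),
            "smoking", "alcohol_audit", "deployments")
  intersect(cand, colnames(clinical))
}

#' Default clinical feature columns of a clinical table
#'
#' The 34 symptom/function scores; everything that is neither a covariate,
#' an id, a diagnosis label, nor a severity total.
#' @param clinical clinical table.
#' @export
clinical_feature_columns <- function(clinical) {
  drop <- c("sample_id", confounder_columns(clinical),
            "diagnosis", "caps_total", "pcl_total_score")
  setdiff(colnames(clinical), drop)
}

#' Scan regions for clinical association free of confounding
#'
#' Returns regions whose maximum absolute Pearson correlation with the
#' clinical features exceeds `r_clin` while the maximum absolute correlation
#' with every confounder stays at or below `r_conf`. Constant regions or
#' features contribute r = 0.
#'
#' @param regions `region_matrix` (or samples x regions numeric matrix).
#' @param clinical clinical table with rownames = sample ids.
#' @param features clinical feature columns (default: auto-detected 34).
#' @param confounders confounder columns (default: auto-detected).
#' @param r_clin clinical-association threshold (default 0.2, strict >).
#' @param r_conf confounder-association ceiling (default 0.2, inclusive <=).
#' @param details if `TRUE`, return a data.frame with per-region max |r|
#'   values and pass flags instead of just the passing ids.
#' @return character vector of passing region ids (or a data.frame).
#' @export
clinical_association_scan <- function(regions, clinical, features = NULL,
                                      confounders = NULL,
                                      r_clin = 0.2, r_conf = 0.2,
                                      details = FALSE) {
  vals <- if (inherits(regions, "region_matrix")) regions$values else regions
  features <- features %||% clinical_feature_columns(clinical)
  confounders <- confounders %||% confounder_columns(clinical)
  clin <- align_samples(clinical, rownames(vals), "clinical table")

  fmat <- as.matrix(clin[, features, drop = FALSE])
  cmat <- as.matrix(clin[, confounders, drop = FALSE])
  r_f <- abs(safe_cor_matrix(vals, fmat))
  r_c <- abs(safe_cor_matrix(vals, cmat))
  max_clin <- apply(r_f, 1L, max)
  max_conf <- apply(r_c, 1L, max)
  pass <- max_clin > r_clin & max_conf <= r_conf
  if (details) {
    return(data.frame(region = colnames(vals), max_r_clin = max_clin,
                      max_r_conf = max_conf, pass = pass,
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  colnames(vals)[pass]
}

#' Stabilize the clinical scan by leave-k-out frequency ranking
#'
#' Repeats the clinical association scan `n_iter` times, each time removing
#' `leave_out` samples drawn uniformly without replacement, and ranks
#' regions by the frequency with which they pass. Ties are broken by the
#' full-sample maximum clinical |r| (descending), then by region id.
#'
#' @inheritParams clinical_association_scan
#' @param n_iter number of resampling iterations (default 5000).
#' @param leave_out samples removed per iteration (default 5).
#' @param top_k regions to select (default 100).
#' @param seed integer seed; each iteration uses its own substream so the
#'   first iterations are identical whatever `n_iter` is.
#' @return object of class `screen_result`: list with `selected` (top_k
#'   region ids), `ranking` (data.frame region/frequency/rank/max_r_clin/
#'   max_r_conf) and the call parameters.
#' @export
cv_frequency_ranking <- function(regions, clinical, features = NULL,
                                 confounders = NULL, r_clin = 0.2,
                                 r_conf = 0.2, n_iter = 5000L,
                                 leave_out = 5L, top_k = 100L, seed = 1L) {
  vals <- if (inherits(regions, "region_matrix")) regions$values else regions
  stopifnot(n_iter >= 1L, leave_out < nrow(vals))
  features <- features %||% clinical_feature_columns(clinical)
  confounders <- confounders %||% confounder_columns(clinical)
  clin <- align_samples(clinical, rownames(vals), "clinical table")

  n <- nrow(vals)
  hits <- stats::setNames(numeric(ncol(vals)), colnames(vals))
  for (it in seq_len(n_iter)) {
    set.seed(sub_seed(seed, paste0("screen_iter_", it)))
    keep <- if (leave_out > 0L) {
      setdiff(seq_len(n), sample.int(n, leave_out))
    } else seq_len(n)
    pass <- clinical_association_scan(vals[keep, , drop = FALSE],
                                      clin[keep, , drop = FALSE],
                                      features, confounders, r_clin, r_conf)
    hits[pass] <- hits[pass] + 1
  }
  freq <- hits / n_iter

  full <- clinical_association_scan(vals, clin, features, confounders,
                                    r_clin, r_conf, details = TRUE)
  ord <- order(-freq, -full$max_r_clin, full$region)
  ranking <- data.frame(region = full$region[ord],
                        frequency = unname(freq[ord]),
                        rank = seq_along(ord),
                        max_r_clin = full$max_r_clin[ord],
                        max_r_conf = full$max_r_conf[ord],
                        stringsAsFactors = FALSE)
  if (top_k > nrow(ranking)) {
    warning("top_k exceeds the number of regions; returning all")
    top_k <- nrow(ranking)
  }
  structure(list(selected = ranking$region[seq_len(top_k)],
                 ranking = ranking,
                 params = list(r_clin = r_clin, r_conf = r_conf,
                               n_iter = n_iter, leave_out = leave_out,
                               top_k = top_k, seed = seed)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Region screen: %d regions ranked over %d leave-%d-out iterations\n",
              nrow(x$ranking), x$params$n_iter, x$params$leave_out))
  cat(sprintf("  selected top %d; frequency range of selection: [%.3f, %.3f]\n",
              length(x$selected),
              min(x$ranking$frequency[seq_along(x$selected)]),
              max(x$ranking$frequency[seq_along(x$selected)])))
  invisible(x)
}

#' Write a screen result as TSV
#' @param x `screen_result`.
#' @param path output TSV.
#' @export
write_screen_result <- function(x, path) {
  utils::write.table(x$ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
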