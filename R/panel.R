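# Diagnostic marker-panel selection: candidate probes consistent across
# cohorts, a random-subset linear-SVM search with frequency ranking, a
# forward-AUC cutoff, collinearity pruning, biotype-aware refinement, and
# ROC/Youden evaluation.
#
# Cohorts are passed as lists: `beta` (samples x probes), `is_case`
# (logical), and optionally `biotype` ("G1"/"G2" for cases, NA otherwise).

#' Candidate differentially methylated probes, consistent across cohorts
#'
#' Training DMPs at relaxed thresholds (moderated-t p < `p_cut`, absolute
#' median case-control beta difference > `d_cut`, covariate-adjusted),
#' retained only when the sign of the median beta difference matches in
#' every validation cohort.
#'
#' @param train training cohort list (`beta`, `is_case`).
#' @param validations list of validation cohort lists.
#' @param covariates optional samples x k matrix of training covariates for
#'   the moderated t-test (e.g. cell fractions and age).
#' @param p_cut relaxed p cutoff (default 0.1).
#' @param d_cut absolute median beta-difference cutoff (default 0.02).
#' @return character vector of candidate probe ids.
#' @export
candidate_dmps <- function(train, validations, covariates = NULL,
                           p_cut = 0.1, d_cut = 0.02) {
  shared <- Reduce(intersect, c(list(colnames(train$beta)),
                                lapply(validations, function(v) colnames(v$beta))))
  if (length(shared) == 0L) stop("no shared probes across cohorts", call. = FALSE)
  beta <- train$beta[, shared, drop = FALSE]
  dm <- moderated_ttest(beta, train$is_case, covariates = covariates)
  med_diff <- function(b, is_case) {
    apply(b[is_case, , drop = FALSE], 2L, stats::median) -
      apply(b[!is_case, , drop = FALSE], 2L, stats::median)
  }
  dtrain <- med_diff(beta, train$is_case)
  keep <- dm$table$p < p_cut & abs(dtrain) > d_cut
  for (v in validations) {
    dv <- med_diff(v$beta[, shared, drop = FALSE], v$is_case)
    keep <- keep & sign(dv) == sign(dtrain)
  }
  shared[keep]
}

# ---- linear SVM with training-set standardization ----

train_lsvm <- function(x, is_case, cost = 1) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, `/`)
  y <- factor(ifelse(is_case, "case", "control"), levels = c("control", "case"))
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
  dv <- as.numeric(attr(stats::predict(fit, xs, decision.values = TRUE),
                        "decision.values"))
  flip <- mean(dv[is_case]) < mean(dv[!is_case])
  structure(list(fit = fit, center = ctr, scale = scl, flip = flip,
                 probes = colnames(x)),
            class = "lsvm_model")
}

#' Decision scores of a trained linear SVM (higher = more case-like)
#' @param object an `lsvm_model` from the panel search.
#' @param newdata samples x probes matrix with the model's probes.
#' @param ... unused.
#' @export
predict.lsvm_model <- function(object, newdata, ...) {
  xs <- as.matrix(newdata)[, object$probes, drop = FALSE]
  xs <- sweep(sweep(xs, 2L, object$center), 2L, object$scale, `/`)
  dv <- as.numeric(attr(stats::predict(object$fit, xs, decision.values = TRUE),
                        "decision.values"))
  if (object$flip) -dv else dv
}

# ---- ROC ----

#' ROC curve, trapezoidal AUC, and the Youden operating point
#'
#' @param scores numeric decision scores (higher = more case-like).
#' @param is_case logical labels.
#' @return list: `auc`, `sensitivity`, `specificity` (at the Youden-index
#'   maximizing threshold), `threshold`, and the full `curve` data.frame.
#' @export
roc_metrics <- function(scores, is_case) {
  is_case <- as.logical(is_case)
  if (length(unique(is_case)) < 2L) {
    stop("test set contains a single class", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(is_case); n0 <- sum(!is_case)
  sens <- vapply(thr, function(t) sum(scores >= t & is_case) / n1, 1)
  spec <- vapply(thr, function(t) sum(scores < t & !is_case) / n0, 1)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1L] + sens[-length(sens)]) / 2)
  youden <- sens + spec - 1
  best <- which.max(youden)
  list(auc = auc, sensitivity = sens[best], specificity = spec[best],
       threshold = thr[best],
       curve = data.frame(threshold = thr, sensitivity = sens,
                          specificity = spec))
}

# mean validation AUC of an SVM trained on `probes`
panel_mean_auc <- function(probes, train, validations, cost = 1,
                           per_biotype = FALSE) {
  model <- train_lsvm(train$beta[, probes, drop = FALSE], train$is_case,
                      cost = cost)
  aucs <- unlist(lapply(validations, function(v) {
    sc <- predict(model, v$beta)
    if (!per_biotype) {
      return(roc_metrics(sc, v$is_case)$auc)
    }
    vapply(c("G1", "G2"), function(g) {
      keep <- !v$is_case | (!is.na(v$biotype) & v$biotype == g)
      if (sum(v$is_case[keep]) == 0L) {
        stop("biotype ", g, " absent in a validation cohort", call. = FALSE)
      }
      roc_metrics(sc[keep], v$is_case[keep])$auc
    }, 1)
  }))
  mean(aucs)
}

#' Random-subset SVM search with frequency ranking
#'
#' Each run draws `subset_size` candidate probes without replacement, trains
#' a linear SVM on the training cohort (features z-scored with training
#' parameters), and computes the AUC on each validation cohort. Subsets
#' whose mean validation AUC exceeds `auc_keep` are retained; probes are
#' ranked by their frequency among retained subsets, with ties broken by
#' training-cohort univariate AUC and then probe id.
#'
#' @param candidates character vector of candidate probe ids.
#' @param train,validations cohort lists (`beta`, `is_case`).
#' @param n_runs number of random subsets (default 1000; the full-scale
#'   analysis uses 100000).
#' @param subset_size probes per subset (default 10).
#' @param auc_keep retention threshold on the mean validation AUC
#'   (default 0.8).
#' @param cost SVM soft-margin cost (default 1).
#' @param seed integer seed; per-run substreams keep early runs stable when
#'   `n_runs` changes.
#' @return object of class `panel_ranking`: data.frame `ranking` (probe,
#'   frequency, rank, univariate_auc), `n_retained`, and the parameters.
#' @export
random_subset_search <- function(candidates, train, validations,
                                 n_runs = 1000L, subset_size = 10L,
                                 auc_keep = 0.8, cost = 1, seed = 1L) {
  stopifnot(length(candidates) >= subset_size)
  hits <- stats::setNames(numeric(length(candidates)), candidates)
  n_retained <- 0L
  for (run in seq_len(n_runs)) {
    set.seed(sub_seed(seed, paste0("panel_run_", run)))
    subset <- sample(candidates, subset_size)
    auc <- panel_mean_auc(subset, train, validations, cost = cost)
    if (auc > auc_keep) {
      n_retained <- n_retained + 1L
      hits[subset] <- hits[subset] + 1
    }
  }
  if (n_retained == 0L) {
    stop("no subset reached mean validation AUC > ", auc_keep,
         "; lower auc_keep", call. = FALSE)
  }
  freq <- hits / n_retained
  uni <- vapply(candidates, function(pr) {
    roc_metrics(train$beta[, pr], train$is_case)$auc
  }, 1)
  ord <- order(-freq, -uni, candidates)
  structure(list(ranking = data.frame(probe = candidates[ord],
                                      frequency = unname(freq[ord]),
                                      rank = seq_along(ord),
                                      univariate_auc = unname(uni[ord]),
                                      stringsAsFactors = FALSE),
                 n_retained = n_retained,
                 params = list(n_runs = n_runs, subset_size = subset_size,
                               auc_keep = auc_keep, cost = cost, seed = seed)),
            class = "panel_ranking")
}

#' @export
print.panel_ranking <- function(x, ...) {
  cat(sprintf("Panel search: %d candidates, %d/%d subsets retained (AUC > %.2f)\n",
              nrow(x$ranking), x$n_retained, x$params$n_runs,
              x$params$auc_keep))
  print(utils::head(x$ranking, 10L), row.names = FALSE)
  invisible(x)
}

#' Forward-AUC trajectory and panel-size cutoff
#'
#' Trains the SVM on the top-k ranked probes for k = 1..`k_max` and records
#' the mean validation AUC. The default cutoff is the smallest k whose AUC
#' is within `tolerance` of the trajectory maximum (the full-scale choice
#' was heuristic, so the cutoff is overridable).
#'
#' @param ranking a `panel_ranking` (or data.frame with a `probe` column in
#'   rank order).
#' @param train,validations cohort lists.
#' @param k_max largest panel size to scan (default: all ranked probes).
#' @param tolerance AUC tolerance to the maximum (default 0.005).
#' @param cost SVM cost.
#' @return list: `k` (chosen cutoff), `trajectory` data.frame (k, mean_auc).
#' @export
forward_auc_cutoff <- function(ranking, train, validations, k_max = NULL,
                               tolerance = 0.005, cost = 1) {
  probes <- if (inherits(ranking, "panel_ranking")) ranking$ranking$probe
            else ranking$probe
  k_max <- k_max %||% length(probes)
  traj <- vapply(seq_len(k_max), function(k) {
    panel_mean_auc(probes[seq_len(k)], train, validations, cost = cost)
  }, 1)
  k <- which(traj >= max(traj) - tolerance)[1L]
  list(k = k, trajectory = data.frame(k = seq_len(k_max), mean_auc = traj))
}

#' Greedy collinearity pruning of a ranked panel
#'
#' Walks the panel in rank order and drops any probe whose absolute Pearson
#' correlation (in the training cohort) with an already-kept probe exceeds
#' `prune_r`.
#'
#' @param probes character vector in rank order.
#' @param train training cohort list.
#' @param prune_r correlation threshold (default 0.8).
#' @return the pruned probe vector (rank order preserved).
#' @export
collinearity_prune <- function(probes, train, prune_r = 0.8) {
  stopifnot(length(probes) > 0L)
  kept <- character(0)
  for (pr in probes) {
    if (length(kept) == 0L) { kept <- pr; next }
    r <- abs(safe_cor_matrix(train$beta[, pr, drop = FALSE],
                             train$beta[, kept, drop = FALSE]))
    if (all(r <= prune_r)) kept <- c(kept, pr)
  }
  kept
}

#' Biotype-aware greedy refinement of a panel
#'
#' Forward-selects probes from the panel maximizing the mean of per-biotype
#' validation AUCs (G1-vs-control and G2-vs-control in each validation
#' cohort), stopping when the objective stops improving by more than
#' `tolerance`.
#'
#' @param probes panel probe ids (rank order used for tie-breaking).
#' @param train training cohort list (`beta`, `is_case`).
#' @param validations validation cohorts carrying `biotype` labels for
#'   cases; both biotypes must be present in each.
#' @param tolerance minimum objective improvement to continue (default
#'   0.005).
#' @param cost SVM cost.
#' @return list: `probes` (the refined sub-panel), `objective`, `trace`.
#' @export
biotype_refine <- function(probes, train, validations, tolerance = 0.005,
                           cost = 1) {
  chosen <- character(0)
  best_obj <- -Inf
  trace <- numeric(0)
  remaining <- probes
  while (length(remaining) > 0L) {
    objs <- vapply(remaining, function(pr) {
      panel_mean_auc(c(chosen, pr), train, validations, cost = cost,
                     per_biotype = TRUE)
    }, 1)
    cand <- which.max(objs)
    if (objs[cand] <= best_obj + tolerance && length(chosen) > 0L) break
    best_obj <- objs[cand]
    chosen <- c(chosen, remaining[cand])
    trace <- c(trace, best_obj)
    remaining <- remaining[-cand]
  }
  list(probes = chosen, objective = best_obj, trace = trace)
}

#' Train and evaluate a panel classifier on a test cohort
#'
#' Trains the linear SVM on the training cohort restricted to the panel and
#' reports AUC, sensitivity and specificity at the Youden-index operating
#' point on the test cohort. Cases can be restricted to a single biotype
#' (all controls are kept).
#'
#' @param probes panel probe ids.
#' @param train,test cohort lists; `test$biotype` required when `group` is
#'   given.
#' @param group optional `"G1"` or `"G2"` restriction of the test cases.
#' @param cost SVM cost.
#' @return list: `auc`, `sensitivity`, `specificity`, `threshold`, `n_case`,
#'   `n_control`, `model` (the `lsvm_model`).
#' @export
evaluate_panel <- function(probes, train, test, group = NULL, cost = 1) {
  model <- train_lsvm(train$beta[, probes, drop = FALSE], train$is_case,
                      cost = cost)
  keep <- rep(TRUE, nrow(test$beta))
  if (!is.null(group)) {
    keep <- !test$is_case | (!is.na(test$biotype) & test$biotype == group)
  }
  sc <- predict(model, test$beta[keep, , drop = FALSE])
  m <- roc_metrics(sc, test$is_case[keep])
  c(m[c("auc", "sensitivity", "specificity", "threshold")],
    list(n_case = sum(test$is_case[keep]), n_control = sum(!test$is_case[keep]),
         model = model))
}
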