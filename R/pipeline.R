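# End-to-end orchestration with reproducible configuration and JSON model
# serialization. The functions here (plus the module functions they call)
# are the pipeline interface; scripts can wrap them directly.

#' Pipeline configuration with the standard defaults
#'
#' Collects every stage threshold in one validated list. Defaults are the
#' pipeline's standard operating values: probe filters sd >= 0.05 and mean
#' beta in [0.01, 0.99], region collapsing at r > 0.8, recall stability at
#' r >= 0.65, clinical screen at |r| > 0.2 with confounder ceiling 0.2,
#' 5000 leave-5-out iterations selecting the top 100 regions, 4 gene PCs and
#' 6 clinical PCs into 2 canonical pairs gated at Wilks p < 1e-4, DMG
#' calling at p < 0.01 and |delta beta| > 0.02, and the panel search with
#' 10-probe subsets kept at mean validation AUC > 0.8.
#'
#' @param sd_min,mean_lo,mean_hi probe filters.
#' @param r_collapse region-collapse correlation threshold.
#' @param collapse_scope `"gene"` or `"global"` correlation-graph scope.
#' @param r_recall recall-stability threshold.
#' @param r_clin,r_conf clinical screen thresholds.
#' @param n_iter,leave_out,top_k resampled screen parameters.
#' @param n_pcs_gene,n_pcs_clin,n_cca_pairs,wilks_alpha correlate stage.
#' @param lda_significant_only fit the LDA boundary only on canonical pairs
#'   passing the Wilks gate (the first pair is always kept).
#' @param boundary_labels how the two LDA classes are defined: `"cluster"`
#'   (default) discriminates the two 2-means clusters of the latent scores
#'   (a control-like and a distinct cluster), `"diagnosis"` discriminates
#'   cases from controls directly.
#' @param severity_col clinical column used to orient canonical signs.
#' @param flip_sign flip the biotype score axis.
#' @param dm_p_cut,dm_d_cut DMG calling thresholds.
#' @param panel_p_cut,panel_d_cut,panel_n_runs,panel_subset_size,
#'   panel_auc_keep,panel_prune_r panel-search parameters.
#' @param seed master seed; stages draw named substreams from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sd_min = 0.05, mean_lo = 0.01, mean_hi = 0.99,
                            r_collapse = 0.8, collapse_scope = "gene",
                            r_recall = 0.65, r_clin = 0.2, r_conf = 0.2,
                            n_iter = 5000L, leave_out = 5L, top_k = 100L,
                            n_pcs_gene = 4L, n_pcs_clin = 6L,
                            n_cca_pairs = 2L, wilks_alpha = 1e-4,
                            lda_significant_only = TRUE,
                            boundary_labels = c("cluster", "diagnosis"),
                            severity_col = "caps_total", flip_sign = FALSE,
                            dm_p_cut = 0.01, dm_d_cut = 0.02,
                            panel_p_cut = 0.1, panel_d_cut = 0.02,
                            panel_n_runs = 1000L, panel_subset_size = 10L,
                            panel_auc_keep = 0.8, panel_prune_r = 0.8,
                            seed = 1L) {
  cfg <- as.list(environment())
  cfg$boundary_labels <- match.arg(boundary_labels)
  stopifnot(cfg$sd_min > 0, cfg$mean_lo < cfg$mean_hi,
            cfg$r_collapse > 0, cfg$r_collapse < 1,
            cfg$n_iter >= 1L, cfg$top_k >= 1L,
            cfg$collapse_scope %in% c("gene", "global"))
  structure(cfg, class = "pipeline_config")
}

#' Run the discovery pipeline on a cohort
#'
#' Thin wrapper over [fit_biotype()] that also writes the fitted model,
#' screen ranking and assignments to `out_dir` when given, together with
#' the resolved configuration.
#'
#' @inheritParams fit_biotype
#' @param out_dir optional output directory.
#' @return the `biotype_fit`.
#' @export
run_discovery <- function(beta, annotation, clinical,
                          config = pipeline_config(), recall = NULL,
                          case_label = "PTSD", out_dir = NULL) {
  fit <- fit_biotype(beta, annotation, clinical, config = config,
                     recall = recall, case_label = case_label)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_biotype_model(fit, file.path(out_dir, "biotype_model.json"))
    write_screen_result(fit$screen, file.path(out_dir, "screen.tsv"))
    utils::write.csv(fit$assignment, file.path(out_dir, "assignments.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  fit
}

#' Apply a fitted biotype model to a new cohort
#'
#' Projects and assigns without refitting, using the training centering.
#'
#' @param fit a `biotype_fit` (or the path of a model JSON written by
#'   [write_biotype_model()]).
#' @param beta new cohort beta matrix (samples x probes).
#' @param clinical optional clinical table with a `diagnosis` column; used
#'   to flag cases.
#' @param case_label diagnosis value identifying cases.
#' @param include_controls label non-cases too.
#' @return the assignment data.frame.
#' @export
run_apply <- function(fit, beta, clinical = NULL, case_label = "PTSD",
                      include_controls = FALSE) {
  if (is.character(fit)) fit <- read_biotype_model(fit)
  if (nrow(beta) == 0L) stop("empty cohort", call. = FALSE)
  is_case <- if (!is.null(clinical)) {
    align_samples(clinical, rownames(beta), "clinical table")$diagnosis == case_label
  } else NULL
  predict(fit, beta, is_case = is_case, include_controls = include_controls)
}

#' Serialize a fitted biotype model to JSON
#'
#' Stores the per-region weight table (region id, weight, training mean,
#' member probes), the latent-space boundary, and the PCA/CCA matrices
#' needed for projection, with explicit matrix shapes.
#'
#' @param fit a `biotype_fit`.
#' @param path output JSON path.
#' @export
write_biotype_model <- function(fit, path) {
  stopifnot(inherits(fit, "biotype_fit"))
  m <- fit$model
  cm <- m$correlates
  obj <- list(
    regions = m$regions,
    weights = unname(m$weights),
    center = unname(m$center[m$regions]),
    intercept = m$intercept,
    boundary = list(normal = unname(m$boundary$normal),
                    intercept = m$boundary$intercept),
    pca_gene = list(rotation = cm$pca_gene$rotation,
                    center = unname(cm$pca_gene$center),
                    n_pcs = cm$pca_gene$n_pcs),
    cca = list(xcoef = cm$cca$xcoef, xcenter = unname(cm$cca$xcenter),
               cor = cm$cca$cor),
    membership = fit$regions$membership[m$regions]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a biotype model JSON back into a minimal applicable fit
#'
#' The returned object supports [predict.biotype_fit()] (scoring and
#' assignment) but not refitting; projection uses the stored PCA/CCA
#' matrices.
#'
#' @param path model JSON from [write_biotype_model()].
#' @return a `biotype_fit`-classed list with the fields prediction needs.
#' @export
read_biotype_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- obj$regions
  rotation <- obj$pca_gene$rotation         # simplified to a matrix on read
  dimnames(rotation) <- list(regions, NULL)
  xcoef <- obj$cca$xcoef
  pca_gene <- structure(list(center = stats::setNames(obj$pca_gene$center, regions),
                             scale = NULL, rotation = rotation,
                             n_pcs = obj$pca_gene$n_pcs),
                        class = "pca_model")
  cca <- structure(list(xcoef = xcoef, xcenter = obj$cca$xcenter,
                        cor = obj$cca$cor),
                   class = "cca_model")
  correlates <- structure(list(pca_gene = pca_gene, cca = cca,
                               regions = regions),
                          class = "correlate_model")
  boundary <- structure(list(normal = obj$boundary$normal,
                             intercept = obj$boundary$intercept),
                        class = "lda_boundary")
  model <- structure(list(regions = regions,
                          center = stats::setNames(obj$center, regions),
                          weights = stats::setNames(obj$weights, regions),
                          intercept = obj$intercept,
                          boundary = boundary, correlates = correlates),
                     class = "biotype_model")
  membership <- lapply(obj$membership, as.character)
  structure(list(model = model,
                 regions = list(membership = membership)),
            class = "biotype_fit")
}
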