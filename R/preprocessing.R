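# Probe filtering and correlation-graph region collapsing.
#
# The preprocessing contract, in order: (1) drop probes with low variance,
# extreme means, or intergenic location; (2) keep only genes with at least
# two surviving probes ("confident" genes); (3) collapse correlated probes
# within each gene into averaged regions; (4) optionally drop regions that
# are unstable between an original and a recall assay.

new_region_matrix <- function(values, membership) {
  stopifnot(is.matrix(values), identical(colnames(values), names(membership)))
  structure(list(values = values, membership = membership),
            class = "region_matrix")
}

#' @export
print.region_matrix <- function(x, ...) {
  sizes <- lengths(x$membership)
  cat(sprintf("Region matrix: %d samples x %d regions (probes per region: %d-%d, median %g)\n",
              nrow(x$values), ncol(x$values), min(sizes), max(sizes),
              stats::median(sizes)))
  invisible(x)
}

#' @export
dim.region_matrix <- function(x) dim(x$values)

#' Filter probes by variability, mean extremity, location and gene support
#'
#' Retains probes whose beta standard deviation is at least `sd_min`, whose
#' mean beta lies in `[mean_lo, mean_hi]`, that are annotated to a gene
#' (non-intergenic), and whose gene keeps at least `min_probes_per_gene`
#' probes after the preceding filters. Probe order is preserved.
#'
#' @param beta samples x probes beta matrix.
#' @param annotation probe annotation data.frame (`probe_id`, `gene`,
#'   `region_class`); must cover every probe in `beta`.
#' @param sd_min minimum beta standard deviation (default 0.05).
#' @param mean_lo,mean_hi admissible mean-beta range (defaults 0.01, 0.99).
#' @param min_probes_per_gene gene-support filter (default 2).
#' @return the filtered beta matrix (same orientation).
#' @export
filter_probes <- function(beta, annotation, sd_min = 0.05,
                          mean_lo = 0.01, mean_hi = 0.99,
                          min_probes_per_gene = 2L) {
  stopifnot(sd_min > 0, sd_min < 1, mean_lo > 0, mean_hi < 1, mean_lo < mean_hi)
  probes <- colnames(beta)
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx)) {
    stop("annotation missing probes: ",
         paste(utils::head(probes[is.na(idx)], 5L), collapse = ", "), call. = FALSE)
  }
  gene <- annotation$gene[idx]
  cls <- annotation$region_class[idx]

  sds <- apply(beta, 2L, stats::sd)
  mns <- colMeans(beta)
  keep <- sds >= sd_min & mns >= mean_lo & mns <= mean_hi &
    gene != "" & cls != "intergenic"
  gene_counts <- table(gene[keep])
  confident <- names(gene_counts)[gene_counts >= min_probes_per_gene]
  keep <- keep & gene %in% confident
  if (!any(keep)) warning("no probes survive filtering")
  beta[, keep, drop = FALSE]
}

#' Collapse correlated probes into gene regions
#'
#' Within each gene, builds a graph over probes with an edge wherever the
#' pairwise Pearson correlation exceeds `r_thresh`; each connected component
#' becomes a region whose value is the per-sample mean of its member probes.
#' Singleton components pass through as single-probe regions so that no
#' confident gene silently vanishes. Undefined correlations (zero-variance
#' probes) are treated as 0 (no edge).
#'
#' @param beta probe-filtered samples x probes beta matrix.
#' @param annotation probe annotation covering all probes.
#' @param r_thresh correlation threshold for an edge (default 0.8).
#' @param scope `"gene"` (default) restricts the graph to probes of the same
#'   gene; `"global"` builds one genome-wide graph (regions then carry the
#'   gene of their first member probe).
#' @return a `region_matrix`: list with `values` (samples x regions, region
#'   ids `GENE.k`) and `membership` (region -> member probe ids).
#' @export
collapse_regions <- function(beta, annotation, r_thresh = 0.8,
                             scope = c("gene", "global")) {
  scope <- match.arg(scope)
  probes <- colnames(beta)
  gene <- annotation$gene[match(probes, annotation$probe_id)]
  if (anyNA(gene)) stop("annotation missing probes", call. = FALSE)

  sds <- apply(beta, 2L, stats::sd)
  n_zero <- sum(sds == 0)
  if (n_zero > 0L) {
    message(n_zero, " zero-variance probes: correlations treated as 0")
  }

  comp_of <- integer(length(probes))
  if (scope == "gene") {
    offset <- 0L
    for (g in unique(gene)) {
      cols <- which(gene == g)
      comp <- correlation_components(beta[, cols, drop = FALSE], r_thresh)
      comp_of[cols] <- comp + offset
      offset <- offset + max(comp)
    }
  } else {
    comp_of <- correlation_components(beta, r_thresh)
  }

  # region ids: gene + within-gene component index, ordered by first probe
  order_first <- order(vapply(split(seq_along(probes), comp_of), min, 1L))
  comps <- split(seq_along(probes), comp_of)[order_first]
  region_gene <- vapply(comps, function(ix) gene[ix[1L]], "")
  k_within <- stats::ave(seq_along(comps), region_gene, FUN = seq_along)
  region_ids <- sprintf("%s.%d", region_gene, k_within)

  values <- vapply(comps, function(ix) rowMeans(beta[, ix, drop = FALSE]),
                   numeric(nrow(beta)))
  colnames(values) <- region_ids
  membership <- stats::setNames(lapply(comps, function(ix) probes[ix]), region_ids)
  new_region_matrix(values, membership)
}

# Connected components of the |probe| graph with edges where r > r_thresh.
correlation_components <- function(beta, r_thresh) {
  p <- ncol(beta)
  if (p == 1L) return(1L)
  r <- suppressWarnings(stats::cor(beta))
  r[!is.finite(r)] <- 0
  adj <- (r > r_thresh)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

#' Filter regions by original-vs-recall stability
#'
#' Keeps regions whose Pearson correlation between original and recall
#' values, computed over the stable samples, is at least `r_min`.
#'
#' @param regions `region_matrix` from the original assay.
#' @param recall_regions `region_matrix` from the recall assay (same region
#'   set).
#' @param stable_sample_ids ids of samples present in both assays whose
#'   status did not change.
#' @param r_min minimum test-retest correlation (default 0.65).
#' @return the filtered `region_matrix` (original values).
#' @export
recall_stability_filter <- function(regions, recall_regions, stable_sample_ids,
                                    r_min = 0.65) {
  stopifnot(inherits(regions, "region_matrix"),
            inherits(recall_regions, "region_matrix"))
  if (length(stable_sample_ids) < 3L) {
    stop("need at least 3 stable samples for a meaningful correlation", call. = FALSE)
  }
  if (!setequal(colnames(regions$values), colnames(recall_regions$values))) {
    stop("original and recall region sets differ", call. = FALSE)
  }
  orig <- align_samples(regions$values, stable_sample_ids, "original regions")
  rec <- align_samples(recall_regions$values, stable_sample_ids, "recall regions")
  rec <- rec[, colnames(orig), drop = FALSE]
  r <- vapply(seq_len(ncol(orig)),
              function(j) safe_cor(orig[, j], rec[, j]), numeric(1L))
  keep <- r >= r_min
  new_region_matrix(regions$values[, keep, drop = FALSE],
                    regions$membership[keep])
}

#' Run the full preprocessing stage
#'
#' Convenience wrapper: probe filters, region collapsing and (when a recall
#' assay is supplied) the stability filter, with the standard defaults.
#'
#' @inheritParams filter_probes
#' @inheritParams collapse_regions
#' @param recall optional list with `beta` (recall samples x probes) and
#'   `stable_sample_ids`.
#' @param r_recall recall-stability threshold (default 0.65).
#' @return a `region_matrix`.
#' @export
preprocess_beta <- function(beta, annotation, sd_min = 0.05, mean_lo = 0.01,
                            mean_hi = 0.99, r_thresh = 0.8,
                            scope = "gene", recall = NULL, r_recall = 0.65) {
  filt <- filter_probes(beta, annotation, sd_min, mean_lo, mean_hi)
  regions <- collapse_regions(filt, annotation, r_thresh, scope)
  if (!is.null(recall)) {
    shared <- intersect(colnames(filt), colnames(recall$beta))
    rec_beta <- recall$beta[, shared, drop = FALSE]
    # recall regions reuse the original membership so region sets match
    rec_values <- vapply(regions$membership, function(pr) {
      pr <- intersect(pr, shared)
      rowMeans(rec_beta[, pr, drop = FALSE])
    }, numeric(nrow(rec_beta)))
    rec_regions <- new_region_matrix(rec_values, regions$membership)
    regions <- recall_stability_filter(regions, rec_regions,
                                       recall$stable_sample_ids, r_recall)
  }
  regions
}
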