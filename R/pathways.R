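# Gene-set enrichment of DMGs and pathway grouping by set dissimilarity.
#
# Enrichment is a one-sided hypergeometric test plus a direction score
# (n_hyper - n_hypo) / sqrt(n_overlap) summarizing whether the overlapping
# DMGs shift coherently; pathways are then grouped by complete-linkage
# clustering of the overlap dissimilarity 1 - |Pi & Pj| / max(|Pi|, |Pj|).

#' Hypergeometric gene-set enrichment with a direction score
#'
#' @param dmgs data.frame with columns `gene` and `direction`
#'   ("hyper"/"hypo"), e.g. the DMG rows of [call_dmg()]'s `genes` table.
#' @param universe character vector of all tested genes (must contain the
#'   DMGs); sets are intersected with it.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param p_cut enrichment p-value cutoff (default 0.01).
#' @param z_cut absolute direction-score cutoff (default 2).
#' @return data.frame: set, n_set, n_overlap, p, direction_score, enriched.
#' @export
enrich_gene_sets <- function(dmgs, universe, sets, p_cut = 0.01, z_cut = 2) {
  stopifnot(is.data.frame(dmgs), all(c("gene", "direction") %in% names(dmgs)))
  if (!all(dmgs$gene %in% universe)) {
    stop("universe must contain all DMGs", call. = FALSE)
  }
  universe <- unique(universe)
  n_univ <- length(universe)
  n_dmg <- nrow(dmgs)
  res <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    ov <- dmgs[dmgs$gene %in% members, , drop = FALSE]
    k <- nrow(ov)
    # P(X >= k) for X ~ Hypergeom(#dmg draws from n_univ with |set| successes)
    p <- if (k == 0L) 1 else {
      stats::phyper(k - 1L, length(members), n_univ - length(members), n_dmg,
                    lower.tail = FALSE)
    }
    dscore <- if (k == 0L) 0 else {
      (sum(ov$direction == "hyper") - sum(ov$direction == "hypo")) / sqrt(k)
    }
    data.frame(set = nm, n_set = length(members), n_overlap = k, p = p,
               direction_score = dscore,
               enriched = p < p_cut & abs(dscore) >= z_cut,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pairwise overlap dissimilarity between gene sets
#'
#' `d(i, j) = 1 - |Pi & Pj| / max(|Pi|, |Pj|)`; zero diagonal, symmetric,
#' values in `[0, 1]`.
#'
#' @param sets named list of non-empty character vectors.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pathway_dissimilarity <- function(sets) {
  stopifnot(length(sets) > 0L, all(lengths(sets) > 0L))
  sets <- lapply(sets, unique)
  k <- length(sets)
  d <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      ov <- length(intersect(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <- 1 - ov / max(length(sets[[i]]), length(sets[[j]]))
    }
  }
  d
}

#' Group pathways by complete-linkage clustering of their dissimilarity
#'
#' @param d symmetric dissimilarity matrix (e.g. from
#'   [pathway_dissimilarity()]).
#' @param n_groups number of groups to cut the dendrogram into (exclusive
#'   with `height`).
#' @param height cut height (complete-linkage merge distance).
#' @return named integer vector of group labels.
#' @export
cluster_pathways <- function(d, n_groups = NULL, height = NULL) {
  stopifnot(is.matrix(d), isTRUE(all.equal(d, t(d))),
            all(diag(d) == 0), all(d >= 0 & d <= 1))
  if (is.null(n_groups) && is.null(height)) {
    stop("specify n_groups or height", call. = FALSE)
  }
  if (!is.null(n_groups) && n_groups > nrow(d)) {
    stop("n_groups exceeds the number of pathways", call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  stats::cutree(hc, k = n_groups, h = height)
}
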