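# Small deterministic fixtures used across the test files.

# Beta matrix with named probes/samples from a plain numeric vector.
beta_fixture <- function(values, n_samples, probe_ids = NULL) {
  m <- matrix(values, nrow = n_samples)
  colnames(m) <- probe_ids %||% sprintf("cg%07d", seq_len(ncol(m)))
  rownames(m) <- sprintf("S%03d", seq_len(n_samples))
  m
}

annotation_fixture <- function(probe_ids, genes, region_class = NULL) {
  data.frame(probe_id = probe_ids, gene = genes,
             region_class = region_class %||%
               ifelse(genes == "", "intergenic", "body"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small cohort used by several module tests (fast to generate).
small_cohort <- function(seed = 42, ...) {
  generate_cohort(synth_config(n_control = 40, n_g1 = 20, n_g2 = 20,
                               n_genes = 250, n_signal_genes_g1 = 15,
                               n_signal_genes_g2 = 15, n_physical_genes = 8,
                               seed = seed, ...))
}

# Two-class cohort list (beta/is_case/biotype) for the panel module, with
# `n_signal` planted separating probes among `n_null` null probes.
panel_cohort_fixture <- function(n_case = 30, n_control = 30, n_signal = 3,
                                 n_null = 57, shift = 0.12, seed = 1,
                                 biotype_split = TRUE) {
  set.seed(seed)
  n <- n_case + n_control
  p <- n_signal + n_null
  beta <- matrix(stats::plogis(stats::rnorm(n * p, sd = 0.35)), nrow = n)
  colnames(beta) <- sprintf("cg%07d", seq_len(p))
  rownames(beta) <- sprintf("P%03d", seq_len(n))
  is_case <- c(rep(TRUE, n_case), rep(FALSE, n_control))
  if (n_signal > 0L) {
    beta[is_case, seq_len(n_signal)] <- beta[is_case, seq_len(n_signal)] + shift
  }
  beta <- pmin(pmax(beta, 0.001), 0.999)
  biotype <- rep(NA_character_, n)
  if (biotype_split) {
    biotype[is_case] <- rep_len(c("G1", "G2"), n_case)
  }
  list(beta = beta, is_case = is_case, biotype = biotype)
}
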