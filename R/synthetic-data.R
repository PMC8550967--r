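# Seeded synthetic methylation cohorts.
#
# The generator produces the statistical structure every downstream stage
# assumes: bounded 450K-like beta values with logit-normal probe noise,
# gene-grouped correlated probes, covariate effects on methylation, two
# planted case biotypes with opposite-direction shifts, and a clinical table
# organized around two latent factors ("Psychological" and
# "Physical-Dissociative").

#' Configuration for a synthetic methylation cohort
#'
#' Captures the generative assumptions of the simulated study: cohort sizes,
#' gene/probe layout, planted biotype effect sizes, noise levels, and the
#' coupling between latent clinical factors and the clinical feature table.
#'
#' @param n_control,n_g1,n_g2 sample counts for controls and the two planted
#'   case biotypes.
#' @param n_genes number of genes; each gene carries 1-6 probes.
#' @param probes_per_gene integer vector of allowed probe counts per gene
#'   (sampled uniformly).
#' @param n_signal_genes_g1,n_signal_genes_g2 number of genes carrying the
#'   planted methylation shift for each biotype.
#' @param signal_overlap fraction of the G1 signal genes shared with the G2
#'   set (default 0.75). Shared genes shift in opposite directions in the
#'   two biotypes, so they wash out of a pooled case-vs-control contrast
#'   while remaining fully shifted in each per-biotype contrast.
#' @param delta_g1,delta_g2 mean beta-scale shift applied to signal genes in
#'   the respective biotype's samples. Conventionally `delta_g1 < 0`
#'   (hypomethylation) and `delta_g2 > 0` (hypermethylation).
#' @param probe_noise_sd probe-level noise standard deviation on the logit
#'   scale.
#' @param within_gene_corr target Pearson correlation between probes of the
#'   same gene, induced by a shared per-gene latent draw.
#' @param clinical_loading scale of the loading of the two latent factors on
#'   the 34 clinical features.
#' @param clinical_noise_sd residual noise sd of clinical features.
#' @param factor_shift_g1,factor_shift_g2 length-2 numeric: mean shift of the
#'   (Psychological, Physical-Dissociative) latent factors in each biotype
#'   relative to control. G2 is the more severe biotype.
#' @param methylation_factor_coupling extra continuous coupling between a
#'   sample's Psychological factor and its signal-gene methylation, on the
#'   beta scale per factor SD. Makes signal regions track severity, not only
#'   group membership.
#' @param n_physical_genes number of genes (disjoint from the biotype signal
#'   genes) whose methylation tracks the Physical-Dissociative factor; these
#'   give the second gene-clinical composite pair real structure.
#' @param physical_coupling beta-scale coupling of those genes per
#'   Physical-Dissociative factor SD.
#' @param covariate_effects named list of logit-scale effect sds for
#'   `age`, `bmi`, `cell`, `ancestry`: each probe receives a random
#'   coefficient with that sd multiplying the standardized covariate.
#' @param intergenic_frac fraction of additional intergenic probes appended
#'   (no gene annotation; removed by probe filtering downstream).
#' @param recall_corr target test-retest correlation of stable regions in
#'   recall pairs.
#' @param recall_unstable_frac fraction of genes whose probes are redrawn
#'   independently at recall (test-retest r near 0).
#' @param population_seed integer seed for the population-level structure:
#'   gene/probe layout, baseline methylation, signal-gene identities, and
#'   per-probe covariate coefficients. Cohorts sharing `population_seed`
#'   (e.g. a discovery and a replication cohort) share their biology and
#'   differ only in the sampled individuals.
#' @param seed integer master seed for the per-sample draws; together with
#'   `population_seed` it fully determines the cohort.
#' @return an object of class `synth_config` (a validated list).
#' @seealso [generate_cohort()], [generate_recall_pair()]
#' @export
synth_config <- function(n_control = 100, n_g1 = 50, n_g2 = 50,
                         n_genes = 1500,
                         probes_per_gene = 1:6,
                         n_signal_genes_g1 = 40, n_signal_genes_g2 = 40,
                         signal_overlap = 0.75,
                         delta_g1 = -0.06, delta_g2 = 0.06,
                         probe_noise_sd = 0.2,
                         within_gene_corr = 0.8,
                         clinical_loading = 1,
                         clinical_noise_sd = 0.6,
                         factor_shift_g1 = c(0.4, 0.15),
                         factor_shift_g2 = c(2.2, 1.0),
                         methylation_factor_coupling = 0.01,
                         n_physical_genes = 20, physical_coupling = 0.015,
                         covariate_effects = list(age = 0.03, bmi = 0.02,
                                                  cell = 0.05, ancestry = 0.02),
                         intergenic_frac = 0.05,
                         recall_corr = 0.9,
                         recall_unstable_frac = 0,
                         population_seed = 100L,
                         seed = 1L) {
  cfg <- list(n_control = n_control, n_g1 = n_g1, n_g2 = n_g2,
              n_genes = n_genes, probes_per_gene = probes_per_gene,
              n_signal_genes_g1 = n_signal_genes_g1,
              n_signal_genes_g2 = n_signal_genes_g2,
              signal_overlap = signal_overlap,
              delta_g1 = delta_g1, delta_g2 = delta_g2,
              probe_noise_sd = probe_noise_sd,
              within_gene_corr = within_gene_corr,
              clinical_loading = clinical_loading,
              clinical_noise_sd = clinical_noise_sd,
              factor_shift_g1 = factor_shift_g1,
              factor_shift_g2 = factor_shift_g2,
              methylation_factor_coupling = methylation_factor_coupling,
              n_physical_genes = n_physical_genes,
              physical_coupling = physical_coupling,
              covariate_effects = covariate_effects,
              intergenic_frac = intergenic_frac,
              recall_corr = recall_corr,
              recall_unstable_frac = recall_unstable_frac,
              population_seed = as.integer(population_seed),
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$n_control, cfg$n_g1, cfg$n_g2, cfg$n_genes,
              cfg$n_signal_genes_g1, cfg$n_signal_genes_g2)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (cfg$n_signal_genes_g1 + cfg$n_signal_genes_g2 > cfg$n_genes) {
    stop("n_genes smaller than the number of signal genes", call. = FALSE)
  }
  if (cfg$within_gene_corr < 0 || cfg$within_gene_corr > 1) {
    stop("within_gene_corr must be in [0, 1]", call. = FALSE)
  }
  if (cfg$signal_overlap < 0 || cfg$signal_overlap > 1) {
    stop("signal_overlap must be in [0, 1]", call. = FALSE)
  }
  if (cfg$recall_corr < 0 || cfg$recall_corr > 1) {
    stop("recall_corr must be in [0, 1]", call. = FALSE)
  }
  # Shifts are applied around baseline betas drawn mostly in (0.12, 0.88);
  # reject shifts that push the central baseline out of (0, 1).
  if (max(abs(cfg$delta_g1), abs(cfg$delta_g2)) > 0.3) {
    stop("planted beta shifts beyond 0.3 would push expected betas outside (0,1)",
         call. = FALSE)
  }
  invisible(cfg)
}

# The 34 clinical features mirror the instrument groups of the study design:
# CAPS subscales, PCL, depression/psychopathology scales, sleep, SCL-90
# subscales, quality-of-life (SF-12) and peri-traumatic dissociation (PDEQ).
# Column 1 of `factor_loading` is the Psychological factor, column 2 the
# Physical-Dissociative factor.
default_clinical_features <- function() {
  feats <- c("caps_b", "caps_c", "caps_d", "pcl_total", "bdi", "msc", "psqi",
             paste0("scl90_", c("som", "obs", "int", "dep", "anx", "hos",
                                "phob", "par", "psy")),
             "sf12_pcs", "sf12_mcs", "pdeq",
             paste0("feat_", sprintf("%02d", 1:15)))
  stopifnot(length(feats) == 34L)
  loading <- matrix(0, nrow = 34L, ncol = 2L,
                    dimnames = list(feats, c("psychological", "physical_dissociative")))
  psych <- c("caps_b", "caps_c", "caps_d", "pcl_total", "bdi",
             "scl90_obs", "scl90_int", "scl90_dep", "scl90_anx", "scl90_hos",
             "scl90_par", "scl90_psy", "msc", "psqi",
             paste0("feat_", sprintf("%02d", 1:8)))
  phys <- c("scl90_som", "scl90_phob", "sf12_pcs", "sf12_mcs", "pdeq",
            paste0("feat_", sprintf("%02d", 9:15)))
  loading[psych, 1L] <- 1
  loading[phys, 2L] <- 1
  # SF-12 is a quality-of-life scale: higher = better health, so it loads
  # negatively on the physical factor.
  loading[c("sf12_pcs", "sf12_mcs"), 2L] <- -1
  # mild cross-loadings so the two blocks are correlated but separable
  loading[c("scl90_som", "pdeq"), 1L] <- 0.3
  loading[c("psqi", "msc"), 2L] <- 0.3
  loading
}

#' Generate a synthetic methylation cohort
#'
#' Draws a seeded cohort of controls and two planted case biotypes. Probe
#' betas are logit-normal around per-gene baselines, with a shared per-gene
#' latent draw inducing within-gene correlation, covariate effects injected
#' on the logit scale, and biotype-specific beta shifts planted on disjoint
#' signal-gene sets (G1 shifted by `delta_g1` on its signal genes, G2 by
#' `delta_g2` on its own). Clinical features load on two latent factors whose
#' means shift with biotype membership.
#'
#' @param config a [synth_config()] object.
#' @return a list of class `synth_cohort` with elements
#'   \describe{
#'     \item{beta}{samples x probes beta matrix in `[0.001, 0.999]`.}
#'     \item{annotation}{data.frame `probe_id`, `gene`, `region_class`
#'       (promoter/body/intergenic; intergenic probes have empty gene).}
#'     \item{clinical}{data.frame with 34 clinical feature columns, covariates
#'       (age, bmi, cell fractions `cell_1..cell_5` summing to 1, ancestry
#'       PCs, smoking, alcohol_audit, deployments), `diagnosis`, `caps_total`,
#'       `pcl_total_score`.}
#'     \item{truth}{ground truth: `labels` (control/G1/G2), `signal_genes_g1`,
#'       `signal_genes_g2`, `factors` (per-sample latent factor scores).}
#'   }
#' @examples
#' cohort <- generate_cohort(synth_config(n_control = 20, n_g1 = 10,
#'                                        n_g2 = 10, n_genes = 100, seed = 1))
#' dim(cohort$beta)
#' table(cohort$truth$labels)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  cfg <- config

  ## ---- population-level structure (shared across cohorts) ----
  set.seed(sub_seed(cfg$population_seed, "population"))
  n <- cfg$n_control + cfg$n_g1 + cfg$n_g2
  labels <- c(rep("control", cfg$n_control), rep("G1", cfg$n_g1),
              rep("G2", cfg$n_g2))
  sample_ids <- sprintf("S%03d", seq_len(n))

  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  ppg <- sample(cfg$probes_per_gene, cfg$n_genes, replace = TRUE)
  gene_of_probe <- rep(genes, times = ppg)
  n_gene_probes <- length(gene_of_probe)
  n_intergenic <- ceiling(cfg$intergenic_frac * n_gene_probes)
  probe_ids <- sprintf("cg%07d", seq_len(n_gene_probes + n_intergenic))
  region_class <- c(
    sample(c("promoter", "body"), n_gene_probes, replace = TRUE, prob = c(0.4, 0.6)),
    rep("intergenic", n_intergenic)
  )
  annotation <- data.frame(
    probe_id = probe_ids,
    gene = c(gene_of_probe, rep("", n_intergenic)),
    region_class = region_class,
    stringsAsFactors = FALSE
  )

  n_shared <- min(round(cfg$signal_overlap * cfg$n_signal_genes_g1),
                  cfg$n_signal_genes_g2)
  n_distinct <- cfg$n_signal_genes_g2 + (cfg$n_signal_genes_g1 - n_shared)
  sig_idx <- sample.int(cfg$n_genes, n_distinct)
  signal_g2 <- genes[sig_idx[seq_len(cfg$n_signal_genes_g2)]]
  signal_g1 <- c(signal_g2[seq_len(n_shared)],
                 genes[sig_idx[cfg$n_signal_genes_g2 +
                                 seq_len(cfg$n_signal_genes_g1 - n_shared)]])
  phys_pool <- setdiff(genes, union(signal_g1, signal_g2))
  physical_genes <- if (cfg$n_physical_genes > 0L) {
    sample(phys_pool, min(cfg$n_physical_genes, length(phys_pool)))
  } else character(0)

  gene_base <- stats::rnorm(cfg$n_genes, 0, 1)
  names(gene_base) <- genes
  ig_base <- stats::rnorm(n_intergenic, 0, 1)
  eff <- cfg$covariate_effects
  coef_sd <- c(eff$age, eff$bmi, rep(eff$cell, 4L), rep(eff$ancestry, 3L))
  probe_coefs <- matrix(stats::rnorm(length(coef_sd) * n_gene_probes,
                                     sd = coef_sd), nrow = length(coef_sd))

  ## ---- per-sample draws ----
  set.seed(sub_seed(cfg$seed, "cohort"))

  ## ---- latent clinical factors ----
  factors <- matrix(stats::rnorm(n * 2L), nrow = n,
                    dimnames = list(sample_ids, c("psychological",
                                                  "physical_dissociative")))
  factors[labels == "G1", ] <- sweep(factors[labels == "G1", , drop = FALSE],
                                     2L, cfg$factor_shift_g1, `+`)
  factors[labels == "G2", ] <- sweep(factors[labels == "G2", , drop = FALSE],
                                     2L, cfg$factor_shift_g2, `+`)

  ## ---- covariates ----
  age <- stats::rnorm(n, 38, 9)
  bmi <- stats::rnorm(n, 27.5, 4)
  cell_raw <- matrix(stats::rgamma(n * 5L, shape = c(8, 4, 3, 2, 1)), nrow = n,
                     byrow = TRUE)
  cell <- cell_raw / rowSums(cell_raw)
  colnames(cell) <- paste0("cell_", 1:5)
  ancestry <- matrix(stats::rnorm(n * 3L), nrow = n,
                     dimnames = list(NULL, paste0("ancestry_pc", 1:3)))
  smoking <- stats::rbinom(n, 1L, 0.35)
  alcohol_audit <- round(pmax(stats::rnorm(n, 6, 4), 0))
  deployments <- stats::rpois(n, 1.6)

  ## ---- methylation ----
  # gene baselines (population-level) are on the logit scale: betas mostly
  # within (0.12, 0.88)
  rho <- cfg$within_gene_corr
  sd_tot <- cfg$probe_noise_sd
  gene_latent <- matrix(stats::rnorm(n * cfg$n_genes, sd = sd_tot * sqrt(rho)),
                        nrow = n, dimnames = list(sample_ids, genes))
  gene_col <- match(gene_of_probe, genes)
  probe_noise <- matrix(stats::rnorm(n * n_gene_probes,
                                     sd = sd_tot * sqrt(1 - rho)), nrow = n)
  logit <- gene_latent[, gene_col, drop = FALSE] + probe_noise
  logit <- sweep(logit, 2L, gene_base[gene_col], `+`)
  dimnames(logit) <- list(sample_ids, probe_ids[seq_len(n_gene_probes)])

  # covariate effects: population-level per-probe coefficients applied to
  # the standardized covariates
  covs_std <- cbind(scale(age), scale(bmi), scale(cell[, 1:4]), scale(ancestry))
  logit <- logit + covs_std %*% probe_coefs

  beta <- stats::plogis(logit)

  # planted biotype shifts on the beta scale (group shift plus a mild
  # severity coupling through the Psychological factor)
  shift_for <- function(beta, signal_genes, grp, delta) {
    cols <- which(gene_of_probe %in% signal_genes)
    in_grp <- labels == grp
    beta[in_grp, cols] <- beta[in_grp, cols] + delta
    beta
  }
  beta <- shift_for(beta, signal_g1, "G1", cfg$delta_g1)
  beta <- shift_for(beta, signal_g2, "G2", cfg$delta_g2)
  # severity coupling rides on the control-distinct (G2) signal genes so the
  # clinically informative regions track the Psychological factor, not just
  # group membership
  psych_c <- factors[, 1L] - mean(factors[, 1L])
  cols_g2 <- which(gene_of_probe %in% signal_g2)
  beta[, cols_g2] <- beta[, cols_g2] +
    sign(cfg$delta_g2) * cfg$methylation_factor_coupling * psych_c
  # genes tracking the Physical-Dissociative factor (disjoint from the
  # biotype signal genes) anchor the second gene-clinical composite pair
  if (length(physical_genes) > 0L) {
    phys_c <- factors[, 2L] - mean(factors[, 2L])
    cols_ph <- which(gene_of_probe %in% physical_genes)
    beta[, cols_ph] <- beta[, cols_ph] + cfg$physical_coupling * phys_c
  }

  # intergenic probes: plain logit-normal noise
  if (n_intergenic > 0L) {
    ig <- stats::plogis(sweep(matrix(stats::rnorm(n * n_intergenic, sd = sd_tot),
                                     nrow = n), 2L, ig_base, `+`))
    colnames(ig) <- probe_ids[n_gene_probes + seq_len(n_intergenic)]
    rownames(ig) <- sample_ids
    beta <- cbind(beta, ig)
  }
  beta <- pmin(pmax(beta, 0.001), 0.999)

  ## ---- clinical feature table ----
  loading <- default_clinical_features() * cfg$clinical_loading
  clin_feat <- factors %*% t(loading) +
    matrix(stats::rnorm(n * nrow(loading), sd = cfg$clinical_noise_sd),
           nrow = n)
  colnames(clin_feat) <- rownames(loading)

  caps_total <- pmax(30 + 18 * factors[, 1L] + stats::rnorm(n, 0, 6), 0)
  pcl_total_score <- pmax(25 + 12 * factors[, 1L] + stats::rnorm(n, 0, 5), 0)
  clinical <- data.frame(
    sample_id = sample_ids,
    clin_feat,
    age = age, bmi = bmi, cell,
    ancestry,
    smoking = smoking, alcohol_audit = alcohol_audit,
    deployments = deployments,
    diagnosis = ifelse(labels == "control", "control", "PTSD"),
    caps_total = caps_total,
    pcl_total_score = pcl_total_score,
    stringsAsFactors = FALSE
  )
  rownames(clinical) <- sample_ids

  truth <- list(labels = stats::setNames(labels, sample_ids),
                signal_genes_g1 = signal_g1,
                signal_genes_g2 = signal_g2,
                physical_genes = physical_genes,
                factors = factors)

  structure(list(beta = beta, annotation = annotation, clinical = clinical,
                 truth = truth, config = cfg),
            class = "synth_cohort")
}

#' Generate an original/recall methylation pair for stability filtering
#'
#' Simulates a re-assayed subset of the cohort: the recall betas share the
#' per-gene latent structure of the originals with test-retest correlation
#' `recall_corr` on the logit scale, while a configurable fraction of
#' "unstable" genes is redrawn independently (test-retest r near 0).
#'
#' @param config a [synth_config()] object; `recall_corr` and
#'   `recall_unstable_frac` control the pairing.
#' @param n_recall number of samples re-assayed (taken from the start of the
#'   cohort sample list).
#' @return list with `original` and `recall` beta matrices over the shared
#'   samples, `mapping` (named vector recall id -> original id), and
#'   `unstable_genes`.
#' @export
generate_recall_pair <- function(config, n_recall = 41L) {
  stopifnot(inherits(config, "synth_config"))
  cohort <- generate_cohort(config)
  cfg <- config
  set.seed(sub_seed(cfg$seed, "recall"))

  n <- nrow(cohort$beta)
  n_recall <- min(n_recall, n)
  ids <- rownames(cohort$beta)[seq_len(n_recall)]
  orig <- cohort$beta[ids, , drop = FALSE]

  genes <- unique(cohort$annotation$gene[cohort$annotation$gene != ""])
  n_unstable <- round(cfg$recall_unstable_frac * length(genes))
  unstable <- if (n_unstable > 0L) sample(genes, n_unstable) else character(0)

  gene_of_probe <- cohort$annotation$gene[match(colnames(orig),
                                                cohort$annotation$probe_id)]
  r <- cfg$recall_corr
  lg <- stats::qlogis(pmin(pmax(orig, 0.001), 0.999))
  mu <- matrix(colMeans(lg), nrow = nrow(lg), ncol = ncol(lg), byrow = TRUE)
  sdv <- apply(lg, 2L, stats::sd)
  noise <- matrix(stats::rnorm(length(lg)), nrow = nrow(lg))
  noise <- sweep(noise, 2L, sdv, `*`)
  recall_lg <- mu + r * (lg - mu) + sqrt(1 - r^2) * noise
  # unstable genes: independent redraw, no shared signal
  unstable_cols <- which(gene_of_probe %in% unstable)
  if (length(unstable_cols) > 0L) {
    fresh <- matrix(stats::rnorm(nrow(lg) * length(unstable_cols)), nrow = nrow(lg))
    fresh <- sweep(fresh, 2L, sdv[unstable_cols], `*`)
    recall_lg[, unstable_cols] <- mu[, unstable_cols] + fresh
  }
  recall <- pmin(pmax(stats::plogis(recall_lg), 0.001), 0.999)
  if (r == 1 && length(unstable_cols) == 0L) recall <- orig

  mapping <- stats::setNames(ids, ids)
  list(original = orig, recall = recall, mapping = mapping,
       unstable_genes = unstable, annotation = cohort$annotation)
}

#' @export
print.synth_cohort <- function(x, ...) {
  tr <- table(x$truth$labels)
  cat("Synthetic methylation cohort\n")
  cat(sprintf("  samples: %d (%s)\n", nrow(x$beta),
              paste(sprintf("%s=%d", names(tr), tr), collapse = ", ")))
  cat(sprintf("  probes:  %d over %d genes (+%d intergenic)\n",
              ncol(x$beta), x$config$n_genes,
              sum(x$annotation$gene == "")))
  cat(sprintf("  planted signal genes: %d (G1), %d (G2)\n",
              length(x$truth$signal_genes_g1), length(x$truth$signal_genes_g2)))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the beta matrix as probes x samples TSV, the probe annotation as
#' TSV, the clinical table as CSV, and the ground truth as JSON.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             truth = file.path(dir, "truth.json"))
  write_beta_matrix(cohort$beta, paths[["beta"]])
  utils::write.table(cohort$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$clinical, paths[["clinical"]], row.names = FALSE)
  jsonlite::write_json(
    list(labels = as.list(cohort$truth$labels),
         signal_genes_g1 = cohort$truth$signal_genes_g1,
         signal_genes_g2 = cohort$truth$signal_genes_g2),
    paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
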