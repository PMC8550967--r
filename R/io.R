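# Plain-text readers/writers for the pipeline's tabular formats.
# Beta matrices travel as probes x samples TSV (first column = probe id,
# header = sample ids); internally samples are rows.

#' Read a beta-value matrix from TSV
#'
#' The file stores probes as rows and samples as columns, with a header row
#' of sample ids and probe ids in the first column. The returned matrix is
#' transposed to the internal samples x probes orientation.
#'
#' @param path TSV file path.
#' @return numeric matrix, samples x probes, values checked to lie in `[0,1]`.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  probes <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  beta <- t(m)
  if (anyNA(beta)) stop("beta matrix contains missing values: ", path, call. = FALSE)
  if (any(beta < 0 | beta > 1)) stop("beta values outside [0,1]: ", path, call. = FALSE)
  beta
}

#' Write a beta-value matrix to TSV (probes x samples)
#' @param beta samples x probes matrix.
#' @param path output file.
#' @export
write_beta_matrix <- function(beta, path) {
  m <- t(beta)
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table (probe_id, gene, region_class)
#' @param path TSV file path.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("probe_id", "gene", "region_class")
  if (!all(need %in% names(df))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$gene[is.na(df$gene)] <- ""
  df
}

#' Read a clinical feature table (CSV, one row per sample)
#' @param path CSV file path.
#' @param id_col name of the sample-id column.
#' @export
read_clinical <- function(path, id_col = "sample_id") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_col %in% names(df)) stop("clinical table lacks column ", id_col, call. = FALSE)
  rownames(df) <- df[[id_col]]
  df
}

#' Write a region matrix as TSV plus a JSON membership map
#' @param regions a `region_matrix` (see [collapse_regions()]).
#' @param path TSV output; the membership map goes to `<path>.membership.json`.
#' @export
write_region_matrix <- function(regions, path) {
  m <- t(regions$values)
  df <- data.frame(region_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(regions$membership, paste0(path, ".membership.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read a region matrix written by [write_region_matrix()]
#' @param path TSV path; expects `<path>.membership.json` alongside.
#' @export
read_region_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  membership <- jsonlite::read_json(paste0(path, ".membership.json"),
                                    simplifyVector = TRUE)
  if (is.data.frame(membership)) membership <- as.list(membership)
  membership <- lapply(membership, as.character)
  new_region_matrix(t(m), membership[ids])
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated: name, description, member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (unique members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  if (any(lengths(sets) == 0L)) stop("GMT contains empty gene sets", call. = FALSE)
  sets
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [pipeline_config()] defaults.
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
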