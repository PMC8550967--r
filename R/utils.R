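# Internal helpers shared across the pipeline stages.

#' Derive a reproducible sub-seed from a master seed and a stage name
#'
#' Each pipeline stage draws its randomness from its own substream so that
#' changing, say, the number of panel-search runs never reshuffles the
#' synthetic cohort. The substream seed is a deterministic 31-bit hash of
#' the master seed and a stage label.
#'
#' @param seed master integer seed.
#' @param stream character label of the substream (e.g. "cohort", "screen").
#' @return an integer in [0, 2^31 - 1] usable with [set.seed()].
#' @keywords internal
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Pearson correlation that maps undefined (zero-variance) pairs to 0
# rather than NA, per the pipeline convention for constant regions/features.
safe_cor <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    return(0)
  }
  stats::cor(x, y)
}

# Column-wise correlation matrix between two matrices, with zero-variance
# columns yielding r = 0 instead of NA.
safe_cor_matrix <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  sx <- apply(x, 2L, stats::sd)
  sy <- apply(y, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(x, y))
  r[!is.finite(r)] <- 0
  r[sx == 0, ] <- 0
  r[, sy == 0] <- 0
  r
}

# Align rows of a matrix/data.frame to the given sample ids, erroring on
# missing samples.
align_samples <- function(x, ids, what = "input") {
  rn <- rownames(x)
  if (is.null(rn)) stop(what, " has no sample ids (rownames)", call. = FALSE)
  missing <- setdiff(ids, rn)
  if (length(missing) > 0L) {
    stop(what, " is missing samples: ", paste(utils::head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  x[ids, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
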