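#' Counts-per-million on raw library sizes
#'
#' CPM computed with no normalization factors and no prior count; this is the
#' scale on which the expression filter operates.
#'
#' @param counts Genes x samples count matrix.
#' @return Matrix of the same shape.
#' @export
cpm_raw <- function(counts) {
  ls <- colSums(counts)
  if (any(ls <= 0))
    stop("sample(s) with non-positive library size: ",
         paste(colnames(counts)[ls <= 0], collapse = ", "))
  sweep(counts, 2, ls, "/") * 1e6
}

#' Filter genes by expression level
#'
#' Retains genes whose CPM exceeds `cpm_threshold` (strictly) in at least
#' `min_samples` samples. CPM is computed on raw library sizes with no prior
#' count, so filtering is independent of normalization. The gene-level
#' default (CPM > 1 in >= 3 samples) matches standard DE practice; exon-level
#' analyses use CPM > 0.125 in >= 10 samples, scaling the gene cutoff down by
#' the average number of exons per gene.
#'
#' @param counts Genes x samples count matrix.
#' @param cpm_threshold CPM value a gene must strictly exceed to count as
#'   expressed in a sample.
#' @param min_samples Minimum number of samples in which the gene must be
#'   expressed; must not exceed the number of samples.
#' @return The filtered count matrix (possibly zero rows).
#' @examples
#' m <- matrix(c(2, 2, 2, 0, 2, 2, 0, 0), 2, 4, byrow = TRUE,
#'             dimnames = list(c("a", "b"), paste0("s", 1:4)))
#' m <- rbind(m, matrix(1e6 - colSums(m), 1, 4, dimnames = list("filler", NULL)))
#' rownames(filter_by_expression(m))
#' @export
filter_by_expression <- function(counts, cpm_threshold = 1, min_samples = 3) {
  if (is.null(dim(counts)) || ncol(counts) == 0L)
    stop("'counts' must be a non-empty matrix")
  if (min_samples > ncol(counts))
    stop("'min_samples' (", min_samples, ") exceeds the number of samples (",
         ncol(counts), ")")
  # a zero-library sample carries only zero counts, hence CPM 0 everywhere
  ls <- pmax(colSums(counts), 1)
  cpm <- sweep(counts, 2, ls, "/") * 1e6
  keep <- rowSums(cpm > cpm_threshold) >= min_samples
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Per-sample scaling factors from the trimmed mean of M-values method: the
#' weighted trimmed mean of gene-wise log2 ratios against a reference sample
#' (the one whose 75th-percentile CPM is closest to the mean 75th percentile),
#' doubly trimmed by M and by average expression, with inverse-variance
#' weights; genes with a zero count in either sample of a pair are excluded.
#' Factors are rescaled so their geometric mean is 1. Computation is
#' delegated to [edgeR::calcNormFactors()].
#'
#' @param counts Genes x samples count matrix; every sample must have a
#'   positive library size.
#' @param logratio_trim Fraction trimmed from each tail of the M values.
#' @param abs_trim Fraction trimmed from each tail of the average (A) values.
#' @return Named numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  ls <- colSums(counts)
  if (any(ls <= 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[ls <= 0], collapse = ", "))
  f <- edgeR::calcNormFactors(as.matrix(counts), method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  names(f) <- colnames(counts)
  f
}

#' TMM-normalized log2 counts-per-million
#'
#' Computes `log2((count + prior_count) / (effective_lib_size + 1) * 1e6)`
#' with `effective_lib_size = library_size * tmm_factor` — the transformation
#' convention of voom. The half-count offset keeps zero counts finite; the +1
#' on the library size keeps the transformed value below `log2(1e6)` even for
#' a count equal to the library size.
#'
#' @param counts Genes x samples count matrix.
#' @param factors Per-sample normalization factors; computed by
#'   [tmm_factors()] when `NULL`.
#' @param prior_count Offset added to every count before the log.
#' @return A `mix_norm` object: list with `logcpm` (matrix), `tmm_factors`,
#'   `lib_sizes` and `effective_lib_sizes`.
#' @examples
#' counts <- matrix(rpois(400, 50), 100, 4,
#'                  dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
#' norm <- log_cpm(counts)
#' range(norm$logcpm)
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("'factors' must be positive and finite")
  ls <- colSums(counts)
  eff <- ls * factors
  lc <- log2(sweep(counts + prior_count, 2, eff + 1, "/") * 1e6)
  structure(
    list(logcpm = lc, tmm_factors = factors, lib_sizes = ls,
         effective_lib_sizes = eff, prior_count = prior_count),
    class = "mix_norm"
  )
}

#' @export
print.mix_norm <- function(x, ...) {
  cat("mix_norm: ", nrow(x$logcpm), " genes x ", ncol(x$logcpm),
      " samples (TMM-normalized log2-CPM, prior count ", x$prior_count,
      ")\n", sep = "")
  invisible(x)
}

# Extract a log-CPM matrix from either a mix_norm object or a bare matrix.
.as_logcpm <- function(expr) {
  if (inherits(expr, "mix_norm")) return(expr$logcpm)
  if (is.matrix(expr)) return(expr)
  stop("'expr' must be a mix_norm object or a log-CPM matrix")
}
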