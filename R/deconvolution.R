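#' Informative-gene filter for deconvolution
#'
#' Under the linear mixture structure `Y = (1 - p) N + p T`, genes expressed
#' at the same level in both sources carry no information about `p`; the
#' filter keeps genes whose pure-sample fold-change `T/N` exceeds `fc_hi` or
#' falls below `fc_lo`. Genes with a zero mean in either source are excluded
#' first and counted.
#'
#' @param pure_mean_N,pure_mean_T Per-gene mean CPM of the pure samples of
#'   the two sources, matched by name/position.
#' @param fc_hi,fc_lo Fold-change cutoffs; `fc_lo < fc_hi` required.
#' @return Logical mask over genes with attribute `n_zero_excluded`.
#' @examples
#' informative_gene_filter(c(a = 10, b = 10, c = 10), c(a = 30, b = 10, c = 4))
#' @export
informative_gene_filter <- function(pure_mean_N, pure_mean_T,
                                    fc_hi = 2, fc_lo = 0.5) {
  if (length(pure_mean_N) != length(pure_mean_T))
    stop("gene universes differ in length")
  if (!is.finite(fc_hi) || !is.finite(fc_lo) || fc_lo >= fc_hi)
    stop("'fc_lo' must be smaller than 'fc_hi'")
  nonzero <- pure_mean_N > 0 & pure_mean_T > 0
  ratio <- pure_mean_T / pure_mean_N
  mask <- nonzero & (ratio > fc_hi | ratio < fc_lo)
  names(mask) <- names(pure_mean_N)
  attr(mask, "n_zero_excluded") <- sum(!nonzero)
  mask
}

#' Estimate the mixing proportion of a mixed sample
#'
#' Least-squares estimate of `p` in `mixed = (1 - p) N + p T` over the masked
#' genes, solved in closed form
#' (`p = sum((mixed - N)(T - N)) / sum((T - N)^2)`) and clipped to `[0, 1]`.
#' Estimation is on the linear CPM scale because the mixture structure is
#' linear in concentrations.
#'
#' @param mixed Per-gene CPM of the mixed sample.
#' @param ref_N,ref_T Per-gene reference CPM profiles of the two pure
#'   sources.
#' @param mask Logical gene mask from [informative_gene_filter()]; must
#'   select at least one gene where the references differ.
#' @return Estimated proportion of source T, in `[0, 1]`.
#' @export
estimate_proportion <- function(mixed, ref_N, ref_T, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(mixed))
  if (length(mixed) != length(ref_N) || length(mixed) != length(ref_T) ||
      length(mask) != length(mixed))
    stop("mixed, ref_N, ref_T and mask must have equal length")
  if (!any(mask)) stop("empty gene mask")
  d <- ref_T[mask] - ref_N[mask]
  if (all(d == 0))
    stop("references identical on every masked gene; proportion unidentifiable")
  p <- sum((mixed[mask] - ref_N[mask]) * d) / sum(d^2)
  min(1, max(0, p))
}

#' Deconvolve a mixed expression profile
#'
#' Inverts the linear mixture for the T component:
#' `T_hat = (mixed - (1 - p) N) / p`, clipped at zero because concentrations
#' are non-negative; the number of clipped genes is reported as attribute
#' `n_clipped`.
#'
#' @param mixed Per-gene CPM of the mixed sample.
#' @param p_hat Estimated proportion of source T; must be > 0.
#' @param ref_N Reference profile of source N.
#' @return Per-gene deconvolved T profile.
#' @export
deconvolve_expression <- function(mixed, p_hat, ref_N) {
  if (!is.finite(p_hat) || p_hat <= 0)
    stop("'p_hat' must be > 0: nothing to deconvolve")
  if (length(mixed) != length(ref_N)) stop("gene universes differ in length")
  raw <- (mixed - (1 - p_hat) * ref_N) / p_hat
  out <- pmax(0, raw)
  attr(out, "n_clipped") <- sum(raw < 0)
  out
}

#' Deconvolve all mixed samples of a mixture experiment
#'
#' Computes TMM-normalized CPM, takes the reference profiles as the per-gene
#' means of the good pure samples (proportion 1 for T, 0 for N), applies the
#' informative-gene filter, and estimates the proportion and deconvolved T
#' profile for every sample with an intermediate proportion.
#'
#' @param counts Genes x samples count matrix.
#' @param design A `mix_design`; pure samples are those at proportion 0 or 1.
#' @param fc_hi,fc_lo Informative-gene fold-change cutoffs.
#' @param include_degraded Also deconvolve degraded mixed samples.
#' @return A `deconvolution_result` list: `estimates` (data frame with
#'   `sample_id`, `proportion`, `p_hat`), `T_hat` (genes x mixed samples),
#'   `mask`, `ref_N`, `ref_T`.
#' @export
deconvolve_samples <- function(counts, design, fc_hi = 2, fc_lo = 0.5,
                               include_degraded = TRUE) {
  f <- tmm_factors(counts)
  cpm <- sweep(counts, 2, colSums(counts) * f, "/") * 1e6
  is_pure_T <- design$proportion == 1 & design$quality == "good"
  is_pure_N <- design$proportion == 0 & design$quality == "good"
  if (!any(is_pure_T) || !any(is_pure_N))
    stop("design must contain good pure samples of both sources")
  ref_T <- rowMeans(cpm[, design$sample_id[is_pure_T], drop = FALSE])
  ref_N <- rowMeans(cpm[, design$sample_id[is_pure_N], drop = FALSE])
  mask <- informative_gene_filter(ref_N, ref_T, fc_hi, fc_lo)
  mixed_rows <- design$proportion > 0 & design$proportion < 1
  if (!include_degraded) mixed_rows <- mixed_rows & design$quality == "good"
  mixed <- design[mixed_rows, , drop = FALSE]
  if (nrow(mixed) == 0L) stop("no mixed samples to deconvolve")

  p_hat <- numeric(nrow(mixed))
  T_hat <- matrix(NA_real_, nrow(cpm), nrow(mixed),
                  dimnames = list(rownames(cpm), mixed$sample_id))
  for (i in seq_len(nrow(mixed))) {
    y <- cpm[, mixed$sample_id[i]]
    p_hat[i] <- estimate_proportion(y, ref_N, ref_T, mask)
    if (p_hat[i] > 0) {
      T_hat[, i] <- deconvolve_expression(y, p_hat[i], ref_N)
    } else {
      # estimate clipped at 0: no T component to recover for this sample
      warning("sample ", mixed$sample_id[i],
              " estimated at proportion 0; profile left missing")
    }
  }
  structure(list(
    estimates = data.frame(sample_id = mixed$sample_id,
                           proportion = mixed$proportion,
                           quality = mixed$quality,
                           p_hat = p_hat, stringsAsFactors = FALSE),
    T_hat = T_hat, mask = mask, ref_N = ref_N, ref_T = ref_T
  ), class = "deconvolution_result")
}

#' Evaluate deconvolution estimates against the design truth
#'
#' Per mixed sample: the proportion error `p_hat - truth` and the Pearson
#' correlation of the deconvolved T profile with the supplied pure T profile.
#' A constant profile makes the correlation undefined; it is reported as
#' `NA` with a warning. The summary attributes give the largest absolute
#' proportion error and the smallest correlation.
#'
#' @param result A `deconvolution_result` from [deconvolve_samples()].
#' @param truth_proportions True proportions, matched to
#'   `result$estimates$sample_id` (defaults to the design proportions stored
#'   in the result).
#' @param truth_profile Per-gene CPM profile of the pure T source.
#' @return Data frame with `sample_id`, `p_hat`, `truth`, `error`,
#'   `correlation`; attributes `max_abs_error`, `min_correlation`.
#' @export
evaluate_deconvolution <- function(result, truth_proportions = NULL,
                                   truth_profile = NULL) {
  est <- result$estimates
  if (is.null(truth_proportions)) truth_proportions <- est$proportion
  if (length(truth_proportions) != nrow(est))
    stop("'truth_proportions' length must match the number of mixed samples")
  corr <- rep(NA_real_, nrow(est))
  if (!is.null(truth_profile)) {
    if (length(truth_profile) != nrow(result$T_hat))
      stop("'truth_profile' length must match the gene universe")
    if (stats::sd(truth_profile) == 0) {
      warning("constant truth profile; correlations undefined")
    } else {
      for (i in seq_len(nrow(est))) {
        th <- result$T_hat[, i]
        if (any(!is.finite(th))) {
          corr[i] <- NA_real_
        } else if (stats::sd(th) == 0) {
          warning("constant deconvolved profile for ", est$sample_id[i])
        } else {
          corr[i] <- stats::cor(th, truth_profile)
        }
      }
    }
  }
  out <- data.frame(sample_id = est$sample_id, p_hat = est$p_hat,
                    truth = truth_proportions,
                    error = est$p_hat - truth_proportions,
                    correlation = corr, stringsAsFactors = FALSE)
  attr(out, "max_abs_error") <- max(abs(out$error))
  attr(out, "min_correlation") <- if (all(is.na(corr))) NA_real_
                                  else min(corr, na.rm = TRUE)
  out
}
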