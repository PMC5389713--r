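#' Fit the gene-wise non-linear mixture model
#'
#' For each gene the log-CPM values across the titration series are modelled
#' as
#' \deqn{logCPM_{gi} = \log_2\{p_i X_g + (1 - p_i) Y_g\} + \epsilon_{gi},}
#' where \eqn{p_i} is the known mixing proportion of source A in sample
#' \eqn{i}, \eqn{X_g} and \eqn{Y_g} are the gene's concentrations in the two
#' pure sources, and the errors have mean zero and gene-specific standard
#' deviation \eqn{\phi_g}. Least-squares estimates are obtained by a
#' vectorized Gauss-Newton algorithm run simultaneously over all genes,
#' parameterized in \eqn{(a, b) = (\log_2 X, \log_2 Y)} so positivity is
#' automatic, with per-gene step-halving and a small Levenberg ridge for
#' near-singular steps. Unweighted least squares is used.
#'
#' Starting values come from a per-gene linear regression of `2^logCPM` on
#' `(p, 1 - p)` without intercept; genes whose linear coefficients are not
#' positive fall back to the mean log-CPM of the samples at the extreme
#' proportions.
#'
#' @param expr A `mix_norm` object from [log_cpm()] or a log-CPM matrix with
#'   sample-id column names; rows must be finite.
#' @param design A `mix_design` naming the samples to fit; every
#'   `sample_id` must be a column of `expr`, and extra columns of `expr` are
#'   ignored. At least 3 samples spanning at least 2 distinct proportions
#'   are required.
#' @param max_iter Maximum Gauss-Newton iterations per gene.
#' @param tol Convergence tolerance on the relative decrease in the residual
#'   sum of squares.
#'
#' @return A `mixture_fit` data frame with one row per gene: `gene_id`,
#'   `Xhat`, `Yhat`, `M` (= log2(Xhat) - log2(Yhat)), `phi_hat`
#'   (= sqrt(RSS / (n - 2))), `converged`, `n_iter`. Attributes:
#'   `samples_used` (sample ids in fit order), `proportions`, `n_samples`.
#'   Non-converged genes are flagged, not dropped; their values come from the
#'   best iterate.
#'
#' @examples
#' p <- rep(c(1, 0.75, 0.5, 0.25, 0), each = 3)
#' design <- data.frame(sample_id = sprintf("s%02d", 1:15), proportion = p,
#'                      replicate = rep(1:3, 5), quality = "good")
#' Z <- rbind(g1 = log2(p * 64 + (1 - p) * 16))
#' colnames(Z) <- design$sample_id
#' fit <- fit_mixture(Z, design)
#' fit[, c("Xhat", "Yhat", "M")]
#' @export
fit_mixture <- function(expr, design, max_iter = 50, tol = 1e-8) {
  Z <- .as_logcpm(expr)
  if (is.null(colnames(Z))) stop("'expr' must have sample-id column names")
  if (!all(c("sample_id", "proportion") %in% names(design)))
    stop("'design' must have sample_id and proportion columns")
  missing <- setdiff(design$sample_id, colnames(Z))
  if (length(missing))
    stop("design sample(s) absent from 'expr': ", paste(missing, collapse = ", "))
  Z <- Z[, design$sample_id, drop = FALSE]
  p <- design$proportion
  n <- length(p)
  if (n < 3L) stop("at least 3 samples are required")
  if (length(unique(p)) < 2L)
    stop("design error: fewer than 2 distinct proportions; ",
         "the mixture model is unidentifiable")

  bad_rows <- !apply(Z, 1L, function(z) all(is.finite(z)))
  if (any(bad_rows)) {
    warning(sum(bad_rows), " gene(s) with non-finite log-CPM excluded from the fit")
    Z <- Z[!bad_rows, , drop = FALSE]
  }
  G <- nrow(Z)
  if (G == 0L) stop("no genes left to fit")

  # --- initialization: LS of 2^logCPM on (p, 1-p), positive-clipped --------
  P <- cbind(p, 1 - p)
  W <- 2^Z
  coef <- W %*% P %*% solve(crossprod(P))      # G x 2
  hi <- p == max(p); lo <- p == min(p)
  a_fb <- rowMeans(Z[, hi, drop = FALSE])
  b_fb <- rowMeans(Z[, lo, drop = FALSE])
  ok1 <- is.finite(coef[, 1]) & coef[, 1] > 0
  ok2 <- is.finite(coef[, 2]) & coef[, 2] > 0
  a <- a_fb; a[ok1] <- log2(coef[ok1, 1])
  b <- b_fb; b[ok2] <- log2(coef[ok2, 2])

  sse_of <- function(a, b) {
    S <- (2^a) %o% p + (2^b) %o% (1 - p)
    rowSums((Z - log2(S))^2)
  }
  SSE <- sse_of(a, b)
  converged <- rep(FALSE, G)
  n_iter <- rep(0L, G)
  active <- rep(TRUE, G)
  abs_floor <- 1e-24 * n

  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    idx <- which(active)
    aa <- a[idx]; bb <- b[idx]
    Za <- Z[idx, , drop = FALSE]
    X <- 2^aa; Y <- 2^bb
    S <- X %o% p + Y %o% (1 - p)
    R <- Za - log2(S)
    J1 <- (X %o% p) / S
    J2 <- (Y %o% (1 - p)) / S
    A11 <- rowSums(J1 * J1); A12 <- rowSums(J1 * J2); A22 <- rowSums(J2 * J2)
    g1 <- rowSums(J1 * R);   g2 <- rowSums(J2 * R)
    ridge <- 1e-10 * (A11 + A22) + 1e-300
    det <- (A11 + ridge) * (A22 + ridge) - A12^2
    da <- ((A22 + ridge) * g1 - A12 * g2) / det
    db <- ((A11 + ridge) * g2 - A12 * g1) / det
    # cap absurd steps (log2 units) before halving
    cap <- pmax(abs(da), abs(db))
    shrink <- ifelse(cap > 16, 16 / cap, 1)
    da <- da * shrink; db <- db * shrink

    old_sse <- SSE[idx]
    step <- rep(1, length(idx))
    new_a <- aa + da; new_b <- bb + db
    new_sse <- {
      Sn <- (2^new_a) %o% p + (2^new_b) %o% (1 - p)
      rowSums((Za - log2(Sn))^2)
    }
    for (h in seq_len(20L)) {
      worse <- which(!(new_sse <= old_sse) )
      if (!length(worse)) break
      step[worse] <- step[worse] / 2
      new_a[worse] <- aa[worse] + step[worse] * da[worse]
      new_b[worse] <- bb[worse] + step[worse] * db[worse]
      Sw <- (2^new_a[worse]) %o% p + (2^new_b[worse]) %o% (1 - p)
      new_sse[worse] <- rowSums((Za[worse, , drop = FALSE] - log2(Sw))^2)
    }
    improved <- new_sse <= old_sse
    # keep best iterate
    new_a[!improved] <- aa[!improved]
    new_b[!improved] <- bb[!improved]
    new_sse[!improved] <- old_sse[!improved]

    a[idx] <- new_a; b[idx] <- new_b; SSE[idx] <- new_sse
    n_iter[idx] <- iter
    rel_dec <- (old_sse - new_sse) / pmax(old_sse, .Machine$double.xmin)
    done <- rel_dec < tol | new_sse < abs_floor | !improved
    converged[idx[done]] <- TRUE
    active[idx[done]] <- FALSE
  }
  # genes still active after max_iter did not meet the tolerance
  converged[active] <- FALSE

  out <- data.frame(
    gene_id = rownames(Z),
    Xhat = 2^a,
    Yhat = 2^b,
    M = a - b,
    phi_hat = if (n > 2) sqrt(SSE / (n - 2)) else rep(NA_real_, G),
    converged = converged,
    n_iter = n_iter,
    stringsAsFactors = FALSE
  )
  attr(out, "samples_used") <- design$sample_id
  attr(out, "proportions") <- p
  attr(out, "n_samples") <- n
  attr(out, "rss") <- SSE
  attr(out, "excluded_genes") <- if (any(bad_rows)) sum(bad_rows) else 0L
  class(out) <- c("mixture_fit", "data.frame")
  out
}

#' Predict log-fold-changes between two mixing proportions
#'
#' From the fitted concentrations, the log2 fold-change between a group mixed
#' at proportion `p` and one mixed at proportion `q` is
#' \deqn{\hat\delta_g(p, q) = \log_2\{p \hat X_g + (1-p) \hat Y_g\}
#'   - \log_2\{q \hat X_g + (1-q) \hat Y_g\}.}
#' Non-converged genes yield `NA`. The prediction is antisymmetric in
#' `(p, q)`, zero at `p == q`, and equals the fitted `M` at `(1, 0)`.
#'
#' @param fit A `mixture_fit` from [fit_mixture()].
#' @param p,q Mixing proportions of the two groups, each in `[0, 1]`.
#' @return A `contrast_prediction` data frame: `gene_id`, `delta`; attributes
#'   `p` and `q`.
#' @export
predicted_logfc <- function(fit, p, q) {
  if (!inherits(fit, "mixture_fit")) stop("'fit' must be a mixture_fit")
  if (!is.finite(p) || p < 0 || p > 1 || !is.finite(q) || q < 0 || q > 1)
    stop("'p' and 'q' must lie in [0, 1]")
  delta <- log2(p * fit$Xhat + (1 - p) * fit$Yhat) -
    log2(q * fit$Xhat + (1 - q) * fit$Yhat)
  delta[!fit$converged] <- NA_real_
  out <- data.frame(gene_id = fit$gene_id, delta = delta,
                    stringsAsFactors = FALSE)
  attr(out, "p") <- p
  attr(out, "q") <- q
  class(out) <- c("contrast_prediction", "data.frame")
  out
}

#' Root-mean-square error of estimated versus predicted log-fold-changes
#'
#' \deqn{RMSE = \sqrt{ \frac{1}{G} \sum_g (logFC_g - \hat\delta_g(p,q))^2 }}
#' over the G genes shared between the estimate and the prediction. Genes
#' with a missing prediction (non-converged fits) are excluded pairwise and
#' the exclusion count reported as attribute `n_excluded`.
#'
#' @param estimated Named numeric vector of per-gene log-fold-changes, or a
#'   data frame with `gene_id` and `logFC` columns (e.g. a `de_result`).
#' @param predicted A `contrast_prediction` from [predicted_logfc()].
#' @return The RMSE as a single number, with attributes `n` (genes compared)
#'   and `n_excluded`.
#' @export
rmse_logfc <- function(estimated, predicted) {
  if (is.data.frame(estimated)) {
    if (!all(c("gene_id", "logFC") %in% names(estimated)))
      stop("'estimated' data frame needs gene_id and logFC columns")
    est <- stats::setNames(estimated$logFC, estimated$gene_id)
  } else {
    if (is.null(names(estimated)))
      stop("'estimated' vector must be named by gene id")
    est <- estimated
  }
  pred <- stats::setNames(predicted$delta, predicted$gene_id)
  genes <- intersect(names(est), names(pred))
  if (!length(genes)) stop("no genes in common between estimate and prediction")
  ok <- is.finite(est[genes]) & is.finite(pred[genes])
  if (!any(ok)) stop("no finite pairs to compare")
  d <- est[genes][ok] - pred[genes][ok]
  out <- sqrt(mean(d^2))
  attr(out, "n") <- sum(ok)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Refit the mixture model excluding a comparison's samples
#'
#' To score a differential-expression comparison against model predictions
#' without over-fitting, the samples used in that comparison are excluded
#' from the non-linear fit and the predictions come from the remaining
#' samples only.
#'
#' @param expr,design,max_iter,tol As in [fit_mixture()].
#' @param exclude Sample ids to drop: a character vector, or a list of two
#'   character vectors (the comparison's two groups).
#' @return A `mixture_fit` on the retained samples; `samples_used` records
#'   the retained sample ids.
#' @export
leave_out_fit <- function(expr, design, exclude, max_iter = 50, tol = 1e-8) {
  if (is.list(exclude)) exclude <- unique(unlist(exclude, use.names = FALSE))
  if (!is.character(exclude)) stop("'exclude' must give sample ids")
  Z <- .as_logcpm(expr)
  unknown <- setdiff(exclude, colnames(Z))
  if (length(unknown))
    stop("unknown sample id(s) in 'exclude': ", paste(unknown, collapse = ", "))
  keep <- setdiff(colnames(Z), exclude)
  kept_design <- design[design$sample_id %in% keep, , drop = FALSE]
  if (length(unique(kept_design$proportion)) < 2L)
    stop("design error: exclusion leaves fewer than 2 distinct proportions")
  fit_mixture(Z[, keep, drop = FALSE], kept_design,
              max_iter = max_iter, tol = tol)
}
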