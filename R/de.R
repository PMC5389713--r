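#' Moderated two-group t-test on log-CPM
#'
#' A deliberately simple reference differential-expression method so the
#' benchmark harness can run end-to-end without any external caller. For
#' every gene: `logFC` is the difference of group mean log-CPMs, the pooled
#' variance \eqn{s_g^2} is shrunk towards its across-gene mean \eqn{s_0^2}
#' (a method-of-moments prior location) via
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},}
#' and a two-sided t-test on \eqn{d_g + d_0} degrees of freedom is applied.
#' With `prior_df = 0` this is the ordinary pooled two-sample t-test; as
#' `prior_df` grows it approaches a z-like test with common variance
#' \eqn{s_0^2}. The default `prior_df = 4` reflects the strongly
#' gene-specific variability regime a mixture experiment with biological
#' replication produces.
#'
#' @param expr A `mix_norm` object or log-CPM matrix.
#' @param group1,group2 Disjoint character vectors of sample ids, each of
#'   size >= 2. `logFC` is group1 minus group2.
#' @param prior_df Prior degrees of freedom (>= 0; may be `Inf`).
#' @param fdr_cutoff Cutoff defining the `significant` column.
#' @param method_label Label stored with the result.
#' @return A `de_result` data frame: `gene_id`, `logFC`, `p_value`, `fdr`,
#'   `significant`, `method_label`.
#' @export
moderated_two_group_test <- function(expr, group1, group2, prior_df = 4,
                                     fdr_cutoff = 0.05,
                                     method_label = "moderated-t") {
  Z <- .as_logcpm(expr)
  if (length(intersect(group1, group2)))
    stop("groups overlap: ", paste(intersect(group1, group2), collapse = ", "))
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 samples")
  miss <- setdiff(c(group1, group2), colnames(Z))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  if (!is.finite(prior_df) && !is.infinite(prior_df) || prior_df < 0)
    stop("'prior_df' must be >= 0")

  Z1 <- Z[, group1, drop = FALSE]
  Z2 <- Z[, group2, drop = FALSE]
  n1 <- ncol(Z1); n2 <- ncol(Z2)
  m1 <- rowMeans(Z1); m2 <- rowMeans(Z2)
  logFC <- m1 - m2
  df <- n1 + n2 - 2
  s2 <- (rowSums((Z1 - m1)^2) + rowSums((Z2 - m2)^2)) / df
  s02 <- mean(s2)
  post <- if (is.infinite(prior_df)) rep(s02, length(s2))
          else if (prior_df == 0) s2
          else (prior_df * s02 + df * s2) / (prior_df + df)
  tt <- logFC / sqrt(post * (1 / n1 + 1 / n2))
  total_df <- if (is.infinite(prior_df)) Inf else df + prior_df
  p <- 2 * stats::pt(-abs(tt), df = total_df)
  p[!is.finite(tt)] <- ifelse(logFC[!is.finite(tt)] == 0, 1, 0)
  fdr <- bh_adjust(p)
  out <- data.frame(
    gene_id = rownames(Z), logFC = logFC, p_value = p, fdr = fdr,
    significant = fdr < fdr_cutoff, method_label = method_label,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1
#' and mapped back to input order; delegated to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("'p_values' must be numeric")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Read or write differential-expression result tables
#'
#' The `de_result` TSV (gene_id, logFC, p_value, fdr, significant,
#' method_label) is the interchange format every benchmark operation
#' consumes; results from any external caller can be ingested through it.
#' On read, `fdr` is recomputed from `p_value` only when absent.
#'
#' @param result A `de_result` data frame.
#' @param path File path.
#' @param fdr_cutoff Cutoff used to reconstruct `significant` when absent.
#' @name de_io
NULL

#' @rdname de_io
#' @export
write_de_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(result)
}

#' @rdname de_io
#' @export
read_de_tsv <- function(path, fdr_cutoff = 0.05) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "logFC", "p_value") %in% names(df)))
    stop("a de_result table needs at least gene_id, logFC, p_value")
  if (is.null(df$fdr)) df$fdr <- bh_adjust(df$p_value)
  if (is.null(df$significant)) df$significant <- df$fdr < fdr_cutoff
  if (is.null(df$method_label)) df$method_label <- "external"
  class(df) <- c("de_result", "data.frame")
  df
}
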