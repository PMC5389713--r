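#' Significant genes of a DE result at a cutoff
#'
#' @param result A `de_result` with an `fdr` column.
#' @param fdr_cutoff FDR cutoff; genes with `fdr < fdr_cutoff` (strictly) are
#'   significant.
#' @return Character vector of gene ids.
#' @export
significant_genes <- function(result, fdr_cutoff = 0.05) {
  if (is.null(result$fdr)) stop("'result' has no fdr column")
  result$gene_id[result$fdr < fdr_cutoff]
}

#' Sensitivity: number of genes called significant
#'
#' In a mixture design the same genes are differentially expressed in every
#' comparison, so the raw count of discoveries at a fixed FDR cutoff is a
#' within-method sensitivity measure.
#'
#' @inheritParams significant_genes
#' @return Integer count.
#' @export
sensitivity <- function(result, fdr_cutoff = 0.05) {
  length(significant_genes(result, fdr_cutoff))
}

# Intersect two results' gene universes; returns list of the two subsets.
.shared_universe <- function(anchor, subtle) {
  genes <- intersect(anchor$gene_id, subtle$gene_id)
  if (!length(genes)) stop("anchor and subtle share no genes")
  list(anchor = anchor[match(genes, anchor$gene_id), , drop = FALSE],
       subtle = subtle[match(genes, subtle$gene_id), , drop = FALSE],
       dropped = length(anchor$gene_id) + length(subtle$gene_id) - 2L * length(genes))
}

#' Recovery rate of a subtler comparison against an anchor
#'
#' The proportion of the anchor comparison's significant genes (typically the
#' pure-versus-pure comparison, where differences are largest) that are also
#' significant in a subtler comparison by the same method:
#' `|S_anchor intersect S_subtle| / |S_anchor|`. Gene universes are
#' intersected first. If the anchor has no significant genes the rate is
#' undefined and `NA` is returned with a warning.
#'
#' @param anchor,subtle `de_result` tables from the same method on the two
#'   comparisons.
#' @param fdr_cutoff FDR cutoff applied to both.
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
recovery_rate <- function(anchor, subtle, fdr_cutoff = 0.05) {
  u <- .shared_universe(anchor, subtle)
  sa <- significant_genes(u$anchor, fdr_cutoff)
  ss <- significant_genes(u$subtle, fdr_cutoff)
  if (!length(sa)) {
    warning("anchor comparison has no significant genes; recovery undefined")
    return(NA_real_)
  }
  length(intersect(sa, ss)) / length(sa)
}

#' Inconsistency rate of a subtler comparison against an anchor
#'
#' The proportion of the subtler comparison's significant genes that are
#' absent from the anchor's significant set:
#' `|S_subtle \\ S_anchor| / |S_subtle|`. Genes significant only where the
#' signal is weaker are treated as a method's errors. If the subtle
#' comparison has no significant genes the rate is undefined (`NA` with a
#' warning), mirroring the exclusion of comparisons with no detections.
#'
#' @inheritParams recovery_rate
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
inconsistency_rate <- function(anchor, subtle, fdr_cutoff = 0.05) {
  u <- .shared_universe(anchor, subtle)
  sa <- significant_genes(u$anchor, fdr_cutoff)
  ss <- significant_genes(u$subtle, fdr_cutoff)
  if (!length(ss)) {
    warning("subtle comparison has no significant genes; inconsistency undefined")
    return(NA_real_)
  }
  length(setdiff(ss, sa)) / length(ss)
}

#' Membership counts of every intersection region of significant sets
#'
#' Venn-style region counts for 2 to 5 result sets over their shared gene
#' universe. Regions are keyed by a 0/1 membership pattern in the order of
#' `results`; counts over all non-empty patterns sum to the size of the
#' union of significant sets.
#'
#' @param results Named list of 2-5 `de_result` tables.
#' @param fdr_cutoff FDR cutoff.
#' @return Data frame with one row per membership pattern (2^k - 1 rows):
#'   `region` (e.g. "110"), one logical column per result, and `count`.
#' @export
overlap_sets <- function(results, fdr_cutoff = 0.05) {
  k <- length(results)
  if (k < 2L || k > 5L) stop("between 2 and 5 result sets are supported")
  if (is.null(names(results))) names(results) <- paste0("set", seq_len(k))
  genes <- Reduce(intersect, lapply(results, function(r) r$gene_id))
  if (!length(genes)) stop("result sets share no genes")
  sets <- lapply(results, function(r)
    intersect(significant_genes(r, fdr_cutoff), genes))
  un <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) un %in% s, logical(length(un)))
  if (length(un) == 0L) member <- matrix(logical(0), 0, k)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  colnames(patterns) <- names(results)
  code <- apply(patterns, 1L, function(x) paste0(as.integer(x), collapse = ""))
  counts <- if (length(un)) {
    obs <- apply(member, 1L, function(x) paste0(as.integer(x), collapse = ""))
    as.integer(table(factor(obs, levels = code)))
  } else {
    integer(length(code))
  }
  out <- data.frame(region = code, patterns, count = counts,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

# "075:025" or c(0.75, 0.25) -> numeric pair
.parse_comparison <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("comparison string must look like '075:025'")
    x <- as.numeric(parts) / 100
  }
  x <- as.numeric(x)
  if (length(x) != 2L || any(!is.finite(x)) || any(x < 0 | x > 1))
    stop("a comparison is a pair of proportions in [0, 1]")
  x
}

.comparison_label <- function(pq) {
  paste0(sprintf("%03d", round(100 * pq[1])), "v", sprintf("%03d", round(100 * pq[2])))
}

# Sample ids of the good replicates at a proportion (or degraded-substituted).
.group_samples <- function(design, prop, use_degraded = FALSE,
                           degraded_replicate = NULL) {
  rows <- design[abs(design$proportion - prop) < 1e-9, , drop = FALSE]
  if (!use_degraded) return(rows$sample_id[rows$quality == "good"])
  deg <- rows[rows$quality == "degraded", , drop = FALSE]
  good <- rows[rows$quality == "good" &
                 !(rows$replicate %in% deg$replicate), , drop = FALSE]
  c(good$sample_id, deg$sample_id)
}

#' Run the full within-method benchmark over a set of comparisons
#'
#' Filters and normalizes the counts, then for every comparison (a pair of
#' mixing proportions, each group being the good replicates at that
#' proportion) runs every method, computes its sensitivity, its recovery and
#' inconsistency rates against the anchor comparison, and the RMSE of its
#' estimated log-fold-changes against the predictions of a leave-out mixture
#' model fitted without the comparison's samples.
#'
#' @param counts Genes x samples count matrix.
#' @param design A `mix_design` covering the columns of `counts`.
#' @param comparisons List of proportion pairs, numeric `c(p, q)` or strings
#'   like `"075:025"`. The anchor is prepended if absent.
#' @param methods Named list of functions `f(norm, group1, group2)` returning
#'   a `de_result`; defaults to the built-in moderated t-test. A method that
#'   errors on a comparison is recorded as missing and the run continues.
#' @param fdr_cutoff FDR cutoff for all set metrics.
#' @param anchor Anchor comparison (default pure versus pure, which should
#'   yield the most discoveries).
#' @param cpm_threshold,min_samples Expression-filter settings.
#' @param prior_df Prior degrees of freedom for the default method.
#' @param use_degraded Replace the good sample of each degraded replicate
#'   with its degraded twin when forming groups.
#'
#' @return A `benchmark_report` list: `sensitivity`, `rates` and `rmse` data
#'   frames (method x comparison), `fdr_cutoff`, `anchor`, `G` (genes after
#'   filtering), and the per-comparison `de_results`.
#' @export
run_benchmark <- function(counts, design,
                          comparisons = list(c(1, 0), c(0.75, 0.25),
                                             c(0.5, 0.25), c(0.75, 0.5)),
                          methods = NULL,
                          fdr_cutoff = 0.05,
                          anchor = c(1, 0),
                          cpm_threshold = 1, min_samples = 3,
                          prior_df = 4,
                          use_degraded = FALSE) {
  anchor <- .parse_comparison(anchor)
  comparisons <- lapply(comparisons, .parse_comparison)
  labels <- vapply(comparisons, .comparison_label, character(1))
  anchor_label <- .comparison_label(anchor)
  if (!anchor_label %in% labels) {
    comparisons <- c(list(anchor), comparisons)
    labels <- c(anchor_label, labels)
  }
  if (is.null(methods)) {
    methods <- list("moderated-t" = function(norm, g1, g2)
      moderated_two_group_test(norm, g1, g2, prior_df = prior_df,
                               fdr_cutoff = fdr_cutoff))
  }

  filtered <- filter_by_expression(counts, cpm_threshold, min_samples)
  norm <- log_cpm(filtered)
  G <- nrow(filtered)

  de_results <- list()
  rmse_rows <- list()
  sens_rows <- list()
  for (ci in seq_along(comparisons)) {
    pq <- comparisons[[ci]]
    lab <- labels[ci]
    g1 <- .group_samples(design, pq[1], use_degraded)
    g2 <- .group_samples(design, pq[2], use_degraded)
    if (length(g1) < 2L || length(g2) < 2L)
      stop("comparison ", lab, " does not map to groups of >= 2 samples")
    lo_fit <- leave_out_fit(norm, design, exclude = c(g1, g2))
    pred <- predicted_logfc(lo_fit, pq[1], pq[2])
    for (m in names(methods)) {
      res <- tryCatch(methods[[m]](norm, g1, g2), error = function(e) {
        warning("method '", m, "' failed on ", lab, ": ", conditionMessage(e))
        NULL
      })
      de_results[[lab]][[m]] <- res
      sens_rows[[length(sens_rows) + 1L]] <- data.frame(
        method = m, comparison = lab,
        sensitivity = if (is.null(res)) NA_integer_
                      else sensitivity(res, fdr_cutoff),
        stringsAsFactors = FALSE)
      rm_val <- if (is.null(res)) NA_real_ else as.numeric(rmse_logfc(res, pred))
      rmse_rows[[length(rmse_rows) + 1L]] <- data.frame(
        method = m, comparison = lab, rmse = rm_val,
        stringsAsFactors = FALSE)
    }
  }

  rate_rows <- list()
  for (lab in labels) {
    for (m in names(methods)) {
      a <- de_results[[anchor_label]][[m]]
      s <- de_results[[lab]][[m]]
      rec <- inc <- NA_real_
      if (!is.null(a) && !is.null(s)) {
        rec <- suppressWarnings(recovery_rate(a, s, fdr_cutoff))
        inc <- suppressWarnings(inconsistency_rate(a, s, fdr_cutoff))
      }
      rate_rows[[length(rate_rows) + 1L]] <- data.frame(
        method = m, anchor = anchor_label, comparison = lab,
        recovery = rec, inconsistency = inc, stringsAsFactors = FALSE)
    }
  }

  structure(list(
    sensitivity = do.call(rbind, sens_rows),
    rates = do.call(rbind, rate_rows),
    rmse = do.call(rbind, rmse_rows),
    fdr_cutoff = fdr_cutoff,
    anchor = anchor_label,
    G = G,
    de_results = de_results
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report: ", x$G, " genes, FDR cutoff ", x$fdr_cutoff,
      ", anchor ", x$anchor, "\n\n", sep = "")
  print(x$rates, row.names = FALSE)
  invisible(x)
}
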