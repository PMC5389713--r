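#' Simulate ground-truth reference transcriptomes for a two-source mixture
#'
#' Draws per-gene concentrations for the two RNA sources of a mixture design.
#' Source-A concentrations `X` are log-normal on the CPM scale (the design
#' gives no generative model for abundance; log-normal reproduces the wide
#' dynamic range seen in real titration data). A fixed fraction of genes is
#' differentially expressed between the sources: their log2 ratio is drawn
#' from a zero-mean normal truncated away from the DE threshold, all other
#' genes have ratio exactly 1. Gene-specific negative-binomial dispersions
#' follow a scaled inverse chi-square with low prior degrees of freedom, so
#' that gene-level variability is gene-specific rather than purely technical.
#'
#' @param n_genes Number of genes (>= 1).
#' @param de_fraction Fraction of genes differentially expressed between the
#'   two sources; exactly `round(n_genes * de_fraction)` genes are DE.
#' @param lfc_sd Standard deviation of the log2 ratio for DE genes (> 0).
#' @param abundance_params List with `meanlog` and `sdlog` for the log-normal
#'   abundance of source A on the CPM scale.
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#'   The caller's RNG state is left untouched.
#' @param de_lfc_threshold Absolute log2-ratio at or above which a gene is
#'   considered DE; DE draws are truncated away from `(-t, t)`.
#' @param dispersion_mean Mean negative-binomial dispersion across genes
#'   (edgeR convention, `var = mu + dispersion * mu^2`). Zero gives Poisson
#'   counts for every gene.
#' @param dispersion_prior_df Prior degrees of freedom of the scaled inverse
#'   chi-square spread of gene-wise dispersions (> 2). Low values (default 5)
#'   emulate gene-specific biological variability; `Inf` gives a constant
#'   dispersion, the purely technical regime.
#'
#' @return A `mix_reference` data frame with columns `gene_id`, `X`, `Y`,
#'   `R` (= X/Y), `phi` (asymptotic log2-scale residual standard deviation,
#'   `sqrt(dispersion)/log(2)`), `dispersion` and `is_de`, plus attribute
#'   `de_lfc_threshold`.
#'
#' @examples
#' ref <- simulate_reference_profiles(100, de_fraction = 0.2, seed = 1)
#' sum(ref$is_de)
#' @export
simulate_reference_profiles <- function(n_genes,
                                        de_fraction = 0.1,
                                        lfc_sd = 2,
                                        abundance_params = list(meanlog = log(50), sdlog = 1.5),
                                        seed = NULL,
                                        de_lfc_threshold = 1,
                                        dispersion_mean = 0.05,
                                        dispersion_prior_df = 5) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || !is.finite(n_genes) || n_genes < 1)
    stop("'n_genes' must be a single integer >= 1")
  n_genes <- as.integer(n_genes)
  if (!is.numeric(de_fraction) || !is.finite(de_fraction) ||
      de_fraction < 0 || de_fraction > 1)
    stop("'de_fraction' must be a finite value in [0, 1]")
  if (!is.numeric(lfc_sd) || !is.finite(lfc_sd) || lfc_sd <= 0)
    stop("'lfc_sd' must be a finite value > 0")
  if (!is.list(abundance_params) ||
      !all(c("meanlog", "sdlog") %in% names(abundance_params)) ||
      !all(is.finite(unlist(abundance_params[c("meanlog", "sdlog")]))))
    stop("'abundance_params' must be a list with finite 'meanlog' and 'sdlog'")
  if (!is.finite(de_lfc_threshold) || de_lfc_threshold < 0)
    stop("'de_lfc_threshold' must be finite and >= 0")
  if (!is.numeric(dispersion_mean) || is.na(dispersion_mean) || dispersion_mean < 0)
    stop("'dispersion_mean' must be >= 0")
  if (is.finite(dispersion_prior_df) && dispersion_prior_df <= 2)
    stop("'dispersion_prior_df' must be > 2 (or Inf for constant dispersion)")

  draw <- function() {
    X <- stats::rlnorm(n_genes, abundance_params$meanlog, abundance_params$sdlog)
    lr <- numeric(n_genes)
    n_de <- as.integer(round(n_genes * de_fraction))
    if (n_de > 0L) {
      idx <- sample.int(n_genes, n_de)
      # rejection-sample N(0, lfc_sd^2) truncated away from (-t, t)
      vals <- numeric(0)
      while (length(vals) < n_de) {
        cand <- stats::rnorm(2L * n_de, 0, lfc_sd)
        vals <- c(vals, cand[abs(cand) >= de_lfc_threshold])
      }
      lr[idx] <- vals[seq_len(n_de)]
    }
    if (dispersion_mean == 0) {
      disp <- rep(0, n_genes)
    } else if (is.infinite(dispersion_prior_df)) {
      disp <- rep(dispersion_mean, n_genes)
    } else {
      # scaled inverse chi-square with mean dispersion_mean
      disp <- dispersion_mean * (dispersion_prior_df - 2) /
        stats::rchisq(n_genes, df = dispersion_prior_df)
    }
    list(X = X, lr = lr, disp = disp)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())

  out <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(n_genes)),
    X = d$X,
    Y = d$X / 2^d$lr,
    R = 2^d$lr,
    phi = sqrt(d$disp) / log(2),
    dispersion = d$disp,
    is_de = abs(d$lr) >= de_lfc_threshold,
    stringsAsFactors = FALSE
  )
  attr(out, "de_lfc_threshold") <- de_lfc_threshold
  class(out) <- c("mix_reference", "data.frame")
  out
}

#' Build the default mixture-experiment sample layout
#'
#' The default design mirrors the classic titration layout: the two pure
#' sources (proportions 1 and 0 of source A) and three intermediate mixtures
#' (0.75, 0.5, 0.25), each grown and mixed independently `n_replicates` times.
#' One designated replicate of every proportion is additionally duplicated as
#' a degraded aliquot, emulating a sample whose RNA integrity was deliberately
#' compromised; the duplicate shares its twin's proportion and replicate index
#' and differs only in `quality`.
#'
#' @param n_replicates Number of good replicates per proportion (>= 1).
#' @param degraded_replicate Index of the replicate that gets a degraded
#'   duplicate at every proportion (<= `n_replicates`); `NULL` or 0 for no
#'   degraded samples.
#' @param proportions Mixing proportions of source A; at least two distinct
#'   values in `[0, 1]`.
#' @param protocol Protocol label stored with every sample.
#'
#' @return A `mix_design` data frame with columns `sample_id`, `proportion`,
#'   `replicate`, `quality` ("good"/"degraded") and `protocol`. Defaults give
#'   15 good + 5 degraded = 20 samples.
#'
#' @examples
#' design <- make_default_design()
#' table(design$quality)
#' @export
make_default_design <- function(n_replicates = 3,
                                degraded_replicate = 2,
                                proportions = c(1, 0.75, 0.5, 0.25, 0),
                                protocol = "polyA") {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      !is.finite(n_replicates) || n_replicates < 1)
    stop("'n_replicates' must be a single integer >= 1")
  n_replicates <- as.integer(n_replicates)
  if (is.null(degraded_replicate) || identical(degraded_replicate, 0) ||
      identical(degraded_replicate, 0L)) {
    degraded_replicate <- NA_integer_
  } else {
    degraded_replicate <- as.integer(degraded_replicate)
    if (is.na(degraded_replicate) || degraded_replicate < 1 ||
        degraded_replicate > n_replicates)
      stop("'degraded_replicate' must lie between 1 and 'n_replicates'")
  }
  if (any(!is.finite(proportions)) || any(proportions < 0 | proportions > 1))
    stop("'proportions' must all lie in [0, 1]")
  if (length(unique(proportions)) < 2L)
    stop("at least two distinct proportions are required")
  if (anyDuplicated(proportions))
    stop("'proportions' must be distinct")

  sid <- function(p, r, degraded) {
    paste0("p", sprintf("%03d", as.integer(round(100 * p))), "_r", r,
           if (degraded) "d" else "")
  }
  good <- expand.grid(replicate = seq_len(n_replicates), proportion = proportions,
                      KEEP.OUT.ATTRS = FALSE)
  good <- good[order(-good$proportion, good$replicate), , drop = FALSE]
  rows <- data.frame(
    sample_id = sid(good$proportion, good$replicate, FALSE),
    proportion = good$proportion,
    replicate = good$replicate,
    quality = "good",
    protocol = protocol,
    stringsAsFactors = FALSE
  )
  if (!is.na(degraded_replicate)) {
    p_sorted <- sort(proportions, decreasing = TRUE)
    deg <- data.frame(
      sample_id = sid(p_sorted, degraded_replicate, TRUE),
      proportion = p_sorted,
      replicate = degraded_replicate,
      quality = "degraded",
      protocol = protocol,
      stringsAsFactors = FALSE
    )
    rows <- rbind(rows, deg)
  }
  rownames(rows) <- NULL
  class(rows) <- c("mix_design", "data.frame")
  rows
}

# Deterministic per-sample RNG sub-stream seed. Quality is deliberately
# excluded from the key: a degraded sample shares its good twin's stream, so
# with dispersion multiplier 1 the two columns are identical and the
# multiplier is the only source of difference between them.
.sample_substream_seed <- function(seed, proportion, replicate) {
  as.integer((as.numeric(seed) * 31 +
                round(proportion * 1000) * 104729 +
                replicate * 7919) %% 2147483647)
}

#' Simulate mixture-experiment counts
#'
#' For sample \eqn{i} with mixing proportion \eqn{p_i}, the expected relative
#' concentration of gene \eqn{g} is \eqn{p_i X_g + (1 - p_i) Y_g}; counts are
#' negative-binomial with mean \eqn{N_i} times the normalized concentration
#' and dispersion equal to the gene's dispersion, inflated by
#' `degradation_dispersion_multiplier` for degraded samples. Dispersion zero
#' reduces to Poisson. Each sample draws from its own deterministic RNG
#' sub-stream keyed by (seed, proportion, replicate) — not quality — so a
#' degraded column with multiplier 1 is identical to its good twin.
#'
#' @param ref A `mix_reference` from [simulate_reference_profiles()] (or any
#'   data frame with `gene_id`, `X`, `Y`, `dispersion`).
#' @param design A `mix_design` from [make_default_design()].
#' @param lib_size_mean Expected library size in reads (> 0). The real design
#'   sequences tens of millions of reads per library; tests scale this down.
#' @param lib_size_cv Coefficient of variation of library sizes (>= 0); 0
#'   gives every sample exactly `lib_size_mean` reads in expectation.
#' @param degradation_dispersion_multiplier Dispersion inflation factor for
#'   degraded samples (>= 1).
#' @param seed Integer seed; identical seeds give identical matrices.
#'
#' @return An integer matrix of counts, genes x samples, with `gene_id`
#'   rownames and `sample_id` colnames. Library sizes are the column sums.
#'
#' @examples
#' ref <- simulate_reference_profiles(200, seed = 1)
#' design <- make_default_design()
#' counts <- simulate_mixture_counts(ref, design, lib_size_mean = 1e5, seed = 1)
#' dim(counts)
#' @export
simulate_mixture_counts <- function(ref, design,
                                    lib_size_mean = 2e6,
                                    lib_size_cv = 0,
                                    degradation_dispersion_multiplier = 4,
                                    seed = 1) {
  if (!is.data.frame(ref) || nrow(ref) == 0L)
    stop("'ref' must be a non-empty reference data frame")
  if (!is.data.frame(design) || nrow(design) == 0L)
    stop("'design' must be a non-empty design data frame")
  if (!all(c("X", "Y", "dispersion", "gene_id") %in% names(ref)))
    stop("'ref' must have columns gene_id, X, Y, dispersion")
  if (all(ref$X == 0) || all(ref$Y == 0))
    stop("reference has an all-zero source; nothing to simulate")
  if (any(ref$X < 0) || any(ref$Y < 0) || any(ref$dispersion < 0))
    stop("reference concentrations and dispersions must be non-negative")
  if (!is.finite(lib_size_mean) || lib_size_mean <= 0)
    stop("'lib_size_mean' must be > 0")
  if (!is.finite(lib_size_cv) || lib_size_cv < 0)
    stop("'lib_size_cv' must be >= 0")
  if (!is.finite(degradation_dispersion_multiplier) ||
      degradation_dispersion_multiplier < 1)
    stop("'degradation_dispersion_multiplier' must be >= 1")
  seed <- as.integer(seed)

  G <- nrow(ref)
  n <- nrow(design)
  counts <- matrix(0L, G, n, dimnames = list(ref$gene_id, design$sample_id))

  withr::with_preserve_seed({
    for (i in seq_len(n)) {
      set.seed(.sample_substream_seed(seed, design$proportion[i], design$replicate[i]))
      N <- if (lib_size_cv > 0) {
        max(1, round(stats::rnorm(1, lib_size_mean, lib_size_cv * lib_size_mean)))
      } else {
        round(lib_size_mean)
      }
      p <- design$proportion[i]
      conc <- p * ref$X + (1 - p) * ref$Y
      mu <- N * conc / sum(conc)
      mult <- if (identical(design$quality[i], "degraded"))
        degradation_dispersion_multiplier else 1
      d <- ref$dispersion * mult
      pos <- d > 0
      col <- numeric(G)
      if (any(pos))
        col[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / d[pos])
      if (any(!pos))
        col[!pos] <- stats::rpois(sum(!pos), mu[!pos])
      counts[, i] <- as.integer(col)
    }
  })
  counts
}

#' Per-sample library sizes of a count matrix
#'
#' @param counts Genes x samples count matrix.
#' @return Named numeric vector of column sums.
#' @export
library_sizes <- function(counts) colSums(counts)

#' Read and write the plain-text interchange tables
#'
#' Counts are written as TSV with a `gene_id` column followed by one column
#' per sample; designs and reference truths as plain TSV with their natural
#' columns. These formats round-trip exactly for integer counts.
#'
#' @param counts,design,ref Objects to write.
#' @param path File path.
#' @return The input invisibly (writers); the reconstructed object (readers).
#' @name mix_io
NULL

#' @rdname mix_io
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts)
}

#' @rdname mix_io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname mix_io
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(design)
}

#' @rdname mix_io
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("mix_design", "data.frame")
  df
}

#' @rdname mix_io
#' @export
write_reference_tsv <- function(ref, path) {
  utils::write.table(as.data.frame(ref), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ref)
}
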