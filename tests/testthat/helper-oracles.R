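# Independent oracles, coded directly from the published definitions.
# These deliberately share no code with the package implementations.

# Trimmed mean of M-values, brute force: reference sample by 75th-percentile
# CPM closest to the mean, pairwise zero exclusion, double trim by M and by
# average log expression, inverse-asymptotic-variance weights, geometric-mean
# rescaling.
tmm_oracle <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref_col <- which.min(abs(f75 - mean(f75)))
  one <- function(k) {
    obs <- as.numeric(counts[, k]); nO <- lib[k]
    rf <- as.numeric(counts[, ref_col]); nR <- lib[ref_col]
    logR <- log2((obs / nO) / (rf / nR))
    absE <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * abs_trim) + 1;     hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
            (rank(absE) >= loS & rank(absE) <= hiS)
    2^(sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE))
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Benjamini-Hochberg step-up, brute force over the definition
# q_(i) = min_{j >= i} p_(j) * n / j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(n), function(i) {
    j <- i:n
    min(1, min(n / j * ps[j]))
  }, numeric(1))
  out <- numeric(n)
  out[o] <- q
  out
}

# Ordinary pooled-variance two-sample t-test p-values, one gene per row.
pooled_t_oracle <- function(Z1, Z2) {
  vapply(seq_len(nrow(Z1)), function(g)
    t.test(Z1[g, ], Z2[g, ], var.equal = TRUE)$p.value, numeric(1))
}

# Per-gene SSE of the mixture model minimized by Nelder-Mead simplex in
# (log2 X, log2 Y), restarted once from its own optimum.
simplex_sse_oracle <- function(z, p) {
  f <- function(ab) {
    s <- 2^ab[1] * p + 2^ab[2] * (1 - p)
    sum((z - log2(s))^2)
  }
  a0 <- mean(z[p == max(p)]); b0 <- mean(z[p == min(p)])
  o <- optim(c(a0, b0), f, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 20000))
  o <- optim(o$par, f, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 20000))
  o$value
}

# Random count matrix with positive library sizes.
rand_counts <- function(G, n, seed, lambda = 60) {
  withr::with_seed(seed, {
    m <- matrix(rpois(G * n, lambda * rexp(G)), G, n)
    dimnames(m) <- list(sprintf("g%04d", seq_len(G)), sprintf("s%02d", seq_len(n)))
    m
  })
}

# Forward-generate a log-CPM matrix from the mixture model for a design,
# with iid N(0, phi^2) noise.
model_logcpm <- function(X, Y, design, phi = 0, seed = NULL) {
  gen <- function() {
    p <- design$proportion
    Z <- log2(outer(X, p) + outer(Y, 1 - p))
    if (phi > 0) Z <- Z + matrix(rnorm(length(Z), 0, phi), nrow(Z))
    dimnames(Z) <- list(if (is.null(names(X))) sprintf("g%04d", seq_along(X))
                        else names(X),
                        design$sample_id)
    Z
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

good_design <- function(n_replicates = 3) {
  d <- make_default_design(n_replicates = n_replicates)
  d[d$quality == "good", , drop = FALSE]
}

group_ids <- function(design, p, quality = "good") {
  design$sample_id[abs(design$proportion - p) < 1e-9 & design$quality == quality]
}

# A de_result carrying prescribed fdr values (for set-metric tests).
fake_de <- function(gene_id, fdr, logFC = 0) {
  structure(data.frame(gene_id = gene_id, logFC = logFC,
                       p_value = fdr, fdr = fdr,
                       significant = fdr < 0.05, method_label = "fake",
                       stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}
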