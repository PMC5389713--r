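test_that("the fit inverts noise-free data generated from the model", {
  d <- good_design()
  p <- d$proportion
  # single gene with X=64, Y=16: logCPM at the five proportions is
  # log2(64), log2(52), log2(40), log2(28), log2(16)
  Z <- model_logcpm(c(g1 = 64), c(g1 = 16), d)
  expect_equal(unname(Z[1, match(c(1, .75, .5, .25, 0), p)]),
               c(6, 5.70044, 5.32193, 4.80735, 4), tolerance = 1e-5)
  fit <- fit_mixture(Z, d)
  expect_equal(fit$Xhat, 64, tolerance = 1e-6)
  expect_equal(fit$Yhat, 16, tolerance = 1e-6)
  expect_equal(fit$M, 2, tolerance = 1e-6)
  expect_lt(fit$phi_hat, 1e-6)
  expect_true(fit$converged)

  # a batch of genes with random positive concentrations
  withr::with_seed(10, {
    X <- rlnorm(100, log(50), 1.5)
    Y <- X / 2^rnorm(100, 0, 2)
  })
  Zb <- model_logcpm(X, Y, d)
  fb <- fit_mixture(Zb, d)
  expect_lt(max(abs(log2(fb$Xhat) - log2(X))), 1e-6)
  expect_lt(max(abs(log2(fb$Yhat) - log2(Y))), 1e-6)
  expect_lt(max(fb$phi_hat), 1e-6)
})

test_that("with only pure samples the fit decouples into per-group log means", {
  d <- good_design()
  d <- d[d$proportion %in% c(0, 1), , drop = FALSE]
  Z <- model_logcpm(c(g1 = 40, g2 = 8), c(g1 = 10, g2 = 80), d, phi = 0.3,
                    seed = 12)
  fit <- fit_mixture(Z, d)
  a_expect <- rowMeans(Z[, d$sample_id[d$proportion == 1]])
  b_expect <- rowMeans(Z[, d$sample_id[d$proportion == 0]])
  expect_equal(log2(fit$Xhat), unname(a_expect), tolerance = 1e-7)
  expect_equal(log2(fit$Yhat), unname(b_expect), tolerance = 1e-7)
})

test_that("Gauss-Newton reaches the simplex oracle's SSE on noisy genes", {
  d <- good_design()
  withr::with_seed(21, {
    X <- rlnorm(20, log(40), 1.2)
    Y <- X / 2^rnorm(20, 0, 1.5)
  })
  Z <- model_logcpm(X, Y, d, phi = 0.1, seed = 22)
  fit <- fit_mixture(Z, d)
  rss <- attr(fit, "rss")
  for (g in seq_along(X)) {
    oracle <- simplex_sse_oracle(Z[g, ], d$proportion)
    expect_lt(rss[g], oracle + 1e-6)
    expect_lt(abs(rss[g] - oracle), 1e-6)
  }
})

test_that("fitted log-ratios agree with the reference vectorized implementation", {
  skip_if_not_installed("limma")
  d <- good_design()
  withr::with_seed(31, {
    X <- rlnorm(50, log(60), 1)
    Y <- X / 2^rnorm(50, 0, 1.2)
  })
  Z <- model_logcpm(X, Y, d, phi = 0.08, seed = 32)
  fit <- fit_mixture(Z, d)
  ref <- limma::fitmixture(Z, d$proportion)
  expect_equal(fit$M, unname(ref$M), tolerance = 1e-4)
})

test_that("identifiability and input contracts are enforced", {
  d <- good_design()
  one_prop <- d[d$proportion == 0.5, , drop = FALSE]
  Z <- model_logcpm(c(g1 = 10), c(g1 = 10), d)
  expect_error(fit_mixture(Z, one_prop), "distinct proportions")
  expect_error(fit_mixture(Z[, 1:2, drop = FALSE], d[1:2, ]), "3 samples")
  expect_error(fit_mixture(unname(Z), d), "column names")
})

test_that("contrast predictions obey the model identities", {
  d <- good_design()
  withr::with_seed(41, {
    X <- rlnorm(60, log(50), 1.3)
    Y <- X / 2^rnorm(60, 0, 1.5)
  })
  fit <- fit_mixture(model_logcpm(X, Y, d, phi = 0.05, seed = 42), d)
  grid <- expand.grid(p = c(0, 0.25, 0.6, 1), q = c(0, 0.4, 0.75, 1))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; q <- grid$q[i]
    dpq <- predicted_logfc(fit, p, q)$delta
    dqp <- predicted_logfc(fit, q, p)$delta
    expect_lt(max(abs(dpq + dqp)), 1e-12)
    if (p == q) expect_true(all(dpq == 0))
  }
  expect_lt(max(abs(predicted_logfc(fit, 1, 0)$delta - fit$M)), 1e-12)

  # hand-evaluated: X=64, Y=16 at (0.75, 0.25) -> log2(52/28)
  f1 <- fit_mixture(model_logcpm(c(g = 64), c(g = 16), d), d)
  expect_equal(predicted_logfc(f1, 0.75, 0.25)$delta, log2(52 / 28),
               tolerance = 1e-6)
  expect_equal(log2(52 / 28), 0.89308, tolerance = 1e-5)

  expect_error(predicted_logfc(fit, 1.2, 0), "0, 1")
})

test_that("predicted log-FC is strictly increasing in the fitted ratio", {
  d <- good_design()
  R <- 2^seq(-4, 4, length.out = 30)
  X <- 100 * R; Y <- rep(100, 30)
  fit <- fit_mixture(model_logcpm(X, Y, d), d)
  for (pq in list(c(0.75, 0.25), c(0.5, 0.25), c(1, 0), c(0.75, 0.5))) {
    delta <- predicted_logfc(fit, pq[1], pq[2])$delta
    expect_true(all(diff(delta[order(fit$M)]) > 0))
  }
})

test_that("non-converged genes yield missing predictions", {
  d <- good_design()
  fit <- fit_mixture(model_logcpm(c(g1 = 64, g2 = 32), c(g1 = 16, g2 = 8), d), d)
  fit$converged[2] <- FALSE
  delta <- predicted_logfc(fit, 0.75, 0.25)$delta
  expect_false(is.na(delta[1]))
  expect_true(is.na(delta[2]))
})

test_that("RMSE of log-FCs follows the root-mean-square definition", {
  d <- good_design()
  fit <- fit_mixture(model_logcpm(c(g1 = 64, g2 = 32), c(g1 = 16, g2 = 8), d), d)
  pred <- predicted_logfc(fit, 1, 0)

  exact <- setNames(pred$delta, pred$gene_id)
  expect_equal(as.numeric(rmse_logfc(exact, pred)), 0)

  pred0 <- pred; pred0$delta <- c(0, 0)
  expect_equal(as.numeric(rmse_logfc(setNames(c(1, 1), pred$gene_id), pred0)), 1)
  expect_equal(as.numeric(rmse_logfc(setNames(c(3, 0), pred$gene_id), pred0)),
               sqrt(4.5))
  expect_equal(sqrt(4.5), 2.12132, tolerance = 1e-5)

  # missing predictions are excluded pairwise and counted
  predNA <- pred; predNA$delta[2] <- NA
  r <- rmse_logfc(exact, predNA)
  expect_identical(attr(r, "n"), 1L)
  expect_identical(attr(r, "n_excluded"), 1L)
  expect_error(rmse_logfc(setNames(1, "absent"), pred), "common")
})

test_that("leave-out refits exclude exactly the comparison samples", {
  d <- good_design()
  withr::with_seed(51, {
    X <- rlnorm(40, log(50), 1)
    Y <- X / 2^rnorm(40, 0, 1.2)
  })
  Z <- model_logcpm(X, Y, d, phi = 0.05, seed = 52)
  excl <- list(group_ids(d, 0.75), group_ids(d, 0.5))
  lo <- leave_out_fit(Z, d, excl)
  expect_identical(length(attr(lo, "samples_used")), 9L)
  expect_false(any(unlist(excl) %in% attr(lo, "samples_used")))

  # excluding nothing reproduces the full fit
  full <- fit_mixture(Z, d)
  lo0 <- leave_out_fit(Z, d, character(0))
  expect_identical(as.data.frame(lo0), as.data.frame(full))

  # leave-out predictions track full-fit predictions closely
  delta_full <- predicted_logfc(full, 0.75, 0.5)$delta
  delta_lo <- predicted_logfc(lo, 0.75, 0.5)$delta
  expect_gt(cor(delta_full, delta_lo), 0.99)

  # collapsing the design is a design error
  d2 <- d[d$proportion %in% c(1, 0), , drop = FALSE]
  expect_error(leave_out_fit(Z[, d2$sample_id], d2, group_ids(d, 1)),
               "distinct proportions")
  expect_error(leave_out_fit(Z, d, "nonexistent"), "unknown")
})

test_that("degraded-substituted fits show inflated residual variability", {
  ref <- simulate_reference_profiles(800, seed = 61)
  d <- make_default_design()
  counts <- simulate_mixture_counts(ref, d, lib_size_mean = 1e6,
                                    degradation_dispersion_multiplier = 4,
                                    seed = 61)
  norm <- log_cpm(filter_by_expression(counts))
  good <- d[d$quality == "good", ]
  sub_ids <- c(d$sample_id[d$quality == "good" & d$replicate != 2],
               d$sample_id[d$quality == "degraded"])
  fit_good <- fit_mixture(norm, good)
  fit_sub <- fit_mixture(norm, d[d$sample_id %in% sub_ids, ])
  common <- intersect(fit_good$gene_id, fit_sub$gene_id)
  v_good <- fit_good$phi_hat[match(common, fit_good$gene_id)]^2
  v_sub <- fit_sub$phi_hat[match(common, fit_sub$gene_id)]^2
  expect_gt(median(v_sub), median(v_good))
  expect_lt(binom.test(sum(v_sub > v_good), length(common))$p.value, 0.01)
})
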