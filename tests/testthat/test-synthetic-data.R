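test_that("reference profiles honour the DE fraction and threshold exactly", {
  ref0 <- simulate_reference_profiles(100, de_fraction = 0, seed = 1)
  expect_true(all(ref0$R == 1))
  expect_false(any(ref0$is_de))

  ref5 <- simulate_reference_profiles(10, de_fraction = 0.5, seed = 2)
  expect_identical(sum(ref5$is_de), 5L)

  # is_de <=> |log2 R| >= threshold, and no DE gene sneaks inside the gap
  ref <- simulate_reference_profiles(500, de_fraction = 0.3, seed = 3,
                                     de_lfc_threshold = 1)
  expect_equal(ref$is_de, abs(log2(ref$R)) >= 1)
  expect_true(all(abs(log2(ref$R[ref$is_de])) >= 1))
  expect_true(all(ref$R[!ref$is_de] == 1))
})

test_that("reference profiles are strictly positive, self-consistent and seeded", {
  ref <- simulate_reference_profiles(200, de_fraction = 0.2, seed = 7)
  expect_true(all(ref$X > 0) && all(ref$Y > 0))
  expect_equal(ref$R, ref$X / ref$Y)
  expect_true(all(ref$dispersion >= 0) && all(ref$phi >= 0))

  again <- simulate_reference_profiles(200, de_fraction = 0.2, seed = 7)
  expect_identical(ref, again)
  other <- simulate_reference_profiles(200, de_fraction = 0.2, seed = 8)
  expect_false(identical(ref$X, other$X))
})

test_that("reference profile generation rejects bad parameters", {
  expect_error(simulate_reference_profiles(0), "n_genes")
  expect_error(simulate_reference_profiles(10, lfc_sd = 0), "lfc_sd")
  expect_error(simulate_reference_profiles(10, lfc_sd = NaN), "lfc_sd")
  expect_error(simulate_reference_profiles(10, de_fraction = 1.5), "de_fraction")
  expect_error(simulate_reference_profiles(
    10, abundance_params = list(meanlog = Inf, sdlog = 1)), "abundance_params")
})

test_that("the default design is the titration layout with degraded duplicates", {
  d <- make_default_design()
  expect_identical(nrow(d), 20L)
  expect_identical(sum(d$quality == "good"), 15L)
  expect_identical(sum(d$quality == "degraded"), 5L)
  expect_equal(sort(unique(d$proportion)), c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(d$replicate[d$quality == "degraded"] == 2))
  # (proportion, replicate, quality) triples unique
  key <- paste(d$proportion, d$replicate, d$quality)
  expect_false(anyDuplicated(key) > 0)
  expect_false(anyDuplicated(d$sample_id) > 0)

  d1 <- make_default_design(n_replicates = 1, degraded_replicate = 1)
  expect_identical(table(d1$quality)[["good"]], 5L)
  expect_identical(table(d1$quality)[["degraded"]], 5L)

  expect_error(make_default_design(n_replicates = 0), "n_replicates")
  expect_error(make_default_design(degraded_replicate = 4), "degraded_replicate")
  expect_identical(sum(make_default_design(degraded_replicate = NULL)$quality ==
                         "degraded"), 0L)
})

test_that("simulated counts are seeded, integral and library-sized", {
  ref <- simulate_reference_profiles(100, seed = 1)
  d <- make_default_design()
  c1 <- simulate_mixture_counts(ref, d, lib_size_mean = 1e5, seed = 11)
  c2 <- simulate_mixture_counts(ref, d, lib_size_mean = 1e5, seed = 11)
  c3 <- simulate_mixture_counts(ref, d, lib_size_mean = 1e5, seed = 12)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
  expect_true(all(c1 >= 0))
  expect_identical(storage.mode(c1), "integer")
  expect_identical(dimnames(c1), list(ref$gene_id, d$sample_id))
  expect_equal(library_sizes(c1), colSums(c1))
})

test_that("pure columns at dispersion zero reflect the source-A profile only", {
  ref <- simulate_reference_profiles(500, de_fraction = 0.3, seed = 4,
                                     dispersion_mean = 0)
  d <- make_default_design()
  counts <- simulate_mixture_counts(ref, d, lib_size_mean = 2e6, seed = 4)
  pure <- counts[, group_ids(d, 1), drop = FALSE]
  cpm <- rowMeans(sweep(pure, 2, colSums(pure), "/") * 1e6)
  expected <- ref$X / sum(ref$X) * 1e6
  expect_gt(cor(cpm, expected), 0.999)
  hi <- expected > 10
  expect_lt(median(abs(cpm[hi] / expected[hi] - 1)), 0.05)
})

test_that("mean CPM across the series converges to the normalized mixture mean", {
  # law-of-large-numbers check: Poisson counts, deep libraries
  ref <- simulate_reference_profiles(400, de_fraction = 0.3, seed = 9,
                                     dispersion_mean = 0)
  d <- good_design()
  counts <- simulate_mixture_counts(ref, d, lib_size_mean = 1e7, seed = 9)
  for (p in c(1, 0.5, 0)) {
    cols <- counts[, group_ids(d, p), drop = FALSE]
    cpm <- rowMeans(sweep(cols, 2, colSums(cols), "/") * 1e6)
    mix <- p * ref$X + (1 - p) * ref$Y
    expected <- mix / sum(mix) * 1e6
    hi <- expected > 10
    rel <- abs(cpm[hi] / expected[hi] - 1)
    # a gene at the CPM-10 boundary has Poisson rel. sd ~ 2.6% here, so a
    # 5% band holds for the bulk of genes and the typical error is tiny
    expect_gt(mean(rel < 0.05), 0.9)
    expect_lt(median(rel), 0.02)
    expect_gt(cor(cpm, expected), 0.9999)
  }
})

test_that("a degraded column with multiplier 1 equals its good twin", {
  ref <- simulate_reference_profiles(1000, seed = 5)
  d <- make_default_design()
  counts <- simulate_mixture_counts(ref, d, lib_size_mean = 1e5,
                                    degradation_dispersion_multiplier = 1,
                                    seed = 5)
  for (p in unique(d$proportion)) {
    good_twin <- d$sample_id[d$proportion == p & d$replicate == 2 &
                               d$quality == "good"]
    degraded <- d$sample_id[d$proportion == p & d$quality == "degraded"]
    expect_identical(counts[, good_twin], counts[, degraded])
  }
})

test_that("dispersion multiplier > 1 inflates per-gene variance of degraded columns", {
  ref <- simulate_reference_profiles(2000, seed = 6)
  base <- make_default_design(n_replicates = 3, degraded_replicate = NULL)
  half <- base[base$proportion == 0.5, , drop = FALSE]
  deg <- half
  deg$quality <- "degraded"
  deg$sample_id <- paste0(half$sample_id, "d")
  design <- rbind(half, deg)
  counts <- simulate_mixture_counts(ref, design, lib_size_mean = 2e6,
                                    degradation_dispersion_multiplier = 4,
                                    seed = 6)
  lc <- log2(sweep(counts, 2, colSums(counts), "/") * 1e6 + 0.5)
  v_good <- apply(lc[, half$sample_id], 1, var)
  v_deg <- apply(lc[, deg$sample_id], 1, var)
  expect_gt(median(v_deg), median(v_good))
  bt <- binom.test(sum(v_deg > v_good), length(v_good))
  expect_lt(bt$p.value, 0.01)
})

test_that("degenerate simulator inputs are rejected", {
  ref <- simulate_reference_profiles(10, seed = 1)
  d <- make_default_design()
  zero <- ref; zero$X <- 0; zero$Y <- 0
  expect_error(simulate_mixture_counts(zero, d), "all-zero")
  expect_error(simulate_mixture_counts(ref, d, lib_size_mean = 0), "lib_size_mean")
  expect_error(simulate_mixture_counts(ref, d, degradation_dispersion_multiplier = 0.5),
               "multiplier")
  expect_error(simulate_mixture_counts(ref[0, ], d), "non-empty")
})

test_that("count, design and reference tables round-trip through TSV", {
  ref <- simulate_reference_profiles(50, seed = 2)
  d <- make_default_design()
  counts <- simulate_mixture_counts(ref, d, lib_size_mean = 1e4, seed = 2)
  tmp <- withr::local_tempdir()
  write_counts_tsv(counts, file.path(tmp, "c.tsv"))
  write_design_tsv(d, file.path(tmp, "d.tsv"))
  expect_identical(read_counts_tsv(file.path(tmp, "c.tsv")), counts)
  expect_equal(as.data.frame(read_design_tsv(file.path(tmp, "d.tsv"))),
               as.data.frame(d))
})
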