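#' Default pipeline configuration
#'
#' Nested list of every stage's parameters with the package defaults: the
#' simulation block mirrors the titration design (five proportions in
#' triplicate, degraded duplicates of replicate 2), the preprocess block the
#' gene-level expression filter, the fit, benchmark and deconvolution blocks
#' their respective function defaults.
#'
#' @return Named nested list; see [run_full_pipeline()] for the block
#'   meanings.
#' @export
default_run_config <- function() {
  list(
    paths = list(counts = NULL, design = NULL),
    simulation = list(
      n_genes = 2000L, de_fraction = 0.1, lfc_sd = 2,
      abundance_meanlog = log(50), abundance_sdlog = 1.5,
      de_lfc_threshold = 1, dispersion_mean = 0.05, dispersion_prior_df = 5,
      n_replicates = 3L, degraded_replicate = 2L,
      lib_size_mean = 2e6, lib_size_cv = 0,
      degradation_dispersion_multiplier = 4, seed = 1L
    ),
    preprocess = list(cpm_threshold = 1, min_samples = 3, prior_count = 0.5),
    fit = list(tol = 1e-8, max_iter = 50L),
    benchmark = list(
      comparisons = c("100:000", "075:025", "050:025", "075:050"),
      anchor = "100:000", fdr_cutoff = 0.05, prior_df = 4,
      use_degraded = FALSE
    ),
    deconvolution = list(fc_hi = 2, fc_lo = 0.5)
  )
}

# Validate a config against the defaults: unknown keys (at the top level or
# inside a block) are rejected; missing keys are filled with defaults.
.validate_run_config <- function(config) {
  defaults <- default_run_config()
  if (!is.list(config)) stop("config must be a list")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  for (block in names(defaults)) {
    if (is.null(config[[block]])) {
      config[[block]] <- defaults[[block]]
      next
    }
    bad <- setdiff(names(config[[block]]), names(defaults[[block]]))
    if (length(bad))
      stop("unknown key(s) in config block '", block, "': ",
           paste(bad, collapse = ", "))
    for (key in names(defaults[[block]]))
      if (is.null(config[[block]][[key]]) && !key %in% c("counts", "design"))
        config[[block]][[key]] <- defaults[[block]][[key]]
  }
  config
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown blocks or keys are rejected outright; omitted keys take the
#' values of [default_run_config()].
#'
#' @param path Path to a YAML file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  .validate_run_config(yaml::read_yaml(path))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full mixture-benchmark pipeline
#'
#' Simulates counts (or loads them from the configured TSV paths), filters
#' and normalizes, fits the mixture model on the good samples and on the
#' degraded-substituted set, runs the reference DE method and benchmark
#' metrics over the configured comparisons with leave-out predictions,
#' deconvolves the mixed samples, and writes every stage output as TSV plus
#' a JSON manifest with MD5 checksums, the seed, package version and every
#' decision flag. Any stage failure aborts with the stage name; outputs
#' written before the failure are preserved.
#'
#' @param config Config list as from [default_run_config()] /
#'   [read_run_config()], or a path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage objects and the manifest.
#' @export
run_full_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  config <- .validate_run_config(config)
  if (missing(out_dir)) stop("'out_dir' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- simulate or load ----------------------------------------------------
  sim <- config$simulation
  truth <- NULL
  if (!is.null(config$paths$counts)) {
    counts <- stage("load", read_counts_tsv(config$paths$counts))
    design <- stage("load", read_design_tsv(config$paths$design))
    note("loaded ", nrow(counts), " genes x ", ncol(counts), " samples")
  } else {
    counts_design <- stage("simulate", {
      truth <- simulate_reference_profiles(
        n_genes = sim$n_genes, de_fraction = sim$de_fraction,
        lfc_sd = sim$lfc_sd,
        abundance_params = list(meanlog = sim$abundance_meanlog,
                                sdlog = sim$abundance_sdlog),
        seed = sim$seed, de_lfc_threshold = sim$de_lfc_threshold,
        dispersion_mean = sim$dispersion_mean,
        dispersion_prior_df = sim$dispersion_prior_df)
      design <- make_default_design(n_replicates = sim$n_replicates,
                                    degraded_replicate = sim$degraded_replicate)
      counts <- simulate_mixture_counts(
        truth, design, lib_size_mean = sim$lib_size_mean,
        lib_size_cv = sim$lib_size_cv,
        degradation_dispersion_multiplier = sim$degradation_dispersion_multiplier,
        seed = sim$seed)
      list(counts = counts, design = design, truth = truth)
    })
    counts <- counts_design$counts
    design <- counts_design$design
    truth <- counts_design$truth
    write_reference_tsv(truth, file.path(out_dir, "truth.tsv"))
    files <- c(files, file.path(out_dir, "truth.tsv"))
    note("simulated ", nrow(counts), " genes x ", ncol(counts),
         " samples (seed ", sim$seed, ")")
  }
  write_counts_tsv(counts, file.path(out_dir, "counts.tsv"))
  write_design_tsv(design, file.path(out_dir, "design.tsv"))
  files <- c(files, file.path(out_dir, c("counts.tsv", "design.tsv")))

  # --- filter + normalize --------------------------------------------------
  pp <- config$preprocess
  norm <- stage("normalize", {
    filtered <- filter_by_expression(counts, pp$cpm_threshold, pp$min_samples)
    log_cpm(filtered, prior_count = pp$prior_count)
  })
  note("filter: ", nrow(counts) - nrow(norm$logcpm), " genes removed, ",
       nrow(norm$logcpm), " kept (CPM > ", pp$cpm_threshold, " in >= ",
       pp$min_samples, " samples)")
  files <- c(files, .write_tsv(
    data.frame(sample_id = names(norm$tmm_factors),
               tmm_factor = norm$tmm_factors),
    file.path(out_dir, "tmm_factors.tsv")))
  files <- c(files, .write_tsv(
    data.frame(gene_id = rownames(norm$logcpm), norm$logcpm,
               check.names = FALSE),
    file.path(out_dir, "logcpm.tsv")))

  # --- mixture-model fits --------------------------------------------------
  ft <- config$fit
  good_ids <- design$sample_id[design$quality == "good"]
  fit_good <- stage("fit", fit_mixture(
    norm$logcpm[, good_ids, drop = FALSE],
    design[design$quality == "good", , drop = FALSE],
    max_iter = ft$max_iter, tol = ft$tol))
  note("fit (good samples): ", sum(!fit_good$converged), " of ",
       nrow(fit_good), " genes non-converged")
  files <- c(files, .write_tsv(as.data.frame(fit_good),
                               file.path(out_dir, "fit_good.tsv")))
  has_degraded <- any(design$quality == "degraded")
  if (has_degraded) {
    sub_ids <- unlist(lapply(unique(design$proportion), function(p)
      .group_samples(design, p, use_degraded = TRUE)))
    fit_sub <- stage("fit", fit_mixture(
      norm$logcpm[, sub_ids, drop = FALSE],
      design[design$sample_id %in% sub_ids, , drop = FALSE],
      max_iter = ft$max_iter, tol = ft$tol))
    files <- c(files, .write_tsv(as.data.frame(fit_sub),
                                 file.path(out_dir, "fit_degraded_substituted.tsv")))
  }

  # --- benchmark -----------------------------------------------------------
  bm <- config$benchmark
  report <- stage("benchmark", run_benchmark(
    counts, design,
    comparisons = as.list(bm$comparisons),
    fdr_cutoff = bm$fdr_cutoff, anchor = bm$anchor,
    cpm_threshold = pp$cpm_threshold, min_samples = pp$min_samples,
    prior_df = bm$prior_df, use_degraded = isTRUE(bm$use_degraded)))
  files <- c(files,
             .write_tsv(report$sensitivity, file.path(out_dir, "sensitivity.tsv")),
             .write_tsv(report$rates, file.path(out_dir, "rates.tsv")),
             .write_tsv(report$rmse, file.path(out_dir, "rmse.tsv")))
  for (lab in names(report$de_results))
    for (m in names(report$de_results[[lab]]))
      if (!is.null(report$de_results[[lab]][[m]]))
        files <- c(files, .write_tsv(
          as.data.frame(report$de_results[[lab]][[m]]),
          file.path(out_dir, paste0("de_", lab, "_", gsub("[^A-Za-z0-9]", "-", m), ".tsv"))))
  report_json <- file.path(out_dir, "benchmark_report.json")
  jsonlite::write_json(list(sensitivity = report$sensitivity,
                            rates = report$rates, rmse = report$rmse,
                            fdr_cutoff = report$fdr_cutoff,
                            anchor = report$anchor, G = report$G),
                       report_json, auto_unbox = TRUE, digits = NA)
  files <- c(files, report_json)

  # --- deconvolution -------------------------------------------------------
  dc <- config$deconvolution
  deconv <- stage("deconvolve", deconvolve_samples(
    counts, design, fc_hi = dc$fc_hi, fc_lo = dc$fc_lo))
  truth_profile <- if (!is.null(truth)) {
    x <- truth$X / sum(truth$X) * 1e6
    names(x) <- truth$gene_id
    x[rownames(deconv$T_hat)]
  } else NULL
  eval_tab <- stage("deconvolve", evaluate_deconvolution(
    deconv, truth_profile = truth_profile))
  note("deconvolution: ", sum(deconv$mask), " informative genes, max |p_hat - p| = ",
       signif(attr(eval_tab, "max_abs_error"), 3))
  files <- c(files,
             .write_tsv(deconv$estimates, file.path(out_dir, "deconv_estimates.tsv")),
             .write_tsv(eval_tab, file.path(out_dir, "deconv_evaluation.tsv")))

  # --- manifest ------------------------------------------------------------
  files <- unique(files)
  manifest <- list(
    package = "mixbench",
    version = as.character(utils::packageVersion("mixbench")),
    r_version = as.character(getRversion()),
    seed = sim$seed,
    config = config,
    log = log_lines,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(counts = counts, design = design, truth = truth,
                 norm = norm, fit_good = fit_good, report = report,
                 deconvolution = deconv, evaluation = eval_tab,
                 manifest = manifest, out_dir = out_dir))
}
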