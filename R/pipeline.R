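#' Run an end-to-end analysis from a configuration file
#'
#' Executes the standard chain — input (or simulation), preprocessing,
#' frame construction, model fit and optional threshold test — and writes
#' results as tab-separated files plus a run log recording seeds and the
#' package version. Configuration is a YAML file (or an equivalent named
#' list) with blocks:
#' \preformatted{
#' simulate:   n_variants, seed          # either this ...
#' input:      counts, dialect, assignment, variant_map, labels  # ... or this
#' preprocess: min_count, min_barcodes, outlier_sd, outlier_removal,
#'             downsample_percentile, seed
#' fit:        design (variant|element), mode (barcode|aggregate)
#' threshold:  negative_label, percentile, direction   # optional
#' output_dir: path
#' qc_plots:   true|false
#' }
#'
#' @param config Path to a YAML file or a named list.
#' @return Invisibly, a list with the fit object and the output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_mprabc("config file not found: %s", config,
                  class = "mprabc_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop_mprabc("config must set output_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("mprabc %s", as.character(utils::packageVersion("mprabc"))),
                 sprintf("started %s", format(Sys.time())))
  outputs <- character(0)

  truth <- NULL
  map <- NULL
  labels <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    seed <- if (is.null(sc$seed)) 1L else as.integer(sc$seed)
    spec <- simulation_spec(
      n_variants = if (is.null(sc$n_variants)) 5000L else as.integer(sc$n_variants),
      seed = seed)
    sim <- simulate_dataset(spec)
    counts <- sim$counts
    map <- sim$map
    truth <- sim$truth
    log_lines <- c(log_lines, sprintf("simulated %d variants, seed %d",
                                      spec$n_variants, seed))
    truth_path <- file.path(out_dir, "truth.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, truth_path)
  } else if (!is.null(config$input)) {
    ic <- config$input
    counts <- read_count_table(
      ic$counts,
      dialect = if (is.null(ic$dialect)) "long" else ic$dialect,
      assignment = ic$assignment)
    if (!is.null(ic$variant_map)) map <- read_variant_map(ic$variant_map)
    if (!is.null(ic$labels)) labels <- read_label_table(ic$labels)
    log_lines <- c(log_lines, sprintf("read %d count records", nrow(counts)))
  } else {
    stop_mprabc("config must provide either a 'simulate' or an 'input' block")
  }

  pc <- config$preprocess
  if (!is.null(pc)) {
    counts <- preprocess_counts(
      counts,
      min_count = if (is.null(pc$min_count)) 1L else pc$min_count,
      min_barcodes = if (is.null(pc$min_barcodes)) 10L else pc$min_barcodes,
      n_sd = if (is.null(pc$outlier_sd)) 3 else pc$outlier_sd,
      outlier_removal = !isFALSE(pc$outlier_removal),
      downsample_percentile = pc$downsample_percentile,
      seed = pc$seed)
    log_lines <- c(log_lines, sprintf("preprocessed: %d records retained",
                                      nrow(counts)))
  }

  fc <- if (is.null(config$fit)) list() else config$fit
  design <- if (is.null(fc$design)) {
    if (!is.null(map)) "variant" else "element"
  } else fc$design
  mode <- if (is.null(fc$mode)) "barcode" else fc$mode
  if (design == "variant") {
    if (is.null(map)) stop_mprabc("variant design requires a variant map")
    # preprocessing may have removed oligos entirely; keep testable variants
    present <- map$ref_oligo %in% counts$oligo &
      map$alt_oligo %in% counts$oligo
    if (!all(present)) {
      message(sprintf(
        "run_pipeline: %d variant(s) dropped (an allele was filtered out)",
        sum(!present)))
      map <- map[present, , drop = FALSE]
      log_lines <- c(log_lines, sprintf("dropped %d unfittable variant(s)",
                                        sum(!present)))
    }
    frame <- create_variant_frame(counts, map)
    fit <- fit_variants(frame, mode = mode)
  } else {
    frame <- create_element_frame(counts, labels)
    fit <- fit_elements(frame, mode = mode)
  }
  log_lines <- c(log_lines, sprintf(
    "fitted %s design on %s counts: consensus rho %.3f, prior df %s",
    design, mode, fit$consensus_rho, format(fit$df_prior, digits = 4)))

  if (!is.null(config$threshold)) {
    tc <- config$threshold
    cfg <- threshold_config(
      negative_label = tc$negative_label,
      percentile = if (is.null(tc$percentile)) 0.975 else tc$percentile,
      direction = if (is.null(tc$direction)) "activating" else tc$direction)
    fit <- treat_test(fit, cfg)
    log_lines <- c(log_lines, sprintf(
      "threshold test: direction %s, tau %.4g", cfg$direction,
      fit$threshold$tau))
  }

  res_path <- file.path(out_dir, "results.tsv")
  write_results(fit, res_path)
  outputs <- c(outputs, res_path)

  if (isTRUE(config$qc_plots)) {
    plot_path <- file.path(out_dir, "fit_plot.pdf")
    grDevices::pdf(plot_path, width = 6, height = 5)
    plot(fit)
    grDevices::dev.off()
    outputs <- c(outputs, plot_path)
  }

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(log_lines, sprintf("finished %s", format(Sys.time()))),
             log_path)
  invisible(list(fit = fit, outputs = c(outputs, log_path),
                 truth = truth))
}

#' Simulation benchmark of barcode versus aggregated modelling
#'
#' Reproduces the simulation study at a configurable scale: fits the clean
#' dataset in barcode and aggregate mode, then, for every outlier fraction
#' and repetition, injects multiplicative RNA outliers and refits both
#' modes. Reported metrics per condition: per-effect-group significant
#' counts at the BH threshold, Pearson correlation of logFCs (and Spearman
#' of adjusted p-values) with the clean fit of the same mode, the
#' barcode-vs-aggregate logFC correlation, and the Kolmogorov-Smirnov
#' statistic of the neutral-group raw p-values against uniformity.
#'
#' @param n_variants Number of simulated variants (divisible by 5;
#'   default 5000).
#' @param outlier_fractions Outlier fractions to scan (default
#'   c(0.1, 0.05, 0.01, 0.005, 0.001)).
#' @param n_repetitions Random outlier repetitions per fraction
#'   (default 5).
#' @param alpha BH significance threshold (default 0.05).
#' @param seed Master seed; all stage seeds derive from it.
#' @param fast Scale down to 1000 variants and 2 repetitions.
#' @return List with \code{metrics} (long data.frame: fraction, repetition,
#'   mode, metric, group, value; fraction 0 = clean data) and the clean
#'   \code{fits}.
#' @export
run_benchmark <- function(n_variants = 5000,
                          outlier_fractions = c(0.1, 0.05, 0.01, 0.005,
                                                0.001),
                          n_repetitions = 5, alpha = 0.05, seed = 1L,
                          fast = FALSE) {
  if (fast) {
    n_variants <- 1000
    n_repetitions <- 2
  }
  spec <- simulation_spec(n_variants, seed = seed)
  sim <- simulate_dataset(spec)
  frame <- create_variant_frame(sim$counts, sim$map)
  group <- sim$truth$group

  fits <- list(barcode = fit_variants(frame, "barcode"),
               aggregate = fit_variants(frame, "aggregate"))

  rows <- list()
  add <- function(fraction, repetition, mode, metric, group, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      fraction = fraction, repetition = repetition, mode = mode,
      metric = metric, group = group, value = value,
      stringsAsFactors = FALSE)
  }

  sig_counts <- function(fit) {
    sig <- !is.na(fit$adj_p_value) & fit$adj_p_value < alpha
    tapply(sig, group, sum)
  }
  for (mode in names(fits)) {
    sc <- sig_counts(fits[[mode]])
    for (gname in names(sc)) {
      add(0, 0L, mode, "n_significant", gname, sc[[gname]])
    }
    neutral_p <- fits[[mode]]$p_value[group == "neutral"]
    neutral_p <- neutral_p[!is.na(neutral_p)]
    add(0, 0L, mode, "null_ks_stat", NA_character_,
        unname(stats::ks.test(neutral_p, "punif")$statistic))
  }
  add(0, 0L, "barcode_vs_aggregate", "logfc_pearson", NA_character_,
      stats::cor(fits$barcode$coef, fits$aggregate$coef,
                 use = "complete.obs"))

  counter <- 0L
  for (f in outlier_fractions) {
    for (r in seq_len(n_repetitions)) {
      counter <- counter + 1L
      cfg <- outlier_config(f, seed = seed + 7919L * counter)
      inj <- inject_outliers(sim$counts, cfg)
      frame_o <- create_variant_frame(inj$counts, sim$map)
      for (mode in names(fits)) {
        fit_o <- fit_variants(frame_o, mode)
        add(f, r, mode, "logfc_pearson_vs_clean", NA_character_,
            stats::cor(fit_o$coef, fits[[mode]]$coef,
                       use = "complete.obs"))
        add(f, r, mode, "adjp_spearman_vs_clean", NA_character_,
            stats::cor(fit_o$adj_p_value, fits[[mode]]$adj_p_value,
                       method = "spearman", use = "complete.obs"))
        sig <- !is.na(fit_o$adj_p_value) & fit_o$adj_p_value < alpha
        sc <- tapply(sig, group, sum)
        for (gname in names(sc)) {
          add(f, r, mode, "n_significant", gname, sc[[gname]])
        }
      }
    }
  }
  list(metrics = do.call(rbind, rows), fits = fits)
}
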