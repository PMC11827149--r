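#' Negative-binomial parameters from mean and variance
#'
#' Method-of-moments parameterization of an overdispersed count distribution:
#' \code{n = mu^2 / (var - mu)}, \code{p = n / (n + mu)}, so that the NB mean
#' \code{n (1 - p) / p} equals \code{mu} exactly and the variance equals
#' \code{var}.
#'
#' @param mu Mean (> 0).
#' @param var Variance (> mu; overdispersion is required).
#' @return List with elements \code{n} (size) and \code{p} (success
#'   probability), vectorized over the inputs.
#' @export
nb_params <- function(mu, var) {
  if (any(mu <= 0)) {
    stop_mprabc("nb_params: mu must be positive",
                class = "mprabc_param_error")
  }
  if (any(var <= mu)) {
    stop_mprabc("nb_params: variance must exceed the mean (overdispersion)",
                class = "mprabc_param_error")
  }
  n <- mu^2 / (var - mu)
  list(n = n, p = n / (n + mu))
}

#' Sample synthetic per-variant count templates
#'
#' Draws plausible (mean, variance, barcode multiplicity) templates for each
#' variant and base replicate, mimicking templates read off one library
#' sequence per variant: variant-level DNA and RNA means log-uniform over
#' \code{mu_range}, scaled per base replicate by a modest lognormal factor
#' (sdlog \code{replicate_sdlog}) emulating replicate-to-replicate depth and
#' efficiency differences; variances \code{phi * mu} with the dispersion
#' factor \code{phi} log-uniform over \code{dispersion_range} (> 1
#' guarantees overdispersion), shared across a variant's replicates; and the
#' number of barcodes per variant uniform on \code{barcode_range} (shared
#' between the two alleles of a variant). Uses the current RNG stream.
#'
#' @param n_variants Number of variants.
#' @param n_base_replicates Number of base replicate templates per variant
#'   (default 3).
#' @param mu_range Range of variant-level DNA/RNA means (default
#'   c(20, 500)).
#' @param dispersion_range Range of the dispersion factor \code{phi = var/mu}
#'   (default c(1.5, 10)).
#' @param barcode_range Range of barcodes per variant (default c(10, 60)).
#' @param replicate_sdlog Log-scale standard deviation of the per-replicate
#'   mean scaling (default 0.25, i.e. typical replicate shifts within about
#'   1.3-fold).
#' @return List with \code{params}, a data.frame with one row per
#'   (variant, base replicate) and columns \code{mu_dna}, \code{var_dna},
#'   \code{mu_rna}, \code{var_rna}; and \code{n_barcodes}, an integer vector
#'   per variant.
#' @export
make_templates <- function(n_variants, n_base_replicates = 3,
                           mu_range = c(20, 500),
                           dispersion_range = c(1.5, 10),
                           barcode_range = c(10, 60),
                           replicate_sdlog = 0.25) {
  if (barcode_range[1] < 10) {
    stop_mprabc("make_templates: barcode_range must start at >= 10",
                class = "mprabc_param_error")
  }
  m <- n_variants * n_base_replicates
  runif_log <- function(n, range) {
    exp(stats::runif(n, log(range[1]), log(range[2])))
  }
  each_rep <- function(x) rep(x, each = n_base_replicates)
  rep_scale <- function() exp(stats::rnorm(m, 0, replicate_sdlog))
  mu_dna <- each_rep(runif_log(n_variants, mu_range)) * rep_scale()
  mu_rna <- each_rep(runif_log(n_variants, mu_range)) * rep_scale()
  phi_dna <- each_rep(runif_log(n_variants, dispersion_range))
  phi_rna <- each_rep(runif_log(n_variants, dispersion_range))
  n_barcodes <- sample(seq.int(barcode_range[1], barcode_range[2]),
                       n_variants, replace = TRUE)
  list(
    params = data.frame(
      variant = rep(seq_len(n_variants), each = n_base_replicates),
      base_replicate = rep(seq_len(n_base_replicates), n_variants),
      mu_dna = mu_dna, var_dna = phi_dna * mu_dna,
      mu_rna = mu_rna, var_rna = phi_rna * mu_rna
    ),
    n_barcodes = n_barcodes
  )
}

#' Simulation specification
#'
#' Describes a synthetic MPRA dataset: variants equally divided into five
#' effect groups with log2 fold changes -2, -0.5, 0, 0.5, 2 (alternative-
#' allele RNA mean multipliers 0.25, 1/sqrt(2), 1, sqrt(2), 4), negative-
#' binomial count templates per variant and base replicate, and each base
#' replicate duplicated into \code{replicate_duplication} independent
#' replicates (default 3 x 2 = 6 replicates).
#'
#' @param n_variants Number of variants, divisible by 5 (default 5000).
#' @param n_base_replicates Base replicate templates (default 3).
#' @param replicate_duplication Independent replicates drawn per base
#'   template (default 2).
#' @param seed Integer seed.
#' @param templates Optional templates as returned by
#'   \code{\link{make_templates}}; generated under \code{seed} when NULL.
#' @param ... Passed to \code{\link{make_templates}}.
#' @return A list of class \code{mpra_sim_spec}.
#' @export
simulation_spec <- function(n_variants = 5000, n_base_replicates = 3,
                            replicate_duplication = 2, seed = 1L,
                            templates = NULL, ...) {
  if (n_variants %% 5 != 0) {
    stop_mprabc("n_variants must be divisible by 5 (equal effect groups)",
                class = "mprabc_param_error")
  }
  if (is.null(templates)) {
    templates <- with_seed(seed, {
      make_templates(n_variants, n_base_replicates, ...)
    })
  }
  stopifnot(nrow(templates$params) == n_variants * n_base_replicates,
            length(templates$n_barcodes) == n_variants)
  with(templates$params, {
    if (any(var_dna <= mu_dna) || any(var_rna <= mu_rna)) {
      stop_mprabc("all templates must be overdispersed (var > mu)",
                  class = "mprabc_param_error")
    }
  })
  if (any(templates$n_barcodes < 10)) {
    stop_mprabc("templates must have >= 10 barcodes per variant",
                class = "mprabc_param_error")
  }
  groups <- c("strong_repressing", "weak_repressing", "neutral",
              "weak_activating", "strong_activating")
  structure(list(
    n_variants = n_variants,
    n_base_replicates = n_base_replicates,
    replicate_duplication = replicate_duplication,
    n_replicates = n_base_replicates * replicate_duplication,
    groups = groups,
    logfc = c(-2, -0.5, 0, 0.5, 2),
    multiplier = 2^c(-2, -0.5, 0, 0.5, 2),
    group_of = rep(groups, each = n_variants / 5),
    templates = templates,
    seed = as.integer(seed)
  ), class = "mpra_sim_spec")
}

#' Simulate a barcode-level MPRA dataset
#'
#' For each variant, replicate and allele, draws barcode counts i.i.d. from
#' a negative binomial with the template's (mean, variance) via
#' \code{\link{nb_params}}. DNA counts of the reference and alternative
#' alleles share the same distribution; alternative-allele RNA counts are
#' drawn with the mean scaled by the variant's effect-group multiplier and
#' the variance scaled to preserve the template's dispersion factor
#' \code{var/mu}. Each base replicate template yields
#' \code{replicate_duplication} independent replicates. Bit-reproducible for
#' a given spec seed.
#'
#' @param spec An \code{\link{simulation_spec}}.
#' @return List of class \code{mpra_sim} with \code{counts}
#'   (\code{\link{mpra_counts}}), \code{map} (\code{\link{variant_map}}) and
#'   \code{truth} (data.frame: variant_id, group, true_logfc).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "mpra_sim_spec"))
  nv <- spec$n_variants
  nb_bc <- spec$templates$n_barcodes
  n_rep <- spec$n_replicates
  dup <- spec$replicate_duplication
  par <- spec$templates$params
  mult <- spec$multiplier[match(spec$group_of, spec$groups)]

  variant_id <- sprintf("var%05d", seq_len(nv))
  # one cell block per (variant, replicate): nb_bc[v] barcodes each
  base_of_rep <- rep(seq_len(spec$n_base_replicates), each = dup)
  # long skeleton over (variant, barcode) once; replicates drawn per column
  v_of_bc <- rep(seq_len(nv), nb_bc)
  n_bc_total <- length(v_of_bc)
  slot_of_bc <- sequence(nb_bc)
  ref_bc <- int_to_dna((seq_len(n_bc_total) - 1L) * 2L)
  alt_bc <- int_to_dna((seq_len(n_bc_total) - 1L) * 2L + 1L)

  draws <- with_seed(spec$seed, {
    lapply(seq_len(n_rep), function(r) {
      pr <- par[par$base_replicate == base_of_rep[r], ]
      stopifnot(nrow(pr) == nv)
      mu_dna <- pr$mu_dna[v_of_bc]; var_dna <- pr$var_dna[v_of_bc]
      mu_rna <- pr$mu_rna[v_of_bc]; var_rna <- pr$var_rna[v_of_bc]
      phi_rna <- var_rna / mu_rna
      mu_alt <- (mult[v_of_bc]) * mu_rna
      var_alt <- phi_rna * mu_alt
      pd <- nb_params(mu_dna, var_dna)
      pr_rna <- nb_params(mu_rna, var_rna)
      pa <- nb_params(mu_alt, var_alt)
      list(
        ref_dna = stats::rnbinom(n_bc_total, size = pd$n, prob = pd$p),
        ref_rna = stats::rnbinom(n_bc_total, size = pr_rna$n, prob = pr_rna$p),
        alt_dna = stats::rnbinom(n_bc_total, size = pd$n, prob = pd$p),
        alt_rna = stats::rnbinom(n_bc_total, size = pa$n, prob = pa$p)
      )
    })
  })

  oligo_ref <- paste0(variant_id, "_ref")
  oligo_alt <- paste0(variant_id, "_alt")
  parts <- lapply(seq_len(n_rep), function(r) {
    d <- draws[[r]]
    data.frame(
      replicate = r,
      barcode = c(ref_bc, alt_bc),
      oligo = c(oligo_ref[v_of_bc], oligo_alt[v_of_bc]),
      dna_count = c(d$ref_dna, d$alt_dna),
      rna_count = c(d$ref_rna, d$alt_rna),
      stringsAsFactors = FALSE
    )
  })
  counts <- mpra_counts(do.call(rbind, parts))
  map <- variant_map(data.frame(variant_id = variant_id,
                                ref_oligo = oligo_ref,
                                alt_oligo = oligo_alt,
                                stringsAsFactors = FALSE))
  truth <- data.frame(
    variant_id = variant_id,
    group = spec$group_of,
    true_logfc = spec$logfc[match(spec$group_of, spec$groups)],
    n_barcodes = nb_bc,
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, map = map, truth = truth, spec = spec),
            class = "mpra_sim")
}

#' Outlier injection configuration
#'
#' @param fraction Fraction of barcodes to perturb (in (0, 1]).
#' @param multiplier RNA count multiplier for perturbed cells (default 25).
#' @param replicate_hit_probs Probability that a perturbed barcode is hit in
#'   k = 1, 2, ... replicates; must sum to 1 (default
#'   c(0.85, 0.05, 0.04, 0.03, 0.02, 0.01) for six replicates).
#' @param seed Integer seed.
#' @return A list of class \code{mpra_outlier_config}.
#' @export
outlier_config <- function(fraction, multiplier = 25,
                           replicate_hit_probs = c(0.85, 0.05, 0.04,
                                                   0.03, 0.02, 0.01),
                           seed = 1L) {
  if (fraction <= 0 || fraction > 1) {
    stop_mprabc("fraction must lie in (0, 1]", class = "mprabc_param_error")
  }
  if (multiplier <= 1) {
    stop_mprabc("multiplier must exceed 1", class = "mprabc_param_error")
  }
  if (abs(sum(replicate_hit_probs) - 1) > 1e-8) {
    stop_mprabc("replicate_hit_probs must sum to 1",
                class = "mprabc_param_error")
  }
  structure(list(fraction = fraction, multiplier = multiplier,
                 replicate_hit_probs = replicate_hit_probs,
                 seed = as.integer(seed)),
            class = "mpra_outlier_config")
}

#' Inject multiplicative RNA outliers
#'
#' Selects a uniformly random fraction of all barcodes; for each selected
#' barcode draws the number of affected replicates k from
#' \code{replicate_hit_probs}, picks k distinct replicates uniformly, and
#' multiplies the RNA count in those replicates by \code{multiplier}
#' (rounded to an integer). Deterministic given the config seed.
#'
#' @param counts An \code{\link{mpra_counts}} table.
#' @param cfg An \code{\link{outlier_config}}.
#' @return List with \code{counts} (perturbed table) and \code{registry}
#'   (data.frame of modified cells: barcode, oligo, replicate, old_rna,
#'   new_rna).
#' @export
inject_outliers <- function(counts, cfg) {
  stopifnot(inherits(cfg, "mpra_outlier_config"))
  reps <- levels(counts$replicate)
  if (length(reps) != length(cfg$replicate_hit_probs)) {
    stop_mprabc("replicate_hit_probs length (%d) must equal the number of replicates (%d)",
                length(cfg$replicate_hit_probs), length(reps),
                class = "mprabc_param_error")
  }
  barcodes <- unique(counts$barcode)
  n_sel <- round(cfg$fraction * length(barcodes))
  empty <- data.frame(barcode = character(0), oligo = character(0),
                      replicate = character(0), old_rna = integer(0),
                      new_rna = integer(0), stringsAsFactors = FALSE)
  if (n_sel == 0) return(list(counts = counts, registry = empty))
  hit <- with_seed(cfg$seed, {
    sel <- sample(barcodes, n_sel)
    k <- sample.int(length(reps), n_sel, replace = TRUE,
                    prob = cfg$replicate_hit_probs)
    hit_rep <- lapply(k, function(ki) sample(reps, ki))
    data.frame(barcode = rep(sel, k),
               replicate = unlist(hit_rep),
               stringsAsFactors = FALSE)
  })
  key <- paste(counts$barcode, as.character(counts$replicate), sep = "\r")
  idx <- match(paste(hit$barcode, hit$replicate, sep = "\r"), key)
  idx <- idx[!is.na(idx)]
  old <- counts$rna_count[idx]
  new <- as.integer(round(cfg$multiplier * old))
  registry <- data.frame(
    barcode = counts$barcode[idx],
    oligo = counts$oligo[idx],
    replicate = as.character(counts$replicate[idx]),
    old_rna = old, new_rna = new,
    stringsAsFactors = FALSE
  )
  counts$rna_count[idx] <- new
  list(counts = counts, registry = registry)
}
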