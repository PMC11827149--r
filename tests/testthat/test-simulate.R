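test_that("NB parameterization matches the method-of-moments formulas", {
  expect_equal(nb_params(10, 20), list(n = 10, p = 0.5))
  expect_equal(nb_params(4, 8), list(n = 4, p = 0.5))
  expect_error(nb_params(10, 10), class = "mprabc_param_error")
  expect_error(nb_params(10, 5), class = "mprabc_param_error")
  # implied NB mean identity n(1-p)/p = mu, exactly, across random templates
  set.seed(1)
  mu <- runif(200, 1, 500)
  v <- mu * runif(200, 1.1, 12)
  par <- nb_params(mu, v)
  expect_equal(par$n * (1 - par$p) / par$p, mu, tolerance = 1e-12)
  expect_true(all(par$p > 0 & par$p < 1))
})

test_that("templates are overdispersed with adequate barcode support", {
  set.seed(2)
  tpl <- make_templates(2000)
  expect_true(all(tpl$params$var_dna > tpl$params$mu_dna))
  expect_true(all(tpl$params$var_rna > tpl$params$mu_rna))
  expect_true(all(tpl$n_barcodes >= 10))
  # multiplicity law: uniform over 10..60 (chi-square goodness of fit)
  set.seed(3)
  tpl2 <- make_templates(10000)
  tab <- table(factor(tpl2$n_barcodes, levels = 10:60))
  expect_gt(chisq.test(tab)$p.value, 0.001)
  expect_error(make_templates(10, barcode_range = c(5, 20)),
               class = "mprabc_param_error")
})

test_that("simulation is reproducible and group sizes are validated", {
  s1 <- simulate_dataset(simulation_spec(n_variants = 50, seed = 5))
  s2 <- simulate_dataset(simulation_spec(n_variants = 50, seed = 5))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(simulation_spec(n_variants = 50, seed = 6))
  expect_false(identical(s1$counts, s3$counts))
  expect_equal(unname(table(s1$truth$group)), rep(10L, 5),
               ignore_attr = TRUE)
  expect_error(simulation_spec(n_variants = 7), class = "mprabc_param_error")
  expect_equal(nlevels(s1$counts$replicate), 6)
})

test_that("effect groups scale alternative-allele RNA means as specified", {
  sim <- small_sim(n_variants = 500, seed = 23)
  counts <- sim$counts
  vid <- sub("_(ref|alt)$", "", counts$oligo)
  is_alt <- grepl("_alt$", counts$oligo)
  ratio_for <- function(group) {
    ids <- sim$truth$variant_id[sim$truth$group == group]
    sel <- vid %in% ids
    expect_gt(sum(sel), 2e4)   # at least 1e4 draws per allele
    mean(counts$rna_count[sel & is_alt]) /
      mean(counts$rna_count[sel & !is_alt])
  }
  expect_equal(ratio_for("neutral"), 1, tolerance = 0.02)
  expect_equal(ratio_for("strong_repressing"), 0.25, tolerance = 0.02 / 0.25)
  expect_equal(ratio_for("strong_activating"), 4, tolerance = 0.02)
  expect_equal(ratio_for("weak_activating"), sqrt(2), tolerance = 0.02)
})

test_that("simulated counts recover their template moments", {
  # one variant with many barcodes: pooled mean/variance per replicate
  tpl <- list(params = data.frame(variant = 1, base_replicate = 1:3,
                                  mu_dna = 100, var_dna = 400,
                                  mu_rna = 50, var_rna = 250),
              n_barcodes = 5000L)
  spec <- simulation_spec(n_variants = 5, seed = 9,
                          templates = list(
                            params = do.call(rbind, lapply(1:5, function(v) {
                              d <- tpl$params; d$variant <- v; d
                            })),
                            n_barcodes = rep(5000L, 5)))
  sim <- simulate_dataset(spec)
  ref <- sim$counts[sim$counts$oligo == "var00001_ref" &
                      sim$counts$replicate == "1", ]
  expect_equal(mean(ref$dna_count), 100, tolerance = 0.02)
  expect_equal(var(ref$dna_count), 400, tolerance = 0.1)
  expect_equal(mean(ref$rna_count), 50, tolerance = 0.02)
  expect_equal(var(ref$rna_count), 250, tolerance = 0.1)
})

test_that("reference and alternative DNA counts are exchangeable", {
  sim <- small_sim(n_variants = 200, seed = 29)
  counts <- sim$counts
  is_alt <- grepl("_alt$", counts$oligo)
  set.seed(1)
  ref_d <- sample(counts$dna_count[!is_alt], 1e4)
  alt_d <- sample(counts$dna_count[is_alt], 1e4)
  ks <- suppressWarnings(stats::ks.test(ref_d, alt_d))
  expect_gt(ks$p.value, 0.01)
})

test_that("outlier injection follows the configured law", {
  sim <- small_sim(n_variants = 100, seed = 37)
  counts <- sim$counts
  n_bc <- length(unique(counts$barcode))

  # fraction picking exactly one barcode
  cfg1 <- outlier_config(fraction = 1.0001 / n_bc, seed = 2)
  out1 <- inject_outliers(counts, cfg1)
  expect_equal(length(unique(out1$registry$barcode)), 1)

  # registry records new = round(25 * old)
  cfg <- outlier_config(fraction = 0.05, seed = 3)
  out <- inject_outliers(counts, cfg)
  expect_equal(out$registry$new_rna,
               as.integer(round(25 * out$registry$old_rna)))
  # modified cells in the table match the registry
  key <- paste(counts$barcode, counts$replicate)
  idx <- match(paste(out$registry$barcode, out$registry$replicate), key)
  expect_equal(out$counts$rna_count[idx], out$registry$new_rna)
  # everything else untouched
  untouched <- setdiff(seq_len(nrow(counts)), idx)
  expect_equal(out$counts$rna_count[untouched],
               counts$rna_count[untouched])
  expect_identical(out$counts$dna_count, counts$dna_count)

  # determinism
  out_b <- inject_outliers(counts, cfg)
  expect_identical(out$counts, out_b$counts)

  # a fraction that rounds to zero barcodes returns the input unchanged
  cfg0 <- outlier_config(fraction = 0.4 / n_bc, seed = 4)
  out0 <- inject_outliers(counts, cfg0)
  expect_identical(out0$counts, counts)
  expect_equal(nrow(out0$registry), 0)
})

test_that("replicate-hit counts follow the configured probabilities", {
  sim <- small_sim(n_variants = 300, seed = 41)
  counts <- sim$counts
  cfg <- outlier_config(fraction = 0.5, seed = 11)
  out <- inject_outliers(counts, cfg)
  k <- table(out$registry$barcode)
  n <- length(k)
  expect_gt(n, 5000)
  probs <- cfg$replicate_hit_probs
  emp <- as.numeric(table(factor(k, levels = 1:6))) / n
  # binomial standard error bound per category (4 sigma)
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(emp - probs) < 4 * se + 1e-3))
})

test_that("invalid outlier configurations are rejected", {
  expect_error(outlier_config(0), class = "mprabc_param_error")
  expect_error(outlier_config(0.5, multiplier = 1),
               class = "mprabc_param_error")
  expect_error(outlier_config(0.5, replicate_hit_probs = c(0.5, 0.4)),
               class = "mprabc_param_error")
  sim <- small_sim(n_variants = 50, seed = 43)
  cfg <- outlier_config(0.1, replicate_hit_probs = c(0.9, 0.1), seed = 1)
  expect_error(inject_outliers(sim$counts, cfg),
               class = "mprabc_param_error")
})
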