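test_that("GLS at rho = 0 with equal weights reduces to OLS exactly", {
  set.seed(14)
  lr <- cs_logratios(50, n_block = 3, k = 8, rho = 0)
  g <- cs_gls_fit(lr$logratio, lr$weight, lr$block, lr$allele, rho = 0)
  # closed-form OLS: coef = difference of group means
  ref_mean <- rowMeans(lr$logratio[, lr$allele == 0])
  alt_mean <- rowMeans(lr$logratio[, lr$allele == 1])
  expect_equal(g$coef, alt_mean - ref_mean, tolerance = 1e-10)
  expect_equal(g$intercept, ref_mean, tolerance = 1e-10)
  m <- ncol(lr$logratio)
  expect_equal(g$df, rep(m - 2, 50))
  expect_equal(g$stdev_unscaled, rep(sqrt(2 / (m / 2)), 50),
               tolerance = 1e-10)
})

test_that("an exact-fit row returns its group values", {
  y <- matrix(rep(c(0, 0, 1, 1), 3), 1)
  w <- matrix(1, 1, 12)
  block <- rep(1:3, each = 4)
  allele <- rep(c(0L, 0L, 1L, 1L), 3)
  g <- cs_gls_fit(y, w, factor(block), allele, rho = 0)
  expect_equal(g$coef, 1)
  expect_equal(g$intercept, 0)
  expect_equal(g$sigma2, 0)
})

test_that("GLS agrees with a dense-matrix oracle on random problems", {
  set.seed(15)
  for (trial in 1:10) {
    n_block <- sample(2:4, 1)
    k <- sample(c(4, 6, 8), 1)
    m <- n_block * k
    block <- rep(seq_len(n_block), each = k)
    allele <- rep(rep(c(0L, 1L), each = k / 2), n_block)
    y <- rnorm(m)
    w <- runif(m, 0.2, 3)
    rho <- runif(1, -0.1, 0.8)
    # knock out a couple of cells
    y_na <- y
    drop_idx <- sample(m, 2)
    y_na[drop_idx] <- NA
    g <- cs_gls_fit(matrix(y_na, 1), matrix(w, 1), factor(block), allele,
                    rho = rho)
    o <- brute_gls(y_na, w, block, allele, rho)
    expect_equal(g$coef, o$beta[2], tolerance = 1e-8)
    expect_equal(g$intercept, o$beta[1], tolerance = 1e-8)
    expect_equal(g$stdev_unscaled, o$su[2], tolerance = 1e-8)
    expect_equal(g$sigma2, o$sigma2, tolerance = 1e-8)
    expect_equal(g$logdet_sigma, o$logdet_sigma, tolerance = 1e-8)
    expect_equal(g$logdet_xvx, o$logdet_xvx, tolerance = 1e-8)
  }
})

test_that("rank-deficient rows are flagged, not imputed", {
  y <- matrix(rnorm(12), 1)
  w <- matrix(1, 1, 12)
  allele <- rep(c(0L, 0L, 1L, 1L), 3)
  y[allele == 1] <- NA   # all alt cells missing
  g <- cs_gls_fit(y, w, factor(rep(1:3, each = 4)), allele, rho = 0)
  expect_true(is.na(g$coef))
  expect_true(is.na(g$df))
})

test_that("per-row REML matches a dense-matrix profile maximizer", {
  set.seed(16)
  for (rho_true in c(0.2, 0.7)) {
    lr <- cs_logratios(1, n_block = 4, k = 10, rho = rho_true)
    est <- estimate_consensus_correlation(lr)
    brute <- optimize(function(r) {
      brute_reml(lr$logratio[1, ], lr$weight[1, ], as.integer(lr$block),
                 lr$allele, r)
    }, c(-0.1, 0.95), maximum = TRUE)$maximum
    expect_lt(abs(est - brute), 0.03)
  }
})

test_that("consensus correlation recovers known values", {
  lr <- cs_logratios(2000, n_block = 4, k = 8, rho = 0, seed = 17)
  expect_lt(abs(estimate_consensus_correlation(lr)), 0.05)

  # all within-block columns duplicated with small jitter -> near 1
  set.seed(18)
  n <- 500; n_block <- 4; k <- 6
  Y <- matrix(0, n, n_block * k)
  block <- factor(rep(seq_len(n_block), each = k))
  for (b in seq_len(n_block)) {
    Y[, as.integer(block) == b] <- rnorm(n) +
      matrix(rnorm(n * k, 0, 0.05), n)
  }
  lr2 <- list(logratio = Y, weight = matrix(1, n, n_block * k),
              block = block,
              allele = rep(rep(c(0L, 1L), each = k / 2), n_block))
  expect_gt(estimate_consensus_correlation(lr2), 0.9)

  # trimmed atanh mean of identical per-row estimates is that value
  lr3 <- cs_logratios(40, n_block = 4, k = 6, rho = 0.5, seed = 19)
  lr3$logratio <- lr3$logratio[rep(1, 40), ]
  est3 <- estimate_consensus_correlation(lr3)
  est1 <- estimate_consensus_correlation(
    lapply(lr3, function(x) if (is.matrix(x)) x[1, , drop = FALSE] else x))
  expect_equal(est3, est1, tolerance = 1e-8)
})

test_that("consensus correlation agrees with the mixed-model oracle", {
  # independent implementation: limma::duplicateCorrelation (REML mixed
  # model via statmod) on the same equal-weight data
  lr <- cs_logratios(400, n_block = 4, k = 8, rho = 0.6, seed = 20)
  est <- estimate_consensus_correlation(lr)
  design <- cbind(1, lr$allele)
  dc <- limma::duplicateCorrelation(lr$logratio, design,
                                    block = lr$block)
  expect_equal(est, dc$consensus.correlation, tolerance = 0.05)
})

test_that("single-observation blocks make the correlation unidentifiable", {
  lr <- list(logratio = matrix(rnorm(40), 10),
             weight = matrix(1, 10, 4),
             block = factor(1:4), allele = c(0L, 1L, 0L, 1L))
  expect_error(estimate_consensus_correlation(lr), "aggregated",
               class = "mprabc_correlation_error")
})

test_that("variance squeezing handles the degenerate equal-variance case", {
  s2 <- rep(0.25, 50)
  sq <- squeeze_variances(s2, rep(10, 50))
  expect_equal(sq$df_prior, Inf)
  expect_equal(sq$s2_prior, 0.25, tolerance = 1e-6)
  expect_equal(sq$s2_post, s2, tolerance = 1e-6)
})

test_that("variance squeezing recovers its own prior", {
  set.seed(21)
  d0 <- 4; s02 <- 0.25; df <- 20; n <- 5000
  sigma2_true <- d0 * s02 / rchisq(n, d0)
  s2 <- sigma2_true * rchisq(n, df) / df
  sq <- squeeze_variances(s2, rep(df, n))
  expect_equal(sq$df_prior, d0, tolerance = 0.3)
  expect_equal(sq$s2_prior, s02, tolerance = 0.1)
  # posterior is a convex combination of observation and prior
  expect_true(all(sq$s2_post >= pmin(s2, sq$s2_prior) - 1e-12))
  expect_true(all(sq$s2_post <= pmax(s2, sq$s2_prior) + 1e-12))
})

test_that("variance squeezing matches the established implementation", {
  set.seed(22)
  s2 <- 0.5 * rchisq(300, 8) / 8 * (2 / rchisq(300, 6) * 3)
  df <- sample(5:30, 300, replace = TRUE)
  sq <- squeeze_variances(s2, df)
  ref <- limma::squeezeVar(s2, df)
  expect_equal(sq$df_prior, ref$df.prior, tolerance = 0.05)
  expect_equal(sq$s2_prior, ref$var.prior, tolerance = 0.05)
  expect_equal(sq$s2_post, ref$var.post, tolerance = 0.01)
})

test_that("moderation is skipped with a warning below 2 usable rows", {
  expect_warning(sq <- squeeze_variances(0.5, 10), "skipped")
  expect_equal(sq$s2_post, 0.5)
  expect_equal(sq$df_prior, 0)
})

test_that("BH adjustment matches its step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  mt <- moderated_test(rep(1, 4), rep(1, 4), rep(1, 4), rep(10, 4))
  # direct check of p.adjust usage through the documented example
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  # brute-force definition: min over the tail of p * m / rank, capped at 1
  set.seed(23)
  for (trial in 1:5) {
    pv <- runif(20)
    m <- length(pv)
    o <- order(pv)
    brute <- numeric(m)
    for (i in seq_len(m)) {
      r <- which(o == i)
      brute[i] <- min(1, min(pv[o][r:m] * m / (r:m)))
    }
    coef <- qnorm(1 - pv / 2)
    mt <- moderated_test(coef, rep(1, m), rep(1, m), rep(Inf, m))
    expect_equal(mt$p_value, pv, tolerance = 1e-10)
    expect_equal(mt$adj_p_value, brute, tolerance = 1e-12)
  }
})

test_that("moderated t uses the t or normal distribution as appropriate", {
  mt_t <- moderated_test(2, 1, 1, 10)
  expect_equal(mt_t$p_value, 2 * pt(-2, 10))
  mt_n <- moderated_test(2, 1, 1, Inf)
  expect_equal(mt_n$p_value, 2 * pnorm(-2))
  expect_equal(mt_t$t, 2)
})

test_that("zero-weight columns have no influence on the fit", {
  set.seed(24)
  y <- matrix(rnorm(24), 2)
  w <- matrix(runif(24, 0.5, 2), 2)
  block <- factor(rep(1:3, each = 4))
  allele <- rep(c(0L, 0L, 1L, 1L), 3)
  g1 <- cs_gls_fit(y, w, block, allele, rho = 0.4)
  # append columns with zero weight / NA
  y2 <- cbind(y, matrix(NA_real_, 2, 4))
  w2 <- cbind(w, matrix(0, 2, 4))
  block2 <- factor(c(as.character(block), rep("1", 4)))
  allele2 <- c(allele, c(0L, 0L, 1L, 1L))
  g2 <- cs_gls_fit(y2, w2, block2, allele2, rho = 0.4)
  expect_equal(g2$coef, g1$coef, tolerance = 1e-12)
  expect_equal(g2$stdev_unscaled, g1$stdev_unscaled, tolerance = 1e-12)
  expect_equal(g2$sigma2, g1$sigma2, tolerance = 1e-12)
})
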