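# Small programmatic fixtures shared across test files.

# A toy count table: `n_oligos` oligos x `n_barcodes` barcodes x `n_reps`
# replicates with Poisson-ish deterministic counts.
toy_counts <- function(n_oligos = 2, n_barcodes = 4, n_reps = 3,
                       base = 50) {
  oligos <- sprintf("oligo%02d", seq_len(n_oligos))
  recs <- expand.grid(replicate = seq_len(n_reps),
                      bc_idx = seq_len(n_barcodes),
                      oligo = oligos, stringsAsFactors = FALSE)
  recs$barcode <- paste0(recs$oligo, "_bc", recs$bc_idx)
  recs$dna_count <- base + recs$bc_idx * 3 + recs$replicate
  recs$rna_count <- base + recs$bc_idx * 5 + 2 * recs$replicate
  mpra_counts(recs[c("replicate", "barcode", "oligo",
                     "dna_count", "rna_count")])
}

# Random NB count table over arbitrary per-oligo barcode multiplicities.
random_counts <- function(n_oligos = 5, barcode_range = c(3, 8),
                          n_reps = 3, mu = 40, size = 5, seed = 1) {
  set.seed(seed)
  oligos <- sprintf("o%03d", seq_len(n_oligos))
  nb <- sample(seq(barcode_range[1], barcode_range[2]), n_oligos,
               replace = TRUE)
  bc <- unlist(lapply(seq_len(n_oligos), function(i) {
    paste0(oligos[i], "_b", seq_len(nb[i]))
  }))
  oligo_of <- rep(oligos, nb)
  recs <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    data.frame(replicate = r, barcode = bc, oligo = oligo_of,
               dna_count = rnbinom(length(bc), mu = mu, size = size),
               rna_count = rnbinom(length(bc), mu = mu, size = size),
               stringsAsFactors = FALSE)
  }))
  mpra_counts(recs)
}

# Synthetic log-ratio frame with known within-block correlation, for the
# GLS and correlation estimators.
cs_logratios <- function(n_row, n_block = 6, k = 8, rho = 0.5,
                         allele = TRUE, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  block <- factor(rep(seq_len(n_block), each = k))
  al <- if (allele) rep(rep(c(0L, 1L), each = k / 2), n_block) else NULL
  Y <- matrix(0, n_row, n_block * k)
  for (b in seq_len(n_block)) {
    shared <- rnorm(n_row, 0, sd * sqrt(rho))
    noise <- matrix(rnorm(n_row * k, 0, sd * sqrt(1 - rho)), n_row)
    Y[, as.integer(block) == b] <- shared + noise
  }
  list(logratio = Y, weight = matrix(1, n_row, n_block * k),
       block = block, allele = al)
}

# Dense-matrix GLS of a single row: the independent oracle for cs_gls_fit.
brute_gls <- function(y, w, block, allele, rho) {
  keep <- !is.na(y) & w > 0
  y <- y[keep]; w <- w[keep]
  block <- block[keep]; allele <- allele[keep]
  m <- length(y)
  Sigma <- matrix(0, m, m)
  for (b in unique(block)) {
    i <- which(block == b)
    Sigma[i, i] <- rho
  }
  diag(Sigma) <- 1
  V <- diag(1 / sqrt(w)) %*% Sigma %*% diag(1 / sqrt(w))
  X <- cbind(1, allele)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  list(beta = unname(drop(beta)), su = unname(sqrt(diag(solve(XtVX)))),
       sigma2 = rss / (m - 2), rss = rss,
       logdet_sigma = as.numeric(determinant(Sigma)$modulus),
       logdet_xvx = as.numeric(determinant(XtVX)$modulus))
}

# Restricted log-likelihood of a single row at correlation rho, dense form.
brute_reml <- function(y, w, block, allele, rho) {
  g <- brute_gls(y, w, block, allele, rho)
  m <- sum(!is.na(y) & w > 0)
  -0.5 * ((m - 2) * log(g$rss / (m - 2)) + g$logdet_sigma + g$logdet_xvx)
}

# Small simulated dataset plus frame and truth, memoized per options.
small_sim <- function(n_variants = 500, seed = 7) {
  spec <- simulation_spec(n_variants = n_variants, seed = seed)
  sim <- simulate_dataset(spec)
  sim$frame <- create_variant_frame(sim$counts, sim$map)
  sim
}
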