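# Core generalized least squares machinery.
#
# Model per row g: y = X beta + e,  Var(e) = sigma_g^2 W^(-1/2) S W^(-1/2)
# with W the diagonal precision weights and S block-diagonal compound
# symmetric: correlation rho between any two cells of the same replicate
# block, independence across blocks. A compound-symmetric block of size k
# has eigenvalues 1 + (k-1) rho (once) and 1 - rho (k-1 times), giving a
# closed-form inverse square root S^(-1/2) = a I + g J with
# a = 1/sqrt(1-rho) and g = (1/sqrt(1+(k-1) rho) - a)/k. Whitening is
# therefore O(cells) and vectorizes across all rows at once; missing cells
# enter with weight zero and whitened rows identical to zero, so they
# contribute nothing to the normal equations.

#' Row-wise compound-symmetry GLS
#'
#' Fits, for every row simultaneously, the weighted generalized least
#' squares problem with the within-block equicorrelated covariance at a
#' fixed correlation \code{rho}. The design is the intercept
#' (\code{allele = NULL}, element mode) or intercept plus ref/alt indicator
#' (variant mode; the tested coefficient is the allele effect, i.e. the
#' logFC).
#'
#' @param Y Row x column observation matrix (NA = missing).
#' @param W Matching non-negative weight matrix (0 = missing).
#' @param block Per-column replicate factor, or NULL for fully independent
#'   columns.
#' @param allele Per-column 0/1 indicator or NULL.
#' @param rho Within-block correlation; must satisfy
#'   \code{rho > -1/(k_max - 1)} and \code{rho < 1}.
#' @return List of per-row vectors: \code{coef} (tested coefficient:
#'   allele effect or intercept), \code{intercept}, \code{stdev_unscaled}
#'   (unscaled standard error of the tested coefficient), \code{sigma2}
#'   (residual variance), \code{df} (residual degrees of freedom),
#'   \code{n_obs}, \code{rss}, and the REML determinant terms
#'   \code{logdet_sigma} and \code{logdet_xvx}. Rows whose non-missing
#'   cells leave the design rank deficient carry NA.
#' @export
cs_gls_fit <- function(Y, W, block = NULL, allele = NULL, rho = 0) {
  M <- !is.na(Y) & !is.na(W) & W > 0
  sw <- matrix(0, nrow(Y), ncol(Y))
  sw[M] <- sqrt(W[M])
  Z <- matrix(0, nrow(Y), ncol(Y))
  Z[M] <- Y[M] * sw[M]
  U1 <- sw
  U2 <- if (!is.null(allele)) sweep(sw, 2, allele, "*") else NULL

  n_row <- nrow(Y)
  logdet_sigma <- numeric(n_row)
  if (!is.null(block) && rho != 0) {
    if (rho >= 1) stop_mprabc("rho must be < 1", class = "mprabc_param_error")
    a <- 1 / sqrt(1 - rho)
    for (cols in split(seq_len(ncol(Y)), block)) {
      K <- rowSums(M[, cols, drop = FALSE])
      lead <- 1 + (K - 1) * rho
      if (any(K > 0 & lead <= 0)) {
        stop_mprabc("rho = %.3f outside the admissible range for block size %d",
                    rho, max(K), class = "mprabc_param_error")
      }
      g <- ifelse(K > 0, (1 / sqrt(pmax(lead, 1e-12)) - a) / pmax(K, 1), 0)
      for (nm in c("Z", "U1", "U2")) {
        A <- get(nm)
        if (is.null(A)) next
        S <- rowSums(A[, cols, drop = FALSE])
        A[, cols] <- (a * A[, cols, drop = FALSE] + g * S) *
          M[, cols, drop = FALSE]
        assign(nm, A)
      }
      logdet_sigma <- logdet_sigma +
        ifelse(K > 0, log(pmax(lead, 1e-12)) + (K - 1) * log(1 - rho), 0)
    }
  }

  n_obs <- rowSums(M)
  a11 <- rowSums(U1^2)
  b1 <- rowSums(U1 * Z)
  yy <- rowSums(Z^2)
  if (is.null(allele)) {
    p <- 1L
    ok <- a11 > 0
    coef <- ifelse(ok, b1 / a11, NA_real_)
    rss <- pmax(yy - coef^2 * a11, 0)
    stdev_unscaled <- ifelse(ok, 1 / sqrt(a11), NA_real_)
    intercept <- coef
    logdet_xvx <- ifelse(ok, log(a11), NA_real_)
  } else {
    p <- 2L
    a12 <- rowSums(U1 * U2)
    a22 <- rowSums(U2^2)
    b2 <- rowSums(U2 * Z)
    det <- a11 * a22 - a12^2
    ok <- det > 1e-10 * pmax(a11 * a22, 1e-300)
    beta2 <- ifelse(ok, (a11 * b2 - a12 * b1) / det, NA_real_)
    beta1 <- ifelse(ok, (a22 * b1 - a12 * b2) / det, NA_real_)
    rss <- pmax(yy - beta1 * b1 - beta2 * b2, 0)
    coef <- beta2
    intercept <- beta1
    stdev_unscaled <- ifelse(ok, sqrt(a11 / det), NA_real_)
    logdet_xvx <- ifelse(ok, log(det), NA_real_)
  }
  df <- ifelse(ok, n_obs - p, NA_real_)
  sigma2 <- ifelse(!is.na(df) & df > 0, rss / df, NA_real_)
  list(coef = coef, intercept = intercept, stdev_unscaled = stdev_unscaled,
       sigma2 = sigma2, df = df, n_obs = n_obs, rss = ifelse(ok, rss, NA_real_),
       logdet_sigma = logdet_sigma, logdet_xvx = logdet_xvx)
}

# Per-row restricted log-likelihood, profiled over beta and sigma^2, up to
# rho-independent constants.
reml_profile <- function(fit) {
  with(fit, {
    l <- -0.5 * (df * log(rss / df) + logdet_sigma + logdet_xvx)
    l[!is.finite(l) | is.na(df) | df <= 0 | rss <= 0] <- NA_real_
    l
  })
}

#' Consensus within-replicate correlation
#'
#' Estimates, for every row, the intra-block correlation of the weighted
#' residuals under the compound-symmetric model by restricted maximum
#' likelihood (grid profile with parabolic refinement), then combines the
#' per-row estimates robustly: atanh transform, 15 percent trimmed mean,
#' tanh back.
#'
#' @param lr An \code{\link{logratio_frame}} object (or any list with
#'   \code{logratio}, \code{weight}, \code{block}, \code{allele}).
#' @param trim Trimming fraction of the mean on the atanh scale
#'   (default 0.15).
#' @param grid_length Number of grid points for the profile (default 25).
#' @return The consensus correlation (scalar).
#' @export
estimate_consensus_correlation <- function(lr, trim = 0.15,
                                           grid_length = 25) {
  M <- !is.na(lr$logratio) & lr$weight > 0
  k_max <- 0
  for (cols in split(seq_len(ncol(M)), lr$block)) {
    k_max <- max(k_max, rowSums(M[, cols, drop = FALSE]))
  }
  if (k_max <= 1) {
    stop_mprabc(paste0(
      "within-replicate correlation is unidentifiable: every replicate ",
      "block holds a single observation per row; fit the aggregated model ",
      "instead"), class = "mprabc_correlation_error")
  }
  lo <- max(-1 / (k_max - 1) + 0.01, -0.3)
  grid <- seq(lo, 0.95, length.out = grid_length)
  ll <- matrix(NA_real_, nrow(lr$logratio), grid_length)
  for (i in seq_along(grid)) {
    fit <- cs_gls_fit(lr$logratio, lr$weight, lr$block, lr$allele,
                      rho = grid[i])
    ll[, i] <- reml_profile(fit)
  }
  usable <- rowSums(is.na(ll)) == 0
  if (!any(usable)) {
    warning("no rows with residual variation; consensus correlation set to 0")
    return(0)
  }
  ll <- ll[usable, , drop = FALSE]
  best <- max.col(ll, ties.method = "first")
  rho_hat <- grid[best]
  # parabolic refinement at interior maxima
  h <- grid[2] - grid[1]
  interior <- best > 1 & best < grid_length
  if (any(interior)) {
    i <- best[interior]
    idx <- cbind(seq_len(nrow(ll))[interior], i)
    l0 <- ll[cbind(idx[, 1], i - 1L)]
    l1 <- ll[idx]
    l2 <- ll[cbind(idx[, 1], i + 1L)]
    denom <- l0 - 2 * l1 + l2
    shift <- ifelse(abs(denom) > 1e-12, 0.5 * h * (l0 - l2) / denom, 0)
    rho_hat[interior] <- grid[i] + pmin(pmax(shift, -h), h)
  }
  rho_hat <- pmin(pmax(rho_hat, -0.999), 0.999)
  tanh(mean(atanh(rho_hat), trim = trim))
}

# Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Empirical Bayes variance moderation
#'
#' Models the per-row residual variances as scaled chi-square observations
#' of row variances drawn from a scaled inverse chi-square prior with
#' \code{df_prior} degrees of freedom and location \code{s2_prior}. The
#' hyperparameters are estimated by moment matching on
#' \code{e_g = log(s_g^2) - digamma(df_g/2) + log(df_g/2)}: the excess of
#' \code{var(e_g)} over the chi-square contribution
#' \code{mean(trigamma(df_g/2))} determines \code{df_prior} via the inverse
#' trigamma; no excess means the observed spread is pure chi-square noise
#' and \code{df_prior = Inf}. The posterior (moderated) variance is the
#' precision-weighted convex combination
#' \code{(df_prior * s2_prior + df_g * s_g^2) / (df_prior + df_g)}.
#'
#' @param sigma2 Per-row residual variances.
#' @param df Per-row residual degrees of freedom.
#' @return List with \code{df_prior}, \code{s2_prior} (scalars) and
#'   \code{s2_post} (per row; NA rows keep NA).
#' @export
squeeze_variances <- function(sigma2, df) {
  ok <- !is.na(sigma2) & !is.na(df) & df > 0 & sigma2 > 0
  if (sum(ok) < 2) {
    warning("fewer than 2 usable rows; variance moderation skipped")
    return(list(df_prior = 0, s2_prior = NA_real_, s2_post = sigma2))
  }
  e <- log(sigma2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  e_mean <- mean(e)
  excess <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(excess) && excess > 0) {
    df_prior <- 2 * trigamma_inverse(excess)
    s2_prior <- exp(e_mean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # observed spread is pure chi-square noise: infinite prior df, and the
    # common variance is estimated directly by the mean
    df_prior <- Inf
    s2_prior <- mean(sigma2[ok])
  }
  s2_post <- rep(NA_real_, length(sigma2))
  use <- !is.na(sigma2) & !is.na(df)
  if (is.infinite(df_prior)) {
    s2_post[use] <- s2_prior
  } else {
    s2_post[use] <- (df_prior * s2_prior + df[use] * sigma2[use]) /
      (df_prior + df[use])
  }
  list(df_prior = df_prior, s2_prior = s2_prior, s2_post = s2_post)
}

#' Moderated t-test with BH adjustment
#'
#' @param coef Tested coefficients.
#' @param stdev_unscaled Unscaled standard errors.
#' @param s2_post Moderated variances.
#' @param df_total Total degrees of freedom (residual + prior); infinite
#'   values use the normal distribution.
#' @return List with \code{t}, \code{p_value}, \code{adj_p_value}.
#' @export
moderated_test <- function(coef, stdev_unscaled, s2_post, df_total) {
  se <- sqrt(s2_post) * stdev_unscaled
  t <- coef / se
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t)),
              2 * stats::pt(-abs(t), df = df_total))
  adj <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  list(t = t, p_value = p, adj_p_value = adj)
}
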