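#' Fit variant effects (allelic log fold changes)
#'
#' The full barcode-level chain: per-replicate library normalization and
#' log2 RNA/DNA ratios, mean-variance trend precision weights, consensus
#' within-replicate correlation, per-row compound-symmetry GLS with design
#' (intercept, allele), empirical Bayes variance moderation, moderated
#' two-sided t-tests and Benjamini-Hochberg adjustment. The tested
#' coefficient is the log2 fold change of the alternative versus the
#' reference allele.
#'
#' \code{mode = "aggregate"} reproduces the classical analysis: barcode
#' counts are first summed per (replicate, allele) column and the identical
#' chain runs on the collapsed frame, with the ref/alt pair of each
#' replicate forming the correlation block.
#'
#' @param frame A variant-mode \code{\link{mpra_frame}}.
#' @param mode \code{"barcode"} (default) or \code{"aggregate"}.
#' @param pseudocount,target_library Normalization constants (see
#'   \code{\link{normalize_and_logratio}}).
#' @param span LOWESS span of the mean-variance trend (default 0.5).
#' @param trim Trimming fraction for the consensus correlation
#'   (default 0.15).
#' @param interp Weight interpolation basis (see \code{\link{voom_weights}}).
#' @return An object of class \code{mpra_fit}; see
#'   \code{\link{mpra_fit-methods}}.
#' @export
fit_variants <- function(frame, mode = c("barcode", "aggregate"),
                         pseudocount = 1, target_library = 1e6,
                         span = 0.5, trim = 0.15,
                         interp = c("fitted", "cell")) {
  mode <- match.arg(mode)
  stopifnot(inherits(frame, "mpra_frame"))
  if (frame$mode != "variant") {
    stop_mprabc("fit_variants requires a variant-mode frame (see create_variant_frame)")
  }
  if (mode == "aggregate") frame <- aggregate_frame(frame)
  fit_chain(frame, mode, pseudocount, target_library, span, trim, interp)
}

#' Fit element activities
#'
#' Intercept-only fit per oligo: the coefficient is the fitted log2
#' activity (normalized log2 RNA/DNA ratio) of the sequence, tested against
#' zero with moderated t-statistics. In \code{mode = "aggregate"} counts are
#' summed per replicate first; each replicate then holds a single
#' observation, so no within-replicate correlation is estimated.
#'
#' @inheritParams fit_variants
#' @param frame An element-mode \code{\link{mpra_frame}}.
#' @return An object of class \code{mpra_fit}.
#' @export
fit_elements <- function(frame, mode = c("barcode", "aggregate"),
                         pseudocount = 1, target_library = 1e6,
                         span = 0.5, trim = 0.15,
                         interp = c("fitted", "cell")) {
  mode <- match.arg(mode)
  stopifnot(inherits(frame, "mpra_frame"))
  if (frame$mode != "element") {
    stop_mprabc("fit_elements requires an element-mode frame (see create_element_frame)")
  }
  if (mode == "aggregate") frame <- aggregate_frame(frame)
  fit_chain(frame, mode, pseudocount, target_library, span, trim, interp)
}

# Shared fitting chain for both designs and both input modes.
fit_chain <- function(frame, input_mode, pseudocount, target_library,
                      span, trim, interp = "fitted") {
  lr <- logratio_frame(frame, pseudocount, target_library, span, interp)
  M <- !is.na(lr$logratio) & lr$weight > 0

  single_obs_blocks <- TRUE
  for (cols in split(seq_len(ncol(M)), lr$block)) {
    if (max(rowSums(M[, cols, drop = FALSE])) > 1) {
      single_obs_blocks <- FALSE
      break
    }
  }
  rho <- if (single_obs_blocks) 0 else
    estimate_consensus_correlation(lr, trim = trim)

  g <- cs_gls_fit(lr$logratio, lr$weight, lr$block, lr$allele, rho = rho)
  dropped <- is.na(g$coef)
  if (any(dropped)) {
    message(sprintf(
      "fit: %d row(s) dropped (design rank deficient on the available cells)",
      sum(dropped)))
  }
  sq <- squeeze_variances(g$sigma2, g$df)
  df_total <- g$df + sq$df_prior
  mt <- moderated_test(g$coef, g$stdev_unscaled, sq$s2_post, df_total)

  # distinct barcode slots with any data (column position within replicate
  # is the slot index, identical across replicates)
  pos <- stats::ave(seq_along(lr$block), lr$block, FUN = seq_along)
  per_rep <- max(pos)
  slot_ind <- matrix(0, ncol(M), per_rep)
  slot_ind[cbind(seq_len(ncol(M)), pos)] <- 1
  n_slots <- rowSums((M %*% slot_ind) > 0)

  structure(list(
    row_ids = lr$row_ids,
    coef = g$coef,
    intercept = g$intercept,
    stdev_unscaled = g$stdev_unscaled,
    sigma = sqrt(g$sigma2),
    df_residual = g$df,
    df_prior = sq$df_prior,
    s2_prior = sq$s2_prior,
    s2_post = sq$s2_post,
    t = mt$t,
    p_value = mt$p_value,
    adj_p_value = mt$adj_p_value,
    consensus_rho = rho,
    n_obs = g$n_obs,
    n_barcodes = n_slots,
    design = frame$mode,
    input_mode = input_mode,
    labels = frame$labels
  ), class = "mpra_fit")
}

#' Methods for fitted MPRA models
#'
#' \code{coef} returns the named vector of tested coefficients (logFC in
#' variant design, log2 activity in element design). \code{as.data.frame}
#' returns the per-row results table written by \code{\link{write_results}}.
#' \code{summary} reports significance counts at the given threshold.
#' \code{plot} draws a volcano plot (variant design) or an activity/
#' significance plot (element design).
#'
#' @param object,x An \code{mpra_fit} object.
#' @param ... Unused.
#' @name mpra_fit-methods
NULL

#' @rdname mpra_fit-methods
#' @export
coef.mpra_fit <- function(object, ...) {
  stats::setNames(object$coef, object$row_ids)
}

#' @rdname mpra_fit-methods
#' @param row.names,optional Ignored (data.frame method signature).
#' @export
as.data.frame.mpra_fit <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  tab <- data.frame(
    id = x$row_ids,
    coef = x$coef,
    t = x$t,
    p_value = x$p_value,
    adj_p_value = x$adj_p_value,
    n_barcodes = x$n_barcodes,
    stringsAsFactors = FALSE
  )
  names(tab)[2] <- if (x$design == "variant") "logFC" else "activity"
  tab
}

#' @rdname mpra_fit-methods
#' @export
print.mpra_fit <- function(x, ...) {
  cat(sprintf("MPRA %s fit (%s counts): %d rows\n",
              x$design, x$input_mode, length(x$row_ids)))
  cat(sprintf("  consensus within-replicate correlation: %.3f\n",
              x$consensus_rho))
  cat(sprintf("  prior df: %s, prior variance: %.4g\n",
              format(x$df_prior, digits = 4), x$s2_prior))
  cat(sprintf("  significant at BH 0.05: %d\n",
              sum(x$adj_p_value < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' @rdname mpra_fit-methods
#' @param alpha Significance threshold on the BH-adjusted p-value
#'   (default 0.05).
#' @export
summary.mpra_fit <- function(object, alpha = 0.05, ...) {
  tab <- as.data.frame(object)
  sig <- !is.na(tab$adj_p_value) & tab$adj_p_value < alpha
  out <- list(
    design = object$design,
    input_mode = object$input_mode,
    n = nrow(tab),
    n_tested = sum(!is.na(tab$p_value)),
    n_significant = sum(sig),
    alpha = alpha,
    consensus_rho = object$consensus_rho,
    df_prior = object$df_prior,
    top = utils::head(tab[order(tab$adj_p_value), ], 10)
  )
  class(out) <- "summary.mpra_fit"
  out
}

#' @export
print.summary.mpra_fit <- function(x, ...) {
  cat(sprintf("MPRA %s fit (%s counts)\n", x$design, x$input_mode))
  cat(sprintf("  %d rows (%d tested), %d significant at BH %.3g\n",
              x$n, x$n_tested, x$n_significant, x$alpha))
  cat(sprintf("  consensus correlation %.3f, prior df %s\n",
              x$consensus_rho, format(x$df_prior, digits = 4)))
  cat("Top rows by adjusted p-value:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @rdname mpra_fit-methods
#' @param sig_col,nonsig_col Point colours for significant and other rows.
#' @export
plot.mpra_fit <- function(x, alpha = 0.05, sig_col = "firebrick",
                          nonsig_col = "grey60", ...) {
  tab <- as.data.frame(x)
  eff <- tab[[2]]
  logp <- -log10(pmax(tab$adj_p_value, 1e-300))
  sig <- !is.na(tab$adj_p_value) & tab$adj_p_value < alpha
  graphics::plot(eff, logp,
                 col = ifelse(sig, sig_col, nonsig_col), pch = 16,
                 cex = 0.4,
                 xlab = if (x$design == "variant") {
                   expression(log[2] ~ "fold change (alt vs ref)")
                 } else {
                   expression(log[2] ~ "activity")
                 },
                 ylab = expression(-log[10] ~ "BH-adjusted p"), ...)
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(data.frame(effect = eff, neg_log10_adj_p = logp,
                       significant = sig))
}
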