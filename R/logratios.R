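#' Normalized log2 RNA/DNA ratios
#'
#' Library sizes are computed per replicate block: for column j, the DNA
#' (resp. RNA) library size is the total DNA (RNA) count over all columns in
#' j's replicate and all rows. Counts are offset by a pseudocount, scaled to
#' a common target library size (counts-per-million convention), and the
#' activity readout is
#' \code{log2(rna_cpm) - log2(dna_cpm)} per cell. The DNA abundance
#' \code{log2(dna_cpm)} is returned alongside as the covariate of the
#' mean-variance trend.
#'
#' @param frame An \code{\link{mpra_frame}}.
#' @param pseudocount Added to every count before scaling (default 1).
#' @param target_library Common library scale (default 1e6).
#' @return List with matrices \code{logratio} and \code{log_dna} (NA at
#'   missing slots) and per-block library size vectors \code{lib_dna},
#'   \code{lib_rna}.
#' @export
normalize_and_logratio <- function(frame, pseudocount = 1,
                                   target_library = 1e6) {
  block <- frame$block
  blocks <- levels(block)
  lib_dna <- vapply(blocks, function(b) {
    sum(frame$dna[, block == b, drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  lib_rna <- vapply(blocks, function(b) {
    sum(frame$rna[, block == b, drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  if (any(lib_dna == 0) || any(lib_rna == 0)) {
    bad <- blocks[lib_dna == 0 | lib_rna == 0]
    stop_mprabc("replicate block(s) with zero total counts: %s",
                paste(bad, collapse = ", "),
                class = "mprabc_normalization_error")
  }
  ld <- lib_dna[as.character(block)]
  lr <- lib_rna[as.character(block)]
  log_dna <- log2(sweep(frame$dna + pseudocount, 2, ld, "/") * target_library)
  log_rna <- log2(sweep(frame$rna + pseudocount, 2, lr, "/") * target_library)
  list(logratio = log_rna - log_dna, log_dna = log_dna,
       lib_dna = lib_dna, lib_rna = lib_rna)
}

#' Mean-variance trend precision weights
#'
#' The variance of a barcode's log-ratio depends on its DNA abundance: low
#' plasmid input makes the RNA/DNA ratio noisy. The trend is estimated as in
#' voom, adapted to DNA abundance: (1) row-wise ordinary least squares of the
#' log-ratios on the design; (2) per-row residual standard deviation
#' \code{s_g} and mean DNA log-abundance \code{d_g}; (3) a LOWESS fit of
#' \code{sqrt(s_g)} on \code{d_g}; (4) the curve is interpolated (clamped to
#' the fitted range) at a per-cell abundance and the precision weight is the
#' interpolated value to the power -4, i.e. the reciprocal of the predicted
#' residual variance.
#'
#' The interpolation abundance is controlled by \code{interp}. The default
#' \code{"fitted"} uses the design-fitted DNA abundance of each cell (the
#' mean abundance of the cell's row and allele group), the analogue of
#' interpolating at fitted values in voom: because a cell's observed DNA
#' count also enters its own log-ratio, interpolating at the observed
#' (\code{"cell"}) abundance correlates weights with errors and makes the
#' moderated tests conservative, which is why it is not the default.
#' \code{"cell"} remains available for data where per-barcode abundance
#' differences are persistent rather than stochastic.
#'
#' @param logratio Row x column log-ratio matrix (NA at missing cells).
#' @param log_dna Matching DNA log-abundance matrix.
#' @param allele Per-column 0/1 allele indicator, or NULL for an
#'   intercept-only design.
#' @param span LOWESS span (default 0.5).
#' @param interp Abundance at which the trend is evaluated per cell:
#'   \code{"fitted"} (default) or \code{"cell"}.
#' @return Weight matrix: strictly positive at data cells, exactly zero at
#'   missing cells.
#' @export
voom_weights <- function(logratio, log_dna, allele = NULL, span = 0.5,
                         interp = c("fitted", "cell")) {
  interp <- match.arg(interp)
  ones <- matrix(1, nrow(logratio), ncol(logratio))
  ones[is.na(logratio)] <- 0
  ols <- cs_gls_fit(logratio, ones, block = NULL, allele = allele, rho = 0)
  ok <- !is.na(ols$df) & ols$df > 0 & !is.na(ols$sigma2)
  if (!any(ok)) {
    stop_mprabc("no rows with residual degrees of freedom; cannot estimate the mean-variance trend",
                class = "mprabc_weight_error")
  }
  s_root <- sqrt(sqrt(ols$sigma2[ok]))         # sigma^(1/2)
  d_g <- rowMeans(log_dna, na.rm = TRUE)[ok]
  trend <- stats::lowess(d_g, s_root, f = span)

  xout <- log_dna
  if (interp == "fitted") {
    if (is.null(allele)) {
      xout[] <- rowMeans(log_dna, na.rm = TRUE)
    } else {
      for (a in unique(allele)) {
        cols <- allele == a
        xout[, cols] <- rowMeans(log_dna[, cols, drop = FALSE], na.rm = TRUE)
      }
    }
    xout[is.na(log_dna)] <- NA
  }
  if (length(unique(trend$x)) < 2) {
    vals <- rep(mean(trend$y), length(xout))
  } else {
    vals <- stats::approx(trend$x, trend$y, xout = as.vector(xout),
                          rule = 2, ties = mean)$y
  }
  vals <- pmax(vals, 1e-4)
  w <- matrix(vals^(-4), nrow(logratio), ncol(logratio))
  w[is.na(logratio)] <- 0
  dimnames(w) <- dimnames(logratio)
  w
}

#' Weighted log-ratio frame
#'
#' Applies \code{\link{normalize_and_logratio}} and
#' \code{\link{voom_weights}} to a count frame, yielding the observations
#' the linear model consumes.
#'
#' @inheritParams normalize_and_logratio
#' @param span LOWESS span for the mean-variance trend (default 0.5).
#' @param interp Weight interpolation basis (see \code{\link{voom_weights}}).
#' @return A list of class \code{mpra_logratios}: \code{row_ids},
#'   \code{logratio}, \code{weight}, \code{log_dna}, \code{block},
#'   \code{allele}, \code{mode}, \code{labels}.
#' @export
logratio_frame <- function(frame, pseudocount = 1, target_library = 1e6,
                           span = 0.5, interp = c("fitted", "cell")) {
  nl <- normalize_and_logratio(frame, pseudocount, target_library)
  w <- voom_weights(nl$logratio, nl$log_dna, allele = frame$allele,
                    span = span, interp = interp)
  structure(list(
    row_ids = frame$row_ids, logratio = nl$logratio, weight = w,
    log_dna = nl$log_dna, block = frame$block, allele = frame$allele,
    mode = frame$mode, labels = frame$labels
  ), class = "mpra_logratios")
}
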